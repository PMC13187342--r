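# Acoustic and thermal material properties per phantom label.
#
# These are LITERATURE SUBSTITUTE values assembled from standard tissue
# property compilations (absorption quoted in Np/m at the 500 kHz
# fundamental), not a reproduction of any study-specific table. Edit freely;
# pass the edited file to material_table().
#
# Fields: sound_speed [m/s], density [kg/m^3], absorption [Np/m at f0],
# thermal_conductivity [W/(m.K)], specific_heat [J/(kg.K)],
# perfusion_rate [1/s].
exterior_water:
  sound_speed: 1482
  density: 1000
  absorption: 0.0
  thermal_conductivity: 0.60
  specific_heat: 4180
  perfusion_rate: 0.0
bone:
  sound_speed: 2800
  density: 1900
  absorption: 100.0
  thermal_conductivity: 0.32
  specific_heat: 1300
  perfusion_rate: 0.0005
soft_tissue_csf:
  sound_speed: 1540
  density: 1040
  absorption: 3.5
  thermal_conductivity: 0.50
  specific_heat: 3600
  perfusion_rate: 0.002
brain:
  sound_speed: 1540
  density: 1040
  absorption: 3.45
  thermal_conductivity: 0.52
  specific_heat: 3630
  perfusion_rate: 0.009
electrode:
  sound_speed: 3300
  density: 21500
  absorption: 20.0
  thermal_conductivity: 31.0
  specific_heat: 130
  perfusion_rate: 0.0
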