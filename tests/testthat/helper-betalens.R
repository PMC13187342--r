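# Shared fixtures for the suite. The full planning chain on a seeded
# phantom is expensive (~5 s), so runs are memoised per seed within the
# test session.

.chain_cache <- new.env(parent = emptyenv())

#' Backward sim -> placement -> lens -> forward verification on one phantom
lens_chain <- function(seed, with_lens = TRUE, config = solver_config()) {
  key <- paste0(seed, "/", with_lens)
  if (!is.null(.chain_cache[[key]])) return(.chain_cache[[key]])
  vol <- generate_head_phantom(phantom_spec(seed = seed))
  med <- acoustic_medium(vol)
  rec <- receiver_line_for(vol)
  bw <- point_source_backward(med, vol$targets$gpi, rec, config = config,
                              volume = vol)
  pose <- place_transducer(bw)
  lens <- if (with_lens) design_lens(bw, pose) else NULL
  masks <- list(brain = label_mask(vol, "brain"),
                electrode = label_mask(vol, "electrode"))
  fv <- forward_verify(med, pose, lens, pulse_protocol(), masks,
                       vol$targets$gpi, config = config)
  out <- list(vol = vol, med = med, bw = bw, pose = pose, lens = lens,
              masks = masks, field = fv$field, metrics = fv$metrics)
  .chain_cache[[key]] <- out
  out
}

#' Homogeneous water medium sized like the default phantom grid
water_medium <- function(n = 181, spacing = 0.5) {
  homogeneous_medium(c(n, n), spacing = spacing)
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(max(abs(actual - expected) / abs(expected)), tol)
}

world_to_index_test <- function(pos, spacing = 0.5) {
  round(pos / spacing) + 1L
}

mk_scaled_field <- function(p, spacing = 0.5) {
  structure(list(p = p, spacing = spacing, origin = c(0, 0),
                 frequency = 5e5, pml_width = 0L, drive_scale = 1),
            class = "complex_field")
}

with_seed_test <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

#' Unit-RMS narrowband noise for constructed-coherence inputs
narrowband_test_signal <- function(n, fs, centre, bandwidth) {
  X <- fft(rnorm(n))
  f <- c(0, seq_len(n - 1)) * fs / n
  f <- pmin(f, fs - f)
  g <- exp(-(f - centre)^2 / (2 * (bandwidth / 2.355)^2))
  y <- Re(fft(X * g, inverse = TRUE)) / n
  y / sd(y)
}
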