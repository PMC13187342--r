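#' Generate random-dot-motion behaviour for a two-day cross-over
#'
#' Per participant-day: two RDM blocks (sham then active) of 120 trials
#' each, 240 trials per day. Inter-stimulus intervals are uniform in
#' [1.25, 1.75] s, dot coherence is drawn from {8%, 50%}, and reaction
#' times are a 0.1 s floor plus a log-normal component, clamped to the
#' recorded [0.1, 2] s window.
#'
#' The planted condition effect is parameterised as the *normalised-median
#' reduction* `r` the downstream contrast measures: RTs are min/max
#' normalised over the day's 240 trials before block medians are compared,
#' so the generator solves for the multiplicative factor `a` on the
#' log-normal component that yields an expected normalised-median
#' reduction of `r` (fixed point over the expected day minimum).
#'
#' @param spec a [participant_spec()] (uses its `rt` settings and `seed`)
#' @param seed optional override of the behaviour seed
#' @param trials_per_block trials per RDM block (two blocks per day)
#' @return object of class `behaviour_data`: `trials` data.frame (day,
#'   condition, trial, onset, dot_coherence, direction, response, rt) and
#'   `ground_truth` (planted reduction per day and the solved factors)
#' @export
generate_behaviour <- function(spec, seed = NULL,
                               trials_per_block = 120L) {
  rt <- spec$rt
  floor_s <- 0.1
  mu <- log(rt$median - floor_s)
  days <- c("GPi_day", "Ventricle_day")
  reductions <- c(GPi_day = rt$gpi_reduction,
                  Ventricle_day = rt$ventricle_reduction)
  n_day <- 2L * trials_per_block

  solve_factor <- function(r) {
    if (r == 0) return(1)
    a <- 1 - r
    for (it in 1:6) {
      # expected day minimum: quantile 1/(n+1) of the sham/active mixture
      qmix <- function(p) {
        lo <- 0; hi <- exp(mu + 4 * rt$sdlog)
        for (k in 1:60) {
          mid <- (lo + hi) / 2
          fm <- 0.5 * stats::plnorm(mid, mu, rt$sdlog) +
            0.5 * stats::plnorm(mid / a, mu, rt$sdlog)
          if (fm < p) lo <- mid else hi <- mid
        }
        mid
      }
      xmin <- qmix(1 / (n_day + 1))
      med <- exp(mu)
      a_new <- 1 - r * (med + floor_s - (floor_s + xmin)) / med
      if (a_new <= 0)
        abort_invalid("requested reaction-time reduction is not attainable")
      if (abs(a_new - a) < 1e-10) { a <- a_new; break }
      a <- a_new
    }
    a
  }

  rows <- list()
  factors <- numeric(0)
  sd_base <- if (is.null(seed)) derive_seed(spec$seed, "behaviour")
             else as.integer(seed)
  for (d in days) {
    a <- solve_factor(reductions[[d]])
    factors[d] <- a
    rows[[d]] <- with_seed(derive_seed(sd_base, paste0("rdm/", d)), {
      out <- list()
      for (cond in c("sham", "active")) {
        isi <- runif(trials_per_block, 1.25, 1.75)
        x <- rlnorm(trials_per_block, mu, rt$sdlog)
        if (cond == "active") x <- x * a
        rtv <- pmin(pmax(floor_s + x, floor_s), 2)
        direction <- sample(c("left", "right"), trials_per_block, TRUE)
        out[[cond]] <- data.frame(
          day = d, condition = cond, trial = seq_len(trials_per_block),
          onset = cumsum(isi),
          dot_coherence = sample(c(0.08, 0.5), trials_per_block, TRUE),
          direction = direction,
          response = direction,   # accuracy is not analysed here
          rt = rtv)
      }
      do.call(rbind, out)
    })
  }
  structure(list(trials = do.call(rbind, rows),
                 ground_truth = list(planted_reduction = reductions,
                                     factors = factors,
                                     median = rt$median, sdlog = rt$sdlog)),
            class = "behaviour_data")
}

#' Write / read a behavioural trial table as CSV
#' @param behaviour a [generate_behaviour()] output
#' @param path CSV file path
#' @export
write_behaviour <- function(behaviour, path) {
  write.csv(behaviour$trials, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_behaviour
#' @export
read_behaviour <- function(path) {
  tr <- read.csv(path, stringsAsFactors = FALSE)
  req <- c("day", "condition", "trial", "onset", "dot_coherence",
           "direction", "response", "rt")
  miss <- setdiff(req, names(tr))
  if (length(miss))
    abort_invalid(paste0("behaviour table missing column(s): ",
                         paste(miss, collapse = ", ")))
  structure(list(trials = tr, ground_truth = NULL),
            class = "behaviour_data")
}
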