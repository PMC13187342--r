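#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Stop with a classed validation error
#' @noRd
abort_invalid <- function(msg, class = "betalens_validation_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' Derive a child seed from a master seed and a fixed component label
#'
#' Generators take one master seed; each component draws from its own child
#' stream derived from a fixed label, so adding a new generator never
#' perturbs the draws of existing ones. The derivation is a small string
#' hash folded into the 31-bit signed-integer range R requires.
#'
#' @param master integer master seed
#' @param label character component label
#' @return integer seed in `[0, 2^31 - 2]`
#' @export
derive_seed <- function(master, label) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(label))
  h <- 0
  for (code in utf8ToInt(paste(label, collapse = "/")))
    h <- (h * 31 + code) %% 2147480009
  as.integer((abs(master) + h) %% 2147483646)
}

#' Evaluate an expression under a temporary RNG state
#' @noRd
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Wrap phase into (-pi, pi]
#' @noRd
wrap_phase <- function(phi) {
  out <- (phi + pi) %% (2 * pi) - pi
  out[out == -pi] <- pi
  out
}
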