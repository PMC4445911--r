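#' @importFrom rlang %||% .data abort warn inform :=
#' @importFrom stats quantile median optimize pt pf setNames complete.cases
#'   model.matrix reformulate rnorm rexp rbinom rlnorm rpois runif terms
#' @importFrom utils head
NULL

# Evaluate an expression under a fixed seed without disturbing the caller's
# RNG stream. `seed = NULL` leaves the stream untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) {
    return(expr)
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  expr
}

# Canonical tip/species label form: trimmed, internal whitespace collapsed to
# a single underscore. Applied identically to trees and trait tables so that
# matching is exact after normalization.
normalise_labels <- function(x, underscore = TRUE) {
  x <- trimws(x)
  x <- gsub("^['\"]|['\"]$", "", x)   # quoted Newick labels
  if (underscore) x <- gsub("[[:space:]]+", "_", x)
  x
}

# Percentile summary used everywhere across-tree statistics are reported:
# 5th percentile, median, 95th percentile with linear interpolation
# (R quantile type 7).
pctl_summary <- function(x) {
  q <- quantile(x, probs = c(0.05, 0.5, 0.95), type = 7, names = FALSE,
                na.rm = TRUE)
  c(p05 = q[1], median = q[2], p95 = q[3])
}

stopf <- function(fmt, ...) abort(sprintf(fmt, ...))
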