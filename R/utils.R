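# Internal helpers: structured conditions, seed derivation, misc numerics.

ee_stop <- function(class, msg) {
  stop(errorCondition(msg, class = c(class, "embryoexpress_error", "error")))
}

ee_input_error       <- function(msg) ee_stop("ee_input_error", msg)
ee_design_error      <- function(msg) ee_stop("ee_design_error", msg)
ee_generation_error  <- function(msg) ee_stop("ee_generation_error", msg)
ee_no_embryo_error   <- function(msg) ee_stop("ee_no_embryo_error", msg)
ee_orientation_error <- function(msg) ee_stop("ee_orientation_error", msg)
ee_degenerate_error  <- function(msg) ee_stop("ee_degenerate_error", msg)
ee_placement_error   <- function(msg) ee_stop("ee_placement_error", msg)
ee_config_error      <- function(msg) ee_stop("ee_config_error", msg)
ee_io_error          <- function(msg) ee_stop("ee_io_error", msg)

#' Derive a child seed from a master seed and a stage label
#'
#' Stages of a pipeline run draw their randomness from seeds derived
#' deterministically from a single master seed, so each stage is
#' independently reproducible. The derivation is a fixed integer hash of
#' the label folded into the seed, kept below 2^31.
#'
#' @param seed integer master seed.
#' @param label character stage label (e.g. `"render/3"`).
#' @return A single integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label))
  h <- 0
  for (k in utf8ToInt(paste(label, collapse = "/"))) {
    h <- (h * 131 + k) %% 2147483647
  }
  as.integer((abs(seed) %% 2147483647 * 69069 + h) %% 2147483646 + 1)
}

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG state. `seed = NULL` evaluates as-is.
with_seed_ee <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  withr::with_seed(as.integer(seed), code)
}

# Otsu threshold of a numeric vector (histogram form, `levels` bins).
# Returns the threshold value; values strictly above it are foreground.
otsu_threshold <- function(x, levels = 256L) {
  x <- x[is.finite(x)]
  if (length(x) == 0L) ee_input_error("no finite values to threshold")
  rng <- range(x)
  if (diff(rng) == 0) return(rng[1])
  br <- seq(rng[1], rng[2], length.out = levels + 1L)
  h <- tabulate(findInterval(x, br, rightmost.closed = TRUE), nbins = levels)
  p <- h / sum(h)
  mids <- (br[-1] + br[-length(br)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[levels]
  w0c <- w0[-levels]
  between <- (mu_t * w0c - mu[-levels])^2 / (w0c * (1 - w0c))
  between[!is.finite(between)] <- -Inf
  # classes are bins <= k vs > k: the separating value is bin k's upper edge
  br[which.max(between) + 1L]
}

# round-half-even-free rounding used for score discretisation
int_round <- function(x) as.integer(floor(x + 0.5))

`%||%` <- function(a, b) if (is.null(a)) b else a
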