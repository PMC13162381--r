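#' Sample from a log-normal distribution truncated by clipping
#'
#' Draws `exp(N(mu_log, sigma^2))` and clips the result to `[lo, hi]`:
#' values outside the bounds are set to the bound rather than redrawn, so
#' the truncation bounds carry point mass. This is the sampling scheme used
#' for the mineral goal maxima (sodium, calcium, potassium), whose clinical
#' guideline ceilings are meaningful prescriptions in themselves — e.g. a
#' sodium maximum of exp(N(log 2000, 0.01)) clipped to [750, 2000] mg/day
#' prescribes "2000 mg" for half of all patients.
#'
#' @param n Number of draws.
#' @param mu_log Mean of the underlying normal, on the log scale.
#' @param sigma Standard deviation on the log scale (`>= 0`).
#' @param lo,hi Clipping bounds on the natural scale, `lo <= hi`.
#' @return Numeric vector of length `n`, every element in `[lo, hi]`.
#' @examples
#' set.seed(1)
#' x <- sample_truncated_lognormal(5, log(2000), 0.1, 750, 2000)
#' all(x >= 750 & x <= 2000)
#' @export
sample_truncated_lognormal <- function(n, mu_log, sigma, lo = -Inf, hi = Inf) {
  if (!is.finite(mu_log)) stop("mu_log must be finite", call. = FALSE)
  if (!is.finite(sigma) || sigma < 0) {
    stop("sigma must be a finite non-negative number", call. = FALSE)
  }
  if (lo > hi) stop("invalid clipping bounds: lo > hi", call. = FALSE)
  clip(exp(rnorm(n, mu_log, sigma)), lo, hi)
}
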