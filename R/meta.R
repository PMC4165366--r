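#' Inverse-variance-weighted combination of per-SNV scores
#'
#' Fixed-effects meta-analysis of per-SNV scores \code{z} with known
#' variances \code{variance}: the combined score is
#' \eqn{\sum z_i/v_i / \sum 1/v_i} with variance \eqn{1/\sum 1/v_i}, and the
#' Cochran heterogeneity statistic is
#' \eqn{Q = \sum (z_i - \bar z)^2 / v_i}. The DerSimonian-Laird
#' between-SNV variance \eqn{\tau^2} is returned as a diagnostic only; it
#' does not enter the point estimate, and inference on both the combined
#' score and Q is by simulation downstream.
#'
#' @param z Numeric vector of per-SNV scores.
#' @param variance Positive variances, same length as \code{z}.
#' @return A list: \code{combined_z}, \code{combined_variance},
#'   \code{q_stat}, \code{k} (number of SNVs) and \code{tau2}.
#' @examples
#' meta_combine(c(1, 2), c(0.1, 0.1)) # combined_z 1.5, q_stat 5
#' @export
meta_combine <- function(z, variance) {
  if (length(z) == 0L) stop("'z' must be non-empty")
  if (length(z) != length(variance)) {
    stop("'z' and 'variance' must have equal length")
  }
  if (any(!is.finite(z)) || any(!is.finite(variance))) {
    stop("scores and variances must be finite")
  }
  if (any(variance <= 0)) stop("variances must be positive")
  w <- 1 / variance
  sw <- sum(w)
  combined_z <- sum(w * z) / sw
  q_stat <- sum(w * (z - combined_z)^2)
  k <- length(z)
  tau2 <- if (k > 1) {
    max(0, (q_stat - (k - 1)) / (sw - sum(w^2) / sw))
  } else {
    0
  }
  list(combined_z = combined_z,
       combined_variance = 1 / sw,
       q_stat = q_stat,
       k = k,
       tau2 = tau2)
}
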