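#' Freeman-Tukey double-arcsine transform of allelic counts
#'
#' Variance-stabilizing transform of a binomial count \code{x} out of
#' \code{n} trials,
#' \deqn{z = \sin^{-1}\sqrt{x/(n+1)} + \sin^{-1}\sqrt{(x+1)/(n+1)},}
#' which is approximately normal with mean \eqn{2\sin^{-1}\sqrt{p}} and
#' variance \eqn{1/(n + 0.5)} when \eqn{x \sim Binomial(n, p)}.
#'
#' @param x Non-negative integer count(s), \code{0 <= x <= n}.
#' @param n Positive integer total(s).
#' @return A list with components \code{z} (transformed score),
#'   \code{variance} (nominal variance \code{1/(n + 0.5)}) and \code{n}.
#'   All components are vectorized over the inputs.
#' @seealso [ft_backtransform()], [ft_variance()]
#' @examples
#' ft_transform(5, 10)$z    # pi/2: balanced counts
#' @export
ft_transform <- function(x, n) {
  if (length(x) == 0L || length(n) == 0L) {
    stop("'x' and 'n' must be non-empty")
  }
  xn <- recycle2(x, n)
  x <- xn[[1]]; n <- xn[[2]]
  if (any(!is.finite(x)) || any(!is.finite(n))) {
    stop("'x' and 'n' must be finite")
  }
  if (any(n < 1)) stop("'n' must be >= 1")
  if (any(x < 0) || any(x > n)) stop("'x' must satisfy 0 <= x <= n")
  z <- asin(sqrt(x / (n + 1))) + asin(sqrt((x + 1) / (n + 1)))
  list(z = z, variance = 1 / (n + 0.5), n = n)
}

#' Invert the Freeman-Tukey transform to a proportion
#'
#' Exact inversion of the mean map of the transform: a score \code{z} is
#' mapped back to the proportion \code{p} solving
#' \eqn{2\sin^{-1}\sqrt{p} = z}, i.e. \eqn{p = \sin^2(z/2)}, after clipping
#' \code{z} to \eqn{[0, \pi]}.
#'
#' @param z Numeric score(s).
#' @return Proportion(s) in \code{[0, 1]}.
#' @export
ft_backtransform <- function(z) {
  if (any(!is.finite(z))) stop("'z' must be finite")
  sin(pmin(pmax(z, 0), pi) / 2)^2
}

#' Variance of a Freeman-Tukey score under beta-binomial counts
#'
#' Nominal variance \code{1/(n + 0.5)} inflated by the beta-binomial
#' variance inflation factor \eqn{\rho(n-1) + 1} (first-order delta-method
#' propagation of the beta-binomial count variance).
#'
#' @param n Positive integer total(s).
#' @param rho Overdispersion in \code{[0, 1)}; 0 recovers the binomial case.
#' @return Numeric variance(s).
#' @export
ft_variance <- function(n, rho = 0) {
  if (any(n < 1)) stop("'n' must be >= 1")
  if (any(rho < 0) || any(rho >= 1)) stop("'rho' must be in [0, 1)")
  (rho * (n - 1) + 1) / (n + 0.5)
}

#' Map a transcript-scale allele frequency to the read-count scale
#'
#' Under pre-existing allelic bias, an allele whose true transcript
#' frequency is \code{maf} is observed in reads with probability
#' \deqn{\mu = \frac{maf \cdot f}{maf \cdot f + (1 - maf)(1 - f)},}
#' where \code{f} is the probability of observing that allele when the true
#' frequency is 0.5. \code{f = 0.5} (no bias) is the identity.
#'
#' @param maf True allele/haplotype frequency, strictly in (0, 1).
#' @param f_allele_null Allele observation probability at balanced
#'   expression, strictly in (0, 1).
#' @return Read-scale probability strictly in (0, 1).
#' @seealso [bias_invert_mu()] for the inverse map.
#' @export
bias_adjusted_mu <- function(maf, f_allele_null) {
  check_open_unit(maf, "maf")
  check_open_unit(f_allele_null, "f_allele_null")
  maf * f_allele_null /
    (maf * f_allele_null + (1 - maf) * (1 - f_allele_null))
}

#' Map a read-count-scale frequency back to the transcript scale
#'
#' Inverse of [bias_adjusted_mu()]: recovers the transcript-scale frequency
#' from an observed read-scale probability \code{mu} under bias
#' \code{f_allele_null}. Closed form
#' \eqn{m(1-f) / (m(1-f) + f(1-m))}.
#'
#' @param mu Read-scale probability, strictly in (0, 1).
#' @param f_allele_null Allele observation probability at balanced
#'   expression, strictly in (0, 1).
#' @return Transcript-scale frequency strictly in (0, 1).
#' @export
bias_invert_mu <- function(mu, f_allele_null) {
  check_open_unit(mu, "mu")
  check_open_unit(f_allele_null, "f_allele_null")
  mu * (1 - f_allele_null) /
    (mu * (1 - f_allele_null) + f_allele_null * (1 - mu))
}

#' Draw beta-binomial counts
#'
#' Counts with mean \code{size * mu} and variance
#' \code{mu (1 - mu) size (rho (size - 1) + 1)}. Parametrized by the mean
#' \code{mu} and overdispersion \code{rho}; internally \code{(mu, rho)} maps
#' to beta shape parameters \code{alpha = mu (1 - rho) / rho},
#' \code{beta = (1 - mu)(1 - rho) / rho}. \code{rho = 0} short-circuits to
#' plain binomial sampling.
#'
#' @param nn Number of draws.
#' @param size Positive integer total(s), recycled to length \code{nn}.
#' @param mu Mean parameter(s), strictly in (0, 1), recycled.
#' @param rho Overdispersion(s) in \code{[0, 1)}, recycled.
#' @return Integer vector of length \code{nn}.
#' @examples
#' set.seed(1)
#' mean(rbetabinom(1e4, 20, 0.5, 0.004)) # close to 10
#' @export
rbetabinom <- function(nn, size, mu, rho = 0) {
  if (length(nn) != 1L || !is.finite(nn) || nn < 0) {
    stop("'nn' must be a single non-negative number")
  }
  if (any(size < 1)) stop("'size' must be >= 1")
  check_open_unit(mu, "mu")
  if (any(rho < 0) || any(rho >= 1)) stop("'rho' must be in [0, 1)")
  size <- rep_len(size, nn)
  mu <- rep_len(mu, nn)
  rho <- rep_len(rho, nn)
  out <- integer(nn)
  plain <- rho == 0
  if (any(plain)) {
    out[plain] <- stats::rbinom(sum(plain), size[plain], mu[plain])
  }
  if (any(!plain)) {
    r <- rho[!plain]
    m <- mu[!plain]
    p <- stats::rbeta(sum(!plain), m * (1 - r) / r, (1 - m) * (1 - r) / r)
    out[!plain] <- stats::rbinom(sum(!plain), size[!plain], p)
  }
  out
}

# --- internal helpers -------------------------------------------------------

check_open_unit <- function(x, name) {
  if (any(!is.finite(x)) || any(x <= 0) || any(x >= 1)) {
    stop(sprintf("'%s' must be strictly inside (0, 1)", name))
  }
  invisible(x)
}

recycle2 <- function(a, b) {
  len <- max(length(a), length(b))
  list(rep_len(a, len), rep_len(b, len))
}

# Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Deterministic stream seed derived from a user seed and a key string,
# kept below 2^31 so it is a valid set.seed() input.
derive_seed <- function(seed, key) {
  h <- sum(utf8ToInt(key) * (seq_len(nchar(key)) %% 97 + 1))
  as.integer((abs(as.numeric(seed)) %% 2^20 * 2147483 + h * 7919) %%
               2147483646) + 1L
}
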