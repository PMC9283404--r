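# von Mises building blocks: density, mixture density, random generation
# (Best & Fisher 1979 wrapped-Cauchy envelope), maximum-likelihood
# concentration.  Written against closed forms; no circular-statistics
# dependency.

#' von Mises density
#'
#' @param theta angles (radians).
#' @param mu mean direction (radians).
#' @param kappa concentration (>= 0; 0 is the circular uniform).
#' @return density values.
#' @export
dvonmises <- function(theta, mu, kappa) {
  # exponentially-scaled Bessel keeps this finite for very large kappa
  exp(kappa * (cos(theta - mu) - 1)) /
    (2 * pi * besselI(kappa, 0, expon.scaled = TRUE))
}

#' Density of a von Mises mixture
#'
#' @param theta angles (radians).
#' @param mixture data.frame or list with components `weight`, `mu`,
#'   `kappa`; weights must sum to 1.
#' @return density values.
#' @export
dmixvm <- function(theta, mixture) {
  mixture <- as.data.frame(mixture)
  stopifnot(abs(sum(mixture$weight) - 1) < 1e-8, all(mixture$kappa >= 0))
  out <- numeric(length(theta))
  for (i in seq_len(nrow(mixture)))
    out <- out + mixture$weight[i] * dvonmises(theta, mixture$mu[i], mixture$kappa[i])
  out
}

#' von Mises random deviates
#'
#' Best-Fisher rejection sampler with a wrapped-Cauchy envelope; vectorised
#' in batches.
#'
#' @param n number of deviates.
#' @param mu mean direction (radians).
#' @param kappa concentration (>= 0).
#' @return angles in `[0, 2*pi)`.
#' @export
rvonmises <- function(n, mu, kappa) {
  if (n == 0) return(numeric(0))
  if (kappa < 1e-10) return(stats::runif(n, 0, 2 * pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(0)
  while (length(out) < n) {
    m <- max(16L, ceiling((n - length(out)) * 1.5))
    u1 <- stats::runif(m); u2 <- stats::runif(m); u3 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    th <- sign(u3[ok] - 0.5) * acos(f[ok])
    out <- c(out, th)
  }
  (mu + out[seq_len(n)]) %% (2 * pi)
}

#' Deviates from a von Mises mixture
#'
#' @inheritParams dmixvm
#' @param n number of deviates.
#' @return angles in `[0, 2*pi)`.
#' @export
rmixvm <- function(n, mixture) {
  mixture <- as.data.frame(mixture)
  comp <- sample.int(nrow(mixture), n, replace = TRUE, prob = mixture$weight)
  out <- numeric(n)
  for (i in seq_len(nrow(mixture))) {
    idx <- comp == i
    out[idx] <- rvonmises(sum(idx), mixture$mu[i], mixture$kappa[i])
  }
  out
}

# A(kappa) = I1/I0 and maximum-likelihood concentration given the mean
# resultant length rbar (Best-Fisher starting value + Newton refinement).
vm_A <- function(kappa) {
  besselI(kappa, 1, expon.scaled = TRUE) / besselI(kappa, 0, expon.scaled = TRUE)
}

vm_kappa_ml <- function(x, kmax = Inf) {
  rbar <- sqrt(mean(cos(x))^2 + mean(sin(x))^2)
  if (rbar >= 1 - 1e-12) return(min(kmax, 1e6))
  k <- if (rbar < 0.53) {
    2 * rbar + rbar^3 + 5 * rbar^5 / 6
  } else if (rbar < 0.85) {
    -0.4 + 1.39 * rbar + 0.43 / (1 - rbar)
  } else {
    1 / (rbar^3 - 4 * rbar^2 + 3 * rbar)
  }
  for (i in 1:4) {                       # Newton on A(k) - rbar
    A <- vm_A(k)
    k <- max(k - (A - rbar) / (1 - A / k - A^2), 1e-8)
  }
  min(k, kmax)
}
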