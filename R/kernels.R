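#' von Mises random deviates
#'
#' Best--Fisher (1979) rejection sampler. `kappa = 0` gives the uniform
#' distribution on `(-pi, pi]`.
#'
#' @param n number of draws.
#' @param mu mean direction (rad).
#' @param kappa concentration (>= 0).
#' @return numeric vector of angles in `(-pi, pi]`.
#' @export
rvonmises <- function(n, mu = 0, kappa = 1) {
  if (kappa < 0) stop("`kappa` must be non-negative", call. = FALSE)
  if (kappa < 1e-10) {
    return(wrap_angle(stats::runif(n, -pi, pi)))
  }
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u1 <- stats::runif(1)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    c_ <- kappa * (r - f)
    u2 <- stats::runif(1)
    if (c_ * (2 - c_) - u2 > 0 || log(c_ / u2) + 1 - c_ >= 0) {
      u3 <- stats::runif(1)
      out[i] <- sign(u3 - 0.5) * acos(f)
      i <- i + 1L
    }
  }
  wrap_angle(out + mu)
}

# A(kappa) = I1(kappa)/I0(kappa), overflow-safe
vm_A <- function(kappa) {
  besselI(kappa, 1, expon.scaled = TRUE) / besselI(kappa, 0, expon.scaled = TRUE)
}

#' von Mises maximum-likelihood fit
#'
#' Mean direction from the circular mean; concentration by inverting
#' `A(kappa) = Rbar` (mean resultant length), using the standard series
#' approximations as a start and Newton refinement on the Bessel-function
#' ratio. Nearly degenerate samples are capped at `kappa_max`.
#'
#' @param angles angles (rad).
#' @param kappa_max upper cap on the fitted concentration.
#' @return list with `mu` (rad) and `kappa`.
#' @export
fit_vonmises <- function(angles, kappa_max = 500) {
  angles <- angles[is.finite(angles)]
  if (length(angles) < 2) stop("need at least 2 angles", call. = FALSE)
  C <- mean(cos(angles))
  S <- mean(sin(angles))
  mu <- atan2(S, C)
  rbar <- sqrt(C^2 + S^2)
  if (rbar >= 1 - 1e-12) {
    return(list(mu = mu, kappa = kappa_max))
  }
  # Fisher (1993) starting approximations
  k <- if (rbar < 0.53) {
    2 * rbar + rbar^3 + 5 * rbar^5 / 6
  } else if (rbar < 0.85) {
    -0.4 + 1.39 * rbar + 0.43 / (1 - rbar)
  } else {
    1 / (rbar^3 - 4 * rbar^2 + 3 * rbar)
  }
  k <- min(max(k, 1e-8), kappa_max)
  for (it in 1:50) {
    Ak <- vm_A(k)
    # d A/d kappa = 1 - A/kappa - A^2
    deriv <- 1 - Ak / k - Ak^2
    if (!is.finite(deriv) || deriv <= 0) break
    step <- (Ak - rbar) / deriv
    k_new <- min(max(k - step, 1e-10), kappa_max)
    if (abs(k_new - k) < 1e-10 * (1 + k)) {
      k <- k_new
      break
    }
    k <- k_new
  }
  list(mu = mu, kappa = min(k, kappa_max))
}

#' Gamma maximum-likelihood fit
#'
#' Newton iteration on the profile score for the shape (the digamma
#' equation `log(shape) - digamma(shape) = log(mean) - mean(log)`), with the
#' scale given by `mean / shape`.
#'
#' @param x positive observations (m).
#' @return list with `shape` and `scale`.
#' @export
fit_gamma <- function(x) {
  x <- x[is.finite(x)]
  if (any(x <= 0)) stop("gamma fit requires positive values", call. = FALSE)
  if (length(unique(x)) < 2) {
    stop("need at least 2 distinct values for a gamma fit", call. = FALSE)
  }
  s <- log(mean(x)) - mean(log(x))
  # initial value from the standard approximation
  k <- (3 - s + sqrt((s - 3)^2 + 24 * s)) / (12 * s)
  for (it in 1:100) {
    num <- log(k) - digamma(k) - s
    den <- 1 / k - trigamma(k)
    k_new <- k - num / den
    if (!is.finite(k_new) || k_new <= 0) k_new <- k / 2
    if (abs(k_new - k) < 1e-12 * (1 + k)) {
      k <- k_new
      break
    }
    k <- k_new
  }
  list(shape = k, scale = mean(x) / k)
}
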