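#' Moments of a truncated normal distribution
#'
#' Closed-form mean and standard deviation of a normal distribution with
#' parameters `mu` and `sigma` truncated to the interval `[lower, upper]`.
#'
#' @param mu,sigma Parameters of the underlying (untruncated) normal.
#' @param lower,upper Truncation bounds, `lower < upper`.
#' @return A list with elements `mean` and `sd` of the truncated distribution.
#' @examples
#' tn_moments(0, 1, -1, 1)
#' @export
tn_moments <- function(mu, sigma, lower, upper) {
  stopifnot(sigma > 0, lower < upper)
  a <- (lower - mu) / sigma
  b <- (upper - mu) / sigma
  # evaluate the normalizing mass in whichever tail keeps precision
  Z <- if (a > 0) {
    stats::pnorm(a, lower.tail = FALSE) - stats::pnorm(b, lower.tail = FALSE)
  } else {
    stats::pnorm(b) - stats::pnorm(a)
  }
  if (!is.finite(Z) || Z < 1e-300) {
    # essentially no mass on the interval: collapse onto the nearer bound
    m <- if (mu < lower) lower else upper
    return(list(mean = m, sd = 0))
  }
  da <- stats::dnorm(a)
  db <- stats::dnorm(b)
  r1 <- (da - db) / Z
  m <- mu + sigma * r1
  v <- sigma^2 * (1 + (a * da - b * db) / Z - r1^2)
  list(mean = m, sd = sqrt(max(v, 0)))
}

#' Largest standard deviation attainable on a bounded support at a given mean
#'
#' For any distribution supported on `[lower, upper]` with mean `mean`, the
#' variance is bounded by that of the two-point distribution placing all mass
#' on the endpoints, `(mean - lower) * (upper - mean)`.
#'
#' @inheritParams tn_moments
#' @param mean Target mean, inside `[lower, upper]`.
#' @return The upper bound on the standard deviation.
#' @export
max_feasible_sd <- function(mean, lower, upper) {
  stopifnot(lower < upper, mean >= lower, mean <= upper)
  sqrt((mean - lower) * (upper - mean))
}

#' Calibrate a truncated normal to target post-truncation moments
#'
#' Finds underlying normal parameters `(mu, sigma)` such that the truncated
#' distribution on `[lower, upper]` has the requested mean (to within 1e-6)
#' and, where attainable, the requested standard deviation. Survey tables
#' often print a standard deviation that no distribution on the stated
#' support can have; in that case the mean is matched exactly and the
#' standard deviation is clipped to the largest attainable value, with a
#' warning of class `pandaniche_sd_clip`.
#'
#' The solver nests two monotone root-finders: for a fixed `sigma` the
#' post-truncation mean is strictly increasing in `mu`, and with the mean
#' constraint enforced the post-truncation standard deviation is increasing
#' in `sigma`.
#'
#' @inheritParams max_feasible_sd
#' @param sd Target post-truncation standard deviation, `> 0`.
#' @return A list with `mu`, `sigma`, the achieved `mean` and `sd`, the
#'   requested `sd_requested`, and a logical `clipped`.
#' @examples
#' cal <- calibrate_truncated_normal(0.289, 0.25, 0, 1)
#' tn_moments(cal$mu, cal$sigma, 0, 1)
#' @export
calibrate_truncated_normal <- function(mean, sd, lower, upper) {
  if (!is.finite(lower) || !is.finite(upper) || lower >= upper) {
    stop("invalid spec: need finite bounds with lower < upper", call. = FALSE)
  }
  if (!is.finite(mean) || mean < lower || mean > upper) {
    stop("invalid spec: mean must lie inside [lower, upper]", call. = FALSE)
  }
  if (!is.finite(sd) || sd < 0) {
    stop("invalid spec: sd must be non-negative", call. = FALSE)
  }
  rng <- upper - lower
  clipped <- FALSE
  target_sd <- sd
  cap <- max_feasible_sd(mean, lower, upper)
  if (sd > cap) {
    clipped <- TRUE
    target_sd <- cap
    warning(warningCondition(
      sprintf(paste0(
        "requested sd %.4g exceeds the maximum %.4g possible on [%g, %g] at ",
        "mean %.4g; sd clipped, mean matched exactly"), sd, cap, lower, upper,
        mean),
      class = c("pandaniche_sd_clip", "warning")))
  }

  # degenerate spike: all mass (numerically) at the mean
  if (target_sd <= 1e-8 * rng) {
    return(list(mu = mean, sigma = 1e-12 * rng, mean = mean, sd = 0,
                sd_requested = sd, clipped = clipped))
  }

  solve_mu <- function(sigma) {
    f <- function(mu) tn_moments(mu, sigma, lower, upper)$mean - mean
    lo <- mean - sigma
    step <- sigma + rng
    it <- 0
    while (f(lo) > 0 && it < 60) {
      lo <- lo - step
      step <- step * 2
      it <- it + 1
    }
    hi <- mean + sigma
    step <- sigma + rng
    it <- 0
    while (f(hi) < 0 && it < 60) {
      hi <- hi + step
      step <- step * 2
      it <- it + 1
    }
    stats::uniroot(f, c(lo, hi), tol = 1e-11 * max(1, rng))$root
  }
  sd_at <- function(sigma) {
    tn_moments(solve_mu(sigma), sigma, lower, upper)$sd
  }

  sig_hi <- 10 * rng  # close to the exponential-tilt limit of the family
  if (sd_at(sig_hi) < target_sd) {
    # requested sd lies beyond what the truncated-normal family can reach at
    # this mean (the two-point bound is not attainable by a unimodal density)
    if (!clipped) {
      warning(warningCondition(
        sprintf(paste0(
          "requested sd %.4g is not attainable by a truncated normal on ",
          "[%g, %g] with mean %.4g; using the largest attainable sd %.4g"),
          sd, lower, upper, mean, sd_at(sig_hi)),
        class = c("pandaniche_sd_clip", "warning")))
    }
    clipped <- TRUE
    sigma <- sig_hi
  } else {
    sig_lo <- 1e-4 * rng
    if (sd_at(sig_lo) > target_sd) sig_lo <- 1e-8 * rng
    sigma <- stats::uniroot(function(s) sd_at(s) - target_sd,
                            c(sig_lo, sig_hi), tol = 1e-10 * rng)$root
  }
  mu <- solve_mu(sigma)
  ach <- tn_moments(mu, sigma, lower, upper)
  list(mu = mu, sigma = sigma, mean = ach$mean, sd = ach$sd,
       sd_requested = sd, clipped = clipped)
}

#' Draw from a truncated normal distribution
#'
#' Inverse-CDF sampler, numerically stable when the truncation interval sits
#' far in one tail of the underlying normal (the regime used to emulate
#' heavy-spread bounded survey variables).
#'
#' @param n Number of draws.
#' @inheritParams tn_moments
#' @return Numeric vector of length `n` inside `[lower, upper]`.
#' @export
rtruncnorm <- function(n, mu, sigma, lower, upper) {
  stopifnot(lower < upper)
  if (sigma <= 1e-10 * (upper - lower)) {
    return(rep(min(max(mu, lower), upper), n))
  }
  a <- (lower - mu) / sigma
  b <- (upper - mu) / sigma
  u <- stats::runif(n)
  if (a > 0) {
    # interval in the upper tail: interpolate survival probabilities
    qa <- stats::pnorm(a, lower.tail = FALSE)
    qb <- stats::pnorm(b, lower.tail = FALSE)
    z <- stats::qnorm(qb + u * (qa - qb), lower.tail = FALSE)
  } else {
    pa <- stats::pnorm(a)
    pb <- stats::pnorm(b)
    z <- stats::qnorm(pa + u * (pb - pa))
  }
  pmin(pmax(mu + sigma * z, lower), upper)
}

#' Calibrate a 3-level ordinal distribution to a printed mean and sd
#'
#' Finds probabilities `(p1, p2, p3)` on levels `{1, 2, 3}` whose mean equals
#' the target exactly. Given the mean, the variance is linear and decreasing
#' in the middle-level probability, so the sd is matched where feasible and
#' otherwise clipped to the nearest attainable value (warning of class
#' `pandaniche_sd_clip`).
#'
#' @param mean Target mean in `[1, 3]`.
#' @param sd Target standard deviation.
#' @return A list with `probs` (length 3), achieved `mean` and `sd`, and
#'   logical `clipped`.
#' @export
calibrate_ordinal3 <- function(mean, sd) {
  if (!is.finite(mean) || mean < 1 || mean > 3) {
    stop("invalid spec: ordinal mean must lie in [1, 3]", call. = FALSE)
  }
  if (!is.finite(sd) || sd < 0) {
    stop("invalid spec: sd must be non-negative", call. = FALSE)
  }
  vfun <- function(t) {
    p3 <- (mean - 1 - t) / 2
    p1 <- (3 - mean - t) / 2
    p1 * (1 - mean)^2 + t * (2 - mean)^2 + p3 * (3 - mean)^2
  }
  t_upper <- 1 - abs(mean - 2)
  v_max <- vfun(0)
  v_min <- vfun(t_upper)
  target <- sd^2
  clipped <- FALSE
  if (target > v_max + 1e-12) {
    t <- 0
    clipped <- TRUE
    warning(warningCondition(
      sprintf(paste0("requested sd %.4g exceeds the maximum %.4g possible ",
                     "for a 3-level ordinal with mean %.4g; sd clipped"),
              sd, sqrt(v_max), mean),
      class = c("pandaniche_sd_clip", "warning")))
  } else if (target < v_min - 1e-12) {
    t <- t_upper
    clipped <- TRUE
    warning(warningCondition(
      sprintf(paste0("requested sd %.4g is below the minimum %.4g possible ",
                     "for a 3-level ordinal with mean %.4g; sd clipped"),
              sd, sqrt(v_min), mean),
      class = c("pandaniche_sd_clip", "warning")))
  } else if (v_max - v_min < 1e-14) {
    t <- 0
  } else {
    t <- (v_max - target) / (v_max - v_min) * t_upper
  }
  p3 <- (mean - 1 - t) / 2
  p1 <- (3 - mean - t) / 2
  probs <- pmax(c(p1, t, p3), 0)
  probs <- probs / sum(probs)
  ach_mean <- sum(probs * (1:3))
  ach_sd <- sqrt(sum(probs * ((1:3) - ach_mean)^2))
  list(probs = probs, mean = ach_mean, sd = ach_sd, clipped = clipped)
}
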