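## Circular geometry and circular statistics primitives.
##
## Angle conventions used throughout the package:
##   * world frame is East/North/Up (ENU); the device reports a unit vector
##     (e, n, u) on this frame.
##   * compass heading h = atan2(e, n), degrees clockwise from North.
##   * body azimuth = wrap(h - facing_heading) in (-180, 180], positive to the
##     participant's right.
##   * elevation = asin(u), degrees in [-90, 90], positive up. Elevation does
##     not wrap and is treated as a linear variable unless explicitly asked
##     for otherwise.

DEG <- 180 / pi

#' Wrap angles into (-180, 180]
#'
#' @param x numeric vector of angles in degrees.
#' @return angles wrapped to the half-open interval (-180, 180].
#' @examples
#' wrap_angle(c(350, -180, 540))
#' @export
wrap_angle <- function(x) {
  r <- ((x + 180) %% 360) - 180
  r[r <= -180] <- r[r <= -180] + 360
  r
}

#' Signed circular distance between two angles
#'
#' Returns the signed smallest rotation (degrees) taking `b` onto `a`,
#' in (-180, 180]. Positive means `a` lies clockwise (to the right, in the
#' body-azimuth convention) of `b`.
#'
#' @param a,b angles in degrees; recycled to common length.
#' @return signed degrees in (-180, 180].
#' @examples
#' circ_distance(10, 350)   # 20
#' circ_distance(-170, 170) # 20
#' @export
circ_distance <- function(a, b) {
  wrap_angle(a - b)
}

#' Convert a pointing vector to body-referenced direction angles
#'
#' The ENU unit vector is mapped to azimuth/elevation relative to the
#' participant's facing direction. Azimuth is undefined for (near-)vertical
#' vectors: when |elevation| > 89.9 degrees the azimuth is still reported but
#' flagged as undefined.
#'
#' @param v numeric length-3 vector (e, n, u), or a matrix with 3 columns.
#' @param facing_heading_deg compass heading (degrees clockwise from North)
#'   the participant faces.
#' @return a data.frame with columns `azimuth_deg`, `elevation_deg`,
#'   `azimuth_defined`.
#' @export
vector_to_angles <- function(v, facing_heading_deg = 0) {
  if (is.null(dim(v))) v <- matrix(v, ncol = 3, byrow = TRUE)
  stopifnot(ncol(v) == 3)
  nrm <- sqrt(rowSums(v^2))
  if (any(nrm < 1e-12)) stop("degenerate input: zero pointing vector")
  v <- v / nrm
  elevation <- asin(pmin(1, pmax(-1, v[, 3]))) * DEG
  heading <- atan2(v[, 1], v[, 2]) * DEG
  azimuth <- wrap_angle(heading - facing_heading_deg)
  data.frame(
    azimuth_deg = azimuth,
    elevation_deg = elevation,
    azimuth_defined = abs(elevation) <= 89.9
  )
}

#' Convert direction angles to an ENU unit vector
#'
#' Inverse of [vector_to_angles()].
#'
#' @param azimuth_deg body azimuth in degrees (positive right).
#' @param elevation_deg elevation in degrees, within [-90, 90].
#' @param facing_heading_deg facing compass heading in degrees.
#' @return a matrix with columns e, n, u; one row per input angle.
#' @export
angles_to_vector <- function(azimuth_deg, elevation_deg, facing_heading_deg = 0) {
  stopifnot(all(elevation_deg >= -90 & elevation_deg <= 90))
  h <- (azimuth_deg + facing_heading_deg) / DEG
  el <- elevation_deg / DEG
  cbind(
    e = cos(el) * sin(h),
    n = cos(el) * cos(h),
    u = sin(el)
  )
}

#' Great-circle angle between two directions
#'
#' @param az1,el1,az2,el2 angles in degrees (vectors recycled).
#' @param facing_heading_deg facing heading; cancels out, kept for symmetry.
#' @return nonnegative angle in degrees in [0, 180].
#' @export
great_circle_angle <- function(az1, el1, az2, el2, facing_heading_deg = 0) {
  v1 <- angles_to_vector(az1, el1, facing_heading_deg)
  v2 <- angles_to_vector(az2, el2, facing_heading_deg)
  d <- pmin(1, pmax(-1, rowSums(v1 * v2)))
  acos(d) * DEG
}

#' Circular mean, resultant length and circular SD
#'
#' Computes the first trigonometric moment of a (optionally weighted) sample
#' of angles: mean direction atan2(S, C), resultant length
#' R = sqrt(C^2 + S^2) / sum(w), and the circular standard deviation
#' sqrt(-2 log R), reported in degrees. The angular deviation
#' sqrt(2 (1 - R)) is also reported. When R is numerically zero the mean is
#' undefined and the circular SD is +Inf.
#'
#' @param angles_deg numeric vector of angles in degrees (any real values;
#'   wrapped internally).
#' @param weights optional nonnegative weights, same length; must not sum
#'   to zero.
#' @return an object of class `circ_summary`: a list with `mean_deg`,
#'   `resultant_length`, `circ_sd_deg`, `angular_dev_deg`, `n`,
#'   `mean_defined`.
#' @examples
#' circ_mean(c(350, 10))      # mean 0
#' circ_mean(c(0, 90))        # R = sqrt(2)/2
#' @export
circ_mean <- function(angles_deg, weights = NULL) {
  n <- length(angles_deg)
  if (n < 1) stop("empty circular sample")
  if (is.null(weights)) weights <- rep(1, n)
  stopifnot(length(weights) == n, all(weights >= 0))
  sw <- sum(weights)
  if (sw <= 0) stop("weights sum to zero")
  th <- angles_deg / DEG
  C <- sum(weights * cos(th)) / sw
  S <- sum(weights * sin(th)) / sw
  R <- sqrt(C^2 + S^2)
  defined <- R >= 1e-12
  mean_deg <- if (defined) wrap_angle(atan2(S, C) * DEG) else NA_real_
  circ_sd <- if (defined) sqrt(-2 * log(min(R, 1))) * DEG else Inf
  structure(
    list(
      mean_deg = mean_deg,
      resultant_length = R,
      circ_sd_deg = circ_sd,
      angular_dev_deg = sqrt(2 * (1 - R)) * DEG,
      n = n,
      mean_defined = defined
    ),
    class = "circ_summary"
  )
}

#' @export
print.circ_summary <- function(x, ...) {
  cat(sprintf(
    "Circular summary (n = %d): mean = %s deg, R = %.4f, circ SD = %.2f deg\n",
    x$n,
    if (x$mean_defined) sprintf("%.2f", x$mean_deg) else "undefined",
    x$resultant_length, x$circ_sd_deg
  ))
  invisible(x)
}

#' Rayleigh test of circular uniformity
#'
#' Tests the null hypothesis that the sample is drawn from the uniform
#' distribution on the circle, against a unimodal alternative. The statistic
#' is z = n R^2; the p-value uses the classical small-sample-corrected
#' approximation
#' p = exp(sqrt(1 + 4 n + 4 (n^2 - n^2 R^2)) - (1 + 2 n)), clipped to [0, 1].
#'
#' @param angles_deg numeric vector of angles in degrees, unweighted, n >= 2.
#' @return a list with `z`, `p_value`, `n`, `resultant_length`.
#' @export
rayleigh_test <- function(angles_deg) {
  n <- length(angles_deg)
  if (n < 2) stop("Rayleigh test needs n >= 2")
  R <- circ_mean(angles_deg)$resultant_length
  z <- n * R^2
  p <- exp(sqrt(1 + 4 * n + 4 * (n^2 - n^2 * R^2)) - (1 + 2 * n))
  list(z = z, p_value = min(1, max(0, p)), n = n, resultant_length = R)
}

## Ratio A(kappa) = I1(kappa)/I0(kappa); exponentially scaled Bessel
## functions keep this finite for arbitrarily large kappa.
vm_A <- function(kappa) {
  ifelse(kappa == 0, 0, besselI(kappa, 1, expon.scaled = TRUE) /
    besselI(kappa, 0, expon.scaled = TRUE))
}

## Invert A(kappa) = r: Best-Fisher piecewise starting value, then a few
## Newton steps (A'(k) = 1 - A/k - A^2).
vm_A_inv <- function(r, newton = TRUE) {
  if (r < 0) r <- 0
  if (r >= 1) return(Inf)
  k <- if (r < 0.53) {
    2 * r + r^3 + 5 * r^5 / 6
  } else if (r < 0.85) {
    -0.4 + 1.39 * r + 0.43 / (1 - r)
  } else {
    1 / (r^3 - 4 * r^2 + 3 * r)
  }
  if (newton && k > 0) {
    for (i in 1:25) {
      A <- vm_A(k)
      dA <- 1 - A / k - A^2
      if (dA <= 0) break
      step <- (A - r) / dA
      k <- max(k - step, 1e-12)
      if (abs(step) < 1e-12 * max(1, k)) break
    }
  }
  k
}

#' Maximum-likelihood von Mises fit
#'
#' Fits mean direction and concentration by maximum likelihood: mu is the
#' circular mean and kappa solves A(kappa) = I1/I0 = R via the Best-Fisher
#' piecewise approximation refined by Newton iteration. For small samples
#' (n <= 15) the standard downward bias correction for kappa is applied.
#' Nearly degenerate samples (R ~ 1) cap kappa at `kappa_max` and set a
#' saturation flag.
#'
#' @param angles_deg numeric vector of angles in degrees, n >= 2.
#' @param bias_correct apply the small-sample correction when n <= 15.
#' @param kappa_max cap for the concentration (default 1e6).
#' @return a list of class `vonmises_fit` with `mu_deg`, `kappa`, `loglik`,
#'   `n`, `saturated`.
#' @export
vonmises_fit <- function(angles_deg, bias_correct = TRUE, kappa_max = 1e6) {
  n <- length(angles_deg)
  if (n < 2) stop("von Mises fit needs n >= 2")
  cs <- circ_mean(angles_deg)
  R <- cs$resultant_length
  kappa <- vm_A_inv(R)
  if (bias_correct && n <= 15 && is.finite(kappa)) {
    kappa <- if (kappa < 2) max(kappa - 2 / (n * kappa), 0) else
      (n - 1)^3 * kappa / (n^3 + n)
  }
  saturated <- !is.finite(kappa) || kappa > kappa_max
  if (saturated) kappa <- kappa_max
  mu <- if (cs$mean_defined) cs$mean_deg else 0
  th <- (angles_deg - mu) / DEG
  ll <- sum(kappa * cos(th)) - n * (log(2 * pi) + log(besselI(kappa, 0, TRUE)) + kappa)
  structure(
    list(mu_deg = mu, kappa = kappa, loglik = ll, n = n, saturated = saturated),
    class = "vonmises_fit"
  )
}

#' @export
print.vonmises_fit <- function(x, ...) {
  cat(sprintf(
    "von Mises fit (n = %d): mu = %.2f deg, kappa = %.3f, loglik = %.3f%s\n",
    x$n, x$mu_deg, x$kappa, x$loglik,
    if (isTRUE(x$saturated)) " [kappa saturated]" else ""
  ))
  invisible(x)
}

## von Mises log-density at angle th (radians) about mu (radians)
vm_logdens <- function(th, mu, kappa) {
  kappa * cos(th - mu) - log(2 * pi) - log(besselI(kappa, 0, TRUE)) - kappa
}

#' Two-component von Mises mixture via expectation-maximisation
#'
#' Fits a 2-component von Mises mixture, the model used to describe bimodal
#' mental-rotation errors (a main mode plus a flip mode near +-90 or 180
#' degrees). EM runs from `restarts` seeded random initialisations; the best
#' log-likelihood wins. Components are reported in descending weight order.
#' If a component degenerates (weight below 1/n) the fit falls back to a
#' single von Mises and sets a collapse flag.
#'
#' @param angles_deg angles in degrees, n >= 8.
#' @param restarts number of random initialisations (default 5).
#' @param seed integer seed controlling the initialisations.
#' @param max_iter maximum EM iterations per start (default 500).
#' @param tol stop when the log-likelihood gain drops below this (default 1e-8).
#' @param kappa_max concentration cap (default 1e4).
#' @return a list of class `vonmises_mixture` with `mu_deg` (length 2),
#'   `kappa` (length 2), `weight` (length 2, decreasing), `loglik`,
#'   `converged`, `n_iter`, `collapsed`, `n`.
#' @export
vonmises_mixture_fit <- function(angles_deg, restarts = 5, seed = 1,
                                 max_iter = 500, tol = 1e-8, kappa_max = 1e4) {
  n <- length(angles_deg)
  if (n < 8) stop("mixture fit needs n >= 8")
  th <- wrap_angle(angles_deg) / DEG

  run_em <- function(mu0, kappa0, w0) {
    mu <- mu0; kappa <- pmin(kappa0, kappa_max); w <- w0
    ll_old <- -Inf; iter <- 0; converged <- FALSE
    repeat {
      iter <- iter + 1
      ld <- cbind(
        log(w[1]) + vm_logdens(th, mu[1], kappa[1]),
        log(w[2]) + vm_logdens(th, mu[2], kappa[2])
      )
      m <- pmax(ld[, 1], ld[, 2])
      lse <- m + log(exp(ld[, 1] - m) + exp(ld[, 2] - m))
      ll <- sum(lse)
      g <- exp(ld - lse) # responsibilities
      if (ll - ll_old < tol && iter > 1) { converged <- TRUE; break }
      if (iter >= max_iter) break
      ll_old <- ll
      for (j in 1:2) {
        wj <- g[, j]
        swj <- sum(wj)
        C <- sum(wj * cos(th)) / swj
        S <- sum(wj * sin(th)) / swj
        mu[j] <- atan2(S, C)
        kappa[j] <- min(vm_A_inv(sqrt(C^2 + S^2)), kappa_max)
        w[j] <- swj / n
      }
      w <- w / sum(w)
    }
    list(mu = mu, kappa = kappa, w = w, loglik = ll, converged = converged,
         n_iter = iter)
  }

  set.seed(seed)
  best <- NULL
  for (r in seq_len(restarts)) {
    i2 <- sample(n, 2)
    mu0 <- th[i2]
    fit <- run_em(mu0, c(2, 2), c(0.5, 0.5))
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }

  collapsed <- any(best$w < 1 / n)
  if (collapsed) {
    single <- vonmises_fit(angles_deg, bias_correct = FALSE)
    best <- list(
      mu = c(single$mu_deg / DEG, single$mu_deg / DEG),
      kappa = c(single$kappa, single$kappa),
      w = c(1, 0), loglik = single$loglik,
      converged = TRUE, n_iter = 0
    )
  }
  ord <- order(best$w, decreasing = TRUE)
  structure(
    list(
      mu_deg = wrap_angle(best$mu[ord] * DEG),
      kappa = best$kappa[ord],
      weight = best$w[ord],
      loglik = best$loglik,
      converged = best$converged,
      n_iter = best$n_iter,
      collapsed = collapsed,
      n = n
    ),
    class = "vonmises_mixture"
  )
}

#' @export
print.vonmises_mixture <- function(x, ...) {
  cat(sprintf("2-component von Mises mixture (n = %d, loglik = %.3f)\n",
              x$n, x$loglik))
  for (j in 1:2) {
    cat(sprintf("  comp %d: mu = %7.2f deg, kappa = %8.3f, weight = %.3f\n",
                j, x$mu_deg[j], x$kappa[j], x$weight[j]))
  }
  if (x$collapsed) cat("  [collapsed to single component]\n")
  invisible(x)
}

#' Draw from a von Mises distribution
#'
#' Best-Fisher rejection sampler. `kappa = 0` gives the circular uniform.
#'
#' @param n number of draws.
#' @param mu_deg mean direction in degrees.
#' @param kappa concentration >= 0.
#' @return angles in degrees in (-180, 180].
#' @export
rvonmises <- function(n, mu_deg = 0, kappa = 1) {
  stopifnot(kappa >= 0)
  if (kappa == 0) return(wrap_angle(stats::runif(n, -180, 180)))
  if (kappa > 5e5) {
    ## Gaussian limit; the rejection constants overflow at extreme kappa
    return(wrap_angle(mu_deg + stats::rnorm(n, 0, DEG / sqrt(kappa))))
  }
  mu <- mu_deg / DEG
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1
  while (i <= n) {
    u <- stats::runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    if (cc * (2 - cc) - u[2] > 0 || log(cc / u[2]) + 1 - cc >= 0) {
      out[i] <- mu + sign(u[3] - 0.5) * acos(f)
      i <- i + 1
    }
  }
  wrap_angle(out * DEG)
}

#' Flag suspected compass-flip trials
#'
#' The magnetometer of some handsets reports a direction rotated by ~180
#' degrees when pointing strongly downward. Trials with elevation below
#' `elevation_threshold_deg` whose azimuth error lies within
#' `window_deg` of +-180 degrees are flagged as suspect.
#'
#' @param errors_deg signed azimuth errors in degrees.
#' @param elevations_deg elevations in degrees, same length.
#' @param elevation_threshold_deg flag only below this elevation
#'   (default -15).
#' @param window_deg half-width of the window about 180 degrees (default 20).
#' @return logical vector of flags.
#' @export
detect_sensor_flips <- function(errors_deg, elevations_deg,
                                elevation_threshold_deg = -15,
                                window_deg = 20) {
  stopifnot(length(errors_deg) == length(elevations_deg))
  near_180 <- abs(wrap_angle(abs(errors_deg) - 180)) <= window_deg
  (elevations_deg < elevation_threshold_deg) & near_180
}
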