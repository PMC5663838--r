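#' Large-volume nonequilibrium potential
#'
#' In the WKB (eikonal) limit the stationary distribution takes the form
#' \eqn{p(x) = N(x) \exp[-\Omega \Phi(x)]}.  For a one-dimensional
#' birth-death chain the potential derivative is
#' \deqn{\Phi'(x) = \ln\frac{w_{-1}(x) + w_{+2}(x)}{w_{+1}(x) + w_{-2}(x)},}
#' the log-ratio of the total down- and up-rates, which (i) vanishes exactly
#' at the macroscopic fixed points, (ii) is the continuum limit of the exact
#' stationary recursion, and (iii) reduces to the detailed-balance potential
#' at the equilibrium driving b0.  (An often-quoted variant takes the log of
#' net over total rate; that expression vanishes at fixed points inside the
#' log rather than outside and is not a usable potential derivative, so the
#' birth-death form above is used.)  \eqn{\Phi} is computed by adaptive
#' quadrature of \eqn{\Phi'} and anchored to 0 at the smallest stable fixed
#' point; \eqn{\Phi''} is analytic.
#'
#' @param object a \code{\link{schloegl}} model.
#' @param x_grid positive increasing grid covering all fixed points, or
#'   \code{NULL} for an automatic grid.
#' @param n grid size for the automatic grid.
#' @return Object of class \code{"schloegl_wkb"}: \code{x}, \code{phi},
#'   \code{phi_prime}, \code{phi_at_fp}, \code{phi2_at_fp}, the fixed-point
#'   table \code{fp}, and the \code{model}.
#' @export
wkb_potential <- function(object, x_grid = NULL, n = 1501) {
  object <- as_schloegl(object)
  fp <- fixed_points(object)
  if (is.null(x_grid))
    x_grid <- seq(min(1e-3, 0.2 * min(fp$x_star)), 1.4 * max(fp$x_star) + 0.2,
                  length.out = n)
  if (any(diff(x_grid) <= 0) || x_grid[1] <= 0)
    stop("x_grid must be positive and strictly increasing")
  if (x_grid[1] > min(fp$x_star) || x_grid[length(x_grid)] < max(fp$x_star))
    stop("x_grid does not cover all fixed points")
  k <- coef(object)
  phip <- function(x) {
    log((k["k_minus1"] * x + k["k_plus2"] * x^3) /
          (k["k_plus1"] * k["a"] + k["k_minus2"] * k["b"] * x^2))
  }
  quad <- function(lo, hi) {
    if (lo == hi) return(0)
    stats::integrate(phip, lo, hi, rel.tol = 1e-10, abs.tol = 1e-10,
                     subdivisions = 400L)$value
  }
  m <- length(x_grid)
  seg <- vapply(seq_len(m - 1), function(i) quad(x_grid[i], x_grid[i + 1]),
                numeric(1))
  phi <- c(0, cumsum(seg))
  phi_fp <- vapply(fp$x_star, function(xs) quad(x_grid[1], xs), numeric(1))
  x_ref <- min(fp$x_star[fp$stability == "stable"])
  ref <- quad(x_grid[1], x_ref)
  structure(list(x = x_grid, phi = phi - ref, phi_prime = phip(x_grid),
                 phi_at_fp = phi_fp - ref,
                 phi2_at_fp = wkb_phi2(object, fp$x_star),
                 fp = fp, model = object),
            class = "schloegl_wkb")
}

# analytic second derivative of the birth-death WKB potential
wkb_phi2 <- function(object, x) {
  k1a <- object$k_plus1 * object$a
  (object$k_minus1 + 3 * object$k_plus2 * x^2) /
    (object$k_minus1 * x + object$k_plus2 * x^3) -
    (2 * object$k_minus2 * object$b * x) /
      (k1a + object$k_minus2 * object$b * x^2)
}

#' @export
print.schloegl_wkb <- function(x, ...) {
  cat(sprintf("WKB nonequilibrium potential on [%g, %g] (%d points)\n",
              min(x$x), max(x$x), length(x$x)))
  df <- cbind(x$fp, phi = x$phi_at_fp, phi2 = x$phi2_at_fp)
  print(df, digits = 4)
  invisible(x)
}

#' @export
plot.schloegl_wkb <- function(x, ...) {
  graphics::plot(x$x, x$phi, type = "l", xlab = "concentration x",
                 ylab = expression(Phi(x)), main = "WKB potential", ...)
  graphics::points(x$fp$x_star, x$phi_at_fp)
  invisible(x)
}

#' WKB approximation to the stationary distribution
#'
#' Density proportional to \eqn{N(x) \exp[-\Omega \Phi(x)]}.  The default
#' prefactor is the standard birth-death form
#' \eqn{N(x) \propto [(w_{+1}+w_{-2})(w_{-1}+w_{+2})]^{-1/2}}; the
#' \code{"constant"} mode keeps only the exponential (the peak-height
#' approximation \eqn{N(x^*)\exp[-\Omega\Phi(x)]}).
#'
#' @param pot a \code{\link{wkb_potential}} result.
#' @param omega system size (defaults to the model's).
#' @param prefactor \code{"birth-death-standard"} or \code{"constant"}.
#' @param x_max if supplied, return a discrete pmf over X = 0, ..., x_max
#'   (log-density interpolated at X/omega); otherwise a continuous density
#'   normalized on the potential grid.
#' @return list with \code{x}, \code{density} (trapezoid-normalized) when
#'   continuous, or \code{X}, \code{pmf} when discrete.
#' @export
wkb_density <- function(pot, omega = pot$model$omega,
                        prefactor = c("birth-death-standard", "constant"),
                        x_max = NULL) {
  prefactor <- match.arg(prefactor)
  x <- pot$x
  logN <- if (prefactor == "constant") numeric(length(x)) else {
    w <- macroscopic_rates(pot$model, x)
    -0.5 * log((w$w_plus1 + w$w_minus2) * (w$w_minus1 + w$w_plus2))
  }
  logd <- logN - omega * pot$phi
  logd <- logd - max(logd)
  if (is.null(x_max)) {
    d <- exp(logd)
    z <- sum((d[-1] + d[-length(d)]) / 2 * diff(x))
    return(list(x = x, density = d / z, prefactor = prefactor))
  }
  xs <- (0:x_max) / omega
  ld <- stats::approx(x, logd, xout = xs, rule = 1)$y
  p <- exp(ifelse(is.na(ld), -Inf, ld))
  list(X = 0:x_max, pmf = p / sum(p), prefactor = prefactor)
}

#' Gaussian-peak model of the stationary weights
#'
#' Taylor expansion of the potential around each stable fixed point turns the
#' WKB density into a two-Gaussian mixture: peak k is centered at
#' \eqn{x_k^*} with standard deviation \eqn{1/\sqrt{\Omega \Phi''(x_k^*)}} and
#' weight \eqn{N p(x_k^*)}, \eqn{N = [p(x_1^*)+p(x_2^*)]^{-1}} with peak
#' heights read from the WKB density.
#'
#' @param pot a \code{\link{wkb_potential}} result (bistable model).
#' @param omega system size.
#' @param prefactor passed to \code{\link{wkb_density}}.
#' @return Object of class \code{"schloegl_peaks"}: \code{centers},
#'   \code{sds}, \code{weights} (summing to 1), plus a \code{density}
#'   function of x.
#' @export
gaussian_peaks <- function(pot, omega = pot$model$omega,
                           prefactor = "birth-death-standard") {
  st <- pot$fp$stability == "stable"
  if (sum(st) < 2) stop("Gaussian-peak model requires bistable parameters")
  xk <- pot$fp$x_star[st]
  phi2 <- pot$phi2_at_fp[st]
  dens <- wkb_density(pot, omega = omega, prefactor = prefactor)
  hk <- stats::approx(dens$x, dens$density, xout = xk)$y
  wk <- hk / sum(hk)
  sds <- 1 / sqrt(omega * phi2)
  f <- function(x) {
    out <- 0
    for (k in seq_along(xk)) out <- out + wk[k] * stats::dnorm(x, xk[k], sds[k])
    out
  }
  structure(list(centers = xk, sds = sds, weights = wk, density = f,
                 omega = omega, model = pot$model),
            class = "schloegl_peaks")
}

#' @export
print.schloegl_peaks <- function(x, ...) {
  cat("Gaussian-peak model:\n")
  print(data.frame(center = x$centers, sd = x$sds, weight = x$weights),
        digits = 4)
  invisible(x)
}

#' Escape-rate ratio between the two states
#'
#' Kramers-type asymptotics for the ratio of switching rates
#' \eqn{r_{1\to2}/r_{2\to1} =
#' \frac{N(x_2)}{N(x_1)}\sqrt{\Phi''(x_1)/\Phi''(x_2)}
#' \exp\{\Omega[\Phi(x_1) - \Phi(x_2)]\}}:
#' the deeper state (lower \eqn{\Phi}) is exponentially harder to leave, and
#' at stationarity the ratio equals the weight ratio of the two states.  The
#' sign of the exponent is fixed by requiring agreement with the exact
#' mean first-passage times (\code{\link{exact_mfpt}}), for which
#' \eqn{r_{1\to2}/r_{2\to1} = T_{2\to1}/T_{1\to2}}; the growth of the exact
#' ratio with \eqn{\Omega} singles out this orientation.  With
#' \code{prefactor = "curvature-only"} the \eqn{N(x)} ratio is dropped,
#' leaving the bare curvature attempt-frequency factor (correct only up to an
#' \eqn{e^{O(1)}} volume-independent factor).
#'
#' @param pot a \code{\link{wkb_potential}} result (bistable model).
#' @param omega system size.
#' @param prefactor \code{"birth-death-standard"} (include the N(x) ratio) or
#'   \code{"curvature-only"}.
#' @return the rate ratio \eqn{r_{1\to2}/r_{2\to1}} (low to high over high to
#'   low).
#' @export
escape_rate_ratio <- function(pot, omega = pot$model$omega,
                              prefactor = c("birth-death-standard",
                                            "curvature-only")) {
  prefactor <- match.arg(prefactor)
  st <- pot$fp$stability == "stable"
  if (sum(st) < 2) stop("escape-rate ratio requires bistable parameters")
  xk <- pot$fp$x_star[st]
  phi <- pot$phi_at_fp[st]
  phi2 <- pot$phi2_at_fp[st]
  Nratio <- if (prefactor == "curvature-only") 1 else {
    w <- macroscopic_rates(pot$model, xk)
    up <- w$w_plus1 + w$w_minus2
    dn <- w$w_minus1 + w$w_plus2
    sqrt((up[1] * dn[1]) / (up[2] * dn[2]))   # N(x2)/N(x1)
  }
  Nratio * sqrt(phi2[1] / phi2[2]) * exp(omega * (phi[1] - phi[2]))
}

#' Write a WKB potential table to CSV
#'
#' Columns \code{x, phi, phi_prime, phi2} at 17 significant digits.
#'
#' @param pot a \code{\link{wkb_potential}} result.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_potential_csv <- function(pot, path) {
  df <- data.frame(x = trimws(format(pot$x, digits = 17)),
                   phi = trimws(format(pot$phi, digits = 17)),
                   phi_prime = trimws(format(pot$phi_prime, digits = 17)),
                   phi2 = trimws(format(wkb_phi2(pot$model, pot$x), digits = 17)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
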