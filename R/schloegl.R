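#' Define a Schloegl reaction network
#'
#' Constructs a model object for the autocatalytic Schloegl network
#' \deqn{A \rightleftharpoons X, \qquad 3X \rightleftharpoons 2X + B,}
#' in which the reservoir species A and B are held at fixed concentrations
#' \code{a} and \code{b} and drive the intermediate species X out of
#' equilibrium.  The model is the canonical one-species system exhibiting
#' bistability and a first-order nonequilibrium phase transition, and is the
#' test bed used throughout this package for entropy-production state
#' selection.
#'
#' Concentrations are molecule numbers per reaction volume \code{omega}; time
#' is measured in units of the autocatalytic rate constant (\code{k_plus2 = 1}
#' by default), and all entropies are in units of Boltzmann's constant.
#'
#' @param b reservoir concentration of species B (the driving parameter).
#' @param omega reaction volume (dimensionless system size).
#' @param k_plus1,k_minus1 rate constants of \eqn{A \rightleftharpoons X}.
#' @param a reservoir concentration of species A.
#' @param k_plus2,k_minus2 rate constants of \eqn{3X \rightleftharpoons 2X+B}.
#'
#' @return An object of class \code{"schloegl"}: a list with the rate
#'   constants, reservoir concentrations and volume.
#'
#' @examples
#' m <- schloegl(b = 4, omega = 100)
#' summary(m)
#' fixed_points(m)
#' @export
schloegl <- function(b, omega = 100, k_plus1 = 0.5, a = 1,
                     k_minus1 = 3, k_plus2 = 1, k_minus2 = 1) {
  stopifnot(is.numeric(b), length(b) == 1L, is.numeric(omega), length(omega) == 1L)
  if (b < 0 || a < 0) stop("reservoir concentrations must be >= 0")
  if (omega <= 0) stop("omega must be > 0")
  ks <- c(k_plus1 = k_plus1, k_minus1 = k_minus1,
          k_plus2 = k_plus2, k_minus2 = k_minus2)
  if (any(ks < 0)) stop("rate constants must be >= 0")
  structure(list(k_plus1 = unname(k_plus1), a = unname(a),
                 k_minus1 = unname(k_minus1), k_plus2 = unname(k_plus2),
                 k_minus2 = unname(k_minus2), b = unname(b),
                 omega = unname(omega)),
            class = "schloegl")
}

as_schloegl <- function(object) {
  if (!inherits(object, "schloegl")) stop("not a 'schloegl' model object")
  object
}

#' @export
print.schloegl <- function(x, ...) {
  cat("Schloegl reaction network\n")
  cat(sprintf("  A <-> X        k+1*a = %g, k-1 = %g\n", x$k_plus1 * x$a, x$k_minus1))
  cat(sprintf("  3X <-> 2X + B  k+2 = %g, k-2 = %g\n", x$k_plus2, x$k_minus2))
  cat(sprintf("  driving b = %g, volume omega = %g\n", x$b, x$omega))
  invisible(x)
}

#' @export
coef.schloegl <- function(object, ...) {
  unlist(object[c("k_plus1", "a", "k_minus1", "k_plus2", "k_minus2", "b", "omega")])
}

#' Macroscopic reaction rates
#'
#' Mass-action rates of the four reaction channels at concentration \code{x}:
#' \eqn{w_{+1} = k_{+1}a}, \eqn{w_{-1} = k_{-1}x}, \eqn{w_{+2} = k_{+2}x^3},
#' \eqn{w_{-2} = k_{-2}bx^2} (concentration per time).
#'
#' @param object a \code{\link{schloegl}} model.
#' @param x concentration of species X (vectorized, must be >= 0).
#' @param a,b reservoir concentrations; default to the model's values.  They
#'   are arguments so that the flux-constrained dynamics, where the reservoirs
#'   become dynamic variables, can reuse the same rate laws.
#' @return list with components \code{w_plus1}, \code{w_minus1},
#'   \code{w_plus2}, \code{w_minus2}, each the length of \code{x}.
#' @export
macroscopic_rates <- function(object, x, a = object$a, b = object$b) {
  object <- as_schloegl(object)
  if (any(x < 0)) stop("concentration x must be >= 0")
  list(w_plus1  = object$k_plus1 * a + 0 * x,
       w_minus1 = object$k_minus1 * x,
       w_plus2  = object$k_plus2 * x^3,
       w_minus2 = object$k_minus2 * b * x^2)
}

#' Deterministic drift and effective-potential derivatives
#'
#' The macroscopic rate equation is \eqn{dx/dt = w_{+1} - w_{-1} + w_{-2} -
#' w_{+2} = -\Phi'_{ODE}(x)}, the gradient flow of an effective (deterministic)
#' potential.  Returns the drift, \eqn{\Phi'_{ODE}(x) = -dx/dt}, and its
#' analytic derivative \eqn{\Phi''_{ODE}(x) = 3k_{+2}x^2 - 2k_{-2}bx + k_{-1}},
#' the curvature used for stability classification and Gaussian peak widths.
#'
#' @inheritParams macroscopic_rates
#' @return list with components \code{drift}, \code{phi1_ode}, \code{phi2_ode}.
#' @export
ode_drift <- function(object, x, a = object$a, b = object$b) {
  w <- macroscopic_rates(object, x, a = a, b = b)
  drift <- w$w_plus1 - w$w_minus1 + w$w_minus2 - w$w_plus2
  list(drift = drift,
       phi1_ode = -drift,
       phi2_ode = 3 * object$k_plus2 * x^2 - 2 * object$k_minus2 * b * x +
         object$k_minus1)
}

#' Steady states of the macroscopic rate equation
#'
#' Finds all real nonnegative roots of the cubic drift polynomial and
#' classifies their stability from the sign of the potential curvature
#' \eqn{\Phi''_{ODE}}.  In the bistable regime there are three roots
#' (stable, unstable, stable); a near-double root (saddle-node) is classified
#' as \code{"marginal"}.
#'
#' @param object a \code{\link{schloegl}} model.
#' @param b driving concentration (defaults to the model's).
#' @return A data frame of class \code{"schloegl_fp"} with one row per root,
#'   sorted ascending: \code{x_star}, \code{stability} (\code{"stable"},
#'   \code{"unstable"} or \code{"marginal"}), \code{curvature}
#'   (\eqn{\Phi''_{ODE}(x^*)}) and \code{flux} (the steady-state reservoir
#'   flux \eqn{F = w_{+1} - w_{-1}}).
#' @export
fixed_points <- function(object, b = object$b) {
  object <- as_schloegl(object)
  # drift = k1a - km1 x + km2 b x^2 - k2 x^3; ascending coefficients
  co <- c(object$k_plus1 * object$a, -object$k_minus1,
          object$k_minus2 * b, -object$k_plus2)
  if (co[4] == 0) stop("k_plus2 must be > 0 for a cubic rate law")
  z <- polyroot(co)
  keep <- abs(Im(z)) <= 1e-9 * pmax(1, abs(Re(z)))
  x <- sort(pmax(Re(z[keep]), 0))
  # collapse numerically coincident roots (saddle-node)
  if (length(x) > 1) {
    tol <- 1e-7 * max(1, max(x))
    x <- x[c(TRUE, diff(x) > tol)]
  }
  cv <- ode_drift(object, x, b = b)$phi2_ode
  stab <- ifelse(abs(cv) < 1e-7, "marginal", ifelse(cv > 0, "stable", "unstable"))
  w <- macroscopic_rates(object, x, b = b)
  out <- data.frame(x_star = x, stability = stab, curvature = cv,
                    flux = w$w_plus1 - w$w_minus1)
  class(out) <- c("schloegl_fp", "data.frame")
  out
}

#' Bifurcation sweep over the driving parameter
#'
#' Evaluates \code{\link{fixed_points}} and the macroscopic entropy production
#' on a grid of driving concentrations b.  The set of b values with three
#' roots is the bistable window, a single contiguous interval for this model.
#'
#' @param object a \code{\link{schloegl}} model.
#' @param b_grid nonempty vector of driving concentrations (>= 0).
#' @return A data frame with one row per (b, root): columns \code{b},
#'   \code{x_star}, \code{stability}, \code{curvature}, \code{flux} and
#'   \code{dsi_dt} (macroscopic entropy production rate at the root, kB per
#'   volume per time).
#' @export
bifurcation_sweep <- function(object, b_grid) {
  object <- as_schloegl(object)
  if (length(b_grid) == 0) stop("b_grid must be nonempty")
  if (any(b_grid < 0)) stop("b_grid values must be >= 0")
  rows <- lapply(b_grid, function(b) {
    fp <- fixed_points(object, b = b)
    fp$dsi_dt <- vapply(fp$x_star, function(x)
      macroscopic_ep(object, x, b = b)$dsi_dt, numeric(1))
    cbind(b = b, fp)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Detailed-balance (equilibrium) point
#'
#' The unique driving concentration at which every reaction channel
#' individually balances (\eqn{w_{+r} = w_{-r}}): \eqn{x_0 = k_{+1}a/k_{-1}}
#' and \eqn{b_0 = k_{+2}x_0/k_{-2}}.  At \eqn{(x_0, b_0)} the entropy
#' production vanishes; for the default constants \eqn{b_0 = x_0 = 1/6}.
#'
#' @param object a \code{\link{schloegl}} model.
#' @return named numeric vector \code{c(b0, x0)}.
#' @export
equilibrium_point <- function(object) {
  object <- as_schloegl(object)
  if (object$k_minus1 <= 0 || object$k_minus2 <= 0)
    stop("degenerate model: k_minus1 and k_minus2 must be > 0")
  x0 <- object$k_plus1 * object$a / object$k_minus1
  b0 <- object$k_plus2 * x0 / object$k_minus2
  c(b0 = b0, x0 = x0)
}

#' Macroscopic entropy production rate
#'
#' Schnakenberg's formula in the large-volume limit,
#' \deqn{ds_i/dt = \sum_{r=1,2} (w_{+r} - w_{-r}) \ln(w_{+r}/w_{-r}) \ge 0,}
#' in units of kB per volume per time: each summand is a flux times the
#' chemical-potential difference (affinity) of that reaction.  At a fixed
#' point the two channel fluxes are equal to the reservoir flux F, so the
#' rate reduces to \eqn{F[\ln(w_{+1}/w_{-1}) + \ln(w_{+2}/w_{-2})]}.
#'
#' If one rate of a channel vanishes while its partner does not (e.g. at
#' \code{x = 0}), the affinity is infinite; the rate is reported as \code{Inf}
#' with \code{infinite = TRUE} rather than raising, so that sweeps through the
#' boundary do not abort.
#'
#' @inheritParams macroscopic_rates
#' @param x a single concentration.
#' @return list with \code{dsi_dt}, \code{per_reaction} (the two summands),
#'   \code{flux} (\eqn{w_{+1} - w_{-1}}) and logical \code{infinite}.
#' @export
macroscopic_ep <- function(object, x, a = object$a, b = object$b) {
  w <- macroscopic_rates(object, x, a = a, b = b)
  term <- function(wp, wm) {
    if (wp == 0 && wm == 0) return(0)
    if (wp == 0 || wm == 0) return(Inf)
    (wp - wm) * log(wp / wm)
  }
  per <- c(r1 = term(w$w_plus1, w$w_minus1), r2 = term(w$w_plus2, w$w_minus2))
  list(dsi_dt = sum(per), per_reaction = per,
       flux = w$w_plus1 - w$w_minus1, infinite = any(is.infinite(per)))
}

#' @export
summary.schloegl <- function(object, ...) {
  fp <- fixed_points(object)
  eq <- equilibrium_point(object)
  fp$dsi_dt <- vapply(fp$x_star, function(x)
    macroscopic_ep(object, x)$dsi_dt, numeric(1))
  out <- list(model = object, fixed_points = fp, equilibrium = eq,
              bistable = sum(fp$stability == "stable") == 2)
  class(out) <- "summary.schloegl"
  out
}

#' @export
print.summary.schloegl <- function(x, ...) {
  print(x$model)
  cat(sprintf("\nDetailed balance at b0 = %.6g (x0 = %.6g)\n",
              x$equilibrium["b0"], x$equilibrium["x0"]))
  cat(if (x$bistable) "Bistable at this driving.\n" else
    "Monostable at this driving.\n")
  cat("\nMacroscopic steady states:\n")
  print(x$fixed_points, digits = 4)
  invisible(x)
}

#' Read model parameters from a flat config file
#'
#' Accepts YAML (or JSON, a YAML subset) with flat keys \code{k_plus1_a},
#' \code{k_minus1}, \code{k_plus2}, \code{k_minus2}, \code{b}, \code{omega}.
#' \code{k_plus1_a} is the product \eqn{k_{+1}a}; it is stored as
#' \code{k_plus1} with \code{a = 1}.
#'
#' @param path path to the config file.
#' @return a \code{\link{schloegl}} model.
#' @export
read_schloegl_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  need <- c("k_plus1_a", "k_minus1", "k_plus2", "k_minus2", "b", "omega")
  bad <- setdiff(names(cfg), need)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  miss <- setdiff(need, names(cfg))
  if (length(miss)) stop("missing config key(s): ", paste(miss, collapse = ", "))
  schloegl(b = cfg$b, omega = cfg$omega, k_plus1 = cfg$k_plus1_a, a = 1,
           k_minus1 = cfg$k_minus1, k_plus2 = cfg$k_plus2,
           k_minus2 = cfg$k_minus2)
}

#' Write a bifurcation sweep to CSV
#'
#' Columns \code{b, x_star, stability, curvature, flux, dsi_dt}, floats at 17
#' significant digits so the file round-trips exactly.
#'
#' @param sweep result of \code{\link{bifurcation_sweep}}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_sweep_csv <- function(sweep, path) {
  df <- sweep
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) trimws(format(v, digits = 17)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
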