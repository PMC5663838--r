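#' Microscopic transition rates (propensities)
#'
#' Jump rates out of state X on the birth-death chain underlying the Schloegl
#' master equation (events per time, volume \code{omega}):
#' \deqn{W_{+1} = k_{+1} a \Omega, \quad W_{-1} = k_{-1} X,}
#' \deqn{W_{+2} = k_{+2} X(X-1)(X-2)/\Omega^2, \quad
#'       W_{-2} = k_{-2} b X(X-1)/\Omega.}
#' \eqn{W_{+1}} and \eqn{W_{-2}} move X up by one, \eqn{W_{-1}} and
#' \eqn{W_{+2}} move it down; the chain is reflecting at X = 0.  These are the
#' standard combinatorial mass-action propensities, chosen so that
#' \eqn{W_{\pm r}/\Omega} converges to the macroscopic rates
#' \code{\link{macroscopic_rates}} as \eqn{\Omega \to \infty}.
#'
#' @param object a \code{\link{schloegl}} model.
#' @param X vector of molecule numbers (nonnegative integers).
#' @return list with components \code{W_plus1}, \code{W_minus1},
#'   \code{W_plus2}, \code{W_minus2}.
#' @export
propensities <- function(object, X) {
  object <- as_schloegl(object)
  if (any(X < 0)) stop("molecule number X must be >= 0")
  om <- object$omega
  list(W_plus1  = rep(object$k_plus1 * object$a * om, length(X)),
       W_minus1 = object$k_minus1 * X,
       W_plus2  = object$k_plus2 * X * pmax(X - 1, 0) * pmax(X - 2, 0) / om^2,
       W_minus2 = object$k_minus2 * object$b * X * pmax(X - 1, 0) / om)
}

birth_death_rates <- function(object, x_max) {
  W <- propensities(object, 0:x_max)
  list(birth = W$W_plus1 + W$W_minus2,   # X -> X+1
       death = W$W_minus1 + W$W_plus2)   # X -> X-1
}

#' Exact stationary distribution of the master equation
#'
#' For a one-dimensional birth-death chain the stationary probability flux
#' vanishes across every bond, giving the recursion
#' \eqn{[W_{+1} + W_{-2}](X) P(X) = [W_{-1} + W_{+2}](X+1) P(X+1)},
#' solved in log space and normalized.  With \code{x_max = NULL} the
#' truncation starts at \code{max(8 * omega * x_high, 50)} (x_high the largest
#' macroscopic fixed point) and grows geometrically until the pmf tail decays
#' (step ratio < 1/2) and the geometric bound on the discarded mass is below
#' \code{1e-10}; a hard cap of \code{50 * omega} states raises an error.
#'
#' @param object a \code{\link{schloegl}} model.
#' @param x_max truncation bound (molecule count), or \code{NULL} for the
#'   automatic rule.
#' @return Object of class \code{"schloegl_pmf"}: list with \code{X} (0 to
#'   x_max), \code{pmf}, \code{omega}, \code{x_max}, \code{tail_mass_bound}
#'   and the \code{model}.
#' @export
stationary_distribution <- function(object, x_max = NULL) {
  object <- as_schloegl(object)
  x_high <- if (object$k_plus2 > 0) max(fixed_points(object)$x_star)
  else object$k_plus1 * object$a / max(object$k_minus1, .Machine$double.eps)
  auto <- is.null(x_max)
  if (auto) x_max <- max(ceiling(8 * object$omega * max(x_high, 0.1)), 50)
  cap <- ceiling(50 * object$omega) + 50
  repeat {
    bd <- birth_death_rates(object, x_max)
    n <- x_max + 1
    logp <- c(0, cumsum(log(bd$birth[-n]) - log(bd$death[-1])))
    logp <- logp - max(logp)
    p <- exp(logp)
    p <- p / sum(p)
    r <- bd$birth[n] / (object$k_minus1 * (x_max + 1) +
      object$k_plus2 * (x_max + 1) * x_max * (x_max - 1) / object$omega^2)
    tail_bound <- if (r < 1) p[n] * r / (1 - r) else Inf
    if (r < 0.5 && tail_bound < 1e-10) break
    if (!auto) {
      if (!(tail_bound < 1e-6))
        warning("truncation may discard appreciable probability mass (bound ",
                signif(tail_bound, 3), ")")
      break
    }
    if (x_max >= cap)
      stop("no decaying tail found before truncation cap; increase x_max")
    x_max <- min(ceiling(x_max * 1.6), cap)
  }
  structure(list(X = 0:x_max, pmf = p, omega = object$omega, x_max = x_max,
                 tail_mass_bound = tail_bound, model = object),
            class = "schloegl_pmf")
}

#' @export
print.schloegl_pmf <- function(x, ...) {
  cat(sprintf("Stationary pmf: omega = %g, b = %g, %d states, tail bound %.2e\n",
              x$omega, x$model$b, length(x$pmf), x$tail_mass_bound))
  mu <- sum(x$X * x$pmf) / x$omega
  cat(sprintf("  mean concentration <x> = %.5g\n", mu))
  invisible(x)
}

#' @export
plot.schloegl_pmf <- function(x, ...) {
  graphics::plot(x$X / x$omega, x$pmf * x$omega, type = "l",
                 xlab = "concentration x", ylab = "probability density",
                 main = sprintf("stationary distribution (b = %g)", x$model$b), ...)
  invisible(x)
}

#' Generator matrix of the truncated chain
#'
#' Tridiagonal generator G with \code{dP/dt = G P} (columns index the source
#' state), reflecting at both ends of the truncation.
#'
#' @param object a \code{\link{schloegl}} model.
#' @param x_max truncation bound.
#' @return a sparse \code{\link[Matrix]{dgCMatrix}} of dimension
#'   \code{(x_max+1)^2}.
#' @export
generator_matrix <- function(object, x_max) {
  bd <- birth_death_rates(object, x_max)
  n <- x_max + 1
  up <- bd$birth
  up[n] <- 0                      # reflecting at truncation
  dn <- bd$death
  i <- c(seq_len(n),  seq_len(n - 1) + 1L, seq_len(n - 1))
  j <- c(seq_len(n),  seq_len(n - 1),      seq_len(n - 1) + 1L)
  v <- c(-(up + dn),  up[-n],              dn[-1])
  Matrix::sparseMatrix(i = i, j = j, x = v, dims = c(n, n))
}

#' Entropy production and flow rates of a distribution
#'
#' For a probability vector P over the truncated chain, the entropy production
#' rate sums, over every bond and reaction channel, terms of the form
#' \eqn{(f - g)\ln(f/g)} with f and g the forward and backward probability
#' fluxes; it is nonnegative for any P (second law).  The entropy flow rate is
#' the negative sum of the fluxes weighted by the log-ratio of the transition
#' rates alone (the medium-entropy form); at stationarity
#' \eqn{dS_i/dt = -dS_e/dt}.  Both in units of kB per time.
#'
#' Channels with one vanishing flux and a nonvanishing partner contribute an
#' infinite term (infinite affinity); this is reported as \code{Inf}, not an
#' error.
#'
#' @param object a \code{\link{schloegl}} model.
#' @param P normalized probability vector over X = 0, ..., length(P)-1.
#' @return list with \code{dSi_dt} and \code{dSe_dt}.
#' @export
entropy_rates <- function(object, P) {
  if (abs(sum(P) - 1) > 1e-6) stop("P must be normalized")
  P <- pmax(P, 0)
  x_max <- length(P) - 1L
  W <- propensities(object, 0:x_max)
  i <- seq_len(x_max)             # bond: X = i-1  ->  X = i
  # channel 1: up via W+1 out of X=i-1, down via W-1 out of X=i
  f1 <- W$W_plus1[i] * P[i];  g1 <- W$W_minus1[i + 1] * P[i + 1]
  # channel 2: up via W-2 out of X=i-1, down via W+2 out of X=i
  f2 <- W$W_minus2[i] * P[i]; g2 <- W$W_plus2[i + 1] * P[i + 1]
  dsi <- sum(ep_pair_terms(f1, g1)) + sum(ep_pair_terms(f2, g2))
  dse <- -sum(flow_pair_terms(f1, g1, W$W_plus1[i], W$W_minus1[i + 1])) -
    sum(flow_pair_terms(f2, g2, W$W_minus2[i], W$W_plus2[i + 1]))
  list(dSi_dt = dsi, dSe_dt = dse)
}

# (f - g) ln(f/g) per bond-channel pair, with 0 ln 0 := 0.  A pair with one
# vanishing flux is an infinite affinity only when the partner flux is
# appreciable; pairs at the double-underflow floor of the pmf are negligible
# and set to 0 rather than polluting the sum with spurious Inf.
ep_pair_terms <- function(f, g) {
  out <- numeric(length(f))
  both <- f > 0 & g > 0
  out[both] <- (f[both] - g[both]) * log(f[both] / g[both])
  out[xor(f > 0, g > 0) & pmax(f, g) > 1e-250] <- Inf
  out
}

# (f - g) ln(W_up / W_down) per bond-channel pair
flow_pair_terms <- function(f, g, W_up, W_down) {
  out <- numeric(length(f))
  act <- f > 0 | g > 0           # flux present somewhere on the bond
  out[act] <- (f[act] - g[act]) * log(W_up[act] / W_down[act])
  out
}

#' Time-dependent solution of the master equation
#'
#' Integrates \eqn{dP/dt = G P} with a stiff solver (banded Jacobian; the
#' generator is tridiagonal) and records, at each requested time, the Shannon
#' entropy \eqn{S(t) = -\sum_X P \ln P} (internal molecular entropies set to
#' zero), the entropy production and flow rates, and the analytic
#' \eqn{dS/dt = -\sum_X \dot P (\ln P + 1)} for balance checks.
#'
#' @param object a \code{\link{schloegl}} model.
#' @param P0 normalized initial pmf over X = 0, ..., length(P0)-1.
#' @param t_grid increasing vector of output times starting at 0.
#' @param rtol,atol integration tolerances.
#' @return Object of class \code{"schloegl_transient"}: \code{times},
#'   \code{P} (rows = times), \code{S}, \code{dSi_dt}, \code{dSe_dt},
#'   \code{dS_dt}.
#' @export
evolve_distribution <- function(object, P0, t_grid, rtol = 1e-9, atol = 1e-12) {
  object <- as_schloegl(object)
  if (abs(sum(P0) - 1) > 1e-8) stop("P0 must be normalized")
  x_max <- length(P0) - 1L
  G <- generator_matrix(object, x_max)
  n <- x_max + 1L
  # banded Jacobian, band element (i, j) at position (i - j + bandup + 1, j)
  band <- matrix(0, 3, n)
  band[1, 2:n] <- Matrix::diag(G[-n, -1])      # superdiagonal: death rates
  band[2, ] <- Matrix::diag(G)
  band[3, 1:(n - 1)] <- Matrix::diag(G[-1, -n])  # subdiagonal: birth rates
  sol <- deSolve::ode(y = P0, times = t_grid,
                      func = function(t, y, parms) list(as.vector(G %*% y)),
                      jacfunc = function(t, y, parms) band,
                      jactype = "bandusr", bandup = 1, banddown = 1,
                      method = "lsoda", rtol = rtol, atol = atol)
  P <- unname(sol[, -1, drop = FALSE])
  S <- apply(P, 1, function(p) { p <- pmax(p, 0); -sum(p[p > 0] * log(p[p > 0])) })
  rates <- apply(P, 1, function(p) unlist(entropy_rates(object, p / sum(p))))
  dS <- apply(P, 1, function(p) {
    dp <- as.vector(G %*% p)
    p <- pmax(p, 1e-300)
    -sum(dp * (log(p) + 1))
  })
  structure(list(times = sol[, 1], P = P, S = S,
                 dSi_dt = rates["dSi_dt", ], dSe_dt = rates["dSe_dt", ],
                 dS_dt = dS, model = object),
            class = "schloegl_transient")
}

#' @export
print.schloegl_transient <- function(x, ...) {
  cat(sprintf("Master-equation transient: %d states, t in [%g, %g]\n",
              ncol(x$P), min(x$times), max(x$times)))
  cat(sprintf("  final S = %.6g, final dSi/dt = %.6g\n",
              utils::tail(x$S, 1), utils::tail(x$dSi_dt, 1)))
  invisible(x)
}

# locate modes of a pmf: 3-point moving-maximum smoothing, adjacent candidate
# runs collapsed, so single-bin oscillations at small omega do not split peaks
find_pmf_peaks <- function(p) {
  n <- length(p)
  if (n < 3) return(which.max(p))
  left <- c(0, p[-n]); right <- c(p[-1], 0)
  cand <- which(p >= left & p >= right & p > 0)
  if (length(cand) == 0) return(which.max(p))
  runs <- split(cand, cumsum(c(1, diff(cand) > 2)))
  vapply(runs, function(ix) ix[which.max(p[ix])], numeric(1))
}

#' Split a bimodal stationary distribution at the separatrix
#'
#' The separatrix is the interior local minimum of the stationary pmf between
#' the two modes -- the natural boundary between the basins of the low and
#' high states.  Probability weights, mean concentrations and extensive
#' entropy production rates (kB per time) are summed on each side; the
#' separatrix bin and the bond terms crossing it are split half-half between
#' the states, so weights and entropy productions remain exactly additive to
#' the totals.  For a unimodal pmf a single state with weight 1 is returned.
#'
#' @param pmf a \code{\link{stationary_distribution}} result.
#' @param object the model (defaults to the one stored in \code{pmf}).
#' @return Object of class \code{"schloegl_partition"}: \code{separatrix_X},
#'   \code{separatrix_x}, \code{weights}, \code{means}, \code{ep_rates}
#'   (each named low/high), \code{total_ep}, \code{unimodal}.
#' @export
partition_states <- function(pmf, object = pmf$model) {
  p <- pmf$pmf
  om <- pmf$omega
  peaks <- find_pmf_peaks(p)
  peaks <- peaks[order(p[peaks], decreasing = TRUE)]
  # keep metastable peaks however exponentially suppressed, but not artifacts
  # at the underflow floor of the recursion
  peaks <- peaks[p[peaks] > 1e-200 * p[peaks[1]]]
  if (length(peaks) > 2) stop("ambiguous partition: more than two modes")
  total <- entropy_rates(object, p)$dSi_dt
  if (length(peaks) < 2) {
    return(structure(list(separatrix_X = NA_integer_, separatrix_x = NA_real_,
                          weights = c(low = 1), means = c(low = sum(pmf$X * p) / om),
                          ep_rates = c(low = total), total_ep = total,
                          unimodal = TRUE, model = object),
                     class = "schloegl_partition"))
  }
  lo <- min(peaks); hi <- max(peaks)
  s <- lo + which.min(p[lo:hi]) - 1L        # index (1-based) of pmf minimum
  sep_X <- s - 1L
  below <- seq_len(s - 1L); above <- seq.int(s + 1L, length(p))
  w_low <- sum(p[below]) + p[s] / 2
  w_high <- sum(p[above]) + p[s] / 2
  m_low <- (sum(pmf$X[below] * p[below]) + sep_X * p[s] / 2) / w_low / om
  m_high <- (sum(pmf$X[above] * p[above]) + sep_X * p[s] / 2) / w_high / om
  # bond-channel entropy production terms with half-weight on bonds touching
  # the separatrix bin
  x_max <- length(p) - 1L
  W <- propensities(object, 0:x_max)
  i <- seq_len(x_max)
  f1 <- W$W_plus1[i] * p[i];  g1 <- W$W_minus1[i + 1] * p[i + 1]
  f2 <- W$W_minus2[i] * p[i]; g2 <- W$W_plus2[i + 1] * p[i + 1]
  term <- ep_pair_terms(f1, g1) + ep_pair_terms(f2, g2)
  share_low <- ifelse(i <= s - 2L, 1, ifelse(i >= s + 1L, 0, 0.5))
  ep_low <- sum(term * share_low)
  ep_high <- sum(term * (1 - share_low))
  structure(list(separatrix_X = sep_X, separatrix_x = sep_X / om,
                 weights = c(low = w_low, high = w_high),
                 means = c(low = m_low, high = m_high),
                 ep_rates = c(low = ep_low, high = ep_high),
                 total_ep = ep_low + ep_high, unimodal = FALSE, model = object),
            class = "schloegl_partition")
}

#' @export
print.schloegl_partition <- function(x, ...) {
  if (x$unimodal) {
    cat("Unimodal stationary distribution: single state, weight 1\n")
  } else {
    cat(sprintf("Separatrix at X = %d (x = %.4g)\n", x$separatrix_X, x$separatrix_x))
    cat(sprintf("  weights   low %.4g / high %.4g\n", x$weights["low"], x$weights["high"]))
    cat(sprintf("  EP (kB/t) low %.4g / high %.4g\n", x$ep_rates["low"], x$ep_rates["high"]))
  }
  invisible(x)
}

#' Per-state entropy production from the delta-peak approximation
#'
#' Approximates each stationary peak by a delta function at the macroscopic
#' fixed point, so the extensive entropy production of state k becomes
#' \eqn{dS_{i,k}/dt = N p(x_k^*) \Omega \; ds_{i,k}/dt}, with
#' \eqn{ds_{i,k}/dt} the macroscopic rate (\code{\link{macroscopic_ep}}),
#' peak heights read from the exact pmf at the fixed points, and
#' \eqn{N = [p(x_1^*) + p(x_2^*)]^{-1}}.
#'
#' @param object a \code{\link{schloegl}} model (must be bistable).
#' @param pmf a \code{\link{stationary_distribution}} result.
#' @param fp optional precomputed \code{\link{fixed_points}}.
#' @return named vector \code{c(low, high)} of extensive EP rates (kB/time).
#' @export
state_ep_delta_approx <- function(object, pmf, fp = fixed_points(object)) {
  st <- fp[fp$stability == "stable", ]
  if (nrow(st) < 2) stop("delta-peak approximation requires bistable parameters")
  Xk <- round(object$omega * st$x_star)
  h <- pmf$pmf[pmin(Xk, pmf$x_max) + 1L]
  N <- 1 / sum(h)
  dsk <- vapply(st$x_star, function(x) macroscopic_ep(object, x)$dsi_dt, numeric(1))
  out <- N * h * object$omega * dsk
  names(out) <- c("low", "high")
  out
}

#' Critical driving strength of the first-order transition
#'
#' Bisection for the b value at which the exact stationary distribution
#' carries equal probability weight on the two sides of the separatrix: the
#' finite-volume analogue of the first-order phase transition point.  Also
#' locates the nearby b at which the two per-state extensive entropy
#' production rates cross; the two need not coincide exactly.
#'
#' @param object a \code{\link{schloegl}} model (its b is ignored).
#' @param bracket interval of b values, inside the bistable window, with a
#'   weight-ordering change.
#' @param tol bisection tolerance on b.
#' @return list with \code{b_c} (weight crossing), \code{b_c_ep} (EP
#'   crossing, \code{NA} if absent in the bracket) and \code{omega}.
#' @export
critical_b <- function(object, bracket = c(3.4, 3.9), tol = 1e-4) {
  object <- as_schloegl(object)
  part_at <- function(b) {
    m <- object; m$b <- b
    partition_states(stationary_distribution(m))
  }
  dw <- function(b) {
    pt <- part_at(b)
    if (pt$unimodal) stop("bracket not inside the bistable window (b = ", b, ")")
    pt$weights["low"] - pt$weights["high"]
  }
  f_lo <- dw(bracket[1]); f_hi <- dw(bracket[2])
  if (sign(f_lo) == sign(f_hi))
    stop("no weight-ordering change in bracket [", bracket[1], ", ", bracket[2], "]")
  b_c <- stats::uniroot(dw, bracket, f.lower = f_lo, f.upper = f_hi, tol = tol)$root
  de <- function(b) {
    pt <- part_at(b)
    pt$ep_rates["low"] - pt$ep_rates["high"]
  }
  e_lo <- de(bracket[1]); e_hi <- de(bracket[2])
  b_c_ep <- if (sign(e_lo) != sign(e_hi))
    stats::uniroot(de, bracket, f.lower = e_lo, f.upper = e_hi, tol = tol)$root
  else NA_real_
  list(b_c = unname(b_c), b_c_ep = unname(b_c_ep), omega = object$omega)
}

#' Exact mean first-passage time on the chain
#'
#' MFPT between two molecule numbers via the standard nested-sum solution of
#' the birth-death first-passage problem (reflecting at 0 and, for downward
#' passages, at the truncation bound).  Serves as the exact reference for the
#' WKB escape-rate asymptotics.
#'
#' @param object a \code{\link{schloegl}} model.
#' @param from_X,to_X distinct molecule numbers.
#' @param x_max truncation for downward passages; defaults to the stationary
#'   auto rule.
#' @return the mean first-passage time.
#' @export
exact_mfpt <- function(object, from_X, to_X, x_max = NULL) {
  object <- as_schloegl(object)
  if (from_X == to_X) stop("from_X and to_X must differ")
  if (is.null(x_max)) x_max <- stationary_distribution(object)$x_max
  x_max <- max(x_max, from_X, to_X)
  bd <- birth_death_rates(object, x_max)
  B <- bd$birth; D <- bd$death      # index X+1 holds state X
  if (to_X > from_X) {
    # T(z -> z+1) = 1/B(z) + D(z)/B(z) T(z-1 -> z), reflecting at 0
    Tup <- 0
    total <- 0
    for (z in 0:(to_X - 1)) {
      if (B[z + 1] <= 0) stop("target unreachable: zero birth rate at X = ", z)
      Tup <- 1 / B[z + 1] + if (z > 0) D[z + 1] / B[z + 1] * Tup else 0
      if (z >= from_X) total <- total + Tup
    }
  } else {
    # T(z -> z-1) = 1/D(z) + B(z)/D(z) T(z+1 -> z), reflecting at x_max
    Tdn <- 0
    total <- 0
    for (z in x_max:(to_X + 1)) {
      if (D[z + 1] <= 0) stop("target unreachable: zero death rate at X = ", z)
      Tdn <- 1 / D[z + 1] + if (z < x_max) B[z + 1] / D[z + 1] * Tdn else 0
      if (z <= from_X) total <- total + Tdn
    }
  }
  total
}

#' Write a stationary pmf to CSV
#'
#' Columns \code{X, x, P} at 17 significant digits.
#'
#' @param pmf a \code{\link{stationary_distribution}} result.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_pmf_csv <- function(pmf, path) {
  df <- data.frame(X = pmf$X,
                   x = trimws(format(pmf$X / pmf$omega, digits = 17)),
                   P = trimws(format(pmf$pmf, digits = 17)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
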