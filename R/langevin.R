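#' @rdname simulate_langevin
#' @export
langevin_target <- function(object, state = c("high", "low"), F = NULL) {
  object <- as_schloegl(object)
  state <- match.arg(state)
  fp <- fixed_points(object)
  st <- fp[fp$stability == "stable", ]
  if (nrow(st) == 0) stop("no stable fixed point")
  xs <- if (state == "low") min(st$x_star) else max(st$x_star)
  w <- macroscopic_rates(object, xs)
  if (is.null(F)) F <- w$w_plus1 - w$w_minus1
  gstar <- c(a = w$w_plus1 + w$w_minus1, b = w$w_plus2 + w$w_minus2)
  gstar["x"] <- gstar["a"] + gstar["b"]
  # the dynamics conserve x + a + b exactly (drift and noise both sum to 0),
  # so stability lives in the 2D (a, b) reduction on the conservation shell
  k1 <- object$k_plus1; km1 <- object$k_minus1
  k2 <- object$k_plus2; km2 <- object$k_minus2
  C <- xs + object$a + object$b
  fa <- function(a, b) { x <- C - a - b; km1 * x - k1 * a + F }
  fb <- function(a, b) { x <- C - a - b; k2 * x^3 - km2 * b * x^2 - F }
  h <- 1e-7; a0 <- object$a; b0 <- object$b
  J <- matrix(c((fa(a0 + h, b0) - fa(a0 - h, b0)) / (2 * h),
                (fa(a0, b0 + h) - fa(a0, b0 - h)) / (2 * h),
                (fb(a0 + h, b0) - fb(a0 - h, b0)) / (2 * h),
                (fb(a0, b0 + h) - fb(a0, b0 - h)) / (2 * h)),
              2, 2, byrow = TRUE)
  ev <- Re(eigen(J, only.values = TRUE)$values)
  stable <- ev[ev < 0]
  relax <- if (length(stable)) 1 / min(abs(stable)) else Inf
  lambda <- max(0, max(ev))
  list(x_star = xs, F = F, gstar = gstar, relax = relax,
       lambda_unstable = lambda, state = state)
}

# vectorized Euler-Maruyama integrator for the flux-constrained three-variable
# Langevin system; optionally records full paths and noise increments, and
# always accumulates the midpoint (Stratonovich) functionals used by the
# action and entropy-production estimators past burn_in
langevin_engine <- function(object, x0, a0, b0, F, gstar, eps, dt, n_steps,
                            n_paths, burn_in_steps = 0L, record = FALSE,
                            record_noise = FALSE, checkpoints = integer(0)) {
  k1 <- object$k_plus1; km1 <- object$k_minus1
  k2 <- object$k_plus2; km2 <- object$k_minus2
  ga <- gstar[["a"]]; gb <- gstar[["b"]]
  sqa <- sqrt(eps * ga * dt); sqb <- sqrt(eps * gb * dt)
  x <- rep(x0, n_paths); a <- rep(a0, n_paths); bb <- rep(b0, n_paths)
  if (record) {
    xm <- matrix(NA_real_, n_steps + 1, n_paths); am <- xm; bm <- xm
    xm[1, ] <- x; am[1, ] <- a; bm[1, ] <- bb
  }
  if (record_noise) {
    ea <- matrix(NA_real_, n_steps, n_paths); eb <- ea; ex <- ea
  }
  zero <- numeric(n_paths)
  acc <- list(adot_phia = zero, bdot_phib = zero, xdot_phix = zero,
              qdot2 = list(x = zero, a = zero, b = zero),
              phiF2 = list(x = zero, a = zero, b = zero),
              schnak = zero, mean_x = zero, n = 0L, n_reflect = 0L)
  ds_run <- zero
  cp <- matrix(NA_real_, length(checkpoints), n_paths)
  om <- 1 / eps
  for (s in seq_len(n_steps)) {
    wp1 <- k1 * a; wm1 <- km1 * x; wp2 <- k2 * x^3; wm2 <- km2 * bb * x^2
    dx <- (wp1 - wm1 + wm2 - wp2) * dt
    da <- (-(wp1 - wm1) + F) * dt
    db <- (-(wm2 - wp2) - F) * dt
    na <- sqa * stats::rnorm(n_paths)
    nb <- sqb * stats::rnorm(n_paths)
    nx <- -(na + nb)
    x1 <- x + dx + nx; a1 <- a + da + na; b1 <- bb + db + nb
    refl <- (x1 < 0) | (a1 < 0) | (b1 < 0)
    if (any(refl)) {
      acc$n_reflect <- acc$n_reflect + sum(refl)
      x1 <- abs(x1); a1 <- abs(a1); b1 <- abs(b1)
    }
    if (any(!is.finite(x1)))
      stop("integration blow-up: decrease dt or increase omega")
    if (s > burn_in_steps) {
      xmid <- (x + x1) / 2; amid <- (a + a1) / 2; bmid <- (bb + b1) / 2
      wp1m <- k1 * amid; wm1m <- km1 * xmid
      wp2m <- k2 * xmid^3; wm2m <- km2 * bmid * xmid^2
      phia <- wp1m - wm1m
      phib <- wm2m - wp2m
      phix <- -(wp1m - wm1m + wm2m - wp2m)
      xdot <- (x1 - x) / dt; adot <- (a1 - a) / dt; bdot <- (b1 - bb) / dt
      acc$adot_phia <- acc$adot_phia + adot * phia
      acc$bdot_phib <- acc$bdot_phib + bdot * phib
      acc$xdot_phix <- acc$xdot_phix + xdot * phix
      acc$qdot2$x <- acc$qdot2$x + xdot^2
      acc$qdot2$a <- acc$qdot2$a + adot^2
      acc$qdot2$b <- acc$qdot2$b + bdot^2
      acc$phiF2$x <- acc$phiF2$x + phix^2
      acc$phiF2$a <- acc$phiF2$a + (phia - F)^2
      acc$phiF2$b <- acc$phiF2$b + (phib + F)^2
      acc$schnak <- acc$schnak +
        (wp1m - wm1m) * log(wp1m / wm1m) + (wp2m - wm2m) * log(wp2m / wm2m)
      acc$mean_x <- acc$mean_x + xmid
      acc$n <- acc$n + 1L
      ds_run <- ds_run -
        2 * om * dt * (adot * phia / ga + bdot * phib / gb)
    }
    x <- x1; a <- a1; bb <- b1
    if (record) { xm[s + 1, ] <- x; am[s + 1, ] <- a; bm[s + 1, ] <- bb }
    if (record_noise) { ea[s, ] <- na; eb[s, ] <- nb; ex[s, ] <- nx }
    hit <- which(checkpoints == s)
    if (length(hit)) cp[hit, ] <- ds_run
  }
  out <- list(acc = acc, ds = ds_run, checkpoints = cp,
              final = list(x = x, a = a, b = bb))
  if (record) out <- c(out, list(x = xm, a = am, b = bm))
  if (record_noise) out <- c(out, list(eta_a = ea, eta_b = eb, eta_x = ex))
  out
}

#' Flux-constrained Langevin dynamics
#'
#' Simulates the three-variable Langevin extension of the Schloegl network in
#' which the reservoir concentrations a and b become dynamic and a constant
#' imposed flux F maintains them, driving x out of equilibrium:
#' \deqn{\dot x = w_{+1} - w_{-1} + w_{-2} - w_{+2} + \eta_x,\quad
#'       \dot a = -(w_{+1}-w_{-1}) + F + \eta_a,\quad
#'       \dot b = -(w_{-2}-w_{+2}) - F + \eta_b,}
#' with additive noise of variance \eqn{\varepsilon g_q^*} per unit time
#' (amplitude \eqn{\sqrt{\varepsilon g_q^*}}; effective temperatures
#' \eqn{g_a^* = w_{+1}+w_{-1}}, \eqn{g_b^* = w_{+2}+w_{-2}}, frozen at the
#' target steady state, \eqn{\varepsilon = 1/\Omega}) and
#' \eqn{\eta_x = -(\eta_a + \eta_b)}: the noise in x only reflects the
#' reservoir noises, so noise is not double counted, and the variances add
#' exactly, \eqn{g_x^* = g_a^* + g_b^*}.  Integration is Euler-Maruyama; negative excursions are reflected
#' at 0 and counted (a run with more than 0.1\% reflected steps warns that the
#' additive-noise approximation is breaking down).
#'
#' By default F is pinned to the target state's steady flux
#' \eqn{F = w_{+1}(x^*) - w_{-1}(x^*)}, making \eqn{(x^*, a, b)} a fixed point
#' of the noiseless dynamics.
#'
#' @param object a \code{\link{schloegl}} model.
#' @param state \code{"high"} or \code{"low"}: which stable state to prepare.
#' @param F imposed flux; default the target state's steady flux.
#' @param eps noise strength (default \code{1/omega}).
#' @param dt Euler-Maruyama step.
#' @param t_max duration.
#' @param seed optional integer seed.
#' @param n_paths number of simultaneous paths (vectorized).
#' @param record_noise also store the per-step noise increments.
#' @return Object of class \code{"schloegl_path"}: matrices \code{x},
#'   \code{a}, \code{b} of dimension (steps+1) x n_paths, \code{times},
#'   \code{dt}, \code{eps}, \code{F}, \code{gstar}, \code{n_reflect}, target
#'   info, and optionally \code{eta_a}, \code{eta_b}, \code{eta_x}.
#' @export
simulate_langevin <- function(object, state = c("high", "low"), F = NULL,
                              eps = 1 / object$omega, dt = 1e-3, t_max,
                              seed = NULL, n_paths = 1, record_noise = FALSE) {
  object <- as_schloegl(object)
  tg <- langevin_target(object, state, F = F)
  if (!is.null(seed)) set.seed(seed)
  n_steps <- round(t_max / dt)
  eng <- langevin_engine(object, tg$x_star, object$a, object$b, tg$F,
                         tg$gstar, eps, dt, n_steps, n_paths,
                         record = TRUE, record_noise = record_noise)
  frac <- eng$acc$n_reflect / (n_steps * n_paths)
  if (frac > 1e-3)
    warning(sprintf("%.2f%% of steps reflected at 0: additive noise unreliable, increase omega", 100 * frac))
  structure(list(times = seq(0, n_steps) * dt, x = eng$x, a = eng$a, b = eng$b,
                 dt = dt, eps = eps, F = tg$F, gstar = tg$gstar,
                 x_star = tg$x_star, state = tg$state,
                 n_reflect = eng$acc$n_reflect, seed = seed, model = object,
                 eta_a = eng$eta_a, eta_b = eng$eta_b, eta_x = eng$eta_x),
            class = "schloegl_path")
}

#' @export
print.schloegl_path <- function(x, ...) {
  cat(sprintf("Langevin path(s): %d x %d steps, dt = %g, eps = %g, %s state (x* = %.4g)\n",
              ncol(x$x), nrow(x$x) - 1, x$dt, x$eps, x$state, x$x_star))
  cat(sprintf("  F = %.5g; reflected steps: %d\n", x$F, x$n_reflect))
  invisible(x)
}

# midpoint (Stratonovich) per-step quantities of a recorded path matrix
path_midpoints <- function(path, object) {
  k1 <- object$k_plus1; km1 <- object$k_minus1
  k2 <- object$k_plus2; km2 <- object$k_minus2
  n <- nrow(path$x)
  up <- 2:n; lo <- 1:(n - 1)
  xm <- (path$x[up, , drop = FALSE] + path$x[lo, , drop = FALSE]) / 2
  am <- (path$a[up, , drop = FALSE] + path$a[lo, , drop = FALSE]) / 2
  bm <- (path$b[up, , drop = FALSE] + path$b[lo, , drop = FALSE]) / 2
  wp1 <- k1 * am; wm1 <- km1 * xm; wp2 <- k2 * xm^3; wm2 <- km2 * bm * xm^2
  list(xdot = (path$x[up, , drop = FALSE] - path$x[lo, , drop = FALSE]) / path$dt,
       adot = (path$a[up, , drop = FALSE] - path$a[lo, , drop = FALSE]) / path$dt,
       bdot = (path$b[up, , drop = FALSE] - path$b[lo, , drop = FALSE]) / path$dt,
       phix = -(wp1 - wm1 + wm2 - wp2),
       phia = wp1 - wm1,
       phib = wm2 - wp2,
       phi2x = 3 * k2 * xm^2 - 2 * km2 * bm * xm + km1,
       phi2a = matrix(k1, nrow(xm), ncol(xm)),
       phi2b = km2 * xm^2,
       wp1 = wp1, wm1 = wm1, wp2 = wp2, wm2 = wm2)
}

#' Onsager-Machlup action of a Langevin path
#'
#' Discretizes the stochastic action of the flux-constrained Langevin system
#' with the midpoint (Stratonovich-consistent) rule:
#' \deqn{A = \int dt \Big\{ \frac{\Omega}{2}\sum_q
#'   \frac{[\dot q + \Phi'_{ODE}(q) - F\sigma_q]^2}{g_q^*}
#'   - \frac{1}{2}\sum_q \Phi''_{ODE}(q) \Big\},}
#' \eqn{\sigma_a = 1, \sigma_b = -1, \sigma_x = 0}, and returns its
#' decomposition into a kinetic-minus-potential term, an entropy-production
#' cross term \eqn{\Omega \sum_q \dot q\,\Phi'(q)/g_q^*} (entering with a
#' negative contribution to the trajectory weight: trajectories maximize it),
#' a noise/curvature term, and the \eqn{-\Omega F \sigma_q \dot q/g_q^*}
#' cross term that time-averages to zero on stationary paths.  The total is
#' the exact sum of the four parts.
#'
#' @param path a \code{\link{simulate_langevin}} result.
#' @param object the model (defaults to the path's).
#' @return Object of class \code{"schloegl_action"}: per-path vectors
#'   \code{total}, \code{kin_pot}, \code{ep_term}, \code{noise_term},
#'   \code{fdot_term}.
#' @export
path_action <- function(path, object = path$model) {
  md <- path_midpoints(path, object)
  om <- 1 / path$eps
  g2 <- path$gstar          # noise variance per unit time is eps * gstar
  dt <- path$dt
  sumdt <- function(m) colSums(m) * dt
  kin_pot <- om * (sumdt(md$xdot^2 + md$phix^2) / (2 * g2[["x"]]) +
                   sumdt(md$adot^2 + (md$phia - path$F)^2) / (2 * g2[["a"]]) +
                   sumdt(md$bdot^2 + (md$phib + path$F)^2) / (2 * g2[["b"]]))
  ep_term <- om * (sumdt(md$xdot * md$phix) / g2[["x"]] +
                   sumdt(md$adot * md$phia) / g2[["a"]] +
                   sumdt(md$bdot * md$phib) / g2[["b"]])
  noise_term <- -0.5 * sumdt(md$phi2x + md$phi2a + md$phi2b)
  fdot_term <- -om * path$F * (sumdt(md$adot) / g2[["a"]] -
                               sumdt(md$bdot) / g2[["b"]])
  structure(list(total = kin_pot + ep_term + noise_term + fdot_term,
                 kin_pot = kin_pot, ep_term = ep_term,
                 noise_term = noise_term, fdot_term = fdot_term),
            class = "schloegl_action")
}

#' @export
print.schloegl_action <- function(x, ...) {
  cat("Onsager-Machlup action (per path):\n")
  print(data.frame(total = x$total, kin_pot = x$kin_pot, ep = x$ep_term,
                   noise = x$noise_term, f_cross = x$fdot_term), digits = 5)
  invisible(x)
}

#' Trajectory entropy production from the Langevin action
#'
#' The difference between backward and forward actions reduces to
#' \deqn{\Delta S_\Gamma = -2\Omega t \Big[
#'   \frac{\overline{\dot a\,\Phi'_{ODE}(a)}}{g_a^*} +
#'   \frac{\overline{\dot b\,\Phi'_{ODE}(b)}}{g_b^*} \Big],}
#' with time averages over the duration (the x term averages to zero at
#' stationarity and is excluded by construction).  Products are evaluated at
#' midpoints (Stratonovich).
#'
#' @param path a \code{\link{simulate_langevin}} result.
#' @param object the model (defaults to the path's).
#' @param burn_in initial time span to discard (must be < duration).
#' @return per-path vector of \eqn{\Delta S_\Gamma} (kB).
#' @export
path_entropy_production <- function(path, object = path$model, burn_in = 0) {
  t_max <- utils::tail(path$times, 1)
  if (burn_in >= t_max) stop("burn_in must be smaller than the duration")
  md <- path_midpoints(path, object)
  keep <- (path$times[-1] > burn_in)
  om <- 1 / path$eps
  g2 <- path$gstar
  dt <- path$dt
  -2 * om * dt * (colSums(md$adot[keep, , drop = FALSE] *
                            md$phia[keep, , drop = FALSE]) / g2[["a"]] +
                  colSums(md$bdot[keep, , drop = FALSE] *
                            md$phib[keep, , drop = FALSE]) / g2[["b"]])
}

#' Memory-light ensemble of Langevin entropy productions
#'
#' Runs \code{n_paths} paths without storing them, accumulating the
#' trajectory entropy production online (optionally at intermediate
#' checkpoint times, for growth-in-t diagnostics).  Burn-in defaults to 5
#' linearized relaxation times of the target state.
#'
#' @inheritParams simulate_langevin
#' @param burn_in burn-in time before accumulation starts.
#' @param checkpoint_times times (past burn-in) at which the running entropy
#'   production is recorded.
#' @return list with per-path \code{ds} (at t_max), matrix \code{checkpoints}
#'   (rows = checkpoint times), \code{burn_in}, \code{t_eff} (accumulation
#'   span) and the target info.
#' @export
langevin_ep_ensemble <- function(object, state = c("high", "low"), F = NULL,
                                 eps = 1 / object$omega, dt = 1e-3, t_max,
                                 n_paths = 100, seed = NULL, burn_in = NULL,
                                 checkpoint_times = numeric(0)) {
  object <- as_schloegl(object)
  tg <- langevin_target(object, state, F = F)
  if (is.null(burn_in)) burn_in <- 5 * tg$relax
  if (burn_in >= t_max) stop("t_max must exceed the burn-in (", signif(burn_in, 3), ")")
  if (!is.null(seed)) set.seed(seed)
  n_steps <- round(t_max / dt)
  bsteps <- round(burn_in / dt)
  cps <- pmin(pmax(round(checkpoint_times / dt), bsteps + 1L), n_steps)
  eng <- langevin_engine(object, tg$x_star, object$a, object$b, tg$F,
                         tg$gstar, eps, dt, n_steps, n_paths,
                         burn_in_steps = bsteps, checkpoints = cps)
  list(ds = eng$ds, checkpoints = eng$checkpoints,
       checkpoint_times = cps * dt, burn_in = bsteps * dt,
       t_eff = (n_steps - bsteps) * dt, target = tg,
       mean_x = eng$acc$mean_x / max(eng$acc$n, 1),
       n_reflect = eng$acc$n_reflect)
}

#' Steady-state weight terms of the trajectory ensemble
#'
#' Evaluates, separately for ensembles prepared in each basin at the same
#' driving, the two leading terms that control the steady-state weight
#' \eqn{p(x^*)} of a state in the trajectory picture: the classical-action
#' term \eqn{\sum_q [\langle \dot q^2\rangle + \langle(\Phi'_{ODE}(q) -
#' F\sigma_q)^2\rangle]/(2 g_q^*)} and the Schnakenberg
#' entropy-production term \eqn{\frac12 \sum_r \langle (w_{+r}-w_{-r})
#' \ln(w_{+r}/w_{-r}) \rangle}, which enters the weight with a positive sign:
#' the state with the larger entropy-production term is favored, all else
#' being equal.
#'
#' A mixed-basin ensemble (paths whose time-averaged x falls on opposite
#' sides of the unstable fixed point) is rejected.
#'
#' @inheritParams langevin_ep_ensemble
#' @param states which basins to evaluate.  \code{t_max = NULL} means
#'   burn-in plus 30 time units of accumulation per state.
#' @return data frame of class \code{"schloegl_weight_terms"}, one row per
#'   state: \code{class_action}, \code{ep_term}, \code{mean_x}, \code{F};
#'   attribute \code{max_ep_state}.
#' @export
weight_terms <- function(object, t_max = NULL, dt = 1e-3,
                         eps = 1 / object$omega, n_paths = 50, seed = NULL,
                         burn_in = NULL, states = c("low", "high")) {
  object <- as_schloegl(object)
  fp <- fixed_points(object)
  x_unst <- if (any(fp$stability == "unstable"))
    fp$x_star[fp$stability == "unstable"][1] else NA_real_
  if (!is.null(seed)) set.seed(seed)
  rows <- lapply(states, function(st) {
    tg <- langevin_target(object, st)
    bi <- if (is.null(burn_in)) 5 * tg$relax else burn_in
    # a flux-constrained saddle (the low state under driving) admits only a
    # quasi-stationary ensemble: accumulate before the unstable mode grows
    acc_span <- if (tg$lambda_unstable > 0)
      min(30, 0.7 / tg$lambda_unstable) else 30
    tm <- if (is.null(t_max)) bi + acc_span else t_max
    n_steps <- round(tm / dt)
    bsteps <- round(bi / dt)
    if (bsteps >= n_steps) stop("t_max must exceed the burn-in")
    eng <- langevin_engine(object, tg$x_star, object$a, object$b, tg$F,
                           tg$gstar, eps, dt, n_steps, n_paths,
                           burn_in_steps = bsteps)
    n <- eng$acc$n
    mx <- eng$acc$mean_x / n
    if (!is.na(x_unst)) {
      side <- sign(mx - x_unst)
      if (length(unique(side)) > 1)
        stop("mixed-basin ensemble: paths crossed the separatrix, shorten t_max or increase omega")
    }
    g2 <- tg$gstar
    ca <- (mean(eng$acc$qdot2$x / n) + mean(eng$acc$phiF2$x / n)) / (2 * g2[["x"]]) +
      (mean(eng$acc$qdot2$a / n) + mean(eng$acc$phiF2$a / n)) / (2 * g2[["a"]]) +
      (mean(eng$acc$qdot2$b / n) + mean(eng$acc$phiF2$b / n)) / (2 * g2[["b"]])
    data.frame(state = st, class_action = ca,
               ep_term = 0.5 * mean(eng$acc$schnak / n),
               mean_x = mean(mx), F = tg$F)
  })
  out <- do.call(rbind, rows)
  attr(out, "max_ep_state") <- out$state[which.max(out$ep_term)]
  class(out) <- c("schloegl_weight_terms", "data.frame")
  out
}
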