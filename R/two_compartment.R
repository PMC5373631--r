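#' Parameters for the two-compartment foot-process model
#'
#' Splits the foot-process pool into two fractions that share a single,
#' instantly mixed monomer pool (G-actin is assumed to diffuse infinitely
#' fast). Compartment 1 keeps the baseline positive feedback `alpha_f`;
#' compartment 2 receives an increment `delta_alpha_f` (sustained) or a
#' transient stimulus.
#'
#' @param base a [kinetic_params()] object.
#' @param frac_fp2 volume fraction of the FP pool in compartment 2 (0..1).
#' @param delta_alpha_f sustained additive increment to `alpha_f` in
#'   compartment 2.
#' @return A `two_compartment_params` object.
#' @export
two_compartment_params <- function(base = kinetic_params(), frac_fp2 = 0.5,
                                   delta_alpha_f = 0) {
  if (frac_fp2 <= 0 || frac_fp2 >= 1)
    stop("'frac_fp2' must be strictly between 0 and 1")
  if (delta_alpha_f < 0) stop("'delta_alpha_f' must be >= 0")
  structure(list(base = base, frac_fp2 = frac_fp2,
                 delta_alpha_f = delta_alpha_f),
            class = "two_compartment_params")
}

#' Transient stimulus protocol for the two-compartment model
#'
#' A pulse rises linearly from `t0` over `t_rise` to its peak relative
#' `amplitude` and then decays exponentially with time constant `tau`; a
#' step stays at `amplitude` from `t0` on. The stimulated rate in
#' compartment 2 is `alpha_f * (1 + amplitude * shape(t))`, so
#' `amplitude = 1` means the stimulated compartment transiently reaches
#' twice the baseline feedback.
#'
#' @param amplitude peak relative amplitude (`delta_alpha_f / alpha_f`).
#' @param shape `"pulse"` or `"step"`.
#' @param t0 onset time (default 40).
#' @param t_rise linear rise time.
#' @param tau exponential decay constant.
#' @param param stimulated parameter (only `"alpha_f"` is meaningful here).
#' @return A `stimulus_protocol` object.
#' @export
stimulus_protocol <- function(amplitude, shape = c("pulse", "step"),
                              t0 = 40, t_rise = 60, tau = 10,
                              param = "alpha_f") {
  shape <- match.arg(shape)
  if (amplitude < 0) stop("'amplitude' must be non-negative")
  structure(list(amplitude = amplitude, shape = shape, t0 = t0,
                 t_rise = t_rise, tau = tau, param = param),
            class = "stimulus_protocol")
}

# relative stimulus value at time t (0 = baseline)
stimulus_value <- function(proto, t) {
  if (is.null(proto)) return(0)
  if (proto$shape == "step") return(ifelse(t < proto$t0, 0, proto$amplitude))
  if (t <= proto$t0) return(0)
  if (t <= proto$t0 + proto$t_rise)
    return(proto$amplitude * (t - proto$t0) / proto$t_rise)
  proto$amplitude * exp(-(t - (proto$t0 + proto$t_rise)) / proto$tau)
}

#' Right-hand side of the two-compartment model
#'
#' Each compartment follows the single-compartment kinetics with its own
#' feedback rate; the shared monomer pool is fixed by conservation across
#' both fractions:
#' `Ga = total_actin - phi_fp * (frac_fp1*(Fa1+Bu1) + frac_fp2*(Fa2+Bu2))`.
#'
#' @param state numeric vector `c(Fa1, Bu1, Fa2, Bu2)`.
#' @param p2 a [two_compartment_params()] object.
#' @param t time (used to evaluate a transient stimulus).
#' @param protocol optional [stimulus_protocol()] applied to compartment 2
#'   on top of the sustained `delta_alpha_f`.
#' @return Named derivative vector `c(dFa1, dBu1, dFa2, dBu2)`.
#' @export
rhs_two_compartment <- function(state, p2, t = 0, protocol = NULL) {
  if (any(state < 0)) stop("state components must be non-negative")
  p <- p2$base
  f2 <- p2$frac_fp2; f1 <- 1 - f2
  Fa1 <- state[[1]]; Bu1 <- state[[2]]; Fa2 <- state[[3]]; Bu2 <- state[[4]]
  Ga <- p$total_actin -
    p$phi_fp * (f1 * (Fa1 + Bu1) + f2 * (Fa2 + Bu2))
  if (Ga < -1e-12)
    stop("infeasible state: polymer exceeds the total actin pool")
  Ga <- max(Ga, 0)
  af2 <- p$alpha_f + p2$delta_alpha_f +
    p$alpha_f * stimulus_value(protocol, t)
  d1 <- actin_rates(Ga, Fa1, Bu1, p)
  d2 <- actin_rates(Ga, Fa2, Bu2, p, alpha_f = af2)
  c(dFa1 = d1$dFa, dBu1 = d1$dBu, dFa2 = d2$dFa, dBu2 = d2$dBu)
}

#' Integrate the two-compartment model
#'
#' @param p2 a [two_compartment_params()] object.
#' @param init named vector `c(Fa1, Bu1, Fa2, Bu2)`; defaults to the
#'   symmetric healthy equilibrium of the baseline model.
#' @param t_end final time.
#' @param protocol optional [stimulus_protocol()].
#' @param times output grid (default 500 points).
#' @param rtol,atol integrator tolerances.
#' @return data.frame with `time`, `Ga`, `Fa1`, `Bu1`, `Fa2`, `Bu2`.
#' @export
simulate_two_compartment <- function(p2, init = NULL, t_end = 4000,
                                     protocol = NULL, times = NULL,
                                     rtol = 1e-8, atol = 1e-10) {
  if (is.null(init)) {
    h <- healthy_equilibrium()
    init <- c(Fa1 = unname(h["Fa"]), Bu1 = unname(h["Bu"]),
              Fa2 = unname(h["Fa"]), Bu2 = unname(h["Bu"]))
  }
  if (is.null(times)) times <- seq(0, t_end, length.out = 500)
  deriv <- function(t, y, parms)
    list(unname(rhs_two_compartment(pmax(y, 0), p2, t, protocol)))
  sol <- deSolve::ode(y = init, times = times, func = deriv, parms = NULL,
                      method = "lsoda", rtol = rtol, atol = atol,
                      maxsteps = 50000)
  if (attr(sol, "istate")[1] < 0)
    stop("integration failed at t = ", max(sol[, "time"]))
  out <- as.data.frame(sol)
  p <- p2$base; f2 <- p2$frac_fp2
  out$Ga <- p$total_actin - p$phi_fp *
    ((1 - f2) * (out$Fa1 + out$Bu1) + f2 * (out$Fa2 + out$Bu2))
  out[, c("time", "Ga", "Fa1", "Bu1", "Fa2", "Bu2")]
}

# integrate until steady (max |d/dt| < tol at 10 consecutive checkpoints)
# or flag as non-convergent; returns list(state, steady, oscillatory)
settle_two_compartment <- function(p2, init, protocol = NULL,
                                   t_start = 0, chunk = 400,
                                   max_time = 40000, tol = 1e-8) {
  y <- init; t <- t_start; hits <- 0L
  bu_extremes <- c()
  while (t < max_time) {
    tr <- simulate_two_compartment(
      p2, y, t_end = chunk, protocol = NULL,
      times = seq(0, chunk, length.out = 11))
    # protocol handled by caller through time-shifted dynamics; only called
    # with protocol == NULL once the stimulus has decayed to nothing
    y <- c(Fa1 = tr$Fa1[11], Bu1 = tr$Bu1[11], Fa2 = tr$Fa2[11],
           Bu2 = tr$Bu2[11])
    d <- rhs_two_compartment(pmax(unname(y), 0), p2, t + chunk, NULL)
    t <- t + chunk
    if (max(abs(d)) < tol) hits <- hits + 1L else hits <- 0L
    if (hits >= 10L) return(list(state = y, steady = TRUE,
                                 oscillatory = FALSE))
    bu_extremes <- c(utils::tail(bu_extremes, 20), max(tr$Bu1, tr$Bu2))
  }
  osc <- length(bu_extremes) > 10 &&
    stats::sd(utils::tail(bu_extremes, 10)) >
    1e-4 * max(abs(bu_extremes), 1e-12)
  list(state = y, steady = FALSE, oscillatory = osc)
}

#' Steady-state response surface under sustained asymmetric feedback
#'
#' For each combination of sustained relative increment `delta_alpha_f /
#' alpha_f` and compartment-2 fraction, integrates from the symmetric
#' healthy state to steady state and reports both compartments' bundle
#' concentrations. Non-convergent (oscillatory) grid points are flagged.
#'
#' @param base a [kinetic_params()] object.
#' @param delta_grid relative increments (`delta_alpha_f / alpha_f`).
#' @param frac_grid compartment-2 fractions.
#' @return data.frame with `delta_rel`, `frac_fp2`, `Bu1`, `Bu2`,
#'   `converged`.
#' @export
steady_response_surface <- function(base = kinetic_params(),
                                    delta_grid, frac_grid) {
  stopifnot(length(delta_grid) > 0, length(frac_grid) > 0)
  h <- healthy_equilibrium()
  init <- c(Fa1 = unname(h["Fa"]), Bu1 = unname(h["Bu"]),
            Fa2 = unname(h["Fa"]), Bu2 = unname(h["Bu"]))
  out <- expand.grid(delta_rel = delta_grid, frac_fp2 = frac_grid)
  out$Bu1 <- out$Bu2 <- NA_real_
  out$converged <- FALSE
  for (i in seq_len(nrow(out))) {
    p2 <- two_compartment_params(base, out$frac_fp2[i],
                                 delta_alpha_f = out$delta_rel[i] * base$alpha_f)
    st <- settle_two_compartment(p2, init)
    out$Bu1[i] <- st$state[["Bu1"]]; out$Bu2[i] <- st$state[["Bu2"]]
    out$converged[i] <- st$steady
  }
  out
}

#' Outcome of a transient localized stimulus
#'
#' Integrates the two-compartment model through and beyond a transient
#' stimulus to compartment 2 and classifies the final state by the
#' effacement check on each compartment: both recover, compartment 1
#' collapses (moderate stimulus: the stimulated region drains the shared
#' monomer pool), or compartment 2 collapses (strong stimulus: overshoot
#' and crash after the stimulus is withdrawn).
#'
#' @param base a [kinetic_params()] object.
#' @param protocol a [stimulus_protocol()] (pulse).
#' @param frac_fp2 compartment-2 fraction.
#' @param t_end integration horizon.
#' @param threshold effacement threshold.
#' @return list with `trajectory` (data.frame) and `outcome` (one of
#'   `"BOTH_RECOVER"`, `"FP1_COLLAPSES"`, `"FP2_COLLAPSES"`,
#'   `"BOTH_COLLAPSE"`, `"UNRESOLVED"`).
#' @export
transient_response <- function(base = kinetic_params(), protocol,
                               frac_fp2 = 0.5, t_end = 8000,
                               threshold = NULL) {
  if (is.null(threshold)) threshold <- default_effacement_threshold()
  p2 <- two_compartment_params(base, frac_fp2, delta_alpha_f = 0)
  tr <- simulate_two_compartment(p2, t_end = t_end, protocol = protocol,
                                 times = seq(0, t_end, length.out = 800))
  fin <- tr[nrow(tr), ]
  d <- rhs_two_compartment(pmax(c(fin$Fa1, fin$Bu1, fin$Fa2, fin$Bu2), 0),
                           p2, t_end, protocol)
  outcome <- if (max(abs(d)) > 1e-6) "UNRESOLVED"
  else {
    e1 <- fin$Bu1 < threshold; e2 <- fin$Bu2 < threshold
    if (e1 && e2) "BOTH_COLLAPSE"
    else if (e1) "FP1_COLLAPSES"
    else if (e2) "FP2_COLLAPSES"
    else "BOTH_RECOVER"
  }
  list(trajectory = tr, outcome = outcome)
}

#' Scan transient-stimulus amplitude and locate outcome switches
#'
#' Classifies the final state along a monotone amplitude grid and refines
#' the two switching amplitudes (recover to FP1-collapse, FP1-collapse to
#' FP2-collapse) by bisection.
#'
#' @param base a [kinetic_params()] object.
#' @param frac_fp2 compartment-2 fraction.
#' @param amplitude_range range of relative amplitudes to scan.
#' @param n number of grid points.
#' @param bisect_iter bisection refinement iterations per switch.
#' @param ... passed to [transient_response()].
#' @return list with `scan` (data.frame amplitude/Bu1/Bu2/outcome),
#'   `switch_recover_fp1`, `switch_fp1_fp2` (NA when a switch is absent
#'   from the scanned range).
#' @export
outcome_boundary_scan <- function(base = kinetic_params(), frac_fp2 = 0.5,
                                  amplitude_range = c(0, 3), n = 13,
                                  bisect_iter = 8, ...) {
  amps <- seq(amplitude_range[1], amplitude_range[2], length.out = n)
  run <- function(a) {
    r <- transient_response(base, stimulus_protocol(a), frac_fp2, ...)
    fin <- r$trajectory[nrow(r$trajectory), ]
    list(outcome = r$outcome, Bu1 = fin$Bu1, Bu2 = fin$Bu2)
  }
  res <- lapply(amps, run)
  scan <- data.frame(amplitude = amps,
                     Bu1 = vapply(res, `[[`, numeric(1), "Bu1"),
                     Bu2 = vapply(res, `[[`, numeric(1), "Bu2"),
                     outcome = vapply(res, `[[`, character(1), "outcome"))
  bisect <- function(lo, hi, from) {
    for (i in seq_len(bisect_iter)) {
      mid <- (lo + hi) / 2
      if (run(mid)$outcome == from) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }
  sw1 <- sw2 <- NA_real_
  oc <- scan$outcome
  i1 <- which(oc == "BOTH_RECOVER" & c(oc[-1], NA) != "BOTH_RECOVER")
  if (length(i1))
    sw1 <- bisect(amps[i1[1]], amps[i1[1] + 1], "BOTH_RECOVER")
  i2 <- which(oc == "FP1_COLLAPSES" & c(oc[-1], NA) == "FP2_COLLAPSES")
  if (length(i2))
    sw2 <- bisect(amps[i2[1]], amps[i2[1] + 1], "FP1_COLLAPSES")
  list(scan = scan, switch_recover_fp1 = sw1, switch_fp1_fp2 = sw2)
}
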