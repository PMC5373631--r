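#' Right-hand side of the three-state actin model
#'
#' Evaluates the reaction rates of the minimal actin model. Filaments grow by
#' filament-templated positive feedback (a Hill function of Fa, representing
#' Arp2/3-dependent branched nucleation downstream of nephrin/Rac1) and by
#' basal elongation plus nucleation; they are consumed by bundling and
#' turnover. Bundles form by filament merging and grow by filament addition
#' (both scaled by `alpha_b`) and by direct monomer addition (`gamma_b`), and
#' decay with rate `beta_b`. The monomer rate is the local bookkeeping
#' counterpart so that `dGa + dFa + dBu = 0` exactly (per unit foot-process
#' volume).
#'
#' @param state named numeric vector with components `Ga`, `Fa`, `Bu`
#'   (non-negative, non-dimensional concentrations).
#' @param p a [kinetic_params()] object.
#' @return Named vector `c(dGa, dFa, dBu)` of time derivatives.
#' @export
actin_rhs <- function(state, p) {
  if (any(state < 0)) stop("state components must be non-negative")
  Ga <- state[["Ga"]]; Fa <- state[["Fa"]]; Bu <- state[["Bu"]]
  d <- actin_rates(Ga, Fa, Bu, p)
  c(dGa = -(d$dFa + d$dBu), dFa = d$dFa, dBu = d$dBu)
}

# vectorised core: filament and bundle rates at given (possibly vector)
# Ga, Fa, Bu; parameter overrides let protocols modulate single rates.
actin_rates <- function(Ga, Fa, Bu, p, alpha_f = p$alpha_f,
                        alpha_b = p$alpha_b, beta_b = p$beta_b,
                        beta_f = p$beta_f) {
  h <- p$hill_h
  feedback <- alpha_f * Ga * Fa^h / (Fa^h + p$k^h)
  nuc <- if (is.null(p$nucleation_n)) p$gamma_f else p$nucleation_n
  basal <- p$gamma_f * Ga * Fa + 2 * nuc * Ga * Ga
  bundling <- alpha_b * Fa * (2 * Fa + Bu)
  dFa <- feedback + basal - bundling - beta_f * Fa
  dBu <- bundling + p$gamma_b * Ga * Bu - beta_b * Bu
  list(dFa = dFa, dBu = dBu)
}

#' Monomer concentration implied by mass conservation
#'
#' In the non-spatial model the conserved total actin (whole-cell scale,
#' reference volume 1) fixes the monomer pool:
#' `Ga = total_actin - phi_fp * (Fa + Bu)`.
#'
#' @param Fa,Bu filament and bundle concentrations (non-negative).
#' @param p a [kinetic_params()] object.
#' @return Monomer concentration `Ga`.
#' @export
ga_from_conservation <- function(Fa, Bu, p) {
  if (any(Fa < 0) || any(Bu < 0)) stop("Fa and Bu must be non-negative")
  Ga <- p$total_actin - p$phi_fp * (Fa + Bu)
  if (any(Ga < -1e-12))
    stop("infeasible state: Fa + Bu exceeds the total actin pool")
  pmax(Ga, 0)
}

# reduced planar vector field with Ga eliminated by conservation;
# vectorised over Fa, Bu. Returns list(dFa, dBu, Ga).
reduced_field <- function(Fa, Bu, p, ...) {
  Ga <- p$total_actin - p$phi_fp * (Fa + Bu)
  d <- actin_rates(Ga, Fa, Bu, p, ...)
  list(dFa = d$dFa, dBu = d$dBu, Ga = Ga)
}

#' Time-dependent modulation of a kinetic parameter
#'
#' Describes how one rate constant changes over time during a perturbation
#' protocol. Two shapes are supported: a `"step"` that multiplies the rate by
#' `factor` from `t0` on (optionally reverting at `t1`, or switching to
#' `factor2` at `t1` for two-stage interventions), and a `"pulse"` whose
#' relative amplitude rises linearly over `t_rise` and then decays
#' exponentially with time constant `tau` (the rate is
#' `base * (1 + amplitude * shape(t))`, so `amplitude` is the peak relative
#' increase).
#'
#' @param param name of the modulated rate (e.g. `"alpha_b"`).
#' @param type `"step"` or `"pulse"`.
#' @param t0 onset time.
#' @param factor multiplicative factor applied from `t0` (step).
#' @param t1 optional second event time (step revert / second stage).
#' @param factor2 factor applied from `t1` on; default 1 (revert to baseline).
#' @param amplitude peak relative amplitude of the pulse.
#' @param t_rise linear rise time of the pulse.
#' @param tau exponential decay constant of the pulse.
#' @return A `param_modulation` object.
#' @export
param_modulation <- function(param, type = c("step", "pulse"), t0 = 40,
                             factor = 1, t1 = Inf, factor2 = 1,
                             amplitude = 0, t_rise = 60, tau = 10) {
  type <- match.arg(type)
  if (t1 < t0) stop("'t1' must not precede 't0'")
  if (amplitude < 0) stop("'amplitude' must be non-negative")
  structure(list(param = param, type = type, t0 = t0, factor = factor,
                 t1 = t1, factor2 = factor2, amplitude = amplitude,
                 t_rise = t_rise, tau = tau),
            class = "param_modulation")
}

# multiplicative factor of a modulation at time t (vectorised over t)
modulation_factor <- function(m, t) {
  if (is.null(m)) return(rep(1, length(t)))
  if (m$type == "step") {
    ifelse(t < m$t0, 1, ifelse(t < m$t1, m$factor, m$factor2))
  } else {
    s <- numeric(length(t))
    rising <- t > m$t0 & t <= m$t0 + m$t_rise
    decay <- t > m$t0 + m$t_rise
    s[rising] <- (t[rising] - m$t0) / m$t_rise
    s[decay] <- exp(-(t[decay] - (m$t0 + m$t_rise)) / m$tau)
    1 + m$amplitude * s
  }
}

# resolve per-time parameter overrides from a (list of) modulation(s)
protocol_overrides <- function(protocol, p, t) {
  out <- list()
  if (is.null(protocol)) return(out)
  if (inherits(protocol, "param_modulation")) protocol <- list(protocol)
  for (m in protocol) {
    out[[m$param]] <- p[[m$param]] * modulation_factor(m, t)
  }
  out
}

#' Integrate the non-spatial actin model
#'
#' Solves the reduced (Fa, Bu) system with Ga eliminated by conservation,
#' using a stiff-capable integrator. Total actin is therefore conserved
#' exactly at every output time.
#'
#' @param p a [kinetic_params()] object.
#' @param init initial state: named vector with `Fa` and `Bu` (and optionally
#'   `Ga`, which is checked against conservation).
#' @param t_end final time.
#' @param protocol optional [param_modulation()] (or list of them) applied
#'   during the run.
#' @param times output time grid; default 500 points over `[0, t_end]`.
#' @param rtol,atol integrator tolerances.
#' @return A data.frame with columns `time`, `Ga`, `Fa`, `Bu`.
#' @export
simulate_actin <- function(p, init, t_end, protocol = NULL, times = NULL,
                           rtol = 1e-8, atol = 1e-10) {
  if (!is.null(init["Ga"]) && !is.na(init["Ga"])) {
    expect <- ga_from_conservation(init[["Fa"]], init[["Bu"]], p)
    if (abs(init[["Ga"]] - expect) > 1e-6 * max(1, p$total_actin))
      stop("initial state violates mass conservation (Eq. for total actin)")
  }
  if (is.null(times)) times <- seq(0, t_end, length.out = 500)
  deriv <- function(t, y, parms) {
    ov <- protocol_overrides(protocol, p, t)
    d <- do.call(reduced_field, c(list(Fa = max(y[1], 0), Bu = max(y[2], 0),
                                       p = p), ov))
    list(c(d$dFa, d$dBu))
  }
  sol <- deSolve::ode(y = c(Fa = init[["Fa"]], Bu = init[["Bu"]]),
                      times = times, func = deriv, parms = NULL,
                      method = "lsoda", rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1] < 0)
    stop("integration failed at t = ", max(sol[, "time"]))
  out <- as.data.frame(sol)
  out$Fa <- pmax(out$Fa, 0); out$Bu <- pmax(out$Bu, 0)
  out$Ga <- pmax(p$total_actin - p$phi_fp * (out$Fa + out$Bu), 0)
  out[, c("time", "Ga", "Fa", "Bu")]
}

#' Nullclines of the reduced (Fa, Bu) phase plane
#'
#' For each Fa on a grid, finds all Bu values where `dFa/dt = 0` (the
#' filament nullcline) and where `dBu/dt = 0` (the bundle nullcline), with Ga
#' eliminated by conservation. Multivalued curves are split into branches
#' indexed from the lowest Bu root upward.
#'
#' @param p a [kinetic_params()] object.
#' @param fa_range range of Fa to scan; defaults to the feasible box
#'   `[0, total_actin/phi_fp]`.
#' @param resolution number of grid points per axis.
#' @return A data.frame with columns `curve` (`"dFa"` or `"dBu"`), `Fa`,
#'   `Bu`, `branch` (root index per Fa column; `NA` for points found by the
#'   transposed scan that resolves near-vertical curve sections).
#' @export
nullclines <- function(p, fa_range = NULL, resolution = 400) {
  if (is.null(fa_range)) fa_range <- c(0, p$total_actin / p$phi_fp)
  stopifnot(resolution > 1, diff(fa_range) > 0)
  lim <- p$total_actin / p$phi_fp
  # log-augmented grids so collapsed-branch structure near the origin is
  # resolved (same rationale as in find_equilibria)
  aug <- function(lo, hi, n) {
    g <- seq(lo, hi, length.out = n)
    if (lo <= 0 && hi > 0)
      g <- c(g, hi * 10^seq(-6, -1.2, length.out = 30))
    sort(unique(g[g >= lo & g <= hi]))
  }
  fa_grid <- aug(fa_range[1], fa_range[2], resolution)
  scan_column <- function(curve, Fa) {
    bu_max <- lim - Fa
    if (bu_max <= 0) return(numeric(0))
    bu_grid <- aug(0, bu_max, resolution)
    v <- reduced_field(Fa, bu_grid, p)[[curve]]
    s <- sign(v)
    idx <- which(s[-1] * s[-length(s)] < 0)
    roots <- numeric(0)
    for (i in idx) {
      r <- stats::uniroot(function(b) reduced_field(Fa, b, p)[[curve]],
                          c(bu_grid[i], bu_grid[i + 1]), tol = 1e-12)$root
      roots <- c(roots, r)
    }
    # grid points that are exact zeros (e.g. Bu = 0 on the bundle curve
    # only when Fa = 0)
    sort(unique(c(roots, bu_grid[abs(v) < 1e-14])))
  }
  # transposed scan (fixed Bu, roots in Fa) fills in the near-vertical
  # curve sections a column scan cannot see
  scan_row <- function(curve, Bu) {
    fa_max <- min(fa_range[2], lim - Bu)
    if (fa_max <= fa_range[1]) return(numeric(0))
    fa_g <- aug(fa_range[1], fa_max, resolution)
    v <- reduced_field(fa_g, Bu, p)[[curve]]
    s <- sign(v)
    idx <- which(s[-1] * s[-length(s)] < 0)
    roots <- numeric(0)
    for (i in idx) {
      r <- stats::uniroot(function(f) reduced_field(f, Bu, p)[[curve]],
                          c(fa_g[i], fa_g[i + 1]), tol = 1e-12)$root
      roots <- c(roots, r)
    }
    roots
  }
  rows <- list()
  bu_grid_all <- aug(0, lim, resolution)
  for (curve in c("dFa", "dBu")) {
    for (Fa in fa_grid) {
      roots <- scan_column(curve, Fa)
      if (length(roots))
        rows[[length(rows) + 1L]] <-
          data.frame(curve = curve, Fa = Fa, Bu = roots,
                     branch = seq_along(roots))
    }
    for (Bu in bu_grid_all) {
      roots <- scan_row(curve, Bu)
      if (length(roots))
        rows[[length(rows) + 1L]] <-
          data.frame(curve = curve, Fa = roots, Bu = Bu,
                     branch = NA_integer_)
    }
  }
  if (!length(rows))
    return(data.frame(curve = character(), Fa = numeric(), Bu = numeric(),
                      branch = integer()))
  do.call(rbind, rows)
}

#' Find all equilibria of the reduced actin model
#'
#' Scans the feasible box `[0, total_actin/phi_fp]^2` (intersected with the
#' conservation constraint) on a dense grid, seeds a damped Newton polisher
#' in every grid cell where both components of the vector field change sign,
#' and classifies each converged root by the eigenvalues of the reduced
#' Jacobian.
#'
#' @param p a [kinetic_params()] object.
#' @param n_grid grid resolution per axis for the sign scan.
#' @param threshold effacement threshold used to flag equilibria inside the
#'   effacement region; default [default_effacement_threshold()].
#' @param tol residual tolerance for accepting a polished root.
#' @return A data.frame sorted by Fa with columns `Fa`, `Bu`, `Ga`,
#'   `stability` (`"stable"`, `"unstable"`, `"saddle"`), `eig_re1`, `eig_re2`,
#'   `eig_im` (imaginary part magnitude), `in_effacement`.
#' @export
find_equilibria <- function(p, n_grid = 300, threshold = NULL, tol = 1e-10) {
  if (is.null(threshold)) threshold <- default_effacement_threshold()
  lim <- p$total_actin / p$phi_fp
  # uniform grid augmented with a geometric sub-grid near the origin:
  # collapsed-branch roots scale like gamma_f*total^2/beta_f and can fall
  # below a uniform grid's resolution
  g <- sort(unique(c(seq(0, lim, length.out = n_grid),
                     lim * 10^seq(-6, -1.2, length.out = 48))))
  n_grid <- length(g)
  FA <- matrix(g, n_grid, n_grid)
  BU <- matrix(g, n_grid, n_grid, byrow = TRUE)
  feas <- FA + BU <= lim
  fld <- reduced_field(FA, BU, p)
  sf <- matrix(sign(fld$dFa), n_grid, n_grid)
  sb <- matrix(sign(fld$dBu), n_grid, n_grid)
  i <- seq_len(n_grid - 1L)
  chF <- (sf[i, i] != sf[i + 1L, i]) | (sf[i, i] != sf[i, i + 1L]) |
    (sf[i, i] != sf[i + 1L, i + 1L])
  chB <- (sb[i, i] != sb[i + 1L, i]) | (sb[i, i] != sb[i, i + 1L]) |
    (sb[i, i] != sb[i + 1L, i + 1L])
  cand <- which(chF & chB & feas[i, i], arr.ind = TRUE)
  roots <- matrix(numeric(0), ncol = 2)
  for (r in seq_len(nrow(cand))) {
    x0 <- c(g[cand[r, 1]], g[cand[r, 2]])
    x <- newton_polish(x0, p, lim)
    if (is.null(x)) next
    if (x[1] + x[2] > lim + 1e-9) next   # conservation infeasible
    v <- reduced_field(x[1], x[2], p)
    if (max(abs(c(v$dFa, v$dBu))) > tol) next
    if (nrow(roots) == 0 ||
        all(sqrt(rowSums(sweep(roots, 2, x)^2)) > 1e-6 * max(1, lim)))
      roots <- rbind(roots, x)
  }
  if (nrow(roots) == 0)
    return(data.frame(Fa = numeric(), Bu = numeric(), Ga = numeric(),
                      stability = character(), eig_re1 = numeric(),
                      eig_re2 = numeric(), eig_im = numeric(),
                      in_effacement = logical()))
  out <- lapply(seq_len(nrow(roots)), function(ri) {
    Fa <- roots[ri, 1]; Bu <- roots[ri, 2]
    J <- reduced_jacobian(Fa, Bu, p)
    ev <- eigen(J, only.values = TRUE)$values
    re <- sort(Re(ev))
    stab <- if (all(re < 0)) "stable" else if (all(re > 0)) "unstable" else "saddle"
    data.frame(Fa = Fa, Bu = Bu, Ga = ga_from_conservation(Fa, Bu, p),
               stability = stab, eig_re1 = re[1], eig_re2 = re[2],
               eig_im = abs(Im(ev[1])), in_effacement = Bu < threshold)
  })
  out <- do.call(rbind, out)
  out[order(out$Fa), , drop = FALSE]
}

# damped Newton with numeric central-difference Jacobian on the reduced field
newton_polish <- function(x0, p, lim, max_iter = 60) {
  x <- pmax(x0, 0)
  for (it in seq_len(max_iter)) {
    v <- reduced_field(x[1], x[2], p)
    f <- c(v$dFa, v$dBu)
    if (max(abs(f)) < 1e-13) return(x)
    J <- reduced_jacobian(x[1], x[2], p)
    step <- tryCatch(solve(J, f), error = function(e) NULL)
    if (is.null(step)) return(NULL)
    lam <- 1
    repeat {
      xn <- x - lam * step
      xn <- pmin(pmax(xn, 0), lim)
      vn <- reduced_field(xn[1], xn[2], p)
      if (sum(c(vn$dFa, vn$dBu)^2) < sum(f^2) || lam < 1e-4) break
      lam <- lam / 2
    }
    if (sqrt(sum((xn - x)^2)) < 1e-14 && max(abs(f)) > 1e-10) return(NULL)
    x <- xn
  }
  v <- reduced_field(x[1], x[2], p)
  if (max(abs(c(v$dFa, v$dBu))) < 1e-10) x else NULL
}

# numeric Jacobian of the reduced (Fa, Bu) field
reduced_jacobian <- function(Fa, Bu, p, h = 1e-7) {
  f <- function(x) {
    v <- reduced_field(x[1], x[2], p)
    c(v$dFa, v$dBu)
  }
  x <- c(Fa, Bu)
  J <- matrix(0, 2, 2)
  for (j in 1:2) {
    e <- c(0, 0); e[j] <- h * max(1, abs(x[j]))
    J[, j] <- (f(x + e) - f(pmax(x - e, 0))) / (e[j] + min(x[j], e[j]))
  }
  J
}

# Jacobian of the local (Fa, Bu) kinetics with Ga held fixed; relevant for
# the spatial model where the ambient monomer pool buffers a single FP
local_jacobian <- function(Fa, Bu, Ga, p, h = 1e-7) {
  f <- function(x) {
    d <- actin_rates(Ga, x[1], x[2], p)
    c(d$dFa, d$dBu)
  }
  x <- c(Fa, Bu)
  J <- matrix(0, 2, 2)
  for (j in 1:2) {
    e <- c(0, 0); e[j] <- h * max(1, abs(x[j]))
    J[, j] <- (f(x + e) - f(pmax(x - e, 0))) / (e[j] + min(x[j], e[j]))
  }
  J
}

# cached healthy reference equilibrium of the baseline (fig2C) set
.podoactin_cache <- new.env(parent = emptyenv())

#' Healthy reference equilibrium of the baseline parameter set
#'
#' The unique stable equilibrium of the calibrated baseline model; its bundle
#' concentration anchors the default effacement threshold.
#'
#' @return Named vector `c(Fa, Bu, Ga)`.
#' @export
healthy_equilibrium <- function() {
  if (is.null(.podoactin_cache$healthy)) {
    p <- kinetic_params()
    eq <- find_equilibria(p, threshold = 0)
    eq <- eq[eq$stability == "stable", , drop = FALSE]
    if (nrow(eq) != 1)
      stop("baseline parameter set does not have a unique stable equilibrium")
    .podoactin_cache$healthy <- c(Fa = eq$Fa, Bu = eq$Bu, Ga = eq$Ga)
  }
  .podoactin_cache$healthy
}

#' Default effacement threshold
#'
#' Bundles below this concentration cannot sustain foot-process morphology.
#' The default is 10% of the healthy-equilibrium bundle concentration of the
#' calibrated baseline set.
#'
#' @return Scalar threshold.
#' @export
default_effacement_threshold <- function() {
  0.1 * unname(healthy_equilibrium()["Bu"])
}

#' Is a state inside the effacement region?
#'
#' @param state named vector with a `Bu` component, or a bare numeric vector
#'   of bundle concentrations.
#' @param threshold effacement threshold (default
#'   [default_effacement_threshold()]).
#' @return Logical: `TRUE` where bundles are below threshold.
#' @export
effacement_check <- function(state, threshold = default_effacement_threshold()) {
  stopifnot(threshold > 0)
  Bu <- if (!is.null(names(state)) && "Bu" %in% names(state))
    state[["Bu"]] else state
  Bu < threshold
}

#' Classify the dynamical regime of a parameter set
#'
#' Regimes follow the phase-plane taxonomy of the model: a single stable
#' equilibrium with strong bundles (`MONOSTABLE_HEALTHY`), coexistence of a
#' healthy and a collapsed stable state (`BISTABLE`), no stable equilibrium
#' but a bounded attracting cycle (`OSCILLATORY`), or collapse of every
#' trajectory into the effacement region (`COLLAPSE`).
#'
#' @param p a [kinetic_params()] object.
#' @param threshold effacement threshold.
#' @param t_horizon integration horizon for cycle/collapse detection.
#' @return One of `"MONOSTABLE_HEALTHY"`, `"BISTABLE"`, `"OSCILLATORY"`,
#'   `"COLLAPSE"`, `"UNRESOLVED"`.
#' @export
classify_regime <- function(p, threshold = NULL, t_horizon = 6000) {
  if (is.null(threshold)) threshold <- default_effacement_threshold()
  eq <- find_equilibria(p, threshold = threshold)
  stab <- eq[eq$stability == "stable", , drop = FALSE]
  healthy <- stab[!stab$in_effacement, , drop = FALSE]
  if (nrow(stab) >= 2 && nrow(stab[stab$in_effacement, ]) >= 1)
    return("BISTABLE")
  if (nrow(healthy) == 1 && nrow(stab) == 1)
    return("MONOSTABLE_HEALTHY")
  # no healthy stable state: integrate from a standard grid of initial
  # conditions and look for a sustained cycle vs terminal collapse
  lim <- p$total_actin / p$phi_fp
  ics <- expand.grid(Fa = lim * c(0.05, 0.2, 0.4),
                     Bu = lim * c(0.05, 0.2, 0.4))
  ics <- ics[ics$Fa + ics$Bu < lim, ]
  all_collapse <- TRUE
  any_cycle <- FALSE
  for (i in seq_len(nrow(ics))) {
    tr <- simulate_actin(p, c(Fa = ics$Fa[i], Bu = ics$Bu[i]), t_horizon,
                         rtol = 1e-8, atol = 1e-10)
    late <- tr[tr$time > t_horizon / 2, ]
    osc <- is_oscillating(late$time, late$Bu)
    if (osc && min(late$Bu) > 0) any_cycle <- TRUE
    if (osc || late$Bu[nrow(late)] >= threshold) all_collapse <- FALSE
  }
  if (all_collapse) return("COLLAPSE")
  if (any_cycle) return("OSCILLATORY")
  "UNRESOLVED"
}

# sustained-oscillation detector: >= 3 interior peaks with prominence above
# 1% of the observed amplitude
is_oscillating <- function(t, x, min_amp_frac = 0.01) {
  amp <- max(x) - min(x)
  if (amp < 1e-6 * max(abs(x), 1e-12)) return(FALSE)
  n <- length(x)
  pk <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
  if (length(pk) < 3) return(FALSE)
  prom <- vapply(pk, function(i) {
    lo <- max(1, i - 10L); hi <- min(n, i + 10L)
    x[i] - min(x[lo:hi])
  }, numeric(1))
  sum(prom > min_amp_frac * amp) >= 3
}

#' Period of a sustained oscillation from trajectory peaks
#'
#' @param trajectory data.frame from [simulate_actin()].
#' @param var column used for peak detection (default `"Bu"`).
#' @param discard fraction of the record discarded as transient.
#' @return Mean peak-to-peak interval, or `NA` if fewer than 3 peaks.
#' @export
oscillation_period <- function(trajectory, var = "Bu", discard = 0.5) {
  tr <- trajectory[trajectory$time >= discard * max(trajectory$time), ]
  x <- tr[[var]]; t <- tr$time; n <- length(x)
  amp <- max(x) - min(x)
  pk <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
  pk <- pk[vapply(pk, function(i) {
    lo <- max(1, i - 10L); hi <- min(n, i + 10L)
    (x[i] - min(x[lo:hi])) > 0.01 * amp
  }, logical(1))]
  if (length(pk) < 3) return(NA_real_)
  mean(diff(t[pk]))
}
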