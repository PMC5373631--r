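#' Parameters for the spatial reaction-diffusion model
#'
#' G-actin diffuses through every compartment of the network; filaments and
#' bundles are carried only in foot-process cells, where all reactions
#' (including the positive feedback, which is localized to FPs) take place.
#' `phi_fp` of the kinetic set is unused here: the geometry supplies the
#' actual volumes.
#'
#' @param kinetics a [kinetic_params()] object.
#' @param D_Ga monomer diffusion coefficient (um^2/time).
#' @return A `spatial_params` object.
#' @export
spatial_params <- function(kinetics = kinetic_params(), D_Ga = 3) {
  if (D_Ga <= 0) stop("'D_Ga' must be positive")
  structure(list(kinetics = kinetics, D_Ga = D_Ga),
            class = "spatial_params")
}

#' Region- and time-dependent perturbation protocol
#'
#' A protocol is a list of events; each event modulates one kinetic
#' parameter over time (via [param_modulation()]) within a region mask
#' (a vector of foot-process indices, or `NULL` for all FPs).
#'
#' @param ... events created by [rd_event()].
#' @return An `rd_protocol` object.
#' @export
rd_protocol <- function(...) {
  events <- list(...)
  for (e in events)
    if (!inherits(e$modulation, "param_modulation"))
      stop("each event needs a 'param_modulation'")
  structure(events, class = "rd_protocol")
}

#' @rdname rd_protocol
#' @param modulation a [param_modulation()].
#' @param fp_mask integer indices of the affected foot processes, or `NULL`
#'   for all of them.
#' @export
rd_event <- function(modulation, fp_mask = NULL) {
  list(modulation = modulation, fp_mask = fp_mask)
}

# per-FP multiplicative factors for each modulated parameter at time t
protocol_factors <- function(protocol, t, n_fp) {
  out <- list()
  if (is.null(protocol)) return(out)
  for (e in protocol) {
    pm <- e$modulation$param
    if (is.null(out[[pm]])) out[[pm]] <- rep(1, n_fp)
    f <- modulation_factor(e$modulation, t)
    if (is.null(e$fp_mask)) out[[pm]] <- out[[pm]] * f
    else out[[pm]][e$fp_mask] <- out[[pm]][e$fp_mask] * f
  }
  out
}

#' Uniform healthy initial field
#'
#' The spatially uniform state with every FP at the healthy equilibrium and
#' the monomer pool at its equilibrium concentration is an exact steady
#' state of the spatial model (no gradients, local kinetics at rest).
#'
#' @param net a `compartment_network`.
#' @return list with `Ga` (per cell), `Fa`, `Bu` (per FP cell).
#' @export
rd_initial_state <- function(net) {
  h <- healthy_equilibrium()
  n_fp <- sum(net$cells$label == "FP")
  list(Ga = rep(unname(h["Ga"]), nrow(net$cells)),
       Fa = rep(unname(h["Fa"]), n_fp),
       Bu = rep(unname(h["Bu"]), n_fp))
}

#' Simulate the reaction-diffusion model on a compartment network
#'
#' Method-of-lines finite-volume integration: for every cell i,
#' `dGa_i/dt = sum_j A_ij D / (d_ij V_i) (Ga_j - Ga_i)` plus, in FP cells,
#' the local reaction source; Fa and Bu evolve locally in FP cells only.
#' The outer boundary is no-flux, so total actin is conserved to integrator
#' tolerance.
#'
#' @param net a `compartment_network`.
#' @param p a [spatial_params()] object.
#' @param protocol optional [rd_protocol()].
#' @param t_end final time.
#' @param dt_out output interval.
#' @param init initial field (default [rd_initial_state()]).
#' @param rtol,atol integrator tolerances.
#' @return An `rd_timecourse`: list with `times`, matrices `Ga`
#'   (cells x times), `Fa`, `Bu` (FPs x times), the network and parameters.
#' @export
simulate_rd <- function(net, p, protocol = NULL, t_end = 2400, dt_out = 10,
                        init = NULL, rtol = 1e-7, atol = 1e-9) {
  stopifnot(inherits(net, "compartment_network"),
            inherits(p, "spatial_params"))
  kin <- p$kinetics
  n <- nrow(net$cells)
  fp_idx <- which(net$cells$label == "FP")
  n_fp <- length(fp_idx)
  if (is.null(init)) init <- rd_initial_state(net)
  Lm <- network_laplacian(net)
  V <- net$cells$volume
  y0 <- c(init$Ga, init$Fa, init$Bu)
  deriv <- function(t, y, parms) {
    y <- pmax(y, 0)
    Ga <- y[seq_len(n)]
    Fa <- y[n + seq_len(n_fp)]
    Bu <- y[n + n_fp + seq_len(n_fp)]
    fac <- protocol_factors(protocol, t, n_fp)
    Gf <- Ga[fp_idx]
    d <- actin_rates(
      Gf, Fa, Bu, kin,
      alpha_f = kin$alpha_f * (fac$alpha_f %||% 1),
      alpha_b = kin$alpha_b * (fac$alpha_b %||% 1),
      beta_b = kin$beta_b * (fac$beta_b %||% 1),
      beta_f = kin$beta_f * (fac$beta_f %||% 1))
    dGa <- p$D_Ga * as.numeric(Lm %*% Ga) / V
    dGa[fp_idx] <- dGa[fp_idx] - (d$dFa + d$dBu)
    list(c(dGa, d$dFa, d$dBu))
  }
  times <- seq(0, t_end, by = dt_out)
  sol <- deSolve::ode(y = y0, times = times, func = deriv, parms = NULL,
                      method = "lsodes", rtol = rtol, atol = atol,
                      maxsteps = 100000)
  if (attr(sol, "istate")[1] < 0)
    stop("reaction-diffusion integration failed at t = ", max(sol[, 1]))
  m <- t(unname(sol[, -1, drop = FALSE]))
  structure(list(times = times,
                 Ga = m[seq_len(n), , drop = FALSE],
                 Fa = m[n + seq_len(n_fp), , drop = FALSE],
                 Bu = m[n + n_fp + seq_len(n_fp), , drop = FALSE],
                 fp_idx = fp_idx, net = net, params = p,
                 protocol = protocol),
            class = "rd_timecourse")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Total actin over an RD timecourse
#'
#' @param tc an `rd_timecourse`.
#' @return Numeric vector of total actin (concentration x volume) at each
#'   output time.
#' @export
rd_total_actin <- function(tc) {
  V <- tc$net$cells$volume
  Vfp <- V[tc$fp_idx]
  as.numeric(crossprod(tc$Ga, V)) +
    as.numeric(crossprod(tc$Fa + tc$Bu, Vfp))
}

#' Detect per-foot-process effacement in an RD timecourse
#'
#' A foot process is effaced when its bundle concentration stays below
#' `threshold` from some time t* through t* + `persistence_window` and
#' through the end of the record (a permanent, not transient, loss).
#'
#' @param tc an `rd_timecourse`.
#' @param threshold effacement threshold (default
#'   [default_effacement_threshold()]).
#' @param persistence_window minimum time bundles must stay below threshold
#'   (default 10% of the record length).
#' @return An `effacement_report`: data.frame with `fp_id`, `status`
#'   (`"survived"`, `"effaced"`, `"unresolved"`), `t_effaced`; attributes
#'   `n_effaced`, `n_survived`, `final_mean_Bu_survivors`, `net_signature`.
#' @export
detect_effacement <- function(tc, threshold = NULL,
                              persistence_window = NULL) {
  if (is.null(threshold)) threshold <- default_effacement_threshold()
  span <- diff(range(tc$times))
  if (is.null(persistence_window)) persistence_window <- 0.1 * span
  stopifnot(threshold > 0, persistence_window > 0)
  n_fp <- nrow(tc$Bu)
  nt <- length(tc$times)
  status <- character(n_fp); t_eff <- rep(NA_real_, n_fp)
  short <- span < persistence_window
  for (i in seq_len(n_fp)) {
    below <- tc$Bu[i, ] < threshold
    if (short) { status[i] <- "unresolved"; next }
    if (!below[nt]) { status[i] <- "survived"; next }
    last_above <- max(c(0L, which(!below)))
    t_star <- if (last_above == 0L) tc$times[1] else tc$times[last_above + 1L]
    if (max(tc$times) - t_star >= persistence_window) {
      status[i] <- "effaced"; t_eff[i] <- t_star
    } else status[i] <- "survived"
  }
  surv <- status == "survived"
  rep <- data.frame(fp_id = seq_len(n_fp), status = status,
                    t_effaced = t_eff)
  structure(rep,
            n_effaced = sum(status == "effaced"),
            n_survived = sum(surv),
            final_mean_Bu_survivors =
              if (any(surv)) mean(tc$Bu[surv, nt]) else NA_real_,
            net_signature = network_signature(tc$net),
            class = c("effacement_report", "data.frame"))
}

network_signature <- function(net) {
  c(n_cells = nrow(net$cells), n_fp = sum(net$cells$label == "FP"),
    volume = round(sum(net$cells$volume), 6))
}

#' @export
print.effacement_report <- function(x, ...) {
  cat(sprintf("Effacement report: %d/%d FPs effaced; survivor mean Bu = %.3f\n",
              attr(x, "n_effaced"), nrow(x),
              attr(x, "final_mean_Bu_survivors")))
  invisible(x)
}

#' Normalized disagreement between two effacement patterns
#'
#' The deterministic spatial model is chaotically sensitive: nearly
#' identical perturbations produce different survived/effaced patterns.
#' This computes the fraction of foot processes whose status differs.
#'
#' @param report_a,report_b `effacement_report`s over the same network.
#' @return list with `divergence` (fraction in 0..1) and `agreement_map`
#'   (logical per FP, `TRUE` where the two reports agree).
#' @export
pattern_divergence <- function(report_a, report_b) {
  if (!identical(attr(report_a, "net_signature"),
                 attr(report_b, "net_signature")))
    stop("effacement reports come from different networks")
  agree <- report_a$status == report_b$status
  list(divergence = mean(!agree), agreement_map = agree)
}

#' Asynchrony index of foot-process bundle timecourses
#'
#' One minus the mean pairwise Pearson correlation of the per-FP bundle
#' timecourses over a window, rescaled to 0..1 (0 = perfectly synchronous,
#' 1 = anti-phase). Constant (degenerate) records are excluded; if fewer
#' than two FPs vary, the index is 0.
#'
#' @param tc an `rd_timecourse`.
#' @param window time window `c(t0, t1)`; default the full record.
#' @return Scalar in 0..1.
#' @export
asynchrony_index <- function(tc, window = NULL) {
  if (nrow(tc$Bu) < 2) stop("asynchrony needs at least 2 foot processes")
  sel <- if (is.null(window)) rep(TRUE, length(tc$times))
  else tc$times >= window[1] & tc$times <= window[2]
  W <- tc$Bu[, sel, drop = FALSE]
  sds <- apply(W, 1, stats::sd)
  W <- W[sds > 1e-12, , drop = FALSE]
  if (nrow(W) < 2) return(0)
  C <- stats::cor(t(W))
  m <- mean(C[upper.tri(C)])
  max(0, min(1, (1 - m) / 2))
}

#' Run a named perturbation scenario on the spatial model
#'
#' Available scenarios:
#' \describe{
#'   \item{fig3_global_ab}{sudden spatially uniform increase of the
#'     bundling rate `alpha_b` at t = 40 (default to 0.05 from 0.03),
#'     triggering asynchronous, progressive bundle collapse.}
#'   \item{fig5_local_af_pulse}{transient localized increase of the
#'     positive feedback `alpha_f` in a contiguous FP region.}
#'   \item{fig6_bb_drop}{sustained decrease of bundle turnover `beta_b`
#'     from t = 0 (progressive FP loss).}
#'   \item{fig6_bb_drop_restore}{as above, reverting `beta_b` to baseline
#'     at `t1`.}
#'   \item{fig6_bb_drop_ab_comp}{compensation by lowering `alpha_b` at
#'     `t1` while `beta_b` stays low.}
#'   \item{fig6_bb_drop_af_comp}{compensation by raising `alpha_f` at
#'     `t1` while `beta_b` stays low.}
#' }
#'
#' @param name scenario name.
#' @param net a `compartment_network`.
#' @param p a [spatial_params()] object.
#' @param config named list of overrides: `factor` (perturbation factor),
#'   `t0`, `t1`, `t_end`, `amplitude`, `region` (FP indices for fig5),
#'   `dt_out`, `rtol`, `atol`, `threshold`.
#' @return list with `timecourse`, `report` ([detect_effacement()]), and
#'   the fully resolved `config`.
#' @export
run_scenario <- function(name, net, p = spatial_params(), config = list()) {
  n_fp <- sum(net$cells$label == "FP")
  cfg <- function(key, default) config[[key]] %||% default
  proto <- switch(
    name,
    fig3_global_ab = {
      t_end <- cfg("t_end", 2400)
      rd_protocol(rd_event(param_modulation(
        "alpha_b", "step", t0 = cfg("t0", 40), factor = cfg("factor", 5 / 3))))
    },
    fig5_local_af_pulse = {
      t_end <- cfg("t_end", 1500)
      region <- cfg("region", seq(floor(n_fp * 0.1), floor(n_fp * 0.6)))
      rd_protocol(rd_event(param_modulation(
        "alpha_f", "pulse", t0 = cfg("t0", 40),
        amplitude = cfg("amplitude", 2.5), t_rise = 60, tau = 10),
        fp_mask = region))
    },
    fig6_bb_drop = {
      t_end <- cfg("t_end", 1500)
      rd_protocol(rd_event(param_modulation(
        "beta_b", "step", t0 = cfg("t0", 0), factor = cfg("factor", 0.5))))
    },
    fig6_bb_drop_restore = {
      t_end <- cfg("t_end", cfg("t1", 500) + cfg("t_obs", 1000))
      rd_protocol(rd_event(param_modulation(
        "beta_b", "step", t0 = cfg("t0", 0), factor = cfg("factor", 0.5),
        t1 = cfg("t1", 500), factor2 = 1)))
    },
    fig6_bb_drop_ab_comp = {
      t_end <- cfg("t_end", cfg("t1", 500) + cfg("t_obs", 1000))
      rd_protocol(
        rd_event(param_modulation("beta_b", "step", t0 = cfg("t0", 0),
                                  factor = cfg("factor", 0.5))),
        rd_event(param_modulation("alpha_b", "step", t0 = cfg("t1", 500),
                                  factor = cfg("comp_factor", 0.5))))
    },
    fig6_bb_drop_af_comp = {
      t_end <- cfg("t_end", cfg("t1", 500) + cfg("t_obs", 1000))
      rd_protocol(
        rd_event(param_modulation("beta_b", "step", t0 = cfg("t0", 0),
                                  factor = cfg("factor", 0.5))),
        rd_event(param_modulation("alpha_f", "step", t0 = cfg("t1", 500),
                                  factor = cfg("comp_factor", 2))))
    },
    stop("unknown scenario '", name, "'")
  )
  tc <- simulate_rd(net, p, proto, t_end = t_end,
                    dt_out = cfg("dt_out", 10),
                    rtol = cfg("rtol", 1e-7), atol = cfg("atol", 1e-9))
  rep <- detect_effacement(tc, threshold = config$threshold,
                           persistence_window = config$persistence_window)
  list(timecourse = tc, report = rep,
       config = utils::modifyList(list(name = name, t_end = t_end), config))
}

#' Survivor count over time
#'
#' Number of foot processes whose bundles are at or above threshold at each
#' output time (an instantaneous, not persistence-filtered, count).
#'
#' @param tc an `rd_timecourse`.
#' @param threshold effacement threshold.
#' @return Integer vector along `tc$times`.
#' @export
survivor_timecourse <- function(tc, threshold = NULL) {
  if (is.null(threshold)) threshold <- default_effacement_threshold()
  colSums(tc$Bu >= threshold)
}
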