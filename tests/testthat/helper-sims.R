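# Shared, lazily computed fixtures for the heavier simulations. Everything
# is deterministic, so computing each once per test run is safe.

.sims <- new.env(parent = emptyenv())

memo <- function(key, fun) {
  if (is.null(.sims[[key]])) .sims[[key]] <- fun()
  .sims[[key]]
}

get_geom <- function() memo("geom", function() build_idealized_podocyte())

get_net <- function() memo("net", function()
  as_compartment_network(get_geom(), axial_resolution = 2))

get_fig3 <- function() memo("fig3", function()
  run_scenario("fig3_global_ab", get_net()))

# same scenario with the bundling step larger by one part in a thousand
get_fig3_perturbed <- function() memo("fig3b", function()
  run_scenario("fig3_global_ab", get_net(),
               config = list(factor = (5 / 3) * 1.001)))

get_fig5 <- function() memo("fig5", function()
  run_scenario("fig5_local_af_pulse", get_net()))

get_fig6 <- function() memo("fig6", function() {
  out <- list()
  for (mode in c("fig6_bb_drop_restore", "fig6_bb_drop_ab_comp",
                 "fig6_bb_drop_af_comp"))
    for (t1 in c(500, 1500))
      out[[paste(mode, t1, sep = "@")]] <-
        run_scenario(mode, get_net(),
                     config = list(t1 = t1, persistence_window = 150))
  out
})

get_fig6_injury <- function() memo("fig6_injury", function()
  run_scenario("fig6_bb_drop", get_net(), config = list(t_end = 2500)))

# well-mixed limit: D scaled x1000 under the global bundling step, plus the
# matched single-compartment reduction (phi and total from the network)
get_wellmixed <- function() memo("wellmixed", function() {
  net <- get_net()
  step <- param_modulation("alpha_b", "step", t0 = 40, factor = 5 / 3)
  tc <- simulate_rd(net, spatial_params(D_Ga = 3000),
                    rd_protocol(rd_event(step)), t_end = 600, dt_out = 5)
  V <- net$cells$volume
  phi <- sum(V[net$cells$label == "FP"]) / sum(V)
  h <- healthy_equilibrium()
  p <- kinetic_params(total_actin = h[["Ga"]] + phi * (h[["Fa"]] + h[["Bu"]]),
                      phi_fp = phi)
  tr <- simulate_actin(p, c(Fa = h[["Fa"]], Bu = h[["Bu"]]), 600,
                       protocol = step, times = seq(0, 600, 5))
  list(tc = tc, ode = tr)
})

get_fig4_outcomes <- function() memo("fig4", function()
  vapply(c(0.5, 1, 2), function(a)
    transient_response(kinetic_params(), stimulus_protocol(a),
                       frac_fp2 = 0.5)$outcome, character(1)))

# a minimal hand-built timecourse object for the detector unit tests
fake_timecourse <- function(Bu, times = seq(0, by = 10,
                                            length.out = ncol(Bu))) {
  n_fp <- nrow(Bu)
  cells <- data.frame(id = seq_len(n_fp), label = "FP", volume = 1,
                      exposed_area = 1, fp_id = seq_len(n_fp))
  net <- list(cells = cells, interfaces = data.frame())
  class(net) <- "compartment_network"
  structure(list(times = times, Ga = matrix(0, n_fp, length(times)),
                 Fa = Bu * 0, Bu = Bu, fp_idx = seq_len(n_fp), net = net),
            class = "rd_timecourse")
}
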