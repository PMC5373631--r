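test_that("reaction rates match the model structure and close stoichiometrically", {
  p <- kinetic_params()
  # without filaments, only spontaneous nucleation produces them
  g <- 0.3
  d <- actin_rhs(c(Ga = g, Fa = 0, Bu = 0), p)
  expect_equal(d[["dFa"]], 2 * p$gamma_f * g^2)
  expect_equal(d[["dBu"]], 0)
  # local reaction sum is zero to machine precision at arbitrary states
  set.seed(1)
  for (i in 1:25) {
    s <- c(Ga = runif(1, 0, 1), Fa = runif(1, 0, 2), Bu = runif(1, 0, 3))
    expect_lt(abs(sum(actin_rhs(s, p))), 1e-14)
  }
  expect_error(actin_rhs(c(Ga = -0.1, Fa = 0, Bu = 0), p), "non-negative")
})

test_that("conservation fixes the monomer pool", {
  p <- kinetic_params()
  expect_equal(ga_from_conservation(0, 0, p), p$total_actin)
  set.seed(2)
  for (i in 1:20) {
    Fa <- runif(1, 0, 1); Bu <- runif(1, 0, 1)
    Ga <- ga_from_conservation(Fa, Bu, p)
    expect_identical(Ga + p$phi_fp * (Fa + Bu), p$total_actin)
  }
  expect_error(ga_from_conservation(10, 10, p), "exceeds")
})

test_that("the healthy baseline satisfies the 1:2 monomer:polymer ratio", {
  h <- healthy_equilibrium()
  polymer <- kinetic_params()$phi_fp * (h[["Fa"]] + h[["Bu"]])
  expect_equal(polymer / h[["Ga"]], 2, tolerance = 0.01)
  # and the equilibrium residual is tiny
  d <- actin_rhs(c(Ga = h[["Ga"]], Fa = h[["Fa"]], Bu = h[["Bu"]]),
                 kinetic_params())
  expect_lt(max(abs(d)), 1e-8)
})

test_that("trajectories behave: frozen dynamics, convergence, non-negativity", {
  frozen <- kinetic_params(alpha_f = 0, gamma_f = 0, beta_f = 0,
                           alpha_b = 0, gamma_b = 0, beta_b = 0)
  tr <- simulate_actin(frozen, c(Fa = 0.4, Bu = 0.8), 100)
  expect_equal(max(abs(tr$Fa - 0.4)), 0, tolerance = 1e-12)
  expect_equal(max(abs(tr$Bu - 0.8)), 0, tolerance = 1e-12)
  # monostable set: two distinct starts converge to the same equilibrium
  p <- actin_params("fig2C")
  a <- simulate_actin(p, c(Fa = 0.05, Bu = 0.05), 4000)
  b <- simulate_actin(p, c(Fa = 0.8, Bu = 1.2), 4000)
  expect_equal(a$Bu[nrow(a)], b$Bu[nrow(b)], tolerance = 1e-5)
  expect_equal(a$Bu[nrow(a)], healthy_equilibrium()[["Bu"]],
               tolerance = 1e-5)
  expect_true(all(a$Fa >= 0 & a$Bu >= 0 & a$Ga >= 0))
})

test_that("the raised-bundling regime oscillates with a tolerance-stable period", {
  p <- actin_params("fig2E")
  h <- healthy_equilibrium()
  init <- c(Fa = h[["Fa"]], Bu = h[["Bu"]])
  tr1 <- simulate_actin(p, init, 4000, times = seq(0, 4000, 2))
  late <- tr1[tr1$time > 2000, ]
  expect_gt(max(late$Bu) - min(late$Bu), 0.5)
  per1 <- oscillation_period(tr1)
  tr2 <- simulate_actin(p, init, 4000, times = seq(0, 4000, 2),
                        rtol = 1e-10, atol = 1e-12)
  per2 <- oscillation_period(tr2)
  expect_equal(per1, per2, tolerance = 0.01)
  # cycles keep bundles above the effacement threshold
  expect_gt(min(late$Bu), default_effacement_threshold())
})

test_that("nullclines satisfy their defining equations and shift as expected", {
  p <- kinetic_params()
  nc <- nullclines(p, resolution = 150)
  for (curve in c("dFa", "dBu")) {
    pts <- nc[nc$curve == curve, ]
    pts <- pts[sample.int(nrow(pts), min(nrow(pts), 40)), ]
    v <- podoactin:::reduced_field(pts$Fa, pts$Bu, p)[[curve]]
    expect_lt(max(abs(v)), 1e-6)
  }
  # arrow table: raising a rate moves its nullcline branch at fixed Fa
  shift <- function(param, curve, dir) {
    args <- unclass(p); args$nucleation_n <- NULL
    args[[param]] <- args[[param]] * 1.1
    nc2 <- nullclines(do.call(kinetic_params, args), resolution = 150)
    sel <- function(d) d[d$curve == curve & !is.na(d$branch) &
                          d$branch == 1 & d$Fa > 0.15 & d$Fa < 0.5, ]
    mm <- merge(sel(nc), sel(nc2), by = "Fa")
    expect_true(dir * mean(mm$Bu.y - mm$Bu.x) > 0, label = param)
  }
  shift("alpha_f", "dFa", +1)   # stronger feedback lifts the filament curve
  shift("beta_f", "dFa", -1)    # faster filament turnover lowers it
  shift("alpha_b", "dBu", +1)   # stronger bundling lifts the bundle curve
  shift("beta_b", "dBu", -1)    # faster bundle turnover lowers it
})

test_that("nullcline intersections coincide with the polished equilibria", {
  p <- actin_params("fig2D")
  nc <- nullclines(p, resolution = 400)
  eq <- find_equilibria(p)
  step <- (p$total_actin / p$phi_fp) / 400
  for (i in seq_len(nrow(eq))) {
    for (curve in c("dFa", "dBu")) {
      pts <- nc[nc$curve == curve, ]
      dmin <- min(sqrt((pts$Fa - eq$Fa[i])^2 + (pts$Bu - eq$Bu[i])^2))
      expect_lt(dmin, 2 * step)
    }
  }
})

test_that("equilibrium structure matches the phase-plane taxonomy", {
  eqC <- find_equilibria(actin_params("fig2C"))
  expect_identical(sum(eqC$stability == "stable"), 1L)
  expect_false(any(eqC$in_effacement[eqC$stability == "stable"]))
  eqD <- find_equilibria(actin_params("fig2D"))
  expect_identical(nrow(eqD), 3L)
  expect_identical(sum(eqD$stability == "stable"), 2L)
  expect_identical(sum(eqD$stability != "stable"), 1L)
  # the weaker stable state lies in the effacement region
  st <- eqD[eqD$stability == "stable", ]
  expect_true(min(st$Bu) < default_effacement_threshold())
  expect_true(max(st$Bu) > default_effacement_threshold())
  # pure decay: unique stable equilibrium at the origin
  dec <- kinetic_params(alpha_f = 0, gamma_f = 0, alpha_b = 0, gamma_b = 0,
                        beta_f = 0.1, beta_b = 0.05)
  eq0 <- find_equilibria(dec, threshold = 0.01)
  expect_identical(nrow(eq0), 1L)
  expect_equal(eq0$Fa, 0, tolerance = 1e-10)
  expect_equal(eq0$Bu, 0, tolerance = 1e-10)
  expect_identical(eq0$stability, "stable")
})

test_that("the root finder agrees with the sign-scan oracle on random sets", {
  set.seed(7)
  for (i in 1:20) {
    p <- random_kinetics()
    expect_identical(nrow(find_equilibria(p, threshold = 0.01)),
                     nrow(oracle_roots(p)),
                     label = paste("random set", i))
  }
})

test_that("regime classification reproduces the four scenarios", {
  expect_identical(classify_regime(actin_params("fig2C")),
                   "MONOSTABLE_HEALTHY")
  expect_identical(classify_regime(actin_params("fig2D")), "BISTABLE")
  expect_identical(classify_regime(actin_params("fig2E")), "OSCILLATORY")
  expect_identical(classify_regime(actin_params("fig2F")), "COLLAPSE")
  dec <- kinetic_params(alpha_f = 0, gamma_f = 0, alpha_b = 0, gamma_b = 0,
                        beta_f = 0.1, beta_b = 0.05)
  expect_identical(classify_regime(dec), "COLLAPSE")
})

test_that("pool scalings shift the oscillatory regime as observed", {
  p <- actin_params("fig2E")
  h <- healthy_equilibrium()
  init <- c(Fa = h[["Fa"]], Bu = h[["Bu"]])
  # 70% pool: terminal collapse
  expect_identical(classify_regime(actin_params("fig3E")), "COLLAPSE")
  # 115% pool: still cyclic, with stronger bundles on average
  tr100 <- simulate_actin(p, init, 5000, times = seq(0, 5000, 2))
  tr115 <- simulate_actin(actin_params("fig3F"), init, 5000,
                          times = seq(0, 5000, 2))
  late <- function(tr) tr[tr$time > 2500, ]
  expect_true(podoactin:::is_oscillating(late(tr115)$time, late(tr115)$Bu))
  expect_gt(mean(late(tr115)$Bu), mean(late(tr100)$Bu))
})

test_that("effacement check is a plain bundle threshold", {
  expect_true(effacement_check(c(Bu = 0)))
  expect_false(effacement_check(healthy_equilibrium()))
  expect_false(effacement_check(c(Bu = 0.5), threshold = 1e-12))
  expect_true(all(effacement_check(c(0, 0.01)), !effacement_check(10)))
})

test_that("splitting nucleation from elongation at equal rates is an identity", {
  p1 <- kinetic_params()
  p2 <- kinetic_params(nucleation_n = p1$gamma_f)
  s <- c(Ga = 0.2, Fa = 0.31, Bu = 0.9)
  expect_identical(actin_rhs(s, p1), actin_rhs(s, p2))
  expect_equal(find_equilibria(p2), find_equilibria(p1))
})

test_that("the finder handles a steeper feedback Hill exponent", {
  p4 <- kinetic_params(hill_h = 4)
  expect_identical(nrow(find_equilibria(p4, threshold = 0.01)),
                   nrow(oracle_roots(p4)))
})
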