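test_that("idealized generator hits the measured quarter-cell targets", {
  m <- morphometrics(get_geom())
  # body targets are hit exactly by construction
  expect_equal(m$V_CB_MP, 420, tolerance = 1e-10)
  expect_equal(m$A_CB_MP, 695, tolerance = 1e-10)
  # post-FP totals within a fraction of a percent of the measured values
  expect_equal(m$V, 530, tolerance = 0.005)
  expect_equal(m$A, 1683, tolerance = 0.005)
  # diagnostic ratios of the measured table
  expect_equal(m$AV, 3.2, tolerance = 0.1 / 3.2)
  expect_equal(m$AV_FP, 9.0, tolerance = 0.2 / 9)
  expect_equal(m$V_FP_over_V_pct, 20, tolerance = 1 / 20)
  expect_identical(m$n_branches, 36L)
  expect_equal(m$mean_branchpoint_distance, 18, tolerance = 1e-10)
  expect_equal(m$mean_furthest_endpoint_distance, 39, tolerance = 1e-10)
})

test_that("with no foot processes the quarter cell is the bare body", {
  g0 <- build_idealized_podocyte(geometry_params(n_fp_quarter = 0))
  m <- morphometrics(g0)
  expect_equal(m$V, 420, tolerance = 1e-10)
  expect_equal(m$A, 695, tolerance = 1e-10)
  expect_equal(m$V_FP, 0)
})

test_that("FP cylinder dimensions follow the closed forms", {
  geom <- get_geom()
  r <- geom$dims$fp_radius
  expect_equal(r, 2 / 9)
  fp <- geom$parts[geom$parts$label == "FP", ][1, ]
  # lateral-surface cylinder: A/V = 2/r identically, V = pi r^2 L
  expect_equal(fp$area / fp$volume, 9)
  expect_equal(fp$volume, pi * r^2 * fp$length)
  expect_equal(fp$area, 2 * pi * r * fp$length)
  # per-FP volume close to the measured share (530 - 420)/233
  expect_equal(fp$volume, (530 - 420) / 233, tolerance = 0.005)
})

test_that("morphometric totals are additive and scale-invariant", {
  geom <- get_geom()
  m <- morphometrics(geom)
  expect_equal(m$V_CB_MP + m$V_FP, m$V)
  expect_equal(sum(geom$parts$volume), m$V)
  expect_equal(sum(geom$parts$area), m$A)
  # quarter-sphere cell body: A/V = 3/R in closed form
  cb <- geom$parts[geom$parts$label == "CB", ]
  expect_equal(cb$area / cb$volume, 3 / geom$dims$cb_radius)
  # whole-cell scaling by the symmetry factor leaves every ratio unchanged
  s <- geom$symmetry_factor
  expect_equal((s * m$A) / (s * m$V), m$AV)
  expect_equal((s * m$A_FP) / (s * m$V_FP), m$AV_FP)
})

test_that("infeasible target combinations raise named errors", {
  expect_error(
    build_idealized_podocyte(geometry_params(fp_area_to_volume = 0.5)),
    "minimum achievable")
  expect_error(
    build_idealized_podocyte(geometry_params(quarter_body_area = 200)),
    "area-to-volume target")
  expect_error(
    build_idealized_podocyte(geometry_params(mean_branchpoint_distance = 4,
                                             branchpoint_spread = 1)),
    "cell-body radius")
})

test_that("seeded jitter is reproducible and preserves the distance targets", {
  pj <- geometry_params(jitter = 1.5)
  g1 <- build_idealized_podocyte(pj, seed = 42)
  g2 <- build_idealized_podocyte(pj, seed = 42)
  g3 <- build_idealized_podocyte(pj, seed = 43)
  expect_identical(g1$segments, g2$segments)
  expect_false(identical(g1$segments, g3$segments))
  m <- morphometrics(g1)
  expect_equal(m$mean_branchpoint_distance, 18, tolerance = 1e-10)
  expect_equal(m$mean_furthest_endpoint_distance, 39, tolerance = 1e-10)
})

test_that("network discretization conserves volume and stays connected", {
  geom <- get_geom()
  for (res in c(1, 2)) {
    net <- as_compartment_network(geom, axial_resolution = res)
    expect_equal(sum(net$cells$volume), sum(geom$parts$volume),
                 tolerance = 1e-3)
    expect_equal(sum(net$cells$fp_id > 0, na.rm = TRUE), 233L)
  }
  expect_warning(as_compartment_network(geom, axial_resolution = 12),
                 "coarser")
})

test_that("a two-cell toy network has the finite-volume exchange rate", {
  cells <- data.frame(id = 1:2, label = "CB", volume = 5,
                      exposed_area = 1)
  net <- compartment_network(cells,
                             data.frame(a = 1, b = 2, area = 2, dist = 0.5))
  L <- podoactin:::network_laplacian(net)
  D <- 7
  # rate coefficient a*D/(d*V) for each cell
  expect_equal(D * L[1, 2] / cells$volume[1], 2 * 7 / (0.5 * 5))
  expect_equal(D * as.numeric(L[1, 1]), -D * as.numeric(L[1, 2]))
})

test_that("stratification identifies the cell body and handles edge cases", {
  st <- stratify_cell_body(get_net())
  expect_true(all(st$rel_conc[st$label == "CB"] >= 0.9))
  expect_true(all(st$rel_conc[st$label == "FP"] < 0.9))
  expect_true(all(st$rel_conc[st$label == "MP"] < 0.9))
  expect_true(all(st$is_cb == (st$rel_conc >= 0.9)))
  # no synthesis anywhere -> uniform zero field
  st0 <- stratify_cell_body(get_net(), synthesis_rate = 0)
  expect_true(all(st0$rel_conc == 0))
  # a single well-mixed cell: relative concentration 1, labeled CB
  one <- compartment_network(
    data.frame(id = 1, label = "CB", volume = 4 * pi / 3, exposed_area = 4 * pi),
    data.frame(a = integer(), b = integer(), area = numeric(),
               dist = numeric()))
  st1 <- stratify_cell_body(one)
  expect_equal(st1$rel_conc, 1)
  expect_true(st1$is_cb)
  # zero export everywhere: no steady state exists
  expect_error(stratify_cell_body(get_net(), export_coeff = 0),
               "no steady state")
})

test_that("stratification is monotone in export and converges under refinement", {
  net <- get_net()
  prev <- NULL
  for (ec in 0.05 * 10^seq(0, 1, length.out = 4)) {
    st <- stratify_cell_body(net, export_coeff = ec)
    if (!is.null(prev)) {
      below_max <- st$rel_conc < 1 - 1e-12
      expect_true(all(st$rel_conc[below_max] <=
                        prev$rel_conc[below_max] + 1e-9))
    }
    prev <- st
  }
  # grid convergence: the steady diffusion profile along each major
  # process, interpolated at matched arclength positions, changes < 2%
  # between 2 um and 1 um resolution
  profile <- function(res, arcs_by_part) {
    netr <- as_compartment_network(get_geom(), res)
    str <- stratify_cell_body(netr)
    mp <- netr$cells$label == "MP"
    out <- list()
    for (pt in unique(netr$cells$part[mp])) {
      sel <- mp & netr$cells$part == pt
      out[[as.character(pt)]] <- stats::approx(
        netr$cells$arc[sel], str$rel_conc[sel],
        xout = arcs_by_part[[as.character(pt)]], rule = 2)$y
    }
    out
  }
  net2 <- as_compartment_network(get_geom(), 2)
  mp2 <- net2$cells$label == "MP"
  arcs <- split(net2$cells$arc[mp2], net2$cells$part[mp2])
  p2 <- profile(2, arcs); p1 <- profile(1, arcs)
  expect_lt(max(abs(unlist(p2) - unlist(p1))), 0.02)
})

test_that("geometry and network survive a JSON round trip", {
  geom <- get_geom()
  tmp <- tempfile(fileext = ".json")
  write_geometry_json(geom, tmp)
  back <- read_geometry_json(tmp)
  expect_equal(morphometrics(back), morphometrics(geom))
  tmp2 <- tempfile(fileext = ".json")
  write_geometry_json(get_net(), tmp2)
  net2 <- read_geometry_json(tmp2)
  expect_equal(net2$cells$volume, get_net()$cells$volume)
  expect_equal(nrow(net2$interfaces), nrow(get_net()$interfaces))
  # morphometric CSV carries the measured-table row labels
  tmp3 <- tempfile(fileext = ".csv")
  df <- write_morphometrics_csv(geom, tmp3)
  expect_true("A_FP / V_FP, um^-1" %in% df$quantity)
  expect_equal(df$value[df$quantity == "No of branches"], 36)
})
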