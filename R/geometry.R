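#' Morphometric targets for the idealized podocyte geometry
#'
#' Collects the measured targets that the synthetic quarter-cell generator
#' must hit: foot-process count, branch count, area-to-volume ratios, the
#' cell-body-plus-major-process volume and area, and the characteristic
#' centroid-to-branch-point and endpoint distances. Defaults are the
#' idealized values for a healthy adult rat podocyte.
#'
#' @param n_fp_quarter number of foot processes (FPs) in the quarter cell.
#' @param n_branches_total number of major-process branches in the whole
#'   cell (the quarter-cell construction carries a quarter of them).
#' @param fp_area_to_volume target exposed-area-to-volume ratio of FPs
#'   (1/um).
#' @param body_area_to_volume target A/V for cell body plus major processes;
#'   `NULL` (default) derives it as `quarter_body_area/quarter_body_volume`.
#' @param quarter_body_volume volume of the quarter cell before FPs (um^3).
#' @param quarter_body_area exposed area of the quarter cell before FPs
#'   (um^2).
#' @param mean_branchpoint_distance target mean arclength from the cell
#'   centroid to the branch points (um).
#' @param furthest_endpoint_distance target mean arclength to the three
#'   furthest process endpoints (um).
#' @param cb_volume_share fraction of the body volume assigned to the cell
#'   body primitive (remainder goes to major processes).
#' @param fp_length length of each FP cylinder (um).
#' @param branchpoint_spread half-range of branch-point distances about
#'   their mean (um); the measured spread is about 6 um.
#' @param secondary_short_length length of the shorter secondary branches
#'   (um), matching the measured mean branch length.
#' @param jitter half-width of seeded uniform jitter applied to branch-point
#'   and endpoint distances (um); after jittering, distances are re-centred
#'   so the two distance targets still hold exactly.
#'
#' @return A `geometry_params` object.
#' @export
geometry_params <- function(n_fp_quarter = 233, n_branches_total = 36,
                            fp_area_to_volume = 9.0,
                            body_area_to_volume = NULL,
                            quarter_body_volume = 420,
                            quarter_body_area = 695,
                            mean_branchpoint_distance = 18,
                            furthest_endpoint_distance = 39,
                            cb_volume_share = 0.48, fp_length = 3.04,
                            branchpoint_spread = 6,
                            secondary_short_length = 11,
                            jitter = 0) {
  if (is.null(body_area_to_volume))
    body_area_to_volume <- quarter_body_area / quarter_body_volume
  p <- list(n_fp_quarter = as.integer(n_fp_quarter),
            n_branches_total = as.integer(n_branches_total),
            fp_area_to_volume = fp_area_to_volume,
            body_area_to_volume = body_area_to_volume,
            quarter_body_volume = quarter_body_volume,
            quarter_body_area = quarter_body_area,
            mean_branchpoint_distance = mean_branchpoint_distance,
            furthest_endpoint_distance = furthest_endpoint_distance,
            cb_volume_share = cb_volume_share, fp_length = fp_length,
            branchpoint_spread = branchpoint_spread,
            secondary_short_length = secondary_short_length,
            jitter = jitter)
  num <- p[!names(p) %in% c("n_fp_quarter", "jitter")]
  if (any(!vapply(num, function(x) is.numeric(x) && x > 0, logical(1))))
    stop("all geometry targets must be positive numbers")
  if (p$n_fp_quarter < 0) stop("'n_fp_quarter' must be >= 0")
  if (p$n_branches_total < 4) stop("'n_branches_total' must be >= 4")
  if (p$cb_volume_share >= 1) stop("'cb_volume_share' must be < 1")
  structure(p, class = "geometry_params")
}

# perimeter of a full ellipse with semi-axes a, b (Ramanujan II approximation;
# relative error < 1e-6 for the aspect ratios used here)
ellipse_perimeter <- function(a, b) {
  h <- ((a - b) / (a + b))^2
  pi * (a + b) * (1 + 3 * h / (10 + sqrt(4 - 3 * h)))
}

#' Build the idealized quarter-podocyte geometry
#'
#' Constructs a tree of geometric primitives matching the morphometric
#' targets: the cell body (CB) is a quarter-sphere (two reflective symmetry
#' planes), major processes (MP) are half-elliptical ribbons lying on the
#' sagittal plane (primary branches ending at branch points, each carrying
#' secondary branches), and foot processes (FP) are thin cylinders emanating
#' perpendicular to the symmetry plane, evenly spaced along the MP
#' centerlines. The CB radius follows from the CB volume share; the MP
#' cross-section semi-axes are solved so the CB+MP area and volume targets
#' hold exactly; branch points and endpoints are placed so the distance
#' targets hold exactly; the FP radius is `2 / fp_area_to_volume` (lateral
#' cylinder surface).
#'
#' @param params a [geometry_params()] object.
#' @param seed integer seed for the optional placement jitter; ignored when
#'   `jitter = 0`.
#' @return A `podocyte_geometry` object: list with `parts` (data.frame of
#'   primitives with label, volume, area, length, parent and attachment
#'   arclength), `segments` (MP centerline table), `params`, and
#'   `symmetry_factor = 4`.
#' @export
build_idealized_podocyte <- function(params = geometry_params(), seed = NULL) {
  p <- params
  V_body <- p$quarter_body_volume
  A_body <- p$quarter_body_area
  V_cb <- p$cb_volume_share * V_body
  R <- (3 * V_cb / pi)^(1 / 3)            # quarter-sphere: V = pi R^3 / 3
  A_cb <- pi * R^2                        # exposed quarter of sphere surface
  if (A_cb >= A_body)
    stop("infeasible targets: cell-body area (", round(A_cb, 1),
         ") exceeds the quarter body area target (", A_body,
         "); reduce 'cb_volume_share'")
  V_mp <- V_body - V_cb
  A_mp <- A_body - A_cb

  # --- branch layout ------------------------------------------------------
  nq <- p$n_branches_total / 4
  if (nq != round(nq))
    stop("'n_branches_total' must be divisible by the symmetry factor 4")
  nq <- as.integer(nq)
  n_primary <- max(1L, as.integer(round(nq / 3)))
  n_secondary <- nq - n_primary
  if (n_secondary < 3)
    stop("branch layout needs at least 3 secondary branches per quarter")
  spread <- if (n_primary > 1)
    p$branchpoint_spread * seq(-1, 1, length.out = n_primary) else 0
  bp <- p$mean_branchpoint_distance + spread
  far <- p$furthest_endpoint_distance + seq(-1, 1, length.out = 3)
  if (p$jitter > 0) {
    if (!is.null(seed)) set.seed(seed)
    bp <- bp + stats::runif(n_primary, -p$jitter, p$jitter)
    bp <- bp + (p$mean_branchpoint_distance - mean(bp))     # re-centre mean
    far <- far + stats::runif(3, -p$jitter, p$jitter)
    far <- far + (p$furthest_endpoint_distance - mean(far))
  }
  if (any(bp <= R))
    stop("infeasible targets: branch-point distance (min ", round(min(bp), 1),
         " um) does not clear the cell-body radius (", round(R, 1), " um)")
  # secondaries per primary, round-robin; the three far endpoints go to
  # distinct primaries (cycled), the rest are short branches
  sec_of <- rep(seq_len(n_primary), length.out = n_secondary)
  segs <- data.frame(seg_id = integer(), parent = integer(),
                     arc_start = numeric(), arc_end = numeric(),
                     kind = character())
  sid <- 0L
  for (i in seq_len(n_primary)) {
    sid <- sid + 1L
    segs <- rbind(segs, data.frame(seg_id = sid, parent = 0L,
                                   arc_start = R, arc_end = bp[i],
                                   kind = "primary"))
  }
  far_assigned <- 0L
  for (j in seq_len(n_secondary)) {
    i <- sec_of[j]
    first_on_primary <- !any(segs$parent == i & segs$kind == "secondary")
    if (first_on_primary && far_assigned < 3) {
      far_assigned <- far_assigned + 1L
      tip <- far[far_assigned]
    } else {
      tip <- bp[i] + p$secondary_short_length
    }
    if (tip <= bp[i])
      stop("infeasible targets: endpoint distance ", round(tip, 1),
           " um does not clear its branch point at ", round(bp[i], 1), " um")
    sid <- sid + 1L
    segs <- rbind(segs, data.frame(seg_id = sid, parent = i,
                                   arc_start = bp[i], arc_end = tip,
                                   kind = "secondary"))
  }
  segs$length <- segs$arc_end - segs$arc_start
  sum_L <- sum(segs$length)

  # --- MP cross-section: half-ellipse solved from area + volume ----------
  area_cs <- V_mp / sum_L                 # cross-section area  = pi a b / 2
  per_target <- A_mp / sum_L              # exposed half-perimeter per length
  ab_prod <- 2 * area_cs / pi
  circle_per <- ellipse_perimeter(sqrt(ab_prod), sqrt(ab_prod)) / 2
  if (per_target <= circle_per)
    stop("infeasible targets: body area-to-volume target (",
         round(p$body_area_to_volume, 2), " 1/um) is below the minimum ",
         "achievable for half-elliptical major processes of the required ",
         "total length")
  f_aspect <- function(asp) {
    a <- sqrt(ab_prod * asp)
    ellipse_perimeter(a, a / asp) / 2 - per_target
  }
  asp <- stats::uniroot(f_aspect, c(1 + 1e-9, 1e4), tol = 1e-12)$root
  a_mp <- sqrt(ab_prod * asp)
  b_mp <- a_mp / asp

  # --- FP primitive: cylinder, lateral surface exposed --------------------
  r_fp <- 2 / p$fp_area_to_volume
  if (r_fp >= p$fp_length)
    stop("infeasible targets: FP area-to-volume target ",
         p$fp_area_to_volume, " 1/um is below the minimum achievable for ",
         "a cylinder of length ", p$fp_length, " um")
  V_fp1 <- pi * r_fp^2 * p$fp_length
  A_fp1 <- 2 * pi * r_fp * p$fp_length

  # --- assemble parts table ----------------------------------------------
  parts <- data.frame(part_id = 1L, label = "CB", volume = V_cb,
                      area = A_cb, length = R, parent = NA_integer_,
                      attach_arc = NA_real_)
  for (s in seq_len(nrow(segs))) {
    parts <- rbind(parts, data.frame(
      part_id = 1L + segs$seg_id[s], label = "MP",
      volume = area_cs * segs$length[s], area = per_target * segs$length[s],
      length = segs$length[s],
      parent = if (segs$parent[s] == 0L) 1L else 1L + segs$parent[s],
      attach_arc = segs$arc_start[s]))
  }
  n_mp_parts <- nrow(segs)
  if (p$n_fp_quarter > 0) {
    pos <- (seq_len(p$n_fp_quarter) - 0.5) / p$n_fp_quarter * sum_L
    cum <- c(0, cumsum(segs$length))
    seg_of <- findInterval(pos, cum, rightmost.closed = TRUE)
    arc <- segs$arc_start[seg_of] + (pos - cum[seg_of])
    parts <- rbind(parts, data.frame(
      part_id = 1L + n_mp_parts + seq_len(p$n_fp_quarter), label = "FP",
      volume = V_fp1, area = A_fp1, length = p$fp_length,
      parent = 1L + segs$seg_id[seg_of], attach_arc = arc))
  }
  structure(list(parts = parts, segments = segs, params = p,
                 symmetry_factor = 4,
                 dims = list(cb_radius = R, mp_a = a_mp, mp_b = b_mp,
                             mp_cross_section = area_cs,
                             mp_perimeter = per_target, fp_radius = r_fp,
                             branch_points = bp, far_endpoints = far)),
            class = "podocyte_geometry")
}

#' @export
print.podocyte_geometry <- function(x, ...) {
  m <- morphometrics(x)
  cat(sprintf(paste0("Idealized quarter-podocyte: V = %.1f um^3, ",
                     "A = %.1f um^2, %d FPs, %d branches (whole cell)\n"),
              m$V, m$A, sum(x$parts$label == "FP"), m$n_branches))
  invisible(x)
}

#' Morphometric summary of a podocyte geometry
#'
#' Computes volumes, areas and the diagnostic ratios of the geometry.
#' Volumes and areas are quarter-cell values (the construction scale);
#' counts (`n_branches`) are reported at whole-cell scale via the symmetry
#' factor. Ratios are scale-invariant.
#'
#' @param geom a `podocyte_geometry`.
#' @return A list with fields `V`, `A`, `V_CB_MP`, `A_CB_MP`, `V_FP`,
#'   `A_FP`, `AV`, `AV_CB_MP`, `AV_FP`, `V_FP_over_V_pct`, `area_gain_pct`,
#'   `n_branches`, `mean_branchpoint_distance`,
#'   `mean_furthest_endpoint_distance`, `symmetry_factor`.
#' @export
morphometrics <- function(geom) {
  stopifnot(inherits(geom, "podocyte_geometry"))
  pt <- geom$parts
  body <- pt$label %in% c("CB", "MP")
  V <- sum(pt$volume); A <- sum(pt$area)
  V_body <- sum(pt$volume[body]); A_body <- sum(pt$area[body])
  V_fp <- V - V_body; A_fp <- A - A_body
  tips <- geom$segments$arc_end[
    !geom$segments$seg_id %in% geom$segments$parent]
  list(V = V, A = A, V_CB_MP = V_body, A_CB_MP = A_body,
       V_FP = V_fp, A_FP = A_fp,
       AV = A / V, AV_CB_MP = A_body / V_body,
       AV_FP = if (V_fp > 0) A_fp / V_fp else NA_real_,
       V_FP_over_V_pct = 100 * V_fp / V,
       area_gain_pct = 100 * (A - A_body) / A_body,
       n_branches = as.integer(nrow(geom$segments) * geom$symmetry_factor),
       mean_branchpoint_distance = mean(geom$dims$branch_points),
       mean_furthest_endpoint_distance =
         mean(sort(tips, decreasing = TRUE)[1:min(3, length(tips))]),
       symmetry_factor = geom$symmetry_factor)
}

#' Write a morphometric summary as a CSV with the measured-table row labels
#'
#' @param geom a `podocyte_geometry`.
#' @param path output CSV path.
#' @return Invisibly, the written data.frame.
#' @export
write_morphometrics_csv <- function(geom, path) {
  m <- morphometrics(geom)
  df <- data.frame(
    quantity = c("A_CB+MP / V_CB+MP, um^-1", "A / V, um^-1",
                 "A_FP / V_FP, um^-1", "(A-A_CB+MP)/A_CB+MP, %",
                 "V_FP/V, %", "No of branches"),
    value = c(m$AV_CB_MP, m$AV, m$AV_FP, m$area_gain_pct,
              m$V_FP_over_V_pct, m$n_branches))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}

#' Construct a compartment network directly from tables
#'
#' Lower-level constructor used by [as_compartment_network()] and handy for
#' building toy networks in analyses and tests.
#'
#' @param cells data.frame with columns `id`, `label`, `volume`,
#'   `exposed_area`, and optionally `fp_id` (index of the foot process the
#'   cell belongs to) and `arc`.
#' @param interfaces data.frame with columns `a`, `b` (cell ids), `area`,
#'   `dist` (contact area and centre-to-centre distance).
#' @return A `compartment_network`.
#' @export
compartment_network <- function(cells, interfaces) {
  stopifnot(all(c("id", "label", "volume", "exposed_area") %in% names(cells)),
            all(c("a", "b", "area", "dist") %in% names(interfaces)) ||
              nrow(interfaces) == 0)
  if (!"fp_id" %in% names(cells)) cells$fp_id <- NA_integer_
  if (any(cells$volume <= 0)) stop("cell volumes must be positive")
  if (nrow(interfaces) && any(interfaces$area <= 0 | interfaces$dist <= 0))
    stop("interface areas and distances must be positive")
  net <- structure(list(cells = cells, interfaces = interfaces),
                   class = "compartment_network")
  if (!network_connected(net)) stop("compartment network is not connected")
  net
}

network_connected <- function(net) {
  n <- nrow(net$cells)
  if (n <= 1) return(TRUE)
  idx <- match(c(net$interfaces$a, net$interfaces$b), net$cells$id)
  adj <- split(c(matrix(idx, ncol = 2)[, 2:1]), matrix(idx, ncol = 2))
  seen <- logical(n); seen[1] <- TRUE; queue <- 1L
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    nb <- adj[[as.character(v)]]
    new <- nb[!seen[nb]]
    seen[new] <- TRUE
    queue <- c(queue, new)
  }
  all(seen)
}

#' Discretize a podocyte geometry into a finite-volume compartment network
#'
#' Major-process centerlines are divided into cells of length at most
#' `axial_resolution`; the cell body becomes concentric quarter-sphere
#' shells of comparable thickness; each foot process becomes a single
#' well-mixed cell connected to its parent MP cell through a neck interface.
#' Interface areas are the cross-section areas of the primitives; distances
#' are centre-to-centre along the centerlines. Total volume is conserved
#' exactly by construction.
#'
#' @param geom a `podocyte_geometry`.
#' @param axial_resolution maximum axial cell length (um).
#' @return A `compartment_network` whose cells carry `label`
#'   (CB/MP/FP), `volume`, `exposed_area`, `fp_id` and arclength `arc`.
#' @export
as_compartment_network <- function(geom, axial_resolution = 2) {
  stopifnot(inherits(geom, "podocyte_geometry"), axial_resolution > 0)
  d <- geom$dims
  segs <- geom$segments
  if (axial_resolution > min(segs$length))
    warning("axial_resolution is coarser than the shortest MP segment (",
            round(min(segs$length), 2), " um); such segments get one cell")
  cells <- list(); ifaces <- list()
  nid <- 0L
  new_cell <- function(label, volume, area, fp_id = NA_integer_, arc = NA,
                       part = NA_integer_) {
    nid <<- nid + 1L
    cells[[nid]] <<- data.frame(id = nid, label = label, volume = volume,
                                exposed_area = area, fp_id = fp_id,
                                arc = arc, part = part)
    nid
  }
  add_iface <- function(a, b, area, dist) {
    ifaces[[length(ifaces) + 1L]] <<- data.frame(a = a, b = b, area = area,
                                                 dist = dist)
  }
  # junction grading: cells abutting a junction get a fixed small width so
  # junction conductances do not depend on axial_resolution (keeps the
  # stratification and reaction-diffusion profiles grid-convergent)
  l_junction <- min(0.25, axial_resolution / 2)
  # CB: concentric quarter-sphere shells; membrane area on the outer shell;
  # thin outermost shell per the junction grading
  R <- d$cb_radius
  nsh <- max(1L, ceiling((R - l_junction) / axial_resolution))
  edges <- c(seq(0, R - l_junction, length.out = nsh + 1), R)
  nsh <- nsh + 1L
  shell_ids <- integer(nsh)
  for (s in seq_len(nsh)) {
    vol <- pi * (edges[s + 1]^3 - edges[s]^3) / 3
    area <- if (s == nsh) pi * R^2 else 0
    shell_ids[s] <- new_cell("CB", vol, area,
                             arc = (edges[s] + edges[s + 1]) / 2, part = 1L)
    if (s > 1) {
      # exact quarter-sphere radial conductance between shell centers a, b:
      # g = pi*D/(1/a - 1/b) = D * (pi*a*b)/(b - a), encoded as an
      # effective interface area pi*a*b (2nd-order accurate under refinement)
      a <- (edges[s - 1] + edges[s]) / 2
      b <- (edges[s] + edges[s + 1]) / 2
      add_iface(shell_ids[s - 1], shell_ids[s], pi * a * b, b - a)
    }
  }
  cb_outer <- shell_ids[nsh]
  # MP segments
  seg_cells <- vector("list", nrow(segs))
  for (s in seq_len(nrow(segs))) {
    s0 <- segs$arc_start[s]; s1 <- segs$arc_end[s]
    L <- s1 - s0
    grade <- function() {
      ws <- numeric(0); w <- l_junction
      while (sum(ws) + w < L / 2 - axial_resolution / 2) {
        ws <- c(ws, w); w <- min(2 * w, axial_resolution)
      }
      ws
    }
    left <- grade(); right <- grade()
    mid <- L - sum(left) - sum(right)
    nmid <- max(1L, ceiling(mid / axial_resolution))
    b <- s0 + cumsum(c(0, left, rep(mid / nmid, nmid), rev(right)))
    b[length(b)] <- s1
    n <- length(b) - 1L
    ids <- integer(n)
    for (ci in seq_len(n)) {
      l <- b[ci + 1] - b[ci]
      ids[ci] <- new_cell("MP", d$mp_cross_section * l, d$mp_perimeter * l,
                          arc = (b[ci] + b[ci + 1]) / 2,
                          part = 1L + segs$seg_id[s])
      if (ci > 1)
        add_iface(ids[ci - 1], ids[ci], d$mp_cross_section,
                  (b[ci + 1] - b[ci - 1]) / 2)
    }
    seg_cells[[s]] <- list(ids = ids, bounds = b)
    if (segs$parent[s] == 0L) {
      add_iface(cb_outer, ids[1], d$mp_cross_section,
                (b[2] - b[1]) / 2 + (R - cells[[cb_outer]]$arc))
    } else {
      par <- which(segs$seg_id == segs$parent[s])
      pids <- seg_cells[[par]]$ids; pb <- seg_cells[[par]]$bounds
      add_iface(pids[length(pids)], ids[1], d$mp_cross_section,
                (pb[length(pb)] - pb[length(pb) - 1]) / 2 + (b[2] - b[1]) / 2)
    }
  }
  # FPs: one cell each, neck interface to the containing MP cell
  fps <- geom$parts[geom$parts$label == "FP", , drop = FALSE]
  if (nrow(fps)) {
    for (fi in seq_len(nrow(fps))) {
      s <- which(segs$seg_id == fps$parent[fi] - 1L)
      sc <- seg_cells[[s]]
      ci <- findInterval(fps$attach_arc[fi], sc$bounds,
                         rightmost.closed = TRUE)
      ci <- min(max(ci, 1L), length(sc$ids))
      fid <- new_cell("FP", fps$volume[fi], fps$area[fi], fp_id = fi,
                      arc = fps$attach_arc[fi], part = fps$part_id[fi])
      add_iface(sc$ids[ci], fid, pi * d$fp_radius^2,
                fps$length[fi] / 2 + d$mp_b / 2)
    }
  }
  compartment_network(do.call(rbind, cells), do.call(rbind, ifaces))
}

#' @export
print.compartment_network <- function(x, ...) {
  tab <- table(x$cells$label)
  cat(sprintf("Compartment network: %d cells (%s), %d interfaces, V = %.1f um^3\n",
              nrow(x$cells),
              paste(names(tab), tab, sep = ":", collapse = ", "),
              nrow(x$interfaces), sum(x$cells$volume)))
  invisible(x)
}

# sparse exchange (graph Laplacian-like) matrix with entries A_ij/d_ij;
# multiply by D and divide rows by cell volume to get rate coefficients
network_laplacian <- function(net) {
  n <- nrow(net$cells)
  ia <- match(net$interfaces$a, net$cells$id)
  ib <- match(net$interfaces$b, net$cells$id)
  g <- net$interfaces$area / net$interfaces$dist
  Matrix::sparseMatrix(
    i = c(ia, ib, ia, ib), j = c(ib, ia, ia, ib),
    x = c(g, g, -g, -g), dims = c(n, n))
}

#' Identify the cell body by diffusion stratification
#'
#' Solves the steady linear balance of a species synthesized uniformly
#' throughout the volume, diffusing between compartments, and exported
#' across the membrane in proportion to the local concentration (the heat
#' transfer analogue of uniform volumetric generation with a convective
#' boundary). Regions with low surface-to-volume ratio, i.e. the cell body,
#' retain close to the maximum concentration; thin processes equilibrate
#' much lower. Cells at or above `threshold` of the maximum are labeled as
#' cell body.
#'
#' @param net a `compartment_network`.
#' @param D diffusion coefficient (um^2/time).
#' @param synthesis_rate uniform volumetric synthesis rate (conc/time);
#'   scalar or per-cell.
#' @param export_coeff membrane export (mass-transfer) coefficient
#'   (um/time, default 0.15); scalar or per-cell.
#' @param threshold relative concentration above which a cell is labeled CB
#'   (default 0.9).
#' @return data.frame with `id`, `label` (geometric label), `rel_conc`
#'   (concentration normalized by the maximum), `is_cb`.
#' @export
stratify_cell_body <- function(net, D = 10, synthesis_rate = 1,
                               export_coeff = 0.15, threshold = 0.9) {
  stopifnot(inherits(net, "compartment_network"), D > 0, threshold > 0)
  n <- nrow(net$cells)
  syn <- rep_len(synthesis_rate, n)
  exp_c <- rep_len(export_coeff, n)
  if (any(syn < 0) || any(exp_c < 0))
    stop("synthesis and export coefficients must be non-negative")
  if (all(exp_c * net$cells$exposed_area == 0) && any(syn > 0))
    stop("no membrane export anywhere: no steady state exists with nonzero synthesis")
  L <- network_laplacian(net)
  M <- Matrix::Diagonal(x = exp_c * net$cells$exposed_area) - D * L
  conc <- as.numeric(Matrix::solve(M, syn * net$cells$volume))
  rel <- if (max(conc) > 0) conc / max(conc) else conc
  data.frame(id = net$cells$id, label = net$cells$label, rel_conc = rel,
             is_cb = rel >= threshold)
}

#' Serialize a geometry or network to JSON
#'
#' The JSON schema mirrors the in-memory structure: a geometry has `parts`,
#' `segments`, `params` and `dims`; a network has `cells` and `interfaces`.
#'
#' @param x a `podocyte_geometry` or `compartment_network`.
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
write_geometry_json <- function(x, path) {
  obj <- unclass(x)
  if (!is.null(obj$params)) obj$params <- unclass(obj$params)
  obj$.class <- class(x)[1]
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       dataframe = "columns")
  invisible(path)
}

#' Read a geometry or network serialized by [write_geometry_json()]
#'
#' @param path JSON file.
#' @return The restored object.
#' @export
read_geometry_json <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  cls <- obj$.class
  obj$.class <- NULL
  for (nm in intersect(names(obj), c("parts", "segments", "cells",
                                     "interfaces")))
    obj[[nm]] <- as.data.frame(obj[[nm]])
  if (identical(cls, "compartment_network"))
    return(compartment_network(obj$cells, obj$interfaces))
  structure(obj, class = cls)
}
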