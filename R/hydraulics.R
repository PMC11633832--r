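#' Theoretical axial conductivity of elliptical xylem conduits
#'
#' Hagen-Poiseuille law adapted for elliptical conduits:
#' `Kh = pi / (64 * eta) * sum_i a_i^3 b_i^3 / (a_i^2 + b_i^2)`,
#' where `a_i` and `b_i` are the minor and major diameters of vessel i in
#' metres and `eta` the dynamic viscosity of water. Additive over vessels;
#' in the circular limit (a = b = d) it reduces to the classical
#' `pi d^4 / (128 eta)`.
#'
#' @param minor,major vessel minor/major diameters, metres (same length).
#' @param eta dynamic viscosity, MPa s (default water at 20 degC,
#'   1.002e-9).
#' @return axial conductivity in m^4 s^-1 MPa^-1.
#' @export
kh_theoretical <- function(minor, major, eta = 1.002e-9) {
  if (!length(minor)) stop("at least one vessel required")
  if (length(minor) != length(major)) stop("minor/major length mismatch")
  if (any(minor <= 0) || any(major <= 0)) stop("vessel dimensions must be > 0")
  if (any(minor > major + 1e-15)) stop("minor diameter exceeds major")
  stopifnot(eta > 0)
  pi / (64 * eta) * sum(minor^3 * major^3 / (minor^2 + major^2))
}

#' Convert axial conductivity to head-based per-day units
#'
#' Converts Kh in m^4 s^-1 MPa^-1 (pressure-gradient based) to
#' cm^3 d^-1 per unit head gradient (cm cm^-1): multiply by
#' 9.80665e-3 MPa m^-1 (the pressure gradient equivalent to 1 cm head per
#' cm), 86400 s d^-1 and 1e6 cm^3 m^-3.
#'
#' @param kh conductivity, m^4 s^-1 MPa^-1 (vectorized, >= 0).
#' @return conductivity in cm^3 d^-1 (per cm/cm head gradient).
#' @export
convert_kh_units <- function(kh) kh * 9.80665e-3 * 86400 * 1e6

#' Inverse of [convert_kh_units()]
#' @param kh_cm conductivity in cm^3 d^-1 per unit head gradient.
#' @return m^4 s^-1 MPa^-1.
#' @export
convert_kh_units_inv <- function(kh_cm) kh_cm / (9.80665e-3 * 86400 * 1e6)

#' Fit a power-law conductivity-diameter relation
#'
#' Fits `Kh = alpha * d^beta` to (root diameter, axial conductivity)
#' samples by damped (Levenberg-Marquardt) least squares, initialized from
#' ordinary least squares on the log-log transformed data.
#'
#' @param diameter root diameters at the sampled cross-sections, cm (> 0,
#'   at least 3 distinct values).
#' @param kh axial conductivities (any consistent unit; the fitted alpha
#'   inherits it).
#' @return list of class `kx_fit`: `alpha`, `beta`, `rss`, `fitted`.
#' @export
fit_kx_vs_diameter <- function(diameter, kh) {
  stopifnot(length(diameter) == length(kh))
  if (any(diameter <= 0)) stop("diameters must be positive")
  if (length(unique(diameter)) < 3L) stop("need >= 3 distinct diameters")
  if (any(kh <= 0)) stop("conductivities must be positive")
  init <- stats::lm(log(kh) ~ log(diameter))
  start <- list(alpha = exp(stats::coef(init)[[1]]),
                beta = stats::coef(init)[[2]])
  if (abs(start$beta) < 1e-8) start$beta <- 1e-8  # allow constant data
  df <- data.frame(d = diameter, kh = kh)
  fit <- minpack.lm::nlsLM(kh ~ alpha * d^beta, data = df, start = start,
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  co <- stats::coef(fit)
  structure(list(alpha = co[["alpha"]], beta = co[["beta"]],
                 rss = sum(stats::resid(fit)^2), fitted = fit),
            class = "kx_fit")
}

#' Hydraulic parameter set
#'
#' Bundles what the water-flow solver needs: a power-law mapping from root
#' diameter (cm) to axial conductance kx (cm^3 d^-1 per unit head
#' gradient), and a radial-conductivity lookup kr (d^-1: flux per unit
#' head per unit root surface) keyed by root type and age class.
#'
#' The default kr table is a synthetic placeholder with three classes
#' (unsuberized young laterals, suberized older laterals, woody type-1
#' roots), orders of magnitude consistent with published grapevine
#' fine-root Lpr around 1e-7 m s^-1 MPa^-1; override it with measured
#' values via `kr_table` or a YAML config for any serious use.
#'
#' @param kx_alpha,kx_beta power-law coefficients for kx(d) = alpha*d^beta
#'   with d in cm and kx in cm^3/d per cm/cm.
#' @param kr_table data.frame with columns `type`, `age_min`, `age_max`,
#'   `kr`; age classes must be non-overlapping and cover `[0, Inf)` per
#'   type present in the root system.
#' @param eta dynamic viscosity, MPa s.
#' @param file optional YAML file with fields `kx: {alpha, beta}` and
#'   `kr: [{type, age_min, age_max, kr}, ...]` overriding the defaults.
#' @return list of class `hydraulic_params`.
#' @export
hydraulic_params <- function(kx_alpha = 0.05, kx_beta = 2.5,
                             kr_table = NULL, eta = 1.002e-9, file = NULL) {
  if (!is.null(file)) {
    cfg <- yaml::read_yaml(file)
    if (!is.null(cfg$kx)) { kx_alpha <- cfg$kx$alpha; kx_beta <- cfg$kx$beta }
    if (!is.null(cfg$kr))
      kr_table <- do.call(rbind, lapply(cfg$kr, as.data.frame))
    if (!is.null(cfg$eta)) eta <- cfg$eta
  }
  if (is.null(kr_table)) {
    kr_table <- data.frame(
      type = c(0L, 1L, 2L, 2L, 3L, 3L),
      age_min = c(0, 0, 0, 30, 0, 30),
      age_max = c(Inf, Inf, 30, Inf, 30, Inf),
      kr = c(0,       # stem: non-absorbing
             5e-6,    # woody adventitious
             8.5e-5, 2e-5,   # type 2: unsuberized < 30 d, suberized
             8.5e-5, 2e-5))  # type 3: idem
  }
  stopifnot(all(kr_table$kr >= 0), eta > 0, kx_alpha > 0)
  structure(list(kx_alpha = kx_alpha, kx_beta = kx_beta,
                 kr_table = kr_table, eta = eta),
            class = "hydraulic_params")
}

# kr lookup (vectorized over segments)
kr_lookup <- function(hp, type, age) {
  tab <- hp$kr_table
  out <- numeric(length(type))
  for (i in seq_along(type)) {
    hit <- which(tab$type == type[i] & age[i] >= tab$age_min &
                   age[i] < tab$age_max)
    if (!length(hit))
      stop("no kr entry for type ", type[i], ", age ", age[i])
    out[i] <- tab$kr[hit[1]]
  }
  out
}

# axial conductance from diameter via the power law
kx_lookup <- function(hp, diameter) hp$kx_alpha * diameter^hp$kx_beta

# flatten a root system into a segment table with global node indices;
# shared branch nodes map to a single global node
build_segment_network <- function(rs) {
  n_axes <- length(rs$axes)
  node_gid <- vector("list", n_axes)
  coords <- list(); gid <- 0L
  for (i in seq_len(n_axes)) {
    a <- rs$axes[[i]]
    n <- nrow(a$nodes)
    ids <- integer(n)
    start <- 1L
    if (!is.na(a$parent)) {
      ids[1L] <- node_gid[[a$parent]][a$parent_node]
      start <- 2L
    }
    for (k in start:n) {
      gid <- gid + 1L
      ids[k] <- gid
      coords[[gid]] <- a$nodes[k, ]
    }
    node_gid[[i]] <- ids
  }
  segs <- list()
  for (i in seq_len(n_axes)) {
    a <- rs$axes[[i]]
    n <- nrow(a$nodes)
    gl <- node_gid[[i]]
    len <- sqrt(rowSums((a$nodes[-1, , drop = FALSE] -
                           a$nodes[-n, , drop = FALSE])^2))
    segs[[i]] <- data.frame(
      axis = i, prox = gl[-n], dist = gl[-1],
      length = len, radius = a$radius, type = a$type,
      age = (a$ages[-n] + a$ages[-1]) / 2,
      z_mid = (a$nodes[-n, 3] + a$nodes[-1, 3]) / 2)
  }
  segs <- do.call(rbind, segs)
  list(segments = segs, n_nodes = gid,
       coords = do.call(rbind, coords), node_gid = node_gid)
}

#' Solve the root-system water-flow model for SUF and Krs
#'
#' Doussan-type steady-state xylem flow on the segment network: each
#' segment j carries an axial conductance `kx(d_j) / l_j` between its end
#' nodes and a radial conductance `kr(type_j, age_j) * 2 pi a_j l_j`
#' linking the soil to the xylem (lumped half to each end node, which
#' makes the discretization second-order accurate). With a uniform soil
#' total potential (hydrostatic equilibrium, so gravity terms cancel) and
#' a fixed collar potential, node xylem potentials solve a sparse
#' symmetric mass-balance system. The standard uptake fraction of a
#' segment is its share of total radial inflow; the root system
#' conductance is total inflow per unit soil-to-collar potential
#' difference. By linearity, SUF is independent of the chosen potentials.
#'
#' @param rs a `root_system` with radii and node ages.
#' @param hp a `hydraulic_params` object.
#' @param psi_soil,psi_collar soil and collar total potentials, cm head
#'   (only their difference matters, and SUF not even on that).
#' @return list of class `hydraulic_solution`: `suf` (per segment, sums
#'   to 1), `krs` (cm^3 cm^-1 d^-1), `psi` (per global node, cm head),
#'   `segments` (the segment table with `suf` column), `network`.
#' @export
solve_suf_krs <- function(rs, hp, psi_soil = 0, psi_collar = -1000) {
  net <- build_segment_network(rs)
  sg <- net$segments
  if (any(is.na(sg$radius))) stop("every axis needs a radius")
  n <- net$n_nodes
  kx <- kx_lookup(hp, 2 * sg$radius)
  if (any(kx <= 0)) stop("non-positive axial conductance")
  c_ax <- kx / sg$length
  kr <- kr_lookup(hp, sg$type, sg$age)
  c_rad <- kr * 2 * pi * sg$radius * sg$length

  # collar = proximal end of the stem if present, else of the first axis
  types <- axis_types(rs)
  collar_axis <- if (any(types == 0L)) which(types == 0L)[1] else 1L
  collar <- net$node_gid[[collar_axis]][1L]

  # assemble sparse system over all nodes, then impose Dirichlet collar
  ii <- c(sg$prox, sg$dist, sg$prox, sg$dist)
  jj <- c(sg$dist, sg$prox, sg$prox, sg$dist)
  xx <- c(-c_ax, -c_ax, c_ax + c_rad / 2, c_ax + c_rad / 2)
  A <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n))
  b <- numeric(n)
  half <- c_rad / 2
  for (s in seq_len(nrow(sg))) {
    b[sg$prox[s]] <- b[sg$prox[s]] + half[s] * psi_soil
    b[sg$dist[s]] <- b[sg$dist[s]] + half[s] * psi_soil
  }
  free <- setdiff(seq_len(n), collar)
  b_free <- b[free] - A[free, collar, drop = TRUE] * psi_collar
  psi <- numeric(n)
  psi[collar] <- psi_collar
  sol <- tryCatch(
    Matrix::solve(A[free, free, drop = FALSE], b_free),
    error = function(e) stop("singular hydraulic system: ",
                             conditionMessage(e)))
  psi[free] <- as.numeric(sol)

  inflow <- half * (psi_soil - psi[sg$prox]) + half * (psi_soil - psi[sg$dist])
  total <- sum(inflow)
  if (total <= 0) stop("no radial uptake (all kr zero?)")
  suf <- inflow / total
  krs <- total / (psi_soil - psi_collar)
  sg$suf <- suf
  structure(list(suf = suf, krs = krs, psi = psi, segments = sg,
                 network = net),
            class = "hydraulic_solution")
}

#' @export
print.hydraulic_solution <- function(x, ...) {
  cat(sprintf("hydraulic_solution: %d segments, Krs = %.4g cm^3 cm^-1 d^-1\n",
              length(x$suf), x$krs))
  invisible(x)
}

#' SUF aggregated per soil layer and horizon
#'
#' Apportions each segment's uptake fraction to depth bins by the same
#' linear clipping rule as the root-length depth profile, then aggregates
#' layers into the stated soil horizons. Refining the layer thickness
#' leaves horizon aggregates unchanged.
#'
#' @param sol a `hydraulic_solution`.
#' @param layer_thickness layer height, cm.
#' @param horizon_breaks horizon boundaries in cm depth (default
#'   `c(0, 30, 60, 90, 120)`, i.e. horizons 0-30, 31-60, 61-90, 91-120).
#' @return list `layers` (data.frame `depth_top`, `depth_bottom`, `suf`),
#'   `horizons` (data.frame `horizon`, `suf`).
#' @export
suf_profile <- function(sol, layer_thickness = 1,
                        horizon_breaks = c(0, 30, 60, 90, 120)) {
  sg <- sol$segments
  net <- sol$network
  z1 <- net$coords[sg$prox, 3]
  z2 <- net$coords[sg$dist, 3]
  layers <- bin_by_depth(z1, z2, sol$suf, layer_thickness)
  names(layers)[3] <- "suf"
  hb <- sort(horizon_breaks)
  labs <- paste0(hb[-length(hb)], "-", hb[-1])
  mids <- (layers$depth_top + layers$depth_bottom) / 2
  hz <- vapply(seq_along(labs), function(k)
    sum(layers$suf[mids >= hb[k] & mids < hb[k + 1]]), numeric(1))
  below <- sum(layers$suf[mids >= hb[length(hb)]])
  above <- sum(layers$suf[mids < hb[1]])
  hor <- data.frame(horizon = c(paste0("<", hb[1]), labs,
                                paste0(">", hb[length(hb)])),
                    suf = c(above, hz, below))
  list(layers = layers, horizons = hor)
}

#' Closed-form conductance of a single uniform unbranched root
#'
#' Analytical Krs for a root of length L with uniform axial conductance
#' kx and radial conductivity kr, radius a, sealed tip:
#' `Krs = sqrt(kx * kr * 2 pi a) * tanh(L * sqrt(kr * 2 pi a / kx))`.
#' Used as the independent oracle for the numerical solver.
#'
#' @param L root length, cm.
#' @param kx axial conductance, cm^3/d per unit head gradient.
#' @param kr radial conductivity, d^-1.
#' @param a root radius, cm.
#' @return Krs in cm^3 cm^-1 d^-1.
#' @export
krs_single_root <- function(L, kx, kr, a) {
  krl <- kr * 2 * pi * a
  sqrt(kx * krl) * tanh(L * sqrt(krl / kx))
}
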