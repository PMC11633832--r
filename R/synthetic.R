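#' Digitization noise model for synthetic fixtures
#'
#' @param point_sd expected 3D displacement magnitude of every digitized
#'   point, cm (technical accuracy).
#' @param double_sd expected extra 3D displacement of the second recording
#'   of each branch point, cm (operator error at double points).
#' @param loss_fraction fraction of each fine (type 3) root's length lost,
#'   emulating excavation loss (length shrinks, counts are preserved).
#' @return list of class `noise_model`.
#' @export
noise_model <- function(point_sd = 0, double_sd = 0, loss_fraction = 0) {
  stopifnot(point_sd >= 0, double_sd >= 0,
            loss_fraction >= 0, loss_fraction <= 1)
  structure(list(point_sd = point_sd, double_sd = double_sd,
                 loss_fraction = loss_fraction), class = "noise_model")
}

#' Static initial root-system template
#'
#' Builds the planting-time skeleton a simulation starts from: a stem
#' descending from the grafting point through the soil surface to a basal
#' node about 20 cm deep, `n_type1` woody adventitious roots (around
#' 13 cm long) radiating from near-basal stem nodes, and `n_type2_per`
#' short type-2 stub axes per adventitious root marking the lateral
#' emergence points observed in the field. The soil-surface stem node sits
#' at the origin, so the template can be written with [write_digitizer()]
#' and round-trips through [parse_points()]/[build_root_system()].
#'
#' @param n_type1 number of adventitious (type 1) axes.
#' @param n_type2_per type-2 emergence stubs per type-1 axis.
#' @param type1_length approximate adventitious root length, cm.
#' @param basal_depth depth of the stem's basal node, cm.
#' @param seed RNG seed.
#' @return a `root_system`.
#' @export
static_template <- function(n_type1 = 8, n_type2_per = 3,
                            type1_length = 13, basal_depth = 20,
                            seed = 1L) {
  set.seed(seed)
  # stem: grafting point above ground, soil ref at origin, then one node
  # per adventitious root down to the basal zone
  zs <- c(5, 0, seq(-basal_depth + 2, -basal_depth,
                    length.out = max(n_type1, 2)))
  stem_nodes <- cbind(0, 0, zs)
  axes <- list(root_axis(stem_nodes, type = 0L, id = "", radius = 0.6))
  n_nodes_t1 <- n_type2_per + 3L
  for (k in seq_len(n_type1)) {
    jp <- 2L + k  # stem node carrying this root
    az <- 2 * pi * (k - 1) / n_type1 + stats::runif(1, -0.2, 0.2)
    dip <- stats::runif(1, 20, 55) * pi / 180  # below horizontal
    dirv <- c(cos(az) * cos(dip), sin(az) * cos(dip), -sin(dip))
    len <- type1_length * stats::runif(1, 0.85, 1.15)
    s <- seq(0, len, length.out = n_nodes_t1)
    wig <- function(s) 0.08 * sin(s / len * pi * 2 + k)
    nodes <- cbind(stem_nodes[jp, 1] + dirv[1] * s + wig(s),
                   stem_nodes[jp, 2] + dirv[2] * s - wig(s),
                   stem_nodes[jp, 3] + dirv[3] * s)
    nodes[1, ] <- stem_nodes[jp, ]
    axes[[length(axes) + 1L]] <-
      root_axis(nodes, type = 1L, id = as.character(k), radius = 0.2,
                parent = 1L, parent_node = jp)
    t1_idx <- length(axes)
    # type-2 stubs at interior nodes (excluding first and last)
    at <- round(seq(2, n_nodes_t1 - 1L, length.out = n_type2_per))
    for (j in unique(at)) {
      p0 <- nodes[j, ]
      pdir <- axis_direction_at(axes[[t1_idx]], j)
      h <- deflect(pdir, 60 * pi / 180, stats::runif(1, 0, 2 * pi))
      stub <- rbind(p0, p0 + h * 1.0)
      axes[[length(axes) + 1L]] <-
        root_axis(stub, type = 2L, id = paste0(k, ".", j), radius = 0.1,
                  parent = t1_idx, parent_node = j)
    }
  }
  root_system(axes)
}

# keep polyline vertices at direction changes > angle_deg plus forced ones
downsample_polyline <- function(nodes, keep, angle_deg = 10) {
  n <- nrow(nodes)
  if (n <= 2L) return(seq_len(n))
  sel <- rep(FALSE, n)
  sel[c(1L, n)] <- TRUE
  sel[keep] <- TRUE
  last_dir <- NULL
  last_kept <- 1L
  for (k in 2:(n - 1L)) {
    v <- nodes[k, ] - nodes[last_kept, ]
    nv <- sqrt(sum(v^2))
    if (nv == 0) next
    v <- v / nv
    w <- nodes[k + 1L, ] - nodes[k, ]
    nw <- sqrt(sum(w^2))
    if (nw == 0) next
    w <- w / nw
    ang <- acos(max(-1, min(1, sum(v * w)))) * 180 / pi
    if (ang > angle_deg || sel[k]) { sel[k] <- TRUE; last_kept <- k }
  }
  which(sel)
}

#' Down-sample a root system to digitization-like vertex density
#'
#' Emulates the field protocol of placing points only where the growth
#' direction changes (> `angle_deg`) or where a branch attaches; branch
#' nodes and axis endpoints are always kept. Child attachment indices are
#' remapped onto the retained vertices.
#'
#' @param rs a `root_system`.
#' @param angle_deg direction-change threshold, degrees.
#' @return a `root_system` with sparser polylines.
#' @export
downsample_root_system <- function(rs, angle_deg = 10) {
  kids <- axis_children(rs)
  n <- length(rs$axes)
  keep_idx <- vector("list", n)
  for (i in seq_len(n)) {
    forced <- vapply(kids[[i]], function(j) rs$axes[[j]]$parent_node,
                     integer(1))
    keep_idx[[i]] <- downsample_polyline(rs$axes[[i]]$nodes, forced,
                                         angle_deg)
  }
  axes <- vector("list", n)
  for (i in seq_len(n)) {
    a <- rs$axes[[i]]
    sel <- keep_idx[[i]]
    pn <- a$parent_node
    if (!is.na(pn)) pn <- match(pn, keep_idx[[a$parent]])
    axes[[i]] <- root_axis(a$nodes[sel, , drop = FALSE], type = a$type,
                           id = a$id, ages = a$ages[sel], radius = a$radius,
                           parent = a$parent, parent_node = pn)
  }
  root_system(axes)
}

#' Generate a synthetic digitized root system
#'
#' Closure generator for the whole pipeline: simulates genotype-specific
#' growth from a static template, down-samples each axis to
#' digitization-like vertex density, and writes the digitizer point file
#' dialect including the double points at branch nodes, optionally
#' degraded by a [noise_model()]. Returns both the ground truth and the
#' file, so parsers, trait extractors and parameter estimators can be
#' validated end to end without field data.
#'
#' @param params a `genotype_params` object.
#' @param template a static `root_system` (default [static_template()]).
#' @param days simulation horizon, days.
#' @param seed RNG seed (drives simulation, down-sampling and noise).
#' @param noise a `noise_model`.
#' @param path output .txt path, or `NULL` to return lines only.
#' @return list: `truth` (down-sampled, noise-free `root_system`),
#'   `lines` (digitizer file lines), `sim` (full-resolution simulation).
#' @export
synth_root_system <- function(params, template = NULL, days = 180,
                              seed = 1L, noise = noise_model(),
                              path = NULL) {
  if (is.null(template)) template <- static_template(seed = seed)
  state <- initialize_static(template, params)
  sim <- simulate_growth(state, days = days, seed = seed)
  truth <- downsample_root_system(sim)
  set.seed(seed + 1L)
  noisy <- truth
  if (noise$loss_fraction > 0) {
    for (i in seq_along(noisy$axes)) {
      a <- noisy$axes[[i]]
      if (a$type != 3L) next
      s <- node_arc_positions(a)
      target <- s[length(s)] * (1 - noise$loss_fraction)
      keep <- which(s <= target)
      if (length(keep) < 2L) keep <- 1:2
      last <- max(keep)
      nodes <- a$nodes[seq_len(last), , drop = FALSE]
      if (s[last] > target && last > 1L) {
        # trim the last retained segment to the exact target length
        frac <- (target - s[last - 1L]) / (s[last] - s[last - 1L])
        if (frac > 0)
          nodes[last, ] <- nodes[last - 1L, ] +
            frac * (nodes[last, ] - nodes[last - 1L, ])
      } else if (s[last] < target && last < nrow(a$nodes)) {
        frac <- (target - s[last]) / (s[last + 1L] - s[last])
        nodes <- rbind(nodes, nodes[last, ] +
                         frac * (a$nodes[last + 1L, ] - a$nodes[last, ]))
      }
      noisy$axes[[i]]$nodes <- nodes
      noisy$axes[[i]]$ages <- a$ages[seq_len(nrow(nodes))]
    }
  }
  lines <- write_digitizer(noisy, path = NULL)
  if (noise$point_sd > 0 || noise$double_sd > 0) {
    lines <- jitter_digitizer_lines(lines, noise)
  }
  if (!is.null(path)) writeLines(lines, path)
  list(truth = noisy, lines = lines, sim = sim)
}

# apply point jitter and extra double-point jitter to digitizer lines;
# the noise_model SDs are expected 3D displacement magnitudes, so the
# per-coordinate Gaussian SD is value * sqrt(pi/8) (mean of a Maxwell
# distribution with per-axis SD s is s * 2 * sqrt(2/pi))
jitter_digitizer_lines <- function(lines, noise) {
  is_data <- !startsWith(trimws(lines), "#") & nzchar(trimws(lines))
  ids <- vapply(strsplit(lines[is_data], "[ \t]+"),
                function(t) t[1], character(1))
  # double points: the first recorded point of every non-stem axis
  is_double <- grepl("\\.1$", ids)
  out <- lines
  rows <- which(is_data)
  s_point <- noise$point_sd * sqrt(pi / 8)
  s_double <- noise$double_sd * sqrt(pi / 8)
  for (k in seq_along(rows)) {
    tok <- strsplit(lines[rows[k]], "[ \t]+")[[1]]
    xyz <- as.numeric(tok[3:5])
    if (s_point > 0) xyz <- xyz + stats::rnorm(3, 0, s_point)
    if (is_double[k] && s_double > 0) xyz <- xyz + stats::rnorm(3, 0, s_double)
    out[rows[k]] <- sprintf("%s %s %.6f %.6f %.6f", tok[1], tok[2],
                            xyz[1], xyz[2], xyz[3])
  }
  out
}

#' Synthetic calibration-object records
#'
#' Emulates digitizing a standard object with two known segment lengths
#' at random poses within the transmitter's range: each pose yields one
#' record per true length, with additive Gaussian length error whose SD
#' may grow linearly with transmitter distance.
#'
#' @param n_poses number of random poses.
#' @param true_lengths known segment lengths, cm.
#' @param noise_sd baseline length-error SD, cm.
#' @param max_distance maximum transmitter distance, cm.
#' @param distance_slope extra SD per cm of distance (default 0).
#' @param seed RNG seed.
#' @return data.frame `digitized`, `true`, `distance`, `pose`.
#' @export
synth_calibration <- function(n_poses = 30, true_lengths = c(5, 10),
                              noise_sd = 0.15, max_distance = 180,
                              distance_slope = 0, seed = 1L) {
  stopifnot(n_poses >= 1)
  set.seed(seed)
  recs <- list()
  for (p in seq_len(n_poses)) {
    dist <- stats::runif(1, 10, max_distance)
    for (L in true_lengths) {
      sd_eff <- noise_sd + distance_slope * dist
      recs[[length(recs) + 1L]] <-
        data.frame(digitized = L + stats::rnorm(1, 0, sd_eff),
                   true = L, distance = dist, pose = p)
    }
  }
  do.call(rbind, recs)
}

#' Synthetic double-digitized branch-point pairs
#'
#' @param n number of pairs.
#' @param deviation_sd per-axis SD of the offset between the two
#'   recordings, cm (total 3D deviation has mean
#'   `deviation_sd * sqrt(8/pi)`... see Details).
#' @param distance_slope linear growth of the offset SD with transmitter
#'   distance (per cm).
#' @param max_distance maximum transmitter distance, cm.
#' @param seed RNG seed.
#' @details With isotropic per-axis offset SD s the Euclidean deviation is
#'   Maxwell distributed with mean `2 s sqrt(2/pi)`... practically: pass
#'   `deviation_sd = target_mean / 1.5958` to hit a target mean deviation.
#' @return data.frame `x1,y1,z1,x2,y2,z2,distance`.
#' @export
synth_double_points <- function(n = 1000, deviation_sd = 0.114,
                                distance_slope = 0, max_distance = 180,
                                seed = 1L) {
  set.seed(seed)
  dist <- stats::runif(n, 10, max_distance)
  p1 <- matrix(stats::runif(3 * n, -60, 60), ncol = 3)
  s <- deviation_sd + distance_slope * dist
  off <- matrix(stats::rnorm(3 * n), ncol = 3) * s
  data.frame(x1 = p1[, 1], y1 = p1[, 2], z1 = p1[, 3],
             x2 = p1[, 1] + off[, 1], y2 = p1[, 2] + off[, 2],
             z2 = p1[, 3] + off[, 3], distance = dist)
}

#' Synthetic xylem-vessel cross-section tables
#'
#' Generates cross-sections with lognormal vessel dimensions whose size
#' scales with root diameter, so theoretical axial conductivity follows a
#' power-law trend in diameter; vessel minor <= major is enforced.
#'
#' @param n_sections number of cross-sections.
#' @param diameter_range root diameter range, cm.
#' @param mean_vessels mean vessel count per section.
#' @param genotype label written to the table.
#' @param seed RNG seed.
#' @return data.frame `genotype`, `zone`, `section`, `root_diameter_cm`,
#'   `minor_um`, `major_um`.
#' @export
synth_vessels <- function(n_sections = 33, diameter_range = c(0.05, 0.6),
                          mean_vessels = 25, genotype = "synthetic",
                          seed = 1L) {
  stopifnot(n_sections >= 1)
  set.seed(seed)
  out <- list()
  for (s in seq_len(n_sections)) {
    d <- stats::runif(1, diameter_range[1], diameter_range[2])
    nv <- max(1L, stats::rpois(1, mean_vessels))
    # vessel size grows with root diameter -> power-law Kh(d)
    mu <- log(30 * (d / 0.2)^0.7)
    minor <- stats::rlnorm(nv, mu, 0.25)
    major <- minor * stats::runif(nv, 1, 1.6)
    zone <- if (d > 0.3) "type1" else
      sample(c("type2_suberized", "type2_unsuberized"), 1)
    out[[s]] <- data.frame(genotype = genotype, zone = zone, section = s,
                           root_diameter_cm = d, minor_um = minor,
                           major_um = major)
  }
  do.call(rbind, out)
}

#' Theoretical conductivity per cross-section of a vessel table
#'
#' @param vessels data.frame as from [synth_vessels()] (micron columns).
#' @param eta dynamic viscosity, MPa s.
#' @return data.frame `section`, `root_diameter_cm`, `kh` (m^4 s^-1
#'   MPa^-1).
#' @export
kh_per_section <- function(vessels, eta = 1.002e-9) {
  do.call(rbind, lapply(split(vessels, vessels$section), function(v)
    data.frame(section = v$section[1],
               root_diameter_cm = v$root_diameter_cm[1],
               kh = kh_theoretical(v$minor_um * 1e-6, v$major_um * 1e-6,
                                   eta))))
}
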