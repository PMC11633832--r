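#' Architectural trait report for a root system
#'
#' Computes the standard RSA trait set from a digitized or simulated root
#' system in the soil frame: per-type and total length, count, mean length,
#' mean diameter, surface area (2*pi*a*l) and volume (pi*a^2*l) using the
#' per-axis caliper radius; root system height (max depth minus min depth
#' of root nodes, clipped at the soil surface) and width (maximum pairwise
#' horizontal-projection distance between root nodes); the 3D convex hull
#' volume over all root nodes (reported in m^3); planar convex hull areas
#' of the XY (top view) and XZ (front view) projections (cm^2); and the
#' depth profile of root length per soil layer, apportioning each segment
#' to depth bins by linear clipping at bin boundaries.
#'
#' The stem (type 0) is excluded from all root traits. Segment endpoints
#' exactly on a bin boundary belong to the deeper bin (half-open bins
#' `[d, d + h)` in depth = -z).
#'
#' @param rs a `root_system`.
#' @param layer_thickness depth bin height in cm.
#' @return a list of class `trait_report`: `by_type` (data.frame), `total`
#'   (named list), `height_cm`, `width_cm`, `bbox` (named extents),
#'   `hull_volume_m3` (attribute `degenerate` if <4 non-coplanar nodes),
#'   `hull_area_xy_cm2`, `hull_area_xz_cm2`, `depth_profile` (data.frame
#'   `depth_top`, `depth_bottom`, `length_cm`).
#' @export
compute_traits <- function(rs, layer_thickness = 1) {
  stopifnot(layer_thickness > 0)
  types <- axis_types(rs)
  root_idx <- which(types != 0L)
  if (!length(root_idx)) stop("root system has no root axes (only a stem)")
  lens <- axis_lengths(rs)

  by_type <- do.call(rbind, lapply(sort(unique(types[root_idx])), function(t) {
    idx <- which(types == t)
    rr <- vapply(rs$axes[idx], function(a) a$radius, numeric(1))
    ll <- lens[idx]
    surf <- sum(2 * pi * rr * ll, na.rm = FALSE)
    vol <- sum(pi * rr^2 * ll, na.rm = FALSE)
    data.frame(type = t, count = length(idx), total_length_cm = sum(ll),
               mean_length_cm = mean(ll),
               mean_diameter_cm = mean(2 * rr),
               surface_cm2 = surf, volume_cm3 = vol)
  }))

  nodes <- do.call(rbind, lapply(rs$axes[root_idx], function(a) a$nodes))
  depth <- -nodes[, 3]
  height <- max(depth) - max(min(depth), 0)
  # width: max pairwise distance of horizontal projections (via 2D hull)
  xy <- unique(nodes[, 1:2, drop = FALSE])
  width <- if (nrow(xy) < 2L) 0 else {
    h <- if (nrow(xy) > 3L) xy[grDevices::chull(xy), , drop = FALSE] else xy
    max(stats::dist(h))
  }
  bbox <- c(x = diff(range(nodes[, 1])), y = diff(range(nodes[, 2])),
            z = diff(range(nodes[, 3])))

  hull_v <- convex_hull_volume(nodes) * 1e-6  # cm^3 -> m^3
  hull_xy <- convex_hull_area(nodes[, c(1, 2)])
  hull_xz <- convex_hull_area(nodes[, c(1, 3)])

  prof <- depth_profile(rs, layer_thickness)

  out <- list(
    by_type = by_type,
    total = list(length_cm = sum(by_type$total_length_cm),
                 count = sum(by_type$count),
                 surface_cm2 = sum(by_type$surface_cm2),
                 volume_cm3 = sum(by_type$volume_cm3)),
    height_cm = height, width_cm = width, bbox_cm = bbox,
    hull_volume_m3 = hull_v,
    hull_area_xy_cm2 = hull_xy, hull_area_xz_cm2 = hull_xz,
    depth_profile = prof)
  class(out) <- "trait_report"
  out
}

#' @export
print.trait_report <- function(x, ...) {
  cat("RSA trait report\n")
  print(x$by_type, row.names = FALSE)
  cat(sprintf("total length %.1f cm | height %.1f cm | width %.1f cm\n",
              x$total$length_cm, x$height_cm, x$width_cm))
  cat(sprintf("convex hull %.4g m^3 | plan hull %.1f cm^2 | profile bins %d\n",
              x$hull_volume_m3, x$hull_area_xy_cm2, nrow(x$depth_profile)))
  invisible(x)
}

# distribute one quantity per segment over depth bins by linear clipping;
# returns data.frame(depth_top, depth_bottom, value)
bin_by_depth <- function(z1, z2, value, h) {
  d1 <- -z1; d2 <- -z2
  lo <- pmin(d1, d2); hi <- pmax(d1, d2)
  kmin <- floor(min(lo) / h)
  kmax <- floor(max(hi) / h)
  bins <- kmin:kmax
  acc <- numeric(length(bins))
  for (s in seq_along(value)) {
    if (value[s] == 0) next
    if (hi[s] - lo[s] < 1e-12) {  # horizontal segment: one bin
      k <- floor(lo[s] / h) - kmin + 1L
      acc[k] <- acc[k] + value[s]
    } else {
      span <- hi[s] - lo[s]
      for (k in floor(lo[s] / h):floor((hi[s] - 1e-12) / h)) {
        top <- k * h; bot <- (k + 1) * h
        frac <- (min(hi[s], bot) - max(lo[s], top)) / span
        if (frac > 0) acc[k - kmin + 1L] <- acc[k - kmin + 1L] + frac * value[s]
      }
    }
  }
  keep <- range(c(which(acc > 0), 1L))  # trim empty boundary bins
  sel <- keep[1]:keep[2]
  data.frame(depth_top = bins[sel] * h, depth_bottom = (bins[sel] + 1) * h,
             value = acc[sel])
}

#' Root length per soil layer
#'
#' @param rs a `root_system`.
#' @param layer_thickness bin height, cm.
#' @return data.frame `depth_top`, `depth_bottom`, `length_cm`; the bin sum
#'   equals total root length (mass conservation).
#' @export
depth_profile <- function(rs, layer_thickness = 1) {
  types <- axis_types(rs)
  segs <- list()
  for (i in which(types != 0L)) {
    nd <- rs$axes[[i]]$nodes
    n <- nrow(nd)
    segs[[length(segs) + 1L]] <-
      data.frame(z1 = nd[-n, 3], z2 = nd[-1, 3],
                 len = sqrt(rowSums((nd[-1, , drop = FALSE] -
                                       nd[-n, , drop = FALSE])^2)))
  }
  segs <- do.call(rbind, segs)
  out <- bin_by_depth(segs$z1, segs$z2, segs$len, layer_thickness)
  names(out)[3] <- "length_cm"
  out
}

# arc-length positions along an axis at each node
node_arc_positions <- function(axis) {
  d <- diff(axis$nodes)
  c(0, cumsum(sqrt(rowSums(d^2))))
}

# local direction of an axis at node j (central difference; one-sided at ends)
axis_direction_at <- function(axis, j) {
  n <- nrow(axis$nodes)
  a <- max(1L, j - 1L); b <- min(n, j + 1L)
  v <- axis$nodes[b, ] - axis$nodes[a, ]
  v / sqrt(sum(v^2))
}

#' Branching parameters from a digitized root system
#'
#' Estimates the branching geometry the growth model consumes: basal zone
#' length lb (arc length from axis base to first lateral), apical zone la
#' (last lateral to tip), interlateral distances ln (successive lateral
#' spacings), insertion angle theta (angle between the parent's local
#' direction at the branch node, central difference, and the lateral's
#' first segment; degrees) and radius a. lb/la/ln are pooled over parent
#' axes of each root type; theta and a are pooled over the lateral axes of
#' each type.
#'
#' @param rs a `root_system`.
#' @return list of class `estimated_params` with per-type components
#'   `lb`, `la`, `ln`, `theta`, `a`, each `c(mean, sd, n)`.
#' @export
branching_parameters <- function(rs) {
  kids <- axis_children(rs)
  types <- axis_types(rs)
  lb <- la <- lnv <- list(); theta <- avals <- list()
  key <- function(t) as.character(t)
  for (i in seq_along(rs$axes)) {
    a <- rs$axes[[i]]
    t <- a$type
    if (t > 0) {
      avals[[key(t)]] <- c(avals[[key(t)]], a$radius)
      if (!is.na(a$parent)) {
        pa <- rs$axes[[a$parent]]
        pdir <- axis_direction_at(pa, a$parent_node)
        cdir <- a$nodes[2L, ] - a$nodes[1L, ]
        cdir <- cdir / sqrt(sum(cdir^2))
        ang <- acos(max(-1, min(1, sum(pdir * cdir)))) * 180 / pi
        theta[[key(t)]] <- c(theta[[key(t)]], ang)
      }
    }
    ch <- kids[[i]]
    if (t > 0 && length(ch)) {
      s <- node_arc_positions(a)
      pos <- sort(s[vapply(rs$axes[ch], function(x) x$parent_node, integer(1))])
      L <- s[length(s)]
      lb[[key(t)]] <- c(lb[[key(t)]], pos[1])
      la[[key(t)]] <- c(la[[key(t)]], L - pos[length(pos)])
      if (length(pos) >= 2L) lnv[[key(t)]] <- c(lnv[[key(t)]], diff(pos))
    }
  }
  msd <- function(v) if (is.null(v)) c(mean = NA, sd = NA, n = 0) else
    c(mean = mean(v), sd = if (length(v) > 1) stats::sd(v) else 0,
      n = length(v))
  all_t <- sort(unique(types[types > 0]))
  out <- lapply(all_t, function(t)
    list(lb = msd(lb[[key(t)]]), la = msd(la[[key(t)]]),
         ln = msd(lnv[[key(t)]]), theta = msd(theta[[key(t)]]),
         a = msd(avals[[key(t)]])))
  names(out) <- paste0("type", all_t)
  class(out) <- "estimated_params"
  out
}

#' Estimate lmax and the initial elongation rate r
#'
#' Under the negative-exponential elongation law
#' `l(t) = lmax * (1 - exp(-r * t / lmax))`, lmax is estimated as the
#' maximum observed axis length of the type (or a quantile of the
#' observed lengths) and r as the rate that makes the law reproduce the
#' observed mean length at the observation age, solved by bisection.
#'
#' @param root_lengths numeric axis lengths of one root type, cm.
#' @param age observation age, days (> 0).
#' @param lmax_quantile quantile of the observed lengths used as lmax
#'   (default 1 = maximum).
#' @param r_max upper bracket for the elongation rate, cm/d.
#' @return list `lmax` (cm), `r` (cm/d).
#' @export
estimate_lmax_r <- function(root_lengths, age, lmax_quantile = 1,
                            r_max = 10) {
  if (!length(root_lengths)) stop("no root lengths supplied")
  if (age <= 0) stop("age must be positive")
  lmax <- as.numeric(stats::quantile(root_lengths, lmax_quantile, names = FALSE))
  ml <- mean(root_lengths)
  if (ml == 0) return(list(lmax = lmax, r = 0))
  if (ml >= lmax)
    stop("mean length >= lmax: elongation rate unbounded")
  f <- function(r) growth_length(age, lmax, r) - ml
  r <- stats::uniroot(f, c(1e-12, r_max), tol = 1e-12)$root
  list(lmax = lmax, r = r)
}

#' Estimate the plagiotropism probability of type-2 roots
#'
#' The share of long type-2 roots whose tips remain in the topsoil:
#' among type-2 axes longer than `length_threshold`, the fraction whose
#' tip node lies at a depth shallower than `depth_threshold`. This is the
#' probability of plagiotropic behaviour; its complement is the
#' gravitropism probability used by the growth simulator.
#'
#' @param rs a `root_system`.
#' @param length_threshold qualifying root length, cm.
#' @param depth_threshold topsoil depth bound, cm.
#' @return fraction in `[0, 1]`.
#' @export
estimate_tropism_probability <- function(rs, length_threshold = 40,
                                         depth_threshold = 50) {
  types <- axis_types(rs)
  idx <- which(types == 2L)
  idx <- idx[axis_lengths(rs)[idx] > length_threshold]
  if (!length(idx))
    stop("no type-2 axes longer than ", length_threshold, " cm")
  tip_depth <- vapply(rs$axes[idx], function(a)
    -a$nodes[nrow(a$nodes), 3], numeric(1))
  mean(tip_depth < depth_threshold)
}
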