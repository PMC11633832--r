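#' Construct a root axis
#'
#' An axis is one polyline of a root system: the stem (type 0), a static
#' woody adventitious root (type 1), a first-order lateral (type 2) or a
#' second-order/fine lateral (type 3). Coordinates are in the soil frame:
#' right-handed, z = 0 at the soil surface and z < 0 below ground, all units
#' cm.
#'
#' @param nodes numeric matrix (n x 3) of node coordinates, cm, soil frame.
#' @param type integer root type in 0:3.
#' @param id character label; for digitized data the dot-separated ID prefix
#'   of the axis (e.g. "2.1"), otherwise any unique label.
#' @param ages numeric vector of per-node ages (days since the node was
#'   formed); 0 for digitized data where formation times are unknown.
#' @param radius axis radius in cm (per-axis, caliper-style), or `NA`.
#' @param parent integer index of the parent axis within the root system's
#'   axis list, or `NA` for the stem.
#' @param parent_node integer node index on the parent axis where this axis
#'   is attached, or `NA`.
#' @return an object of class `root_axis`.
#' @export
root_axis <- function(nodes, type, id = NA_character_, ages = NULL,
                      radius = NA_real_, parent = NA_integer_,
                      parent_node = NA_integer_) {
  nodes <- as.matrix(nodes)
  storage.mode(nodes) <- "double"
  if (ncol(nodes) != 3L) stop("axis nodes must be an n x 3 matrix")
  if (nrow(nodes) < 2L) stop("an axis needs at least 2 nodes")
  if (!all(is.finite(nodes))) stop("axis coordinates must be finite")
  if (!type %in% 0:3) stop("root type must be in 0:3")
  if (is.null(ages)) ages <- rep(0, nrow(nodes))
  if (length(ages) != nrow(nodes)) stop("one age per node required")
  colnames(nodes) <- c("x", "y", "z")
  structure(list(id = as.character(id), type = as.integer(type),
                 nodes = nodes, ages = as.numeric(ages),
                 radius = as.numeric(radius),
                 parent = as.integer(parent),
                 parent_node = as.integer(parent_node)),
            class = "root_axis")
}

#' Construct a root system
#'
#' Container for a set of [root_axis] objects forming one plant's root
#' system. Topology is encoded by each axis's `parent`/`parent_node`
#' reference; a child's first node coincides with the referenced parent
#' node (branch points are stored on both axes, mirroring the double-point
#' digitization protocol).
#'
#' @param axes list of [root_axis] objects.
#' @param genotype optional genotype label.
#' @param age observation age in days (time since planting), or `NA`.
#' @param validate logical; run [validate_root_system()]?
#' @return an object of class `root_system`.
#' @export
root_system <- function(axes, genotype = NA_character_, age = NA_real_,
                        validate = TRUE) {
  rs <- structure(list(axes = axes, genotype = as.character(genotype),
                       age = as.numeric(age)),
                  class = "root_system")
  if (validate) validate_root_system(rs)
  rs
}

#' Validate root-system topology
#'
#' Checks the structural invariants: at most one stem (type 0), acyclic
#' parent chains, every non-stem axis reachable from an anchored axis,
#' parent node indices in range, child first node coinciding with the
#' referenced parent node, and no two children sharing the same
#' (parent, parent node) attachment.
#'
#' @param rs a `root_system`.
#' @param tol coordinate tolerance (cm) for the shared-node check.
#' @return `rs`, invisibly; errors on violation.
#' @export
validate_root_system <- function(rs, tol = 1e-6) {
  axes <- rs$axes
  n <- length(axes)
  if (n == 0L) stop("root system has no axes")
  types <- vapply(axes, function(a) a$type, integer(1))
  if (sum(types == 0L) > 1L) stop("more than one stem (type 0) axis")
  seen <- character(0)
  for (i in seq_len(n)) {
    a <- axes[[i]]
    if (!inherits(a, "root_axis")) stop("axes must be root_axis objects")
    p <- a$parent
    if (!is.na(p)) {
      if (p < 1L || p > n) stop("axis ", i, ": parent index out of range")
      pa <- axes[[p]]
      j <- a$parent_node
      if (is.na(j) || j < 1L || j > nrow(pa$nodes))
        stop("axis ", i, ": parent node index out of range")
      d <- sqrt(sum((a$nodes[1L, ] - pa$nodes[j, ])^2))
      if (d > tol)
        stop("axis ", i, ": first node does not coincide with parent node (",
             format(d), " cm apart)")
      key <- paste(p, j)
      if (key %in% seen)
        stop("two child axes share parent attachment (axis ", p,
             ", node ", j, ")")
      seen <- c(seen, key)
      # acyclicity / reachability: walk up
      walk <- i; cur <- p
      while (!is.na(cur)) {
        if (cur %in% walk) stop("cycle in parent chain at axis ", i)
        walk <- c(walk, cur)
        cur <- axes[[cur]]$parent
      }
    }
  }
  invisible(rs)
}

#' @export
print.root_system <- function(x, ...) {
  types <- vapply(x$axes, function(a) a$type, integer(1))
  cat("root_system:", length(x$axes), "axes",
      if (!is.na(x$genotype)) paste0("(genotype ", x$genotype, ")"), "\n")
  for (t in sort(unique(types))) {
    idx <- which(types == t)
    len <- sum(vapply(x$axes[idx], axis_length, numeric(1)))
    cat(sprintf("  type %d: %d axes, total length %.2f cm\n",
                t, length(idx), len))
  }
  invisible(x)
}

#' Per-axis root types
#' @param rs a `root_system`.
#' @return integer vector of axis types.
#' @export
axis_types <- function(rs) vapply(rs$axes, function(a) a$type, integer(1))

#' Euclidean length of one axis polyline
#' @param axis a `root_axis`.
#' @return length in cm.
#' @export
axis_length <- function(axis) {
  d <- diff(axis$nodes)
  sum(sqrt(rowSums(d^2)))
}

#' Per-segment Euclidean lengths of every axis
#'
#' Root lengths are Euclidean distances between consecutive digitized (or
#' simulated) points; an axis length is their sum.
#'
#' @param rs a `root_system`.
#' @return a list, one numeric vector of segment lengths (cm) per axis.
#' @export
segment_lengths <- function(rs) {
  lapply(rs$axes, function(a) {
    d <- diff(a$nodes)
    sqrt(rowSums(d^2))
  })
}

#' Total and per-axis lengths
#' @param rs a `root_system`.
#' @return numeric vector of axis lengths (cm).
#' @export
axis_lengths <- function(rs) vapply(rs$axes, axis_length, numeric(1))

#' Indices of the child axes of each axis
#' @param rs a `root_system`.
#' @return list mapping axis index -> integer vector of child indices.
#' @keywords internal
axis_children <- function(rs) {
  n <- length(rs$axes)
  kids <- vector("list", n)
  for (i in seq_len(n)) {
    p <- rs$axes[[i]]$parent
    if (!is.na(p)) kids[[p]] <- c(kids[[p]], i)
  }
  kids
}
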