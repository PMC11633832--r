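#' Parse a 3D-digitizer point file
#'
#' Reads DigiTool-style plain text: one point per line,
#' `<dot-ID> <organ> <x> <y> <z>` (whitespace separated, coordinates in cm,
#' digitizer frame with the x axis pointing vertically downward). Lines
#' starting with `#` are comments; an optional header `# soil_ref=<dot-ID>`
#' names the stem point digitized at the soil horizon (default point "1",
#' following the protocol where stem points 0, 1, 2 mark the grafting
#' point, the soil horizon and the basal node).
#'
#' Point IDs are hierarchical: a point's ID is its axis's ID prefix plus a
#' 1-based running index, and an axis's prefix is the full ID of the parent
#' branch point (axis "2.1.3" branches at point 3 of axis "2.1"). Branch
#' points are digitized twice: the first point of a lateral duplicates the
#' parent's branch point.
#'
#' @param source path to a file, or a character vector of lines.
#' @return data.frame with columns `id`, `organ`, `x`, `y`, `z`, `line_no`,
#'   carrying attribute `soil_ref` (the soil-horizon point ID).
#' @export
parse_points <- function(source) {
  lines <- if (length(source) == 1L && !grepl("\n", source) &&
               file.exists(source)) readLines(source) else source
  soil_ref <- "1"
  trimmed <- trimws(lines)
  for (ln in trimmed[startsWith(trimmed, "#")]) {
    m <- regmatches(ln, regexec("soil_ref\\s*=\\s*([0-9.]+)", ln))[[1]]
    if (length(m) == 2L) soil_ref <- m[2]
  }
  data_rows <- which(nzchar(trimmed) & !startsWith(trimmed, "#"))
  if (!length(data_rows)) stop("no data lines found")
  toks <- strsplit(trimmed[data_rows], "[ \t]+")
  nf <- lengths(toks)
  if (any(nf != 5L)) {
    i <- data_rows[which(nf != 5L)[1]]
    stop("line ", i, ": expected '<id> <organ> <x> <y> <z>', got ",
         nf[which(nf != 5L)[1]], " fields")
  }
  tok <- matrix(unlist(toks), ncol = 5L, byrow = TRUE)
  bad <- !grepl("^[0-9]+(\\.[0-9]+)*$", tok[, 1])
  if (any(bad))
    stop("line ", data_rows[which(bad)[1]], ": malformed point ID '",
         tok[which(bad)[1], 1], "'")
  organ <- tolower(tok[, 2])
  bad <- !organ %in% c("stem", "root")
  if (any(bad))
    stop("line ", data_rows[which(bad)[1]], ": unknown organ code '",
         tok[which(bad)[1], 2], "'")
  xyz <- suppressWarnings(matrix(as.numeric(tok[, 3:5]), ncol = 3L))
  bad <- !is.finite(rowSums(xyz))
  if (any(bad))
    stop("line ", data_rows[which(bad)[1]],
         ": non-numeric or non-finite coordinate")
  dup <- duplicated(tok[, 1])
  if (any(dup))
    stop("line ", data_rows[which(dup)[1]], ": duplicate point ID '",
         tok[which(dup)[1], 1], "'")
  out <- data.frame(id = tok[, 1], organ = organ, x = xyz[, 1],
                    y = xyz[, 2], z = xyz[, 3], line_no = data_rows)
  attr(out, "soil_ref") <- soil_ref
  out
}

#' Split a dot-separated point ID into an integer path
#' @param id character ID like "2.1.3".
#' @return integer vector.
#' @export
id_path <- function(id) as.integer(strsplit(id, ".", fixed = TRUE)[[1]])

# ID prefix of the axis a point belongs to ("" for stem points)
axis_prefix_of <- function(id) {
  p <- strsplit(id, ".", fixed = TRUE)[[1]]
  if (length(p) == 1L) "" else paste(p[-length(p)], collapse = ".")
}

# digitizer frame -> soil frame: x_dig (down) -> -z, y_dig -> x, z_dig -> y
dig_to_soil <- function(xyz) {
  xyz <- rbind(xyz)
  cbind(x = xyz[, 2], y = xyz[, 3], z = -xyz[, 1])
}
soil_to_dig <- function(xyz) {
  xyz <- rbind(xyz)
  cbind(-xyz[, 3], xyz[, 1], xyz[, 2])
}

#' Reconstruct root-system topology from digitized points
#'
#' Groups points into axes by their ID prefix, merges the double-digitized
#' branch points (the lateral's first point is snapped onto the parent's
#' branch point after recording their Euclidean deviation, which is itself
#' the human-error measurement of the digitization protocol), transforms
#' coordinates from the digitizer frame to the soil frame (z = 0 at the
#' soil-reference point, z negative downward) and assigns root types from
#' hierarchy depth (stem 0; deeper levels 1, 2, 3, capped at 3).
#'
#' @param points data.frame from [parse_points()].
#' @param merge_tolerance deviation (cm) above which a double point is
#'   flagged with a warning (it is still merged and kept).
#' @return list with elements `root_system` and `deviations` (data.frame
#'   `axis`, `deviation` in cm, one row per lateral).
#' @export
build_root_system <- function(points, merge_tolerance = 1.0) {
  soil_ref <- attr(points, "soil_ref")
  if (is.null(soil_ref)) soil_ref <- "1"
  paths <- strsplit(points$id, ".", fixed = TRUE)
  prefix <- vapply(points$id, axis_prefix_of, character(1), USE.NAMES = FALSE)
  last <- vapply(paths, function(p) as.integer(p[length(p)]), integer(1))

  prefix_key <- ifelse(prefix == "", ".", prefix)  # "" is not a valid list name
  stem_rows <- which(prefix == "")
  if (!length(stem_rows)) stop("no stem points (single-component IDs) found")
  if (length(stem_rows) < 2L) stop("stem needs at least 2 points")

  # per-axis point groups, ordered by running index
  groups <- split(seq_len(nrow(points)), prefix_key)
  for (g in names(groups)) {
    o <- order(last[groups[[g]]])
    groups[[g]] <- groups[[g]][o]
    if (g != ".") {
      idx <- last[groups[[g]]]
      if (!identical(idx, seq_along(idx)))
        stop("axis '", g, "': point indices are not 1..k (got ",
             paste(idx, collapse = ","), ")")
    }
  }
  # orphan check: every non-stem prefix must itself be a recorded point
  for (g in setdiff(names(groups), ".")) {
    if (!g %in% points$id)
      stop("orphan lateral: axis '", g,
           "' has no parent branch point '", g, "'")
  }

  coords <- dig_to_soil(as.matrix(points[, c("x", "y", "z")]))
  ref_row <- match(soil_ref, points$id)
  if (is.na(ref_row)) ref_row <- stem_rows[1]
  origin <- coords[ref_row, ]
  coords <- sweep(coords, 2L, origin)

  # build axes in hierarchical order (stem first, then by prefix depth)
  prefixes <- names(groups)
  depth <- vapply(prefixes, function(p)
    if (p == ".") 0L else length(strsplit(p, ".", fixed = TRUE)[[1]]),
    integer(1))
  prefixes <- prefixes[order(depth)]

  axes <- list()
  axis_index <- new.env(parent = emptyenv()) # prefix -> index in axes
  devs <- data.frame(axis = character(0), deviation = numeric(0))

  for (p in prefixes) {
    rows <- groups[[p]]
    nodes <- coords[rows, , drop = FALSE]
    if (p == ".") {
      axes[[length(axes) + 1L]] <- root_axis(nodes, type = 0L, id = "")
      assign(".", length(axes), envir = axis_index)
      next
    }
    d <- length(strsplit(p, ".", fixed = TRUE)[[1]])
    type <- min(d, 3L)
    parent_prefix <- axis_prefix_of(p)
    if (parent_prefix == "") parent_prefix <- "."
    pidx <- get0(parent_prefix, envir = axis_index, ifnotfound = NA)
    if (is.na(pidx))
      stop("axis '", p, "': parent axis '", parent_prefix, "' missing")
    # which node of the parent axis is the branch point?
    parent_rows <- groups[[parent_prefix]]
    jnode <- match(match(p, points$id), parent_rows)
    if (is.na(jnode))
      stop("axis '", p, "': branch point not on parent axis")
    pnode <- axes[[pidx]]$nodes[jnode, ]
    dev <- sqrt(sum((nodes[1L, ] - pnode)^2))
    devs <- rbind(devs, data.frame(axis = p, deviation = dev))
    if (dev > merge_tolerance)
      warning("axis '", p, "': double-point deviation ", format(dev),
              " cm exceeds merge tolerance ", merge_tolerance, " cm")
    nodes[1L, ] <- pnode
    if (nrow(nodes) < 2L)
      stop("axis '", p, "' has fewer than 2 points")
    axes[[length(axes) + 1L]] <-
      root_axis(nodes, type = type, id = p,
                parent = pidx, parent_node = jnode)
    assign(p, length(axes), envir = axis_index)
  }
  rs <- root_system(axes)
  list(root_system = rs, deviations = devs)
}

#' Write a root system as a digitizer point file
#'
#' Inverse of [parse_points()] + [build_root_system()]: assigns hierarchical
#' dot IDs (stem points `0..k`; each lateral's prefix is the full ID of its
#' parent branch point, points indexed from 1, the first duplicating the
#' branch point), maps the soil frame back to the digitizer frame and
#' writes one point per line. At most one lateral may attach per parent
#' node, the only topology the ID dialect can encode.
#'
#' @param rs a `root_system` whose first axis set contains a stem (type 0).
#' @param path output file path, or `NULL` to return the lines.
#' @param offset numeric length-3 translation applied in the digitizer
#'   frame (emulates an arbitrary transmitter position).
#' @return the lines, invisibly if written to `path`.
#' @export
write_digitizer <- function(rs, path = NULL, offset = c(0, 0, 0)) {
  types <- axis_types(rs)
  stem <- which(types == 0L)
  if (length(stem) != 1L) stop("need exactly one stem (type 0) axis")
  n <- length(rs$axes)
  # point IDs per axis node
  node_ids <- vector("list", n)
  node_ids[[stem]] <- as.character(seq_len(nrow(rs$axes[[stem]]$nodes)) - 1L)
  order_idx <- order(vapply(seq_len(n), function(i) {
    d <- 0L; cur <- rs$axes[[i]]$parent
    while (!is.na(cur)) { d <- d + 1L; cur <- rs$axes[[cur]]$parent }
    d
  }, integer(1)))
  used <- character(0)
  for (i in order_idx) {
    if (i == stem) next
    a <- rs$axes[[i]]
    if (is.na(a$parent)) stop("axis ", i, " is not attached to the system")
    pid <- node_ids[[a$parent]]
    if (is.null(pid)) stop("parent axis of axis ", i, " not yet labelled")
    prefix <- pid[[a$parent_node]]
    if (prefix %in% used)
      stop("two laterals attach at parent point ", prefix,
           "; the ID dialect cannot encode siblings at one node")
    used <- c(used, prefix)
    node_ids[[i]] <- paste(prefix, seq_len(nrow(a$nodes)), sep = ".")
  }
  lines <- c("# woodyroot digitizer export", "# soil_ref=1")
  for (i in c(stem, setdiff(order_idx, stem))) {
    a <- rs$axes[[i]]
    organ <- if (a$type == 0L) "stem" else "root"
    dig <- soil_to_dig(a$nodes)
    dig <- sweep(dig, 2L, -offset)
    for (k in seq_len(nrow(dig)))
      lines <- c(lines, sprintf("%s %s %.6f %.6f %.6f",
                                node_ids[[i]][k], organ,
                                dig[k, 1], dig[k, 2], dig[k, 3]))
  }
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}
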