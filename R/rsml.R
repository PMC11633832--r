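#' Write a root system to RSML
#'
#' Serializes a [root_system] as Root System Markup Language 1.0
#' (`<rsml><metadata/><scene><plant><root>...`). Branch attachment is
#' encoded by element nesting, with the shared branch node repeated as the
#' child's first polyline point; each axis's caliper-style diameter (cm) is
#' written as a per-root `diameter` property and the root type as a `type`
#' property. RSML has no stem element, so the stem (type 0) is written as a
#' top-level root flagged `type=0`; readers that ignore it still see a
#' valid root system. Non-zero per-node ages are emitted as an RSML
#' `age` function sampled on the polyline.
#'
#' @param rs a `root_system`.
#' @param path destination file, or `NULL` to return the `xml_document`.
#' @return the `xml2::xml_document`, invisibly if written to `path`.
#' @export
write_rsml <- function(rs, path = NULL) {
  doc <- xml2::xml_new_root("rsml", version = "1.0")
  meta <- xml2::xml_add_child(doc, "metadata")
  xml2::xml_add_child(meta, "version", "1")
  xml2::xml_add_child(meta, "unit", "cm")
  xml2::xml_add_child(meta, "resolution", "1")
  xml2::xml_add_child(meta, "software", "woodyroot")
  if (!is.na(rs$genotype)) {
    props <- xml2::xml_add_child(meta, "property-definitions")
    xml2::xml_add_child(meta, "label", rs$genotype)
  }
  if (!is.na(rs$age)) xml2::xml_add_child(meta, "observation-age", format(rs$age))
  scene <- xml2::xml_add_child(doc, "scene")
  plant <- xml2::xml_add_child(scene, "plant")

  kids <- axis_children(rs)
  types <- axis_types(rs)
  add_root <- function(parent_el, i) {
    a <- rs$axes[[i]]
    el <- xml2::xml_add_child(parent_el, "root", ID = as.character(i))
    props <- xml2::xml_add_child(el, "properties")
    pr <- xml2::xml_add_child(props, "property", name = "type",
                              value = as.character(a$type))
    if (is.na(a$radius)) {
      warning("axis ", i, ": missing radius; diameter property omitted")
    } else {
      xml2::xml_add_child(props, "property", name = "diameter",
                          value = format(2 * a$radius, digits = 12))
    }
    geom <- xml2::xml_add_child(el, "geometry")
    poly <- xml2::xml_add_child(geom, "polyline")
    for (k in seq_len(nrow(a$nodes)))
      xml2::xml_add_child(poly, "point",
                          x = sprintf("%.10g", a$nodes[k, 1]),
                          y = sprintf("%.10g", a$nodes[k, 2]),
                          z = sprintf("%.10g", a$nodes[k, 3]))
    if (any(a$ages != 0)) {
      fns <- xml2::xml_add_child(el, "functions")
      fn <- xml2::xml_add_child(fns, "function", name = "age",
                                domain = "polyline")
      for (v in a$ages)
        xml2::xml_add_child(fn, "sample", value = sprintf("%.10g", v))
    }
    for (j in kids[[i]]) add_root(el, j)
  }
  # top level: stem (if any, written without nesting its children so
  # type-1 roots sit at depth 1 and depth == type) then every axis
  # without a parent or whose parent is the stem
  stem <- which(types == 0L)
  for (i in stem) {
    kids[[i]] <- integer(0)
    add_root(plant, i)
  }
  top <- which(is.na(vapply(rs$axes, function(a) a$parent, integer(1))) &
                 types != 0L)
  top <- c(top, which(!is.na(vapply(rs$axes, function(a) a$parent, integer(1))) &
                        types == 1L))
  for (i in sort(unique(top))) add_root(plant, i)

  if (!is.null(path)) {
    xml2::write_xml(doc, path)
    return(invisible(doc))
  }
  doc
}

rsml_unit_scale <- function(unit) {
  switch(tolower(unit),
         "cm" = 1, "mm" = 0.1, "m" = 100, "um" = 1e-4,
         "micrometer" = 1e-4, "inch" = 2.54, "pixel" = NA_real_,
         stop("unsupported RSML unit '", unit, "'"))
}

#' Read a root system from RSML
#'
#' Inverse of [write_rsml()]. Root types are inferred from element nesting
#' depth (top-level roots are type 1, their children type 2, then 3),
#' overridden by a `type` property when present (this is how the stem,
#' written as a top-level root with `type=0`, is recognised). Coordinates
#' are converted to cm from the declared metadata unit. A polyline with
#' fewer than 2 points rejects that root with a warning. Children are
#' re-attached to the nearest parent polyline node (the shared first point
#' of the child).
#'
#' @param path RSML file path (or `xml_document`).
#' @return a `root_system`.
#' @export
read_rsml <- function(path) {
  doc <- if (inherits(path, "xml_document")) path else xml2::read_xml(path)
  unit_node <- xml2::xml_find_first(doc, ".//metadata/unit")
  scale <- if (inherits(unit_node, "xml_missing")) 1 else
    rsml_unit_scale(xml2::xml_text(unit_node))
  if (is.na(scale)) stop("RSML unit not convertible to cm")
  label <- xml2::xml_find_first(doc, ".//metadata/label")
  genotype <- if (inherits(label, "xml_missing")) NA_character_ else
    xml2::xml_text(label)
  age_node <- xml2::xml_find_first(doc, ".//metadata/observation-age")
  obs_age <- if (inherits(age_node, "xml_missing")) NA_real_ else
    as.numeric(xml2::xml_text(age_node))

  axes <- list()
  read_root <- function(el, depth, parent_idx) {
    pts <- xml2::xml_find_all(el, "./geometry/polyline/point")
    nodes <- NULL
    if (length(pts) >= 2L) {
      nodes <- cbind(as.numeric(xml2::xml_attr(pts, "x")),
                     as.numeric(xml2::xml_attr(pts, "y")),
                     as.numeric(xml2::xml_attr(pts, "z"))) * scale
    }
    props <- xml2::xml_find_all(el, "./properties/property")
    pnames <- xml2::xml_attr(props, "name")
    pvals <- xml2::xml_attr(props, "value")
    type <- if ("type" %in% pnames)
      as.integer(pvals[match("type", pnames)]) else min(depth, 3L)
    radius <- if ("diameter" %in% pnames)
      as.numeric(pvals[match("diameter", pnames)]) * scale / 2 else NA_real_
    samples <- xml2::xml_find_all(
      el, "./functions/function[@name='age']/sample")
    this_idx <- NA_integer_
    if (is.null(nodes)) {
      warning("RSML root with <2 polyline points skipped")
    } else {
      ages <- if (length(samples) == nrow(nodes))
        as.numeric(xml2::xml_attr(samples, "value")) else rep(0, nrow(nodes))
      pn <- NA_integer_
      pidx <- parent_idx
      if (!is.na(parent_idx)) {
        pa <- axes[[parent_idx]]
        d2 <- rowSums(sweep(pa$nodes, 2L, nodes[1L, ])^2)
        pn <- which.min(d2)
        nodes[1L, ] <- pa$nodes[pn, ]  # snap shared node
      }
      axes[[length(axes) + 1L]] <<-
        root_axis(nodes, type = type, id = as.character(length(axes) + 1L),
                  ages = ages, radius = radius,
                  parent = pidx, parent_node = pn)
      this_idx <- length(axes)
    }
    for (ch in xml2::xml_find_all(el, "./root"))
      read_root(ch, depth + 1L, this_idx)
  }
  tops <- xml2::xml_find_all(doc, ".//scene/plant/root")
  # first pass: the stem (type=0 property), so type-1 roots can attach to it
  stem_idx <- NA_integer_
  is_stem <- vapply(tops, function(el) {
    props <- xml2::xml_find_all(el, "./properties/property")
    any(xml2::xml_attr(props, "name") == "type" &
          xml2::xml_attr(props, "value") == "0")
  }, logical(1))
  for (el in tops[is_stem]) read_root(el, 0L, NA_integer_)
  if (length(axes)) stem_idx <- which(axis_types(
    root_system(axes, validate = FALSE)) == 0L)[1]
  for (el in tops[!is_stem]) read_root(el, 1L, stem_idx)
  if (!length(axes)) stop("RSML contains no readable roots")

  # type-1 roots read with stem parent: verify coincidence, else detach
  for (i in seq_along(axes)) {
    a <- axes[[i]]
    if (!is.na(a$parent) && axes[[a$parent]]$type == 0L) {
      d <- sqrt(sum((a$nodes[1L, ] -
                       axes[[a$parent]]$nodes[a$parent_node, ])^2))
      if (d > 1e-6) { # not actually anchored on the stem polyline
        axes[[i]]$parent <- NA_integer_
        axes[[i]]$parent_node <- NA_integer_
      }
    }
  }
  root_system(axes, genotype = genotype, age = obs_age)
}

#' Summary counts and lengths per root type
#'
#' @param rs a `root_system` (or RSML path).
#' @return data.frame with per-type axis counts and total lengths (cm).
#' @export
rsml_info <- function(rs) {
  if (is.character(rs)) rs <- read_rsml(rs)
  types <- axis_types(rs)
  lens <- axis_lengths(rs)
  out <- do.call(rbind, lapply(sort(unique(types)), function(t)
    data.frame(type = t, n_axes = sum(types == t),
               total_length_cm = sum(lens[types == t]),
               mean_length_cm = mean(lens[types == t]))))
  out
}
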