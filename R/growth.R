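#' Genotype growth-parameter sets
#'
#' Loads per-genotype, per-root-type growth and tropism parameters from a
#' YAML table. The package ships presets for the grapevine rootstock
#' genotypes "101-14", "SO4" and "R110" (type-2 first-order laterals and
#' type-3 fine laterals), estimated from 3D-digitized field root systems
#' six months after planting. Fields per type: `lmax` (cm), `r` (cm/d),
#' `lb`, `la`, `ln` (cm, mean + sd; type 2 only), `theta` (degrees,
#' mean + sd), `a` (cm, mean + sd), `p_gravi` (gravitropism probability;
#' type 3 is fixed gravitropic), `N` (tropism strength: candidate
#' directions per segment), `sigma` (SD of random angular change per unit
#' length). Global fields: `dx` (segment resolution, cm),
#' `emergence_time` (d), `emergence_prob`, `tropism_mode`
#' ("per_segment" or "per_root").
#'
#' @param genotype genotype name present in the table, or a path to a YAML
#'   file with a single genotype's parameter block.
#' @param file YAML table path; default the shipped presets.
#' @return list of class `genotype_params`.
#' @export
genotype_params <- function(genotype = "101-14", file = NULL) {
  if (is.null(file))
    file <- system.file("extdata", "genotypes.yaml", package = "woodyroot")
  tab <- yaml::read_yaml(file)
  gp <- if (genotype %in% names(tab)) tab[[genotype]] else
    stop("genotype '", genotype, "' not in ", file,
         " (available: ", paste(names(tab), collapse = ", "), ")")
  gp$genotype <- genotype
  defaults <- list(dx = 0.5, emergence_time = 0, emergence_prob = 1,
                   tropism_mode = "per_segment")
  gp$global <- utils::modifyList(defaults, if (is.null(gp$global)) list()
                                 else gp$global)
  validate_genotype_params(gp)
}

validate_genotype_params <- function(gp) {
  for (t in c("type2", "type3")) {
    p <- gp[[t]]
    if (is.null(p)) stop("missing parameter block ", t)
    # a bare YAML key N parses as boolean FALSE under YAML 1.1; recover it
    if (is.null(p$N) && !is.null(p[["FALSE"]])) {
      p$N <- p[["FALSE"]]
      gp[[t]] <- p
    }
    stopifnot(length(p$N) == 1L, is.numeric(p$N))
    stopifnot(p$lmax > 0, p$r > 0, p$theta$mean > 0, p$theta$sd >= 0,
              p$a$mean > 0, p$a$sd >= 0, p$N >= 1, p$sigma >= 0)
    if (!is.null(p$p_gravi)) stopifnot(p$p_gravi >= 0, p$p_gravi <= 1)
  }
  p2 <- gp$type2
  stopifnot(p2$lb$mean >= 0, p2$la$mean >= 0, p2$ln$mean > 0,
            p2$lb$mean + p2$la$mean < p2$lmax)
  stopifnot(gp$global$dx > 0,
            gp$global$tropism_mode %in% c("per_segment", "per_root"))
  class(gp) <- "genotype_params"
  gp
}

#' Negative-exponential root elongation law
#'
#' `l(t) = lmax * (1 - exp(-r * t / lmax))`: length grows at initial rate
#' r (cm/d) and saturates at the maximal root length lmax (cm). Monotone
#' increasing and bounded by lmax.
#'
#' @param t age since emergence, days (>= 0); vectorized.
#' @param lmax maximal root length, cm.
#' @param r initial elongation rate, cm/d.
#' @return length in cm.
#' @export
growth_length <- function(t, lmax, r) {
  if (any(t < 0)) stop("negative age")
  stopifnot(lmax > 0, r >= 0)
  lmax * (1 - exp(-r * t / lmax))
}

#' Inverse of the elongation law
#'
#' Time at which a root first reaches length `l`.
#'
#' @param l length, cm, `0 <= l < lmax`.
#' @inheritParams growth_length
#' @return age in days (`Inf` if `l >= lmax`).
#' @export
growth_time <- function(l, lmax, r) {
  stopifnot(lmax > 0, r > 0, all(l >= 0))
  ifelse(l >= lmax, Inf, -lmax / r * log(1 - l / lmax))
}

#' Arc-length positions of lateral emergence points
#'
#' First lateral at the end of the basal zone (`s1 = lb`), subsequent ones
#' spaced by the interlateral-distance draws, truncated so that no lateral
#' falls within the apical zone of the fully elongated root
#' (`s <= lmax_realized - la`). A lateral at position s becomes active
#' only once the parent length reaches `s + la` (the apical-zone delay);
#' activation times are handled by the simulator.
#'
#' @param lb basal zone length, cm.
#' @param ln_draws positive interlateral distance draws, cm (recycled as
#'   needed is NOT done: supply at least enough draws).
#' @param la apical zone length, cm.
#' @param lmax_realized realized maximal length of the parent, cm.
#' @return numeric vector of arc-length positions (possibly empty).
#' @export
emergence_schedule <- function(lb, ln_draws, la, lmax_realized) {
  stopifnot(lb >= 0, la >= 0, all(ln_draws > 0))
  smax <- lmax_realized - la
  if (lb > smax) return(numeric(0))
  s <- lb + c(0, cumsum(ln_draws))
  s[s <= smax + 1e-12]
}

# orthonormal basis perpendicular to unit vector h
perp_basis <- function(h) {
  ref <- if (abs(h[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  u <- cross3(h, ref); u <- u / sqrt(sum(u^2))
  v <- cross3(h, u)
  list(u = u, v = v)
}

# rotate unit vector h by angle alpha toward azimuth beta in its normal plane
deflect <- function(h, alpha, beta) {
  b <- perp_basis(h)
  cos(alpha) * h + sin(alpha) * (cos(beta) * b$u + sin(beta) * b$v)
}

#' Draw the next growth heading under the probabilistic tropism objective
#'
#' Candidate headings are the previous heading deflected by an angle
#' `alpha ~ |N(0, sigma_eff)|` about a uniform azimuth, `N` candidates per
#' step; the one optimizing the tropism objective wins. Gravitropism
#' minimizes the vertical component z (z negative is down, so the most
#' downward candidate wins); plagiotropism minimizes |z|, keeping growth
#' near horizontal. For type-2 roots in `per_segment` mode the objective
#' is redrawn each segment: gravitropic with probability `p_gravi`, else
#' plagiotropic. Types 1/3 and roots assigned a fixed objective
#' (`per_root` mode) always use that objective. `sigma_eff` scales as
#' `sigma * sqrt(dx)` (length-scaled random walk), so with `sigma = 0`
#' every candidate equals the old heading and roots grow straight.
#'
#' @param heading unit length-3 vector, previous growth direction.
#' @param root_type integer 1:3.
#' @param tp list with `N`, `sigma`, `p_gravi` (type 2), and optionally
#'   `objective` ("gravi"/"plagio") fixing the objective.
#' @param dx segment length, cm.
#' @return unit heading; attribute `objective` records the draw.
#' @export
tropism_next_heading <- function(heading, root_type, tp, dx) {
  nh <- sqrt(sum(heading^2))
  if (nh == 0) stop("zero-length heading")
  heading <- heading / nh
  n_cand <- max(1L, as.integer(tp$N))
  sigma_eff <- tp$sigma * sqrt(dx)
  objective <- if (!is.null(tp$objective)) tp$objective
  else if (root_type == 2L) {
    if (stats::runif(1) < tp$p_gravi) "gravi" else "plagio"
  } else "gravi"
  if (sigma_eff == 0)
    return(structure(heading, objective = objective))
  alpha <- abs(stats::rnorm(n_cand, 0, sigma_eff))
  beta <- stats::runif(n_cand, 0, 2 * pi)
  cand <- vapply(seq_len(n_cand), function(i)
    deflect(heading, alpha[i], beta[i]), numeric(3))
  score <- if (objective == "gravi") cand[3, ] else abs(cand[3, ])
  best <- cand[, which.min(score)]
  structure(best / sqrt(sum(best^2)), objective = objective)
}

#' Initialize a static root system for simulation
#'
#' The stem (type 0) and the 1-year-old woody adventitious roots (type 1)
#' of the source root system are copied verbatim as immutable, persistent
#' axes. Every attachment point where a type-2 root exists in the source
#' becomes a scheduled lateral emergence point (the source's measured
#' type-2/3 geometry itself is discarded and regenerated by simulation),
#' so simulated laterals emerge exactly where roots were present in the
#' field data.
#'
#' @param source a `root_system` or an RSML file path.
#' @param params a `genotype_params` object.
#' @return list of class `sim_state`: `static` (root_system of type-0/1
#'   axes), `emergence` (data.frame `axis`, `node`), `params`.
#' @export
initialize_static <- function(source, params) {
  rs <- if (is.character(source)) read_rsml(source) else source
  types <- axis_types(rs)
  keep <- which(types <= 1L)
  if (!any(types[keep] == 1L)) stop("no type-1 (adventitious) axis in source")
  remap <- match(seq_along(rs$axes), keep)  # old index -> new index or NA
  static_axes <- lapply(keep, function(i) {
    a <- rs$axes[[i]]
    a$parent <- if (is.na(a$parent)) NA_integer_ else remap[a$parent]
    a
  })
  emergence <- do.call(rbind, c(list(
    data.frame(axis = integer(0), node = integer(0))),
    lapply(which(types == 2L), function(i) {
      a <- rs$axes[[i]]
      p <- remap[a$parent]
      if (is.na(a$parent) || is.na(p))
        stop("type-2 axis ", i, " is not attached to a static axis")
      data.frame(axis = p, node = a$parent_node)
    })))
  structure(list(static = root_system(static_axes, genotype = params$genotype,
                                      age = rs$age),
                 emergence = emergence, params = params),
            class = "sim_state")
}

# sample from N(mean, sd) truncated to positive values (resample)
rtrunc_pos <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      v <- stats::rnorm(1, mean, sd)
      if (v > 0) { out[i] <- v; break }
    }
  }
  out
}

# grow one axis analytically: the elongation law has a closed-form inverse,
# so the polyline is laid down by exact arc-length stepping (dx segments,
# final partial segment allowed); node ages follow from the inverse law.
grow_axis <- function(type, t_emerge, days, origin, heading0, tp, global,
                      counters) {
  age <- days - t_emerge
  L <- growth_length(age, tp$lmax, tp$r)
  dx <- global$dx
  n_seg <- ceiling(max(L, 1e-12) / dx - 1e-9)
  if (L < 1e-6 || n_seg < 1L) return(NULL)
  nodes <- matrix(0, n_seg + 1L, 3)
  nodes[1L, ] <- origin
  s <- numeric(n_seg + 1L)
  h <- heading0
  pos <- origin
  tp_draw <- tp
  if (global$tropism_mode == "per_root" && type == 2L)
    tp_draw$objective <- if (stats::runif(1) < tp$p_gravi) "gravi" else "plagio"
  for (k in seq_len(n_seg)) {
    step <- min(dx, L - (k - 1L) * dx)
    if (k > 1L) {  # first segment keeps the insertion heading
      h <- tropism_next_heading(h, type, tp_draw, step)
      if (type == 2L && is.null(tp_draw$objective)) {
        # probabilistic per-segment draws only (the genotype threshold)
        obj <- attr(h, "objective")
        counters[[obj]] <- counters[[obj]] + 1L
      }
    }
    pos <- pos + step * h
    nodes[k + 1L, ] <- pos
    s[k + 1L] <- s[k] + step
  }
  t_node <- t_emerge + growth_time(pmin(s, tp$lmax * (1 - 1e-12)),
                                   tp$lmax, tp$r)
  ages <- pmax(days - t_node, 0)
  list(nodes = nodes, ages = ages, arc = s, final_length = L)
}

#' Simulate genotype-specific root growth from a static root system
#'
#' Grows type-2 laterals from the static emergence points and type-3 fine
#' laterals from the interlateral schedule on each type-2 root, over
#' `days` days. Per-axis parameters (insertion angle, radius; for type 2
#' also basal/apical zone and interlateral distances) are sampled once at
#' emergence from truncated normal distributions; lmax and r are
#' deterministic. Elongation follows [growth_length()]; headings follow
#' [tropism_next_heading()], with each lateral's first segment set by the
#' sampled insertion angle about a uniform azimuth. A type-3 lateral at
#' arc position s activates when its parent's length first reaches
#' `s + la`. The elongation law is integrated exactly (closed-form
#' inverse), so the result is independent of the bookkeeping time step
#' `dt`; `dt` is validated for API compatibility. Static axes are never
#' modified; their node ages are set to `days + 365` (1-year-old woody
#' roots at planting).
#'
#' @param state a `sim_state` from [initialize_static()].
#' @param days simulation horizon, days (>= 0).
#' @param dt time step, days (> 0); the exact integration makes results
#'   independent of it.
#' @param seed RNG seed for full reproducibility.
#' @return a `root_system` with per-node ages; attribute `tropism_draws`
#'   counts the probabilistic segment-level gravitropic/plagiotropic
#'   objective draws of type-2 roots (the genotype threshold's long-run
#'   fraction).
#' @export
simulate_growth <- function(state, days, dt = 1, seed = 1L) {
  stopifnot(inherits(state, "sim_state"))
  if (dt <= 0) stop("dt must be positive")
  if (days < 0) stop("days must be non-negative")
  set.seed(seed)
  gp <- state$params
  global <- gp$global
  axes <- state$static$axes
  for (i in seq_along(axes)) axes[[i]]$ages <- rep(days + 365,
                                                   nrow(axes[[i]]$nodes))
  counters <- new.env(parent = emptyenv())
  counters$gravi <- 0L; counters$plagio <- 0L

  n_t2 <- 0; n_t3 <- 0
  if (days > 0 && nrow(state$emergence)) {
    for (e in seq_len(nrow(state$emergence))) {
      if (stats::runif(1) > global$emergence_prob) next
      pi_ <- state$emergence$axis[e]
      pj <- state$emergence$node[e]
      parent_axis <- axes[[pi_]]
      t0 <- global$emergence_time
      if (t0 >= days) next
      p2 <- gp$type2
      theta2 <- rtrunc_pos(1, p2$theta$mean, p2$theta$sd) * pi / 180
      a2 <- rtrunc_pos(1, p2$a$mean, p2$a$sd)
      pdir <- axis_direction_at(parent_axis, pj)
      h0 <- deflect(pdir, theta2, stats::runif(1, 0, 2 * pi))
      g2 <- grow_axis(2L, t0, days, parent_axis$nodes[pj, ], h0,
                      p2, global, counters)
      if (is.null(g2)) next
      axes[[length(axes) + 1L]] <-
        root_axis(g2$nodes, type = 2L, id = sprintf("T2_%d", e),
                  ages = g2$ages, radius = a2,
                  parent = pi_, parent_node = pj)
      t2_idx <- length(axes)
      n_t2 <- n_t2 + 1
      # schedule type-3 laterals on this type-2 root
      lb <- rtrunc_pos(1, p2$lb$mean, p2$lb$sd)
      la <- rtrunc_pos(1, p2$la$mean, p2$la$sd)
      n_draw <- ceiling(p2$lmax / max(p2$ln$mean, 1e-6)) + 10L
      ln_draws <- rtrunc_pos(n_draw, p2$ln$mean, p2$ln$sd)
      sched <- emergence_schedule(lb, ln_draws, la, p2$lmax)
      if (!length(sched)) next
      act_len <- sched + la
      used_nodes <- integer(0)
      p3 <- gp$type3
      for (s_k in sched[act_len <= g2$final_length + 1e-12]) {
        t_k <- t0 + growth_time(min(s_k + la, p2$lmax * (1 - 1e-12)),
                                p2$lmax, p2$r)
        if (t_k >= days) next
        j <- which.min(abs(g2$arc - s_k))  # nearest laid-down node
        if (j == nrow(g2$nodes)) j <- j - 1L
        if (j == 1L) j <- 2L
        if (j %in% used_nodes) next  # one lateral per parent node
        used_nodes <- c(used_nodes, j)
        theta3 <- rtrunc_pos(1, p3$theta$mean, p3$theta$sd) * pi / 180
        a3 <- rtrunc_pos(1, p3$a$mean, p3$a$sd)
        t2ax <- axes[[t2_idx]]
        pdir3 <- axis_direction_at(t2ax, j)
        h3 <- deflect(pdir3, theta3, stats::runif(1, 0, 2 * pi))
        g3 <- grow_axis(3L, t_k, days, t2ax$nodes[j, ], h3,
                        p3, global, counters)
        if (is.null(g3)) next
        axes[[length(axes) + 1L]] <-
          root_axis(g3$nodes, type = 3L, id = sprintf("T3_%d_%d", e, j),
                    ages = g3$ages, radius = a3,
                    parent = t2_idx, parent_node = j)
        n_t3 <- n_t3 + 1
      }
    }
  }
  out <- root_system(axes, genotype = gp$genotype, age = days)
  attr(out, "tropism_draws") <- c(gravi = counters$gravi,
                                  plagio = counters$plagio)
  out
}
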