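#' Run the field-to-parameter pipeline end to end
#'
#' Orchestrates the full chain on one digitized root system: parse the
#' digitizer point file, reconstruct topology, write RSML, compute the
#' trait report, estimate growth parameters, simulate genotype-specific
#' growth from the static initial system, and solve the hydraulic model
#' for the SUF depth distribution. Every stage's output is written to
#' `out_dir`; a manifest records input hashes, the seed and the package
#' version, making a run reproducible and auditable. Stage failures abort
#' with the stage name; outputs of completed stages are retained.
#'
#' @param config a list or YAML file path with fields: `input` (digitizer
#'   .txt path), `genotype`, `age` (observation age, d), `days_sim`
#'   (simulation horizon, default 180), `layer` (cm, default 1),
#'   `horizons` (depth breaks, default `c(0, 30, 60, 90, 120)`),
#'   `hydraulics` (YAML path or `NULL` for defaults), `seed`, `out_dir`.
#' @return named list of output paths, invisibly; also the in-memory
#'   results as attribute `results`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- list(days_sim = 180, layer = 1,
                   horizons = c(0, 30, 60, 90, 120),
                   hydraulics = NULL, seed = 1L)
  config <- utils::modifyList(defaults, config)
  for (f in c("input", "genotype", "age", "out_dir"))
    if (is.null(config[[f]])) stop("pipeline config: missing field '", f, "'")
  if (config$age <= 0) stop("pipeline config: age must be positive")
  if (!file.exists(config$input))
    stop("stage parse: input file not found: ", config$input)
  if (!is.null(config$hydraulics) && !file.exists(config$hydraulics))
    stop("stage hydraulics: config file not found: ", config$hydraulics)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage ", name, ": ", conditionMessage(e), call. = FALSE))
  }

  pts <- stage("parse", parse_points(config$input))
  built <- stage("build", build_root_system(pts))
  rs <- built$root_system
  rs$genotype <- config$genotype
  rs$age <- config$age
  # digitizer files carry no radii; fill per-type defaults from the
  # genotype table so traits and hydraulics are computable
  gp <- stage("params", genotype_params(config$genotype))
  for (i in seq_along(rs$axes)) {
    if (is.na(rs$axes[[i]]$radius))
      rs$axes[[i]]$radius <- switch(as.character(rs$axes[[i]]$type),
                                    "0" = 0.6, "1" = 0.2,
                                    "2" = gp$type2$a$mean,
                                    "3" = gp$type3$a$mean)
  }
  out$rsml <- file.path(config$out_dir, "root_system.rsml")
  stage("rsml", write_rsml(rs, out$rsml))

  tr <- stage("traits", compute_traits(rs, config$layer))
  out$traits <- file.path(config$out_dir, "traits.json")
  jsonlite::write_json(list(
    by_type = tr$by_type, total = tr$total, height_cm = tr$height_cm,
    width_cm = tr$width_cm, hull_volume_m3 = tr$hull_volume_m3,
    depth_profile = tr$depth_profile),
    out$traits, auto_unbox = TRUE, digits = NA)

  est <- stage("estimate", {
    bp <- branching_parameters(rs)
    types <- axis_types(rs)
    lens <- axis_lengths(rs)
    lr2 <- if (any(types == 2L))
      estimate_lmax_r(lens[types == 2L], config$age) else NULL
    lr3 <- if (any(types == 3L))
      estimate_lmax_r(lens[types == 3L], config$age) else NULL
    p_plagio <- tryCatch(estimate_tropism_probability(rs),
                         error = function(e) NA)
    list(branching = bp, lmax_r_type2 = lr2, lmax_r_type3 = lr3,
         p_plagio = p_plagio)
  })
  out$params <- file.path(config$out_dir, "params.yaml")
  yaml::write_yaml(rapply(unclass(est$branching), as.list, how = "replace"),
                   out$params)

  sim <- stage("simulate", {
    state <- initialize_static(rs, gp)
    simulate_growth(state, days = config$days_sim, seed = config$seed)
  })
  out$sim_rsml <- file.path(config$out_dir, "simulated.rsml")
  stage("rsml", write_rsml(sim, out$sim_rsml))

  suf <- stage("hydraulics", {
    hp <- hydraulic_params(file = config$hydraulics)
    sol <- solve_suf_krs(sim, hp)
    list(sol = sol,
         profile = suf_profile(sol, config$layer, config$horizons))
  })
  out$suf <- file.path(config$out_dir, "suf.csv")
  utils::write.csv(suf$profile$layers, out$suf, row.names = FALSE)
  out$suf_horizons <- file.path(config$out_dir, "suf_horizons.csv")
  utils::write.csv(suf$profile$horizons, out$suf_horizons, row.names = FALSE)

  out$manifest <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(list(
    input = config$input,
    input_md5 = unname(tools::md5sum(config$input)),
    genotype = config$genotype, age = config$age,
    days_sim = config$days_sim, seed = config$seed,
    krs = suf$sol$krs,
    package_version = as.character(utils::packageVersion("woodyroot")),
    r_version = R.version.string),
    out$manifest, auto_unbox = TRUE, digits = NA)

  structure(invisible(out),
            results = list(root_system = rs, traits = tr, estimates = est,
                           simulation = sim, hydraulics = suf))
}
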