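#' Default pipeline configuration
#'
#' One nested list drives the whole phantom-to-FFR chain; every block maps
#' onto one stage's arguments. Write it to YAML with [yaml::write_yaml()]
#' or load a modified copy with [read_pipeline_config()].
#'
#' @param seed Global seed (drives the phantom noise stream and any cohort
#'   simulation).
#' @param outdir Output directory for run artifacts.
#' @return A `pipeline_config` list with blocks `phantom`, `segmentation`,
#'   `reconstruction`, `hemodynamics`, `cohort`.
#' @export
default_pipeline_config <- function(seed = 1L, outdir = tempfile("ctffr-run-")) {
  structure(list(
    seed = as.integer(seed),
    outdir = outdir,
    phantom = list(
      L = 30, R0 = 2, d = 0.5, s0 = 15, w = 3,
      spacing = 0.4, lumen = 400, background = 50,
      noise_sd = 20, margin = 2, supersample = 1
    ),
    segmentation = list(step = 1, connectivity = 26),
    reconstruction = list(
      isolevel = 0.5, pre_smooth = 0,
      smooth_iterations = 0, smooth_factor = 0.5
    ),
    hemodynamics = list(
      rho = 1060, mu = 0.0035,
      p_aortic_mmhg = 100,
      hyperemia = "flow", # "flow": prescribed hyperemic flow; "resistance": distal resistance
      rest_flow_ml_s = 1, hyper_factor = 3,
      distal_resistance = 12
    ),
    cohort = list(
      n = 90,
      r_target = c(tc = 0.234, tg = 0.237, ldl = 0.285, apo = 0.298),
      event_prob = c(low = 0.1, medium = 0.1, high = 0.4)
    )
  ), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Missing fields are filled from [default_pipeline_config()].
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  ext <- tolower(tools::file_ext(path))
  user <- if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    abort("config must be .yaml, .yml or .json.")
  }
  base <- default_pipeline_config()
  merged <- utils::modifyList(unclass(base), user, keep.null = TRUE)
  structure(merged, class = "pipeline_config")
}

#' Validate a pipeline configuration
#'
#' Checks every stage block against its module's preconditions before any
#' stage runs; all violations are reported together.
#'
#' @param config A `pipeline_config` (or plain list with the same blocks).
#' @return A tibble of violations (`field`, `message`); zero rows means
#'   valid. Attribute `valid` carries the overall flag.
#' @export
validate_pipeline_config <- function(config) {
  v <- list()
  bad <- function(field, message) v[[length(v) + 1L]] <<- tibble(field = field, message = message)
  ph <- config$phantom
  num_pos <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x) && x > 0
  if (!num_pos(ph$L)) bad("phantom.L", "vessel length must be > 0")
  if (!num_pos(ph$R0)) bad("phantom.R0", "baseline radius must be > 0")
  if (!num_pos(ph$w)) bad("phantom.w", "stenosis width must be > 0")
  if (!is.numeric(ph$d) || ph$d < 0 || ph$d >= 1) {
    bad("phantom.d", "stenosis severity must lie in [0, 1)")
  }
  if (!all(vapply(ph$spacing, num_pos, TRUE))) bad("phantom.spacing", "voxel spacing must be > 0")
  if (!is.numeric(ph$lumen) || !is.numeric(ph$background) || ph$lumen <= ph$background) {
    bad("phantom.lumen", "lumen intensity must exceed background")
  }
  if (!is.numeric(ph$noise_sd) || ph$noise_sd < 0) bad("phantom.noise_sd", "noise sd must be >= 0")
  sg <- config$segmentation
  if (!num_pos(sg$step)) bad("segmentation.step", "scan step must be > 0")
  if (!sg$connectivity %in% c(6, 18, 26)) {
    bad("segmentation.connectivity", "connectivity must be 6, 18 or 26")
  }
  rc <- config$reconstruction
  if (!is.numeric(rc$isolevel)) bad("reconstruction.isolevel", "isolevel must be numeric")
  if (rc$smooth_iterations < 0) bad("reconstruction.smooth_iterations", "iterations must be >= 0")
  hd <- config$hemodynamics
  if (!num_pos(hd$rho)) bad("hemodynamics.rho", "density must be > 0")
  if (!num_pos(hd$mu)) bad("hemodynamics.mu", "viscosity must be > 0")
  if (!num_pos(hd$p_aortic_mmhg)) bad("hemodynamics.p_aortic_mmhg", "aortic pressure must be > 0")
  if (!hd$hyperemia %in% c("flow", "resistance")) {
    bad("hemodynamics.hyperemia", "hyperemia model must be 'flow' or 'resistance'")
  }
  if (hd$hyperemia == "flow" && !num_pos(hd$rest_flow_ml_s * hd$hyper_factor)) {
    bad("hemodynamics.rest_flow_ml_s", "hyperemic flow must be > 0")
  }
  if (hd$hyperemia == "resistance" && !num_pos(hd$distal_resistance)) {
    bad("hemodynamics.distal_resistance", "distal resistance must be > 0")
  }
  ch <- config$cohort
  if (!is.null(ch)) {
    r_tgt <- unlist(ch$r_target)
    e_pr <- unlist(ch$event_prob)
    if (!is.numeric(ch$n) || ch$n < 1) bad("cohort.n", "cohort size must be >= 1")
    if (any(abs(r_tgt) >= 1)) bad("cohort.r_target", "correlations must lie in (-1, 1)")
    if (any(e_pr < 0 | e_pr > 1)) {
      bad("cohort.event_prob", "event probabilities must lie in [0, 1]")
    }
  }
  out <- if (length(v)) dplyr::bind_rows(v) else tibble(field = character(), message = character())
  attr(out, "valid") <- nrow(out) == 0L
  out
}

# stage functions ------------------------------------------------------------
# Each stage reads its inputs from files and writes its outputs to files, so
# a stagewise run and a single-shot pipeline are bit-identical.

#' Pipeline stages
#'
#' File-mediated stage functions behind [run_pipeline()] and the command
#' line front-end. Each reads the documented input files, runs one module,
#' and writes its artifacts into `outdir`.
#'
#' @param config A `pipeline_config`.
#' @param outdir Output directory (created if needed).
#' @param volume_path,mask_path,profile_path Input artifact paths.
#' @return Named list of output paths, invisibly.
#' @name pipeline_stages
NULL

#' @rdname pipeline_stages
#' @export
stage_phantom <- function(config, outdir = config$outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  ph <- config$phantom
  geom <- vessel_geometry(L = ph$L, R0 = ph$R0, d = ph$d, s0 = ph$s0, w = ph$w)
  vol <- rasterize_ct(geom,
    spacing = ph$spacing, lumen = ph$lumen, background = ph$background,
    noise_sd = ph$noise_sd, margin = ph$margin,
    supersample = ph$supersample, seed = config$seed
  )
  truth <- lumen_truth_mask(geom, spacing = ph$spacing, margin = ph$margin)
  paths <- list(
    volume = file.path(outdir, "volume.mhd"),
    truth = file.path(outdir, "truth_mask.mhd")
  )
  write_ct_volume(vol, paths$volume)
  write_ct_volume(truth, paths$truth)
  invisible(paths)
}

#' @rdname pipeline_stages
#' @export
stage_segment <- function(volume_path, config, outdir = config$outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  vol <- read_ct_volume(volume_path)
  thr <- optimal_threshold(vol, step = config$segmentation$step)
  mask <- apply_threshold(vol, thr$t_star)
  mask <- largest_component(mask, connectivity = config$segmentation$connectivity)
  paths <- list(
    mask = file.path(outdir, "mask.mhd"),
    threshold = file.path(outdir, "threshold.json")
  )
  write_ct_volume(mask, paths$mask)
  jsonlite::write_json(
    list(
      t_star = thr$t_star, G_star = thr$G_star,
      a1 = thr$a1, a2 = thr$a2, M1 = thr$M1, M2 = thr$M2, abar = thr$abar,
      curve = thr$curve
    ),
    paths$threshold,
    auto_unbox = TRUE, digits = NA
  )
  invisible(paths)
}

#' @rdname pipeline_stages
#' @export
stage_reconstruct <- function(mask_path, config, outdir = config$outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  mask <- read_ct_volume(mask_path, mask = TRUE)
  rc <- config$reconstruction
  mesh <- marching_cubes(mask, isolevel = rc$isolevel, pre_smooth = rc$pre_smooth)
  if (rc$smooth_iterations > 0) {
    mesh <- smooth_mesh(mesh, iterations = rc$smooth_iterations, factor = rc$smooth_factor)
  }
  paths <- list(
    mesh_stl = file.path(outdir, "mesh.stl"),
    mesh_ply = file.path(outdir, "mesh.ply"),
    report = file.path(outdir, "mesh_report.json")
  )
  write_mesh(mesh, paths$mesh_stl, "stl")
  write_mesh(mesh, paths$mesh_ply, "ply")
  jsonlite::write_json(mesh_report(mesh), paths$report, auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' @rdname pipeline_stages
#' @export
stage_profile <- function(mask_path, config, outdir = config$outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  mask <- read_ct_volume(mask_path, mask = TRUE)
  prof <- extract_lumen_profile(mask, axis = 3)
  paths <- list(profile = file.path(outdir, "profile.csv"))
  readr::write_csv(prof[, c("s", "r")], paths$profile)
  invisible(paths)
}

#' @rdname pipeline_stages
#' @export
stage_simulate <- function(profile_path, config, outdir = config$outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  prof <- readr::read_csv(profile_path, show_col_types = FALSE)
  hd <- config$hemodynamics
  fluid <- fluid_model(rho = hd$rho, mu = hd$mu)
  bc <- if (hd$hyperemia == "flow") {
    flow_bc(
      inlet_pressure = hd$p_aortic_mmhg,
      inlet_flow = hd$rest_flow_ml_s * hd$hyper_factor
    )
  } else {
    flow_bc(
      inlet_pressure = hd$p_aortic_mmhg,
      outlet_resistance = hd$distal_resistance
    )
  }
  sol <- solve_steady_flow(prof, fluid, bc)
  ffr <- compute_ffr(
    sol$pressure_mmhg[nrow(sol)],
    sol$pressure_mmhg[1]
  )
  paths <- list(
    stations = file.path(outdir, "stations.csv"),
    ffr = file.path(outdir, "ffr.json")
  )
  readr::write_csv(tidy(sol), paths$stations)
  jsonlite::write_json(
    list(
      ffr = ffr$ffr, ps_mmhg = ffr$ps, pr_mmhg = ffr$pr,
      q_ml_s = attr(sol, "q_ml_s"), dp_pa = attr(sol, "dp_pa"),
      station_proximal = sol$s[1], station_distal = sol$s[nrow(sol)]
    ),
    paths$ffr,
    auto_unbox = TRUE, digits = NA
  )
  invisible(paths)
}

#' @rdname pipeline_stages
#' @export
stage_cohort <- function(config, outdir = config$outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  ch <- config$cohort
  coh <- simulate_cohort(
    n = ch$n, r_target = unlist(ch$r_target), event_prob = unlist(ch$event_prob),
    seed = config$seed
  )
  paths <- list(
    cohort = file.path(outdir, "cohort.csv"),
    stats = file.path(outdir, "cohort_stats.json")
  )
  readr::write_csv(coh, paths$cohort)
  jsonlite::write_json(cohort_statistics(coh), paths$stats, auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Standard statistical analysis of a cohort table
#'
#' Score-lipid Pearson correlations, one-way ANOVA of the score across
#' binary covariates, and the per-group MACCE incidence comparison.
#'
#' @param cohort A cohort tibble (as from [simulate_cohort()]).
#' @return Nested list of tidy results.
#' @export
cohort_statistics <- function(cohort) {
  lipids <- c("total_cholesterol", "triglyceride", "ldl_c", "apob_apoa1")
  cors <- purrr::map(lipids, function(v) {
    pearson_r(cohort$syntax_score, cohort[[v]])
  })
  names(cors) <- lipids
  covs <- c("smoking", "diabetes", "hypertension", "hyperlipidemia", "unstable_angina")
  anovas <- purrr::map(covs, function(v) {
    g <- cohort[[v]]
    if (length(unique(g)) < 2L) return(NULL)
    anova_oneway(cohort$syntax_score, g)
  })
  names(anovas) <- covs
  ev <- group_event_rates(cohort)
  list(
    correlations = cors,
    anova = anovas[!vapply(anovas, is.null, TRUE)],
    events = list(
      rates = ev$rates, overall = ev$overall, pairwise = ev$pairwise,
      degenerate = ev$degenerate
    )
  )
}

#' Run the full phantom-to-FFR pipeline
#'
#' Executes phantom, segmentation, reconstruction, profile extraction and
#' the steady flow solve in sequence (plus the cohort stage when a cohort
#' block is present), writing every intermediate artifact and a
#' machine-readable run manifest (package version, seed, config, MD5 of
#' each artifact). All stages are file-mediated, so re-running any stage on
#' the saved intermediates reproduces the single-shot outputs bit for bit.
#'
#' @param config A `pipeline_config`; validated before any stage runs.
#' @param outdir Output directory (defaults to `config$outdir`).
#' @return Invisibly, a list: `paths` (all artifact paths), `ffr` (the
#'   parsed FFR result), `manifest` (path to `manifest.json`).
#' @examples
#' \donttest{
#' cfg <- default_pipeline_config(seed = 7)
#' res <- run_pipeline(cfg)
#' jsonlite::read_json(res$paths$ffr)$ffr
#' }
#' @export
run_pipeline <- function(config = default_pipeline_config(), outdir = config$outdir) {
  viol <- validate_pipeline_config(config)
  if (!attr(viol, "valid")) {
    abort(paste(
      "invalid pipeline config:",
      paste(sprintf("%s: %s", viol$field, viol$message), collapse = "; ")
    ))
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  log <- list()
  tick <- function(stage, expr) {
    t0 <- Sys.time()
    out <- tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)))
    })
    log[[stage]] <<- list(elapsed_s = as.numeric(Sys.time() - t0, units = "secs"))
    out
  }
  p1 <- tick("phantom", stage_phantom(config, outdir))
  p2 <- tick("segment", stage_segment(p1$volume, config, outdir))
  p3 <- tick("reconstruct", stage_reconstruct(p2$mask, config, outdir))
  p4 <- tick("profile", stage_profile(p2$mask, config, outdir))
  p5 <- tick("simulate", stage_simulate(p4$profile, config, outdir))
  p6 <- if (!is.null(config$cohort)) tick("cohort", stage_cohort(config, outdir)) else NULL

  paths <- c(p1, p2, p3, p4, p5, p6)
  cfg_json <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA)
  artifacts <- unlist(paths)
  manifest <- list(
    package = "ctffr",
    version = as.character(utils::packageVersion("ctffr")),
    seed = config$seed,
    config = jsonlite::fromJSON(cfg_json, simplifyVector = TRUE),
    config_md5 = unname(tools::md5sum(write_temp_text(cfg_json))),
    artifacts = as.list(stats::setNames(unname(tools::md5sum(artifacts)), basename(artifacts))),
    stages = log
  )
  manifest_path <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA)
  invisible(list(
    paths = paths,
    ffr = jsonlite::read_json(paths$ffr, simplifyVector = TRUE),
    manifest = manifest_path
  ))
}

write_temp_text <- function(txt) {
  f <- tempfile(fileext = ".json")
  writeLines(txt, f)
  f
}
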