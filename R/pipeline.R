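## Config-driven pipeline entry points.  Each run_* function takes a config
## (a named list, or a path to a YAML/JSON file), validates it against the
## known keys, writes its outputs into out_dir, and drops a provenance log
## (config echo + package version + seed) so a run can be repeated
## bit-identically.  A thin command-line wrapper over these functions lives
## in scripts/vesicurv.R.

default_config <- function() {
  list(
    seed = 1L,
    out_dir = ".",
    population = list(n = 30L, m_true = 0.4, kappa_ratio = 0,
                      R_alpha_median = 7.5, R_alpha_sdlog = 0.25,
                      radius_noise = 0.02),
    deformation = list(R0 = 10, r_max = 1.05, tau_field = 1.5, t_uv = 7.2,
                       delta_A_max = 0.046, tau_uv = 10, frame_dt = 0.2,
                       t_end = 40, frame_noise = 0.005),
    contour = list(n_points = 100L, point_noise = 0.05),
    elution = list(incorporated_share = 0.0074, step = 0.01,
                   v_range = c(3, 10.5), noise_sd = 0),
    analysis = list(kappa_ratio_grid = c(0, 0.5, 1, 1.5, 2),
                    c_total = 0.25e-3, c_lipid = 0.1e-3,
                    incorporated_window = c(4.8, 6.0),
                    free_windows = list(c(6.0, 7.55), c(7.55, 9.3)),
                    baseline = "none"),
    paths = list(radius_table = NULL, deformation_csv = NULL,
                 elution_csv = NULL)
  )
}

## Merge user config over defaults, rejecting unknown keys at every level.
merge_config <- function(user, defaults = default_config(), path = "") {
  if (is.null(user)) return(defaults)
  if (!is.list(user)) stop("config section '", path, "' must be a mapping")
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ",
         paste0(path, unknown, collapse = ", "))
  for (k in names(user)) {
    if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]]))) {
      defaults[[k]] <- merge_config(user[[k]], defaults[[k]],
                                    paste0(path, k, "."))
    } else defaults[[k]] <- user[[k]]
  }
  defaults
}

#' Load and validate a run configuration
#'
#' @param config A named list, a path to a YAML or JSON file, or \code{NULL}
#'   for the defaults.  Unknown keys are rejected by name.
#' @param seed,out_dir Optional overrides.
#' @return The fully merged config list.
#' @export
load_config <- function(config = NULL, seed = NULL, out_dir = NULL) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- if (grepl("\\.json$", config, ignore.case = TRUE))
      jsonlite::read_json(config, simplifyVector = TRUE)
    else yaml::read_yaml(config)
  }
  cfg <- merge_config(config)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  if (!is.null(out_dir)) cfg$out_dir <- out_dir
  cfg
}

write_provenance <- function(cfg, out_dir, what) {
  log <- list(task = what,
              package = "vesicurv",
              version = as.character(utils::packageVersion("vesicurv")),
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
              config = cfg)
  jsonlite::write_json(log, file.path(out_dir, paste0(what, "_log.json")),
                       auto_unbox = TRUE, pretty = TRUE, null = "null",
                       digits = NA)
}

ensure_dir <- function(d) {
  if (!dir.exists(d) && !dir.create(d, recursive = TRUE))
    stop("cannot create output directory: ", d)
  d
}

#' Generate all synthetic datasets of a run
#'
#' Writes the four synthetic inputs (radius table, deformation series,
#' contour table, elution trace) as CSV plus a JSON ground-truth sidecar and
#' a provenance log.  Identical config and seed reproduce identical files.
#'
#' @param config Config list or YAML/JSON path (see \code{\link{load_config}}).
#' @param seed,out_dir Optional overrides.
#' @return Invisibly, the named vector of written file paths.
#' @export
run_simulate <- function(config = NULL, seed = NULL, out_dir = NULL) {
  cfg <- load_config(config, seed, out_dir)
  d <- ensure_dir(cfg$out_dir)

  pop <- do.call(gen_budded_population, c(cfg$population,
                                          list(seed = cfg$seed)))
  series <- do.call(gen_deformation_series,
                    c(cfg$deformation, list(seed = cfg$seed + 1L)))
  ct <- gen_contour(budded_shape(5, 1), n_points = cfg$contour$n_points,
                    point_noise = cfg$contour$point_noise,
                    seed = cfg$seed + 2L)
  peaks <- sec_default_peaks(cfg$elution$incorporated_share)
  trace <- gen_elution_trace(peaks, v_range = cfg$elution$v_range,
                             step = cfg$elution$step,
                             noise_sd = cfg$elution$noise_sd,
                             seed = cfg$seed + 3L)

  files <- c(
    radius_table = write_csv_strict(pop$shapes, file.path(d, "radius_table.csv")),
    deformation = write_csv_strict(
      data.frame(t_s = series$t_s, a_um = series$a_um, b_um = series$b_um,
                 uv_on = as.integer(series$uv_on)),
      file.path(d, "deformation_series.csv")),
    contours = write_csv_strict(
      data.frame(vesicle_id = 1L, point_index = seq_len(nrow(ct)),
                 x_um = ct$x, y_um = ct$y),
      file.path(d, "contours.csv")),
    elution = write_csv_strict(as.data.frame(trace),
                               file.path(d, "elution_trace.csv")))
  truth <- list(population = pop$truth,
                n_rejected = pop$n_rejected,
                deformation = attr(series, "truth"),
                contour = list(R_alpha = 5, R_beta = 1,
                               point_noise = cfg$contour$point_noise),
                elution = list(peaks = peaks,
                               true_areas = attr(trace, "true_areas")))
  jsonlite::write_json(truth, file.path(d, "ground_truth.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  write_provenance(cfg, d, "simulate")
  invisible(files)
}

#' Analyse a budded-vesicle radius table
#'
#' Runs \code{\link{neck_fit}} over the configured rigidity-ratio grid,
#' writes the per-vesicle curvature table, the per-ratio summary, the
#' limit-line point sets and a morphology-diagram figure.
#'
#' @inheritParams run_simulate
#' @return Invisibly, the \code{\link{neck_fit}} object.
#' @export
run_analyze_buds <- function(config = NULL, seed = NULL, out_dir = NULL) {
  cfg <- load_config(config, seed, out_dir)
  d <- ensure_dir(cfg$out_dir)
  path <- cfg$paths$radius_table
  if (is.null(path)) stop("config paths.radius_table is required")
  shapes <- read_radius_table(path)
  fit <- neck_fit(shapes, kappa_ratio = cfg$analysis$kappa_ratio_grid)
  write_csv_strict(fit$vesicles, file.path(d, "curvature_per_vesicle.csv"))
  write_csv_strict(fit$summary, file.path(d, "curvature_summary.csv"))
  for (kr in cfg$analysis$kappa_ratio_grid) {
    ln <- limit_shape_line(kr)
    write_csv_strict(as.data.frame(ln),
                     file.path(d, sprintf("limit_line_kr%g.csv", kr)))
  }
  grDevices::png(file.path(d, "morphology_diagram.png"),
                 width = 900, height = 700, res = 120)
  graphics::plot(fit)
  grDevices::dev.off()
  write_provenance(cfg, d, "analyze_buds")
  invisible(fit)
}

#' Analyse electrodeformation series
#'
#' @inheritParams run_simulate
#' @return Invisibly, the \code{\link{analyze_series}} result.
#' @export
run_deformation <- function(config = NULL, seed = NULL, out_dir = NULL) {
  cfg <- load_config(config, seed, out_dir)
  d <- ensure_dir(cfg$out_dir)
  path <- cfg$paths$deformation_csv
  if (is.null(path)) stop("config paths.deformation_csv is required")
  series <- read_deformation_csv(path)
  res <- analyze_series(series)
  write_csv_strict(
    data.frame(A_baseline_um2 = res$A_baseline, A_uv_max_um2 = res$A_uv_max,
               delta_A_rel = res$delta_A_rel, nu_baseline = res$nu_baseline),
    file.path(d, "area_increase.csv"))
  write_provenance(cfg, d, "deformation")
  invisible(res)
}

#' Analyse an SEC elution trace
#'
#' @inheritParams run_simulate
#' @return Invisibly, the \code{\link{partition_analysis}} result.
#' @export
run_partitioning <- function(config = NULL, seed = NULL, out_dir = NULL) {
  cfg <- load_config(config, seed, out_dir)
  d <- ensure_dir(cfg$out_dir)
  path <- cfg$paths$elution_csv
  if (is.null(path)) stop("config paths.elution_csv is required")
  trace <- read_elution_csv(path)
  res <- partition_analysis(trace,
                            incorporated_window = cfg$analysis$incorporated_window,
                            free_windows = cfg$analysis$free_windows,
                            c_total = cfg$analysis$c_total,
                            c_lipid = cfg$analysis$c_lipid,
                            baseline = cfg$analysis$baseline)
  write_csv_strict(
    data.frame(c_incorporated_M = res$c_incorporated,
               fraction_percent = res$fraction_percent,
               lipids_per_switch = res$lipids_per_switch,
               area_incorporated = res$area_incorporated,
               area_total = res$area_total),
    file.path(d, "partitioning.csv"))
  write_provenance(cfg, d, "partitioning")
  invisible(res)
}
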