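#' Run the full CSP analysis pipeline
#'
#' Orchestrates load -> CSP -> global fit -> classification ->
#' (optional) structure mapping, writing `csp_profiles.csv`,
#' `fit_report.json`, `classification.csv`, optionally a scored PDB,
#' and `run_log.json` (config echo, thresholds, seed, package version)
#' into `out_dir`. Deterministic for a fixed config and seed.
#'
#' @param config a named list or a path to a JSON/YAML config file.
#'   Recognised fields: `manifest` (path, required), `base_dir`,
#'   `n_weight`, `scale` (CSP convention), `fit` (list: `residues`,
#'   `min_points`, `sd_mult`, `bounds`, `bootstrap_n`, `seed`),
#'   `classification` (list: `sd_mult` ignored — tiers are fixed at
#'   1/2/3 s.d.), `structure` (list: `path`, `offset`), `out_dir`.
#' @param out_dir overrides `config$out_dir`.
#' @return Invisibly, a list with `profiles`, `fit`, `bootstrap`,
#'   `classification`, `paths` of the written artifacts.
#' @export
run_analysis <- function(config, out_dir = NULL) {
  config <- load_config(config)
  if (is.null(config$manifest)) {
    stop("config error: 'manifest' is required", call. = FALSE)
  }
  if (!file.exists(config$manifest)) {
    stop("config error: manifest not found: ", config$manifest,
         call. = FALSE)
  }
  out_dir <- out_dir %||% config$out_dir %||% "cspfit_results"
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  n_weight <- config$n_weight %||% 0.14
  scale <- config$scale %||% 0.5
  fit_cfg <- config$fit %||% list()
  seed <- fit_cfg$seed %||% 1L

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  series <- stage("load",
                  load_titration_series(config$manifest,
                                        base_dir = config$base_dir))
  profiles <- stage("csp",
                    build_csp_profiles(series, n_weight = n_weight,
                                       scale = scale))
  residues <- stage("select",
                    select_fit_residues(profiles,
                                        residues = fit_cfg$residues,
                                        min_points = fit_cfg$min_points %||% 3,
                                        sd_mult = fit_cfg$sd_mult %||% 1))
  fit <- stage("fit",
               fit_global_kd(profiles, residues,
                             bounds = fit_cfg$bounds %||% c(1e-3, 1e6)))
  boot <- NULL
  if (!is.null(fit_cfg$bootstrap_n) && fit_cfg$bootstrap_n > 0) {
    boot <- stage("bootstrap",
                  bootstrap_kd(profiles, residues,
                               n_boot = fit_cfg$bootstrap_n,
                               seed = seed))
  }
  ep <- stage("classify", endpoint_csp(profiles))
  cls <- stage("classify", classify_by_sd(ep))

  paths <- list(
    csp_profiles = file.path(out_dir, "csp_profiles.csv"),
    fit_report = file.path(out_dir, "fit_report.json"),
    classification = file.path(out_dir, "classification.csv"),
    run_log = file.path(out_dir, "run_log.json")
  )
  write_csp_profiles(profiles, paths$csp_profiles)
  write_classification(cls, paths$classification)

  if (!is.null(config$structure) && !is.null(config$structure$path)) {
    paths$scored_pdb <- file.path(out_dir, "classification_scored.pdb")
    stage("map",
          map_classification_to_structure(
            cls, config$structure$path, paths$scored_pdb,
            offset = config$structure$offset %||% 0L,
            shift_types = series$tables[[1]]))
  }

  report <- list(
    kd_uM = fit$kd,
    kd_stderr_uM = fit$kd_stderr,
    kd_bootstrap = if (!is.null(boot)) {
      list(lower_uM = boot$interval[["lower"]],
           upper_uM = boot$interval[["upper"]],
           level = boot$level, n_boot = length(boot$kd_boot),
           kind = "percentile")
    },
    dmax_ppm = as.list(fit$dmax),
    dmax_stderr_ppm = as.list(fit$dmax_stderr),
    residues_used = fit$residues_used,
    n_obs = fit$n_obs,
    converged = fit$converged,
    kd_at_bound = fit$kd_at_bound,
    endpoint_fraction_bound = fit$endpoint_fraction_bound
  )
  jsonlite::write_json(report, paths$fit_report, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")

  log <- list(
    package = "cspfit",
    version = as.character(utils::packageVersion("cspfit")),
    seed = seed,
    n_weight = n_weight, scale = scale,
    classification_thresholds = as.list(cls$thresholds),
    classification_mean = cls$mean_csp,
    classification_sd = cls$sd_csp,
    residues_selected = residues,
    dropped_residues = attr(profiles, "dropped_residues"),
    config = config
  )
  jsonlite::write_json(log, paths$run_log, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")

  invisible(list(profiles = profiles, fit = fit, bootstrap = boot,
                 classification = cls, paths = paths))
}

#' Simulate a titration bundle to disk
#'
#' Thin wrapper: builds (or loads) a [titration_spec()], runs
#' [simulate_titration()] and writes the bundle with
#' [write_titration_bundle()], printing a ground-truth summary.
#'
#' @param spec a `titration_spec`, a preset name (see
#'   [titration_preset()]), or a path to a JSON spec file.
#' @param out_dir output directory.
#' @param seed seed used when `spec` is a preset name or JSON file.
#' @return the output directory, invisibly.
#' @export
run_simulate <- function(spec, out_dir, seed = 1L) {
  if (is.character(spec)) {
    if (file.exists(spec)) {
      j <- jsonlite::read_json(spec, simplifyVector = TRUE)
      j$binders <- as.data.frame(j$binders)
      if (is.null(j$seed)) j$seed <- seed
      spec <- do.call(titration_spec, j)
    } else {
      spec <- titration_preset(spec, seed = seed)
    }
  }
  sim <- simulate_titration(spec)
  write_titration_bundle(sim, out_dir)
  message(sprintf(
    "simulated %d-point titration (P = %g uM, L up to %g uM), true K_D = %g uM, %d binders -> %s",
    length(spec$L_schedule), spec$P_conc, max(spec$L_schedule), spec$kd,
    nrow(spec$binders), out_dir))
  invisible(out_dir)
}

load_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) {
      stop("config error: no such file: ", config, call. = FALSE)
    }
    ext <- tolower(tools::file_ext(config))
    config <- if (ext %in% c("yaml", "yml")) {
      if (!requireNamespace("yaml", quietly = TRUE)) {
        stop("YAML config requires the 'yaml' package", call. = FALSE)
      }
      yaml::read_yaml(config)
    } else {
      jsonlite::read_json(config, simplifyVector = TRUE)
    }
  }
  if (!is.list(config)) stop("config must be a list or a file path",
                             call. = FALSE)
  config
}

`%||%` <- function(a, b) if (is.null(a)) b else a
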