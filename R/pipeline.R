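#' End-to-end run configuration
#'
#' @param input Path to a track CSV, or `NULL` when simulating.
#' @param simulation A [simulation_config()], or `NULL` when reading a
#'   file. Exactly one of `input`/`simulation` must be given.
#' @param acquisition An [acquisition_spec()].
#' @param dialect A [track_dialect()] for file input.
#' @param metrics_filter Preset name for the motility-metrics stage.
#' @param grid A [make_grid()].
#' @param kernel A [spread_kernel()].
#' @param velocity_method `"centered"` or `"forward"` (see
#'   [infer_cells()]).
#' @param clustering List of clustering settings: `k`, `eps`, `min_pts`,
#'   `n_restarts`, `n_reps`.
#' @param compare Condition column for pairwise proportion z tests, or
#'   `NULL` to use the first condition column when at least two levels are
#'   present.
#' @param seed Global integer seed; per-stage streams are derived from it,
#'   so e.g. changing the number of bootstrap replicates does not perturb
#'   the simulation draws.
#' @param out_dir Output directory for stage artifacts.
#' @return An object of class `run_config`.
#' @export
run_config <- function(input = NULL, simulation = NULL,
                       acquisition = acquisition_spec(),
                       dialect = track_dialect(),
                       metrics_filter = "speed_2d3d",
                       grid = make_grid(), kernel = spread_kernel(),
                       velocity_method = "centered",
                       clustering = list(k = 4, eps = 0.5, min_pts = 5,
                                         n_restarts = 10, n_reps = 100),
                       compare = NULL, seed = 1L, out_dir = tempfile("prwalk_run_")) {
  if (is.null(input) == is.null(simulation)) {
    abort("exactly one of `input` or `simulation` must be given")
  }
  defaults <- list(k = 4, eps = 0.5, min_pts = 5, n_restarts = 10, n_reps = 100)
  clustering <- utils::modifyList(defaults, clustering)
  structure(list(input = input, simulation = simulation,
                 acquisition = acquisition, dialect = dialect,
                 metrics_filter = metrics_filter, grid = grid,
                 kernel = kernel, velocity_method = velocity_method,
                 clustering = clustering, compare = compare,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Understands top-level keys `input`, `simulation` (with `populations` as a
#' list of `{label, fraction, q, a, n_steps, immobile}` records, plus
#' `n_cells`, `frame_interval`, `gap_rate`, `initial_speed_mode`),
#' `metrics_filter`, `grid` (`q_bounds`, `a_bounds`, `n_q`, `n_a`),
#' `kernel` (`half_width_q`, `half_width_a`), `velocity_method`,
#' `clustering`, `compare`, `seed`, `out_dir`.
#'
#' @param path Path to a YAML file.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  seed <- if (!is.null(y$seed)) as.integer(y$seed) else 1L
  acq <- if (!is.null(y$acquisition)) {
    do.call(acquisition_spec, y$acquisition)
  } else acquisition_spec()
  sim <- NULL
  if (!is.null(y$simulation)) {
    pops <- bind_rows(lapply(y$simulation$populations, function(p) {
      do.call(population_spec, p)
    }))
    sim_args <- y$simulation
    sim_args$populations <- pops
    if (is.null(sim_args$seed)) sim_args$seed <- seed
    sim <- do.call(simulation_config, sim_args)
  }
  grid <- if (!is.null(y$grid)) {
    make_grid(q_bounds = unlist(y$grid$q_bounds %||% c(-1, 1)),
              a_bounds = unlist(y$grid$a_bounds %||% c(0, 10)),
              n_q = y$grid$n_q %||% 101L, n_a = y$grid$n_a %||% 100L)
  } else make_grid()
  kernel <- if (!is.null(y$kernel)) do.call(spread_kernel, y$kernel) else
    spread_kernel()
  run_config(input = y$input, simulation = sim, acquisition = acq,
             metrics_filter = y$metrics_filter %||% "speed_2d3d",
             grid = grid, kernel = kernel,
             velocity_method = y$velocity_method %||% "centered",
             clustering = y$clustering %||% list(),
             compare = y$compare, seed = seed,
             out_dir = y$out_dir %||% tempfile("prwalk_run_"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.stage_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) * 48271 + stage * 16807) %% 2147483587)
}

#' Run the full analysis pipeline
#'
#' Simulate-or-ingest, filter, compute motility metrics, infer per-cell
#' random-walk parameters, cluster sub-populations with bootstrap, and write
#' all stage outputs plus a machine-readable manifest. Deterministic given
#' the config seed.
#'
#' @param config A [run_config()].
#' @return The run manifest (class `run_manifest`), invisibly; all stage
#'   artifacts are written under `config$out_dir`.
#' @details Outputs: `tracks.csv`, `exclusions.csv`, `track_metrics.csv`,
#'   `msd.csv`, `cell_params.csv`, `step_params.csv`, `cluster_report.json`,
#'   `proportions.csv`, `bootstrap.csv`, `contours.csv`,
#'   `comparisons.csv` (when at least two condition levels are present),
#'   `manifest.json`. Counts in the manifest reconcile:
#'   tracks read = analyzed + excluded.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  timings <- c()
  tick <- function(expr, name) {
    t0 <- proc.time()[["elapsed"]]
    res <- force(expr)
    timings[name] <<- round(proc.time()[["elapsed"]] - t0, 3)
    res
  }

  # --- ingest / simulate -------------------------------------------------
  tracks <- tick({
    if (!is.null(config$input)) {
      read_tracks(config$input, dialect = config$dialect,
                  acquisition = config$acquisition)
    } else {
      simulate_cohort(config$simulation)$tracks
    }
  }, "ingest")
  write_tracks(tracks, file.path(config$out_dir, "tracks.csv"))
  n_read <- length(unique(tracks$track_id))

  # --- metrics with eligibility filter -----------------------------------
  acq <- get_acquisition(tracks, if (!is.null(config$input)) config$acquisition)
  flt <- tick(apply_track_filters(tracks, config$metrics_filter, acq), "filter")
  readr::write_csv(flt$exclusions, file.path(config$out_dir, "exclusions.csv"),
                   progress = FALSE)
  metrics <- tick(track_metrics(flt$tracks, acquisition = acq), "metrics")
  readr::write_csv(metrics, file.path(config$out_dir, "track_metrics.csv"),
                   progress = FALSE)
  msd <- msd_ensemble(flt$tracks, max_lag = 10, require_continuous = 10,
                      acquisition = acq)
  readr::write_csv(as_tibble(msd), file.path(config$out_dir, "msd.csv"),
                   progress = FALSE)

  # --- inference ---------------------------------------------------------
  fit <- tick(infer_cells(tracks, grid = config$grid, kernel = config$kernel,
                          method = config$velocity_method,
                          policy = filter_preset("clustering"),
                          acquisition = acq), "inference")
  readr::write_csv(fit$summary, file.path(config$out_dir, "cell_params.csv"),
                   progress = FALSE)
  readr::write_csv(fit$steps, file.path(config$out_dir, "step_params.csv"),
                   progress = FALSE)
  contours <- tryCatch(
    joint_density_contours(fit$steps,
                           a_domain = c(0, max(config$grid$a))),
    error = function(e) NULL)
  if (!is.null(contours)) {
    readr::write_csv(tidy(contours), file.path(config$out_dir, "contours.csv"),
                     progress = FALSE)
  }

  # --- clustering --------------------------------------------------------
  eligible <- fit$summary[fit$summary$eligible, , drop = FALSE]
  cl_cfg <- config$clustering
  cl_seed <- .stage_seed(config$seed, 2L)
  cluster_out <- NULL; boot <- NULL; comparisons <- NULL
  n_outliers <- NA_integer_
  if (nrow(eligible) >= cl_cfg$k) {
    cluster_out <- tick({
      mask <- suppressWarnings(
        remove_outliers(eligible, cl_cfg$eps, cl_cfg$min_pts))
      rep0 <- label_and_merge(
        cluster_cells(eligible[mask, , drop = FALSE], k = cl_cfg$k,
                      n_restarts = cl_cfg$n_restarts, seed = cl_seed))
      list(mask = mask, report = rep0)
    }, "clustering")
    n_outliers <- sum(!cluster_out$mask)
    rep0 <- cluster_out$report
    jsonlite::write_json(
      list(k = rep0$k_used,
           centroids = rep0$tags %||% rep0$centroids,
           proportions = rep0$proportions,
           silhouette_by_k = rep0$silhouette_by_k,
           parameters = cl_cfg, seed = cl_seed),
      file.path(config$out_dir, "cluster_report.json"),
      dataframe = "rows", auto_unbox = TRUE, digits = NA)
    readr::write_csv(rep0$proportions,
                     file.path(config$out_dir, "proportions.csv"),
                     progress = FALSE)
    boot <- tick(
      bootstrap_proportions(eligible, k = cl_cfg$k, eps = cl_cfg$eps,
                            min_pts = cl_cfg$min_pts,
                            n_restarts = cl_cfg$n_restarts,
                            n_reps = cl_cfg$n_reps, seed = cl_seed),
      "bootstrap")
    readr::write_csv(boot$summary, file.path(config$out_dir, "bootstrap.csv"),
                     progress = FALSE)

    # condition comparisons
    cond <- config$compare %||% track_conditions(tracks)[1]
    if (!is.null(cond) && !is.na(cond) && cond %in% names(fit$summary)) {
      lab <- left_join(rep0$labels,
                       fit$summary[, c("track_id", cond)], by = "track_id")
      if (length(unique(lab[[cond]])) >= 2) {
        comparisons <- compare_proportions(lab, cond)
        readr::write_csv(comparisons,
                         file.path(config$out_dir, "comparisons.csv"),
                         progress = FALSE)
      }
    }
  }

  manifest <- structure(list(
    package_version = as.character(utils::packageVersion("prwalk")),
    seed = config$seed,
    input = config$input %||% "simulation",
    metrics_filter = config$metrics_filter,
    velocity_method = config$velocity_method,
    grid = list(q_bounds = config$grid$q_bounds,
                a_bounds = config$grid$a_bounds,
                n_q = config$grid$n_q, n_a = config$grid$n_a),
    kernel = list(half_width_q = config$kernel$half_width_q,
                  half_width_a = config$kernel$half_width_a),
    clustering = cl_cfg,
    counts = list(
      tracks_read = n_read,
      tracks_excluded = unname(flt$counts["n_excluded"]),
      tracks_analyzed = unname(flt$counts["n_kept"]),
      cells_inferred = nrow(fit$summary),
      cells_eligible = nrow(eligible),
      outliers = n_outliers,
      cells_clustered = if (!is.null(cluster_out))
        sum(cluster_out$mask) else 0L,
      bootstrap_redraws = if (!is.null(boot)) boot$n_redraws else NA_integer_
    ),
    timings_s = as.list(timings),
    out_dir = config$out_dir
  ), class = "run_manifest")
  stopifnot(manifest$counts$tracks_read ==
              manifest$counts$tracks_analyzed + manifest$counts$tracks_excluded)
  jsonlite::write_json(unclass(manifest),
                       file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(manifest)
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("<run_manifest> prwalk", x$package_version, "seed", x$seed, "\n")
  utils::str(x$counts, give.attr = FALSE)
  invisible(x)
}
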