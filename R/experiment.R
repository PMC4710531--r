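#' Configuration for an end-to-end simulation experiment
#'
#' Bundles everything one run needs: the VTG input (a file path, a VTG input
#' table, or a [cohort_spec()] to generate one), the window length, the
#' replication level, the spawning design and the master seed.
#'
#' @param vtg_input Path to a VTG input file, or a VTG input data.frame, or
#'   a [cohort_spec()] (generated with a seed derived from `seed`).
#' @param simulation_days Exposure window length (default 21, the
#'   standardized assay length).
#' @param n_replicates Independent replicate simulations per fish
#'   (default 50, the evaluation workflow's replication).
#' @param design `"group"` (four females per tank; same-day spawns binned)
#'   or `"paired"` (one female per tank; binning is a no-op and skipped).
#' @param seed Master integer seed.
#' @param out_dir Output directory, or `NULL` for no file output.
#' @param params An [model_parameters()] object.
#' @param verbose Emit progress messages (to stderr).
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(vtg_input, simulation_days = 21,
                              n_replicates = 50,
                              design = c("group", "paired"),
                              seed = 1L, out_dir = NULL,
                              params = model_parameters(),
                              verbose = TRUE) {
  design <- match.arg(design)
  if (missing(vtg_input) || is.null(vtg_input)) {
    stop("no VTG input given; supply a file path, a VTG input table, or a ",
         "cohort_spec (e.g. experiment_config(\"vtg.csv\"))", call. = FALSE)
  }
  if (simulation_days < 1 || n_replicates < 1) {
    stop("`simulation_days` and `n_replicates` must be >= 1", call. = FALSE)
  }
  structure(
    list(vtg_input = vtg_input, simulation_days = as.numeric(simulation_days),
         n_replicates = as.integer(n_replicates), design = design,
         seed = as.integer(seed), out_dir = out_dir, params = params,
         verbose = isTRUE(verbose)),
    class = "experiment_config"
  )
}

#' Run a replicated simulation experiment end to end
#'
#' Resolves the VTG input, simulates every fish `n_replicates` times,
#' computes the per-(replicate, group) reproduction metrics (with same-day
#' spawn binning under the group design) and, when an output directory is
#' configured, writes per-replicate output files (results summaries,
#' clutch-size matrix, spawning totals), the tidy metrics table, the input
#' table and the fully resolved parameter/experiment configuration so the
#' run can be reproduced exactly.
#'
#' @param config An [experiment_config()].
#' @return A list of class `experiment_result` with `cohort`
#'   (the `cohort_simulation`), `metrics` (tidy data.frame), `vtg_table`,
#'   `config` and `out_dir`.
#' @examples
#' cfg <- experiment_config(
#'   data.frame(fish_id = c("a", "b"), c_vtg_exposure = c(0.1, 0.08)),
#'   simulation_days = 21, n_replicates = 2, design = "paired",
#'   seed = 1, verbose = FALSE)
#' res <- run_experiment(cfg)
#' head(res$metrics)
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  log_info <- function(...) if (config$verbose) message(sprintf(...))

  vin <- config$vtg_input
  if (inherits(vin, "cohort_spec")) {
    set.seed(substream_seed(config$seed, "cohort-generation", 0L))
    vtg_table <- generate_cohort(vin)
  } else if (is.character(vin)) {
    vtg_table <- read_vtg_input(vin)
  } else if (is.data.frame(vin)) {
    vtg_table <- vin
  } else {
    stop("unusable VTG input of class ", paste(class(vin), collapse = "/"),
         call. = FALSE)
  }
  if (config$design == "paired") {
    # one female per group: give every fish its own group if not already so
    if (anyDuplicated(vtg_table$group_id)) vtg_table$group_id <- vtg_table$fish_id
  }
  log_info("simulating %d fish x %d replicates over %g days (+%g start-up), seed %d",
           nrow(vtg_table), config$n_replicates, config$simulation_days,
           config$params$startup_days, config$seed)

  cohort <- simulate_cohort(vtg_table, config$simulation_days,
                            config$n_replicates, config$params,
                            seed = config$seed)
  metrics <- cohort_metrics(cohort, design = config$design,
                            n_days = config$simulation_days)
  log_info("computed %d metric rows (%s design)", nrow(metrics), config$design)

  out_dir <- config$out_dir
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    for (r in seq_along(cohort)) {
      write_replicate_outputs(cohort[[r]], file.path(out_dir, sprintf("rep_%03d", r)))
    }
    utils::write.csv(metrics, file.path(out_dir, "metrics.csv"), row.names = FALSE)
    write_vtg_input(vtg_table, file.path(out_dir, "vtg_input.csv"))
    write_params_config(config$params, file.path(out_dir, "params.yml"))
    yaml::write_yaml(
      list(simulation_days = config$simulation_days,
           n_replicates = config$n_replicates, design = config$design,
           seed = config$seed),
      file.path(out_dir, "experiment.yml")
    )
    log_info("wrote outputs under %s", out_dir)
  }
  structure(list(cohort = cohort, metrics = metrics, vtg_table = vtg_table,
                 config = config, out_dir = out_dir),
            class = "experiment_result")
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf("Experiment: %d fish, %d replicates, %g-day window (%s design)\n",
              nrow(x$vtg_table), x$config$n_replicates,
              x$config$simulation_days, x$config$design))
  af <- x$metrics$average_fecundity
  cat(sprintf("  average fecundity across %d (replicate, group) cells: median %.3g, range [%.3g, %.3g]\n",
              nrow(x$metrics), stats::median(af), min(af), max(af)))
  invisible(x)
}

#' Recompute reproduction metrics from written output files
#'
#' Reads an experiment output directory (as written by [run_experiment()])
#' and recomputes the per-(replicate, group) metrics from the files alone:
#' egg totals from the spawning summaries, binned spawn counts from the
#' clutch-size matrices (group design) or raw spawn counts from the
#' spawning summaries (paired design).
#'
#' @param dir Experiment output directory.
#' @return A data.frame in the same shape as the `metrics` component of
#'   [run_experiment()].
#' @export
metrics_from_dir <- function(dir) {
  exp_cfg <- yaml::read_yaml(file.path(dir, "experiment.yml"))
  vtg <- read_vtg_input(file.path(dir, "vtg_input.csv"))
  n_days <- exp_cfg$simulation_days
  rep_dirs <- sort(list.dirs(dir, recursive = FALSE))
  rep_dirs <- rep_dirs[grepl("rep_\\d+$", rep_dirs)]
  groups <- unique(vtg[, c("group_id", "treatment")])
  group_sizes <- table(vtg$group_id)

  out <- do.call(rbind, lapply(seq_along(rep_dirs), function(r) {
    spawn <- read_spawning_summary(file.path(rep_dirs[r], "spawning_summary.txt"))
    clutch <- read_clutch_size_summary(file.path(rep_dirs[r], "clutch_size_summary.txt"))
    exposure <- clutch$day >= 0 & clutch$day < n_days
    do.call(rbind, lapply(seq_len(nrow(groups)), function(gi) {
      g <- groups$group_id[gi]
      fish <- vtg$fish_id[vtg$group_id == g]
      nf <- as.integer(group_sizes[[g]])
      n_egg <- sum(spawn$eggs_exposure[spawn$fish_id %in% fish])
      if (exp_cfg$design == "group") {
        day_tot <- rowSums(clutch[exposure, fish, drop = FALSE])
        n_sp <- sum(day_tot > 0)
      } else {
        n_sp <- sum(spawn$spawns_exposure[spawn$fish_id %in% fish])
      }
      data.frame(replicate = r, treatment = groups$treatment[gi],
                 group_id = g, n_female = nf, n_egg_total = n_egg,
                 n_spawns = n_sp,
                 average_fecundity = average_fecundity(n_egg, nf, n_days),
                 eggs_per_spawn = eggs_per_spawn(n_egg, n_sp),
                 spawns_per_female = spawns_per_female(n_sp, nf),
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  out
}
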