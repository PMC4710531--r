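#' Specification of one simulated female
#'
#' @param fish_id Unique fish label.
#' @param c_vtg_exposure Plasma VTG concentration during the exposure window
#'   (nmol uL^-1, >= 0); in the evaluation workflow this is the concentration
#'   measured at the end of a 21-day assay, held constant.
#' @param group_id Replicate tank / pair label (used for spawn binning in
#'   group designs).
#' @param treatment Treatment label.
#' @param c_vtg_pre Pre-exposure plasma VTG concentration; defaults to the
#'   parameter set's baseline (`c_vtg_pre_default`) when `NULL`.
#' @return An object of class `fish_spec`.
#' @export
fish_spec <- function(fish_id, c_vtg_exposure, group_id = "g1",
                      treatment = "control", c_vtg_pre = NULL) {
  stopifnot(length(fish_id) == 1L, is.numeric(c_vtg_exposure),
            length(c_vtg_exposure) == 1L)
  if (!is.finite(c_vtg_exposure) || c_vtg_exposure < 0) {
    stop("`c_vtg_exposure` must be a finite number >= 0", call. = FALSE)
  }
  if (!is.null(c_vtg_pre) && (!is.numeric(c_vtg_pre) || c_vtg_pre < 0)) {
    stop("`c_vtg_pre` must be >= 0", call. = FALSE)
  }
  structure(list(fish_id = as.character(fish_id),
                 group_id = as.character(group_id),
                 treatment = as.character(treatment),
                 c_vtg_exposure = as.numeric(c_vtg_exposure),
                 c_vtg_pre = if (is.null(c_vtg_pre)) NULL else as.numeric(c_vtg_pre)),
            class = "fish_spec")
}

# Two-segment protocol for a fish: baseline over the start-up window,
# measured exposure concentration from day 0 on. Collapses to one segment
# when there is no start-up.
fish_protocol <- function(spec, params) {
  c_pre <- if (is.null(spec$c_vtg_pre)) params$c_vtg_pre_default else spec$c_vtg_pre
  if (params$startup_days > 0) {
    vtg_protocol(c(-params$startup_days, 0), c(c_pre, spec$c_vtg_exposure))
  } else {
    vtg_protocol(0, spec$c_vtg_exposure)
  }
}

#' Simulate one female through start-up and exposure
#'
#' Runs the individual-based model for a single female: starting at the
#' beginning of the 81-day start-up window (study day -81), batches of
#' oogonia are recruited at sampled truncated-lognormal intervals with
#' sampled truncated-lognormal clutch sizes; each batch grows by absorbing
#' plasma VTG under the fish's two-segment concentration protocol and spawns
#' when its volume reaches the threshold. Spawn times are binned to integer
#' study days (eggs are collected daily in the assay); days < 0 are
#' pre-exposure, day 0 is the first exposure day.
#'
#' Uses the current R random number stream; seed it (or use
#' [simulate_cohort()]) for reproducibility.
#'
#' @param spec A [fish_spec()].
#' @param simulation_days Length of the exposure window in days (>= 1).
#' @param params An [model_parameters()] object.
#' @param method Growth integration method, passed to [grow_batch()].
#' @return An object of class `fish_simulation`: a list with `fish_id`,
#'   `spec`, `simulation_days`, `startup_days`, `batches` (one row per
#'   recruited batch, spawned or not), `events` (one row per spawn,
#'   chronological) and `totals` (spawns/eggs for the full period and for
#'   the exposure window alone).
#' @examples
#' p <- model_parameters()
#' set.seed(42)
#' sim <- simulate_fish(fish_spec("f1", 0.1), 21, p)
#' sim$totals
#' @export
simulate_fish <- function(spec, simulation_days, params,
                          method = c("closed_form", "ode")) {
  stopifnot(inherits(spec, "fish_spec"), inherits(params, "oocyte_params"))
  method <- match.arg(method)
  if (!is.numeric(simulation_days) || length(simulation_days) != 1L ||
      simulation_days < 1) {
    stop("`simulation_days` must be >= 1", call. = FALSE)
  }
  simulation_days <- as.numeric(simulation_days)
  protocol <- fish_protocol(spec, params)
  t_start <- -params$startup_days
  t_end <- simulation_days

  recruit_times <- numeric(0)
  clutches <- integer(0)
  intervals <- numeric(0)
  t <- t_start
  if (!params$first_recruit_at_start) {
    gap <- sample_recruitment_interval(params)
    intervals <- c(intervals, gap)
    t <- t + gap
  } else {
    intervals <- c(intervals, NA_real_)
  }
  while (t < t_end) {
    recruit_times <- c(recruit_times, t)
    clutches <- c(clutches, sample_clutch_size(params))
    gap <- sample_recruitment_interval(params)
    intervals <- c(intervals, gap)
    t <- t + gap
  }
  if (!params$first_recruit_at_start) intervals <- c(NA_real_, intervals)
  intervals <- intervals[seq_along(recruit_times)]

  n <- length(recruit_times)
  batches <- data.frame(
    batch_id = seq_len(n), recruit_time = recruit_times,
    recruit_day = floor(recruit_times), n_oogonia = clutches,
    interval_since_prev = intervals,
    m_vtg = NA_real_, v_ooc = NA_real_, status = character(n),
    spawn_time = NA_real_, spawn_day = NA_integer_,
    stringsAsFactors = FALSE
  )
  for (i in seq_len(n)) {
    b <- new_batch(recruit_times[i], clutches[i], params)
    b <- grow_batch(b, protocol, t_end, params, method = method, final = TRUE)
    batches$m_vtg[i] <- b$m_vtg
    batches$v_ooc[i] <- b$v_ooc
    batches$status[i] <- b$status
    if (b$status == "spawned") {
      batches$spawn_time[i] <- b$spawn_time
      batches$spawn_day[i] <- as.integer(min(floor(b$spawn_time), simulation_days - 1))
    }
  }

  sp <- batches[batches$status == "spawned", , drop = FALSE]
  sp <- sp[order(sp$spawn_time), , drop = FALSE]
  events <- data.frame(
    fish_id = rep(spec$fish_id, nrow(sp)),
    group_id = rep(spec$group_id, nrow(sp)),
    treatment = rep(spec$treatment, nrow(sp)),
    study_day = as.integer(sp$spawn_day),
    clutch_size = as.integer(sp$n_oogonia),
    spawn_time = sp$spawn_time,
    v_at_spawn = sp$v_ooc,
    stringsAsFactors = FALSE
  )
  exposure <- events$study_day >= 0
  totals <- list(
    full = list(spawns = nrow(events), eggs = sum(events$clutch_size)),
    exposure = list(spawns = sum(exposure),
                    eggs = sum(events$clutch_size[exposure]))
  )
  structure(
    list(fish_id = spec$fish_id, spec = spec,
         simulation_days = simulation_days,
         startup_days = params$startup_days,
         batches = batches, events = events, totals = totals),
    class = "fish_simulation"
  )
}

#' @export
print.fish_simulation <- function(x, ...) {
  cat(sprintf("Fish %s: %d batches, %d spawns (%d eggs) over [%g, %g) days;",
              x$fish_id, nrow(x$batches), x$totals$full$spawns,
              x$totals$full$eggs, -x$startup_days, x$simulation_days))
  cat(sprintf(" exposure window: %d spawns, %d eggs\n",
              x$totals$exposure$spawns, x$totals$exposure$eggs))
  invisible(x)
}

# Deterministic per-(fish, replicate) substream seed: a polynomial string
# hash keyed on the master seed, so adding or removing fish from a cohort
# never perturbs another fish's draws.
substream_seed <- function(seed, fish_id, replicate) {
  h <- as.double(seed %% 2147483647)
  for (ch in utf8ToInt(paste0(fish_id, "\r", replicate))) {
    h <- (h * 31 + ch) %% 2147483629
  }
  as.integer(h)
}

# Normalise a specs argument (list of fish_spec or a VTG input table) to a
# list of fish_spec.
as_fish_specs <- function(specs, params) {
  if (is.data.frame(specs)) {
    specs <- lapply(seq_len(nrow(specs)), function(i) {
      row <- specs[i, ]
      fish_spec(row$fish_id, row$c_vtg_exposure,
                group_id = if ("group_id" %in% names(row)) row$group_id else "g1",
                treatment = if ("treatment" %in% names(row)) row$treatment else "control",
                c_vtg_pre = if ("c_vtg_pre" %in% names(row) && !is.na(row$c_vtg_pre))
                  row$c_vtg_pre else NULL)
    })
  }
  if (!all(vapply(specs, inherits, logical(1), "fish_spec"))) {
    stop("`specs` must be fish_spec objects or a VTG input table", call. = FALSE)
  }
  ids <- vapply(specs, `[[`, character(1), "fish_id")
  if (anyDuplicated(ids)) {
    stop("duplicate fish_id: ", paste(unique(ids[duplicated(ids)]), collapse = ", "),
         call. = FALSE)
  }
  specs
}

#' Simulate a cohort of females with replication
#'
#' Runs `n_replicates` independent simulations of every fish. Each
#' (fish, replicate) pair gets its own random substream derived from the
#' master seed, so results are reproducible and per-fish randomness is
#' unaffected by the rest of the cohort's composition.
#'
#' @param specs A list of [fish_spec()] objects, or a VTG input table
#'   (data.frame with `fish_id`, `c_vtg_exposure` and optionally `group_id`,
#'   `treatment`, `c_vtg_pre` columns) as returned by [read_vtg_input()].
#' @param simulation_days Exposure window length (days).
#' @param n_replicates Number of independent replicate simulations (>= 1).
#' @param params An [model_parameters()] object.
#' @param seed Master integer seed.
#' @param method Growth integration method, passed to [grow_batch()].
#' @return An object of class `cohort_simulation`: a list of replicates,
#'   each a named list of `fish_simulation` objects.
#' @examples
#' p <- model_parameters()
#' cohort <- simulate_cohort(list(fish_spec("f1", 0.1), fish_spec("f2", 0.05)),
#'                           simulation_days = 21, n_replicates = 2,
#'                           params = p, seed = 7)
#' nrow(spawn_events(cohort))
#' @export
simulate_cohort <- function(specs, simulation_days, n_replicates = 1L,
                            params = model_parameters(), seed = 1L,
                            method = c("closed_form", "ode")) {
  method <- match.arg(method)
  if (!is.numeric(n_replicates) || n_replicates < 1) {
    stop("`n_replicates` must be >= 1", call. = FALSE)
  }
  specs <- as_fish_specs(specs, params)
  n_replicates <- as.integer(n_replicates)
  reps <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    sims <- vector("list", length(specs))
    for (i in seq_along(specs)) {
      set.seed(substream_seed(seed, specs[[i]]$fish_id, r))
      sims[[i]] <- simulate_fish(specs[[i]], simulation_days, params,
                                 method = method)
    }
    names(sims) <- vapply(specs, `[[`, character(1), "fish_id")
    reps[[r]] <- sims
  }
  structure(reps, class = "cohort_simulation",
            simulation_days = simulation_days,
            startup_days = params$startup_days, seed = seed)
}

#' Combined spawn-event table of a simulation
#'
#' @param x A `fish_simulation` or `cohort_simulation`.
#' @return A data.frame with one row per spawn event: `replicate` (for
#'   cohorts), `fish_id`, `group_id`, `treatment`, `study_day`,
#'   `clutch_size`, `spawn_time`, `v_at_spawn`.
#' @export
spawn_events <- function(x) {
  if (inherits(x, "fish_simulation")) return(x$events)
  if (!inherits(x, "cohort_simulation")) {
    stop("`x` must be a fish_simulation or cohort_simulation", call. = FALSE)
  }
  out <- do.call(rbind, lapply(seq_along(x), function(r) {
    ev <- do.call(rbind, lapply(x[[r]], `[[`, "events"))
    if (is.null(ev) || nrow(ev) == 0L) return(NULL)
    cbind(replicate = r, ev)
  }))
  if (is.null(out)) {
    out <- data.frame(replicate = integer(0), fish_id = character(0),
                      group_id = character(0), treatment = character(0),
                      study_day = integer(0), clutch_size = integer(0),
                      spawn_time = numeric(0), v_at_spawn = numeric(0))
  }
  rownames(out) <- NULL
  out
}
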