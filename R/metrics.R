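#' Reproduction metrics of the 21-day assay
#'
#' The three scalar endpoints used to evaluate model predictions against the
#' standardized short-term reproduction assay, each an exact quotient of
#' counts:
#' average fecundity = (total eggs / number of females) / number of days
#' (eggs female^-1 day^-1); eggs per spawn = total eggs / number of spawns;
#' spawns per female = number of spawns / number of females.
#'
#' Eggs per spawn is mathematically undefined when no spawning occurred; it
#' is returned as `NA` (a typed sentinel, deliberately distinct from 0) and
#' only converted to 0 at presentation time with [undefined_as_zero()],
#' mirroring how undefined values are anchored at zero in plots.
#'
#' @param n_egg_total Total eggs spawned (count >= 0).
#' @param n_female Number of females that produced them (>= 1).
#' @param n_days Number of days over which eggs were collected (>= 1).
#' @param n_spawns Number of spawning events (>= 0).
#' @return A single number (`NA_real_` for undefined eggs per spawn).
#' @examples
#' average_fecundity(749, 8, 1)   # 93.625, ~94 eggs per female on one day
#' eggs_per_spawn(0, 0)           # NA: no spawns, undefined
#' spawns_per_female(7, 4)        # 1.75
#' @export
average_fecundity <- function(n_egg_total, n_female, n_days) {
  if (any(n_female < 1) || any(n_days < 1)) {
    stop("`n_female` and `n_days` must be >= 1", call. = FALSE)
  }
  if (any(n_egg_total < 0)) stop("`n_egg_total` must be >= 0", call. = FALSE)
  (n_egg_total / n_female) / n_days
}

#' @rdname average_fecundity
#' @export
eggs_per_spawn <- function(n_egg_total, n_spawns) {
  if (any(n_egg_total < 0) || any(n_spawns < 0)) {
    stop("counts must be >= 0", call. = FALSE)
  }
  ifelse(n_spawns > 0, n_egg_total / n_spawns, NA_real_)
}

#' @rdname average_fecundity
#' @export
spawns_per_female <- function(n_spawns, n_female) {
  if (any(n_female < 1)) stop("`n_female` must be >= 1", call. = FALSE)
  if (any(n_spawns < 0)) stop("`n_spawns` must be >= 0", call. = FALSE)
  n_spawns / n_female
}

#' Render undefined metric values as zero for presentation
#'
#' @param x Numeric vector possibly containing `NA` sentinels.
#' @return `x` with `NA` replaced by 0.
#' @export
undefined_as_zero <- function(x) {
  x[is.na(x)] <- 0
  x
}

#' Cumulative fecundity series
#'
#' Running total of eggs collected across all groups through each day of
#' `day_range`: on day `d` the value is the sum of every clutch with
#' `study_day <= d`. Optionally divided by the number of females to give the
#' cumulative number of eggs spawned per female.
#'
#' @param events Spawn-event data.frame with `study_day` and `clutch_size`
#'   columns (e.g. from [spawn_events()]), already restricted to one
#'   treatment/replicate as desired.
#' @param day_range Integer vector of days to report (default `0:20`, the
#'   21-day exposure window).
#' @param per_female If not `NULL`, divide the series by this female count.
#' @return A data.frame with columns `day` and `cumulative_eggs`.
#' @examples
#' ev <- data.frame(study_day = 3L, clutch_size = 50L)
#' cumulative_fecundity(ev, day_range = 1:5)
#' @export
cumulative_fecundity <- function(events, day_range = 0:20, per_female = NULL) {
  stopifnot(all(c("study_day", "clutch_size") %in% names(events)))
  ev <- events[events$study_day >= min(day_range) &
                 events$study_day <= max(day_range), , drop = FALSE]
  daily <- vapply(day_range, function(d) {
    sum(ev$clutch_size[ev$study_day == d])
  }, numeric(1))
  cum <- cumsum(daily)
  if (!is.null(per_female)) {
    stopifnot(per_female >= 1)
    cum <- cum / per_female
  }
  data.frame(day = day_range, cumulative_eggs = cum)
}

#' Bin same-day spawns within groups
#'
#' In a group spawning design (typically four females per tank) the eggs
#' collected on one day cannot be attributed to individual females, so all
#' model-predicted eggs spawned by a group's females on the same study day
#' are counted as one spawn whose clutch is the sum of the members' eggs.
#' Total eggs are conserved; only the spawn count (and hence eggs per spawn
#' and spawns per female) changes.
#'
#' @param events Spawn-event data.frame with `fish_id`, `study_day`,
#'   `clutch_size` columns; a `replicate` column, if present, is respected
#'   (binning never crosses replicates).
#' @param fish_groups Named character vector mapping every `fish_id` to its
#'   group label; if `NULL`, the events' own `group_id` column is used.
#' @return A data.frame of binned events with columns `replicate` (if
#'   present in the input), `group_id`, `study_day`, `clutch_size`,
#'   `n_contributing` (number of raw events merged).
#' @export
bin_group_spawns <- function(events, fish_groups = NULL) {
  stopifnot(all(c("fish_id", "study_day", "clutch_size") %in% names(events)))
  if (is.null(fish_groups)) {
    if (!"group_id" %in% names(events)) {
      stop("events lack `group_id`; supply `fish_groups`", call. = FALSE)
    }
    grp <- events$group_id
  } else {
    unmapped <- setdiff(unique(events$fish_id), names(fish_groups))
    if (length(unmapped) > 0L) {
      stop("fish not mapped to a group: ", paste(unmapped, collapse = ", "),
           call. = FALSE)
    }
    grp <- unname(fish_groups[events$fish_id])
  }
  has_rep <- "replicate" %in% names(events)
  key <- if (has_rep) {
    interaction(events$replicate, grp, events$study_day, drop = TRUE)
  } else {
    interaction(grp, events$study_day, drop = TRUE)
  }
  if (nrow(events) == 0L) {
    out <- data.frame(group_id = character(0), study_day = integer(0),
                      clutch_size = integer(0), n_contributing = integer(0))
    if (has_rep) out <- cbind(replicate = integer(0), out)
    return(out)
  }
  agg <- lapply(split(seq_len(nrow(events)), key), function(ix) {
    data.frame(
      replicate = if (has_rep) events$replicate[ix[1]] else NA_integer_,
      group_id = grp[ix[1]],
      study_day = events$study_day[ix[1]],
      clutch_size = sum(events$clutch_size[ix]),
      n_contributing = length(ix),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, agg)
  if (!has_rep) out$replicate <- NULL
  ord <- if (has_rep) order(out$replicate, out$group_id, out$study_day)
         else order(out$group_id, out$study_day)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Reproduction metrics for one set of spawn events
#'
#' Convenience wrapper computing all four metrics for an event table over a
#' given window.
#'
#' @param events Spawn-event data.frame (`study_day`, `clutch_size`).
#' @param n_female Number of females behind the events.
#' @param n_days Number of days in the window.
#' @param day_range Days for the cumulative series (default
#'   `0:(n_days - 1)`).
#' @return A list of class `reproduction_metrics` with `average_fecundity`,
#'   `eggs_per_spawn`, `spawns_per_female`, `n_egg_total`, `n_spawns` and the
#'   `cumulative_fecundity` data.frame.
#' @export
reproduction_metrics <- function(events, n_female, n_days,
                                 day_range = seq_len(n_days) - 1L) {
  ev <- events[events$study_day >= min(day_range) &
                 events$study_day <= max(day_range), , drop = FALSE]
  n_egg_total <- sum(ev$clutch_size)
  n_spawns <- nrow(ev)
  structure(
    list(average_fecundity = average_fecundity(n_egg_total, n_female, n_days),
         eggs_per_spawn = eggs_per_spawn(n_egg_total, n_spawns),
         spawns_per_female = spawns_per_female(n_spawns, n_female),
         n_egg_total = n_egg_total, n_spawns = n_spawns,
         n_female = n_female, n_days = n_days,
         cumulative_fecundity = cumulative_fecundity(ev, day_range)),
    class = "reproduction_metrics"
  )
}

#' @export
print.reproduction_metrics <- function(x, ...) {
  cat(sprintf(
    "Reproduction metrics (%d females, %d days): %d eggs in %d spawns\n",
    x$n_female, x$n_days, x$n_egg_total, x$n_spawns))
  cat(sprintf("  average fecundity: %.3g eggs/female/day\n", x$average_fecundity))
  cat(sprintf("  eggs per spawn:    %s\n",
              if (is.na(x$eggs_per_spawn)) "undefined (no spawns)"
              else sprintf("%.3g", x$eggs_per_spawn)))
  cat(sprintf("  spawns per female: %.3g\n", x$spawns_per_female))
  invisible(x)
}

#' Two-sample Kolmogorov-Smirnov comparison
#'
#' The nonparametric comparison used throughout the model evaluation: the
#' statistic is the supremum distance between the two empirical CDFs and the
#' p-value comes from the asymptotic Kolmogorov distribution
#' (via [stats::ks.test]).
#'
#' @param sample_a,sample_b Non-empty numeric vectors.
#' @return A list with `statistic` (D) and `p_value`.
#' @export
ks_two_sample <- function(sample_a, sample_b) {
  if (length(sample_a) == 0L || length(sample_b) == 0L) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  res <- suppressWarnings(stats::ks.test(sample_a, sample_b, exact = FALSE))
  list(statistic = unname(res$statistic), p_value = unname(res$p.value))
}

#' Tidy metrics table for a replicated cohort simulation
#'
#' Computes the scalar reproduction metrics per (replicate, treatment,
#' group), optionally after same-day spawn binning (the group-design
#' convention), yielding the distribution of each metric across replicates
#' in a long-friendly wide table.
#'
#' @param cohort A `cohort_simulation`.
#' @param design `"group"` (bin same-day spawns within groups) or
#'   `"paired"` (one female per group; binning would be a no-op and is
#'   skipped).
#' @param n_days Window length in days; defaults to the cohort's
#'   `simulation_days`.
#' @return A data.frame with one row per (replicate, treatment, group) and
#'   columns `n_female`, `n_egg_total`, `n_spawns`, `average_fecundity`,
#'   `eggs_per_spawn`, `spawns_per_female`.
#' @export
cohort_metrics <- function(cohort, design = c("group", "paired"),
                           n_days = attr(cohort, "simulation_days")) {
  design <- match.arg(design)
  stopifnot(inherits(cohort, "cohort_simulation"))
  # group sizes come from the cohort composition, not from who spawned
  specs <- lapply(cohort[[1]], `[[`, "spec")
  fish_group <- vapply(specs, `[[`, character(1), "group_id")
  fish_treat <- vapply(specs, `[[`, character(1), "treatment")
  groups <- unique(data.frame(group_id = fish_group, treatment = fish_treat,
                              stringsAsFactors = FALSE))
  group_sizes <- table(fish_group)

  ev <- spawn_events(cohort)
  ev <- ev[ev$study_day >= 0 & ev$study_day < n_days, , drop = FALSE]
  if (design == "group") {
    binned <- bin_group_spawns(ev)
  } else {
    binned <- ev
    binned$group_id <- ev$group_id
  }
  out <- do.call(rbind, lapply(seq_along(cohort), function(r) {
    do.call(rbind, lapply(seq_len(nrow(groups)), function(gi) {
      g <- groups$group_id[gi]
      nf <- as.integer(group_sizes[[g]])
      sel <- binned$replicate == r & binned$group_id == g
      n_egg <- sum(binned$clutch_size[sel])
      n_sp <- sum(sel)
      data.frame(
        replicate = r, treatment = groups$treatment[gi], group_id = g,
        n_female = nf, n_egg_total = n_egg, n_spawns = n_sp,
        average_fecundity = average_fecundity(n_egg, nf, n_days),
        eggs_per_spawn = eggs_per_spawn(n_egg, n_sp),
        spawns_per_female = spawns_per_female(n_sp, nf),
        stringsAsFactors = FALSE
      )
    }))
  }))
  rownames(out) <- NULL
  out
}
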