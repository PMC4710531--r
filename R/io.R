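#' Read a plasma VTG input table
#'
#' Accepts either (i) a bare one-column file of concentrations, one per line
#' (fish ids `fish_01`, `fish_02`, ... are generated, all assigned to one
#' group), or (ii) a delimited file (comma or tab) with a header naming at
#' least `c_vtg_exposure` (or `c_vtg`) and optionally `fish_id`, `group_id`,
#' `treatment`, `c_vtg_pre`.
#'
#' @param path Path to the input file.
#' @return A data.frame (VTG input table) with columns `fish_id`,
#'   `group_id`, `treatment`, `c_vtg_exposure` and, when present in the
#'   file, `c_vtg_pre`.
#' @export
read_vtg_input <- function(path) {
  if (!file.exists(path)) stop("VTG input file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("VTG input file is empty: ", path, call. = FALSE)

  delim <- if (grepl("\t", lines[1])) "\t" else if (grepl(",", lines[1])) "," else NULL
  first_fields <- if (is.null(delim)) trimws(lines[1]) else
    trimws(strsplit(lines[1], delim, fixed = TRUE)[[1]])
  has_header <- any(is.na(suppressWarnings(as.numeric(first_fields))))

  if (!has_header && is.null(delim)) {
    vals <- suppressWarnings(as.numeric(trimws(lines)))
    bad <- which(is.na(vals))
    if (length(bad) > 0L) {
      stop("non-numeric VTG concentration at row ", bad[1], " of ", path,
           call. = FALSE)
    }
    tab <- data.frame(
      fish_id = sprintf("fish_%02d", seq_along(vals)),
      group_id = "g1", treatment = "unspecified",
      c_vtg_exposure = vals, stringsAsFactors = FALSE
    )
  } else {
    tab <- utils::read.table(text = lines, header = has_header,
                             sep = if (is.null(delim)) "" else delim,
                             stringsAsFactors = FALSE, strip.white = TRUE)
    if (!has_header) {
      stop("delimited VTG input must have a header row naming its columns",
           call. = FALSE)
    }
    if ("c_vtg" %in% names(tab) && !"c_vtg_exposure" %in% names(tab)) {
      names(tab)[names(tab) == "c_vtg"] <- "c_vtg_exposure"
    }
    if (!"c_vtg_exposure" %in% names(tab)) {
      stop("VTG input needs a `c_vtg_exposure` (or `c_vtg`) column", call. = FALSE)
    }
    if (!"fish_id" %in% names(tab)) {
      tab$fish_id <- sprintf("fish_%02d", seq_len(nrow(tab)))
    }
    tab$fish_id <- as.character(tab$fish_id)
    if (!"group_id" %in% names(tab)) tab$group_id <- "g1"
    if (!"treatment" %in% names(tab)) tab$treatment <- "unspecified"
    tab$group_id <- as.character(tab$group_id)
    tab$treatment <- as.character(tab$treatment)
  }

  cvals <- suppressWarnings(as.numeric(tab$c_vtg_exposure))
  bad <- which(is.na(cvals) | cvals < 0)
  if (length(bad) > 0L) {
    stop("invalid VTG concentration (non-numeric or negative) at data row ",
         bad[1], " of ", path, call. = FALSE)
  }
  tab$c_vtg_exposure <- cvals
  if ("c_vtg_pre" %in% names(tab)) {
    pre <- suppressWarnings(as.numeric(tab$c_vtg_pre))
    if (any(!is.na(tab$c_vtg_pre) & (is.na(pre) | pre < 0))) {
      stop("invalid `c_vtg_pre` value in ", path, call. = FALSE)
    }
    tab$c_vtg_pre <- pre
  }
  if (nrow(tab) > 1000L) {
    warning("more than 1000 fish in one run; the original tool caps at 1000",
            call. = FALSE)
  }
  keep <- intersect(c("fish_id", "group_id", "treatment", "c_vtg_exposure",
                      "c_vtg_pre"), names(tab))
  tab[, keep, drop = FALSE]
}

#' Write a VTG input table
#'
#' Writes a table in the delimited-with-header dialect that
#' [read_vtg_input()] accepts, so generated cohorts round-trip through the
#' same entry point as measured data.
#'
#' @param table A VTG input data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vtg_input <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write the per-fish results summary file
#'
#' One CSV per fish: a commented header block carrying the input plasma VTG
#' concentrations, then one row per recruited batch (including batches that
#' never spawned) with its recruitment day, size, spawn day (or `UNSPAWNED`)
#' and the sampled interval since the previous recruitment.
#'
#' @param result A `fish_simulation`.
#' @param path_stem Directory or path prefix; the file is named
#'   `results_summary_<fish_id>.csv` under/after it.
#' @return The written path, invisibly.
#' @export
write_results_summary <- function(result, path_stem) {
  stopifnot(inherits(result, "fish_simulation"))
  path <- if (dir.exists(path_stem)) {
    file.path(path_stem, sprintf("results_summary_%s.csv", result$fish_id))
  } else {
    paste0(path_stem, sprintf("results_summary_%s.csv", result$fish_id))
  }
  spec <- result$spec
  c_pre <- if (is.null(spec$c_vtg_pre)) NA_real_ else spec$c_vtg_pre
  hdr <- c(
    sprintf("# fish_id: %s", result$fish_id),
    sprintf("# c_vtg_exposure: %.10g", spec$c_vtg_exposure),
    sprintf("# c_vtg_pre: %s", ifelse(is.na(c_pre), "default", sprintf("%.10g", c_pre))),
    sprintf("# simulation_days: %g", result$simulation_days),
    sprintf("# startup_days: %g", result$startup_days)
  )
  b <- result$batches
  rows <- data.frame(
    batch_id = b$batch_id,
    recruit_day = b$recruit_day,
    batch_size = b$n_oogonia,
    spawn_day = ifelse(b$status == "spawned", as.character(b$spawn_day), "UNSPAWNED"),
    interval_since_prev = ifelse(is.na(b$interval_since_prev), "NA",
                                 sprintf("%.6f", b$interval_since_prev)),
    stringsAsFactors = FALSE
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines(paste(names(rows), collapse = ","), con)
  if (nrow(rows) > 0L) {
    writeLines(do.call(paste, c(rows, sep = ",")), con)
  }
  invisible(path)
}

#' Read back a results summary file
#'
#' @param path Path written by [write_results_summary()].
#' @return A list with `fish_id`, `c_vtg_exposure`, `simulation_days`,
#'   `startup_days` and a `batches` data.frame (`batch_id`, `recruit_day`,
#'   `batch_size`, `spawn_day` with `NA` for unspawned,
#'   `interval_since_prev`).
#' @export
read_results_summary <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- lines[startsWith(lines, "#")]
  get <- function(key) sub(sprintf("^# %s: ", key), "",
                           hdr[startsWith(hdr, sprintf("# %s:", key))])
  body <- lines[!startsWith(lines, "#")]
  tab <- utils::read.csv(text = paste(body, collapse = "\n"),
                         stringsAsFactors = FALSE,
                         colClasses = c(spawn_day = "character"))
  tab$spawn_day <- suppressWarnings(as.integer(tab$spawn_day))  # UNSPAWNED -> NA
  list(
    fish_id = get("fish_id"),
    c_vtg_exposure = as.numeric(get("c_vtg_exposure")),
    simulation_days = as.numeric(get("simulation_days")),
    startup_days = as.numeric(get("startup_days")),
    batches = tab
  )
}

#' Write the clutch-size matrix file
#'
#' Tab-delimited matrix of eggs spawned per (day, fish): rows are study days
#' from `-startup_days` to `simulation_days - 1` (negative = pre-exposure),
#' columns are fish, cells are the eggs spawned by that fish on that day
#' (0 if none).
#'
#' @param results List of `fish_simulation` objects sharing one day range.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_clutch_size_summary <- function(results, path) {
  stopifnot(length(results) >= 1L,
            all(vapply(results, inherits, logical(1), "fish_simulation")))
  days_vec <- vapply(results, `[[`, numeric(1), "simulation_days")
  start_vec <- vapply(results, `[[`, numeric(1), "startup_days")
  if (length(unique(days_vec)) != 1L || length(unique(start_vec)) != 1L) {
    stop("all results must share the same day range", call. = FALSE)
  }
  days <- seq.int(-start_vec[1], days_vec[1] - 1)
  mat <- sapply(results, function(res) {
    out <- integer(length(days))
    ev <- res$events
    if (nrow(ev) > 0L) {
      idx <- match(ev$study_day, days)
      for (j in seq_len(nrow(ev))) out[idx[j]] <- out[idx[j]] + ev$clutch_size[j]
    }
    out
  })
  mat <- matrix(mat, nrow = length(days),
                dimnames = list(NULL, vapply(results, `[[`, character(1), "fish_id")))
  df <- cbind(data.frame(day = days), as.data.frame(mat, check.names = FALSE))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read back a clutch-size matrix file
#'
#' @param path Path written by [write_clutch_size_summary()].
#' @return A data.frame with a `day` column followed by one column per fish.
#' @export
read_clutch_size_summary <- function(path) {
  utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}

#' Write the spawning totals file
#'
#' Tab-delimited, one row per fish: total spawns and eggs over the entire
#' simulated period (start-up plus exposure) and over the exposure window
#' alone.
#'
#' @param results List of `fish_simulation` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spawning_summary <- function(results, path) {
  stopifnot(all(vapply(results, inherits, logical(1), "fish_simulation")))
  df <- do.call(rbind, lapply(results, function(res) {
    data.frame(
      fish_id = res$fish_id,
      spawns_full = res$totals$full$spawns,
      eggs_full = res$totals$full$eggs,
      spawns_exposure = res$totals$exposure$spawns,
      eggs_exposure = res$totals$exposure$eggs,
      stringsAsFactors = FALSE
    )
  }))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read back a spawning totals file
#'
#' @param path Path written by [write_spawning_summary()].
#' @return A data.frame with columns `fish_id`, `spawns_full`, `eggs_full`,
#'   `spawns_exposure`, `eggs_exposure`.
#' @export
read_spawning_summary <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(fish_id = "character"))
}

#' Write all three output files for one replicate
#'
#' @param results Named list of `fish_simulation` objects (one replicate).
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_replicate_outputs <- function(results, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (res in results) write_results_summary(res, dir)
  write_clutch_size_summary(results, file.path(dir, "clutch_size_summary.txt"))
  write_spawning_summary(results, file.path(dir, "spawning_summary.txt"))
  invisible(dir)
}
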