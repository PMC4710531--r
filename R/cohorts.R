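#' Specification of a synthetic VTG cohort
#'
#' Describes a study-like cohort for which plasma VTG concentrations are
#' generated rather than measured: a set of treatments, each with
#' `n_groups` replicate tanks of `females_per_group` females. Control
#' concentrations are drawn from a lognormal tuned to measured control fish
#' (roughly 0.02-0.21 nmol uL^-1, mean near 0.086); each treatment applies a
#' multiplicative depression factor in [0, 1] to that distribution,
#' emulating how steroid-synthesis inhibitors suppress VTG production.
#'
#' @param n_groups Replicate tanks per treatment (default 3).
#' @param females_per_group Females per tank (default 4).
#' @param treatments Named numeric vector of depression factors in `[0, 1]`,
#'   one per treatment (default `c(control = 1)`).
#' @param control_meanlog,control_sdlog Log-scale parameters of the control
#'   VTG generator; defaults are the lognormal MLE fitted to the packaged
#'   ketoconazole-study control column.
#' @return A list of class `cohort_spec`.
#' @examples
#' sp <- cohort_spec(treatments = c(control = 1, low = 0.5, high = 0.1))
#' set.seed(1)
#' head(generate_cohort(sp))
#' @export
cohort_spec <- function(n_groups = 3L, females_per_group = 4L,
                        treatments = c(control = 1),
                        control_meanlog = NULL, control_sdlog = NULL) {
  if (n_groups < 1 || females_per_group < 1) {
    stop("`n_groups` and `females_per_group` must be >= 1", call. = FALSE)
  }
  if (is.null(names(treatments)) || any(!nzchar(names(treatments)))) {
    stop("`treatments` must be a named vector of depression factors", call. = FALSE)
  }
  if (any(treatments < 0 | treatments > 1)) {
    stop("depression factors must lie in [0, 1]", call. = FALSE)
  }
  if (is.null(control_meanlog) || is.null(control_sdlog)) {
    fit <- control_vtg_generator()
    if (is.null(control_meanlog)) control_meanlog <- fit$meanlog
    if (is.null(control_sdlog)) control_sdlog <- fit$sdlog
  }
  stopifnot(control_sdlog > 0)
  structure(
    list(n_groups = as.integer(n_groups),
         females_per_group = as.integer(females_per_group),
         treatments = treatments,
         control_meanlog = control_meanlog, control_sdlog = control_sdlog),
    class = "cohort_spec"
  )
}

#' Control plasma VTG generator parameters
#'
#' Lognormal maximum-likelihood fit to the packaged control-column VTG
#' measurements (ketoconazole study), used as the default generator for
#' synthetic control fish.
#'
#' @return A list with `meanlog` and `sdlog`.
#' @export
control_vtg_generator <- function() {
  tab <- load_fixture("ketoconazole_table2")
  x <- tab$c_vtg_exposure[tab$treatment == "0"]
  lx <- log(x)
  list(meanlog = mean(lx), sdlog = sqrt(mean((lx - mean(lx))^2)))
}

#' Generate a synthetic VTG input table
#'
#' Draws per-fish plasma VTG concentrations for every treatment/group in
#' the spec from the depressed control lognormal. Uses the current R random
#' number stream.
#'
#' @param spec A [cohort_spec()].
#' @return A VTG input data.frame (`fish_id`, `group_id`, `treatment`,
#'   `c_vtg_exposure`) compatible with [simulate_cohort()] and
#'   [write_vtg_input()].
#' @export
generate_cohort <- function(spec) {
  if (!inherits(spec, "cohort_spec")) {
    stop("`spec` must be a cohort_spec", call. = FALSE)
  }
  rows <- list()
  for (tr in names(spec$treatments)) {
    f <- spec$treatments[[tr]]
    for (g in seq_len(spec$n_groups)) {
      c_vtg <- f * stats::rlnorm(spec$females_per_group,
                                 spec$control_meanlog, spec$control_sdlog)
      rows[[length(rows) + 1L]] <- data.frame(
        fish_id = sprintf("%s_g%df%d", tr, g, seq_len(spec$females_per_group)),
        group_id = sprintf("%s_g%d", tr, g),
        treatment = tr,
        c_vtg_exposure = c_vtg,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Load a packaged data fixture
#'
#' `"ketoconazole_table2"` is the table of plasma VTG concentrations
#' (nmol uL^-1) measured in fathead minnows after 21 days of ketoconazole
#' exposure at 0 (control), 6, 25, 100 and 400 ug L^-1, four replicate
#' tanks per treatment; a few fish have no measurement and are absent.
#'
#' @param name Fixture name.
#' @return A VTG input data.frame with columns `fish_id`, `group_id`,
#'   `treatment` (exposure concentration as character), `replicate`, `fish`
#'   and `c_vtg_exposure`.
#' @examples
#' tab <- load_fixture("ketoconazole_table2")
#' round(tapply(tab$c_vtg_exposure, tab$treatment, mean), 3)
#' @export
load_fixture <- function(name) {
  if (!identical(name, "ketoconazole_table2")) {
    stop("unknown fixture: ", name, " (available: ketoconazole_table2)",
         call. = FALSE)
  }
  path <- system.file("extdata", "ketoconazole_table2.csv",
                      package = "oocytedyn", mustWork = TRUE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  data.frame(
    fish_id = sprintf("ktc%d_r%df%d", raw$treatment_ug_L, raw$replicate, raw$fish),
    group_id = sprintf("ktc%d_rep%d", raw$treatment_ug_L, raw$replicate),
    treatment = as.character(raw$treatment_ug_L),
    replicate = raw$replicate, fish = raw$fish,
    c_vtg_exposure = raw$c_vtg,
    stringsAsFactors = FALSE
  )
}

#' Maximum-likelihood fit of a truncated lognormal
#'
#' Test-support estimator used to check that the package's samplers carry
#' the distribution they claim: fits (mu, sigma) of a lognormal truncated to
#' `[lower, upper]` by direct likelihood maximisation. With bounds far wider
#' than the data the estimates coincide with the untruncated lognormal MLE.
#'
#' @param samples Positive numeric vector, length >= 30, all within bounds.
#' @param lower,upper Truncation bounds (0 < lower < upper).
#' @return A list with `mu`, `sigma` and the optimizer `convergence` code.
#' @export
fit_truncated_lognormal <- function(samples, lower, upper) {
  if (length(samples) < 30L) {
    stop("need at least 30 samples to fit", call. = FALSE)
  }
  if (any(samples < lower | samples > upper)) {
    stop("samples outside the truncation bounds", call. = FALSE)
  }
  lx <- log(samples)
  if (stats::sd(lx) < 1e-12) {
    stop("degenerate sample (all values equal); sigma is not estimable",
         call. = FALSE)
  }
  nll <- function(par) {
    mu <- par[1]
    sigma <- exp(par[2])
    z <- stats::plnorm(upper, mu, sigma) - stats::plnorm(lower, mu, sigma)
    if (z <= 0) return(1e10)
    -sum(stats::dlnorm(samples, mu, sigma, log = TRUE)) + length(samples) * log(z)
  }
  fit <- stats::optim(c(mean(lx), log(stats::sd(lx))), nll,
                      method = "Nelder-Mead",
                      control = list(reltol = 1e-12, maxit = 2000))
  list(mu = fit$par[1], sigma = exp(fit$par[2]), convergence = fit$convergence)
}
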