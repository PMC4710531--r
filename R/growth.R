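#' Piecewise-constant plasma VTG protocol
#'
#' The simulator drives oocyte growth with a plasma VTG concentration that is
#' constant within segments: in the standard two-segment protocol the
#' pre-exposure baseline applies over the start-up window and the measured
#' end-of-study concentration from exposure start onward (the assay measures
#' VTG once, at day 21, and the model holds it constant over the exposure).
#'
#' @param start_times Numeric vector of segment start times (days), strictly
#'   increasing. Each segment runs until the next start time (the last one is
#'   open-ended).
#' @param c_vtg Plasma VTG concentration per segment (nmol uL^-1), >= 0.
#' @return An object of class `vtg_protocol`.
#' @examples
#' vtg_protocol(c(-81, 0), c(0.1, 0.05))
#' @export
vtg_protocol <- function(start_times, c_vtg) {
  stopifnot(is.numeric(start_times), is.numeric(c_vtg),
            length(start_times) == length(c_vtg), length(c_vtg) >= 1L)
  if (any(!is.finite(start_times)) || any(!is.finite(c_vtg))) {
    stop("protocol times and concentrations must be finite", call. = FALSE)
  }
  if (any(diff(start_times) <= 0)) {
    stop("segment start times must be strictly increasing", call. = FALSE)
  }
  if (any(c_vtg < 0)) stop("c_vtg must be >= 0 in every segment", call. = FALSE)
  structure(list(start_times = as.numeric(start_times),
                 c_vtg = as.numeric(c_vtg)),
            class = "vtg_protocol")
}

# Concentration in force at time t (right-continuous step function).
protocol_c_at <- function(protocol, t) {
  idx <- findInterval(t, protocol$start_times)
  if (any(idx == 0L)) {
    stop("protocol does not cover time ", min(t), call. = FALSE)
  }
  protocol$c_vtg[idx]
}

#' Oocyte volume from absorbed VTG mass
#'
#' Volume is affine in absorbed VTG mass:
#' `V = w_vtg * r_vtg * M + v_oog`, where `w_vtg` converts nmol of VTG to mg
#' and `r_vtg` converts mg absorbed to uL of oocyte volume (oocytes take up
#' water and other nutrients along with VTG).
#'
#' @param m_vtg Absorbed VTG mass (nmol), >= 0.
#' @param params An [model_parameters()] object.
#' @return Oocyte volume (uL).
#' @export
oocyte_volume <- function(m_vtg, params) {
  stopifnot(inherits(params, "oocyte_params"))
  if (any(m_vtg < 0)) stop("m_vtg must be >= 0", call. = FALSE)
  params$w_vtg * params$r_vtg * m_vtg + params$v_oog
}

# Inverse of oocyte_volume.
mass_from_volume <- function(v_ooc, params) {
  (v_ooc - params$v_oog) / (params$w_vtg * params$r_vtg)
}

#' Time for an oocyte to reach the spawning threshold under constant VTG
#'
#' Under a constant plasma concentration `C` the volume grows exponentially,
#' `V(t) = v_oog * exp(w_vtg * r_vtg * rho * C * t)`, so the first time the
#' threshold is hit is
#' `t* = log(v_threshold / v_oog) / (w_vtg * r_vtg * rho * C)`.
#' `t*` is inversely proportional to `C` and to the rate product.
#'
#' @param c_vtg Plasma VTG concentration (nmol uL^-1), >= 0. Zero gives
#'   `Inf` (the oocyte never matures).
#' @param params An [model_parameters()] object.
#' @return Maturation time in days (possibly `Inf`).
#' @export
maturation_time <- function(c_vtg, params) {
  stopifnot(inherits(params, "oocyte_params"))
  if (any(c_vtg < 0)) stop("c_vtg must be >= 0", call. = FALSE)
  k <- params$w_vtg * params$r_vtg * params$rho_per_day * c_vtg
  ifelse(k > 0, log(params$v_threshold / params$v_oog) / k, Inf)
}

#' Calibrate the absorption-rate / volume-ratio product
#'
#' The growth dynamics depend on `rho_vtg_ooc` and `r_vtg` only through
#' their product, so spawning data identify the product alone. This returns
#' the unique product (per day, per nmol uL^-1) for which
#' [maturation_time()] at a reference concentration equals a target duration:
#' `product = log(v_threshold / v_oog) / (w_vtg * c_ref * target)`.
#'
#' The shipped default pins maturation at the baseline concentration
#' (0.1 nmol uL^-1) to the mean recruitment interval, so that at steady
#' state a control female's spawn throughput equals the fitted
#' clutch-size / interval throughput.
#'
#' @param target_maturation_days Desired maturation time (days), > 0.
#' @param c_ref Reference plasma VTG concentration (nmol uL^-1), > 0.
#' @param params An `oocyte_params` object (only `v_oog`, `v_threshold`,
#'   `w_vtg` are used).
#' @return The product `rho_per_day * r_vtg` (uL mg^-1 d^-1).
#' @export
calibrate_rates <- function(target_maturation_days, c_ref, params) {
  if (!is.numeric(target_maturation_days) || target_maturation_days <= 0 ||
      !is.numeric(c_ref) || c_ref <= 0) {
    stop("`target_maturation_days` and `c_ref` must be > 0", call. = FALSE)
  }
  log(params$v_threshold / params$v_oog) /
    (params$w_vtg * c_ref * target_maturation_days)
}

#' Create a newly recruited oocyte batch
#'
#' @param recruit_time Simulation-clock recruitment time (days; negative
#'   during the start-up window).
#' @param n_oogonia Number of oogonia in the batch (>= 1).
#' @param params An [model_parameters()] object.
#' @return A list of class `oocyte_batch` with fields `recruit_time`,
#'   `n_oogonia`, `m_vtg`, `v_ooc`, `t` (time of current state), `status`
#'   (one of `"growing"`, `"spawned"`, `"unspawned_at_end"`) and
#'   `spawn_time` (`NA` unless spawned).
#' @export
new_batch <- function(recruit_time, n_oogonia, params) {
  stopifnot(inherits(params, "oocyte_params"), n_oogonia >= 1)
  structure(
    list(recruit_time = as.numeric(recruit_time),
         n_oogonia = as.integer(n_oogonia),
         m_vtg = 0, v_ooc = params$v_oog, t = as.numeric(recruit_time),
         status = "growing", spawn_time = NA_real_),
    class = "oocyte_batch"
  )
}

#' Grow an oocyte batch under a piecewise-constant VTG protocol
#'
#' Advances the batch state from its current time to `t_end`, or to the
#' moment its volume first reaches the spawning threshold, whichever comes
#' first. Within each constant-concentration segment the linear ODE has the
#' exact solution `V(t) = V(t0) * exp(k C (t - t0))` with
#' `k = w_vtg * r_vtg * rho_per_day`; the threshold crossing is solved with a
#' logarithm, not a root finder. A crossing exactly at `t_end` counts as a
#' spawn. With `method = "ode"` the same trajectory is integrated numerically
#' ([deSolve::lsodar] with root-triggered stopping at the threshold), which
#' exists for fidelity checks against the closed form.
#'
#' @param batch An [new_batch()] object with status `"growing"`.
#' @param protocol A [vtg_protocol()] covering `[batch$t, t_end]`.
#' @param t_end End of the growth window (days), >= current batch time.
#' @param params An [model_parameters()] object.
#' @param method `"closed_form"` (default) or `"ode"`.
#' @param final If `TRUE`, a batch still growing at `t_end` is marked
#'   `"unspawned_at_end"`.
#' @return The updated `oocyte_batch`.
#' @export
grow_batch <- function(batch, protocol, t_end, params,
                       method = c("closed_form", "ode"), final = TRUE) {
  stopifnot(inherits(batch, "oocyte_batch"), inherits(protocol, "vtg_protocol"),
            inherits(params, "oocyte_params"))
  method <- match.arg(method)
  if (batch$status != "growing") {
    stop("batch is not growing (status: ", batch$status, ")", call. = FALSE)
  }
  if (t_end < batch$t) stop("t_end precedes the batch's current time", call. = FALSE)
  if (batch$t < protocol$start_times[1L]) {
    stop("protocol does not cover the batch's growth window", call. = FALSE)
  }

  k <- params$w_vtg * params$r_vtg * params$rho_per_day
  t <- batch$t
  v <- batch$v_ooc
  # segment boundaries inside (t, t_end)
  cuts <- protocol$start_times[protocol$start_times > t & protocol$start_times < t_end]
  seg_ends <- c(cuts, t_end)

  for (s_end in seg_ends) {
    C <- protocol_c_at(protocol, t)
    if (method == "closed_form") {
      if (C > 0 && v < params$v_threshold) {
        dt_star <- log(params$v_threshold / v) / (k * C)
        if (t + dt_star <= s_end) {
          batch$spawn_time <- t + dt_star
          batch$t <- batch$spawn_time
          batch$v_ooc <- params$v_threshold
          batch$m_vtg <- mass_from_volume(params$v_threshold, params)
          batch$status <- "spawned"
          return(batch)
        }
      }
      v <- v * exp(k * C * (s_end - t))
      t <- s_end
    } else {
      sol <- .grow_ode_segment(v, t, s_end, C, params)
      v <- sol$v
      t <- sol$t
      if (sol$spawned) {
        batch$spawn_time <- t
        batch$t <- t
        batch$v_ooc <- v
        batch$m_vtg <- mass_from_volume(v, params)
        batch$status <- "spawned"
        return(batch)
      }
    }
    if (v >= params$v_threshold) {  # boundary tie at segment end
      batch$spawn_time <- t
      batch$t <- t
      batch$v_ooc <- params$v_threshold
      batch$m_vtg <- mass_from_volume(params$v_threshold, params)
      batch$status <- "spawned"
      return(batch)
    }
  }
  batch$t <- t_end
  batch$v_ooc <- v
  batch$m_vtg <- mass_from_volume(v, params)
  if (final) batch$status <- "unspawned_at_end"
  batch
}

# Numeric integration of one constant-C segment with threshold root stopping.
.grow_ode_segment <- function(v0, t0, t1, C, params) {
  if (t1 <= t0) return(list(v = v0, t = t0, spawned = v0 >= params$v_threshold))
  k <- params$w_vtg * params$r_vtg * params$rho_per_day
  deriv <- function(t, y, parms) list(k * C * y[1])
  rootf <- function(t, y, parms) y[1] - params$v_threshold
  out <- deSolve::lsodar(
    y = c(v = v0), times = c(t0, t1), func = deriv, parms = NULL,
    rootfunc = rootf, rtol = params$ode_rtol, atol = params$ode_atol
  )
  last <- out[nrow(out), ]
  list(v = unname(last["v"]), t = unname(last["time"]),
       spawned = !is.null(attr(out, "troot")) && length(attr(out, "troot")) > 0)
}

#' Per-batch mass/volume trajectory
#'
#' Evaluates the closed-form trajectory of a growing batch on a time grid,
#' for inspection or export (the optional mass/volume dump).
#'
#' @param batch A freshly recruited [new_batch()].
#' @param protocol A [vtg_protocol()].
#' @param times Increasing numeric vector of evaluation times (days), all
#'   >= the recruitment time.
#' @param params An [model_parameters()] object.
#' @return A data.frame with columns `time`, `m_vtg`, `v_ooc`.
#' @export
batch_trajectory <- function(batch, protocol, times, params) {
  stopifnot(all(diff(times) > 0), all(times >= batch$recruit_time))
  k <- params$w_vtg * params$r_vtg * params$rho_per_day
  v <- numeric(length(times))
  v_cur <- batch$v_ooc
  t_cur <- batch$t
  for (i in seq_along(times)) {
    t_next <- times[i]
    cuts <- protocol$start_times[protocol$start_times > t_cur &
                                   protocol$start_times < t_next]
    for (s_end in c(cuts, t_next)) {
      C <- protocol_c_at(protocol, t_cur)
      v_cur <- v_cur * exp(k * C * (s_end - t_cur))
      t_cur <- s_end
    }
    v[i] <- v_cur
  }
  data.frame(time = times, m_vtg = mass_from_volume(v, params), v_ooc = v)
}
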