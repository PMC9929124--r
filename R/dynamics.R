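#' Schedule for a transient community simulation
#'
#' Describes one run of the continuous-time occupancy dynamics: an initial
#' state, a fecundity profile, optionally a second profile swapped in at
#' `switch_time` (the in-model "fertilization" event), and the sampling grid.
#'
#' @param profile_before Fecundity profile governing `[0, switch_time)`.
#' @param profile_after Profile governing `[switch_time, end_time]`, or
#'   `NULL` for a run without an event (then `switch_time` is ignored).
#' @param switch_time Time of the fertilization event (default 10,000).
#' @param end_time End of the run (default 90,000).
#' @param sample_interval Spacing of recorded states (default 100 time units).
#' @param initial Initial frequency vector (length n, nonnegative, sum <= 1);
#'   default is a uniform trace occupancy of `initial_frequency` per species,
#'   from which the pre-event community assembles.
#' @param initial_frequency Per-species default initial frequency (1e-3).
#' @return An object of class `simulation_schedule`.
#' @export
simulation_schedule <- function(profile_before, profile_after = NULL,
                                switch_time = 10000, end_time = 90000,
                                sample_interval = 100,
                                initial = NULL, initial_frequency = 1e-3) {
  stopifnot(inherits(profile_before, "fecundity_profile"))
  if (!is.null(profile_after)) {
    stopifnot(inherits(profile_after, "fecundity_profile"),
              profile_after$n == profile_before$n)
    if (switch_time < 0 || switch_time > end_time)
      stop("need 0 <= switch_time <= end_time", call. = FALSE)
  }
  if (sample_interval <= 0) stop("`sample_interval` must be positive", call. = FALSE)
  if (end_time <= 0) stop("`end_time` must be positive", call. = FALSE)
  n <- profile_before$n
  if (is.null(initial)) initial <- rep(initial_frequency, n)
  if (length(initial) != n || any(initial < 0) || sum(initial) > 1)
    stop("`initial` must be length n, nonnegative, with sum <= 1", call. = FALSE)
  structure(list(profile_before = profile_before,
                 profile_after = profile_after,
                 switch_time = switch_time, end_time = end_time,
                 sample_interval = sample_interval,
                 initial = as.numeric(initial)),
            class = "simulation_schedule")
}

#' Time derivatives of site-occupancy frequencies
#'
#' The displacement-competition colonization dynamics: species i gains sites
#' it colonizes among those not already held by itself or better competitors,
#' loses sites to colonization pressure from better competitors, and loses
#' occupied sites to disturbance at rate m:
#' \deqn{\dot p_i = q f_i p_i \Big(1 - \sum_{j \le i} p_j\Big)
#'   - q \Big(\sum_{j < i} f_j p_j\Big) p_i - m p_i + \epsilon,}
#' with \eqn{\epsilon} the immigration rate from `params` (in its
#' `"open_site"` form the last term is
#' \eqn{\epsilon (1 - \sum_{j \le i} p_j)}).
#'
#' @param p Frequency vector (length n, entries >= 0).
#' @param profile A [fecundity_profile()] of matching length.
#' @param params A [community_params()].
#' @return Numeric vector of dp_i/dt.
#' @export
rate_of_change <- function(p, profile, params) {
  stopifnot(inherits(profile, "fecundity_profile"),
            inherits(params, "community_params"))
  if (length(p) != profile$n)
    stop("state length does not match profile length", call. = FALSE)
  f <- profile$values
  open_above <- 1 - cumsum(p)             # sites free of species <= i
  pressure <- cumsum(f * p) - f * p       # colonization pressure from j < i
  dp <- params$q * f * p * open_above -
    params$q * pressure * p - params$m * p
  if (params$immigration > 0) {
    dp <- dp + switch(params$immigration_form,
                      constant = params$immigration,
                      open_site = params$immigration * open_above)
  }
  dp
}

#' Integrate the occupancy dynamics
#'
#' Runs the continuous-time model over the schedule with an adaptive
#' stiff-capable integrator (`deSolve::ode`, method `lsoda`). When the
#' schedule contains a fertilization event the integration is restarted
#' exactly at `switch_time` under the post-event profile. Sampled states are
#' clipped at 0 from below (the integrator can undershoot by less than its
#' absolute tolerance).
#'
#' @param schedule A [simulation_schedule()].
#' @param params A [community_params()] (its `immigration` applies throughout).
#' @param rtol,atol Relative / absolute integrator tolerances. The defaults
#'   (1e-9, 1e-13) resolve frequencies near the 1e-10 immigration floor.
#' @param maxsteps Maximum internal steps per output interval.
#' @return An object of class `trajectory`: `times`, a samples-by-n matrix
#'   `states`, the `schedule` and `params`, and `final_max_rate`, the largest
#'   absolute derivative at the final sample (a run can be called at
#'   equilibrium when this is below ~1e-12; it is reported, never enforced).
#' @export
#' @examples
#' sched <- simulation_schedule(preset_profile("f0"), switch_time = 0,
#'                              end_time = 2000, sample_interval = 200)
#' traj <- simulate_community(sched, community_params(0.3, 0.2))
#' tail(traj$times, 1)
simulate_community <- function(schedule, params,
                               rtol = 1e-9, atol = 1e-13, maxsteps = 100000) {
  stopifnot(inherits(schedule, "simulation_schedule"),
            inherits(params, "community_params"))
  sample_times <- unique(c(seq(0, schedule$end_time,
                               by = schedule$sample_interval),
                           schedule$end_time))
  has_switch <- !is.null(schedule$profile_after) &&
    schedule$switch_time < schedule$end_time

  integrate_leg <- function(y0, times, profile) {
    rhs <- function(t, p, parms) list(rate_of_change(p, profile, params))
    out <- deSolve::ode(y = y0, times = times, func = rhs, parms = NULL,
                        method = "lsoda", rtol = rtol, atol = atol,
                        maxsteps = maxsteps)
    attr_diag <- attributes(out)$istate
    if (!is.null(attr_diag) && attr_diag[1] < 0)
      stop(sprintf("integration failed near t = %g (istate = %d)",
                   out[nrow(out), 1], attr_diag[1]), call. = FALSE)
    if (nrow(out) < length(times))
      stop(sprintf("integrator stopped early at t = %g of %g",
                   out[nrow(out), 1], times[length(times)]), call. = FALSE)
    out
  }

  if (has_switch) {
    t1 <- unique(c(sample_times[sample_times <= schedule$switch_time],
                   schedule$switch_time))
    out1 <- integrate_leg(schedule$initial, t1, schedule$profile_before)
    y_switch <- pmax(out1[nrow(out1), -1], 0)
    t2 <- unique(c(schedule$switch_time,
                   sample_times[sample_times > schedule$switch_time]))
    out2 <- integrate_leg(y_switch, t2, schedule$profile_after)
    keep1 <- out1[, 1] %in% sample_times
    keep2 <- out2[, 1] %in% sample_times & out2[, 1] > schedule$switch_time
    times <- c(out1[keep1, 1], out2[keep2, 1])
    states <- rbind(out1[keep1, -1, drop = FALSE],
                    out2[keep2, -1, drop = FALSE])
  } else {
    out <- integrate_leg(schedule$initial, sample_times, schedule$profile_before)
    times <- out[, 1]
    states <- out[, -1, drop = FALSE]
  }
  states <- pmax(states, 0)
  dimnames(states) <- list(NULL, paste0("sp", seq_len(schedule$profile_before$n)))
  final_profile <- if (has_switch) schedule$profile_after else schedule$profile_before
  final_rate <- max(abs(rate_of_change(states[nrow(states), ],
                                       final_profile, params)))
  structure(list(times = times, states = states,
                 schedule = schedule, params = params,
                 final_max_rate = final_rate),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf(
    "Trajectory: %d samples over t = [%g, %g], n = %d species, max |dp/dt| at end = %.3g\n",
    length(x$times), x$times[1], x$times[length(x$times)],
    ncol(x$states), x$final_max_rate))
  invisible(x)
}

#' Sampled state at (or just before) a time point
#'
#' @param trajectory A [simulate_community()] result.
#' @param t Query time within the recorded range.
#' @return List with `time` (the sample time actually used, the latest
#'   recorded time <= `t`) and `frequencies`.
#' @export
state_at <- function(trajectory, t) {
  stopifnot(inherits(trajectory, "trajectory"))
  if (t < trajectory$times[1] || t > trajectory$times[length(trajectory$times)])
    stop("`t` outside the recorded time range", call. = FALSE)
  idx <- max(which(trajectory$times <= t))
  list(time = trajectory$times[idx],
       frequencies = as.numeric(trajectory$states[idx, ]))
}

#' Occupied-fraction time series of a trajectory
#'
#' @param trajectory A [simulate_community()] result.
#' @return data.frame with columns `time`, `occupied`.
#' @export
occupied_series <- function(trajectory) {
  stopifnot(inherits(trajectory, "trajectory"))
  data.frame(time = trajectory$times,
             occupied = rowSums(trajectory$states))
}

#' Detectable-richness time series of a trajectory
#'
#' @param trajectory A [simulate_community()] result.
#' @param threshold Detection cutoff (default 1e-5).
#' @return data.frame with columns `time`, `richness_relative`,
#'   `richness_raw` (the cutoff applied to relative abundance and to raw site
#'   frequency respectively).
#' @export
richness_series <- function(trajectory, threshold = 1e-5) {
  stopifnot(inherits(trajectory, "trajectory"))
  rel <- apply(trajectory$states, 1, function(p)
    richness(p, threshold, convention = "relative"))
  raw <- apply(trajectory$states, 1, function(p)
    richness(p, threshold, convention = "raw"))
  data.frame(time = trajectory$times,
             richness_relative = rel, richness_raw = raw)
}
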