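#' Configuration of a fertilization scenario
#'
#' Bundles every knob of an end-to-end fertilization experiment. The defaults
#' are the study conditions of the equilibrium and transient analyses:
#' n = 80 potential species, q = 0.3, m = 0.2, fertilization at t = 10,000,
#' run to t = 90,000, immigration 1e-10 during the transient, detection
#' threshold 1e-5, and the top 8 species tracked across the event.
#'
#' @param before,after Trade-off specifications: a preset name (`"f0"`,
#'   `"f1"`, `"f2"`), a [tradeoff_params()] or a [fecundity_profile()].
#' @param n Species pool size (used when presets / params are given).
#' @param q,m Colonization and extinction rates.
#' @param immigration Immigration rate for the transient run (default 1e-10).
#' @param switch_time,end_time Fertilization time and run end.
#' @param sample_interval Trajectory sampling interval (default 100).
#' @param snapshot_interval Spacing of transient RAD snapshots after the
#'   event (default 1,000 time units).
#' @param threshold Detection cutoff (default 1e-5).
#' @param convention Abundance convention for RADs, `"relative"` or `"raw"`.
#' @param top_k Number of most abundant pre-event species to track.
#' @param initial_frequency Initial per-species occupancy (default 1e-3).
#' @param seed Optional seed recorded with the run (used only when profiles
#'   are perturbed).
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(before = "f0", after = "f1", n = 80,
                            q = 0.3, m = 0.2, immigration = 1e-10,
                            switch_time = 10000, end_time = 90000,
                            sample_interval = 100, snapshot_interval = 1000,
                            threshold = 1e-5,
                            convention = c("relative", "raw"),
                            top_k = 8, initial_frequency = 1e-3,
                            seed = NULL) {
  convention <- match.arg(convention)
  if (snapshot_interval <= 0 || sample_interval <= 0)
    stop("intervals must be positive", call. = FALSE)
  if (threshold <= 0) stop("`threshold` must be positive", call. = FALSE)
  if (top_k < 1) stop("`top_k` must be at least 1", call. = FALSE)
  cfg <- structure(list(before = before, after = after, n = n, q = q, m = m,
                        immigration = immigration, switch_time = switch_time,
                        end_time = end_time, sample_interval = sample_interval,
                        snapshot_interval = snapshot_interval,
                        threshold = threshold, convention = convention,
                        top_k = top_k, initial_frequency = initial_frequency,
                        seed = seed),
                   class = "scenario_config")
  # fail fast on bad rates / times
  community_params(q, m, immigration)
  resolve_profile(before, n)
  resolve_profile(after, n)
  if (switch_time < 0 || switch_time > end_time)
    stop("need 0 <= switch_time <= end_time", call. = FALSE)
  cfg
}

# Accept a preset token, tradeoff_params or ready profile.
resolve_profile <- function(x, n) {
  if (inherits(x, "fecundity_profile")) {
    if (x$n != n) stop("profile length does not match n", call. = FALSE)
    return(x)
  }
  if (inherits(x, "tradeoff_params")) return(fecundity_profile(x))
  if (is.character(x) && length(x) == 1L) return(preset_profile(x, n))
  stop("cannot interpret trade-off specification; supply a preset name, ",
       "tradeoff_params or fecundity_profile", call. = FALSE)
}

#' Run a full fertilization scenario
#'
#' Reproduces one fertilization experiment end to end: the pre- and
#' post-event equilibria and their RADs and labeled comparison, the transient
#' trajectory under weak immigration with the profile swap at `switch_time`,
#' RAD snapshots at regular intervals after the event, and occupied-fraction
#' and richness time series.
#'
#' @param config A [scenario_config()].
#' @param ... Passed to [simulate_community()] (integrator tolerances).
#' @return An object of class `scenario_bundle`: `config`, resolved profiles,
#'   `equilibrium_before`/`equilibrium_after`, `rad_before`/`rad_after`,
#'   `comparison`, `trajectory`, `snapshots` (named list of `rank_abundance`
#'   at `switch_time + k * snapshot_interval`), `occupied_series`,
#'   `richness_series`, and a scalar `summary` data.frame.
#' @export
#' @examples
#' cfg <- scenario_config("f0", "f1", switch_time = 500, end_time = 1000,
#'                        sample_interval = 100, snapshot_interval = 250)
#' bundle <- run_fertilization_scenario(cfg)
#' bundle$comparison
run_fertilization_scenario <- function(config, ...) {
  stopifnot(inherits(config, "scenario_config"))
  prof_b <- resolve_profile(config$before, config$n)
  prof_a <- resolve_profile(config$after, config$n)
  eq_params <- community_params(config$q, config$m, immigration = 0)
  run_params <- community_params(config$q, config$m,
                                 immigration = config$immigration)

  eq_b <- solve_equilibrium(prof_b, eq_params)
  eq_a <- solve_equilibrium(prof_a, eq_params)
  rad_b <- build_rad(eq_b$frequencies, config$threshold, config$convention)
  rad_a <- build_rad(eq_a$frequencies, config$threshold, config$convention)
  cmp <- compare_communities(eq_b$frequencies, eq_a$frequencies,
                             config$threshold, config$top_k, config$convention)

  sched <- simulation_schedule(prof_b, prof_a,
                               switch_time = config$switch_time,
                               end_time = config$end_time,
                               sample_interval = config$sample_interval,
                               initial_frequency = config$initial_frequency)
  traj <- simulate_community(sched, run_params, ...)

  snap_times <- seq(config$switch_time + config$snapshot_interval,
                    config$end_time, by = config$snapshot_interval)
  snapshots <- lapply(snap_times, function(tt)
    build_rad(state_at(traj, tt)$frequencies, config$threshold,
              config$convention))
  names(snapshots) <- sprintf("t%d", as.integer(round(snap_times)))

  occ <- occupied_series(traj)
  rich <- richness_series(traj, config$threshold)
  pre_idx <- max(which(traj$times <= config$switch_time))
  summary <- data.frame(
    richness_before = nrow(rad_b$entries),
    richness_after = nrow(rad_a$entries),
    n_new = length(cmp$new_species),
    n_lost = length(cmp$lost_species),
    n_retained = length(cmp$retained),
    occupied_before = occupied_fraction(eq_b),
    occupied_after = occupied_fraction(eq_a),
    occupied_pre_switch = occ$occupied[pre_idx],
    occupied_end = occ$occupied[nrow(occ)],
    # transient hump is a post-event phenomenon; the assembly phase from the
    # uniform trace initial state would trivially dominate the maximum
    max_transient_richness = max(
      rich$richness_relative[rich$time > config$switch_time]))

  structure(list(config = config,
                 profile_before = prof_b, profile_after = prof_a,
                 equilibrium_before = eq_b, equilibrium_after = eq_a,
                 rad_before = rad_b, rad_after = rad_a,
                 comparison = cmp, trajectory = traj,
                 snapshots = snapshots,
                 occupied_series = occ, richness_series = rich,
                 summary = summary),
            class = "scenario_bundle")
}

#' @export
print.scenario_bundle <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "Fertilization scenario: richness %d -> %d (%d new, %d lost); occupied %.4g -> %.4g\n",
    s$richness_before, s$richness_after, s$n_new, s$n_lost,
    s$occupied_before, s$occupied_after))
  invisible(x)
}

#' Equilibrium richness and biomass over a grid of trade-off parameters
#'
#' For every (alpha, beta) pair the closed-community equilibrium is solved
#' and summarized by its detectable richness (both threshold conventions)
#' and occupied fraction. Each grid cell is independent, so the surface does
#' not depend on traversal order.
#'
#' @param alpha,beta Numeric grids of trade-off parameters (all positive).
#' @param params A [community_params()] (immigration ignored).
#' @param n Species pool size (default 80).
#' @param threshold Detection cutoff (default 1e-5).
#' @return Long-format data.frame with columns `alpha`, `beta`, `richness`
#'   (relative convention), `richness_raw`, `biomass`.
#' @export
#' @examples
#' sweep_alpha_beta(3, 16, community_params(0.3, 0.2))
sweep_alpha_beta <- function(alpha, beta, params, n = 80, threshold = 1e-5) {
  stopifnot(inherits(params, "community_params"))
  if (length(alpha) == 0L || length(beta) == 0L ||
      any(alpha <= 0) || any(beta <= 0))
    stop("alpha and beta grids must be nonempty and positive", call. = FALSE)
  grid <- expand.grid(alpha = alpha, beta = beta, KEEP.OUT.ATTRS = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(k) {
    prof <- fecundity_profile(tradeoff_params(grid$alpha[k], grid$beta[k], n))
    p <- solve_equilibrium(prof, params)$frequencies
    c(richness = richness(p, threshold, "relative"),
      richness_raw = richness(p, threshold, "raw"),
      biomass = occupied_fraction(p))
  })
  cbind(grid, do.call(rbind, res))
}

#' Decompose a fertilization into its fecundity and saturation components
#'
#' Solves the equilibrium under the four combinations of the base and
#' fertilized alpha (maximum fecundity) and beta (saturation): the two pure
#' single-factor changes plus the two corners. Used to ask which component of
#' fertilization drives the reshaping of the RAD.
#'
#' @param base,fert [tradeoff_params()] for the pre- and post-fertilization
#'   trade-off (must share `n`).
#' @param params A [community_params()].
#' @param threshold Detection cutoff.
#' @param convention Abundance convention for the RADs.
#' @return List with `cells` (named list `base`, `alpha_only`, `beta_only`,
#'   `fert`, each holding the params, equilibrium and RAD) and `summary`
#'   (data.frame of richness, slope, evenness, biomass per cell).
#' @export
decomposition_experiment <- function(base, fert, params, threshold = 1e-5,
                                     convention = c("relative", "raw")) {
  stopifnot(inherits(base, "tradeoff_params"),
            inherits(fert, "tradeoff_params"),
            inherits(params, "community_params"),
            base$n == fert$n)
  convention <- match.arg(convention)
  combos <- list(
    base       = tradeoff_params(base$alpha, base$beta, base$n),
    alpha_only = tradeoff_params(fert$alpha, base$beta, base$n),
    beta_only  = tradeoff_params(base$alpha, fert$beta, base$n),
    fert       = tradeoff_params(fert$alpha, fert$beta, base$n))
  cells <- lapply(combos, function(tp) {
    eq <- solve_equilibrium(fecundity_profile(tp), params)
    rad <- build_rad(eq$frequencies, threshold, convention)
    list(params = tp, equilibrium = eq, rad = rad)
  })
  summary <- do.call(rbind, lapply(names(cells), function(nm) {
    cell <- cells[[nm]]
    sl <- rad_slope(cell$rad)
    data.frame(cell = nm, alpha = cell$params$alpha, beta = cell$params$beta,
               richness = nrow(cell$rad$entries),
               slope = sl$slope, evenness = sl$evenness,
               biomass = occupied_fraction(cell$equilibrium))
  }))
  list(cells = cells, summary = summary)
}

#' Robustness of fertilization trends to trade-off fluctuation
#'
#' Repeatedly fluctuates the before/after trade-off pair by independent
#' multiplicative noise (see [perturb_profile_pair()]), solves both
#' equilibria, and summarizes how often the fertilization trends (richness
#' and evenness both declining) survive a non-smooth trade-off.
#'
#' @param before,after `fecundity_profile` objects (the unfluctuated pair).
#' @param magnitude Relative fluctuation in `[0, 1)` (default 0.05).
#' @param replicates Number of replicate draws (default 50).
#' @param seed Master seed; replicate r uses `seed + r`.
#' @param params A [community_params()].
#' @param threshold Detection cutoff.
#' @param convention Abundance convention.
#' @param share_multipliers Reuse the same per-species multipliers for both
#'   profiles of a pair (default `FALSE`: independent draws).
#' @return List with `replicates` (one row per replicate: richness, slope,
#'   evenness, biomass before and after) and `summary` (medians plus
#'   `fraction_both_decline`, the share of replicates in which richness and
#'   evenness both drop after fertilization).
#' @export
fluctuation_experiment <- function(before, after, magnitude = 0.05,
                                   replicates = 50, seed = 1,
                                   params = community_params(0.3, 0.2),
                                   threshold = 1e-5,
                                   convention = c("relative", "raw"),
                                   share_multipliers = FALSE) {
  stopifnot(inherits(before, "fecundity_profile"),
            inherits(after, "fecundity_profile"))
  if (replicates < 1) stop("`replicates` must be >= 1", call. = FALSE)
  convention <- match.arg(convention)
  one <- function(prof) {
    eq <- solve_equilibrium(prof, params)
    rad <- build_rad(eq$frequencies, threshold, convention)
    sl <- if (nrow(rad$entries) >= 2) rad_slope(rad)
          else list(slope = NA_real_, evenness = NA_real_)
    c(richness = nrow(rad$entries), slope = sl$slope,
      evenness = sl$evenness, biomass = occupied_fraction(eq))
  }
  rows <- lapply(seq_len(replicates), function(r) {
    pair <- perturb_profile_pair(before, after, magnitude,
                                 seed = seed + r,
                                 share_multipliers = share_multipliers)
    b <- one(pair$before); a <- one(pair$after)
    data.frame(replicate = r,
               richness_before = b["richness"], richness_after = a["richness"],
               slope_before = b["slope"], slope_after = a["slope"],
               evenness_before = b["evenness"], evenness_after = a["evenness"],
               biomass_before = b["biomass"], biomass_after = a["biomass"],
               row.names = NULL)
  })
  reps <- do.call(rbind, rows)
  both <- reps$richness_after < reps$richness_before &
    reps$evenness_after < reps$evenness_before
  summary <- data.frame(
    magnitude = magnitude, replicates = replicates, seed = seed,
    median_richness_before = stats::median(reps$richness_before),
    median_richness_after = stats::median(reps$richness_after),
    median_evenness_before = stats::median(reps$evenness_before),
    median_evenness_after = stats::median(reps$evenness_after),
    median_biomass_before = stats::median(reps$biomass_before),
    median_biomass_after = stats::median(reps$biomass_after),
    fraction_both_decline = mean(both))
  list(replicates = reps, summary = summary)
}
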