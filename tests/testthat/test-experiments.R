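# Scenario runs in this file use shortened horizons; the full study horizon
# (switch at t = 10,000, end at t = 90,000) is exercised by the acceptance
# suite where the transient claims need it.

test_that("scenario config fills study defaults and validates", {
  cfg <- scenario_config()
  expect_equal(cfg$n, 80)
  expect_equal(cfg$q, 0.3)
  expect_equal(cfg$m, 0.2)
  expect_equal(cfg$immigration, 1e-10)
  expect_equal(cfg$switch_time, 10000)
  expect_equal(cfg$end_time, 90000)
  expect_equal(cfg$snapshot_interval, 1000)
  expect_equal(cfg$threshold, 1e-5)
  expect_equal(cfg$top_k, 8)
  expect_error(scenario_config(q = 0), "q")
  expect_error(scenario_config(switch_time = 10, end_time = 5), "switch_time")
  expect_error(scenario_config(before = "f9"), "arg")
})

test_that("a fertilization scenario bundles equilibria, transients and snapshots", {
  cfg <- scenario_config("f0", "f1", switch_time = 1000, end_time = 3000,
                         sample_interval = 100, snapshot_interval = 500)
  b <- run_fertilization_scenario(cfg)
  expect_s3_class(b, "scenario_bundle")
  expect_equal(nrow(b$rad_after$entries), 31)
  expect_equal(b$summary$richness_before, 48)
  expect_equal(b$summary$n_new + b$summary$n_retained, 31)
  # snapshots at switch_time + k * snapshot_interval
  expect_named(b$snapshots, sprintf("t%d", seq(1500, 3000, by = 500)))
  # series span the whole run
  expect_equal(nrow(b$occupied_series), length(b$trajectory$times))
  expect_equal(b$richness_series$time, b$trajectory$times)
})

test_that("a no-op fertilization changes nothing and stays at equilibrium", {
  eq <- solve_equilibrium(preset_profile("f0"), paper_params())
  cfg <- scenario_config("f0", "f0", immigration = 0, switch_time = 500,
                         end_time = 1500, sample_interval = 250,
                         snapshot_interval = 500)
  b <- run_fertilization_scenario(cfg)
  expect_length(b$comparison$new_species, 0)
  expect_length(b$comparison$lost_species, 0)
  # started from the uniform trace state the run heads to the f0 equilibrium;
  # restart it from the equilibrium itself to check stationarity
  sched <- simulation_schedule(preset_profile("f0"), preset_profile("f0"),
                               switch_time = 500, end_time = 1500,
                               sample_interval = 250,
                               initial = eq$frequencies)
  traj <- simulate_community(sched, paper_params())
  expect_lt(max(abs(t(traj$states) - eq$frequencies)), 1e-8)
})

test_that("late transients recover the post-event equilibrium community", {
  # with immigration on, near-marginal species are held just above or below
  # the detection cutoff indefinitely, so the late-time detectable set and the
  # closed-community equilibrium set can only disagree about species whose
  # equilibrium relative abundance sits at the cutoff itself
  eq_after <- solve_equilibrium(preset_profile("f1"), paper_params())
  rel_eq <- eq_after$frequencies / sum(eq_after$frequencies)
  det_eq <- build_rad(eq_after$frequencies)$entries$species_index
  cfg <- scenario_config("f0", "f1", switch_time = 1000, end_time = 500000,
                         sample_interval = 20000, snapshot_interval = 100000)
  b <- run_fertilization_scenario(cfg)
  late <- state_at(b$trajectory, 500000)$frequencies
  det_late <- build_rad(late)$entries$species_index
  # every clearly detectable equilibrium species has been recovered
  expect_true(all(which(rel_eq >= 2e-5) %in% det_late))
  # every extra species is at equilibrium below the cutoff (most are
  # immigration-rescued species with zero closed-community frequency)
  extras <- setdiff(det_late, det_eq)
  expect_true(all(rel_eq[extras] < 1e-5))
  # and any equilibrium species not yet detected is itself borderline
  missing <- setdiff(det_eq, det_late)
  expect_true(all(rel_eq[missing] < 2e-5))
})

test_that("the richness/biomass sweep matches per-cell equilibrium solves", {
  surf <- sweep_alpha_beta(3, 16, paper_params())
  expect_equal(nrow(surf), 1)
  expect_equal(surf$richness, 31)
  grid <- sweep_alpha_beta(c(2, 3), c(4, 16, 18), paper_params())
  expect_equal(nrow(grid), 6)
  expect_true(all(grid$biomass >= 0 & grid$biomass <= 1))
  # richness falls as saturation strengthens at fixed alpha = 3
  at3 <- grid[grid$alpha == 3, ]
  at3 <- at3[order(at3$beta), ]
  expect_true(all(diff(at3$richness) <= 0))
  # independent of traversal order: same cells whichever way the grid is given
  flipped <- sweep_alpha_beta(c(3, 2), c(18, 16, 4), paper_params())
  key <- function(d) d[order(d$alpha, d$beta), c("richness", "biomass")]
  expect_equal(key(grid), key(flipped), ignore_attr = TRUE)
  expect_error(sweep_alpha_beta(numeric(0), 4, paper_params()), "nonempty")
})

test_that("decomposition separates the fecundity and saturation components", {
  base <- tradeoff_params(2, 4, 80)
  fert <- tradeoff_params(3, 16, 80)
  res <- decomposition_experiment(base, fert, paper_params())
  expect_named(res$cells, c("base", "alpha_only", "beta_only", "fert"))
  expect_equal(nrow(res$summary), 4)
  s <- res$summary
  rich <- function(cell) s$richness[s$cell == cell]
  # stronger saturation costs more species than the fecundity increment
  expect_gt(rich("base") - rich("beta_only"), rich("base") - rich("alpha_only"))
  # degenerate decomposition: all four cells identical
  same <- decomposition_experiment(base, base, paper_params())
  expect_equal(length(unique(same$summary$richness)), 1)
  expect_equal(length(unique(round(same$summary$biomass, 12))), 1)
})

test_that("fluctuation replicates are deterministic and magnitude-0 is exact", {
  f0 <- preset_profile("f0")
  f1 <- preset_profile("f1")
  null_run <- fluctuation_experiment(f0, f1, magnitude = 0, replicates = 3,
                                     seed = 4)
  expect_equal(unique(null_run$replicates$richness_before), 48)
  expect_equal(unique(null_run$replicates$richness_after), 31)
  a <- fluctuation_experiment(f0, f1, magnitude = 0.05, replicates = 5, seed = 9)
  b <- fluctuation_experiment(f0, f1, magnitude = 0.05, replicates = 5, seed = 9)
  expect_identical(a$summary, b$summary)
  expect_identical(a$replicates, b$replicates)
  c_ <- fluctuation_experiment(f0, f1, magnitude = 0.05, replicates = 5, seed = 10)
  expect_false(identical(a$replicates, c_$replicates))
})

test_that("trade-off fluctuation depresses richness relative to the smooth curve", {
  f0 <- preset_profile("f0")
  f1 <- preset_profile("f1")
  res <- fluctuation_experiment(f0, f1, magnitude = 0.05, replicates = 20,
                                seed = 2)
  smooth_richness <- richness(
    solve_equilibrium(f0, paper_params())$frequencies)
  expect_lte(res$summary$median_richness_before, smooth_richness)
})
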