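test_that("build_rad filters, sorts and breaks ties by competitive rank", {
  rad <- build_rad(c(0.5, 1e-6, 0.1), threshold = 1e-5, convention = "raw")
  expect_equal(rad$entries$species_index, c(1, 3))
  expect_equal(rad$entries$abundance, c(0.5, 0.1))
  expect_equal(rad$entries$rank, 1:2)
  # ties: better competitor first
  tie <- build_rad(c(0.2, 0.3, 0.2), convention = "raw")
  expect_equal(tie$entries$species_index, c(2, 1, 3))
  # empty RAD when everything is below threshold
  expect_equal(nrow(build_rad(rep(1e-7, 5), convention = "raw")$entries), 0)
  expect_error(build_rad(c(0.1, -0.1)), "negative")
})

test_that("relative convention normalizes by the occupied fraction", {
  p <- c(0.4, 0.1, 2e-6)
  rad <- build_rad(p, convention = "relative")
  expect_equal(rad$entries$abundance, c(0.4, 0.1) / sum(p),
               tolerance = 1e-15)
  # species 3: relative abundance ~4e-6 is still below the cutoff
  expect_equal(nrow(rad$entries), 2)
  # re-thresholding at the same cutoff is idempotent
  again <- build_rad(p, convention = "relative")
  expect_identical(rad$entries, again$entries)
})

test_that("raw- and relative-detectable sets differ only near the threshold", {
  set.seed(33)
  for (k in 1:25) {
    n <- sample(3:40, 1)
    p <- runif(n, 0, 2e-5)
    p[sample(n, 2)] <- runif(2, 0.05, 0.3)  # ensure some clearly detectable
    p <- p / max(1, sum(p))
    s <- sum(p)
    raw_set <- build_rad(p, convention = "raw")$entries$species_index
    rel_set <- build_rad(p, convention = "relative")$entries$species_index
    expect_true(all(raw_set %in% rel_set))  # sum <= 1 so relative >= raw
    boundary <- setdiff(rel_set, raw_set)
    expect_true(all(p[boundary] >= 1e-5 * s & p[boundary] < 1e-5))
  }
})

test_that("richness counts the RAD entries", {
  expect_equal(richness(numeric(10)), 0)
  set.seed(5)
  p <- runif(30, 0, 0.03)
  expect_equal(richness(p, 1e-3, "raw"),
               nrow(build_rad(p, 1e-3, "raw")$entries))
})

test_that("community comparison partitions the detectable sets", {
  p <- c(0.5, 0.2, 0)
  cmp0 <- compare_communities(p, p)
  expect_length(cmp0$new_species, 0)
  expect_length(cmp0$lost_species, 0)
  expect_equal(cmp0$retained, c(1, 2))

  before <- c(0.4, 0.3, 0)
  after <- c(0, 0.3, 0.4)
  cmp <- compare_communities(before, after)
  expect_equal(cmp$new_species, 3)
  expect_equal(cmp$lost_species, 1)
  expect_equal(cmp$retained, 2)
  expect_error(compare_communities(1:3 / 10, 1:4 / 10), "equal length")
})

test_that("partition identities hold on random communities", {
  set.seed(77)
  for (k in 1:30) {
    n <- sample(2:50, 1)
    before <- runif(n, 0, 0.02) * rbinom(n, 1, 0.6)
    after <- runif(n, 0, 0.02) * rbinom(n, 1, 0.6)
    cmp <- compare_communities(before, after, threshold = 1e-3, k = 5)
    det_b <- cmp$before$entries$species_index
    det_a <- cmp$after$entries$species_index
    expect_setequal(c(cmp$new_species, cmp$lost_species, cmp$retained),
                    union(det_b, det_a))
    expect_equal(length(det_a), length(cmp$retained) + length(cmp$new_species))
    expect_equal(length(det_b), length(cmp$retained) + length(cmp$lost_species))
    # tracked top-k species map to their after-rank or NA when absent
    tk <- cmp$top_k_tracking
    expect_lte(nrow(tk), 5)
    present <- !is.na(tk$after_rank)
    expect_equal(cmp$after$entries$species_index[tk$after_rank[present]],
                 tk$species_index[present])
    expect_true(all(!tk$species_index[!present] %in% det_a))
  }
})

test_that("RAD slope and evenness have exact values on constructed diagrams", {
  flat <- build_rad(c(0.2, 0.2), convention = "raw")
  s <- rad_slope(flat)
  expect_equal(s$slope, 0, tolerance = 1e-12)
  expect_equal(s$evenness, 1, tolerance = 1e-12)
  geo <- rad_slope(build_rad(c(0.1, 0.01, 0.001), convention = "raw"))
  expect_equal(geo$slope, -1, tolerance = 1e-12)
  expect_error(rad_slope(build_rad(c(0.5, 0), convention = "raw")), "fewer than 2")
})

test_that("equilibrium RADs reproduce the fertilization headline counts", {
  p1 <- solve_equilibrium(preset_profile("f1"), paper_params())$frequencies
  p2 <- solve_equilibrium(preset_profile("f2"), paper_params())$frequencies
  expect_equal(nrow(build_rad(p1)$entries), 31)
  expect_equal(richness(p2), 28)
  # new/retained split recorded across the f0 -> f1 event
  p0 <- solve_equilibrium(preset_profile("f0"), paper_params())$frequencies
  cmp <- compare_communities(p0, p1)
  expect_equal(length(cmp$new_species) + length(cmp$retained), 31)
  expect_equal(length(cmp$new_species), 8)
  cmp2 <- compare_communities(p0, p2)
  expect_equal(length(cmp2$new_species), 17)
  expect_equal(length(cmp2$new_species) + length(cmp2$retained), 28)
})

test_that("fertilization steepens the RAD and reorders the top ranks", {
  p0 <- solve_equilibrium(preset_profile("f0"), paper_params())$frequencies
  p1 <- solve_equilibrium(preset_profile("f1"), paper_params())$frequencies
  p2 <- solve_equilibrium(preset_profile("f2"), paper_params())$frequencies
  expect_lt(richness(p1), richness(p0))
  expect_lt(richness(p2), richness(p0))
  expect_lt(rad_slope(build_rad(p1))$slope, rad_slope(build_rad(p0))$slope)
  cmp <- compare_communities(p0, p1, k = 8)
  expect_false(identical(cmp$top_k_tracking$after_rank, 1:8))
})
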