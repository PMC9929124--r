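#' Rank abundance diagram with a detection threshold
#'
#' Species at or above the detection cutoff are ranked by decreasing
#' abundance; ties are broken in favour of the better competitor (smaller
#' index). Under the `"relative"` convention (the default, matching how the
#' exclusion cutoff is stated for the equilibrium diagrams) abundances are
#' site frequencies normalized by the total occupied fraction; `"raw"` ranks
#' and thresholds the site frequencies themselves.
#'
#' @param frequencies Nonnegative site-frequency vector (one entry per
#'   competitive rank).
#' @param threshold Detection cutoff below which species are excluded
#'   (default 1e-5).
#' @param convention `"relative"` or `"raw"`.
#' @return An object of class `rank_abundance`: a data.frame `entries` with
#'   columns `rank`, `species_index`, `abundance`, plus the `threshold` and
#'   `convention` used.
#' @export
#' @examples
#' rad <- build_rad(c(0.5, 1e-6, 0.1), threshold = 1e-5, convention = "raw")
#' rad$entries
build_rad <- function(frequencies, threshold = 1e-5,
                      convention = c("relative", "raw")) {
  convention <- match.arg(convention)
  if (!is.numeric(frequencies) || any(!is.finite(frequencies)))
    stop("`frequencies` must be finite numbers", call. = FALSE)
  if (any(frequencies < 0))
    stop("negative frequency supplied to build_rad()", call. = FALSE)
  total <- sum(frequencies)
  abundance <- if (convention == "relative" && total > 0)
    frequencies / total else frequencies
  keep <- which(abundance >= threshold & abundance > 0)
  ord <- keep[order(-abundance[keep], keep)]
  structure(list(entries = data.frame(rank = seq_along(ord),
                                      species_index = ord,
                                      abundance = abundance[ord]),
                 threshold = threshold, convention = convention),
            class = "rank_abundance")
}

#' @export
print.rank_abundance <- function(x, ...) {
  cat(sprintf("RAD: %d detectable species (threshold %g, %s abundance)\n",
              nrow(x$entries), x$threshold, x$convention))
  invisible(x)
}

#' Detectable species richness
#'
#' @inheritParams build_rad
#' @return Count of species at or above the threshold.
#' @export
richness <- function(frequencies, threshold = 1e-5,
                     convention = c("relative", "raw")) {
  nrow(build_rad(frequencies, threshold, convention)$entries)
}

#' Labeled-SAD comparison of two communities
#'
#' Tracks individual species identities across a treatment: which detectable
#' species are new, lost or retained, and where the pre-treatment top-k
#' species end up in the post-treatment ranking (species reordering).
#'
#' @param before,after Site-frequency vectors of equal length.
#' @inheritParams build_rad
#' @param k How many of the most abundant pre-treatment species to track
#'   (default 8).
#' @return An object of class `community_comparison` with the two
#'   `rank_abundance` objects, integer sets `new_species`, `lost_species`,
#'   `retained`, and a data.frame `top_k_tracking` with columns
#'   `species_index`, `before_rank`, `after_rank` (`NA` when the species is
#'   absent after the treatment).
#' @export
compare_communities <- function(before, after, threshold = 1e-5, k = 8,
                                convention = c("relative", "raw")) {
  if (length(before) != length(after))
    stop("`before` and `after` must have equal length", call. = FALSE)
  convention <- match.arg(convention)
  rad_b <- build_rad(before, threshold, convention)
  rad_a <- build_rad(after, threshold, convention)
  set_b <- rad_b$entries$species_index
  set_a <- rad_a$entries$species_index
  kk <- min(k, length(set_b))
  top_b <- rad_b$entries$species_index[seq_len(kk)]
  after_rank <- rad_a$entries$rank[match(top_b, rad_a$entries$species_index)]
  structure(list(before = rad_b, after = rad_a,
                 new_species = sort(setdiff(set_a, set_b)),
                 lost_species = sort(setdiff(set_b, set_a)),
                 retained = sort(intersect(set_b, set_a)),
                 top_k_tracking = data.frame(species_index = top_b,
                                             before_rank = seq_len(kk),
                                             after_rank = after_rank)),
            class = "community_comparison")
}

#' @export
print.community_comparison <- function(x, ...) {
  cat(sprintf(
    "Community comparison: %d -> %d detectable species (%d new, %d lost, %d retained)\n",
    nrow(x$before$entries), nrow(x$after$entries),
    length(x$new_species), length(x$lost_species), length(x$retained)))
  invisible(x)
}

#' RAD steepness and evenness summaries
#'
#' Steepness is the least-squares slope of log10(abundance) against rank
#' (more negative = steeper diagram = less even community). Evenness is the
#' Pielou index of the detectable species: Shannon entropy of their normalized
#' abundances divided by the log of richness.
#'
#' @param rad A [build_rad()] result with at least 2 entries.
#' @return List with `slope` and `evenness`.
#' @export
#' @examples
#' rad_slope(build_rad(c(0.1, 0.01, 0.001), convention = "raw"))
rad_slope <- function(rad) {
  stopifnot(inherits(rad, "rank_abundance"))
  ab <- rad$entries$abundance
  if (length(ab) < 2L)
    stop("RAD slope is undefined for fewer than 2 detectable species",
         call. = FALSE)
  slope <- unname(stats::coef(
    stats::lm(log10(ab) ~ rad$entries$rank))[2])
  rel <- ab / sum(ab)
  evenness <- -sum(rel * log(rel)) / log(length(rel))
  list(slope = slope, evenness = evenness)
}
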