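#' Community-level rates of the colonization model
#'
#' @param q Basal colonization rate: probability that a propagule arrives at
#'   a site and reaches the colony growth stage, in (0, 1].
#' @param m Extinction (disturbance) rate: probability per unit time that an
#'   occupied site is emptied, > 0.
#' @param immigration Constant external immigration rate added to every
#'   species' dynamics (default 0; the transient fertilization runs use
#'   1e-10 to keep all species rescuable from extinction). Ignored by the
#'   equilibrium recursion, which describes the closed community.
#' @param immigration_form How the immigration term enters the dynamics:
#'   `"constant"` adds the rate to every derivative; `"open_site"` scales it
#'   by the fraction of sites not occupied by the species or its superiors.
#'   At rates near 1e-10 the two are numerically indistinguishable.
#' @return An object of class `community_params`.
#' @export
#' @examples
#' community_params(q = 0.3, m = 0.2)
community_params <- function(q, m, immigration = 0,
                             immigration_form = c("constant", "open_site")) {
  if (!is.numeric(q) || length(q) != 1L || q <= 0 || q > 1)
    stop("`q` must lie in (0, 1]", call. = FALSE)
  if (!is.numeric(m) || length(m) != 1L || !is.finite(m) || m <= 0)
    stop("`m` must be a positive rate", call. = FALSE)
  if (!is.numeric(immigration) || length(immigration) != 1L || immigration < 0)
    stop("`immigration` must be a nonnegative rate", call. = FALSE)
  structure(list(q = as.numeric(q), m = as.numeric(m),
                 immigration = as.numeric(immigration),
                 immigration_form = match.arg(immigration_form)),
            class = "community_params")
}

#' @export
print.community_params <- function(x, ...) {
  cat(sprintf("Community rates: q = %g, m = %g, immigration = %g (%s)\n",
              x$q, x$m, x$immigration, x$immigration_form))
  invisible(x)
}

#' Minimum fecundity for persistence
#'
#' A species can only persist (in the absence of superior competitors) when
#' its fecundity exceeds `m/q`: colonization gains must outrun disturbance.
#'
#' @param params A [community_params()] object.
#' @return The rate `m/q`.
#' @export
persistence_floor <- function(params) {
  stopifnot(inherits(params, "community_params"))
  params$m / params$q
}

#' Most competitive species able to persist alone
#'
#' @param profile A [fecundity_profile()].
#' @param params A [community_params()].
#' @return The smallest rank `i` with `f_i > m/q`, or `NA_integer_` if no
#'   species clears the persistence floor.
#' @export
first_persistent_index <- function(profile, params) {
  stopifnot(inherits(profile, "fecundity_profile"))
  idx <- which(profile$values > persistence_floor(params))
  if (length(idx) == 0L) NA_integer_ else idx[1L]
}

#' Equilibrium occupancy by forward recursion
#'
#' Solves the closed-community (no immigration) equilibrium of the
#' displacement-competition colonization model. Because a species' equilibrium
#' frequency depends only on its own fecundity and on the frequencies of its
#' competitive superiors, the fixed point is obtained by one forward pass over
#' ranks i = 1..n:
#' \deqn{p_i^* = 1 - \sum_{j<i} p_j^* -
#'   \frac{1}{f_i}\Big(\sum_{j<i} f_j p_j^* + m/q\Big)}
#' when that quantity is positive, and 0 otherwise. Species assigned 0
#' contribute nothing to the running sums. Values below 1e-15 are truncated
#' to 0 to keep floating-point dust out of downstream thresholding (the
#' detection threshold in use is ten orders of magnitude larger).
#'
#' @param profile A [fecundity_profile()]; need not be monotone (perturbed
#'   profiles are handled identically).
#' @param params A [community_params()]. The immigration field is ignored
#'   here; equilibria with immigration are only available by long integration
#'   of the dynamics.
#' @return An object of class `equilibrium_state` with fields `frequencies`
#'   (p_1*..p_n*), `profile` and `params`.
#' @export
#' @examples
#' eq <- solve_equilibrium(preset_profile("f0"), community_params(0.3, 0.2))
#' occupied_fraction(eq)
solve_equilibrium <- function(profile, params) {
  stopifnot(inherits(profile, "fecundity_profile"),
            inherits(params, "community_params"))
  f <- profile$values
  n <- profile$n
  floor_rate <- persistence_floor(params)
  p <- numeric(n)
  sum_p <- 0    # running occupied fraction over superiors with p* > 0
  sum_fp <- 0   # running colonization pressure from those superiors
  for (i in seq_len(n)) {
    if (f[i] <= 0) next  # cannot colonize; p_i* = 0
    v <- 1 - sum_p - (sum_fp + floor_rate) / f[i]
    if (v > 1e-15) {
      p[i] <- v
      sum_p <- sum_p + v
      sum_fp <- sum_fp + f[i] * v
    }
  }
  structure(list(frequencies = p, profile = profile, params = params),
            class = "equilibrium_state")
}

#' @export
print.equilibrium_state <- function(x, ...) {
  cat(sprintf(
    "Equilibrium: %d of %d species at positive frequency, occupied fraction %.6g\n",
    sum(x$frequencies > 0), length(x$frequencies), occupied_fraction(x)))
  invisible(x)
}

#' Total occupied fraction (community biomass proxy)
#'
#' The summed site occupancy, i.e. one minus the frequency of empty sites,
#' used as the model's biomass measure.
#'
#' @param x An `equilibrium_state` or a numeric frequency vector.
#' @return A fraction in `[0, 1]`.
#' @export
occupied_fraction <- function(x) {
  p <- if (inherits(x, "equilibrium_state")) x$frequencies else x
  stopifnot(is.numeric(p), all(p >= 0))
  sum(p)
}

#' Tabulate an equilibrium state
#'
#' @param x An `equilibrium_state`.
#' @param row.names,optional Unused, present for the generic.
#' @param threshold Detection cutoff applied to relative abundance for the
#'   `detectable` flag (default 1e-5).
#' @param ... Unused.
#' @return A data.frame with columns `species_index`, `fecundity`,
#'   `frequency`, `relative_abundance`, `detectable`.
#' @export
as.data.frame.equilibrium_state <- function(x, row.names = NULL,
                                            optional = FALSE,
                                            threshold = 1e-5, ...) {
  p <- x$frequencies
  total <- sum(p)
  rel <- if (total > 0) p / total else p
  data.frame(species_index = seq_along(p),
             fecundity = x$profile$values,
             frequency = p,
             relative_abundance = rel,
             detectable = as.integer(rel >= threshold & p > 0))
}
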