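#' Parameters of the competition-fecundity trade-off
#'
#' The trade-off maps a species' competitive rank `i` (1 = best competitor)
#' onto its reproductive rate
#' \deqn{f_i = \alpha \frac{1 - e^{-\beta i / n}}{1 + e^{-\beta i / n}}
#'          = \alpha \tanh\!\left(\frac{\beta i}{2n}\right),}
#' so competitively inferior species (large `i`) are more fecund, saturating
#' at the maximum fecundity `alpha`; `beta` controls how fast the curve
#' saturates along the rank axis.
#'
#' @param alpha Maximum fecundity (reproductive rate scale), > 0.
#' @param beta Saturation intensity (dimensionless), > 0.
#' @param n Number of potential species in the pool, positive integer.
#' @return An object of class `tradeoff_params`.
#' @seealso [fecundity_profile()], [preset_tradeoff()]
#' @export
#' @examples
#' tradeoff_params(alpha = 2, beta = 4, n = 80)
tradeoff_params <- function(alpha, beta, n) {
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) || alpha <= 0)
    stop("`alpha` must be a single positive number", call. = FALSE)
  if (!is.numeric(beta) || length(beta) != 1L || !is.finite(beta) || beta <= 0)
    stop("`beta` must be a single positive number", call. = FALSE)
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != round(n))
    stop("`n` must be a positive integer", call. = FALSE)
  structure(list(alpha = as.numeric(alpha), beta = as.numeric(beta),
                 n = as.integer(n)),
            class = "tradeoff_params")
}

#' @export
print.tradeoff_params <- function(x, ...) {
  cat(sprintf("Competition-fecundity trade-off: alpha = %g, beta = %g, n = %d\n",
              x$alpha, x$beta, x$n))
  invisible(x)
}

#' Named trade-off presets
#'
#' The three parameterizations used throughout the fertilization experiments:
#' `f0` (alpha = 2, beta = 4) is the unfertilized baseline, `f1`
#' (alpha = 3, beta = 16) and `f2` (alpha = 3, beta = 18) are two
#' fertilization scenarios in which both the fecundity ceiling and its
#' saturation along the competitive hierarchy increase.
#'
#' @param name One of `"f0"`, `"f1"`, `"f2"`.
#' @param n Species pool size (default 80).
#' @return A [tradeoff_params()] object.
#' @export
preset_tradeoff <- function(name = c("f0", "f1", "f2"), n = 80) {
  name <- match.arg(name)
  ab <- switch(name,
               f0 = c(2, 4),
               f1 = c(3, 16),
               f2 = c(3, 18))
  tradeoff_params(alpha = ab[1], beta = ab[2], n = n)
}

#' Evaluate the trade-off at one or more competitive ranks
#'
#' @param i Species index (competitive rank), values in `0..n`. `i = 0` is
#'   accepted for limit checks and returns 0; community species are `1..n`.
#' @param params A [tradeoff_params()] object.
#' @return Numeric vector of reproductive rates, same length as `i`.
#' @export
#' @examples
#' fecundity_value(80, tradeoff_params(2, 4, 80))  # ~1.92806
fecundity_value <- function(i, params) {
  stopifnot(inherits(params, "tradeoff_params"))
  if (!is.numeric(i) || any(!is.finite(i)) || any(i < 0) || any(i > params$n))
    stop("species index `i` must lie in [0, n]", call. = FALSE)
  # tanh form of alpha * (1 - exp(-b i/n)) / (1 + exp(-b i/n)); identical
  # analytically, better conditioned for large beta * i / n
  params$alpha * tanh(params$beta * i / (2 * params$n))
}

#' Build the full fecundity profile f_1..f_n
#'
#' @param params A [tradeoff_params()] object.
#' @return An object of class `fecundity_profile` with fields `n`, `values`
#'   (ordered rates for ranks 1..n) and `provenance` (how it was built).
#' @export
#' @examples
#' prof <- fecundity_profile(preset_tradeoff("f0"))
#' head(prof$values)
fecundity_profile <- function(params) {
  stopifnot(inherits(params, "tradeoff_params"))
  values <- fecundity_value(seq_len(params$n), params)
  new_fecundity_profile(values,
                        provenance = list(kind = "tradeoff",
                                          alpha = params$alpha,
                                          beta = params$beta))
}

#' Construct a profile directly from a vector of rates
#'
#' Used for profiles read from file or otherwise supplied externally;
#' positions in `values` are competitive ranks 1..n.
#'
#' @param values Strictly positive reproductive rates, rank-ordered.
#' @param provenance A list describing where the values came from.
#' @return A `fecundity_profile`.
#' @export
as_fecundity_profile <- function(values, provenance = list(kind = "custom")) {
  new_fecundity_profile(as.numeric(values), provenance)
}

new_fecundity_profile <- function(values, provenance) {
  if (length(values) < 1L || any(!is.finite(values)) || any(values <= 0))
    stop("profile values must be finite and strictly positive", call. = FALSE)
  structure(list(n = length(values), values = values, provenance = provenance),
            class = "fecundity_profile")
}

#' Shortcut: profile for a named preset
#'
#' @inheritParams preset_tradeoff
#' @return A `fecundity_profile`.
#' @export
preset_profile <- function(name = c("f0", "f1", "f2"), n = 80) {
  fecundity_profile(preset_tradeoff(name, n))
}

#' @export
print.fecundity_profile <- function(x, ...) {
  cat(sprintf("Fecundity profile: n = %d, range [%.6g, %.6g] (%s)\n",
              x$n, min(x$values), max(x$values),
              x$provenance$kind))
  invisible(x)
}

#' Randomly fluctuate a fecundity profile
#'
#' Multiplies each species' rate by an independent uniform draw on
#' \eqn{[1 - \delta, 1 + \delta]}. This is the robustness perturbation used
#' to test whether fertilization trends survive a non-smooth trade-off;
#' perturbed profiles are generally no longer monotone in rank and downstream
#' code must not assume sortedness.
#'
#' @param profile A `fecundity_profile`.
#' @param magnitude Relative fluctuation \eqn{\delta} in `[0, 1)` (0.05 for
#'   the "plus or minus 5 percent" experiment).
#' @param seed Integer seed; the draw is reproducible and recorded in the
#'   returned profile's provenance.
#' @param multipliers Optional pre-drawn multiplier vector (length n); used to
#'   share one set of multipliers across a before/after profile pair.
#' @return A perturbed `fecundity_profile`.
#' @export
perturb_profile <- function(profile, magnitude, seed = NULL, multipliers = NULL) {
  stopifnot(inherits(profile, "fecundity_profile"))
  if (!is.numeric(magnitude) || length(magnitude) != 1L ||
      magnitude < 0 || magnitude >= 1)
    stop("`magnitude` must lie in [0, 1): larger values could produce ",
         "nonpositive fecundities", call. = FALSE)
  if (is.null(multipliers)) {
    if (is.null(seed))
      stop("supply `seed` (or explicit `multipliers`) so the perturbation ",
           "is reproducible", call. = FALSE)
    multipliers <- with_seed(seed,
      stats::runif(profile$n, 1 - magnitude, 1 + magnitude))
  } else {
    stopifnot(length(multipliers) == profile$n)
  }
  new_fecundity_profile(
    profile$values * multipliers,
    provenance = list(kind = "perturbed",
                      parent = profile$provenance,
                      magnitude = magnitude,
                      seed = seed,
                      multipliers = multipliers))
}

#' Perturb a before/after profile pair
#'
#' Convenience wrapper for the fluctuation experiments: both profiles of a
#' fertilization pair are fluctuated, either with independent multiplier
#' draws (default) or sharing the same per-species multipliers.
#'
#' @param before,after `fecundity_profile` objects of equal length.
#' @inheritParams perturb_profile
#' @param share_multipliers If `TRUE`, one multiplier vector is drawn and
#'   applied to both profiles; if `FALSE` (default) each profile gets an
#'   independent draw.
#' @return List with elements `before` and `after`.
#' @export
perturb_profile_pair <- function(before, after, magnitude, seed,
                                 share_multipliers = FALSE) {
  stopifnot(inherits(before, "fecundity_profile"),
            inherits(after, "fecundity_profile"),
            before$n == after$n)
  mult <- with_seed(seed, {
    m1 <- stats::runif(before$n, 1 - magnitude, 1 + magnitude)
    m2 <- if (share_multipliers) m1
          else stats::runif(after$n, 1 - magnitude, 1 + magnitude)
    list(m1, m2)
  })
  list(before = perturb_profile(before, magnitude, seed, multipliers = mult[[1]]),
       after  = perturb_profile(after,  magnitude, seed, multipliers = mult[[2]]))
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG stream afterwards.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L)
    stop("`seed` must be a single integer", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
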