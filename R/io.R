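# Serialization helpers. Floats are written with 17 significant digits so a
# write/read round trip is bit-exact.

fmt17 <- function(x) sprintf("%.17g", x)

write_table <- function(df, path) {
  num <- vapply(df, is.double, logical(1))
  out <- df
  out[num] <- lapply(df[num], fmt17)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write / read a fecundity profile as CSV
#'
#' Columns `species_index` (1-based) and `fecundity`, full double precision.
#'
#' @param profile A [fecundity_profile()].
#' @param path Output / input file path.
#' @return `write_profile_csv` returns `path` invisibly; `read_profile_csv`
#'   returns a `fecundity_profile` whose provenance records the source file.
#' @export
write_profile_csv <- function(profile, path) {
  stopifnot(inherits(profile, "fecundity_profile"))
  write_table(data.frame(species_index = seq_len(profile$n),
                         fecundity = profile$values), path)
}

#' @rdname write_profile_csv
#' @export
read_profile_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("species_index", "fecundity")
  if (!all(need %in% names(df)))
    stop("profile CSV must have columns species_index, fecundity", call. = FALSE)
  df <- df[order(df$species_index), ]
  if (!identical(as.integer(df$species_index), seq_len(nrow(df))))
    stop("species_index must be 1..n without gaps", call. = FALSE)
  as_fecundity_profile(df$fecundity,
                       provenance = list(kind = "csv", path = path))
}

#' Write an equilibrium state as CSV plus a metadata sidecar
#'
#' The CSV holds one row per species (`species_index`, `fecundity`,
#' `frequency`, `relative_abundance`, `detectable`); `<path>.json` records
#' the community parameters and profile provenance.
#'
#' @param state An `equilibrium_state`.
#' @param path CSV path; the sidecar is written next to it.
#' @param threshold Detection cutoff for the `detectable` column.
#' @return `path`, invisibly.
#' @export
write_equilibrium_csv <- function(state, path, threshold = 1e-5) {
  stopifnot(inherits(state, "equilibrium_state"))
  write_table(as.data.frame(state, threshold = threshold), path)
  meta <- list(params = unclass(state$params),
               profile_provenance = state$profile$provenance,
               threshold = threshold)
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write a rank abundance diagram as CSV
#'
#' Columns `rank`, `species_index`, `abundance`, `convention`, `threshold`.
#'
#' @param rad A [build_rad()] result.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_rad_csv <- function(rad, path) {
  stopifnot(inherits(rad, "rank_abundance"))
  df <- rad$entries
  df$convention <- rad$convention
  df$threshold <- rad$threshold
  write_table(df, path)
}

#' Write a trajectory as long-format CSV
#'
#' Columns `time`, `species_index`, `frequency` (one row per sample and
#' species).
#'
#' @param trajectory A [simulate_community()] result.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(trajectory, path) {
  stopifnot(inherits(trajectory, "trajectory"))
  n <- ncol(trajectory$states)
  df <- data.frame(time = rep(trajectory$times, each = n),
                   species_index = rep(seq_len(n), length(trajectory$times)),
                   frequency = as.vector(t(trajectory$states)))
  write_table(df, path)
}

#' Write a community comparison as JSON
#'
#' @param comparison A [compare_communities()] result.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_comparison_json <- function(comparison, path) {
  stopifnot(inherits(comparison, "community_comparison"))
  sl_or_na <- function(rad) {
    if (nrow(rad$entries) >= 2) rad_slope(rad)
    else list(slope = NA, evenness = NA)
  }
  sb <- sl_or_na(comparison$before); sa <- sl_or_na(comparison$after)
  out <- list(
    threshold = comparison$before$threshold,
    convention = comparison$before$convention,
    before = list(richness = nrow(comparison$before$entries),
                  species = comparison$before$entries$species_index,
                  slope = sb$slope, evenness = sb$evenness),
    after = list(richness = nrow(comparison$after$entries),
                 species = comparison$after$entries$species_index,
                 slope = sa$slope, evenness = sa$evenness),
    new_species = comparison$new_species,
    lost_species = comparison$lost_species,
    retained = comparison$retained,
    top_k_tracking = comparison$top_k_tracking)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Write a scenario bundle to a directory
#'
#' Emits every artifact of a [run_fertilization_scenario()] result with
#' stable filenames, a plain-text run log (resolved config, seed, package
#' version, convergence diagnostic) and a `manifest.json` listing each file
#' with its MD5 checksum. Reruns with the same config and seed are
#' byte-identical.
#'
#' @param bundle A `scenario_bundle`.
#' @param out_dir Output directory (created if missing).
#' @return The manifest as a data.frame (`file`, `md5`), invisibly.
#' @export
write_bundle <- function(bundle, out_dir) {
  stopifnot(inherits(bundle, "scenario_bundle"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  cfg <- bundle$config
  cfg_json <- unclass(cfg)
  describe_tradeoff <- function(x) {
    if (inherits(x, "tradeoff_params")) unclass(x)
    else if (inherits(x, "fecundity_profile")) list(kind = "profile",
                                                    provenance = x$provenance)
    else x
  }
  cfg_json$before <- describe_tradeoff(cfg_json$before)
  cfg_json$after <- describe_tradeoff(cfg_json$after)
  jsonlite::write_json(cfg_json[!vapply(cfg_json, is.null, logical(1))],
                       file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_equilibrium_csv(bundle$equilibrium_before,
                        file.path(out_dir, "equilibrium_before.csv"),
                        threshold = cfg$threshold)
  write_equilibrium_csv(bundle$equilibrium_after,
                        file.path(out_dir, "equilibrium_after.csv"),
                        threshold = cfg$threshold)
  write_rad_csv(bundle$rad_before, file.path(out_dir, "rad_before.csv"))
  write_rad_csv(bundle$rad_after, file.path(out_dir, "rad_after.csv"))
  write_comparison_json(bundle$comparison, file.path(out_dir, "comparison.json"))
  write_trajectory_csv(bundle$trajectory, file.path(out_dir, "trajectory.csv"))
  snap_dir <- file.path(out_dir, "snapshots")
  if (!dir.exists(snap_dir)) dir.create(snap_dir)
  for (nm in names(bundle$snapshots))
    write_rad_csv(bundle$snapshots[[nm]],
                  file.path(snap_dir, sprintf("rad_%s.csv", nm)))
  write_table(bundle$occupied_series, file.path(out_dir, "occupied_series.csv"))
  write_table(bundle$richness_series, file.path(out_dir, "richness_series.csv"))
  write_table(bundle$summary, file.path(out_dir, "summary.csv"))
  log_lines <- c(
    sprintf("patchcomm version: %s",
            as.character(utils::packageVersion("patchcomm"))),
    sprintf("seed: %s", if (is.null(cfg$seed)) "none" else cfg$seed),
    sprintf("final max |dp/dt|: %.17g", bundle$trajectory$final_max_rate),
    "resolved config:",
    vapply(setdiff(names(unclass(cfg)), "seed"), function(k) {
      v <- cfg[[k]]
      shown <- if (is.character(v) || is.numeric(v)) paste(format(v), collapse = " ")
               else sprintf("<%s>", class(v)[1])
      sprintf("  %s: %s", k, shown)
    }, character(1)))
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))

  files <- sort(setdiff(
    list.files(out_dir, recursive = TRUE, full.names = FALSE),
    "manifest.json"), method = "radix")
  manifest <- data.frame(
    file = files,
    md5 = unname(tools::md5sum(file.path(out_dir, files))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Parse a scenario configuration file with flag overrides
#'
#' Reads a YAML file whose keys mirror the arguments of [scenario_config()],
#' applies overrides on top (overrides win), fills remaining defaults, and
#' validates. Unknown keys are rejected by name.
#'
#' @param path YAML file path, or `NULL` to use defaults plus overrides only.
#' @param overrides Named list of values that take precedence over the file.
#' @return A validated [scenario_config()] with all defaults resolved.
#' @export
parse_config <- function(path = NULL, overrides = list()) {
  from_file <- if (is.null(path)) list() else {
    if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
    cfg <- yaml::read_yaml(path)
    if (is.null(cfg)) list() else cfg
  }
  merged <- utils::modifyList(from_file, overrides)
  allowed <- names(formals(scenario_config))
  unknown <- setdiff(names(merged), allowed)
  if (length(unknown) > 0L)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  do.call(scenario_config, merged)
}
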