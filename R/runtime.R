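#' @include scoring.R
NULL

# Configuration, seeding and run manifests.
#
# All stochastic components derive child seeds from a single base seed by a
# stable integer hash of (base seed, stage name, item index), so any stage is
# reproducible in isolation and results never depend on scheduling.

#' Derive a child seed from a base seed, stage name and item index
#'
#' Deterministic, stable across platforms and sessions; result is a
#' non-negative integer below 2^31.
#'
#' @param base Base integer seed.
#' @param stage Stage name (character scalar).
#' @param index Item index within the stage.
#' @return Integer seed.
#' @export
childSeed <- function(base, stage = "", index = 0L) {
  m <- 2147483629  # prime < 2^31; arithmetic kept exact in doubles
  h <- as.numeric(base) %% m
  for (code in utf8ToInt(stage)) h <- (h * 131 + code) %% m
  h <- (h * 131 + as.numeric(index) + 1) %% m
  as.integer(h)
}

.config_defaults <- list(
  k = 6, n = 10, threads = 1, seed = 1, local_steps = 50,
  fn = "vina_class", n_backbones = 100, rounds = 1, closure_tolerance = 0.3,
  top_m = 5, near_native_rmsd = 2.5, affinity_threshold_nM = 500,
  minimize = FALSE)

.config_check <- function(cfg) {
  num_pos <- c("n", "threads", "local_steps", "n_backbones", "rounds",
               "top_m", "near_native_rmsd", "affinity_threshold_nM",
               "closure_tolerance")
  if (cfg$k < 0) stop("config error: k must be >= 0")
  for (key in num_pos) {
    if (!is.numeric(cfg[[key]]) || length(cfg[[key]]) != 1 || cfg[[key]] <= 0)
      stop("config error: ", key, " must be a positive number")
  }
  .check_fn(cfg$fn)
  if (!is.logical(cfg$minimize)) stop("config error: minimize must be logical")
  cfg
}

#' Load and validate a run configuration
#'
#' Merges defaults, an optional YAML file and explicit flag overrides (flags
#' win over the file, the file over defaults).  Unknown keys and
#' out-of-range values are configuration errors naming the offending key.
#'
#' @param path Optional YAML file path.
#' @param flags Named list of overrides.
#' @return Validated named list of class \code{"phlaConfig"}.
#' @export
loadConfig <- function(path = NULL, flags = list()) {
  cfg <- .config_defaults
  merge_in <- function(cfg, vals, origin) {
    unknown <- setdiff(names(vals), names(.config_defaults))
    if (length(unknown))
      stop("config error: unknown key(s) in ", origin, ": ",
           paste(unknown, collapse = ", "))
    cfg[names(vals)] <- vals
    cfg
  }
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    vals <- yaml::read_yaml(path)
    if (length(vals)) cfg <- merge_in(cfg, vals, path)
  }
  if (length(flags)) cfg <- merge_in(cfg, flags, "flags")
  cfg <- .config_check(cfg)
  class(cfg) <- c("phlaConfig", "list")
  cfg
}

.pkg_version <- function() {
  as.character(utils::packageVersion("pHLAdock"))
}

#' Write a run manifest
#'
#' Records the command, configuration snapshot, base seed, package version,
#' stage timings and warnings for one invocation; a manifest plus the same
#' package version reproduces all outputs bit-identically.
#'
#' @param path Output JSON path.
#' @param command Command name (e.g. \code{"dock"}).
#' @param config Configuration list used.
#' @param seed Base seed.
#' @param outputs Named character vector of output file paths; their MD5
#'   hashes are recorded.
#' @param timings Optional named numeric (seconds per stage).
#' @param warnings Character vector of warnings raised.
#' @return Invisibly, the manifest list.
#' @export
writeManifest <- function(path, command, config, seed, outputs = character(),
                          timings = numeric(), warnings = character()) {
  hashes <- if (length(outputs)) unname(tools::md5sum(outputs)) else character()
  manifest <- list(command = command, config = unclass(config), seed = seed,
                   version = .pkg_version(),
                   outputs = as.list(structure(hashes, names = names(outputs))),
                   output_paths = as.list(outputs),
                   timings = as.list(timings), warnings = warnings)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(manifest)
}

#' Replay a manifest and verify outputs
#'
#' Re-executes the recorded command with the recorded configuration and seed
#' through \code{runner}, then compares the MD5 hashes of the regenerated
#' outputs with those in the manifest.  Refuses to replay a manifest written
#' by a different package version.
#'
#' @param path Manifest JSON path.
#' @param runner Function called as \code{runner(command, config, seed,
#'   out_dir)}; it must write outputs with the recorded file names into
#'   \code{out_dir} and return the named vector of paths.
#' @param out_dir Directory for regenerated outputs.
#' @return List: \code{identical} (logical), per-file \code{hashes}.
#' @export
replayManifest <- function(path, runner, out_dir = tempfile("replay")) {
  manifest <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(manifest$version, .pkg_version()))
    stop("manifest version ", manifest$version,
         " does not match installed package ", .pkg_version(),
         "; refusing to replay")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- loadConfig(flags = manifest$config[names(manifest$config) %in%
                                              names(.config_defaults)])
  outs <- runner(manifest$command, cfg, manifest$seed, out_dir)
  new_hash <- unname(tools::md5sum(outs))
  old_hash <- unlist(manifest$outputs)
  same <- identical(unname(new_hash), unname(old_hash))
  if (!same) warning("replayed outputs differ from manifest hashes")
  list(identical = same, hashes = new_hash, expected = old_hash)
}
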