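#' Run configuration
#'
#' Collects the physical and threshold parameters shared across pipeline
#' stages, with the defaults used throughout the package: 0.1/0.1/0.4 um
#' voxels, 87.5 nm bead radius, 310.15 K, a 1.5e-6 um^2/s tracking noise
#' floor, 1e5 Hz correlator base frequency, a 1.6 um centrosome-split
#' threshold, 60-frame minimum track length and a 110 nM condensate
#' concentration threshold.
#'
#' @param seed Integer seed recorded in every output.
#' @param voxel A [voxel_geometry()].
#' @param bead_radius Tracer bead radius, m.
#' @param temperature Temperature, K.
#' @param noise_floor Tracking noise floor, um^2/s.
#' @param base_frequency Correlator base frequency, Hz.
#' @param split_threshold Centrosome split distance, um.
#' @param min_track_length Minimum track length, frames.
#' @param condensate_threshold Condensate concentration threshold, nM.
#' @return Validated list of class `run_config`.
#' @export
run_config <- function(seed = 1L, voxel = voxel_geometry(),
                       bead_radius = 87.5e-9, temperature = 310.15,
                       noise_floor = 1.5e-6, base_frequency = 1e5,
                       split_threshold = 1.6, min_track_length = 60L,
                       condensate_threshold = 110) {
  check_scalar(seed, "seed")
  stopifnot(inherits(voxel, "voxel_geometry"))
  check_scalar(bead_radius, "bead_radius", positive = TRUE)
  check_scalar(temperature, "temperature", positive = TRUE)
  check_scalar(noise_floor, "noise_floor", nonneg = TRUE)
  check_scalar(base_frequency, "base_frequency", positive = TRUE)
  check_scalar(split_threshold, "split_threshold", positive = TRUE)
  min_track_length <- check_count(min_track_length, "min_track_length",
                                  min = 2L)
  check_scalar(condensate_threshold, "condensate_threshold",
               positive = TRUE)
  structure(as.list(environment()), class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Unknown keys raise an error rather than being ignored; voxel geometry
#' is given as `voxel: {dx: ..., dy: ..., dz: ...}`.
#'
#' @param path YAML file path.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- setdiff(names(formals(run_config)), "voxel")
  extra <- setdiff(names(y), c(known, "voxel"))
  if (length(extra))
    stop_param("unknown config key(s): ", paste(extra, collapse = ", "))
  args <- y[intersect(names(y), known)]
  if (!is.null(y$voxel))
    args$voxel <- voxel_geometry(y$voxel$dx, y$voxel$dy, y$voxel$dz)
  do.call(run_config, args)
}

# Stable hash of a config for provenance (md5 of its canonical JSON).
config_hash <- function(config) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  plain <- lapply(unclass(config), function(v)
    if (inherits(v, "voxel_geometry")) unclass(v) else v)
  jsonlite::write_json(plain, f, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(f))
}

.pipeline_stages <- c("simulate_fcs", "correct", "correlate", "fit",
                      "concentration")

#' Run the FCS concentration pipeline
#'
#' Chains the stages `simulate_fcs` -> `correct` -> `correlate` ->
#' `fit` -> `concentration` (any prefix of this chain is allowed) under
#' one configuration and seed, recording provenance (config hash, seed,
#' package version) in the result.  Unknown stage names raise an error
#' before anything runs; a stage failure aborts with the failing stage
#' named, preserving the stages already computed.
#'
#' @param config A [run_config()].
#' @param stages Character vector of stage names (in order).
#' @param sim_params An [fcs_sim_params()] for the simulate stage; its
#'   seed is taken from `config` when unset.
#' @param background_rate Background count rate for the correct stage,
#'   counts/s.
#' @param volume A [confocal_volume_from_dye()] result for the
#'   concentration stage (defaults to the dye-calibrated 0.225 um / k
#'   volume implied by `sim_params`).
#' @return List of class `pipeline_result` with `provenance`, one entry
#'   per executed stage, and `summary` (plain list, JSON-ready).
#' @export
run_pipeline <- function(config, stages = .pipeline_stages,
                         sim_params = fcs_sim_params(duration = 2,
                                                     D = 20),
                         background_rate = 0,
                         volume = NULL) {
  stopifnot(inherits(config, "run_config"))
  unknown <- setdiff(stages, .pipeline_stages)
  if (length(unknown))
    stop_param("unknown stage name(s): ", paste(unknown, collapse = ", "))
  if (!identical(stages, .pipeline_stages[seq_along(stages)]))
    stop_param("stages must be a prefix of: ",
               paste(.pipeline_stages, collapse = " -> "))
  prov <- list(config_hash = config_hash(config), seed = config$seed,
               package_version =
                 as.character(utils::packageVersion("condensorheo")))
  out <- list(provenance = prov)
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(errorCondition(
        paste0("pipeline stage '", name, "' failed: ",
               conditionMessage(e)),
        class = c("condensorheo_stage_error", "error", "condition"))))
  }
  if (is.null(sim_params$seed)) sim_params$seed <- config$seed
  for (stage in stages) {
    if (stage == "simulate_fcs") {
      out$trace <- run_stage(stage, simulate_fcs_trace(sim_params))
    } else if (stage == "correct") {
      out$corrected <- run_stage(stage,
        correct_trace(out$trace, background_rate = background_rate))
    } else if (stage == "correlate") {
      out$curve <- run_stage(stage,
        compute_autocorrelation(out$corrected,
                                base_frequency = min(config$base_frequency,
                                  1 / out$corrected$bin_width)))
    } else if (stage == "fit") {
      out$fit <- run_stage(stage,
        fit_triplet_diffusion(out$curve,
                              fixed = list(theta_t =
                                sim_params$triplet_fraction,
                                tau_t = sim_params$triplet_lifetime,
                                k = sim_params$k)))
    } else if (stage == "concentration") {
      v <- if (is.null(volume))
        confocal_volume_from_dye(diffusion_time(sim_params$w0, 521.46),
                                 sim_params$k)
      else volume
      out$concentration <- run_stage(stage,
        concentration_from_fit(out$fit$params$N, v))
    }
  }
  out$summary <- list(
    provenance = prov,
    stages = stages,
    mean_rate = if (!is.null(out$trace)) mean_count_rate(out$trace),
    fit = if (!is.null(out$fit)) out$fit$params,
    C_nM = if (!is.null(out$concentration)) out$concentration$C_nM)
  class(out) <- "pipeline_result"
  out
}
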