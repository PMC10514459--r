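# Readers/writers for the package's tabular outputs, seed derivation and
# run manifests.

#' Write / read a simulated time series as tidy TSV
#'
#' Columns: replicate, year_bp, population, N, mean_fitness, het_per_kb,
#' f_roh_100kb, realized_load, masked_load, n_weak, n_moderate, n_strong,
#' n_very_strong (per-individual sample means), plus year_bp_full when the
#' run was rescaled.
#'
#' @param ts a `sim_timeseries` from [run_scenario()].
#' @param path output TSV path.
#' @return `path` invisibly / the read data.frame.
#' @export
write_timeseries <- function(ts, path) {
  utils::write.table(as.data.frame(ts), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_timeseries
#' @export
read_timeseries <- function(path) {
  out <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  class(out) <- c("sim_timeseries", "data.frame")
  out
}

#' Per-replicate seeds derived from a base seed
#'
#' Replicate r runs with seed `base_seed + r`; every source of randomness in
#' a run flows from that single seed through R's RNG.
#'
#' @param base_seed integer base seed.
#' @param replicates number of replicates.
#' @return integer vector of per-replicate seeds.
#' @export
derive_seeds <- function(base_seed, replicates) {
  as.integer(base_seed) + seq_len(replicates)
}

#' Run manifest
#'
#' A JSON-serialisable record sufficient to reproduce a run bit for bit:
#' command, configuration snapshot, package version, base seed and derived
#' per-replicate seeds, timestamp, and checksums of the outputs.
#'
#' @param command the command or function name executed.
#' @param config list snapshot of all parameters.
#' @param base_seed base seed.
#' @param replicates number of replicates.
#' @param outputs character vector of output file paths (checksummed).
#' @return a `run_manifest` list.
#' @export
run_manifest <- function(command, config, base_seed, replicates = 1L,
                         outputs = character()) {
  sums <- vapply(outputs, function(p)
    if (file.exists(p)) unname(tools::md5sum(p)) else NA_character_,
    character(1))
  structure(list(command = command,
                 package = "foundersim",
                 version = as.character(utils::packageVersion("foundersim")),
                 config = config,
                 base_seed = base_seed,
                 replicate_seeds = derive_seeds(base_seed, replicates),
                 timestamp = format(Sys.time(), tz = "UTC",
                                    "%Y-%m-%dT%H:%M:%SZ"),
                 outputs = as.list(sums)),
            class = "run_manifest")
}

#' Write a run manifest as JSON
#'
#' @param manifest a [run_manifest()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, force = TRUE)
  invisible(path)
}
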