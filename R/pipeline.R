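#' Knockout-subtracted occupancy score from raw tracks
#'
#' The full scoring chain for one sample: depth-normalise ChIP and input,
#' take the per-bin log2 ratio, robust z-score it, do the same for the
#' matched knockout (scar) sample, and subtract.
#'
#' @param chip,input Raw [occupancy_track()]s for the sample.
#' @param scar_chip,scar_input Raw tracks for the matched scar control
#'   (same medium and phase).
#' @param pseudocount Pseudocount for the log ratio (default 1).
#' @param target_total Depth-normalisation total (default 1e6).
#' @return A scar-subtracted [occupancy_track()].
#' @export
occupancy_score <- function(chip, input, scar_chip, scar_input,
                            pseudocount = 1, target_total = 1e6) {
  rz <- function(c_, i_) {
    robust_z(log_ratio(normalize_depth(c_, target_total),
                       normalize_depth(i_, target_total), pseudocount))
  }
  subtract_scar(rz(chip, input), rz(scar_chip, scar_input))
}

#' Simulate and score one sample in a single call
#'
#' Convenience wrapper used in examples and end-to-end tests: generates the
#' regulator ChIP and input tracks for `sample` plus the matched scar
#' control (same medium, phase and replicate indices), and returns the
#' scar-subtracted occupancy track.
#'
#' @param config A [sim_config()].
#' @param truth A [simulate_truth()] object.
#' @param sample A [sample_meta()].
#' @inheritParams occupancy_score
#' @return A scar-subtracted [occupancy_track()].
#' @export
simulate_scored_track <- function(config, truth, sample, pseudocount = 1) {
  pair <- simulate_chip_tracks(config, truth, sample)
  scar_meta <- sample_meta("scar", sample$medium, sample$phase,
                           sample$lineage, sample$biorep, sample$assay)
  scar_pair <- simulate_chip_tracks(config, truth, scar_meta)
  occupancy_score(pair$chip, pair$input, scar_pair$chip, scar_pair$input,
                  pseudocount = pseudocount)
}
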