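#' Sample metadata for one ChIP track
#'
#' Describes one sequencing sample along the axes of the experimental design:
#' the \code{lrp} genotype carried by the strain, the growth medium (minimal
#' medium, or the same medium supplemented with leucine/isoleucine/valine),
#' the growth phase at harvest, and the replicate structure.  Lineage
#' replicates are independently constructed strains with the same intended
#' genotype; biological replicates are independent cultures of one lineage.
#'
#' @param genotype One of \code{"WT"}, \code{"D114E"}, \code{"L136R"},
#'   \code{"dC11"}, \code{"scar"}.  \code{"scar"} marks the regulator-knockout
#'   control whose signal is subtracted from all other tracks.
#' @param medium \code{"Min"} (minimal medium) or \code{"LIV"} (minimal medium
#'   plus leucine, isoleucine and valine).
#' @param phase \code{"Log"} (mid-exponential) or \code{"Stat"} (stationary).
#' @param lineage,biorep Small positive integers identifying the lineage
#'   replicate and the biological replicate within it.
#' @param assay \code{"Lrp"} for regulator ChIP or \code{"RNAP"} for RNA
#'   polymerase ChIP.
#' @return An object of class \code{"sample_meta"} (a named list).
#' @export
sample_meta <- function(genotype = "WT", medium = "Min", phase = "Log",
                        lineage = 1L, biorep = 1L, assay = "Lrp") {
  genotype <- match.arg(genotype, c("WT", "D114E", "L136R", "dC11", "scar"))
  medium <- match.arg(medium, c("Min", "LIV"))
  phase <- match.arg(phase, c("Log", "Stat"))
  assay <- match.arg(assay, c("Lrp", "RNAP"))
  stopifnot(lineage >= 1, biorep >= 1)
  structure(list(genotype = genotype, medium = medium, phase = phase,
                 lineage = as.integer(lineage), biorep = as.integer(biorep),
                 assay = assay),
            class = "sample_meta")
}

#' @export
format.sample_meta <- function(x, ...) {
  sprintf("%s/%s/%s/L%d.B%d/%s", x$genotype, x$medium, x$phase,
          x$lineage, x$biorep, x$assay)
}

#' @export
print.sample_meta <- function(x, ...) {
  cat("<sample_meta>", format(x), "\n")
  invisible(x)
}

track_stages <- c("raw", "log_ratio", "rz", "scar_subtracted")

#' Binned occupancy track
#'
#' The substrate of all occupancy scoring: a fixed-width binned signal over a
#' single (circular) replicon, together with sample metadata and a processing
#' stage.  Stages advance only forward through
#' \code{raw -> log_ratio -> rz -> scar_subtracted}.
#'
#' @param values Numeric vector, one value per bin, ordered along the replicon.
#' @param bin_size Bin width in bases.
#' @param replicon Replicon identifier (a string).
#' @param meta A [sample_meta()] object (optional).
#' @param stage Processing stage; new tracks are normally \code{"raw"}.
#' @return An object of class \code{"occupancy_track"}.
#' @export
occupancy_track <- function(values, bin_size = 25L, replicon = "chr",
                            meta = NULL, stage = "raw") {
  stage <- match.arg(stage, track_stages)
  stopifnot(is.numeric(values), length(values) >= 1, bin_size >= 1)
  if (!is.null(meta) && !inherits(meta, "sample_meta")) {
    stop("`meta` must be a sample_meta object")
  }
  structure(list(values = as.numeric(values), bin_size = as.integer(bin_size),
                 replicon = replicon, meta = meta, stage = stage),
            class = "occupancy_track")
}

#' @export
print.occupancy_track <- function(x, ...) {
  cat(sprintf("<occupancy_track> %s: %d bins x %d bp (stage %s)%s\n",
              x$replicon, length(x$values), x$bin_size, x$stage,
              if (is.null(x$meta)) "" else paste0(" [", format(x$meta), "]")))
  invisible(x)
}

#' @export
length.occupancy_track <- function(x) length(x$values)

#' Genome length spanned by a track, in bases
#' @param track An [occupancy_track()].
#' @export
track_span <- function(track) length(track$values) * track$bin_size

check_compatible <- function(a, b) {
  if (!identical(a$replicon, b$replicon)) {
    stop("tracks are on different replicons: ", a$replicon, " vs ", b$replicon)
  }
  if (a$bin_size != b$bin_size) stop("tracks have different bin sizes")
  if (length(a$values) != length(b$values)) {
    stop("tracks have different lengths: ", length(a$values), " vs ",
         length(b$values))
  }
  invisible(TRUE)
}

stage_at_least <- function(track, stage) {
  match(track$stage, track_stages) >= match(stage, track_stages)
}

#' Scale a raw track to a target total signal
#'
#' Sequencing-depth normalisation: multiplies the track so that its total
#' signal equals \code{target_total}.  ChIP and input tracks are scaled to a
#' common total before forming their log-ratio, so that "relative to the
#' input" compares depth-matched signals.
#'
#' @param track A raw [occupancy_track()].
#' @param target_total Desired total signal; default \code{1e6} (signal per
#'   million).
#' @return The rescaled track (still stage \code{"raw"}).
#' @export
normalize_depth <- function(track, target_total = 1e6) {
  stopifnot(inherits(track, "occupancy_track"))
  tot <- sum(track$values)
  if (tot <= 0) stop("track has non-positive total signal; cannot normalize")
  track$values <- track$values * (target_total / tot)
  track
}

#' Per-bin log2 ratio of ChIP over input
#'
#' Computes \code{log2((chip + pseudocount) / (input + pseudocount))} per bin.
#' The pseudocount stabilises empty bins; apply [normalize_depth()] to both
#' tracks first if they differ in sequencing depth.
#'
#' @param chip,input [occupancy_track()]s on the same replicon with identical
#'   binning.
#' @param pseudocount Positive value added to both numerator and denominator.
#' @return A track at stage \code{"log_ratio"} carrying `chip`'s metadata.
#' @export
log_ratio <- function(chip, input, pseudocount = 1) {
  stopifnot(inherits(chip, "occupancy_track"), inherits(input, "occupancy_track"))
  check_compatible(chip, input)
  if (pseudocount <= 0) stop("pseudocount must be > 0")
  if (any(chip$values < 0) || any(input$values < 0)) {
    stop("negative coverage values are not allowed in log_ratio()")
  }
  out <- chip
  out$values <- log2((chip$values + pseudocount) / (input$values + pseudocount))
  out$stage <- "log_ratio"
  out
}

#' Robust z-score of a log-ratio track
#'
#' Centres by the median and scales by the normal-consistent median absolute
#' deviation (MAD with constant 1.4826), the "rz" in the rz-log-ratio
#' occupancy statistic.  The output track has median 0 and normalised MAD 1.
#'
#' @param track A track at stage \code{"log_ratio"}.
#' @return A track at stage \code{"rz"}.
#' @export
robust_z <- function(track) {
  stopifnot(inherits(track, "occupancy_track"))
  if (track$stage != "log_ratio") {
    stop("robust_z() expects a log_ratio-stage track, got stage '",
         track$stage, "'")
  }
  med <- stats::median(track$values)
  s <- stats::mad(track$values, center = med)  # constant 1.4826 by default
  if (s == 0) {
    stop("MAD of track is zero (more than half the bins share one value); ",
         "robust z-score is undefined")
  }
  track$values <- (track$values - med) / s
  track$stage <- "rz"
  track
}

#' Subtract the knockout (scar) control track
#'
#' The scar strain carries no regulator, so its rz-log-ratio track measures
#' condition-specific artefacts; subtracting it bin-by-bin leaves
#' regulator-specific occupancy.  Both tracks must be at stage \code{"rz"}
#' and, unless \code{force = TRUE}, from the same medium and phase.
#'
#' @param sample_rz,scar_rz Tracks at stage \code{"rz"}.
#' @param force Skip the medium/phase metadata match check.
#' @return A track at stage \code{"scar_subtracted"}.
#' @export
subtract_scar <- function(sample_rz, scar_rz, force = FALSE) {
  stopifnot(inherits(sample_rz, "occupancy_track"),
            inherits(scar_rz, "occupancy_track"))
  check_compatible(sample_rz, scar_rz)
  if (sample_rz$stage != "rz" || scar_rz$stage != "rz") {
    stop("subtract_scar() expects both tracks at stage 'rz'")
  }
  if (!force && !is.null(sample_rz$meta) && !is.null(scar_rz$meta)) {
    if (sample_rz$meta$medium != scar_rz$meta$medium ||
        sample_rz$meta$phase != scar_rz$meta$phase) {
      stop("sample and scar tracks are from different conditions (",
           format(sample_rz$meta), " vs ", format(scar_rz$meta),
           "); use force = TRUE to override")
    }
  }
  out <- sample_rz
  out$values <- sample_rz$values - scar_rz$values
  out$stage <- "scar_subtracted"
  out
}

#' Average tracks within replicate groups
#'
#' Per-bin arithmetic mean of tracks sharing the same values of the grouping
#' metadata keys.  By default lineages are kept separate (each lineage
#' replicate forms its own group) and biological replicates within a lineage
#' are averaged.
#'
#' @param tracks A list of [occupancy_track()]s at a common stage, each with
#'   metadata.
#' @param group_by Character vector of `sample_meta` field names defining the
#'   groups.
#' @return A named list of averaged tracks, one per group; names are the
#'   concatenated group keys.
#' @export
average_replicates <- function(tracks,
                               group_by = c("genotype", "medium", "phase",
                                            "lineage", "assay")) {
  stopifnot(length(tracks) >= 1)
  if (any(!vapply(tracks, inherits, logical(1), "occupancy_track"))) {
    stop("all elements must be occupancy_track objects")
  }
  keys <- vapply(tracks, function(tr) {
    if (is.null(tr$meta)) stop("average_replicates() needs track metadata")
    paste(vapply(group_by, function(k) as.character(tr$meta[[k]]),
                 character(1)), collapse = ".")
  }, character(1))
  groups <- split(seq_along(tracks), keys)
  out <- lapply(groups, function(idx) {
    grp <- tracks[idx]
    ref <- grp[[1]]
    for (tr in grp[-1]) check_compatible(ref, tr)
    ref$values <- Reduce(`+`, lapply(grp, `[[`, "values")) / length(grp)
    ref$meta$biorep <- NA_integer_
    ref
  })
  out
}
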