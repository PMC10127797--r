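# Readers and writers.  Standard formats go through rtracklayer; internal
# coordinates are 0-based half-open (BED-native); GFF3 is converted at the
# boundary.  Readers validate and reject rather than silently coerce.

#' Read a bedGraph coverage file into an occupancy track
#'
#' Validates that records are sorted, non-overlapping and non-negative, then
#' re-bins to `bin_size` by length-weighted mean (positions not covered by
#' any record contribute signal 0 to their bin).
#'
#' @param path Path to a bedGraph file.
#' @param bin_size Output bin width in bases.
#' @param replicon_length Optional replicon length; default the largest
#'   record end rounded up to a bin multiple.
#' @param meta Optional [sample_meta()] attached to the track.
#' @param allow_negative Permit negative values (for re-reading derived
#'   occupancy statistics rather than raw coverage).  Default FALSE.
#' @param stage Stage to stamp on the returned track (default \code{"raw"}).
#' @return An [occupancy_track()].
#' @export
read_bedgraph <- function(path, bin_size = 25, replicon_length = NULL,
                          meta = NULL, allow_negative = FALSE,
                          stage = "raw") {
  gr <- rtracklayer::import(path, format = "bedGraph")
  if (length(gr) == 0) stop("no records in ", path)
  if (length(unique(as.character(GenomicRanges::seqnames(gr)))) > 1) {
    stop("bedGraph spans multiple replicons; expected exactly one")
  }
  s <- GenomicRanges::start(gr) - 1L   # to 0-based half-open
  e <- GenomicRanges::end(gr)
  v <- gr$score
  ord <- order(s)
  s <- s[ord]; e <- e[ord]; v <- v[ord]
  if (!allow_negative && any(v < 0)) {
    stop("negative coverage at record ", which(v < 0)[1], " of ", path)
  }
  if (length(s) > 1 && any(s[-1] < e[-length(e)])) {
    bad <- which(s[-1] < e[-length(e)])[1] + 1
    stop("overlapping records at record ", bad, " of ", path)
  }
  if (is.null(replicon_length)) {
    replicon_length <- ceiling(max(e) / bin_size) * bin_size
  }
  if (replicon_length %% bin_size != 0) {
    stop("replicon_length must be a multiple of bin_size")
  }
  n_bins <- replicon_length / bin_size
  acc <- numeric(n_bins)
  for (i in seq_along(s)) {
    b0 <- floor(s[i] / bin_size) + 1
    b1 <- ceiling(e[i] / bin_size)
    for (b in b0:b1) {
      lo <- max(s[i], (b - 1) * bin_size)
      hi <- min(e[i], b * bin_size)
      if (hi > lo) acc[b] <- acc[b] + v[i] * (hi - lo)
    }
  }
  occupancy_track(acc / bin_size, bin_size = bin_size,
                  replicon = as.character(GenomicRanges::seqnames(gr)[1]),
                  meta = meta, stage = stage)
}

#' Write an occupancy track as bedGraph
#'
#' @param track An [occupancy_track()].
#' @param path Output path.
#' @export
write_bedgraph <- function(track, path) {
  n <- length(track$values)
  gr <- GenomicRanges::GRanges(
    seqnames = track$replicon,
    ranges = IRanges::IRanges(start = (seq_len(n) - 1L) * track$bin_size + 1L,
                              width = track$bin_size),
    score = track$values)
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Read a TU/TSS annotation from GFF3 or BED
#'
#' Accepts GFF3 (1-based, converted to internal 0-based half-open) or BED
#' (already 0-based).  TSS features are taken from records of type
#' \code{"TSS"} when present; otherwise each transcription-unit record
#' contributes a TSS at its strand-appropriate end.
#'
#' @param path Path to a `.gff3`/`.gff` or `.bed` file.
#' @return List with `tss` and `tus` data frames (as in
#'   [simulate_annotation()]).
#' @export
read_annotation <- function(path) {
  is_gff <- grepl("\\.gff3?$", path, ignore.case = TRUE)
  gr <- rtracklayer::import(path, format = if (is_gff) "GFF3" else "BED")
  strand <- as.character(GenomicRanges::strand(gr))
  if (any(strand == "*")) {
    stop("record(s) without strand: ", paste(which(strand == "*"),
                                             collapse = ", "))
  }
  start0 <- GenomicRanges::start(gr) - 1L
  end0 <- GenomicRanges::end(gr)  # GRanges end is 1-based closed == 0-based open
  type <- if (!is.null(gr$type)) as.character(gr$type) else rep("TU", length(gr))
  name <- if (!is.null(gr$ID)) as.character(gr$ID) else
    if (!is.null(gr$name)) as.character(gr$name) else
      sprintf("TU%04d", seq_along(gr))
  is_tss <- type %in% c("TSS", "tss")
  tu_sel <- !is_tss
  tus <- data.frame(tu_id = name[tu_sel], start = start0[tu_sel],
                    end = end0[tu_sel], strand = strand[tu_sel],
                    gene = name[tu_sel], stringsAsFactors = FALSE)
  if (any(is_tss)) {
    tss <- data.frame(tu_id = name[is_tss], position = start0[is_tss],
                      strand = strand[is_tss], stringsAsFactors = FALSE)
  } else {
    tss <- data.frame(tu_id = tus$tu_id,
                      position = ifelse(tus$strand == "+", tus$start,
                                        tus$end - 1L),
                      strand = tus$strand, stringsAsFactors = FALSE)
  }
  list(tss = tss, tus = tus)
}

#' Write an annotation as GFF3
#'
#' @param annotation List with `tus` (and `tss`) data frames.
#' @param path Output path.
#' @param replicon Replicon name.
#' @export
write_annotation_gff3 <- function(annotation, path, replicon = "chr") {
  tus <- annotation$tus
  gr <- GenomicRanges::GRanges(
    seqnames = replicon,
    ranges = IRanges::IRanges(start = tus$start + 1L, end = tus$end),
    strand = tus$strand, type = "transcript", ID = tus$tu_id)
  rtracklayer::export(gr, path, format = "GFF3")
  invisible(path)
}

#' Write peaks as BED6
#'
#' Score column carries the peak occupancy; the name column the site id.
#'
#' @param peaks Peak data frame (needs start, end; score and replicon
#'   optional).
#' @param path Output path.
#' @export
write_peaks_bed <- function(peaks, path) {
  n <- nrow(peaks)
  df <- data.frame(
    chrom = if (!is.null(peaks$replicon)) peaks$replicon else "chr",
    start = as.integer(peaks$start), end = as.integer(peaks$end),
    name = if (!is.null(peaks$site_id)) peaks$site_id else
      sprintf("peak%04d", seq_len(n)),
    score = if (!is.null(peaks$score)) round(peaks$score, 3) else 0,
    strand = ".")
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED6 peak file
#' @param path Path to a BED file written by [write_peaks_bed()].
#' @return Peak data frame with replicon, start, end, site_id, score.
#' @export
read_peaks_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  data.frame(replicon = df[[1]], start = as.integer(df[[2]]),
             end = as.integer(df[[3]]), site_id = df[[4]],
             score = as.numeric(df[[5]]), stringsAsFactors = FALSE)
}

#' Write a posterior summary table as TSV
#'
#' Column names follow the reporting convention of the quantification
#' models: `value`, `ci.lo`, `ci.hi`, and `P_diff` / `log10_bf` where
#' present.
#'
#' @param summary A \code{posterior_summary} data frame.
#' @param path Output path.
#' @export
write_posterior_tsv <- function(summary, path) {
  utils::write.table(as.data.frame(summary), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a run manifest recording parameters and seeds
#'
#' @param config Named list of all parameters used (must include every seed).
#' @param path Output JSON path.
#' @export
write_manifest <- function(config, path) {
  keep <- config[!vapply(config, is.function, logical(1))]
  manifest <- list(
    parameters = keep,
    seeds = keep[grepl("seed", names(keep))],
    config_hash = sum(utf8ToInt(paste(
      names(keep), vapply(keep, function(x) paste(format(x), collapse = ","),
                          character(1)),
      collapse = ";"))))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a run configuration from YAML
#'
#' @param path YAML file of pipeline parameters.
#' @return Named list; round-trips through [write_run_config()] unchanged.
#' @export
read_run_config <- function(path) yaml::read_yaml(path)

#' Write a run configuration to YAML
#' @param config Named list.
#' @param path Output path.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}
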