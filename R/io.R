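#' Read / write genome FASTA
#'
#' @param path FASTA file path.
#' @return [Biostrings::DNAStringSet].
#' @export
read_genome_fasta <- function(path) Biostrings::readDNAStringSet(path)

#' @rdname read_genome_fasta
#' @param genome A [Biostrings::DNAStringSet].
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path)
  invisible(path)
}

#' Read / write the TE segment annotation TSV
#'
#' Columns: chrom, start, end, strand, te_id, family, segment_type
#' (1-based closed coordinates, tab-separated, with header).
#'
#' @param path TSV path.
#' @return data.table.
#' @export
read_te_annotation <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          showProgress = FALSE)
  req <- c("chrom", "start", "end", "strand", "te_id", "family",
           "segment_type")
  if (!all(req %in% names(dt)))
    stop("annotation lacks required columns: ",
         paste(setdiff(req, names(dt)), collapse = ", "))
  data.table::setorder(dt, chrom, start)
  dt[]
}

#' @rdname read_te_annotation
#' @param annotation Annotation data.table.
#' @export
write_te_annotation <- function(annotation, path) {
  data.table::fwrite(annotation, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Read / write a bedGraph coverage track
#'
#' On disk bedGraph is 0-based half-open; in memory intervals are 1-based
#' closed.
#'
#' @param path bedGraph path.
#' @param library_size Optional mapped-read count for [normalize_cpm()].
#' @return A [coverage_track()].
#' @export
read_bedgraph <- function(path, library_size = NULL) {
  dt <- data.table::fread(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "start", "end", "depth"),
                          showProgress = FALSE)
  dt[, start := as.integer(start) + 1L]
  dt[, end := as.integer(end)]
  coverage_track(dt, library_size)
}

#' @rdname read_bedgraph
#' @param track A [coverage_track()].
#' @export
write_bedgraph <- function(track, path) {
  dt <- track$data[, .(chrom, start = start - 1L, end, depth)]
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write BED6 intervals
#'
#' On disk BED is 0-based half-open; in memory 1-based closed.
#'
#' @param path BED path.
#' @return data.table: chrom, start, end, name, score, strand.
#' @export
read_bed <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = FALSE,
                          showProgress = FALSE)
  data.table::setnames(dt, seq_len(min(6L, ncol(dt))),
                       c("chrom", "start", "end", "name", "score",
                         "strand")[seq_len(min(6L, ncol(dt)))])
  dt[, start := as.integer(start) + 1L]
  dt[, end := as.integer(end)]
  dt[]
}

#' @rdname read_bed
#' @param intervals data.table with chrom/start/end and optional
#'   name/score/strand.
#' @export
write_bed <- function(intervals, path) {
  dt <- data.table::as.data.table(intervals)
  if (!"name" %in% names(dt)) dt[, name := "."]
  if (!"score" %in% names(dt)) dt[, score := 0L]
  if (!"strand" %in% names(dt)) dt[, strand := "."]
  out <- dt[, .(chrom, start = start - 1L, end, name, score, strand)]
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write / read the simulation ground truth as JSON
#'
#' @param truth Ground-truth list from [simulate_genome()].
#' @param path JSON path.
#' @return `path` (write) or the reconstructed truth list (read).
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, dataframe = "columns", digits = NA,
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_dt <- function(x) {
    dt <- data.table::as.data.table(x)
    for (cl in intersect(c("start", "end", "n_copies"), names(dt)))
      data.table::set(dt, j = cl, value = as.integer(dt[[cl]]))
    if ("targeted" %in% names(dt))
      data.table::set(dt, j = "targeted", value = as.logical(dt$targeted))
    dt
  }
  truth <- list(families = as_dt(raw$families),
                target_family = raw$target_family,
                te = as_dt(raw$te), motifs = as_dt(raw$motifs),
                arrays = as_dt(raw$arrays), hypo = as_dt(raw$hypo))
  if (!is.null(raw$evolution)) truth$evolution <- raw$evolution
  truth
}

#' Write an aligned FASTA file
#'
#' @param alignment Named character vector of equal-length aligned
#'   sequences (`-` gaps allowed).
#' @param path Output path.
#' @export
write_aligned_fasta <- function(alignment, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(alignment))
    writeLines(c(paste0(">", nm), alignment[[nm]]), con)
  invisible(path)
}

#' @rdname write_aligned_fasta
#' @return Named character vector of aligned sequences.
#' @export
read_aligned_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  stats::setNames(as.character(x), names(x))
}
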