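#' Read a per-cytosine methylation report (bismark CX dialect)
#'
#' Seven tab-separated columns: chrom, 1-based position, strand (+/-),
#' methylated count, unmethylated count, context (CG/CHG/CHH), trinucleotide.
#' Records are returned sorted by (chrom, pos); malformed lines raise an
#' error naming the offending line number.
#'
#' @param path Path to a CX report TSV (no header).
#' @return data.table: chrom, pos, strand, meth, unmeth, context,
#'   trinucleotide.
#' @export
read_cx_report <- function(path) {
  if (file.exists(path) && file.size(path) == 0L)
    return(data.table::data.table(chrom = character(), pos = integer(),
                                  strand = character(), meth = integer(),
                                  unmeth = integer(), context = character(),
                                  trinucleotide = character()))
  dt <- data.table::fread(path, sep = "\t", header = FALSE,
                          colClasses = list(character = c(1, 3, 6, 7),
                                            integer = c(2, 4, 5)),
                          col.names = c("chrom", "pos", "strand", "meth",
                                        "unmeth", "context",
                                        "trinucleotide"),
                          showProgress = FALSE)
  if (nrow(dt) == 0L) return(dt)
  bad_ctx <- which(!dt$context %in% c("CG", "CHG", "CHH"))
  if (length(bad_ctx))
    stop("unknown context '", dt$context[bad_ctx[1]], "' at line ",
         bad_ctx[1], " of ", path)
  bad_strand <- which(!dt$strand %in% c("+", "-"))
  if (length(bad_strand))
    stop("invalid strand at line ", bad_strand[1], " of ", path)
  bad_n <- which(is.na(dt$meth) | is.na(dt$unmeth) |
                   dt$meth < 0L | dt$unmeth < 0L)
  if (length(bad_n))
    stop("negative or missing counts at line ", bad_n[1], " of ", path)
  bad_pos <- which(is.na(dt$pos) | dt$pos < 1L)
  if (length(bad_pos))
    stop("invalid position at line ", bad_pos[1], " of ", path)
  data.table::setorder(dt, chrom, pos)
  dt[]
}

#' Write a per-cytosine report in the CX dialect
#'
#' @param records Cytosine data.table as returned by [read_cx_report()] or
#'   [simulate_methylomes()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_cx_report <- function(records, path) {
  data.table::fwrite(records[, .(chrom, pos, strand, meth, unmeth, context,
                                 trinucleotide)],
                     path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}
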