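#' Enumerate cytosine positions and contexts on both strands of a genome
#'
#' Contexts follow the plant convention: CG, CHG, CHH (H = A/C/T), read
#' 5'->3' on the cytosine's own strand. Cytosines within 2 bp of a sequence
#' end, where the trinucleotide is incomplete, are skipped.
#'
#' @param genome A [Biostrings::DNAStringSet].
#' @return data.table: chrom, pos (1-based), strand, context, trinucleotide.
#' @export
genome_cytosines <- function(genome) {
  out <- vector("list", length(genome))
  for (ci in seq_along(genome)) {
    ch <- strsplit(as.character(genome[[ci]]), "")[[1]]
    L <- length(ch)
    if (L < 3L) next
    ## + strand: C at i, context from i+1, i+2
    ip <- which(ch == "C")
    ip <- ip[ip <= L - 2L]
    n1 <- ch[ip + 1L]; n2 <- ch[ip + 2L]
    ctx_p <- ifelse(n1 == "G", "CG", ifelse(n2 == "G", "CHG", "CHH"))
    tri_p <- paste0("C", n1, n2)
    ## - strand: G at i on the + sequence; context from i-1, i-2 complemented
    im <- which(ch == "G")
    im <- im[im >= 3L]
    comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
    p1 <- comp[ch[im - 1L]]; p2 <- comp[ch[im - 2L]]
    ctx_m <- ifelse(p1 == "G", "CG", ifelse(p2 == "G", "CHG", "CHH"))
    tri_m <- paste0("C", p1, p2)
    out[[ci]] <- data.table::data.table(
      chrom = names(genome)[ci],
      pos = c(ip, im),
      strand = rep(c("+", "-"), c(length(ip), length(im))),
      context = c(ctx_p, ctx_m),
      trinucleotide = c(tri_p, tri_m))
  }
  dt <- data.table::rbindlist(out)
  data.table::setorder(dt, chrom, pos)
  dt[]
}

## logical: which positions in `dt` (chrom,pos) fall inside intervals `iv`
## (chrom,start,end; 1-based closed)
pos_in_intervals <- function(dt, iv) {
  if (nrow(iv) == 0L) return(rep(FALSE, nrow(dt)))
  q <- GenomicRanges::GRanges(dt$chrom, IRanges::IRanges(dt$pos, dt$pos))
  s <- GenomicRanges::GRanges(iv$chrom, IRanges::IRanges(iv$start, iv$end))
  IRanges::overlapsAny(q, s)
}

#' Simulate paired wild-type and transgenic methylomes
#'
#' For every cytosine, the total read count is Poisson(`mean_coverage`) and
#' the methylated count Binomial(total, p). In the wild type p is the
#' configured per-context level inside TEs and a low background level
#' elsewhere. In the transgenic condition, TEs of the targeted family lose CG
#' methylation only within `hypo_local_radius` of their planted motif arrays,
#' while CHG/CHH levels drop across the whole element; other families and the
#' background are untouched.
#'
#' @param genome,annotation,truth Output of [simulate_genome()].
#' @param config The same [sim_config()].
#' @return List with `wt` and `treated` cytosine-report data.tables
#'   (chrom, pos, strand, meth, unmeth, context, trinucleotide).
#' @export
simulate_methylomes <- function(genome, annotation, truth, config) {
  set.seed(stage_seed(config$seed, "methylome"))
  cyt <- genome_cytosines(genome)
  n <- nrow(cyt)

  in_te <- pos_in_intervals(cyt, te_intervals(annotation))
  p_wt <- unname(config$bg_meth_levels[cyt$context])
  p_wt[in_te] <- unname(config$wt_meth_levels[cyt$context[in_te]])

  p_tr <- p_wt
  drops <- c(CG = config$hypo_cg_drop, CHG = config$hypo_chg_drop,
             CHH = config$hypo_chh_drop)
  for (ctx in c("CG", "CHG", "CHH")) {
    sel <- cyt$context == ctx &
      pos_in_intervals(cyt, truth$hypo[context == ctx])
    p_tr[sel] <- pmax(p_tr[sel] - drops[[ctx]], 0.01)
  }

  draw <- function(p) {
    total <- stats::rpois(n, config$mean_coverage)
    meth <- stats::rbinom(n, total, p)
    data.table::data.table(chrom = cyt$chrom, pos = cyt$pos,
                           strand = cyt$strand, meth = meth,
                           unmeth = total - meth, context = cyt$context,
                           trinucleotide = cyt$trinucleotide)
  }
  list(wt = draw(p_wt), treated = draw(p_tr))
}
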