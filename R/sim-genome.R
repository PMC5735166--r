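#' Simulate a genome with TE families carrying planted motif arrays
#'
#' Builds a uniform-random background genome and places non-overlapping TE
#' copies on it. Each copy is split into non-coding and coding segments; one
#' non-coding segment carries the family's degenerate motif as a tandem array
#' in consistent orientation on the TE's annotated strand (one concrete motif
#' instance per repeat unit). Coding segments are scrubbed of any match to the
#' family motif on either strand.
#'
#' @param config A [sim_config()].
#' @return List with `genome` (a [Biostrings::DNAStringSet]), `annotation`
#'   (data.table: chrom, start, end, strand, te_id, family, segment_type;
#'   1-based closed coordinates) and `truth` (list with planted motif
#'   positions, arrays, per-context hypomethylated intervals, TE table and
#'   family motifs/units).
#' @export
simulate_genome <- function(config) {
  validate_sim_config(config)
  set.seed(stage_seed(config$seed, "genome"))
  nfam <- config$n_te_families
  ncopy <- config$copies_per_family
  nte <- nfam * ncopy
  ulen <- config$repeat_unit_length

  ## one repeat unit per family, carrying a concrete motif instance
  fam <- data.table::data.table(
    family = paste0("FAM", seq_len(nfam)),
    motif = config$motif_per_family
  )
  units <- character(nfam); uoff <- integer(nfam)
  for (f in seq_len(nfam)) {
    w <- nchar(fam$motif[f])
    if (ulen < w + 2L) stop("repeat_unit_length too small for family motif")
    inst <- sample(iupac_instances(fam$motif[f]), 1L)
    off <- sample.int(ulen - w + 1L, 1L)
    ## target loci are methylated in the wild type, so the unit must carry
    ## CG sites for local CG hypomethylation to exist at all
    repeat {
      u <- strsplit(random_dna(ulen), "")[[1]]
      u[off:(off + w - 1L)] <- strsplit(inst, "")[[1]]
      ustr <- paste(u, collapse = "")
      ncg <- sum(unlist(gregexpr("CG", ustr, fixed = TRUE)) > 0L)
      if (ncg >= 2L) break
    }
    units[f] <- ustr; uoff[f] <- off
  }
  fam$unit <- units; fam$unit_motif_offset <- uoff

  ## build each TE copy in local (TE 5'->3') orientation
  copies <- vector("list", nte)
  te_meta <- data.table::data.table(
    te_id = sprintf("TE%03d", seq_len(nte)),
    family = rep(fam$family, each = ncopy),
    strand = sample(c("+", "-"), nte, replace = TRUE),
    length = resample(seq(config$te_length_range[1],
                          config$te_length_range[2]), nte, replace = TRUE)
  )
  nc_left <- 300L; nc_pre <- 150L; nc_post <- 150L
  for (i in seq_len(nte)) {
    f <- match(te_meta$family[i], fam$family)
    k <- resample(seq(config$repeat_copies_range[1],
                      config$repeat_copies_range[2]))
    ## per-copy repeat unit: non-motif sites diverge from the family
    ## consensus (units within one copy's array evolve together), while the
    ## embedded motif stays intact; its concrete instance (e.g. C- vs
    ## T-type) is drawn per unit, as instance types mix within real arrays
    w <- nchar(fam$motif[f])
    uc <- strsplit(fam$unit[f], "")[[1]]
    mspan <- fam$unit_motif_offset[f]:(fam$unit_motif_offset[f] + w - 1L)
    mut <- setdiff(which(runif(ulen) < config$unit_divergence), mspan)
    for (mpos in mut)
      uc[mpos] <- sample(setdiff(c("A", "C", "G", "T"), uc[mpos]), 1L)
    inst <- sample(iupac_instances(fam$motif[f]), k, replace = TRUE)
    arr <- paste(vapply(inst, function(ins) {
      u1 <- uc; u1[mspan] <- strsplit(ins, "")[[1]]
      paste(u1, collapse = "")
    }, character(1)), collapse = "")
    alen <- nchar(arr)
    clen <- te_meta$length[i] - nc_left - nc_pre - alen - nc_post
    if (clen < 100L) stop("te_length_range too small for segment layout")
    coding <- random_dna(clen)
    rx <- paste0("(?=", iupac_to_regex(fam$motif[f]), ")")
    rxr <- paste0("(?=", iupac_to_regex(revcomp(fam$motif[f])), ")")
    for (iter in 1:50) {
      hit <- c(unlist(gregexpr(rx, coding, perl = TRUE)),
               unlist(gregexpr(rxr, coding, perl = TRUE)))
      hit <- hit[hit > 0]
      if (!length(hit)) break
      cc <- strsplit(coding, "")[[1]]
      for (h in hit) {
        span <- h:min(h + nchar(fam$motif[f]) - 1L, clen)
        cc[span] <- sample(c("A", "C", "G", "T"), length(span), replace = TRUE)
      }
      coding <- paste(cc, collapse = "")
    }
    seq_local <- paste0(random_dna(nc_left), coding, random_dna(nc_pre),
                        arr, random_dna(nc_post))
    ## local segment table and motif coordinates (1-based closed)
    seg <- data.table::data.table(
      start = c(1L, nc_left + 1L, nc_left + clen + 1L),
      end = c(nc_left, nc_left + clen, te_meta$length[i]),
      segment_type = c("noncoding", "coding", "noncoding")
    )
    a_start <- nc_left + clen + nc_pre + 1L
    m_start <- a_start + fam$unit_motif_offset[f] - 1L + (0:(k - 1L)) * ulen
    copies[[i]] <- list(seq = seq_local, seg = seg, n_copies = k,
                        array = c(a_start, a_start + alen - 1L),
                        motif_starts = m_start, motif_w = nchar(fam$motif[f]))
  }

  ## place TEs along the chromosome with random intergenic gaps
  total_te <- sum(te_meta$length)
  spare <- config$genome_length - total_te
  if (spare < (nte + 1L) * 200L)
    stop("genome_length too short to place requested TEs")
  gw <- runif(nte + 1L)
  gaps <- floor(spare * gw / sum(gw))
  gaps[nte + 1L] <- spare - sum(gaps[seq_len(nte)])
  ord <- sample.int(nte)  # interleave families along the genome

  pieces <- character(2L * nte + 1L)
  ann <- vector("list", nte)
  motifs <- vector("list", nte)
  arrays <- vector("list", nte)
  cursor <- 0L
  te_start <- integer(nte); te_end <- integer(nte)
  for (j in seq_len(nte)) {
    i <- ord[j]
    pieces[2L * j - 1L] <- random_dna(gaps[j])
    cursor <- cursor + gaps[j]
    cp <- copies[[i]]
    L <- te_meta$length[i]
    s0 <- cursor + 1L
    te_start[i] <- s0; te_end[i] <- cursor + L
    if (te_meta$strand[i] == "+") {
      pieces[2L * j] <- cp$seq
      seg_g <- data.table::data.table(start = s0 + cp$seg$start - 1L,
                                      end = s0 + cp$seg$end - 1L,
                                      segment_type = cp$seg$segment_type)
      m_g <- s0 + cp$motif_starts - 1L
      arr_g <- s0 + cp$array - 1L
    } else {
      pieces[2L * j] <- revcomp(cp$seq)
      ## local [a,b] maps to genome [s0 + L - b, s0 + L - a]
      seg_g <- data.table::data.table(start = s0 + L - cp$seg$end,
                                      end = s0 + L - cp$seg$start,
                                      segment_type = cp$seg$segment_type)
      data.table::setorder(seg_g, start)
      m_end_local <- cp$motif_starts + cp$motif_w - 1L
      m_g <- s0 + L - m_end_local
      arr_g <- c(s0 + L - cp$array[2], s0 + L - cp$array[1])
    }
    ann[[i]] <- data.table::data.table(
      chrom = "chr1", start = seg_g$start, end = seg_g$end,
      strand = te_meta$strand[i], te_id = te_meta$te_id[i],
      family = te_meta$family[i], segment_type = seg_g$segment_type)
    motifs[[i]] <- data.table::data.table(
      te_id = te_meta$te_id[i], family = te_meta$family[i], chrom = "chr1",
      start = sort(m_g), end = sort(m_g) + cp$motif_w - 1L,
      strand = te_meta$strand[i])
    arrays[[i]] <- data.table::data.table(
      te_id = te_meta$te_id[i], family = te_meta$family[i], chrom = "chr1",
      start = arr_g[1], end = arr_g[2], strand = te_meta$strand[i],
      n_copies = cp$n_copies)
    cursor <- cursor + L
  }
  pieces[2L * nte + 1L] <- random_dna(gaps[nte + 1L])
  genome_seq <- paste(pieces, collapse = "")
  stopifnot(nchar(genome_seq) == config$genome_length)

  annotation <- data.table::rbindlist(ann)
  data.table::setorder(annotation, chrom, start)
  truth_motifs <- data.table::rbindlist(motifs)
  truth_arrays <- data.table::rbindlist(arrays)
  data.table::setorder(truth_motifs, chrom, start)
  data.table::setorder(truth_arrays, chrom, start)

  te_tab <- data.table::data.table(
    te_id = te_meta$te_id, family = te_meta$family, chrom = "chr1",
    start = te_start, end = te_end, strand = te_meta$strand,
    targeted = te_meta$family == fam$family[config$target_family])
  data.table::setorder(te_tab, start)

  ## planted hypomethylated intervals for the targeted family
  tgt <- fam$family[config$target_family]
  ta <- truth_arrays[family == tgt]
  r <- config$hypo_local_radius
  hypo_cg <- merge(ta[, .(te_id, chrom, start, end)],
                   te_tab[, .(te_id, te_start = start, te_end = end)],
                   by = "te_id")
  hypo_cg <- hypo_cg[, .(te_id, context = "CG", chrom,
                         start = pmax(start - r, te_start),
                         end = pmin(end + r, te_end))]
  hypo_ncg <- te_tab[family == tgt,
                     .(te_id = rep(te_id, 2L),
                       context = rep(c("CHG", "CHH"), each = .N),
                       chrom = rep(chrom, 2L), start = rep(start, 2L),
                       end = rep(end, 2L))]
  hypo <- data.table::rbindlist(list(hypo_cg, hypo_ncg))
  data.table::setorder(hypo, context, chrom, start)

  genome <- Biostrings::DNAStringSet(genome_seq)
  names(genome) <- "chr1"
  list(genome = genome, annotation = annotation,
       truth = list(families = fam[, .(family, motif, unit)],
                    target_family = tgt,
                    te = te_tab, motifs = truth_motifs, arrays = truth_arrays,
                    hypo = hypo))
}

#' TE-level intervals from a segment annotation
#'
#' @param annotation Segment table as produced by [simulate_genome()].
#' @return data.table with one row per TE: chrom, start, end, strand, te_id,
#'   family.
#' @export
te_intervals <- function(annotation) {
  out <- annotation[, .(chrom = chrom[1], start = min(start), end = max(end),
                        strand = strand[1], family = family[1]),
                    by = te_id]
  data.table::setorder(out, chrom, start)
  out[]
}
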