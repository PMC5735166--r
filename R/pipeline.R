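## genome subsequences for an interval table (1-based closed, forward strand)
interval_seqs <- function(genome, iv) {
  out <- character(nrow(iv))
  for (i in seq_len(nrow(iv)))
    out[i] <- as.character(Biostrings::subseq(genome[[iv$chrom[i]]],
                                              iv$start[i], iv$end[i]))
  names(out) <- sprintf("%s:%d-%d", iv$chrom, iv$start, iv$end)
  out
}

## sample n background intervals (outside TEs) matching a length profile
sample_background <- function(genome, annotation, lengths, n) {
  tes <- te_intervals(annotation)
  glen <- stats::setNames(Biostrings::width(genome), names(genome))
  out <- vector("list", n)
  got <- 0L; tries <- 0L
  while (got < n && tries < 50L * n) {
    tries <- tries + 1L
    len <- sample(lengths, 1L)
    chr <- sample(names(glen), 1L)
    if (glen[[chr]] <= len + 1L) next
    s0 <- sample.int(glen[[chr]] - len, 1L)
    cand <- data.table::data.table(chrom = chr, start = s0,
                                   end = s0 + len - 1L)
    if (any(tes$chrom == chr & tes$start <= cand$end & tes$end >= cand$start))
      next
    got <- got + 1L
    out[[got]] <- cand
  }
  if (got < n) stop("could not sample enough background intervals")
  data.table::rbindlist(out)
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full synthetic analysis pipeline
#'
#' Simulates a genome, paired methylomes and ChIP data under `config`, then
#' runs the downstream analyses in dependency order: per-TE methylation
#' changes, CG-DMR calling, summit metaplot, motif scanning / per-TE counts
#' / array detection, discriminative motif discovery on the DMR sequences
#' (against length-matched background sequences), and the protein-family
#' evolution summaries (alignment, Poisson distances, NJ tree with
#' bootstrap). All outputs are written as plain-text files under `outdir`
#' and their MD5 checksums recorded in a manifest; re-running with the same
#' config reproduces identical checksums.
#'
#' @param config A [sim_config()].
#' @param outdir Output directory (created if needed).
#' @param n_background Background sequences for motif discovery (default
#'   50).
#' @param dmr_args,discover_args,metaplot_args Named lists overriding
#'   defaults of [call_cg_dmrs()], [discover_motifs()], [summit_metaplot()].
#' @return The manifest, invisibly: package version, config, per-file MD5
#'   checksums.
#' @export
run_full <- function(config = sim_config(), outdir,
                     n_background = 50L, dmr_args = list(),
                     discover_args = list(), metaplot_args = list()) {
  if (!inherits(config, "sim_config"))
    stop("config error: expected a sim_config object")
  validate_sim_config(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  pth <- function(f) file.path(outdir, f)

  sim <- run_stage("simulate_genome", {
    s <- simulate_genome(config)
    write_genome_fasta(s$genome, pth("genome.fa"))
    write_te_annotation(s$annotation, pth("annotation.tsv"))
    write_truth(s$truth, pth("truth.json"))
    s
  })
  meth <- run_stage("simulate_methylomes", {
    m <- simulate_methylomes(sim$genome, sim$annotation, sim$truth, config)
    write_cx_report(m$wt, pth("wt.CX_report.txt"))
    write_cx_report(m$treated, pth("treated.CX_report.txt"))
    m
  })
  chip <- run_stage("simulate_chip", {
    cc <- simulate_chip(sim$genome, sim$annotation, sim$truth, config)
    write_bedgraph(cc$ip, pth("chip_ip.bedgraph"))
    write_bedgraph(cc$input, pth("chip_input.bedgraph"))
    write_bed(chip_summits_bed(cc$summits), pth("summits.bed"))
    cc
  })

  changes <- run_stage("per_te_changes", {
    x <- per_te_changes(meth$wt, meth$treated, sim$annotation)
    data.table::fwrite(x, pth("te_changes.tsv"), sep = "\t", quote = FALSE)
    x
  })
  dmrs <- run_stage("call_cg_dmrs", {
    x <- do.call(call_cg_dmrs, c(list(meth$wt, meth$treated), dmr_args))
    data.table::fwrite(x, pth("cg_dmrs.tsv"), sep = "\t", quote = FALSE)
    x
  })
  meta <- run_stage("summit_metaplot", {
    x <- do.call(summit_metaplot,
                 c(list(meth$wt, chip$summits), metaplot_args))
    x2 <- do.call(summit_metaplot,
                  c(list(meth$treated, chip$summits), metaplot_args))
    x[, condition := "wt"]; x2[, condition := "treated"]
    out <- rbind(x, x2)
    data.table::fwrite(out, pth("metaplot.tsv"), sep = "\t", quote = FALSE)
    out
  })

  target_motif <- sim$truth$families[
    family == sim$truth$target_family, motif]
  hits <- run_stage("scan_motifs", {
    x <- scan_motifs(sim$genome, target_motif)
    data.table::fwrite(x, pth("motif_hits.tsv"), sep = "\t", quote = FALSE)
    x
  })
  counts <- run_stage("count_motifs_per_te", {
    x <- count_motifs_per_te(hits, sim$annotation)
    data.table::fwrite(x, pth("motif_counts.tsv"), sep = "\t", quote = FALSE)
    x
  })
  arrays <- run_stage("find_motif_arrays", {
    x <- find_motif_arrays(hits)
    data.table::fwrite(x, pth("motif_arrays.tsv"), sep = "\t", quote = FALSE)
    x
  })
  disc <- run_stage("discover_motifs", {
    set.seed(stage_seed(config$seed, "analysis"))
    if (nrow(dmrs)) {
      pos <- interval_seqs(sim$genome, dmrs[, .(chrom, start, end)])
      neg_iv <- sample_background(sim$genome, sim$annotation,
                                  dmrs$end - dmrs$start + 1L, n_background)
      neg <- interval_seqs(sim$genome, neg_iv)
      x <- do.call(discover_motifs, c(list(pos, neg), discover_args))
    } else x <- discover_motifs(character(0), character(0))
    data.table::fwrite(x, pth("discovered_motifs.tsv"), sep = "\t",
                       quote = FALSE)
    x
  })

  evo <- run_stage("family_evolution", {
    fe <- simulate_family_evolution(config$tree, config = config)
    write_aligned_fasta(fe$alignment, pth("vanc_alignment.fa"))
    d <- poisson_dist_matrix(fe$alignment)
    dd <- data.table::as.data.table(d, keep.rownames = "label")
    data.table::fwrite(dd, pth("poisson_distances.tsv"), sep = "\t",
                       quote = FALSE)
    bt <- bootstrap_tree(fe$alignment, n_replicates = 100L,
                         seed = stage_seed(config$seed, "analysis"))
    ape::write.tree(bt$tree, pth("nj_tree.nwk"))
    data.table::fwrite(
      data.table::data.table(node = seq_along(bt$supports) +
                               length(bt$tree$tip.label),
                             support = bt$supports),
      pth("nj_bootstrap.tsv"), sep = "\t", quote = FALSE)
    list(fe = fe, d = d, bt = bt)
  })

  files <- c("genome.fa", "annotation.tsv", "truth.json", "wt.CX_report.txt",
             "treated.CX_report.txt", "chip_ip.bedgraph",
             "chip_input.bedgraph", "summits.bed", "te_changes.tsv",
             "cg_dmrs.tsv", "metaplot.tsv", "motif_hits.tsv",
             "motif_counts.tsv", "motif_arrays.tsv", "discovered_motifs.tsv",
             "vanc_alignment.fa", "poisson_distances.tsv", "nj_tree.nwk",
             "nj_bootstrap.tsv")
  manifest <- list(
    package = "vanscape",
    version = as.character(utils::packageVersion("vanscape")),
    seed = config$seed,
    parameters = unclass(config),
    checksums = as.list(stats::setNames(
      unname(tools::md5sum(file.path(outdir, files))), files)))
  jsonlite::write_json(manifest, pth("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(manifest = manifest, sim = sim, methylomes = meth,
                 chip = chip, changes = changes, dmrs = dmrs,
                 metaplot = meta, hits = hits, counts = counts,
                 arrays = arrays, discovered = disc, evolution = evo))
}

chip_summits_bed <- function(summits) {
  summits[, .(chrom, start, end, name, score, strand)]
}

#' Score pipeline outputs against the planted ground truth
#'
#' Computes recovery metrics for a [run_full()] result: base-level
#' sensitivity of CG-DMRs over fully hypomethylated 100-bp windows,
#' base-level precision of DMR calls against planted CG-hypomethylation
#' intervals, the separation margin of per-TE CHH significance between
#' targeted and non-targeted families, the discovery rank of the planted
#' motif, and summit-annotation accuracy.
#'
#' @param outputs List returned by [run_full()].
#' @param truth Ground-truth list (defaults to the one inside `outputs`).
#' @param window DMR window width used (default 100).
#' @param genome Optional [Biostrings::DNAStringSet] (defaults to the
#'   simulated genome in `outputs`); when available, planted windows with
#'   fewer than `min_sites` CG cytosines — windows where CG
#'   hypomethylation cannot exist, let alone be called — are excluded from
#'   the sensitivity denominator.
#' @param min_sites CG-site threshold matching the DMR caller's coverage
#'   filter (default 4).
#' @return data.table with columns metric, value.
#' @export
validate_against_truth <- function(outputs, truth = outputs$sim$truth,
                                   window = 100L,
                                   genome = outputs$sim$genome,
                                   min_sites = 4L) {
  dmrs <- outputs$dmrs
  hypo_cg <- truth$hypo[context == "CG"]

  ## planted windows: full tiles lying inside a planted CG interval
  planted_windows <- hypo_cg[, {
    w0 <- ceiling((start - 1L) / window)      # first full tile index
    w1 <- (end %/% window) - 1L               # last full tile index
    if (w1 >= w0) list(chrom = chrom, win = seq(w0, w1)) else
      list(chrom = character(0), win = integer(0))
  }, by = .(te_id)][, .(chrom, win)]
  if (!is.null(genome) && nrow(planted_windows)) {
    ## count CG cytosine records (both strands) per tile from the sequence
    keep <- logical(nrow(planted_windows))
    cg_pos <- lapply(stats::setNames(seq_along(genome), names(genome)),
                     function(ci) {
      p <- unlist(gregexpr("CG", as.character(genome[[ci]]), fixed = TRUE))
      p[p > 0L]
    })
    for (i in seq_len(nrow(planted_windows))) {
      ws <- planted_windows$win[i] * window + 1L
      we <- ws + window - 1L
      p <- cg_pos[[planted_windows$chrom[i]]]
      nsites <- sum(p >= ws & p <= we) + sum(p + 1L >= ws & p + 1L <= we)
      keep[i] <- nsites >= min_sites
    }
    planted_windows <- planted_windows[keep]
  }
  sens <- NA_real_
  if (nrow(planted_windows)) {
    covered <- logical(nrow(planted_windows))
    if (nrow(dmrs)) {
      ws <- planted_windows$win * window + 1L
      we <- ws + window - 1L
      for (i in seq_len(nrow(planted_windows)))
        covered[i] <- any(dmrs$chrom == planted_windows$chrom[i] &
                            dmrs$start <= ws[i] & dmrs$end >= we[i])
    }
    sens <- mean(covered)
  }

  prec <- NA_real_
  if (nrow(dmrs)) {
    total <- sum(dmrs$end - dmrs$start + 1L)
    ov <- 0L
    g_dmr <- GenomicRanges::GRanges(dmrs$chrom,
                                    IRanges::IRanges(dmrs$start, dmrs$end))
    g_hyp <- GenomicRanges::reduce(
      GenomicRanges::GRanges(hypo_cg$chrom,
                             IRanges::IRanges(hypo_cg$start, hypo_cg$end)))
    ints <- GenomicRanges::intersect(g_dmr, g_hyp)
    ov <- sum(GenomicRanges::width(ints))
    prec <- ov / total
  }

  ch <- outputs$changes[context == "CHH"]
  ch <- merge(ch, truth$te[, .(te_id, targeted)], by = "te_id")
  sep <- min(ch[targeted == TRUE, value], na.rm = TRUE) -
    max(ch[targeted == FALSE, value], na.rm = TRUE)

  ## discovery rank of the planted motif: first candidate whose instances
  ## intersect the planted motif's instances (substring either way)
  planted <- truth$families[family == truth$target_family, motif]
  rank <- NA_real_
  disc <- outputs$discovered
  if (nrow(disc)) {
    pinst <- iupac_instances(planted)
    for (i in seq_len(nrow(disc))) {
      ci <- iupac_instances(disc$pattern[i])
      hit <- any(vapply(ci, function(w)
        any(grepl(w, pinst, fixed = TRUE)) ||
          any(grepl(revcomp(w), pinst, fixed = TRUE)), logical(1)))
      if (hit) { rank <- i; break }
    }
  }

  ann <- annotate_summits(outputs$chip$summits, outputs$sim$annotation)
  acc <- mean(ann$family == truth$target_family &
                ann$segment_type == "noncoding")

  data.table::data.table(
    metric = c("dmr_window_sensitivity", "dmr_base_precision",
               "chh_significance_separation", "planted_motif_rank",
               "summit_annotation_accuracy", "n_dmrs", "n_planted_windows"),
    value = c(sens, prec, sep, rank, acc, nrow(dmrs),
              nrow(planted_windows)))
}
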