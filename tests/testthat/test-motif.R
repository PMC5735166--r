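test_that("degenerate scanning reports all instances on both strands", {
  h <- scan_motifs(c(s = "CAGTATTAC"), "YAGTATTAY")
  expect_equal(h[, .(start, end, strand, matched)],
               data.table::data.table(start = 1L, end = 9L, strand = "+",
                                      matched = "CAGTATTAC"))
  ## reverse complement of TAGTATTAT
  h <- scan_motifs(c(s = "ATAATACTA"), "YAGTATTAY")
  expect_equal(h$strand, "-")
  expect_equal(h$matched, "TAGTATTAT")
  expect_equal(nrow(scan_motifs(c(s = "AAAAAAAAA"), "YAGTATTAY")), 0L)
  ## overlapping hits are all reported
  expect_equal(scan_motifs(c(s = "AAAA"), "AA", both_strands = FALSE)$start,
               1:3)
  ## N never matches a pattern symbol
  expect_equal(nrow(scan_motifs(c(s = "NAGTATTAC"), "YAGTATTAY")), 0L)
  expect_error(scan_motifs(c(s = "ACGT"), "AXGT"), "IUPAC")
})

test_that("scanner agrees with the regex oracle and mirrors under revcomp", {
  set.seed(12)
  for (rep in 1:3) {
    s <- random_dna(10000)
    got9 <- scan_motifs(c(x = s), "YAGTATTAY")
    ref9 <- naive_scan(s, "YAGTATTAY")
    expect_equal(got9[, .(start, end, strand)],
                 ref9[, .(start, end, strand)])
    ## denser degenerate pattern so hits are plentiful
    got <- scan_motifs(c(x = s), "RAGTY")
    ref <- naive_scan(s, "RAGTY")
    expect_gt(nrow(got), 10L)
    expect_equal(got[, .(start, end, strand)],
                 ref[, .(start, end, strand)])
    ## strand symmetry under reverse complement
    rcg <- scan_motifs(c(x = revcomp(s)), "RAGTY")
    L <- nchar(s)
    mirrored <- got[, .(start = L - end + 1L, end = L - start + 1L,
                        strand = ifelse(strand == "+", "-", "+"))]
    data.table::setorder(mirrored, start, strand)
    expect_equal(rcg[order(start, strand), .(start, end, strand)], mirrored)
  }
})

test_that("motif typing follows the C/T and CC/AC definitions", {
  expect_equal(classify_motif(c("TAGTATTAC", "CAGTATTAC")), c("C", "C"))
  expect_equal(classify_motif(c("CAGTATTAT", "TAGTATTAT")), c("T", "T"))
  expect_equal(classify_motif("AGTTGTCC"), "CC")
  expect_equal(classify_motif("AGTTGTAC"), "AC")
  expect_equal(classify_motif("AAAAAAAAA"), "other")
})

test_that("per-TE counting assigns hits by start containment", {
  ann <- data.table::data.table(chrom = "chr1", start = 101L, end = 400L,
                                strand = "+", te_id = "TE1", family = "F",
                                segment_type = "noncoding")
  hits <- data.table::data.table(
    seq_id = "chr1", start = c(150L, 200L, 380L, 500L),
    end = c(158L, 208L, 388L, 508L), strand = "+",
    matched = c("TAGTATTAC", "TAGTATTAC", "CAGTATTAT", "TAGTATTAC"))
  hits[, motif_type := classify_motif(matched)]
  tab <- count_motifs_per_te(hits, ann)
  expect_equal(tab[te_id == "TE1", C], 2L)
  expect_equal(tab[te_id == "TE1", T], 1L)
  expect_equal(tab[te_id == "background", C], 1L)
  empty <- count_motifs_per_te(hits[0], ann)
  expect_true(all(empty[, .(C, T, CC, AC, other)] == 0L))
})

test_that("array detection segments same-strand runs like the loop oracle", {
  mk <- function(starts, strand)
    data.table::data.table(seq_id = "chr1", start = as.integer(starts),
                           end = as.integer(starts + 8L), strand = strand,
                           matched = "TAGTATTAC", motif_type = "C")
  a <- find_motif_arrays(mk(seq(100, by = 30, length.out = 6), "+"))
  expect_equal(a[, .(n_hits, start, end)],
               data.table::data.table(n_hits = 6L, start = 100L, end = 258L))
  expect_equal(a$density, 6 / (159 / 1000))
  expect_equal(nrow(find_motif_arrays(mk(c(100, 130), "+"))), 0L)
  ## strand switch splits adjacent runs
  both <- rbind(mk(c(100, 130, 160), "+"), mk(c(190, 220, 250), "-"))
  expect_equal(find_motif_arrays(both)$strand, c("+", "-"))

  set.seed(5)
  for (rep in 1:10) {
    h <- mk(sort(sample(1:5000, 40)), sample(c("+", "-"), 40, TRUE))
    got <- find_motif_arrays(h)
    ref <- brute_arrays(as.data.frame(h))
    expect_equal(nrow(got), nrow(ref))
    if (nrow(ref)) {
      expect_equal(got$start, ref$start)
      expect_equal(got$n_hits, ref$n_hits)
      expect_equal(got$strand, ref$strand)
    }
  }
})

test_that("minimum mismatch matches exhaustive enumeration", {
  expect_equal(motif_min_mismatch("CAGTATTAC", "CAGTATTAC"), 0L)
  expect_equal(motif_min_mismatch("AGTTGTAC", "YAGTATTAY"), 2L)
  expect_equal(motif_min_mismatch("AGTTGTCC", "YAGTATTAY"), 3L)
  ## independent brute force over all instances and offsets
  brute <- function(q, t) {
    qa <- iupac_instances(q); ta <- iupac_instances(t)
    if (nchar(q) > nchar(t)) { tmp <- qa; qa <- ta; ta <- tmp }
    best <- Inf
    for (x in qa) for (y in ta)
      for (off in 0:(nchar(y) - nchar(x))) {
        mm <- sum(strsplit(x, "")[[1]] !=
                    strsplit(substr(y, off + 1, off + nchar(x)), "")[[1]])
        best <- min(best, mm)
      }
    best
  }
  for (q in c("AGTTGTCC", "AGTTGTAC", "YAGTATTAY", "ACGT"))
    for (t in c("YAGTATTAY", "AGTTGTCC"))
      expect_equal(motif_min_mismatch(q, t), brute(q, t))
  expect_error(motif_min_mismatch("", "ACGT"), "empty")
})

test_that("discovery p-values equal the exact Fisher oracle", {
  set.seed(31)
  word <- "GATTCCGTA"
  pos <- vapply(1:10, function(i) {
    s <- random_dna(200); paste0(substr(s, 1, 90), word, substr(s, 100, 200))
  }, character(1))
  neg <- vapply(1:10, function(i) random_dna(200), character(1))
  out <- discover_motifs(pos, neg, e_threshold = Inf, top_generalize = 50)
  row <- out[pattern == word]
  expect_equal(nrow(row), 1L)
  ## oracle: one-sided Fisher exact test on the presence contingency table
  ref <- stats::fisher.test(matrix(c(row$pos_with, 10 - row$pos_with,
                                     row$neg_with, 10 - row$neg_with), 2,
                                   byrow = TRUE),
                            alternative = "greater")$p.value
  expect_equal(row$p, ref, tolerance = 1e-12)
  expect_equal(row$e, row$p * row$n_words_tested)
})

test_that("discovery is order-invariant and null on exchangeable sets", {
  set.seed(8)
  word <- "TTACGGATC"
  pos <- vapply(1:12, function(i) {
    s <- random_dna(150)
    if (i <= 11) paste0(substr(s, 1, 70), word, substr(s, 80, 150)) else s
  }, character(1))
  neg <- vapply(1:12, function(i) random_dna(150), character(1))
  a <- discover_motifs(pos, neg, top_generalize = 10)
  b <- discover_motifs(rev(pos), sample(neg), top_generalize = 10)
  expect_equal(a, b)
  ## E-values are monotone down the ranking
  expect_true(!is.unsorted(a$e))
  ## identical positive and negative sets: nothing significant
  expect_equal(nrow(discover_motifs(pos, pos, top_generalize = 10)), 0L)
  expect_error(discover_motifs(character(0), neg), "non-empty")
})
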