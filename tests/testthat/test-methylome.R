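cg_rec <- function(pos, meth, unmeth, chrom = "chr1", context = "CG") {
  data.table::data.table(chrom = chrom, pos = as.integer(pos), strand = "+",
                         meth = as.integer(meth),
                         unmeth = as.integer(unmeth), context = context,
                         trinucleotide = "CGA")
}

test_that("significance statistic matches hand-evaluated values", {
  expect_equal(significance_value(50, 100, 50, 100), 0)
  expect_equal(significance_value(90, 100, 10, 100), 4)
  expect_equal(significance_value(360, 400, 40, 400), 8)
  expect_true(is.na(significance_value(0, 0, 5, 10)))
  expect_error(significance_value(11, 10, 0, 10), "exceed")
})

test_that("significance statistic is antisymmetric and scales with sqrt counts", {
  set.seed(1)
  for (i in 1:20) {
    Cn <- sample(20:200, 1); Ct <- Cn
    Mn <- sample(0:Cn, 1); Mt <- sample(0:Ct, 1)
    expect_equal(significance_value(Mn, Cn, Mt, Ct),
                 -significance_value(Mt, Ct, Mn, Cn))
    for (k in c(2, 3, 5))
      expect_equal(significance_value(Mn * k^2, Cn * k^2, Mt * k^2, Ct * k^2),
                   k * significance_value(Mn, Cn, Mt, Ct))
  }
})

test_that("fractional profiles pool counts exactly as brute-force windows", {
  te <- data.table::data.table(chrom = "chr1", start = 1001L, end = 2000L,
                               strand = "+", te_id = "TE1")
  ## constant methylation: every window at 0.8
  rec <- cg_rec(seq(1001, 2000, by = 10), 4, 1)
  prof <- fractional_profile(rec, te, flank = FALSE, contexts = "CG")
  expect_equal(nrow(prof), 94L)  # 100 - 7 + 1 windows, 10-bp fractions
  expect_equal(unique(prof$level), 0.8)

  ## random records: compare to naive per-fraction enumeration
  set.seed(42)
  pos <- sort(sample(1001:2000, 150))
  rec <- cg_rec(pos, rbinom(150, 10, 0.5), rbinom(150, 10, 0.5))
  prof <- fractional_profile(rec, te, flank = FALSE, contexts = "CG")
  for (j in c(1L, 17L, 50L, 94L)) {
    fr <- (j - 1L):(j + 5L)                     # fraction ids 0-based
    sel <- floor((pos - 1001L) * 100 / 1000) %in% fr
    expect_equal(prof$meth[j], sum(rec$meth[sel]))
    expect_equal(prof$total[j], sum(rec$meth[sel] + rec$unmeth[sel]))
  }

  ## a window stays defined when one member fraction lacks coverage
  rec2 <- cg_rec(c(1001, 1031), c(5, 5), c(5, 5))  # fractions 0 and 3 only
  prof2 <- fractional_profile(rec2, te, flank = FALSE, contexts = "CG")
  expect_equal(prof2$level[1], 0.5)
  expect_equal(prof2$total[1], 20)

  ## minus-strand TE: profile is the plus-strand profile read 3'->5'
  te_m <- data.table::copy(te)[, strand := "-"]
  prof_m <- fractional_profile(rec, te_m, flank = FALSE, contexts = "CG")
  expect_equal(prof_m$meth, rev(prof$meth))
  expect_equal(prof_m$total, rev(prof$total))

  ## TEs shorter than the fraction count are skipped explicitly
  short <- data.table::data.table(chrom = "chr1", start = 1L, end = 50L,
                                  strand = "+", te_id = "tiny")
  skipped <- fractional_profile(rec, short)
  expect_equal(nrow(skipped), 0L)
  expect_true(attr(skipped, "skipped"))
})

test_that("running 5-cytosine profile pools successive same-context sites", {
  rec <- cg_rec(1:5 * 10, rep(1, 5), rep(0, 5))
  rp <- running_profile(rec, k = 5)
  expect_equal(rp$level, c(1, NA, NA, NA, NA))

  ## alternating fully methylated / unmethylated, equal coverage
  rec <- cg_rec(1:10 * 10, rep(c(1, 0), 5), rep(c(0, 1), 5))
  rp <- running_profile(rec, k = 5)
  expect_equal(rp$level[1:6], rep(c(0.6, 0.4), 3))

  rec4 <- cg_rec(1:4 * 10, rep(1, 4), rep(0, 4))
  expect_true(all(is.na(running_profile(rec4, k = 5)$level)))
})

test_that("per-TE changes pool interval counts and respect the length filter", {
  ann <- data.table::data.table(
    chrom = "chr1", start = c(1001L, 5001L), end = c(2200L, 5900L),
    strand = "+", te_id = c("TE1", "TE2"), family = "FAMX",
    segment_type = "noncoding")
  wt <- cg_rec(c(1100, 1200, 5100), c(8, 6, 5), c(2, 4, 5))
  tr <- cg_rec(c(1100, 1200, 5100), c(2, 1, 5), c(8, 9, 5))
  ch <- per_te_changes(wt, tr, ann, contexts = "CG", min_length = 1000L)
  expect_equal(ch$te_id, "TE1")  # 900-bp TE2 filtered out
  expect_equal(ch[, .(Mn, Cn, Mt, Ct)],
               data.table::data.table(Mn = 14L, Cn = 20L, Mt = 3L, Ct = 20L))
  expect_equal(ch$value, significance_value(14, 20, 3, 20))

  ## uncovered context yields a row with an undefined value
  ch2 <- per_te_changes(wt, tr, ann, contexts = c("CG", "CHH"),
                        min_length = 100L)
  expect_true(is.na(ch2[te_id == "TE1" & context == "CHH", value]))
  expect_equal(nrow(ch2), 4L)
})

test_that("DMR caller applies the 0.5 threshold and one-gap merge rule", {
  win_rec <- function(win, level, n = 6, cov = 10) {
    pos <- (win - 1L) * 100L + seq(5L, by = 15L, length.out = n)
    cg_rec(pos, round(cov * level), cov - round(cov * level))
  }
  ## single seed window
  wt <- win_rec(1, 0.9); tr <- win_rec(1, 0.3)
  d <- call_cg_dmrs(wt, tr)
  expect_equal(d[, .(start, end, n_windows)],
               data.table::data.table(start = 1L, end = 100L, n_windows = 1L))
  expect_gte(d$diff, 0.5)

  ## seeds in tiles 1 and 3, non-seed tile 2 in between: one merged DMR
  wt <- rbind(win_rec(1, 0.9), win_rec(2, 0.9), win_rec(3, 0.9))
  tr <- rbind(win_rec(1, 0.2), win_rec(2, 0.8), win_rec(3, 0.2))
  d <- call_cg_dmrs(wt, tr)
  expect_equal(d[, .(start, end, n_windows)],
               data.table::data.table(start = 1L, end = 300L, n_windows = 2L))

  ## seeds in tiles 1 and 4 (two-tile gap): two DMRs
  wt <- rbind(win_rec(1, 0.9), win_rec(4, 0.9))
  tr <- rbind(win_rec(1, 0.2), win_rec(4, 0.2))
  d <- call_cg_dmrs(wt, tr)
  expect_equal(nrow(d), 2L)

  ## coverage filter: 3 covered sites < min_covered_sites
  wt <- win_rec(1, 0.9, n = 3); tr <- win_rec(1, 0.2, n = 3)
  expect_equal(nrow(call_cg_dmrs(wt, tr)), 0L)
  expect_error(call_cg_dmrs(wt, tr, window = 0), "window")
})

test_that("DMR caller equals the brute-force oracle on random toy genomes", {
  set.seed(99)
  for (rep in 1:20) {
    toy <- random_cg_pair(20000L, n_sites = 300L)
    got <- call_cg_dmrs(toy$wt, toy$treated)
    ref <- brute_dmr(toy$wt, toy$treated)
    expect_equal(nrow(got), nrow(ref))
    if (nrow(ref)) {
      expect_equal(got$start, ref$start)
      expect_equal(got$end, ref$end)
      expect_equal(got$n_windows, ref$n_windows)
    }
  }
})

test_that("summit metaplot pools counts exactly and flattens constant input", {
  set.seed(7)
  pos <- sort(sample(1:20000, 800))
  rec <- cg_rec(pos, rep(1, 800), rep(1, 800))  # constant 0.5
  summits <- data.table::data.table(chrom = "chr1", pos = 10000L)
  mp <- summit_metaplot(rec, summits, span = 5000L, contexts = "CG")
  expect_equal(nrow(mp), 191L)  # (10000 - 500)/50 + 1 offsets
  expect_equal(unique(stats::na.omit(mp$level)), 0.5)

  ## random counts: every offset equals naive per-base accumulation
  rec <- cg_rec(pos, rbinom(800, 8, 0.4), rbinom(800, 8, 0.6))
  mp <- summit_metaplot(rec, summits, span = 2000L, contexts = "CG")
  for (o in c(-1750L, -250L, 0L, 1000L, 1750L)) {
    ref <- naive_pool(rec, "chr1", 10000L + o - 250L, 10000L + o + 249L, "CG")
    row <- mp[offset == o]
    expect_equal(row$meth, unname(ref["meth"]))
    expect_equal(row$total, unname(ref["total"]))
  }

  expect_equal(nrow(summit_metaplot(rec, summits[0])), 0L)
})
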