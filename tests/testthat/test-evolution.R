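# dot plots, tandem repeats, distances and trees

test_that("DNA dot plot reproduces exact-word geometry", {
  set.seed(60)
  ## unit with no internal 10-mer self-match, checked by brute force
  repeat {
    unit <- random_dna(20)
    words <- substring(unit, 1:11, 10:20)
    if (!anyDuplicated(words)) break
  }
  x <- strrep(unit, 3); y <- strrep(unit, 2)
  dp <- dotplot_dna(x, y, word = 10)
  ## brute-force oracle for the point set
  ref <- list()
  for (i in 1:(nchar(x) - 9)) for (j in 1:(nchar(y) - 9))
    if (substr(x, i, i + 9) == substr(y, j, j + 9))
      ref[[length(ref) + 1L]] <- c(i, j)
  ref <- do.call(rbind, ref)
  expect_equal(nrow(dp$points), nrow(ref))
  expect_equal(as.matrix(dp$points[order(x, y)]),
               ref[order(ref[, 1], ref[, 2]), ], ignore_attr = TRUE)
  ## 3 vs 2 repetitions give n + m - 1 = 4 parallel diagonals
  expect_equal(nrow(dp$diagonals), 4L)
  expect_equal(sort(dp$diagonals$offset), c(-20L, 0L, 20L, 40L))

  ## self-plot contains the full main diagonal
  s <- random_dna(200)
  dps <- dotplot_dna(s, s, word = 10)
  main <- dps$diagonals[offset == 0]
  expect_equal(main$length, 191L)
  ## transpose symmetry
  dpt <- dotplot_dna(y, x, word = 10)
  expect_equal(dpt$points[order(x, y), .(x, y)],
               dp$points[order(y, x), .(x = y, y = x)])

  ## independent random kilobase sequences: essentially no 10-mer matches
  a <- random_dna(1000); b <- random_dna(1000)
  expect_lte(nrow(dotplot_dna(a, b, word = 10)$points), 2L)
  expect_error(dotplot_dna("ACGT", "ACGT", word = 10), "word")
})

test_that("protein dot plot applies the windowed BLOSUM62 threshold", {
  p <- "MKVLHEQWRSTNADGYFPIC"
  dp <- dotplot_protein(p, p, window = 10, threshold = 23)
  expect_equal(dp$diagonals[offset == 0, length], nchar(p) - 10L + 1L)
  ## poly-A window scores 10 x 4 = 40 under BLOSUM62
  dpa <- dotplot_protein("AAAAAAAAAA", "AAAAAAAAAA")
  expect_equal(dpa$points, data.table::data.table(x = 1L, y = 1L))
  ## unattainable threshold (10 x max score + 1) empties the plot
  expect_equal(nrow(dotplot_protein(p, p, threshold = 10 * 11 + 1)$points),
               0L)
  expect_error(dotplot_protein("AAAOAAAAAAA", p), "alphabet")
})

test_that("tandem repeat finder recovers planted periodicity", {
  tr <- find_tandem_repeats("ACGTACGTACGT", min_unit = 2, max_unit = 8,
                            min_identity = 1)
  expect_equal(nrow(tr), 1L)
  expect_equal(tr$unit_length, 4L)
  expect_equal(tr$copy_number, 3)
  expect_equal(tr$consensus_unit, "ACGT")
  expect_equal(tr$percent_identity, 1)
  expect_equal(tr$end - tr$start + 1, tr$unit_length * tr$copy_number)

  ## translation invariance inside random flanks
  set.seed(14)
  left <- random_dna(80); right <- random_dna(70)
  emb <- paste0(left, strrep("ACGT", 3), right)
  tre <- find_tandem_repeats(emb, min_unit = 4, max_unit = 8,
                             min_identity = 1)
  hit <- tre[unit_length == 4 & start <= 81 + 1 & end >= 92 - 1]
  expect_gte(nrow(hit), 1L)

  ## seeded negative control: no calls in random sequence
  expect_equal(nrow(find_tandem_repeats(random_dna(500), min_unit = 10,
                                        max_unit = 50, min_identity = 0.9)),
               0L)
  ## imperfect copies still detected below the identity ceiling
  unit <- random_dna(30)
  u2 <- unit; substr(u2, 7, 7) <- if (substr(u2, 7, 7) == "A") "C" else "A"
  seqr <- paste0(unit, unit, u2, unit)
  trr <- find_tandem_repeats(seqr, min_unit = 20, max_unit = 40,
                             min_identity = 0.9)
  expect_equal(trr$unit_length, 30L)
  expect_gte(trr$copy_number, 3.9)
  expect_error(find_tandem_repeats("ACGT", min_unit = 0), "min_unit")
})

test_that("Poisson correction distance matches its closed form", {
  expect_equal(poisson_distance("ACDEFGHIKL", "ACDEFGHIKL"), 0)
  expect_equal(poisson_distance("ACDEFGHIKL", "MCDEFGHIKL"), -log(0.9))
  ## gapped columns are excluded pairwise
  expect_equal(poisson_distance("AC-T", "ACG-"), 0)
  expect_warning(d1 <- poisson_distance("AAAA", "CCCC"), "undefined")
  expect_true(is.nan(d1))
  expect_warning(d2 <- poisson_distance("--", "AA"), "ungapped")
  expect_true(is.nan(d2))
  ## correction inflates: d >= p, equality only at p = 0; d ~ p for small p
  for (ndiff in c(0, 1, 2, 5)) {
    n <- 1000
    a <- strrep("A", n)
    b <- paste0(strrep("C", ndiff), strrep("A", n - ndiff))
    p <- ndiff / n
    d <- poisson_distance(a, b)
    expect_gte(d, p)
    if (p == 0) expect_equal(d, 0) else if (p <= 0.01)
      expect_lt(abs(d - p) / p, 0.01)
  }
  m <- poisson_dist_matrix(c(a = "AAAA", b = "AACA", c = "CCAA"))
  expect_equal(m, t(m))
  expect_equal(diag(m), c(a = 0, b = 0, c = 0))
})

test_that("neighbor joining solves the three-taxon case in closed form", {
  d <- matrix(c(0, 2, 3, 2, 0, 4, 3, 4, 0), 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- neighbor_joining(d)
  expect_equal(sort(tr$edge.length), c(0.5, 1.5, 2.5))
  expect_equal(ape::cophenetic.phylo(tr)[rownames(d), colnames(d)], d)
  expect_error(neighbor_joining(d[1:2, 1:2]), "3 taxa")
  dn <- d; dn[1, 2] <- dn[2, 1] <- NaN
  expect_error(neighbor_joining(dn), "NaN")
})

test_that("neighbor joining is exact on additive matrices of random trees", {
  set.seed(20)
  for (n in 4:8) {
    tr <- ape::rtree(n)
    d <- ape::cophenetic.phylo(tr)
    nj <- neighbor_joining(d)
    expect_equal(ape::cophenetic.phylo(nj)[rownames(d), colnames(d)], d,
                 tolerance = 1e-10)
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(tr), nj)), 0)
  }
  ## star distances: the internal branch collapses
  ds <- matrix(2, 4, 4,
               dimnames = list(letters[1:4], letters[1:4])); diag(ds) <- 0
  njs <- neighbor_joining(ds)
  internal <- njs$edge[, 1] > 4 & njs$edge[, 2] > 4
  expect_lt(max(abs(njs$edge.length[internal])), 1e-12)
})

test_that("bootstrap supports clean bipartitions and is seed-deterministic", {
  taxa <- c("A", "B", "C", "D")
  n <- 60
  mat <- matrix("G", 4, n, dimnames = list(taxa, NULL))
  mat[c("A", "B"), 1:15] <- "K"; mat[c("C", "D"), 1:15] <- "E"
  mat["A", 16:20] <- "P"; mat["B", 21:25] <- "W"
  mat["C", 26:30] <- "Y"; mat["D", 31:35] <- "F"
  aln <- apply(mat, 1, paste, collapse = "")
  bt <- bootstrap_tree(aln, n_replicates = 50, seed = 4)
  ## non-trivial bipartitions are fully supported (trivial root entry is NA)
  sup <- bt$supports[!is.na(bt$supports)]
  expect_gte(length(sup), 1L)
  expect_equal(unname(sup), rep(1, length(sup)))
  bt2 <- bootstrap_tree(aln, n_replicates = 50, seed = 4)
  expect_equal(bt$supports, bt2$supports)
  expect_error(bootstrap_tree(aln, n_replicates = 0), "n_replicates")
})
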