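test_that("progressive_align base cases", {
  same <- c(a = "ACGTAC", b = "ACGTAC", c = "ACGTAC")
  aln <- progressive_align(same)
  expect_equal(ncol(aln), 6L)
  expect_false(any(unclass(aln) == "-"))
  expect_true(all(apply(aln, 2L, function(col) length(unique(col)) == 1L)))

  # "ACGT" vs "ACT": length 4 with exactly one gap in the second row
  aln2 <- progressive_align(c(x = "ACGT", y = "ACT"))
  expect_equal(ncol(aln2), 4L)
  expect_equal(sum(aln2["y", ] == "-"), 1L)
  expect_equal(sum(aln2["x", ] == "-"), 0L)

  expect_error(progressive_align(c(a = "ACGT")), "at least 2")
  expect_error(progressive_align(c(a = "ACGT", a = "ACG")), "duplicate")
  expect_error(progressive_align(c(a = "ACGT", b = "")), "empty")
})

test_that("pairwise alignments are optimal against a brute-force DP oracle", {
  set.seed(41)
  for (rep in 1:50) {
    a <- paste(sample(c("A", "C", "G", "T"), 100, TRUE), collapse = "")
    b <- paste(sample(c("A", "C", "G", "T"), sample(80:100, 1L), TRUE),
               collapse = "")
    aln <- progressive_align(c(x = a, y = b))
    expect_equal(score_pairwise_alignment(unclass(aln)),
                 oracle_affine_score(a, b))
  }
})

test_that("guide tree drives the merge order", {
  set.seed(42)
  root <- paste(sample(c("A", "C", "G", "T"), 120, TRUE), collapse = "")
  seqs <- c(A = root, B = root, C = root, D = root)
  aln <- progressive_align(seqs, guide = toy_tree())
  expect_setequal(rownames(aln), names(seqs))
  expect_identical(ungapped_seqs(aln)[names(seqs)], seqs)
  expect_error(progressive_align(seqs[1:3], guide = toy_tree()), "tips")
})

test_that("homology_pairs extracts co-columned residue pairs", {
  aln <- ncb_alignment(c(r1 = "AC-G", r2 = "ACTG"))
  hp <- homology_pairs(aln, "r1", "r2")
  expect_equal(unname(hp$pairs), cbind(c(0L, 1L, 2L), c(0L, 1L, 3L)),
               ignore_attr = TRUE)
  expect_equal(hp$partner_j, c(0L, 1L, -1L, 2L))  # residue 2 gap-partnered

  disj <- ncb_alignment(c(r1 = "AC--", r2 = "--GT"))
  expect_equal(nrow(homology_pairs(disj, "r1", "r2")$pairs), 0L)

  # symmetry: (i,j) pairs are the transpose of (j,i) pairs
  sym <- homology_pairs(aln, "r2", "r1")
  expect_equal(unname(sym$pairs[, c(2, 1)]), unname(hp$pairs))
  expect_error(homology_pairs(aln, "r1", "nope"), "unknown")
})

test_that("hot_sps and hot_cs arithmetic", {
  h <- ncb_alignment(c(x = "ACG-", y = "ACGT"))  # pairs (0,0),(1,1),(2,2)
  t_ <- ncb_alignment(c(x = "AC-G", y = "ACGT")) # pairs (0,0),(1,1),(2,3)
  expect_equal(hot_sps(h, h), 100)
  expect_equal(hot_cs(h, h), 100)
  expect_equal(hot_sps(h, t_), 100 * 2 / 3, tolerance = 1e-12)
  expect_equal(hot_sps(t_, h), hot_sps(h, t_))   # symmetry
  expect_equal(hot_cs(t_, h), hot_cs(h, t_))

  # non-empty but disjoint pair sets -> 0
  d1 <- ncb_alignment(c(x = "ACG", y = "TTG"))    # pairs (0,0),(1,1),(2,2)
  d2 <- ncb_alignment(c(x = "ACG-", y = "-TTG"))  # pairs (1,0),(2,1)
  expect_equal(hot_sps(d1, d2), 0)

  # both pools empty -> 100 by convention
  e1 <- ncb_alignment(c(x = "AC--", y = "--GT"))
  expect_equal(hot_sps(e1, e1), 100)

  # 4 vs 5 columns sharing 3 identical columns -> 100 * 3 / 4.5
  c1 <- ncb_alignment(c(x = "ACGT", y = "ACGA"))
  c2 <- ncb_alignment(c(x = "ACG-T", y = "ACGA-"))
  expect_equal(hot_cs(c1, c2), 100 * 3 / 4.5)

  # mismatched sequence content is an error
  bad <- ncb_alignment(c(x = "ACGA", y = "ACGT"))
  expect_error(hot_sps(h, bad), "differ")
})

test_that("CS is 100 iff alignments match up to all-gap columns", {
  a <- ncb_alignment(c(x = "AC-GT", y = "ACT-T"))
  b <- ncb_alignment(c(x = "AC--GT", y = "ACT--T"))  # extra all-gap column
  expect_equal(hot_cs(a, b), 100)
  shifted <- ncb_alignment(c(x = "AC-GT", y = "AC-TT"))
  # same sequences, different column structure: CS strictly below 100
  expect_lt(hot_cs(a, shifted), 100)
})

test_that("hot_pipeline: reversal protocol and trivial symmetric cases", {
  # identical sequences: both orientations align gap-free
  seqs <- c(a = "ACGTTGCA", b = "ACGTTGCA", c = "ACGTTGCA")
  expect_equal(unname(hot_pipeline(seqs)), c(100, 100))

  # palindrome-invariant sequences give identical heads and tails
  pal <- c(a = "ACCA", b = "AGGA")
  expect_equal(unname(hot_pipeline(pal)), c(100, 100))

  # reversing twice is the identity
  aln <- progressive_align(c(x = "ACGGT", y = "AGGT"))
  expect_identical(unclass(reverse_alignment(reverse_alignment(aln))),
                   unclass(aln))
})

test_that("hot scores stay within [0, 100] on simulated data", {
  p <- evolution_params(toy_tree(), root_length = 150L)
  set.seed(43)
  for (i in 1:5) {
    ds <- simulate_dataset(p)
    sc <- hot_pipeline(ds$leaf_seqs)
    expect_true(all(sc >= 0 & sc <= 100))
  }
})
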