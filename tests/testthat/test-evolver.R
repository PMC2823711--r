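test_that("indel length model: degenerate and mixture means", {
  m1 <- indel_length_model(w = 1, q1 = 1, q2 = 0.1)
  expect_true(all(sample_indel_length(m1, 1000L) == 1L))

  set.seed(21)
  m2 <- indel_length_model(w = 1, q1 = 0.5, q2 = 0.1)
  expect_equal(mean(sample_indel_length(m2, 1e5L)), 2.0, tolerance = 0.02)
  m3 <- indel_length_model(w = 0.5, q1 = 0.5, q2 = 0.1)
  # mixture mean 0.5*2 + 0.5*10 = 6
  expect_equal(mean(sample_indel_length(m3, 1e5L)), 6.0, tolerance = 0.03)
  expect_error(indel_length_model(w = 1.4), "w")
})

test_that("block placement: empty case, coverage, deterministic lengths", {
  expect_error(place_conserved_blocks(1000, 1), "alpha")
  b0 <- place_conserved_blocks(1000, 0)
  expect_length(b0$start, 0L)
  expect_true(all(site_multipliers(b0) == 1))

  set.seed(22)
  cov <- replicate(300, block_coverage(place_conserved_blocks(2000, 0.2)))
  expect_equal(mean(cov), 0.2, tolerance = 0.1)

  # all blocks length 50, alpha 0.5 -> coverage ~0.5 on 10 kb roots
  det <- structure(function(n) rep(50L, n), mean = 50)
  cov2 <- replicate(100, block_coverage(place_conserved_blocks(10000, 0.5, det)))
  expect_equal(mean(cov2), 0.5, tolerance = 0.04)

  b <- place_conserved_blocks(5000, 0.3)
  expect_true(all(b$start < b$end))
  expect_true(all(b$end <= 5000))
  if (length(b$start) > 1L)
    expect_true(all(b$start[-1L] >= b$end[-length(b$end)]))
})

test_that("evolve_branch: zero branch length is a no-op", {
  p <- evolution_params(toy_tree(), root_length = 100L)
  out <- evolve_branch("ACGTACGTAC", 0, p)
  expect_equal(out$sequence, "ACGTACGTAC")
  expect_equal(nrow(out$events), 0L)
})

test_that("substitution counts follow the Gillespie rate calculus", {
  # neutral sites, indels disabled: events ~ Poisson(brlen * length)
  tr <- parse_newick("(A:0.5,B:0);")
  p <- evolution_params(tr, sub_indel_ratio = Inf, alpha = 0,
                        root_length = 300L)
  set.seed(23)
  counts <- replicate(200, {
    out <- evolve_branch(paste(sample(c("A", "C", "G", "T"), 300,
                                      replace = TRUE), collapse = ""),
                         0.5, p)
    nrow(out$events)
  })
  expect_equal(mean(counts), 150, tolerance = 0.05)
  expect_equal(stats::var(counts), 150, tolerance = 0.3)
})

test_that("block sites substitute at beta times the neutral rate", {
  tr <- parse_newick("(A:0.4,B:0);")
  p <- evolution_params(tr, sub_indel_ratio = Inf, alpha = 0.3, beta = 0.1,
                        root_length = 1000L)
  set.seed(24)
  sub_in <- 0; sub_out <- 0; sites_in <- 0; sites_out <- 0
  for (i in 1:60) {
    blocks <- place_conserved_blocks(1000L, 0.3)
    mult <- site_multipliers(blocks)
    parent <- list(ids = seq_len(1000L),
                   bases = sample.int(4L, 1000L, replace = TRUE),
                   mult = mult)
    out <- evolve_branch(parent, 0.4, p)
    inblk <- mult < 1
    sites_in <- sites_in + sum(inblk); sites_out <- sites_out + sum(!inblk)
    pos <- out$events$position + 1L   # no indels: positions are root sites
    sub_in <- sub_in + sum(inblk[pos]); sub_out <- sub_out + sum(!inblk[pos])
  }
  ratio <- (sub_in / sites_in) / (sub_out / sites_out)
  expect_equal(ratio, 0.1, tolerance = 0.2)
})

test_that("simulate_dataset invariants hold", {
  p <- evolution_params(toy_tree(), root_length = 400L)
  set.seed(25)
  ds <- simulate_dataset(p)
  # rows ungap to leaf sequences
  expect_identical(ungapped_seqs(ds$alignment)[names(ds$leaf_seqs)],
                   ds$leaf_seqs)
  # columns = root length + inserted residues
  ins <- ds$events[ds$events$kind == "insertion", ]
  expect_equal(ds$n_columns, 400L + sum(ins$length))
  # event positions and times in range
  expect_true(all(ds$events$time >= 0))
  expect_true(all(ds$events$position >= 0))
  expect_true(all(ds$events$aln_col_start >= 0 &
                  ds$events$aln_col_end <= ds$n_columns))
  # bit-reproducible under the same seed
  set.seed(25)
  ds2 <- simulate_dataset(p)
  expect_identical(ds$leaf_seqs, ds2$leaf_seqs)
  expect_identical(unclass(ds$alignment), unclass(ds2$alignment))
  expect_identical(ds$events$kind, ds2$events$kind)
})

test_that("zero-length tree reproduces the root everywhere", {
  tr <- parse_newick("((A:0,B:0):0,C:0);")
  p <- evolution_params(tr, root_length = 150L)
  set.seed(26)
  ds <- simulate_dataset(p)
  expect_equal(unname(nchar(ds$leaf_seqs)), rep(150L, 3L))
  expect_true(all(ds$leaf_seqs == ds$root_sequence))
  expect_false(any(unclass(ds$alignment) == "-"))
  expect_equal(nrow(ds$events), 0L)
})

test_that("event ratios track rho and r at reduced scale", {
  p <- evolution_params(toy_tree(), sub_indel_ratio = 10, ins_del_ratio = 1,
                        root_length = 600L)
  set.seed(27)
  kind <- character(0)
  for (i in 1:40) kind <- c(kind, simulate_dataset(p)$events$kind)
  n_sub <- sum(kind == "substitution")
  n_ins <- sum(kind == "insertion"); n_del <- sum(kind == "deletion")
  expect_equal(n_sub / (n_ins + n_del), 10, tolerance = 0.12)
  expect_equal(n_ins / n_del, 1, tolerance = 0.15)
})

test_that("deletions are truncated at the sequence end, never beyond", {
  tr <- parse_newick("(A:1.5,B:0);")
  p <- evolution_params(tr, sub_indel_ratio = 2, root_length = 40L,
                        indel_model = indel_length_model(0, 0.5, 0.05))
  set.seed(28)
  for (i in 1:20) {
    out <- evolve_branch(paste(rep("ACGT", 10), collapse = ""), 1.5, p)
    del <- out$events[out$events$kind == "deletion", ]
    expect_true(all(del$length >= 1L))
  }
})

test_that("root pool windows are honored and validated", {
  pool <- c(s1 = paste(rep("ACGT", 100), collapse = ""))
  p <- evolution_params(toy_tree(), root_length = 200L)
  set.seed(29)
  ds <- simulate_dataset(p, root_source = pool)
  expect_equal(nchar(ds$root_sequence), 200L)
  p2 <- evolution_params(toy_tree(), root_length = 5000L)
  expect_error(simulate_dataset(p2, root_source = pool), "root length")
})

test_that("base composition is stationary at pi", {
  pi <- c(0.1, 0.2, 0.3, 0.4)
  tr <- parse_newick("(A:0.5,B:0);")
  p <- evolution_params(tr, sub_indel_ratio = Inf, alpha = 0,
                        base_freqs = pi, root_length = 20000L)
  set.seed(30)
  root <- sample.int(4L, 20000L, replace = TRUE, prob = pi)
  out <- evolve_branch(list(ids = seq_len(20000L), bases = root,
                            mult = rep(1, 20000L)), 0.5, p)
  counts <- table(factor(strsplit(out$sequence, "")[[1]],
                         levels = c("A", "C", "G", "T")))
  expect_gt(stats::chisq.test(counts, p = pi)$p.value, 0.01)
})

test_that("true_indel_annotation nets out same-branch insert-then-delete", {
  p <- evolution_params(toy_tree(), sub_indel_ratio = 3, root_length = 300L)
  set.seed(31)
  for (i in 1:10) {
    ds <- simulate_dataset(p)
    ann <- true_indel_annotation(ds)   # constructor enforces disjointness
    expect_s3_class(ann, "indel_annotation")
    expect_true(all(unlist(ann$columns) >= 0 &
                    unlist(ann$columns) < ds$n_columns))
  }
})
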