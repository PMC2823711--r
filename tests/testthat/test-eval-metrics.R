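test_that("identity comparison gives perfect scores", {
  set.seed(51)
  ds <- simulate_dataset(evolution_params(toy_tree(), root_length = 200L))
  cmp <- compare_alignments(ds$alignment, ds$alignment)
  expect_equal(cmp$agreement, 1)
  expect_equal(cmp$sensitivity, 1)
  expect_equal(cmp$specificity, 1)
  expect_true(all(cmp$per_pair$agreement == 1))
})

test_that("toy case matches hand enumeration", {
  truth <- ncb_alignment(c(r1 = "AC-G", r2 = "ACTG"))
  pred <- ncb_alignment(c(r1 = "ACG-", r2 = "ACTG"))
  cmp <- compare_alignments(pred, truth)
  o <- oracle_compare(pred, truth)
  expect_equal(cmp$agreement, o$agreement)
  expect_equal(cmp$sensitivity, o$sensitivity)
  expect_equal(cmp$specificity, o$specificity)
  # truth pairs {(0,0),(1,1),(2,3)}; pred pairs {(0,0),(1,1),(2,2)}
  expect_equal(cmp$sensitivity, 2 / 3)
  expect_equal(cmp$specificity, 2 / 3)
})

test_that("all-gapped-apart prediction: sensitivity 0, specificity NA", {
  truth <- ncb_alignment(c(r1 = "AC", r2 = "GT"))
  pred <- ncb_alignment(c(r1 = "AC--", r2 = "--GT"))
  cmp <- compare_alignments(pred, truth)
  expect_equal(cmp$sensitivity, 0)
  expect_true(is.na(cmp$specificity))
})

test_that("comparison equals the brute-force oracle on random toys", {
  set.seed(52)
  for (rep in 1:300) {
    seqs <- random_toy_sequences()
    truth <- random_alignment_of(seqs)
    pred <- random_alignment_of(seqs)
    cmp <- compare_alignments(pred, truth)
    o <- oracle_compare(pred, truth)
    expect_equal(cmp$agreement, o$agreement)
    expect_equal(cmp$sensitivity, o$sensitivity)
    expect_equal(cmp$specificity, o$specificity)
  }
})

test_that("metrics are invariant to row order and all-gap columns", {
  set.seed(53)
  seqs <- random_toy_sequences(4L)
  truth <- random_alignment_of(seqs)
  pred <- random_alignment_of(seqs)
  cmp <- compare_alignments(pred, truth)

  perm <- sample(rownames(pred))
  pred_p <- ncb_alignment(unclass(pred)[perm, , drop = FALSE])
  cmp_p <- compare_alignments(pred_p, truth)
  expect_equal(cmp_p$agreement, cmp$agreement)
  expect_equal(cmp_p$sensitivity, cmp$sensitivity)

  # splice an all-gap column into the prediction
  m <- unclass(pred)
  m2 <- cbind(m[, 1:2, drop = FALSE], rep("-", nrow(m)),
              m[, -(1:2), drop = FALSE])
  rownames(m2) <- rownames(m)
  cmp_g <- compare_alignments(ncb_alignment(m2), truth)
  expect_equal(cmp_g$agreement, cmp$agreement)
  expect_equal(cmp_g$specificity, cmp$specificity)
})

test_that("sensitivity equals specificity when pair counts match", {
  set.seed(54)
  for (rep in 1:20) {
    seqs <- random_toy_sequences(2L)
    truth <- random_alignment_of(seqs)
    pred <- random_alignment_of(seqs)
    cmp <- compare_alignments(pred, truth)
    if (isTRUE(all.equal(cmp$counts[["true_pairs"]],
                         cmp$counts[["pred_pairs"]])))
      expect_equal(cmp$sensitivity, cmp$specificity)
  }
})

test_that("mismatched inputs are rejected", {
  a <- ncb_alignment(c(r1 = "ACG", r2 = "ACG"))
  b <- ncb_alignment(c(r1 = "ACG", r3 = "ACG"))
  expect_error(compare_alignments(a, b), "taxa")
  c_ <- ncb_alignment(c(r1 = "ACT", r2 = "ACG"))
  expect_error(compare_alignments(a, c_), "differ")
})

test_that("indel annotation validates disjointness within a branch", {
  expect_error(
    indel_annotation(c("b1", "b1"), c("insertion", "deletion"),
                     list(0:4, 3:6)),
    "share")
  ann <- indel_annotation(c("b1", "b1", "b2"),
                          c("insertion", "deletion", "deletion"),
                          list(0:4, 7:9, 0:9))
  expect_s3_class(ann, "indel_annotation")
  expect_error(indel_annotation("b1", "dupe", list(0:1)), "kind")
})

test_that("ICA: optimum at identity, direct arithmetic cases", {
  tr <- indel_annotation(rep("b", 20L),
                         rep(c("insertion", "deletion"), each = 10L),
                         as.list(0:19))
  expect_identical(indel_count_agreement(tr, tr, "b"), 0)

  pr <- indel_annotation(rep("b", 22L),
                         rep(c("insertion", "deletion"), c(12L, 10L)),
                         as.list(0:21))
  expect_equal(indel_count_agreement(tr, pr, "b"), 0.10)

  dbl <- indel_annotation(rep("b", 40L),
                          rep(c("insertion", "deletion"), each = 20L),
                          as.list(0:39))
  expect_equal(indel_count_agreement(tr, dbl, "b"), 1.0)

  empty <- indel_annotation(character(0), character(0), list())
  expect_true(is.na(indel_count_agreement(empty, tr, "b")))
})

test_that("IRA: optimum at identity, arithmetic, and its blind spot", {
  tr <- indel_annotation(rep("b", 20L),
                         rep(c("insertion", "deletion"), each = 10L),
                         as.list(0:19))
  expect_identical(indel_ratio_agreement(tr, tr, "b"), 1)

  pr <- indel_annotation(rep("b", 22L),
                         rep(c("insertion", "deletion"), c(12L, 10L)),
                         as.list(0:21))
  expect_equal(indel_ratio_agreement(tr, pr, "b"), (12 / 22) / 0.5)

  # swapping equal insertion/deletion counts leaves IRA at 1
  sw <- indel_annotation(rep("b", 20L),
                         rep(c("deletion", "insertion"), each = 10L),
                         as.list(0:19))
  expect_equal(indel_ratio_agreement(tr, sw, "b"), 1)
})

test_that("IAC: set arithmetic over (column, kind) positions", {
  tr <- indel_annotation("b", "deletion", list(0:9))
  expect_equal(indel_annotation_coverage(tr, tr, "b"),
               c(sensitivity = 1, specificity = 1))
  pr <- indel_annotation("b", "deletion", list(0:7))
  expect_equal(indel_annotation_coverage(tr, pr, "b"),
               c(sensitivity = 0.8, specificity = 1))
  # right columns, wrong kind everywhere
  wk <- indel_annotation("b", "insertion", list(0:9))
  expect_equal(indel_annotation_coverage(tr, wk, "b"),
               c(sensitivity = 0, specificity = 0))
  none <- indel_annotation(character(0), character(0), list())
  expect_true(all(is.na(indel_annotation_coverage(none, none, "b"))))
})

test_that("insertion/deletion-excess stratification harness runs end-to-end", {
  # expected counts in the manifest split data sets into the two regimes
  tmp <- withr::local_tempdir()
  tr <- toy_tree()
  p_ins <- evolution_params(tr, ins_del_ratio = 3, root_length = 150L)
  cfg <- benchmark_config(p_ins, n_datasets = 3L,
                          out_dir = file.path(tmp, "bench"),
                          master_seed = 55L)
  man <- generate_benchmark(cfg)
  expect_true(all(man$expected_insertions >= 2 * man$expected_deletions))
  preds <- file.path(tmp, "preds"); dir.create(preds)
  for (id in man$dataset) {
    seqs <- read_fasta(file.path(tmp, "bench", id, "leaves.fasta"))
    write_alignment_fasta(progressive_align(seqs),
                          file.path(preds, paste0(id, ".fasta")))
  }
  out <- evaluate_benchmark(file.path(tmp, "bench"), preds,
                            file.path(tmp, "report.tsv"))
  agg <- out$aggregate
  expect_equal(agg$n[agg$stratum == "insertion_excess"], 3L)
  expect_equal(agg$n[agg$stratum == "deletion_excess"], 0L)
})
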