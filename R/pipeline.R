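#' Benchmark run configuration
#'
#' @param template An [evolution_params()]; in sampled mode its tree should
#'   carry *overall* (observed-scale) branch lengths when a branch-length
#'   distribution is registered (they are adjusted to the neutral scale per
#'   draw), neutral-scale otherwise.
#' @param n_datasets Number of data sets to simulate (`>= 1`).
#' @param out_dir Output directory (created; must not require privileges).
#' @param mode `"traditional"` (fixed template parameters) or `"sampled"`
#'   (per-data-set draws from `distributions`).
#' @param distributions Named list of [empirical_distribution()]s or TSV
#'   file paths (labels as in [sample_parameters()]); required in sampled
#'   mode.
#' @param k_species Optional subset size: the tree is pruned to the
#'   `k_species` leaves closest to `reference` (patristic distance),
#'   including the reference itself.
#' @param reference Reference leaf for subsetting (default: first tip).
#' @param leaves Optional explicit leaf subset, overriding `k_species`.
#' @param master_seed Integer master seed; per-data-set seeds derive from it.
#' @param root_pool Optional FASTA path / named sequences for root windows.
#' @return Object of class `benchmark_config`.
#' @export
benchmark_config <- function(template, n_datasets, out_dir,
                             mode = c("traditional", "sampled"),
                             distributions = list(), k_species = NULL,
                             reference = NULL, leaves = NULL,
                             master_seed = 1L, root_pool = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(template, "evolution_params"),
            is.numeric(n_datasets), n_datasets >= 1,
            is.character(out_dir), length(out_dir) == 1L)
  tree <- template$tree
  ntip <- length(tree$tip.label)
  if (is.null(reference)) reference <- tree$tip.label[1L]
  if (!reference %in% tree$tip.label) stop("unknown reference leaf")
  if (!is.null(leaves)) {
    if (!all(leaves %in% tree$tip.label)) stop("unknown leaf in subset")
    if (length(leaves) < 2L) stop("need >= 2 leaves")
  } else if (!is.null(k_species)) {
    if (k_species < 2L || k_species > ntip)
      stop("k_species must be between 2 and the number of leaves")
  }
  if (mode == "sampled") {
    if (!length(distributions)) stop("sampled mode needs distributions")
    distributions <- load_registry(distributions)
  }
  structure(list(template = template, n_datasets = as.integer(n_datasets),
                 out_dir = out_dir, mode = mode,
                 distributions = distributions, k_species = k_species,
                 reference = reference, leaves = leaves,
                 master_seed = as.integer(master_seed),
                 root_pool = root_pool),
            class = "benchmark_config")
}

load_registry <- function(distributions) {
  lapply(stats::setNames(names(distributions), names(distributions)),
         function(nm) {
    d <- distributions[[nm]]
    if (inherits(d, "empirical_distribution")) return(d)
    kind <- if (nm == "branch_lengths") "vector" else "scalar"
    load_distribution(d, kind = kind, label = nm)
  })
}

#' Deterministic per-data-set seed from the master seed
#'
#' Splittable linear scheme: regenerating any subset of data sets only needs
#' the master seed and the data-set index. Kept below 2^31.
#'
#' @param master_seed,index Integers.
#' @return Integer seed.
#' @export
derive_seed <- function(master_seed, index) {
  as.integer((as.double(master_seed) * 48271 + as.double(index) * 1009 + 7)
             %% 2147483629)
}

#' Prune a tree to the k leaves nearest a reference leaf
#'
#' @param tree `phylo` object.
#' @param k Number of leaves to keep (the reference included).
#' @param reference Reference leaf name.
#' @return Pruned `phylo`.
#' @export
prune_to_k <- function(tree, k, reference) {
  tree <- validate_phylogeny(tree)
  stopifnot(reference %in% tree$tip.label, k >= 2,
            k <= length(tree$tip.label))
  d <- ape::cophenetic.phylo(tree)[reference, ]
  keep <- names(sort(d))[seq_len(k)]     # reference has distance 0
  ape::keep.tip(tree, keep)
}

expected_indel_counts <- function(params) {
  mult_sum <- params$root_length *
    (params$alpha * params$beta + 1 - params$alpha)
  tlen <- sum(params$tree$edge.length)
  if (!is.finite(params$sub_indel_ratio)) return(c(ins = 0, del = 0))
  base <- mult_sum / params$sub_indel_ratio * tlen
  r <- params$ins_del_ratio
  c(ins = (base + tlen / params$sub_indel_ratio) * r / (1 + r),
    del = base / (1 + r))
}

#' Generate a benchmark directory
#'
#' Simulates `n_datasets` data sets (traditional or sampled mode), writing
#' per-data-set subdirectories (`leaves.fasta`, `true_alignment.fasta`,
#' `events.tsv`, `params.tsv`), a `manifest.tsv` with the seed, the drawn
#' parameters, expected and realized event counts (enabling insertion-excess
#' vs deletion-excess stratification), a resolved `config.txt` and a
#' `run.log`. Fully reproducible from the master seed.
#'
#' @param config A [benchmark_config()].
#' @return The manifest data frame, invisibly.
#' @export
generate_benchmark <- function(config) {
  stopifnot(inherits(config, "benchmark_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out)) stop("cannot create output directory: ", out)
  template <- config$template
  if (!is.null(config$leaves)) {
    tr <- ape::keep.tip(template$tree, config$leaves)
    template$tree <- tr
  } else if (!is.null(config$k_species)) {
    template$tree <- prune_to_k(template$tree, config$k_species,
                                config$reference)
  }
  logf <- file.path(out, "run.log")
  cat(sprintf("ncbench %s | mode=%s n=%d master_seed=%d\n",
              as.character(utils::packageVersion("ncbench")),
              config$mode, config$n_datasets, config$master_seed),
      file = logf)
  write_config_file(config, file.path(out, "config.txt"))

  rows <- vector("list", config$n_datasets)
  for (i in seq_len(config$n_datasets)) {
    seed_i <- derive_seed(config$master_seed, i)
    set.seed(seed_i)
    params <- if (config$mode == "sampled")
      sample_parameters(config$distributions, template) else template
    t0 <- proc.time()[[3L]]
    ds <- simulate_dataset(params, config$root_pool)
    id <- sprintf("ds%04d", i)
    ddir <- file.path(out, id)
    dir.create(ddir, showWarnings = FALSE)
    write_fasta(ds$leaf_seqs, file.path(ddir, "leaves.fasta"))
    write_alignment_fasta(ds$alignment, file.path(ddir, "true_alignment.fasta"))
    write_event_log(ds$events, file.path(ddir, "events.tsv"))
    write_param_draw(params, file.path(ddir, "params.tsv"))
    exp_cnt <- expected_indel_counts(params)
    kind <- ds$events$kind
    rows[[i]] <- data.frame(
      dataset = id, seed = seed_i,
      sub_indel_ratio = params$sub_indel_ratio,
      ins_del_ratio = params$ins_del_ratio,
      alpha = params$alpha, beta = params$beta,
      tree_length = sum(params$tree$edge.length),
      root_length = params$root_length,
      expected_insertions = exp_cnt[["ins"]],
      expected_deletions = exp_cnt[["del"]],
      substitutions = sum(kind == "substitution"),
      insertions = sum(kind == "insertion"),
      deletions = sum(kind == "deletion"),
      stringsAsFactors = FALSE)
    cat(sprintf("%s seed=%d events=%d %.2fs\n", id, seed_i, nrow(ds$events),
                proc.time()[[3L]] - t0),
        file = logf, append = TRUE)
  }
  manifest <- do.call(rbind, rows)
  utils::write.table(manifest, file.path(out, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(manifest)
}

write_event_log <- function(events, path) {
  ev <- events
  ev$cols <- vapply(ev$cols, paste, character(1), collapse = ",")
  utils::write.table(
    ev[, c("branch_id", "kind", "time", "position", "length",
           "inserted_bases", "aln_col_start", "aln_col_end", "cols")],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read an event-log TSV back into the event data frame
#' @param path Path to `events.tsv`.
#' @return Data frame matching `simulate_dataset()$events`.
#' @export
read_event_log <- function(path) {
  ev <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE,
                          colClasses = c(cols = "character"))
  ev$cols <- lapply(strsplit(ev$cols, ",", fixed = TRUE), as.integer)
  ev$inserted_bases[is.na(ev$inserted_bases)] <- ""
  ev
}

#' Build an indel annotation from an event-log data frame
#' @param events Event data frame (from a dataset or [read_event_log()]).
#' @return An [indel_annotation()].
#' @export
annotation_from_events <- function(events) {
  ev <- events[events$kind != "substitution", , drop = FALSE]
  indel_annotation(ev$branch_id, ev$kind, ev$cols)
}

write_param_draw <- function(params, path) {
  kv <- c(sub_indel_ratio = params$sub_indel_ratio,
          ins_del_ratio = params$ins_del_ratio,
          alpha = params$alpha, beta = params$beta,
          root_length = params$root_length,
          tree_length = sum(params$tree$edge.length))
  utils::write.table(data.frame(key = names(kv), value = unname(kv)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(c(readLines(path), paste0("tree\t", write_newick(params$tree))),
             path)
}

write_config_file <- function(config, path) {
  p <- config$template
  kv <- c(mode = config$mode, n_datasets = config$n_datasets,
          master_seed = config$master_seed,
          sub_indel_ratio = p$sub_indel_ratio,
          ins_del_ratio = p$ins_del_ratio, alpha = p$alpha, beta = p$beta,
          root_length = p$root_length,
          indel_w = p$indel_model$w, indel_q1 = p$indel_model$q1,
          indel_q2 = p$indel_model$q2,
          tree = write_newick(p$tree))
  writeLines(paste0(names(kv), "=", kv), path)
}

#' Read a flat key=value configuration file
#' @param path File path.
#' @return Named character vector.
#' @export
read_config_file <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- regmatches(lines, regexpr("=", lines, fixed = TRUE),
                   invert = TRUE)
  stats::setNames(vapply(kv, `[`, character(1), 2L),
                  vapply(kv, `[`, character(1), 1L))
}

#' Evaluate predicted alignments against a benchmark
#'
#' For every data set in the benchmark, looks for `<id>.fasta` in
#' `predictions_dir`, compares it to the true alignment, and writes a
#' long-format TSV (`dataset`, `metric`, `scope`, `value`) followed by
#' micro-averaged aggregate rows for all data sets and for the
#' insertion-excess / deletion-excess strata (expected insertions at least
#' twice the expected deletions, and vice versa). Missing predictions are
#' skipped with a warning; content mismatches produce per-data-set error
#' rows.
#'
#' @param benchmark_dir Directory written by [generate_benchmark()].
#' @param predictions_dir Directory of predicted gapped multi-FASTA files.
#' @param report_path Output TSV path.
#' @return List with `report` (the long table) and `aggregate` (data frame
#'   of pooled scores per stratum), invisibly.
#' @export
evaluate_benchmark <- function(benchmark_dir, predictions_dir, report_path) {
  manifest <- utils::read.table(file.path(benchmark_dir, "manifest.tsv"),
                                sep = "\t", header = TRUE,
                                stringsAsFactors = FALSE)
  rows <- list(); counts <- list()
  for (i in seq_len(nrow(manifest))) {
    id <- manifest$dataset[i]
    pred_path <- file.path(predictions_dir, paste0(id, ".fasta"))
    if (!file.exists(pred_path)) {
      warning("missing prediction for ", id, "; skipped")
      next
    }
    truth <- read_alignment_fasta(file.path(benchmark_dir, id,
                                            "true_alignment.fasta"))
    cmp <- tryCatch(
      compare_alignments(read_alignment_fasta(pred_path), truth),
      error = function(e) e)
    if (inherits(cmp, "error")) {
      rows[[length(rows) + 1L]] <- data.frame(
        dataset = id, metric = "error", scope = "all_pairs",
        value = NA_real_, note = conditionMessage(cmp),
        stringsAsFactors = FALSE)
      next
    }
    for (m in c("agreement", "sensitivity", "specificity"))
      rows[[length(rows) + 1L]] <- data.frame(
        dataset = id, metric = m, scope = "all_pairs", value = cmp[[m]],
        note = "", stringsAsFactors = FALSE)
    pp <- cmp$per_pair
    for (k in seq_len(nrow(pp))) for (m in c("agreement", "sensitivity",
                                             "specificity"))
      rows[[length(rows) + 1L]] <- data.frame(
        dataset = id, metric = m,
        scope = paste0(pp$taxon_a[k], "-", pp$taxon_b[k]),
        value = pp[[m]][k], note = "", stringsAsFactors = FALSE)
    counts[[id]] <- cmp$counts
  }
  report <- do.call(rbind, rows)

  strata <- list(
    all = manifest$dataset,
    insertion_excess = manifest$dataset[
      manifest$expected_insertions >= 2 * manifest$expected_deletions],
    deletion_excess = manifest$dataset[
      manifest$expected_deletions >= 2 * manifest$expected_insertions])
  agg <- do.call(rbind, lapply(names(strata), function(s) {
    ids <- intersect(strata[[s]], names(counts))
    if (!length(ids))
      return(data.frame(stratum = s, n = 0L, agreement = NA_real_,
                        sensitivity = NA_real_, specificity = NA_real_))
    cs <- Reduce(`+`, counts[ids])
    data.frame(stratum = s, n = length(ids),
               agreement = cs[["label_matched"]] / cs[["label_total"]],
               sensitivity = cs[["matched"]] / cs[["true_pairs"]],
               specificity = cs[["matched"]] / cs[["pred_pairs"]])
  }))

  utils::write.table(report, report_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  agg_path <- sub("(\\.[^.]*)?$", "_aggregate.tsv",
                  report_path)
  utils::write.table(agg, agg_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(list(report = report, aggregate = agg))
}

#' Write the example fixture inputs
#'
#' Writes everything the pipeline consumes, so no external download is ever
#' needed: a synthetic eight-species tree on the overall (observed) scale, a
#' small set of empirical-distribution TSVs (branch-length vectors,
#' substitution:indel and insertion:deletion ratios, block fractions), a
#' small FASTA root pool, and an example conservation score track. All
#' values are synthetic stand-ins shaped like fly non-coding data, not
#' measurements.
#'
#' @param dir Output directory.
#' @return Named character vector of paths, invisibly.
#' @export
write_example_fixtures <- function(dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tree_txt <- paste0(
    "((((((dmel:0.02,dsim:0.02):0.01,dyak:0.04):0.04,dana:0.10):0.05,",
    "dpse:0.19):0.03,dwil:0.22):0.02,(dmoj:0.12,dgri:0.12):0.12);")
  tree_path <- file.path(dir, "tree_overall_synthetic.nwk")
  writeLines(tree_txt, tree_path)
  tree <- parse_newick(tree_txt)
  ne <- nrow(tree$edge)
  bl <- file.path(dir, "branch_lengths.tsv")
  base <- tree$edge.length
  con <- file(bl, "w")
  writeLines(paste(paste0("edge", seq_len(ne)), collapse = "\t"), con)
  for (f in c(0.5, 0.8, 1, 1.3, 1.8, 2.5))
    writeLines(paste(signif(base * f, 6), collapse = "\t"), con)
  close(con)
  scal <- list(
    sub_indel_ratio = c(6, 8, 10, 10, 12, 15, 20, 25, 35, 50),
    ins_del_ratio = c(0.4, 0.6, 0.8, 1, 1, 1.2, 1.6, 2.2),
    alpha = c(0.05, 0.1, 0.15, 0.2, 0.2, 0.25, 0.3, 0.4, 0.55))
  paths <- c(tree = tree_path, branch_lengths = bl)
  for (nm in names(scal)) {
    p <- file.path(dir, paste0(nm, ".tsv"))
    writeLines(format(scal[[nm]]), p)
    paths[nm] <- p
  }
  pool <- vapply(1:3, function(i) paste(
    sample(DNA_BASES, 3000, replace = TRUE), collapse = ""), character(1))
  names(pool) <- paste0("pool_seq", 1:3)
  paths["root_pool"] <- file.path(dir, "root_pool_synthetic.fasta")
  write_fasta(pool, paths[["root_pool"]])
  sc <- rep(0.2, 120); sc[31:60] <- 0.95; sc[91:104] <- 0.92
  gp <- rep(0L, 120); gp[45] <- 1L
  paths["score_track"] <- file.path(dir, "score_track_example.tsv")
  utils::write.table(data.frame(0:119, sc, gp), paths[["score_track"]],
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(paths)
}
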