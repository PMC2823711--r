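#' Compare a predicted alignment to the true alignment
#'
#' Three accuracy measures over unordered taxon pairs. Each residue of each
#' row, within a pair, has a partner: the residue of the other row sharing
#' its column, or "gap". *Agreement* is the fraction of partner assignments
#' (residue-residue and residue-gap, pooled over both rows of all pairs)
#' identical between predicted and true alignment. *Sensitivity* and
#' *specificity* use residue-residue pairs only: matched pairs divided by
#' true pairs, and by predicted pairs, respectively. Multi-species scores
#' pool counts over all pairs (micro-average); `aggregate = "macro"` averages
#' per-pair scores instead. Undefined ratios (0/0) are reported as `NA`,
#' never coerced to 0.
#'
#' @param predicted,truth `ncb_alignment`s over the same taxa with identical
#'   ungapped sequences.
#' @param aggregate `"micro"` (pooled counts, default) or `"macro"`.
#' @return Object of class `alignment_comparison`: list with `agreement`,
#'   `sensitivity`, `specificity`, `per_pair` (one row per unordered pair)
#'   and `counts`.
#' @export
compare_alignments <- function(predicted, truth,
                               aggregate = c("micro", "macro")) {
  aggregate <- match.arg(aggregate)
  stopifnot(inherits(predicted, "ncb_alignment"),
            inherits(truth, "ncb_alignment"))
  taxa <- sort(rownames(truth))
  if (!setequal(rownames(predicted), taxa))
    stop("predicted and true alignments must cover the same taxa")
  up <- ungapped_seqs(predicted); ut <- ungapped_seqs(truth)
  if (!identical(up[taxa], ut[taxa]))
    stop("ungapped sequences differ between predicted and true alignments")

  pairs <- utils::combn(taxa, 2L)
  pp <- vector("list", ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    a <- pairs[1L, k]; b <- pairs[2L, k]
    pr <- partner_vectors(predicted[a, ], predicted[b, ])
    tr <- partner_vectors(truth[a, ], truth[b, ])
    lab_match <- sum(pr$a == tr$a) + sum(pr$b == tr$b)
    lab_total <- length(pr$a) + length(pr$b)
    rr <- pr$a >= 0L & tr$a >= 0L & pr$a == tr$a
    matched <- sum(rr)
    true_pairs <- sum(tr$a >= 0L)
    pred_pairs <- sum(pr$a >= 0L)
    pp[[k]] <- data.frame(
      taxon_a = a, taxon_b = b,
      agreement = lab_match / lab_total,
      sensitivity = if (true_pairs > 0L) matched / true_pairs else NA_real_,
      specificity = if (pred_pairs > 0L) matched / pred_pairs else NA_real_,
      matched = matched, true_pairs = true_pairs, pred_pairs = pred_pairs,
      label_matched = lab_match, label_total = lab_total,
      stringsAsFactors = FALSE)
  }
  pp <- do.call(rbind, pp)
  counts <- c(matched = sum(pp$matched), true_pairs = sum(pp$true_pairs),
              pred_pairs = sum(pp$pred_pairs),
              label_matched = sum(pp$label_matched),
              label_total = sum(pp$label_total))
  if (aggregate == "micro") {
    agr <- counts[["label_matched"]] / counts[["label_total"]]
    sen <- if (counts[["true_pairs"]] > 0L)
      counts[["matched"]] / counts[["true_pairs"]] else NA_real_
    spe <- if (counts[["pred_pairs"]] > 0L)
      counts[["matched"]] / counts[["pred_pairs"]] else NA_real_
  } else {
    agr <- mean(pp$agreement)
    sen <- mean(pp$sensitivity, na.rm = TRUE)
    spe <- mean(pp$specificity, na.rm = TRUE)
  }
  structure(list(agreement = agr, sensitivity = sen, specificity = spe,
                 per_pair = pp, counts = counts, aggregate = aggregate),
            class = "alignment_comparison")
}

#' @export
print.alignment_comparison <- function(x, ...) {
  cat(sprintf(
    "alignment comparison (%s): agreement %.4f, sensitivity %s, specificity %s\n",
    x$aggregate, x$agreement, format(x$sensitivity, digits = 4),
    format(x$specificity, digits = 4)))
  invisible(x)
}

# ---- indel annotations ----------------------------------------------------

#' Per-branch indel annotation
#'
#' Each event is an insertion or deletion on one branch spanning a set of
#' true-alignment columns (0-based). Within a branch, events of the same
#' annotation must not share columns.
#'
#' @param branch Character vector of branch labels, one per event.
#' @param kind `"insertion"` or `"deletion"`, one per event.
#' @param columns List of integer vectors: the 0-based alignment columns each
#'   event spans.
#' @return Object of class `indel_annotation`.
#' @export
indel_annotation <- function(branch, kind, columns) {
  stopifnot(is.character(branch), is.character(kind), is.list(columns),
            length(branch) == length(kind),
            length(kind) == length(columns))
  if (length(kind) && !all(kind %in% c("insertion", "deletion")))
    stop("kind must be 'insertion' or 'deletion'")
  for (b in unique(branch)) {
    cols <- unlist(columns[branch == b])
    if (anyDuplicated(cols))
      stop("events on branch '", b, "' share alignment columns")
  }
  df <- data.frame(branch = branch, kind = kind, stringsAsFactors = FALSE)
  df$columns <- lapply(columns, as.integer)
  structure(df, class = c("indel_annotation", "data.frame"))
}

annotation_branch <- function(ann, branch) {
  stopifnot(inherits(ann, "indel_annotation"))
  ann[ann$branch == branch, , drop = FALSE]
}

branch_counts <- function(ann, branch) {
  x <- annotation_branch(ann, branch)
  c(ins = sum(x$kind == "insertion"), del = sum(x$kind == "deletion"))
}

#' Indel Count Agreement (ICA)
#'
#' Agreement of total indel counts between a true and a predicted
#' annotation on one branch:
#' `ICA = |(N_Ie + N_De) - (N_It + N_Dt)| / (N_It + N_Dt)`,
#' where `N_It`/`N_Dt` are true insertion/deletion counts and `N_Ie`/`N_De`
#' predicted ones. The optimum is 0, attained when total counts agree. The
#' closed form is a reconstruction consistent with the measure's stated
#' optimum and published score ranges.
#'
#' @param truth,predicted `indel_annotation`s.
#' @param branch Branch label present in both.
#' @return ICA, or `NA` when the truth has no indels on the branch.
#' @export
indel_count_agreement <- function(truth, predicted, branch) {
  tc <- branch_counts(truth, branch); pc <- branch_counts(predicted, branch)
  nt <- sum(tc)
  if (nt == 0L) return(NA_real_)
  abs(sum(pc) - nt) / nt
}

#' Indel Ratio Agreement (IRA)
#'
#' Agreement of the insertion fraction between annotations on one branch:
#' `IRA = [N_Ie / (N_Ie + N_De)] / [N_It / (N_It + N_Dt)]`. The optimum is
#' 1. Reconstruction, as for [indel_count_agreement()].
#'
#' @inheritParams indel_count_agreement
#' @return IRA, or `NA` when a denominator is zero (no events on the branch
#'   in either annotation, or no true insertions).
#' @export
indel_ratio_agreement <- function(truth, predicted, branch) {
  tc <- branch_counts(truth, branch); pc <- branch_counts(predicted, branch)
  if (sum(tc) == 0L || sum(pc) == 0L || tc[["ins"]] == 0L) return(NA_real_)
  (pc[["ins"]] / sum(pc)) / (tc[["ins"]] / sum(tc))
}

#' Indel Annotation Coverage (IAC)
#'
#' Position-level agreement between annotations on one branch. A position is
#' a (column, kind) item; sensitivity is the fraction of true positions also
#' predicted (with the same kind), specificity the fraction of predicted
#' positions that are true.
#'
#' @inheritParams indel_count_agreement
#' @return Named numeric vector `c(sensitivity=, specificity=)`; a component
#'   is `NA` when its denominator set is empty.
#' @export
indel_annotation_coverage <- function(truth, predicted, branch) {
  pos_set <- function(ann) {
    x <- annotation_branch(ann, branch)
    if (!nrow(x)) return(character(0))
    unlist(lapply(seq_len(nrow(x)),
                  function(i) paste0(x$kind[i], ":", x$columns[[i]])))
  }
  tp <- pos_set(truth); pp <- pos_set(predicted)
  inter <- length(intersect(tp, pp))
  c(sensitivity = if (length(tp)) inter / length(tp) else NA_real_,
    specificity = if (length(pp)) inter / length(pp) else NA_real_)
}
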