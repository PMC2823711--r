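#' Per-column conservation scores with gap flags
#'
#' @param scores Numeric vector of per-column conservation scores in
#'   `[0, 1]` (phastCons-like).
#' @param gapped Logical vector: `TRUE` where any alignment row has a gap in
#'   that column. Defaults to no gaps.
#' @return Object of class `scored_columns`.
#' @export
scored_columns <- function(scores, gapped = NULL) {
  stopifnot(is.numeric(scores), all(scores >= 0), all(scores <= 1))
  if (is.null(gapped)) gapped <- rep(FALSE, length(scores))
  stopifnot(is.logical(gapped), length(gapped) == length(scores),
            !anyNA(gapped))
  structure(list(scores = scores, gapped = gapped,
                 length = length(scores)), class = "scored_columns")
}

#' Read a conservation score track from TSV
#'
#' Two columns (0-based column index, score) or three (index, score, gapped
#' as 0/1). Indices must cover `0 .. n-1`.
#'
#' @param path TSV path (optional header detected).
#' @return A [scored_columns()].
#' @export
read_score_track <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  if (is.character(df[[1L]])) df <- df[-1L, , drop = FALSE]
  idx <- as.integer(df[[1L]]); sc <- as.numeric(df[[2L]])
  o <- order(idx)
  if (!identical(idx[o], seq_along(idx) - 1L))
    stop("score track indices must cover 0..n-1")
  g <- if (ncol(df) >= 3L) as.logical(as.integer(df[[3L]][o])) else NULL
  scored_columns(sc[o], g)
}

#' Detect conserved blocks from per-column conservation scores
#'
#' A conserved block is a maximal run of consecutive columns that are
#' non-gapped (no gap in any row) and whose score is at least `min_score`;
#' runs shorter than `min_run` columns are discarded. A gapped or low-score
#' column always terminates a run.
#'
#' @param columns A [scored_columns()].
#' @param min_run Minimum run length in columns (default 10).
#' @param min_score Inclusive score threshold (default 0.9).
#' @return Integer matrix with columns `start`, `end`: 0-based half-open
#'   alignment-column intervals.
#' @export
find_conserved_blocks <- function(columns, min_run = 10L, min_score = 0.9) {
  stopifnot(inherits(columns, "scored_columns"), min_run >= 1)
  ok <- !columns$gapped & columns$scores >= min_score
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_run
  cbind(start = starts[keep] - 1L, end = ends[keep])
}

#' Fraction of alignment columns inside blocks
#'
#' @param blocks Interval matrix as returned by [find_conserved_blocks()]
#'   (0-based half-open), or a `block_map`.
#' @param alignment_length Total number of columns.
#' @return Fraction in `[0, 1]`.
#' @export
block_fraction <- function(blocks, alignment_length) {
  if (inherits(blocks, "block_map"))
    blocks <- cbind(start = blocks$start, end = blocks$end)
  stopifnot(is.matrix(blocks) || (is.null(dim(blocks)) && length(blocks) == 0))
  if (is.null(dim(blocks)) || nrow(blocks) == 0L) return(0)
  stopifnot(alignment_length >= 1,
            all(blocks[, "start"] >= 0), all(blocks[, "end"] <= alignment_length),
            all(blocks[, "end"] > blocks[, "start"]))
  o <- order(blocks[, "start"])
  b <- blocks[o, , drop = FALSE]
  if (nrow(b) > 1L && any(b[-1L, "start"] < b[-nrow(b), "end"]))
    stop("overlapping block intervals")
  sum(b[, "end"] - b[, "start"]) / alignment_length
}

#' Project alignment-column intervals onto a reference row
#'
#' Maps 0-based half-open column intervals to the ungapped coordinates of
#' one alignment row (columns where the reference row is gapped contribute
#' no positions; an interval entirely inside a reference gap is dropped).
#'
#' @param blocks Interval matrix (`start`, `end` columns).
#' @param aln An `ncb_alignment`.
#' @param reference Row name.
#' @return Interval matrix in reference sequence coordinates.
#' @export
project_blocks <- function(blocks, aln, reference) {
  stopifnot(inherits(aln, "ncb_alignment"), reference %in% rownames(aln))
  row <- aln[reference, ]
  seqpos <- cumsum(row != "-")    # residues seen up to each column
  out <- matrix(integer(0), 0L, 2L, dimnames = list(NULL, c("start", "end")))
  for (i in seq_len(nrow(blocks))) {
    cols <- (blocks[i, "start"] + 1L):blocks[i, "end"]
    res <- seqpos[cols][row[cols] != "-"]
    if (length(res))
      out <- rbind(out, c(start = min(res) - 1L, end = max(res)))
  }
  out
}
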