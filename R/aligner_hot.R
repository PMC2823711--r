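#' @useDynLib ncbench, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

ALN_CODE <- c(A = 1L, C = 2L, G = 3L, T = 4L, N = 5L, "-" = 0L)

encode_profile <- function(seqs) {
  m <- do.call(rbind, strsplit(toupper(unname(seqs)), "", fixed = TRUE))
  bad <- !m %in% names(ALN_CODE)
  if (any(bad)) stop("sequence characters must be in {A,C,G,T,N,-}")
  p <- matrix(ALN_CODE[m], nrow = nrow(m))
  rownames(p) <- names(seqs)
  p
}

decode_profile <- function(p) {
  chars <- c("-", "A", "C", "G", "T", "N")
  m <- matrix(chars[p + 1L], nrow = nrow(p), dimnames = list(rownames(p), NULL))
  ncb_alignment(m)
}

reverse_strings <- function(x) {
  vapply(strsplit(x, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

kmer_distance <- function(seqs, k = 4L) {
  counts <- lapply(seqs, function(s) {
    n <- nchar(s)
    if (n < k) return(table(character(0)))
    table(substring(s, 1:(n - k + 1L), k:n))
  })
  nseq <- length(seqs)
  d <- matrix(0, nseq, nseq, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(nseq - 1L)) for (j in (i + 1L):nseq) {
    ci <- counts[[i]]; cj <- counts[[j]]
    shared <- intersect(names(ci), names(cj))
    ov <- sum(pmin(ci[shared], cj[shared]))
    d[i, j] <- d[j, i] <- 1 - 2 * ov / (sum(ci) + sum(cj))
  }
  stats::as.dist(d)
}

#' Built-in deterministic progressive aligner
#'
#' Global profile-profile alignment with affine gap penalties (match +5,
#' mismatch -4, gap open -10, gap extend -0.5 by default), merged
#' progressively along a guide tree under the "once a gap, always a gap"
#' rule. When no guide tree is given, a UPGMA tree on a shared-k-mer
#' distance is used. Entirely deterministic, which is what HoT scoring
#' requires; it is a convenience aligner, not a competitor to dedicated
#' alignment tools.
#'
#' @param sequences Named character vector of DNA sequences (no gaps).
#' @param guide Optional `phylo` guide tree whose tip labels match
#'   `names(sequences)`.
#' @param match,mismatch,gap_open,gap_extend Scoring parameters.
#' @return An [ncb_alignment()] with rows in input order.
#' @export
progressive_align <- function(sequences, guide = NULL, match = 5,
                              mismatch = -4, gap_open = -10,
                              gap_extend = -0.5) {
  if (is.null(names(sequences)) || any(!nzchar(names(sequences))))
    stop("sequences must be named")
  if (anyDuplicated(names(sequences))) stop("duplicate sequence names")
  if (length(sequences) < 2L) stop("need at least 2 sequences")
  if (any(nchar(sequences) == 0L)) stop("empty sequence")
  seqs <- toupper(sequences)

  merge_profiles <- function(pa, pb) {
    out <- cpp_profile_align(pa, pb, match, mismatch, gap_open, gap_extend)
    L <- length(out$ai)
    newa <- matrix(0L, nrow(pa), L)
    keep <- out$ai > 0L
    newa[, keep] <- pa[, out$ai[keep], drop = FALSE]
    newb <- matrix(0L, nrow(pb), L)
    keep <- out$bi > 0L
    newb[, keep] <- pb[, out$bi[keep], drop = FALSE]
    res <- rbind(newa, newb)
    rownames(res) <- c(rownames(pa), rownames(pb))
    res
  }

  profiles <- lapply(names(seqs), function(nm) encode_profile(seqs[nm]))
  names(profiles) <- names(seqs)

  if (!is.null(guide)) {
    guide <- validate_phylogeny(guide)
    if (!setequal(guide$tip.label, names(seqs)))
      stop("guide tree tips must match sequence names")
    build <- function(node) {
      ntip <- length(guide$tip.label)
      if (node <= ntip) return(profiles[[guide$tip.label[node]]])
      kids <- guide$edge[guide$edge[, 1L] == node, 2L]
      prof <- build(kids[1L])
      for (k in kids[-1L]) prof <- merge_profiles(prof, build(k))
      prof
    }
    final <- build(length(guide$tip.label) + 1L)
  } else if (length(seqs) == 2L) {
    final <- merge_profiles(profiles[[1L]], profiles[[2L]])
  } else {
    hc <- stats::hclust(kmer_distance(seqs), method = "average")
    sub <- vector("list", nrow(hc$merge))
    pick <- function(k) if (k < 0L) profiles[[-k]] else sub[[k]]
    for (s in seq_len(nrow(hc$merge)))
      sub[[s]] <- merge_profiles(pick(hc$merge[s, 1L]), pick(hc$merge[s, 2L]))
    final <- sub[[nrow(hc$merge)]]
  }
  aln <- decode_profile(final[names(seqs), , drop = FALSE])
  stopifnot(identical(unname(ungapped_seqs(aln)), unname(seqs)))
  aln
}

# ---- HoT scores -----------------------------------------------------------

check_hot_inputs <- function(aln_heads, aln_tails) {
  stopifnot(inherits(aln_heads, "ncb_alignment"),
            inherits(aln_tails, "ncb_alignment"))
  taxa <- sort(rownames(aln_heads))
  if (!setequal(rownames(aln_tails), taxa))
    stop("the two alignments must cover the same sequences")
  uh <- ungapped_seqs(aln_heads)[taxa]
  ut <- ungapped_seqs(aln_tails)[taxa]
  if (!identical(uh, ut))
    stop("ungapped sequences differ between the two alignments")
  taxa
}

pooled_pair_keys <- function(aln, taxa) {
  keys <- character(0)
  for (k in seq_len(length(taxa) - 1L)) for (l in (k + 1L):length(taxa)) {
    pv <- partner_vectors(aln[taxa[k], ], aln[taxa[l], ])
    p <- which(pv$a >= 0L)
    if (length(p))
      keys <- c(keys, paste0(k, ".", l, ":", p - 1L, ",", pv$a[p]))
  }
  keys
}

#' HoT sum-of-pairs agreement between two alignments
#'
#' Pools residue-residue pairs over all unordered row pairs of each
#' alignment and scores their agreement:
#' `100 * |P_H inters P_T| / ((|P_H| + |P_T|) / 2)` (or divided by `|P_H|`
#' with `denominator = "heads"`). Returns 100 when both pools are empty.
#'
#' @param aln_heads,aln_tails `ncb_alignment`s of the same sequences.
#' @param denominator `"mean"` (default) or `"heads"`.
#' @return Score in `[0, 100]`.
#' @export
hot_sps <- function(aln_heads, aln_tails, denominator = c("mean", "heads")) {
  denominator <- match.arg(denominator)
  taxa <- check_hot_inputs(aln_heads, aln_tails)
  kh <- pooled_pair_keys(aln_heads, taxa)
  kt <- pooled_pair_keys(aln_tails, taxa)
  denom <- if (denominator == "mean") (length(kh) + length(kt)) / 2
           else length(kh)
  if (denom == 0) return(100)
  100 * length(intersect(kh, kt)) / denom
}

column_signatures <- function(aln, taxa) {
  sub <- aln[taxa, , drop = FALSE]
  gaps <- sub == "-"
  res <- matrix("g", nrow(sub), ncol(sub))
  for (i in seq_len(nrow(sub)))
    res[i, !gaps[i, ]] <- as.character(seq_len(sum(!gaps[i, ])))
  sig <- apply(res, 2L, paste, collapse = "|")
  sig[colSums(!gaps) > 0L]          # drop all-gap columns
}

#' HoT column-score agreement between two alignments
#'
#' A column is the full assignment, per row, of a residue index or a gap.
#' After removing all-gap columns, the score is
#' `100 * shared columns / ((columns_H + columns_T) / 2)`.
#'
#' @inheritParams hot_sps
#' @return Score in `[0, 100]`; 100 iff the alignments are identical up to
#'   all-gap-column removal.
#' @export
hot_cs <- function(aln_heads, aln_tails, denominator = c("mean", "heads")) {
  denominator <- match.arg(denominator)
  taxa <- check_hot_inputs(aln_heads, aln_tails)
  sh <- column_signatures(aln_heads, taxa)
  st <- column_signatures(aln_tails, taxa)
  denom <- if (denominator == "mean") (length(sh) + length(st)) / 2
           else length(sh)
  if (denom == 0) return(100)
  100 * length(intersect(sh, st)) / denom
}

#' Heads-or-tails (HoT) reliability scoring of an alignment task
#'
#' Aligns the sequences as given ("heads"), then reverses every sequence,
#' aligns the reversed set, and reverses the resulting alignment's columns so
#' that it is again an alignment of the original sequences ("tails"). A
#' trustworthy alignment should not depend on sequence orientation, so the
#' agreement between heads and tails — the SPS and CS scores — serves as a
#' reference-free surrogate for alignment reliability.
#'
#' @param sequences Named ungapped DNA sequences.
#' @param aligner Deterministic aligner: `function(sequences) -> ncb_alignment`
#'   (default: the built-in [progressive_align()]).
#' @param ... Passed to [hot_sps()] and [hot_cs()] (e.g. `denominator`).
#' @return Named numeric vector `c(sps=, cs=)`.
#' @export
hot_pipeline <- function(sequences, aligner = progressive_align, ...) {
  if (length(sequences) < 2L) stop("need at least 2 sequences")
  heads <- aligner(sequences)
  rev_aln <- aligner(reverse_strings(sequences))
  tails <- reverse_alignment(rev_aln)
  c(sps = hot_sps(heads, tails, ...), cs = hot_cs(heads, tails, ...))
}

#' Wrap an external command-line aligner as an adapter
#'
#' Builds a `function(sequences) -> ncb_alignment` that writes the sequences
#' as FASTA, runs a shell command (with `{input}` and `{output}` placeholders;
#' if `{output}` is absent, standard output is captured), reads the gapped
#' multi-FASTA result, re-orders rows by name and verifies that sequence
#' content was preserved.
#'
#' @param command_template Shell command, e.g.
#'   `"mafft --retree 1 {input} > {output}"`.
#' @return An aligner adapter function usable with [hot_pipeline()].
#' @export
make_command_aligner <- function(command_template) {
  force(command_template)
  function(sequences) {
    inp <- tempfile(fileext = ".fa"); outp <- tempfile(fileext = ".fa")
    on.exit(unlink(c(inp, outp)))
    write_fasta(sequences, inp)
    cmd <- gsub("{input}", inp, command_template, fixed = TRUE)
    has_out <- grepl("{output}", command_template, fixed = TRUE)
    cmd <- gsub("{output}", outp, cmd, fixed = TRUE)
    if (!has_out) cmd <- paste(cmd, ">", outp)
    status <- system(cmd)
    if (status != 0L)
      stop("external aligner failed (exit ", status, "): ", cmd)
    aln <- read_alignment_fasta(outp)
    if (!setequal(rownames(aln), names(sequences)))
      stop("external aligner changed the sequence set")
    aln <- ncb_alignment(unclass(aln)[names(sequences), , drop = FALSE])
    if (!identical(unname(ungapped_seqs(aln)), unname(toupper(sequences))))
      stop("external aligner did not preserve sequence content")
    aln
  }
}
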