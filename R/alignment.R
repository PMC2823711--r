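ALN_ALPHABET <- c("A", "C", "G", "T", "N", "-")

#' Multiple alignment container
#'
#' A multiple alignment is stored as a character matrix (one row per taxon,
#' one column per alignment column) over the alphabet `A C G T N -`.
#'
#' @param x Either a character matrix of single characters with row names, or
#'   a named character vector of equal-length gapped strings.
#' @param drop_all_gap Remove columns that are gaps in every row.
#' @return Object of class `ncb_alignment` (a character matrix).
#' @export
ncb_alignment <- function(x, drop_all_gap = FALSE) {
  if (is.character(x) && !is.matrix(x)) {
    if (is.null(names(x)) || any(!nzchar(names(x))))
      stop("sequences must be named")
    if (length(unique(nchar(x))) != 1L)
      stop("alignment rows must have equal length")
    nm <- names(x)
    x <- do.call(rbind, strsplit(toupper(unname(x)), "", fixed = TRUE))
    rownames(x) <- nm
  }
  if (!is.matrix(x) || !is.character(x)) stop("expected a character matrix")
  if (is.null(rownames(x)) || any(!nzchar(rownames(x))))
    stop("alignment rows must be named")
  if (anyDuplicated(rownames(x))) stop("duplicate taxon names")
  if (ncol(x) && !all(x %in% ALN_ALPHABET))
    stop("alignment characters must be in {A,C,G,T,N,-}")
  if (drop_all_gap && ncol(x)) {
    keep <- colSums(x != "-") > 0L
    x <- x[, keep, drop = FALSE]
  }
  structure(x, class = c("ncb_alignment", class(matrix())))
}

aln_from_strings <- function(seqs) {
  m <- do.call(rbind, strsplit(toupper(unname(seqs)), "", fixed = TRUE))
  rownames(m) <- names(seqs)
  ncb_alignment(m)
}

#' @export
print.ncb_alignment <- function(x, ...) {
  cat(sprintf("multiple alignment: %d rows x %d columns\n", nrow(x), ncol(x)))
  w <- min(60L, ncol(x))
  for (i in seq_len(min(8L, nrow(x))))
    cat(sprintf("  %-12s %s%s\n", rownames(x)[i],
                paste(x[i, seq_len(w)], collapse = ""),
                if (ncol(x) > w) "..." else ""))
  invisible(x)
}

#' Ungapped sequences of an alignment
#' @param aln An `ncb_alignment`.
#' @return Named character vector of ungapped row texts.
#' @export
ungapped_seqs <- function(aln) {
  stopifnot(inherits(aln, "ncb_alignment"))
  out <- apply(aln, 1L, function(r) paste(r[r != "-"], collapse = ""))
  names(out) <- rownames(aln)
  out
}

#' Reverse an alignment
#'
#' Reverses the column order (equivalently: reverses each row's text),
#' turning the alignment of reversed sequences back into an alignment of the
#' original sequences. Used by the HoT protocol.
#'
#' @param aln An `ncb_alignment`.
#' @return The column-reversed alignment.
#' @export
reverse_alignment <- function(aln) {
  stopifnot(inherits(aln, "ncb_alignment"))
  if (ncol(aln) == 0L) return(aln)
  ncb_alignment(aln[, rev(seq_len(ncol(aln))), drop = FALSE])
}

# ---- FASTA I/O (via Biostrings; '-' gaps allowed) ------------------------

#' Read sequences (or a gapped alignment) from FASTA
#'
#' @param path FASTA file path.
#' @return Named character vector (names are the first whitespace-delimited
#'   token of each header).
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write sequences to FASTA
#' @param seqs Named character vector.
#' @param path Output path.
#' @param width Line wrap width.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path,
                              width = max(width, 1L))
  invisible(path)
}

#' @rdname read_fasta
#' @export
read_alignment_fasta <- function(path) aln_from_strings(read_fasta(path))

#' @rdname write_fasta
#' @param aln An `ncb_alignment`.
#' @export
write_alignment_fasta <- function(aln, path, width = 70L) {
  stopifnot(inherits(aln, "ncb_alignment"))
  rows <- apply(aln, 1L, paste, collapse = "")
  names(rows) <- rownames(aln)
  write_fasta(rows, path, width)
}

# ---- residue partner machinery -------------------------------------------
# For one unordered row pair, each residue's partner in the other row is
# either a residue index or "gap". Encoded as an integer vector over the
# residues of each row: 0-based partner index, or -1 for gap-partnered.

partner_vectors <- function(rowA, rowB) {
  agap <- rowA == "-"; bgap <- rowB == "-"
  ra <- cumsum(!agap)          # residue index (1-based) of A at each column
  rb <- cumsum(!bgap)
  acols <- which(!agap); bcols <- which(!bgap)
  a_partner <- ifelse(bgap[acols], -1L, rb[acols] - 1L)
  b_partner <- ifelse(agap[bcols], -1L, ra[bcols] - 1L)
  list(a = as.integer(a_partner), b = as.integer(b_partner))
}

#' Residue homology pairs of one row pair
#'
#' Extracts, for rows `i` and `j` of an alignment, the set of residue pairs
#' `(p, q)` such that residue `p` of row `i` shares a column with residue `q`
#' of row `j` (0-based indices into the ungapped sequences), plus each
#' residue's partner label (`-1` marks a residue whose column has a gap in
#' the other row).
#'
#' @param aln An `ncb_alignment`.
#' @param row_i,row_j Row names or indices.
#' @return List with `pairs` (2-column integer matrix), `partner_i` and
#'   `partner_j` (per-residue partner vectors).
#' @export
homology_pairs <- function(aln, row_i, row_j) {
  stopifnot(inherits(aln, "ncb_alignment"))
  get_row <- function(k) {
    if (is.character(k) && !k %in% rownames(aln)) stop("unknown row: ", k)
    aln[k, ]
  }
  pv <- partner_vectors(get_row(row_i), get_row(row_j))
  p <- which(pv$a >= 0L)
  pairs <- cbind(i = p - 1L, j = pv$a[p])
  list(pairs = pairs, partner_i = pv$a, partner_j = pv$b)
}
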