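# Independent brute-force oracles and toy-data generators used across tests.
# These deliberately avoid the package's vectorized code paths.

# pure-R Gotoh DP returning only the optimal global affine-gap score
oracle_affine_score <- function(a, b, match = 5, mis = -4, go = -10,
                                ge = -0.5) {
  A <- strsplit(a, "", fixed = TRUE)[[1]]
  B <- strsplit(b, "", fixed = TRUE)[[1]]
  n <- length(A); m <- length(B)
  M <- matrix(-Inf, n + 1, m + 1); X <- M; Y <- M
  M[1, 1] <- 0
  for (i in seq_len(n) + 1) X[i, 1] <- go + (i - 1) * ge
  for (j in seq_len(m) + 1) Y[1, j] <- go + (j - 1) * ge
  for (i in seq_len(n) + 1) for (j in seq_len(m) + 1) {
    s <- if (A[i - 1] == B[j - 1]) match else mis
    M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + s
    X[i, j] <- max(M[i - 1, j] + go + ge, X[i - 1, j] + ge)
    Y[i, j] <- max(M[i, j - 1] + go + ge, Y[i, j - 1] + ge)
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# score a realized pairwise alignment under the same affine convention
# (each maximal run of columns gapped in the same row is one gap)
score_pairwise_alignment <- function(aln, match = 5, mis = -4, go = -10,
                                     ge = -0.5) {
  a <- aln[1, ]; b <- aln[2, ]
  s <- 0; gap_a <- FALSE; gap_b <- FALSE
  for (k in seq_along(a)) {
    if (a[k] == "-") {
      if (!gap_a) s <- s + go
      s <- s + ge; gap_a <- TRUE; gap_b <- FALSE
    } else if (b[k] == "-") {
      if (!gap_b) s <- s + go
      s <- s + ge; gap_b <- TRUE; gap_a <- FALSE
    } else {
      s <- s + if (a[k] == b[k]) match else mis
      gap_a <- gap_b <- FALSE
    }
  }
  s
}

# explicit column-walking partner enumeration for one row pair:
# returns character labels, one per residue of each row ("q<index>" or "gap")
oracle_partner_labels <- function(rowA, rowB) {
  la <- character(0); lb <- character(0)
  pa <- 0L; pb <- 0L
  for (k in seq_along(rowA)) {
    ra <- rowA[k] != "-"; rb <- rowB[k] != "-"
    if (ra) pa <- pa + 1L
    if (rb) pb <- pb + 1L
    if (ra) la <- c(la, if (rb) paste0("q", pb - 1L) else "gap")
    if (rb) lb <- c(lb, if (ra) paste0("q", pa - 1L) else "gap")
  }
  list(a = la, b = lb)
}

# brute-force version of compare_alignments (micro-averaged)
oracle_compare <- function(pred, truth) {
  taxa <- sort(rownames(truth))
  lab_match <- 0; lab_total <- 0
  matched <- 0; true_pairs <- 0; pred_pairs <- 0
  for (i in seq_len(length(taxa) - 1L)) for (j in (i + 1L):length(taxa)) {
    a <- taxa[i]; b <- taxa[j]
    P <- oracle_partner_labels(pred[a, ], pred[b, ])
    T <- oracle_partner_labels(truth[a, ], truth[b, ])
    lab_match <- lab_match + sum(P$a == T$a) + sum(P$b == T$b)
    lab_total <- lab_total + length(P$a) + length(P$b)
    rr_p <- P$a != "gap"; rr_t <- T$a != "gap"
    matched <- matched + sum(rr_p & rr_t & P$a == T$a)
    true_pairs <- true_pairs + sum(rr_t)
    pred_pairs <- pred_pairs + sum(rr_p)
  }
  list(agreement = lab_match / lab_total,
       sensitivity = if (true_pairs) matched / true_pairs else NA_real_,
       specificity = if (pred_pairs) matched / pred_pairs else NA_real_)
}

# random gapped alignment of the given ungapped sequences (valid by
# construction: row order of residues preserved, no all-gap columns)
random_alignment_of <- function(seqs) {
  lens <- nchar(seqs)
  L <- max(lens) + sample.int(6L, 1L) - 1L
  rows <- matrix("-", nrow = length(seqs), ncol = L,
                 dimnames = list(names(seqs), NULL))
  for (i in seq_along(seqs)) {
    n <- nchar(seqs[[i]])
    rows[i, sort(sample.int(L, n))] <- strsplit(seqs[[i]], "",
                                                fixed = TRUE)[[1]]
  }
  keep <- colSums(rows != "-") > 0L
  ncb_alignment(rows[, keep, drop = FALSE])
}

random_toy_sequences <- function(n_taxa = NULL) {
  if (is.null(n_taxa)) n_taxa <- sample(2:5, 1L)
  seqs <- vapply(seq_len(n_taxa), function(i)
    paste(sample(c("A", "C", "G", "T"), sample(1:8, 1L), replace = TRUE),
          collapse = ""), character(1))
  names(seqs) <- paste0("t", seq_len(n_taxa))
  seqs
}

toy_tree <- function() parse_newick("((A:0.2,B:0.2):0.1,(C:0.2,D:0.2):0.1);")
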