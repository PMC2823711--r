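#' Parse a Newick tree
#'
#' Reads a single rooted Newick expression into an [ape::phylo] object and
#' validates it for use as a simulation phylogeny: unique non-empty leaf
#' labels and finite, non-negative branch lengths (a branch with no length
#' annotation defaults to 0).
#'
#' @param text Newick text, a single tree terminated by `;`.
#' @return An object of class `phylo` (see \pkg{ape}).
#' @examples
#' tr <- parse_newick("((A:0.1,B:0.1):0.05,C:0.2);")
#' sum(tr$edge.length)
#' @export
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  text <- trimws(text)
  if (!nzchar(text) || !endsWith(text, ";"))
    stop("Newick text must be a single expression terminated by ';'")
  # balance check up front so we can report a position; ape's message is vague
  depth <- 0L
  chars <- strsplit(text, "", fixed = TRUE)[[1L]]
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") depth <- depth - 1L
    if (depth < 0L)
      stop(sprintf("unbalanced parenthesis at position %d", i))
  }
  if (depth != 0L)
    stop("unbalanced parentheses: ", depth, " '(' left open")
  tree <- tryCatch(
    ape::read.tree(text = text),
    error = function(e) stop("malformed Newick: ", conditionMessage(e)),
    warning = function(w) stop("malformed Newick: ", conditionMessage(w))
  )
  if (is.null(tree)) stop("malformed Newick: unparseable text")
  validate_phylogeny(tree)
}

#' @rdname parse_newick
#' @param tree A `phylo` object.
#' @param path File path; when `NULL`, the Newick string is returned.
#' @export
write_newick <- function(tree, path = NULL) {
  tree <- validate_phylogeny(tree)
  txt <- ape::write.tree(tree, digits = 12)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' Validate a simulation phylogeny
#'
#' @param tree A `phylo` object.
#' @return The tree, invisibly unchanged, with `NULL` branch lengths replaced
#'   by zeros.
#' @keywords internal
validate_phylogeny <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a 'phylo' object")
  if (is.null(tree$edge.length))
    tree$edge.length <- rep(0, nrow(tree$edge))
  if (anyNA(tree$edge.length) || any(!is.finite(tree$edge.length)))
    stop("branch lengths must be finite")
  bad <- which(tree$edge.length < 0)
  if (length(bad))
    stop(sprintf("negative branch length (%g) on edge %d",
                 tree$edge.length[bad[1L]], bad[1L]))
  lab <- tree$tip.label
  if (any(!nzchar(lab))) stop("empty leaf label")
  if (anyDuplicated(lab))
    stop("duplicate leaf label: ", lab[anyDuplicated(lab)])
  tree
}

#' Scale every branch length by a constant factor
#'
#' Multiplies all branch lengths of the phylogeny by `factor` (the tree-scale
#' factor often written as tau), leaving the topology untouched. Used to
#' build families of scaled phylogenies for mixture-model simulation.
#'
#' @param tree A `phylo` object.
#' @param factor Positive scalar.
#' @return The scaled `phylo` object.
#' @export
scale_tree <- function(tree, factor) {
  tree <- validate_phylogeny(tree)
  if (!is.numeric(factor) || length(factor) != 1L || !is.finite(factor) ||
      factor <= 0)
    stop("scale factor must be a positive finite scalar")
  tree$edge.length <- tree$edge.length * factor
  tree
}

#' Convert observed overall branch lengths to neutral-scale branch lengths
#'
#' Branch lengths estimated from whole non-coding alignments average the slow
#' rate inside conserved blocks with the neutral rate outside. If a fraction
#' `alpha` of the sequence lies in blocks evolving at `beta` times the
#' neutral rate, the overall rate `t_o` and neutral rate `t_n` are related by
#' `t_o = t_n * (alpha * beta + 1 - alpha)`. The simulator's phylogeny must
#' carry neutral rates, so observed branch lengths are divided by
#' `alpha * beta + 1 - alpha`.
#'
#' @param tree A `phylo` object with overall (block-averaged) branch lengths.
#' @param alpha Fraction of sequence length inside conserved blocks, in
#'   `[0, 1]`.
#' @param beta Ratio of the block rate to the neutral rate, in `(0, 1]`.
#' @return Tree with every branch length divided by
#'   `alpha * beta + 1 - alpha`.
#' @seealso [overall_rate()], [conserved_fraction_for_rates()]
#' @export
adjust_branch_lengths <- function(tree, alpha, beta) {
  tree <- validate_phylogeny(tree)
  check_alpha_beta(alpha, beta)
  f <- alpha * beta + 1 - alpha
  if (f <= 0) stop("alpha*beta + 1 - alpha must be positive")
  tree$edge.length <- tree$edge.length / f
  tree
}

check_alpha_beta <- function(alpha, beta) {
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) ||
      alpha < 0 || alpha > 1)
    stop("alpha must be a fraction in [0, 1]")
  if (!is.numeric(beta) || length(beta) != 1L || is.na(beta) ||
      beta <= 0 || beta > 1)
    stop("beta must be in (0, 1]")
  invisible(TRUE)
}

#' Overall (block-averaged) rate implied by a neutral rate
#'
#' Forward form of the block-averaging relation:
#' `t_o = t_n * (alpha * beta + 1 - alpha)`.
#'
#' @param t_n Neutral rate (expected substitutions per site outside blocks).
#' @param alpha,beta Block coverage fraction and block:neutral rate ratio.
#' @return Overall rate `t_o`.
#' @export
overall_rate <- function(t_n, alpha, beta) {
  check_alpha_beta(alpha, beta)
  stopifnot(is.numeric(t_n), all(t_n >= 0))
  t_n * (alpha * beta + 1 - alpha)
}

#' Conserved fraction consistent with an observed overall/neutral rate pair
#'
#' Solves `t_o = t_n * (alpha * beta + 1 - alpha)` for `alpha`:
#' `alpha = (1 - t_o / t_n) / (1 - beta)`.
#'
#' @param t_o Observed overall rate.
#' @param t_n Assumed neutral rate; must satisfy `t_o <= t_n`.
#' @param beta Block:neutral rate ratio, strictly below 1.
#' @return The conserved-block coverage fraction `alpha`.
#' @export
conserved_fraction_for_rates <- function(t_o, t_n, beta) {
  stopifnot(is.numeric(t_o), is.numeric(t_n), t_o >= 0, t_n > 0)
  if (!is.numeric(beta) || beta <= 0 || beta >= 1)
    stop("beta must be in (0, 1) to solve for alpha")
  alpha <- (1 - t_o / t_n) / (1 - beta)
  if (alpha < 0 || alpha > 1)
    stop(sprintf("rates imply alpha = %.4f outside [0, 1]", alpha))
  alpha
}
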