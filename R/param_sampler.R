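#' Empirical parameter distribution
#'
#' A sampleable collection of observed parameter values: scalars (one number
#' per genomic fragment, e.g. a substitution:indel ratio) or fixed-length
#' vectors (e.g. one branch-length vector per fragment). Sampling returns an
#' observation verbatim; weights bias the draw.
#'
#' @param observations Numeric vector (scalar kind) or a matrix / list of
#'   equal-length numeric vectors (vector kind).
#' @param label Name of the parameter the distribution describes.
#' @param weights Optional positive per-observation weights.
#' @return Object of class `empirical_distribution`.
#' @export
empirical_distribution <- function(observations, label = "param",
                                   weights = NULL) {
  if (is.list(observations)) {
    dims <- lengths(observations)
    if (!length(dims)) stop("empty distribution")
    if (length(unique(dims)) != 1L) stop("ragged vector observations")
    observations <- do.call(rbind, observations)
  }
  if (is.matrix(observations)) {
    kind <- "vector"
    n <- nrow(observations)
  } else {
    stopifnot(is.numeric(observations))
    kind <- "scalar"
    n <- length(observations)
  }
  if (n == 0L) stop("empty distribution")
  if (anyNA(observations)) stop("non-numeric or missing observation")
  if (is.null(weights)) weights <- rep(1, n)
  stopifnot(length(weights) == n, all(weights > 0))
  structure(list(label = label, kind = kind, observations = observations,
                 weights = weights / sum(weights)),
            class = "empirical_distribution")
}

#' @export
print.empirical_distribution <- function(x, ...) {
  n <- if (x$kind == "vector") nrow(x$observations) else length(x$observations)
  dim <- if (x$kind == "vector") ncol(x$observations) else 1L
  cat(sprintf("empirical distribution '%s': %d %s observations (dim %d)\n",
              x$label, n, x$kind, dim))
  invisible(x)
}

n_obs <- function(d) {
  if (d$kind == "vector") nrow(d$observations) else length(d$observations)
}

#' Draw one observation from an empirical distribution
#' @param d An `empirical_distribution`.
#' @return A scalar, or a numeric vector for vector-kind distributions.
#' @export
sample_observation <- function(d) {
  stopifnot(inherits(d, "empirical_distribution"))
  i <- sample.int(n_obs(d), 1L, prob = d$weights)
  if (d$kind == "vector") d$observations[i, ] else d$observations[i]
}

#' Load an empirical distribution from a TSV file
#'
#' Scalar kind: one numeric value per line. Vector kind: tab-separated
#' numeric fields, one observation per line, all lines the same width; an
#' optional header line naming the components (e.g. branches in tree
#' traversal order) is detected as a non-numeric first line.
#'
#' @param path TSV file path.
#' @param kind `"scalar"` or `"vector"`.
#' @param label Distribution label (defaults to the file name).
#' @return An [empirical_distribution()].
#' @export
load_distribution <- function(path, kind = c("scalar", "vector"),
                              label = NULL) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(label)) label <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty distribution file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- NULL
  if (suppressWarnings(anyNA(as.numeric(fields[[1L]])))) {
    header <- fields[[1L]]
    fields <- fields[-1L]
    if (!length(fields)) stop("no data rows in ", path)
  }
  vals <- lapply(seq_along(fields), function(i) {
    v <- suppressWarnings(as.numeric(fields[[i]]))
    if (anyNA(v))
      stop(sprintf("non-numeric field at data row %d of %s", i, path))
    v
  })
  if (kind == "scalar") {
    if (any(lengths(vals) != 1L))
      stop(sprintf("row %d of %s is not a single value",
                   which(lengths(vals) != 1L)[1L], path))
    d <- empirical_distribution(unlist(vals), label)
  } else {
    w <- lengths(vals)
    if (length(unique(w)) != 1L)
      stop(sprintf("ragged vector at data row %d of %s (width %d, expected %d)",
                   which(w != w[1L])[1L], path, w[which(w != w[1L])[1L]],
                   w[1L]))
    d <- empirical_distribution(vals, label)
    if (!is.null(header)) colnames(d$observations) <- header
  }
  d
}

#' Sample a complete parameter draw from registered distributions
#'
#' Draws one value per registered distribution and returns the template
#' parameter set with those values substituted. Parameter types are sampled
#' independently of each other; a branch-length vector, when registered
#' under `"branch_lengths"`, replaces the template tree's branch lengths
#' jointly (preserving inter-branch correlation) in `ape` edge order, and
#' [adjust_branch_lengths()] is then applied with the (possibly drawn)
#' `alpha` and the template `beta` to convert the observed overall rates to
#' the neutral scale. Recognized labels: `branch_lengths`,
#' `sub_indel_ratio`, `ins_del_ratio`, `alpha`.
#'
#' @param registry Named list of [empirical_distribution()]s (may be empty:
#'   the template is returned unchanged, i.e. traditional mode).
#' @param template An [evolution_params()] supplying every unregistered
#'   value; its tree is on the *overall* (observed) scale when
#'   `branch_lengths` is registered, neutral scale otherwise.
#' @return An [evolution_params()] carrying the draw, with attribute
#'   `"draw"` (named list of the sampled raw values).
#' @export
sample_parameters <- function(registry, template) {
  stopifnot(inherits(template, "evolution_params"))
  stopifnot(is.list(registry))
  known <- c("branch_lengths", "sub_indel_ratio", "ins_del_ratio", "alpha")
  bad <- setdiff(names(registry), known)
  if (length(bad)) stop("unknown distribution label(s): ",
                        paste(bad, collapse = ", "))
  draw <- list()
  p <- template
  for (nm in c("sub_indel_ratio", "ins_del_ratio", "alpha")) {
    if (!is.null(registry[[nm]])) {
      v <- sample_observation(registry[[nm]])
      draw[[nm]] <- v
      p[[nm]] <- v
    }
  }
  if (p$alpha < 0 || p$alpha >= 1) stop("drawn alpha outside [0, 1)")
  if (!is.null(registry$branch_lengths)) {
    v <- sample_observation(registry$branch_lengths)
    ne <- nrow(p$tree$edge)
    if (length(v) != ne)
      stop(sprintf("branch-length vector dimension %d != %d tree edges",
                   length(v), ne))
    draw$branch_lengths <- v
    tr <- p$tree
    tr$edge.length <- v
    p$tree <- adjust_branch_lengths(tr, p$alpha, p$beta)
  }
  out <- do.call(evolution_params, p[c(
    "tree", "sub_indel_ratio", "ins_del_ratio", "indel_model", "alpha",
    "beta", "root_length", "base_freqs", "block_sampler",
    "indel_block_scaling", "insert_inherit")])
  attr(out, "draw") <- draw
  out
}

# ---- EM over mixture weights ---------------------------------------------

#' Fit mixture weights over fixed component score densities by EM
#'
#' The component densities are fixed (one binned density per candidate
#' parameter setting, e.g. per scaled phylogeny); only the mixture weights
#' are trained, by expectation-maximization on observations binned on the
#' same edges. E-step: responsibilities proportional to `w_k * f_k(bin(x))`;
#' M-step: each weight is the mean responsibility. The log-likelihood is
#' non-decreasing across iterations.
#'
#' @param component_histograms `K x B` matrix of component densities over
#'   `B` equal bins spanning `[0, 100]` (rows are renormalized after adding
#'   `pseudocount` to every bin).
#' @param observations Numeric scores within `[0, 100]`.
#' @param max_iter Maximum EM iterations.
#' @param tol Stop when the log-likelihood gain drops below this.
#' @param init Initial weights (default uniform).
#' @param pseudocount Added to every bin before renormalization.
#' @return Object of class `mixture_fit`: list with `weights`,
#'   `loglik_trace`, `n_iter`, `K`.
#' @export
fit_mixture_weights <- function(component_histograms, observations,
                                max_iter = 1000L, tol = 1e-8,
                                init = NULL, pseudocount = 1e-6) {
  f <- as.matrix(component_histograms)
  K <- nrow(f); B <- ncol(f)
  stopifnot(K >= 1L, B >= 1L, all(f >= 0))
  stopifnot(is.numeric(observations), length(observations) >= 1L,
            all(observations >= 0), all(observations <= 100))
  f <- f + pseudocount
  f <- f / rowSums(f)
  bins <- pmin(pmax(ceiling(observations / (100 / B)), 1L), B)
  fx <- f[, bins, drop = FALSE]          # K x n component mass at each obs
  if (any(colSums(fx) == 0))
    stop("an observation falls in a bin with zero mass in every component; ",
         "increase the pseudocount")
  w <- if (is.null(init)) rep(1 / K, K) else init / sum(init)
  stopifnot(length(w) == K, all(w >= 0))
  trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    mix <- as.numeric(crossprod(fx, w))  # n: sum_k w_k f_k(bin(x))
    ll <- sum(log(mix))
    trace <- c(trace, ll)
    if (it > 1L && ll - trace[it - 1L] < tol) break
    resp <- (fx * w) / rep(mix, each = K)
    w <- rowMeans(resp)
  }
  structure(list(weights = w, loglik_trace = trace, n_iter = length(trace),
                 K = K), class = "mixture_fit")
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf("mixture fit: K = %d, %d EM iterations, logL %.4f\n",
              x$K, x$n_iter, x$loglik_trace[x$n_iter]))
  cat("weights:", paste(sprintf("%.4f", x$weights), collapse = " "), "\n")
  invisible(x)
}

#' Bin scores into a normalized histogram density over [0, 100]
#'
#' @param scores Numeric scores in `[0, 100]`.
#' @param bins Number of equal bins (default 100).
#' @return Numeric vector of bin probabilities summing to 1.
#' @export
score_histogram <- function(scores, bins = 100L) {
  stopifnot(all(scores >= 0), all(scores <= 100))
  idx <- pmin(pmax(ceiling(scores / (100 / bins)), 1L), bins)
  tabulate(idx, nbins = bins) / length(scores)
}
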