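DNA_BASES <- c("A", "C", "G", "T")

#' Mixture-of-two-geometrics indel length model
#'
#' Indel lengths follow `w * Geom(q1) + (1 - w) * Geom(q2)` on support
#' `{1, 2, ...}`, so the mean length is `w/q1 + (1-w)/q2`. The default
#' parameters are fixture values giving a short-indel-dominated distribution
#' with a long tail (mean 7.4 bp), typical of non-coding indel spectra; they
#' are meant to be replaced by values fitted to the data being emulated.
#'
#' @param w Mixture weight of the first component, in `[0, 1]`.
#' @param q1,q2 Geometric success parameters in `(0, 1]`; mean length of a
#'   component is `1/q`.
#' @return An object of class `indel_length_model`.
#' @export
indel_length_model <- function(w = 0.7, q1 = 0.5, q2 = 0.05) {
  stopifnot(is.numeric(w), w >= 0, w <= 1,
            is.numeric(q1), q1 > 0, q1 <= 1,
            is.numeric(q2), q2 > 0, q2 <= 1)
  structure(list(w = w, q1 = q1, q2 = q2), class = "indel_length_model")
}

#' Draw indel lengths from a mixture-of-geometrics model
#'
#' @param model An [indel_length_model()].
#' @param n Number of draws.
#' @return Integer vector of lengths, all `>= 1`.
#' @export
sample_indel_length <- function(model, n = 1L) {
  stopifnot(inherits(model, "indel_length_model"))
  first <- stats::runif(n) < model$w
  len <- integer(n)
  len[first] <- stats::rgeom(sum(first), model$q1) + 1L
  len[!first] <- stats::rgeom(sum(!first), model$q2) + 1L
  len
}

#' @export
print.indel_length_model <- function(x, ...) {
  cat(sprintf(
    "indel length model: %.2f * Geom(%.3g) + %.2f * Geom(%.3g), mean %.2f bp\n",
    x$w, x$q1, 1 - x$w, x$q2, x$w / x$q1 + (1 - x$w) / x$q2))
  invisible(x)
}

#' Geometric block-length sampler
#'
#' Returns a sampler function for conserved-block lengths, geometric on
#' `{1, 2, ...}` with the given mean. The mean is attached as an attribute so
#' that [place_conserved_blocks()] can size spacers without extra sampling.
#'
#' @param mean Mean block length in bp (> 1).
#' @return `function(n)` drawing `n` integer lengths, with attribute `"mean"`.
#' @export
geometric_block_sampler <- function(mean = 50) {
  stopifnot(is.numeric(mean), mean > 1)
  f <- function(n) stats::rgeom(n, 1 / mean) + 1L
  attr(f, "mean") <- mean
  f
}

#' Place conserved blocks on a root sequence
#'
#' Lays out alternating neutral spacers and conserved blocks left to right.
#' Spacer lengths are geometric (support `{0, 1, ...}`) with mean
#' `mu_b * (1 - alpha) / alpha` where `mu_b` is the mean block length, so
#' that the long-run fraction of sites inside blocks equals `alpha`. The last
#' block is truncated at the sequence end.
#'
#' @param root_length Sequence length in bp.
#' @param alpha Target block coverage fraction, `0 <= alpha < 1`.
#' @param block_sampler `function(n)` drawing block lengths (`>= 1`); if it
#'   lacks a `"mean"` attribute the mean is estimated from 2000 draws.
#' @param beta Rate multiplier inside blocks, in `(0, 1]`.
#' @return An object of class `block_map`: list with `length`, integer
#'   vectors `start`/`end` (0-based half-open intervals), and `multiplier`.
#' @export
place_conserved_blocks <- function(root_length, alpha,
                                   block_sampler = geometric_block_sampler(50),
                                   beta = 0.1) {
  stopifnot(is.numeric(root_length), root_length >= 1)
  if (!is.numeric(alpha) || alpha < 0 || alpha >= 1)
    stop("alpha must be in [0, 1); alpha = 1 is degenerate")
  stopifnot(is.numeric(beta), beta > 0, beta <= 1)
  root_length <- as.integer(root_length)
  if (alpha == 0)
    return(structure(list(length = root_length, start = integer(0),
                          end = integer(0), multiplier = numeric(0)),
                     class = "block_map"))
  mu_b <- attr(block_sampler, "mean")
  if (is.null(mu_b)) mu_b <- mean(block_sampler(2000L))
  mu_s <- mu_b * (1 - alpha) / alpha
  p_s <- 1 / (1 + mu_s)   # geometric on {0,1,...} with mean mu_s
  start <- integer(0); end <- integer(0)
  pos <- 0L
  repeat {
    pos <- pos + stats::rgeom(1L, p_s)
    if (pos >= root_length) break
    b <- block_sampler(1L)
    e <- min(pos + b, root_length)
    start <- c(start, pos); end <- c(end, as.integer(e))
    pos <- as.integer(e)
    if (pos >= root_length) break
  }
  structure(list(length = root_length, start = start, end = end,
                 multiplier = rep(beta, length(start))),
            class = "block_map")
}

#' Per-site rate multipliers implied by a block map
#'
#' @param blocks A `block_map`.
#' @return Numeric vector of length `blocks$length`: block multiplier inside
#'   intervals, 1 outside.
#' @export
site_multipliers <- function(blocks) {
  stopifnot(inherits(blocks, "block_map"))
  m <- rep(1, blocks$length)
  for (i in seq_along(blocks$start))
    m[(blocks$start[i] + 1L):blocks$end[i]] <- blocks$multiplier[i]
  m
}

#' Fraction of sites covered by blocks
#' @param blocks A `block_map`.
#' @return Covered fraction in `[0, 1]`.
#' @export
block_coverage <- function(blocks) {
  stopifnot(inherits(blocks, "block_map"))
  sum(blocks$end - blocks$start) / blocks$length
}

#' Simulation parameter set
#'
#' Bundles everything one simulated data set needs: the neutral-scale
#' phylogeny, the substitution:indel ratio `rho` (10 means 10 substitutions
#' per indel; `Inf` disables indels), the insertion:deletion ratio `r`, the
#' indel length model, conserved-block parameters `alpha`/`beta`, root length
#' and base frequencies.
#'
#' @param tree `phylo` object with neutral-scale branch lengths (expected
#'   substitutions per neutral site).
#' @param sub_indel_ratio Substitutions per indel event, `> 0` or `Inf`.
#' @param ins_del_ratio Insertions per deletion, `> 0`.
#' @param indel_model An [indel_length_model()].
#' @param alpha Conserved-block coverage fraction in `[0, 1)`.
#' @param beta Block rate multiplier in `(0, 1]`.
#' @param root_length Root sequence length in bp.
#' @param base_freqs F81 equilibrium frequencies for A, C, G, T; normalized.
#' @param block_sampler Block length sampler, see [geometric_block_sampler()].
#' @param indel_block_scaling If `TRUE` (default) indel initiation rates are
#'   scaled by the site multiplier like substitution rates; if `FALSE` only
#'   substitutions slow down inside blocks.
#' @param insert_inherit `"left"` (default): inserted residues inherit the
#'   rate multiplier of the site to their left (neutral at the 5' end);
#'   `"neutral"`: inserted residues are always neutral.
#' @return Object of class `evolution_params`.
#' @export
evolution_params <- function(tree,
                             sub_indel_ratio = 10,
                             ins_del_ratio = 1,
                             indel_model = indel_length_model(),
                             alpha = 0.2,
                             beta = 0.1,
                             root_length = 10000L,
                             base_freqs = rep(0.25, 4),
                             block_sampler = geometric_block_sampler(50),
                             indel_block_scaling = TRUE,
                             insert_inherit = c("left", "neutral")) {
  tree <- validate_phylogeny(tree)
  stopifnot(is.numeric(sub_indel_ratio), sub_indel_ratio > 0,
            is.numeric(ins_del_ratio), ins_del_ratio > 0,
            is.finite(ins_del_ratio),
            inherits(indel_model, "indel_length_model"),
            is.numeric(root_length), root_length >= 1,
            is.numeric(base_freqs), length(base_freqs) == 4L,
            all(base_freqs > 0))
  if (!is.numeric(alpha) || alpha < 0 || alpha >= 1)
    stop("alpha must be in [0, 1)")
  stopifnot(is.numeric(beta), beta > 0, beta <= 1)
  structure(list(
    tree = tree,
    sub_indel_ratio = sub_indel_ratio,
    ins_del_ratio = ins_del_ratio,
    indel_model = indel_model,
    alpha = alpha,
    beta = beta,
    root_length = as.integer(root_length),
    base_freqs = base_freqs / sum(base_freqs),
    block_sampler = block_sampler,
    indel_block_scaling = isTRUE(indel_block_scaling),
    insert_inherit = match.arg(insert_inherit)
  ), class = "evolution_params")
}

# ---- residue-identity recorder -------------------------------------------
# Every residue ever created (root residues and inserted residues) gets a
# unique integer id. A doubly linked list over ids maintains the global
# left-to-right homology order; each lineage's id vector is a subsequence of
# that order, which is what makes the true alignment recoverable: one global
# column per id.

new_event_recorder <- function(n0) {
  e <- new.env(parent = emptyenv())
  cap <- max(64L, 2L * n0)
  e$nxt <- integer(cap); e$prv <- integer(cap)
  if (n0 > 0L) {
    idx <- seq_len(n0)
    e$nxt[idx] <- c(idx[-1L], 0L)
    e$prv[idx] <- c(0L, idx[-n0])
  }
  e$head <- if (n0 > 0L) 1L else 0L
  e$tail <- if (n0 > 0L) n0 else 0L
  e$n_id <- n0
  e$ev_branch <- character(256L); e$ev_kind <- character(256L)
  e$ev_time <- numeric(256L); e$ev_pos <- integer(256L)
  e$ev_len <- integer(256L); e$ev_chars <- character(256L)
  e$ev_ids <- vector("list", 256L)
  e$n_ev <- 0L
  e
}

rec_grow_ids <- function(e, need) {
  cap <- length(e$nxt)
  if (need <= cap) return(invisible(NULL))
  newcap <- max(need, 2L * cap)
  length(e$nxt) <- newcap; length(e$prv) <- newcap
  e$nxt[(cap + 1L):newcap] <- 0L; e$prv[(cap + 1L):newcap] <- 0L
  invisible(NULL)
}

# allocate L fresh ids, linked as a chain placed before id `before`
# (before = 0 means: after id `after`; after = 0 with before = 0 appends at
# the global tail)
rec_new_ids <- function(e, L, before = 0L, after = 0L) {
  rec_grow_ids(e, e$n_id + L)
  ids <- e$n_id + seq_len(L)
  e$n_id <- e$n_id + L
  if (L > 1L) {
    e$nxt[ids[-L]] <- ids[-1L]
    e$prv[ids[-1L]] <- ids[-L]
  }
  if (before != 0L) {
    p <- e$prv[before]
    e$prv[ids[1L]] <- p
    e$nxt[ids[L]] <- before
    e$prv[before] <- ids[L]
    if (p == 0L) e$head <- ids[1L] else e$nxt[p] <- ids[1L]
  } else {
    if (after == 0L) after <- e$tail
    if (after == 0L) {           # empty global list
      e$prv[ids[1L]] <- 0L; e$nxt[ids[L]] <- 0L
      e$head <- ids[1L]; e$tail <- ids[L]
    } else {
      nx <- e$nxt[after]
      e$nxt[after] <- ids[1L]; e$prv[ids[1L]] <- after
      e$nxt[ids[L]] <- nx
      if (nx == 0L) e$tail <- ids[L] else e$prv[nx] <- ids[L]
    }
  }
  ids
}

rec_event <- function(e, branch, kind, time, pos, len, chars, ids) {
  i <- e$n_ev + 1L
  cap <- length(e$ev_time)
  if (i > cap) {
    newcap <- 2L * cap
    length(e$ev_branch) <- newcap; length(e$ev_kind) <- newcap
    length(e$ev_time) <- newcap; length(e$ev_pos) <- newcap
    length(e$ev_len) <- newcap; length(e$ev_chars) <- newcap
    length(e$ev_ids) <- newcap
  }
  e$ev_branch[i] <- branch; e$ev_kind[i] <- kind
  e$ev_time[i] <- time; e$ev_pos[i] <- pos
  e$ev_len[i] <- len; e$ev_chars[i] <- chars
  e$ev_ids[[i]] <- ids
  e$n_ev <- i
  invisible(NULL)
}

# ---- branch simulation ----------------------------------------------------

#' Evolve one sequence along one branch
#'
#' Exact Gillespie simulation of the jump process on a branch of length
#' `branch_length` expected substitutions per neutral site. Per-site
#' substitution rates are `m_s * (1 - pi[b]) / (1 - sum(pi^2))` (F81 with the
#' standard normalization, `m_s` the site's block multiplier); indel
#' initiation rates are `m_s / rho`, split `r/(1+r)` insertion vs `1/(1+r)`
#' deletion. Insertions place i.i.d.-from-`pi` residues immediately left of
#' the sampled anchor; one virtual terminal anchor (multiplier 1) admits
#' 3'-end insertions. Deletions extend rightward from the sampled site and
#' are truncated at the sequence end.
#'
#' @param parent A sequence state: list with integer vectors `ids` (residue
#'   identities), `bases` (1..4 = A,C,G,T) and numeric `mult` (site rate
#'   multipliers); or a plain DNA string (neutral sites, fresh ids).
#' @param branch_length Branch length `>= 0`.
#' @param params An [evolution_params()].
#' @param recorder Internal event recorder; created fresh when `NULL`.
#' @param branch_id Label stored with each event.
#' @return List with `state` (child sequence state), `events` (data frame:
#'   `branch_id`, `kind`, `time`, `position`, `length`, `inserted_bases`),
#'   and `sequence` (the child's DNA text).
#' @export
evolve_branch <- function(parent, branch_length, params,
                          recorder = NULL, branch_id = "branch") {
  stopifnot(inherits(params, "evolution_params"),
            is.numeric(branch_length), branch_length >= 0)
  if (is.character(parent)) {
    b <- match(strsplit(toupper(parent), "", fixed = TRUE)[[1L]], DNA_BASES)
    if (anyNA(b)) stop("parent sequence must be over ACGT")
    parent <- list(ids = seq_along(b), bases = b, mult = rep(1, length(b)))
  }
  n <- length(parent$ids)
  if (n == 0L) stop("parent sequence is empty")
  if (is.null(recorder)) {
    parent$ids <- seq_len(n)   # standalone call: fresh identity space
    recorder <- new_event_recorder(n)
  }
  state <- evolve_branch_core(parent$ids, parent$bases, parent$mult,
                              branch_length, params, recorder, branch_id)
  ev <- recorder_events(recorder)
  list(state = state,
       events = ev[ev$branch_id == branch_id, , drop = FALSE],
       sequence = paste(DNA_BASES[state$bases], collapse = ""))
}

recorder_events <- function(e) {
  i <- seq_len(e$n_ev)
  df <- data.frame(branch_id = e$ev_branch[i], kind = e$ev_kind[i],
                   time = e$ev_time[i], position = e$ev_pos[i],
                   length = e$ev_len[i], inserted_bases = e$ev_chars[i],
                   stringsAsFactors = FALSE)
  df$ids <- e$ev_ids[i]
  df
}

evolve_branch_core <- function(ids, bases, mult, brlen, params, rec,
                               branch_id) {
  pi <- params$base_freqs
  cnorm <- 1 - sum(pi^2)
  rho <- params$sub_indel_ratio
  r <- params$ins_del_ratio
  indels_on <- is.finite(rho)
  ins_frac <- r / (1 + r)
  scale_indels <- params$indel_block_scaling
  inherit_left <- params$insert_inherit == "left"

  # incrementally maintained rates; recomputed only when the sequence changes
  sub_w <- mult * (1 - pi[bases]) / cnorm
  S_sub <- sum(sub_w)
  iw <- if (scale_indels) mult else rep(1, length(mult))
  S_iw <- sum(iw)

  t <- 0
  repeat {
    n <- length(ids)
    if (indels_on && n > 0L) {
      S_ins <- (S_iw + 1) / rho * ins_frac      # +1: virtual 3' anchor
      S_del <- S_iw / rho * (1 - ins_frac)
    } else if (indels_on) {
      S_ins <- ins_frac / rho; S_del <- 0
    } else {
      S_ins <- 0; S_del <- 0
    }
    R <- S_sub + S_ins + S_del
    if (R <= 0) break
    t <- t + stats::rexp(1L, R)
    if (t > brlen) break
    u <- stats::runif(1L) * R

    if (u < S_sub) {
      s <- sample.int(n, 1L, prob = sub_w)
      old <- bases[s]
      p2 <- pi; p2[old] <- 0
      newb <- sample.int(4L, 1L, prob = p2)
      bases[s] <- newb
      nw <- mult[s] * (1 - pi[newb]) / cnorm
      S_sub <- S_sub + nw - sub_w[s]
      sub_w[s] <- nw
      rec_event(rec, branch_id, "substitution", t, s - 1L, 1L,
                DNA_BASES[newb], ids[s])
    } else if (u < S_sub + S_ins) {
      a <- if (n == 0L) 1L else sample.int(n + 1L, 1L, prob = c(iw, 1))
      L <- sample_indel_length(params$indel_model, 1L)
      newb <- sample.int(4L, L, replace = TRUE, prob = pi)
      newm <- if (!inherit_left || a == 1L) 1 else mult[a - 1L]
      new_ids <-
        if (n == 0L) rec_new_ids(rec, L)
        else if (a <= n) rec_new_ids(rec, L, before = ids[a])
        else rec_new_ids(rec, L, after = ids[n])
      left <- seq_len(a - 1L)
      right <- if (a <= n) a:n else integer(0)
      ids <- c(ids[left], new_ids, ids[right])
      bases <- c(bases[left], newb, bases[right])
      mult <- c(mult[left], rep(newm, L), mult[right])
      sub_w <- mult * (1 - pi[bases]) / cnorm
      S_sub <- sum(sub_w)
      iw <- if (scale_indels) mult else rep(1, length(mult))
      S_iw <- sum(iw)
      rec_event(rec, branch_id, "insertion", t, a - 1L, L,
                paste(DNA_BASES[newb], collapse = ""), new_ids)
    } else {
      s <- sample.int(n, 1L, prob = iw)
      L <- sample_indel_length(params$indel_model, 1L)
      Lr <- min(L, n - s + 1L)
      kill <- s:(s + Lr - 1L)
      dead <- ids[kill]
      ids <- ids[-kill]; bases <- bases[-kill]; mult <- mult[-kill]
      sub_w <- mult * (1 - pi[bases]) / cnorm
      S_sub <- sum(sub_w)
      iw <- if (scale_indels) mult else rep(1, length(mult))
      S_iw <- sum(iw)
      rec_event(rec, branch_id, "deletion", t, s - 1L, Lr, "", dead)
    }
  }
  list(ids = ids, bases = bases, mult = mult)
}

# ---- full data set --------------------------------------------------------

#' Simulate one benchmark data set
#'
#' Generates a root sequence (i.i.d. from the base frequencies, or a window
#' of a supplied FASTA pool), places conserved blocks on it, evolves it down
#' the phylogeny branch by branch, and assembles the true multiple alignment
#' in which every residue ever created occupies exactly one column.
#'
#' @param params An [evolution_params()]; the tree needs `>= 2` leaves.
#' @param root_source `NULL` for an i.i.d. root, or a named character vector
#'   of DNA sequences (or path to a FASTA file) from which a random window of
#'   `root_length` bp containing only A/C/G/T is drawn.
#' @return Object of class `simulated_dataset`: list with `leaf_seqs` (named
#'   ungapped DNA strings), `alignment` (an [ncb_alignment()] over the
#'   leaves), `events` (data frame with `branch_id`, `kind`, `time`,
#'   `position`, `length`, `inserted_bases`, `aln_col_start`, `aln_col_end`
#'   0-based half-open, plus a list column `cols` of exact 0-based columns),
#'   `params`, `block_map`, `root_sequence` and `n_columns`.
#' @export
simulate_dataset <- function(params, root_source = NULL) {
  stopifnot(inherits(params, "evolution_params"))
  tree <- params$tree
  ntip <- length(tree$tip.label)
  if (ntip < 2L) stop("tree must have at least 2 leaves")
  n0 <- params$root_length
  pi <- params$base_freqs

  root_bases <- if (is.null(root_source)) {
    sample.int(4L, n0, replace = TRUE, prob = pi)
  } else {
    draw_root_window(root_source, n0)
  }
  blocks <- place_conserved_blocks(n0, params$alpha, params$block_sampler,
                                   params$beta)
  mult <- site_multipliers(blocks)

  rec <- new_event_recorder(n0)
  root_node <- ntip + 1L
  states <- vector("list", ntip + tree$Nnode)
  states[[root_node]] <- list(ids = seq_len(n0), bases = root_bases,
                              mult = mult)
  tr <- ape::reorder.phylo(tree, "cladewise")   # parents before children
  for (k in seq_len(nrow(tr$edge))) {
    par <- tr$edge[k, 1L]; chd <- tr$edge[k, 2L]
    lab <- if (chd <= ntip) tree$tip.label[chd] else paste0("node", chd)
    st <- states[[par]]
    states[[chd]] <- evolve_branch_core(st$ids, st$bases, st$mult,
                                        tr$edge.length[k], params, rec, lab)
  }

  # global column order from the linked list
  ncol_aln <- rec$n_id
  col_of_id <- integer(ncol_aln)
  id <- rec$head; cc <- 0L
  while (id != 0L) {
    cc <- cc + 1L
    col_of_id[id] <- cc
    id <- rec$nxt[id]
  }
  stopifnot(cc == ncol_aln)

  rows <- matrix("-", nrow = ntip, ncol = ncol_aln,
                 dimnames = list(tree$tip.label, NULL))
  leaf_seqs <- character(ntip); names(leaf_seqs) <- tree$tip.label
  for (i in seq_len(ntip)) {
    st <- states[[i]]
    rows[i, col_of_id[st$ids]] <- DNA_BASES[st$bases]
    leaf_seqs[i] <- paste(DNA_BASES[st$bases], collapse = "")
  }
  aln <- ncb_alignment(rows, drop_all_gap = FALSE)

  ev <- recorder_events(rec)
  cols0 <- lapply(ev$ids, function(v) sort(col_of_id[v]) - 1L)
  ev$aln_col_start <- vapply(cols0, function(v) v[1L], integer(1))
  ev$aln_col_end <- vapply(cols0, function(v) v[length(v)] + 1L, integer(1))
  ev$cols <- cols0
  ev$ids <- NULL

  for (i in seq_len(ntip))
    stopifnot(identical(gsub("-", "", paste(rows[i, ], collapse = ""),
                             fixed = TRUE), leaf_seqs[[i]]))
  total_ins <- sum(ev$length[ev$kind == "insertion"])
  stopifnot(ncol_aln == n0 + total_ins)

  structure(list(leaf_seqs = leaf_seqs, alignment = aln, events = ev,
                 params = params, block_map = blocks,
                 root_sequence = paste(DNA_BASES[root_bases], collapse = ""),
                 n_columns = ncol_aln),
            class = "simulated_dataset")
}

draw_root_window <- function(root_source, n0) {
  pool <- if (is.character(root_source) && length(root_source) == 1L &&
              file.exists(root_source)) read_fasta(root_source)
          else root_source
  stopifnot(is.character(pool), length(pool) >= 1L)
  lens <- nchar(pool)
  ok <- which(lens >= n0)
  if (!length(ok)) stop("FASTA pool has no sequence of length >= root length")
  for (try in seq_len(200L)) {
    s <- if (length(ok) == 1L) ok else sample(ok, 1L)
    start <- sample.int(lens[s] - n0 + 1L, 1L)
    win <- toupper(substr(pool[s], start, start + n0 - 1L))
    b <- match(strsplit(win, "", fixed = TRUE)[[1L]], DNA_BASES)
    if (!anyNA(b)) return(b)
  }
  stop("could not draw an ACGT-only window of the requested length")
}

#' @export
print.simulated_dataset <- function(x, ...) {
  cat(sprintf("simulated data set: %d leaves, %d alignment columns, %d events\n",
              length(x$leaf_seqs), x$n_columns, nrow(x$events)))
  invisible(x)
}

#' Extract the true indel annotation from a simulated data set
#'
#' Builds the per-branch ground-truth annotation from the event log. When a
#' residue is inserted and then deleted on the *same* branch it leaves no
#' observable trace, so such columns are removed from both events (and
#' events emptied this way are dropped): the annotation records the net
#' observable history of each branch, which is what annotation tools can be
#' expected to predict.
#'
#' @param dataset A `simulated_dataset`.
#' @param branches Branch labels to keep (default: all with indel events).
#' @return An [indel_annotation()] with each event's exact set of
#'   true-alignment columns.
#' @export
true_indel_annotation <- function(dataset, branches = NULL) {
  stopifnot(inherits(dataset, "simulated_dataset"))
  ev <- dataset$events
  ev <- ev[ev$kind != "substitution", , drop = FALSE]
  if (!is.null(branches)) ev <- ev[ev$branch_id %in% branches, , drop = FALSE]
  keep <- rep(TRUE, nrow(ev))
  for (b in unique(ev$branch_id)) {
    idx <- which(ev$branch_id == b)
    shared <- intersect(
      unlist(ev$cols[idx[ev$kind[idx] == "insertion"]]),
      unlist(ev$cols[idx[ev$kind[idx] == "deletion"]]))
    if (length(shared)) {
      for (i in idx) ev$cols[[i]] <- setdiff(ev$cols[[i]], shared)
      keep[idx] <- lengths(ev$cols[idx]) > 0L
    }
  }
  ev <- ev[keep, , drop = FALSE]
  indel_annotation(branch = ev$branch_id, kind = ev$kind, columns = ev$cols)
}
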