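#' Control parameters for maximum-likelihood tree search
#'
#' @param bl_tol convergence tolerance (log-likelihood units) for
#'   branch-length sweeps.
#' @param bl_rounds maximum branch-length sweeps per optimization call.
#' @param nni_tol minimum log-likelihood gain to accept an NNI swap.
#' @param max_nni maximum number of accepted swaps before giving up.
#' @param min_bl,max_bl branch-length bounds.
#' @param ttol Brent tolerance on individual branch lengths.
#' @return a list of class `ml_control`.
#' @export
ml_control <- function(bl_tol = 1e-4, bl_rounds = 5L, nni_tol = 1e-4,
                       max_nni = 200L, min_bl = 1e-8, max_bl = 50,
                       ttol = 1e-7) {
  structure(list(bl_tol = bl_tol, bl_rounds = bl_rounds, nni_tol = nni_tol,
                 max_nni = max_nni, min_bl = min_bl, max_bl = max_bl,
                 ttol = ttol), class = "ml_control")
}

# one NNI hill-climbing run from a given tree (branch lengths already set)
nni_search_internal <- function(dat, tree, control) {
  tree <- optimize_bl_internal(dat, tree, tol = control$bl_tol,
                               max_rounds = control$bl_rounds,
                               min_bl = control$min_bl,
                               max_bl = control$max_bl,
                               ttol = control$ttol, warn = FALSE)
  ll <- attr(tree, "loglik")
  n_swaps <- 0L
  repeat {
    if (n_swaps >= control$max_nni) {
      warning("NNI search stopped after ", n_swaps, " swaps")
      break
    }
    tt <- tree_tables(tree)
    a <- cpp_args(dat, tt)
    ev <- cpp_nni_eval(a$edge, a$el, a$nTip, a$po, a$childEdges, a$tipcode,
                       a$codeTab, a$w, a$U, a$Ui, a$lam, a$pi, a$rates,
                       control$min_bl, control$max_bl,
                       max(control$ttol, 1e-5))
    if (nrow(ev) == 0L) break
    gains <- cbind(ev[, 4L] - ev[, 2L], ev[, 6L] - ev[, 2L])
    best <- which(gains == max(gains), arr.ind = TRUE)[1L, ]
    if (gains[best[1L], best[2L]] <= control$nni_tol) break
    e <- as.integer(ev[best[1L], 1L])
    alt <- best[2L]  # 1 or 2
    t_new <- ev[best[1L], if (alt == 1L) 5L else 7L]
    cand <- apply_nni(tt, e, alt, t_new)
    cand <- optimize_bl_internal(dat, cand, tol = control$bl_tol,
                                 max_rounds = 2L, min_bl = control$min_bl,
                                 max_bl = control$max_bl,
                                 ttol = control$ttol, warn = FALSE)
    ll_new <- attr(cand, "loglik")
    if (ll_new < ll + control$nni_tol / 10) break  # no real progress
    tree <- cand
    ll <- ll_new
    n_swaps <- n_swaps + 1L
  }
  attr(tree, "loglik") <- ll
  attr(tree, "n_swaps") <- n_swaps
  tree
}

# Apply one NNI swap around internal edge e of the rooted bookkeeping in
# `tt`. `alt` follows the scoring convention of cpp_nni_eval: with v the
# parent, c the child (children x, y) and the v-side units (W1, W2),
# alt 1 groups (W1, X | W2, Y) and alt 2 groups (W1, Y | W2, X).
apply_nni <- function(tt, e, alt, t_new) {
  tree <- tt$tree
  E <- tree$edge
  n_tip <- tt$n_tip
  root <- n_tip + 1L
  v <- E[e, 1L]; cnode <- E[e, 2L]
  ck <- tt$kids[[cnode]]
  ex <- ck[1L]; ey <- ck[2L]
  if (v == root) {
    others <- setdiff(tt$kids[[v]], e)
    eb <- others[2L]
    swap <- if (alt == 1L) ex else ey
    E[eb, 1L] <- cnode
    E[swap, 1L] <- v
  } else {
    ea <- setdiff(tt$kids[[v]], e)
    swap <- if (alt == 1L) ey else ex
    E[ea, 1L] <- cnode
    E[swap, 1L] <- v
  }
  tree$edge <- E
  tree$edge.length[e] <- t_new
  attr(tree, "order") <- NULL  # edges were rearranged; force a real reorder
  ape::reorder.phylo(tree, "postorder")
}

#' NNI hill climbing from a starting tree
#'
#' Repeatedly scores every nearest-neighbour interchange around each
#' internal branch (re-optimizing only the central branch length), applies
#' the best improving swap, re-optimizes branch lengths, and stops when no
#' swap improves the log-likelihood by more than `control$nni_tol`.
#'
#' @inheritParams log_likelihood
#' @param control an [ml_control()].
#' @return the locally optimal tree with attribute `loglik`.
#' @export
nni_search <- function(aln, tree, model, control = ml_control()) {
  stopifnot(inherits(aln, "dna_alignment"))
  dat <- ml_data(aln, model)
  nni_search_internal(dat, prepare_tree(tree), control)
}

#' Maximum-likelihood tree search
#'
#' Best of `n_starts` independent hill climbs, each from a randomized
#' maximum-parsimony stepwise-addition starting tree followed by NNI
#' rearrangements with branch-length re-optimization. When `model` is
#' omitted, a GTR+Gamma model is first estimated on the initial starting
#' tree (empirical base frequencies, then full model optimization).
#'
#' @inheritParams log_likelihood
#' @param model a [gtr_model()], or `NULL` to estimate one.
#' @param n_starts number of random-addition starts.
#' @param seed top-level seed; per-start seeds are derived with
#'   [derive_seeds()].
#' @param control an [ml_control()].
#' @return the best tree found, with attributes `loglik` and `model`.
#' @export
search_ml_tree <- function(aln, model = NULL, n_starts = 10L, seed = NULL,
                           control = ml_control()) {
  stopifnot(inherits(aln, "dna_alignment"))
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max - 1L, 1L)
  seeds <- derive_seeds(seed, n_starts)
  if (is.null(model)) {
    start0 <- parsimony_random_addition_tree(aln, seeds[1L])
    model <- gtr_model(base_freqs = empirical_base_freqs(aln),
                       alpha = 1, n_categories = 4L)
    model <- optimize_model_parameters(aln, start0, model,
                                       optimize_bl = TRUE)
    attr(model, "tree") <- NULL
  }
  dat <- ml_data(aln, model)
  best <- NULL
  for (s in seeds) {
    start <- parsimony_random_addition_tree(aln, s)
    fit <- nni_search_internal(dat, start, control)
    if (is.null(best) || attr(fit, "loglik") > attr(best, "loglik"))
      best <- fit
  }
  attr(best, "model") <- model
  best
}
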