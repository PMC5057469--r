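# ---------------------------------------------------------------------------
# internal plumbing: site-pattern compression and tree bookkeeping for the
# C++ engine

# Compress alignment columns into unique site patterns with weights and
# encode each taxon/pattern as an IUPAC bitmask (1..15).
compress_patterns <- function(aln) {
  m <- aln$seq
  key <- do.call(paste0, as.data.frame(t(m), stringsAsFactors = FALSE))
  idx <- match(key, unique(key))
  first <- which(!duplicated(idx))
  w <- as.numeric(tabulate(idx, nbins = length(first)))
  codes <- matrix(.iupac_bits[m[, first, drop = FALSE]],
                  nrow = nrow(m), ncol = length(first))
  rownames(codes) <- rownames(m)
  list(codes = codes, w = w, n_sites = ncol(m))
}

# Rooted bookkeeping tables for a phylo object: postorder edge matrix,
# internal nodes in postorder, and child-edge lists per node.
tree_tables <- function(tree) {
  tree <- ape::reorder.phylo(tree, "postorder")
  E <- tree$edge
  n_tip <- length(tree$tip.label)
  n_nodes <- n_tip + tree$Nnode
  kids <- vector("list", n_nodes)
  for (v in seq_len(n_nodes)) kids[[v]] <- integer(0)
  sp <- split(seq_len(nrow(E)), E[, 1L])
  for (nm in names(sp)) kids[[as.integer(nm)]] <- as.integer(sp[[nm]])
  po <- unique(E[, 1L])
  list(tree = tree, edge = E, el = tree$edge.length, n_tip = n_tip,
       po = as.integer(po), kids = kids)
}

# Ensure an unrooted, binary-sense representation with branch lengths.
prepare_tree <- function(tree, default_bl = 0.1) {
  if (!inherits(tree, "phylo")) stop("'tree' must be a phylo object")
  if (is.null(tree$edge.length)) tree$edge.length <- rep(default_bl,
                                                         nrow(tree$edge))
  if (length(tree$tip.label) > 2L && ape::is.rooted(tree))
    tree <- ape::unroot(tree)
  tree
}

# Assemble everything cpp_* needs for one (alignment, model) pair.
ml_data <- function(aln, model) {
  pat <- compress_patterns(aln)
  eig <- gtr_eigen(model)
  rates <- discrete_gamma_rates(model$alpha, model$n_categories)
  list(pat = pat, eig = eig, rates = rates, model = model,
       taxa = rownames(pat$codes))
}

# tip codes in tree tip order
tip_codes <- function(dat, tree) {
  i <- match(tree$tip.label, dat$taxa)
  if (anyNA(i))
    stop("tree taxa missing from alignment: ",
         paste(tree$tip.label[is.na(i)], collapse = ", "))
  dat$pat$codes[i, , drop = FALSE]
}

cpp_args <- function(dat, tt) {
  list(edge = tt$edge, el = tt$el, nTip = tt$n_tip, po = tt$po,
       childEdges = tt$kids, tipcode = tip_codes(dat, tt$tree),
       codeTab = .code_table, w = dat$pat$w, U = dat$eig$U, Ui = dat$eig$Ui,
       lam = dat$eig$lam, pi = unname(dat$model$base_freqs),
       rates = dat$rates)
}

loglik_internal <- function(dat, tree) {
  tt <- tree_tables(tree)
  a <- cpp_args(dat, tt)
  do.call(cpp_loglik, a)
}

# ---------------------------------------------------------------------------

#' Phylogenetic log-likelihood under GTR + Gamma
#'
#' Felsenstein pruning over compressed site patterns. Gaps and IUPAC
#' ambiguity codes are partial missing data: a tip's conditional likelihood
#' is 1 for every compatible state. The likelihood is computed in the
#' unrooted sense and is invariant to where the tree is rooted.
#'
#' @param aln a [dna_alignment()]; its taxa must include all tree tips.
#' @param tree a `phylo` tree with branch lengths in expected
#'   substitutions/site.
#' @param model a [gtr_model()].
#' @return the log-likelihood (a finite negative number for non-degenerate
#'   data).
#' @export
log_likelihood <- function(aln, tree, model) {
  stopifnot(inherits(aln, "dna_alignment"))
  tree <- prepare_tree(tree)
  dat <- ml_data(aln, model)
  loglik_internal(dat, tree)
}

#' Optimize branch lengths by coordinate ascent
#'
#' Cycles over edges, maximizing the log-likelihood in each branch length by
#' Brent's method against exact conditional likelihoods, until a full sweep
#' improves the log-likelihood by less than `tol` or `max_rounds` sweeps are
#' reached. The log-likelihood never decreases. Lengths are clamped to
#' `[min_bl, max_bl]`.
#'
#' @inheritParams log_likelihood
#' @param tol convergence tolerance in log-likelihood units per sweep.
#' @param max_rounds maximum number of sweeps.
#' @param min_bl,max_bl branch-length bounds.
#' @param ttol relative Brent tolerance on individual branch lengths.
#' @return the tree with optimized `edge.length`; attributes `loglik` and
#'   `converged`. A warning is raised when `max_rounds` is exhausted.
#' @export
optimize_branch_lengths <- function(aln, tree, model, tol = 1e-6,
                                    max_rounds = 10L, min_bl = 1e-8,
                                    max_bl = 50, ttol = 1e-7) {
  stopifnot(inherits(aln, "dna_alignment"))
  tree <- prepare_tree(tree)
  dat <- ml_data(aln, model)
  optimize_bl_internal(dat, tree, tol, max_rounds, min_bl, max_bl,
                       ttol = ttol)
}

optimize_bl_internal <- function(dat, tree, tol = 1e-6, max_rounds = 10L,
                                 min_bl = 1e-8, max_bl = 50, ttol = 1e-8,
                                 warn = TRUE) {
  tt <- tree_tables(tree)
  a <- cpp_args(dat, tt)
  res <- cpp_optim_bl(a$edge, a$el, a$nTip, a$po, a$childEdges, a$tipcode,
                      a$codeTab, a$w, a$U, a$Ui, a$lam, a$pi, a$rates,
                      tol, as.integer(max_rounds), min_bl, max_bl, ttol)
  out <- tt$tree
  out$edge.length <- res$el
  if (!res$converged && warn)
    warning("branch-length optimization stopped after ", res$rounds,
            " sweeps without meeting tol; returning best tree so far")
  attr(out, "loglik") <- res$loglik
  attr(out, "converged") <- res$converged
  out
}

#' Optimize GTR + Gamma model parameters
#'
#' Maximizes the log-likelihood over the five free exchangeabilities (GT is
#' fixed at 1), the base-frequency simplex, and the gamma shape, holding the
#' tree (topology and branch lengths) fixed. Optionally alternates with
#' branch-length re-optimization. Parameters are optimized on unconstrained
#' transformed scales (log rates, log alpha, additive log-ratio
#' frequencies) with Nelder-Mead.
#'
#' @inheritParams log_likelihood
#' @param optimize_bl also re-optimize branch lengths once before and after
#'   the model fit.
#' @param maxit maximum Nelder-Mead iterations.
#' @return a [gtr_model()]; attribute `loglik` holds the final
#'   log-likelihood (under the final branch lengths when
#'   `optimize_bl = TRUE`, in which case attribute `tree` holds the tree).
#' @export
optimize_model_parameters <- function(aln, tree, model,
                                      optimize_bl = FALSE, maxit = 500L) {
  stopifnot(inherits(aln, "dna_alignment"))
  tree <- prepare_tree(tree)
  pat <- compress_patterns(aln)
  if (length(pat$w) < 2L) {
    warning("degenerate alignment (single site pattern); returning the ",
            "input model unchanged")
    return(model)
  }
  bl_fast <- function(dat, tr)
    optimize_bl_internal(dat, tr, tol = 1e-3, max_rounds = 5L,
                         ttol = 1e-6, warn = FALSE)
  if (optimize_bl)
    tree <- bl_fast(ml_data(aln, model), tree)
  tt <- tree_tables(tree)
  k <- model$n_categories

  build <- function(par) {
    gtr_model(exchangeabilities = c(exp(par[1:5]), 1),
              base_freqs = softmax4(par[7:9]),
              alpha = exp(par[6]), n_categories = k)
  }
  par0 <- c(log(model$exchangeabilities[1:5]), log(model$alpha),
            alr4(model$base_freqs))
  negll <- function(par) {
    if (any(!is.finite(par)) || any(abs(par) > 30)) return(1e10)
    m <- build(par)
    dat <- ml_data_cached(pat, m)
    a <- cpp_args(dat, tt)
    -do.call(cpp_loglik, a)
  }
  ll0 <- -negll(par0)
  fit <- optim(par0, negll, method = "Nelder-Mead",
               control = list(maxit = as.integer(maxit), reltol = 1e-9))
  # quasi-Newton polish: Nelder-Mead alone stalls on 9 coupled parameters
  fit2 <- tryCatch(
    optim(fit$par, negll, method = "BFGS",
          control = list(maxit = 100L, reltol = 1e-10)),
    error = function(e) fit)
  if (fit2$value < fit$value) fit <- fit2
  out <- if (-fit$value >= ll0) build(fit$par) else model
  ll <- max(-fit$value, ll0)
  if (optimize_bl) {
    tree <- bl_fast(ml_data_cached(pat, out), tt$tree)
    ll <- attr(tree, "loglik")
    attr(out, "tree") <- tree
  }
  attr(out, "loglik") <- ll
  out
}

# ml_data when patterns are already compressed
ml_data_cached <- function(pat, model) {
  list(pat = pat, eig = gtr_eigen(model),
       rates = discrete_gamma_rates(model$alpha, model$n_categories),
       model = model, taxa = rownames(pat$codes))
}

softmax4 <- function(p3) {
  e <- exp(c(p3, 0))
  e / sum(e)
}

alr4 <- function(f) log(f[1:3] / f[4])
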