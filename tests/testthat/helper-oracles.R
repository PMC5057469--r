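# Independent oracles: deliberately naive implementations that share no code
# with the package internals they check.

oracle_iupac <- c(A = 1, C = 2, G = 4, T = 8, M = 3, R = 5, W = 9, S = 6,
                  Y = 10, K = 12, V = 7, H = 11, D = 13, B = 14, N = 15,
                  "-" = 15, "?" = 15)

oracle_tipvec <- function(ch) {
  as.numeric(bitwAnd(oracle_iupac[[ch]], c(1, 2, 4, 8)) > 0)
}

# transition probabilities via matrix exponential (Matrix::expm)
oracle_pmat <- function(model, t, rate = 1) {
  r <- model$exchangeabilities
  f <- as.numeric(model$base_freqs)
  S <- matrix(0, 4, 4)
  S[1, 2] <- S[2, 1] <- r[["AC"]]; S[1, 3] <- S[3, 1] <- r[["AG"]]
  S[1, 4] <- S[4, 1] <- r[["AT"]]; S[2, 3] <- S[3, 2] <- r[["CG"]]
  S[2, 4] <- S[4, 2] <- r[["CT"]]; S[3, 4] <- S[4, 3] <- r[["GT"]]
  Q <- S %*% diag(f)
  diag(Q) <- -rowSums(Q)
  Q <- Q / -sum(f * diag(Q))
  as.matrix(Matrix::expm(Q * t * rate))
}

# log-likelihood by exhaustive enumeration of internal-state assignments
oracle_loglik <- function(aln, tree, model) {
  tree <- ape::unroot(tree)
  E <- tree$edge
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  intn <- (ntip + 1):nn
  rates <- discrete_gamma_rates(model$alpha, model$n_categories)
  f <- as.numeric(model$base_freqs)
  m <- aln$seq[tree$tip.label, , drop = FALSE]
  grid <- as.matrix(expand.grid(rep(list(1:4), length(intn))))
  tot <- 0
  for (s in seq_len(ncol(m))) {
    sl <- 0
    for (r in rates) {
      Ps <- lapply(seq_len(nrow(E)), function(e)
        oracle_pmat(model, tree$edge.length[e], r))
      acc <- 0
      for (g in seq_len(nrow(grid))) {
        st <- integer(nn)
        st[intn] <- grid[g, ]
        pr <- f[st[ntip + 1]]
        for (e in seq_len(nrow(E))) {
          par <- E[e, 1]; ch <- E[e, 2]
          if (ch <= ntip)
            pr <- pr * sum(Ps[[e]][st[par], ] * oracle_tipvec(m[ch, s]))
          else pr <- pr * Ps[[e]][st[par], st[ch]]
        }
        acc <- acc + pr
      }
      sl <- sl + acc / length(rates)
    }
    tot <- tot + log(sl)
  }
  tot
}

# discrete gamma category means by numerical integration
oracle_gamma_rates <- function(alpha, k) {
  qs <- qgamma(seq_len(k - 1) / k, shape = alpha, rate = alpha)
  lo <- c(0, qs); hi <- c(qs, Inf)
  r <- mapply(function(a, b)
    integrate(function(x) x * dgamma(x, alpha, alpha), a, b,
              rel.tol = 1e-10)$value * k, lo, hi)
  r / mean(r)
}

# per-column tallies, written independently of the package's matrix code
oracle_site_counts <- function(aln) {
  n_var <- 0L; n_inf <- 0L
  for (j in seq_len(ncol(aln$seq))) {
    col <- aln$seq[, j]
    col <- col[col %in% c("A", "C", "G", "T")]
    tab <- table(col)
    if (length(tab) >= 2L) n_var <- n_var + 1L
    if (sum(tab >= 2L) >= 2L) n_inf <- n_inf + 1L
  }
  c(variable = n_var, informative = n_inf)
}
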