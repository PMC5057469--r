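#' GTR + Gamma substitution model
#'
#' The general time-reversible nucleotide model with discrete-gamma rate
#' heterogeneity. Exchangeabilities are relative rates for the unordered
#' pairs AC, AG, AT, CG, CT, GT; for identifiability the GT rate is fixed to
#' 1 (the constructor renormalizes). Base frequencies must be positive and
#' are renormalized to sum to exactly 1. The rate matrix is scaled so one
#' unit of branch length equals one expected substitution per site, and the
#' discrete-gamma category rates have mean exactly 1.
#'
#' @param exchangeabilities numeric(6), order AC, AG, AT, CG, CT, GT.
#' @param base_freqs numeric(4), order A, C, G, T.
#' @param alpha gamma shape (> 0).
#' @param n_categories number of discrete gamma categories (>= 1).
#' @return an object of class `gtr_model`.
#' @examples
#' m <- gtr_model(c(1, 4, 1, 1, 4, 1), rep(0.25, 4), alpha = 0.5)
#' m
#' @export
gtr_model <- function(exchangeabilities = rep(1, 6),
                      base_freqs = rep(0.25, 4),
                      alpha = 1, n_categories = 4L) {
  r <- as.numeric(exchangeabilities)
  f <- as.numeric(base_freqs)
  if (length(r) != 6L || any(!is.finite(r)) || any(r <= 0))
    stop("exchangeabilities must be 6 positive numbers")
  if (length(f) != 4L || any(!is.finite(f)) || any(f <= 0))
    stop("base_freqs must be 4 positive numbers")
  if (abs(sum(f) - 1) > 1e-9)
    stop("base frequencies must sum to 1 (got ", format(sum(f)), ")")
  if (!is.finite(alpha) || alpha <= 0) stop("alpha must be > 0")
  n_categories <- as.integer(n_categories)
  if (n_categories < 1L) stop("n_categories must be >= 1")
  structure(list(
    exchangeabilities = setNames(r / r[6L],
                                 c("AC", "AG", "AT", "CG", "CT", "GT")),
    base_freqs = setNames(f / sum(f), c("A", "C", "G", "T")),
    alpha = alpha,
    n_categories = n_categories
  ), class = "gtr_model")
}

#' @export
print.gtr_model <- function(x, ...) {
  cat("GTR+Gamma model\n")
  cat("  exchangeabilities:",
      paste(sprintf("%s=%.4g", names(x$exchangeabilities),
                    x$exchangeabilities), collapse = " "), "\n")
  cat("  base frequencies: ",
      paste(sprintf("%s=%.4f", names(x$base_freqs), x$base_freqs),
            collapse = " "), "\n")
  cat(sprintf("  alpha = %.4g with %d rate categories\n", x$alpha,
              x$n_categories))
  invisible(x)
}

#' Discrete gamma category rates
#'
#' Mean-of-bin discretization of the Gamma(alpha, alpha) distribution: the
#' rate axis is cut at the k-quantiles and each category rate is the mean of
#' its bin, computed with the incomplete-gamma identity, then renormalized so
#' the category mean is exactly 1.
#'
#' @param alpha gamma shape (> 0).
#' @param n_categories number of categories (>= 1).
#' @return numeric vector of positive, non-decreasing rates with mean 1.
#' @examples
#' discrete_gamma_rates(0.5, 4)
#' @export
discrete_gamma_rates <- function(alpha, n_categories) {
  if (!is.finite(alpha) || alpha <= 0) stop("alpha must be > 0")
  k <- as.integer(n_categories)
  if (k < 1L) stop("n_categories must be >= 1")
  if (k == 1L) return(1)
  q <- qgamma(seq_len(k - 1L) / k, shape = alpha, rate = alpha)
  p <- c(0, pgamma(q, shape = alpha + 1, rate = alpha), 1)
  r <- k * diff(p)
  r / mean(r)
}

# eigen system of the scaled GTR generator Q; Q = U diag(lam) Ui
gtr_eigen <- function(model) {
  r <- model$exchangeabilities
  f <- model$base_freqs
  S <- matrix(0, 4, 4)
  S[1, 2] <- S[2, 1] <- r[["AC"]]
  S[1, 3] <- S[3, 1] <- r[["AG"]]
  S[1, 4] <- S[4, 1] <- r[["AT"]]
  S[2, 3] <- S[3, 2] <- r[["CG"]]
  S[2, 4] <- S[4, 2] <- r[["CT"]]
  S[3, 4] <- S[4, 3] <- r[["GT"]]
  Q <- S %*% diag(f)
  diag(Q) <- -rowSums(Q)
  mu <- -sum(f * diag(Q))
  Q <- Q / mu
  sq <- sqrt(f)
  B <- diag(sq) %*% Q %*% diag(1 / sq)
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  list(U = diag(1 / sq) %*% e$vectors,
       Ui = t(e$vectors) %*% diag(sq),
       lam = e$values,
       Q = Q)
}

#' Transition probability matrix
#'
#' `P(t) = exp(Q t r)` for the scaled GTR generator `Q`, branch length `t`
#' in expected substitutions per site, and a rate multiplier (for example a
#' discrete-gamma category rate).
#'
#' @param model a [gtr_model()].
#' @param t branch length (>= 0).
#' @param category_rate rate multiplier (> 0).
#' @return 4x4 row-stochastic matrix, rows/columns ordered A, C, G, T.
#' @export
transition_probabilities <- function(model, t, category_rate = 1) {
  if (!is.finite(t) || t < 0) stop("t must be >= 0")
  eig <- gtr_eigen(model)
  P <- eig$U %*% diag(exp(eig$lam * t * category_rate)) %*% eig$Ui
  P[P < 0] <- 0
  P <- P / rowSums(P)
  dimnames(P) <- list(.base_chars, .base_chars)
  P
}

#' Empirical base frequencies of an alignment
#'
#' Counts unambiguous nucleotides only (gaps and ambiguity codes are
#' ignored).
#'
#' @param aln a [dna_alignment()].
#' @return named numeric(4) summing to 1.
#' @export
empirical_base_freqs <- function(aln) {
  counts <- vapply(.base_chars, function(b) sum(aln$seq == b), 0)
  if (sum(counts) == 0) stop("alignment contains no unambiguous bases")
  counts <- pmax(counts, 1)  # keep frequencies strictly positive
  counts / sum(counts)
}
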