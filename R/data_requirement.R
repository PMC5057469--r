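#' Bootstrap support at one alignment size
#'
#' Draws `n_boot` subsampled pseudo-alignments of `size` columns, infers an
#' ML tree for each (one randomized-parsimony start plus NNI hill climbing,
#' with the model parameters fixed at the full-data optimum), and records
#' the percentage of inferred trees containing each internal bipartition of
#' the reference topology. The summary proportions are the fraction of
#' reference branches with support strictly above 90% and exactly 100%.
#'
#' @param aln the full [dna_alignment()].
#' @param ref_tree reference topology (`phylo`) whose branches are scored.
#' @param model a [gtr_model()] (typically the full-data optimum).
#' @param size number of columns per pseudo-alignment.
#' @param n_boot number of bootstrap datasets.
#' @param seed top-level seed for this call.
#' @param control an [ml_control()] for the per-replicate searches.
#' @param source label carried into the result (e.g. a rate category).
#' @param replicate replicate index carried into the result.
#' @return a list of class `support_result`: `source`, `size`,
#'   `replicate`, `support` (named percent vector), `prop_ge90`,
#'   `prop_eq100`, `n_trees`.
#' @export
support_for_size <- function(aln, ref_tree, model, size, n_boot,
                             seed = NULL, control = ml_control(),
                             source = "all", replicate = 1L) {
  stopifnot(inherits(aln, "dna_alignment"), n_boot >= 1L)
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max - 1L, 1L)
  seeds <- derive_seeds(seed, 2L * n_boot)
  dat_template <- NULL
  trees <- vector("list", n_boot)
  failed <- 0L
  for (b in seq_len(n_boot)) {
    sub <- subsample_columns(aln, size, seeds[b])
    tr <- tryCatch({
      dat <- ml_data(sub, model)
      start <- parsimony_random_addition_tree(sub, seeds[n_boot + b])
      nni_search_internal(dat, start, control)
    }, error = function(e) {
      message("replicate ", b, " failed (", conditionMessage(e),
              "); skipped")
      NULL
    })
    trees[[b]] <- tr
    if (is.null(tr)) failed <- failed + 1L
  }
  trees <- trees[!vapply(trees, is.null, TRUE)]
  if (!length(trees)) stop("all bootstrap replicates failed")
  supp <- bipartition_support(ref_tree, trees)
  structure(list(source = source, size = as.integer(size),
                 replicate = as.integer(replicate), support = supp,
                 prop_ge90 = mean(supp > 90), prop_eq100 = mean(supp == 100),
                 n_trees = length(trees), n_failed = failed),
            class = "support_result")
}

#' @export
print.support_result <- function(x, ...) {
  cat(sprintf(
    "support at %d nt (%s, replicate %d): %.0f%% of branches > 90, %.0f%% at 100\n",
    x$size, x$source, x$replicate, 100 * x$prop_ge90, 100 * x$prop_eq100))
  invisible(x)
}

#' Support as a function of alignment size
#'
#' The subsampling experiment: for each size and each replicate, an
#' independent batch of `n_boot` bootstrap datasets is analysed with
#' [support_for_size()]. Replicate seeds are derived from the top-level
#' seed, making the whole experiment reproducible and each cell
#' independently re-runnable.
#'
#' @inheritParams support_for_size
#' @param sizes vector of alignment sizes (nt).
#' @param n_replicates replicate analyses per size.
#' @return a list of class `dr_curve`: `summary` (data.frame with one row
#'   per size x replicate: source, size, replicate, prop_ge90, prop_eq100)
#'   and `supports` (long data.frame of per-branch support).
#' @export
data_requirement_curve <- function(aln, ref_tree, model, sizes,
                                   n_replicates = 3L, n_boot = 30L,
                                   seed = NULL, control = ml_control(),
                                   source = "all") {
  stopifnot(length(sizes) >= 1L)
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max - 1L, 1L)
  grid <- expand.grid(replicate = seq_len(n_replicates),
                      size = as.integer(sizes))
  seeds <- derive_seeds(seed, nrow(grid))
  rows <- vector("list", nrow(grid))
  longs <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    res <- support_for_size(aln, ref_tree, model, grid$size[i], n_boot,
                            seed = seeds[i], control = control,
                            source = source, replicate = grid$replicate[i])
    rows[[i]] <- data.frame(source = source, size = res$size,
                            replicate = res$replicate,
                            prop_ge90 = res$prop_ge90,
                            prop_eq100 = res$prop_eq100,
                            n_trees = res$n_trees,
                            stringsAsFactors = FALSE)
    longs[[i]] <- data.frame(source = source, size = res$size,
                             replicate = res$replicate,
                             bipartition = names(res$support),
                             support = unname(res$support),
                             stringsAsFactors = FALSE)
  }
  structure(list(summary = do.call(rbind, rows),
                 supports = do.call(rbind, longs)),
            class = "dr_curve")
}

#' Support-vs-size curves per rate category
#'
#' Runs [data_requirement_curve()] on each category's concatenated
#' alignment (typically shorter sizes than the genome-wide experiment,
#' since categories hold less data).
#'
#' @param category_alignments named list of [dna_alignment()] objects, one
#'   per rate category (e.g. slow/medium/fast).
#' @inheritParams data_requirement_curve
#' @return a combined `dr_curve` over all categories.
#' @export
category_requirement_curves <- function(category_alignments, ref_tree,
                                        model, sizes, n_replicates = 3L,
                                        n_boot = 30L, seed = NULL,
                                        control = ml_control()) {
  if (is.null(names(category_alignments)) ||
      any(!nzchar(names(category_alignments))))
    stop("category alignments must be named")
  for (nm in names(category_alignments))
    if (is.null(category_alignments[[nm]]))
      stop("empty category: '", nm, "'")
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max - 1L, 1L)
  seeds <- derive_seeds(seed, length(category_alignments))
  parts <- lapply(seq_along(category_alignments), function(i) {
    nm <- names(category_alignments)[i]
    a <- category_alignments[[i]]
    ok_sizes <- sizes[sizes <= aln_nsites(a)]
    if (!length(ok_sizes))
      stop("category '", nm, "' (", aln_nsites(a),
           " nt) is shorter than every requested size")
    data_requirement_curve(a, ref_tree, model, ok_sizes, n_replicates,
                           n_boot, seed = seeds[i], control = control,
                           source = nm)
  })
  structure(list(summary = do.call(rbind, lapply(parts, `[[`, "summary")),
                 supports = do.call(rbind, lapply(parts, `[[`, "supports"))),
            class = "dr_curve")
}

#' @export
summary.dr_curve <- function(object, ...) {
  s <- object$summary
  agg <- aggregate(cbind(prop_ge90, prop_eq100) ~ source + size, data = s,
                   FUN = mean)
  rng <- aggregate(cbind(prop_ge90, prop_eq100) ~ source + size, data = s,
                   FUN = function(x) diff(range(x)))
  names(agg)[3:4] <- c("mean_prop_ge90", "mean_prop_eq100")
  agg$range_prop_ge90 <- rng$prop_ge90
  agg$range_prop_eq100 <- rng$prop_eq100
  agg[order(agg$source, agg$size), ]
}

#' @export
print.dr_curve <- function(x, ...) {
  cat("data-requirement curve\n")
  print(summary(x))
  invisible(x)
}

#' Plot support-vs-size curves
#'
#' Mean proportion of reference branches above 90% (solid) and at 100%
#' (dashed) bootstrap support, against alignment size, one colour per
#' source.
#'
#' @param x a `dr_curve`.
#' @param ... passed to [graphics::matplot()].
#' @return the summary table, invisibly.
#' @export
plot.dr_curve <- function(x, ...) {
  s <- summary(x)
  sources <- unique(s$source)
  cols <- setNames(palette.colors(max(3L, length(sources)))[
    seq_along(sources)], sources)
  plot(NA, xlim = range(s$size), ylim = c(0, 1), log = "x",
       xlab = "alignment size (nt)",
       ylab = "proportion of reference branches", ...)
  for (src in sources) {
    d <- s[s$source == src, ]
    lines(d$size, d$mean_prop_ge90, type = "b", col = cols[src], pch = 16)
    lines(d$size, d$mean_prop_eq100, type = "b", col = cols[src], pch = 1,
          lty = 2)
  }
  legend("bottomright", legend = sources, col = cols, lty = 1, pch = 16,
         bty = "n")
  invisible(s)
}
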