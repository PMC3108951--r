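#' ROC curve and AUC between positive and negative score sets
#'
#' Sweeps every distinct value as a cutoff and computes true/false
#' positive rates; the AUC equals the Mann-Whitney U statistic normalized
#' by n_pos x n_neg, with ties counted one half.
#'
#' @param values_pos scores of the positive set.
#' @param values_neg scores of the negative set.
#' @param lower_is_positive if TRUE (the energy convention), lower values
#'   call positives.
#' @return a list of class `"roc_result"`: `thresholds`, `fpr`, `tpr`,
#'   `auc`.
#' @export
roc_auc <- function(values_pos, values_neg, lower_is_positive = TRUE) {
  if (!length(values_pos) || !length(values_neg)) {
    stop("both score sets must be non-empty")
  }
  pos <- as.numeric(values_pos); neg <- as.numeric(values_neg)
  if (lower_is_positive) { pos <- -pos; neg <- -neg }
  ## now higher = more positive-like
  np <- length(pos); nn <- length(neg)
  r <- rank(c(pos, neg), ties.method = "average")
  auc <- (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)
  thr <- sort(unique(c(pos, neg)), decreasing = TRUE)
  tpr <- vapply(thr, function(t) mean(pos >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(neg >= t), numeric(1))
  structure(list(thresholds = if (lower_is_positive) -thr else thr,
                 fpr = c(0, fpr, 1), tpr = c(0, tpr, 1), auc = auc),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC over %d thresholds, AUC = %.4f\n",
              length(x$thresholds), x$auc))
  invisible(x)
}

#' Wilcoxon rank-sum test between two score distributions
#'
#' Standard Mann-Whitney/Wilcoxon with normal approximation and tie
#' correction. Fully tied samples return p = 1.
#'
#' @param a,b numeric vectors.
#' @return a list with `statistic` (the W/U statistic) and `p_value`
#'   (two-sided).
#' @export
rank_sum_test <- function(a, b) {
  if (!length(a) || !length(b)) stop("both samples must be non-empty")
  if (length(unique(c(a, b))) == 1L) {
    return(list(statistic = length(a) * length(b) / 2, p_value = 1))
  }
  wt <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE,
                                            correct = FALSE))
  p <- wt$p.value
  if (!is.finite(p)) p <- 1
  list(statistic = unname(wt$statistic), p_value = p)
}

#' Enrichment of bona fide targets in top-scoring gene sets
#'
#' Genes are ranked ascending by score (most negative = strongest
#' predicted target; ties break by gene id). For each top-N set (N
#' growing by `increment`, with the final partial set truncated at the
#' gene count), the enrichment is the fraction of bona fide targets in
#' the set divided by their fraction in the full gene set. Bona fide =
#' observed log2 fold change at or below `cutoff`.
#'
#' @param scores named numeric vector of predicted scores per gene.
#' @param observed named numeric vector of observed log2 fold changes,
#'   keyed identically.
#' @param cutoff bona fide cutoff on observed log2 fold change.
#' @param increment set-size increment.
#' @return a list of class `"enrichment_curve"`: `set_sizes`,
#'   `enrichment`, `cutoff`, `prevalence`, `n_genes`, `n_bona_fide`.
#' @export
enrichment_curve <- function(scores, observed, cutoff, increment = 50L) {
  if (is.null(names(scores)) || is.null(names(observed))) {
    stop("scores and observed must be named by gene id")
  }
  if (!setequal(names(scores), names(observed))) {
    stop("scores and observed must be keyed by the same gene ids")
  }
  observed <- observed[names(scores)]
  n <- length(scores)
  bona <- observed <= cutoff
  nb <- sum(bona)
  if (nb == 0L) stop("no bona fide genes at cutoff ", cutoff)
  o <- order(scores, names(scores))
  hits <- cumsum(bona[o])
  sizes <- unique(c(seq.int(increment, n, by = increment), n))
  enr <- (hits[sizes] / sizes) / (nb / n)
  structure(list(set_sizes = sizes, enrichment = unname(enr),
                 cutoff = cutoff, prevalence = nb / n,
                 n_genes = n, n_bona_fide = nb),
            class = "enrichment_curve")
}

#' @export
print.enrichment_curve <- function(x, ...) {
  cat(sprintf(
    "Enrichment over %d set sizes (%d genes, %d bona fide at log2FC <= %g)\n",
    length(x$set_sizes), x$n_genes, x$n_bona_fide, x$cutoff))
  show <- utils::head(data.frame(N = x$set_sizes,
                                 enrichment = round(x$enrichment, 3)), 10L)
  print(show, row.names = FALSE)
  invisible(x)
}

#' Baseline enrichment of a canonical seed-match search
#'
#' Enrichment of bona fide genes among genes carrying at least one
#' canonical 6-mer (or better) site, versus the full gene set. On a gene
#' set restricted to 6-mer-containing genes this equals 1 by construction.
#'
#' @param has_6mer named logical vector: gene carries a canonical site.
#' @param observed named numeric vector of observed log2 fold changes.
#' @param cutoff bona fide cutoff.
#' @return the constant enrichment ratio.
#' @export
seed_baseline_enrichment <- function(has_6mer, observed, cutoff) {
  if (!any(has_6mer)) stop("no genes carry a canonical site")
  if (!is.null(names(has_6mer)) && !is.null(names(observed))) {
    observed <- observed[names(has_6mer)]
  }
  bona <- observed <= cutoff
  if (!any(bona)) stop("no bona fide genes at cutoff ", cutoff)
  (sum(bona & has_6mer) / sum(has_6mer)) / (mean(bona))
}

#' Paired empirical CDF curves on a merged grid
#'
#' @param values_a,values_b numeric vectors.
#' @return a data.frame with columns `value`, `cdf_a`, `cdf_b` (step
#'   functions evaluated on the merged sorted grid), exportable as TSV.
#' @export
cdf_compare <- function(values_a, values_b) {
  if (!length(values_a) || !length(values_b)) {
    stop("both samples must be non-empty")
  }
  grid <- sort(unique(c(values_a, values_b)))
  Fa <- stats::ecdf(values_a); Fb <- stats::ecdf(values_b)
  data.frame(value = grid, cdf_a = Fa(grid), cdf_b = Fb(grid))
}
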