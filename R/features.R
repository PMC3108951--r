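FEATURE_NAMES <- c("best_ddG", "second_best_ddG",
                   "best_dG_H", "second_best_dG_H",
                   "best_dG_open", "second_best_dG_open",
                   "dG_H_at_best_ddG", "dG_H_at_second_ddG",
                   "dG_open_at_best_ddG", "dG_open_at_second_ddG",
                   "sum_ddG", "sum_dG_H", "sum_dG_open", "utr_length")

#' Names of the 14 per-UTR energy features
#' @return character vector of feature names, in table order.
#' @export
feature_names <- function() FEATURE_NAMES

#' Collapse the sites of one miRNA-UTR pair into the 14 energy features
#'
#' "Best" means the most favorable value: the minimum for ddG and dG_H,
#' the maximum for dG_open (the most accessible site). The companion
#' features dG_H / dG_open at the best and second-best ddG site are read
#' off the sites ranked by ddG. Sums run over all sites. When fewer than
#' two (or any) sites exist, the affected energy features are 0, so every
#' gene stays scorable; `utr_length` is always populated.
#'
#' @param sites site data.frame for one miRNA-UTR pair (post overlap
#'   resolution and any seed filtering).
#' @param utr_length UTR length in nt.
#' @return a named numeric vector of length 14.
#' @export
utr_features <- function(sites, utr_length) {
  if (utr_length < 0) stop("negative utr_length")
  f <- stats::setNames(numeric(14L), FEATURE_NAMES)
  f["utr_length"] <- utr_length
  n <- nrow(sites)
  if (n == 0L) return(f)
  ddG <- sites$ddG; dG_H <- sites$dG_H; dG_open <- sites$dG_open
  o <- order(ddG)
  f["best_ddG"] <- ddG[o[1L]]
  f["best_dG_H"] <- min(dG_H)
  f["best_dG_open"] <- max(dG_open)
  f["dG_H_at_best_ddG"] <- dG_H[o[1L]]
  f["dG_open_at_best_ddG"] <- dG_open[o[1L]]
  if (n >= 2L) {
    f["second_best_ddG"] <- ddG[o[2L]]
    f["second_best_dG_H"] <- sort(dG_H)[2L]
    f["second_best_dG_open"] <- sort(dG_open, decreasing = TRUE)[2L]
    f["dG_H_at_second_ddG"] <- dG_H[o[2L]]
    f["dG_open_at_second_ddG"] <- dG_open[o[2L]]
  }
  f["sum_ddG"] <- sum(ddG)
  f["sum_dG_H"] <- sum(dG_H)
  f["sum_dG_open"] <- sum(dG_open)
  f
}

#' Build the feature table over all miRNA-gene pairs
#'
#' One row per pair, in the order of `pairs`; pairs without sites get the
#' zero-imputed feature vector. Duplicate (mirna_id, gene_id) keys are an
#' error.
#'
#' @param sites site data.frame covering all pairs (the `utr_id` column is
#'   matched against `pairs$gene_id`).
#' @param pairs data.frame with columns `mirna_id`, `gene_id`,
#'   `utr_length`.
#' @return a data.frame: `mirna_id`, `gene_id`, then the 14 features.
#' @export
feature_table <- function(sites, pairs) {
  key <- paste(pairs$mirna_id, pairs$gene_id, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (mirna_id, gene_id) pair(s) in feature table")
  }
  skey <- paste(sites$mirna_id, sites$utr_id, sep = "\r")
  mat <- matrix(0, nrow = nrow(pairs), ncol = 14L,
                dimnames = list(NULL, FEATURE_NAMES))
  idx <- split(seq_len(nrow(sites)), skey)
  for (i in seq_len(nrow(pairs))) {
    si <- idx[[key[i]]]
    mat[i, ] <- utr_features(sites[si %||% integer(0), , drop = FALSE],
                             pairs$utr_length[i])
  }
  cbind(data.frame(mirna_id = pairs$mirna_id, gene_id = pairs$gene_id,
                   stringsAsFactors = FALSE),
        as.data.frame(mat))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a feature table as TSV
#' @param features data.frame from [feature_table()].
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_feature_table <- function(features, path) {
  write_tsv(features, path)
}

#' Read a feature table written by [write_feature_table()]
#' @param path path to the TSV.
#' @return the feature data.frame.
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  missing <- setdiff(c("mirna_id", "gene_id", FEATURE_NAMES), names(df))
  if (length(missing)) stop("feature table missing column(s): ",
                            paste(missing, collapse = ", "))
  df
}
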