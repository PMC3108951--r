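RNA_BASES <- c("A", "C", "G", "U")

## Watson-Crick complement lookup for the RNA alphabet
WC_COMP <- c(A = "U", C = "G", G = "C", U = "A")

#' Normalize a nucleotide string to the RNA alphabet
#'
#' Uppercases and converts T to U. Any character outside A/C/G/U after
#' normalization (including ambiguity codes such as N) is an error:
#' energies on ambiguous bases are undefined, so the package fails loudly
#' rather than skipping.
#'
#' @param x character vector of sequences.
#' @param what label used in error messages (e.g. the record id).
#' @return character vector of normalized RNA sequences.
#' @export
normalize_rna <- function(x, what = "sequence") {
  x <- toupper(x)
  x <- gsub("T", "U", x, fixed = TRUE)
  bad <- regexpr("[^ACGU]", x)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1L]
    stop(sprintf("illegal character '%s' at position %d in %s",
                 substr(x[i], bad[i], bad[i]), bad[i],
                 if (length(what) == length(x)) what[i] else what))
  }
  x
}

#' Read a miRNA FASTA file
#'
#' Records are normalized to the uppercase RNA alphabet (T converted to U).
#' miRNAs must be at least 9 nt long (seed positions 1-8 plus at least one
#' 3' base) and ids must be unique.
#'
#' @param path path to a FASTA file (RNA or DNA alphabet).
#' @return a data.frame with columns `id`, `sequence`, `length`.
#' @export
read_mirna_fasta <- function(path) {
  recs <- read_fasta_records(path)
  if (nrow(recs) == 0L) return(data.frame(id = character(), sequence = character(),
                                          length = integer(), stringsAsFactors = FALSE))
  recs$sequence <- normalize_rna(recs$sequence, what = recs$id)
  dup <- duplicated(recs$id)
  if (any(dup)) stop("duplicate miRNA id(s): ", paste(unique(recs$id[dup]), collapse = ", "))
  short <- nchar(recs$sequence) < 9L
  if (any(short)) stop("miRNA shorter than 9 nt: ", paste(recs$id[short], collapse = ", "))
  recs$length <- nchar(recs$sequence)
  recs
}

#' Read a 3'UTR FASTA file, optionally with upstream CDS context
#'
#' When a context FASTA is given, records are matched to UTRs by id and the
#' context sequence (the CDS tail immediately preceding the UTR) is attached;
#' UTRs without a context entry get an empty context. Context ids without a
#' matching UTR are skipped with a warning.
#'
#' @param path path to the UTR FASTA.
#' @param context_path optional path to an upstream-context FASTA.
#' @return a data.frame with columns `id`, `sequence`, `upstream_context`,
#'   `length`.
#' @export
read_utr_fasta <- function(path, context_path = NULL) {
  recs <- read_fasta_records(path)
  if (nrow(recs) == 0L) {
    return(data.frame(id = character(), sequence = character(),
                      upstream_context = character(), length = integer(),
                      stringsAsFactors = FALSE))
  }
  recs$sequence <- normalize_rna(recs$sequence, what = recs$id)
  dup <- duplicated(recs$id)
  if (any(dup)) stop("duplicate UTR id(s): ", paste(unique(recs$id[dup]), collapse = ", "))
  recs$upstream_context <- ""
  if (!is.null(context_path)) {
    ctx <- read_fasta_records(context_path)
    if (nrow(ctx) > 0L) {
      ctx$sequence <- normalize_rna(ctx$sequence, what = ctx$id)
      missing <- !(ctx$id %in% recs$id)
      if (any(missing)) {
        warning("context id(s) without matching UTR, skipped: ",
                paste(ctx$id[missing], collapse = ", "))
        ctx <- ctx[!missing, , drop = FALSE]
      }
      recs$upstream_context[match(ctx$id, recs$id)] <- ctx$sequence
    }
  }
  recs$length <- nchar(recs$sequence)
  recs[, c("id", "sequence", "upstream_context", "length")]
}

## FASTA parsing via Biostrings; returns id + raw sequence.
read_fasta_records <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("malformed FASTA in ", path, ": ",
                                           conditionMessage(e), call. = FALSE))
  ids <- sub("\\s.*$", "", names(set))
  data.frame(id = ids, sequence = as.character(set),
             stringsAsFactors = FALSE, row.names = NULL)
}

SITE_TABLE_COLS <- c("utr_id", "mirna_id", "utr_start", "utr_end",
                     "mirna_nucleus_start", "seed_type", "dG_H", "dG_open", "ddG")

#' Write a target-site table as TSV
#'
#' Coordinates are 0-based half-open on the UTR; energies are written in
#' kcal/mol with 2 decimals (computed at full precision internally).
#' Missing values are written as '.'.
#'
#' @param sites a site data.frame as returned by [score_sites()].
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_site_table <- function(sites, path) {
  out <- data.frame(
    utr_id = as.character(sites$utr_id),
    mirna_id = as.character(sites$mirna_id),
    utr_start = sites$utr_start,
    utr_end = sites$utr_end,
    mirna_nucleus_start = sites$mirna_pos,
    seed_type = as.character(sites$seed_type),
    dG_H = sprintf("%.2f", sites$dG_H),
    dG_open = sprintf("%.2f", sites$dG_open),
    ddG = sprintf("%.2f", sites$ddG),
    stringsAsFactors = FALSE
  )
  if (nrow(sites) == 0L) out <- out[0L, , drop = FALSE]
  write_tsv(out, path, SITE_TABLE_COLS)
  invisible(path)
}

#' Read a target-site table written by [write_site_table()]
#'
#' @param path path to the TSV.
#' @return a data.frame with the site-table columns.
#' @export
read_site_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = ".")
  missing <- setdiff(SITE_TABLE_COLS, names(df))
  if (length(missing)) stop("site table missing column(s): ", paste(missing, collapse = ", "))
  df
}

write_tsv <- function(df, path, cols = names(df)) {
  ok <- tryCatch({
    utils::write.table(df[, cols, drop = FALSE], path, sep = "\t",
                       quote = FALSE, row.names = FALSE, na = ".")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write ", path, ": ", conditionMessage(ok))
  invisible(path)
}
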