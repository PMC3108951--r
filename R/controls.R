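#' Configuration for shuffled-miRNA control construction
#'
#' Defaults mirror the control design used throughout the package's
#' evaluation machinery: 10 shuffled miRNAs per input miRNA, each assigned
#' 10 randomly selected UTRs, with a first-order Markov walk that must
#' place at least 85% of the sequence before random insertion of
#' leftovers, and exclusion of shuffles whose seed collides with known
#' miRNA seeds or poly-A motifs.
#'
#' @param n_shuffles_per_mirna shuffled miRNAs generated per input miRNA.
#' @param n_utrs_per_shuffle UTRs sampled (without replacement) for each
#'   shuffled miRNA.
#' @param first_order_min_fraction minimum fraction of the sequence the
#'   first-order walk must place for an attempt to be accepted.
#' @param forbidden_seeds character vector of heptamers (miRNA positions
#'   2-8 of known miRNAs) that a shuffle's seed must not equal.
#' @param poly_a_motifs motifs that must not occur within the shuffle's
#'   positions 1-8.
#' @param strict_6mer also reject shuffles whose positions 2-7 equal the
#'   corresponding hexamer of a forbidden seed.
#' @param max_retries attempts per shuffle before giving up.
#' @return a list of class `"shuffle_config"`.
#' @export
shuffle_config <- function(n_shuffles_per_mirna = 10L,
                           n_utrs_per_shuffle = 10L,
                           first_order_min_fraction = 0.85,
                           forbidden_seeds = character(0),
                           poly_a_motifs = c("AAAAAA", "AAUAAA"),
                           strict_6mer = FALSE,
                           max_retries = 1000L) {
  stopifnot(first_order_min_fraction > 0, first_order_min_fraction <= 1,
            n_shuffles_per_mirna >= 0L, max_retries >= 1L)
  structure(list(n_shuffles_per_mirna = as.integer(n_shuffles_per_mirna),
                 n_utrs_per_shuffle = as.integer(n_utrs_per_shuffle),
                 first_order_min_fraction = first_order_min_fraction,
                 forbidden_seeds = toupper(forbidden_seeds),
                 poly_a_motifs = toupper(poly_a_motifs),
                 strict_6mer = strict_6mer,
                 max_retries = as.integer(max_retries)),
            class = "shuffle_config")
}

#' Dinucleotide shuffle of a miRNA by a first-order Markov walk
#'
#' The start base is drawn from the input's mononucleotide frequencies;
#' the sequence is then extended by consuming the input's dinucleotide
#' multiset, each step choosing uniformly among the remaining
#' dinucleotides that begin with the current base and whose second base is
#' still available in the remaining mononucleotide pool. If the walk gets
#' stuck after placing at least `first_order_min_fraction` of the length,
#' leftover bases are inserted at uniformly random positions; otherwise
#' the attempt is discarded and retried. Output length and mononucleotide
#' composition always equal the input's.
#'
#' @param mirna_seq RNA string to shuffle (length >= 2).
#' @param config a [shuffle_config()].
#' @return the shuffled string, with attributes `first_order_fraction`
#'   (fraction placed by the walk before insertion) and `n_inserted`.
#' @export
dinucleotide_shuffle <- function(mirna_seq, config = shuffle_config()) {
  chars <- strsplit(mirna_seq, "", fixed = TRUE)[[1L]]
  L <- length(chars)
  if (L < 2L) stop("sequence too short to shuffle: ", mirna_seq)
  mono0 <- table(factor(chars, levels = RNA_BASES))
  di0 <- table(factor(paste0(chars[-L], chars[-1L]),
                      levels = as.vector(outer(RNA_BASES, RNA_BASES, paste0))))
  for (attempt in seq_len(config$max_retries)) {
    mono <- mono0
    di <- di0
    start <- sample(RNA_BASES, 1L, prob = as.numeric(mono0) / L)
    out <- start
    mono[start] <- mono[start] - 1L
    cur <- start
    while (length(out) < L) {
      cand <- paste0(cur, RNA_BASES)
      w <- as.numeric(di[cand])
      w[as.numeric(mono) <= 0] <- 0   # second base must remain available
      if (sum(w) == 0) break
      nxt <- RNA_BASES[sample.int(4L, 1L, prob = w)]
      out <- c(out, nxt)
      di[paste0(cur, nxt)] <- di[paste0(cur, nxt)] - 1L
      mono[nxt] <- mono[nxt] - 1L
      cur <- nxt
    }
    placed <- length(out)
    if (placed / L < config$first_order_min_fraction) next
    leftover <- rep(RNA_BASES, times = as.integer(mono))
    for (b in sample(leftover)) {
      pos <- sample.int(length(out) + 1L, 1L)
      out <- append(out, b, after = pos - 1L)
    }
    return(structure(paste(out, collapse = ""),
                     first_order_fraction = placed / L,
                     n_inserted = length(leftover)))
  }
  stop("dinucleotide shuffle failed after ", config$max_retries,
       " attempts for sequence ", mirna_seq,
       " (pathological composition?)")
}

#' Seed-conflict filter for shuffled miRNAs
#'
#' Rejects a shuffle whose positions 2-8 equal any forbidden heptamer, or
#' whose positions 1-8 contain any poly-A motif. With
#' `config$strict_6mer`, positions 2-7 matching a forbidden seed's first
#' hexamer also reject.
#'
#' @param shuffled_seq shuffled RNA string (length >= 8).
#' @param config a [shuffle_config()].
#' @return TRUE to accept, FALSE to reject.
#' @export
seed_conflict_filter <- function(shuffled_seq, config = shuffle_config()) {
  stopifnot(nchar(shuffled_seq) >= 8L)
  seed7 <- substr(shuffled_seq, 2L, 8L)
  if (seed7 %in% config$forbidden_seeds) return(FALSE)
  head8 <- substr(shuffled_seq, 1L, 8L)
  for (m in config$poly_a_motifs) {
    if (grepl(m, head8, fixed = TRUE)) return(FALSE)
  }
  if (config$strict_6mer && nchar(shuffled_seq) >= 7L) {
    if (substr(shuffled_seq, 2L, 7L) %in% substr(config$forbidden_seeds, 1L, 6L))
      return(FALSE)
  }
  TRUE
}

#' Generate shuffled miRNA-UTR control pairings
#'
#' For each input miRNA, emits `n_shuffles_per_mirna` accepted shuffles
#' (each retried through [seed_conflict_filter()] up to `max_retries`
#' times), each paired with `n_utrs_per_shuffle` UTR ids sampled without
#' replacement from the pool. Fully reproducible from `rng_seed`.
#'
#' @param mirnas data.frame from [read_mirna_fasta()].
#' @param utr_ids character vector of candidate UTR ids.
#' @param config a [shuffle_config()].
#' @param rng_seed integer seed; NULL uses the current RNG state.
#' @return a data.frame with one row per (shuffle, UTR) pair: `mirna_id`,
#'   `shuffle`, `control_id`, `shuffled_seq`, `utr_id`, `rng_seed`.
#' @export
generate_control_pairs <- function(mirnas, utr_ids,
                                   config = shuffle_config(),
                                   rng_seed = NULL) {
  if (length(utr_ids) < config$n_utrs_per_shuffle) {
    stop("UTR pool smaller than n_utrs_per_shuffle")
  }
  if (!is.null(rng_seed)) set.seed(rng_seed)
  rows <- list()
  for (i in seq_len(nrow(mirnas))) {
    for (s in seq_len(config$n_shuffles_per_mirna)) {
      shuf <- NULL
      for (try in seq_len(config$max_retries)) {
        cand <- dinucleotide_shuffle(mirnas$sequence[i], config)
        if (seed_conflict_filter(cand, config)) { shuf <- cand; break }
      }
      if (is.null(shuf)) {
        stop("no shuffle of ", mirnas$id[i], " passed the seed-conflict ",
             "filter after ", config$max_retries, " attempts")
      }
      picked <- sample(utr_ids, config$n_utrs_per_shuffle, replace = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        mirna_id = mirnas$id[i], shuffle = s,
        control_id = sprintf("%s_shuf%02d", mirnas$id[i], s),
        shuffled_seq = as.character(shuf), utr_id = picked,
        rng_seed = if (is.null(rng_seed)) NA_integer_ else rng_seed,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(mirna_id = character(), shuffle = integer(),
                      control_id = character(), shuffled_seq = character(),
                      utr_id = character(), rng_seed = integer(),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Sample one control site per control miRNA-UTR pair
#'
#' Uniform choice among each pair's scored sites; pairs with no match
#' contribute nothing.
#'
#' @param sites site data.frame covering the control pairs (grouped by
#'   `utr_id` and `mirna_id`).
#' @param rng_seed integer seed; NULL uses the current RNG state.
#' @return a site data.frame with at most one row per (mirna_id, utr_id).
#' @export
sample_control_site <- function(sites, rng_seed = NULL) {
  if (!is.null(rng_seed)) set.seed(rng_seed)
  if (nrow(sites) == 0L) return(sites)
  key <- paste(sites$mirna_id, sites$utr_id, sep = "\r")
  pick <- vapply(split(seq_len(nrow(sites)), key), function(idx) {
    if (length(idx) == 1L) idx else idx[sample.int(length(idx), 1L)]
  }, integer(1))
  out <- sites[sort(unname(pick)), , drop = FALSE]
  rownames(out) <- NULL
  out
}
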