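## Independent oracles and stub engines used across the suite.

COMP <- c(A = "U", C = "G", G = "C", U = "A")

chars <- function(x) strsplit(x, "", fixed = TRUE)[[1L]]

revcomp_chr <- function(x) paste(rev(unname(COMP[chars(x)])), collapse = "")

## Brute-force nucleus scanner: walk every UTR offset and every nucleus
## start, testing the four opposing bases one by one with the complement
## table (never string matching).
brute_force_matches <- function(mirna_seq, utr_seq) {
  mir <- chars(mirna_seq); utr <- chars(utr_seq)
  out <- data.frame(utr_start = integer(), mirna_pos = integer(),
                    nucleus = character(), stringsAsFactors = FALSE)
  for (j in seq_len(max(0L, length(utr) - 3L)) - 1L) {
    for (p in 2:5) {
      hit <- TRUE
      for (k in 0:3) {
        ## utr base at j+k faces miRNA base p + (3 - k)
        if (COMP[[mir[p + 3L - k]]] != utr[j + k + 1L]) { hit <- FALSE; break }
      }
      if (hit) {
        out <- rbind(out, data.frame(
          utr_start = j, mirna_pos = p,
          nucleus = paste(mir[p:(p + 3L)], collapse = ""),
          stringsAsFactors = FALSE))
      }
    }
  }
  out[order(out$utr_start, out$mirna_pos), , drop = FALSE]
}

## Independent seed classifier: tests every category definition directly
## and returns the first satisfied label in priority order.
oracle_seed_label <- function(paired, opp1A) {
  consec_within <- function(idx) {
    best <- 0L; run <- 0L
    for (i in idx) {
      run <- if (paired[i]) run + 1L else 0L
      best <- max(best, run)
    }
    best
  }
  in8 <- sum(paired[2:8]) + (if (paired[1L] || opp1A) 1L else 0L)
  defs <- list(
    `8mer` = all(paired[1:8]),
    `7mer-A` = all(paired[2:8]) && opp1A,
    `7mer` = consec_within(2:8) >= 7L,
    `6mer` = consec_within(2:8) >= 6L,
    `7in8` = in8 >= 7L,
    `6in8` = in8 >= 6L,
    `5mer` = consec_within(2:8) >= 5L,
    `5in8` = in8 >= 5L,
    `4mer` = TRUE)
  names(defs)[[which(unlist(defs))[1L]]]
}

## Pairwise-comparison AUC oracle: count pos-better-than-neg pairs, half
## credit for ties (lower value = more positive-like).
oracle_auc <- function(pos, neg) {
  wins <- 0
  for (p in pos) for (n in neg) {
    wins <- wins + if (p < n) 1 else if (p == n) 0.5 else 0
  }
  wins / (length(pos) * length(neg))
}

## Engine whose cofold leaves one nucleus base unpaired and adds an
## intramolecular pair, to force the repair path.
broken_cofold_engine <- function(base = toy_engine()) {
  eng <- base
  eng$constrained_cofold <- function(seq_a, seq_b, forced_pairs) {
    res <- base$constrained_cofold(seq_a, seq_b, forced_pairs)
    st <- res$structure
    drop_key <- paste(forced_pairs$mirna_pos[1L], forced_pairs$context_pos[1L])
    keep <- paste(st$pos_i, st$pos_j) != drop_key
    st <- st[keep, , drop = FALSE]
    st <- rbind(st, data.frame(mol_i = 2L, pos_i = 1L, mol_j = 2L,
                               pos_j = nchar(seq_b)))
    list(structure = st, energy = res$energy + 5)
  }
  eng$name <- "broken-cofold"
  eng
}

## Engine with a caller-scripted sequence of unpaired probabilities.
scripted_p_engine <- function(p_values) {
  i <- 0L
  eng <- toy_engine()
  eng$unpaired_probability <- function(window_seq, region_start, region_end,
                                       max_span) {
    if (region_end <= region_start) return(1)
    i <<- i + 1L
    p_values[[((i - 1L) %% length(p_values)) + 1L]]
  }
  eng$name <- "scripted-p"
  eng
}

write_fasta <- function(ids, seqs, path) {
  lines <- if (length(ids)) paste0(">", ids, "\n", seqs) else character(0)
  writeLines(lines, path)
  path
}

## small deterministic site table for filter/overlap tests
make_sites <- function(seed_type, ddG = seq_along(seed_type) * -1,
                       utr_start = seq(0, by = 10, length.out = length(seed_type)),
                       utr_id = "u1", mirna_id = "m1") {
  data.frame(utr_id = utr_id, mirna_id = mirna_id,
             utr_start = utr_start, utr_end = utr_start + 4L,
             mirna_pos = 2L, nucleus = "ACGU", seed_type = seed_type,
             dG_H = ddG - 0.5, dG_open = -0.5, ddG = ddG,
             stringsAsFactors = FALSE)
}
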