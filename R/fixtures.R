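#' Random UTR sequence
#'
#' @param length sequence length in nt (> 0).
#' @param composition named base probabilities (A, C, G, U), summing to 1.
#' @return the sequence string.
#' @export
random_utr <- function(length,
                       composition = c(A = 0.3, C = 0.2, G = 0.2, U = 0.3)) {
  stopifnot(length > 0)
  check_composition(composition)
  paste(sample(RNA_BASES, length, replace = TRUE,
               prob = composition[RNA_BASES]), collapse = "")
}

#' Random miRNA sequence
#'
#' @param length miRNA length in nt (>= 9).
#' @inheritParams random_utr
#' @return the sequence string.
#' @export
random_mirna <- function(length = 22L,
                         composition = c(A = 0.25, C = 0.25,
                                         G = 0.25, U = 0.25)) {
  stopifnot(length >= 9L)
  check_composition(composition)
  paste(sample(RNA_BASES, length, replace = TRUE,
               prob = composition[RNA_BASES]), collapse = "")
}

check_composition <- function(composition) {
  if (!all(RNA_BASES %in% names(composition)) ||
      any(composition < 0) || abs(sum(composition) - 1) > 1e-6) {
    stop("composition must be named probabilities over A, C, G, U summing to 1")
  }
  invisible(TRUE)
}

## Watson-Crick pairing pattern (miRNA positions 1-8) and opposite-1 rule
## that realises each seed type without accidental upgrades
SEED_PLANS <- list(
  `8mer`   = list(paired = 1:8,                opp1 = "pair"),
  `7mer-A` = list(paired = 2:8,                opp1 = "A"),
  `7mer`   = list(paired = 2:8,                opp1 = "mismatch"),
  `6mer`   = list(paired = 2:7,                opp1 = "mismatch"),
  `7in8`   = list(paired = c(2, 3, 4, 5, 7, 8), opp1 = "A"),
  `6in8`   = list(paired = c(2, 3, 4, 5, 7),   opp1 = "A"),
  `5mer`   = list(paired = 2:6,                opp1 = "mismatch"),
  `5in8`   = list(paired = c(2, 3, 4, 5, 7),   opp1 = "mismatch"),
  `4mer`   = list(paired = 2:5,                opp1 = "mismatch")
)

#' Plant a target site of a requested seed type into a UTR
#'
#' Writes an 8-nt window (opposite miRNA positions 8..1) into the UTR such
#' that [assign_seed_type()] classifies the site exactly as requested.
#' Mismatch positions get a base that neither Watson-Crick-pairs the miRNA
#' base nor (at position 1) is an adenine, so accidental upgrades cannot
#' occur; the planted label is re-verified before returning. Planting over
#' a previously planted window overwrites it with a warning.
#'
#' @param utr_seq UTR sequence (plain string, possibly carrying a
#'   `planted_spans` attribute from earlier calls).
#' @param mirna_seq miRNA sequence.
#' @param seed_type requested label, one of [seed_types()].
#' @param position 0-based UTR start of the 8-nt window (must leave room
#'   for 8 nt).
#' @return the modified UTR string with an updated `planted_spans`
#'   attribute (data.frame `start`, `end`, `seed_type`).
#' @export
plant_site <- function(utr_seq, mirna_seq, seed_type, position) {
  if (!seed_type %in% names(SEED_PLANS)) stop("unknown seed type: ", seed_type)
  if (position < 0 || position + 8L > nchar(utr_seq)) {
    stop("position leaves no room for an 8-nt site")
  }
  plan <- SEED_PLANS[[seed_type]]
  mir <- strsplit(substr(mirna_seq, 1L, 8L), "", fixed = TRUE)[[1L]]
  if (seed_type == "7mer-A" && mir[1L] == "U") {
    stop("impossible request: 7mer-A with a miRNA starting in U is an 8mer")
  }
  window <- character(8L)                # window index k holds miRNA pos 8-k+1
  for (i in 1:8) {
    k <- 9L - i                          # window slot for miRNA position i
    if (i %in% plan$paired) {
      window[k] <- unname(WC_COMP[mir[i]])
    } else if (i == 1L) {
      window[k] <- switch(plan$opp1,
                          A = "A",
                          pair = unname(WC_COMP[mir[1L]]),
                          mismatch = mismatch_base(mir[1L], forbid_A = TRUE))
    } else {
      window[k] <- mismatch_base(mir[i])
    }
  }
  spans <- attr(utr_seq, "planted_spans")
  new_span <- data.frame(start = position, end = position + 8L,
                         seed_type = seed_type, stringsAsFactors = FALSE)
  if (!is.null(spans) &&
      any(spans$start < new_span$end & new_span$start < spans$end)) {
    warning("planting over a previously planted window; overwriting")
  }
  out <- paste0(substr(utr_seq, 1L, position),
                paste(window, collapse = ""),
                substr(utr_seq, position + 9L, nchar(utr_seq)))
  ## closed loop: the register places the nucleus (positions 2-5) such
  ## that utr_start = position + 3 for mirna_pos = 2
  got <- assign_seed_type(position + 3L, 2L, mirna_seq, out)
  if (!identical(got, seed_type)) {
    stop("planting failed: requested ", seed_type, " but produced ", got)
  }
  attr(out, "planted_spans") <- rbind(spans, new_span)
  out
}

## deterministic-ish mismatch base: not the WC partner, optionally not A
mismatch_base <- function(mirna_base, forbid_A = FALSE) {
  cand <- setdiff(RNA_BASES, WC_COMP[mirna_base])
  if (forbid_A) cand <- setdiff(cand, "A")
  cand[1L]
}

#' Simulate expression responses linear in the energy features
#'
#' observed = intercept + sum(beta_i x feature_i) + Normal(0, noise_sd).
#'
#' @param features feature data.frame from [feature_table()].
#' @param coefficients named numeric vector over (a subset of) the 14
#'   feature names, optionally including `"(Intercept)"`.
#' @param noise_sd Gaussian noise standard deviation (log2FC units).
#' @param rng_seed integer seed; NULL uses the current RNG state.
#' @return numeric vector of simulated log2 fold changes.
#' @export
simulate_expression <- function(features, coefficients, noise_sd = 0,
                                rng_seed = NULL) {
  stopifnot(noise_sd >= 0)
  if (!is.null(rng_seed)) set.seed(rng_seed)
  intercept <- if ("(Intercept)" %in% names(coefficients)) {
    coefficients[["(Intercept)"]]
  } else 0
  beta <- coefficients[setdiff(names(coefficients), "(Intercept)")]
  unknown <- setdiff(names(beta), FEATURE_NAMES)
  if (length(unknown)) stop("unknown feature(s): ",
                            paste(unknown, collapse = ", "))
  X <- as.matrix(features[, names(beta), drop = FALSE])
  storage.mode(X) <- "double"
  drop(intercept + X %*% beta) + stats::rnorm(nrow(X), 0, noise_sd)
}

#' Default generating coefficients for synthetic studies
#'
#' Directions follow the biology: more favorable energies (lower ddG and
#' dG_H, higher dG_open) and longer UTRs associate with stronger
#' down-regulation, so ddG / dG_H features carry positive weights,
#' dG_open features negative ones, and UTR length a small negative
#' weight. The three features that are exact linear combinations of the
#' others (because ddG = dG_H - dG_open holds at every site:
#' `dG_open_at_best_ddG`, `dG_open_at_second_ddG`, `sum_dG_open`) carry
#' zero generating weight — any weight put there would be absorbed into
#' the identifiable features anyway.
#'
#' @return named numeric vector over `"(Intercept)"` and the 14 features.
#' @seealso [dependent_feature_names()]
#' @export
default_true_coefficients <- function() {
  ## scaled so that simulated log2 fold changes look like transfection
  ## data: most genes within +/- 0.5, strong targets near -1
  c(`(Intercept)` = 0.5,
    best_ddG = 0.01, second_best_ddG = 0.006,
    best_dG_H = 0.006, second_best_dG_H = 0.004,
    best_dG_open = -0.02, second_best_dG_open = -0.012,
    dG_H_at_best_ddG = 0.004, dG_H_at_second_ddG = 0.003,
    dG_open_at_best_ddG = 0, dG_open_at_second_ddG = 0,
    sum_ddG = 8e-04, sum_dG_H = 6e-04, sum_dG_open = 0,
    utr_length = -5e-05)
}

#' Structurally dependent features of the 14-feature set
#'
#' Because the total energy is defined as ddG = dG_H - dG_open at every
#' site, three features are exact linear combinations of the others:
#' `dG_open_at_best_ddG = dG_H_at_best_ddG - best_ddG`,
#' `dG_open_at_second_ddG = dG_H_at_second_ddG - second_best_ddG`, and
#' `sum_dG_open = sum_dG_H - sum_ddG`. A design over all 14 features is
#' therefore always rank-deficient and individual weights for this triple
#' are not identifiable (their contribution is absorbed by the companion
#' features); a plain least-squares fitter reports them as aliased.
#'
#' @return character vector of the three dependent feature names.
#' @export
dependent_feature_names <- function() {
  c("dG_open_at_best_ddG", "dG_open_at_second_ddG", "sum_dG_open")
}

#' Generate a complete synthetic miRNA transfection study
#'
#' Emulates the statistical structure of a transfection experiment at desk
#' scale: random miRNAs, log-normal UTR lengths with a slightly AU-rich
#' base composition, target sites of chosen seed types planted into a
#' fraction of genes (plus whatever background 4-mer matches arise by
#' chance), energies from a deterministic engine, and expression change
#' linear in the energy features plus Gaussian noise.
#'
#' @param n_genes number of genes (UTRs).
#' @param n_mirnas number of miRNAs; expression is simulated for every
#'   miRNA-gene pair.
#' @param mirna_length miRNA length in nt.
#' @param utr_meanlog,utr_sdlog log-normal parameters of UTR length.
#' @param utr_range UTR lengths are clamped to this range.
#' @param composition UTR base composition.
#' @param planted_fraction fraction of genes receiving a planted site per
#'   miRNA.
#' @param planted_types seed types sampled for planted sites.
#' @param true_coefficients generating coefficients (see
#'   [default_true_coefficients()]).
#' @param noise_sd response noise standard deviation, log2FC units.
#' @param engine thermodynamics engine for site scoring.
#' @param config a [thermo_config()].
#' @param seed_filter seed-stringency level for site scoring.
#' @param rng_seed integer seed; NULL uses the current RNG state.
#' @return a list: `mirnas`, `utrs` (data.frames), `sites`, `features`,
#'   `noiseless`, `observed`, `true_coefficients`, `planted` (per-pair
#'   planted seed type or NA).
#' @export
synthetic_study <- function(n_genes = 300L, n_mirnas = 1L,
                            mirna_length = 22L,
                            utr_meanlog = log(800), utr_sdlog = 0.6,
                            utr_range = c(60L, 4000L),
                            composition = c(A = 0.3, C = 0.2,
                                            G = 0.2, U = 0.3),
                            planted_fraction = 0.3,
                            planted_types = c("8mer", "7mer", "6mer", "6in8"),
                            true_coefficients = default_true_coefficients(),
                            noise_sd = 0.2,
                            engine = toy_engine(accessibility = "au",
                                                position_weight = 0.02),
                            config = thermo_config(),
                            seed_filter = "4mer",
                            rng_seed = NULL) {
  if (!is.null(rng_seed)) set.seed(rng_seed)
  mirnas <- data.frame(
    id = sprintf("mir%02d", seq_len(n_mirnas)),
    sequence = vapply(seq_len(n_mirnas), function(i)
      random_mirna(mirna_length), character(1)),
    stringsAsFactors = FALSE)
  mirnas$length <- nchar(mirnas$sequence)
  lens <- pmin(pmax(round(stats::rlnorm(n_genes, utr_meanlog, utr_sdlog)),
                    utr_range[1L]), utr_range[2L])
  utrs <- data.frame(
    id = sprintf("gene%04d", seq_len(n_genes)),
    sequence = vapply(lens, random_utr, character(1),
                      composition = composition),
    upstream_context = "",
    length = lens, stringsAsFactors = FALSE)
  planted <- matrix(NA_character_, n_genes, n_mirnas,
                    dimnames = list(utrs$id, mirnas$id))
  for (m in seq_len(n_mirnas)) {
    chosen <- which(stats::runif(n_genes) < planted_fraction)
    for (g in chosen) {
      type <- sample(planted_types, 1L)
      if (type == "7mer-A" &&
          substr(mirnas$sequence[m], 1L, 1L) == "U") type <- "8mer"
      pos <- sample.int(lens[g] - 8L, 1L)
      utrs$sequence[g] <- as.character(
        plant_site(utrs$sequence[g], mirnas$sequence[m], type, pos))
      planted[g, m] <- type
    }
  }
  sites <- score_all_sites(mirnas, utrs, engine = engine, config = config,
                           seed_filter = seed_filter)
  pairs <- expand.grid(mirna_id = mirnas$id, gene_id = utrs$id,
                       stringsAsFactors = FALSE)
  pairs$utr_length <- utrs$length[match(pairs$gene_id, utrs$id)]
  feats <- feature_table(sites, pairs)
  noiseless <- simulate_expression(feats, true_coefficients, noise_sd = 0)
  observed <- noiseless + stats::rnorm(nrow(feats), 0, noise_sd)
  list(mirnas = mirnas, utrs = utrs, sites = sites, features = feats,
       noiseless = noiseless, observed = observed,
       true_coefficients = true_coefficients, planted = planted)
}
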