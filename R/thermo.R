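#' Thermodynamics configuration
#'
#' Parameters of the local-folding energetics. Defaults follow common
#' practice for local RNA accessibility scanning: window size W = 80 nt,
#' maximum base-pair span L = 40 nt, open region size u = 20 nt, and
#' RT at 37 C (0.0019872 kcal/mol/K x 310.15 K = 0.6163 kcal/mol).
#'
#' @param window_W local-structure window size in nt.
#' @param max_span_L maximum distance between paired bases in nt.
#' @param open_len_u open-region size in nt.
#' @param temperature temperature in Kelvin.
#' @param RT gas constant times temperature, kcal/mol.
#' @param windows_over what the sliding open regions must contain:
#'   `"nucleus"` (default) slides u-length open regions over the 4-mer
#'   nucleus; `"span"` uses the full extracted site span instead.
#' @param p_floor numeric floor applied to unpaired probabilities before
#'   taking the log (probability 0 is an engine artifact).
#' @return a list of class `"thermo_config"`.
#' @export
thermo_config <- function(window_W = 80L, max_span_L = 40L, open_len_u = 20L,
                          temperature = 310.15,
                          RT = 0.0019872 * temperature,
                          windows_over = c("nucleus", "span"),
                          p_floor = 1e-12) {
  windows_over <- match.arg(windows_over)
  stopifnot(open_len_u >= 1L, open_len_u <= max_span_L,
            max_span_L <= window_W, RT > 0)
  structure(list(window_W = as.integer(window_W),
                 max_span_L = as.integer(max_span_L),
                 open_len_u = as.integer(open_len_u),
                 temperature = temperature, RT = RT,
                 windows_over = windows_over, p_floor = p_floor),
            class = "thermo_config")
}

#' Deterministic toy thermodynamics engine
#'
#' A pair-counting stand-in for a folding backend, so the full pipeline is
#' testable and exactly reproducible: every intermolecular Watson-Crick
#' pair contributes -1.0 kcal/mol, every G-U wobble -0.5, intramolecular
#' pairs are never formed, and the unpaired probability is a constant.
#' Cofolding fixes the antisense register implied by the forced nucleus
#' pairs and extends it over both sequences.
#'
#' @param p_unpaired constant unpaired probability returned for any
#'   non-empty region (a region of length 0 has probability 1).
#' @param accessibility `"constant"` returns `p_unpaired` everywhere;
#'   `"au"` makes the probability sequence-dependent,
#'   `0.05 + 0.9 x (AU fraction of the open region)`, mimicking the fact
#'   that unstructured AU-rich regions are more accessible while staying
#'   fully deterministic.
#' @param position_weight deepens pairs towards the miRNA 3' end: a pair
#'   at miRNA position i contributes an extra
#'   `-position_weight x (i - 1)` (half that for G-U). The default 0
#'   keeps the plain -1 / -0.5 counts; a small positive value breaks the
#'   half-kcal quantization so that fixture feature matrices are full
#'   rank.
#' @return an engine: a list with functions `constrained_cofold`,
#'   `evaluate` and `unpaired_probability` (see [thermo_config()] for the
#'   calling pipeline), plus a `name`.
#' @export
toy_engine <- function(p_unpaired = 1, accessibility = c("constant", "au"),
                       position_weight = 0) {
  accessibility <- match.arg(accessibility)
  stopifnot(p_unpaired > 0, p_unpaired <= 1, position_weight >= 0)
  pair_energy <- function(a, b, apos) {
    base <- ifelse(WC_COMP[a] == b, -1,
                   ifelse((a == "G" & b == "U") | (a == "U" & b == "G"),
                          -0.5, 0))
    base * (1 + position_weight * (apos - 1))
  }
  cofold <- function(seq_a, seq_b, forced_pairs) {
    ach <- strsplit(seq_a, "", fixed = TRUE)[[1L]]
    bch <- strsplit(seq_b, "", fixed = TRUE)[[1L]]
    reg <- forced_pairs$mirna_pos[1L] + forced_pairs$context_pos[1L]
    a_pos <- seq_along(ach)
    b_pos <- reg - a_pos
    ok <- b_pos >= 1L & b_pos <= length(bch)
    a_pos <- a_pos[ok]; b_pos <- b_pos[ok]
    e <- pair_energy(ach[a_pos], bch[b_pos], a_pos)
    bind <- e < 0
    forced <- paste(forced_pairs$mirna_pos, forced_pairs$context_pos) %in%
      paste(a_pos, b_pos)
    if (!all(forced)) stop("forced pairs do not lie on one antisense register")
    pairs <- data.frame(mol_i = 1L, pos_i = a_pos[bind],
                        mol_j = 2L, pos_j = b_pos[bind])
    list(structure = pairs, energy = sum(e[bind]))
  }
  eval_struct <- function(seq_a, seq_b, structure) {
    if (nrow(structure) == 0L) return(0)
    inter <- structure$mol_i != structure$mol_j
    if (!any(inter)) return(0)
    ach <- strsplit(seq_a, "", fixed = TRUE)[[1L]]
    bch <- strsplit(seq_b, "", fixed = TRUE)[[1L]]
    s <- structure[inter, , drop = FALSE]
    a <- ifelse(s$mol_i == 1L, s$pos_i, s$pos_j)
    b <- ifelse(s$mol_i == 1L, s$pos_j, s$pos_i)
    sum(pair_energy(ach[a], bch[b], a))
  }
  unpaired <- function(window_seq, region_start, region_end, max_span) {
    if (region_end <= region_start) return(1)
    if (accessibility == "constant") return(p_unpaired)
    region <- substr(window_seq, region_start + 1L, region_end)
    au <- nchar(gsub("[^AU]", "", region)) / nchar(region)
    0.05 + 0.9 * au
  }
  list(name = sprintf("toy(p=%s)", if (accessibility == "au") "au"
                      else format(p_unpaired)),
       constrained_cofold = cofold,
       evaluate = eval_struct,
       unpaired_probability = unpaired)
}

#' Hybridization energy of the miRNA with its local site context
#'
#' Cofolds the miRNA against the extracted duplex context, forcing the four
#' nucleus pairs. If the returned structure has all four nucleus bases
#' intermolecularly paired to their designated partners and neither
#' molecule carries intramolecular pairs, the cofold energy is returned
#' directly. Otherwise the structure is repaired — nucleus pairs enforced,
#' every intramolecular pair deleted, all other intermolecular pairs kept —
#' and re-evaluated.
#'
#' @param mirna_seq miRNA sequence (molecule 1).
#' @param context duplex context string (molecule 2), from
#'   [extract_duplex_context()].
#' @param nucleus_alignment data.frame with columns `mirna_pos`,
#'   `context_pos` (1-based) mapping the 4 nucleus miRNA bases to their
#'   context partners.
#' @param engine a thermodynamics engine, e.g. [toy_engine()] or
#'   [vienna_engine()].
#' @param config a [thermo_config()].
#' @return a list with `dG_H` (kcal/mol) and `structure` (the pair table
#'   used for the energy).
#' @export
hybridization_energy <- function(mirna_seq, context, nucleus_alignment,
                                 engine, config = thermo_config()) {
  res <- tryCatch(
    engine$constrained_cofold(mirna_seq, context, nucleus_alignment),
    error = function(e) stop("engine failure on miRNA '", mirna_seq,
                             "' vs context '", context, "': ",
                             conditionMessage(e), call. = FALSE))
  st <- res$structure
  inter <- st$mol_i != st$mol_j
  key <- function(a, b) paste(a, b)
  have <- key(ifelse(st$mol_i == 1L, st$pos_i, st$pos_j)[inter],
              ifelse(st$mol_i == 1L, st$pos_j, st$pos_i)[inter])
  want <- key(nucleus_alignment$mirna_pos, nucleus_alignment$context_pos)
  if (all(want %in% have) && all(inter)) {
    return(list(dG_H = res$energy, structure = st))
  }
  repaired <- repair_structure(st, nucleus_alignment)
  list(dG_H = engine$evaluate(mirna_seq, context, repaired),
       structure = repaired)
}

## nucleus pairs enforced, intramolecular pairs deleted, other
## intermolecular pairs retained (dropping any that clash with the nucleus)
repair_structure <- function(structure, nucleus_alignment) {
  st <- structure[structure$mol_i != structure$mol_j, , drop = FALSE]
  if (nrow(st)) {
    a <- ifelse(st$mol_i == 1L, st$pos_i, st$pos_j)
    b <- ifelse(st$mol_i == 1L, st$pos_j, st$pos_i)
    clash <- a %in% nucleus_alignment$mirna_pos |
      b %in% nucleus_alignment$context_pos
    st <- data.frame(mol_i = 1L, pos_i = a[!clash],
                     mol_j = 2L, pos_j = b[!clash])
  }
  forced <- data.frame(mol_i = 1L, pos_i = nucleus_alignment$mirna_pos,
                       mol_j = 2L, pos_j = nucleus_alignment$context_pos)
  out <- rbind(st, forced)
  out[order(out$pos_i), , drop = FALSE]
}

#' Sliding open-region placements over a required interval
#'
#' All placements of a u-length open region that fully contain the required
#' interval and lie within the sequence; an interval longer than u instead
#' yields all u-regions fully inside it. For an interior 4-mer nucleus and
#' u = 20 this gives u - 4 + 1 = 17 placements.
#'
#' @param region_start,region_end 0-based half-open required interval.
#' @param seq_len total sequence length.
#' @param u open-region length.
#' @return integer vector of 0-based open-region start positions.
#' @export
sliding_open_regions <- function(region_start, region_end, seq_len, u) {
  if (seq_len < u) return(0L)  # single full-length region, handled upstream
  rlen <- region_end - region_start
  if (rlen <= u) {
    lo <- max(0L, region_end - u)
    hi <- min(region_start, seq_len - u)
  } else {
    lo <- region_start
    hi <- region_end - u
  }
  if (hi < lo) return(integer(0))
  seq.int(lo, hi)
}

#' Disruption energy of a target site
#'
#' For every placement of a u-length open region containing the site's
#' 4-mer nucleus, a window of exactly W nt centered on the open region
#' (shifted inward at sequence ends, shrunk only when the whole sequence is
#' shorter than W) is passed to the engine, the unpaired probability of the
#' open region is converted to an energy via RT ln(P), and the mean over
#' all placements is returned. The log is taken before averaging because
#' the expectation of a log is not the log of the expectation.
#'
#' @param seq the UTR sequence with any upstream context prepended.
#' @param nucleus_start,nucleus_end 0-based half-open interval of the 4-mer
#'   nucleus within `seq` (or of the full site span when
#'   `config$windows_over == "span"`; pass the span instead).
#' @param engine a thermodynamics engine.
#' @param config a [thermo_config()].
#' @param detail if TRUE, also return the per-placement table.
#' @return dG_open in kcal/mol (non-positive), or a list
#'   `(dG_open, placements)` when `detail = TRUE`.
#' @export
disruption_energy <- function(seq, nucleus_start, nucleus_end, engine,
                              config = thermo_config(), detail = FALSE) {
  n <- nchar(seq)
  u <- config$open_len_u
  W <- config$window_W
  if (n < u) {
    warning("sequence shorter than the open-region size; using one ",
            "full-length open region")
    starts <- 0L
    u_eff <- n
  } else {
    starts <- sliding_open_regions(nucleus_start, nucleus_end, n, u)
    u_eff <- u
  }
  ws <- integer(length(starts)); p <- numeric(length(starts))
  for (i in seq_along(starts)) {
    s <- starts[i]
    if (n <= W) {
      w0 <- 0L; w1 <- n
    } else {
      w0 <- s - (W - u_eff) %/% 2L
      w0 <- max(0L, min(w0, n - W))
      w1 <- w0 + W
    }
    ws[i] <- w0
    win <- substr(seq, w0 + 1L, w1)
    pr <- engine$unpaired_probability(win, s - w0, s - w0 + u_eff,
                                      config$max_span_L)
    p[i] <- min(1, max(config$p_floor, pr))
  }
  dg <- config$RT * log(p)
  out <- mean(dg)
  if (!detail) return(out)
  list(dG_open = out,
       placements = data.frame(open_start = starts, window_start = ws,
                               p_unpaired = p, dG_open = dg))
}

#' Total energy of stepwise duplex formation
#'
#' @param dG_H hybridization energy, kcal/mol.
#' @param dG_open disruption energy, kcal/mol.
#' @return ddG = dG_H - dG_open.
#' @export
total_energy <- function(dG_H, dG_open) dG_H - dG_open

#' Score all candidate target sites of a miRNA in one UTR
#'
#' End-to-end per-site scoring: 4-mer nucleus scan, duplex-context
#' extraction, hybridization and disruption energies, seed-type
#' assignment, overlap resolution by best ddG, and optional seed-type
#' filtering. Deterministic for a fixed engine.
#'
#' @param mirna_id,mirna_seq miRNA identity and sequence.
#' @param utr_id,utr_seq UTR identity and sequence.
#' @param upstream_context CDS tail preceding the UTR ("" if none).
#' @param engine a thermodynamics engine.
#' @param config a [thermo_config()].
#' @param seed_filter seed-stringency level passed to [filter_by_seed()].
#' @param resolve if TRUE (default), overlapping 4-mers are reduced to
#'   their best-ddG representative.
#' @param symmetric_flanks passed to [extract_duplex_context()].
#' @return a site data.frame: `utr_id`, `mirna_id`, `utr_start`, `utr_end`,
#'   `mirna_pos`, `nucleus`, `seed_type`, `dG_H`, `dG_open`, `ddG`,
#'   `span_start`, `span_end`, `context`, `open_context`.
#' @export
score_sites <- function(mirna_id, mirna_seq, utr_id, utr_seq,
                        upstream_context = "", engine = toy_engine(),
                        config = thermo_config(),
                        seed_filter = "4mer", resolve = TRUE,
                        symmetric_flanks = FALSE) {
  matches <- find_nucleus_matches(mirna_seq, utr_seq)
  n <- nrow(matches)
  empty <- data.frame(utr_id = character(), mirna_id = character(),
                      utr_start = integer(), utr_end = integer(),
                      mirna_pos = integer(), nucleus = character(),
                      seed_type = character(), dG_H = numeric(),
                      dG_open = numeric(), ddG = numeric(),
                      span_start = integer(), span_end = integer(),
                      context = character(), open_context = character(),
                      stringsAsFactors = FALSE)
  if (n == 0L) return(empty)
  ctx_len <- nchar(upstream_context)
  full <- paste0(upstream_context, utr_seq)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    m <- matches[i, ]
    dc <- extract_duplex_context(m$utr_start, m$mirna_pos, mirna_seq,
                                 utr_seq, upstream_context,
                                 symmetric_flanks = symmetric_flanks)
    align <- data.frame(mirna_pos = m$mirna_pos + 0:3,
                        context_pos = dc$nucleus_offset + 4:1)
    hyb <- hybridization_energy(mirna_seq, dc$context, align, engine, config)
    if (config$windows_over == "span") {
      r0 <- dc$span_start + ctx_len; r1 <- dc$span_end + ctx_len
    } else {
      r0 <- m$utr_start + ctx_len; r1 <- r0 + 4L
    }
    dis <- disruption_energy(full, r0, r1, engine, config, detail = TRUE)
    w0 <- min(dis$placements$window_start)
    w1 <- max(dis$placements$window_start) + min(nchar(full), config$window_W)
    rows[[i]] <- data.frame(
      utr_id = utr_id, mirna_id = mirna_id,
      utr_start = m$utr_start, utr_end = m$utr_start + 4L,
      mirna_pos = m$mirna_pos, nucleus = m$nucleus,
      seed_type = assign_seed_type(m$utr_start, m$mirna_pos, mirna_seq, utr_seq),
      dG_H = hyb$dG_H, dG_open = dis$dG_open,
      ddG = total_energy(hyb$dG_H, dis$dG_open),
      span_start = dc$span_start, span_end = dc$span_end,
      context = dc$context,
      open_context = substr(full, w0 + 1L, w1),
      stringsAsFactors = FALSE)
  }
  sites <- do.call(rbind, rows)
  if (resolve) sites <- resolve_overlaps(sites)
  sites <- filter_by_seed(sites, seed_filter)
  rownames(sites) <- NULL
  sites
}

#' Score a set of miRNAs against a set of UTRs
#'
#' Convenience wrapper over [score_sites()] for whole input tables.
#'
#' @param mirnas data.frame from [read_mirna_fasta()].
#' @param utrs data.frame from [read_utr_fasta()].
#' @param pairs optional data.frame (`mirna_id`, `utr_id`) restricting
#'   which combinations are scanned; default is all-vs-all.
#' @inheritParams score_sites
#' @return a combined site data.frame.
#' @export
score_all_sites <- function(mirnas, utrs, pairs = NULL,
                            engine = toy_engine(), config = thermo_config(),
                            seed_filter = "4mer", resolve = TRUE) {
  if (is.null(pairs)) {
    pairs <- expand.grid(mirna_id = mirnas$id, utr_id = utrs$id,
                         stringsAsFactors = FALSE)
  }
  res <- vector("list", nrow(pairs))
  mi <- match(pairs$mirna_id, mirnas$id)
  ui <- match(pairs$utr_id, utrs$id)
  if (anyNA(mi) || anyNA(ui)) stop("pair refers to unknown mirna_id/utr_id")
  for (i in seq_len(nrow(pairs))) {
    res[[i]] <- score_sites(pairs$mirna_id[i], mirnas$sequence[mi[i]],
                            pairs$utr_id[i], utrs$sequence[ui[i]],
                            upstream_context = utrs$upstream_context[ui[i]],
                            engine = engine, config = config,
                            seed_filter = seed_filter, resolve = resolve)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
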