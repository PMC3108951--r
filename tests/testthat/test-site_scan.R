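test_that("nucleus scanner reproduces the four-register seed example", {
  m <- "UGGAAUGUAAAGAAGUAUGUAU"
  hits <- find_nucleus_matches(m, "ACAUUCC")
  expect_equal(hits$utr_start, 0:3)
  expect_equal(hits$mirna_pos, c(5L, 4L, 3L, 2L))
  expect_equal(hits$nucleus, c("AUGU", "AAUG", "GAAU", "GGAA"))
})

test_that("scanner equals the brute-force oracle on random pairs", {
  set.seed(401)
  for (i in 1:200) {
    m <- random_mirna(sample(18:24, 1L))
    u <- random_utr(sample(20:300, 1L))
    got <- find_nucleus_matches(m, u)
    want <- brute_force_matches(m, u)
    rownames(got) <- rownames(want) <- NULL
    expect_identical(got, want)
  }
})

test_that("G-U wobble never seeds a nucleus and poly-A UTRs stay empty", {
  ## seed 2-5 = GGAA; WC target UUCC; wobble-only pseudo-target UUUU
  m <- "UGGAAUGUAAAGAAGUAUGUAU"
  expect_equal(nrow(find_nucleus_matches(m, "GGUUUUGG")), 0L)
  expect_equal(nrow(find_nucleus_matches(m, strrep("A", 50))), 0L)
})

test_that("duplex context flanks are twice each remaining miRNA arm", {
  m <- random_mirna(22)
  u <- random_utr(200)
  ## nucleus at positions 2-5: 5' remainder 1 nt -> downstream flank 2,
  ## 3' remainder 17 nt -> upstream flank 34; total context 40
  dc <- extract_duplex_context(100L, 2L, m, u)
  expect_equal(nchar(dc$context), 34L + 4L + 2L)
  expect_equal(dc$span_start, 100L - 34L)
  expect_equal(dc$span_end, 100L + 4L + 2L)
  expect_equal(dc$nucleus_offset, 34L)
  expect_equal(substr(dc$context, 35L, 38L), substr(u, 101L, 104L))

  ## nucleus at 5-8: arms 4 and 14 -> flanks 8 (downstream) and 28 (upstream)
  dc2 <- extract_duplex_context(100L, 5L, m, u)
  expect_equal(nchar(dc2$context), 28L + 4L + 8L)

  ## truncation at the UTR start without context
  dc3 <- extract_duplex_context(0L, 2L, m, u)
  expect_equal(dc3$span_start, 0L)
  expect_equal(nchar(dc3$context), 4L + 2L)

  ## the 5' flank extends into upstream CDS context when present
  ctx <- random_utr(50)
  dc4 <- extract_duplex_context(0L, 2L, m, u, upstream_context = ctx)
  expect_equal(nchar(dc4$context), 34L + 4L + 2L)
  expect_equal(dc4$span_start, -34L)
  expect_equal(substr(dc4$context, 1L, 34L), substr(ctx, 17L, 50L))
})

test_that("seed taxonomy matches its definitions on a full truth table", {
  mir <- "GACGCUAGAAGGCCAAUUGGCC"   # position 1 is G, so opposite-A never pairs
  flank <- strrep("C", 6)
  mismatch_for <- function(b, forbid_A = FALSE) {
    setdiff(c("G", "A", "C", "U"),
            c(COMP[[b]], if (forbid_A) "A"))[1L]
  }
  mirc <- chars(substr(mir, 1, 8))
  for (bits in 0:255) {
    paired <- as.logical(bitwAnd(bits, 2^(0:7)))
    opp1_options <- if (paired[1L]) FALSE else c(TRUE, FALSE)
    for (oppA in opp1_options) {
      window <- character(8L)
      for (i in 1:8) {
        slot <- 9L - i
        window[slot] <- if (paired[i]) COMP[[mirc[i]]]
          else if (i == 1L && oppA) "A"
          else mismatch_for(mirc[i], forbid_A = i == 1L)
      }
      utr <- paste0(flank, paste(window, collapse = ""), flank)
      got <- assign_seed_type(6L + 3L, 2L, mir, utr)
      expect_identical(got, oracle_seed_label(paired, oppA),
                       label = paste("pattern", bits, "oppA", oppA))
    }
  }
})

test_that("adenine opposite a U-starting miRNA upgrades to a real pair", {
  mirU <- paste0("U", substr(random_mirna(21), 1, 21))
  window <- revcomp_chr(substr(mirU, 1, 8))   # full complement: opp1 is A
  utr <- paste0("CCCCC", window, "CCCCC")
  expect_identical(assign_seed_type(5L + 3L, 2L, mirU, utr), "8mer")
})

test_that("seed typing scores positions beyond the UTR ends as mismatches", {
  mir <- "GACGCUAGAAGGCCAAUUGGCC"
  window <- revcomp_chr(substr(mir, 1, 8))
  ## cut off the two UTR bases opposite positions 1-2 (the window's 3' end)
  utr <- paste0("CCCC", substr(window, 1, 6))
  expect_identical(assign_seed_type(4L + 3L, 2L, mir, utr), "6mer")
})

test_that("seed filters nest and unknown levels error", {
  sites <- make_sites(seed_types())   # one site of every label
  f6 <- filter_by_seed(sites, "6mer")
  f68 <- filter_by_seed(sites, "6in8")
  f4 <- filter_by_seed(sites, "4mer")
  expect_setequal(f6$seed_type, c("8mer", "7mer-A", "7mer", "6mer"))
  expect_setequal(f68$seed_type,
                  c("8mer", "7mer-A", "7mer", "6mer", "7in8", "6in8"))
  expect_identical(f4, sites)
  expect_true(all(f6$seed_type %in% f68$seed_type))
  expect_true(all(f68$seed_type %in% f4$seed_type))
  expect_error(filter_by_seed(sites, "5mer"))

  mixed <- make_sites(c("8mer", "6in8", "5mer"))
  expect_equal(filter_by_seed(mixed, "6mer")$seed_type, "8mer")
  expect_setequal(filter_by_seed(mixed, "6in8")$seed_type, c("8mer", "6in8"))
})

test_that("upgrading any mismatch to a pair never lowers seed priority", {
  set.seed(77)
  for (i in 1:300) {
    paired <- sample(c(TRUE, FALSE), 8L, replace = TRUE)
    oppA <- !paired[1L] && runif(1) < 0.5
    base <- classify_seed_pattern(paired, oppA)
    w <- which(!paired)
    if (!length(w)) next
    j <- w[sample.int(length(w), 1L)]
    up <- paired; up[j] <- TRUE
    upgraded <- classify_seed_pattern(up, if (j == 1L) FALSE else oppA)
    expect_lte(seed_priority(upgraded), seed_priority(base))
  }
})

test_that("overlap resolution keeps the best ddG per overlap group", {
  ## the four overlapping registers of the seed example
  sites <- make_sites(rep("4mer", 4), ddG = c(-3, -5, -4, -2),
                      utr_start = c(0L, 1L, 2L, 3L))
  kept <- resolve_overlaps(sites)
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$ddG, -5)

  ## disjoint sites are both retained
  apart <- make_sites(rep("4mer", 2), ddG = c(-1, -2), utr_start = c(0L, 10L))
  expect_equal(nrow(resolve_overlaps(apart)), 2L)

  ## ties break to the leftmost site
  tied <- make_sites(rep("4mer", 2), ddG = c(-3, -3), utr_start = c(5L, 7L))
  expect_equal(resolve_overlaps(tied)$utr_start, 5L)
})

test_that("after overlap resolution intervals are disjoint and minimal ddG", {
  set.seed(11)
  for (rep in 1:50) {
    n <- sample(2:30, 1L)
    sites <- make_sites(rep("4mer", n),
                        ddG = round(runif(n, -10, 0), 2),
                        utr_start = sample(0:60, n, replace = TRUE))
    sites <- sites[!duplicated(sites$utr_start), , drop = FALSE]
    kept <- resolve_overlaps(sites)
    ks <- sort(kept$utr_start)
    if (length(ks) > 1L) expect_true(all(diff(ks) >= 4L))
    ## every discarded site overlapping a kept one has ddG >= the kept ddG
    for (i in seq_len(nrow(sites))) {
      over <- kept$utr_start < sites$utr_start[i] + 4L &
        sites$utr_start[i] < kept$utr_start + 4L
      if (any(over)) expect_true(min(kept$ddG[over]) <= sites$ddG[i])
    }
  }
})

test_that("identical isoform sites collapse once per gene", {
  base <- make_sites(rep("8mer", 3), ddG = c(-5, -5, -7),
                     utr_id = c("iso1", "iso2", "iso3"))
  base$nucleus <- "ACGU"
  base$context <- c("AAACGUAA", "AAACGUAA", "AAACGUAA")
  base$open_context <- c("W1", "W1", "W2")
  map <- data.frame(isoform_id = c("iso1", "iso2", "iso3"),
                    gene_id = c("g1", "g1", "g1"))
  out <- dedupe_isoform_sites(base, map)
  ## iso1/iso2 share all context sequences; iso3 differs in window context
  expect_equal(nrow(out), 2L)

  single <- dedupe_isoform_sites(base[3L, ], map)
  expect_equal(nrow(single), 1L)

  expect_warning(dedupe_isoform_sites(base, map[1:2, ]), "own gene")
})
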