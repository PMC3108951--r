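test_that("config invariants are enforced", {
  cfg <- thermo_config()
  expect_equal(cfg$window_W, 80L)
  expect_equal(cfg$max_span_L, 40L)
  expect_equal(cfg$open_len_u, 20L)
  expect_equal(cfg$RT, 0.0019872 * 310.15)
  expect_error(thermo_config(open_len_u = 50, max_span_L = 40))
  expect_error(thermo_config(max_span_L = 100, window_W = 80))
})

test_that("toy cofold counts pairs on the forced antisense register", {
  ## fully complementary 8-nt duplex, nucleus = positions 2-5
  m8 <- "ACGUACGU"
  ctx <- revcomp_chr(m8)
  align <- data.frame(mirna_pos = 2:5, context_pos = 7:4)
  hyb <- hybridization_energy(m8, ctx, align, toy_engine())
  expect_equal(hyb$dG_H, -8)

  ## nucleus-only duplex: 4 forced WC pairs
  m <- "ACGUACGUA"
  nuc <- substr(m, 2, 5)
  hyb2 <- hybridization_energy(m, revcomp_chr(nuc),
                               data.frame(mirna_pos = 2:5, context_pos = 4:1),
                               toy_engine())
  expect_equal(hyb2$dG_H, -4)
})

test_that("unpaired nucleus bases trigger the repair path", {
  m8 <- "ACGUACGU"
  ctx <- revcomp_chr(m8)
  align <- data.frame(mirna_pos = 2:5, context_pos = 7:4)
  eng <- broken_cofold_engine()
  hyb <- hybridization_energy(m8, ctx, align, eng)
  ## repaired energy is evaluated from the pair table, not the bogus
  ## cofold energy, and stays non-positive under the toy model
  expect_equal(hyb$dG_H, -8)
  expect_lte(hyb$dG_H, 0)
  ## no intramolecular pairs survive the repair
  expect_true(all(hyb$structure$mol_i != hyb$structure$mol_j))
  ## repairing an already-repaired structure changes nothing
  again <- mirddg:::repair_structure(hyb$structure, align)
  rownames(again) <- rownames(hyb$structure) <- NULL
  expect_identical(again, hyb$structure)
})

test_that("disruption energy matches the closed form for constant P", {
  seqn <- strrep("ACGU", 30)           # 120 nt, interior nucleus
  RT <- thermo_config()$RT
  for (p in c(1, exp(-1), 0.5)) {
    d <- disruption_energy(seqn, 60L, 64L, toy_engine(p), detail = TRUE)
    expect_equal(d$dG_open, RT * log(p), tolerance = 1e-9)
    expect_equal(nrow(d$placements), 17L)
  }
  ## u-length open regions containing a 4-mer: u - 4 + 1 placements
  expect_length(sliding_open_regions(60L, 64L, 120L, 20L), 17L)
  ## boundary truncation near the sequence start
  expect_length(sliding_open_regions(2L, 6L, 120L, 20L), 3L)
})

test_that("disruption energy is the mean of per-window RT log P", {
  seqn <- strrep("ACGU", 30)
  ps <- c(0.2, 0.4, 0.6, 0.8)
  eng <- scripted_p_engine(ps)
  d <- disruption_energy(seqn, 60L, 64L, eng, detail = TRUE)
  RT <- thermo_config()$RT
  want <- mean(RT * log(rep_len(ps, 17)))
  expect_equal(d$dG_open, want, tolerance = 1e-12)
  ## log-then-average, not average-then-log
  expect_false(isTRUE(all.equal(d$dG_open,
                                RT * log(mean(rep_len(ps, 17))))))
})

test_that("dG_open is non-positive and decreasing in P_unpaired", {
  seqn <- strrep("GCAU", 40)
  vals <- vapply(c(0.9, 0.5, 0.1, 1e-4),
                 function(p) disruption_energy(seqn, 80L, 84L, toy_engine(p)),
                 numeric(1))
  expect_true(all(vals <= 0))
  expect_true(all(diff(vals) < 0))
})

test_that("short sequences fall back to one full-length open region", {
  expect_warning(d <- disruption_energy("ACGUACGUAC", 2L, 6L,
                                        toy_engine(0.5), detail = TRUE),
                 "shorter")
  expect_equal(nrow(d$placements), 1L)
})

test_that("total energy is the exact difference of its parts", {
  expect_identical(total_energy(-20, -5), -15)
  expect_identical(total_energy(-8, 0), -8)
  x <- runif(10, -20, 0)
  expect_identical(total_energy(x, x), rep(0, 10))
})

test_that("end-to-end site scoring is deterministic and self-consistent", {
  set.seed(55)
  m <- random_mirna(22)
  u <- random_utr(400)
  s1 <- score_sites("m1", m, "u1", u, engine = toy_engine(0.5))
  s2 <- score_sites("m1", m, "u1", u, engine = toy_engine(0.5))
  expect_identical(s1, s2)
  expect_equal(s1$ddG, s1$dG_H - s1$dG_open)
  expect_true(all(s1$dG_open <= 0))
  ## a UTR with no possible nucleus yields an empty frame
  expect_equal(nrow(score_sites("m1", "UGGCCGCGCGCGGCGCGCCGGC", "u1",
                                strrep("A", 100))), 0L)
})

test_that("pipeline output is identical across engines that agree", {
  ## two independently constructed toy engines agree on every contract
  ## call, so the pipeline must produce identical sites
  set.seed(56)
  m <- random_mirna(22)
  u <- random_utr(300)
  a <- score_sites("m", m, "u", u, engine = toy_engine(0.7))
  b <- score_sites("m", m, "u", u, engine = toy_engine(0.7))
  expect_identical(a, b)
})

test_that("windows can slide over the full site span when configured", {
  set.seed(57)
  m <- random_mirna(22)
  u <- random_utr(300)
  cfg <- thermo_config(windows_over = "span")
  s <- score_sites("m", m, "u", u, engine = toy_engine(0.5), config = cfg)
  expect_true(all(s$ddG == s$dG_H - s$dG_open))
})
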