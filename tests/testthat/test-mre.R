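test_that("seed_match classifies canonical site types at exact coordinates", {
  # miRNA UGGAAUGUAAGG: positions 2-8 = GGAAUGU, reverse complement ACAUUCC
  mirna <- "UGGAAUGUAAGG"
  sm <- seed_match(mirna, "UUACAUUCC")
  expect_identical(nrow(sm), 1L)
  expect_identical(sm$seed_type, "7mer-m8")
  expect_identical(c(sm$start, sm$end), c(2L, 9L))   # 0-based half-open

  # an A opposite position 1 upgrades to 8mer
  sm8 <- seed_match(mirna, "UUACAUUCCAGG")
  expect_identical(sm8$seed_type[1], "8mer")
  expect_identical(c(sm8$start[1], sm8$end[1]), c(2L, 10L))

  # perfect full-length complement contains an 8mer-or-m8 call
  target <- paste0("GG", revcomp_rna(mirna), "AGG")
  smf <- seed_match(mirna, target)
  expect_true(any(smf$seed_type %in% c("7mer-m8", "8mer")))

  # zero complementarity
  expect_identical(nrow(seed_match("AAAAAAAA", "AAAAAAAAAA")), 0L)
  # shorter than the seed
  expect_identical(nrow(seed_match(mirna, "ACG")), 0L)
  # seed_len_min = 7 drops 6mer/7mer-A1 calls
  sm6 <- seed_match(mirna, "UCAUUCCA")      # core only, no m8 match
  expect_identical(sm6$seed_type, "7mer-A1")
  expect_identical(nrow(seed_match(mirna, "UCAUUCCA", seed_len_min = 7)), 0L)
})

test_that("seed_match agrees with a brute-force window scan", {
  set.seed(31)
  for (i in 1:25) {
    mirna <- random_rna_string(22)
    target <- random_rna_string(120)
    sm <- seed_match(mirna, target)
    expect_setequal(sm$core_start, oracle_seed_cores(mirna, target))
  }
})

test_that("duplex alignment reproduces hand-computed scores", {
  # 8-nt perfect Watson-Crick duplex entirely in the weighted 5' region:
  # 8 pairs x (+5) x 2 = 80
  m8 <- "ACGUACGU"
  al <- duplex_align(m8, revcomp_rna(m8))
  expect_equal(al$score, 80)
  expect_identical(al$columns$kind, rep("match", 8))
  expect_equal(c(al$target_start, al$target_end), c(0, 8))

  # no positive-scoring pair: local floor at 0
  expect_equal(duplex_align("AAAAAAA", "AAAAAAA")$score, 0)

  # 21-nt complement of positions 2-22 of a 22-mer: 7 seed pairs doubled
  # (positions 2-8) + 14 plain matches = 7*10 + 14*5 = 140
  set.seed(32)
  m22 <- random_rna_string(22)
  al21 <- duplex_align(m22, revcomp_rna(substr(m22, 2, 22)))
  expect_gte(al21$score, 140)

  expect_error(duplex_align(m22, random_rna_string(81)), "80")
})

test_that("alignment DP equals the exhaustive enumeration oracle", {
  set.seed(33)
  for (i in 1:40) {
    m <- random_rna_string(sample(3:8, 1))
    w <- random_rna_string(sample(3:8, 1))
    expect_equal(duplex_align(m, w)$score, oracle_align_score(m, w),
                 info = paste(m, w))
  }
})

test_that("duplex energy is the documented additive pair model", {
  gc10 <- duplex_align(strrep("G", 10), strrep("C", 10))
  expect_equal(duplex_energy(gc10$columns), -30)        # 10 G:C pairs
  expect_equal(duplex_energy(gc10$columns[0, ]), 0)     # empty alignment

  # adding one G:U pair lowers the energy by exactly 1
  base <- duplex_align("GGGG", "CCCC")$columns
  plus_gu <- rbind(base, data.frame(mirna_pos = 5L, mirna_base = "G",
                                    window_pos = 5L, window_base = "U",
                                    kind = "wobble"))
  expect_equal(duplex_energy(plus_gu), duplex_energy(base) - 1)

  # mismatches and gaps are destabilizing
  mixed <- data.frame(mirna_pos = c(1L, NA), mirna_base = c("A", NA),
                      window_pos = c(1L, 2L), window_base = c("C", "G"),
                      kind = c("mismatch", "gap"))
  expect_equal(duplex_energy(mixed), 1.0)
})

test_that("predict_mres recovers planted sites coordinate-exactly", {
  ds <- simulate_dataset(small_sim_config(seed = 41))
  tr <- ds$truth
  mirnas <- structure(unclass(ds$mirna_fa)[tr$circuits$mirna_id],
                      moltype = "miRNA", class = "rna_seqs")
  tids <- c(tr$circuits$mrna_id, tr$circuits$circ_id)
  targets <- structure(unclass(ds$target_fa)[tids], moltype = "mRNA_target",
                       target_class = attr(ds$target_fa, "target_class")[tids],
                       class = "rna_seqs")
  mres <- predict_mres(mirnas, targets)
  for (j in seq_len(nrow(tr$planted_sites))) {
    s <- tr$planted_sites[j, ]
    hit <- mres[mres$mirna_id == s$mirna_id & mres$target_id == s$target_id, ]
    expect_identical(nrow(hit), 1L)
    expect_identical(c(hit$start, hit$end), c(s$start, s$end))
    expect_gte(hit$align_score, 140)
    expect_lte(hit$energy, -20)
  }
  # planted pairs only: no cross-circuit MREs at default thresholds here
  expect_identical(nrow(mres), nrow(tr$planted_sites))

  # impossible threshold -> empty output
  expect_identical(nrow(predict_mres(mirnas, targets, score_min = Inf)), 0L)

  # monotone filtering: stricter thresholds never add MREs
  lo <- predict_mres(mirnas, targets, score_min = 100, energy_max = -10)
  hi <- predict_mres(mirnas, targets, score_min = 140, energy_max = -20)
  expect_gte(nrow(lo), nrow(hi))

  # shuffled targets lose the planted signal
  set.seed(42)
  shuf <- vapply(unclass(targets), function(s) {
    paste(sample(strsplit(s, "")[[1]]), collapse = "")
  }, character(1))
  targets_shuf <- structure(shuf, moltype = "mRNA_target",
                            target_class = attr(targets, "target_class"),
                            class = "rna_seqs")
  mres_shuf <- predict_mres(mirnas, targets_shuf)
  expect_lt(nrow(mres_shuf) / (length(mirnas) * length(targets)), 0.05)
})

test_that("predict_mres is invariant to input record order", {
  ds <- simulate_dataset(small_sim_config(seed = 43))
  tr <- ds$truth
  mir_ids <- tr$circuits$mirna_id
  t_ids <- c(tr$circuits$mrna_id, tr$circuits$circ_id)
  mk <- function(ids, pool, cls) structure(unclass(pool)[ids],
                                           moltype = "mRNA_target",
                                           target_class = cls[ids],
                                           class = "rna_seqs")
  cls <- attr(ds$target_fa, "target_class")
  m1 <- structure(unclass(ds$mirna_fa)[mir_ids], moltype = "miRNA", class = "rna_seqs")
  m2 <- structure(unclass(ds$mirna_fa)[rev(mir_ids)], moltype = "miRNA", class = "rna_seqs")
  expect_identical(predict_mres(m1, mk(t_ids, ds$target_fa, cls)),
                   predict_mres(m2, mk(rev(t_ids), ds$target_fa, cls)))
})

test_that("circular targets are scanned across the backsplice junction", {
  set.seed(44)
  mirna <- random_rna_string(22)
  site <- revcomp_rna(substr(mirna, 2, 22))          # 21-nt planted site
  # place the site across the junction: last 10 nt at the sequence end,
  # first 11 nt wrapping to the front
  L <- 120L
  backbone <- random_rna_string(L)
  tail_part <- substr(site, 1, 10)
  head_part <- substr(site, 11, 21)
  circ_seq <- paste0(head_part, substr(backbone, 12, L - 10), tail_part)
  expect_identical(nchar(circ_seq), L)
  mirnas <- rna_seqs(structure(c(mirna), names = "m1"), "miRNA")
  targets <- structure(c(t1 = circ_seq), moltype = "circRNA_target",
                       target_class = c(t1 = "circRNA"), class = "rna_seqs")
  mres <- predict_mres(mirnas, targets, score_min = 140)
  junction <- mres[mres$end > L, , drop = FALSE]
  expect_gte(nrow(junction), 1L)
  expect_identical(junction$start[1], L - 10L)       # modulo original length
  expect_identical(junction$end[1], L - 10L + 21L)
  # the same sequence treated as linear misses the junction site
  targets_lin <- structure(c(t1 = circ_seq), moltype = "mRNA_target",
                           target_class = c(t1 = "mRNA"), class = "rna_seqs")
  lin <- predict_mres(mirnas, targets_lin, score_min = 140)
  expect_identical(nrow(lin[lin$end > L, , drop = FALSE]), 0L)
})

test_that("collapse_to_pairs groups sites and respects the pigeonhole bound", {
  mres <- data.frame(
    mirna_id = c("m1", "m1", "m1", "m1"),
    target_id = c("t1", "t1", "t1", "t2"),
    target_class = "mRNA",
    start = c(0L, 30L, 60L, 5L), end = c(7L, 37L, 67L, 12L),
    seed_type = "7mer-m8",
    align_score = c(150, 160, 145, 150), energy = c(-25, -30, -22, -21),
    stringsAsFactors = FALSE)
  pairs <- collapse_to_pairs(mres)
  expect_identical(pairs$n_sites, c(3L, 1L))
  expect_equal(pairs$best_score, c(160, 150))
  expect_equal(pairs$best_energy, c(-30, -21))
  expect_identical(nrow(collapse_to_pairs(mres[0, ])), 0L)
  expect_lte(nrow(pairs), nrow(mres))
  # equality iff all sites already sit on distinct pairs
  distinct <- mres[c(1, 4), ]
  expect_identical(nrow(collapse_to_pairs(distinct)), nrow(distinct))
})
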