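make_counts <- function(m, groups = c("case", "case", "case",
                                      "control", "control", "control")) {
  colnames(m) <- sprintf("s%d", seq_len(ncol(m)))
  if (is.null(rownames(m))) rownames(m) <- sprintf("f%d", seq_len(nrow(m)))
  expression_matrix(m, "counts", structure(groups[seq_len(ncol(m))],
                                           names = colnames(m)))
}

test_that("median-of-ratios size factors: symmetry, scaling, zero-row exclusion", {
  m <- matrix(rep(c(10, 20, 40), 3), 3, 3)
  expect_equal(unname(size_factors(make_counts(m, rep(c("case", "control"), 2)))),
               c(1, 1, 1))

  # column 2 = 2 x column 1: ratios to the geometric mean give
  # (1/sqrt(2), sqrt(2)), proportional to (1, 2), geometric mean 1
  m2 <- matrix(c(10, 100, 20, 200), 2, 2)
  sf <- unname(size_factors(make_counts(m2, c("case", "control"))))
  expect_equal(sf, c(1 / sqrt(2), sqrt(2)))
  expect_equal(sf[2] / sf[1], 2)

  # an all-zero row is excluded and changes nothing
  m3 <- rbind(m2, c(0, 0))
  expect_equal(unname(size_factors(make_counts(m3, c("case", "control")))), sf)

  # no all-nonzero feature -> instructive error
  m4 <- matrix(c(0, 5, 5, 0), 2, 2)
  expect_error(size_factors(make_counts(m4, c("case", "control"))),
               "pseudocount")
})

test_that("size factors equal the DESeq median-of-ratios estimator", {
  skip_if_not_installed("DESeq2")
  set.seed(4)
  m <- matrix(rnbinom(300, mu = 100 * exp(rnorm(50)), size = 5), 50, 6)
  m <- m + 1  # ensure all-positive rows exist
  em <- make_counts(m)
  theirs <- DESeq2::estimateSizeFactorsForMatrix(m)
  theirs <- theirs / exp(mean(log(theirs)))   # same geometric-mean-1 convention
  expect_equal(unname(size_factors(em)), unname(theirs))
})

test_that("normalized counts re-derive unit size factors", {
  set.seed(8)
  m <- matrix(rnbinom(240, mu = 200, size = 10) + 1, 40, 6)
  em <- make_counts(m)
  sf <- size_factors(em)
  renorm <- make_counts(sweep(m, 2, sf, "/"))
  expect_equal(unname(size_factors(renorm)), rep(1, 6), tolerance = 1e-8)
})

test_that("a feature with identical values in all samples is degenerate", {
  # identical columns keep size factors at 1, so constant rows stay constant
  m <- matrix(rep(c(64, 10, 200), 6), 3, 6)
  de <- suppressMessages(de_test_counts(make_counts(m), "circRNA"))
  expect_equal(de$log2fc, rep(0, 3))
  expect_equal(de$p_value, rep(1, 3))
  ei <- make_counts(m)
  ei$layer <- "log_intensity"
  dei <- suppressMessages(de_test_intensity(ei))
  expect_equal(dei$p_value, rep(1, 3))
})

test_that("Welch DE matches stats::t.test feature by feature", {
  set.seed(11)
  m <- matrix(rnbinom(60, mu = 150, size = 5), 10, 6)
  em <- make_counts(m)
  de <- de_test_counts(em, "circRNA")
  expect_identical(de$direction, ifelse(de$log2fc > 0, "up", "down"))
  y <- normalize_counts(em)$values
  for (f in c(1, 2, 5, 10)) {
    tt <- t.test(y[f, 1:3], y[f, 4:6])
    expect_equal(de$p_value[f], tt$p.value)
    expect_equal(de$log2fc[f], unname(diff(rev(tt$estimate))))
  }
  # BH q-values dominate p and are monotone in p
  expect_true(all(de$q_value >= de$p_value))
  ord <- order(de$p_value)
  expect_true(all(diff(de$q_value[ord]) >= -1e-12))
})

test_that("swapping group labels negates log2fc and preserves p", {
  set.seed(12)
  m <- matrix(rnbinom(60, mu = 150, size = 5) + 1, 10, 6)
  de1 <- de_test_counts(make_counts(m), "mRNA")
  de2 <- de_test_counts(make_counts(m, rep(c("control", "case"), each = 3)),
                        "mRNA")
  expect_equal(de2$log2fc, -de1$log2fc)
  expect_equal(de2$p_value, de1$p_value)
  expect_identical(de2$direction == "up", de1$direction == "down")
})

test_that("near-zero dispersion recovers the planted fold change", {
  # planted 4-fold feature, dispersion -> 0: estimated log2fc within 0.1 of 2
  set.seed(13)
  hits <- replicate(200, {
    a <- rpois(3, 2000 * 4); b <- rpois(3, 2000)
    est <- mean(log2(a + 1)) - mean(log2(b + 1))
    abs(est - 2) < 0.1
  })
  expect_gte(mean(hits), 0.95)
})

test_that("intensity DE power and the fold-change boundary", {
  set.seed(14)
  run_rate <- function(shift, sd) {
    mean(replicate(200, {
      y <- matrix(rnorm(6, 0, sd), 1)
      y[1, 1:3] <- y[1, 1:3] + shift
      m <- y; colnames(m) <- sprintf("s%d", 1:6); rownames(m) <- "f1"
      em <- expression_matrix(m, "log_intensity",
                              structure(rep(c("case", "control"), each = 3),
                                        names = colnames(m)))
      nrow(filter_de(de_test_intensity(em))$kept) == 1
    }))
  }
  # comfortably above the 1.5-fold boundary: high power
  expect_gte(run_rate(1.0, 0.1), 0.9)
  # exactly at the boundary the fold-change condition is a coin flip
  at_boundary <- run_rate(log2(1.5), 0.1)
  expect_gt(at_boundary, 0.3)
  expect_lt(at_boundary, 0.7)
})

test_that("filter_de applies the printed thresholds verbatim", {
  rec <- data.frame(feature_id = c("a", "b", "c"), class = "mRNA",
                    log2fc = c(log2(1.5), 3, -2),
                    fold_change = c(1.5, 8, 0.25),
                    p_value = c(0.049, 0.06, 0.01),
                    q_value = c(0.10, 0.09, 0.02),
                    direction = c("up", "up", "down"),
                    mean_case = 0, mean_control = 0,
                    stringsAsFactors = FALSE)
  out <- filter_de(rec, fc_threshold = 1.5, alpha = 0.05)
  # fold change exactly 1.5 with p = 0.049 is kept; p = 0.06 is dropped
  expect_identical(out$kept$feature_id, c("a", "c"))
  expect_identical(unname(out$summary), c(1L, 1L))
  out_q <- filter_de(rec, use_q = TRUE)
  expect_identical(out_q$kept$feature_id, "c")
  empty <- filter_de(rec[0, ])
  expect_identical(nrow(empty$kept), 0L)
  expect_identical(unname(empty$summary), c(0L, 0L))
})

test_that("type-I error is nominal under the null simulation", {
  ds <- simulate_dataset(simulation_config(
    n_circ = 5, n_mirna = 5, n_mrna = 1000, n_circuits = 0,
    n_extra_de_circ = 0, n_extra_de_mirna = 0, n_extra_de_mrna = 0,
    n_sets = 1, seed = 21))
  de <- de_test_counts(ds$mrna, "mRNA")
  rate <- mean(de$p_value < 0.05)
  se <- sqrt(0.05 * 0.95 / nrow(de))
  expect_lt(abs(rate - 0.05), 3 * se)
})
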