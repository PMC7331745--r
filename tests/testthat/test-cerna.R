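test_that("validated pairs are the exact intersection of the two evidence sets", {
  pairs <- data.frame(mirna_id = c("m1", "m1"), target_id = c("t1", "t2"),
                      target_class = "circRNA", n_sites = 1L,
                      best_score = 150, best_energy = -25,
                      stringsAsFactors = FALSE)
  edges <- data.frame(a_id = c("m1", "m2"), a_class = "miRNA",
                      b_id = c("t1", "t1"), b_class = "circRNA",
                      r = -0.95, p_value = 0.01, required_sign = "negative",
                      stringsAsFactors = FALSE)
  v <- filter_targets_by_coexpression(pairs, edges)
  expect_identical(nrow(v), 1L)
  expect_identical(c(v$mirna_id, v$target_id), c("m1", "t1"))
  expect_true(all(c("best_score", "r", "p_coexpr") %in% names(v)))
  expect_lt(v$r, 0)

  disjoint <- edges; disjoint$b_id <- c("tX", "tY")
  expect_identical(nrow(filter_targets_by_coexpression(pairs, disjoint)), 0L)
  pos <- edges; pos$required_sign <- "positive"
  expect_error(filter_targets_by_coexpression(pairs, pos), "negative")
  expect_lte(nrow(v), min(nrow(pairs), nrow(edges)))
})

test_that("paper-scale set logic: pair/interaction intersections at printed sizes", {
  # miRNA-circRNA track: 165 filtered target pairs x 167 coexpression
  # interactions sharing exactly 21 -> 21 validated pairs
  mirnas <- sprintf("miR-%02d", 1:22)
  circs <- sprintf("circ-%02d", 1:37)
  fx <- make_setlogic_fixture(165, 167, 21, mirnas, circs, "circRNA", seed = 61)
  v <- filter_targets_by_coexpression(fx$pairs, fx$edges)
  expect_identical(nrow(v), 21L)
  expect_setequal(paste(v$mirna_id, v$target_id),
                  paste(fx$shared$mirna_id, fx$shared$target_id))

  # miRNA-mRNA track: 5043 filtered target pairs x 2438 interactions
  # sharing exactly 1062
  genes <- sprintf("gene-%03d", 1:544)
  fy <- make_setlogic_fixture(5043, 2438, 1062, mirnas, genes, "mRNA",
                              seed = 62)
  expect_identical(nrow(filter_targets_by_coexpression(fy$pairs, fy$edges)),
                   1062L)
})

test_that("cerna_score equals the enumeration oracle and handles edge cases", {
  # k = 0 -> P(X >= 0) = 1
  expect_equal(cerna_score(character(0), c("m1"), 10)$p_hyper, 1)
  # saturation: all partners shared
  sat <- cerna_score(sprintf("m%d", 1:5), sprintf("m%d", 1:5), 5)
  expect_identical(sat$k, 5L)
  expect_equal(sat$p_hyper, 1)

  # M = 10, K = 4, n = 5, k = 3 against exhaustive enumeration over C(10,5)
  got <- cerna_score(sprintf("m%d", 1:4), sprintf("m%d", c(1, 2, 3, 9, 10)), 10)
  expect_identical(got$k, 3L)
  expect_equal(got$p_hyper, oracle_hyper_ge(3, 10, 4, 5))

  expect_error(cerna_score(sprintf("m%d", 1:5), "m1", 4), "universe")
})

test_that("hypergeometric tail equals enumeration for every universe <= 12", {
  for (M in c(3, 6, 9, 12)) {
    for (K in 0:M) {
      for (n in c(0, 1, M %/% 2, M)) {
        for (k in 0:min(K, n)) {
          expect_equal(phyper(k - 1, K, M - K, n, lower.tail = FALSE),
                       oracle_hyper_ge(k, M, K, n),
                       info = sprintf("M=%d K=%d n=%d k=%d", M, K, n, k))
        }
      }
    }
  }
})

fixture_de <- function(circs, mirnas, mrnas, dir_circ = "up",
                       dir_mirna = "down", dir_mrna = "up") {
  rbind(
    data.frame(feature_id = circs, class = "circRNA",
               direction = rep_len(dir_circ, length(circs)),
               stringsAsFactors = FALSE),
    data.frame(feature_id = mirnas, class = "miRNA",
               direction = rep_len(dir_mirna, length(mirnas)),
               stringsAsFactors = FALSE),
    data.frame(feature_id = mrnas, class = "mRNA",
               direction = rep_len(dir_mrna, length(mrnas)),
               stringsAsFactors = FALSE))
}

vpair <- function(mirna, target, class) {
  data.frame(mirna_id = mirna, target_id = target, target_class = class,
             n_sites = 1L, best_score = 150, best_energy = -25,
             r = -0.95, p_coexpr = 0.01, stringsAsFactors = FALSE)
}

cm_edge <- function(circ, mrna) {
  data.frame(a_id = circ, a_class = "circRNA", b_id = mrna, b_class = "mRNA",
             r = 0.95, p_value = 0.01, required_sign = "positive",
             stringsAsFactors = FALSE)
}

test_that("network assembly: candidate scoring, overlap and direction filters", {
  # 22 DE miRNAs (the study-scale universe); one shared partner gives
  # p = 1/22 < 0.05
  mirnas <- sprintf("m%02d", 1:22)
  de <- fixture_de(c("c1", "c2"), mirnas, c("g1", "g2"))
  vc <- rbind(vpair("m01", "c1", "circRNA"), vpair("m02", "c2", "circRNA"))
  vm <- rbind(vpair("m01", "g1", "mRNA"), vpair("m02", "g2", "mRNA"))
  edges <- rbind(cm_edge("c1", "g1"), cm_edge("c2", "g2"))
  net <- build_cerna_network(vc, vm, edges, de)
  expect_identical(nrow(net$candidates[net$candidates$coexpr_supported, ]), 2L)
  expect_equal(net$candidates$p_hyper[1], 1 / 22)
  expect_identical(circuit_key(net$triplets), c("c1 m01 g1", "c2 m02 g2"))

  # empty circRNA-mRNA edge set kills all triplets regardless of score
  net0 <- build_cerna_network(vc, vm, edges[0, ], de)
  expect_identical(nrow(net0$triplets), 0L)
  expect_gt(nrow(net0$candidates), 0L)

  # a direction-inconsistent combination (circ up, miR down, mRNA down) is
  # excluded at the last step while consistent ones survive
  de_bad <- de
  de_bad$direction[de_bad$feature_id == "g1"] <- "down"
  net_bad <- build_cerna_network(vc, vm, edges, de_bad)
  expect_false("c1 m01 g1" %in% circuit_key(net_bad$triplets))
  expect_true("c2 m02 g2" %in% circuit_key(net_bad$triplets))

  # ids missing from the DE table are a hard error naming the feature
  expect_error(build_cerna_network(vc, vm, edges, de[de$feature_id != "g2", ]),
               "g2")
})

test_that("triplets have referential integrity and threshold monotonicity", {
  mirnas <- sprintf("m%02d", 1:22)
  de <- fixture_de(c("c1", "c2"), mirnas, c("g1", "g2"))
  vc <- rbind(vpair("m01", "c1", "circRNA"), vpair("m02", "c1", "circRNA"),
              vpair("m03", "c2", "circRNA"))
  vm <- rbind(vpair("m01", "g1", "mRNA"), vpair("m02", "g1", "mRNA"),
              vpair("m03", "g2", "mRNA"))
  edges <- rbind(cm_edge("c1", "g1"), cm_edge("c2", "g2"))
  net <- build_cerna_network(vc, vm, edges, de)
  for (j in seq_len(nrow(net$triplets))) {
    tr <- net$triplets[j, ]
    expect_true(paste(tr$mirna_id, tr$circ_id) %in%
                  paste(vc$mirna_id, vc$target_id))
    expect_true(paste(tr$mirna_id, tr$mrna_id) %in%
                  paste(vm$mirna_id, vm$target_id))
    expect_true(paste(tr$circ_id, tr$mrna_id) %in%
                  paste(edges$a_id, edges$b_id))
  }
  # larger alpha / smaller k_min never removes triplets
  netA <- build_cerna_network(vc, vm, edges, de, alpha = 0.01)
  netB <- build_cerna_network(vc, vm, edges, de, alpha = 0.10)
  expect_true(all(circuit_key(netA$triplets) %in% circuit_key(netB$triplets)))
  netK <- build_cerna_network(vc, vm, edges, de, k_min = 2)
  expect_true(all(circuit_key(netK$triplets) %in% circuit_key(net$triplets)))
})

test_that("paper-scale ceRNA overlap: 52 scored candidates, 51 supported", {
  # 52 circRNA-mRNA pairs each sharing one distinct validated miRNA
  mirnas <- sprintf("m%02d", 1:52)
  circs <- sprintf("c%02d", 1:52)
  genes <- sprintf("g%02d", 1:52)
  de <- fixture_de(circs, mirnas, genes)
  vc <- do.call(rbind, Map(vpair, mirnas, circs, "circRNA"))
  vm <- do.call(rbind, Map(vpair, mirnas, genes, "mRNA"))
  # 51 of the 52 scored pairs also have positive circRNA-mRNA coexpression
  edges <- do.call(rbind, Map(cm_edge, circs[-52], genes[-52]))
  net <- build_cerna_network(vc, vm, edges, de)
  expect_identical(nrow(net$candidates), 52L)
  expect_identical(sum(net$candidates$coexpr_supported), 51L)
  expect_identical(nrow(net$triplets), 51L)
})

test_that("planted circuits are recovered end-to-end on synthetic data", {
  set.seed(71)
  rec <- 0; tot <- 0; cross <- 0L
  for (i in 1:6) {
    ds <- simulate_dataset(simulation_config(lfc_de = 2,
                                             seed = sample.int(1e6, 1)))
    net <- infer_network(ds)
    tr <- ds$truth$circuits
    rec <- rec + sum(circuit_key(tr) %in% circuit_key(net$triplets))
    tot <- tot + nrow(tr)
    # no triplet mixes three different circuits
    if (nrow(net$triplets)) {
      cid <- match(net$triplets$circ_id, tr$circ_id)
      mid <- match(net$triplets$mirna_id, tr$mirna_id)
      gid <- match(net$triplets$mrna_id, tr$mrna_id)
      cross <- cross + sum(!is.na(cid) & !is.na(mid) & !is.na(gid) &
                             cid != mid & mid != gid & cid != gid)
    }
  }
  expect_gte(rec / tot, 0.75)
  expect_identical(cross, 0L)
})
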