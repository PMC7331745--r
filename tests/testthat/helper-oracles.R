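# Independent oracles used to freeze expected values. These deliberately use
# different algorithms from the implementation they check.

# Exhaustive anchor-set enumeration of the local duplex alignment score:
# every alignment is a monotone set of aligned columns plus contiguous gap
# runs, so enumerating all monotone index-pair sets with affine gap costs
# between consecutive anchors visits every alignment.
oracle_align_score <- function(mirna, window, params = align_params()) {
  M <- nchar(mirna); N <- nchar(window)
  if (M == 0 || N == 0) return(0)
  qa <- rev(strsplit(mirna, "")[[1]])   # reversed miRNA; row a = position M-a+1
  wb <- strsplit(window, "")[[1]]
  ps <- matrix(0, M, N)
  for (a in 1:M) for (j in 1:N) {
    pair <- paste0(qa[a], wb[j])
    base <- if (pair %in% c("AU", "UA", "GC", "CG")) params$match
            else if (pair %in% c("GU", "UG")) params$wobble else params$mismatch
    mpos <- M - a + 1
    w <- if (mpos >= params$seed_from && mpos <= params$seed_to)
      params$seed_weight else 1
    ps[a, j] <- base * w
  }
  gapcost <- function(g) ifelse(g == 0, 0, params$gap_open + (g - 1) * params$gap_ext)
  best <- 0
  for (k in 1:min(M, N)) {
    As <- utils::combn(M, k); Bs <- utils::combn(N, k)
    for (ia in seq_len(ncol(As))) {
      A <- As[, ia]
      gapsA <- if (k > 1) sum(gapcost(diff(A) - 1)) else 0
      for (ib in seq_len(ncol(Bs))) {
        B <- Bs[, ib]
        sc <- sum(ps[cbind(A, B)]) + gapsA +
          (if (k > 1) sum(gapcost(diff(B) - 1)) else 0)
        if (sc > best) best <- sc
      }
    }
  }
  best
}

# Hypergeometric upper tail P(|query-draw of size n intersects K-set| >= k)
# by exhaustive enumeration over all C(M, n) draws.
oracle_hyper_ge <- function(k, M, K, n) {
  if (n == 0) return(as.numeric(k <= 0))
  draws <- utils::combn(M, n)
  hits <- colSums(draws <= K)   # treat 1..K as the success states
  mean(hits >= k)
}

# Brute-force seed scan: report every target window equal to the reverse
# complement of miRNA positions 2-7 by direct window comparison.
oracle_seed_cores <- function(mirna, target) {
  core <- revcomp_rna(substr(mirna, 2, 7))
  n <- nchar(target)
  if (n < 6) return(integer(0))
  which(substring(target, 1:(n - 5), 6:n) == core) - 1L  # 0-based
}

random_rna_string <- function(len) {
  paste(sample(c("A", "C", "G", "U"), len, replace = TRUE), collapse = "")
}

# Pair/edge fixtures with an exactly known intersection, at arbitrary scale.
make_setlogic_fixture <- function(n_pairs, n_edges, n_overlap,
                                  mirna_ids, target_ids, target_class,
                                  seed = 1) {
  stopifnot(n_overlap <= min(n_pairs, n_edges))
  combos <- expand.grid(mirna_id = mirna_ids, target_id = target_ids,
                        stringsAsFactors = FALSE)
  need <- n_pairs + n_edges - n_overlap
  stopifnot(need <= nrow(combos))
  set.seed(seed)
  picked <- combos[sample.int(nrow(combos), need), , drop = FALSE]
  shared <- picked[seq_len(n_overlap), , drop = FALSE]
  pair_only <- picked[n_overlap + seq_len(n_pairs - n_overlap), , drop = FALSE]
  edge_only <- picked[n_pairs + seq_len(n_edges - n_overlap), , drop = FALSE]
  pairs_df <- rbind(shared, pair_only)
  edges_df <- rbind(shared, edge_only)
  list(
    pairs = data.frame(mirna_id = pairs_df$mirna_id,
                       target_id = pairs_df$target_id,
                       target_class = target_class, n_sites = 1L,
                       best_score = 150, best_energy = -25,
                       stringsAsFactors = FALSE),
    edges = data.frame(a_id = edges_df$mirna_id, a_class = "miRNA",
                       b_id = edges_df$target_id, b_class = target_class,
                       r = -0.95, p_value = 0.01, required_sign = "negative",
                       stringsAsFactors = FALSE),
    shared = shared)
}

circuit_key <- function(d) paste(d$circ_id, d$mirna_id, d$mrna_id)

# Small, fast simulation config for unit tests.
small_sim_config <- function(...) {
  simulation_config(n_circ = 12, n_mirna = 24, n_mrna = 60, n_circuits = 2,
                    n_extra_de_circ = 4, n_extra_de_mirna = 20,
                    n_extra_de_mrna = 10, len_circ = 200, len_mrna = 240,
                    n_sets = 5, ...)
}
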