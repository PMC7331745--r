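#' Intersect sequence-predicted target pairs with coexpression evidence
#'
#' A miRNA-target pair is validated when it is both sequence-predicted
#' ([collapse_to_pairs()]) and supported by a negative coexpression edge
#' ([coexpression_edges()] with `required_sign = "negative"`, miRNA as the
#' `a` side). Exact set intersection on (mirna_id, target_id).
#'
#' @param pairs Target-pair data frame (sequence evidence).
#' @param edges Negative coexpression edge data frame (miRNA in `a_id`).
#' @return Data frame of validated pairs carrying both evidence tracks:
#'   `mirna_id`, `target_id`, `target_class`, `n_sites`, `best_score`,
#'   `best_energy`, `r`, `p_coexpr`.
#' @export
filter_targets_by_coexpression <- function(pairs, edges) {
  if (nrow(edges) && any(edges$required_sign != "negative"))
    stop("edges must carry required_sign = 'negative'", call. = FALSE)
  if (!nrow(pairs) || !nrow(edges)) {
    return(data.frame(mirna_id = character(0), target_id = character(0),
                      target_class = character(0), n_sites = integer(0),
                      best_score = numeric(0), best_energy = numeric(0),
                      r = numeric(0), p_coexpr = numeric(0),
                      stringsAsFactors = FALSE))
  }
  m <- merge(pairs,
             data.frame(mirna_id = edges$a_id, target_id = edges$b_id,
                        r = edges$r, p_coexpr = edges$p_value,
                        stringsAsFactors = FALSE),
             by = c("mirna_id", "target_id"))
  m <- m[order(m$mirna_id, m$target_id),
         c("mirna_id", "target_id", "target_class", "n_sites",
           "best_score", "best_energy", "r", "p_coexpr")]
  rownames(m) <- NULL
  m
}

#' Hypergeometric ceRNA score for a circRNA-mRNA pair
#'
#' Scores the sharing of validated miRNA partners between a circRNA and an
#' mRNA: with M differentially expressed miRNAs in total, K validated
#' partners of the circRNA and n of the mRNA, the score is the
#' hypergeometric tail probability P(X >= k) of observing at least the
#' k = |shared| partners by chance.
#'
#' @param circ_partners,mrna_partners Character vectors of validated miRNA
#'   partner ids.
#' @param M Total number of DE miRNAs (the universe); must be >= both
#'   partner-set sizes.
#' @return List with `k` (shared count) and `p_hyper`.
#' @export
cerna_score <- function(circ_partners, mrna_partners, M) {
  circ_partners <- unique(circ_partners)
  mrna_partners <- unique(mrna_partners)
  K <- length(circ_partners); n <- length(mrna_partners)
  if (M < K || M < n)
    stop("miRNA universe M smaller than a partner set", call. = FALSE)
  k <- length(intersect(circ_partners, mrna_partners))
  p <- phyper(k - 1, K, M - K, n, lower.tail = FALSE)
  list(k = k, p_hyper = p)
}

#' Assemble the direction-consistent ceRNA network
#'
#' Four steps: (1) every circRNA-mRNA combination with at least `k_min`
#' shared validated miRNA partners and hypergeometric `p_hyper < alpha`
#' becomes a candidate (BH q-values over all scored combinations are
#' reported alongside); (2) candidates are kept only if the (circRNA, mRNA)
#' pair also has a positive coexpression edge; (3) surviving candidates are
#' expanded into one circRNA-miRNA-mRNA triplet per shared miRNA;
#' (4) triplets violating sponge-direction consistency (circRNA and mRNA in
#' the same DE direction, miRNA opposite) are dropped. Outputs are sorted
#' lexicographically.
#'
#' @param validated_circ Validated miRNA-circRNA pairs
#'   ([filter_targets_by_coexpression()]).
#' @param validated_mrna Validated miRNA-mRNA pairs.
#' @param circ_mrna_edges Positive circRNA-mRNA coexpression edges
#'   (circRNA in `a_id`).
#' @param de Combined data frame of retained DE records for all three
#'   classes (the output of [filter_de()] row-bound across classes); defines
#'   the miRNA universe M and the feature directions.
#' @param alpha Candidate significance threshold on raw `p_hyper`
#'   (default 0.05).
#' @param k_min Minimum shared-miRNA count (default 1; the emulated study's
#'   final networks contain single-miRNA links).
#' @return List with `candidates` (data frame: `circ_id`, `mrna_id`,
#'   `shared_mirnas` (comma-joined), `k`, `K`, `n`, `M`, `p_hyper`,
#'   `q_hyper`, `coexpr_supported`) and `triplets` (data frame: `circ_id`,
#'   `mirna_id`, `mrna_id` and the three `*_direction` columns).
#' @export
build_cerna_network <- function(validated_circ, validated_mrna,
                                circ_mrna_edges, de,
                                alpha = 0.05, k_min = 1) {
  stopifnot(alpha > 0, alpha <= 1, k_min >= 0)
  M <- sum(de$class == "miRNA")
  dir_of <- structure(de$direction, names = de$feature_id)
  ids_used <- unique(c(validated_circ$target_id, validated_circ$mirna_id,
                       validated_mrna$target_id, validated_mrna$mirna_id))
  unknown <- setdiff(ids_used, de$feature_id)
  if (length(unknown))
    stop("feature(s) without a DE record: ",
         paste(head(unknown, 5), collapse = ", "), call. = FALSE)

  empty_cand <- data.frame(circ_id = character(0), mrna_id = character(0),
                           shared_mirnas = character(0), k = integer(0),
                           K = integer(0), n = integer(0), M = integer(0),
                           p_hyper = numeric(0), q_hyper = numeric(0),
                           coexpr_supported = logical(0),
                           stringsAsFactors = FALSE)
  empty_trip <- data.frame(circ_id = character(0), mirna_id = character(0),
                           mrna_id = character(0),
                           circ_direction = character(0),
                           mirna_direction = character(0),
                           mrna_direction = character(0),
                           stringsAsFactors = FALSE)
  if (!nrow(validated_circ) || !nrow(validated_mrna))
    return(list(candidates = empty_cand, triplets = empty_trip))

  circ_sets <- split(validated_circ$mirna_id, validated_circ$target_id)
  mrna_sets <- split(validated_mrna$mirna_id, validated_mrna$target_id)
  combos <- expand.grid(circ_id = sort(names(circ_sets)),
                        mrna_id = sort(names(mrna_sets)),
                        stringsAsFactors = FALSE)
  scored <- lapply(seq_len(nrow(combos)), function(i) {
    cs <- unique(circ_sets[[combos$circ_id[i]]])
    ms <- unique(mrna_sets[[combos$mrna_id[i]]])
    sc <- cerna_score(cs, ms, M)
    shared <- sort(intersect(cs, ms))
    data.frame(circ_id = combos$circ_id[i], mrna_id = combos$mrna_id[i],
               shared_mirnas = paste(shared, collapse = ","),
               k = sc$k, K = length(cs), n = length(ms), M = M,
               p_hyper = sc$p_hyper, stringsAsFactors = FALSE)
  })
  cand <- do.call(rbind, scored)
  cand$q_hyper <- p.adjust(cand$p_hyper, method = "BH")
  cand <- cand[cand$k >= k_min & cand$p_hyper < alpha, , drop = FALSE]

  edge_key <- paste(circ_mrna_edges$a_id, circ_mrna_edges$b_id, sep = "\r")
  cand$coexpr_supported <- paste(cand$circ_id, cand$mrna_id, sep = "\r") %in%
    edge_key
  cand <- cand[order(cand$circ_id, cand$mrna_id), , drop = FALSE]
  rownames(cand) <- NULL

  surviving <- cand[cand$coexpr_supported, , drop = FALSE]
  if (!nrow(surviving))
    return(list(candidates = cand, triplets = empty_trip))
  trips <- lapply(seq_len(nrow(surviving)), function(i) {
    mirnas <- strsplit(surviving$shared_mirnas[i], ",", fixed = TRUE)[[1L]]
    data.frame(circ_id = surviving$circ_id[i], mirna_id = mirnas,
               mrna_id = surviving$mrna_id[i], stringsAsFactors = FALSE)
  })
  trips <- do.call(rbind, trips)
  trips$circ_direction <- unname(dir_of[trips$circ_id])
  trips$mirna_direction <- unname(dir_of[trips$mirna_id])
  trips$mrna_direction <- unname(dir_of[trips$mrna_id])
  ok <- trips$circ_direction == trips$mrna_direction &
    trips$mirna_direction != trips$circ_direction
  trips <- trips[ok, , drop = FALSE]
  trips <- trips[order(trips$circ_id, trips$mirna_id, trips$mrna_id), ,
                 drop = FALSE]
  rownames(trips) <- NULL
  list(candidates = cand, triplets = trips)
}
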