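#' Find canonical miRNA seed-match sites on a target
#'
#' Scans the target (5'->3') for exact reverse complements of the miRNA seed
#' (positions 2-7) and classifies every occurrence: `6mer` (2-7 matched),
#' `7mer-m8` (2-8 matched), `7mer-A1` (2-7 matched plus target A opposite
#' miRNA position 1) or `8mer` (both). Overlapping sites are all reported.
#' Coordinates are 0-based half-open on the target and span the matched
#' region (including the m8 pair and/or A1 anchor where applicable).
#'
#' @param mirna Canonical RNA miRNA sequence (single string, 5'->3').
#' @param target Canonical RNA target sequence (single string, 5'->3').
#' @param seed_len_min Minimum number of matched seed positions: 6 keeps all
#'   types, 7 keeps only `7mer-m8`/`8mer` (default 6).
#' @return Data frame with columns `start`, `end`, `seed_type`, `core_start`
#'   (0-based start of the matched 2-7 core). Empty when either sequence is
#'   shorter than the seed.
#' @examples
#' seed_match("UGGAAUGUAAGG", "UUACAUUCC") # one 7mer-m8 site at [2, 9)
#' @export
seed_match <- function(mirna, target, seed_len_min = 6) {
  stopifnot(seed_len_min %in% c(6, 7))
  empty <- data.frame(start = integer(0), end = integer(0),
                      seed_type = character(0), core_start = integer(0),
                      stringsAsFactors = FALSE)
  n <- nchar(target)
  if (nchar(mirna) < 7 || n < 6) return(empty)
  core <- revcomp_rna(substr(mirna, 2, 7))
  starts <- find_all_fixed(core, target)  # 1-based, overlapping occurrences
  if (!length(starts)) return(empty)
  m8c <- if (nchar(mirna) >= 8) chartr("ACGU", "UGCA", substr(mirna, 8, 8)) else NA
  has_m8 <- !is.na(m8c) & starts > 1 &
    substring(target, starts - 1, starts - 1) == m8c
  has_a1 <- starts + 6 <= n & substring(target, starts + 6, starts + 6) == "A"
  type <- ifelse(has_m8 & has_a1, "8mer",
                 ifelse(has_m8, "7mer-m8", ifelse(has_a1, "7mer-A1", "6mer")))
  out <- data.frame(start = ifelse(has_m8, starts - 1L, starts) - 1L,
                    end = ifelse(has_a1, starts + 6L, starts + 5L),
                    seed_type = type, core_start = starts - 1L,
                    stringsAsFactors = FALSE)
  if (seed_len_min == 7)
    out <- out[out$seed_type %in% c("7mer-m8", "8mer"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_mre_df <- function() {
  data.frame(mirna_id = character(0), target_id = character(0),
             target_class = character(0), start = integer(0),
             end = integer(0), seed_type = character(0),
             align_score = numeric(0), energy = numeric(0),
             stringsAsFactors = FALSE)
}

# All (possibly overlapping) 1-based occurrences of a fixed pattern.
find_all_fixed <- function(pattern, subject) {
  pos <- integer(0)
  from <- 1L
  n <- nchar(subject)
  while (from <= n) {
    m <- regexpr(pattern, substring(subject, from), fixed = TRUE)
    if (m == -1L) break
    s <- from + as.integer(m) - 1L
    pos <- c(pos, s)
    from <- s + 1L
  }
  pos
}

#' Predict miRNA response elements on a set of targets
#'
#' For every miRNA x target combination, seed matches anchor candidate
#' windows (the site extended 30 nt toward the target 5' end, covering
#' 3'-supplementary pairing); each window is scored by [duplex_align()] and
#' [duplex_energy()], and a site is kept iff
#' `align_score >= score_min` and `energy <= energy_max`. circRNA targets are
#' treated as circular: the sequence is extended by its first
#' (miRNA length - 1) nt so junction-spanning sites are found, and start
#' coordinates are reported modulo the original length (`end` may exceed the
#' target length for a junction-spanning site). Output rows are deduplicated
#' and sorted by (mirna_id, target_id, start); the result does not depend on
#' input record order.
#'
#' @param mirnas `rna_seqs` of mature miRNAs.
#' @param targets `rna_seqs` of target sequences. Per-record classes are taken
#'   from a `target_class` attribute (named vector of `"mRNA"`/`"circRNA"`)
#'   when present, else from the set's `moltype`.
#' @param score_min Minimum alignment score (default 140).
#' @param energy_max Maximum (most positive) duplex energy in kcal/mol
#'   (default -20).
#' @param seed_len_min Passed to [seed_match()] (default 6).
#' @param params [align_params()] for the duplex alignment.
#' @return Data frame of MREs: `mirna_id`, `target_id`, `target_class`,
#'   `start`, `end` (0-based half-open on the target), `seed_type`,
#'   `align_score`, `energy`.
#' @export
predict_mres <- function(mirnas, targets, score_min = 140, energy_max = -20,
                         seed_len_min = 6, params = align_params()) {
  tclass <- attr(targets, "target_class")
  if (is.null(tclass)) {
    tclass <- structure(rep(switch(attr(targets, "moltype"),
                                   circRNA_target = "circRNA", "mRNA"),
                            length(targets)), names = names(targets))
  }
  mirna_ids <- sort(names(mirnas))
  target_ids <- sort(names(targets))
  out <- vector("list", length(mirna_ids) * length(target_ids))
  n_out <- 0L
  for (mid in mirna_ids) {
    mseq <- mirnas[[mid]]
    mlen <- nchar(mseq)
    for (tid in target_ids) {
      tseq <- targets[[tid]]
      L <- nchar(tseq)
      circular <- tclass[[tid]] == "circRNA"
      scan_seq <- if (circular)
        paste0(tseq, substr(tseq, 1, min(mlen - 1L, L))) else tseq
      sm <- seed_match(mseq, scan_seq, seed_len_min)
      if (!nrow(sm)) next
      # anchors in the circular extension are kept: junction-spanning sites may
      # only be anchored there; duplicate reports collapse after the modulo
      hits <- list()
      for (k in seq_len(nrow(sm))) {
        ws <- max(1L, sm$start[k] + 1L - 30L)
        we <- min(nchar(scan_seq), sm$end[k] + 2L)
        al <- duplex_align(mseq, substr(scan_seq, ws, we), params)
        if (al$score < score_min) next
        en <- duplex_energy(al$columns)
        if (en > energy_max) next
        s0 <- ws - 1L + al$target_start
        e0 <- ws - 1L + al$target_end
        if (circular) {
          span <- e0 - s0
          s0 <- s0 %% L
          e0 <- s0 + span
        }
        hits[[length(hits) + 1L]] <-
          data.frame(mirna_id = mid, target_id = tid,
                     target_class = tclass[[tid]],
                     start = s0, end = e0, seed_type = sm$seed_type[k],
                     align_score = al$score, energy = en,
                     stringsAsFactors = FALSE)
      }
      if (length(hits)) {
        h <- do.call(rbind, hits)
        h <- h[!duplicated(h[, c("start", "end")]), , drop = FALSE]
        n_out <- n_out + 1L
        out[[n_out]] <- h
      }
    }
  }
  if (!n_out) return(empty_mre_df())
  res <- do.call(rbind, out[seq_len(n_out)])
  res <- res[order(res$mirna_id, res$target_id, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Collapse site-level MREs to unique miRNA-target pairs
#'
#' One row per distinct (mirna_id, target_id) with the number of sites, the
#' best (maximal) alignment score and the best (minimal) energy.
#'
#' @param mres MRE data frame from [predict_mres()].
#' @return Data frame of target pairs: `mirna_id`, `target_id`,
#'   `target_class`, `n_sites`, `best_score`, `best_energy`.
#' @export
collapse_to_pairs <- function(mres) {
  if (!nrow(mres)) {
    return(data.frame(mirna_id = character(0), target_id = character(0),
                      target_class = character(0), n_sites = integer(0),
                      best_score = numeric(0), best_energy = numeric(0),
                      stringsAsFactors = FALSE))
  }
  key <- interaction(mres$mirna_id, mres$target_id, drop = TRUE, sep = "\r")
  idx <- split(seq_len(nrow(mres)), key)
  rows <- lapply(idx, function(i) {
    data.frame(mirna_id = mres$mirna_id[i[1]], target_id = mres$target_id[i[1]],
               target_class = mres$target_class[i[1]],
               n_sites = length(i),
               best_score = max(mres$align_score[i]),
               best_energy = min(mres$energy[i]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$mirna_id, out$target_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
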