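#' Scoring parameters for the miRanda-style duplex alignment
#'
#' Pair scores: Watson-Crick match +5, G:U wobble +2, mismatch -3; affine
#' gaps open -8 / extend -2 (a run of g gapped positions costs
#' open + (g-1) * extend). Pair scores of positions aligned to the miRNA
#' 5' region (`seed_from`..`seed_to`, default 1-8) are multiplied by
#' `seed_weight` (default 2); gap penalties are never weighted. The constants
#' are package defaults inspired by common miRanda usage, not claims about
#' the miRanda binary.
#'
#' @param match,wobble,mismatch Pair scores.
#' @param gap_open,gap_ext Affine gap penalties (negative).
#' @param seed_weight Multiplier for seed-region pair scores.
#' @param seed_from,seed_to 1-based miRNA positions of the weighted region.
#' @return List of class `align_params`.
#' @export
align_params <- function(match = 5, wobble = 2, mismatch = -3,
                         gap_open = -8, gap_ext = -2,
                         seed_weight = 2, seed_from = 1, seed_to = 8) {
  stopifnot(match > 0, gap_open <= 0, gap_ext <= 0, seed_weight >= 1,
            seed_from >= 1, seed_to >= seed_from)
  structure(list(match = match, wobble = wobble, mismatch = mismatch,
                 gap_open = gap_open, gap_ext = gap_ext,
                 seed_weight = seed_weight, seed_from = seed_from,
                 seed_to = seed_to),
            class = "align_params")
}

#' Local duplex alignment of a miRNA against a target window
#'
#' Smith-Waterman-style local alignment (affine gaps, Gotoh) of the miRNA
#' read 3'->5' against the window read 5'->3', with seed-region weighting as
#' described in [align_params()]. The score of an empty alignment is 0.
#'
#' @param mirna Canonical RNA miRNA sequence (5'->3').
#' @param window Canonical RNA target window (5'->3'), at most 80 nt
#'   (callers should tile longer regions).
#' @param params An [align_params()] object.
#' @return List with `score` (maximal local score), `columns` (data frame of
#'   alignment columns in window order: `mirna_pos` (1-based on the miRNA, NA
#'   for gaps), `mirna_base`, `window_pos` (1-based, NA for gaps),
#'   `window_base`, `kind` in match/wobble/mismatch/gap), `target_start`,
#'   `target_end` (0-based half-open consumed window span).
#' @examples
#' duplex_align("ACGUACGU", revcomp_rna("ACGUACGU"))$score # 8 nt in-seed: 80
#' @export
duplex_align <- function(mirna, window, params = align_params()) {
  stopifnot(inherits(params, "align_params"))
  if (nchar(window) > 80)
    stop("window longer than 80 nt; tile the target instead", call. = FALSE)
  mirna <- canonicalize_rna(mirna)
  window <- canonicalize_rna(window)
  res <- .duplex_align_cpp(mirna, window,
                           params$match, params$wobble, params$mismatch,
                           params$gap_open, params$gap_ext,
                           params$seed_weight, params$seed_from, params$seed_to)
  cols <- res$columns
  M <- nchar(mirna)
  a <- ifelse(cols[, 1] == 0L, NA_integer_, cols[, 1])
  j <- ifelse(cols[, 2] == 0L, NA_integer_, cols[, 2])
  mirna_pos <- M - a + 1L
  mb <- ifelse(is.na(a), NA_character_,
               substring(mirna, mirna_pos, mirna_pos))
  wb <- ifelse(is.na(j), NA_character_, substring(window, j, j))
  kind <- ifelse(cols[, 3] != 0L, "gap",
                 vapply(seq_len(nrow(cols)), function(k) {
                   classify_pair(mb[k], wb[k])
                 }, character(1)))
  columns <- data.frame(mirna_pos = mirna_pos, mirna_base = mb,
                        window_pos = j, window_base = wb, kind = kind,
                        stringsAsFactors = FALSE)
  consumed <- j[!is.na(j)]
  list(score = res$score, columns = columns,
       target_start = if (length(consumed)) min(consumed) - 1L else NA_integer_,
       target_end = if (length(consumed)) max(consumed) else NA_integer_)
}

classify_pair <- function(a, b) {
  if (is.na(a) || is.na(b)) return("gap")
  pair <- paste0(a, b)
  if (pair %in% c("AU", "UA", "GC", "CG")) "match"
  else if (pair %in% c("GU", "UG")) "wobble"
  else "mismatch"
}

#' Additive free-energy approximation of an aligned duplex
#'
#' Crude per-pair energy model (not nearest-neighbor thermodynamics):
#' G:C pairs -3.0, A:U pairs -2.0, G:U wobbles -1.0 kcal/mol; mismatches and
#' gap columns +0.5 each. More negative is more stable; an empty alignment
#' has energy 0.
#'
#' @param columns Alignment-columns data frame from [duplex_align()].
#' @return Energy in kcal/mol.
#' @export
duplex_energy <- function(columns) {
  if (is.null(columns) || !nrow(columns)) return(0)
  per <- vapply(seq_len(nrow(columns)), function(k) {
    kind <- columns$kind[k]
    if (kind %in% c("gap", "mismatch")) return(0.5)
    pair <- paste0(columns$mirna_base[k], columns$window_base[k])
    if (pair %in% c("GC", "CG")) -3.0
    else if (pair %in% c("AU", "UA")) -2.0
    else -1.0  # G:U wobble
  }, numeric(1))
  sum(per)
}
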