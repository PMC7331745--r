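#' Median-of-ratios size factors
#'
#' Per-sample scaling factors computed as the median, over features with no
#' zero count, of the ratio of the count to the feature's geometric mean
#' (the DESeq estimator), rescaled to geometric mean 1 so that renormalizing
#' an already-normalized matrix returns unit factors.
#'
#' @param em A counts-layer `expr_matrix`.
#' @return Named numeric vector of positive size factors, one per sample.
#' @export
size_factors <- function(em) {
  stopifnot(inherits(em, "expr_matrix"))
  if (em$layer != "counts") stop("size factors require the counts layer", call. = FALSE)
  x <- em$values
  logx <- log(x)
  ok <- rowSums(!is.finite(logx)) == 0L  # features with all counts > 0
  if (!any(ok))
    stop("no feature has nonzero counts in every sample; ",
         "add a pseudocount or filter samples before normalization",
         call. = FALSE)
  loggeom <- rowMeans(logx[ok, , drop = FALSE])
  logsf <- apply(logx[ok, , drop = FALSE], 2L, function(col) median(col - loggeom))
  exp(logsf - mean(logsf))
}

#' Normalize counts to the log_norm layer
#'
#' Divides counts by their median-of-ratios size factors and applies
#' log2(x + 1).
#'
#' @param em A counts-layer `expr_matrix`.
#' @param sf Optional precomputed size factors.
#' @return A `log_norm`-layer `expr_matrix`.
#' @export
normalize_counts <- function(em, sf = size_factors(em)) {
  y <- log2(sweep(em$values, 2L, sf, "/") + 1)
  expression_matrix(y, "log_norm", em$design)
}

# Vectorized two-sided Welch t-test over matrix rows.
# Degenerate rows (zero variance in both groups): p = 1 when means are equal,
# p = 0 when they differ (perfect separation); flagged via a message.
welch_rows <- function(y, idx_case, idx_ctrl) {
  n1 <- length(idx_case); n2 <- length(idx_ctrl)
  if (n1 < 2 || n2 < 2) stop(">= 2 samples per group required", call. = FALSE)
  yc <- y[, idx_case, drop = FALSE]; yn <- y[, idx_ctrl, drop = FALSE]
  m1 <- rowMeans(yc); m2 <- rowMeans(yn)
  v1 <- rowSums((yc - m1)^2) / (n1 - 1)
  v2 <- rowSums((yn - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  tstat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * pt(-abs(tstat), df)
  degen <- se2 == 0
  if (any(degen)) {
    message(sum(degen), " feature(s) with zero within-group variance")
    p[degen] <- ifelse(m1[degen] == m2[degen], 1, 0)
    tstat[degen] <- ifelse(m1[degen] == m2[degen], 0, Inf * sign(m1 - m2)[degen])
  }
  list(mean_case = m1, mean_control = m2, t = tstat, p = p)
}

de_records <- function(em, y, molecule_class) {
  gi <- group_index(em)
  w <- welch_rows(y, gi$case, gi$control)
  log2fc <- w$mean_case - w$mean_control
  data.frame(feature_id = rownames(y),
             class = molecule_class,
             log2fc = log2fc,
             fold_change = 2^log2fc,
             p_value = w$p,
             q_value = p.adjust(w$p, method = "BH"),
             direction = ifelse(log2fc > 0, "up", "down"),
             mean_case = w$mean_case,
             mean_control = w$mean_control,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Differential expression for count data
#'
#' Median-of-ratios normalization, log2(x + 1) transform, then a two-sided
#' Welch t-test per feature (case vs control). The log2 fold change is the
#' difference of group means on the transformed scale; q-values are
#' Benjamini-Hochberg over all tested features of the class.
#'
#' @param em A counts-layer `expr_matrix` with >= 2 samples per group.
#' @param molecule_class `"circRNA"` or `"mRNA"` (tag carried into results).
#' @return Data frame of per-feature DE records (`feature_id`, `class`,
#'   `log2fc`, `fold_change`, `p_value`, `q_value`, `direction`,
#'   `mean_case`, `mean_control`).
#' @export
de_test_counts <- function(em, molecule_class = c("circRNA", "mRNA")) {
  molecule_class <- match.arg(molecule_class)
  stopifnot(inherits(em, "expr_matrix"))
  if (em$layer != "counts") stop("expected a counts layer", call. = FALSE)
  norm <- normalize_counts(em)
  de_records(em, norm$values, molecule_class)
}

#' Differential expression for log-intensity data
#'
#' As [de_test_counts()] but without the normalization step: the input is
#' already on a (pre-normalized) log2 scale.
#'
#' @param em A log-intensity `expr_matrix` with >= 2 samples per group.
#' @param molecule_class Molecule class tag (default `"miRNA"`).
#' @return Data frame of per-feature DE records.
#' @export
de_test_intensity <- function(em, molecule_class = "miRNA") {
  stopifnot(inherits(em, "expr_matrix"))
  if (em$layer == "counts") stop("expected a log-scale layer", call. = FALSE)
  de_records(em, em$values, molecule_class)
}

#' Filter differential-expression records at study thresholds
#'
#' Keeps records with 2^|log2fc| >= `fc_threshold` and p < `alpha`
#' (or q < `alpha` when `use_q`). The default thresholds are the study's:
#' fold change >= 1.5 and p < 0.05.
#'
#' @param records DE data frame from [de_test_counts()]/[de_test_intensity()],
#'   from a single molecule class.
#' @param fc_threshold Linear fold-change threshold (default 1.5).
#' @param alpha Significance threshold (default 0.05).
#' @param use_q Filter on BH q-values instead of raw p-values (default FALSE,
#'   matching the study's printed "p < 0.05").
#' @return List with `kept` (filtered data frame) and `summary`
#'   (named counts of up/down kept features).
#' @export
filter_de <- function(records, fc_threshold = 1.5, alpha = 0.05, use_q = FALSE) {
  stopifnot(fc_threshold >= 1, alpha > 0, alpha <= 1)
  if (length(unique(records$class)) > 1L)
    stop("filter_de expects records from one molecule class", call. = FALSE)
  pv <- if (use_q) records$q_value else records$p_value
  keep <- 2^abs(records$log2fc) >= fc_threshold & pv < alpha
  kept <- records[which(keep), , drop = FALSE]
  rownames(kept) <- NULL
  list(kept = kept,
       summary = c(up = sum(kept$direction == "up"),
                   down = sum(kept$direction == "down")))
}
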