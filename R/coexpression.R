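#' Pearson correlation with a t-distribution p-value
#'
#' Standard Pearson r with a two-sided p-value from
#' t = r * sqrt((n - 2) / (1 - r^2)) on n - 2 degrees of freedom. For a
#' constant vector r is undefined; (r = 0, p = 1) is returned with a warning.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return List with `r` and `p`.
#' @export
pearson_cor <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length", call. = FALSE)
  if (n < 3) stop("need n >= 3", call. = FALSE)
  if (var(x) == 0 || var(y) == 0) {
    warning("constant vector: correlation undefined, returning r = 0",
            call. = FALSE)
    return(list(r = 0, p = 1))
  }
  r <- cor(x, y)
  list(r = r, p = cor_pvalue(r, n))
}

cor_pvalue <- function(r, n) {
  r <- pmin(pmax(r, -1), 1)
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  2 * pt(-abs(tstat), n - 2)
}

#' Signed coexpression edges between two feature classes
#'
#' Tests all cross-class feature pairs for Pearson correlation across the
#' pooled samples and keeps edges matching the required ceRNA sign pattern:
#' miRNA-circRNA and miRNA-mRNA edges must be negative, circRNA-mRNA edges
#' positive. Count matrices must be normalized and log-transformed first
#' ([normalize_counts()]); correlations are computed on log-scale values.
#'
#' @param a_em,b_em `expr_matrix` objects (log scale) with identical samples
#'   in identical order, typically restricted to DE features.
#' @param a_class,b_class Molecule classes of the two matrices (must differ).
#' @param required_sign `"positive"` or `"negative"`.
#' @param r_min Minimum |r| (default 0.9; with n = 6 approximately the |r|
#'   needed for p < 0.05 is 0.81, so 0.9 is the binding threshold).
#' @param alpha Maximum p-value (default 0.05).
#' @param method `"pearson"` (default) or `"spearman"` (rank-transformed
#'   Pearson with the same t approximation).
#' @return Data frame of retained edges: `a_id`, `a_class`, `b_id`,
#'   `b_class`, `r`, `p_value`, `required_sign`.
#' @export
coexpression_edges <- function(a_em, b_em, a_class, b_class,
                               required_sign = c("negative", "positive"),
                               r_min = 0.9, alpha = 0.05,
                               method = c("pearson", "spearman")) {
  required_sign <- match.arg(required_sign)
  method <- match.arg(method)
  stopifnot(inherits(a_em, "expr_matrix"), inherits(b_em, "expr_matrix"))
  if (a_class == b_class) stop("a_class and b_class must differ", call. = FALSE)
  if (a_em$layer == "counts" || b_em$layer == "counts")
    stop("coexpression requires log-scale layers; normalize counts first",
         call. = FALSE)
  if (!identical(colnames(a_em$values), colnames(b_em$values)))
    stop("sample sets/order differ between the two matrices", call. = FALSE)
  A <- a_em$values; B <- b_em$values
  n <- ncol(A)
  if (n < 3) stop("need >= 3 samples", call. = FALSE)
  if (method == "spearman") {
    A <- t(apply(A, 1L, rank)); B <- t(apply(B, 1L, rank))
  }
  constA <- apply(A, 1L, var) == 0
  constB <- apply(B, 1L, var) == 0
  if (any(constA) || any(constB))
    warning(sum(constA) + sum(constB),
            " constant feature(s): correlations set to 0", call. = FALSE)
  r <- cor(t(A), t(B))           # features(A) x features(B)
  r[constA, ] <- 0; r[, constB] <- 0
  p <- cor_pvalue(r, n)
  p[constA, ] <- 1; p[, constB] <- 1
  keep <- which((if (required_sign == "positive") r > 0 else r < 0) &
                  abs(r) >= r_min & p < alpha, arr.ind = TRUE)
  nk <- nrow(keep)
  out <- data.frame(a_id = rownames(A)[keep[, 1]],
                    a_class = rep_len(a_class, nk),
                    b_id = rownames(B)[keep[, 2]],
                    b_class = rep_len(b_class, nk),
                    r = r[keep], p_value = p[keep],
                    required_sign = rep_len(required_sign, nk),
                    stringsAsFactors = FALSE)
  out <- out[order(out$a_id, out$b_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Restrict an expression matrix to a feature subset
#' @param em An `expr_matrix`.
#' @param feature_ids Features to keep (order preserved).
#' @return The restricted `expr_matrix`.
#' @export
subset_features <- function(em, feature_ids) {
  missing <- setdiff(feature_ids, rownames(em$values))
  if (length(missing))
    stop("feature(s) not in matrix: ", paste(head(missing, 5), collapse = ", "),
         call. = FALSE)
  expression_matrix(em$values[feature_ids, , drop = FALSE], em$layer, em$design)
}
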