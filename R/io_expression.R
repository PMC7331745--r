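#' Expression matrix with sample design
#'
#' Container for a features-by-samples numeric matrix plus the layer it holds
#' and the case/control assignment of every sample. All downstream stages
#' consume this class rather than raw files.
#'
#' @param values Numeric matrix, rows = features, columns = samples, with
#'   unique non-empty dimnames.
#' @param layer One of `"counts"` (non-negative RNA-seq counts),
#'   `"log_intensity"` (microarray log2 intensities) or `"log_norm"`
#'   (size-factor-normalized, log2(x+1)-transformed counts).
#' @param design Named character vector mapping every sample id to
#'   `"case"` or `"control"`.
#' @return An object of class `expr_matrix`: a list with elements `values`,
#'   `layer`, `design`.
#' @examples
#' m <- matrix(rpois(6, 50), 3, 2, dimnames = list(paste0("g", 1:3), c("s1", "s2")))
#' em <- expression_matrix(m, "counts", c(s1 = "case", s2 = "control"))
#' @export
expression_matrix <- function(values, layer = c("counts", "log_intensity", "log_norm"),
                              design) {
  layer <- match.arg(layer)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix", call. = FALSE)
  fid <- rownames(values); sid <- colnames(values)
  if (is.null(fid) || is.null(sid))
    stop("'values' must carry feature rownames and sample colnames", call. = FALSE)
  dup <- unique(fid[duplicated(fid)])
  if (length(dup))
    stop("duplicate feature id(s): ", paste(dup, collapse = ", "), call. = FALSE)
  dup <- unique(sid[duplicated(sid)])
  if (length(dup))
    stop("duplicate sample id(s): ", paste(dup, collapse = ", "), call. = FALSE)
  if (layer == "counts" && any(values < 0, na.rm = TRUE)) {
    bad <- which(values < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative count %g at feature '%s', sample '%s'",
                 values[bad[1], bad[2]], fid[bad[1]], sid[bad[2]]), call. = FALSE)
  }
  if (any(!is.finite(values)))
    stop("non-finite values in expression matrix", call. = FALSE)
  design <- validate_design(design, sid)
  structure(list(values = values, layer = layer, design = design[sid]),
            class = "expr_matrix")
}

validate_design <- function(design, sample_ids) {
  if (is.null(names(design)) || !all(nzchar(names(design))))
    stop("design must be a named sample -> group vector", call. = FALSE)
  missing <- setdiff(sample_ids, names(design))
  if (length(missing))
    stop("sample(s) missing from design: ", paste(missing, collapse = ", "),
         call. = FALSE)
  bad <- setdiff(unique(design), c("case", "control"))
  if (length(bad))
    stop("design groups must be 'case'/'control', got: ",
         paste(bad, collapse = ", "), call. = FALSE)
  design
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix [%s]: %d features x %d samples (%d case, %d control)\n",
              x$layer, nrow(x$values), ncol(x$values),
              sum(x$design == "case"), sum(x$design == "control")))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Case/control column indices of an expression matrix
#' @param em An `expr_matrix`.
#' @return List with integer vectors `case` and `control`.
#' @keywords internal
group_index <- function(em) {
  list(case = which(em$design == "case"),
       control = which(em$design == "control"))
}

#' Read an expression matrix and its sample design from TSV
#'
#' The matrix file is tab-separated with a header row of sample ids and the
#' feature ids in the first column. The design file has columns `sample_id`
#' and `group` (values `case`/`control`). Row and column order is preserved.
#'
#' @param path Path to the matrix TSV.
#' @param layer Layer tag, see [expression_matrix()].
#' @param design_path Path to the design TSV.
#' @return An `expr_matrix`.
#' @export
read_expression <- function(path, layer = c("counts", "log_intensity", "log_norm"),
                            design_path) {
  layer <- match.arg(layer)
  tab <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    colClasses = NA, stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("matrix TSV needs a feature id column plus >= 1 sample")
  fid <- as.character(tab[[1L]])
  dup <- unique(fid[duplicated(fid)])
  if (length(dup))
    stop("duplicate feature id(s) in ", path, ": ", paste(dup, collapse = ", "),
         call. = FALSE)
  vals <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(vals) <- "double"
  rownames(vals) <- fid
  expression_matrix(vals, layer, read_design(design_path))
}

#' Read a sample design table
#' @param path TSV with columns `sample_id`, `group`.
#' @return Named character vector sample id -> group.
#' @export
read_design <- function(path) {
  d <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("sample_id", "group")
  if (!all(need %in% names(d)))
    stop("design TSV must have columns: ", paste(need, collapse = ", "), call. = FALSE)
  structure(as.character(d$group), names = as.character(d$sample_id))
}

#' Write an expression matrix (and optionally its design) to TSV
#'
#' Inverse of [read_expression()]; `read -> write -> read` is value-identical.
#'
#' @param em An `expr_matrix`.
#' @param path Output TSV path for the matrix.
#' @param design_path Optional output path for the design table.
#' @return Invisibly, `path`.
#' @export
write_expression <- function(em, path, design_path = NULL) {
  df <- data.frame(feature_id = rownames(em$values), em$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, path)
  if (!is.null(design_path)) {
    write_tsv(data.frame(sample_id = names(em$design), group = unname(em$design),
                         stringsAsFactors = FALSE), design_path)
  }
  invisible(path)
}

# Single tabular dialect used everywhere: TSV, header, UTF-8, '.' decimal.
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

read_tsv <- function(path) {
  read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
             stringsAsFactors = FALSE)
}
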