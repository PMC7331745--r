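#' Read a qPCR Ct table
#'
#' TSV with columns `sample_id`, `group` (`case`/`control`), `gene_id`,
#' `reference_id`, `ct_gene`, `ct_ref` -- one row per sample x gene, with the
#' matched housekeeping reference Ct (e.g. beta-actin for circRNAs/mRNAs,
#' U6 for miRNAs) on the same row.
#'
#' @param path TSV path.
#' @return Validated data frame of class `ct_table`.
#' @export
read_ct <- function(path) {
  ct <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  ct_table(ct)
}

#' Validate a Ct table
#' @param ct Data frame with the columns described in [read_ct()].
#' @return The validated data frame (class `ct_table`).
#' @export
ct_table <- function(ct) {
  need <- c("sample_id", "group", "gene_id", "reference_id", "ct_gene", "ct_ref")
  missing <- setdiff(need, names(ct))
  if (length(missing))
    stop("Ct table missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  bad_group <- setdiff(unique(ct$group), c("case", "control"))
  if (length(bad_group))
    stop("group must be case/control, got: ", paste(bad_group, collapse = ", "),
         call. = FALSE)
  bad <- !is.finite(ct$ct_gene) | !is.finite(ct$ct_ref) |
    ct$ct_gene <= 0 | ct$ct_ref <= 0
  if (any(bad))
    stop("non-positive or non-finite Ct value(s) for sample(s): ",
         paste(unique(ct$sample_id[bad]), collapse = ", "), call. = FALSE)
  class(ct) <- c("ct_table", "data.frame")
  ct
}

#' Relative quantification by the 2^-ddCt method
#'
#' Per gene: dCt = ct_gene - ct_ref per sample; ddCt = mean dCt(case) -
#' mean dCt(control); fold change = 2^-ddCt (case relative to control).
#' Per-sample relative levels 2^-(dCt - mean dCt control) are also returned
#' for plotting/SEM summaries.
#'
#' @param ct A `ct_table` (or data frame with its columns) with >= 1 sample
#'   per group for every gene.
#' @return List with `per_gene` (data frame: `gene_id`, `reference_id`,
#'   `n_case`, `n_control`, `ddct`, `fold_change`) and `per_sample`
#'   (data frame: `gene_id`, `sample_id`, `group`, `delta_ct`,
#'   `rel_expression`).
#' @export
ddct <- function(ct) {
  ct <- ct_table(as.data.frame(ct))
  ct$delta_ct <- ct$ct_gene - ct$ct_ref
  genes <- unique(ct$gene_id)
  per_gene <- lapply(genes, function(g) {
    d <- ct[ct$gene_id == g, , drop = FALSE]
    dc_case <- d$delta_ct[d$group == "case"]
    dc_ctrl <- d$delta_ct[d$group == "control"]
    if (!length(dc_case) || !length(dc_ctrl))
      stop("gene '", g, "' lacks samples in one group", call. = FALSE)
    dd <- mean(dc_case) - mean(dc_ctrl)
    data.frame(gene_id = g, reference_id = d$reference_id[1],
               n_case = length(dc_case), n_control = length(dc_ctrl),
               ddct = dd, fold_change = 2^(-dd), stringsAsFactors = FALSE)
  })
  per_sample <- lapply(genes, function(g) {
    d <- ct[ct$gene_id == g, , drop = FALSE]
    cal <- mean(d$delta_ct[d$group == "control"])
    data.frame(gene_id = g, sample_id = d$sample_id, group = d$group,
               delta_ct = d$delta_ct,
               rel_expression = 2^(-(d$delta_ct - cal)),
               stringsAsFactors = FALSE)
  })
  list(per_gene = do.call(rbind, per_gene),
       per_sample = do.call(rbind, per_sample))
}
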