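#' Read a FASTA file of RNA sequences
#'
#' Sequences are canonicalized to uppercase RNA (T -> U); the record id is the
#' first whitespace-delimited token of the header. Letters outside
#' `A,C,G,T,U` (either case) are rejected.
#'
#' @param path FASTA file path.
#' @param moltype Molecule role of the records: `"miRNA"`, `"mRNA_target"` or
#'   `"circRNA_target"`. Carried as an attribute; circRNA targets are treated
#'   as circular (backsplice-junction-spanning) sequences by [predict_mres()].
#' @return A named character vector of class `rna_seqs` (names = ids) with a
#'   `moltype` attribute.
#' @export
read_fasta <- function(path, moltype = c("miRNA", "mRNA_target", "circRNA_target")) {
  moltype <- match.arg(moltype)
  ss <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  seqs <- as.character(ss)
  names(seqs) <- ids
  rna_seqs(seqs, moltype)
}

#' Construct a canonicalized RNA sequence set
#'
#' @param seqs Named character vector of sequences (ids as names).
#' @param moltype Molecule role, see [read_fasta()].
#' @return `rna_seqs` object.
#' @export
rna_seqs <- function(seqs, moltype = c("miRNA", "mRNA_target", "circRNA_target")) {
  moltype <- match.arg(moltype)
  ids <- names(seqs)
  if (is.null(ids) || !all(nzchar(ids)))
    stop("all sequences must be named with non-empty ids", call. = FALSE)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate sequence id(s): ", paste(dup, collapse = ", "), call. = FALSE)
  empty <- ids[!nzchar(seqs)]
  if (length(empty))
    stop("empty sequence for id(s): ", paste(empty, collapse = ", "), call. = FALSE)
  bad <- grepl("[^ACGTUacgtu]", seqs)
  if (any(bad))
    stop("invalid letters in sequence(s): ", paste(ids[bad], collapse = ", "),
         call. = FALSE)
  seqs <- canonicalize_rna(seqs)
  structure(seqs, moltype = moltype, class = "rna_seqs")
}

#' Canonicalize nucleotide strings to uppercase RNA
#'
#' Maps lowercase to uppercase and T to U. Idempotent.
#' @param x Character vector of sequences.
#' @return Character vector over `{A,C,G,U}`.
#' @export
canonicalize_rna <- function(x) {
  structure(chartr("acgtuT", "ACGUUU", x), names = names(x))
}

#' Reverse complement of an RNA sequence
#'
#' Watson-Crick complement (A<->U, C<->G) read 3' -> 5', i.e. the sequence a
#' perfectly pairing antiparallel strand would have, written 5' -> 3'.
#' @param x Character vector of canonical RNA sequences.
#' @return Character vector of reverse complements.
#' @examples
#' revcomp_rna("GGAAUGU") # "ACAUUCC"
#' @export
revcomp_rna <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGU", "UGCA", s), "")[[1L]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Write RNA sequences to FASTA
#' @param seqs `rna_seqs` or named character vector.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(seqs, path) {
  ss <- Biostrings::BStringSet(unclass(seqs))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' @export
print.rna_seqs <- function(x, ...) {
  cat(sprintf("rna_seqs [%s]: %d sequences, lengths %d-%d\n",
              attr(x, "moltype"), length(x),
              min(nchar(x)), max(nchar(x))))
  invisible(x)
}
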