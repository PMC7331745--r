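#' Gene-set collection for over-representation analysis
#'
#' @param sets Named list of character vectors (term id -> member gene ids).
#' @param descriptions Named character vector of term descriptions (optional;
#'   defaults to the term ids).
#' @param universe Background gene universe. Defaults to the union of all set
#'   members. Set members are restricted to the universe.
#' @return An object of class `gene_sets` with elements `sets`,
#'   `descriptions`, `universe`.
#' @export
gene_set_collection <- function(sets, descriptions = NULL, universe = NULL) {
  if (!length(sets)) {
    return(structure(list(sets = list(), descriptions = character(0),
                          universe = character(0) %||% universe),
                     class = "gene_sets"))
  }
  ids <- names(sets)
  if (is.null(ids) || !all(nzchar(ids)))
    stop("all gene sets must have term ids", call. = FALSE)
  if (is.null(universe)) universe <- unique(unlist(sets, use.names = FALSE))
  sets <- lapply(sets, function(g) intersect(unique(g), universe))
  empty <- ids[lengths(sets) == 0L]
  if (length(empty))
    stop("empty gene set(s) after universe restriction: ",
         paste(empty, collapse = ", "), call. = FALSE)
  if (is.null(descriptions)) descriptions <- structure(ids, names = ids)
  structure(list(sets = sets, descriptions = descriptions[ids],
                 universe = universe),
            class = "gene_sets")
}

`%||%` <- function(a, b) if (is.null(b)) a else b

#' Read gene sets in GMT format
#'
#' GMT dialect: one set per line, `term_id TAB description TAB gene TAB gene ...`.
#' The universe defaults to the union of all members unless `universe` is given.
#'
#' @param path GMT file path.
#' @param universe Optional explicit background universe.
#' @return A `gene_sets` collection.
#' @export
read_gmt <- function(path, universe = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    warning("empty GMT file: ", path, call. = FALSE)
    return(gene_set_collection(list(), universe = universe %||% character(0)))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(parts) < 3L)
  if (length(short))
    stop(sprintf("GMT parse error at line %d of %s: fewer than 3 fields",
                 short[1L], path), call. = FALSE)
  ids <- vapply(parts, `[[`, character(1), 1L)
  desc <- vapply(parts, `[[`, character(1), 2L)
  sets <- lapply(parts, function(p) p[-(1:2)])
  names(sets) <- ids
  gene_set_collection(sets, structure(desc, names = ids), universe = universe)
}

#' Write gene sets in GMT format
#' @param collection A `gene_sets` collection.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(collection, path) {
  lines <- vapply(names(collection$sets), function(id) {
    paste(c(id, collection$descriptions[[id]], collection$sets[[id]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.gene_sets <- function(x, ...) {
  cat(sprintf("gene_sets: %d sets over a universe of %d genes\n",
              length(x$sets), length(x$universe)))
  invisible(x)
}
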