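#' Construct a gene-set collection
#'
#' A gene-set collection is an ordered list of named gene sets, each carrying
#' an optional category label (e.g. one of the 12 main KEGG metabolic
#' categories). It is the container consumed by [gsva_scores()] and
#' [preranked_gsea()].
#'
#' @param sets Named list; each element a character vector of gene
#'   identifiers. Names are the set names and must be unique.
#' @param categories Character vector of category labels, one per set
#'   (recycled from `""` when omitted). Empty string means "no category".
#' @param source Free-text provenance string.
#' @return An object of class `gene_set_collection`: a list with elements
#'   `sets`, `categories`, `source`.
#' @export
gene_set_collection <- function(sets, categories = NULL, source = "") {
  if (is.null(names(sets)) || anyNA(names(sets)) || any(names(sets) == ""))
    stop("every gene set must be named")
  if (anyDuplicated(names(sets)))
    stop("duplicate gene set name(s): ",
         paste(unique(names(sets)[duplicated(names(sets))]), collapse = ", "))
  if (is.null(categories)) categories <- rep("", length(sets))
  if (length(categories) != length(sets))
    stop("categories must have one entry per set")
  sets <- lapply(sets, function(g) {
    g <- trimws(as.character(g))
    g <- g[g != ""]
    g <- g[!duplicated(g)]
    if (length(g) == 0L) stop("gene sets must be non-empty")
    g
  })
  structure(
    list(sets = sets, categories = as.character(categories), source = source),
    class = "gene_set_collection"
  )
}

#' @export
print.gene_set_collection <- function(x, ...) {
  s <- collection_stats(x)
  cat("Gene-set collection:", s$n_sets, "sets,", s$n_unique_genes,
      "unique genes,", s$n_categories, "categories\n")
  if (nzchar(x$source)) cat("Source:", x$source, "\n")
  invisible(x)
}

#' @export
length.gene_set_collection <- function(x) length(x$sets)

#' Read a gene-set collection from a GMT file
#'
#' GMT is one set per tab-separated line: name, description, then member
#' genes. Here the second column is repurposed to carry the category label
#' (e.g. "glycan biosynthesis and metabolism"); a literal "NA" or empty field
#' means no category. Duplicate genes within a line are dropped, keeping the
#' first occurrence. Gene identifiers are whitespace-trimmed and matched
#' case-sensitively downstream; no alias resolution is attempted.
#'
#' @param path Path to a GMT file (UTF-8, tab-separated).
#' @return A [gene_set_collection()].
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L)
    return(gene_set_collection(stats::setNames(list(), character(0)),
                               character(0), source = path))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L))
    stop("malformed GMT line ", which(nf < 3L)[1L],
         ": fewer than 3 tab-separated fields")
  nm <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(nm))
    stop("duplicate set name(s) in GMT: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  cat_lab <- vapply(fields, `[[`, "", 2L)
  cat_lab[is.na(cat_lab) | cat_lab == "NA"] <- ""
  sets <- lapply(fields, function(f) f[-(1:2)])
  names(sets) <- nm
  gene_set_collection(sets, cat_lab, source = path)
}

#' Write a gene-set collection to a GMT file
#'
#' Inverse of [read_gmt()]; the category label goes into the second column.
#'
#' @param coll A [gene_set_collection()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(coll, path) {
  stopifnot(inherits(coll, "gene_set_collection"))
  lines <- vapply(seq_along(coll$sets), function(i) {
    paste(c(names(coll$sets)[i], coll$categories[i], coll$sets[[i]]),
          collapse = "\t")
  }, "")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Restrict a collection to measured genes and filter by effective size
#'
#' Each set is intersected with the measured gene universe first; sets whose
#' effective size falls outside `[min_size, max_size]` are dropped. The
#' defaults (9 and 300) are the size bounds used for the KEGG metabolic
#' pathway scoring.
#'
#' @param coll A [gene_set_collection()].
#' @param measured Character vector of measured gene identifiers.
#' @param min_size,max_size Inclusive bounds on effective set size.
#' @return A filtered [gene_set_collection()] with a `dropped` attribute: a
#'   data frame naming each removed set and its effective size.
#' @export
filter_by_size <- function(coll, measured, min_size = 9, max_size = 300) {
  stopifnot(inherits(coll, "gene_set_collection"),
            min_size >= 1, max_size >= min_size)
  measured <- unique(trimws(as.character(measured)))
  measured <- measured[measured != ""]
  if (length(measured) == 0L) stop("measured gene set is empty")
  inter <- lapply(coll$sets, function(g) g[g %in% measured])
  eff <- lengths(inter)
  keep <- eff >= min_size & eff <= max_size
  dropped <- data.frame(
    set = names(coll$sets)[!keep],
    effective_size = unname(eff[!keep]),
    stringsAsFactors = FALSE
  )
  out <- gene_set_collection(
    if (any(keep)) inter[keep] else stats::setNames(list(), character(0)),
    coll$categories[keep],
    source = coll$source
  )
  attr(out, "dropped") <- dropped
  out
}

#' Summary statistics of a gene-set collection
#'
#' @param coll A [gene_set_collection()].
#' @return A list: `n_sets`, `n_unique_genes` (cardinality of the union of
#'   member sets), `n_categories` (distinct non-empty labels), and
#'   `size_distribution` (named quantile summary of set sizes).
#' @export
collection_stats <- function(coll) {
  stopifnot(inherits(coll, "gene_set_collection"))
  sizes <- lengths(coll$sets)
  list(
    n_sets = length(coll$sets),
    n_unique_genes = length(unique(unlist(coll$sets, use.names = FALSE))),
    n_categories = length(unique(coll$categories[coll$categories != ""])),
    size_distribution = if (length(sizes))
      stats::quantile(sizes, c(0, 0.25, 0.5, 0.75, 1)) else
      stats::setNames(rep(0, 5), c("0%", "25%", "50%", "75%", "100%"))
  )
}
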