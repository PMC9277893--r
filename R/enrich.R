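#' Read a GMT gene-set file
#'
#' Standard GMT: one term per line, tab-separated `term`, `description`,
#' then member genes. Gene identifiers are case-normalised to upper case and
#' de-duplicated within each term.
#'
#' @param path path to a GMT file.
#' @return Object of class `"gene_set_collection"`: list with `sets` (named
#'   list of character vectors) and `descriptions` (named character).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stopf("empty GMT file: %s", path)
  sets <- list(); descs <- character()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L) {
      stopf("GMT parse error at line %d: fewer than 3 tab-separated fields", i)
    }
    genes <- unique(toupper(f[-(1:2)]))
    genes <- genes[nzchar(genes)]
    if (!length(genes)) stopf("GMT parse error at line %d: empty term", i)
    sets[[f[1]]] <- genes
    descs[[f[1]]] <- f[2]
  }
  gene_set_collection(sets, descs)
}

#' Build a gene-set collection in memory
#'
#' @param sets named list of character vectors (term -> member genes).
#' @param descriptions optional named character vector of term descriptions.
#' @return Object of class `"gene_set_collection"`.
#' @export
gene_set_collection <- function(sets, descriptions = NULL) {
  stopifnot(is.list(sets), length(sets) >= 1L, !is.null(names(sets)),
            all(nzchar(names(sets))))
  sets <- lapply(sets, function(g) unique(toupper(as.character(g))))
  if (any(lengths(sets) == 0L)) stopf("empty term in gene-set collection")
  if (is.null(descriptions)) {
    descriptions <- setNames(rep("", length(sets)), names(sets))
  }
  descriptions <- descriptions[names(sets)]
  descriptions[is.na(descriptions)] <- ""
  names(descriptions) <- names(sets)
  structure(list(sets = sets, descriptions = descriptions),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("<gene_set_collection> %d terms, %d distinct genes\n",
              length(x$sets), length(unique(unlist(x$sets)))))
  invisible(x)
}

#' Write a gene-set collection to GMT
#'
#' @param collection a [gene_set_collection()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "gene_set_collection"))
  lines <- vapply(names(collection$sets), function(tm) {
    paste(c(tm, collection$descriptions[[tm]], collection$sets[[tm]]),
          collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Hypergeometric over-representation of a hit list
#'
#' One-sided upper-tail hypergeometric test per term: with background size
#' `N`, term size in background `K`, hit-list size `n` and overlap `k`,
#' `p = P(X >= k)` for `X ~ Hypergeometric(N, K, n)`. The enrichment factor
#' is `(k/n) / (K/N)`. Rows are filtered by the screen's criteria — minimum
#' overlap, p-value cutoff and minimum enrichment — and sorted by p.
#' Benjamini-Hochberg q-values are computed across all tested terms and
#' reported, but not filtered on. The natural background of a
#' deletion-collection screen is the set of strains analysed, not the whole
#' genome.
#'
#' @param hits character vector of hit genes; must be a subset of
#'   `background`.
#' @param collection a [gene_set_collection()]; each term is intersected
#'   with the background before testing.
#' @param background character vector of all genes analysed.
#' @param min_overlap minimum overlap `k` to keep a term (default 3).
#' @param p_cutoff p-value cutoff (default 0.05, rows with `p >= p_cutoff`
#'   are dropped).
#' @param min_enrichment minimum enrichment factor to keep a term
#'   (default 1.5).
#' @return `data.frame` sorted by `p`: `term`, `description`, `N`, `K`, `n`,
#'   `k`, `enrichment`, `p`, `q`. The unfiltered table of all tested terms
#'   is attached as attribute `"all_terms"`.
#' @export
hypergeom_enrich <- function(hits, collection, background,
                             min_overlap = 3, p_cutoff = 0.05,
                             min_enrichment = 1.5) {
  stopifnot(inherits(collection, "gene_set_collection"))
  background <- unique(toupper(as.character(background)))
  if (!length(background)) stopf("empty background")
  hits <- unique(toupper(as.character(hits)))
  offenders <- setdiff(hits, background)
  if (length(offenders)) {
    stopf("hit gene(s) absent from background: %s",
          paste(sort(offenders), collapse = ", "))
  }
  if (!length(hits)) stopf("empty hit list")
  N <- length(background); n <- length(hits)
  rows <- lapply(names(collection$sets), function(tm) {
    members <- intersect(collection$sets[[tm]], background)
    K <- length(members)
    if (K == 0L) return(NULL) # term absent from the sampling frame
    k <- length(intersect(members, hits))
    data.frame(term = tm, description = collection$descriptions[[tm]],
               N = N, K = K, n = n, k = k,
               enrichment = (k / n) / (K / N),
               p = phyper(k - 1, K, N - K, n, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) {
    stopf("no term overlaps the background: nothing to test")
  }
  tab <- do.call(rbind, rows)
  tab$q <- p.adjust(tab$p, method = "BH")
  tab <- tab[order(tab$p, tab$term), , drop = FALSE]
  rownames(tab) <- NULL
  keep <- tab$k >= min_overlap & tab$p < p_cutoff & tab$enrichment >= min_enrichment
  out <- tab[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "all_terms") <- tab
  out
}
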