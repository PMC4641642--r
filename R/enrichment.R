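# Category enrichment of DE gene lists against a flat term catalog, and
# comparative (cancer-specific) enrichment across tissues.

#' Build an annotation catalog of term gene sets over a universe
#'
#' @param terms Named list: term id -> character vector of member genes.
#' @param universe Character vector of all testable genes; every term must
#'   be a subset of it.
#' @return Object of class \code{annotation_catalog}.
#' @export
annotation_catalog <- function(terms, universe) {
  universe <- sort(unique(toupper(universe)))
  terms <- lapply(terms, function(g) sort(unique(toupper(g))))
  outside <- vapply(terms, function(g) any(!g %in% universe), logical(1))
  if (any(outside)) {
    stop("annotation_catalog: term(s) outside the universe: ",
         paste(names(terms)[outside], collapse = ", "))
  }
  structure(list(terms = terms, universe = universe),
            class = "annotation_catalog")
}

#' Hypergeometric term enrichment of a query gene set
#'
#' Query genes outside the catalog universe are dropped (count reported via
#' message). Each term with at least one query hit gets an enrichment row;
#' rows are sorted by p-value.
#'
#' @param query A \code{gene_set}.
#' @param catalog An \code{annotation_catalog}.
#' @return \code{data.frame} with columns \code{term, k, K, n, N, p_value,
#'   fold_enrichment} where fold enrichment is \code{(k/n)/(K/N)}.
#' @export
enrich <- function(query, catalog) {
  stopifnot(inherits(query, "gene_set"), inherits(catalog, "annotation_catalog"))
  q <- intersect(query$genes, catalog$universe)
  n_drop <- length(query$genes) - length(q)
  if (n_drop > 0) message(n_drop, " query gene(s) outside the universe dropped")
  if (length(q) == 0) stop("enrich: no query gene inside the universe")
  N <- length(catalog$universe)
  n <- length(q)
  rows <- lapply(names(catalog$terms), function(term) {
    genes <- catalog$terms[[term]]
    k <- length(intersect(q, genes))
    if (k == 0) return(NULL)
    K <- length(genes)
    data.frame(term = term, k = k, K = K, n = n, N = N,
               p_value = hypergeometric_tail(k, K, n, N),
               fold_enrichment = (k / n) / (K / N),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(term = character(0), k = integer(0), K = integer(0),
                      n = integer(0), N = integer(0), p_value = numeric(0),
                      fold_enrichment = numeric(0))
  }
  out[order(out$p_value, out$term), , drop = FALSE]
}

#' Flag terms enriched predominantly in one cancer
#'
#' A term is specific to cancer X when its fold enrichment there is at
#' least \code{ratio_min} times the maximum fold enrichment over all other
#' cancers. Terms missing from a cancer's rows count as fold 0 there.
#'
#' @param rows_by_cancer Named list of \code{\link{enrich}} outputs, one per
#'   cancer, computed against the same catalog.
#' @param ratio_min Specificity multiplier (default 2).
#' @return \code{data.frame} with one row per term: per-cancer folds and a
#'   \code{specific_to} label (\code{NA} when no cancer qualifies).
#' @export
comparative_enrichment <- function(rows_by_cancer, ratio_min = 2.0) {
  if (length(rows_by_cancer) < 2) {
    stop("comparative_enrichment: needs at least 2 cancers")
  }
  cancers <- names(rows_by_cancer)
  Ns <- unique(unlist(lapply(rows_by_cancer, function(r) r$N)))
  if (length(Ns) > 1) {
    stop("comparative_enrichment: cancers were enriched against different catalogs")
  }
  all_terms <- sort(unique(unlist(lapply(rows_by_cancer, `[[`, "term"))))
  folds <- vapply(rows_by_cancer, function(r) {
    f <- r$fold_enrichment[match(all_terms, r$term)]
    ifelse(is.na(f), 0, f)
  }, numeric(length(all_terms)))
  folds <- matrix(folds, nrow = length(all_terms),
                  dimnames = list(all_terms, cancers))
  specific_to <- apply(folds, 1, function(fv) {
    for (i in seq_along(fv)) {
      others <- max(fv[-i])
      if (fv[i] > 0 && fv[i] >= ratio_min * others) return(cancers[i])
    }
    NA_character_
  })
  out <- data.frame(term = all_terms, folds, specific_to = specific_to,
                    row.names = NULL, stringsAsFactors = FALSE,
                    check.names = FALSE)
  out
}
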