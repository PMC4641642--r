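# Gene-set containers, Venn accounting, signature-overlap testing against
# GMT-style collections, tissue merging, and recurrence scoring.

#' Construct a gene set
#'
#' Symbols are upper-cased and deduplicated; symbol aliasing/translation is
#' out of scope.
#'
#' @param name Set name.
#' @param genes Character vector of gene symbols (non-empty).
#' @param tissue,study,direction Optional metadata tags.
#' @return Object of class \code{gene_set}.
#' @export
gene_set <- function(name, genes, tissue = NA_character_,
                     study = NA_character_, direction = NA_character_) {
  genes <- sort(unique(toupper(as.character(genes))))
  if (length(genes) == 0) stop("gene_set: '", name, "' has no genes")
  structure(list(name = name, genes = genes, tissue = tissue, study = study,
                 direction = direction),
            class = "gene_set")
}

#' Disjoint-region counts for 2 or 3 gene sets
#'
#' @param sets List of 2 or 3 \code{gene_set} objects.
#' @return List with \code{regions} (named counts of every disjoint Venn
#'   region, names like \code{"A"}, \code{"AB"}, \code{"ABC"}) and
#'   \code{common} (genes in all sets).
#' @export
venn_counts <- function(sets) {
  if (length(sets) < 2 || length(sets) > 3) {
    stop("venn_counts: needs 2 or 3 sets")
  }
  letters_used <- LETTERS[seq_along(sets)]
  all_genes <- unique(unlist(lapply(sets, `[[`, "genes")))
  membership <- vapply(sets, function(s) all_genes %in% s$genes,
                       logical(length(all_genes)))
  membership <- matrix(membership, ncol = length(sets))
  region_of <- apply(membership, 1, function(row) {
    paste(letters_used[row], collapse = "")
  })
  # every non-empty combination, in subset order
  combos <- unlist(lapply(seq_along(sets), function(sz) {
    apply(utils::combn(letters_used, sz), 2, paste, collapse = "")
  }))
  regions <- vapply(combos, function(cb) sum(region_of == cb), integer(1))
  common <- sort(all_genes[rowSums(membership) == length(sets)])
  list(regions = regions, common = common)
}

#' Test the overlap between a query gene list and a known signature
#'
#' Overlap significance comes from the one-sided hypergeometric test; the
#' pair is flagged as a matching signature when the overlap has at least
#' \code{min_common} genes (default 6, i.e. strictly more than 5) and
#' p < \code{p_max}.
#'
#' @param query,sig \code{gene_set} objects.
#' @param universe_size Number of genes in the testing universe; must be at
#'   least the size of the union of the two sets.
#' @param min_common Minimum overlap size (default 6).
#' @param p_max Significance cutoff (default 0.01).
#' @return List with \code{pair}, \code{n_common}, \code{common_genes},
#'   \code{p_value}, \code{pass}.
#' @export
signature_overlap_test <- function(query, sig, universe_size,
                                   min_common = 6, p_max = 0.01) {
  stopifnot(inherits(query, "gene_set"), inherits(sig, "gene_set"))
  union_size <- length(union(query$genes, sig$genes))
  if (universe_size < union_size) {
    stop("signature_overlap_test: universe smaller than the union of the sets")
  }
  common <- intersect(query$genes, sig$genes)
  p <- hypergeometric_tail(length(common), K = length(sig$genes),
                           n = length(query$genes), N = universe_size)
  list(pair = c(query$name, sig$name),
       n_common = length(common),
       common_genes = sort(common),
       p_value = p,
       pass = length(common) >= min_common && p < p_max)
}

#' Merge signature sets by tissue of origin
#'
#' Takes the union of all sets sharing a tissue tag, regardless of study or
#' direction; contributing study names are kept in the \code{study} field.
#'
#' @param collection List of \code{gene_set} objects, each with a tissue tag.
#' @return List of merged \code{gene_set} objects, one per tissue, ordered
#'   by tissue name.
#' @export
merge_signatures_by_tissue <- function(collection) {
  if (length(collection) == 0) return(list())
  tissues <- vapply(collection, function(s) {
    if (is.na(s$tissue) || !nzchar(s$tissue)) {
      stop("merge_signatures_by_tissue: set '", s$name, "' has no tissue tag")
    }
    s$tissue
  }, character(1))
  out <- lapply(sort(unique(tissues)), function(tt) {
    members <- collection[tissues == tt]
    gs <- gene_set(tt, unlist(lapply(members, `[[`, "genes")), tissue = tt)
    gs$study <- paste(vapply(members, `[[`, character(1), "name"),
                      collapse = ";")
    gs
  })
  out
}

#' Count, per query gene, how many collection sets contain it
#'
#' @param query A \code{gene_set}.
#' @param collection List of \code{gene_set} objects.
#' @return Named integer vector over the query genes.
#' @export
recurrence_scores <- function(query, collection) {
  stopifnot(inherits(query, "gene_set"))
  counts <- vapply(query$genes, function(g) {
    sum(vapply(collection, function(s) g %in% s$genes, logical(1)))
  }, integer(1))
  counts
}

#' Genes recurring in at least \code{min_studies} signature sets
#'
#' @param scores Named counts from \code{\link{recurrence_scores}}.
#' @param min_studies Recurrence threshold (default 6, i.e. more than five
#'   studies).
#' @param name Name for the returned set.
#' @return A \code{gene_set} of the recurrent genes, alphabetical; NULL if
#'   none qualifies.
#' @export
robust_signature <- function(scores, min_studies = 6, name = "robust") {
  genes <- sort(names(scores)[scores >= min_studies])
  if (length(genes) == 0) {
    message("robust_signature: no gene reaches ", min_studies, " studies")
    return(NULL)
  }
  gene_set(name, genes)
}
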