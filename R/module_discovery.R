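# Discovery of transcription-factor co-binding modules: pairwise peak
# overlap counting, size normalization, average-linkage clustering, gene
# assignment by the >=2-regulators rule, and the downstream enrichment,
# co-occurrence and external-association statistics.

#' Count pairwise peak overlaps between all TF peak sets
#'
#' For an ordered pair (i, j), count_ij is the number of TF i peaks that
#' overlap at least one TF j peak by >= 1 bp. These counts are asymmetric,
#' so the raw matrix stores \code{min(count_ij, count_ji)}: symmetric and
#' bounded by both peak-set sizes. The diagonal holds each TF's peak count.
#'
#' @param peaks Named list: TF -> interval data.frame (\code{chrom, start,
#'   end}, 0-based half-open). At least 2 TFs, none empty.
#' @return List of class \code{overlap_matrix} with \code{raw} (symmetric
#'   counts), \code{sizes} (peak counts) and \code{normalized = NULL}.
#' @export
count_pairwise_overlaps <- function(peaks) {
  if (length(peaks) < 2) stop("count_pairwise_overlaps: need at least 2 TFs")
  tfs <- names(peaks)
  for (tf in tfs) {
    if (nrow(peaks[[tf]]) == 0) {
      stop("count_pairwise_overlaps: TF '", tf, "' has zero peaks")
    }
    validate_intervals(peaks[[tf]])
  }
  n <- length(tfs)
  sizes <- vapply(peaks, nrow, integer(1))
  raw <- matrix(0, n, n, dimnames = list(tfs, tfs))
  diag(raw) <- sizes
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    hits <- halfopen_overlaps(peaks[[i]], peaks[[j]])
    c_ij <- length(unique(hits$query))     # peaks of i hitting any of j
    c_ji <- length(unique(hits$subject))   # peaks of j hit by any of i
    raw[i, j] <- raw[j, i] <- min(c_ij, c_ji)
  }
  structure(list(raw = raw, sizes = sizes, normalized = NULL,
                 normalization = NA_character_),
            class = "overlap_matrix")
}

#' Normalize a raw overlap matrix by peak-set sizes
#'
#' The default is the overlap (Szymkiewicz-Simpson) coefficient,
#' raw / min(size_i, size_j), which maps identical peak sets to 1 and
#' disjoint ones to 0 regardless of how unequal the set sizes are. Jaccard
#' (raw / (size_i + size_j - raw)) is available as an alternative.
#'
#' @param m An \code{overlap_matrix} with raw counts.
#' @param method \code{"overlap_coefficient"} (default) or \code{"jaccard"}.
#' @return The matrix with \code{normalized} filled (values in [0, 1],
#'   unit diagonal) and the method recorded.
#' @export
normalize_overlap <- function(m, method = c("overlap_coefficient", "jaccard")) {
  stopifnot(inherits(m, "overlap_matrix"))
  method <- match.arg(method)
  if (any(m$sizes == 0)) stop("normalize_overlap: zero peak-set size")
  denom <- if (method == "overlap_coefficient") {
    outer(m$sizes, m$sizes, pmin)
  } else {
    outer(m$sizes, m$sizes, `+`) - m$raw
  }
  m$normalized <- m$raw / denom
  diag(m$normalized) <- 1
  m$normalization <- method
  m
}

#' Cluster TFs into co-binding modules
#'
#' Hierarchically clusters the rows of the normalized overlap matrix with
#' average linkage on correlation distance and cuts the tree at \code{k}
#' modules. TFs whose normalized overlap profiles correlate co-occur on the
#' genome and end up in one module.
#'
#' @param m A normalized \code{overlap_matrix}.
#' @param k Number of modules, 2..number of TFs; \code{"auto"} picks k in
#'   2..(n-1) by maximal mean silhouette width on the correlation distance.
#' @return List of class \code{module_partition}: module id (\code{"M1"},
#'   ...) -> character vector of member TFs.
#' @export
discover_modules <- function(m, k = 4) {
  stopifnot(inherits(m, "overlap_matrix"))
  if (is.null(m$normalized)) stop("discover_modules: normalize the matrix first")
  n <- nrow(m$normalized)
  if (identical(k, "auto")) {
    k <- pick_k_silhouette(m$normalized)
  }
  if (k < 2 || k > n) stop("discover_modules: k out of range [2, n_tf]")
  part <- hcluster_average_corr(m$normalized, k)
  ids <- part$assignment
  mods <- lapply(sort(unique(ids)), function(i) sort(names(ids)[ids == i]))
  names(mods) <- paste0("M", seq_along(mods))
  structure(mods, class = "module_partition")
}

# Mean silhouette width over candidate k, on 1 - correlation distance.
pick_k_silhouette <- function(normalized) {
  n <- nrow(normalized)
  d <- correlation_distance(normalized)
  best_k <- 2; best_s <- -Inf
  for (k in 2:max(2, n - 1)) {
    a <- hcluster_average_corr(normalized, k)$assignment
    s <- mean_silhouette(d, a)
    if (s > best_s + 1e-12) { best_s <- s; best_k <- k }
  }
  best_k
}

mean_silhouette <- function(d, assignment) {
  n <- length(assignment)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- assignment == assignment[i]
    if (sum(own) == 1) { s[i] <- 0; next }
    a_i <- mean(d[i, own & seq_len(n) != i])
    b_i <- min(vapply(setdiff(unique(assignment), assignment[i]),
                      function(cl) mean(d[i, assignment == cl]), numeric(1)))
    s[i] <- (b_i - a_i) / max(a_i, b_i)
  }
  mean(s)
}

#' Assign genes to modules by the >=2-regulators rule
#'
#' A gene is regulated by a module when at least \code{min_tfs} of that
#' module's member TFs bind its promoter window (the binding map must have
#' been built with the module window, by default -2500/+2500 bp around the
#' TSS). A gene can belong to several modules; with the
#' \code{scope = "global"} reading, a gene bound by >= \code{min_tfs} TFs
#' overall is assigned to every module contributing at least one of them.
#'
#' @param bm A \code{binding_map} whose TFs all appear in the partition.
#' @param part A \code{module_partition}.
#' @param min_tfs Minimum number of binding regulators (default 2).
#' @param scope \code{"per_module"} (default) or \code{"global"}.
#' @return List of class \code{module_assignment}: gene -> character vector
#'   of module ids (genes with no module are absent).
#' @export
assign_genes <- function(bm, part, min_tfs = 2,
                         scope = c("per_module", "global")) {
  stopifnot(inherits(bm, "binding_map"), inherits(part, "module_partition"))
  scope <- match.arg(scope)
  missing_tfs <- setdiff(names(bm), unlist(part))
  if (length(missing_tfs) > 0) {
    stop("assign_genes: TF(s) absent from the partition: ",
         paste(missing_tfs, collapse = ", "))
  }
  genes <- sort(unique(unlist(bm)))
  # gene x tf incidence
  inc <- vapply(names(bm), function(tf) genes %in% bm[[tf]],
                logical(length(genes)))
  inc <- matrix(inc, nrow = length(genes),
                dimnames = list(genes, names(bm)))
  asg <- lapply(genes, function(g) {
    hits <- character(0)
    total_bound <- sum(inc[g, ])
    for (mod in names(part)) {
      tfs <- intersect(part[[mod]], colnames(inc))
      n_in_mod <- sum(inc[g, tfs])
      qualifies <- if (scope == "per_module") n_in_mod >= min_tfs
                   else total_bound >= min_tfs && n_in_mod >= 1
      if (qualifies) hits <- c(hits, mod)
    }
    hits
  })
  names(asg) <- genes
  asg <- asg[vapply(asg, length, integer(1)) > 0]
  structure(asg, class = "module_assignment")
}

module_coverage <- function(asg, genes, module_id) {
  assigned <- names(asg)[vapply(asg, function(m) module_id %in% m, logical(1))]
  length(intersect(genes, assigned)) / length(genes)
}

#' Module enrichment in upregulated versus downregulated genes
#'
#' Coverage is the fraction of a gene list assigned to the module; the
#' p-value is a one-sided hypergeometric test for over-representation of
#' the module's genes among the upregulated list; the ratio is up coverage
#' over down coverage (\code{Inf} when the module covers up genes but no
#' down gene).
#'
#' @param asg A \code{module_assignment}.
#' @param up,down,universe \code{gene_set} objects.
#' @return \code{data.frame} with columns \code{module, coverage_up,
#'   coverage_down, p_value, ratio}.
#' @export
module_updown_enrichment <- function(asg, up, down, universe) {
  stopifnot(inherits(asg, "module_assignment"))
  if (length(up$genes) == 0 || length(down$genes) == 0) {
    stop("module_updown_enrichment: empty up or down list")
  }
  modules <- sort(unique(unlist(asg)))
  N <- length(universe$genes)
  rows <- lapply(modules, function(mod) {
    assigned <- names(asg)[vapply(asg, function(m) mod %in% m, logical(1))]
    assigned <- intersect(assigned, universe$genes)
    k_up <- length(intersect(assigned, up$genes))
    k_down <- length(intersect(assigned, down$genes))
    cu <- k_up / length(up$genes)
    cd <- k_down / length(down$genes)
    p <- hypergeometric_tail(k_up, K = length(assigned),
                             n = length(up$genes), N = N)
    ratio <- if (cd == 0) { if (cu > 0) Inf else NaN } else cu / cd
    data.frame(module = mod, coverage_up = cu, coverage_down = cd,
               p_value = p, ratio = ratio, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Fold difference of module-pair co-assignment between up and down genes
#'
#' For every unordered module pair, the fraction of upregulated genes
#' assigned to both modules divided by the same fraction among
#' downregulated genes (\code{Inf} when the down fraction is zero and the
#' up fraction positive).
#'
#' @param asg A \code{module_assignment}.
#' @param up,down \code{gene_set} objects.
#' @return \code{data.frame} with columns \code{module_a, module_b,
#'   frac_up, frac_down, fold}.
#' @export
module_pair_cooccurrence <- function(asg, up, down) {
  stopifnot(inherits(asg, "module_assignment"))
  modules <- sort(unique(unlist(asg)))
  if (length(modules) < 2) stop("module_pair_cooccurrence: need >= 2 modules")
  both_frac <- function(genes, a, b) {
    hit <- vapply(genes, function(g) {
      mods <- asg[[g]]
      !is.null(mods) && a %in% mods && b %in% mods
    }, logical(1))
    mean(hit)
  }
  pairs <- utils::combn(modules, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(p) {
    a <- pairs[1, p]; b <- pairs[2, p]
    fu <- both_frac(up$genes, a, b)
    fd <- both_frac(down$genes, a, b)
    fold <- if (fd == 0) { if (fu > 0) Inf else NaN } else fu / fd
    data.frame(module_a = a, module_b = b, frac_up = fu, frac_down = fd,
               fold = fold, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Rank modules by coverage of each biological process
#'
#' For every term in the catalog, modules are ordered by the fraction of
#' the term's genes they regulate; ties break alphabetically by module id.
#'
#' @param asg A \code{module_assignment}.
#' @param processes An \code{annotation_catalog} of process terms.
#' @return \code{data.frame} with columns \code{process, module, coverage,
#'   rank}.
#' @export
rank_modules_by_process <- function(asg, processes) {
  stopifnot(inherits(asg, "module_assignment"),
            inherits(processes, "annotation_catalog"))
  modules <- sort(unique(unlist(asg)))
  rows <- lapply(names(processes$terms), function(term) {
    genes <- processes$terms[[term]]
    cov <- vapply(modules, function(mod) module_coverage(asg, genes, mod),
                  numeric(1))
    ord <- order(-cov, modules)
    data.frame(process = term, module = modules[ord], coverage = cov[ord],
               rank = seq_along(modules), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Chi-square association between a module and an external gene set
#'
#' Builds the 2x2 table of (assigned to the module) x (member of the
#' external set) over the universe and applies the chi-square test with
#' automatic Yates correction. A positive sign means the module's genes
#' are over-represented in the external set.
#'
#' @param asg A \code{module_assignment}.
#' @param module_id Module to test.
#' @param external \code{gene_set} within the universe.
#' @param universe \code{gene_set} defining the testing population.
#' @return List with \code{chi2}, \code{p_value}, \code{sign}.
#' @export
module_external_association <- function(asg, module_id, external, universe) {
  stopifnot(inherits(asg, "module_assignment"))
  if (!all(external$genes %in% universe$genes)) {
    stop("module_external_association: external set outside the universe")
  }
  assigned <- names(asg)[vapply(asg, function(m) module_id %in% m, logical(1))]
  assigned <- intersect(assigned, universe$genes)
  in_mod <- universe$genes %in% assigned
  in_ext <- universe$genes %in% external$genes
  t <- contingency_2x2(sum(in_mod & in_ext), sum(in_mod & !in_ext),
                       sum(!in_mod & in_ext), sum(!in_mod & !in_ext))
  res <- chi_square_2x2(t, yates = "auto")
  list(chi2 = res$statistic, p_value = res$p_value,
       sign = res$association_sign)
}
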