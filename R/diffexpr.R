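# Two-group microarray differential expression on linear-scale values:
# probe collapsing, pooled-variance t-test on unlogged data, signed fold
# change, DE calling, and sample-profile correlation.

#' Construct an expression matrix with sample groups
#'
#' @param values Numeric matrix of positive linear-scale intensities,
#'   rows = probes or genes, columns = samples; dimnames required.
#' @param groups Character vector per sample, values \code{"normal"} or
#'   \code{"cancer"}.
#' @param tissue Single tissue label.
#' @return Object of class \code{expression_matrix}.
#' @export
expression_matrix <- function(values, groups, tissue = "unspecified") {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("expression_matrix: values must be a numeric matrix")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("expression_matrix: row and column names are required")
  }
  if (anyDuplicated(colnames(values))) {
    stop("expression_matrix: duplicate sample ids")
  }
  if (any(values <= 0)) stop("expression_matrix: values must be positive")
  if (length(groups) != ncol(values)) {
    stop("expression_matrix: one group label per sample required")
  }
  if (!all(groups %in% c("normal", "cancer"))) {
    stop("expression_matrix: groups must be 'normal' or 'cancer'")
  }
  structure(list(values = values, groups = groups, tissue = tissue),
            class = "expression_matrix")
}

#' Collapse probes to genes by highest average intensity
#'
#' For genes measured by several probes, keeps only the probe whose mean
#' intensity across all samples is highest; on an exact tie the probe with
#' the lexicographically smallest id wins. Probes absent from the map are
#' dropped (count reported via message).
#'
#' @param m An \code{expression_matrix} with probe rows.
#' @param probe_gene_map Named character vector, names = probe ids,
#'   values = gene symbols.
#' @return An \code{expression_matrix} with one row per gene.
#' @export
collapse_probes <- function(m, probe_gene_map) {
  stopifnot(inherits(m, "expression_matrix"))
  if (length(probe_gene_map) == 0) stop("collapse_probes: empty probe map")
  probes <- rownames(m$values)
  mapped <- probes[probes %in% names(probe_gene_map)]
  n_drop <- length(probes) - length(mapped)
  if (n_drop > 0) message(n_drop, " unmapped probe(s) dropped")
  if (length(mapped) == 0) stop("collapse_probes: no probe maps to a gene")
  avg <- rowMeans(m$values[mapped, , drop = FALSE])
  genes <- unname(probe_gene_map[mapped])
  ord <- order(genes, -avg, mapped)   # per gene: highest mean, then smallest id
  keep <- mapped[ord][!duplicated(genes[ord])]
  vals <- m$values[keep, , drop = FALSE]
  rownames(vals) <- probe_gene_map[keep]
  vals <- vals[order(rownames(vals)), , drop = FALSE]
  expression_matrix(vals, m$groups, m$tissue)
}

#' Pooled-variance two-sample t-test on linear-scale values
#'
#' Classical Student's t-test (equal-variance) computed directly on unlogged
#' intensities. When the pooled variance is exactly zero the p-value is 1
#' if the group means are equal and 0 otherwise.
#'
#' @param a,b Numeric vectors, each with at least 2 values.
#' @param welch If \code{TRUE} use the Welch (unequal-variance) statistic.
#' @return Two-sided p-value.
#' @export
student_t_unlogged <- function(a, b, welch = FALSE) {
  if (length(a) < 2 || length(b) < 2) {
    stop("student_t_unlogged: each group needs at least 2 samples")
  }
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    return(if (mean(a) == mean(b)) 1 else 0)
  }
  stats::t.test(a, b, var.equal = !welch)$p.value
}

#' Signed fold change between two positive group means
#'
#' Ratio of means, negated when the cancer mean is below the normal mean,
#' so the magnitude is always >= 1 and the sign gives the direction.
#'
#' @param mean_cancer,mean_normal Positive group means.
#' @return Signed fold change; +1 when the means are equal.
#' @export
signed_fold_change <- function(mean_cancer, mean_normal) {
  if (any(c(mean_cancer, mean_normal) <= 0)) {
    stop("signed_fold_change: means must be positive")
  }
  if (mean_cancer >= mean_normal) mean_cancer / mean_normal
  else -mean_normal / mean_cancer
}

#' Differential-expression thresholds
#' @param p_max Maximum raw p-value (default 0.05).
#' @param fc_min Minimum absolute fold change, exceeded strictly
#'   (default 1.5).
#' @return List of class \code{de_thresholds}.
#' @export
de_thresholds <- function(p_max = 0.05, fc_min = 1.5) {
  if (p_max <= 0 || p_max >= 1) stop("de_thresholds: p_max must be in (0,1)")
  if (fc_min < 1) stop("de_thresholds: fc_min must be >= 1")
  structure(list(p_max = p_max, fc_min = fc_min), class = "de_thresholds")
}

# Vectorized pooled-variance t over rows; returns two-sided p-values with
# the same degenerate zero-variance rule as student_t_unlogged.
row_student_p <- function(vals, is_cancer, welch = FALSE) {
  a <- vals[, is_cancer, drop = FALSE]
  b <- vals[, !is_cancer, drop = FALSE]
  n1 <- ncol(a); n2 <- ncol(b)
  m1 <- rowMeans(a); m2 <- rowMeans(b)
  v1 <- apply(a, 1, stats::var); v2 <- apply(b, 1, stats::var)
  if (welch) {
    se2 <- v1 / n1 + v2 / n2
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  } else {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se2 <- sp2 * (1 / n1 + 1 / n2)
    df <- rep(n1 + n2 - 2, length(m1))
  }
  tstat <- (m1 - m2) / sqrt(se2)
  p <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  degen <- se2 == 0
  p[degen] <- ifelse(m1[degen] == m2[degen], 1, 0)
  p
}

#' Call differentially expressed genes per tissue
#'
#' Tests every gene with a pooled-variance Student t-test on linear-scale
#' values and computes the signed fold change of cancer over normal means.
#' A gene is called \code{up} when p < \code{p_max} and fold change > +
#' \code{fc_min} (strict), \code{down} symmetrically, otherwise \code{ns}.
#'
#' @param m A gene-level \code{expression_matrix} containing both groups.
#' @param th A \code{de_thresholds} object.
#' @param welch Use Welch's t instead of Student's.
#' @param log_scale Test on log2 values instead of the default linear scale.
#' @param adjust Multiple-testing adjustment passed to
#'   \code{\link[stats]{p.adjust}} (default \code{"none"}, matching raw-p
#'   calling).
#' @return \code{data.frame} with one row per gene: \code{gene},
#'   \code{mean_cancer}, \code{mean_normal}, \code{fold_change},
#'   \code{p_value}, \code{direction}.
#' @export
call_degs <- function(m, th = de_thresholds(), welch = FALSE,
                      log_scale = FALSE, adjust = "none") {
  stopifnot(inherits(m, "expression_matrix"), inherits(th, "de_thresholds"))
  is_cancer <- m$groups == "cancer"
  if (sum(is_cancer) < 2 || sum(!is_cancer) < 2) {
    stop("call_degs: each group needs at least 2 samples")
  }
  vals <- m$values
  test_vals <- if (log_scale) log2(vals) else vals
  p <- row_student_p(test_vals, is_cancer, welch = welch)
  p <- stats::p.adjust(p, method = adjust)
  mc <- rowMeans(vals[, is_cancer, drop = FALSE])
  mn <- rowMeans(vals[, !is_cancer, drop = FALSE])
  fc <- ifelse(mc >= mn, mc / mn, -mn / mc)
  direction <- rep("ns", nrow(vals))
  direction[p < th$p_max & fc > th$fc_min] <- "up"
  direction[p < th$p_max & fc < -th$fc_min] <- "down"
  data.frame(gene = rownames(vals), mean_cancer = mc, mean_normal = mn,
             fold_change = fc, p_value = p, direction = direction,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Extract the up- or down-regulated gene set from a DE table
#' @param degs Output of \code{\link{call_degs}}.
#' @param direction \code{"up"} or \code{"down"}.
#' @param name,tissue Metadata for the returned set.
#' @return A \code{\link{gene_set}}.
#' @export
deg_gene_set <- function(degs, direction, name = direction,
                         tissue = "unspecified") {
  gene_set(name, degs$gene[degs$direction == direction], tissue = tissue,
           direction = direction)
}

#' Correlate sample expression profiles across two matrices
#'
#' Pearson correlation between every pair of samples (one from each matrix)
#' over the intersection of their gene rows, aligned by gene id.
#'
#' @param a,b \code{expression_matrix} objects sharing at least 3 gene rows.
#' @param log2_transform Correlate on log2 values (default TRUE; expression
#'   similarity between arrays is conventionally assessed on the log scale).
#' @return Matrix of correlations, rows = samples of \code{a},
#'   columns = samples of \code{b}.
#' @export
correlate_profiles <- function(a, b, log2_transform = TRUE) {
  stopifnot(inherits(a, "expression_matrix"), inherits(b, "expression_matrix"))
  shared <- intersect(rownames(a$values), rownames(b$values))
  if (length(shared) == 0) stop("correlate_profiles: empty gene intersection")
  if (length(shared) < 3) stop("correlate_profiles: fewer than 3 shared genes")
  va <- a$values[shared, , drop = FALSE]
  vb <- b$values[shared, , drop = FALSE]
  if (log2_transform) { va <- log2(va); vb <- log2(vb) }
  stats::cor(va, vb, method = "pearson")
}
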