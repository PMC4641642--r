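# Statistical primitives shared by every pipeline stage: one-sided
# hypergeometric enrichment, Fisher's exact test, 2x2 chi-square with
# optional Yates correction, Pearson correlation, and average-linkage
# (UPGMA) clustering on correlation distance.

#' One-sided hypergeometric enrichment p-value
#'
#' Computes the upper-tail probability P(X >= k) where X is the overlap
#' between a query of size \code{n} and a category of size \code{K} drawn
#' without replacement from a universe of size \code{N}. This is the
#' standard over-representation test for gene-set overlap.
#'
#' @param k Observed overlap (non-negative integer).
#' @param K Category size in the universe.
#' @param n Query size.
#' @param N Universe size.
#' @return A p-value in (0, 1].
#' @examples
#' hypergeometric_tail(4, 5, 4, 10)
#' @export
hypergeometric_tail <- function(k, K, n, N) {
  for (v in list(k = k, K = K, n = n, N = N)) {
    if (length(v) != 1L || !is.finite(v) || v < 0 || v != round(v)) {
      stop("hypergeometric_tail: k, K, n, N must be single non-negative integers")
    }
  }
  if (K > N) stop("hypergeometric_tail: category size K exceeds universe N")
  if (n > N) stop("hypergeometric_tail: query size n exceeds universe N")
  if (k > min(K, n)) stop("hypergeometric_tail: overlap k exceeds min(K, n)")
  # P(X >= k) = P(X > k - 1)
  stats::phyper(k - 1, m = K, n = N - K, k = n, lower.tail = FALSE)
}

#' Build a validated 2x2 contingency table
#'
#' Row 1 is "condition present", row 2 "condition absent"; column 1 is
#' "in set", column 2 "out of set".
#'
#' @param a,b,c,d Non-negative integer cell counts (row-wise: a b / c d).
#' @return An object of class \code{contingency_2x2}.
#' @export
contingency_2x2 <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(!is.finite(cells)) || any(cells < 0) || any(cells != round(cells))) {
    stop("contingency_2x2: counts must be non-negative integers")
  }
  if (sum(cells) == 0) stop("contingency_2x2: total count must be positive")
  structure(list(a = a, b = b, c = c, d = d), class = "contingency_2x2")
}

as_matrix_2x2 <- function(t) {
  matrix(c(t$a, t$c, t$b, t$d), nrow = 2)
}

#' Fisher's exact test on a 2x2 table
#'
#' @param t A \code{contingency_2x2} table.
#' @param alternative \code{"greater"} (enrichment of cell a) or
#'   \code{"two_sided"}.
#' @return The exact conditional p-value.
#' @details With \code{alternative = "greater"} on the table
#'   (k, n-k; K-k, N-K-n+k) this equals
#'   \code{hypergeometric_tail(k, K, n, N)}.
#' @export
fisher_exact_2x2 <- function(t, alternative = c("greater", "two_sided")) {
  stopifnot(inherits(t, "contingency_2x2"))
  alternative <- match.arg(alternative)
  alt <- if (alternative == "two_sided") "two.sided" else "greater"
  stats::fisher.test(as_matrix_2x2(t), alternative = alt)$p.value
}

#' Chi-square test of association on a 2x2 table
#'
#' @param t A \code{contingency_2x2} table.
#' @param yates \code{"auto"} applies the continuity correction when any
#'   expected cell count is below 5; \code{"on"}/\code{"off"} force it.
#' @return List with \code{statistic}, \code{p_value} and
#'   \code{association_sign} = sign(ad - bc).
#' @details A table with a zero row or column margin carries no evidence of
#'   association; it returns statistic 0, p 1, sign 0 rather than erroring,
#'   because upstream stages may produce legitimately empty categories.
#' @export
chi_square_2x2 <- function(t, yates = c("auto", "on", "off")) {
  stopifnot(inherits(t, "contingency_2x2"))
  yates <- match.arg(yates)
  m <- as_matrix_2x2(t)
  rs <- rowSums(m); cs <- colSums(m); N <- sum(m)
  sign_assoc <- sign(t$a * t$d - t$b * t$c)
  if (any(rs == 0) || any(cs == 0)) {
    return(list(statistic = 0, p_value = 1, association_sign = 0))
  }
  expected <- outer(rs, cs) / N
  correct <- switch(yates,
    auto = any(expected < 5),
    on   = TRUE,
    off  = FALSE
  )
  res <- suppressWarnings(stats::chisq.test(m, correct = correct))
  list(statistic = unname(res$statistic),
       p_value = unname(res$p.value),
       association_sign = sign_assoc)
}

#' Pearson product-moment correlation
#'
#' @param x,y Numeric vectors of equal length (at least 3), neither constant.
#' @return Correlation coefficient in [-1, 1].
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("pearson_r: vectors must have equal length")
  if (length(x) < 3) stop("pearson_r: need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("pearson_r: correlation undefined for a constant vector")
  }
  stats::cor(x, y, method = "pearson")
}

#' Average-linkage clustering on correlation distance
#'
#' Clusters the rows of a symmetric similarity matrix. The distance between
#' two items is 1 minus the Pearson correlation of their row profiles;
#' clusters are merged by unweighted average linkage (UPGMA) and the tree is
#' cut into \code{k} groups.
#'
#' Ties in merge height are broken by the lexicographically smallest pair of
#' member labels, so the partition is deterministic and invariant to the
#' input ordering of items.
#'
#' @param m Square symmetric numeric matrix with row/column names.
#' @param k Number of clusters, between 1 and \code{nrow(m)}.
#' @return List of class \code{dendrogram_partition} with \code{labels},
#'   \code{merge_tree} (data frame of left/right/height) and
#'   \code{assignment} (named integer vector of cluster ids).
#' @export
hcluster_average_corr <- function(m, k) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) {
    stop("hcluster_average_corr: input must be a square matrix")
  }
  if (max(abs(m - t(m))) > 1e-8) {
    stop("hcluster_average_corr: input matrix is not symmetric")
  }
  n <- nrow(m)
  if (k < 1 || k > n) stop("hcluster_average_corr: k out of range [1, n]")
  labels <- rownames(m)
  if (is.null(labels)) labels <- as.character(seq_len(n))
  d <- correlation_distance(m)
  upgma_partition(d, labels, k)
}

# 1 - Pearson correlation between the row profiles of a square matrix.
# Constant rows (zero variance) get distance 1 to everything, 0 to an
# identical constant row.
correlation_distance <- function(m) {
  n <- nrow(m)
  sds <- apply(m, 1, stats::sd)
  d <- matrix(1, n, n)
  ok <- sds > 0
  if (sum(ok) >= 2) {
    cc <- suppressWarnings(stats::cor(t(m[ok, , drop = FALSE])))
    d[ok, ok] <- 1 - cc
  }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j && !ok[i] && !ok[j] && all(m[i, ] == m[j, ])) d[i, j] <- 0
  }
  diag(d) <- 0
  d
}

# UPGMA with an explicit lexicographic tie rule. Heights are rounded to
# 12 decimals before comparison so floating-point jitter from row
# permutations cannot reorder genuinely tied merges.
upgma_partition <- function(d, labels, k) {
  n <- length(labels)
  active <- seq_len(n)
  members <- as.list(seq_len(n))                 # item indices per cluster
  minlab <- labels                               # lexicographic cluster key
  sizes <- rep(1L, n)
  dist_cur <- d
  merges <- data.frame(left = character(0), right = character(0),
                       height = numeric(0), stringsAsFactors = FALSE)
  # cluster id at each merge step for cutting later
  assignment_steps <- list()
  cluster_of <- seq_len(n)
  step_assign <- list(cluster_of)

  while (length(active) > 1) {
    na <- length(active)
    best <- NULL; best_h <- Inf; best_key <- NULL
    for (ii in seq_len(na - 1)) for (jj in (ii + 1):na) {
      ci <- active[ii]; cj <- active[jj]
      h <- round(dist_cur[ci, cj], 12)
      key <- sort(c(minlab[ci], minlab[cj]))
      if (h < best_h ||
          (h == best_h && (key[1] < best_key[1] ||
            (key[1] == best_key[1] && key[2] < best_key[2])))) {
        best_h <- h; best <- c(ci, cj); best_key <- key
      }
    }
    ci <- best[1]; cj <- best[2]
    merges <- rbind(merges, data.frame(
      left = minlab[ci], right = minlab[cj], height = best_h,
      stringsAsFactors = FALSE))
    # UPGMA update: size-weighted average distance to the merged cluster
    for (co in setdiff(active, c(ci, cj))) {
      newd <- (sizes[ci] * dist_cur[ci, co] + sizes[cj] * dist_cur[cj, co]) /
        (sizes[ci] + sizes[cj])
      dist_cur[ci, co] <- newd; dist_cur[co, ci] <- newd
    }
    members[[ci]] <- c(members[[ci]], members[[cj]])
    sizes[ci] <- sizes[ci] + sizes[cj]
    minlab[ci] <- min(minlab[ci], minlab[cj])
    active <- setdiff(active, cj)
    cluster_of[members[[ci]]] <- ci
    step_assign[[length(step_assign) + 1L]] <- cluster_of
  }

  # cutting at k clusters = state after n - k merges
  state <- step_assign[[n - k + 1L]]
  # renumber clusters 1..k in order of their smallest member label
  reps <- split(seq_len(n), state)
  ord <- order(vapply(reps, function(ix) min(labels[ix]), character(1)))
  ids <- integer(n)
  for (r in seq_along(ord)) ids[reps[[ord[r]]]] <- r
  names(ids) <- labels
  structure(list(labels = labels, merge_tree = merges, k = k,
                 assignment = ids),
            class = "dendrogram_partition")
}
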