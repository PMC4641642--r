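# Strand-aware promoter windows around TSSs, TF -> bound-gene maps from
# peak intervals, and TF enrichment in up- vs down-regulated genes.
# Coordinates follow BED conventions: 0-based, half-open [start, end).

#' Promoter window specification
#' @param upstream,downstream Non-negative extents in bp relative to the
#'   TSS along the gene's strand; their sum must be positive.
#' @return List of class \code{promoter_window_spec}.
#' @export
promoter_window_spec <- function(upstream, downstream) {
  if (upstream < 0 || downstream < 0 || upstream + downstream <= 0) {
    stop("promoter_window_spec: extents must be non-negative with positive sum")
  }
  structure(list(upstream = upstream, downstream = downstream),
            class = "promoter_window_spec")
}

#' Strand-aware promoter window around a TSS
#'
#' On the + strand the window is [tss - upstream, tss + downstream); on the
#' - strand it mirrors to [tss - downstream, tss + upstream). The start is
#' clipped at 0.
#'
#' @param tss 0-based TSS position.
#' @param strand \code{"+"} or \code{"-"}.
#' @param spec A \code{promoter_window_spec}.
#' @return List with \code{start}, \code{end} (0-based half-open).
#' @export
promoter_window <- function(tss, strand, spec) {
  stopifnot(inherits(spec, "promoter_window_spec"), strand %in% c("+", "-"))
  if (strand == "+") {
    s <- tss - spec$upstream; e <- tss + spec$downstream
  } else {
    s <- tss - spec$downstream; e <- tss + spec$upstream
  }
  list(start = max(0, s), end = e)
}

# Promoter windows for a TSS annotation table as a data.frame of 0-based
# half-open intervals.
promoter_windows_table <- function(ann, spec) {
  up <- ifelse(ann$strand == "+", spec$upstream, spec$downstream)
  dn <- ifelse(ann$strand == "+", spec$downstream, spec$upstream)
  data.frame(gene = ann$gene, chrom = ann$chrom,
             start = pmax(0, ann$tss - up), end = ann$tss + dn,
             stringsAsFactors = FALSE)
}

# Overlap of two 0-based half-open interval tables by >= 1 bp, per
# chromosome, via IRanges. Returns hit index pairs (query, subject).
halfopen_overlaps <- function(q, s) {
  hits_q <- integer(0); hits_s <- integer(0)
  for (ch in intersect(unique(q$chrom), unique(s$chrom))) {
    qi <- which(q$chrom == ch); si <- which(s$chrom == ch)
    # shift to 1-based closed coordinates for IRanges
    qr <- IRanges::IRanges(start = q$start[qi] + 1L, end = q$end[qi])
    sr <- IRanges::IRanges(start = s$start[si] + 1L, end = s$end[si])
    ov <- IRanges::findOverlaps(qr, sr, minoverlap = 1L)
    hits_q <- c(hits_q, qi[S4Vectors::queryHits(ov)])
    hits_s <- c(hits_s, si[S4Vectors::subjectHits(ov)])
  }
  list(query = hits_q, subject = hits_s)
}

#' Map transcription factors to the genes whose promoters they bind
#'
#' A gene counts as bound by a TF when any of the TF's peaks overlaps the
#' gene's promoter window by at least 1 bp (half-open intervals; an
#' abutting peak does not bind). With \code{mode = "midpoint"} the peak's
#' midpoint must fall inside the window instead.
#'
#' @param peaks Named list: TF -> data.frame with \code{chrom, start, end}
#'   (0-based half-open).
#' @param ann TSS annotation data.frame with \code{gene, chrom, strand, tss}.
#' @param spec A \code{promoter_window_spec}.
#' @param mode \code{"any_overlap"} (default) or \code{"midpoint"}.
#' @return Named list of class \code{binding_map}: TF -> sorted character
#'   vector of bound genes.
#' @export
bind_tf_to_genes <- function(peaks, ann, spec, mode = c("any_overlap", "midpoint")) {
  mode <- match.arg(mode)
  stopifnot(inherits(spec, "promoter_window_spec"))
  if (anyDuplicated(ann$gene)) {
    dup <- unique(ann$gene[duplicated(ann$gene)])
    message(length(dup), " gene(s) with multiple TSS records; first kept")
    ann <- ann[!duplicated(ann$gene), , drop = FALSE]
  }
  win <- promoter_windows_table(ann, spec)
  bm <- lapply(peaks, function(pk) {
    validate_intervals(pk)
    if (mode == "midpoint") {
      mid <- floor((pk$start + pk$end) / 2)
      pk <- data.frame(chrom = pk$chrom, start = mid, end = mid + 1L)
    }
    hits <- halfopen_overlaps(pk, win)
    sort(unique(win$gene[hits$subject]))
  })
  structure(bm, class = "binding_map")
}

validate_intervals <- function(df) {
  if (!all(c("chrom", "start", "end") %in% names(df))) {
    stop("interval table must have chrom, start, end columns")
  }
  bad <- which(df$start < 0 | df$start >= df$end)
  if (length(bad) > 0) {
    stop("malformed interval at row ", bad[1], ": start=", df$start[bad[1]],
         " end=", df$end[bad[1]])
  }
  invisible(df)
}

#' Per-TF enrichment in upregulated versus downregulated genes
#'
#' For each TF: a one-sided hypergeometric p-value for over-representation
#' of its bound genes among the upregulated list, and the up/down ratio
#' (fraction of up genes bound divided by fraction of down genes bound;
#' \code{Inf} when the TF binds upregulated genes but no downregulated one).
#'
#' @param bm A \code{binding_map}.
#' @param up,down,universe \code{gene_set} objects; up and down must lie in
#'   the universe.
#' @return \code{data.frame} with columns \code{tf, n_bound, k_up, k_down,
#'   p_up, ratio}.
#' @export
tf_updown_enrichment <- function(bm, up, down, universe) {
  stopifnot(inherits(bm, "binding_map"))
  if (length(up$genes) == 0 || length(down$genes) == 0) {
    stop("tf_updown_enrichment: empty up or down list")
  }
  if (!all(up$genes %in% universe$genes) || !all(down$genes %in% universe$genes)) {
    stop("tf_updown_enrichment: up/down genes outside the universe")
  }
  N <- length(universe$genes)
  n_up <- length(up$genes); n_down <- length(down$genes)
  rows <- lapply(names(bm), function(tf) {
    bound <- intersect(bm[[tf]], universe$genes)
    k_up <- length(intersect(bound, up$genes))
    k_down <- length(intersect(bound, down$genes))
    p_up <- hypergeometric_tail(k_up, K = length(bound), n = n_up, N = N)
    fu <- k_up / n_up; fd <- k_down / n_down
    ratio <- if (fd == 0) { if (fu > 0) Inf else NaN } else fu / fd
    data.frame(tf = tf, n_bound = length(bound), k_up = k_up, k_down = k_down,
               p_up = p_up, ratio = ratio, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
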