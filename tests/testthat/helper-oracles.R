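# Independent brute-force oracles used to cross-check the implementation.

# Upper-tail hypergeometric probability from the combinatorial closed form,
# independent of phyper.
enum_hyper_tail <- function(k, K, n, N) {
  hi <- min(K, n)
  sum(vapply(k:hi, function(i) {
    choose(K, i) * choose(N - K, n - i) / choose(N, n)
  }, numeric(1)))
}

# Literal enumeration of every possible draw of n items from a universe of
# N with K marked; returns P(overlap >= k).
draw_enum_hyper_tail <- function(k, K, n, N) {
  draws <- utils::combn(N, n)
  mean(apply(draws, 2, function(d) sum(d <= K) >= k))
}

# O(n*m) all-pairs overlap of two 0-based half-open interval tables;
# returns for each query row whether it overlaps any subject row.
naive_any_overlap <- function(q, s) {
  vapply(seq_len(nrow(q)), function(i) {
    any(q$chrom[i] == s$chrom &
          q$start[i] < s$end & s$start < q$end[i])
  }, logical(1))
}

# Random interval table on a couple of chromosomes.
random_intervals <- function(n, span = 100000, max_len = 500) {
  st <- sample(0:(span - max_len), n, replace = TRUE)
  data.frame(chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
             start = st,
             end = st + sample(1:max_len, n, replace = TRUE),
             stringsAsFactors = FALSE)
}

# Partition vector (module id per TF, TF names as names) from a
# module_partition, for Rand-index comparisons.
partition_vector <- function(part) {
  v <- rep(names(part), lengths(part))
  names(v) <- unlist(part)
  v[sort(names(v))]
}

# Small random symmetric similarity matrix with unit diagonal.
random_similarity <- function(n, labels = sprintf("T%02d", seq_len(n))) {
  m <- matrix(runif(n * n), n, n)
  m <- (m + t(m)) / 2
  diag(m) <- 1
  dimnames(m) <- list(labels, labels)
  m
}
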