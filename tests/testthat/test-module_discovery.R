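# deterministic small peak builders
peak_df <- function(starts, len = 100, chrom = "chr1") {
  data.frame(chrom = chrom, start = starts, end = starts + len,
             stringsAsFactors = FALSE)
}

test_that("pairwise overlap counts match identical/disjoint cases and a naive oracle", {
  p100 <- peak_df(seq(0, by = 1000, length.out = 100))
  om <- count_pairwise_overlaps(list(a = p100, b = p100))
  expect_equal(om$raw["a", "b"], 100)
  expect_equal(unname(diag(om$raw)), c(100, 100))
  dis <- count_pairwise_overlaps(list(
    a = peak_df(seq(0, by = 1000, length.out = 10)),
    b = peak_df(seq(500, by = 1000, length.out = 10))))
  expect_equal(dis$raw["a", "b"], 0)
  set.seed(31)
  for (rep in 1:5) {
    pk <- list(x = random_intervals(300), y = random_intervals(500))
    om <- count_pairwise_overlaps(pk)
    c_xy <- sum(naive_any_overlap(pk$x, pk$y))
    c_yx <- sum(naive_any_overlap(pk$y, pk$x))
    expect_equal(om$raw["x", "y"], min(c_xy, c_yx))
    expect_equal(om$raw, t(om$raw))
  }
  expect_error(count_pairwise_overlaps(list(a = p100)), "at least 2")
  expect_error(count_pairwise_overlaps(list(a = p100, b = p100[0, ])),
               "zero peaks")
})

test_that("normalization yields the overlap coefficient (or Jaccard) in [0,1]", {
  p <- peak_df(seq(0, by = 1000, length.out = 100))
  om <- normalize_overlap(count_pairwise_overlaps(list(a = p, b = p)))
  expect_equal(om$normalized["a", "b"], 1)
  expect_equal(unname(diag(om$normalized)), c(1, 1))
  # raw 50 with sizes 100 and 400 -> coefficient 0.5
  a <- peak_df(seq(0, by = 1000, length.out = 100))
  b <- rbind(peak_df(seq(0, by = 1000, length.out = 50)),
             peak_df(seq(1e6, by = 1000, length.out = 350)))
  om2 <- normalize_overlap(count_pairwise_overlaps(list(a = a, b = b)))
  expect_equal(om2$raw["a", "b"], 50)
  expect_equal(om2$normalized["a", "b"], 0.5)
  omj <- normalize_overlap(count_pairwise_overlaps(list(a = a, b = b)),
                           method = "jaccard")
  expect_equal(omj$normalized["a", "b"], 50 / (100 + 400 - 50))
  expect_true(all(om2$normalized >= 0 & om2$normalized <= 1))
})

# a normalized overlap matrix with planted blocks, built directly
planted_overlap_matrix <- function(tfs, module_of, within = 0.9,
                                   between = 0.05, jitter = 0, seed = 1) {
  set.seed(seed)
  n <- length(tfs)
  m <- matrix(between, n, n, dimnames = list(tfs, tfs))
  for (mod in unique(module_of)) {
    ix <- which(module_of == mod)
    m[ix, ix] <- within
  }
  if (jitter > 0) {
    noise <- matrix(runif(n * n, -jitter, jitter), n, n)
    m <- matrix(pmin(1, pmax(0, m + (noise + t(noise)) / 2)), n, n,
                dimnames = dimnames(m))
  }
  diag(m) <- 1
  structure(list(raw = NULL, sizes = setNames(rep(100L, n), tfs),
                 normalized = m, normalization = "overlap_coefficient"),
            class = "overlap_matrix")
}

test_that("module discovery recovers planted blocks and is invariant to relabeling", {
  skip_if_not_installed("mclust")
  tfs <- sprintf("TF%02d", 1:12)
  truth <- rep(1:4, each = 3)
  om <- planted_overlap_matrix(tfs, truth, jitter = 0.03)
  part <- discover_modules(om, k = 4)
  expect_equal(mclust::adjustedRandIndex(partition_vector(part), truth), 1)
  # k = n gives singletons
  single <- discover_modules(om, k = 12)
  expect_true(all(lengths(single) == 1))
  # relabeled/permuted TFs give the same partition up to names
  perm <- c(5, 3, 11, 1, 8, 2, 12, 6, 9, 4, 10, 7)
  om2 <- om
  om2$normalized <- om$normalized[perm, perm]
  om2$sizes <- om$sizes[perm]
  part2 <- discover_modules(om2, k = 4)
  v1 <- partition_vector(part); v2 <- partition_vector(part2)
  expect_equal(mclust::adjustedRandIndex(v1, v2[names(v1)]), 1)
  expect_error(discover_modules(om, k = 1), "out of range")
  # silhouette-based auto-k finds the planted 4
  expect_equal(length(discover_modules(om, k = "auto")), 4)
})

test_that("gene assignment enforces the >=2-regulators-per-module rule", {
  part <- structure(list(M1 = c("tfA", "tfB", "tfC"), M2 = c("tfD", "tfE")),
                    class = "module_partition")
  bm <- structure(list(tfA = c("g1", "g4"), tfB = c("g4"),
                       tfC = c("g5"), tfD = c("g5", "g6"),
                       tfE = c("g6")),
                  class = "binding_map")
  asg <- assign_genes(bm, part, min_tfs = 2)
  # g1: 1 TF of M1 -> unassigned; g4: 2 of M1; g6: 2 of M2
  expect_null(asg$g1)
  expect_equal(asg$g4, "M1")
  expect_equal(asg$g6, "M2")
  # g5 has one TF from each module: never assigned per-module
  expect_null(asg$g5)
  # min_tfs = 1 assignments are a superset of min_tfs = 2
  asg1 <- assign_genes(bm, part, min_tfs = 1)
  for (g in names(asg)) expect_true(all(asg[[g]] %in% asg1[[g]]))
  expect_true(all(c("g1", "g5") %in% names(asg1)))
  # a gene bound by 2 TFs of M1 and 2 of M2 joins both
  bm2 <- structure(list(tfA = "gx", tfB = "gx", tfD = "gx", tfE = "gx"),
                   class = "binding_map")
  expect_equal(assign_genes(bm2, part)$gx, c("M1", "M2"))
  bm_bad <- structure(list(tfZ = "g1"), class = "binding_map")
  expect_error(assign_genes(bm_bad, part), "tfZ")
})

test_that("the hand-built BED+TSS fixture yields the pre-computed assignment table", {
  fx <- system.file("extdata", "synthetic_module_fixture",
                    package = "gyncomod")
  ann <- read_tss(file.path(fx, "tss.tsv"))
  tf_files <- list.files(fx, pattern = "^TF.\\.bed$", full.names = TRUE)
  peaks <- lapply(tf_files, read_bed)
  names(peaks) <- sub("\\.bed$", "", basename(tf_files))
  bm <- bind_tf_to_genes(peaks, ann, promoter_window_spec(2500, 2500))
  # binding map worked out by hand from the coordinates
  expect_equal(bm$TFA, c("G1", "G3", "G4"))
  expect_equal(bm$TFB, c("G1", "G4"))       # 52500 peak abuts G3's window
  expect_equal(bm$TFC, c("G1", "G5"))
  expect_equal(bm$TFD, c("G2", "G6"))
  expect_equal(bm$TFE, c("G2", "G5", "G6"))
  part <- structure(list(M1 = c("TFA", "TFB", "TFC"), M2 = c("TFD", "TFE")),
                    class = "module_partition")
  asg <- assign_genes(bm, part, min_tfs = 2)
  expect_equal(unclass(asg)[order(names(asg))],
               list(G1 = "M1", G2 = "M2", G4 = "M1", G6 = "M2"))
  # the global two-regulators reading additionally captures G5
  asg_g <- assign_genes(bm, part, min_tfs = 2, scope = "global")
  expect_equal(asg_g$G5, c("M1", "M2"))
})

test_that("module statistics compute coverages, co-occurrence folds and associations", {
  genes <- sprintf("G%03d", 1:100)
  uni <- gene_set("u", genes)
  up <- gene_set("up", genes[1:10])
  down <- gene_set("down", genes[11:20])
  asg <- structure(
    setNames(c(rep(list(c("M1", "M2")), 2),          # G001-G002: both modules
               rep(list("M1"), 8),                   # G003-G010
               rep(list("M1"), 1),                   # G011
               rep(list("M2"), 30)),                 # G012-G041
             genes[1:41]),
    class = "module_assignment")
  res <- module_updown_enrichment(asg, up, down, uni)
  r <- res[res$module == "M1", ]
  expect_equal(r$coverage_up, 1.0)      # all 10 up genes carry M1
  expect_equal(r$coverage_down, 0.1)    # only G011
  expect_equal(r$ratio, 10)
  co <- module_pair_cooccurrence(asg, up, down)
  expect_equal(co$frac_up, 0.2)         # G001, G002 of 10
  expect_equal(co$frac_down, 0)
  expect_equal(co$fold, Inf)
  # external set equal to a module's genes: strong positive association
  m2genes <- names(asg)[vapply(asg, function(m) "M2" %in% m, logical(1))]
  pos <- module_external_association(asg, "M2", gene_set("e", m2genes), uni)
  expect_equal(pos$sign, 1)
  expect_lt(pos$p_value, 0.001)
  # external set avoiding the module entirely: negative association
  neg <- module_external_association(asg, "M2",
                                     gene_set("e", genes[60:100]), uni)
  expect_equal(neg$sign, -1)
})

test_that("module ranking by process coverage orders modules with alphabetical ties", {
  asg <- structure(list(G1 = "M1", G2 = "M1", G3 = "M1", G4 = "M2"),
                   class = "module_assignment")
  cat <- annotation_catalog(
    list(cycle = c("G1", "G2", "G3", "G4", "G5"),
         death = c("G6", "G7")),
    sprintf("G%d", 1:10))
  rk <- rank_modules_by_process(asg, cat)
  cyc <- rk[rk$process == "cycle", ]
  expect_equal(cyc$module[cyc$rank == 1], "M1")
  expect_equal(cyc$coverage[cyc$rank == 1], 3 / 5)
  dth <- rk[rk$process == "death", ]
  expect_equal(dth$coverage, c(0, 0))
  expect_equal(dth$module, c("M1", "M2"))   # tie broken alphabetically
})
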