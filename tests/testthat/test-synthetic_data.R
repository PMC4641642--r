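small_cfg <- function(seed = 1, ...) {
  defaults <- list(seed = seed, n_genes = 300, peaks_per_tf = 100,
                   n_signatures = 10, signature_size = 20,
                   planted_recurrent_genes = 8, cotarget_genes = 10)
  args <- utils::modifyList(defaults, list(...))
  do.call(sim_config, args)
}

test_that("generators are pure functions of the seed", {
  e1 <- gen_expression(small_cfg(5)); e2 <- gen_expression(small_cfg(5))
  expect_identical(e1$by_tissue$cervical$probes$values,
                   e2$by_tissue$cervical$probes$values)
  expect_identical(e1$truth, e2$truth)
  e3 <- gen_expression(small_cfg(6))
  expect_false(identical(e1$by_tissue$cervical$probes$values,
                         e3$by_tissue$cervical$probes$values))
  a1 <- gen_annotation(small_cfg(5))
  cfg <- small_cfg(5)
  p1 <- gen_peaksets(cfg, a1, e1$truth); p2 <- gen_peaksets(cfg, a1, e1$truth)
  expect_identical(p1$peaks, p2$peaks)
  s1 <- gen_signatures(cfg, e1$truth); s2 <- gen_signatures(cfg, e1$truth)
  expect_identical(s1, s2)
})

test_that("annotation has unique TSSs with pairwise-disjoint module windows", {
  ann <- gen_annotation(small_cfg(1, n_genes = 100))
  expect_equal(nrow(ann), 100)
  expect_equal(anyDuplicated(ann$tss), 0)
  win <- promoter_window_spec(2500, 2500)
  starts <- ann$tss - 2500; ends <- ann$tss + 2500
  ord <- order(starts)
  expect_true(all(ends[ord][-100] <= starts[ord][-1]))
  expect_true(all(c("+", "-") %in% ann$strand))
})

test_that("expression design plants shared and tissue-specific DE genes", {
  cfg <- small_cfg(2)
  e <- gen_expression(cfg)
  n_up <- round(cfg$de_fraction_up * cfg$n_genes)
  shared <- Reduce(intersect, e$truth$up)
  expect_equal(length(e$truth$up$cervical), n_up)
  expect_equal(length(shared), round(cfg$shared_de_fraction * n_up))
  # tissue-specific planted genes do not leak across tissues
  spec_cx <- setdiff(e$truth$up$cervical, shared)
  expect_equal(length(intersect(spec_cx, e$truth$up$vulvar)), 0)
  # sample sizes follow the configured design
  m <- e$by_tissue$endometrial$genes
  expect_equal(sum(m$groups == "cancer"), 7)
  expect_equal(sum(m$groups == "normal"), 5)
  expect_true(all(m$values > 0))
})

test_that("planted effects are detectable and sensitivity grows with effect size", {
  weak <- gen_expression(small_cfg(7, effect_size = 1.3))
  strong <- gen_expression(small_cfg(7, effect_size = 3))
  sens <- function(e) {
    de <- call_degs(e$by_tissue$cervical$genes)
    called_up <- de$gene[de$direction == "up"]
    length(intersect(called_up, e$truth$up$cervical)) /
      length(e$truth$up$cervical)
  }
  expect_gt(sens(strong), sens(weak))
  expect_gte(sens(strong), 0.9)
})

test_that("peak sets realize the planted module structure and promoter bias", {
  cfg <- small_cfg(3)
  e <- gen_expression(cfg)
  ann <- gen_annotation(cfg)
  pk <- gen_peaksets(cfg, ann, e$truth)
  expect_equal(length(pk$peaks), cfg$n_tfs)
  expect_true(all(vapply(pk$peaks, nrow, integer(1)) == cfg$peaks_per_tf))
  om <- normalize_overlap(count_pairwise_overlaps(pk$peaks))
  truth_vec <- partition_vector(pk$partition)
  same <- outer(truth_vec, truth_vec, "==")
  offd <- !diag(length(truth_vec))
  within <- om$normalized[same & offd]
  between <- om$normalized[!same]
  expect_gt(min(within), 0.8)
  expect_lt(max(between), 0.2)
})

test_that("recurrent genes appear in exactly recurrence_depth signature sets", {
  cfg <- small_cfg(4)
  e <- gen_expression(cfg)
  s <- gen_signatures(cfg, e$truth)
  q <- gene_set("q", s$recurrent_genes)
  sc <- recurrence_scores(q, s$collection)
  expect_true(all(sc == cfg$recurrence_depth))
  expect_true(all(vapply(s$collection, function(x) length(x$genes),
                         integer(1)) == cfg$signature_size))
})

test_that("a bundle round-trips through the readers and matches its manifest", {
  dir <- withr::local_tempdir()
  cfg <- small_cfg(8)
  b <- gen_bundle(cfg, dir)
  expect_true(all(file.exists(file.path(dir, c(
    "sample_groups.tsv", "probe_gene_map.tsv", "tss_annotation.tsv",
    "signatures.gmt", "truth.json")))))
  gm <- read_group_map(file.path(dir, "sample_groups.tsv"))
  m <- read_expression(file.path(dir, "expression_cervical.tsv"), gm)
  expect_equal(m$values, b$expression$by_tissue$cervical$probes$values,
               tolerance = 1e-6)
  ann <- read_tss(file.path(dir, "tss_annotation.tsv"))
  expect_equal(ann, b$annotation)
  bed <- read_bed(file.path(dir, "peaks", "TF01.bed"))
  expect_equal(bed, b$peaks$peaks$TF01, ignore_attr = TRUE)
  sigs <- read_gmt(file.path(dir, "signatures.gmt"))
  expect_equal(lapply(sigs, `[[`, "genes"),
               lapply(b$signatures$collection, `[[`, "genes"))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  expect_true(all(unlist(truth$true_up) %in% ann$gene))
  expect_true(all(truth$recurrent_genes %in% ann$gene))
  # different seeds give different planted sets of the configured size
  b2 <- gen_bundle(small_cfg(9), withr::local_tempdir())
  expect_false(identical(b$truth$true_up$cervical, b2$truth$true_up$cervical))
  expect_equal(length(b2$truth$true_up$cervical),
               length(b$truth$true_up$cervical))
})

test_that("planted pair co-targeting elevates co-occurrence in upregulated genes", {
  cfg <- sim_config(seed = 12)   # default design: pairs (M1,M2) and (M3,M4)
  e <- gen_expression(cfg)
  ann <- gen_annotation(cfg)
  pk <- gen_peaksets(cfg, ann, e$truth)
  bm <- bind_tf_to_genes(pk$peaks, ann, promoter_window_spec(2500, 2500))
  asg <- assign_genes(bm, pk$partition, min_tfs = 2)
  co <- module_pair_cooccurrence(asg,
                                 gene_set("up", e$truth$up[[1]]),
                                 gene_set("down", e$truth$down[[1]]))
  key <- paste(co$module_a, co$module_b, sep = "-")
  planted <- vapply(pk$cotarget_pairs, paste, character(1), collapse = "-")
  folds <- co$fold[key %in% planted]
  expect_equal(length(folds), 2)
  expect_true(all(folds >= 2.5 - 1e-9 & folds <= 10 + 1e-9))
  # pools of non-planted pairs are disjoint, so no gene carries both labels
  expect_true(all(is.nan(co$fold[!key %in% planted])))
})
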