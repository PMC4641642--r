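# Synthetic-data generators. They produce every input the pipeline
# consumes -- per-tissue two-group expression with planted up/down genes
# partially shared across tissues, multi-probe genes, a TSS annotation on a
# synthetic chromosome, per-TF peak sets with planted co-binding modules
# biased toward upregulated promoters, and GMT signature collections with
# planted recurrent genes -- together with the ground truth that planted
# them. Every generator is a pure function of its configuration and seed.

#' Simulation configuration
#'
#' Defaults mirror a three-tissue gynecological-cancer microarray design
#' (cervical 5 cancer / 5 normal, endometrial 7 / 5, vulvar 6 / 7) with
#' multiplicative fold effects on a log-normal baseline.
#'
#' @param seed Mandatory integer seed.
#' @param n_genes Number of genes.
#' @param probe_weights Probabilities that a gene has 1, 2, ... probes.
#' @param tissues Named list: tissue -> c(n_normal, n_cancer).
#' @param de_fraction_up,de_fraction_down Fractions of genes planted up /
#'   down per tissue.
#' @param shared_de_fraction Fraction of each tissue's planted genes drawn
#'   from a pool common to all tissues.
#' @param effect_size Multiplicative fold applied to cancer means of
#'   planted genes (> 1).
#' @param noise_cv Coefficient of variation of the multiplicative
#'   log-normal noise.
#' @param n_tfs Number of transcription factors.
#' @param k_modules Number of planted co-binding modules.
#' @param peaks_per_tf Peaks per TF.
#' @param within_module_overlap,between_module_overlap Target overlap
#'   coefficients inside and across modules.
#' @param promoter_core_fraction Fraction of each module's shared core
#'   placed at promoters (the rest is shared intergenic background); keeps
#'   the per-module promoter pools disjoint and leaves headroom for the
#'   binding bias.
#' @param up_bias Multiplier on the probability that a module targets a
#'   planted-up promoter (1 = unbiased).
#' @param cotarget_pairs List of module-index pairs that co-target a shared
#'   gene pool, so module pairs co-occur on promoters the way co-operating
#'   regulator modules do; \code{list()} disables co-targeting.
#' @param cotarget_genes Number of co-targeted promoters per planted pair,
#'   taken out of each participating module's intergenic core so peak
#'   counts and overlap targets are preserved.
#' @param n_signatures,signature_size Size of the signature collection.
#' @param planted_recurrent_genes,recurrence_depth Number of genes planted
#'   as recurrent, and in how many sets each is inserted.
#' @return List of class \code{sim_config}.
#' @export
sim_config <- function(seed,
                       n_genes = 2000,
                       probe_weights = c(0.6, 0.3, 0.1),
                       tissues = list(cervical = c(n_normal = 5, n_cancer = 5),
                                      endometrial = c(n_normal = 5, n_cancer = 7),
                                      vulvar = c(n_normal = 7, n_cancer = 6)),
                       de_fraction_up = 0.05,
                       de_fraction_down = 0.05,
                       shared_de_fraction = 0.3,
                       effect_size = 3,
                       noise_cv = 0.2,
                       n_tfs = 12,
                       k_modules = 4,
                       peaks_per_tf = 500,
                       within_module_overlap = 0.9,
                       between_module_overlap = 0.05,
                       promoter_core_fraction = 0.3,
                       up_bias = 3,
                       cotarget_pairs = list(c(1, 2), c(3, 4)),
                       cotarget_genes = 44,
                       n_signatures = 10,
                       signature_size = 50,
                       planted_recurrent_genes = 20,
                       recurrence_depth = 7) {
  if (missing(seed)) stop("sim_config: seed is mandatory")
  fr <- c(de_fraction_up, de_fraction_down, shared_de_fraction,
          within_module_overlap, between_module_overlap)
  if (any(fr < 0 | fr > 1)) stop("sim_config: fractions must lie in [0, 1]")
  if (effect_size <= 1) stop("sim_config: effect_size must exceed 1")
  if (de_fraction_up + de_fraction_down > 1) {
    stop("sim_config: up and down fractions exceed the gene count")
  }
  cfg <- list(seed = seed, n_genes = n_genes, probe_weights = probe_weights,
              tissues = tissues, de_fraction_up = de_fraction_up,
              de_fraction_down = de_fraction_down,
              shared_de_fraction = shared_de_fraction,
              effect_size = effect_size, noise_cv = noise_cv,
              n_tfs = n_tfs, k_modules = k_modules,
              peaks_per_tf = peaks_per_tf,
              within_module_overlap = within_module_overlap,
              between_module_overlap = between_module_overlap,
              promoter_core_fraction = promoter_core_fraction,
              up_bias = up_bias, cotarget_pairs = cotarget_pairs,
              cotarget_genes = cotarget_genes,
              n_signatures = n_signatures,
              signature_size = signature_size,
              planted_recurrent_genes = planted_recurrent_genes,
              recurrence_depth = recurrence_depth)
  structure(cfg, class = "sim_config")
}

gene_ids <- function(n) sprintf("G%05d", seq_len(n))

# log-normal noise multiplier with the configured coefficient of variation
ln_noise <- function(n, cv) {
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Generate per-tissue expression matrices with planted DE genes
#'
#' Each gene gets a log-normal baseline mean; planted up (down) genes have
#' the cancer group mean multiplied (divided) by the effect size; values
#' carry multiplicative log-normal noise. A configured fraction of each
#' tissue's planted genes comes from a pool shared across all tissues.
#' Probe-level matrices are derived by splitting genes over 1..3 probes
#' with probe-specific affinities.
#'
#' @param cfg A \code{sim_config}.
#' @return List with \code{by_tissue} (tissue -> list of \code{genes} and
#'   \code{probes} expression matrices), \code{probe_map} (probe -> gene),
#'   and \code{truth} (per-tissue planted up/down genes).
#' @export
gen_expression <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  genes <- gene_ids(cfg$n_genes)
  baseline <- stats::rlnorm(cfg$n_genes, meanlog = 6, sdlog = 1)
  names(baseline) <- genes

  n_up <- round(cfg$de_fraction_up * cfg$n_genes)
  n_down <- round(cfg$de_fraction_down * cfg$n_genes)
  n_shared_up <- round(cfg$shared_de_fraction * n_up)
  n_shared_down <- round(cfg$shared_de_fraction * n_down)
  pool <- sample(genes)                       # random order, then carve
  shared_up <- sort(pool[seq_len(n_shared_up)])
  shared_down <- sort(pool[n_shared_up + seq_len(n_shared_down)])
  avail <- pool[-(seq_len(n_shared_up + n_shared_down))]

  truth <- list(up = list(), down = list())
  by_tissue <- list()

  # probe structure shared across tissues
  n_probes <- sample(seq_along(cfg$probe_weights), cfg$n_genes,
                     replace = TRUE, prob = cfg$probe_weights)
  probe_map <- character(0)
  for (i in seq_len(cfg$n_genes)) {
    ids <- paste0(genes[i], "_P", seq_len(n_probes[i]))
    pm <- rep(genes[i], n_probes[i]); names(pm) <- ids
    probe_map <- c(probe_map, pm)
  }
  affinity <- stats::rlnorm(length(probe_map), meanlog = 0, sdlog = 0.4)
  names(affinity) <- names(probe_map)

  for (tt in names(cfg$tissues)) {
    n_spec_up <- n_up - n_shared_up
    n_spec_down <- n_down - n_shared_down
    spec <- if (n_spec_up + n_spec_down > 0) {
      picked <- sample(avail, n_spec_up + n_spec_down)
      avail <- setdiff(avail, picked)
      picked
    } else character(0)
    up_g <- sort(c(shared_up, spec[seq_len(n_spec_up)]))
    down_g <- sort(c(shared_down, spec[n_spec_up + seq_len(n_spec_down)]))
    truth$up[[tt]] <- up_g
    truth$down[[tt]] <- down_g

    nn <- cfg$tissues[[tt]][["n_normal"]]
    nc <- cfg$tissues[[tt]][["n_cancer"]]
    sample_ids <- c(paste0(tt, "_N", seq_len(nn)), paste0(tt, "_C", seq_len(nc)))
    groups <- c(rep("normal", nn), rep("cancer", nc))
    mu <- matrix(baseline, nrow = cfg$n_genes, ncol = nn + nc,
                 dimnames = list(genes, sample_ids))
    mu[up_g, groups == "cancer"] <- mu[up_g, groups == "cancer"] * cfg$effect_size
    mu[down_g, groups == "cancer"] <- mu[down_g, groups == "cancer"] / cfg$effect_size
    vals <- mu * matrix(ln_noise(length(mu), cfg$noise_cv), nrow = nrow(mu))
    gm <- expression_matrix(vals, groups, tissue = tt)

    pvals <- vals[probe_map, , drop = FALSE] * affinity *
      matrix(ln_noise(length(probe_map) * ncol(vals), cfg$noise_cv / 2),
             nrow = length(probe_map))
    rownames(pvals) <- names(probe_map)
    pm_mat <- expression_matrix(pvals, groups, tissue = tt)
    by_tissue[[tt]] <- list(genes = gm, probes = pm_mat)
  }
  list(by_tissue = by_tissue, probe_map = probe_map, truth = truth)
}

#' Generate a TSS annotation on a synthetic chromosome
#'
#' Genes are evenly spaced (6 kb apart) on one chromosome with alternating
#' strands, so +/-2500 bp promoter windows are pairwise disjoint with 1 kb
#' intergenic gaps available for background peaks.
#'
#' @param cfg A \code{sim_config}.
#' @return \code{data.frame} with \code{gene, chrom, strand, tss}.
#' @export
gen_annotation <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  genes <- gene_ids(cfg$n_genes)
  data.frame(gene = genes, chrom = "chrS",
             strand = rep(c("+", "-"), length.out = cfg$n_genes),
             tss = 5000 + (seq_len(cfg$n_genes) - 1L) * 6000L,
             stringsAsFactors = FALSE)
}

#' Generate per-TF peak sets with planted co-binding modules
#'
#' TFs are split into \code{k_modules} modules. Each TF's peaks are the
#' union of (i) a module core -- identical peaks at promoters of genes
#' sampled with weight \code{up_bias} for planted-up genes -- shared by all
#' module members, (ii) a small global core of intergenic peaks shared by
#' every TF (setting the between-module overlap), and (iii) TF-specific
#' intergenic background. The within-module overlap coefficient therefore
#' targets \code{within_module_overlap} and the between-module one
#' \code{between_module_overlap}.
#'
#' @param cfg A \code{sim_config}.
#' @param ann Annotation from \code{\link{gen_annotation}}.
#' @param truth Truth list from \code{\link{gen_expression}}; planted-up
#'   genes of the first tissue receive the binding bias.
#' @return List with \code{peaks} (TF -> interval data.frame),
#'   \code{partition} (planted \code{module_partition}) and
#'   \code{up_biased_tfs}.
#' @export
gen_peaksets <- function(cfg, ann, truth) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 1L)
  tfs <- sprintf("TF%02d", seq_len(cfg$n_tfs))
  module_of <- sort(rep(seq_len(cfg$k_modules), length.out = cfg$n_tfs))
  part <- lapply(seq_len(cfg$k_modules), function(m) tfs[module_of == m])
  names(part) <- paste0("M", seq_len(cfg$k_modules))

  n_between <- round(cfg$between_module_overlap * cfg$peaks_per_tf)
  n_core <- round(cfg$within_module_overlap * cfg$peaks_per_tf) - n_between
  n_prom <- round(cfg$promoter_core_fraction * n_core)
  n_igc <- n_core - n_prom                 # intergenic part of a module core
  n_unique <- cfg$peaks_per_tf - n_core - n_between
  if (n_prom * cfg$k_modules > cfg$n_genes) {
    stop("gen_peaksets: too few genes for disjoint module promoter pools")
  }

  up_genes <- truth$up[[1]]
  down_genes <- truth$down[[1]]

  # planted pair co-targeting: a shared promoter pool per configured module
  # pair, carved out of each participating module's intergenic core. Pools
  # are reserved before the module cores are drawn and stratified by
  # planted class with the class counts a weighted draw gives in
  # expectation, so the planted co-occurrence fold sits near up_bias.
  pairs <- Filter(function(p) cfg$cotarget_genes > 0 &&
                    all(p <= cfg$k_modules), cfg$cotarget_pairs)
  cot_load <- vapply(seq_len(cfg$k_modules), function(m) {
    sum(vapply(pairs, function(p) m %in% p, logical(1))) * cfg$cotarget_genes
  }, numeric(1))
  if (any(cot_load > n_igc)) {
    stop("gen_peaksets: co-target load exceeds the intergenic module core")
  }
  free_genes <- ann$gene
  cot_pools <- lapply(pairs, function(p) {
    U <- intersect(free_genes, up_genes)
    D <- intersect(free_genes, down_genes)
    B <- setdiff(free_genes, c(U, D))
    wsum <- cfg$up_bias * length(U) + length(D) + length(B)
    n_up <- min(length(U),
                round(cfg$cotarget_genes * cfg$up_bias * length(U) / wsum))
    n_down <- min(length(D), round(cfg$cotarget_genes * length(D) / wsum))
    pool <- c(sample(U, n_up), sample(D, n_down),
              sample(B, cfg$cotarget_genes - n_up - n_down))
    free_genes <<- setdiff(free_genes, pool)
    pool
  })

  # disjoint promoter target pools for the module cores: one joint weighted
  # sample (planted-up genes weighted by up_bias) over the remaining genes,
  # dealt round-robin across modules by planted class so every module
  # carries the same planted bias
  w <- ifelse(free_genes %in% up_genes, cfg$up_bias, 1)
  picked <- sample(free_genes, n_prom * cfg$k_modules, prob = w)
  cls <- ifelse(picked %in% up_genes, 1L,
                ifelse(picked %in% down_genes, 2L, 3L))
  dealt <- c(sample(picked[cls == 1L]), sample(picked[cls == 2L]),
             sample(picked[cls == 3L]))
  module_targets <- split(dealt, rep_len(seq_len(cfg$k_modules), length(dealt)))

  # intergenic slots: each 1 kb gap after a module window holds two
  # non-overlapping 200 bp peak slots; slots are allocated globally without
  # replacement so distinct cores/backgrounds never collide
  n_slots_needed <- sum(n_igc - cot_load) + n_between + cfg$n_tfs * n_unique
  if (n_slots_needed > 2 * cfg$n_genes) {
    stop("gen_peaksets: too few intergenic slots; increase n_genes")
  }
  gap_start <- ann$tss + 2500L
  slot_ids <- sample(seq_len(2L * cfg$n_genes), n_slots_needed)
  slot_peak <- function(ids) {
    g <- (ids - 1L) %/% 2L + 1L
    sub <- (ids - 1L) %% 2L
    st <- gap_start[g] + 400L * sub + sample(0:100, length(ids), replace = TRUE)
    data.frame(chrom = "chrS", start = st, end = st + 200L,
               stringsAsFactors = FALSE)
  }
  take <- function(n) {
    ids <- slot_ids[seq_len(n)]
    slot_ids <<- slot_ids[-seq_len(n)]
    slot_peak(ids)
  }
  module_igc <- lapply(seq_len(cfg$k_modules),
                       function(m) take(n_igc - cot_load[m]))
  global_core <- take(n_between)
  promoter_peak <- function(genes_sel) {
    ix <- match(genes_sel, ann$gene)
    data.frame(chrom = "chrS", start = ann$tss[ix] - 250L,
               end = ann$tss[ix] + 250L, stringsAsFactors = FALSE)
  }
  peaks <- lapply(seq_len(cfg$n_tfs), function(i) {
    m <- module_of[i]
    cot <- unlist(cot_pools[vapply(pairs, function(p) m %in% p, logical(1))])
    pk <- rbind(promoter_peak(c(module_targets[[m]], cot)),
                module_igc[[m]],
                global_core,
                take(n_unique))
    row.names(pk) <- NULL
    pk[order(pk$start), , drop = FALSE]
  })
  names(peaks) <- tfs
  list(peaks = peaks,
       partition = structure(part, class = "module_partition"),
       up_biased_tfs = if (cfg$up_bias > 1) tfs else character(0),
       cotarget_pairs = lapply(pairs, function(p) paste0("M", p)),
       cotarget_pools = cot_pools)
}

#' Generate a GMT-style signature collection with planted recurrent genes
#'
#' Sets are sampled uniformly from the gene pool; each planted recurrent
#' gene is inserted into \code{recurrence_depth} sets. Tissue tags rotate
#' over a fixed panel of cancer types.
#'
#' @param cfg A \code{sim_config}.
#' @param truth Truth list; planted recurrent genes are drawn from the
#'   first tissue's planted-up genes when enough exist, else from all genes.
#' @return List with \code{collection} (list of \code{gene_set}) and
#'   \code{recurrent_genes}.
#' @export
gen_signatures <- function(cfg, truth = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 2L)
  genes <- gene_ids(cfg$n_genes)
  cand <- if (!is.null(truth) &&
              length(truth$up[[1]]) >= cfg$planted_recurrent_genes) {
    truth$up[[1]]
  } else genes
  recurrent <- sort(sample(cand, cfg$planted_recurrent_genes))
  tissue_panel <- c("breast", "lung", "prostate", "colorectal", "pancreatic")
  sets <- lapply(seq_len(cfg$n_signatures), function(i) {
    base <- sample(setdiff(genes, recurrent), cfg$signature_size)
    gene_set(sprintf("SIG%02d", i), base,
             tissue = tissue_panel[(i - 1) %% length(tissue_panel) + 1],
             study = sprintf("study%02d", i))
  })
  slots <- lapply(recurrent, function(g) {
    sample(cfg$n_signatures, cfg$recurrence_depth)
  })
  for (j in seq_along(recurrent)) {
    for (s in slots[[j]]) {
      # replace one background gene to keep the set size fixed
      bg <- setdiff(sets[[s]]$genes, recurrent)
      sets[[s]]$genes <- sort(c(setdiff(sets[[s]]$genes, bg[1]), recurrent[j]))
    }
  }
  # keep background genes strictly below the planted recurrence depth so the
  # planted genes are the only ones recoverable at the matching threshold
  cap <- max(1, cfg$recurrence_depth - 2)
  repeat {
    bg_counts <- table(unlist(lapply(sets, function(s) {
      setdiff(s$genes, recurrent)
    })))
    over <- names(bg_counts)[bg_counts > cap]
    if (length(over) == 0) break
    for (g in over) {
      holders <- which(vapply(sets, function(s) g %in% s$genes, logical(1)))
      for (s in holders[-seq_len(cap)]) {
        spare <- setdiff(genes, c(recurrent, sets[[s]]$genes,
                                  names(bg_counts)[bg_counts >= cap]))
        sets[[s]]$genes <- sort(c(setdiff(sets[[s]]$genes, g),
                                  sample(spare, 1)))
      }
    }
  }
  list(collection = sets, recurrent_genes = recurrent)
}

#' Generate a complete input bundle on disk
#'
#' Writes per-tissue probe-level expression TSVs, a sample group map, the
#' probe-to-gene map, the TSS annotation, one BED file per TF, the GMT
#' signature collection, and a JSON truth manifest, so the whole pipeline
#' can run from the directory with no other inputs.
#'
#' @param cfg A \code{sim_config}.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the list of generated objects (expression, peaks,
#'   signatures, annotation, truth).
#' @export
gen_bundle <- function(cfg, dir) {
  stopifnot(inherits(cfg, "sim_config"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  expr <- gen_expression(cfg)
  ann <- gen_annotation(cfg)
  pk <- gen_peaksets(cfg, ann, expr$truth)
  sig <- gen_signatures(cfg, expr$truth)

  groups <- do.call(rbind, lapply(names(expr$by_tissue), function(tt) {
    m <- expr$by_tissue[[tt]]$probes
    data.frame(sample_id = colnames(m$values), group = m$groups, tissue = tt,
               stringsAsFactors = FALSE)
  }))
  for (tt in names(expr$by_tissue)) {
    write_expression(expr$by_tissue[[tt]]$probes,
                     file.path(dir, paste0("expression_", tt, ".tsv")))
  }
  utils::write.table(groups, file.path(dir, "sample_groups.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(probe = names(expr$probe_map), gene = unname(expr$probe_map)),
    file.path(dir, "probe_gene_map.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(ann, file.path(dir, "tss_annotation.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  dir.create(file.path(dir, "peaks"), showWarnings = FALSE)
  for (tf in names(pk$peaks)) {
    write_bed(pk$peaks[[tf]], file.path(dir, "peaks", paste0(tf, ".bed")))
  }
  write_gmt(sig$collection, file.path(dir, "signatures.gmt"))
  manifest <- list(
    seed = cfg$seed,
    true_up = expr$truth$up,
    true_down = expr$truth$down,
    true_partition = lapply(pk$partition, identity),
    up_biased_tfs = pk$up_biased_tfs,
    recurrent_genes = sig$recurrent_genes)
  jsonlite::write_json(manifest, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(expression = expr, annotation = ann, peaks = pk,
                 signatures = sig, truth = manifest))
}
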