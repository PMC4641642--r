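#!/usr/bin/env Rscript
# Per-tissue differential expression: collapse probes to genes (highest
# average intensity), test cancer vs normal with an unlogged pooled t-test,
# and call genes at p < 0.05 with |fold change| > 1.5. Then count the
# cross-tissue overlap of the up- and down-regulated lists.

suppressMessages(library(gyncomod))

bundle <- file.path("results", "bundle")
group_map <- read_group_map(file.path(bundle, "sample_groups.tsv"))
pm <- read.table(file.path(bundle, "probe_gene_map.tsv"), header = TRUE,
                 sep = "\t", stringsAsFactors = FALSE)
probe_map <- setNames(pm$gene, pm$probe)

up_sets <- list(); down_sets <- list()
for (path in list.files(bundle, pattern = "^expression_.*\\.tsv$",
                        full.names = TRUE)) {
  m <- read_expression(path, group_map)
  gm <- suppressMessages(collapse_probes(m, probe_map))
  de <- call_degs(gm, de_thresholds(p_max = 0.05, fc_min = 1.5))
  write_table(de, file.path("results", paste0("degs_", m$tissue, ".tsv")))
  n_up <- sum(de$direction == "up"); n_down <- sum(de$direction == "down")
  cat(sprintf("%-12s %4d up  %4d down  of %d genes\n",
              m$tissue, n_up, n_down, nrow(de)))
  up_sets[[m$tissue]] <- deg_gene_set(de, "up", m$tissue, tissue = m$tissue)
  down_sets[[m$tissue]] <- deg_gene_set(de, "down", m$tissue, tissue = m$tissue)
}

vu <- venn_counts(unname(up_sets))
vd <- venn_counts(unname(down_sets))
write_table(data.frame(direction = rep(c("up", "down"),
                                       c(length(vu$regions), length(vd$regions))),
                       region = c(names(vu$regions), names(vd$regions)),
                       count = c(vu$regions, vd$regions)),
            file.path("results", "venn_regions.tsv"))
cat("genes up in all three tissues:", length(vu$common), "\n")
cat("genes down in all three tissues:", length(vd$common), "\n")
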