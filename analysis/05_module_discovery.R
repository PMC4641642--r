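#!/usr/bin/env Rscript
# Module discovery: count pairwise peak overlaps between TFs, normalize by
# peak-set size (overlap coefficient), cluster with average linkage on
# correlation distance into k = 4 modules, assign genes bound by at least
# two of a module's regulators in the -2500/+2500 bp window, and compute
# module enrichment, pair co-occurrence and module-module association.

suppressMessages(library(gyncomod))

bundle <- file.path("results", "bundle")
ann <- read_tss(file.path(bundle, "tss_annotation.tsv"))
bed_paths <- list.files(file.path(bundle, "peaks"), pattern = "\\.bed$",
                        full.names = TRUE)
peaks <- lapply(bed_paths, read_bed)
names(peaks) <- sub("\\.bed$", "", basename(bed_paths))

om <- normalize_overlap(count_pairwise_overlaps(peaks),
                        method = "overlap_coefficient")
part <- discover_modules(om, k = 4)
write_table(data.frame(tf = unlist(part),
                       module = rep(names(part), lengths(part))),
            file.path("results", "module_partition.tsv"))
cat("modules:\n")
for (m in names(part)) cat(" ", m, ":", paste(part[[m]], collapse = " "), "\n")

bm <- bind_tf_to_genes(peaks, ann, promoter_window_spec(2500, 2500))
asg <- assign_genes(bm, part, min_tfs = 2)
write_table(data.frame(gene = names(asg),
                       modules = vapply(asg, paste, character(1),
                                        collapse = ";")),
            file.path("results", "module_assignment.tsv"))

de <- read.table(file.path("results", "degs_cervical.tsv"), header = TRUE,
                 sep = "\t", stringsAsFactors = FALSE)
up <- gene_set("up", de$gene[de$direction == "up"])
down <- gene_set("down", de$gene[de$direction == "down"])
universe <- gene_set("universe", ann$gene)

enr <- module_updown_enrichment(asg, up, down, universe)
write_table(enr, file.path("results", "module_updown.tsv"))
cat("\nmodule enrichment in upregulated genes:\n")
print(enr, row.names = FALSE)

co <- module_pair_cooccurrence(asg, up, down)
write_table(co, file.path("results", "module_cooccurrence.tsv"))
fin <- co$fold[is.finite(co$fold)]
if (length(fin)) {
  cat(sprintf("\npair co-occurrence fold (up vs down), co-targeting pairs: %s\n",
              paste(sprintf("%.1f", sort(fin, decreasing = TRUE)),
                    collapse = ", ")))
}

# association between each module pair: is membership of one module's gene
# set over- or under-represented in another's?
assoc <- do.call(rbind, lapply(names(part), function(a) {
  do.call(rbind, lapply(setdiff(names(part), a), function(b) {
    b_genes <- names(asg)[vapply(asg, function(m) b %in% m, logical(1))]
    r <- module_external_association(asg, a, gene_set(b, b_genes), universe)
    data.frame(module = a, external = b, chi2 = r$chi2, p_value = r$p_value,
               sign = r$sign)
  }))
}))
write_table(assoc, file.path("results", "module_associations.tsv"))
cat("\nsignificant module-module associations (chi-square, p < 0.05):\n")
sig <- assoc[assoc$p_value < 0.05, ]
for (i in seq_len(nrow(sig))) {
  cat(sprintf("  %s ~ %s: %s (chi2 = %.1f, p = %.2g)\n",
              sig$module[i], sig$external[i],
              ifelse(sig$sign[i] > 0, "positive", "negative"),
              sig$chi2[i], sig$p_value[i]))
}
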