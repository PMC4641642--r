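#!/usr/bin/env Rscript
# Promoter binding of each TF (peaks overlapping the -1000/+200 bp window
# around the TSS) and enrichment of every TF's targets among upregulated
# versus downregulated cervical genes.

suppressMessages(library(gyncomod))

bundle <- file.path("results", "bundle")
ann <- read_tss(file.path(bundle, "tss_annotation.tsv"))
bed_paths <- list.files(file.path(bundle, "peaks"), pattern = "\\.bed$",
                        full.names = TRUE)
peaks <- lapply(bed_paths, read_bed)
names(peaks) <- sub("\\.bed$", "", basename(bed_paths))

de <- read.table(file.path("results", "degs_cervical.tsv"), header = TRUE,
                 sep = "\t", stringsAsFactors = FALSE)
up <- gene_set("up", de$gene[de$direction == "up"])
down <- gene_set("down", de$gene[de$direction == "down"])
universe <- gene_set("universe", ann$gene)

bm <- bind_tf_to_genes(peaks, ann, promoter_window_spec(1000, 200))
enr <- tf_updown_enrichment(bm, up, down, universe)
write_table(enr, file.path("results", "tf_updown_enrichment.tsv"))

cat("TFs tested:", nrow(enr), "\n")
cat("enriched in upregulated genes (p < 0.05):", sum(enr$p_up < 0.05), "\n")
fin <- enr$ratio[is.finite(enr$ratio)]
cat(sprintf("up/down ratio range: %.2f to %.2f (median %.2f)\n",
            min(fin), max(fin), median(fin)))
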