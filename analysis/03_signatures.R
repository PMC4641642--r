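#!/usr/bin/env Rscript
# Compare the cervical upregulated list against the signature collection:
# tissue-merged overlap tests (pass = more than 5 genes in common at
# p < 0.01), per-gene recurrence scores, and the robust signature of genes
# recurring in more than five studies.

suppressMessages(library(gyncomod))

bundle <- file.path("results", "bundle")
de <- read.table(file.path("results", "degs_cervical.tsv"), header = TRUE,
                 sep = "\t", stringsAsFactors = FALSE)
up <- gene_set("cervical_up", de$gene[de$direction == "up"],
               tissue = "cervical")
signatures <- read_gmt(file.path(bundle, "signatures.gmt"))
universe_n <- nrow(de)

merged <- merge_signatures_by_tissue(signatures)
overlaps <- do.call(rbind, lapply(merged, function(s) {
  r <- signature_overlap_test(up, s, universe_n,
                              min_common = 6, p_max = 0.01)
  data.frame(signature = s$name, n_common = r$n_common,
             p_value = r$p_value, pass = r$pass)
}))
write_table(overlaps, file.path("results", "signature_overlaps.tsv"))
cat("tissue-merged signatures tested:", nrow(overlaps),
    "| passing the >5-genes & p<0.01 rule:", sum(overlaps$pass), "\n")

scores <- recurrence_scores(up, signatures)
write_table(data.frame(gene = names(scores), n_studies = unname(scores)),
            file.path("results", "recurrence_scores.tsv"))
robust <- robust_signature(scores, min_studies = 6)
n_rob <- if (is.null(robust)) 0 else length(robust$genes)
write_table(data.frame(gene = if (n_rob) robust$genes else character(0)),
            file.path("results", "robust_signature.tsv"))
cat("genes recurring in more than five signature sets:", n_rob, "\n")
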