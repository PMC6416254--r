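#!/usr/bin/env Rscript
# Q-type agglomerative clustering (squared Euclidean, between-groups
# linkage) of the scales on the selected variables; compares k = 7, 8, 9
# and cuts at k = 8, the scheme retained against the fossil evidence.

suppressPackageStartupMessages(library(scalemorph))

tab <- read_measurement_table("results/synthetic_scales.csv")
sel <- select_variables(tab, threshold = 0.90)

cmp <- compare_k(tab, sel$kept, ks = c(7, 8, 9))
cat("Candidate group counts:\n")
print(cmp$diagnostics, row.names = FALSE)
write.csv(cmp$diagnostics, "results/k_diagnostics.csv", row.names = FALSE)
write.csv(data.frame(scale_id = rownames(cmp$scores), cmp$scores),
          "results/pca_scores.csv", row.names = FALSE)

part <- cmp$partitions[["8"]]
print(part)
write.csv(data.frame(scale_id = names(part$labels), group = part$labels),
          "results/partition_k8.csv", row.names = FALSE)
cat("Group sizes at k = 8:",
    paste(sort(tabulate(part$labels, 8), decreasing = TRUE), collapse = "/"),
    "\n")
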