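#!/usr/bin/env Rscript
# Unsupervised structure of splicing-factor expression: covariance PCA and
# complete-linkage hierarchical clustering of samples, with the TIN-group
# separation score along PC1/PC2.

suppressMessages(library(tinscope))

expr <- read_matrix_tsv("results/strong_expr.tsv")
tin <- utils::read.delim("results/strong_tin.tsv")
class(tin) <- c("tin_profile", "data.frame")
sets <- read_gmt("results/sim/strong_genesets.gmt")
sf_expr <- expr[intersect(sets$SPLICING_FACTORS$genes, rownames(expr)), ]

pca <- pca_covariance(sf_expr)
message(sprintf("PC1/PC2 explain %.0f%% / %.0f%% of splicing-factor variance",
                100 * pca$variance_fraction[1],
                100 * pca$variance_fraction[2]))
sep <- tryCatch(tin_separation(pca, tin), error = function(e) {
  message(conditionMessage(e)); NA_real_
})
message(sprintf("TIN-group separation along PC1/PC2: %.3f", sep))

hc <- hierarchical_clustering(sf_expr)
# are TIN-samples concentrated in one arm of the top split?
top_split <- stats::cutree(hc, k = 2)
tab <- table(top_split, tin$is_tin_sample[match(names(top_split),
                                                tin$sample_id)])
message("top dendrogram split vs TIN-sample status:")
print(tab)

scores <- pca$scores[, 1:2]
utils::write.table(
  data.frame(sample_id = tin$sample_id, scores,
             tin_estimate = tin$tin_estimate,
             is_tin_sample = tin$is_tin_sample),
  "results/strong_pca_scores.tsv", sep = "\t", quote = FALSE,
  row.names = FALSE)
utils::write.table(
  data.frame(merge_a = hc$merge[, 1], merge_b = hc$merge[, 2],
             height = hc$height),
  "results/strong_cluster_merges.tsv", sep = "\t", quote = FALSE,
  row.names = FALSE)
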