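#!/usr/bin/env Rscript
# Association between TIN-estimates and splicing-factor expression, tested
# against the two resampling nulls (1,000 permutations of the TIN vector;
# 1,000 random gene sets of matched size), for the strong-coupling and the
# null dataset alike.

suppressMessages(library(tinscope))

for (prefix in c("strong", "null")) {
  expr <- read_matrix_tsv(file.path("results", paste0(prefix, "_expr.tsv")))
  tin <- utils::read.delim(file.path("results", paste0(prefix, "_tin.tsv")))
  class(tin) <- c("tin_profile", "data.frame")
  sets <- read_gmt(file.path("results/sim", paste0(prefix, "_genesets.gmt")))
  sf <- sets$SPLICING_FACTORS$genes

  rec <- correlate_genes_with_tin(expr, tin, sf)
  s <- summarize_association(rec, set_name = "SPLICING_FACTORS")
  message(sprintf(
    "[%s] %.0f%% of %d splicing factors significant (P < 0.05); %d neg / %d pos; mean significant r %.2f",
    prefix, s$pct_significant, s$n_genes_tested,
    s$n_neg_significant, s$n_pos_significant,
    ifelse(is.na(s$mean_r_significant), NA, s$mean_r_significant)))

  perm <- permutation_null(expr, tin, sf, B = 1000L, seed = 10L)
  rgs <- random_geneset_null(expr, tin, sf, B = 1000L, seed = 11L)
  message(sprintf("[%s] permutation empirical p = %.4g; random-gene-set empirical p = %.4g",
                  prefix, perm$empirical_p, rgs$empirical_p))

  utils::write.table(rec, file.path("results", paste0(prefix, "_correlations.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(summary = s,
         permutation = list(observed = perm$observed, B = perm$B,
                            empirical_p = perm$empirical_p, seed = perm$seed),
         random_genesets = list(observed = rgs$observed, B = rgs$B,
                                empirical_p = rgs$empirical_p,
                                seed = rgs$seed)),
    file.path("results", paste0(prefix, "_association.json")),
    auto_unbox = TRUE, digits = NA, dataframe = "rows")
}
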