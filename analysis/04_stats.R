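#!/usr/bin/env Rscript
# Statistical layer: Table-1 style cohort summary, three-group Kruskal-Wallis
# comparisons with Dunn post-hoc tests for the four markers (TREC, KREC, T/S,
# global perturbation), the pooled non-normal category-proportion test, and
# Pearson correlations with CD4 measures in the perinatal group.

library(immunosen)
library(jsonlite)

cohort <- read.csv("results/sim/cohort.csv")
qpcr <- read.delim("results/tables/qpcr_results.tsv")
pert <- read.delim("results/tables/perturbation_per_subject.tsv")

markers <- merge(qpcr, pert[, c("sample_id", "global_perturbation")],
                 by.x = "subject_id", by.y = "sample_id")
markers <- merge(markers, cohort, by = c("subject_id", "group"))

dir.create("results/stats", recursive = TRUE, showWarnings = FALSE)

tab1 <- summarize_table1(cohort)
write.table(tab1$continuous, "results/stats/table1_continuous.tsv",
            sep = "\t", row.names = FALSE, quote = FALSE)
write.table(tab1$tests, "results/stats/table1_tests.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

vars <- c(trec = "trec_copies_per_ml", krec = "krec_copies_per_ml",
          ts = "ts_ratio", perturbation = "global_perturbation")
comparisons <- lapply(names(vars), function(nm) {
  cmp <- compare_groups(markers[[vars[nm]]], markers$group, variable = vars[nm])
  print(cmp)
  cat("\n")
  cmp
})
names(comparisons) <- names(vars)
write_json(lapply(comparisons, function(cmp) {
  list(variable = cmp$variable, kw_h = cmp$kw_h, kw_p = cmp$kw_p,
       summary = cmp$summary, pairwise = cmp$pairwise)
}), "results/stats/group_comparisons.json", auto_unbox = TRUE, digits = NA,
  pretty = TRUE)

classes <- read.delim("results/tables/flag_matrix.tsv")  # not classes; reuse pert
# category-proportion test needs the per-(subject, trbv) classes: recompute
peaks <- parse_peak_table("results/sim/peaks.tsv")
groups <- setNames(cohort$group, cohort$subject_id)
rep_res <- analyze_repertoire(peaks, groups, seed = 1)
cat_test <- category_proportion_test(rep_res$classes, groups)
cat("Pooled non-normal fraction per subject, compared across groups:\n")
print(cat_test)
cat("\n")

ph <- markers[markers$group == "pHIVy", ]
cors <- rbind(
  cbind(pair = "TREC ~ CD4", correlate(ph$trec_copies_per_ml, ph$cd4_abs)),
  cbind(pair = "T/S ~ CD4", correlate(ph$ts_ratio, ph$cd4_abs)),
  cbind(pair = "perturbation ~ CD4/CD8",
        correlate(ph$global_perturbation, ph$cd4_cd8_ratio))
)
write.table(cors, "results/stats/correlations_pHIVy.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
cat("Correlations in the perinatal group (n =", nrow(ph), "):\n")
print(cors, row.names = FALSE)
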