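#!/usr/bin/env Rscript
# Figures: group-level marker distributions (TREC, KREC, T/S, global
# perturbation), clonality-category stacked proportions and the perinatal
# correlation panels.

library(immunosen)
suppressPackageStartupMessages(library(ggplot2))

cohort <- read.csv("results/sim/cohort.csv")
qpcr <- read.delim("results/tables/qpcr_results.tsv")
pert <- read.delim("results/tables/perturbation_per_subject.tsv")
props <- read.delim("results/tables/category_proportions.tsv")

markers <- merge(qpcr, pert[, c("sample_id", "global_perturbation")],
                 by.x = "subject_id", by.y = "sample_id")
markers <- merge(markers, cohort, by = c("subject_id", "group"))
markers$group <- factor(markers$group, levels = c("pHIVy", "npHIVy", "HC"))

dir.create("results/figures", recursive = TRUE, showWarnings = FALSE)
theme_set(theme_bw(base_size = 10))

dot <- function(var, ylab, logy = FALSE) {
  p <- ggplot(markers, aes(group, .data[[var]])) +
    geom_jitter(width = 0.15, size = 1, alpha = 0.7) +
    stat_summary(fun = median, geom = "crossbar", width = 0.4,
                 linewidth = 0.3) +
    labs(x = NULL, y = ylab)
  if (logy) p <- p + scale_y_log10()
  p
}
ggsave("results/figures/markers_by_group.pdf",
       cowplot_grid <- patchwork::wrap_plots(
         dot("trec_copies_per_ml", "TREC copies/ml", TRUE),
         dot("krec_copies_per_ml", "KREC copies/ml", TRUE),
         dot("ts_ratio", "Telomere length (T/S)"),
         dot("global_perturbation", "Global TRBV perturbation (%)"),
         ncol = 2),
       width = 7, height = 6)

props$group <- rownames(props)
long <- reshape(props, direction = "long",
                varying = list(setdiff(names(props), "group")),
                v.names = "pct", timevar = "class",
                times = setdiff(names(props), "group"))
ggsave("results/figures/category_proportions.pdf",
       ggplot(long, aes(group, pct, fill = class)) +
         geom_col() + labs(x = NULL, y = "% of subject x TRBV units"),
       width = 5, height = 4)

ph <- markers[markers$group == "pHIVy", ]
ggsave("results/figures/correlations_pHIVy.pdf",
       patchwork::wrap_plots(
         ggplot(ph, aes(cd4_abs, trec_copies_per_ml)) + geom_point() +
           geom_smooth(method = "lm", formula = y ~ x, se = FALSE) +
           labs(x = "CD4/ul", y = "TREC copies/ml"),
         ggplot(ph, aes(cd4_cd8_ratio, global_perturbation)) + geom_point() +
           geom_smooth(method = "lm", formula = y ~ x, se = FALSE) +
           labs(x = "CD4/CD8 ratio", y = "Global perturbation (%)"),
         ncol = 2),
       width = 7, height = 3.2)

cat("Figures written to results/figures/\n")
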