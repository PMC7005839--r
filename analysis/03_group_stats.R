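#!/usr/bin/env Rscript
# Statistical layer over the classified cohort: Mann-Whitney per criterion
# (test vs control), chi-square of the addicted frequency against the
# control proportion, and Pearson correlations between each criterion and
# the number of criteria achieved.
#
# Reads:  results/attribution.tsv (from 02_score_classify.R)
# Writes: results/group_summary.json

suppressPackageStartupMessages(library(foodaddictr))

att <- utils::read.delim("results/attribution.tsv", stringsAsFactors = FALSE)
classified <- list(
  attribution = att,
  thresholds = c(persistence = att$threshold_persistence[1],
                 motivation = att$threshold_motivation[1],
                 compulsivity = att$threshold_compulsivity[1]),
  group_summary = do.call(rbind, lapply(split(att, att$group), function(g)
    data.frame(group = g$group[1], n = nrow(g),
               n_addicted = sum(g$label == "addicted"),
               addicted_fraction = mean(g$label == "addicted"))))
)

st <- cohort_statistics(classified, control = "control")
write_group_summary(st, "results/group_summary.json")

for (nm in names(st$mann_whitney)) {
  cmp <- st$mann_whitney[[nm]]
  message(sprintf("Mann-Whitney %-28s U = %6.1f  p = %.4g %s",
                  nm, cmp$statistic, cmp$p_value, cmp$stars))
}
for (nm in names(st$chi_square)) {
  cmp <- st$chi_square[[nm]]
  message(sprintf("Chi-square vs control [%s]: X2 = %.2f  p = %.4g %s",
                  nm, cmp$statistic, cmp$p_value, cmp$stars))
}
message("Full summary: results/group_summary.json")
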