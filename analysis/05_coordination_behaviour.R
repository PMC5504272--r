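# Functional coordination and behaviour: within- vs across-module
# functional connectivity for the intermediate-state module split
# (DMN/SMN/AUD vs FPN/SAN/ATN/VIS), the group-by-FC-type interaction, and
# the correlations between dynamics indices and the ADOS-like / FIQ-like
# scores. Empirical per-participant indices at 240 volumes are noisy
# estimators of the ground-truth indices, so the behavioural correlations
# are attenuated relative to their planted values; both are reported.

source("analysis/00_config.R")

cohort <- read_cohort(COHORT_DIR)
res <- run_pipeline(cohort, n_steps = 1e5, n_perm = 1e4,
                    seed = MASTER_SEED + 1)

write_tsv(res$coordination$table, "05_segregation.tsv")
write_tsv(res$coordination$anova_intermediate, "05_segregation_anova.tsv")
message("FC-type x group ANOVA (intermediate-state modules):")
print(res$coordination$anova_intermediate, digits = 4)
seg <- res$coordination$seg_group_test
message(sprintf("segregation TD vs ASD: t(%d) = %.2f, p = %.2g, d = %.2f",
                seg$df, seg$t, seg$p, seg$cohen_d))

pick <- function(x) x[c("r", "df", "p")]
behaviour <- lapply(res$behaviour[c("ados_indirect_asd", "fiq_indirect_td",
                                    "fiq_indirect_asd", "fiq_duration_asd")],
                    pick)

# planted-truth correlations for comparison (exact by construction)
truth <- read_cohort(COHORT_DIR)$ground_truth$truth
mf <- cohort$manifest[match(truth$participant_id, cohort$manifest$participant_id), ]
asd <- truth$group == "ASD"
behaviour$planted <- list(
  ados_indirect_asd = cor(mf$ados[asd], truth$indirect_freq[asd]),
  fiq_indirect_td = cor(mf$fiq[!asd], truth$indirect_freq[!asd]),
  fiq_duration_asd = cor(mf$fiq[asd], truth$mean_major_duration[asd]))
write_json_out(behaviour, "05_behaviour_correlations.json")
message("estimated vs planted behavioural correlations:")
message(sprintf("  ADOS~indirect (ASD): %.2f (planted %.2f)",
                behaviour$ados_indirect_asd$r, behaviour$planted$ados_indirect_asd))
message(sprintf("  FIQ~indirect (TD):   %.2f (planted %.2f)",
                behaviour$fiq_indirect_td$r, behaviour$planted$fiq_indirect_td))
message(sprintf("  FIQ~duration (ASD):  %.2f (planted %.2f)",
                behaviour$fiq_duration_asd$r, behaviour$planted$fiq_duration_asd))
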