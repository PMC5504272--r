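# Diagnosis prediction with external validation: train cutoffs and a
# linear SVM on the main cohort's individual-level dynamics indices, then
# score an independent synthetic test cohort. Individual-level fits are
# noisier than the group fit, so accuracies below the group level are
# expected; the bivariate rule should do at least as well as either
# univariate cutoff.

source("analysis/00_config.R")

train <- read_cohort(COHORT_DIR)
test <- build_cohort(cohort_config(n_td = 15, n_asd = 10),
                     master_seed = MASTER_SEED + 50)

ref <- {
  ls <- build_landscape(planted_params("td_like"))
  define_brain_states(build_disconnectivity_graph(ls), assign_basins(ls),
                      planted_state_grouping())
}
idx_train <- suppressWarnings(
  individual_indices(train, ref, n_steps = 2e4, seed = MASTER_SEED + 51))
idx_test <- suppressWarnings(
  individual_indices(test, ref, n_steps = 2e4, seed = MASTER_SEED + 52))
write_tsv(idx_train, "06_individual_indices_train.tsv")
write_tsv(idx_test, "06_individual_indices_test.tsv")

tr_td <- idx_train$group == "TD"
scores <- list()
for (feat in c("intermediate_freq", "indirect_freq")) {
  clf <- univariate_cutoff(idx_train[[feat]][tr_td], idx_train[[feat]][!tr_td])
  ev <- evaluate_classifier(clf, idx_test[[feat]], idx_test$group)
  scores[[feat]] <- list(threshold = clf$threshold,
                         sensitivity = ev$sensitivity,
                         specificity = ev$specificity)
  message(sprintf("univariate %s: cutoff %.2f%%, sensitivity %.0f%%, specificity %.0f%%",
                  feat, clf$threshold, 100 * ev$sensitivity, 100 * ev$specificity))
}
feats <- c("intermediate_freq", "indirect_freq")
biv <- bivariate_boundary(as.matrix(idx_train[, feats]), idx_train$group)
ev <- evaluate_classifier(biv, as.matrix(idx_test[, feats]), idx_test$group)
scores$bivariate <- list(weights = biv$weights, bias = biv$bias,
                         sensitivity = ev$sensitivity,
                         specificity = ev$specificity)
message(sprintf("bivariate (linear SVM): sensitivity %.0f%%, specificity %.0f%%",
                100 * ev$sensitivity, 100 * ev$specificity))
write_json_out(scores, "06_diagnosis.json")
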