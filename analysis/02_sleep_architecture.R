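#!/usr/bin/env Rscript
# Sleep architecture of control vs fragmented-sleep genotypes: day/night
# totals, bout number and bout length by age, with the screen's statistics
# (Holm-Sidak corrected t tests across the family of age contrasts; ANOVA
# with Tukey HSD across genotypes). Writes per-fly summaries and the stats
# tables under results/.

library(ontosleep)

seed <- 20260922
dir.create("results", showWarnings = FALSE)

models <- list(
  ctrl = genotype_model(genotype = "ctrl"),
  kd = genotype_model(target_ontogeny_ratio = 1.0, fragmentation = 0.5,
                      genotype = "kd"))

sim <- simulate_screen_experiment(models, n_flies_per_group = 24,
                                  seed = seed)
summaries <- lapply(names(sim$monitors), function(mn) {
  al <- align_to_zt(sim$monitors[[mn]], sim$schedule)
  cbind(monitor = mn, sleep_summary_matrix(al))
})
summaries <- do.call(rbind, summaries)
per_fly <- merge(sim$design, summaries, by = c("monitor", "channel"))
write.table(per_fly, "results/sleep_architecture.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

grp <- function(g, a, col) per_fly[[col]][per_fly$genotype == g &
                                            per_fly$age_class == a]
metrics <- c("total_sleep", "day_sleep", "night_sleep",
             "day_bout_number", "day_bout_length_mean")
stats <- lapply(metrics, function(mcol) {
  pairs <- list(ctrl = list(a = grp("ctrl", "young", mcol),
                            b = grp("ctrl", "mature", mcol)),
                kd = list(a = grp("kd", "young", mcol),
                          b = grp("kd", "mature", mcol)))
  cbind(metric = mcol, holm_sidak_ttests(pairs))
})
stats <- do.call(rbind, stats)
write.table(stats, "results/architecture_stats.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

for (mcol in metrics) {
  r <- stats[stats$metric == mcol & stats$comparison == "ctrl", ]
  message(sprintf("%-22s ctrl young-vs-mature: p_adj = %.3g %s", mcol,
                  r$p_adj, ifelse(r$significant, "*", "")))
}

# cross-genotype day-sleep comparison in young flies (ANOVA + Tukey needs
# >= 3 groups; add the fragmented model at a third ratio)
models$mid <- genotype_model(target_ontogeny_ratio = 1.4, genotype = "mid")
sim3 <- simulate_screen_experiment(models, 24, seed = seed + 1)
sm3 <- do.call(rbind, lapply(names(sim3$monitors), function(mn) {
  al <- align_to_zt(sim3$monitors[[mn]], sim3$schedule)
  cbind(monitor = mn, sleep_summary_matrix(al))
}))
pf3 <- merge(sim3$design, sm3, by = c("monitor", "channel"))
young <- split(pf3$day_sleep[pf3$age_class == "young"],
               pf3$genotype[pf3$age_class == "young"])
av <- anova_tukey(young)
write.table(av$pairwise, "results/young_day_sleep_tukey.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message(sprintf("young day-sleep ANOVA: F = %.1f, p = %.3g", av$overall$F,
                av$overall$p))
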