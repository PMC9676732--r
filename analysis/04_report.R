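#!/usr/bin/env Rscript
# Stage 4: aggregate the orphan arrays to the published-table shapes:
# regional/HDI summaries with per-100-death and per-100,000-children rates
# and child-age distributions, and the 14-group cancer-site table.

suppressPackageStartupMessages(library(canorphans))

seed <- 20201L
dir.create("results", showWarnings = FALSE)

cfg <- synthetic_config()
bundle <- make_world(cfg, seed = seed)
arr <- estimate_new_orphans(bundle)
prev <- estimate_prevalent_orphans(bundle, scenario_config("S1", "a"))

for (level in c("world", "region", "hdi")) {
  tab <- orphan_summary(bundle, arr, prev, level = level)
  readr::write_csv(tab, sprintf("results/summary_by_%s.csv", level))
}
groups <- orphan_summary(bundle, arr, prev, level = "site_group")
readr::write_csv(groups, "results/summary_by_site_group.csv")

world <- orphan_summary(bundle, arr, prev, level = "world")
cat("world summary:\n")
cat(sprintf("  %.0f new orphans: %.0f per 100 deaths, %.1f per 100,000 children\n",
            world$new_orphans, world$per_100_deaths, world$per_100k_children))
cat(sprintf("  new-orphan ages: %.0f%% <5, %.0f%% 5-9, %.0f%% 10-17 (mean %.1f y)\n",
            world$share_u5, world$share_5_9, world$share_10_17,
            world$mean_age_at_orphaning))
cat(sprintf("  %.0f prevalent orphans: %.1f per 100,000 children\n",
            world$prevalent_orphans, world$prevalent_per_100k))
cat("by cancer group (new orphans, % of total):\n")
print(groups[, c("unit", "new_orphans", "pct_of_total", "per_100_deaths")])
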