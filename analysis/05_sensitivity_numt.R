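#!/usr/bin/env Rscript
# Step 5 — sensitivity: a seven-step two-fold dilution series with a fixed
# NUMT read count. Mean depth and 20X breadth fall with input, while the
# number of catalogued NUMT alleles reaching the 10% threshold (NAVs)
# rises, because nuclear copy number does not dilute with mtDNA.

source("analysis/common.R")

ref <- study_reference()
panel <- study_panel()
catalog <- study_numt_catalog(ref)
hap <- study_haplotypes(ref)$RR3
out <- results_dir()

sc <- sim_scenario(ref, panel, haplotypes = list(hap),
                   depth = depth_model(1280), error = study_error(),
                   numt = numt_model(catalog, reads = 12L),
                   seed = STUDY_SEED + 500L)
series <- dilution_series(sc, 0.5^(0:6))

tab <- do.call(rbind, lapply(seq_along(series), function(i) {
  p <- series[[i]]$pileup
  h <- assemble_haplotype(p, ref, panel)
  h_nav <- flag_nav(h, catalog)
  data.frame(step = i, depth_factor = 0.5^(i - 1),
             mean_depth = round(sum(p$counts) / p$L, 1),
             breadth_20x = round(coverage_breadth(p, 20L), 4),
             nav_count = count_navs(p, catalog),
             n_calls = nrow(h$calls),
             n_ncalls = sum(h_nav$calls$status == "uncalled_N"))
}))
write.csv(tab, file.path(out, "sensitivity_dilution.csv"), row.names = FALSE)

cat("Dilution series (factor, mean depth, 20X breadth, NAV count, N-calls):\n")
print(tab, row.names = FALSE)
stopifnot(all(diff(tab$nav_count) >= 0))
cat("NAV count is non-decreasing as input falls, as the fixed NUMT reads\n")
cat("make up a growing share of per-position depth.\n")
cat("Wrote", file.path(out, "sensitivity_dilution.csv"), "\n")
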