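# Shared study conditions for the analysis scripts.
#
# One synthetic reference circle and one 110-amplicon two-pool panel are
# used throughout; per-study scenarios (depths, error rates, mixture
# ratios, NUMT catalog) are defined here so every script draws from the
# same conditions.

library(mitovalr)

STUDY_SEED <- 20201113L

study_reference <- function() synthetic_reference(seed = 7L)

study_panel <- function() simulate_panel(110, 163, 11, seed = 2L)

# three distinct single-source donors, 25-32 substitutions each, plus the
# common HVII C-insertion motif
study_haplotypes <- function(ref) {
  list(
    RR1 = c(random_haplotype(ref, 25, seed = 201L), "309.1C", "315.1C"),
    RR2 = c(random_haplotype(ref, 32, seed = 202L), "315.1C"),
    RR3 = random_haplotype(ref, 28, seed = 203L)
  )
}

# per-study error model: 0.2% substitution noise, homopolymer indel noise
# rising with tract length
study_error <- function() error_model(substitution_rate = 0.002,
                                      base_indel_rate = 0.005)

# NUMT catalog: six nuclear-insert alleles scattered over the circle
study_numt_catalog <- function(ref) {
  positions <- c(1200L, 2500L, 5000L, 7500L, 10000L, 14000L)
  data.frame(position = positions,
             allele = vapply(positions, function(pp)
               setdiff(c("A", "C", "G", "T"), ref_base(ref, pp))[1],
               character(1)))
}

results_dir <- function() {
  dir.create("results", showWarnings = FALSE)
  "results"
}
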