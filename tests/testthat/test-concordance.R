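test_that("identical haplotypes produce no discordance records", {
  ref <- fx_ref()
  hap <- random_haplotype(ref, 15, seed = 51)
  sim <- simulate_pileup(fx_scenario(hap, seed = 51), exact = TRUE)
  h <- assemble_haplotype(sim$pileup, ref)
  expect_equal(nrow(compare_haplotypes(h, h, ref)), 0)
})

test_that("discordances are classified by the deterministic rule order", {
  ref <- fx_ref()
  base <- random_haplotype(ref, 10, seed = 52)
  mk <- function(hap, seed) {
    assemble_haplotype(simulate_pileup(fx_scenario(hap, seed = seed),
                                       exact = TRUE)$pileup, ref)
  }
  a <- mk(c(base, "305del"), 1)        # right-aligns to 309del
  b <- mk(base, 2)
  rec <- compare_haplotypes(a, b, ref, labels = c("s5", "miseq"))
  expect_equal(nrow(rec), 1)
  expect_equal(rec$category, "suspect_deletion")
  expect_equal(rec$present_in, "s5")

  # same insertion anchor, different dominant run
  a2 <- mk(c(base, "315.1C"), 3)
  b2 <- mk(c(base, "315.1C", "315.2C"), 4)
  rec2 <- compare_haplotypes(a2, b2, ref)
  expect_equal(rec2$category, "dominant_variant_differs")
  expect_equal(nrow(rec2), 1)

  # non-suspect homopolymer indel seen in one source
  a3 <- mk(c(base, "573.1C"), 5)
  rec3 <- compare_haplotypes(a3, b, ref)
  expect_equal(rec3$category, "homopolymer_indel")

  # heteroplasmy in one source only
  pos <- 5000L
  php <- paste0(pos, iupac_code(ref_base(ref, pos),
                                setdiff(c("A", "C", "G", "T"),
                                        ref_base(ref, pos))[1]))
  a4 <- assemble_haplotype(simulate_pileup(fx_scenario(
    rbind(data.frame(variant = base, frequency = 1),
          data.frame(variant = php, frequency = 0.2)), seed = 6),
    exact = TRUE)$pileup, ref)
  rec4 <- compare_haplotypes(a4, b, ref)
  expect_equal(rec4$category, "php_only_one_source")
})

test_that("sub-threshold variants in the partner pileup are threshold misses", {
  ref <- fx_ref()
  base <- random_haplotype(ref, 8, seed = 53)
  pos <- parse_variant(base[1])$position
  al <- parse_variant(base[1])$allele
  # partner carries the variant at 8%, below the 10% threshold
  partner_hap <- rbind(
    data.frame(variant = base[-1], frequency = 1),
    data.frame(variant = paste0(pos, iupac_code(ref_base(ref, pos), al)),
               frequency = 0.08))
  sim_a <- simulate_pileup(fx_scenario(base, seed = 7), exact = TRUE)
  sim_b <- simulate_pileup(fx_scenario(partner_hap, seed = 8), exact = TRUE)
  ha <- assemble_haplotype(sim_a$pileup, ref)
  hb <- assemble_haplotype(sim_b$pileup, ref)
  rec <- compare_haplotypes(ha, hb, ref, pileup_a = sim_a$pileup,
                            pileup_b = sim_b$pileup)
  miss <- rec[rec$variant == base[1], ]
  expect_equal(miss$category, "threshold_miss")
})

test_that("masked regions are excluded from the comparison", {
  ref <- fx_ref()
  hap <- random_haplotype(ref, 10, seed = 54)
  sim <- simulate_pileup(fx_scenario(hap, seed = 9), exact = TRUE)
  ha <- assemble_haplotype(sim$pileup, ref)
  p2 <- sim$pileup
  pos1 <- parse_variant(hap[1])$position
  p2$counts[pos1, ] <- 0L  # below 20X in the partner
  hb <- assemble_haplotype(p2, ref)
  expect_equal(nrow(compare_haplotypes(ha, hb, ref)), 0)
})

test_that("max pairwise difference equals the brute-force all-pairs maximum", {
  expect_equal(max_pairwise_difference(c(0.10, 0.11, 0.12)), 2.0)
  expect_equal(max_pairwise_difference(rep(0.3, 5)), 0.0)
  expect_error(max_pairwise_difference(0.5), "at least 2")
  set.seed(55)
  for (i in 1:1000) {
    f <- runif(sample(2:8, 1))
    pairs <- utils::combn(f, 2)
    expect_equal(max_pairwise_difference(f),
                 100 * max(abs(pairs[1, ] - pairs[2, ])))
  }
})

test_that("replicate summary is zero for identical replicates", {
  ref <- fx_ref()
  hap <- random_haplotype(ref, 12, seed = 56)
  sim <- simulate_pileup(fx_scenario(hap, seed = 10), exact = TRUE)
  h <- assemble_haplotype(sim$pileup, ref)
  rs <- replicate_set("s", list(r1 = list(haplotype = h, pileup = sim$pileup),
                                r2 = list(haplotype = h, pileup = sim$pileup)))
  summ <- replicate_summary(rs)
  expect_equal(nrow(summ), 12)
  expect_equal(summ$max_pairwise_diff, rep(0, 12))
  expect_equal(summ$type, rep("substitution", 12))
})

test_that("replicate frequency spread matches the binomial expectation", {
  ref <- fx_ref()
  pos <- 4000L
  alt <- setdiff(c("A", "C", "G", "T"), ref_base(ref, pos))[1]
  php <- data.frame(variant = paste0(pos, iupac_code(ref_base(ref, pos), alt)),
                    frequency = 0.12)
  reps <- lapply(1:8, function(i) {
    sim <- simulate_pileup(fx_scenario(php, depth = 500, seed = 100 + i))
    list(haplotype = assemble_haplotype(sim$pileup, ref),
         pileup = sim$pileup)
  })
  rs <- replicate_set("php", reps)
  summ <- replicate_summary(rs)
  row <- summ[summ$variant == php$variant, ]
  expect_equal(row$type, "PHP")
  # expected range of (max - min) over 8 binomial draws at n~500, p=0.12:
  # SD per replicate ~1.45 points; range stays within ~6 SD with margin
  expect_lt(row$max_pairwise_diff, 12)
  expect_gt(row$max_pairwise_diff, 0)
})

test_that("variants just below threshold are listed as sub-threshold", {
  ref <- fx_ref()
  pos <- 7000L
  alt <- setdiff(c("A", "C", "G", "T"), ref_base(ref, pos))[1]
  code <- iupac_code(ref_base(ref, pos), alt)
  mk <- function(freq, seed) {
    sim <- simulate_pileup(fx_scenario(
      data.frame(variant = paste0(pos, code), frequency = freq),
      seed = seed), exact = TRUE)
    list(haplotype = assemble_haplotype(sim$pileup, ref),
         pileup = sim$pileup)
  }
  reps <- list(r1 = mk(0.12, 1), r2 = mk(0.12, 2), r3 = mk(0.098, 3))
  summ <- replicate_summary(replicate_set("s", reps))
  row <- summ[summ$variant == paste0(pos, code), ]
  expect_equal(row$n_called, 2)
  expect_equal(row$n_subthreshold, 1)
})
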