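test_that("single-source error-free pileups contain no MV sites", {
  sim <- simulate_pileup(fx_scenario(random_haplotype(fx_ref(), 20,
                                                      seed = 61),
                                     seed = 20), exact = TRUE)
  expect_equal(nrow(find_mvs(sim$pileup)), 0)
})

test_that("a noiseless 1:4 mixture shows every differing position at 20%", {
  ref <- fx_ref()
  sc <- sim_scenario(ref, fx_panel(),
                     haplotypes = list(random_haplotype(ref, 13, seed = 62),
                                       random_haplotype(ref, 12, seed = 63)),
                     minor_fraction = 0.2, depth = depth_model(1000),
                     error = error_model(0, 0), seed = 21)
  sim <- simulate_mixture(sc, exact = TRUE)
  expected <- attr(sim$truth, "differing_positions")
  mvs <- find_mvs(sim$pileup)
  expect_equal(mvs$position, expected)
  expect_equal(mvs$minor_freq, rep(0.2, length(expected)))
})

test_that("a 10:1 mixture stays below the inclusive 10% threshold", {
  ref <- fx_ref()
  sc <- sim_scenario(ref, fx_panel(),
                     haplotypes = list(random_haplotype(ref, 13, seed = 62),
                                       random_haplotype(ref, 12, seed = 63)),
                     minor_fraction = 1 / 11, depth = depth_model(1000),
                     error = error_model(0, 0), seed = 22)
  sim <- simulate_mixture(sc, exact = TRUE)
  expect_equal(nrow(find_mvs(sim$pileup)), 0)
})

test_that("the mixture flag needs three or more MVs, inclusively", {
  expect_false(flag_mixture(2))
  expect_true(flag_mixture(3))
  expect_false(flag_mixture(0))
  expect_true(flag_mixture(2, calling_thresholds(mv_min_count = 2)))
})

test_that("mixture design arithmetic reproduces the dilution-to-extinction series", {
  d <- mixture_design(2, "20:1")
  expect_equal(d$variable_pg, 40)
  expect_equal(d$total_pg, 42)
  d <- mixture_design(2, "1:10")
  expect_equal(d$variable_pg, 0.2)
  expect_equal(d$total_pg, 2.2)
  expect_equal(mixture_design(2, c(1, 1))$total_pg, 4)
  expect_error(mixture_design(2, c(-1, 1)), "positive")
  expect_error(mixture_design(0, c(2, 1)), "positive")
})

test_that("noiseless 4:1 deconvolution recovers the minor haplotype and ratio", {
  ref <- fx_ref()
  shared <- random_haplotype(ref, 5, seed = 64)
  hap1 <- c(shared, random_haplotype(ref, 12, seed = 65))
  hap2 <- c(shared, random_haplotype(ref, 11, seed = 66))
  sc <- sim_scenario(ref, fx_panel(), haplotypes = list(hap1, hap2),
                     minor_fraction = 0.2, depth = depth_model(1000),
                     error = error_model(0, 0), seed = 23)
  sim <- simulate_mixture(sc, exact = TRUE)
  res <- deconvolve(sim$pileup, ref = ref)
  expect_false(res$unresolvable)
  expect_equal(res$effective_ratio, 4, tolerance = 1e-6)
  expect_setequal(res$minor_variants, sort(hap2))
  expect_setequal(res$major_variants, sort(hap1))
  expect_equal(res$minor_mean, 20, tolerance = 0.1)
})

test_that("an approximately 1:1 mixture is reported unresolvable", {
  ref <- fx_ref()
  sc <- sim_scenario(ref, fx_panel(),
                     haplotypes = list(random_haplotype(ref, 10, seed = 67),
                                       random_haplotype(ref, 10, seed = 68)),
                     minor_fraction = 0.5, depth = depth_model(1000),
                     error = error_model(0, 0), seed = 24)
  sim <- simulate_mixture(sc, exact = TRUE)
  res <- deconvolve(sim$pileup, ref = ref)
  expect_true(res$unresolvable)
  expect_equal(length(res$minor_variants), 0)
})

test_that("deconvolution below the MV minimum is refused", {
  sim <- simulate_pileup(fx_scenario(random_haplotype(fx_ref(), 6,
                                                      seed = 69),
                                     seed = 25), exact = TRUE)
  expect_error(deconvolve(sim$pileup, ref = fx_ref()), "not a mixture")
})

test_that("re-mixing the deconvolved haplotypes reproduces the MV frequencies", {
  ref <- fx_ref()
  hap1 <- random_haplotype(ref, 12, seed = 71)
  hap2 <- random_haplotype(ref, 12, seed = 72)
  sc <- sim_scenario(ref, fx_panel(), haplotypes = list(hap1, hap2),
                     minor_fraction = 0.3, depth = depth_model(1000),
                     error = error_model(0.002, 0), seed = 26)
  sim <- simulate_mixture(sc)
  mvs <- find_mvs(sim$pileup)
  res <- deconvolve(sim$pileup, mvs, ref)
  # feed the estimated haplotypes and ratio back through the generator
  f_hat <- res$minor_mean / (res$minor_mean + res$major_mean)
  sc2 <- sim_scenario(ref, fx_panel(),
                      haplotypes = list(res$major_variants,
                                        res$minor_variants),
                      minor_fraction = f_hat, depth = depth_model(1000),
                      error = error_model(0, 0), seed = 27)
  sim2 <- simulate_mixture(sc2)
  mvs2 <- find_mvs(sim2$pileup)
  common <- intersect(mvs$position, mvs2$position)
  expect_gte(length(common), 0.9 * nrow(mvs))
  m1 <- mvs$minor_freq[match(common, mvs$position)]
  m2 <- mvs2$minor_freq[match(common, mvs2$position)]
  # both sides are binomial draws: bound the per-site gap by 4 SD of the
  # difference of two independent proportions at the realised depth
  d_min <- min(depth_vector(sim$pileup)[common],
               depth_vector(sim2$pileup)[common])
  sd_diff <- sqrt(2 * 0.3 * 0.7 / d_min)
  expect_lt(max(abs(m1 - m2)), 4 * sd_diff)
})

test_that("stochastic outliers among MVs are excluded with an audit note", {
  ref <- fx_ref()
  hap1 <- random_haplotype(ref, 11, seed = 73)
  hap2 <- random_haplotype(ref, 11, seed = 74)
  sc <- sim_scenario(ref, fx_panel(), haplotypes = list(hap1, hap2),
                     minor_fraction = 0.25, depth = depth_model(2000),
                     error = error_model(0, 0), seed = 28)
  sim <- simulate_mixture(sc)
  p <- sim$pileup
  # graft a drop-in allele at 12% far from the 25% minor cluster
  pos <- 222L
  alt <- setdiff(c("A", "C", "G", "T"), ref_base(ref, pos))[1]
  d <- sum(p$counts[pos, ])
  counts <- stats::setNames(list(round(c(0.44, 0.44) * d),
                                 round(c(0.06, 0.06) * d)),
                            c(ref_base(ref, pos), alt))
  p <- do.call(set_counts, c(list(p, pos), counts))
  res <- deconvolve(p, ref = ref)
  expect_true(pos %in% res$excluded$position)
  expect_false(any(grepl(paste0("^", pos), res$minor_variants)))
})
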