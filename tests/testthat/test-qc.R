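# small pileup with a chosen depth at every position
flat_pileup <- function(depths, ref, id = "p") {
  p <- mt_pileup(id, L = length(depths))
  refvec <- strsplit(ref$sequence, "")[[1]][seq_along(depths)]
  fwd <- depths %/% 2L
  p$counts[cbind(seq_along(depths),
                 match(paste0(refvec, "_fwd"), colnames(p$counts)))] <- fwd
  p$counts[cbind(seq_along(depths),
                 match(paste0(refvec, "_rev"), colnames(p$counts)))] <-
    depths - fwd
  p
}

test_that("amplicon median depth uses the mean-of-middle-two rule", {
  ref <- toy_ref(100L)
  p <- flat_pileup(rep(100L, 100L), ref)
  expect_equal(amplicon_median_depth(p, 1, 50), 100)
  p2 <- flat_pileup(c(10L, 20L, 30L, rep(0L, 97L)), ref)
  expect_equal(amplicon_median_depth(p2, 1, 3), 20)
  p3 <- flat_pileup(c(10L, 20L, 30L, 40L, rep(0L, 96L)), ref)
  expect_equal(amplicon_median_depth(p3, 1, 4), 25)
})

test_that("amplicon balance divides each median by the median of medians", {
  ref <- toy_ref(300L)
  pan <- mt_panel(data.frame(id = c("a", "b", "c"), pool = c(1L, 2L, 1L),
                             start = c(1L, 101L, 201L),
                             end = c(100L, 200L, 300L)), L = 300L)
  p <- flat_pileup(rep(c(50L, 100L, 200L), each = 100L), ref)
  bal <- amplicon_balance(p, pan)
  expect_equal(bal$balance, c(0.5, 1.0, 2.0))
  # the worked ratio: an amplicon at 100X against an overall 150X
  p2 <- flat_pileup(rep(c(100L, 150L, 150L), each = 100L), ref)
  expect_equal(round(amplicon_balance(p2, pan)$balance[1], 2), 0.67)
  # all equal medians give balance 1 everywhere
  expect_equal(amplicon_balance(flat_pileup(rep(80L, 300L), ref), pan)$balance,
               rep(1, 3))
  expect_error(amplicon_balance(flat_pileup(rep(0L, 300L), ref), pan),
               "zero")
})

test_that("balance summary matches a brute-force recomputation on random pileups", {
  ref <- fx_ref()
  panel <- fx_panel()
  sc <- fx_scenario(character(0), depth = 100, seed = 14)
  sc$depth$sdlog <- 0.6
  p <- simulate_pileup(sc)$pileup
  bal <- amplicon_balance(p, panel)
  d <- vapply(seq_len(p$L), function(i) sum(p$counts[i, ]), numeric(1))
  brute <- vapply(seq_len(nrow(panel$amplicons)), function(i) {
    span <- amplicon_positions(panel$amplicons$start[i],
                               panel$amplicons$end[i], panel$L)
    median(d[span])
  }, numeric(1))
  expect_equal(bal$median_depth, brute)
  expect_equal(bal$balance, brute / median(brute))
  expect_equal(mean(bal$balance), mean(brute) / median(brute))
})

test_that("coverage breadth counts positions at or above the depth minimum", {
  ref <- toy_ref(200L)
  p <- flat_pileup(rep(25L, 200L), ref)
  expect_equal(coverage_breadth(p, 20L), 1.0)
  p$counts[1:10, ] <- 0L
  expect_equal(coverage_breadth(p, 20L), 190 / 200)
  expect_equal(coverage_breadth(mt_pileup("e", L = 200L), 20L), 0)
  # non-increasing in the depth threshold
  for (md in c(1L, 10L, 26L)) {
    expect_gte(coverage_breadth(p, md), coverage_breadth(p, md + 10L))
  }
})

test_that("relative read depth is a percentage with an undefined guard", {
  ref <- toy_ref(100L)
  pos <- flat_pileup(rep(2000L, 100L), ref, "pos")
  neg <- flat_pileup(rep(50L, 100L), ref, "neg")
  expect_equal(relative_read_depth(neg, pos), rep(2.5, 100))
  neg0 <- mt_pileup("neg0", L = 100L)
  expect_equal(relative_read_depth(neg0, pos), rep(0, 100))
  pos$counts[7L, ] <- 0L
  rel <- relative_read_depth(neg, pos)
  expect_true(is.na(rel[7]))
  expect_equal(rel[8], 2.5)
})

test_that("an exact 1% negative yields a flat profile fully below the bound", {
  ref <- fx_ref()
  sc <- fx_scenario(character(0), depth = 2000, seed = 15,
                    negative = negative_model(scale = 1))
  pos <- simulate_pileup(sc, exact = TRUE)$pileup
  neg <- simulate_negative(sc, pos, exact = TRUE)
  summ <- contamination_summary(list(neg), pos)
  expect_equal(summ$frac_below_bound, 1.0)
  rel <- summ$profile$mean_rel
  expect_true(all(abs(rel - 1.0) < 0.1, na.rm = TRUE))
  expect_equal(summ$profile$sd_rel, rep(0, ref$L))  # single negative
  expect_equal(nrow(summ$flagged), 0)
})

test_that("primer-artifact hotspots are flagged with their amplicons", {
  ref <- fx_ref()
  panel <- fx_panel()
  hot <- data.frame(start = c(2001L, 9001L), end = c(2080L, 9050L),
                    scale = 40)
  sc <- fx_scenario(character(0), depth = 2000, seed = 16,
                    negative = negative_model(scale = 1, hotspots = hot))
  pos <- simulate_pileup(sc, exact = TRUE)$pileup
  neg <- simulate_negative(sc, pos, exact = TRUE)
  summ <- contamination_summary(list(neg), pos, panel = panel)
  expect_equal(nrow(summ$flagged), 2)
  expect_equal(summ$flagged$start, hot$start)
  expect_equal(summ$flagged$end, hot$end)
  expect_true(all(nchar(summ$flagged$amplicons) > 0))
  expect_equal(summ$frac_below_bound,
               1 - (80 + 50) / ref$L)
})

test_that("contamination profile averages across several negatives", {
  ref <- toy_ref(100L)
  pos <- flat_pileup(rep(1000L, 100L), ref, "pos")
  negs <- lapply(c(10L, 20L, 30L), function(d)
    flat_pileup(rep(d, 100L), ref, paste0("n", d)))
  summ <- contamination_summary(negs, pos)
  expect_equal(summ$profile$mean_rel, rep(2, 100))
  expect_equal(summ$profile$sd_rel, rep(1, 100))
})
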