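# pick an alternate base differing from the reference at a position
alt_base <- function(ref, pos, avoid = character(0)) {
  setdiff(c("A", "C", "G", "T"), c(ref_base(ref, pos), avoid))[1]
}

test_that("single-position calls follow the inclusive frequency thresholds", {
  th <- calling_thresholds()
  # 95% non-reference: substitution
  calls <- call_position(pos_counts(G = c(48, 47), A = c(3, 2)), "A", th)
  expect_equal(calls$kind, "substitution")
  expect_equal(calls$rendered, "1G")
  # 12% non-reference: point heteroplasmy with IUPAC code
  calls <- call_position(pos_counts(A = c(44, 44), G = c(6, 6)), "A", th)
  expect_equal(calls$kind, "heteroplasmy")
  expect_equal(calls$allele, "R")
  expect_equal(calls$frequency, 0.12)
  # below the 20X depth minimum: no call at all
  expect_equal(nrow(call_position(pos_counts(G = c(10, 9)), "A", th)), 0)
  # 45% deletion reads
  calls <- call_position(pos_counts(A = c(28, 27), del = c(23, 22)), "A", th)
  expect_true("deletion" %in% calls$kind)
  # frequencies exactly at threshold are called (inclusive)
  calls <- call_position(pos_counts(A = c(45, 45), G = c(5, 5)), "A", th)
  expect_equal(calls$kind, "heteroplasmy")
  calls <- call_position(pos_counts(A = c(30, 30), del = c(20, 20)), "A", th)
  expect_true("deletion" %in% calls$kind)
  calls <- call_position(pos_counts(A = c(50, 50), ins_C = c(15, 15)), "A", th)
  expect_true("insertion" %in% calls$kind)
})

test_that("extreme strand bias flags calls for review instead of dropping them", {
  th <- calling_thresholds()
  # insertion at 73% of depth but with strand bias 0.97
  pc <- pos_counts(A = c(70, 71), ins_C = c(100, 3))
  calls <- call_position(pc, "A", th)
  ins <- calls[calls$kind == "insertion", ]
  expect_equal(nrow(ins), 1)
  expect_equal(ins$status, "review")
  expect_equal(ins$strand_bias, 0.97)
  expect_gt(ins$frequency, 0.70)
})

test_that("multi-base dominant insertions expand to indexed names", {
  pc <- pos_counts(A = c(50, 50), ins_CC = c(20, 20), ins_C = c(5, 5))
  calls <- call_position(pc, "A", calling_thresholds())
  ins <- calls[calls$kind == "insertion", ]
  expect_equal(ins$rendered, c("1.1C", "1.2C"))
  expect_equal(unique(ins$dominant_fraction), 0.8)
})

test_that("a reference-identical pileup yields zero calls and no mask", {
  sim <- simulate_pileup(fx_scenario(character(0), depth = 100), exact = TRUE)
  h <- assemble_haplotype(sim$pileup, fx_ref())
  expect_equal(nrow(h$calls), 0)
  expect_equal(length(h$coverage_mask), 0)
})

test_that("noiseless round trip recovers the simulated haplotype exactly", {
  ref <- fx_ref()
  hap <- c(random_haplotype(ref, 28, seed = 31),
           "309.1C", "315.1C")
  sim <- simulate_pileup(fx_scenario(hap, seed = 5), exact = TRUE)
  h <- assemble_haplotype(sim$pileup, ref)
  expect_setequal(h$calls$rendered, hap)
  expect_true(all(h$calls$status == "confirmed"))
})

test_that("a dropped amplicon span is masked and the rest still called", {
  ref <- fx_ref()
  panel <- fx_panel()
  hap <- random_haplotype(ref, 20, seed = 32)
  sim <- simulate_pileup(fx_scenario(hap, seed = 6), exact = TRUE)
  p <- sim$pileup
  dropped <- amplicon_positions(panel$amplicons$start[5],
                                panel$amplicons$end[5], panel$L)
  # overlap positions keep their second amplicon's reads; zero the rest
  only <- setdiff(dropped, unlist(lapply(c(4, 6), function(i)
    amplicon_positions(panel$amplicons$start[i], panel$amplicons$end[i],
                       panel$L))))
  p$counts[only, ] <- 0L
  h <- assemble_haplotype(p, ref)
  expect_true(all(only %in% h$coverage_mask))
  lost <- vapply(hap, function(v) parse_variant(v)$position %in% only,
                 logical(1))
  expect_setequal(h$calls$rendered, hap[!lost])
})

test_that("raising thresholds never adds heteroplasmy calls or shrinks the mask", {
  ref <- fx_ref()
  hap <- data.frame(variant = random_haplotype(ref, 12, seed = 33),
                    frequency = runif(12, 0.08, 0.5))
  sc <- fx_scenario(hap, depth = 60, error = error_model(0.002, 0.005),
                    seed = 8)
  sc$depth$sdlog <- 0.8
  sim <- simulate_pileup(sc)
  lo <- assemble_haplotype(sim$pileup, ref, th = calling_thresholds())
  hi <- assemble_haplotype(sim$pileup, ref,
                           th = calling_thresholds(php_min = 0.15))
  expect_true(all(hi$calls$rendered[hi$calls$kind == "heteroplasmy"] %in%
                    lo$calls$rendered))
  deep <- assemble_haplotype(sim$pileup, ref,
                             th = calling_thresholds(min_depth = 50))
  expect_true(all(lo$coverage_mask %in% deep$coverage_mask))
})

test_that("suspect deletions are suppressed but kept in the audit record", {
  ref <- fx_ref()
  # 46% deletion reads at the 303-309 C tract: right-aligned to 309del
  sim <- simulate_pileup(fx_scenario(c("305del"), seed = 9), exact = TRUE)
  p <- sim$pileup
  pc <- position_counts(p, 305)
  expect_gt(sum(pc$counts["del", ]) / total_depth(pc), 0.4)
  h <- assemble_haplotype(p, ref)
  expect_true("309del" %in% h$calls$rendered)
  h2 <- apply_suspect_deletions(h)
  expect_equal(h2$calls$status[h2$calls$rendered == "309del"],
               "suppressed_suspect")
  expect_false(grepl("309del", export_haplotype(h2)))
  # empty suspect list is the identity transform
  h3 <- apply_suspect_deletions(h, character(0))
  expect_equal(h3$calls, h$calls)
})

test_that("heteroplasmies matching the NUMT catalog become N-calls", {
  ref <- fx_ref()
  pos <- 8943L
  nav <- alt_base(ref, pos)
  hap <- data.frame(variant = paste0(pos, iupac_code(ref_base(ref, pos), nav)),
                    frequency = 0.31)
  sim <- simulate_pileup(fx_scenario(hap, seed = 10), exact = TRUE)
  h <- assemble_haplotype(sim$pileup, ref)
  expect_equal(h$calls$kind, "heteroplasmy")
  catalog <- data.frame(position = pos, allele = nav)
  h2 <- flag_nav(h, catalog)
  expect_equal(h2$calls$rendered, paste0(pos, "N"))
  expect_equal(h2$calls$status, "uncalled_N")
  expect_match(export_haplotype(h2), paste0(pos, "N"))
  # no catalog hits: identity
  expect_equal(flag_nav(h, data.frame(position = 1, allele = "A"))$calls,
               h$calls)
  # catalog allele as the dominant (>= 90%) allele is a true variant
  sub <- simulate_pileup(fx_scenario(paste0(pos, nav), seed = 10),
                         exact = TRUE)
  hs <- assemble_haplotype(sub$pileup, ref)
  expect_equal(hs$calls$kind, "substitution")
  expect_equal(flag_nav(hs, catalog)$calls$rendered, paste0(pos, nav))
})

test_that("count_navs rises as depth falls against a fixed NUMT read count", {
  ref <- fx_ref()
  positions <- c(800L, 3200L, 6400L, 9000L, 12000L, 15500L)
  catalog <- data.frame(position = positions,
                        allele = vapply(positions, alt_base, character(1),
                                        ref = ref))
  sc <- fx_scenario(character(0), depth = 1280,
                    numt = numt_model(catalog, reads = 12L), seed = 9)
  series <- dilution_series(sc, 0.5^(0:6))
  navs <- vapply(series, function(s) count_navs(s$pileup, catalog),
                 integer(1))
  expect_true(all(diff(navs) >= 0))
  expect_equal(navs[1], 0L)
  expect_equal(navs[length(navs)], nrow(catalog))
})

test_that("exported text lists confirmed calls and annotates masked ranges", {
  ref <- fx_ref()
  a263 <- alt_base(ref, 263)
  hap <- c(paste0(263, a263), "309.1C", "315.1C")
  sim <- simulate_pileup(fx_scenario(hap, seed = 11), exact = TRUE)
  h <- assemble_haplotype(sim$pileup, ref)
  expect_equal(export_haplotype(h),
               paste(paste0(263, a263), "309.1C", "315.1C"))
  # zero-call, zero-coverage haplotype: empty string + full-range annotation
  empty <- assemble_haplotype(mt_pileup("none", L = ref$L), ref)
  out <- export_haplotype(empty)
  expect_match(out, "^\\n# positions below minimum depth: 1-16569$")
})

test_that("VCF export writes anchored indels and filter labels", {
  ref <- fx_ref()
  a500 <- alt_base(ref, 500)
  hap <- c(paste0(500, a500), "305del", "315.1C")
  sim <- simulate_pileup(fx_scenario(hap, seed = 12), exact = TRUE)
  h <- assemble_haplotype(sim$pileup, ref)
  h <- apply_suspect_deletions(h)
  vcf <- withr::local_tempfile(fileext = ".vcf")
  export_vcf(h, ref, vcf)
  lines <- readLines(vcf)
  expect_true(any(grepl("^##fileformat=VCFv4.2", lines)))
  body <- lines[!startsWith(lines, "#")]
  expect_equal(length(body), 3)
  sub_row <- strsplit(body[grepl(paste0(500, a500), body)], "\t")[[1]]
  expect_equal(sub_row[2], "500")
  expect_equal(sub_row[5], a500)
  del_row <- strsplit(body[grepl("309del", body)], "\t")[[1]]
  expect_equal(del_row[2], "308")  # anchored one base 5'
  expect_equal(del_row[7], "suspect_deletion")
  ins_row <- strsplit(body[grepl("\\.insC", body)], "\t")[[1]]
  expect_equal(nchar(ins_row[5]), 2)  # anchor base + inserted base
})
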