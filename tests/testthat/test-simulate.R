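test_that("reference-only libraries are almost entirely concordant", {
  g <- build_toy_genome(seed = 1)
  m <- insert_model()
  pr <- simulate_pairs(as_donor(g), m, coverage = 30, seed = 2)
  # conservation: requested totals are met exactly
  expect_identical(nrow(pr), as.integer(round(30 * 600000 / (2 * 101))))
  cp <- classify_pairs(pr, m)
  # Normal tail beyond 3 sd: expected anomalous fraction ~ 0.0027
  expect_lt(mean(cp$is_anomalous), 0.01)
  expect_true(all(cp$orientation[cp$is_anomalous] == "FACING"))
  # determinism: identical seeds give byte-identical tables
  expect_identical(pr, simulate_pairs(as_donor(g), m, coverage = 30, seed = 2))
  expect_false(identical(pr,
    simulate_pairs(as_donor(g), m, coverage = 30, seed = 3)))
})

test_that("junction-straddling pairs are recovered with the truth orientation", {
  g <- build_toy_genome(seed = 1)
  m <- insert_model()
  res <- implant_events(g, sv_deletion("chr1", 50000, 90000))
  j <- res$truth$junctions
  pr <- simulate_pairs(res$donor, m, coverage = 30, seed = 5)
  cp <- classify_pairs(pr, m)
  near <- cp$is_anomalous & cp$chrom1 == "chr1" &
    abs(cp$pos1 - j$pos_a) < 600 & abs(cp$pos2 - j$pos_b) < 600
  # expected straddlers ~ coverage * (mu - 2L) / mu ~ 18
  expect_gte(sum(near), 5)
  expect_true(all(cp$orientation[near] == j$orientation))
})

test_that("degenerate coverage and short donors are handled", {
  g <- build_toy_genome(seed = 1)
  pr <- simulate_pairs(as_donor(g), insert_model(), coverage = 0.0001,
                       seed = 1)
  expect_lte(nrow(pr), 1)  # possibly zero pairs, no crash
  tiny <- build_toy_genome(seed = 1, n_chroms = 1, chrom_length = 700,
                           n_genes = 0)
  expect_error(simulate_pairs(as_donor(tiny), insert_model(), coverage = 1),
               "shorter than the maximum insert")
})

test_that("repeat-like regions emit mapq-0 mates and clustered anomalies", {
  g <- build_toy_genome(seed = 5, n_chroms = 2, chrom_length = 200000,
                        n_genes = 20)
  g$repeat_regions <- data.frame(chrom = c("chr1", "chr2"),
                                 start = c(40000, 100000),
                                 end = c(50000, 110000))
  pr <- simulate_pairs(as_donor(g), insert_model(), coverage = 20, seed = 6,
                       sample = "normal")
  in_r1 <- pr$chrom1 == "chr1" & pr$pos1 > 40000 & pr$pos1 <= 50000
  expect_gt(sum(pr$mapq_min[in_r1] == 0), 0)
  noise <- grepl("^noise", pr$pair_id)
  expect_gt(sum(noise), 10)
  cp <- classify_pairs(pr, insert_model())
  expect_true(all(cp$is_anomalous[grepl("^noise", cp$pair_id)]))
  # without declared repeats the same genome emits neither
  g2 <- g; g2$repeat_regions <- NULL
  pr2 <- simulate_pairs(as_donor(g2), insert_model(), coverage = 20, seed = 6)
  expect_identical(sum(pr2$mapq_min == 0), 0L)
})

test_that("probe simulation reproduces log2 copy ratios", {
  g <- build_toy_genome(seed = 1)
  cn <- data.frame(chrom = "chr1", start = 50000, end = 80000,
                   total_copies = 8)
  pr0 <- simulate_probes(g, cn, spacing = 1000, noise_sd = 0, seed = 1)
  mid <- (pr0$start + pr0$end) / 2
  inside <- pr0$chrom == "chr1" & mid >= 50000 & mid < 80000
  expect_true(all(pr0$log2ratio[inside] == 2))   # log2(8/2)
  expect_true(all(pr0$log2ratio[!inside] == 0))  # log2(2/2)
  # noise sd is calibrated
  prn <- simulate_probes(g, NULL, spacing = 50, noise_sd = 0.2, seed = 2)
  expect_gt(nrow(prn), 10000)
  expect_lt(abs(sd(prn$log2ratio) - 0.2), 0.01)
})

test_that("DNA-content histograms conserve events and flag unresolvable mixes", {
  h <- simulate_histogram(seed = 1)
  expect_identical(sum(h$count), 50000L)
  expect_gte(length(h$channel), 1024L)
  # single-population degenerate case: one peak only
  h1 <- simulate_histogram(dna_index = 1, g2m_fraction = 0, cv = 0.04,
                           n_events = 20000, diploid_fraction = 0,
                           seed = 2) |> suppressWarnings()
  expect_identical(sum(h1$count), 20000L)
  expect_true(h1$unresolvable)
  expect_warning(simulate_histogram(dna_index = 1.05, cv = 0.04,
                                    n_events = 1000, seed = 3),
                 "unresolvable")
})

test_that("variant tables encode somatic/germline structure by construction", {
  g <- build_toy_genome(seed = 1)
  som <- data.frame(chrom = "chr1", pos = c(1000L, 2000L, 3000L, 4000L, 5000L),
                    ref = "G", alt = "A")
  v <- simulate_variant_table(som, g, n_germline = 40,
                              prob_range = c(0.9, 0.99), seed = 7)
  expect_identical(nrow(v), 45L)
  expect_true(all(v$normal_alt_reads[v$is_somatic_truth] == 0))
  expect_true(all(v$normal_alt_reads[!v$is_somatic_truth] >= 1))
  expect_true(all(v$ref != v$alt))
  # somatic filter recovers the truth exactly when all probabilities pass
  s <- filter_somatic(v)
  expect_identical(sort(s$pos[s$chrom == "chr1" & s$is_somatic_truth]),
                   som$pos)
  expect_identical(nrow(s), 5L)
})

test_that("read pairs round-trip through TSV and minimal SAM", {
  g <- build_toy_genome(seed = 1)
  pr <- simulate_pairs(as_donor(g), insert_model(), coverage = 0.5, seed = 9)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_pairs(pr, tsv)
  expect_identical(read_pairs(tsv), pr)
  sam <- withr::local_tempfile(fileext = ".sam")
  write_sam_pairs(pr, g, sam)
  back <- read_sam_pairs(sam)
  rownames(back) <- NULL
  expect_identical(back, pr)
})
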