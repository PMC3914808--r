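test_that("flat profiles stay unsplit and clean steps split exactly", {
  p0 <- data.frame(chrom = "c1", start = 0:99 * 1000, end = 1:100 * 1000,
                   log2ratio = 0)
  s0 <- call_states(segment_probes(p0))
  expect_identical(nrow(s0), 1L)
  expect_identical(s0$state, "neutral")
  expect_identical(s0$n_probes, 100L)

  p1 <- p0
  p1$log2ratio <- rep(c(0, 2), each = 50)
  s1 <- segment_probes(p1)
  expect_identical(nrow(s1), 2L)
  expect_equal(s1$end[1], 50000)   # split exactly between probes 50/51
  expect_equal(s1$start[2], 50000)
  expect_equal(s1$mean_log2, c(0, 2))
})

test_that("noisy steps are recovered near the truth and match the scan oracle", {
  step_probes <- function(seed, n = 120, sp = 55, delta = 2, sd = 0.2) {
    set.seed(seed)
    data.frame(chrom = "c1", start = 0:(n - 1) * 1000, end = 1:n * 1000,
               log2ratio = c(rnorm(sp, 0, sd), rnorm(n - sp, delta, sd)))
  }
  for (seed in 1:5) {
    p <- step_probes(seed)
    s <- segment_probes(p)
    # split within +/- 2 probes of the true change point
    expect_identical(nrow(s), 2L)
    expect_lte(abs(s$n_probes[1] - 55L), 2L)
    # exhaustive split-scan oracle agrees segment for segment
    oracle <- oracle_segment(p$log2ratio)
    expect_identical(nrow(s), length(oracle))
    expect_identical(s$n_probes,
                     vapply(oracle, function(b) b[2] - b[1] + 1L, integer(1)))
  }
  # multi-step profile against the oracle
  set.seed(99)
  x <- c(rnorm(40, 0, 0.15), rnorm(50, 1.5, 0.15), rnorm(40, -1, 0.15),
         rnorm(70, 0, 0.15))
  p <- data.frame(chrom = "c1", start = seq_along(x) - 1, end = seq_along(x),
                  log2ratio = x)
  s <- segment_probes(p)
  oracle <- oracle_segment(x)
  expect_identical(s$n_probes,
                   vapply(oracle, function(b) b[2] - b[1] + 1L, integer(1)))
})

test_that("probes are conserved and segment means reproduce the grand mean", {
  g <- build_toy_genome(seed = 3)
  cn <- data.frame(chrom = c("chr1", "chr2"), start = c(40000, 100000),
                   end = c(90000, 140000), total_copies = c(8L, 1L))
  pr <- simulate_probes(g, cn, spacing = 1000, noise_sd = 0.2, seed = 4)
  s <- segment_probes(pr)
  expect_identical(sum(s$n_probes), nrow(pr))
  for (cname in unique(pr$chrom)) {
    sc <- s[s$chrom == cname, ]
    pc <- pr[pr$chrom == cname, ]
    expect_equal(sum(sc$mean_log2 * sc$n_probes) / sum(sc$n_probes),
                 mean(pc$log2ratio))
    # segments are ordered, non-overlapping, and cover all probes
    expect_true(all(sc$start[-1] == sc$end[-nrow(sc)]))
  }
})

test_that("state calls follow the gain/loss thresholds", {
  seg <- data.frame(chrom = "c", start = 0, end = 1,
                    mean_log2 = c(2, -1, 0, 0.58, -0.58, 0.5),
                    n_probes = 10)
  st <- call_states(seg, concordance_params())$state
  expect_identical(st, c("gain", "loss", "neutral", "gain", "loss",
                         "neutral"))
})

test_that("called gains overlap truth amplicons (Jaccard >= 0.9)", {
  g <- build_toy_genome(seed = 7)
  res <- implant_events(g, sv_amplicon("chr2", 60000, 120000, copies = 7))
  truth_cn <- res$truth$copy_number
  pr <- simulate_probes(g, truth_cn, spacing = 1000, noise_sd = 0.2, seed = 8)
  s <- call_states(segment_probes(pr))
  gains <- s[s$state == "gain", ]
  expect_gte(nrow(gains), 1)
  inter <- sum(pmax(0, pmin(gains$end, truth_cn$end[1]) -
                      pmax(gains$start, truth_cn$start[1])))
  un <- sum(gains$end - gains$start) +
    (truth_cn$end[1] - truth_cn$start[1]) - inter
  expect_gte(inter / un, 0.9)
})

test_that("breakpoint concordance matches greedily within tolerance", {
  seg <- call_states(data.frame(chrom = "c1", start = c(0, 100000),
                                end = c(100000, 200000),
                                mean_log2 = c(2, 0), n_probes = 50))
  fus <- data.frame(chrom1 = "c1", breakpoint1 = 104000,
                    chrom2 = "c2", breakpoint2 = 500)
  mb <- match_breakpoints(seg, fus, concordance_params(tolerance = 10000))
  expect_identical(nrow(mb$matched), 1L)
  expect_equal(mb$matched$distance, 4000)
  expect_equal(mb$matched$boundary_pos, 100000)
  expect_identical(nrow(mb$unmatched_fusion_breakpoints), 1L)

  # identical coordinates match at tolerance zero
  fus2 <- data.frame(chrom1 = "c1", breakpoint1 = 0,
                     chrom2 = "c1", breakpoint2 = 100000)
  mb2 <- match_breakpoints(seg, fus2, concordance_params(tolerance = 0))
  expect_identical(nrow(mb2$matched), 2L)
  expect_true(all(mb2$matched$distance == 0))

  # empty fusion list: all boundaries unmatched
  mb3 <- match_breakpoints(seg, fus2[0, ], concordance_params())
  expect_identical(nrow(mb3$matched), 0L)
  expect_identical(nrow(mb3$unmatched_boundaries), 2L)

  # each fusion breakpoint consumed at most once
  seg2 <- call_states(data.frame(chrom = "c1", start = c(0, 99000),
                                 end = c(99000, 200000),
                                 mean_log2 = c(2, 0), n_probes = 50))
  fus3 <- data.frame(chrom1 = "c1", breakpoint1 = 99500,
                     chrom2 = "c2", breakpoint2 = 1)
  mb4 <- match_breakpoints(seg2, fus3, concordance_params())
  expect_identical(sum(mb4$matched$fusion == 1 &
                         mb4$matched$chrom == "c1"), 1L)
})
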