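test_that("classification reproduces the exhaustive strand/span truth table", {
  m <- insert_model()  # window [350, 650], read length 101
  far <- 10 * m$mean_insert
  cases <- expand.grid(s1 = c("+", "-"), s2 = c("+", "-"),
                       inter = c(FALSE, TRUE), stringsAsFactors = FALSE)
  expected <- function(s1, s2, inter) {
    ori <- c("+-" = "FACING", "-+" = "OPPOSING",
             "++" = "SAME_FORWARD", "--" = "SAME_REVERSE")[paste0(s1, s2)]
    reason <- if (inter) "interchromosomal"
              else if (paste0(s1, s2) == "+-") "oversized_span"
              else "orientation"
    c(unname(ori), reason)
  }
  for (i in seq_len(nrow(cases))) {
    cs <- cases[i, ]
    p <- mk_pair("chr11", 1000, cs$s1,
                 if (cs$inter) "chr12" else "chr11",
                 if (cs$inter) 1000 else 1000 + far, cs$s2)
    got <- classify_pairs(p, m)
    exp <- expected(cs$s1, cs$s2, cs$inter)
    expect_true(got$is_anomalous)
    expect_identical(got$orientation, exp[1])
    expect_identical(got$reason, exp[2])
  }
})

test_that("concordance window is inclusive at both boundaries", {
  m <- insert_model()
  span_to_pos2 <- function(span) 1000 + span - m$read_length
  for (span in c(350, 500, 650)) {
    got <- classify_pairs(mk_pair("chr1", 1000, "+", "chr1",
                                  span_to_pos2(span), "-"), m)
    expect_identical(got$orientation, "CONCORDANT")
    expect_false(got$is_anomalous)
    expect_identical(got$reason, "none")
  }
  for (span in c(349, 651)) {
    got <- classify_pairs(mk_pair("chr1", 1000, "+", "chr1",
                                  span_to_pos2(span), "-"), m)
    expect_identical(got$orientation, "FACING")
    expect_identical(got$reason, "oversized_span")
  }
})

test_that("classification requires and is invariant under canonical order", {
  m <- insert_model()
  p <- mk_pair("chr2", 5000, "-", "chr1", 1000, "+")
  expect_error(classify_pairs(p, m), "canonical")
  swapped <- canonicalize_pairs(p)
  expect_identical(swapped$chrom1, "chr1")
  expect_identical(swapped$strand1, "+")
  # swapping mate storage and re-canonicalizing changes nothing
  expect_identical(classify_pairs(canonicalize_pairs(swapped), m),
                   classify_pairs(swapped, m))
  # numeric-aware chromosome order: chr2 before chr10
  q <- canonicalize_pairs(mk_pair("chr10", 50, "+", "chr2", 9000, "-"))
  expect_identical(q$chrom1, "chr2")
})

test_that("orientation labels match the report vocabulary", {
  expect_identical(orientation_label(c("FACING", "OPPOSING")),
                   c("Facing", "Opposing"))
  expect_identical(orientation_label("SAME_FORWARD"),
                   "Same direction – forward")
  expect_identical(orientation_label("SAME_REVERSE"),
                   "Same direction – reverse")
  expect_error(orientation_label("CONCORDANT"), "no orientation label")
  # label round trip
  labs <- orientation_label(c("FACING", "OPPOSING", "SAME_FORWARD",
                              "SAME_REVERSE"))
  expect_identical(pairfuse:::orientation_from_label(labs),
                   c("FACING", "OPPOSING", "SAME_FORWARD", "SAME_REVERSE"))
})

test_that("window summaries count mates, anomalies and poor mapq", {
  m <- insert_model()
  grid <- make_windows(c(chrA = 6500, chrB = 6500), m)
  expect_identical(grid$window_size, 650L)

  # empty input: all-zero counts
  s0 <- summarize_windows(mk_pairs(mk_pair("chrA", 1, "+", "chrA", 449, "-"))[0, ],
                          grid, m)
  expect_true(all(s0$n_total == 0) && all(s0$n_anomalous == 0))

  # 5 concordant pairs + 2 anomalous pairs, all mates in window 1
  conc <- do.call(rbind, lapply(1:5, function(i)
    mk_pair("chrA", 10 + i, "+", "chrA", 10 + i + 399, "-")))
  anom <- do.call(rbind, lapply(1:2, function(i)
    mk_pair("chrA", 100 + i, "-", "chrA", 200 + i, "+")))
  s <- summarize_windows(rbind(conc, anom), grid, m)
  expect_identical(s$n_total[1], 14L)
  expect_identical(s$n_anomalous[1], 4L)
  expect_identical(s$n_poor_mapq[1], 0L)

  # conservation: summed mates = 2 x pairs, regardless of placement
  sc <- recall_scenario(seed = 3)
  pr <- simulate_pairs(as_donor(sc$genome), m, coverage = 1, seed = 4)
  grid2 <- make_windows(sc$genome, m)
  s2 <- summarize_windows(pr, grid2, m)
  expect_identical(sum(s2$n_total), 2L * nrow(pr))

  # chromosome absent from the grid is an explicit error
  expect_error(summarize_windows(mk_pair("chrZ", 5, "+", "chrZ", 449, "-"),
                                 grid, m), "absent")
})

test_that("poor-mapq mates are counted against the threshold", {
  m <- insert_model()
  grid <- make_windows(c(chrA = 1300), m)
  p <- rbind(mk_pair("chrA", 5, "+", "chrA", 404, "-", mapq_min = 0),
             mk_pair("chrA", 6, "+", "chrA", 405, "-", mapq_min = 60))
  s <- summarize_windows(p, grid, m, mapq_threshold = 20)
  expect_identical(s$n_poor_mapq[1], 2L)  # both mates of the mapq-0 pair
  expect_identical(s$n_total[1], 4L)
})
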