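test_that("window grids derive their size from the insert model and tile exactly", {
  m <- insert_model()
  expect_identical(make_windows(c(c1 = 6500), m)$window_size, 650L)
  g <- make_windows(c(c1 = 1300), m)$windows
  expect_identical(g$start, c(0L, 650L))
  expect_identical(g$end, c(650L, 1300L))
  g2 <- make_windows(c(c1 = 1000), m)$windows
  expect_identical(g2$end, c(650L, 1000L))  # short tail window
  # every base belongs to exactly one window
  grid <- make_windows(c(a = 2000, b = 1300), m)
  ids <- window_ids(grid, rep("a", 2000), 1:2000)
  expect_identical(as.integer(table(ids)), c(650L, 650L, 650L, 50L))
  expect_identical(window_ids(grid, "b", 1), 5L)
})

test_that("blacklisting follows the fraction rules with an evidence floor", {
  p <- caller_params()
  mk_summary <- function(total, anom, poor) {
    data.frame(wid = seq_along(total), chrom = "c", start = 0, end = 650,
               n_total = total, n_anomalous = anom, n_poor_mapq = poor)
  }
  # 30% anomalous >= 20% threshold -> blacklisted
  expect_identical(build_blacklist(mk_summary(100, 30, 0), p), 1L)
  # below the evidence floor nothing is blacklisted
  expect_identical(build_blacklist(mk_summary(5, 5, 0), p), integer(0))
  # poor-mapq route
  expect_identical(build_blacklist(mk_summary(20, 0, 10), p), 1L)
  expect_identical(build_blacklist(mk_summary(20, 0, 9), p), integer(0))
  # a clean genome yields an empty blacklist
  g <- build_toy_genome(seed = 1)
  m <- insert_model()
  grid <- make_windows(g, m)
  np <- simulate_pairs(as_donor(g), m, coverage = 20, seed = 2,
                       sample = "normal")
  expect_identical(build_blacklist(summarize_windows(np, grid, m), p),
                   integer(0))
})

test_that("window links respect support floors, mapq and the blacklist", {
  m <- insert_model()
  grid <- make_windows(c(cA = 65000, cB = 65000), m)
  anom_pair <- function(i, mapq = 60)
    mk_pair("cA", 1000 + i, "+", "cB", 30000 + i, "+", mapq_min = mapq)
  five <- do.call(rbind, lapply(1:5, anom_pair))
  links <- link_windows(five, grid, integer(0), m, caller_params())
  expect_identical(nrow(links), 1L)
  expect_identical(links$support, 5L)
  expect_identical(links$n_same_forward, 5L)
  # blacklisting either window suppresses the link
  wb <- window_ids(grid, "cB", 30001)
  expect_identical(nrow(link_windows(five, grid, wb, m, caller_params())), 0L)
  # support below the floor
  two <- do.call(rbind, lapply(1:2, anom_pair))
  expect_identical(nrow(link_windows(two, grid, integer(0), m,
                                     caller_params())), 0L)
  # poorly mapped pairs contribute nothing
  poor <- do.call(rbind, lapply(1:5, anom_pair, mapq = 5))
  expect_identical(nrow(link_windows(poor, grid, integer(0), m,
                                     caller_params())), 0L)
})

test_that("breakpoints are refined to the innermost mate edges", {
  # one + mate covering [100, 200] on side A (read length 101)
  sup <- mk_pair("c", 100, "+", "c", 500, "-")
  bp <- refine_breakpoints(sup, "FACING", read_length = 101)
  expect_identical(bp, c(200L, 500L))
  # several supporters: innermost edge wins on each side
  sup3 <- mk_pairs(mk_pair("c", 100, "+", "c", 500, "-"),
                   mk_pair("c", 150, "+", "c", 480, "-"),
                   mk_pair("c", 120, "+", "c", 520, "-"))
  expect_identical(refine_breakpoints(sup3, "FACING"), c(250L, 480L))
  expect_identical(refine_breakpoints(sup3, "OPPOSING"), c(100L, 620L))
  expect_error(refine_breakpoints(sup3[0, ], "FACING"), "at least one")
})

test_that("candidates require coding genes in both windows", {
  m <- insert_model()
  genome <- structure(list(
    chrom_names = c("cA", "cB"),
    chrom_lengths = c(cA = 65000L, cB = 65000L),
    genes = data.frame(
      gene = c("geneA", "geneB", "geneN"),
      chrom = c("cA", "cB", "cA"),
      start = c(500L, 29500L, 40000L), end = c(2500L, 31500L, 42000L),
      strand = "+", is_coding = c(TRUE, TRUE, FALSE)),
    repeat_regions = NULL), class = "toy_genome")
  grid <- make_windows(genome$chrom_lengths, m)
  in_genes <- do.call(rbind, lapply(1:5, function(i)
    mk_pair("cA", 1000 + i, "+", "cB", 30000 + i, "+")))
  links <- link_windows(in_genes, grid, integer(0), m, caller_params())
  cands <- annotate_fusions(links, in_genes, genome, grid, m, caller_params())
  expect_identical(nrow(cands), 1L)
  expect_identical(cands$gene1, "geneA")
  expect_identical(cands$gene2, "geneB")
  expect_identical(cands$kind, "translocation")
  expect_identical(cands$orientation_label, "Same direction – forward")
  # a link with one end in a non-coding gene produces no candidate
  nc <- do.call(rbind, lapply(1:5, function(i)
    mk_pair("cA", 41000 + i, "+", "cB", 30000 + i, "+")))
  links_nc <- link_windows(nc, grid, integer(0), m, caller_params())
  expect_identical(nrow(annotate_fusions(links_nc, nc, genome, grid, m,
                                         caller_params())), 0L)
})

test_that("gene assignment prefers maximal overlap with lexicographic ties", {
  grid <- make_windows(c(cA = 1300), insert_model())
  genes <- data.frame(gene = c("zeta", "beta"), chrom = "cA",
                      start = c(0L, 100L), end = c(650L, 550L),
                      strand = "+", is_coding = TRUE)
  # zeta overlaps the whole window, beta only part of it
  expect_identical(pairfuse:::gene_for_window(grid, 1L, genes), "zeta")
  # exact tie: lexicographically smaller name
  genes2 <- data.frame(gene = c("zeta", "beta"), chrom = "cA",
                       start = 0L, end = 650L, strand = "+",
                       is_coding = TRUE)
  expect_identical(pairfuse:::gene_for_window(grid, 1L, genes2), "beta")
})

test_that("the partner filter flags multi-partner genes without deleting", {
  cands <- data.frame(gene1 = c("A", "A", "D"), gene2 = c("B", "C", "E"),
                      stringsAsFactors = FALSE)
  out <- partner_filter(cands, caller_params())
  expect_identical(out$passes_partner_filter, c(TRUE, TRUE, FALSE))
  expect_identical(nrow(out), 3L)  # deletion-free
  expect_identical(nrow(partner_filter(cands[0, ], caller_params())), 0L)
})

test_that("the partner filter is monotone under added candidates", {
  set.seed(42)
  genes <- LETTERS[1:8]
  for (rep in 1:20) {
    n <- sample(2:10, 1)
    cand <- data.frame(gene1 = sample(genes, n, replace = TRUE),
                       gene2 = sample(genes, n, replace = TRUE),
                       stringsAsFactors = FALSE)
    cand <- cand[cand$gene1 != cand$gene2, , drop = FALSE]
    if (!nrow(cand)) next
    base <- partner_filter(cand, caller_params())
    extra <- data.frame(gene1 = sample(genes, 2, replace = TRUE),
                        gene2 = sample(genes, 2, replace = TRUE))
    extra <- extra[extra$gene1 != extra$gene2, , drop = FALSE]
    grown <- partner_filter(rbind(cand, extra), caller_params())
    expect_true(all(grown$passes_partner_filter[seq_len(nrow(cand))] >=
                      base$passes_partner_filter))
  }
})

test_that("hotspot scanning counts cluster-touching events", {
  cands <- data.frame(gene1 = c("A", "B", "C"), gene2 = c("X", "Y", "A"))
  expect_identical(hotspot_scan(cands, c("A")),
                   c(n_in_cluster = 2L, n_total = 3L))
  expect_identical(hotspot_scan(cands, unique(unlist(cands)))[["n_in_cluster"]],
                   3L)
  expect_identical(hotspot_scan(cands, "ZZZ")[["n_in_cluster"]], 0L)
  expect_error(hotspot_scan(cands, character(0)), "non-empty")
})

test_that("blacklisting suppresses calls in declared repeat-like regions", {
  g <- build_toy_genome(seed = 5, n_chroms = 2, chrom_length = 200000,
                        n_genes = 20)
  gn <- g$genes
  c1 <- which(gn$chrom == "chr1"); c2 <- which(gn$chrom == "chr2")
  g$repeat_regions <- data.frame(
    chrom = c("chr1", "chr2"),
    start = c(gn$start[c1[2]], gn$start[c2[3]]),
    end = c(gn$end[c1[2]], gn$end[c2[3]]))
  m <- insert_model()
  np <- simulate_pairs(as_donor(g), m, coverage = 30, seed = 6,
                       sample = "normal")
  tp <- simulate_pairs(as_donor(g), m, coverage = 30, seed = 7)
  disabled <- call_fusions(tp, NULL, g, m)
  enabled <- call_fusions(tp, np, g, m)
  expect_gt(nrow(disabled$candidates), 0)
  expect_identical(nrow(enabled$candidates), 0L)
  expect_gt(length(enabled$blacklist), 0)
})
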