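test_that("coverage and context filtering is inclusive and per-sample", {
  meth <- matrix(c(5L, 5L, 4L, 6L, 5L, 5L), 3, 2)
  unmeth <- matrix(c(5L, 4L, 5L, 4L, 5L, 6L), 3, 2)
  colnames(meth) <- colnames(unmeth) <- c("s1", "s2")
  mt <- make_methyl_table(meth, unmeth,
                          context = c("CpG", "CpG", "CHH"))
  # coverages: site1 10/10, site2 9/10, site3 (CHH) 9/11
  f <- filter_cytosines(mt, min_coverage = 10, context = "CpG")
  expect_equal(nrow(f$sites), 1)
  expect_equal(f$sites$pos, 10L)
  f9 <- filter_cytosines(mt, min_coverage = 9, context = "CpG")
  expect_equal(nrow(f9$sites), 2)
  expect_error(filter_cytosines(mt, context = "CPG"), "context")
})

test_that("window aggregation uses floor((pos-1)/size) and pools counts", {
  meth <- matrix(c(5L, 3L, 2L), 3, 1, dimnames = list(NULL, "s1"))
  unmeth <- matrix(c(5L, 7L, 8L), 3, 1, dimnames = list(NULL, "s1"))
  mt <- make_methyl_table(meth, unmeth, pos = c(100L, 101L, 40L))
  w <- window_aggregate(mt, window_size = 100)
  expect_equal(w$windows$start, c(0L, 100L))
  expect_equal(w$windows$end, c(100L, 200L))
  # pos 100 and 40 pool into [0,100); pos 101 into [100,200)
  expect_equal(w$meth[, 1], c(7L, 3L))
  expect_equal(w$unmeth[, 1], c(13L, 7L))
  expect_equal(w$windows$n_cytosines, c(2L, 1L))
})

test_that("window pooled counts conserve per-sample totals", {
  cfg <- small_config()
  design <- study_design()
  truth <- ground_truth(design, n_windows = 200, n_transcripts = 300,
                        n_dmr_salinity = c(2, 4, 8),
                        n_de_private = c(2, 5, 10), seed = 5)
  meta <- generate_metadata(design, seed = 5)
  mt <- simulate_methylome(design, truth, meta, n_cytosines = 2000,
                           n_windows = 200, seed = 5)
  f <- filter_cytosines(mt)
  w <- window_aggregate(f)
  expect_equal(colSums(w$meth), unname(colSums(f$meth)))
  expect_equal(colSums(w$unmeth), unname(colSums(f$unmeth)))
  expect_equal(sum(w$windows$n_cytosines), nrow(f$sites))
})

test_that("two-sided Fisher p matches exhaustive enumeration and fisher.test", {
  # all tables with total <= 60 would be slow to sweep exhaustively in a
  # unit test; sweep a dense deterministic subset plus random tables
  tables <- list(c(5, 5, 5, 5), c(10, 90, 50, 50), c(0, 10, 0, 7),
                 c(1, 0, 0, 1), c(0, 0, 0, 0), c(12, 3, 2, 13))
  set.seed(2)
  for (i in 1:80)
    tables[[length(tables) + 1]] <- sample(0:15, 4, replace = TRUE)
  for (tb in tables) {
    p <- fisher_exact_2x2(tb[1], tb[2], tb[3], tb[4])
    expect_equal(p, fisher_enumeration(tb[1], tb[2], tb[3], tb[4]),
                 tolerance = 1e-10)
    if (sum(tb) > 0) {
      pf <- fisher.test(matrix(tb, 2, byrow = TRUE))$p.value
      expect_equal(p, min(pf, 1), tolerance = 1e-10)
    }
  }
  expect_equal(fisher_exact_2x2(5, 5, 5, 5), 1)
  expect_equal(fisher_exact_2x2(0, 10, 0, 7), 1)
})

test_that("Benjamini-Hochberg equals the brute-force step-up on random vectors", {
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04)),
               rep(0.04, 4))
  expect_equal(benjamini_hochberg(0.37), 0.37)
  set.seed(9)
  for (i in 1:1000) {
    p <- runif(sample(1:40, 1))
    expect_equal(benjamini_hochberg(p), bh_bruteforce(p),
                 tolerance = 1e-14)
  }
  # NA handling: family excludes NAs
  p <- c(0.01, NA, 0.02)
  q <- benjamini_hochberg(p)
  expect_true(is.na(q[2]))
  expect_equal(q[c(1, 3)], bh_bruteforce(c(0.01, 0.02)))
  # monotonicity property
  set.seed(10)
  p <- runif(100)
  q <- benjamini_hochberg(p)
  expect_true(all(diff(q[order(p)]) >= -1e-15))
  expect_true(all(q >= p))
})

test_that("dmr_test applies the conjunctive effect + FDR rule with pooling", {
  # window 1: 30/70 vs 55/45 -> effect 25 points; window 2: null
  meth <- matrix(c(15L, 50L, 15L, 50L, 28L, 50L, 27L, 50L), 2, 4)
  unmeth <- matrix(c(35L, 50L, 35L, 50L, 22L, 50L, 23L, 50L), 2, 4)
  colnames(meth) <- colnames(unmeth) <- c("a1", "a2", "b1", "b2")
  mt <- make_methyl_table(meth, unmeth, pos = c(10L, 150L))
  w <- window_aggregate(mt)
  res <- dmr_test(w, c("A", "A", "B", "B"))
  expect_equal(res$effect[1], 100 * (55 / 100 - 30 / 100))
  expect_equal(res$effect[2], 0)
  expect_true(res$significant[1])
  expect_false(res$significant[2])
  expect_true(all(res$q >= res$p_raw, na.rm = TRUE))
  # large effect but weak q is not significant
  res2 <- dmr_test(w, c("A", "A", "B", "B"), q_threshold = 1e-12)
  expect_false(any(res2$significant))
  expect_error(dmr_test(w, c("A", "A", "A", "A")), "two groups")
})

test_that("DMR caller is conservative under the null", {
  design <- study_design()
  meta <- generate_metadata(design, seed = 21)
  truth <- ground_truth(design, n_windows = 500, n_transcripts = 100,
                        n_dmr_treatment = 0, n_dmr_salinity = c(0, 0, 0),
                        n_de_private = c(0, 0, 0), n_de_core = 0,
                        n_de_rho2 = 0, n_de_interaction = 0, seed = 21)
  mt <- simulate_methylome(design, truth, meta, n_cytosines = 5000,
                           n_windows = 500, seed = 21)
  w <- window_aggregate(filter_cytosines(mt))
  res <- dmr_test(w, meta$salinity)
  m <- sum(!is.na(res$q))
  expect_lte(sum(res$significant) / m,
             0.05 + 3 * sqrt(0.05 * 0.95 / m))
})

test_that("DMR caller detects planted 40-point shifts with high sensitivity", {
  # 3 vs 3 pooled samples at coverage 40, ~10 cytosines per window
  set.seed(33)
  n_win <- 200
  n_cyt_per_win <- 10
  shift_windows <- 1:60
  meth <- unmeth <- matrix(0L, n_win, 6)
  colnames(meth) <- colnames(unmeth) <-
    c(paste0("a", 1:3), paste0("b", 1:3))
  base <- runif(n_win, 0.2, 0.5)
  for (s in 1:6) {
    p <- base
    if (s > 3) p[shift_windows] <- p[shift_windows] + 0.4
    cov <- rnbinom(n_win, mu = 40 * n_cyt_per_win, size = 20)
    m <- rbinom(n_win, cov, p)
    meth[, s] <- m
    unmeth[, s] <- cov - m
  }
  w <- structure(list(
    windows = data.frame(chrom = "chr1", start = (0:(n_win - 1)) * 100L,
                         end = (1:n_win) * 100L,
                         n_cytosines = n_cyt_per_win),
    meth = meth, unmeth = unmeth, samples = colnames(meth)),
    class = "methyl_windows")
  res <- dmr_test(w, rep(c("low", "high"), each = 3))
  sens <- mean(res$significant[shift_windows])
  expect_gt(sens, 0.9)
})

test_that("pairwise multi-group DMR testing unions per-pair calls", {
  meth <- matrix(rep(c(20L, 20L, 80L), each = 2), 1)
  unmeth <- matrix(rep(c(80L, 80L, 20L), each = 2), 1)
  colnames(meth) <- colnames(unmeth) <- paste0("s", 1:6)
  mt <- make_methyl_table(meth[rep(1, 1), , drop = FALSE],
                          unmeth[rep(1, 1), , drop = FALSE],
                          pos = 50L)
  w <- window_aggregate(mt)
  out <- dmr_test_pairwise(w, rep(c("A", "B", "C"), each = 2))
  expect_named(out$pairs, c("A.vs.B", "A.vs.C", "B.vs.C"))
  expect_false(out$pairs$A.vs.B$significant[1])
  expect_true(out$pairs$A.vs.C$significant[1])
  expect_equal(out$significant_ids, feature_ids(w))
})

test_that("nearest-TSS assignment minimizes distance with deterministic ties", {
  meth <- matrix(1L, 4, 1, dimnames = list(NULL, "s1"))
  unmeth <- matrix(1L, 4, 1, dimnames = list(NULL, "s1"))
  mt <- make_methyl_table(meth, unmeth, pos = c(500L, 550L, 710L, 95L))
  ann <- data.frame(transcript_id = c("A", "B"), chrom = "chr1",
                    tss = c(400L, 700L), stringsAsFactors = FALSE)
  reg <- assign_nearest_tss(mt, ann)
  # 500 -> A (100 < 200); 550 tie -> A (lower coordinate); 710 -> B;
  # 95 -> A
  expect_equal(reg$assignment$transcript_id, c("A", "A", "B", "A"))
  expect_equal(sort(reg$regions$transcript_id), c("A", "B"))
  expect_equal(reg$regions$n_cytosines[reg$regions$transcript_id == "A"],
               3L)
  expect_equal(reg$meth[reg$regions$transcript_id == "A", 1], 3L)
  # mismatched chromosome warns and returns empty assignment
  ann2 <- data.frame(transcript_id = "X", chrom = "chr9", tss = 1L)
  expect_warning(reg2 <- assign_nearest_tss(mt, ann2), "chromosome")
  expect_equal(nrow(reg2$regions), 0)
})

test_that("nearest-TSS assignment agrees with a GenomicRanges oracle", {
  set.seed(12)
  pos <- sort(sample.int(50000, 300))
  meth <- matrix(1L, 300, 1, dimnames = list(NULL, "s1"))
  mt <- make_methyl_table(meth, meth, pos = pos)
  tss <- sort(sample.int(50000, 40))
  ann <- data.frame(transcript_id = sprintf("t%02d", seq_along(tss)),
                    chrom = "chr1", tss = tss, stringsAsFactors = FALSE)
  reg <- assign_nearest_tss(mt, ann)
  gr_c <- GenomicRanges::GRanges("chr1", IRanges::IRanges(pos, width = 1))
  gr_t <- GenomicRanges::GRanges("chr1", IRanges::IRanges(tss, width = 1))
  hits <- GenomicRanges::distanceToNearest(gr_c, gr_t)
  # GenomicRanges reports gap distance (|pos - tss| - 1 for disjoint
  # single-base ranges)
  expect_equal(pmax(reg$assignment$tss_distance - 1, 0),
               as.numeric(S4Vectors::mcols(hits)$distance))
})

test_that("cis concordance counts region/transcript matches", {
  dm <- data.frame(feature_id = c("t1", "t2", "t3"),
                   significant = c(TRUE, TRUE, FALSE))
  de <- data.frame(feature_id = c("t1", "t4"),
                   significant = c(TRUE, TRUE))
  cc <- cis_concordance(dm, de)
  expect_equal(cc$n_dm, 2)
  expect_equal(cc$n_de_matched, 1)
  expect_equal(cc$matched_ids, "t1")
  cc0 <- cis_concordance(
    data.frame(feature_id = "a", significant = TRUE),
    data.frame(feature_id = "b", significant = TRUE))
  expect_equal(cc0$n_de_matched, 0)
})
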