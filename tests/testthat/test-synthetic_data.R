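test_that("metadata has one record per population x salinity and is deterministic", {
  meta <- generate_metadata(study_design(), seed = 1)
  expect_equal(nrow(meta), 18)
  expect_equal(length(unique(meta$population_id)), 9)
  expect_true(all(table(meta$population_id) == 2))
  meta2 <- generate_metadata(study_design(), seed = 1)
  attr(meta, "series") <- attr(meta2, "series") <- NULL
  expect_identical(meta, meta2)
  # single treatment pair design
  d1 <- study_design(treatments = data.frame(label = c("low", "high"),
                                             rho = c(0, 0.9)),
                     populations_per_treatment = 1)
  expect_equal(nrow(generate_metadata(d1, seed = 1)), 4)
  # realized rho2 tracks the target ordering at the default length
  r2 <- tapply(meta$rho2_realized, meta$treatment, mean)
  expect_lt(r2[["low"]], r2[["intermediate"]])
  expect_lt(r2[["intermediate"]], r2[["high"]])
})

test_that("planted salinity shifts produce the expected pooled methylation difference", {
  design <- study_design()
  truth <- ground_truth(design, n_windows = 100, n_transcripts = 50,
                        n_dmr_treatment = 0, n_dmr_salinity = c(0, 0, 5),
                        n_de_private = c(0, 0, 0), n_de_core = 0,
                        n_de_rho2 = 0, n_de_interaction = 0,
                        meth_shift_range = c(0.4, 0.4), seed = 41)
  meta <- generate_metadata(design, seed = 41)
  mt <- simulate_methylome(design, truth, meta, n_cytosines = 4000,
                           n_windows = 100, mean_coverage = 60, seed = 41)
  w <- window_aggregate(filter_cytosines(mt))
  keep <- meta$treatment == "high"
  res <- dmr_test(subset_samples(w, keep), droplevels(meta$salinity[keep]))
  planted_ids <- feature_ids(w)[match(
    sprintf("chrS1:%d-%d", (truth$dmr$salinity$high$window - 1) * 100,
            truth$dmr$salinity$high$window * 100), feature_ids(w))]
  eff <- res$effect[res$feature_id %in% planted_ids]
  expect_equal(mean(eff), 40, tolerance = 0.12)
  # low-predictability treatment has no planted shift in those windows
  keep_lo <- meta$treatment == "low"
  res_lo <- dmr_test(subset_samples(w, keep_lo),
                     droplevels(meta$salinity[keep_lo]))
  eff_lo <- res_lo$effect[res_lo$feature_id %in% planted_ids]
  expect_lt(max(abs(eff_lo)), 20)
})

test_that("low coverage fails the >= 10 filter for most cytosines", {
  design <- study_design()
  truth <- ground_truth(design, n_windows = 100, n_transcripts = 50,
                        n_dmr_treatment = 2, n_dmr_salinity = c(1, 1, 1),
                        n_de_core = 5, n_de_private = c(1, 1, 1),
                        n_de_rho2 = 2, n_de_interaction = 2, seed = 42)
  meta <- generate_metadata(design, seed = 42)
  mt5 <- simulate_methylome(design, truth, meta, n_cytosines = 1000,
                            n_windows = 100, mean_coverage = 5, seed = 42)
  f <- filter_cytosines(mt5, min_coverage = 10)
  expect_lt(nrow(f$sites) / nrow(mt5$sites), 0.2)
})

test_that("count generator responds to size factors and planted fold changes", {
  design <- study_design()
  truth <- ground_truth(design, n_windows = 50, n_transcripts = 400,
                        n_dmr_salinity = c(1, 1, 1),
                        n_de_private = c(0, 0, 0), n_de_core = 40,
                        n_de_rho2 = 0, n_de_interaction = 0, seed = 43)
  meta <- generate_metadata(design, seed = 43)
  counts <- simulate_counts(design, truth, meta, seed = 43)
  expect_true(is.integer(counts))
  expect_equal(dim(counts), c(400, 18))
  # recovered size factors correlate with the planted ones
  sf_true <- attr(counts, "true_size_factors")
  expect_gt(cor(size_factors(counts), sf_true), 0.95)
  # planted core log2FC recovered from normalized group means
  sl <- stabilized_log(counts)
  core <- truth$de$salinity_core
  hi <- meta$salinity == "high"
  est <- rowMeans(sl[core$transcript, hi]) -
    rowMeans(sl[core$transcript, !hi])
  expect_gt(cor(est, core$lfc), 0.95)
  # determinism
  counts2 <- simulate_counts(design, truth, meta, seed = 43)
  expect_identical(counts, counts2)
})

test_that("morphology generator plants the distance-predictability line", {
  design <- study_design()
  meta <- generate_metadata(design, seed = 44)
  # zero slope, intercept 1, no noise: distances cluster near 1
  truth0 <- ground_truth(design, plasticity_intercept = 1,
                         plasticity_slope = 0, plasticity_noise_sd = 0,
                         n_dmr_salinity = c(1, 1, 1),
                         n_de_private = c(1, 1, 1), seed = 44)
  morph <- simulate_morphology(design, truth0, meta, seed = 44)
  expect_equal(nrow(morph), 9 * 2 * 150)
  rec <- plasticity_records(
    as.matrix(morph[c("FSC", "SSC", "RedB")]),
    data.frame(morph, rho2_realized = meta$rho2_realized[
      match(morph$sample_id, meta$sample_id)]))
  expect_lt(max(abs(rec$distance - 1)), 0.75)
  expect_equal(mean(rec$distance), 1, tolerance = 0.25)
  # near-zero cell variance: sample means equal population means, so
  # distances equal the planted norm almost exactly
  morph0 <- simulate_morphology(design, truth0, meta, cell_sd = 1e-6,
                                seed = 44)
  rec0 <- plasticity_records(
    as.matrix(morph0[c("FSC", "SSC", "RedB")]),
    data.frame(morph0, rho2_realized = meta$rho2_realized[
      match(morph0$sample_id, meta$sample_id)]))
  expect_equal(rec0$distance, rep(1, 9), tolerance = 1e-3)
})

test_that("annotation generator hits the annotated fraction and GFF3 round-trips", {
  ann <- simulate_annotation(n_transcripts = 2000, genome_length = 1e5,
                             annotated_fraction = 0.3, seed = 45)
  n_annot <- length(unique(ann$go_map$transcript_id))
  expect_equal(n_annot, 600)
  expect_true(all(ann$annotation$tss ==
                    ifelse(ann$annotation$strand == "+",
                           ann$annotation$start, ann$annotation$end)))
  expect_error(simulate_annotation(annotated_fraction = 0), "fraction")
  tmp <- tempfile(fileext = ".gff3")
  write_annotation_gff3(ann$annotation, tmp)
  back <- read_annotation_gff3(tmp)
  back <- back[match(ann$annotation$transcript_id, back$transcript_id), ]
  expect_equal(back$start, ann$annotation$start)
  expect_equal(back$end, ann$annotation$end)
  expect_equal(back$tss, ann$annotation$tss)
  unlink(tmp)
})

test_that("tabular writers and readers round-trip", {
  design <- study_design()
  truth <- ground_truth(design, n_windows = 30, n_transcripts = 40,
                        n_dmr_treatment = 2, n_dmr_salinity = c(1, 1, 2),
                        n_de_core = 5, n_de_private = c(1, 1, 1),
                        n_de_rho2 = 3, n_de_interaction = 2, seed = 46)
  meta <- generate_metadata(design, seed = 46)
  mt <- simulate_methylome(design, truth, meta, n_cytosines = 300,
                           n_windows = 30, seed = 46)
  tmp <- tempfile(fileext = ".tsv")
  write_methylation_tsv(mt, tmp)
  back <- read_methylation_tsv(tmp)
  expect_equal(back$meth, mt$meth)
  expect_equal(back$sites$pos, mt$sites$pos)
  counts <- simulate_counts(design, truth, meta, seed = 46)
  write_counts_tsv(counts, tmp)
  cb <- read_counts_tsv(tmp)
  expect_equal(unname(cb), unname(counts), ignore_attr = TRUE)
  expect_equal(colnames(cb), colnames(counts))
  write_metadata_tsv(meta, tmp)
  mb <- read_metadata_tsv(tmp, treatment_levels = levels(meta$treatment))
  expect_equal(mb$sample_id, meta$sample_id)
  expect_equal(levels(mb$treatment), levels(meta$treatment))
  unlink(tmp)
})
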