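test_that("median-of-ratios size factors match hand evaluation", {
  set.seed(4)
  a <- rpois(20, 200) + 1L
  cm <- cbind(s1 = a, s2 = 2L * a)
  sf <- size_factors(cm)
  expect_equal(unname(sf), c(1 / sqrt(2), sqrt(2)), tolerance = 1e-12)
  # identical samples -> all ones
  cm2 <- cbind(a, a, a)
  expect_equal(unname(size_factors(cm2)), rep(1, 3))
  # invariance to transcript order
  perm <- sample(nrow(cm))
  expect_equal(size_factors(cm[perm, ]), sf)
  expect_error(size_factors(matrix(c(0L, 1L, 1L, 0L), 2)), "normalize")
})

test_that("NB IRLS at alpha = 0 matches an independent Poisson GLM solver", {
  set.seed(5)
  for (i in 1:100) {
    n <- 18
    X <- cbind(1, rnorm(n), rbinom(n, 1, 0.5))
    colnames(X) <- c("(Intercept)", "x1", "x2")
    sf <- exp(rnorm(n, 0, 0.2))
    y <- rpois(n, sf * exp(2 + 0.5 * X[, 2] - 0.3 * X[, 3]))
    if (all(y == 0)) next
    f <- fit_nb_glm(y, X, sf, alpha = 0)
    g <- stats::glm(y ~ X[, 2] + X[, 3] + offset(log(sf)),
                    family = poisson())
    expect_equal(unname(f$coefficients), unname(coef(g)),
                 tolerance = 1e-6)
  }
})

test_that("saturated two-group NB fit recovers group means and planted log2FC", {
  y <- c(rep(100L, 5), rep(400L, 5))
  X <- cbind(`(Intercept)` = 1, grp = rep(c(0, 1), each = 5))
  f <- fit_nb_glm(y, X, rep(1, 10), alpha = 0.1)
  expect_equal(unname(f$coefficients["grp"]) / log(2), 2,
               tolerance = 1e-8)
  expect_equal(unname(exp(f$coefficients["(Intercept)"])), 100,
               tolerance = 1e-6)
  # all-zero row is flagged
  f0 <- fit_nb_glm(rep(0L, 10), X, rep(1, 10), alpha = 0.1)
  expect_false(f0$converged)
  expect_error(fit_nb_glm(y, cbind(X, X[, 2]), rep(1, 10), 0.1),
               "rank deficient")
})

test_that("dispersion estimation recovers Poisson and NB regimes", {
  X <- matrix(1, 18, 1, dimnames = list(NULL, "(Intercept)"))
  set.seed(6)
  y_pois <- rpois(18, 500)
  a_pois <- estimate_dispersion(y_pois, X, rep(1, 18))
  expect_lte(as.numeric(a_pois), 0.05)
  # frozen recovery check: alpha = 0.5 at large mean, within 50%
  y_nb <- rnbinom(18, mu = 1000, size = 2)
  a_nb <- as.numeric(estimate_dispersion(y_nb, X, rep(1, 18)))
  expect_gt(a_nb, 0.25)
  expect_lt(a_nb, 0.75)
  # constant row equal to the fitted mean has no overdispersion
  a_const <- as.numeric(estimate_dispersion(rep(50L, 18), X, rep(1, 18)))
  expect_equal(a_const, 1e-8)
})

test_that("Wald test applies the conjunctive FDR + fold-change rule", {
  set.seed(7)
  n <- 12
  X <- cbind(`(Intercept)` = 1, salinityhigh = rep(c(0, 1), each = 6))
  meta_counts <- rbind(
    big = as.integer(round(c(rep(500, 6), rep(2000, 6)))),   # lfc 2
    small = as.integer(round(c(rep(500, 6), rep(707, 6)))),  # lfc 0.5
    null = rep(500L, n))
  fs <- nb_fit_all(meta_counts, X, sf = rep(1, n),
                   alphas = rep(1e-3, 3))
  w <- wald_test(fs, "salinityhigh")
  expect_true(w$significant[w$feature_id == "big"])
  expect_false(w$significant[w$feature_id == "small"]) # effect cutoff
  expect_false(w$significant[w$feature_id == "null"])
  expect_equal(w$log2FC[1], 2, tolerance = 1e-3)
})

test_that("Wald type-I error is near nominal under the null", {
  # asymptotic check: large enough n that the normal Wald reference is
  # accurate (at small n the normal-vs-t gap mildly inflates the rate)
  set.seed(8)
  n_tx <- 400
  n <- 60
  X <- cbind(`(Intercept)` = 1, salinityhigh = rep(c(0, 1), 30))
  counts <- matrix(rnbinom(n_tx * n, mu = 300, size = 10), n_tx, n,
                   dimnames = list(sprintf("t%03d", 1:n_tx), NULL))
  fs <- nb_fit_all(counts, X, sf = rep(1, n))
  w <- wald_test(fs, "salinityhigh")
  rate <- mean(w$p_raw < 0.05, na.rm = TRUE)
  se <- sqrt(0.05 * 0.95 / n_tx)
  expect_lt(abs(rate - 0.05), 3 * se)
  expect_equal(sum(w$significant), 0)
})

test_that("LRT statistic, df and p follow the chi-square reference", {
  set.seed(9)
  n <- 18
  meta <- data.frame(g = factor(rep(c("a", "b", "c"), each = 6)),
                     s = factor(rep(c("lo", "hi"), 9)))
  Xf <- model.matrix(~ g * s, meta)
  Xr <- model.matrix(~ g + s, meta)
  counts <- matrix(rnbinom(20 * n, mu = 200, size = 8), 20, n,
                   dimnames = list(sprintf("t%02d", 1:20), NULL))
  alphas <- rep(0.1, 20)
  full <- nb_fit_all(counts, Xf, sf = rep(1, n), alphas = alphas)
  red <- nb_fit_all(counts, Xr, sf = rep(1, n), alphas = alphas)
  out <- lrt_test(full, red)
  expect_equal(unique(out$df), 2)
  expect_equal(out$p_raw,
               pchisq(out$stat, df = 2, lower.tail = FALSE))
  expect_true(all(out$stat >= 0))
  # identical models are rejected; identical fits give p = 1 via stat 0
  expect_error(lrt_test(full, full), "identical")
  expect_equal(pchisq(3.841459, df = 1, lower.tail = FALSE), 0.05,
               tolerance = 1e-6)
})

test_that("Wald and LRT p-values agree asymptotically for one coefficient", {
  set.seed(10)
  n <- 18
  X <- cbind(`(Intercept)` = 1, salinityhigh = rep(c(0, 1), 9))
  Xr <- X[, 1, drop = FALSE]
  lfc <- rnorm(150, 0, 0.3)
  counts <- t(vapply(lfc, function(b)
    rnbinom(n, mu = 2000 * 2^(b * X[, 2]), size = 50), numeric(n)))
  storage.mode(counts) <- "integer"
  rownames(counts) <- sprintf("t%03d", seq_len(nrow(counts)))
  alphas <- rep(0.02, nrow(counts))
  full <- nb_fit_all(counts, X, sf = rep(1, n), alphas = alphas)
  red <- nb_fit_all(counts, Xr, sf = rep(1, n), alphas = alphas)
  pw <- wald_test(full, "salinityhigh")$p_raw
  pl <- lrt_test(full, red)$p_raw
  expect_gt(cor(pw, pl, method = "spearman", use = "complete.obs"), 0.99)
})

test_that("stabilized log transform has the documented invariances", {
  expect_equal(stabilized_log(matrix(0L, 1, 1), sf = 1)[1, 1], 0)
  expect_equal(stabilized_log(matrix(3L, 1, 1), sf = 1)[1, 1], 2)
  cm <- matrix(rpois(40, 50) + 1L, 10, 4)
  sf <- c(1, 2, 0.5, 1)
  doubled <- cm
  doubled[, 2] <- cm[, 2] * 2L
  expect_equal(stabilized_log(cm, sf)[, 2],
               stabilized_log(doubled, sf * c(1, 2, 1, 1))[, 2])
})

test_that("planted effects are recovered end-to-end by de_analysis", {
  cfg <- small_config()
  design <- study_design()
  truth <- ground_truth(design, n_windows = 200, n_transcripts = 300,
                        n_dmr_salinity = c(2, 4, 8),
                        n_de_private = c(2, 5, 10), seed = 31)
  meta <- generate_metadata(design, seed = 31)
  counts <- simulate_counts(design, truth, meta, seed = 31)
  de <- de_analysis(counts, meta)
  # estimated vs planted log2FC in the reference (low) treatment:
  # core transcripts only, Wald within treatment
  w_low <- de$per_treatment_salinity$low
  core <- truth$de$salinity_core
  est <- w_low$log2FC[match(rownames(counts)[core$transcript],
                            w_low$feature_id)]
  fit <- lm(est ~ core$lfc)
  expect_gt(coef(fit)[2], 0.9)
  expect_lt(coef(fit)[2], 1.1)
  # interaction LRT finds predictability-graded transcripts
  inter_ids <- rownames(counts)[truth$de$interaction$transcript]
  sig_inter <- de$terms$interaction$feature_id[
    de$terms$interaction$significant]
  expect_gt(mean(inter_ids %in% sig_inter), 0.5)
})
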