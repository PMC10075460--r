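#' Median-of-ratios library size factors
#'
#' For each sample, the size factor is the median over transcripts (with
#' nonzero counts in all samples) of the ratio of the sample's count to
#' the transcript's geometric mean count across samples.
#'
#' @param counts Integer matrix, transcripts x samples.
#' @return Named numeric vector of positive per-sample factors.
#' @export
size_factors <- function(counts) {
  use <- rowSums(counts > 0) == ncol(counts)
  if (!any(use))
    stop("no transcript has nonzero counts in all samples; ",
         "cannot normalize", call. = FALSE)
  lg <- log(counts[use, , drop = FALSE])
  geo <- rowMeans(lg)
  sf <- apply(lg, 2L, function(col) exp(stats::median(col - geo)))
  names(sf) <- colnames(counts)
  sf
}

# Negative-binomial log-likelihood at fixed dispersion alpha (Poisson in
# the alpha -> 0 limit).
nb_loglik <- function(y, mu, alpha) {
  if (alpha < 1e-10) sum(stats::dpois(y, mu, log = TRUE))
  else sum(stats::dnbinom(y, size = 1 / alpha, mu = mu, log = TRUE))
}

#' Fit a negative-binomial GLM with log link by IRLS
#'
#' Maximizes the NB log-likelihood with log link and offset
#' `log(size_factors)` at fixed dispersion `alpha`, by Fisher-scoring
#' iteratively reweighted least squares (working weights
#' `mu / (1 + alpha * mu)`). `alpha = 0` is the Poisson limit. The fit is
#' deterministic.
#'
#' @param y Non-negative integer response (counts for one transcript).
#' @param design_matrix Full-rank numeric design matrix (samples x
#'   coefficients), including the intercept column.
#' @param size_factors Positive per-sample normalization factors.
#' @param alpha Gene-wise NB dispersion (>= 0).
#' @param max_iter,tol IRLS iteration cap and coefficient-change
#'   convergence tolerance.
#' @return An object of class `nb_fit`: list with `coefficients`
#'   (natural-log scale), `se`, `mu`, `alpha`, `log_likelihood`,
#'   `converged`, `df` (number of coefficients).
#' @export
fit_nb_glm <- function(y, design_matrix, size_factors, alpha,
                       max_iter = 50, tol = 1e-8) {
  X <- as.matrix(design_matrix)
  n <- length(y)
  stopifnot(nrow(X) == n, length(size_factors) == n, alpha >= 0)
  p <- ncol(X)
  empty_fit <- function(converged) {
    structure(list(coefficients = stats::setNames(rep(NA_real_, p),
                                                  colnames(X)),
                   se = rep(NA_real_, p), mu = rep(0, n), alpha = alpha,
                   log_likelihood = NA_real_, converged = converged,
                   df = p), class = "nb_fit")
  }
  if (all(y == 0)) {
    # boundary: zero mean; flagged, coefficients unidentifiable
    return(empty_fit(FALSE))
  }
  if (qr(X)$rank < p)
    stop("design matrix is rank deficient", call. = FALSE)
  offset <- log(size_factors)
  mu <- pmax(y, 0.5)
  eta <- log(mu)
  beta <- rep(0, p)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    w <- mu / (1 + alpha * mu)
    z <- (eta - offset) + (y - mu) / mu
    fit <- tryCatch(stats::lm.wfit(X, z, w), error = function(e) NULL)
    if (is.null(fit) || anyNA(fit$coefficients)) return(empty_fit(FALSE))
    new_beta <- fit$coefficients
    eta <- drop(X %*% new_beta) + offset
    eta <- pmin(pmax(eta, -30), 30)
    mu <- exp(eta)
    delta <- max(abs(new_beta - beta))
    beta <- new_beta
    if (delta < tol * max(1, max(abs(beta)))) {
      converged <- TRUE
      break
    }
  }
  w <- mu / (1 + alpha * mu)
  info <- crossprod(X, w * X)
  cov <- tryCatch(solve(info), error = function(e) NULL)
  se <- if (is.null(cov)) rep(NA_real_, p) else sqrt(pmax(diag(cov), 0))
  structure(list(coefficients = stats::setNames(beta, colnames(X)),
                 se = stats::setNames(se, colnames(X)),
                 mu = mu, alpha = alpha,
                 log_likelihood = nb_loglik(y, mu, alpha),
                 converged = converged, df = p),
            class = "nb_fit")
}

#' @export
print.nb_fit <- function(x, ...) {
  cat(sprintf("NB GLM fit: %d coefficients, alpha = %.4g, logLik = %.3f%s\n",
              x$df, x$alpha, x$log_likelihood,
              if (x$converged) "" else " (NOT converged)"))
  print(x$coefficients)
  invisible(x)
}

#' Gene-wise maximum adjusted-likelihood NB dispersion
#'
#' Estimates the dispersion of one transcript by profiling the Cox-Reid
#' adjusted NB log-likelihood over `log(alpha)` (the GLM is refit at each
#' candidate; the adjustment `-0.5 log det(X'WX)` corrects the downward
#' bias of the plain profile MLE caused by estimating the mean
#' coefficients), starting from a method-of-moments value computed on the
#' Poisson fit. The estimate is floored at 1e-8; on failure the
#' method-of-moments value is returned, flagged via the `"method"`
#' attribute.
#'
#' @param counts_row Counts for one transcript.
#' @param design_matrix Design matrix (samples x coefficients).
#' @param size_factors Per-sample normalization factors.
#' @return Dispersion estimate `alpha >= 1e-8` with attribute `method`
#'   (`"ML"` or `"MoM"`).
#' @export
estimate_dispersion <- function(counts_row, design_matrix, size_factors) {
  y <- counts_row
  if (all(y == 0)) return(structure(1e-8, method = "MoM"))
  pois <- fit_nb_glm(y, design_matrix, size_factors, alpha = 0)
  mu <- pois$mu
  mom <- sum((y - mu)^2 - mu) / sum(mu^2)
  mom <- min(max(mom, 1e-8), 100)
  X <- as.matrix(design_matrix)
  prof <- function(la) {
    f <- fit_nb_glm(y, design_matrix, size_factors, alpha = exp(la),
                    tol = 1e-6)
    if (!is.finite(f$log_likelihood)) return(1e10)
    w <- f$mu / (1 + exp(la) * f$mu)
    cr <- 0.5 * as.numeric(determinant(crossprod(X, w * X))$modulus)
    -(f$log_likelihood - cr)
  }
  interval <- c(max(log(1e-8), log(mom) - 6), min(log(100), log(mom) + 6))
  opt <- tryCatch(stats::optimize(prof, interval, tol = 0.02),
                  error = function(e) NULL)
  if (is.null(opt)) return(structure(mom, method = "MoM"))
  alpha <- exp(opt$minimum)
  # accept the boundary floor when the data are under-dispersed
  if (prof(log(1e-8)) <= opt$objective) alpha <- 1e-8
  structure(max(alpha, 1e-8), method = "ML")
}

#' Fit NB GLMs for every transcript of a count matrix
#'
#' @param counts Integer matrix, transcripts x samples.
#' @param design_matrix Design matrix (samples x coefficients).
#' @param sf Size factors; computed by [size_factors()] when `NULL`.
#' @param alphas Per-transcript dispersions; estimated by
#'   [estimate_dispersion()] when `NULL`.
#' @return List with `fits` (list of `nb_fit`), `alphas`, `sf`,
#'   `design_matrix`.
#' @export
nb_fit_all <- function(counts, design_matrix, sf = NULL, alphas = NULL) {
  if (is.null(sf)) sf <- size_factors(counts)
  if (is.null(alphas))
    alphas <- vapply(seq_len(nrow(counts)), function(i)
      as.numeric(estimate_dispersion(counts[i, ], design_matrix, sf)),
      numeric(1))
  fits <- lapply(seq_len(nrow(counts)), function(i)
    fit_nb_glm(counts[i, ], design_matrix, sf, alphas[i]))
  names(fits) <- rownames(counts)
  list(fits = fits, alphas = alphas, sf = sf,
       design_matrix = design_matrix)
}

#' Wald test on one NB-GLM coefficient
#'
#' For each transcript, `z = coefficient / SE` (SE from the Fisher
#' information at the optimum), two-sided normal p-value, effect reported
#' as log2 fold change (natural-log coefficient divided by `log(2)`).
#' Benjamini-Hochberg across converged transcripts; significant when
#' `q < q_threshold` and `|log2FC| > lfc_threshold`.
#'
#' @param fit_set Output of [nb_fit_all()].
#' @param coef Name of the tested coefficient.
#' @param q_threshold FDR threshold (default 0.05).
#' @param lfc_threshold |log2FC| threshold (default 1).
#' @return Data frame (`feature_id`, `log2FC`, `p_raw`, `q`,
#'   `significant`). Non-converged fits get `NA` p and are excluded from
#'   the BH family.
#' @export
wald_test <- function(fit_set, coef, q_threshold = 0.05, lfc_threshold = 1) {
  fits <- fit_set$fits
  get <- function(f) {
    if (!f$converged || !coef %in% names(f$coefficients) ||
        is.na(f$se[coef]) || f$se[coef] <= 0)
      return(c(NA_real_, NA_real_))
    c(f$coefficients[coef], f$se[coef])
  }
  est <- t(vapply(fits, get, numeric(2)))
  lfc <- est[, 1] / log(2)
  z <- est[, 1] / est[, 2]
  p <- 2 * stats::pnorm(-abs(z))
  q <- benjamini_hochberg(p)
  sig <- !is.na(q) & q < q_threshold & abs(lfc) > lfc_threshold
  data.frame(feature_id = names(fits), log2FC = lfc, p_raw = p, q = q,
             significant = sig, row.names = NULL, stringsAsFactors = FALSE)
}

#' Likelihood-ratio test between nested NB-GLM fits
#'
#' Per transcript, the statistic `2 * (ll_full - ll_reduced)` (clipped at
#' zero) is referred to a chi-square law with `df` equal to the
#' difference in coefficient count. The reported effect is the
#' largest-magnitude log2FC among the coefficients present in the full
#' but not the reduced model; the significance rule is conjunctive
#' (`q < q_threshold` and `|log2FC| > lfc_threshold`), with
#' `lfc_threshold = 0` disabling the effect cutoff.
#'
#' @param full_set,reduced_set Outputs of [nb_fit_all()] on nested design
#'   matrices (reduced columns a subset of full columns), same
#'   dispersions.
#' @param q_threshold FDR threshold (default 0.05).
#' @param lfc_threshold |log2FC| threshold (default 1).
#' @return Data frame (`feature_id`, `log2FC`, `stat`, `df`, `p_raw`,
#'   `q`, `significant`).
#' @export
lrt_test <- function(full_set, reduced_set, q_threshold = 0.05,
                     lfc_threshold = 1) {
  full <- full_set$fits
  reduced <- reduced_set$fits
  stopifnot(length(full) == length(reduced))
  full_terms <- colnames(full_set$design_matrix)
  red_terms <- colnames(reduced_set$design_matrix)
  if (!all(red_terms %in% full_terms))
    stop("reduced model is not nested in the full model", call. = FALSE)
  dropped <- setdiff(full_terms, red_terms)
  df <- length(dropped)
  if (df < 1) stop("models are identical", call. = FALSE)
  n <- length(full)
  stat <- p <- lfc <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    f <- full[[i]]; r <- reduced[[i]]
    if (!f$converged || !r$converged) next
    s <- 2 * (f$log_likelihood - r$log_likelihood)
    if (s < -1e-6)
      warning("full model log-likelihood below reduced for '",
              names(full)[i], "'; consider refitting")
    stat[i] <- max(s, 0)
    p[i] <- stats::pchisq(stat[i], df = df, lower.tail = FALSE)
    co <- f$coefficients[dropped] / log(2)
    lfc[i] <- co[which.max(abs(co))]
  }
  q <- benjamini_hochberg(p)
  sig <- !is.na(q) & q < q_threshold & abs(lfc) > lfc_threshold
  data.frame(feature_id = names(full), log2FC = lfc, stat = stat, df = df,
             p_raw = p, q = q, significant = sig, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Variance-stabilized expression matrix
#'
#' Shifted log of normalized counts, `log2(count / size_factor + 1)`: a
#' simple variance-stabilizing transform with the same downstream
#' contract as regularized-log transforms (a real matrix on a log2
#' scale).
#'
#' @param counts Integer matrix, transcripts x samples.
#' @param sf Size factors; computed by [size_factors()] when `NULL`.
#' @return Numeric matrix of the same dimension.
#' @export
stabilized_log <- function(counts, sf = NULL) {
  if (is.null(sf)) sf <- size_factors(counts)
  log2(sweep(counts, 2L, sf, "/") + 1)
}

#' Differential-expression analysis of the predictability design
#'
#' Fits the model `counts ~ treatment + salinity + treatment:salinity`
#' (both factors categorical) per transcript, with gene-wise dispersions
#' estimated once on the full design, and tests:
#' * `salinity`: LRT dropping salinity and interaction terms;
#' * `rho2` (evolution): LRT dropping treatment and interaction terms;
#' * `interaction` (evolution of plasticity): LRT dropping the
#'   interaction;
#' * per-treatment salinity contrasts: Wald test on the salinity
#'   coefficient of a two-group fit within each treatment.
#'
#' @param counts Integer matrix, transcripts x samples (columns match
#'   `metadata$sample_id` order).
#' @param metadata Output of [generate_metadata()].
#' @param q_threshold FDR threshold (default 0.05).
#' @param lfc_threshold |log2FC| threshold (default 1).
#' @return List with `terms` (named list of test result data frames:
#'   `salinity`, `rho2`, `interaction`), `per_treatment_salinity` (named
#'   list of Wald results), `sf`, `alphas`, `stabilized` (variance-
#'   stabilized matrix).
#' @export
de_analysis <- function(counts, metadata, q_threshold = 0.05,
                        lfc_threshold = 1) {
  stopifnot(ncol(counts) == nrow(metadata))
  sf <- size_factors(counts)
  X_full <- stats::model.matrix(~ treatment * salinity, metadata)
  full <- nb_fit_all(counts, X_full, sf = sf)
  reduce <- function(form) {
    X <- stats::model.matrix(form, metadata)
    nb_fit_all(counts, X, sf = sf, alphas = full$alphas)
  }
  terms <- list(
    salinity = lrt_test(full, reduce(~ treatment), q_threshold,
                        lfc_threshold),
    rho2 = lrt_test(full, reduce(~ salinity), q_threshold, lfc_threshold),
    interaction = lrt_test(full, reduce(~ treatment + salinity),
                           q_threshold, lfc_threshold))
  per_tr <- lapply(levels(metadata$treatment), function(tr) {
    keep <- metadata$treatment == tr
    sub_meta <- droplevels(metadata[keep, ])
    X <- stats::model.matrix(~ salinity, sub_meta)
    # dispersions from the full design are reused for the subset fits
    fs <- nb_fit_all(counts[, keep, drop = FALSE], X, sf = sf[keep],
                     alphas = full$alphas)
    wald_test(fs, "salinityhigh", q_threshold, lfc_threshold)
  })
  names(per_tr) <- levels(metadata$treatment)
  list(terms = terms, per_treatment_salinity = per_tr, sf = sf,
       alphas = full$alphas, stabilized = stabilized_log(counts, sf))
}
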