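#' Ezekiel-adjusted R squared
#'
#' Small-sample correction
#' `R2_adj = 1 - (1 - R2) * (n - 1) / (n - m - 1)` for a model with `m`
#' degrees of freedom fitted to `n` samples. May be negative for weak
#' fits; reported as computed. When covariates were projected out first,
#' pass the covariate-reduced sample count as `n_samples` (semi-partial
#' convention).
#'
#' @param R2 Fraction of variance explained, in `[0, 1]`.
#' @param n_samples Number of (effective) samples.
#' @param model_df Model degrees of freedom `m`.
#' @return Adjusted R squared.
#' @examples
#' adjusted_r2(0.5, 18, 2) # 1 - 0.5 * 17 / 15
#' @export
adjusted_r2 <- function(R2, n_samples, model_df) {
  if (n_samples <= model_df + 1)
    stop("insufficient degrees of freedom for adjustment", call. = FALSE)
  1 - (1 - R2) * (n_samples - 1) / (n_samples - model_df - 1)
}

# Build the pieces shared by partial_rda and permutation_anova:
# centered/residualized response, covariate projector, per-term design
# columns. 'terms' is a one-sided formula over 'data'; 'covariates'
# likewise or NULL.
rda_prepare <- function(Y, terms, covariates, data, drop_aliased = FALSE) {
  Y <- as.matrix(Y)
  n <- nrow(Y)
  stopifnot(n == nrow(data))
  keep_feat <- apply(Y, 2L, function(col) stats::var(col) > 0)
  if (!all(keep_feat)) {
    warning(sum(!keep_feat), " zero-variance feature(s) dropped")
    Y <- Y[, keep_feat, drop = FALSE]
  }
  Y <- scale(Y, center = TRUE, scale = FALSE)

  tt <- stats::terms(terms)
  labels <- attr(tt, "term.labels")
  X <- stats::model.matrix(terms, data)
  asgn <- attr(X, "assign")
  X <- X[, asgn != 0, drop = FALSE]
  asgn <- asgn[asgn != 0]

  if (!is.null(covariates)) {
    C <- stats::model.matrix(covariates, data)
  } else {
    C <- matrix(1, n, 1)
  }
  qc <- qr(C)
  df_cov <- qc$rank - 1L # beyond the intercept
  Yr <- qr.resid(qc, Y)
  Xr <- qr.resid(qc, X)

  # detect aliased design columns: absorbed entirely by the covariates
  # (zero residual norm), or linearly dependent among themselves
  orig_norm <- sqrt(colSums(X^2))
  res_norm <- sqrt(colSums(Xr^2))
  absorbed <- res_norm <= 1e-8 * pmax(orig_norm, 1)
  aliased <- colnames(X)[absorbed]
  if (any(!absorbed)) {
    Xr2 <- Xr[, !absorbed, drop = FALSE]
    qx <- qr(Xr2, LAPACK = FALSE)
    if (qx$rank < ncol(Xr2)) {
      dep <- qx$pivot[(qx$rank + 1L):ncol(Xr2)]
      aliased <- c(aliased, colnames(X)[!absorbed][dep])
    }
  }
  if (length(aliased) > 0) {
    if (!drop_aliased)
      stop("aliased design column(s) after conditioning: ",
           paste(aliased, collapse = ", "), call. = FALSE)
    warning("dropping aliased design column(s): ",
            paste(aliased, collapse = ", "))
    keep <- !(colnames(X) %in% aliased)
    Xr <- Xr[, keep, drop = FALSE]
    X <- X[, keep, drop = FALSE]
    asgn <- asgn[keep]
  }
  list(Y = Yr, X = Xr, asgn = asgn, labels = labels, n = n,
       df_cov = df_cov, qc = qc)
}

ss <- function(M) sum(M^2)

#' Partial redundancy analysis with marginal term contributions
#'
#' Constrained ordination by least squares: the response matrix and the
#' explanatory design columns are first residualized on the covariates
#' (and centered), the residualized response is regressed on the
#' residualized design, and constrained axes are the principal components
#' of the fitted values. Each term's R squared is *marginal*: the drop in
#' explained variance when that term (only) is removed from the full
#' conditioned model, as a fraction of the conditioned total variance.
#' Adjusted values use the Ezekiel formula with the covariate degrees of
#' freedom removed from the sample count first.
#'
#' @param Y Numeric samples x features response matrix.
#' @param terms One-sided formula of explanatory factors, e.g.
#'   `~ treatment + salinity + treatment:salinity`.
#' @param covariates Optional one-sided formula of conditioning factors,
#'   e.g. `~ population_id`, or `NULL`.
#' @param data Data frame holding the design variables (one row per
#'   sample).
#' @param drop_aliased Drop design columns aliased after conditioning
#'   (with a warning embedded in the result) instead of erroring.
#' @return An object of class `rda_result`: `terms` data frame (`term`,
#'   `df`, `R2`, `R2_adj`, `pseudo_F`), `eigenvalues` (list `constrained`,
#'   `unconstrained`), `site_scores`, `total_variance`, `residual_df`,
#'   plus bookkeeping used by [permutation_anova()].
#' @export
partial_rda <- function(Y, terms, covariates = NULL, data,
                        drop_aliased = FALSE) {
  pr <- rda_prepare(Y, terms, covariates, data, drop_aliased)
  n <- pr$n
  qx <- qr(pr$X)
  fitted <- qr.fitted(qx, pr$Y)
  resid <- pr$Y - fitted
  ss_tot <- ss(pr$Y)
  ss_model <- ss(fitted)
  df_model <- qx$rank
  df_resid <- n - 1L - pr$df_cov - df_model
  tab <- lapply(unique(pr$asgn), function(t) {
    Xw <- pr$X[, pr$asgn != t, drop = FALSE]
    ss_wo <- if (ncol(Xw) == 0) 0 else ss(qr.fitted(qr(Xw), pr$Y))
    ss_t <- ss_model - ss_wo
    df_t <- sum(pr$asgn == t)
    R2 <- ss_t / ss_tot
    data.frame(term = pr$labels[t], df = df_t, R2 = R2,
               R2_adj = adjusted_r2(R2, n - pr$df_cov, df_t),
               pseudo_F = (ss_t / df_t) / (ss(resid) / df_resid),
               stringsAsFactors = FALSE)
  })
  tab <- if (length(tab) == 0)
    data.frame(term = character(), df = integer(), R2 = numeric(),
               R2_adj = numeric(), pseudo_F = numeric(),
               stringsAsFactors = FALSE)
  else do.call(rbind, tab)
  sv <- svd(fitted)
  pos <- sv$d^2 / (n - 1) > 1e-12 * max(sv$d^2 / (n - 1), 1e-300)
  eig_c <- (sv$d^2 / (n - 1))[pos]
  sv_r <- svd(resid)
  eig_u <- (sv_r$d^2 / (n - 1))
  eig_u <- eig_u[eig_u > 1e-12 * max(eig_u, 1e-300)]
  scores <- sv$u[, pos, drop = FALSE] %*% diag(sv$d[pos], sum(pos))
  colnames(scores) <- sprintf("RDA%d", seq_len(ncol(scores)))
  rownames(scores) <- rownames(Y)
  structure(list(terms = tab,
                 eigenvalues = list(constrained = eig_c,
                                    unconstrained = eig_u),
                 site_scores = scores,
                 total_variance = ss_tot / (n - 1),
                 model_df = df_model, residual_df = df_resid,
                 prepared = pr),
            class = "rda_result")
}

#' @export
print.rda_result <- function(x, ...) {
  cat("Partial redundancy analysis\n")
  cat(sprintf("  conditioned total variance: %.4g (residual df %d)\n",
              x$total_variance, x$residual_df))
  print(x$terms, row.names = FALSE)
  invisible(x)
}

#' ANOVA-like permutation tests for RDA terms
#'
#' Marginal ("by margin") test of each term with the Freedman-Lane
#' scheme: for a term, the reduced model contains the covariates and all
#' other terms; rows of the reduced-model residuals are permuted,
#' re-added to the reduced-model fitted values, and the term's marginal
#' pseudo-F is recomputed. The p-value is
#' `(1 + #{F_perm >= F_obs}) / (1 + n_perm)`.
#'
#' @inheritParams partial_rda
#' @param n_perm Number of permutations (default 999).
#' @param seed Integer seed for the permutation stream.
#' @return Data frame (`term`, `df`, `R2`, `R2_adj`, `pseudo_F`,
#'   `p_perm`).
#' @export
permutation_anova <- function(Y, terms, covariates = NULL, data,
                              n_perm = 999, seed = 1,
                              drop_aliased = FALSE) {
  if (n_perm < 1) stop("'n_perm' must be >= 1", call. = FALSE)
  base <- partial_rda(Y, terms, covariates, data,
                      drop_aliased = drop_aliased)
  pr <- base$prepared
  n <- pr$n
  if (!is.null(seed)) set.seed(seed)
  qx <- qr(pr$X)
  df_resid <- base$residual_df
  p_perm <- numeric(nrow(base$terms))
  for (ti in seq_along(unique(pr$asgn))) {
    t <- unique(pr$asgn)[ti]
    Xw <- pr$X[, pr$asgn != t, drop = FALSE]
    qw <- if (ncol(Xw) > 0) qr(Xw) else NULL
    fit_red <- if (is.null(qw)) matrix(0, n, ncol(pr$Y))
               else qr.fitted(qw, pr$Y)
    res_red <- pr$Y - fit_red
    df_t <- base$terms$df[ti]
    f_obs <- base$terms$pseudo_F[ti]
    count <- 0L
    for (b in seq_len(n_perm)) {
      Yp <- fit_red + res_red[sample.int(n), , drop = FALSE]
      # permuted response must be re-residualized on the covariates
      Yp <- qr.resid(pr$qc, Yp)
      fit_full <- qr.fitted(qx, Yp)
      ss_full <- ss(fit_full)
      ss_wo <- if (is.null(qw)) 0 else ss(qr.fitted(qw, Yp))
      ss_res <- ss(Yp) - ss_full
      f_b <- ((ss_full - ss_wo) / df_t) / (ss_res / df_resid)
      if (f_b >= f_obs) count <- count + 1L
    }
    p_perm[ti] <- (1 + count) / (1 + n_perm)
  }
  out <- base$terms
  out$p_perm <- p_perm
  out
}
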