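#' Multivariate mean of a (population, salinity) cell
#'
#' Arithmetic per-feature mean over the rows of a level matrix belonging
#' to one population at one assay salinity (one row per sample for
#' methylation/expression; one row per cell for morphology).
#'
#' @param level_matrix Numeric rows x features matrix.
#' @param metadata Data frame aligned with the rows, containing
#'   `population_id` and `salinity`.
#' @param population Population id.
#' @param salinity `"low"` or `"high"`.
#' @return Numeric feature-space vector.
#' @export
multivariate_mean <- function(level_matrix, metadata, population, salinity) {
  level_matrix <- as.matrix(level_matrix)
  stopifnot(nrow(level_matrix) == nrow(metadata))
  keep <- metadata$population_id == population &
    metadata$salinity == salinity
  if (!any(keep))
    stop("no rows for population '", population, "' at salinity '",
         salinity, "'", call. = FALSE)
  colMeans(level_matrix[keep, , drop = FALSE])
}

#' Euclidean plasticity distance between two multivariate means
#'
#' @param mean_low,mean_high Equal-length feature-space vectors (means at
#'   low and high salinity).
#' @return Non-negative L2 norm of `mean_high - mean_low`.
#' @examples
#' plasticity_distance(c(0, 0, 0), c(3, 4, 0)) # 5
#' @export
plasticity_distance <- function(mean_low, mean_high) {
  if (length(mean_low) != length(mean_high))
    stop("mean vectors must have equal dimensionality", call. = FALSE)
  sqrt(sum((mean_high - mean_low)^2))
}

#' Per-population plasticity records for one biological level
#'
#' For each population, computes the Euclidean distance between its
#' multivariate means at low and high salinity and pairs it with the
#' population's realized predictability.
#'
#' @param level_matrix Numeric rows x features matrix (samples or cells).
#' @param metadata Data frame aligned with the rows, with
#'   `population_id`, `salinity` and `rho2_realized`.
#' @param level Label stored in the result (e.g. `"methylation"`).
#' @return Data frame (`population_id`, `level`, `rho2_realized`,
#'   `distance`).
#' @export
plasticity_records <- function(level_matrix, metadata, level = "level") {
  pops <- unique(metadata$population_id)
  do.call(rbind, lapply(pops, function(pop) {
    m_lo <- multivariate_mean(level_matrix, metadata, pop, "low")
    m_hi <- multivariate_mean(level_matrix, metadata, pop, "high")
    data.frame(
      population_id = pop, level = level,
      rho2_realized = metadata$rho2_realized[
        match(pop, metadata$population_id)],
      distance = plasticity_distance(m_lo, m_hi),
      stringsAsFactors = FALSE)
  }))
}

#' Regression of plasticity distance on realized predictability
#'
#' Ordinary least squares of the per-population Euclidean plasticity
#' distance on realized rho^2, with a two-sided t test (n - 2 df) on the
#' slope and the 95% confidence band of the fitted line.
#'
#' @param records Data frame from [plasticity_records()] (one level).
#' @return An object of class `slope_test`: `slope`, `intercept`,
#'   `t_stat`, `p`, `n`, `conf_band` (data frame `rho2`, `fit`, `lwr`,
#'   `upr`), `model` (the underlying `lm`).
#' @export
predictability_regression <- function(records) {
  if (nrow(records) < 3)
    stop("need >= 3 populations", call. = FALSE)
  if (length(unique(records$rho2_realized)) < 2)
    stop("realized rho^2 values are all identical", call. = FALSE)
  fit <- stats::lm(distance ~ rho2_realized, data = records)
  co <- summary(fit)$coefficients
  grid <- data.frame(rho2_realized = seq(min(records$rho2_realized),
                                         max(records$rho2_realized),
                                         length.out = 50))
  band <- stats::predict(fit, grid, interval = "confidence", level = 0.95)
  structure(list(slope = co["rho2_realized", "Estimate"],
                 intercept = co["(Intercept)", "Estimate"],
                 t_stat = co["rho2_realized", "t value"],
                 p = co["rho2_realized", "Pr(>|t|)"],
                 n = nrow(records),
                 conf_band = data.frame(rho2 = grid$rho2_realized,
                                        fit = band[, "fit"],
                                        lwr = band[, "lwr"],
                                        upr = band[, "upr"]),
                 model = fit),
            class = "slope_test")
}

#' @export
print.slope_test <- function(x, ...) {
  cat(sprintf(
    "Plasticity ~ realized rho^2: slope = %.4g (t = %.3f, p = %.4g, n = %d)\n",
    x$slope, x$t_stat, x$p, x$n))
  invisible(x)
}
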