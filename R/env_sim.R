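#' Define a stationary salinity fluctuation regime
#'
#' An environmental regime is a stationary AR(1) (first-order
#' autoregressive) law for salinity at successive culture transfers,
#' parameterized by its stationary mean, stationary standard deviation and
#' lag-1 autocorrelation. The innovation variance is derived internally as
#' `sigma^2 * (1 - rho^2)` so that the *stationary* SD equals `sigma` for
#' every `rho`: regimes with different autocorrelation share the same
#' long-term mean and variance and differ only in predictability.
#'
#' @param mu Stationary mean salinity (M NaCl). Default 2.4.
#' @param sigma Stationary standard deviation (M NaCl). Default 1.
#' @param rho Target lag-1 stationary autocorrelation, in (-1, 1).
#' @param bounds Closed feasible salinity interval (M NaCl). Defaults to
#'   `c(0, 4.8)`, the interval achievable by mixing hypo- (0 M) and
#'   hyper-saline (4.8 M) media. Simulated values are clipped to it.
#' @return An object of class `env_regime`.
#' @examples
#' env_regime(mu = 2.4, sigma = 1, rho = 0.9)
#' @export
env_regime <- function(mu = 2.4, sigma = 1, rho = 0, bounds = c(0, 4.8)) {
  if (!is.numeric(sigma) || length(sigma) != 1L || is.na(sigma) || sigma < 0)
    stop("'sigma' must be a single non-negative number", call. = FALSE)
  if (!is.numeric(rho) || length(rho) != 1L || is.na(rho) || abs(rho) >= 1)
    stop("'rho' must satisfy |rho| < 1", call. = FALSE)
  if (length(bounds) != 2L || !(bounds[1] < bounds[2]))
    stop("'bounds' must be an interval with lower < upper", call. = FALSE)
  if (!is.numeric(mu) || length(mu) != 1L || is.na(mu) ||
      mu < bounds[1] || mu > bounds[2])
    stop("'mu' must lie within 'bounds'", call. = FALSE)
  structure(list(mu = mu, sigma = sigma, rho = rho,
                 bounds = as.numeric(bounds)),
            class = "env_regime")
}

#' @export
print.env_regime <- function(x, ...) {
  cat(sprintf(
    "AR(1) salinity regime: mu = %g M, sigma = %g M, rho = %g (rho^2 = %g)\n",
    x$mu, x$sigma, x$rho, x$rho^2))
  cat(sprintf("  feasible bounds: [%g, %g] M NaCl\n",
              x$bounds[1], x$bounds[2]))
  invisible(x)
}

#' Simulate an autocorrelated salinity time series
#'
#' Draws a stationary AR(1) series of salinities at culture transfers:
#' the initial value from the stationary law N(mu, sigma^2), then
#' `s[t+1] = mu + rho * (s[t] - mu) + eps[t]` with independent innovations
#' `eps[t] ~ N(0, sigma^2 * (1 - rho^2))`. Every value is then clipped to
#' `regime$bounds`. Transfers alternate every 3 and 4 days (twice a week).
#'
#' @param regime An [env_regime()].
#' @param n_transfers Number of transfers (>= 2). The returned series has
#'   `n_transfers + 1` values (initial state plus one per transfer). The
#'   default 143 corresponds to roughly 500 generations at one generation
#'   per day with transfers alternating every 3 and 4 days.
#' @param seed Integer seed; the series is deterministic given it. Calls
#'   `set.seed()`, so the global RNG stream is advanced.
#' @param population_id Label carried on the series.
#' @return An object of class `salinity_series` with elements
#'   `population_id`, `regime`, `salinities` (length `n_transfers + 1`) and
#'   `transfer_days` (length `n_transfers`, alternating 3 and 4).
#' @examples
#' s <- simulate_ar1_series(env_regime(rho = 0.9), n_transfers = 50, seed = 1)
#' realized_autocorrelation(s)
#' @export
simulate_ar1_series <- function(regime, n_transfers = 143, seed = NULL,
                                population_id = "pop1") {
  stopifnot(inherits(regime, "env_regime"))
  if (!is.numeric(n_transfers) || length(n_transfers) != 1L || n_transfers < 2)
    stop("'n_transfers' must be >= 2", call. = FALSE)
  n_transfers <- as.integer(n_transfers)
  if (!is.null(seed)) set.seed(seed)
  mu <- regime$mu; sigma <- regime$sigma; rho <- regime$rho
  s <- numeric(n_transfers + 1L)
  s[1] <- stats::rnorm(1L, mu, sigma)
  if (n_transfers > 0L) {
    innov_sd <- sigma * sqrt(1 - rho^2)
    eps <- stats::rnorm(n_transfers, 0, innov_sd)
    for (t in seq_len(n_transfers))
      s[t + 1L] <- mu + rho * (s[t] - mu) + eps[t]
  }
  s <- pmin(pmax(s, regime$bounds[1]), regime$bounds[2])
  structure(list(population_id = population_id, regime = regime,
                 salinities = s,
                 transfer_days = rep_len(c(3L, 4L), n_transfers)),
            class = "salinity_series")
}

#' @export
print.salinity_series <- function(x, ...) {
  cat(sprintf("Salinity series '%s': %d values (%d transfers)\n",
              x$population_id, length(x$salinities),
              length(x$transfer_days)))
  cat(sprintf("  mean %.3f M, sd %.3f M, target rho %g\n",
              mean(x$salinities), stats::sd(x$salinities), x$regime$rho))
  invisible(x)
}

#' @export
as.data.frame.salinity_series <- function(x, ...) {
  data.frame(
    population_id = x$population_id,
    transfer_index = seq_along(x$salinities) - 1L,
    day = cumsum(c(0L, x$transfer_days)),
    salinity_M = x$salinities
  )
}

#' Realized autocorrelation and predictability of a salinity series
#'
#' The realized environmental autocorrelation `rho_hat` is the Pearson
#' correlation between salinities at two subsequent transfers, i.e. of the
#' lag pairs `(s[t], s[t+1])`; realized predictability is its square.
#' Because of the randomness of the stochastic process in finite time, the
#' realized value differs from the stationary target, and is the quantity
#' the plasticity regression uses.
#'
#' @param series A `salinity_series`, or a numeric vector of salinities.
#' @return An object of class `predictability`: list with `rho_hat` and
#'   `rho2_hat`.
#' @examples
#' realized_autocorrelation(c(0, 1, 0, 1, 0)) # rho_hat = -1
#' @export
realized_autocorrelation <- function(series) {
  x <- if (inherits(series, "salinity_series")) series$salinities
       else as.numeric(series)
  if (length(x) < 3L)
    stop("series must contain at least 3 values", call. = FALSE)
  a <- x[-length(x)]
  b <- x[-1L]
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("autocorrelation undefined: series is constant over a lag window",
         call. = FALSE)
  r <- stats::cor(a, b)
  structure(list(rho_hat = r, rho2_hat = r^2), class = "predictability")
}

#' @export
print.predictability <- function(x, ...) {
  cat(sprintf("realized rho = %.4f, realized rho^2 = %.4f\n",
              x$rho_hat, x$rho2_hat))
  invisible(x)
}

#' Target predictability of an autocorrelation treatment
#'
#' Predictability is the proportion of temporal variance in salinity
#' explained by the previous salinity, i.e. the squared lag-1
#' autocorrelation.
#'
#' @param rho Stationary autocorrelation, |rho| < 1.
#' @return `rho^2`.
#' @examples
#' target_predictability(0.9)  # 0.81
#' target_predictability(-0.5) # 0.25
#' @export
target_predictability <- function(rho) {
  if (any(abs(rho) >= 1)) stop("|rho| must be < 1", call. = FALSE)
  rho^2
}

#' Media mixing volumes for a target salinity
#'
#' Solves the salt mass balance for the volumes of hypo- and hyper-saline
#' media needed to reach a target salinity in a fixed total volume,
#' accounting for the salinity of the inoculate:
#' `v_hypo + v_hyper + inoculate_volume = total_volume` and
#' `hypo*v_hypo + hyper*v_hyper + inoc*inoc_vol = target*total_volume`.
#'
#' @param target_salinity Target salinity (M NaCl).
#' @param total_volume Final culture volume (mL). Default 250.
#' @param inoculate_salinity Salinity of the inoculate (M NaCl).
#' @param inoculate_volume Volume of the inoculate (mL).
#' @param hypo_salinity Salinity of the hypo-saline medium (M). Default 0.
#' @param hyper_salinity Salinity of the hyper-saline medium (M). Default 4.8.
#' @return Named numeric vector `c(hypo_volume, hyper_volume)` in mL.
#' @examples
#' mixing_volumes(2.4, 250, inoculate_salinity = 2.4, inoculate_volume = 10)
#' @export
mixing_volumes <- function(target_salinity, total_volume = 250,
                           inoculate_salinity = 0, inoculate_volume = 0,
                           hypo_salinity = 0, hyper_salinity = 4.8) {
  if (!(hypo_salinity < hyper_salinity))
    stop("'hypo_salinity' must be < 'hyper_salinity'", call. = FALSE)
  if (inoculate_volume > total_volume)
    stop("'inoculate_volume' must not exceed 'total_volume'", call. = FALSE)
  v_media <- total_volume - inoculate_volume
  salt_needed <- target_salinity * total_volume -
    inoculate_salinity * inoculate_volume
  v_hyper <- (salt_needed - hypo_salinity * v_media) /
    (hyper_salinity - hypo_salinity)
  v_hypo <- v_media - v_hyper
  tol <- 1e-9 * max(1, total_volume)
  if (v_hyper < -tol || v_hypo < -tol) {
    lo <- (hypo_salinity * v_media + inoculate_salinity * inoculate_volume) /
      total_volume
    hi <- (hyper_salinity * v_media + inoculate_salinity * inoculate_volume) /
      total_volume
    stop(sprintf(
      "target salinity %g M is not achievable; achievable interval is [%g, %g] M",
      target_salinity, lo, hi), call. = FALSE)
  }
  c(hypo_volume = max(v_hypo, 0), hyper_volume = max(v_hyper, 0))
}

# Deterministic per-population RNG stream derivation from one master seed.
# Kept below 2^31 - 1 so the result is a valid R integer seed.
derive_seed <- function(master_seed, index) {
  as.integer((as.numeric(master_seed) + 104729 * as.numeric(index)) %%
               2147483647)
}

#' Write transfer schedules as TSV
#'
#' One row per transfer: `population_id`, `transfer_index`, `day`,
#' `salinity_M`.
#'
#' @param series A `salinity_series` or a list of them.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_schedule_tsv <- function(series, path) {
  if (inherits(series, "salinity_series")) series <- list(series)
  df <- do.call(rbind, lapply(series, as.data.frame))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
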