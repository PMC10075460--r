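#' Study design for a predictability-evolution experiment
#'
#' Describes the sampled experimental design: autocorrelation treatments,
#' populations (evolved lines) per treatment, the two assay salinities of
#' the plasticity assay, and the number of cells measured per sample.
#' Defaults mirror the design analysed by the pipeline: three treatments
#' with target rho 0, -0.5 and 0.9 (predictability rho^2 = 0, 0.25, 0.81),
#' three lines per treatment, assays at 0.8 and 4.0 M NaCl, and 150 cells
#' per sample.
#'
#' @param treatments Data frame with columns `label` (one of "low",
#'   "intermediate", "high") and `rho` (target autocorrelation).
#' @param populations_per_treatment Evolved lines per treatment (>= 1).
#' @param salinities Exactly two assay salinities (M NaCl), low then high.
#' @param cells_per_sample Cells measured per population x salinity.
#' @param n_transfers Transfers simulated per population's salinity
#'   history (see [simulate_ar1_series()]).
#' @param regime Base [env_regime()] whose `mu`, `sigma` and `bounds` are
#'   shared by all treatments; each treatment overrides `rho`.
#' @return An object of class `study_design`.
#' @export
study_design <- function(treatments = data.frame(
                           label = c("low", "intermediate", "high"),
                           rho = c(0, -0.5, 0.9)),
                         populations_per_treatment = 3,
                         salinities = c(0.8, 4.0),
                         cells_per_sample = 150,
                         n_transfers = 143,
                         regime = env_regime()) {
  stopifnot(is.data.frame(treatments),
            all(c("label", "rho") %in% names(treatments)))
  if (nrow(treatments) < 2) stop(">= 2 treatments required", call. = FALSE)
  if (populations_per_treatment < 1)
    stop(">= 1 population per treatment required", call. = FALSE)
  if (length(salinities) != 2 || salinities[1] >= salinities[2])
    stop("exactly 2 assay salinities (low < high) required", call. = FALSE)
  treatments$label <- as.character(treatments$label)
  treatments$rho2 <- treatments$rho^2
  structure(list(treatments = treatments,
                 populations_per_treatment = as.integer(populations_per_treatment),
                 salinities = as.numeric(salinities),
                 cells_per_sample = as.integer(cells_per_sample),
                 n_transfers = as.integer(n_transfers),
                 regime = regime),
            class = "study_design")
}

#' @export
print.study_design <- function(x, ...) {
  cat(sprintf(
    "Study design: %d treatments x %d populations, assay salinities %g / %g M\n",
    nrow(x$treatments), x$populations_per_treatment,
    x$salinities[1], x$salinities[2]))
  print(x$treatments, row.names = FALSE)
  invisible(x)
}

# Treatment "predictability score" in [0, 1]: rho^2 rescaled by the largest
# treatment rho^2. Planted treatment-graded effects scale linearly with it,
# so effect architecture tracks predictability, not treatment order.
treatment_scores <- function(design) {
  r2 <- design$treatments$rho2
  s <- if (max(r2) > 0) r2 / max(r2) else r2
  names(s) <- design$treatments$label
  s
}

#' Planted ground truth for the synthetic data generators
#'
#' Selects which features carry planted effects and with what sizes, with
#' the qualitative structure the analysis is meant to recover:
#' * salinity-responsive DMR windows are private to each treatment
#'   (disjoint sets) and their number is non-decreasing in treatment rho^2;
#' * salinity-responsive DE transcripts share a large common core across
#'   treatments, plus treatment-private sets growing with rho^2;
#' * separate transcript sets carry a rho^2 (evolution) main effect and a
#'   predictability-graded salinity interaction (evolution of plasticity);
#' * morphological plasticity distance is linear in realized rho^2.
#'
#' Methylation shifts all exceed the 20-point calling cutoff and DE
#' |log2FC| all exceed 1, so planted features are recoverable in principle.
#'
#' @param design A [study_design()].
#' @param n_windows Number of 100-bp windows in the synthetic methylome.
#' @param n_transcripts Number of transcripts in the synthetic
#'   transcriptome.
#' @param n_dmr_treatment Windows differentially methylated among
#'   treatments.
#' @param n_dmr_salinity Named or ordered vector, one count per treatment,
#'   of salinity-responsive windows (non-decreasing in treatment rho^2).
#' @param n_de_core Salinity-responsive transcripts shared by all
#'   treatments.
#' @param n_de_private Per-treatment private salinity-responsive
#'   transcripts.
#' @param n_de_rho2 Transcripts with a rho^2 (treatment) main effect.
#' @param n_de_interaction Transcripts whose salinity response is graded
#'   by treatment predictability.
#' @param lfc_range Range of planted |log2FC| (drawn uniformly, random
#'   sign).
#' @param meth_shift_range Range of planted methylation-proportion shifts.
#' @param plasticity_intercept,plasticity_slope,plasticity_noise_sd
#'   Morphology plasticity distance model:
#'   `distance = intercept + slope * rho2_realized + N(0, noise_sd)`.
#' @param seed Integer seed.
#' @return An object of class `ground_truth`.
#' @export
ground_truth <- function(design = study_design(),
                         n_windows = 1000,
                         n_transcripts = 2000,
                         n_dmr_treatment = 15,
                         n_dmr_salinity = c(4, 12, 24),
                         n_de_core = 60,
                         n_de_private = c(6, 16, 36),
                         n_de_rho2 = 40,
                         n_de_interaction = 30,
                         lfc_range = c(1.5, 3),
                         meth_shift_range = c(0.30, 0.45),
                         plasticity_intercept = 1,
                         plasticity_slope = 2,
                         plasticity_noise_sd = 0.2,
                         seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  labels <- design$treatments$label
  k <- length(labels)
  stopifnot(length(n_dmr_salinity) == k, length(n_de_private) == k)
  ord <- order(design$treatments$rho2)
  if (is.unsorted(n_dmr_salinity[ord]))
    stop("salinity-DMR counts must be non-decreasing in treatment rho^2",
         call. = FALSE)
  signed <- function(n, range)
    sample(c(-1, 1), n, replace = TRUE) * stats::runif(n, range[1], range[2])

  n_sal_total <- sum(n_dmr_salinity)
  w <- sample.int(n_windows, n_dmr_treatment + n_sal_total)
  dmr_treatment <- data.frame(
    window = w[seq_len(n_dmr_treatment)],
    shift = stats::runif(n_dmr_treatment, meth_shift_range[1],
                         meth_shift_range[2]))
  w_sal <- split(w[n_dmr_treatment + seq_len(n_sal_total)],
                 factor(rep(seq_len(k), n_dmr_salinity),
                        levels = seq_len(k)))
  dmr_salinity <- lapply(seq_len(k), function(i) {
    data.frame(window = as.integer(w_sal[[i]]),
               shift = stats::runif(n_dmr_salinity[i], meth_shift_range[1],
                                    meth_shift_range[2]))
  })
  names(dmr_salinity) <- labels

  n_priv_total <- sum(n_de_private)
  tx <- sample.int(n_transcripts,
                   n_de_core + n_priv_total + n_de_rho2 + n_de_interaction)
  take <- function(n) {
    if (n == 0) return(integer(0))
    out <- tx[seq_len(n)]
    tx <<- tx[-seq_len(n)]
    out
  }
  de_core <- data.frame(transcript = take(n_de_core),
                        lfc = signed(n_de_core, lfc_range))
  de_private <- lapply(seq_len(k), function(i) {
    n <- n_de_private[i]
    data.frame(transcript = take(n), lfc = signed(n, lfc_range))
  })
  names(de_private) <- labels
  de_rho2 <- data.frame(transcript = take(n_de_rho2),
                        lfc = signed(n_de_rho2, lfc_range))
  de_interaction <- data.frame(transcript = take(n_de_interaction),
                               lfc = signed(n_de_interaction, lfc_range))

  structure(list(
    dmr = list(treatment = dmr_treatment, salinity = dmr_salinity),
    de = list(salinity_core = de_core, salinity_private = de_private,
              rho2 = de_rho2, interaction = de_interaction),
    plasticity = list(intercept = plasticity_intercept,
                      slope = plasticity_slope,
                      noise_sd = plasticity_noise_sd),
    n_windows = n_windows, n_transcripts = n_transcripts),
    class = "ground_truth")
}

#' Generate sample metadata with simulated salinity histories
#'
#' Creates one record per population x assay salinity. Each population is
#' given an independent AR(1) salinity history under its treatment's
#' regime (seeded deterministically from the master seed) from which the
#' realized predictability `rho2_realized` is computed. The simulated
#' series are attached as the `"series"` attribute.
#'
#' @param design A [study_design()].
#' @param seed Master integer seed; per-population streams are derived
#'   from it deterministically.
#' @return Data frame with columns `sample_id`, `population_id`,
#'   `treatment`, `target_rho`, `target_rho2`, `rho2_realized`, `salinity`
#'   ("low"/"high") and `salinity_M`, plus attribute `series`.
#' @export
generate_metadata <- function(design = study_design(), seed = 1) {
  tr <- design$treatments
  rows <- list()
  series <- list()
  idx <- 0L
  for (i in seq_len(nrow(tr))) {
    regime <- env_regime(mu = design$regime$mu, sigma = design$regime$sigma,
                         rho = tr$rho[i], bounds = design$regime$bounds)
    for (j in seq_len(design$populations_per_treatment)) {
      idx <- idx + 1L
      pop <- sprintf("%s_%d", tr$label[i], j)
      ts <- simulate_ar1_series(regime, n_transfers = design$n_transfers,
                                seed = derive_seed(seed, idx),
                                population_id = pop)
      r2 <- realized_autocorrelation(ts)$rho2_hat
      series[[pop]] <- ts
      for (s in c(1L, 2L)) {
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = sprintf("%s_%s", pop, c("low", "high")[s]),
          population_id = pop,
          treatment = tr$label[i],
          target_rho = tr$rho[i],
          target_rho2 = tr$rho2[i],
          rho2_realized = r2,
          salinity = c("low", "high")[s],
          salinity_M = design$salinities[s],
          stringsAsFactors = FALSE)
      }
    }
  }
  meta <- do.call(rbind, rows)
  meta$treatment <- factor(meta$treatment, levels = tr$label)
  meta$salinity <- factor(meta$salinity, levels = c("low", "high"))
  rownames(meta) <- meta$sample_id
  attr(meta, "series") <- series
  meta
}

#' Simulate a per-cytosine methylation count table
#'
#' Scatters cytosines over non-overlapping 100-bp windows of one synthetic
#' chromosome. Each window has a baseline methylation proportion (Beta
#' across background windows, uniform low-to-mid for planted windows so
#' that shifted proportions stay in range). Planted treatment effects
#' shift a window's proportion in proportion to the treatment's
#' predictability score; planted salinity effects shift it at high
#' salinity in the window's target treatment only. Per cytosine and
#' sample, coverage is negative-binomial and the methylated count binomial.
#'
#' @param design A [study_design()].
#' @param truth A [ground_truth()].
#' @param metadata Output of [generate_metadata()].
#' @param n_cytosines Number of CpG positions (>= `n_windows`).
#' @param n_windows Number of 100-bp windows tiling the chromosome.
#' @param mean_coverage Mean per-cytosine read coverage (default 40,
#'   matching deep whole-genome bisulfite runs).
#' @param coverage_size Negative-binomial size (inverse dispersion) of the
#'   coverage law.
#' @param prop_non_cpg Fraction of simulated sites given CHG/CHH context
#'   (removed by the CpG context filter downstream).
#' @param seed Integer seed.
#' @return A [methylation_table()] whose attribute `chrom_length` is the
#'   synthetic chromosome length.
#' @export
simulate_methylome <- function(design, truth, metadata,
                               n_cytosines = 10000, n_windows = NULL,
                               mean_coverage = 40, coverage_size = 5,
                               prop_non_cpg = 0.05, seed = 1) {
  if (is.null(n_windows)) n_windows <- truth$n_windows
  if (n_cytosines < n_windows)
    stop("'n_cytosines' must be >= 'n_windows'", call. = FALSE)
  set.seed(seed)
  window_size <- 100L
  chrom_len <- n_windows * window_size
  pos <- sort(sample.int(chrom_len, n_cytosines))
  win <- (pos - 1L) %/% window_size + 1L # 1-based window index
  strand <- sample(c("+", "-"), n_cytosines, replace = TRUE)
  context <- sample(c("CpG", "CHG", "CHH"), n_cytosines, replace = TRUE,
                    prob = c(1 - prop_non_cpg, prop_non_cpg / 2,
                             prop_non_cpg / 2))

  base <- stats::rbeta(n_windows, 2, 5)
  planted <- c(truth$dmr$treatment$window,
               unlist(lapply(truth$dmr$salinity, `[[`, "window")))
  base[planted] <- stats::runif(length(planted), 0.15, 0.45)

  scores <- treatment_scores(design)
  n_samp <- nrow(metadata)
  # per-window, per-sample methylation proportion
  p_win <- matrix(base, nrow = n_windows, ncol = n_samp)
  for (s in seq_len(n_samp)) {
    tr <- as.character(metadata$treatment[s])
    x <- scores[[tr]]
    td <- truth$dmr$treatment
    p_win[td$window, s] <- p_win[td$window, s] + td$shift * x
    if (metadata$salinity[s] == "high") {
      sd_ <- truth$dmr$salinity[[tr]]
      p_win[sd_$window, s] <- p_win[sd_$window, s] + sd_$shift
    }
  }
  p_win <- pmin(pmax(p_win, 0.01), 0.99)

  meth <- unmeth <- matrix(0L, nrow = n_cytosines, ncol = n_samp,
                           dimnames = list(NULL, metadata$sample_id))
  for (s in seq_len(n_samp)) {
    cov <- stats::rnbinom(n_cytosines, mu = mean_coverage,
                          size = coverage_size)
    m <- stats::rbinom(n_cytosines, cov, p_win[win, s])
    meth[, s] <- m
    unmeth[, s] <- cov - m
  }
  sites <- data.frame(chrom = "chrS1", pos = pos, strand = strand,
                      context = context, stringsAsFactors = FALSE)
  mt <- methylation_table(sites, meth, unmeth)
  attr(mt, "chrom_length") <- chrom_len
  mt
}

#' Simulate a transcript x sample count matrix
#'
#' Counts are negative-binomial with gene-wise log2 baselines and
#' dispersions drawn from configurable log-normal laws, sample-specific
#' library size factors, and planted log2 fold-change effects: a rho^2
#' (treatment) main effect graded by predictability score, a shared-core
#' salinity effect, treatment-private salinity effects, and a
#' predictability-graded salinity interaction.
#'
#' @param design A [study_design()].
#' @param truth A [ground_truth()].
#' @param metadata Output of [generate_metadata()].
#' @param n_transcripts Number of transcripts.
#' @param baseline_log2_mean,baseline_log2_sd Normal law of gene-wise log2
#'   baseline means.
#' @param dispersion_meanlog,dispersion_sdlog Log-normal law of gene-wise
#'   NB dispersions.
#' @param size_factor_sdlog Log-normal spread of the true library size
#'   factors (geometric mean fixed at 1).
#' @param seed Integer seed.
#' @return Integer matrix (transcripts x samples) with rownames
#'   `tx00001`... and attributes `true_dispersion` and
#'   `true_size_factors`.
#' @export
simulate_counts <- function(design, truth, metadata, n_transcripts = NULL,
                            baseline_log2_mean = 7, baseline_log2_sd = 1.5,
                            dispersion_meanlog = log(0.05),
                            dispersion_sdlog = 0.5,
                            size_factor_sdlog = 0.15, seed = 1) {
  if (is.null(n_transcripts)) n_transcripts <- truth$n_transcripts
  set.seed(seed)
  n_samp <- nrow(metadata)
  base <- stats::rnorm(n_transcripts, baseline_log2_mean, baseline_log2_sd)
  alpha <- stats::rlnorm(n_transcripts, dispersion_meanlog, dispersion_sdlog)
  sf <- stats::rlnorm(n_samp, 0, size_factor_sdlog)
  sf <- sf / exp(mean(log(sf)))

  scores <- treatment_scores(design)
  l2mu <- matrix(base, nrow = n_transcripts, ncol = n_samp)
  for (s in seq_len(n_samp)) {
    tr <- as.character(metadata$treatment[s])
    x <- scores[[tr]]
    hi <- metadata$salinity[s] == "high"
    r <- truth$de$rho2
    l2mu[r$transcript, s] <- l2mu[r$transcript, s] + r$lfc * x
    if (hi) {
      core <- truth$de$salinity_core
      l2mu[core$transcript, s] <- l2mu[core$transcript, s] + core$lfc
      priv <- truth$de$salinity_private[[tr]]
      l2mu[priv$transcript, s] <- l2mu[priv$transcript, s] + priv$lfc
      inter <- truth$de$interaction
      l2mu[inter$transcript, s] <- l2mu[inter$transcript, s] + inter$lfc * x
    }
  }
  counts <- matrix(0L, n_transcripts, n_samp,
                   dimnames = list(sprintf("tx%05d", seq_len(n_transcripts)),
                                   metadata$sample_id))
  for (s in seq_len(n_samp))
    counts[, s] <- as.integer(
      stats::rnbinom(n_transcripts, mu = sf[s] * 2^l2mu[, s],
                     size = 1 / alpha))
  attr(counts, "true_dispersion") <- alpha
  attr(counts, "true_size_factors") <- sf
  counts
}

#' Simulate a per-cell morphology table
#'
#' For each population, the between-salinity displacement of the
#' three-channel cell mean (forward scatter, side scatter, red
#' fluorescence; arbitrary units) has Euclidean norm
#' `intercept + slope * rho2_realized + N(0, noise_sd)` in a random
#' direction, the planted linear plasticity-predictability relation.
#' Cells are drawn from a trivariate normal around the salinity-specific
#' mean.
#'
#' @param design A [study_design()].
#' @param truth A [ground_truth()] (its `plasticity` element is used).
#' @param metadata Output of [generate_metadata()].
#' @param base_mean Population-average channel means (FSC, SSC, Red-B).
#' @param between_pop_sd SD of population-level baseline channel shifts.
#' @param cell_sd Within-sample per-channel SD of single cells.
#' @param seed Integer seed.
#' @return Data frame with one row per cell: `population_id`, `salinity`,
#'   `sample_id`, `FSC`, `SSC`, `RedB`.
#' @export
simulate_morphology <- function(design, truth, metadata,
                                base_mean = c(FSC = 200, SSC = 150, RedB = 100),
                                between_pop_sd = 5, cell_sd = 2, seed = 1) {
  set.seed(seed)
  pl <- truth$plasticity
  pops <- unique(metadata$population_id)
  out <- vector("list", 2L * length(pops))
  k <- 0L
  for (pop in pops) {
    rows <- metadata[metadata$population_id == pop, ]
    r2 <- rows$rho2_realized[1]
    centre <- base_mean + stats::rnorm(3, 0, between_pop_sd)
    dir <- stats::rnorm(3)
    dir <- dir / sqrt(sum(dir^2))
    d <- max(pl$intercept + pl$slope * r2 +
               stats::rnorm(1, 0, pl$noise_sd), 0)
    for (s in c("low", "high")) {
      k <- k + 1L
      mu <- if (s == "low") centre - dir * d / 2 else centre + dir * d / 2
      cells <- MASS::mvrnorm(design$cells_per_sample, mu,
                             diag(cell_sd^2, 3))
      colnames(cells) <- names(base_mean)
      out[[k]] <- data.frame(
        population_id = pop, salinity = s,
        sample_id = rows$sample_id[rows$salinity == s],
        cells, stringsAsFactors = FALSE)
    }
  }
  morph <- do.call(rbind, out)
  morph$salinity <- factor(morph$salinity, levels = c("low", "high"))
  rownames(morph) <- NULL
  morph
}

#' Simulate a transcript annotation and GO term map
#'
#' Places transcripts with random strand and transcription start sites on
#' the synthetic chromosome, and assigns Gene Ontology terms to roughly
#' `annotated_fraction` of transcripts across the three namespaces.
#' Optionally, named transcript sets can each be given a dedicated
#' enriched term covering most of the set, so over-representation is
#' recoverable by construction.
#'
#' @param n_transcripts Number of transcripts.
#' @param genome_length Length of the synthetic chromosome (bp).
#' @param n_go_terms Number of background GO terms.
#' @param annotated_fraction Fraction of transcripts with at least one
#'   term (default 0.30, a typical assignment rate for a de novo
#'   annotation of a non-model alga).
#' @param enriched_sets Optional named list of transcript-id vectors; each
#'   gets a dedicated term covering ~70% of the set.
#' @param seed Integer seed.
#' @return List with `annotation` (data frame: `transcript_id`, `chrom`,
#'   `start`, `end`, `strand`, `tss`) and `go_map` (data frame:
#'   `transcript_id`, `term_id`, `category`).
#' @export
simulate_annotation <- function(n_transcripts = 2000, genome_length = 100000,
                                n_go_terms = 40, annotated_fraction = 0.30,
                                enriched_sets = NULL, seed = 1) {
  if (annotated_fraction <= 0 || annotated_fraction > 1)
    stop("'annotated_fraction' must be in (0, 1]", call. = FALSE)
  set.seed(seed)
  ids <- sprintf("tx%05d", seq_len(n_transcripts))
  len <- pmin(pmax(round(stats::rlnorm(n_transcripts, log(800), 0.6)), 200),
              genome_length - 1)
  start <- vapply(len, function(l)
    sample.int(genome_length - l, 1L), integer(1))
  end <- start + len
  strand <- sample(c("+", "-"), n_transcripts, replace = TRUE)
  tss <- ifelse(strand == "+", start, end)
  annotation <- data.frame(transcript_id = ids, chrom = "chrS1",
                           start = start, end = end, strand = strand,
                           tss = tss, stringsAsFactors = FALSE)

  n_annot <- round(annotated_fraction * n_transcripts)
  annotated <- sample(ids, n_annot)
  cats <- c("MF", "CC", "BP")
  term_ids <- sprintf("GO:%07d", seq_len(n_go_terms))
  term_cat <- sample(cats, n_go_terms, replace = TRUE)
  n_terms_per_tx <- sample(1:3, n_annot, replace = TRUE)
  go_map <- data.frame(
    transcript_id = rep(annotated, n_terms_per_tx),
    term_id = term_ids[unlist(lapply(n_terms_per_tx, function(k)
      sample.int(n_go_terms, k)))],
    stringsAsFactors = FALSE)
  go_map$category <- term_cat[match(go_map$term_id, term_ids)]

  if (!is.null(enriched_sets)) {
    for (i in seq_along(enriched_sets)) {
      set <- enriched_sets[[i]]
      if (length(set) < 3) next
      tid <- sprintf("GO:9%06d", i)
      members <- sample(set, max(2, round(0.7 * length(set))))
      go_map <- rbind(go_map, data.frame(
        transcript_id = members, term_id = tid,
        category = sample(cats, 1), stringsAsFactors = FALSE))
    }
  }
  go_map <- go_map[!duplicated(go_map[c("transcript_id", "term_id")]), ]
  rownames(go_map) <- NULL
  list(annotation = annotation, go_map = go_map)
}
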