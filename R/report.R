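#' Exact intersection-region counts for named sets
#'
#' Counts the elements of every intersection region of k sets (the
#' `2^k - 1` regions of a Venn diagram) by inclusion masks.
#'
#' @param named_sets Named list (1 to 6 elements) of id vectors.
#' @return An object of class `overlap_summary`: data frame with one row
#'   per region, columns `region` (labels joined by `&`), one logical
#'   membership column per set, and `count`; attribute `union_size`.
#' @examples
#' overlap_counts(list(A = c(1, 2), B = c(2, 3)))
#' @export
overlap_counts <- function(named_sets) {
  k <- length(named_sets)
  if (k < 1 || k > 6) stop("1 to 6 sets supported", call. = FALSE)
  if (is.null(names(named_sets)) || any(names(named_sets) == ""))
    stop("sets must be named", call. = FALSE)
  named_sets <- lapply(named_sets, unique)
  universe <- unique(unlist(named_sets))
  # integer inclusion mask per element: bit i set iff element in set i
  elem_mask <- rep(0L, length(universe))
  for (i in seq_len(k))
    elem_mask <- elem_mask + ifelse(universe %in% named_sets[[i]],
                                    2L^(i - 1L), 0L)
  masks <- expand.grid(rep(list(c(FALSE, TRUE)), k))[-1, , drop = FALSE]
  names(masks) <- names(named_sets)
  mask_code <- as.integer(as.matrix(masks) %*% 2L^(seq_len(k) - 1L))
  counts <- vapply(mask_code, function(mc)
    sum(elem_mask == mc), integer(1))
  out <- data.frame(region = apply(masks, 1L, function(m)
    paste(names(named_sets)[as.logical(m)], collapse = "&")),
    masks, count = counts,
    stringsAsFactors = FALSE, check.names = FALSE)
  rownames(out) <- NULL
  structure(out, union_size = length(universe),
            class = c("overlap_summary", "data.frame"))
}

#' Default pipeline configuration
#'
#' Every analysis threshold appears as a named key with its standard
#' value: minimum per-sample cytosine coverage 10, 100-bp windows,
#' 20-point methylation difference cutoff, FDR 0.05 for DMR and DE
#' calls, |log2FC| > 1, 999 permutations for the RDA ANOVA, and GO FDR
#' 0.1. Generator keys control the desk-scale synthetic data (2,000
#' transcripts; 10,000 cytosines in 1,000 windows on one synthetic
#' chromosome).
#'
#' @return Nested configuration list.
#' @export
default_config <- function() {
  list(
    design = list(
      treatment_labels = c("low", "intermediate", "high"),
      treatment_rho = c(0, -0.5, 0.9),
      populations_per_treatment = 3,
      salinities = c(0.8, 4.0),
      cells_per_sample = 150,
      n_transfers = 143),
    regime = list(mu = 2.4, sigma = 1, bounds = c(0, 4.8)),
    generator = list(
      n_windows = 1000,
      n_cytosines = 10000,
      n_transcripts = 2000,
      mean_coverage = 40,
      n_go_terms = 40,
      annotated_fraction = 0.30,
      n_dmr_treatment = 15,
      n_dmr_salinity = c(4, 12, 24),
      n_de_core = 60,
      n_de_private = c(6, 16, 36),
      n_de_rho2 = 40,
      n_de_interaction = 30,
      plasticity_intercept = 1,
      plasticity_slope = 2,
      plasticity_noise_sd = 0.2),
    thresholds = list(
      min_coverage = 10,
      context = "CpG",
      window_size = 100,
      min_cytosines_per_window = 1,
      dmr_q = 0.05,
      dmr_effect = 20,
      de_q = 0.05,
      lfc = 1,
      go_fdr = 0.1,
      n_perm = 999))
}

#' Build the study design / ground truth described by a configuration
#'
#' @param config Configuration list (see [default_config()]).
#' @return A [study_design()].
#' @export
config_design <- function(config) {
  study_design(
    treatments = data.frame(label = config$design$treatment_labels,
                            rho = config$design$treatment_rho),
    populations_per_treatment = config$design$populations_per_treatment,
    salinities = config$design$salinities,
    cells_per_sample = config$design$cells_per_sample,
    n_transfers = config$design$n_transfers,
    regime = env_regime(mu = config$regime$mu, sigma = config$regime$sigma,
                        bounds = config$regime$bounds))
}

#' @rdname config_design
#' @param design A [study_design()].
#' @param seed Integer seed for the planted-effect draw.
#' @return For `config_truth`, a [ground_truth()].
#' @export
config_truth <- function(config, design, seed) {
  g <- config$generator
  ground_truth(design,
               n_windows = g$n_windows,
               n_transcripts = g$n_transcripts,
               n_dmr_treatment = g$n_dmr_treatment,
               n_dmr_salinity = g$n_dmr_salinity,
               n_de_core = g$n_de_core,
               n_de_private = g$n_de_private,
               n_de_rho2 = g$n_de_rho2,
               n_de_interaction = g$n_de_interaction,
               plasticity_intercept = g$plasticity_intercept,
               plasticity_slope = g$plasticity_slope,
               plasticity_noise_sd = g$plasticity_noise_sd,
               seed = seed)
}

#' Percent-methylation matrix of pooled windows
#'
#' Samples x windows matrix of `100 * meth / (meth + unmeth)`; windows
#' with zero pooled coverage in any sample are dropped.
#'
#' @param windows A `methyl_windows` (or `methyl_regions`) object.
#' @return Numeric matrix, samples in rows.
#' @export
methylation_level_matrix <- function(windows) {
  tot <- windows$meth + windows$unmeth
  keep <- apply(tot > 0, 1L, all)
  lvl <- 100 * windows$meth[keep, , drop = FALSE] /
    tot[keep, , drop = FALSE]
  out <- t(lvl)
  rownames(out) <- windows$samples
  colnames(out) <- feature_ids(windows)[keep]
  out
}

pipeline_log <- function(con, ...) {
  msg <- sprintf(...)
  if (!is.null(con)) writeLines(paste0(format(Sys.time(), "%H:%M:%S "),
                                       msg), con)
  message(msg)
}

#' Run the full analysis pipeline on synthetic data
#'
#' Executes simulate -> methylation -> expression -> multivariate ->
#' plasticity -> enrichment -> overlaps, writing all tabular outputs, a
#' machine-readable JSON summary and a log to `outdir`, and returning
#' the summary structures.
#'
#' @param config Configuration list (see [default_config()]).
#' @param seed Master integer seed; all stages derive their streams
#'   from it.
#' @param outdir Output directory (`NULL` skips all file output).
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with elements `metadata`, `truth`,
#'   `dmr` (treatment pairwise, per-treatment salinity, overlaps),
#'   `de` (term tests, per-treatment salinity, overlaps), `rda` (per
#'   level), `plasticity` (records and slope tests per level),
#'   `enrichment`, `cis`, and `summary` (the JSON-ready digest).
#' @export
run_pipeline <- function(config = default_config(), seed = 1,
                         outdir = NULL, quiet = FALSE) {
  t0 <- Sys.time()
  log_con <- NULL
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    log_con <- file(file.path(outdir, "log.txt"), "w")
    on.exit(close(log_con), add = TRUE)
  }
  say <- function(...) if (!quiet) pipeline_log(log_con, ...) else
    if (!is.null(log_con)) pipeline_log(log_con, ...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  th <- config$thresholds

  ## --- simulate ----------------------------------------------------
  sim <- stage("simulate", {
    design <- config_design(config)
    truth <- config_truth(config, design, seed = derive_seed(seed, 1))
    metadata <- generate_metadata(design, seed = derive_seed(seed, 2))
    methylome <- simulate_methylome(
      design, truth, metadata,
      n_cytosines = config$generator$n_cytosines,
      n_windows = config$generator$n_windows,
      mean_coverage = config$generator$mean_coverage,
      seed = derive_seed(seed, 3))
    counts <- simulate_counts(design, truth, metadata,
                              seed = derive_seed(seed, 4))
    morphology <- simulate_morphology(design, truth, metadata,
                                      seed = derive_seed(seed, 5))
    ann <- simulate_annotation(
      n_transcripts = config$generator$n_transcripts,
      genome_length = config$generator$n_windows * th$window_size,
      n_go_terms = config$generator$n_go_terms,
      annotated_fraction = config$generator$annotated_fraction,
      enriched_sets = list(
        salinity_core = rownames(counts)[truth$de$salinity_core$transcript],
        interaction = rownames(counts)[truth$de$interaction$transcript]),
      seed = derive_seed(seed, 6))
    list(design = design, truth = truth, metadata = metadata,
         methylome = methylome, counts = counts, morphology = morphology,
         annotation = ann$annotation, go_map = ann$go_map)
  })
  meta <- sim$metadata
  say("simulate: %d samples, %d cytosines, %d transcripts, %d cells",
      nrow(meta), nrow(sim$methylome$sites), nrow(sim$counts),
      nrow(sim$morphology))

  ## --- methylation -------------------------------------------------
  methyl <- stage("methylation", {
    filt <- filter_cytosines(sim$methylome, min_coverage = th$min_coverage,
                             context = th$context)
    win <- window_aggregate(filt, window_size = th$window_size)
    keep <- win$windows$n_cytosines >= th$min_cytosines_per_window
    win$windows <- win$windows[keep, , drop = FALSE]
    win$meth <- win$meth[keep, , drop = FALSE]
    win$unmeth <- win$unmeth[keep, , drop = FALSE]
    treatment_dmr <- dmr_test_pairwise(win, meta$treatment,
                                       q_threshold = th$dmr_q,
                                       effect_threshold = th$dmr_effect)
    sal_dmr <- lapply(levels(meta$treatment), function(tr) {
      keep_s <- meta$treatment == tr
      dmr_test(subset_samples(win, keep_s),
               droplevels(meta$salinity[keep_s]),
               q_threshold = th$dmr_q, effect_threshold = th$dmr_effect)
    })
    names(sal_dmr) <- levels(meta$treatment)
    list(filtered = filt, windows = win, treatment = treatment_dmr,
         salinity = sal_dmr)
  })
  say("methylation: %d cytosines pass filters, %d windows tested",
      nrow(methyl$filtered$sites), nrow(methyl$windows$windows))

  ## --- expression --------------------------------------------------
  de <- stage("expression",
              de_analysis(sim$counts, meta, q_threshold = th$de_q,
                          lfc_threshold = th$lfc))
  say("expression: DE transcripts salinity=%d rho2=%d interaction=%d",
      sum(de$terms$salinity$significant),
      sum(de$terms$rho2$significant),
      sum(de$terms$interaction$significant))

  ## --- multivariate ------------------------------------------------
  rda <- stage("multivariate", {
    run_level <- function(Y, data) {
      # population identity (the covariate) is nested in treatment, so
      # the treatment main effect is aliased under conditioning and is
      # tested in a separate unconditioned analysis
      conditioned <- suppressWarnings(permutation_anova(
        Y, ~ treatment * salinity, ~ population_id, data,
        n_perm = th$n_perm, seed = derive_seed(seed, 7),
        drop_aliased = TRUE))
      evolution <- permutation_anova(
        Y, ~ treatment, NULL, data,
        n_perm = th$n_perm, seed = derive_seed(seed, 8))
      rbind(evolution, conditioned)
    }
    meth_Y <- methylation_level_matrix(methyl$windows)
    list(
      methylation = run_level(meth_Y, meta),
      expression = run_level(t(de$stabilized), meta),
      morphology = run_level(
        as.matrix(sim$morphology[c("FSC", "SSC", "RedB")]),
        data.frame(sim$morphology,
                   treatment = meta$treatment[
                     match(sim$morphology$sample_id, meta$sample_id)])))
  })
  say("multivariate: RDA done for 3 levels (%d permutations)", th$n_perm)

  ## --- plasticity --------------------------------------------------
  plast <- stage("plasticity", {
    meth_Y <- methylation_level_matrix(methyl$windows)
    levels_data <- list(
      methylation = list(Y = meth_Y, meta = meta),
      expression = list(Y = t(de$stabilized), meta = meta),
      morphology = list(
        Y = as.matrix(sim$morphology[c("FSC", "SSC", "RedB")]),
        meta = data.frame(sim$morphology,
                          rho2_realized = meta$rho2_realized[
                            match(sim$morphology$sample_id,
                                  meta$sample_id)])))
    records <- lapply(names(levels_data), function(lv)
      plasticity_records(levels_data[[lv]]$Y, levels_data[[lv]]$meta,
                         level = lv))
    names(records) <- names(levels_data)
    tests <- lapply(records, predictability_regression)
    list(records = records, tests = tests)
  })
  say("plasticity: slopes %s",
      paste(sprintf("%s=%.3g(p=%.3g)", names(plast$tests),
                    vapply(plast$tests, `[[`, 0, "slope"),
                    vapply(plast$tests, `[[`, 0, "p")), collapse = " "))

  ## --- enrichment --------------------------------------------------
  enr <- stage("enrichment", {
    universe <- unique(sim$go_map$transcript_id)
    sets <- list(
      salinity = de$terms$salinity$feature_id[de$terms$salinity$significant],
      rho2 = de$terms$rho2$feature_id[de$terms$rho2$significant],
      interaction = de$terms$interaction$feature_id[
        de$terms$interaction$significant])
    lapply(sets, function(s)
      go_enrichment(intersect(s, universe), universe, sim$go_map,
                    fdr_threshold = th$go_fdr))
  })
  say("enrichment: %s enriched terms",
      paste(names(enr), vapply(enr, nrow, 0L), collapse = " "))

  ## --- cis concordance ---------------------------------------------
  cis <- stage("cis", {
    regions <- assign_nearest_tss(methyl$filtered, sim$annotation)
    reg_treat <- dmr_test_pairwise(regions, meta$treatment,
                                   q_threshold = th$dmr_q,
                                   effect_threshold = th$dmr_effect)
    reg_sal <- lapply(levels(meta$treatment), function(tr) {
      keep_s <- meta$treatment == tr
      dmr_test(subset_samples(regions, keep_s),
               droplevels(meta$salinity[keep_s]),
               q_threshold = th$dmr_q, effect_threshold = th$dmr_effect)
    })
    names(reg_sal) <- levels(meta$treatment)
    dm_treat_ids <- reg_treat$significant_ids
    dm_sal_ids <- unique(unlist(lapply(reg_sal, function(r)
      r$feature_id[r$significant])))
    de_rho2_ids <- de$terms$rho2$feature_id[de$terms$rho2$significant]
    match_treat <- intersect(dm_treat_ids, de_rho2_ids)
    match_sal <- unique(unlist(lapply(levels(meta$treatment), function(tr) {
      w <- de$per_treatment_salinity[[tr]]
      intersect(reg_sal[[tr]]$feature_id[reg_sal[[tr]]$significant],
                w$feature_id[w$significant])
    })))
    list(regions = regions,
         n_regions = nrow(regions$regions),
         n_dm_treatment = length(dm_treat_ids),
         n_dm_salinity = length(dm_sal_ids),
         n_matched = length(unique(c(match_treat, match_sal))),
         matched_ids = unique(c(match_treat, match_sal)))
  })
  say("cis: %d regions, %d DM (treatment) + %d DM (salinity), %d DE-matched",
      cis$n_regions, cis$n_dm_treatment, cis$n_dm_salinity, cis$n_matched)

  ## --- overlaps ----------------------------------------------------
  sal_dmr_sets <- lapply(methyl$salinity, function(r)
    r$feature_id[r$significant])
  sal_de_sets <- lapply(de$per_treatment_salinity, function(r)
    r$feature_id[r$significant])
  overlaps <- list(dmr_salinity = overlap_counts(sal_dmr_sets),
                   de_salinity = overlap_counts(sal_de_sets))

  summary <- list(
    seed = seed,
    n_samples = nrow(meta),
    methylation = list(
      n_cytosines_filtered = nrow(methyl$filtered$sites),
      n_windows = nrow(methyl$windows$windows),
      n_dmr_treatment = length(methyl$treatment$significant_ids),
      n_dmr_salinity = vapply(sal_dmr_sets, length, 0L)),
    expression = list(
      n_transcripts = nrow(sim$counts),
      n_de = vapply(de$terms, function(r) sum(r$significant), 0L),
      n_de_salinity_per_treatment = vapply(sal_de_sets, length, 0L)),
    rda = lapply(rda, function(tab)
      tab[c("term", "df", "R2", "R2_adj", "pseudo_F", "p_perm")]),
    plasticity = lapply(plast$tests, function(tst)
      list(slope = tst$slope, intercept = tst$intercept,
           t_stat = tst$t_stat, p = tst$p, n = tst$n)),
    enrichment = lapply(enr, nrow),
    cis = cis[c("n_regions", "n_dm_treatment", "n_dm_salinity",
                "n_matched")],
    overlaps = list(
      dmr_salinity = as.data.frame(overlaps$dmr_salinity),
      de_salinity = as.data.frame(overlaps$de_salinity)))

  if (!is.null(outdir)) {
    stage("write", {
      write_metadata_tsv(meta, file.path(outdir, "metadata.tsv"))
      write_schedule_tsv(attr(meta, "series"),
                         file.path(outdir, "schedule.tsv"))
      write_methylation_tsv(sim$methylome,
                            file.path(outdir, "methylation.tsv"))
      write_counts_tsv(sim$counts, file.path(outdir, "counts.tsv"))
      utils::write.table(sim$morphology,
                         file.path(outdir, "morphology.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      write_annotation_gff3(sim$annotation,
                            file.path(outdir, "annotation.gff3"))
      write_go_map_tsv(sim$go_map, file.path(outdir, "go_map.tsv"))
      for (tr in names(methyl$salinity))
        write_dmr_bed(methyl$windows, methyl$salinity[[tr]],
                      file.path(outdir,
                                sprintf("dmr_salinity_%s.bed", tr)),
                      file.path(outdir,
                                sprintf("dmr_salinity_%s.tsv", tr)))
      for (nm in names(de$terms))
        utils::write.table(de$terms[[nm]],
                           file.path(outdir, sprintf("de_%s.tsv", nm)),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      for (nm in names(rda))
        utils::write.table(rda[[nm]],
                           file.path(outdir, sprintf("rda_%s.tsv", nm)),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      for (nm in names(plast$records))
        utils::write.table(plast$records[[nm]],
                           file.path(outdir,
                                     sprintf("plasticity_%s.tsv", nm)),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      for (nm in names(enr))
        utils::write.table(enr[[nm]],
                           file.path(outdir,
                                     sprintf("enrichment_%s.tsv", nm)),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      write_config(config, file.path(outdir, "config.yaml"))
      jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      pipeline_log(log_con, "versions: %s, plastevol %s",
                   R.version.string,
                   as.character(utils::packageVersion("plastevol")))
      pipeline_log(log_con, "config md5: %s",
                   unname(tools::md5sum(file.path(outdir, "config.yaml"))))
    })
  }
  say("pipeline complete in %.1f s",
      as.numeric(difftime(Sys.time(), t0, units = "secs")))
  invisible(list(design = sim$design, truth = sim$truth, metadata = meta,
                 methylation = methyl, de = de, rda = rda,
                 plasticity = plast, enrichment = enr, cis = cis,
                 overlaps = overlaps, summary = summary))
}
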