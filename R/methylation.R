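#' Construct a per-cytosine methylation count table
#'
#' Container for per-cytosine, per-sample bisulfite counts: a sites table
#' (chromosome, 1-based position, strand, context) and parallel
#' methylated/unmethylated count matrices.
#'
#' @param sites Data frame with columns `chrom`, `pos` (1-based), `strand`
#'   (`+`/`-`) and `context` (`CpG`/`CHG`/`CHH`).
#' @param meth,unmeth Integer matrices, sites x samples, with identical
#'   column names (sample ids).
#' @return An object of class `methyl_table`.
#' @export
methylation_table <- function(sites, meth, unmeth) {
  stopifnot(is.data.frame(sites),
            all(c("chrom", "pos", "strand", "context") %in% names(sites)),
            nrow(sites) == nrow(meth), nrow(sites) == nrow(unmeth),
            identical(dim(meth), dim(unmeth)),
            identical(colnames(meth), colnames(unmeth)))
  if (any(meth < 0) || any(unmeth < 0))
    stop("counts must be non-negative", call. = FALSE)
  if (anyDuplicated(sites[c("chrom", "pos", "strand")]))
    stop("positions must be unique per (chrom, pos, strand)", call. = FALSE)
  structure(list(sites = sites, meth = meth, unmeth = unmeth,
                 samples = colnames(meth)),
            class = "methyl_table")
}

#' @export
print.methyl_table <- function(x, ...) {
  cat(sprintf("Methylation table: %d cytosines x %d samples\n",
              nrow(x$sites), length(x$samples)))
  cat("  contexts:", paste(names(table(x$sites$context)),
                           table(x$sites$context), collapse = ", "), "\n")
  invisible(x)
}

#' Filter cytosines by context and minimum coverage
#'
#' Retains cytosines of the requested context whose coverage
#' (methylated + unmethylated) is at least `min_coverage` in *every*
#' sample, the standard pre-filter before window aggregation.
#'
#' @param table A [methylation_table()].
#' @param min_coverage Minimum per-sample coverage (inclusive; default 10).
#' @param context Context to keep; one of `"CpG"`, `"CHG"`, `"CHH"`.
#' @return A filtered `methyl_table`.
#' @export
filter_cytosines <- function(table, min_coverage = 10, context = "CpG") {
  stopifnot(inherits(table, "methyl_table"))
  if (min_coverage < 1) stop("'min_coverage' must be >= 1", call. = FALSE)
  if (!context %in% c("CpG", "CHG", "CHH"))
    stop("unknown context '", context, "'", call. = FALSE)
  cov <- table$meth + table$unmeth
  keep <- table$sites$context == context &
    apply(cov >= min_coverage, 1L, all)
  out <- methylation_table(table$sites[keep, , drop = FALSE],
                           table$meth[keep, , drop = FALSE],
                           table$unmeth[keep, , drop = FALSE])
  attr(out, "chrom_length") <- attr(table, "chrom_length")
  out
}

#' Aggregate cytosine counts into non-overlapping fixed-width windows
#'
#' A cytosine at 1-based position `pos` maps to window index
#' `floor((pos - 1) / window_size)`; windows are 0-based half-open
#' intervals `[start, start + window_size)`. Counts are pooled per sample
#' across strands (symmetric CpG assumption); windows with no cytosines
#' are omitted.
#'
#' @param table A [methylation_table()].
#' @param window_size Window width in bp (default 100).
#' @return An object of class `methyl_windows`: list with `windows` (data
#'   frame `chrom`, `start`, `end`, `n_cytosines`), pooled `meth`/`unmeth`
#'   matrices, and `samples`.
#' @export
window_aggregate <- function(table, window_size = 100) {
  stopifnot(inherits(table, "methyl_table"))
  if (window_size < 1) stop("'window_size' must be >= 1", call. = FALSE)
  idx <- (table$sites$pos - 1L) %/% as.integer(window_size)
  key <- paste(table$sites$chrom, idx, sep = "\r")
  meth <- rowsum(table$meth, key)
  unmeth <- rowsum(table$unmeth, key)
  n_cyt <- as.vector(rowsum(rep(1L, nrow(table$sites)), key))
  parts <- strsplit(rownames(meth), "\r", fixed = TRUE)
  chrom <- vapply(parts, `[[`, "", 1L)
  start <- as.integer(vapply(parts, `[[`, "", 2L)) * as.integer(window_size)
  o <- order(chrom, start)
  windows <- data.frame(chrom = chrom[o], start = start[o],
                        end = start[o] + as.integer(window_size),
                        n_cytosines = n_cyt[o], stringsAsFactors = FALSE)
  structure(list(windows = windows,
                 meth = unname(meth[o, , drop = FALSE]),
                 unmeth = unname(unmeth[o, , drop = FALSE]),
                 samples = table$samples),
            class = "methyl_windows")
}

#' @export
print.methyl_windows <- function(x, ...) {
  cat(sprintf("Methylation windows: %d windows x %d samples\n",
              nrow(x$windows), length(x$samples)))
  invisible(x)
}

#' Feature identifiers of a pooled methylation object
#'
#' @param x A `methyl_windows` or `methyl_regions` object.
#' @return Character vector of feature ids (`chrom:start-end` for
#'   windows, transcript ids for gene-associated regions).
#' @export
feature_ids <- function(x) {
  if (inherits(x, "methyl_windows"))
    sprintf("%s:%d-%d", x$windows$chrom, x$windows$start, x$windows$end)
  else if (inherits(x, "methyl_regions"))
    x$regions$transcript_id
  else stop("unsupported object", call. = FALSE)
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Vectorized two-sided Fisher exact p-value for tables
#' `rbind(c(a, b), c(c, d))`, using the minimum-likelihood rule: the
#' p-value is the sum of hypergeometric probabilities of all tables with
#' the observed margins whose probability does not exceed that of the
#' observed table (up to a 1e-7 relative tolerance, as in
#' `stats::fisher.test`).
#'
#' @param a,b,c,d Non-negative integer vectors (recycled to a common
#'   length); rows of the table are (a, b) and (c, d).
#' @return Numeric vector of p-values in `[0, 1]`.
#' @examples
#' fisher_exact_2x2(5, 5, 5, 5)  # 1: identical proportions
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  n <- max(length(a), length(b), length(c), length(d))
  a <- rep_len(as.numeric(a), n); b <- rep_len(as.numeric(b), n)
  c <- rep_len(as.numeric(c), n); d <- rep_len(as.numeric(d), n)
  if (any(is.na(c(a, b, c, d))) || any(c(a, b, c, d) < 0))
    stop("table entries must be non-negative and finite", call. = FALSE)
  vapply(seq_len(n), function(i) {
    r1 <- a[i] + b[i]; r2 <- c[i] + d[i]; c1 <- a[i] + c[i]
    lo <- max(0, c1 - r2); hi <- min(r1, c1)
    if (lo == hi) return(1)
    k <- lo:hi
    dens <- stats::dhyper(k, r1, r2, c1)
    obs <- stats::dhyper(a[i], r1, r2, c1)
    min(1, sum(dens[dens <= obs * (1 + 1e-7)]))
  }, numeric(1))
}

#' Benjamini-Hochberg adjustment of p-values
#'
#' Step-up false-discovery-rate adjustment. `NA` p-values (e.g. from
#' non-converged fits) are excluded from the family and returned as `NA`.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (NAs allowed).
#' @return Vector of BH-adjusted q-values in input order.
#' @export
benjamini_hochberg <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must be in [0, 1]", call. = FALSE)
  q <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  q[ok] <- stats::p.adjust(p[ok], method = "BH")
  q
}

#' Call differentially methylated features between two groups
#'
#' Pools methylated/unmethylated counts within each group by summing
#' across the group's samples (replicate-level overdispersion is therefore
#' ignored, the price of the exact-test framework), computes the
#' methylation difference in percentage points (second group minus first),
#' tests each feature with a two-sided Fisher exact test on the pooled
#' 2x2 table, adjusts by Benjamini-Hochberg across all tested features,
#' and flags features significant when `q < q_threshold` *and*
#' `|effect| > effect_threshold`.
#'
#' @param x A `methyl_windows` or `methyl_regions` object.
#' @param groups Factor (or vector) over `x$samples` with exactly two
#'   levels in use; the effect sign is level 2 minus level 1.
#' @param q_threshold FDR threshold (default 0.05).
#' @param effect_threshold Absolute methylation-difference threshold in
#'   percentage points (default 20).
#' @return Data frame (`feature_id`, `effect`, `p_raw`, `q`,
#'   `significant`). Features with zero pooled coverage in a group get
#'   `NA` effect/p and are excluded from the BH family.
#' @export
dmr_test <- function(x, groups, q_threshold = 0.05, effect_threshold = 20) {
  groups <- droplevels(as.factor(groups))
  if (length(groups) != length(x$samples))
    stop("'groups' must have one value per sample", call. = FALSE)
  if (nlevels(groups) != 2)
    stop("exactly two groups required (got ", nlevels(groups), ")",
         call. = FALSE)
  if (any(table(groups) == 0)) stop("empty group", call. = FALSE)
  ga <- groups == levels(groups)[1]
  meth_a <- rowSums(x$meth[, ga, drop = FALSE])
  unmeth_a <- rowSums(x$unmeth[, ga, drop = FALSE])
  meth_b <- rowSums(x$meth[, !ga, drop = FALSE])
  unmeth_b <- rowSums(x$unmeth[, !ga, drop = FALSE])
  tot_a <- meth_a + unmeth_a
  tot_b <- meth_b + unmeth_b
  ok <- tot_a > 0 & tot_b > 0
  effect <- rep(NA_real_, length(meth_a))
  effect[ok] <- 100 * (meth_b[ok] / tot_b[ok] - meth_a[ok] / tot_a[ok])
  p <- rep(NA_real_, length(meth_a))
  p[ok] <- fisher_exact_2x2(meth_a[ok], unmeth_a[ok], meth_b[ok], unmeth_b[ok])
  q <- benjamini_hochberg(p)
  sig <- !is.na(q) & q < q_threshold & abs(effect) > effect_threshold
  data.frame(feature_id = feature_ids(x), effect = effect, p_raw = p,
             q = q, significant = sig, stringsAsFactors = FALSE)
}

#' Pairwise differential methylation across k groups
#'
#' The exact-test framework is 2x2, so comparisons among more than two
#' groups are run as all pairwise two-group tests (each with its own BH
#' family); a feature is called differential overall if significant in
#' any pair.
#'
#' @inheritParams dmr_test
#' @return List with `pairs` (named list of [dmr_test()] results, names
#'   `"A.vs.B"`) and `significant_ids` (union of significant feature
#'   ids).
#' @export
dmr_test_pairwise <- function(x, groups, q_threshold = 0.05,
                              effect_threshold = 20) {
  groups <- droplevels(as.factor(groups))
  levs <- levels(groups)
  if (length(levs) < 2) stop("need >= 2 groups", call. = FALSE)
  pairs <- utils::combn(levs, 2, simplify = FALSE)
  res <- lapply(pairs, function(pr) {
    keep <- groups %in% pr
    xs <- subset_samples(x, keep)
    dmr_test(xs, factor(groups[keep], levels = pr),
             q_threshold = q_threshold, effect_threshold = effect_threshold)
  })
  names(res) <- vapply(pairs, paste, "", collapse = ".vs.")
  sig <- unique(unlist(lapply(res, function(r) r$feature_id[r$significant])))
  list(pairs = res, significant_ids = sig)
}

#' Subset the sample dimension of a pooled methylation object
#'
#' @param x A `methyl_windows` or `methyl_regions` object.
#' @param keep Logical or integer index over `x$samples`.
#' @return The object restricted to the selected samples.
#' @export
subset_samples <- function(x, keep) {
  x$meth <- x$meth[, keep, drop = FALSE]
  x$unmeth <- x$unmeth[, keep, drop = FALSE]
  x$samples <- x$samples[keep]
  x
}

#' Assign cytosines to the nearest transcription start site
#'
#' Each cytosine is assigned to the transcript whose TSS minimizes
#' absolute genomic distance (ties broken deterministically toward the
#' lower TSS coordinate, then the first transcript id); all cytosines
#' assigned to one transcript are merged into a gene-associated
#' methylation region with pooled counts.
#'
#' @param table A [methylation_table()].
#' @param annotation Data frame with columns `transcript_id`, `chrom`,
#'   `tss` (as from [simulate_annotation()] or [read_annotation_gff3()]).
#' @return An object of class `methyl_regions`: list with `regions` (data
#'   frame `transcript_id`, `n_cytosines`, `mean_tss_distance`), pooled
#'   `meth`/`unmeth` matrices, `samples`, and an `assignment` data frame
#'   (one row per cytosine). Chromosomes absent from the annotation yield
#'   an empty assignment with a warning.
#' @export
assign_nearest_tss <- function(table, annotation) {
  stopifnot(inherits(table, "methyl_table"),
            all(c("transcript_id", "chrom", "tss") %in% names(annotation)))
  if (nrow(annotation) == 0) stop("empty annotation", call. = FALSE)
  assign_tx <- rep(NA_character_, nrow(table$sites))
  assign_d <- rep(NA_real_, nrow(table$sites))
  shared <- intersect(unique(table$sites$chrom), unique(annotation$chrom))
  if (length(shared) == 0)
    warning("no chromosome shared between table and annotation; ",
            "empty assignment")
  for (chr in shared) {
    ann <- annotation[annotation$chrom == chr, ]
    # sort by TSS coordinate then id so ties resolve to the lower
    # coordinate and, within it, the first transcript id
    ann <- ann[order(ann$tss, ann$transcript_id), ]
    rows <- which(table$sites$chrom == chr)
    pos <- table$sites$pos[rows]
    j <- findInterval(pos, ann$tss)
    left <- pmax(j, 1L)
    right <- pmin(j + 1L, nrow(ann))
    d_left <- abs(pos - ann$tss[left])
    d_right <- abs(pos - ann$tss[right])
    use_left <- j >= 1L & (j >= nrow(ann) | d_left <= d_right)
    pick <- ifelse(use_left, left, right)
    # exact duplicate TSS coordinates resolve to the first transcript id
    pick <- match(ann$tss[pick], ann$tss)
    assign_tx[rows] <- ann$transcript_id[pick]
    assign_d[rows] <- abs(pos - ann$tss[pick])
  }
  ok <- !is.na(assign_tx)
  if (!any(ok)) {
    return(structure(list(
      regions = data.frame(transcript_id = character(),
                           n_cytosines = integer(),
                           mean_tss_distance = numeric()),
      meth = matrix(0L, 0, length(table$samples)),
      unmeth = matrix(0L, 0, length(table$samples)),
      samples = table$samples,
      assignment = data.frame()), class = "methyl_regions"))
  }
  tx <- assign_tx[ok]
  meth <- rowsum(table$meth[ok, , drop = FALSE], tx)
  unmeth <- rowsum(table$unmeth[ok, , drop = FALSE], tx)
  n_cyt <- as.vector(table(tx)[rownames(meth)])
  mean_d <- as.vector(tapply(assign_d[ok], tx, mean)[rownames(meth)])
  structure(list(
    regions = data.frame(transcript_id = rownames(meth),
                         n_cytosines = n_cyt,
                         mean_tss_distance = mean_d,
                         stringsAsFactors = FALSE),
    meth = unname(meth), unmeth = unname(unmeth),
    samples = table$samples,
    assignment = data.frame(chrom = table$sites$chrom[ok],
                            pos = table$sites$pos[ok],
                            transcript_id = tx,
                            tss_distance = assign_d[ok],
                            stringsAsFactors = FALSE)),
    class = "methyl_regions")
}

#' @export
print.methyl_regions <- function(x, ...) {
  cat(sprintf(
    "Gene-associated methylation regions: %d regions x %d samples\n",
    nrow(x$regions), length(x$samples)))
  invisible(x)
}

#' Concordance between cis methylation and expression changes
#'
#' Counts gene-associated regions significant for differential
#' methylation whose transcript is also significantly differentially
#' expressed for the same comparison.
#'
#' @param dm_regions [dmr_test()]-style result over gene-associated
#'   regions (feature ids are transcript ids).
#' @param de [wald_test()]/[lrt_test()]-style result over transcripts.
#' @return List with `n_dm` (significant regions), `n_de_matched`
#'   (regions whose transcript is also DE) and `matched_ids`.
#' @export
cis_concordance <- function(dm_regions, de) {
  dm_sig <- dm_regions$feature_id[dm_regions$significant]
  de_sig <- de$feature_id[de$significant]
  matched <- intersect(dm_sig, de_sig)
  list(n_dm = length(dm_sig), n_de_matched = length(matched),
       matched_ids = matched)
}
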