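#' Write / read a methylation count table as TSV
#'
#' Wide dialect: columns `chrom`, `pos`, `strand`, `context`, then
#' `meth_<sample>` and `unmeth_<sample>` for each sample (methylKit-style
#' per-sample methylated/unmethylated read counts).
#'
#' @param table A [methylation_table()].
#' @param path File path.
#' @return `path` (writer) or a `methyl_table` (reader).
#' @export
write_methylation_tsv <- function(table, path) {
  stopifnot(inherits(table, "methyl_table"))
  m <- table$meth; u <- table$unmeth
  colnames(m) <- paste0("meth_", table$samples)
  colnames(u) <- paste0("unmeth_", table$samples)
  df <- cbind(table$sites, m, u)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_methylation_tsv
#' @export
read_methylation_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  meth_cols <- grep("^meth_", names(df), value = TRUE)
  unmeth_cols <- grep("^unmeth_", names(df), value = TRUE)
  samples <- sub("^meth_", "", meth_cols)
  stopifnot(identical(samples, sub("^unmeth_", "", unmeth_cols)))
  meth <- as.matrix(df[meth_cols]); colnames(meth) <- samples
  unmeth <- as.matrix(df[unmeth_cols]); colnames(unmeth) <- samples
  methylation_table(df[c("chrom", "pos", "strand", "context")], meth, unmeth)
}

#' Write / read a transcript count matrix as TSV
#'
#' First column `transcript_id`, remaining header = sample ids.
#'
#' @param counts Integer matrix, transcripts x samples.
#' @param path File path.
#' @export
write_counts_tsv <- function(counts, path) {
  df <- data.frame(transcript_id = rownames(counts), counts,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts_tsv
#' @export
read_counts_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df[[1]]
  m
}

#' Write / read sample metadata as TSV
#'
#' @param metadata Data frame from [generate_metadata()].
#' @param path File path.
#' @export
write_metadata_tsv <- function(metadata, path) {
  utils::write.table(metadata, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_metadata_tsv
#' @param treatment_levels Factor level order for `treatment` (defaults
#'   to order of appearance).
#' @export
read_metadata_tsv <- function(path, treatment_levels = NULL) {
  meta <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (is.null(treatment_levels)) treatment_levels <- unique(meta$treatment)
  meta$treatment <- factor(meta$treatment, levels = treatment_levels)
  meta$salinity <- factor(meta$salinity, levels = c("low", "high"))
  rownames(meta) <- meta$sample_id
  meta
}

#' Write / read a transcript annotation as GFF3
#'
#' Transcripts are exported as `mRNA` features with `ID` attributes;
#' the TSS is recovered on read from the strand (start for `+`, end for
#' `-`).
#'
#' @param annotation Data frame (`transcript_id`, `chrom`, `start`,
#'   `end`, `strand`).
#' @param path File path.
#' @export
write_annotation_gff3 <- function(annotation, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = annotation$chrom,
    ranges = IRanges::IRanges(start = annotation$start,
                              end = annotation$end),
    strand = annotation$strand,
    type = "mRNA",
    ID = annotation$transcript_id)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' @rdname write_annotation_gff3
#' @export
read_annotation_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- data.frame(
    transcript_id = as.character(S4Vectors::mcols(gr)$ID),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE)
  df$tss <- ifelse(df$strand == "-", df$end, df$start)
  df
}

#' Write / read a transcript-to-GO-term map as TSV
#'
#' Columns `transcript_id`, `term_id`, optional `category`.
#'
#' @param go_map Data frame.
#' @param path File path.
#' @export
write_go_map_tsv <- function(go_map, path) {
  utils::write.table(go_map, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_go_map_tsv
#' @export
read_go_map_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Write differential methylation calls as BED6 plus a results TSV
#'
#' The BED file contains the significant windows only (name = feature
#' id, score = `min(1000, round(-10 log10 q))`, strand `.`); the TSV
#' carries effect, p and q for every tested window.
#'
#' @param windows A `methyl_windows` object the result was computed on.
#' @param result [dmr_test()] output.
#' @param bed_path,tsv_path File paths (`NULL` skips the file).
#' @export
write_dmr_bed <- function(windows, result, bed_path, tsv_path = NULL) {
  if (!is.null(tsv_path))
    utils::write.table(result, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  sig <- which(result$significant)
  bed <- data.frame(chrom = windows$windows$chrom[sig],
                    start = windows$windows$start[sig],
                    end = windows$windows$end[sig],
                    name = result$feature_id[sig],
                    score = pmin(1000,
                                 round(-10 * log10(pmax(result$q[sig],
                                                        1e-100)))),
                    strand = ".")
  utils::write.table(bed, bed_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(bed_path)
}

#' Write / read a pipeline configuration file (YAML)
#'
#' @param config Configuration list (see [default_config()]).
#' @param path File path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  utils::modifyList(default_config(), cfg)
}
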