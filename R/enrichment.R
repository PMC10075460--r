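#' Propagate GO annotations to ancestor terms
#'
#' When parent edges of the ontology DAG are available, a transcript
#' annotated to a term is implicitly annotated to all its ancestors;
#' this closure is applied before testing.
#'
#' @param go_map Data frame (`transcript_id`, `term_id`, optional
#'   `category`).
#' @param edges Data frame (`child`, `parent`) of DAG edges.
#' @return Augmented `go_map` (deduplicated).
#' @export
propagate_annotations <- function(go_map, edges) {
  stopifnot(all(c("child", "parent") %in% names(edges)))
  # GO namespaces are closed under parent edges, so propagated rows keep
  # the child's category
  repeat {
    hit <- merge(go_map, edges, by.x = "term_id", by.y = "child")
    if (nrow(hit) == 0) break
    new <- hit
    new$term_id <- new$parent
    new <- new[names(go_map)]
    combined <- rbind(go_map, new)
    combined <- combined[!duplicated(combined[c("transcript_id",
                                                "term_id")]), ]
    if (nrow(combined) == nrow(go_map)) break
    go_map <- combined
  }
  rownames(go_map) <- NULL
  go_map
}

#' GO term over-representation test (classic Fisher)
#'
#' Per-term one-sided (over-representation) Fisher exact test of the
#' 2x2 table (in/out of the differential set x in/out of the term),
#' every term tested independently against the annotated universe (the
#' "classic" algorithm). Benjamini-Hochberg adjustment is applied within
#' each GO category, and results are sorted by increasing p within
#' category.
#'
#' @param de_set Character vector of differential transcript ids (must be
#'   a subset of `universe`).
#' @param universe Character vector of all tested transcript ids.
#' @param gomap Data frame (`transcript_id`, `term_id`, optional
#'   `category`; defaults to a single category `"all"`).
#' @param fdr_threshold Report threshold on the adjusted p (default 0.1).
#' @param min_term_size Terms with fewer annotated transcripts in the
#'   universe are skipped (default 2).
#' @param edges Optional DAG edges (`child`, `parent`); annotations are
#'   propagated to ancestors first.
#' @param all_terms Return all tested terms, not only those passing
#'   `fdr_threshold`.
#' @return Data frame (`term_id`, `category`, `n_term`, `n_de_in_term`,
#'   `expected`, `p_raw`, `q`, `significant`), sorted by category then p.
#' @export
go_enrichment <- function(de_set, universe, gomap, fdr_threshold = 0.1,
                          min_term_size = 2, edges = NULL,
                          all_terms = FALSE) {
  de_set <- unique(as.character(de_set))
  universe <- unique(as.character(universe))
  if (!all(de_set %in% universe))
    stop("'de_set' must be a subset of 'universe'", call. = FALSE)
  if (!"category" %in% names(gomap)) gomap$category <- "all"
  if (!is.null(edges)) gomap <- propagate_annotations(gomap, edges)
  gomap <- gomap[gomap$transcript_id %in% universe, , drop = FALSE]
  n_u <- length(universe)
  n_de <- length(de_set)
  terms <- unique(gomap[c("term_id", "category")])
  res <- lapply(seq_len(nrow(terms)), function(i) {
    members <- unique(gomap$transcript_id[gomap$term_id == terms$term_id[i]])
    k <- length(members)
    if (k < min_term_size) return(NULL)
    x <- sum(de_set %in% members)
    # hypergeometric upper tail: P(overlap >= x)
    p <- stats::phyper(x - 1, k, n_u - k, n_de, lower.tail = FALSE)
    data.frame(term_id = terms$term_id[i], category = terms$category[i],
               n_term = k, n_de_in_term = x,
               expected = n_de * k / n_u, p_raw = p,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  if (is.null(res))
    return(data.frame(term_id = character(), category = character(),
                      n_term = integer(), n_de_in_term = integer(),
                      expected = numeric(), p_raw = numeric(),
                      q = numeric(), significant = logical()))
  res$q <- NA_real_
  for (cat_ in unique(res$category)) {
    sel <- res$category == cat_
    res$q[sel] <- benjamini_hochberg(res$p_raw[sel])
  }
  res$significant <- res$q <= fdr_threshold
  res <- res[order(res$category, res$p_raw), ]
  rownames(res) <- NULL
  if (!all_terms) res <- res[res$significant, , drop = FALSE]
  res
}
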