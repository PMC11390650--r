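# Conserved / species-specific regulated gene sets --------------------------

# matched-pair helper: pairs table carries source/target event and gene ids
check_pairs <- function(pairs) {
  need <- c("source_event_id", "target_event_id",
            "source_gene_id", "target_gene_id")
  stopifnot(all(need %in% names(pairs)))
  pairs
}

#' Background gene set for conservation analyses
#'
#' A gene enters the background when it has at least one orthologous
#' event pair whose target-species event passes the mean-over-samples
#' expression filter (`mean(max(I, S)) > min_count`) in the target
#' dataset and whose source-species event passes the same filter in at
#' least one source dataset. Genes are identified by their
#' target-species id.
#'
#' @param pairs matched-pair table from [match_events()].
#' @param counts_target long count table for the target-species dataset.
#' @param counts_source_list list of long count tables, one per
#'   source-species dataset.
#' @param min_count expression threshold (default 5).
#' @return character vector of target-species gene ids.
#' @export
build_background <- function(pairs, counts_target, counts_source_list,
                             min_count = 5) {
  check_pairs(pairs)
  if (!is.list(counts_source_list) || is.data.frame(counts_source_list)) {
    counts_source_list <- list(counts_source_list)
  }
  ok_t <- filter_expressed(counts_target, min_count = min_count,
                           rule = "mean_over_samples")
  ok_s <- unique(unlist(lapply(counts_source_list, filter_expressed,
                               min_count = min_count,
                               rule = "mean_over_samples")))
  testable <- pairs$target_event_id %in% ok_t & pairs$source_event_id %in% ok_s
  genes <- unique(pairs$target_gene_id[testable])
  if (length(genes) == 0L) stop("empty background gene set")
  sort(genes)
}

#' Orthologous event pairs testable in both species
#'
#' Event-level companion of [build_background()]: the pair ids (target
#' event ids) whose two sides pass the mean-over-samples filter in the
#' target dataset and in at least one source dataset.
#'
#' @inheritParams build_background
#' @return character vector of target event ids.
#' @export
testable_pairs <- function(pairs, counts_target, counts_source_list,
                           min_count = 5) {
  check_pairs(pairs)
  if (!is.list(counts_source_list) || is.data.frame(counts_source_list)) {
    counts_source_list <- list(counts_source_list)
  }
  ok_t <- filter_expressed(counts_target, min_count = min_count,
                           rule = "mean_over_samples")
  ok_s <- unique(unlist(lapply(counts_source_list, filter_expressed,
                               min_count = min_count,
                               rule = "mean_over_samples")))
  pairs$target_event_id[pairs$target_event_id %in% ok_t &
                          pairs$source_event_id %in% ok_s]
}

sig_ids <- function(calls) calls$event_id[calls$significant]

#' Genes with conserved activity-dependent splicing
#'
#' A target-species gene is conservedly regulated when it has at least one
#' orthologous event that is significantly activity-regulated in the
#' target dataset AND its orthologous source-species gene has at least one
#' significantly regulated event in at least one source dataset
#' (gene-level conservation, the default). With `level = "event"` the
#' stricter event-level rule is used: the same orthologous event pair must
#' be significant on both sides.
#'
#' @param calls_target differential calls (see [differential_calls()]) for
#'   the target dataset; event ids are target event ids.
#' @param calls_source_list list of differential-call tables for the
#'   source datasets; event ids are source event ids.
#' @param pairs matched-pair table.
#' @param level `"gene"` (default) or `"event"`.
#' @return character vector of target-species gene ids.
#' @export
conserved_regulated_genes <- function(calls_target, calls_source_list, pairs,
                                      level = c("gene", "event")) {
  level <- match.arg(level)
  check_pairs(pairs)
  if (is.data.frame(calls_source_list)) calls_source_list <- list(calls_source_list)
  sig_t <- sig_ids(calls_target)
  sig_s <- unique(unlist(lapply(calls_source_list, sig_ids)))
  if (level == "gene") {
    genes_t <- unique(pairs$target_gene_id[pairs$target_event_id %in% sig_t])
    genes_s <- unique(pairs$target_gene_id[pairs$source_event_id %in% sig_s])
    sort(intersect(genes_t, genes_s))
  } else {
    both <- pairs$target_event_id %in% sig_t & pairs$source_event_id %in% sig_s
    sort(unique(pairs$target_gene_id[both]))
  }
}

#' Orthologous event pairs regulated in both species
#'
#' Event-level conservation used for splicing-factor target enrichment:
#' the target event ids of pairs significant in the target dataset and in
#' at least one source dataset.
#'
#' @inheritParams conserved_regulated_genes
#' @return character vector of target event ids.
#' @export
conserved_regulated_events <- function(calls_target, calls_source_list, pairs) {
  check_pairs(pairs)
  if (is.data.frame(calls_source_list)) calls_source_list <- list(calls_source_list)
  sig_t <- sig_ids(calls_target)
  sig_s <- unique(unlist(lapply(calls_source_list, sig_ids)))
  pairs$target_event_id[pairs$target_event_id %in% sig_t &
                          pairs$source_event_id %in% sig_s]
}

#' Genes with species-specific activity-dependent splicing
#'
#' Target-species genes with at least one significantly regulated
#' orthologous event whose orthologous source gene never meets the
#' significance criteria in any source dataset. By default a gene only
#' qualifies when its ortholog was *testable* (present in the background):
#' genes whose ortholog could not be tested in any source dataset are
#' excluded rather than counted as species-specific, so absence of
#' evidence is not mistaken for divergence. Set
#' `include_untestable = TRUE` for the permissive reading in which any
#' regulated gene without a significant ortholog qualifies.
#'
#' @inheritParams conserved_regulated_genes
#' @param background background gene set from [build_background()].
#' @param include_untestable include genes whose ortholog is untestable.
#' @return character vector of target-species gene ids.
#' @export
species_specific_regulated_genes <- function(calls_target, calls_source_list,
                                             pairs, background,
                                             include_untestable = FALSE) {
  check_pairs(pairs)
  if (is.data.frame(calls_source_list)) calls_source_list <- list(calls_source_list)
  sig_t <- sig_ids(calls_target)
  regulated <- unique(pairs$target_gene_id[pairs$target_event_id %in% sig_t])
  conserved <- conserved_regulated_genes(calls_target, calls_source_list,
                                         pairs, level = "gene")
  out <- setdiff(regulated, conserved)
  if (!include_untestable) out <- intersect(out, background)
  sort(out)
}

#' Regulation labels partitioning the gene universe
#'
#' Assigns every gene seen in the matched pairs one of: `conserved`
#' (regulated in both species), `species_specific_target`,
#' `species_specific_source`, `unregulated` (testable, regulated in
#' neither) or `untestable` (regulated somewhere but not in the
#' background, or never testable). The first four labels partition the
#' background.
#'
#' @inheritParams species_specific_regulated_genes
#' @return data.frame with `gene_id` (target-species ids) and `label`.
#' @export
regulation_labels <- function(calls_target, calls_source_list, pairs,
                              background) {
  check_pairs(pairs)
  if (is.data.frame(calls_source_list)) calls_source_list <- list(calls_source_list)
  sig_t <- sig_ids(calls_target)
  sig_s <- unique(unlist(lapply(calls_source_list, sig_ids)))
  genes <- sort(unique(pairs$target_gene_id))
  reg_t <- unique(pairs$target_gene_id[pairs$target_event_id %in% sig_t])
  reg_s <- unique(pairs$target_gene_id[pairs$source_event_id %in% sig_s])
  label <- rep("unregulated", length(genes))
  label[genes %in% reg_t & genes %in% reg_s] <- "conserved"
  label[genes %in% reg_t & !genes %in% reg_s] <- "species_specific_target"
  label[!genes %in% reg_t & genes %in% reg_s] <- "species_specific_source"
  label[!genes %in% background] <- "untestable"
  data.frame(gene_id = genes, label = label, stringsAsFactors = FALSE)
}

#' Splicing-factor target enrichment
#'
#' For each splicing factor (for example RBFOX, SAM68, NOVA, PTBP), tests
#' whether its target events are enriched in a foreground event set
#' relative to a background, by Fisher's exact test through the same
#' 2x2 arithmetic as [class_enrichment()] (targets are the reference
#' class, the foreground the query, the background the universe). Both
#' background designs are expressed through the arguments: pass the
#' tested-event universe as `background` with the orthologous subset as
#' `foreground`, or the expressed orthologous events as `background` with
#' the conservedly regulated events as `foreground`.
#'
#' @param target_sets named list of character vectors of event ids, one
#'   per factor.
#' @param foreground event set of interest (subset of `background`).
#' @param background event universe.
#' @param conf confidence level.
#' @return named list of `enrichment_result` objects; empty foregrounds
#'   yield a degenerate flagged result.
#' @export
factor_target_enrichment <- function(target_sets, foreground, background,
                                     conf = 0.95) {
  stopifnot(is.list(target_sets), !is.null(names(target_sets)))
  if (!all(foreground %in% background)) {
    stop("foreground must be a subset of the background")
  }
  lapply(target_sets, function(targets) {
    class_enrichment(reference_ids = intersect(targets, background),
                     query_ids = foreground,
                     universe = background, conf = conf)
  })
}

#' Per-term gene-set enrichment (plain Fisher)
#'
#' Term-by-term Fisher exact enrichment of a gene set against a
#' background, from a flat gene-to-term annotation table. This is the
#' plain per-term test: no ontology-graph decorrelation (such as topGO's
#' weight01) is applied, so p-values for nested terms are not adjusted
#' for each other. Terms annotating fewer than `min_genes` background
#' genes are skipped; annotations outside the background are ignored.
#'
#' @param gene_set character vector, subset of `background_genes`.
#' @param background_genes character vector.
#' @param gene2term data.frame with columns `gene_id`, `term_id`.
#' @param min_genes minimum annotated background genes per term
#'   (default 5).
#' @param p_adjust `"none"` (default) or `"BH"`.
#' @return data.frame: `term_id`, `n_set`, `n_background`,
#'   `fold_enrichment`, `odds_ratio`, `fisher_p`, `p_adjusted`, sorted by
#'   `fisher_p`. Zero rows (flagged via attribute `flag`) when the gene
#'   set is empty.
#' @export
term_enrichment <- function(gene_set, background_genes, gene2term,
                            min_genes = 5, p_adjust = c("none", "BH")) {
  p_adjust <- match.arg(p_adjust)
  stopifnot(all(c("gene_id", "term_id") %in% names(gene2term)))
  if (!all(gene_set %in% background_genes)) {
    stop("gene_set must be a subset of background_genes")
  }
  empty <- data.frame(term_id = character(0), n_set = integer(0),
                      n_background = integer(0), fold_enrichment = numeric(0),
                      odds_ratio = numeric(0), fisher_p = numeric(0),
                      p_adjusted = numeric(0), stringsAsFactors = FALSE)
  if (length(gene_set) == 0L) {
    attr(empty, "flag") <- "empty_gene_set"
    return(empty)
  }
  ann <- gene2term[gene2term$gene_id %in% background_genes,
                   c("gene_id", "term_id"), drop = FALSE]
  ann <- unique(ann)
  terms <- split(ann$gene_id, ann$term_id)
  sizes <- lengths(terms)
  skipped <- sum(sizes < min_genes)
  terms <- terms[sizes >= min_genes]
  if (length(terms) == 0L) {
    attr(empty, "flag") <- "no_terms"
    attr(empty, "n_skipped") <- skipped
    return(empty)
  }
  rows <- lapply(names(terms), function(tm) {
    res <- class_enrichment(reference_ids = terms[[tm]],
                            query_ids = gene_set,
                            universe = background_genes)
    data.frame(term_id = tm,
               n_set = length(intersect(terms[[tm]], gene_set)),
               n_background = length(terms[[tm]]),
               fold_enrichment = res$fold_enrichment,
               odds_ratio = res$odds_ratio,
               fisher_p = res$fisher_p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- if (p_adjust == "BH") {
    stats::p.adjust(out$fisher_p, method = "BH")
  } else {
    out$fisher_p
  }
  out <- out[order(out$fisher_p, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_skipped") <- skipped
  out
}
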