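# Orthologous event matching ------------------------------------------------

#' Read a 1:1 gene ortholog map
#'
#' Two-column tab-separated file (`source_gene_id`, `target_gene_id`).
#' The map must be strictly one-to-one: duplicates on either side are
#' rejected.
#'
#' @param path file path.
#' @return data.frame with columns `source_gene_id`, `target_gene_id`.
#' @export
read_ortholog_map <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character")
  if (ncol(tab) < 2L) stop("ortholog map needs two columns")
  names(tab)[1:2] <- c("source_gene_id", "target_gene_id")
  validate_ortholog_map(tab[, 1:2])
}

#' @rdname read_ortholog_map
#' @param map data.frame with the two gene-id columns.
#' @export
validate_ortholog_map <- function(map) {
  stopifnot(all(c("source_gene_id", "target_gene_id") %in% names(map)))
  if (anyDuplicated(map$source_gene_id) || anyDuplicated(map$target_gene_id)) {
    stop("ortholog map is not 1:1: duplicated gene ids present")
  }
  map
}

#' Match lifted source events to target events within a tolerance
#'
#' Candidate pairs must share chromosome, event type and (post-lift)
#' strand, have a gene pair consistent with the 1:1 ortholog map when one
#' is supplied, and agree on all four boundary coordinates to within
#' `tolerance` base pairs (inclusive: an offset of exactly `tolerance`
#' still matches). Among candidates, a one-to-one pairing is chosen
#' greedily by ascending total absolute offset, with ties broken by source
#' coordinates then event ids, which makes the result independent of input
#' row order. On well-separated events this greedy pairing coincides with
#' the minimum-total-offset assignment.
#'
#' @param lifted_source source-species events already lifted into target
#'   coordinates (see [lift_event()]).
#' @param target target-species events.
#' @param tolerance maximum absolute per-boundary offset in bp (default 10).
#' @param ortholog_map optional 1:1 gene map (`source_gene_id`,
#'   `target_gene_id`); when supplied, matching is restricted to gene
#'   pairs in the map. When omitted the gene check is skipped.
#' @param require_gene_match if `FALSE` (and a map is supplied), the map is
#'   only used to annotate pairs, not to restrict candidates; gene-level
#'   orthology can then be assessed after coordinate matching.
#' @return data.frame of pairs, sorted by target coordinates, with
#'   per-boundary signed offsets (target minus lifted source),
#'   `total_offset`, and the gene pair. Unmatched event ids are attached
#'   as attributes `unmatched_source` and `unmatched_target`.
#' @export
match_events <- function(lifted_source, target, tolerance = 10,
                         ortholog_map = NULL, require_gene_match = TRUE) {
  stopifnot(tolerance >= 0)
  if (anyDuplicated(lifted_source$event_id) || anyDuplicated(target$event_id)) {
    stop("duplicate event_ids in input")
  }
  empty <- data.frame(
    source_event_id = character(0), target_event_id = character(0),
    off_upstream_end = numeric(0), off_target_start = numeric(0),
    off_target_end = numeric(0), off_downstream_start = numeric(0),
    total_offset = numeric(0),
    source_gene_id = character(0), target_gene_id = character(0),
    stringsAsFactors = FALSE
  )
  if (nrow(lifted_source) == 0L || nrow(target) == 0L) {
    attr(empty, "unmatched_source") <- lifted_source$event_id
    attr(empty, "unmatched_target") <- target$event_id
    return(empty)
  }
  src <- lifted_source
  tgt <- target
  if (!is.null(ortholog_map) && require_gene_match) {
    ortholog_map <- validate_ortholog_map(ortholog_map)
    src <- src[src$gene_id %in% ortholog_map$source_gene_id, , drop = FALSE]
    tgt <- tgt[tgt$gene_id %in% ortholog_map$target_gene_id, , drop = FALSE]
    src$.tgt_gene <- ortholog_map$target_gene_id[
      match(src$gene_id, ortholog_map$source_gene_id)]
    key_src <- paste(src$.tgt_gene, src$chrom, src$event_type, src$strand)
    key_tgt <- paste(tgt$gene_id, tgt$chrom, tgt$event_type, tgt$strand)
  } else {
    key_src <- paste(src$chrom, src$event_type, src$strand)
    key_tgt <- paste(tgt$chrom, tgt$event_type, tgt$strand)
  }
  cand <- merge(
    data.frame(i = seq_len(nrow(src)), key = key_src, stringsAsFactors = FALSE),
    data.frame(j = seq_len(nrow(tgt)), key = key_tgt, stringsAsFactors = FALSE),
    by = "key"
  )
  if (nrow(cand) == 0L) {
    attr(empty, "unmatched_source") <- lifted_source$event_id
    attr(empty, "unmatched_target") <- target$event_id
    return(empty)
  }
  off_u <- tgt$upstream_end[cand$j] - src$upstream_end[cand$i]
  off_s <- tgt$target_start[cand$j] - src$target_start[cand$i]
  off_e <- tgt$target_end[cand$j] - src$target_end[cand$i]
  off_d <- tgt$downstream_start[cand$j] - src$downstream_start[cand$i]
  keep <- abs(off_u) <= tolerance & abs(off_s) <= tolerance &
    abs(off_e) <= tolerance & abs(off_d) <= tolerance
  cand <- cand[keep, , drop = FALSE]
  off_u <- off_u[keep]; off_s <- off_s[keep]
  off_e <- off_e[keep]; off_d <- off_d[keep]
  total <- abs(off_u) + abs(off_s) + abs(off_e) + abs(off_d)
  # deterministic greedy 1:1 assignment by ascending total offset
  ord <- order(total, src$chrom[cand$i], src$target_start[cand$i],
               src$event_id[cand$i], tgt$event_id[cand$j])
  cand <- cand[ord, , drop = FALSE]
  off <- cbind(off_u, off_s, off_e, off_d, total)[ord, , drop = FALSE]
  used_src <- logical(nrow(src))
  used_tgt <- logical(nrow(tgt))
  take <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    i <- cand$i[k]; j <- cand$j[k]
    if (!used_src[i] && !used_tgt[j]) {
      take[k] <- TRUE
      used_src[i] <- TRUE
      used_tgt[j] <- TRUE
    }
  }
  cand <- cand[take, , drop = FALSE]
  off <- off[take, , drop = FALSE]
  pairs <- data.frame(
    source_event_id = src$event_id[cand$i],
    target_event_id = tgt$event_id[cand$j],
    off_upstream_end = off[, 1L],
    off_target_start = off[, 2L],
    off_target_end = off[, 3L],
    off_downstream_start = off[, 4L],
    total_offset = off[, 5L],
    source_gene_id = src$gene_id[cand$i],
    target_gene_id = tgt$gene_id[cand$j],
    stringsAsFactors = FALSE
  )
  o <- order(tgt$chrom[cand$j], tgt$target_start[cand$j],
             tgt$target_end[cand$j], pairs$target_event_id)
  pairs <- pairs[o, , drop = FALSE]
  rownames(pairs) <- NULL
  attr(pairs, "unmatched_source") <-
    setdiff(lifted_source$event_id, pairs$source_event_id)
  attr(pairs, "unmatched_target") <-
    setdiff(target$event_id, pairs$target_event_id)
  pairs
}

#' Fraction of each species' events that found an ortholog
#'
#' @param matched matched-pair table from [match_events()] (or a count).
#' @param source_total,target_total numbers of events considered in each
#'   species.
#' @return list with `n_matched`, `source_rate`, `target_rate`; rates are
#'   `NA` (flagged `undefined`) when the corresponding total is zero.
#' @export
orthology_rates <- function(matched, source_total, target_total) {
  n <- if (is.data.frame(matched)) nrow(matched) else as.integer(matched)
  if (source_total < n || target_total < n) {
    stop("totals cannot be smaller than the number of matched events")
  }
  list(
    n_matched = n,
    source_rate = if (source_total > 0) n / source_total else NA_real_,
    target_rate = if (target_total > 0) n / target_total else NA_real_,
    undefined = source_total == 0 || target_total == 0
  )
}
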