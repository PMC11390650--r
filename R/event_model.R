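# Event tables ------------------------------------------------------------

EVENT_COLUMNS <- c(
  "event_id", "species", "gene_id", "gene_symbol", "event_type",
  "chrom", "strand", "upstream_end", "target_start", "target_end",
  "downstream_start"
)

COUNT_COLUMNS <- c(
  "event_id", "condition", "replicate",
  "inc_count", "skip_count", "inc_len", "skip_len"
)

CONDITIONS <- c("basal", "stimulated")

#' Validate a splice-event table
#'
#' A splice-event table holds one cassette exon (`event_type = "SE"`) or
#' retained intron (`"RI"`) per row, anchored by four genomic boundary
#' coordinates in 0-based half-open convention on the genomic (forward)
#' axis, independent of transcriptional strand:
#' `upstream_end <= target_start < target_end <= downstream_start`.
#' `target_start`/`target_end` delimit the alternative exon (SE) or the
#' retained intron (RI); `upstream_end` is the 3' boundary of the upstream
#' flanking exon and `downstream_start` the 5' boundary of the downstream
#' flanking exon, both on the genomic axis.
#'
#' @param events data.frame with columns `event_id`, `species`, `gene_id`,
#'   `gene_symbol`, `event_type` (`"SE"` or `"RI"`), `chrom`, `strand`
#'   (`"+"`/`"-"`), `upstream_end`, `target_start`, `target_end`,
#'   `downstream_start`.
#' @return `events`, invisibly, if valid; otherwise an error naming the
#'   offending rows.
#' @export
validate_events <- function(events) {
  stopifnot(is.data.frame(events))
  missing_cols <- setdiff(EVENT_COLUMNS, names(events))
  if (length(missing_cols) > 0L) {
    stop("event table is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(events$event_id)) {
    stop("duplicate event_id values: ",
         paste(unique(events$event_id[duplicated(events$event_id)]), collapse = ", "))
  }
  bad_type <- !events$event_type %in% c("SE", "RI")
  bad_strand <- !events$strand %in% c("+", "-")
  bad_chrom <- is.na(events$chrom) | !nzchar(events$chrom)
  coords <- events[, c("upstream_end", "target_start", "target_end", "downstream_start")]
  bad_coord <- apply(is.na(coords) | coords < 0, 1L, any) |
    !(events$upstream_end <= events$target_start &
        events$target_start < events$target_end &
        events$target_end <= events$downstream_start)
  bad <- which(bad_type | bad_strand | bad_chrom | bad_coord)
  if (length(bad) > 0L) {
    stop("invalid splice events at rows: ", paste(bad, collapse = ", "),
         " (check coordinate order upstream_end <= target_start < target_end",
         " <= downstream_start, event_type, strand, chrom)")
  }
  invisible(events)
}

#' Validate a replicate-count table
#'
#' Counts are kept in long format: one row per event, condition and
#' replicate, with inclusion- and skipping-junction read counts plus the
#' effective junction lengths used for length normalisation. For
#' junction-count (JC) quantification of a cassette exon the inclusion
#' isoform spans two junctions and the skipping isoform one, so the default
#' effective lengths are 2 and 1.
#'
#' @param counts data.frame with columns `event_id`, `condition` (`"basal"`
#'   or `"stimulated"`), `replicate` (1-based integer), `inc_count`,
#'   `skip_count` (non-negative integers), `inc_len`, `skip_len`
#'   (positive effective lengths).
#' @return `counts`, invisibly.
#' @export
validate_counts <- function(counts) {
  stopifnot(is.data.frame(counts))
  missing_cols <- setdiff(COUNT_COLUMNS, names(counts))
  if (length(missing_cols) > 0L) {
    stop("count table is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (!all(counts$condition %in% CONDITIONS)) {
    stop("condition must be one of: ", paste(CONDITIONS, collapse = ", "))
  }
  if (any(counts$inc_count < 0 | counts$skip_count < 0)) {
    stop("negative junction counts")
  }
  if (any(counts$inc_len <= 0 | counts$skip_len <= 0)) {
    stop("effective lengths must be positive")
  }
  invisible(counts)
}

# PSI ----------------------------------------------------------------------

#' Per-replicate percent spliced in
#'
#' For each replicate, PSI is the length-normalised inclusion ratio
#' `100 * (I/lI) / (I/lI + S/lS)`, where `I` and `S` are the inclusion and
#' skipping junction counts and `lI`, `lS` the effective junction lengths.
#' A replicate with `I = S = 0` carries no information and its PSI is
#' `NA` (undefined).
#'
#' @param counts long replicate-count table (see [validate_counts()]).
#' @return `counts` with an added `psi` column in `[0, 100]` (or `NA`).
#' @export
psi_per_replicate <- function(counts) {
  validate_counts(counts)
  inc_norm <- counts$inc_count / counts$inc_len
  skip_norm <- counts$skip_count / counts$skip_len
  denom <- inc_norm + skip_norm
  psi <- ifelse(denom > 0, 100 * inc_norm / denom, NA_real_)
  counts$psi <- psi
  counts
}

#' Mean PSI per event and condition
#'
#' Per-replicate PSI values are averaged arithmetically over the replicates
#' in which PSI is defined (mean of per-replicate PSIs, not a pooled-count
#' ratio). Events where every replicate is undefined are flagged
#' unquantifiable (`mean_psi = NA`, `quantifiable = FALSE`).
#'
#' @inheritParams psi_per_replicate
#' @return data.frame with one row per (event_id, condition):
#'   `mean_psi`, `n_replicates`, `n_defined`, `quantifiable`.
#' @export
compute_psi <- function(counts) {
  per_rep <- psi_per_replicate(counts)
  key <- interaction(per_rep$event_id, per_rep$condition, drop = TRUE, sep = "\r")
  mean_psi <- tapply(per_rep$psi, key, function(v) {
    v <- v[!is.na(v)]
    if (length(v) == 0L) NA_real_ else mean(v)
  })
  n_rep <- tapply(per_rep$psi, key, length)
  n_def <- tapply(per_rep$psi, key, function(v) sum(!is.na(v)))
  parts <- strsplit(names(mean_psi), "\r", fixed = TRUE)
  out <- data.frame(
    event_id = vapply(parts, `[[`, "", 1L),
    condition = vapply(parts, `[[`, "", 2L),
    mean_psi = as.numeric(mean_psi),
    n_replicates = as.integer(n_rep),
    n_defined = as.integer(n_def),
    stringsAsFactors = FALSE
  )
  out$quantifiable <- out$n_defined > 0L
  rownames(out) <- NULL
  out[order(out$event_id, out$condition), , drop = FALSE]
}

#' Classify mean PSI into inclusion classes
#'
#' Exons are classed as primarily included (PI, PSI above 80), primarily
#' skipped (PS, PSI below 20) or alternatively spliced (AS, PSI strictly
#' between 20 and 80). The boundaries themselves are assigned to the outer
#' classes (PSI of exactly 80 is PI, exactly 20 is PS) so the three classes
#' partition the whole `[0, 100]` range.
#'
#' @param mean_psi numeric vector of mean PSI values in `[0, 100]`.
#' @return character vector of `"PI"`, `"PS"` or `"AS"`.
#' @export
classify_psi <- function(mean_psi) {
  if (any(is.na(mean_psi))) {
    stop("classify_psi: undefined mean_psi (NA) cannot be classified")
  }
  if (any(mean_psi < 0 | mean_psi > 100)) {
    stop("classify_psi: mean_psi outside [0, 100]")
  }
  ifelse(mean_psi >= 80, "PI", ifelse(mean_psi <= 20, "PS", "AS"))
}

#' Expression filter on junction counts
#'
#' Keeps events whose junction-read support exceeds `min_count`. Two rules
#' are provided because both are in routine use: `all_samples` requires
#' `max(I, S) > min_count` in every replicate of every condition supplied
#' (the default for differential calls); `mean_over_samples` requires the
#' mean over all supplied replicates of `max(I, S)` to exceed `min_count`
#' (the default when building enrichment backgrounds).
#'
#' @inheritParams psi_per_replicate
#' @param min_count non-negative threshold; comparison is strict (`>`).
#' @param rule `"all_samples"` or `"mean_over_samples"`.
#' @return character vector of event_ids passing the filter, in first-seen
#'   order. An empty count table yields an empty vector.
#' @export
filter_expressed <- function(counts, min_count = 5,
                             rule = c("all_samples", "mean_over_samples")) {
  rule <- match.arg(rule)
  stopifnot(min_count >= 0)
  if (nrow(counts) == 0L) return(character(0))
  validate_counts(counts)
  best <- pmax(counts$inc_count, counts$skip_count)
  ids <- factor(counts$event_id, levels = unique(counts$event_id))
  keep <- if (rule == "all_samples") {
    tapply(best, ids, function(v) all(v > min_count))
  } else {
    tapply(best, ids, function(v) mean(v) > min_count)
  }
  names(keep)[as.logical(keep)]
}

# Readers / writers ---------------------------------------------------------

RMATS_COLUMNS <- c(
  "ID", "GeneID", "geneSymbol", "chr", "strand",
  "exonStart_0base", "exonEnd", "upstreamES", "upstreamEE",
  "downstreamES", "downstreamEE",
  "IJC_SAMPLE_1", "SJC_SAMPLE_1", "IJC_SAMPLE_2", "SJC_SAMPLE_2",
  "IncFormLen", "SkipFormLen", "PValue", "FDR",
  "IncLevel1", "IncLevel2", "IncLevelDifference"
)

INTERNAL_COLUMNS <- c(
  EVENT_COLUMNS, "inc_len", "skip_len",
  "ijc_basal", "sjc_basal", "ijc_stimulated", "sjc_stimulated",
  "psi_basal", "psi_stimulated"
)

parse_count_field <- function(x, what, lines) {
  parts <- strsplit(as.character(x), ",", fixed = TRUE)
  lapply(seq_along(parts), function(i) {
    v <- suppressWarnings(as.numeric(parts[[i]]))
    if (length(v) == 0L || any(is.na(v)) || any(v != floor(v)) || any(v < 0)) {
      stop("non-integer ", what, " count at line ", lines[i], ": '", x[i], "'")
    }
    as.integer(v)
  })
}

counts_long <- function(event_id, condition, count_lists_inc, count_lists_skip,
                        inc_len, skip_len) {
  n_rep <- lengths(count_lists_inc)
  if (any(n_rep != lengths(count_lists_skip))) {
    stop("inclusion and skipping counts have different replicate numbers")
  }
  data.frame(
    event_id = rep(event_id, n_rep),
    condition = rep(condition, length.out = sum(n_rep)),
    replicate = unlist(lapply(n_rep, seq_len), use.names = FALSE),
    inc_count = unlist(count_lists_inc, use.names = FALSE),
    skip_count = unlist(count_lists_skip, use.names = FALSE),
    inc_len = rep(inc_len, n_rep),
    skip_len = rep(skip_len, n_rep),
    stringsAsFactors = FALSE
  )
}

#' Read an event table
#'
#' Two dialects are supported. `rmats_jc` is the tab-separated
#' junction-count output of rMATS for skipped-exon events (columns `ID`,
#' `GeneID`, `geneSymbol`, `chr`, `strand`, `exonStart_0base`, `exonEnd`,
#' `upstreamES`, `upstreamEE`, `downstreamES`, `downstreamEE`,
#' `IJC_SAMPLE_1`, `SJC_SAMPLE_1`, `IJC_SAMPLE_2`, `SJC_SAMPLE_2`,
#' `IncFormLen`, `SkipFormLen`, `PValue`, `FDR`, `IncLevel1`, `IncLevel2`,
#' `IncLevelDifference`), with counts comma-separated per replicate.
#' `SAMPLE_1` is taken to be the basal condition and `SAMPLE_2` the
#' stimulated one. Retained-intron tables using `riExonStart_0base` /
#' `riExonEnd` in place of `exonStart_0base` / `exonEnd` are recognised and
#' imported with `event_type = "RI"`. `internal_tsv` is this package's
#' lossless round-trip format (see [write_event_table()]).
#'
#' Coordinates are stored 0-based half-open: `exonStart_0base` maps
#' directly to `target_start` and ends are treated as half-open.
#'
#' @param path file path.
#' @param dialect `"rmats_jc"` or `"internal_tsv"`.
#' @param species species label attached to every event.
#' @return list with elements `events` (see [validate_events()]), `counts`
#'   (long format, see [validate_counts()]) and, for `rmats_jc`, `stats`
#'   (the rMATS `PValue`, `FDR` and `IncLevelDifference` columns, carried
#'   through but unused by the package's own tests).
#' @export
read_event_table <- function(path, dialect = c("rmats_jc", "internal_tsv"),
                             species = "unknown") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE)
  if (dialect == "rmats_jc") {
    read_rmats_jc(tab, species)
  } else {
    read_internal_tsv(tab, species)
  }
}

read_rmats_jc <- function(tab, species) {
  ri <- "riExonStart_0base" %in% names(tab)
  want <- RMATS_COLUMNS
  if (ri) {
    want[want == "exonStart_0base"] <- "riExonStart_0base"
    want[want == "exonEnd"] <- "riExonEnd"
  }
  missing_cols <- setdiff(want, names(tab))
  if (length(missing_cols) > 0L) {
    stop("rmats_jc dialect error: missing columns ",
         paste(missing_cols, collapse = ", "))
  }
  n <- nrow(tab)
  lines <- seq_len(n) + 1L  # header is line 1
  num <- function(col) {
    v <- suppressWarnings(as.numeric(tab[[col]]))
    bad <- which(is.na(v) & !tab[[col]] %in% c("NA", ""))
    if (length(bad) > 0L) {
      stop("parse error in column ", col, " at line ", lines[bad[1]])
    }
    v
  }
  events <- data.frame(
    event_id = tab$ID,
    species = rep(species, n),
    gene_id = tab$GeneID,
    gene_symbol = tab$geneSymbol,
    event_type = rep(if (ri) "RI" else "SE", n),
    chrom = tab$chr,
    strand = tab$strand,
    upstream_end = num("upstreamEE"),
    target_start = num(if (ri) "riExonStart_0base" else "exonStart_0base"),
    target_end = num(if (ri) "riExonEnd" else "exonEnd"),
    downstream_start = num("downstreamES"),
    stringsAsFactors = FALSE
  )
  if (n > 0L) {
    ok <- events$upstream_end <= events$target_start &
      events$target_start < events$target_end &
      events$target_end <= events$downstream_start &
      events$upstream_end >= 0
    if (any(!ok)) {
      stop("validation error: coordinate order violated at line(s) ",
           paste(lines[!ok], collapse = ", "))
    }
  }
  inc_len <- num("IncFormLen")
  skip_len <- num("SkipFormLen")
  counts <- rbind(
    counts_long(events$event_id, "basal",
                parse_count_field(tab$IJC_SAMPLE_1, "IJC_SAMPLE_1", lines),
                parse_count_field(tab$SJC_SAMPLE_1, "SJC_SAMPLE_1", lines),
                inc_len, skip_len),
    counts_long(events$event_id, "stimulated",
                parse_count_field(tab$IJC_SAMPLE_2, "IJC_SAMPLE_2", lines),
                parse_count_field(tab$SJC_SAMPLE_2, "SJC_SAMPLE_2", lines),
                inc_len, skip_len)
  )
  if (n > 0L) validate_events(events)
  stats <- data.frame(
    event_id = events$event_id,
    pvalue_rmats = suppressWarnings(as.numeric(tab$PValue)),
    fdr_rmats = suppressWarnings(as.numeric(tab$FDR)),
    inc_level_difference = suppressWarnings(as.numeric(tab$IncLevelDifference)),
    stringsAsFactors = FALSE
  )
  list(events = events, counts = counts, stats = stats)
}

read_internal_tsv <- function(tab, species) {
  missing_cols <- setdiff(INTERNAL_COLUMNS, names(tab))
  if (length(missing_cols) > 0L) {
    stop("internal_tsv dialect error: missing columns ",
         paste(missing_cols, collapse = ", "))
  }
  n <- nrow(tab)
  lines <- seq_len(n) + 1L
  num_cols <- c("upstream_end", "target_start", "target_end", "downstream_start")
  events <- tab[, EVENT_COLUMNS, drop = FALSE]
  for (cc in num_cols) events[[cc]] <- as.numeric(events[[cc]])
  if (!"species" %in% names(tab) || all(!nzchar(tab$species))) {
    events$species <- species
  }
  if (n > 0L) validate_events(events)
  inc_len <- as.numeric(tab$inc_len)
  skip_len <- as.numeric(tab$skip_len)
  counts <- rbind(
    counts_long(events$event_id, "basal",
                parse_count_field(tab$ijc_basal, "ijc_basal", lines),
                parse_count_field(tab$sjc_basal, "sjc_basal", lines),
                inc_len, skip_len),
    counts_long(events$event_id, "stimulated",
                parse_count_field(tab$ijc_stimulated, "ijc_stimulated", lines),
                parse_count_field(tab$sjc_stimulated, "sjc_stimulated", lines),
                inc_len, skip_len)
  )
  psis <- data.frame(
    event_id = events$event_id,
    psi_basal = suppressWarnings(as.numeric(tab$psi_basal)),
    psi_stimulated = suppressWarnings(as.numeric(tab$psi_stimulated)),
    stringsAsFactors = FALSE
  )
  list(events = events, counts = counts, psis = psis)
}

collapse_counts <- function(counts, ids, condition, column) {
  sub <- counts[counts$condition == condition, , drop = FALSE]
  sub <- sub[order(match(sub$event_id, ids), sub$replicate), , drop = FALSE]
  spl <- split(sub[[column]], factor(sub$event_id, levels = ids))
  vapply(spl, function(v) paste(v, collapse = ","), "")
}

#' Write an event table in the internal TSV dialect
#'
#' Produces a UTF-8 tab-separated table with one row per event that
#' round-trips losslessly through [read_event_table()] with
#' `dialect = "internal_tsv"`. Counts are comma-separated per replicate;
#' undefined PSI is written as `NA`.
#'
#' @param events splice-event table.
#' @param counts long replicate-count table covering both conditions.
#' @param path output file path.
#' @param psis optional PSI summary from [compute_psi()]; if supplied, the
#'   per-condition mean PSI columns are populated.
#' @return `path`, invisibly.
#' @export
write_event_table <- function(events, counts, path, psis = NULL) {
  if (nrow(events) > 0L) validate_events(events)
  ids <- events$event_id
  lens <- counts[!duplicated(counts$event_id), c("event_id", "inc_len", "skip_len")]
  lens <- lens[match(ids, lens$event_id), , drop = FALSE]
  out <- events
  out$inc_len <- lens$inc_len
  out$skip_len <- lens$skip_len
  out$ijc_basal <- collapse_counts(counts, ids, "basal", "inc_count")
  out$sjc_basal <- collapse_counts(counts, ids, "basal", "skip_count")
  out$ijc_stimulated <- collapse_counts(counts, ids, "stimulated", "inc_count")
  out$sjc_stimulated <- collapse_counts(counts, ids, "stimulated", "skip_count")
  psi_col <- function(cond) {
    if (is.null(psis)) return(rep(NA_real_, length(ids)))
    sub <- psis[psis$condition == cond, , drop = FALSE]
    sub$mean_psi[match(ids, sub$event_id)]
  }
  out$psi_basal <- psi_col("basal")
  out$psi_stimulated <- psi_col("stimulated")
  out <- out[, INTERNAL_COLUMNS, drop = FALSE]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}
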