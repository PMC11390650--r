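# UCSC chain parsing and coordinate lifting --------------------------------

#' Parse a UCSC chain file
#'
#' A chain describes a gapped pairwise alignment between a target and a
#' query genome: a header line
#' `chain score tName tSize tStrand tStart tEnd qName qSize qStrand qStart qEnd [id]`
#' followed by alignment-block lines `size dt dq` (the last line holding
#' only `size`). Per-chain arithmetic is validated: block sizes plus target
#' gaps must sum to the target span, and block sizes plus query gaps to the
#' query span. Target strand must be `+` (the UCSC convention); query
#' coordinates of `-`-strand chains are given on the reversed query strand
#' and are converted to forward-strand positions at lift time.
#'
#' @param path chain file path.
#' @return A `chain_set`: list with `chains` (one parsed chain each,
#'   carrying precomputed cumulative block offsets) and `index`
#'   (data.frame of target spans and scores used for overlap queries).
#' @export
parse_chain <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- trimws(lines)
  headers <- grep("^chain\\b", lines)
  if (length(headers) == 0L) stop("no chain records found in ", path)
  bounds <- c(headers, length(lines) + 1L)
  chains <- vector("list", length(headers))
  for (i in seq_along(headers)) {
    head_fields <- strsplit(lines[headers[i]], "[ \t]+")[[1]]
    if (length(head_fields) < 12L) {
      stop("malformed chain header: '", lines[headers[i]], "'")
    }
    ch <- list(
      score = as.numeric(head_fields[2]),
      t_name = head_fields[3], t_size = as.numeric(head_fields[4]),
      t_strand = head_fields[5],
      t_start = as.numeric(head_fields[6]), t_end = as.numeric(head_fields[7]),
      q_name = head_fields[8], q_size = as.numeric(head_fields[9]),
      q_strand = head_fields[10],
      q_start = as.numeric(head_fields[11]), q_end = as.numeric(head_fields[12]),
      id = if (length(head_fields) >= 13L) head_fields[13] else as.character(i)
    )
    if (ch$t_strand != "+") stop("chain ", ch$id, ": target strand must be '+'")
    if (!ch$q_strand %in% c("+", "-")) stop("chain ", ch$id, ": bad query strand")
    body <- lines[(headers[i] + 1L):(bounds[i + 1L] - 1L)]
    body <- body[nzchar(body)]
    if (length(body) == 0L) stop("chain ", ch$id, ": no alignment blocks")
    parts <- strsplit(body, "[ \t]+")
    nf <- lengths(parts)
    if (any(nf[-length(nf)] != 3L) || nf[length(nf)] != 1L) {
      stop("chain ", ch$id, ": block lines must be 'size dt dq' with a bare",
           " final size")
    }
    size <- as.numeric(vapply(parts, `[[`, "", 1L))
    dt <- c(as.numeric(vapply(parts[-length(parts)], `[[`, "", 2L)), 0)
    dq <- c(as.numeric(vapply(parts[-length(parts)], `[[`, "", 3L)), 0)
    if (any(is.na(size)) || any(size <= 0)) {
      stop("chain ", ch$id, ": block sizes must be positive integers")
    }
    if (sum(size) + sum(dt) != ch$t_end - ch$t_start) {
      stop("format error in chain ", ch$id,
           ": blocks + target gaps do not sum to the target span")
    }
    if (sum(size) + sum(dq) != ch$q_end - ch$q_start) {
      stop("format error in chain ", ch$id,
           ": blocks + query gaps do not sum to the query span")
    }
    if (ch$t_start < 0 || ch$t_end > ch$t_size || ch$t_start >= ch$t_end ||
        ch$q_start < 0 || ch$q_end > ch$q_size || ch$q_start >= ch$q_end) {
      stop("format error in chain ", ch$id, ": span outside sequence bounds")
    }
    ch$blocks <- data.frame(size = size, dt = dt, dq = dq)
    # cumulative offsets of each block start within the chain
    ch$t_off <- cumsum(c(0, (size + dt)[-length(size)]))
    ch$q_off <- cumsum(c(0, (size + dq)[-length(size)]))
    chains[[i]] <- ch
  }
  index <- data.frame(
    t_name = vapply(chains, `[[`, "", "t_name"),
    t_start = vapply(chains, `[[`, 0, "t_start"),
    t_end = vapply(chains, `[[`, 0, "t_end"),
    score = vapply(chains, `[[`, 0, "score"),
    q_name = vapply(chains, `[[`, "", "q_name"),
    id = vapply(chains, `[[`, "", "id"),
    idx = seq_along(chains),
    stringsAsFactors = FALSE
  )
  structure(list(chains = chains, index = index), class = "chain_set")
}

#' @export
print.chain_set <- function(x, ...) {
  cat("chain_set with", length(x$chains), "chain(s) on",
      length(unique(x$index$t_name)), "target sequence(s)\n")
  invisible(x)
}

#' Chains overlapping a target interval
#'
#' @param chains a `chain_set`.
#' @param chrom target sequence name.
#' @param start,end 0-based half-open interval.
#' @return integer indices into `chains$chains`, ordered by descending
#'   score then (t_start, q_name).
#' @export
chains_overlapping <- function(chains, chrom, start, end) {
  idx <- chains$index
  hit <- idx$t_name == chrom & idx$t_start < end & idx$t_end > start
  sub <- idx[hit, , drop = FALSE]
  sub$idx[order(-sub$score, sub$t_start, sub$q_name)]
}

lift_one_chain <- function(ch, pos) {
  # pos are 0-based target positions within [t_start, t_end)
  off <- pos - ch$t_start
  k <- findInterval(off, ch$t_off)
  in_block <- off - ch$t_off[k] < ch$blocks$size[k]
  q_chain <- ch$q_start + ch$q_off[k] + (off - ch$t_off[k])
  q_fwd <- if (ch$q_strand == "+") q_chain else ch$q_size - 1 - q_chain
  list(mapped = in_block, pos = ifelse(in_block, q_fwd, NA_real_))
}

#' Lift single positions through a chain set
#'
#' Among the chains whose target span covers a position, the
#' highest-scoring one is used (ties broken by `t_start`, then `q_name`,
#' for determinism). A position falling in an aligned block maps to the
#' query coordinate at the same block offset, reported on the forward
#' strand of the query genome (reverse-complement arithmetic for
#' `-`-strand chains). A position inside a target gap (`dt`) of the best
#' covering chain has status `"gap"`; a position covered by no chain is
#' `"unmapped"`.
#'
#' @param chains a `chain_set` from [parse_chain()].
#' @param chrom target sequence name (scalar or vector parallel to `pos`).
#' @param pos 0-based target positions.
#' @return data.frame with columns `chrom_in`, `pos_in`, `status`
#'   (`mapped`/`gap`/`unmapped`), `chrom`, `pos`, `strand_flip`,
#'   `chain_score`, `chain_id`.
#' @export
lift_position <- function(chains, chrom, pos) {
  stopifnot(inherits(chains, "chain_set"))
  n <- length(pos)
  chrom <- rep_len(chrom, n)
  out <- data.frame(
    chrom_in = chrom, pos_in = pos,
    status = rep("unmapped", n),
    chrom = NA_character_, pos = NA_real_,
    strand_flip = NA, chain_score = NA_real_, chain_id = NA_character_,
    stringsAsFactors = FALSE
  )
  for (uc in unique(chrom)) {
    sel <- which(chrom == uc)
    if (length(sel) == 0L) next
    cand <- chains_overlapping(chains, uc, min(pos[sel]), max(pos[sel]) + 1)
    # chains come ordered best-first; assign each position to its best cover
    unassigned <- sel
    for (ci in cand) {
      if (length(unassigned) == 0L) break
      ch <- chains$chains[[ci]]
      covered <- unassigned[pos[unassigned] >= ch$t_start &
                              pos[unassigned] < ch$t_end]
      if (length(covered) == 0L) next
      lifted <- lift_one_chain(ch, pos[covered])
      out$status[covered] <- ifelse(lifted$mapped, "mapped", "gap")
      out$chrom[covered] <- ifelse(lifted$mapped, ch$q_name, NA_character_)
      out$pos[covered] <- lifted$pos
      out$strand_flip[covered] <- ifelse(lifted$mapped, ch$q_strand == "-", NA)
      out$chain_score[covered] <- ch$score
      out$chain_id[covered] <- ch$id
      unassigned <- setdiff(unassigned, covered)
    }
  }
  out
}

#' Lift splice events through a chain set
#'
#' All four boundary coordinates of each event are lifted individually;
#' half-open end coordinates are lifted as `(end - 1)` then incremented, so
#' block edges do not produce off-by-one errors. A lift succeeds only when
#' all four boundaries map, through the same chain, to the same query
#' chromosome, with coordinate order preserved (or uniformly reversed for a
#' strand-flipping chain, in which case the upstream/downstream roles are
#' swapped and the event strand is toggled so the lifted event again
#' satisfies the event invariants). Everything else becomes a failure
#' record with per-boundary statuses.
#'
#' @param chains a `chain_set`.
#' @param events splice-event table (see [validate_events()]).
#' @param species_out species label for lifted events.
#' @return list with `lifted` (event table in query coordinates, same
#'   event_ids) and `failures` (data.frame: event_id, reason and the four
#'   boundary statuses).
#' @export
lift_event <- function(chains, events, species_out = "lifted") {
  if (nrow(events) > 0L) validate_events(events)
  n <- nrow(events)
  # boundary bases to lift: end-type coords as end-1, start-type as-is
  b_u <- lift_position(chains, events$chrom, events$upstream_end - 1)
  b_s <- lift_position(chains, events$chrom, events$target_start)
  b_e <- lift_position(chains, events$chrom, events$target_end - 1)
  b_d <- lift_position(chains, events$chrom, events$downstream_start)
  status <- cbind(b_u$status, b_s$status, b_e$status, b_d$status)
  all_mapped <- rowSums(status == "mapped") == 4L
  same_chain <- b_u$chain_id == b_s$chain_id & b_s$chain_id == b_e$chain_id &
    b_e$chain_id == b_d$chain_id
  same_chrom <- b_u$chrom == b_s$chrom & b_s$chrom == b_e$chrom &
    b_e$chrom == b_d$chrom
  flip <- b_s$strand_flip
  ok <- all_mapped & !is.na(same_chain) & same_chain &
    !is.na(same_chrom) & same_chrom
  up_end <- tg_start <- tg_end <- dn_start <- rep(NA_real_, n)
  w_plus <- which(ok & !flip)
  up_end[w_plus] <- b_u$pos[w_plus] + 1
  tg_start[w_plus] <- b_s$pos[w_plus]
  tg_end[w_plus] <- b_e$pos[w_plus] + 1
  dn_start[w_plus] <- b_d$pos[w_plus]
  w_flip <- which(ok & flip)
  up_end[w_flip] <- b_d$pos[w_flip] + 1
  tg_start[w_flip] <- b_e$pos[w_flip]
  tg_end[w_flip] <- b_s$pos[w_flip] + 1
  dn_start[w_flip] <- b_u$pos[w_flip]
  order_ok <- ok & up_end <= tg_start & tg_start < tg_end & tg_end <= dn_start
  order_ok[is.na(order_ok)] <- FALSE
  strand_out <- events$strand
  strand_out[which(flip)] <- ifelse(events$strand[which(flip)] == "+", "-", "+")
  lifted <- data.frame(
    event_id = events$event_id,
    species = species_out,
    gene_id = events$gene_id,
    gene_symbol = events$gene_symbol,
    event_type = events$event_type,
    chrom = b_s$chrom,
    strand = strand_out,
    upstream_end = up_end,
    target_start = tg_start,
    target_end = tg_end,
    downstream_start = dn_start,
    stringsAsFactors = FALSE
  )[order_ok, , drop = FALSE]
  rownames(lifted) <- NULL
  fail <- !order_ok
  reason <- rep(NA_character_, n)
  reason[fail & !all_mapped] <- "boundary not mapped"
  reason[fail & all_mapped & (is.na(same_chain) | !same_chain)] <- "split across chains"
  reason[fail & all_mapped & !is.na(same_chain) & same_chain &
           (is.na(same_chrom) | !same_chrom)] <- "query chromosomes differ"
  reason[fail & is.na(reason)] <- "boundary order not preserved"
  failures <- data.frame(
    event_id = events$event_id[fail],
    reason = reason[fail],
    upstream_end_status = b_u$status[fail],
    target_start_status = b_s$status[fail],
    target_end_status = b_e$status[fail],
    downstream_start_status = b_d$status[fail],
    stringsAsFactors = FALSE
  )
  rownames(failures) <- NULL
  list(lifted = lifted, failures = failures)
}

#' Write liftover failure records as a BED-like TSV
#'
#' @param failures failure table from [lift_event()].
#' @param events the original event table (for coordinates).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_lift_failures <- function(failures, events, path) {
  m <- match(failures$event_id, events$event_id)
  bed <- data.frame(
    chrom = events$chrom[m],
    start = events$target_start[m],
    end = events$target_end[m],
    name = failures$event_id,
    reason = failures$reason,
    upstream_end_status = failures$upstream_end_status,
    target_start_status = failures$target_start_status,
    target_end_status = failures$target_end_status,
    downstream_start_status = failures$downstream_start_status,
    stringsAsFactors = FALSE
  )
  utils::write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
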