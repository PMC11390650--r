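# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: hypergeometric enumeration for Fisher's test,
# a per-base chain expansion for liftover, and exhaustive assignment
# search for event matching.

# two-sided Fisher exact p by full hypergeometric tail enumeration
oracle_fisher_p <- function(a, b, c, d) {
  N <- a + b + c + d
  r1 <- a + b        # reference-positive margin (row 1)
  c1 <- a + c        # query-positive margin (column 1)
  lo <- max(0, r1 + c1 - N)
  hi <- min(r1, c1)
  support <- lo:hi
  probs <- dhyper(support, c1, N - c1, r1)
  p_obs <- probs[support == a]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# expand one parsed chain into a full per-position target->query map;
# status: "mapped" (with q position) or "gap"
oracle_expand_chain <- function(ch) {
  n_t <- ch$t_end - ch$t_start
  status <- rep("gap", n_t)
  qpos <- rep(NA_real_, n_t)
  t_cursor <- 0
  q_cursor <- 0
  for (k in seq_len(nrow(ch$blocks))) {
    size <- ch$blocks$size[k]
    for (o in seq_len(size) - 1) {
      tp <- t_cursor + o
      qq <- ch$q_start + q_cursor + o
      status[tp + 1] <- "mapped"
      qpos[tp + 1] <- if (ch$q_strand == "+") qq else ch$q_size - 1 - qq
    }
    t_cursor <- t_cursor + size + ch$blocks$dt[k]
    q_cursor <- q_cursor + size + ch$blocks$dq[k]
  }
  list(t_start = ch$t_start, status = status, qpos = qpos)
}

# exhaustive minimum-total-offset maximum-cardinality 1:1 assignment on a
# bipartite candidate edge list (columns i, j, w); returns the selected
# edge rows. Searches connected components independently.
oracle_assignment <- function(edges) {
  if (nrow(edges) == 0L) return(integer(0))
  # connected components over the bipartite graph
  src_nodes <- unique(edges$i)
  comp_of_src <- seq_along(src_nodes)
  repeat {
    changed <- FALSE
    for (j in unique(edges$j)) {
      rows <- which(edges$j == j)
      comps <- comp_of_src[match(edges$i[rows], src_nodes)]
      if (length(unique(comps)) > 1L) {
        comp_of_src[comp_of_src %in% comps] <- min(comps)
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  best_rows <- integer(0)
  for (comp in unique(comp_of_src)) {
    rows <- which(edges$i %in% src_nodes[comp_of_src == comp])
    sel <- oracle_search_component(edges[rows, , drop = FALSE])
    best_rows <- c(best_rows, rows[sel])
  }
  best_rows
}

oracle_search_component <- function(edges) {
  n <- nrow(edges)
  best <- list(card = -1L, w = Inf, sel = integer(0))
  recurse <- function(k, used_i, used_j, sel, w) {
    if (k > n) {
      card <- length(sel)
      if (card > best$card || (card == best$card && w < best$w)) {
        best <<- list(card = card, w = w, sel = sel)
      }
      return(invisible())
    }
    # bound: even taking every remaining edge cannot beat best cardinality
    if (length(sel) + (n - k + 1L) < best$card) return(invisible())
    i <- edges$i[k]; j <- edges$j[k]
    if (!(i %in% used_i) && !(j %in% used_j)) {
      recurse(k + 1L, c(used_i, i), c(used_j, j), c(sel, k), w + edges$w[k])
    }
    recurse(k + 1L, used_i, used_j, sel, w)
  }
  recurse(1L, integer(0), integer(0), integer(0), 0)
  best$sel
}

# quick long-format count constructor for a single event
make_counts <- function(event_id, inc_b, skip_b, inc_s = NULL, skip_s = NULL,
                        inc_len = 1, skip_len = 1) {
  rows <- data.frame(
    event_id = event_id, condition = "basal",
    replicate = seq_along(inc_b),
    inc_count = inc_b, skip_count = skip_b,
    inc_len = inc_len, skip_len = skip_len,
    stringsAsFactors = FALSE
  )
  if (!is.null(inc_s)) {
    rows <- rbind(rows, data.frame(
      event_id = event_id, condition = "stimulated",
      replicate = seq_along(inc_s),
      inc_count = inc_s, skip_count = skip_s,
      inc_len = inc_len, skip_len = skip_len,
      stringsAsFactors = FALSE
    ))
  }
  rows
}

# minimal event-table constructor
make_events <- function(n, chrom = "chr1", species = "sp", gene = NULL,
                        start0 = 1000, spacing = 5000, strand = "+",
                        prefix = "ev") {
  u <- start0 + (seq_len(n) - 1) * spacing
  data.frame(
    event_id = paste0(prefix, seq_len(n)),
    species = species,
    gene_id = if (is.null(gene)) paste0("g", seq_len(n)) else gene,
    gene_symbol = paste0("S", seq_len(n)),
    event_type = "SE",
    chrom = chrom,
    strand = strand,
    upstream_end = u,
    target_start = u + 500,
    target_end = u + 600,
    downstream_start = u + 1100,
    stringsAsFactors = FALSE
  )
}

# write a tiny rmats_jc table; counts given as comma strings
write_rmats_fixture <- function(path, rows) {
  header <- c("ID", "GeneID", "geneSymbol", "chr", "strand",
              "exonStart_0base", "exonEnd", "upstreamES", "upstreamEE",
              "downstreamES", "downstreamEE",
              "IJC_SAMPLE_1", "SJC_SAMPLE_1", "IJC_SAMPLE_2", "SJC_SAMPLE_2",
              "IncFormLen", "SkipFormLen", "PValue", "FDR",
              "IncLevel1", "IncLevel2", "IncLevelDifference")
  lines <- c(paste(header, collapse = "\t"),
             vapply(rows, function(r) paste(r, collapse = "\t"), ""))
  writeLines(lines, path)
  path
}
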