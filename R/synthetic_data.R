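# Synthetic two-species fixtures with planted ground truth -------------------

#' Simulation configuration
#'
#' Bundles every tunable of the synthetic two-species generator. The
#' defaults describe the study conditions exercised by the package's
#' recovery tests: 1250 source genes with two cassette exons each, 80% of
#' genes 1:1 orthologous (2000 orthologous event pairs), basal PSI drawn
#' from a PI/PS/AS mixture with cross-species correlation imposed on the
#' logit scale, 15% of orthologous pairs activity-responsive of which
#' half respond in both species, mean |dPSI| of 25 with skipping
#' responses more common than inclusion ones, sequencing depth of 200
#' expected junction reads per event and 3 replicates per condition.
#'
#' @param n_genes number of source-species genes.
#' @param events_per_gene cassette exons simulated per gene.
#' @param orthologous_fraction fraction of genes with a 1:1 ortholog.
#' @param class_mixture named proportions for the PI/PS/AS basal classes.
#' @param basal_logit_psi_corr cross-species correlation of true basal
#'   logit-PSI for orthologous events (Gaussian copula on the logit
#'   scale, because PSI is bounded).
#' @param responsive_fraction fraction of orthologous pairs that respond
#'   to stimulation (also applied to non-orthologous events within their
#'   own species).
#' @param conserved_response_fraction among responsive pairs, fraction
#'   responding in both species; the remainder respond in exactly one.
#' @param delta_mean,delta_sd mean and sd of the true |dPSI| of a
#'   responsive event, in PSI units.
#' @param sign_up_fraction probability that a response increases
#'   inclusion (default 0.35: activity-induced skipping is the more
#'   common direction in neurons).
#' @param delta_corr correlation of |dPSI| across species for conserved
#'   responders.
#' @param depth expected total junction reads per event and replicate.
#' @param replicates replicates per condition (>= 2).
#' @param dispersion beta-binomial intra-class correlation of replicate
#'   counts; 0 (default) gives plain binomial counts.
#' @param jitter_max maximum per-boundary coordinate jitter (bp) between
#'   the lifted source and the annotated target coordinates of an
#'   orthologous event; keep at or below the matching tolerance.
#' @param decoy_gap_fraction fraction of non-orthologous source genes
#'   given an event boundary inside a chain gap, to exercise liftover
#'   failure paths.
#' @param flip_fraction fraction of chromosomes whose chain aligns to the
#'   reverse strand of the target genome.
#' @param genes_per_chrom genes laid per synthetic chromosome.
#' @param seed integer seed; every downstream stage derives its
#'   randomness from it.
#' @return object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_genes = 1250,
                       events_per_gene = 2,
                       orthologous_fraction = 0.8,
                       class_mixture = c(PI = 0.5, PS = 0.2, AS = 0.3),
                       basal_logit_psi_corr = 0.7,
                       responsive_fraction = 0.15,
                       conserved_response_fraction = 0.5,
                       delta_mean = 25,
                       delta_sd = 5,
                       sign_up_fraction = 0.35,
                       delta_corr = 0.8,
                       depth = 200,
                       replicates = 3,
                       dispersion = 0,
                       jitter_max = 6,
                       decoy_gap_fraction = 0.05,
                       flip_fraction = 0.1,
                       genes_per_chrom = 50,
                       seed = 1) {
  cfg <- as.list(environment())
  fractions <- c(cfg$orthologous_fraction, cfg$responsive_fraction,
                 cfg$conserved_response_fraction, cfg$sign_up_fraction,
                 cfg$decoy_gap_fraction, cfg$flip_fraction, cfg$dispersion)
  if (any(fractions < 0 | fractions > 1)) stop("fractions must lie in [0, 1]")
  if (abs(cfg$basal_logit_psi_corr) > 1 || abs(cfg$delta_corr) > 1) {
    stop("correlations must lie in [-1, 1]")
  }
  if (cfg$depth < 0) stop("depth must be non-negative")
  if (cfg$replicates < 2) stop("at least 2 replicates required")
  if (!setequal(names(cfg$class_mixture), c("PI", "PS", "AS")) ||
      abs(sum(cfg$class_mixture) - 1) > 1e-8) {
    stop("class_mixture must be named proportions PI/PS/AS summing to 1")
  }
  if (cfg$n_genes < 1 || cfg$events_per_gene < 1) {
    stop("need at least one gene and one event per gene")
  }
  structure(cfg, class = "sim_config")
}

# lay out genes with cassette-exon events along one coordinate axis;
# returns per-event boundary coordinates and per-gene spans
layout_genes <- function(n_genes, events_per_gene, id_prefix, chrom,
                         strand, start_at = 1000) {
  rows <- vector("list", n_genes * events_per_gene)
  gene_start <- numeric(n_genes)
  gene_end <- numeric(n_genes)
  cursor <- start_at
  k <- 0L
  for (g in seq_len(n_genes)) {
    gene_start[g] <- cursor
    for (e in seq_len(events_per_gene)) {
      u <- cursor + sample(100:300, 1)
      s <- u + sample(300:1500, 1)
      en <- s + sample(40:250, 1)
      d <- en + sample(300:1500, 1)
      k <- k + 1L
      rows[[k]] <- c(u, s, en, d)
      cursor <- d + sample(500:2000, 1)
    }
    gene_end[g] <- cursor
    cursor <- cursor + sample(3000:8000, 1)
  }
  coords <- do.call(rbind, rows)
  data.frame(
    gene_index = rep(seq_len(n_genes), each = events_per_gene),
    event_in_gene = rep(seq_len(events_per_gene), n_genes),
    upstream_end = coords[, 1], target_start = coords[, 2],
    target_end = coords[, 3], downstream_start = coords[, 4],
    gene_start = rep(gene_start, each = events_per_gene),
    gene_end = rep(gene_end, each = events_per_gene)
  )
}

# map a 0-based position through explicit block structure (generator-side
# arithmetic, independent of the liftover module)
sim_map_pos <- function(t_off, q_off, size, q_start, q_strand, q_size, p) {
  k <- findInterval(p, t_off)
  ok <- k >= 1 & (p - t_off[pmax(k, 1)]) < size[pmax(k, 1)]
  q_chain <- q_start + q_off[pmax(k, 1)] + (p - t_off[pmax(k, 1)])
  q_fwd <- if (q_strand == "+") q_chain else q_size - 1 - q_chain
  ifelse(ok, q_fwd, NA_real_)
}

#' Simulate a pair of genomes, their chain file and ortholog map
#'
#' Lays source-species genes with cassette-exon events on synthetic
#' chromosomes, derives target-species copies through per-chromosome
#' block maps with intergenic insertions/deletions (producing `dt`/`dq`
#' chain gaps), occasional whole-chromosome strand flips and small
#' per-boundary jitter for orthologous events, and emits the UCSC chain
#' that exactly encodes the source-to-target coordinate map. Gaps are
#' placed so that no orthologous event boundary falls inside one
#' (guaranteeing liftability of planted orthologs); a configurable
#' fraction of decoy events straddle gaps to exercise failure paths.
#' Non-orthologous target genes are placed beyond the chain's query span.
#'
#' @param config a [sim_config()].
#' @param seed overrides `config$seed` when given.
#' @return list with `events_source`, `events_target` (event tables),
#'   `chain_lines` (character vector, a valid chain file), `ortholog_map`
#'   (source/target gene pairs), `planted_pairs` (source/target event-id
#'   pairs with gene ids) and `decoy_events` (source event ids that
#'   straddle chain gaps).
#' @export
simulate_genome_pair <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  n_chrom <- ceiling(config$n_genes / config$genes_per_chrom)
  gene_chrom <- rep(seq_len(n_chrom),
                    each = config$genes_per_chrom)[seq_len(config$n_genes)]
  n_orth <- round(config$n_genes * config$orthologous_fraction)
  orth_genes <- sort(sample.int(config$n_genes, n_orth))
  is_orth <- seq_len(config$n_genes) %in% orth_genes
  non_orth <- which(!is_orth)
  n_decoy <- round(length(non_orth) * config$decoy_gap_fraction)
  decoy_genes <- if (n_decoy > 0) sort(sample(non_orth, n_decoy)) else integer(0)
  gene_strand <- sample(c("+", "-"), config$n_genes, replace = TRUE)
  flip_chrom <- stats::runif(n_chrom) < config$flip_fraction

  ev_src <- list(); ev_tgt <- list(); chain_lines <- character(0)
  planted <- list(); decoy_ids <- character(0)
  tgt_only_pool <- which(!is_orth)  # reuse count for target-only genes

  for (ck in seq_len(n_chrom)) {
    genes_here <- which(gene_chrom == ck)
    lay <- layout_genes(length(genes_here), config$events_per_gene,
                        chrom = ck, id_prefix = "s", strand = NULL)
    lay$gene_index <- genes_here[lay$gene_index]
    t_size <- max(lay$downstream_start) + sample(4000:6000, 1)
    src_chrom <- paste0("chrS", ck)
    tgt_chrom <- paste0("chrT", ck)

    # --- chain gap positions: intergenic, plus decoy-intron deletions
    gaps <- list()
    gene_bounds <- unique(lay[, c("gene_index", "gene_start", "gene_end")])
    gene_bounds <- gene_bounds[order(gene_bounds$gene_start), , drop = FALSE]
    if (nrow(gene_bounds) > 1L) {
      for (gi in seq_len(nrow(gene_bounds) - 1L)) {
        if (stats::runif(1) < 0.7) {
          lo <- gene_bounds$gene_end[gi] + 200
          hi <- gene_bounds$gene_start[gi + 1L] - 200
          if (hi - lo > 600) {
            pos <- sample(seq(lo, hi - 500), 1)
            dt <- sample(0:300, 1); dq <- sample(0:300, 1)
            if (dt + dq == 0) dt <- 50
            gaps[[length(gaps) + 1L]] <- c(pos, dt, dq)
          }
        }
      }
    }
    for (dg in intersect(decoy_genes, genes_here)) {
      ev <- lay[lay$gene_index == dg & lay$event_in_gene == 1L, ]
      gaps[[length(gaps) + 1L]] <- c(ev$target_start - 5, 20, 0)
      decoy_ids <- c(decoy_ids, paste0("src_e", dg, "_1"))
    }
    gap_mat <- if (length(gaps) > 0) {
      gm <- do.call(rbind, gaps)
      gm[order(gm[, 1]), , drop = FALSE]
    } else {
      matrix(numeric(0), ncol = 3)
    }
    # drop gaps that would collide (need positive block sizes)
    if (nrow(gap_mat) > 1L) {
      keep <- c(TRUE, diff(gap_mat[, 1]) > gap_mat[-nrow(gap_mat), 2] + 1)
      gap_mat <- gap_mat[keep, , drop = FALSE]
    }
    # --- block structure over [0, t_size)
    size <- numeric(0); dt <- numeric(0); dq <- numeric(0)
    prev <- 0
    if (nrow(gap_mat) > 0L) {
      for (gi in seq_len(nrow(gap_mat))) {
        size <- c(size, gap_mat[gi, 1] - prev)
        dt <- c(dt, gap_mat[gi, 2]); dq <- c(dq, gap_mat[gi, 3])
        prev <- gap_mat[gi, 1] + gap_mat[gi, 2]
      }
    }
    size <- c(size, t_size - prev); dt <- c(dt, 0); dq <- c(dq, 0)
    stopifnot(all(size > 0))
    t_off <- cumsum(c(0, (size + dt)[-length(size)]))
    q_off <- cumsum(c(0, (size + dq)[-length(size)]))
    q_span <- sum(size) + sum(dq)
    q_pad <- sample(1000:3000, 1)
    tail_pad <- 60000 + config$genes_per_chrom * config$events_per_gene * 12000
    q_size <- q_pad + q_span + tail_pad
    q_strand <- if (flip_chrom[ck]) "-" else "+"
    q_start <- q_pad
    chain_lines <- c(chain_lines, sprintf(
      "chain %d %s %d + 0 %d %s %d %s %d %d %d",
      1000L + ck, src_chrom, as.integer(t_size), as.integer(t_size),
      tgt_chrom, as.integer(q_size), q_strand,
      as.integer(q_start), as.integer(q_start + q_span), ck),
      c(paste(as.integer(size[-length(size)]), as.integer(dt[-length(dt)]),
              as.integer(dq[-length(dq)])),
        as.character(as.integer(size[length(size)]))),
      "")

    # --- source events on this chromosome
    src <- data.frame(
      event_id = paste0("src_e", lay$gene_index, "_", lay$event_in_gene),
      species = "source",
      gene_id = paste0("sgene", lay$gene_index),
      gene_symbol = paste0("SG", lay$gene_index),
      event_type = "SE",
      chrom = src_chrom,
      strand = gene_strand[lay$gene_index],
      upstream_end = lay$upstream_end,
      target_start = lay$target_start,
      target_end = lay$target_end,
      downstream_start = lay$downstream_start,
      stringsAsFactors = FALSE
    )
    ev_src[[ck]] <- src

    # --- orthologous target events: mapped coordinates + jitter
    orth_here <- lay[lay$gene_index %in% orth_genes, , drop = FALSE]
    if (nrow(orth_here) > 0L) {
      mp <- function(p) sim_map_pos(t_off, q_off, size, q_start, q_strand,
                                    q_size, p)
      u2 <- mp(orth_here$upstream_end - 1)
      s2 <- mp(orth_here$target_start)
      e2 <- mp(orth_here$target_end - 1)
      d2 <- mp(orth_here$downstream_start)
      stopifnot(!anyNA(c(u2, s2, e2, d2)))  # construction guarantees this
      if (q_strand == "+") {
        up <- u2 + 1; ts <- s2; te <- e2 + 1; dn <- d2
      } else {
        up <- d2 + 1; ts <- e2; te <- s2 + 1; dn <- u2
      }
      jit <- function(n) {
        sample(-config$jitter_max:config$jitter_max, n, replace = TRUE)
      }
      nh <- nrow(orth_here)
      up <- up + jit(nh); ts <- ts + jit(nh); te <- te + jit(nh)
      dn <- dn + jit(nh)
      strand_t <- gene_strand[orth_here$gene_index]
      if (q_strand == "-") strand_t <- ifelse(strand_t == "+", "-", "+")
      tgt <- data.frame(
        event_id = paste0("tgt_e", orth_here$gene_index, "_",
                          orth_here$event_in_gene),
        species = "target",
        gene_id = paste0("tgene", orth_here$gene_index),
        gene_symbol = paste0("TG", orth_here$gene_index),
        event_type = "SE",
        chrom = tgt_chrom,
        strand = strand_t,
        upstream_end = up, target_start = ts, target_end = te,
        downstream_start = dn,
        stringsAsFactors = FALSE
      )
      ev_tgt[[ck]] <- tgt
      planted[[ck]] <- data.frame(
        source_event_id = paste0("src_e", orth_here$gene_index, "_",
                                 orth_here$event_in_gene),
        target_event_id = tgt$event_id,
        source_gene_id = paste0("sgene", orth_here$gene_index),
        target_gene_id = tgt$gene_id,
        stringsAsFactors = FALSE
      )
    }

    # --- target-only genes in the unaligned tail of the target chromosome
    n_only <- sum(gene_chrom[tgt_only_pool] == ck)
    if (n_only > 0L) {
      only_idx <- tgt_only_pool[gene_chrom[tgt_only_pool] == ck]
      lay2 <- layout_genes(n_only, config$events_per_gene,
                           chrom = ck, id_prefix = "t", strand = NULL,
                           start_at = q_start + q_span + 2000)
      ev_tgt[[n_chrom + ck]] <- data.frame(
        event_id = paste0("tgtonly_e", only_idx[lay2$gene_index], "_",
                          lay2$event_in_gene),
        species = "target",
        gene_id = paste0("tgene_only", only_idx[lay2$gene_index]),
        gene_symbol = paste0("TGO", only_idx[lay2$gene_index]),
        event_type = "SE",
        chrom = tgt_chrom,
        strand = sample(c("+", "-"), nrow(lay2), replace = TRUE),
        upstream_end = lay2$upstream_end,
        target_start = lay2$target_start,
        target_end = lay2$target_end,
        downstream_start = lay2$downstream_start,
        stringsAsFactors = FALSE
      )
    }
  }
  events_source <- do.call(rbind, ev_src)
  events_target <- do.call(rbind, ev_tgt[!vapply(ev_tgt, is.null, TRUE)])
  rownames(events_source) <- rownames(events_target) <- NULL
  validate_events(events_source)
  validate_events(events_target)
  planted_pairs <- do.call(rbind, planted[!vapply(planted, is.null, TRUE)])
  rownames(planted_pairs) <- NULL
  ortholog_map <- unique(planted_pairs[, c("source_gene_id", "target_gene_id")])
  rownames(ortholog_map) <- NULL
  list(events_source = events_source,
       events_target = events_target,
       chain_lines = chain_lines,
       ortholog_map = ortholog_map,
       planted_pairs = planted_pairs,
       decoy_events = decoy_ids)
}

# correlated standard-normal pair with correlation rho
corr_pair <- function(n, rho) {
  z1 <- stats::rnorm(n)
  z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(n)
  cbind(z1, z2)
}

CLASS_LOGIT_MEAN <- c(PI = 2.2, PS = -2.2, AS = 0)
CLASS_LOGIT_SD <- c(PI = 0.8, PS = 0.8, AS = 0.7)

# apply a response of magnitude mag and sign sgn to basal PSI (0-100),
# flipping the sign when the stimulated level would leave (1, 99)
apply_response <- function(basal, mag, sgn) {
  stim <- basal + sgn * mag
  flip <- stim < 1 | stim > 99
  stim[flip] <- basal[flip] - sgn[flip] * mag[flip]
  pmin(pmax(stim, 0.5), 99.5)
}

#' Simulate ground-truth PSI and responses
#'
#' Draws true basal PSI per event from the PI/PS/AS mixture, imposing the
#' configured cross-species correlation on the logit scale for
#' orthologous pairs (a Gaussian copula: PSI is bounded, so correlation
#' is imposed on logits and the realized PSI-scale correlation is
#' reported for recovery tests to compare like with like). Responsive
#' pairs are sampled at `responsive_fraction`; conserved responders share
#' the response direction with |dPSI| correlated at `delta_corr`,
#' species-specific responders respond in one species only. Stimulated
#' PSI is kept inside (0, 100); when a response would overshoot a bound
#' its direction is flipped (and finally clipped), and the realized
#' values are what the truth tables record.
#'
#' @param config a [sim_config()].
#' @param genome output of [simulate_genome_pair()].
#' @param seed overrides `config$seed + 1` when given.
#' @return list with `truth_events` (per event and species: true basal
#'   and stimulated PSI, responsive flag, conserved flag),
#'   `truth_pairs` (per orthologous pair: per-species responsiveness and
#'   conservation), `truth_genes` (per orthologous gene: regulation
#'   label) and `realized_basal_corr` (Pearson r of true basal PSI across
#'   species over orthologous pairs).
#' @export
simulate_truth <- function(config, genome, seed = config$seed + 1) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  pairs <- genome$planted_pairs
  np <- nrow(pairs)
  cls <- sample(names(config$class_mixture), np, replace = TRUE,
                prob = config$class_mixture)
  z <- corr_pair(np, config$basal_logit_psi_corr)
  logit_s <- unname(CLASS_LOGIT_MEAN[cls] + CLASS_LOGIT_SD[cls] * z[, 1])
  logit_t <- unname(CLASS_LOGIT_MEAN[cls] + CLASS_LOGIT_SD[cls] * z[, 2])
  basal_s <- 100 * stats::plogis(logit_s)
  basal_t <- 100 * stats::plogis(logit_t)

  responsive <- stats::runif(np) < config$responsive_fraction
  conserved <- responsive & (stats::runif(np) < config$conserved_response_fraction)
  single <- responsive & !conserved
  single_in_source <- single & (stats::runif(np) < 0.5)
  single_in_target <- single & !single_in_source

  mag <- abs(corr_pair(np, config$delta_corr) * config$delta_sd +
               config$delta_mean)
  sgn_shared <- ifelse(stats::runif(np) < config$sign_up_fraction, 1, -1)
  sgn_own <- ifelse(stats::runif(np) < config$sign_up_fraction, 1, -1)

  stim_s <- basal_s
  stim_t <- basal_t
  resp_s <- conserved | single_in_source
  resp_t <- conserved | single_in_target
  sgn_s <- ifelse(conserved, sgn_shared, sgn_own)
  sgn_t <- ifelse(conserved, sgn_shared, sgn_own)
  stim_s[resp_s] <- apply_response(basal_s[resp_s], mag[resp_s, 1],
                                   sgn_s[resp_s])
  stim_t[resp_t] <- apply_response(basal_t[resp_t], mag[resp_t, 2],
                                   sgn_t[resp_t])

  # non-orthologous events: independent draws within their own species
  non_orth_truth <- function(events, planted_ids) {
    ev <- events[!events$event_id %in% planted_ids, , drop = FALSE]
    n <- nrow(ev)
    if (n == 0L) {
      return(data.frame(event_id = character(0), basal = numeric(0),
                        stim = numeric(0), responsive = logical(0)))
    }
    cls2 <- sample(names(config$class_mixture), n, replace = TRUE,
                   prob = config$class_mixture)
    basal <- 100 * unname(stats::plogis(CLASS_LOGIT_MEAN[cls2] +
                                          CLASS_LOGIT_SD[cls2] * stats::rnorm(n)))
    resp <- stats::runif(n) < config$responsive_fraction
    mag2 <- abs(stats::rnorm(n, config$delta_mean, config$delta_sd))
    sgn2 <- ifelse(stats::runif(n) < config$sign_up_fraction, 1, -1)
    stim <- basal
    stim[resp] <- apply_response(basal[resp], mag2[resp], sgn2[resp])
    data.frame(event_id = ev$event_id, basal = basal, stim = stim,
               responsive = resp, stringsAsFactors = FALSE)
  }
  extra_s <- non_orth_truth(genome$events_source, pairs$source_event_id)
  extra_t <- non_orth_truth(genome$events_target, pairs$target_event_id)

  truth_events <- rbind(
    data.frame(event_id = pairs$source_event_id, species = "source",
               gene_id = pairs$source_gene_id,
               true_basal_psi = basal_s, true_stim_psi = stim_s,
               responsive = resp_s, conserved = conserved,
               stringsAsFactors = FALSE),
    data.frame(event_id = pairs$target_event_id, species = "target",
               gene_id = pairs$target_gene_id,
               true_basal_psi = basal_t, true_stim_psi = stim_t,
               responsive = resp_t, conserved = conserved,
               stringsAsFactors = FALSE),
    data.frame(event_id = extra_s$event_id,
               species = rep("source", nrow(extra_s)),
               gene_id = genome$events_source$gene_id[
                 match(extra_s$event_id, genome$events_source$event_id)],
               true_basal_psi = extra_s$basal, true_stim_psi = extra_s$stim,
               responsive = extra_s$responsive,
               conserved = rep(FALSE, nrow(extra_s)),
               stringsAsFactors = FALSE),
    data.frame(event_id = extra_t$event_id,
               species = rep("target", nrow(extra_t)),
               gene_id = genome$events_target$gene_id[
                 match(extra_t$event_id, genome$events_target$event_id)],
               true_basal_psi = extra_t$basal, true_stim_psi = extra_t$stim,
               responsive = extra_t$responsive,
               conserved = rep(FALSE, nrow(extra_t)),
               stringsAsFactors = FALSE)
  )
  truth_pairs <- data.frame(
    source_event_id = pairs$source_event_id,
    target_event_id = pairs$target_event_id,
    target_gene_id = pairs$target_gene_id,
    responsive_source = resp_s,
    responsive_target = resp_t,
    conserved = conserved,
    stringsAsFactors = FALSE
  )
  reg_t <- tapply(resp_t, pairs$target_gene_id, any)
  reg_s <- tapply(resp_s, pairs$target_gene_id, any)
  genes <- names(reg_t)
  label <- rep("unregulated", length(genes))
  label[reg_t & reg_s] <- "conserved"
  label[reg_t & !reg_s] <- "species_specific_target"
  label[!reg_t & reg_s] <- "species_specific_source"
  truth_genes <- data.frame(gene_id = genes, label = label,
                            stringsAsFactors = FALSE)
  rownames(truth_genes) <- NULL
  list(truth_events = truth_events,
       truth_pairs = truth_pairs,
       truth_genes = truth_genes,
       realized_basal_corr = stats::cor(basal_s, basal_t))
}

#' Simulate replicate junction counts
#'
#' Per replicate the total junction count is Poisson with mean `depth`;
#' the inclusion count is binomial with probability
#' `psi * lI / (psi * lI + (1 - psi) * lS)` (so that the
#' length-normalised PSI estimator is centred on the true PSI), or
#' beta-binomial when `dispersion > 0`. Effective lengths are the
#' junction-count defaults `lI = 2`, `lS = 1`.
#'
#' @param config a [sim_config()].
#' @param truth output of [simulate_truth()].
#' @param species `"source"` or `"target"`.
#' @param seed overrides the config-derived seed when given.
#' @return long replicate-count table (see [validate_counts()]).
#' @export
simulate_counts <- function(config, truth, species = c("source", "target"),
                            seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  species <- match.arg(species)
  if (is.null(seed)) {
    seed <- config$seed + 2 + (species == "target")
  }
  set.seed(seed)
  te <- truth$truth_events
  te <- te[te$species == species, , drop = FALSE]
  l_inc <- 2; l_skip <- 1
  n_ev <- nrow(te)
  out <- vector("list", 2L)
  for (cond_i in 1:2) {
    cond <- CONDITIONS[cond_i]
    psi <- if (cond == "basal") te$true_basal_psi else te$true_stim_psi
    psi <- psi / 100
    pstar <- psi * l_inc / (psi * l_inc + (1 - psi) * l_skip)
    reps <- config$replicates
    total <- stats::rpois(n_ev * reps, config$depth)
    p_rep <- rep(pstar, each = reps)
    if (config$dispersion > 0) {
      rho <- config$dispersion
      a <- p_rep * (1 - rho) / rho
      b <- (1 - p_rep) * (1 - rho) / rho
      p_rep <- stats::rbeta(n_ev * reps, a, b)
    }
    inc <- stats::rbinom(n_ev * reps, total, p_rep)
    out[[cond_i]] <- data.frame(
      event_id = rep(te$event_id, each = reps),
      condition = cond,
      replicate = rep(seq_len(reps), n_ev),
      inc_count = inc,
      skip_count = total - inc,
      inc_len = l_inc,
      skip_len = l_skip,
      stringsAsFactors = FALSE
    )
  }
  rbind(out[[1]], out[[2]])
}

#' Simulate a complete two-species bundle
#'
#' Runs [simulate_genome_pair()], [simulate_truth()] and
#' [simulate_counts()] for both species, deriving every stage's seed from
#' `config$seed`, so a bundle is a pure function of its configuration.
#'
#' @param config a [sim_config()].
#' @return list with `config`, `genome`, `truth`, `counts_source`,
#'   `counts_target`.
#' @export
simulate_bundle <- function(config) {
  genome <- simulate_genome_pair(config)
  truth <- simulate_truth(config, genome)
  list(config = config,
       genome = genome,
       truth = truth,
       counts_source = simulate_counts(config, truth, "source"),
       counts_target = simulate_counts(config, truth, "target"))
}

#' Simulate datasets with block-structured cross-dataset correlation
#'
#' Generates per-event values (on a PSI-difference-like scale) for
#' several datasets of two species, with one correlation within species
#' and a lower one between species, via a block-structured Gaussian.
#' Used to exercise [pairwise_matrix()] against a planted within- versus
#' cross-species pattern.
#'
#' @param n_events events per dataset (shared ids).
#' @param n_per_species datasets per species (default 3 and 3).
#' @param rho_within,rho_between correlations within and between species.
#' @param seed integer seed.
#' @param scale multiplier applied to the latent standard normal.
#' @return named list of numeric vectors (names `pair_<i>`), dataset
#'   names `speciesA_1 ... speciesB_k`.
#' @export
simulate_correlated_panel <- function(n_events, n_per_species = c(3, 3),
                                      rho_within = 0.8, rho_between = 0.5,
                                      seed = 1, scale = 10) {
  set.seed(seed)
  k <- sum(n_per_species)
  species <- rep(c("speciesA", "speciesB"), n_per_species)
  sigma <- matrix(rho_between, k, k)
  same <- outer(species, species, "==")
  sigma[same] <- rho_within
  diag(sigma) <- 1
  r <- chol(sigma)
  x <- matrix(stats::rnorm(n_events * k), n_events, k) %*% r * scale
  ids <- paste0("pair_", seq_len(n_events))
  out <- lapply(seq_len(k), function(j) stats::setNames(x[, j], ids))
  names(out) <- paste0(species, "_", unlist(lapply(n_per_species, seq_len)))
  out
}

# rMATS-dialect writer used by the fixture bundle
write_rmats_table <- function(events, counts, path) {
  ids <- events$event_id
  fmt_psi <- function(cond) {
    pr <- psi_per_replicate(counts[counts$condition == cond, , drop = FALSE])
    spl <- split(pr$psi, factor(pr$event_id, levels = ids))
    vapply(spl, function(v) {
      paste(ifelse(is.na(v), "NA", sprintf("%.4f", v / 100)), collapse = ",")
    }, "")
  }
  lens <- counts[!duplicated(counts$event_id), c("event_id", "inc_len", "skip_len")]
  lens <- lens[match(ids, lens$event_id), ]
  tab <- data.frame(
    ID = ids,
    GeneID = events$gene_id,
    geneSymbol = events$gene_symbol,
    chr = events$chrom,
    strand = events$strand,
    exonStart_0base = as.integer(events$target_start),
    exonEnd = as.integer(events$target_end),
    upstreamES = as.integer(events$upstream_end - 50),
    upstreamEE = as.integer(events$upstream_end),
    downstreamES = as.integer(events$downstream_start),
    downstreamEE = as.integer(events$downstream_start + 50),
    IJC_SAMPLE_1 = collapse_counts(counts, ids, "basal", "inc_count"),
    SJC_SAMPLE_1 = collapse_counts(counts, ids, "basal", "skip_count"),
    IJC_SAMPLE_2 = collapse_counts(counts, ids, "stimulated", "inc_count"),
    SJC_SAMPLE_2 = collapse_counts(counts, ids, "stimulated", "skip_count"),
    IncFormLen = lens$inc_len,
    SkipFormLen = lens$skip_len,
    PValue = "NA",
    FDR = "NA",
    IncLevel1 = fmt_psi("basal"),
    IncLevel2 = fmt_psi("stimulated"),
    IncLevelDifference = "NA",
    stringsAsFactors = FALSE
  )
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Write a fixture bundle to a directory
#'
#' Writes the two rMATS-dialect count tables, the chain file, the
#' ortholog map, the three truth tables and a JSON manifest holding the
#' full configuration (seed included). The manifest is sufficient to
#' regenerate the bundle byte-identically with
#' [regenerate_fixture_bundle()].
#'
#' @param bundle output of [simulate_bundle()].
#' @param dir output directory (created if needed).
#' @return the manifest path, invisibly.
#' @export
write_fixture_bundle <- function(bundle, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- list(
    events_source = "source_SE.rmats.tsv",
    events_target = "target_SE.rmats.tsv",
    chain = "source_to_target.chain",
    ortholog_map = "ortholog_map.tsv",
    truth_events = "truth_events.tsv",
    truth_pairs = "truth_pairs.tsv",
    truth_genes = "truth_genes.tsv"
  )
  p <- function(nm) file.path(dir, files[[nm]])
  write_rmats_table(bundle$genome$events_source, bundle$counts_source,
                    p("events_source"))
  write_rmats_table(bundle$genome$events_target, bundle$counts_target,
                    p("events_target"))
  writeLines(bundle$genome$chain_lines, p("chain"))
  utils::write.table(bundle$genome$ortholog_map, p("ortholog_map"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(bundle$truth$truth_events, p("truth_events"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(bundle$truth$truth_pairs, p("truth_pairs"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(bundle$truth$truth_genes, p("truth_genes"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cfg_out <- unclass(bundle$config)
  cfg_out$class_mixture <- as.list(cfg_out$class_mixture)
  manifest <- list(
    format = "orthopsi_fixture_bundle",
    version = 1L,
    config = cfg_out,
    files = files
  )
  manifest_path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(manifest_path)
}

#' Regenerate a fixture bundle from its manifest
#'
#' @param manifest_path path to a `manifest.json` written by
#'   [write_fixture_bundle()].
#' @param dir output directory (defaults to the manifest's directory).
#' @return the regenerated bundle, invisibly.
#' @export
regenerate_fixture_bundle <- function(manifest_path,
                                      dir = dirname(manifest_path)) {
  manifest <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  if (is.null(manifest$config) || is.null(manifest$config$seed)) {
    stop("manifest does not carry a seed; refusing to regenerate")
  }
  cfg_args <- manifest$config
  cfg_args$class_mixture <- unlist(cfg_args$class_mixture)
  config <- do.call(sim_config, cfg_args)
  bundle <- simulate_bundle(config)
  write_fixture_bundle(bundle, dir)
  invisible(bundle)
}
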