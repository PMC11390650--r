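# End-to-end pipeline -------------------------------------------------------

default_params <- function() {
  list(tolerance = 10, alpha = 0.05, min_count = 5, min_delta = 10,
       psi_gate_low = 20, psi_gate_high = 80, expression_band = 0.2)
}

#' Read and validate a run configuration
#'
#' The configuration is a declarative mapping (YAML file or R list) with
#' `source_datasets` and `target_datasets` (lists of `name` + `table`
#' entries pointing at rMATS-dialect tables; the first entry of each list
#' is the primary dataset), `chain` (UCSC chain file lifting source
#' coordinates to the target genome), `ortholog_map` (two-column 1:1
#' gene map), optional `outdir`, and `params` overriding the default
#' thresholds (`tolerance` 10 bp, `alpha` 0.05, `min_count` 5,
#' `min_delta` 10 PSI, basal-PSI gate 20/80, `expression_band` 0.2).
#'
#' @param config path to a YAML file, or a list with the same structure.
#' @return validated config list (class `run_config`).
#' @export
read_run_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  for (field in c("source_datasets", "target_datasets", "chain",
                  "ortholog_map")) {
    if (is.null(config[[field]])) {
      stop("config field missing: ", field)
    }
  }
  norm_ds <- function(ds, role) {
    if (!is.list(ds) || length(ds) == 0L) stop("no ", role, " datasets")
    lapply(ds, function(d) {
      if (is.null(d$name) || is.null(d$table)) {
        stop(role, " dataset entries need 'name' and 'table'")
      }
      if (!file.exists(d$table)) stop("table not found: ", d$table)
      d
    })
  }
  config$source_datasets <- norm_ds(config$source_datasets, "source")
  config$target_datasets <- norm_ds(config$target_datasets, "target")
  for (field in c("chain", "ortholog_map")) {
    if (!file.exists(config[[field]])) {
      stop("config field '", field, "': file not found: ", config[[field]])
    }
  }
  params <- default_params()
  for (nm in names(config$params)) {
    if (!nm %in% names(params)) stop("unknown parameter: ", nm)
    params[[nm]] <- config$params[[nm]]
  }
  config$params <- params
  if (is.null(config$seed)) config$seed <- 1L
  class(config) <- c("run_config", "list")
  config
}

dataset_values <- function(calls, ids, column, gate = NULL) {
  m <- match(ids, calls$event_id)
  v <- calls[[column]][m]
  if (!is.null(gate)) v[!calls$gate_flag[m] %in% TRUE] <- NA_real_
  v
}

#' Run the full two-species comparison
#'
#' Executes the stage graph end to end: read the per-dataset event
#' tables, compute PSI, lift the source-species events through the
#' chain, match orthologous events within the tolerance restricted to
#' the 1:1 gene map, call activity-dependent differential inclusion per
#' dataset, build the pairwise correlation matrices for basal PSI, delta
#' PSI and percent-of-maximum change (the latter gated on basal PSI),
#' derive the background / conserved / species-specific gene sets, and
#' write per-stage TSVs plus a machine-readable JSON summary with every
#' parameter, per-stage record counts and input checksums. The whole run
#' is a pure function of (inputs, parameters, seed): rerunning a config
#' reproduces the summary byte-identically.
#'
#' @param config a run configuration (path, list, or `run_config`).
#' @return (invisibly) a list with all stage results and the summary.
#' @export
run_full_comparison <- function(config) {
  if (!inherits(config, "run_config")) config <- read_run_config(config)
  params <- config$params
  outdir <- config$outdir
  if (!is.null(outdir) && !dir.exists(outdir)) {
    dir.create(outdir, recursive = TRUE)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  read_ds <- function(d, species) {
    tab <- stage(paste0("read:", d$name),
                 read_event_table(d$table, dialect = "rmats_jc",
                                  species = species))
    tab$name <- d$name
    tab
  }
  src <- lapply(config$source_datasets, read_ds, species = "source")
  tgt <- lapply(config$target_datasets, read_ds, species = "target")
  names(src) <- vapply(config$source_datasets, `[[`, "", "name")
  names(tgt) <- vapply(config$target_datasets, `[[`, "", "name")

  chains <- stage("parse_chain", parse_chain(config$chain))
  omap <- stage("ortholog_map", read_ortholog_map(config$ortholog_map))

  events_source <- src[[1]]$events
  events_target <- tgt[[1]]$events

  lifted <- stage("lift", lift_event(chains, events_source,
                                     species_out = "source_lifted"))
  pairs <- stage("match", match_events(lifted$lifted, events_target,
                                       tolerance = params$tolerance,
                                       ortholog_map = omap))

  calls <- lapply(c(src, tgt), function(d) {
    stage(paste0("differential:", d$name),
          differential_calls(d$counts, alpha = params$alpha,
                             min_count = params$min_count,
                             min_delta = params$min_delta))
  })

  # per-dataset values on the shared matched-pair axis (keyed by target id)
  pair_ids <- pairs$target_event_id
  values_for <- function(ds_name, column, gated = FALSE) {
    cl <- calls[[ds_name]]
    ids <- if (ds_name %in% names(src)) pairs$source_event_id else pair_ids
    v <- dataset_values(cl, ids, column, gate = if (gated) TRUE else NULL)
    stats::setNames(v, pair_ids)
  }
  modes <- list(
    basal_psi = list(column = "basal_mean_psi", gated = FALSE),
    delta_psi = list(column = "delta_psi", gated = FALSE),
    pct_max = list(column = "pct_of_max", gated = TRUE)
  )
  matrices <- lapply(modes, function(m) {
    ds <- lapply(names(calls), values_for, column = m$column,
                 gated = m$gated)
    names(ds) <- names(calls)
    pairwise_matrix(ds)
  })

  counts_src_list <- lapply(src, `[[`, "counts")
  background <- stage("background",
                      build_background(pairs, tgt[[1]]$counts,
                                       counts_src_list,
                                       min_count = params$min_count))
  conserved <- conserved_regulated_genes(calls[[names(tgt)[1]]],
                                         calls[names(src)], pairs)
  specific <- species_specific_regulated_genes(calls[[names(tgt)[1]]],
                                               calls[names(src)], pairs,
                                               background)
  labels <- regulation_labels(calls[[names(tgt)[1]]], calls[names(src)],
                              pairs, background)

  summary <- list(
    parameters = params,
    seed = config$seed,
    inputs = c(
      stats::setNames(
        lapply(c(config$source_datasets, config$target_datasets),
               function(d) unname(tools::md5sum(d$table))),
        vapply(c(config$source_datasets, config$target_datasets),
               `[[`, "", "name")),
      list(chain = unname(tools::md5sum(config$chain)),
           ortholog_map = unname(tools::md5sum(config$ortholog_map)))
    ),
    stages = list(
      events_source = nrow(events_source),
      events_target = nrow(events_target),
      lifted = nrow(lifted$lifted),
      lift_failures = nrow(lifted$failures),
      matched_pairs = nrow(pairs),
      orthology_rate_source = nrow(pairs) / max(nrow(events_source), 1),
      orthology_rate_target = nrow(pairs) / max(nrow(events_target), 1),
      significant = lapply(calls, function(cl) sum(cl$significant)),
      background_genes = length(background),
      conserved_genes = length(conserved),
      species_specific_genes = length(specific)
    )
  )

  result <- list(config = config, psi = lapply(c(src, tgt), function(d) {
    compute_psi(d$counts)
  }), lifted = lifted, pairs = pairs, calls = calls,
  matrices = matrices, background = background,
  conserved_genes = conserved, species_specific_genes = specific,
  regulation_labels = labels, summary = summary)

  if (!is.null(outdir)) {
    wt <- function(x, f) {
      utils::write.table(x, file.path(outdir, f), sep = "\t", quote = FALSE,
                         row.names = FALSE)
    }
    wt(pairs, "matched_pairs.tsv")
    wt(lifted$failures, "lift_failures.tsv")
    for (nm in names(calls)) wt(calls[[nm]], paste0("calls_", nm, ".tsv"))
    for (nm in names(matrices)) {
      m <- matrices[[nm]]$r
      wt(data.frame(dataset = rownames(m), m, check.names = FALSE),
         paste0("matrix_", nm, ".tsv"))
    }
    wt(labels, "regulation_labels.tsv")
    writeLines(background, file.path(outdir, "background_genes.txt"))
    writeLines(conserved, file.path(outdir, "conserved_genes.txt"))
    writeLines(specific, file.path(outdir, "species_specific_genes.txt"))
    jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = 10)
  }
  invisible(result)
}
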