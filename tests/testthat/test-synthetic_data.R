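# Synthetic two-species generator: construction guarantees and determinism

small_cfg <- function(...) {
  sim_config(n_genes = 60, genes_per_chrom = 20, seed = 2, ...)
}

test_that("configuration invariants are enforced", {
  expect_error(sim_config(orthologous_fraction = 1.2), "fractions")
  expect_error(sim_config(basal_logit_psi_corr = 1.5), "correlations")
  expect_error(sim_config(replicates = 1), "replicates")
  expect_error(sim_config(class_mixture = c(PI = 0.5, PS = 0.5, AS = 0.5)),
               "class_mixture")
})

test_that("full orthology with zero jitter is recovered perfectly", {
  cfg <- sim_config(n_genes = 40, genes_per_chrom = 20,
                    orthologous_fraction = 1, jitter_max = 0,
                    decoy_gap_fraction = 0, seed = 4)
  geno <- simulate_genome_pair(cfg)
  path <- tempfile(); writeLines(geno$chain_lines, path)
  cs <- parse_chain(path)
  lf <- lift_event(cs, geno$events_source)
  expect_equal(nrow(lf$failures), 0L)
  pairs <- match_events(lf$lifted, geno$events_target, tolerance = 10,
                        ortholog_map = geno$ortholog_map)
  expect_equal(nrow(pairs), nrow(geno$events_source))
  expect_true(all(pairs$total_offset == 0))
  r <- orthology_rates(pairs, nrow(geno$events_source),
                       nrow(geno$events_target))
  expect_equal(r$source_rate, 1)
})

test_that("planted orthologous fraction is recovered and decoys fail lifting", {
  cfg <- small_cfg()
  geno <- simulate_genome_pair(cfg)
  path <- tempfile(); writeLines(geno$chain_lines, path)
  cs <- parse_chain(path)
  lf <- lift_event(cs, geno$events_source)
  expect_true(all(geno$decoy_events %in% lf$failures$event_id))
  pairs <- match_events(lf$lifted, geno$events_target, tolerance = 10,
                        ortholog_map = geno$ortholog_map)
  planted_keys <- paste(geno$planted_pairs$source_event_id,
                        geno$planted_pairs$target_event_id)
  expect_setequal(paste(pairs$source_event_id, pairs$target_event_id),
                  planted_keys)
  # jitter beyond the tolerance breaks the planted matches
  pairs0 <- match_events(lf$lifted, geno$events_target, tolerance = 3,
                         ortholog_map = geno$ortholog_map)
  expect_lt(nrow(pairs0), nrow(pairs))
})

test_that("chain passes its own validation and the per-base oracle", {
  geno <- simulate_genome_pair(small_cfg())
  path <- tempfile(); writeLines(geno$chain_lines, path)
  cs <- parse_chain(path)
  for (ch in cs$chains) {
    oracle <- oracle_expand_chain(ch)
    pos <- ch$t_start:(ch$t_end - 1)
    got <- lift_position(cs, ch$t_name, pos)
    expect_equal(got$status, oracle$status)
    expect_equal(got$pos, oracle$qpos)
  }
})

test_that("truth respects the degenerate configuration corners", {
  cfg <- sim_config(n_genes = 40, genes_per_chrom = 20,
                    responsive_fraction = 0, seed = 6)
  geno <- simulate_genome_pair(cfg)
  truth <- simulate_truth(cfg, geno)
  expect_equal(truth$truth_events$true_stim_psi,
               truth$truth_events$true_basal_psi)
  expect_true(all(truth$truth_genes$label == "unregulated"))
  # perfect basal correlation: identical true PSIs across the pair
  cfg2 <- sim_config(n_genes = 40, genes_per_chrom = 20,
                     basal_logit_psi_corr = 1, seed = 6)
  geno2 <- simulate_genome_pair(cfg2)
  truth2 <- simulate_truth(cfg2, geno2)
  te <- truth2$truth_events
  src <- te[match(truth2$truth_pairs$source_event_id, te$event_id), ]
  tgt <- te[match(truth2$truth_pairs$target_event_id, te$event_id), ]
  expect_equal(src$true_basal_psi, tgt$true_basal_psi)
  expect_equal(truth2$realized_basal_corr, 1)
})

test_that("a moderate planted correlation is realised within tolerance", {
  cfg <- sim_config(n_genes = 1000, events_per_gene = 2, genes_per_chrom = 100,
                    orthologous_fraction = 1, basal_logit_psi_corr = 0.5,
                    class_mixture = c(PI = 0, PS = 0, AS = 1), seed = 8)
  geno <- simulate_genome_pair(cfg)
  truth <- simulate_truth(cfg, geno)
  # with a single AS class the logit copula correlation transfers within
  # a few points to the PSI scale at this sample size
  pairs_r <- stats::cor(
    atanh((truth$truth_events$true_basal_psi[
      match(truth$truth_pairs$source_event_id,
            truth$truth_events$event_id)] / 50) - 1),
    atanh((truth$truth_events$true_basal_psi[
      match(truth$truth_pairs$target_event_id,
            truth$truth_events$event_id)] / 50) - 1)
  )
  expect_gt(pairs_r, 0.43)
  expect_lt(pairs_r, 0.57)
})

test_that("counts are centred on the true PSI at high depth", {
  cfg <- sim_config(n_genes = 40, genes_per_chrom = 20, depth = 1e5, seed = 10)
  geno <- simulate_genome_pair(cfg)
  truth <- simulate_truth(cfg, geno)
  counts <- simulate_counts(cfg, truth, "source")
  psi <- compute_psi(counts)
  psi_b <- psi[psi$condition == "basal", ]
  te <- truth$truth_events[truth$truth_events$species == "source", ]
  diff <- abs(psi_b$mean_psi[match(te$event_id, psi_b$event_id)] -
                te$true_basal_psi)
  expect_lt(max(diff), 0.5)
})

test_that("zero depth produces unquantifiable events failing all filters", {
  cfg <- sim_config(n_genes = 40, genes_per_chrom = 20, depth = 0, seed = 10)
  geno <- simulate_genome_pair(cfg)
  truth <- simulate_truth(cfg, geno)
  counts <- simulate_counts(cfg, truth, "source")
  expect_true(all(counts$inc_count == 0 & counts$skip_count == 0))
  expect_equal(filter_expressed(counts, 5, "all_samples"), character(0))
})

test_that("overdispersed counts spread replicate PSI wider than binomial", {
  cfg0 <- sim_config(n_genes = 100, genes_per_chrom = 50, depth = 500,
                     dispersion = 0, seed = 12)
  cfg1 <- sim_config(n_genes = 100, genes_per_chrom = 50, depth = 500,
                     dispersion = 0.05, seed = 12)
  geno <- simulate_genome_pair(cfg0)
  truth <- simulate_truth(cfg0, geno)
  sd_of <- function(cfg) {
    pr <- psi_per_replicate(simulate_counts(cfg, truth, "source"))
    mean(tapply(pr$psi, paste(pr$event_id, pr$condition), stats::sd),
         na.rm = TRUE)
  }
  expect_gt(sd_of(cfg1), 2 * sd_of(cfg0))
})

test_that("bundles are deterministic and regenerable from the manifest", {
  cfg <- small_cfg()
  d1 <- file.path(tempdir(), "bundle_a")
  d2 <- file.path(tempdir(), "bundle_b")
  write_fixture_bundle(simulate_bundle(cfg), d1)
  write_fixture_bundle(simulate_bundle(cfg), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
  # regeneration from the manifest alone reproduces every file
  d3 <- file.path(tempdir(), "bundle_c")
  dir.create(d3, showWarnings = FALSE)
  file.copy(file.path(d1, "manifest.json"), d3, overwrite = TRUE)
  regenerate_fixture_bundle(file.path(d3, "manifest.json"))
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d3, f)),
                     label = f)
  }
  # a manifest without a seed is refused
  m <- jsonlite::read_json(file.path(d1, "manifest.json"))
  m$config$seed <- NULL
  bad <- tempfile(fileext = ".json")
  jsonlite::write_json(m, bad, auto_unbox = TRUE)
  expect_error(regenerate_fixture_bundle(bad, tempdir()), "seed")
})

test_that("the rmats-dialect bundle tables read back consistently", {
  cfg <- small_cfg()
  b <- simulate_bundle(cfg)
  dir <- file.path(tempdir(), "bundle_rt")
  write_fixture_bundle(b, dir)
  tab <- read_event_table(file.path(dir, "source_SE.rmats.tsv"), "rmats_jc",
                          species = "source")
  expect_equal(tab$events, b$genome$events_source)
  reord <- function(x) {
    x <- x[order(x$event_id, x$condition, x$replicate), ]
    rownames(x) <- NULL
    x
  }
  expect_equal(reord(tab$counts), reord(b$counts_source))
})
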