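# Conserved and species-specific regulated gene sets, enrichment wrappers

# small hand-built fixture: 4 orthologous genes x 1 event each
fixture_pairs <- function() {
  data.frame(
    source_event_id = paste0("s", 1:4),
    target_event_id = paste0("t", 1:4),
    source_gene_id = paste0("gs", 1:4),
    target_gene_id = paste0("gt", 1:4),
    stringsAsFactors = FALSE
  )
}

mk_calls <- function(ids, sig) {
  data.frame(event_id = ids, significant = sig,
             p_value = ifelse(sig, 0.001, 0.5),
             passes_expression = TRUE,
             delta_psi = ifelse(sig, 25, 1),
             stringsAsFactors = FALSE)
}

mk_expressed_counts <- function(ids, depth = 20) {
  do.call(rbind, lapply(ids, function(id) {
    make_counts(id, c(depth, depth), c(depth, depth),
                c(depth, depth), c(depth, depth))
  }))
}

test_that("background requires expression on both sides of a pair", {
  pairs <- fixture_pairs()
  counts_t <- mk_expressed_counts(paste0("t", 1:4))
  # s4 never expressed in any source dataset
  counts_s1 <- mk_expressed_counts(paste0("s", 1:3))
  counts_s1 <- rbind(counts_s1, make_counts("s4", c(0, 0), c(0, 0),
                                            c(0, 0), c(0, 0)))
  bg <- build_background(pairs, counts_t, list(counts_s1))
  expect_equal(bg, c("gt1", "gt2", "gt3"))
  # expression in a second source dataset rescues the gene
  counts_s2 <- mk_expressed_counts("s4")
  bg2 <- build_background(pairs, counts_t, list(counts_s1, counts_s2))
  expect_equal(bg2, paste0("gt", 1:4))
})

test_that("conserved genes need significance in target and any source set", {
  pairs <- fixture_pairs()
  calls_t <- mk_calls(paste0("t", 1:4), c(TRUE, TRUE, FALSE, TRUE))
  # source dataset 1: s1 significant; dataset 2: s2 significant
  calls_s1 <- mk_calls(paste0("s", 1:4), c(TRUE, FALSE, FALSE, FALSE))
  calls_s2 <- mk_calls(paste0("s", 1:4), c(FALSE, TRUE, FALSE, FALSE))
  cons <- conserved_regulated_genes(calls_t, list(calls_s1, calls_s2), pairs)
  expect_equal(cons, c("gt1", "gt2"))
  # single source dataset: only gt1 is conserved
  expect_equal(conserved_regulated_genes(calls_t, list(calls_s1), pairs),
               "gt1")
  # event-level conservation agrees here (one event per gene)
  expect_equal(conserved_regulated_events(calls_t, list(calls_s1), pairs),
               "t1")
})

test_that("species-specific genes exclude untestable orthologs by default", {
  pairs <- fixture_pairs()
  calls_t <- mk_calls(paste0("t", 1:4), c(TRUE, TRUE, FALSE, TRUE))
  calls_s <- mk_calls(paste0("s", 1:4), c(TRUE, FALSE, FALSE, FALSE))
  background <- c("gt1", "gt2", "gt3")  # gt4 untestable in the source
  sp <- species_specific_regulated_genes(calls_t, list(calls_s), pairs,
                                         background)
  expect_equal(sp, "gt2")
  sp_perm <- species_specific_regulated_genes(calls_t, list(calls_s), pairs,
                                              background,
                                              include_untestable = TRUE)
  expect_equal(sp_perm, c("gt2", "gt4"))
  # conserved and species-specific partition the regulated testable genes
  cons <- conserved_regulated_genes(calls_t, list(calls_s), pairs)
  regulated_testable <- intersect(
    unique(pairs$target_gene_id[pairs$target_event_id %in% c("t1", "t2", "t4")]),
    background
  )
  expect_equal(sort(c(cons, sp)), sort(regulated_testable))
  expect_length(intersect(cons, sp), 0)
})

test_that("regulation labels partition the gene universe", {
  pairs <- fixture_pairs()
  calls_t <- mk_calls(paste0("t", 1:4), c(TRUE, TRUE, FALSE, FALSE))
  calls_s <- mk_calls(paste0("s", 1:4), c(TRUE, FALSE, TRUE, FALSE))
  background <- paste0("gt", 1:3)
  lab <- regulation_labels(calls_t, list(calls_s), pairs, background)
  expect_equal(lab$label[match(paste0("gt", 1:4), lab$gene_id)],
               c("conserved", "species_specific_target",
                 "species_specific_source", "untestable"))
  expect_equal(sort(lab$gene_id), sort(unique(pairs$target_gene_id)))
})

test_that("factor target enrichment shares arithmetic with class_enrichment", {
  set.seed(9)
  background <- paste0("e", 1:500)
  foreground <- paste0("e", 1:60)
  targets <- list(F1 = paste0("e", c(1:30, 400:420)),
                  F2 = paste0("e", 450:470))
  res <- factor_target_enrichment(targets, foreground, background)
  direct <- class_enrichment(intersect(targets$F1, background), foreground,
                             background)
  expect_equal(res$F1$table, direct$table)
  expect_equal(res$F1$fisher_p, direct$fisher_p)
  expect_equal(res$F1$fold_enrichment, direct$fold_enrichment)
  # targets absent from the foreground but present in background deplete
  expect_lt(res$F2$fold_enrichment, 1)
  # foreground = background is the degenerate fold-1 case
  res3 <- factor_target_enrichment(targets, background, background)
  expect_equal(res3$F1$fold_enrichment, 1)
  expect_error(factor_target_enrichment(targets, "zzz", background), "subset")
})

test_that("a planted 3x target enrichment is recovered", {
  set.seed(17)
  n <- 5000
  background <- paste0("e", seq_len(n))
  conserved <- sample(background, 500)
  # targets drawn with 3x higher probability inside the conserved set
  p <- ifelse(background %in% conserved, 0.30, 0.10)
  targets <- background[runif(n) < p]
  res <- factor_target_enrichment(list(F = targets), conserved, background)
  expect_gt(res$F$fold_enrichment, 2.5)
  expect_lt(res$F$fold_enrichment, 3.5)
  expect_lt(res$F$fisher_p, 1e-10)
})

test_that("term enrichment ranks the matching term first and flags edge cases", {
  background <- paste0("g", 1:200)
  gene_set <- paste0("g", 1:20)
  gene2term <- rbind(
    data.frame(gene_id = gene_set, term_id = "T_exact"),
    data.frame(gene_id = paste0("g", 1:100), term_id = "T_half"),
    data.frame(gene_id = paste0("g", 198:200), term_id = "T_small"),
    data.frame(gene_id = "not_in_background", term_id = "T_outside")
  )
  res <- term_enrichment(gene_set, background, gene2term)
  expect_equal(res$term_id[1], "T_exact")
  expect_lt(res$fisher_p[1], min(res$fisher_p[-1]))
  # terms under min_genes are skipped
  expect_false("T_small" %in% res$term_id)
  expect_equal(attr(res, "n_skipped"), 1L)
  # empty gene set is flagged, not an error
  res0 <- term_enrichment(character(0), background, gene2term)
  expect_equal(nrow(res0), 0L)
  expect_equal(attr(res0, "flag"), "empty_gene_set")
  # BH adjustment is monotone in p
  resbh <- term_enrichment(gene_set, background, gene2term, p_adjust = "BH")
  expect_true(all(resbh$p_adjusted >= resbh$fisher_p))
})

test_that("null term annotations give approximately uniform p-values", {
  set.seed(23)
  background <- paste0("g", 1:400)
  gene_set <- sample(background, 60)
  pvals <- replicate(200, {
    g2t <- data.frame(gene_id = sample(background, 40), term_id = "T")
    term_enrichment(gene_set, background, g2t)$fisher_p
  })
  # discrete conservative test: p-values stochastically >= uniform
  ks <- suppressWarnings(stats::ks.test(pvals, "punif",
                                        alternative = "greater"))
  expect_gt(ks$p.value, 0.01)
  expect_gt(mean(pvals), 0.4)
})
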