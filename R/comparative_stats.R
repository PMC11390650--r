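# Correlations, enrichments and their comparison ----------------------------

#' Pearson correlation with a Fisher-z confidence interval
#'
#' Pairs with an undefined entry in either vector are dropped. The
#' confidence interval uses the Fisher z-transform `atanh(r)` with
#' standard error `1/sqrt(n - 3)`; the two-sided p-value comes from the
#' corresponding z statistic. With `|r| = 1` the interval collapses at
#' `r`. Fewer than 3 complete pairs leaves the interval undefined; zero
#' variance in either vector leaves `r` undefined (flagged).
#'
#' @param x,y paired numeric vectors.
#' @param conf confidence level (default 0.95).
#' @return object of class `cor_ci`: list with `r`, `n`, `ci_low`,
#'   `ci_high`, `p_value`, `conf`, `flag`.
#' @export
pearson_with_ci <- function(x, y, conf = 0.95) {
  stopifnot(length(x) == length(y))
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  out <- list(r = NA_real_, n = n, ci_low = NA_real_, ci_high = NA_real_,
              p_value = NA_real_, conf = conf, flag = "")
  class(out) <- "cor_ci"
  if (n < 2L || stats::sd(x) == 0 || stats::sd(y) == 0) {
    out$flag <- if (n < 2L) "too_few_pairs" else "zero_variance"
    return(out)
  }
  r <- stats::cor(x, y)
  out$r <- r
  if (n < 3L) {
    out$flag <- "ci_undefined"
    return(out)
  }
  if (abs(r) >= 1) {
    out$ci_low <- r; out$ci_high <- r; out$p_value <- 0
    out$flag <- "degenerate_r"
    return(out)
  }
  z <- atanh(r)
  se <- 1 / sqrt(n - 3)
  crit <- stats::qnorm(1 - (1 - conf) / 2)
  out$ci_low <- tanh(z - crit * se)
  out$ci_high <- tanh(z + crit * se)
  out$p_value <- 2 * stats::pnorm(-abs(z / se))
  out
}

#' @export
print.cor_ci <- function(x, ...) {
  cat(sprintf("Pearson r = %.4f (n = %d), %g%% CI [%.4f, %.4f], p = %.3g\n",
              x$r, x$n, 100 * x$conf, x$ci_low, x$ci_high, x$p_value))
  if (nzchar(x$flag)) cat("flag:", x$flag, "\n")
  invisible(x)
}

#' Enrichment result from a 2x2 table
#'
#' Builds the full enrichment payload from counts `(a, b, c, d)`:
#' fold enrichment as the ratio of proportions `(a/(a+b)) / (c/(c+d))`
#' with a Katz log-interval, the odds ratio `ad/bc` with its Woolf
#' standard error `sqrt(1/a + 1/b + 1/c + 1/d)`, and the two-sided Fisher
#' exact p-value. Tables containing zero cells use the Haldane-Anscombe
#' 0.5 continuity correction for the ratio estimates (never for the
#' Fisher p) and are flagged.
#'
#' @param a,b,c,d non-negative integer cells. Orientation: rows =
#'   reference membership, columns = query membership, so `a` counts
#'   elements in both sets.
#' @param conf confidence level (default 0.95).
#' @return object of class `enrichment_result`.
#' @export
enrichment_from_table <- function(a, b, c, d, conf = 0.95) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(cells < 0) || any(cells != floor(cells))) {
    stop("table cells must be non-negative integers")
  }
  n <- sum(cells)
  if (n == 0) stop("empty 2x2 table")
  fisher_p <- stats::fisher.test(matrix(c(a, c, b, d), nrow = 2))$p.value
  corrected <- any(cells == 0)
  if (corrected) cells <- cells + 0.5
  aa <- cells["a"]; bb <- cells["b"]; cc <- cells["c"]; dd <- cells["d"]
  crit <- stats::qnorm(1 - (1 - conf) / 2)
  degenerate <- (c + d) == 0  # query covers the whole universe
  if (degenerate) {
    fold <- 1
    se_fold <- NA_real_
    ci <- c(NA_real_, NA_real_)
  } else {
    fold <- (aa / (aa + bb)) / (cc / (cc + dd))
    se_fold <- sqrt(1 / aa - 1 / (aa + bb) + 1 / cc - 1 / (cc + dd))
    ci <- exp(log(fold) + c(-1, 1) * crit * se_fold)
  }
  or <- (aa * dd) / (bb * cc)
  se_or <- sqrt(1 / aa + 1 / bb + 1 / cc + 1 / dd)
  or_ci <- exp(log(or) + c(-1, 1) * crit * se_or)
  structure(list(
    table = c(a = a, b = b, c = c, d = d),
    fold_enrichment = unname(fold),
    fold_ci_low = unname(ci[1]), fold_ci_high = unname(ci[2]),
    odds_ratio = unname(or),
    log_or_se = unname(se_or),
    or_ci_low = unname(or_ci[1]), or_ci_high = unname(or_ci[2]),
    fisher_p = fisher_p,
    corrected = corrected,
    degenerate = degenerate,
    conf = conf
  ), class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("2x2 table (a,b,c,d) = (%s)\n",
              paste(x$table, collapse = ", ")))
  cat(sprintf("fold enrichment = %.3f [%.3f, %.3f]; OR = %.3f; Fisher p = %.3g\n",
              x$fold_enrichment, x$fold_ci_low, x$fold_ci_high,
              x$odds_ratio, x$fisher_p))
  if (x$corrected) cat("note: 0.5 continuity correction applied (zero cell)\n")
  invisible(x)
}

#' Enrichment of a reference class within a query set
#'
#' Given two event sets inside a common universe (for example, exons
#' classed as alternatively spliced in two datasets over the matched-pair
#' universe), builds the 2x2 table `a = |ref & query|`,
#' `b = |query \ ref|`, `c = |ref \ query|`, `d = |universe \ (ref|query)|`
#' and reports the enrichment factor. By default the factor conditions on
#' the query set, `P(ref | query) / P(ref | not query)`; setting
#' `conditioning = "universe"` uses `P(ref | query) / P(ref | universe)`
#' instead.
#'
#' @param reference_ids,query_ids character vectors, subsets of
#'   `universe`.
#' @param universe character vector of all eligible ids.
#' @param conditioning `"complement"` (default) or `"universe"`.
#' @param conf confidence level.
#' @return an `enrichment_result` (see [enrichment_from_table()]).
#' @export
class_enrichment <- function(reference_ids, query_ids, universe,
                             conditioning = c("complement", "universe"),
                             conf = 0.95) {
  conditioning <- match.arg(conditioning)
  if (length(universe) == 0L) stop("empty universe")
  reference_ids <- unique(reference_ids)
  query_ids <- unique(query_ids)
  universe <- unique(universe)
  if (!all(reference_ids %in% universe) || !all(query_ids %in% universe)) {
    stop("reference and query sets must be subsets of the universe")
  }
  a <- length(intersect(reference_ids, query_ids))
  b <- length(setdiff(query_ids, reference_ids))
  c_ <- length(setdiff(reference_ids, query_ids))
  d <- length(universe) - a - b - c_
  res <- enrichment_from_table(a, b, c_, d, conf = conf)
  if (conditioning == "universe" && !res$degenerate) {
    p_query <- if (a + b > 0) a / (a + b) else NA_real_
    p_universe <- (a + c_) / length(universe)
    res$fold_enrichment <- p_query / p_universe
    # CI for a ratio of a proportion to a (near-fixed) universe rate uses
    # the same Katz-type log SE with the universe margin
    aa <- a + 0.5 * res$corrected; bb <- b + 0.5 * res$corrected
    mm <- a + c_ + 0.5 * res$corrected
    se <- sqrt(1 / aa - 1 / (aa + bb) + 1 / mm - 1 / length(universe))
    crit <- stats::qnorm(1 - (1 - conf) / 2)
    res$fold_ci_low <- exp(log(res$fold_enrichment) - crit * se)
    res$fold_ci_high <- exp(log(res$fold_enrichment) + crit * se)
  }
  res
}

#' Compare two enrichment results by their log odds ratios
#'
#' Normal approximation to the difference in log odds ratios:
#' `z = (ln OR1 - ln OR2) / sqrt(SE1^2 + SE2^2)` with Woolf standard
#' errors; two-sided normal p-value. Tables with zero cells are
#' continuity-corrected (0.5) and the result flagged.
#'
#' @param e1,e2 `enrichment_result` objects.
#' @return list with `z`, `p_value`, `corrected`.
#' @export
compare_enrichments <- function(e1, e2) {
  stopifnot(inherits(e1, "enrichment_result"), inherits(e2, "enrichment_result"))
  z <- (log(e1$odds_ratio) - log(e2$odds_ratio)) /
    sqrt(e1$log_or_se^2 + e2$log_or_se^2)
  list(z = z, p_value = 2 * stats::pnorm(-abs(z)),
       corrected = e1$corrected || e2$corrected)
}

#' Pairwise correlation matrix across datasets
#'
#' Computes [pearson_with_ci()] for every dataset pair on the
#' intersection of their (named) values. The result is symmetric with a
#' unit diagonal; cells with fewer than 3 shared observations are left
#' `NA` and flagged through the `n` matrix.
#'
#' @param datasets named list of numeric vectors, each named by event (or
#'   pair) id.
#' @param conf confidence level.
#' @return object of class `pairwise_cor`: list of matrices `r`, `n`,
#'   `ci_low`, `ci_high`, `p_value`.
#' @export
pairwise_matrix <- function(datasets, conf = 0.95) {
  stopifnot(is.list(datasets), length(datasets) >= 2L,
            !is.null(names(datasets)))
  k <- length(datasets)
  nm <- names(datasets)
  mats <- lapply(1:5, function(i) {
    m <- matrix(NA_real_, k, k, dimnames = list(nm, nm))
    m
  })
  names(mats) <- c("r", "n", "ci_low", "ci_high", "p_value")
  for (i in seq_len(k)) {
    mats$r[i, i] <- 1
    mats$n[i, i] <- length(datasets[[i]])
    for (j in seq_len(k)) {
      if (j <= i) next
      shared <- intersect(names(datasets[[i]]), names(datasets[[j]]))
      res <- pearson_with_ci(datasets[[i]][shared], datasets[[j]][shared],
                             conf = conf)
      mats$n[i, j] <- mats$n[j, i] <- res$n
      if (res$n >= 3L && !is.na(res$r)) {
        mats$r[i, j] <- mats$r[j, i] <- res$r
        mats$ci_low[i, j] <- mats$ci_low[j, i] <- res$ci_low
        mats$ci_high[i, j] <- mats$ci_high[j, i] <- res$ci_high
        mats$p_value[i, j] <- mats$p_value[j, i] <- res$p_value
      }
    }
  }
  structure(mats, class = "pairwise_cor")
}

#' @export
print.pairwise_cor <- function(x, ...) {
  cat("pairwise Pearson correlations:\n")
  print(round(x$r, 3))
  invisible(x)
}

#' Restrict matched pairs to genes expressed at similar levels
#'
#' Keeps pairs whose gene-expression ratio between species lies within a
#' band around 1. "Within `band` in either direction" is interpreted
#' symmetrically on the log scale: the ratio must lie in
#' `[1/(1 + band), 1 + band]` (bounds inclusive). Setting
#' `symmetric = FALSE` switches to the arithmetic band
#' `[1 - band, 1 + band]`. Pairs whose gene is missing from either
#' expression table are dropped and counted in the `n_missing` attribute.
#'
#' @param pairs matched-pair table with `source_gene_id`,
#'   `target_gene_id` columns.
#' @param expr_source,expr_target data.frames with columns `gene_id`,
#'   `value` (positive expression levels).
#' @param band fractional band width (default 0.2).
#' @param symmetric log-symmetric band if `TRUE` (default).
#' @return the subset of `pairs`, with attribute `n_missing`.
#' @export
expression_matched_subset <- function(pairs, expr_source, expr_target,
                                      band = 0.2, symmetric = TRUE) {
  stopifnot(band >= 0)
  va <- expr_source$value[match(pairs$source_gene_id, expr_source$gene_id)]
  vb <- expr_target$value[match(pairs$target_gene_id, expr_target$gene_id)]
  missing <- is.na(va) | is.na(vb)
  if (any(stats::na.omit(c(va, vb)) <= 0)) {
    stop("expression values must be positive")
  }
  ratio <- vb / va
  lo <- if (symmetric) 1 / (1 + band) else 1 - band
  hi <- 1 + band
  keep <- !missing & ratio >= lo & ratio <= hi
  out <- pairs[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_missing") <- sum(missing)
  out
}
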