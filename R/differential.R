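# Activity-dependent inclusion calls ----------------------------------------

# binomial log-likelihood with 0*log(0) = 0
bin_ll <- function(x, n, p) {
  t1 <- ifelse(x > 0, x * log(p), 0)
  t2 <- ifelse(n - x > 0, (n - x) * log1p(-p), 0)
  t1 + t2
}

#' Binomial likelihood-ratio test for a PSI difference (vectorised)
#'
#' Compares a binomial model with a shared inclusion probability across
#' conditions against one with per-condition probabilities, on
#' length-normalised junction counts, against a chi-squared reference with
#' one degree of freedom. Inputs are the condition totals of normalised
#' counts; the test statistic depends on the replicate counts only through
#' those totals.
#'
#' @param x1,n1 inclusion count and total (inclusion + skipping) in
#'   condition 1, after length normalisation; vectors over events.
#' @param x2,n2 same for condition 2.
#' @return data.frame with `lrt` and `p_value` per event. Events with
#'   `n1 = 0` or `n2 = 0` get `NA`.
#' @export
binomial_lrt <- function(x1, n1, x2, n2) {
  p1 <- ifelse(n1 > 0, x1 / n1, NA_real_)
  p2 <- ifelse(n2 > 0, x2 / n2, NA_real_)
  p0 <- ifelse(n1 + n2 > 0, (x1 + x2) / (n1 + n2), NA_real_)
  ll_alt <- bin_ll(x1, n1, pmin(pmax(p1, 0), 1)) +
    bin_ll(x2, n2, pmin(pmax(p2, 0), 1))
  ll_null <- bin_ll(x1, n1, p0) + bin_ll(x2, n2, p0)
  lrt <- pmax(2 * (ll_alt - ll_null), 0)
  p <- stats::pchisq(lrt, df = 1, lower.tail = FALSE)
  p[n1 == 0 | n2 == 0] <- NA_real_
  lrt[n1 == 0 | n2 == 0] <- NA_real_
  data.frame(lrt = lrt, p_value = p)
}

# beta-binomial log-likelihood for one condition's replicates
bb_ll <- function(x, n, mu, rho) {
  if (rho <= 0) return(sum(bin_ll(x, n, mu)))
  a <- mu * (1 - rho) / rho
  b <- (1 - mu) * (1 - rho) / rho
  sum(lchoose(n, x) + lbeta(x + a, n - x + b) - lbeta(a, b))
}

#' Beta-binomial likelihood-ratio test for one event
#'
#' Replicate-aware overdispersed variant of [binomial_lrt()]: replicate
#' inclusion counts are modelled as beta-binomial with a common
#' intra-class correlation `rho`, shared between conditions; the null
#' shares the mean inclusion probability across conditions, the
#' alternative frees it per condition. One degree of freedom.
#'
#' @param x1,n1 per-replicate normalised inclusion counts and totals,
#'   condition 1.
#' @param x2,n2 same for condition 2.
#' @return list with `lrt`, `p_value`, `rho_hat`.
#' @export
beta_binomial_lrt <- function(x1, n1, x2, n2) {
  if (sum(n1) == 0 || sum(n2) == 0) {
    return(list(lrt = NA_real_, p_value = NA_real_, rho_hat = NA_real_))
  }
  eps <- 1e-6
  clamp <- function(p) pmin(pmax(p, eps), 1 - eps)
  nll_null <- function(par) {
    mu <- clamp(stats::plogis(par[1])); rho <- clamp(stats::plogis(par[2]))
    -(bb_ll(x1, n1, mu, rho) + bb_ll(x2, n2, mu, rho))
  }
  nll_alt <- function(par) {
    mu1 <- clamp(stats::plogis(par[1])); mu2 <- clamp(stats::plogis(par[2]))
    rho <- clamp(stats::plogis(par[3]))
    -(bb_ll(x1, n1, mu1, rho) + bb_ll(x2, n2, mu2, rho))
  }
  p1 <- clamp(sum(x1) / sum(n1)); p2 <- clamp(sum(x2) / sum(n2))
  p0 <- clamp((sum(x1) + sum(x2)) / (sum(n1) + sum(n2)))
  f0 <- stats::optim(c(stats::qlogis(p0), stats::qlogis(0.01)), nll_null,
                     method = "Nelder-Mead")
  f1 <- stats::optim(c(stats::qlogis(p1), stats::qlogis(p2),
                       stats::qlogis(0.01)), nll_alt, method = "Nelder-Mead")
  lrt <- max(2 * (f0$value - f1$value), 0)
  list(lrt = lrt,
       p_value = stats::pchisq(lrt, df = 1, lower.tail = FALSE),
       rho_hat = stats::plogis(f1$par[3]))
}

#' Test one event for differential inclusion
#'
#' Thin single-event wrapper around the table-level [differential_calls()]
#' machinery: computes the PSI difference (stimulated minus basal, in PSI
#' units) and a likelihood-ratio p-value. The likelihood is evaluated on
#' the raw junction counts: because the map between the inclusion-read
#' probability and PSI is monotone and identical in both conditions, the
#' two conditions share an inclusion-read probability exactly when they
#' share a PSI, so the raw-count LRT tests the PSI hypothesis while
#' remaining exactly calibrated. Effective lengths enter only through
#' the PSI scale of `delta_psi`.
#'
#' @param basal,stim single-event replicate-count tables (rows of the long
#'   count format, one condition each).
#' @param method `"binomial"` (default) or `"betabinomial"`.
#' @return list with `delta_psi`, `p_value`.
#' @export
test_differential_inclusion <- function(basal, stim,
                                        method = c("binomial", "betabinomial")) {
  method <- match.arg(method)
  stopifnot(length(unique(basal$event_id)) <= 1L,
            length(unique(stim$event_id)) <= 1L)
  psi_b <- compute_psi(basal)
  psi_s <- compute_psi(stim)
  delta <- psi_s$mean_psi[1] - psi_b$mean_psi[1]
  xb <- basal$inc_count
  sb <- basal$skip_count
  xs <- stim$inc_count
  ss <- stim$skip_count
  if (method == "binomial") {
    res <- binomial_lrt(sum(xb), sum(xb) + sum(sb), sum(xs), sum(xs) + sum(ss))
    list(delta_psi = delta, p_value = res$p_value)
  } else {
    res <- beta_binomial_lrt(xb, xb + sb, xs, xs + ss)
    list(delta_psi = delta, p_value = res$p_value)
  }
}

#' Activity-dependent differential inclusion calls for a count table
#'
#' For every event with counts in both conditions, computes basal and
#' stimulated mean PSI, the PSI difference, a likelihood-ratio p-value
#' (binomial by default, beta-binomial optionally; evaluated on the raw
#' junction counts, see [test_differential_inclusion()]), the expression
#' filter (`all_samples` rule), significance under the standard
#' thresholds, and the percent-of-maximum-change statistic with its
#' basal-PSI gate flag.
#'
#' Significance requires all three of: `p_value < alpha` (strict),
#' expression filter passed, and `|delta_psi| > min_delta` (strict).
#' Events failing the expression filter get `p_value = NA`
#' (`passes_expression = FALSE`); events with all-zero counts in a
#' condition are unquantifiable and flagged by `NA` PSI. No
#' multiple-testing correction is applied: calls filter on the raw
#' p-value together with the effect size.
#'
#' @param counts long replicate-count table with both conditions.
#' @param alpha p-value threshold (default 0.05).
#' @param min_count expression threshold (default 5, strict `>`).
#' @param min_delta minimum absolute PSI difference (default 10, strict).
#' @param method `"binomial"` or `"betabinomial"`.
#' @param keep_filtered_p if `TRUE`, p-values are reported even for events
#'   failing the expression filter (they can never be significant).
#' @return data.frame with one row per event: `event_id`,
#'   `basal_mean_psi`, `stim_mean_psi`, `delta_psi`, `p_value`,
#'   `passes_expression`, `significant`, `pct_of_max`, `gate_flag`.
#' @export
differential_calls <- function(counts, alpha = 0.05, min_count = 5,
                               min_delta = 10,
                               method = c("binomial", "betabinomial"),
                               keep_filtered_p = FALSE) {
  method <- match.arg(method)
  validate_counts(counts)
  psi <- compute_psi(counts)
  ids <- unique(counts$event_id)
  pb <- psi[psi$condition == "basal", ]
  ps <- psi[psi$condition == "stimulated", ]
  basal_psi <- pb$mean_psi[match(ids, pb$event_id)]
  stim_psi <- ps$mean_psi[match(ids, ps$event_id)]
  # raw junction counts, summed per event x condition (see
  # test_differential_inclusion for why the test uses raw counts)
  xnorm <- counts$inc_count
  snorm <- counts$skip_count
  fid <- factor(counts$event_id, levels = ids)
  is_b <- counts$condition == "basal"
  sum_by <- function(v, sel) {
    out <- tapply(v[sel], fid[sel], sum)
    as.numeric(out)[match(ids, levels(fid))]
  }
  x1 <- sum_by(xnorm, is_b); s1 <- sum_by(snorm, is_b)
  x2 <- sum_by(xnorm, !is_b); s2 <- sum_by(snorm, !is_b)
  x1[is.na(x1)] <- 0; s1[is.na(s1)] <- 0
  x2[is.na(x2)] <- 0; s2[is.na(s2)] <- 0
  if (method == "binomial") {
    test <- binomial_lrt(x1, x1 + s1, x2, x2 + s2)
    pvals <- test$p_value
  } else {
    pvals <- vapply(ids, function(id) {
      sel_b <- counts$event_id == id & is_b
      sel_s <- counts$event_id == id & !is_b
      beta_binomial_lrt(xnorm[sel_b], xnorm[sel_b] + snorm[sel_b],
                        xnorm[sel_s], xnorm[sel_s] + snorm[sel_s])$p_value
    }, 0)
  }
  expressed <- filter_expressed(counts, min_count = min_count,
                                rule = "all_samples")
  passes <- ids %in% expressed
  if (!keep_filtered_p) pvals[!passes] <- NA_real_
  delta <- stim_psi - basal_psi
  calls <- data.frame(
    event_id = ids,
    basal_mean_psi = basal_psi,
    stim_mean_psi = stim_psi,
    delta_psi = delta,
    p_value = pvals,
    passes_expression = passes,
    stringsAsFactors = FALSE
  )
  calls$significant <- apply_significance_filters(calls, alpha = alpha,
                                                  min_delta = min_delta)
  defined <- !is.na(basal_psi) & !is.na(stim_psi)
  calls$pct_of_max <- NA_real_
  calls$pct_of_max[defined] <- pct_max_change(basal_psi[defined],
                                              stim_psi[defined])
  calls$gate_flag <- !is.na(basal_psi) & basal_psi > 20 & basal_psi < 80
  rownames(calls) <- NULL
  calls
}

#' Apply the significance filters to differential calls
#'
#' The three filters are applied with strict inequalities exactly as
#' conventionally stated: raw `p < alpha`, junction read count above
#' `min_count` in all samples (the `passes_expression` column, computed by
#' [differential_calls()]), and `|delta_psi| > min_delta` PSI.
#' A call at `p = alpha` or `|delta| = min_delta` is therefore *not*
#' significant.
#'
#' @param calls data.frame with `p_value`, `passes_expression`,
#'   `delta_psi`.
#' @param alpha p threshold (default 0.05).
#' @param min_delta PSI-difference threshold (default 10).
#' @return logical vector.
#' @export
apply_significance_filters <- function(calls, alpha = 0.05, min_delta = 10) {
  ok <- !is.na(calls$p_value) & calls$p_value < alpha &
    calls$passes_expression &
    !is.na(calls$delta_psi) & abs(calls$delta_psi) > min_delta
  ok
}

#' Percent of the maximum possible inclusion-level change
#'
#' An exon's PSI change is bounded by its basal level: an increase can be
#' at most `100 - basal`, a decrease at most `basal`. This statistic
#' expresses the observed change as a percentage of that ceiling: for
#' `delta = stim - basal >= 0` it is `100 * delta / (100 - basal)`, for
#' `delta < 0` it is `100 * delta / basal`. A basal PSI of 95 rising to 98
#' therefore scores 60%. Downstream comparisons conventionally gate on
#' `20 < basal < 80` (see `gate_flag` in [differential_calls()]) to avoid
#' tiny absolute changes producing extreme percentages; the statistic
#' itself is computed without the gate. Degenerate denominators
#' (`basal = 100` with a non-negative change, `basal = 0` with a negative
#' one) yield `NA`.
#'
#' @param basal_psi,stim_psi PSI values in `[0, 100]` (vectorised).
#' @return numeric vector in `[-100, 100]` (or `NA`).
#' @export
pct_max_change <- function(basal_psi, stim_psi) {
  if (any(basal_psi < 0 | basal_psi > 100 | stim_psi < 0 | stim_psi > 100,
          na.rm = TRUE)) {
    stop("PSI values must lie in [0, 100]")
  }
  delta <- stim_psi - basal_psi
  up <- delta >= 0
  denom <- ifelse(up, 100 - basal_psi, basal_psi)
  ifelse(denom > 0, 100 * delta / denom, NA_real_)
}

#' Basal-PSI gate for percent-of-maximum comparisons
#'
#' @param basal_psi numeric vector.
#' @param lower,upper open-interval bounds (defaults 20 and 80).
#' @return logical vector: `TRUE` where `lower < basal_psi < upper`.
#' @export
pct_max_gate <- function(basal_psi, lower = 20, upper = 80) {
  !is.na(basal_psi) & basal_psi > lower & basal_psi < upper
}
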