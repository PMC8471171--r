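# Differential promoter methylation and differential expression.
#
# The test is an empirical-Bayes moderated two-sample t: per-feature pooled
# variances are shrunk toward a common prior fitted by moment-matching the
# mean and variance of log s^2 against their digamma/trigamma expectations
# under a scaled-F sampling model, and the t statistic gains the prior
# degrees of freedom. Multiple testing is controlled by Benjamini-Hochberg.

#' Strand-oriented promoter windows
#'
#' Computes the promoter window of each gene as the interval from 1500 bp
#' upstream to 500 bp downstream of the transcription start site, oriented by
#' strand, in 0-based half-open coordinates: `[tss - 1500, tss + 500)` on the
#' plus strand and `[tss - 500, tss + 1500)` in genome coordinates on the
#' minus strand. Window length is always 2000 bp.
#'
#' @param annot data.frame with columns `gene_id, chrom, strand, tss`
#'   (0-based TSS).
#' @param upstream,downstream extent of the window relative to the TSS.
#' @return data.frame `gene_id, chrom, start, end, strand` (0-based, half-open).
#' @export
promoter_windows <- function(annot, upstream = 1500L, downstream = 500L) {
  need <- c("gene_id", "chrom", "strand", "tss")
  if (!all(need %in% names(annot)))
    stopf("annotation must have columns: %s", paste(need, collapse = ", "))
  if (!all(annot$strand %in% c("+", "-"))) stopf("strand must be '+' or '-'")
  plus <- annot$strand == "+"
  start <- ifelse(plus, annot$tss - upstream, annot$tss - downstream)
  end <- ifelse(plus, annot$tss + downstream, annot$tss + upstream)
  data.frame(gene_id = annot$gene_id, chrom = annot$chrom,
             start = as.integer(start), end = as.integer(end),
             strand = annot$strand, stringsAsFactors = FALSE)
}

#' Per-gene promoter mean methylation
#'
#' Averages CpG-probe beta values over the probes falling inside each gene's
#' strand-oriented promoter window (`-1500/+500` bp around the TSS, 0-based
#' half-open, so a probe exactly at the downstream window edge is excluded).
#' Genes with no in-window probe are omitted from the result and listed in
#' the `dropped` attribute.
#'
#' @param beta probe x sample matrix of beta values (rownames = probe ids).
#' @param probes data.frame `probe_id, chrom, pos` with 0-based positions.
#' @param annot gene annotation as in [promoter_windows()].
#' @return gene x sample matrix of promoter mean beta values, with attribute
#'   `dropped` naming the genes without probes.
#' @export
promoter_mean_beta <- function(beta, probes, annot) {
  if (is.null(rownames(beta))) stopf("'beta' must have probe ids as rownames")
  if (!all(rownames(beta) %in% probes$probe_id))
    stopf("every beta row must have a coordinate in 'probes'")
  rng <- if (any(is.finite(beta))) range(beta, na.rm = TRUE) else c(0, 1)
  if (rng[1] < 0 || rng[2] > 1) stopf("beta values must lie in [0, 1]")
  win <- promoter_windows(annot)

  probes <- probes[match(rownames(beta), probes$probe_id), ]
  probe_gr <- GenomicRanges::GRanges(probes$chrom,
                                     IRanges::IRanges(start = probes$pos + 1L, width = 1L))
  win_gr <- GenomicRanges::GRanges(win$chrom,
                                   IRanges::IRanges(start = win$start + 1L, end = win$end))
  ov <- GenomicRanges::findOverlaps(probe_gr, win_gr)
  if (length(ov) == 0L)
    stopf("no probe falls inside any promoter window")

  gene_of <- factor(win$gene_id[S4Vectors::subjectHits(ov)], levels = win$gene_id)
  rows <- S4Vectors::queryHits(ov)
  out <- vapply(seq_len(ncol(beta)), function(j) {
    as.numeric(tapply(beta[rows, j], gene_of, mean, na.rm = TRUE))
  }, numeric(nlevels(gene_of)))
  out <- matrix(out, nrow = nlevels(gene_of), ncol = ncol(beta),
                dimnames = list(levels(gene_of), colnames(beta)))
  present <- tabulate(gene_of, nbins = nlevels(gene_of)) > 0L
  dropped <- win$gene_id[!present]
  out <- out[present, , drop = FALSE]
  attr(out, "dropped") <- dropped
  out
}

# Newton inversion of the trigamma function; standard for fitting the prior
# degrees of freedom of a scaled-F variance model.
trigamma_inverse <- function(x) {
  if (x <= 0 || !is.finite(x)) return(NA_real_)
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2L)
    y <- y + dif
    if (abs(dif) / y < 1e-8) break
  }
  y
}

# Moment-matching fit of the variance prior (d0, s0^2) from log sample
# variances with d residual df each: Var(log s^2) = trigamma(d/2) +
# trigamma(d0/2), E(log s^2) = log s0^2 + digamma(d/2) - log(d/2) -
# digamma(d0/2) + log(d0/2).
fit_variance_prior <- function(s2, d) {
  ok <- is.finite(s2) & s2 > 0
  if (sum(ok) < 2L) return(list(d0 = 0, s02 = NA_real_))
  z <- log(s2[ok])
  evar <- var(z) - trigamma(d / 2)
  if (!is.finite(evar) || evar <= 0) {
    # variances less dispersed than pure sampling noise: no stable inversion
    return(list(d0 = 0, s02 = NA_real_))
  }
  d0 <- 2 * trigamma_inverse(evar)
  if (!is.finite(d0)) return(list(d0 = 0, s02 = NA_real_))
  s02 <- exp(mean(z) - digamma(d / 2) + log(d / 2) + digamma(d0 / 2) - log(d0 / 2))
  list(d0 = d0, s02 = s02)
}

#' Empirical-Bayes moderated two-sample t-test
#'
#' For each feature (row), computes the difference of group means and a
#' moderated t statistic in which the pooled within-group variance s^2 (with
#' d = n1 + n2 - 2 df) is shrunk toward a prior s0^2 carrying d0 prior df:
#' `s2_post = (d0 s0^2 + d s^2) / (d0 + d)`,
#' `t = effect / sqrt(s2_post (1/n1 + 1/n2))`, with two-sided p-values from a
#' t distribution on `d0 + d` df. The prior is fitted by moment-matching the
#' log sample variances; if the trigamma inversion is infeasible (e.g.
#' near-constant variances) the prior weight drops to d0 = 0 and the test
#' reduces to the ordinary pooled-variance t. If every feature has zero
#' variance, the ordinary t is used with a warning; zero-variance,
#' zero-effect features get t = 0 and p = 1.
#'
#' @param mat feature x sample numeric matrix.
#' @param groups two-level factor over the columns; the effect is
#'   `mean(second level) - mean(first level)`.
#' @param d0 optional override of the prior degrees of freedom (`0` forces
#'   the ordinary t; `Inf` forces a fixed-variance test at the prior).
#' @return data.frame `feature_id, effect, t_mod, p` with attributes `d0`,
#'   `s02` and `df_total`.
#' @export
moderated_t_test <- function(mat, groups, d0 = NULL) {
  mat <- as.matrix(mat)
  if (nrow(mat) < 2L) stopf("need >= 2 features to estimate the variance prior")
  groups <- assert_groups(groups, ncol(mat))
  g2 <- levels(groups)[2L]
  i1 <- groups != g2; i2 <- groups == g2
  n1 <- sum(i1); n2 <- sum(i2)
  d <- n1 + n2 - 2

  m1 <- rowMeans(mat[, i1, drop = FALSE])
  m2 <- rowMeans(mat[, i2, drop = FALSE])
  effect <- m2 - m1
  ss1 <- rowSums((mat[, i1, drop = FALSE] - m1)^2)
  ss2 <- rowSums((mat[, i2, drop = FALSE] - m2)^2)
  s2 <- (ss1 + ss2) / d

  if (all(s2 <= 0)) {
    warning("all features have zero within-group variance; ",
            "falling back to the ordinary t (degenerate)")
    prior <- list(d0 = 0, s02 = NA_real_)
  } else if (is.null(d0)) {
    prior <- fit_variance_prior(s2, d)
  } else {
    prior <- list(d0 = assert_number(d0, "d0", min = 0),
                  s02 = if (d0 > 0) fit_variance_prior(s2, d)$s02 else NA_real_)
    if (is.infinite(prior$d0) || (prior$d0 > 0 && !is.finite(prior$s02)))
      prior$s02 <- mean(s2[is.finite(s2) & s2 > 0])
  }
  d0v <- prior$d0
  s2_post <- if (is.infinite(d0v)) rep(prior$s02, length(s2)) else
    if (d0v > 0) (d0v * prior$s02 + d * s2) / (d0v + d) else s2
  df_total <- if (is.infinite(d0v)) Inf else d0v + d

  se <- sqrt(s2_post * (1 / n1 + 1 / n2))
  t_mod <- ifelse(se > 0, effect / se, ifelse(effect == 0, 0, sign(effect) * Inf))
  p <- 2 * pt(-abs(t_mod), df = df_total)
  p <- pmin(pmax(p, .Machine$double.xmin), 1)

  out <- data.frame(feature_id = rownames(mat) %||% sprintf("f%d", seq_len(nrow(mat))),
                    effect = effect, t_mod = t_mod, p = p,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "d0") <- d0v
  attr(out, "s02") <- prior$s02
  attr(out, "df_total") <- df_total
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: ranks p-values, multiplies by m/rank, applies the
#' cumulative minimum from the largest rank down, and caps at 1. Input values
#' outside `[0, 1]` are an error.
#'
#' @param pvals numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values, elementwise >= the input.
#' @export
bh_adjust <- function(pvals) {
  if (!is.numeric(pvals)) stopf("p-values must be numeric")
  if (any(!is.na(pvals) & (pvals < 0 | pvals > 1))) stopf("p-values must lie in [0, 1]")
  p.adjust(pvals, method = "BH")
}

finish_differential <- function(tab, p_cut, effect_cut) {
  tab$p_adj <- bh_adjust(tab$p)
  tab$significant <- tab$p_adj <= p_cut & abs(tab$effect) >= effect_cut
  class(tab) <- c("differential_table", "data.frame")
  attr(tab, "p_cut") <- p_cut
  attr(tab, "effect_cut") <- effect_cut
  tab
}

#' @export
print.differential_table <- function(x, ...) {
  cat(sprintf("Differential table: %d features, %d significant (p_adj <= %g, |effect| >= %g)\n",
              nrow(x), sum(x$significant), attr(x, "p_cut"), attr(x, "effect_cut")))
  print.data.frame(head(as.data.frame(x), 10L), ...)
  if (nrow(x) > 10L) cat(sprintf("... %d more rows\n", nrow(x) - 10L))
  invisible(x)
}

#' Differential promoter methylation
#'
#' Aggregates CpG beta values to promoter means ([promoter_mean_beta()]),
#' tests case vs control per gene with the moderated t
#' ([moderated_t_test()]; effect = delta beta, the case-minus-control
#' difference of mean promoter methylation), and adjusts by
#' Benjamini-Hochberg. A gene is significant when `p_adj <= p_cut` and
#' `|delta beta| >= effect_cut` (defaults 0.05 and 0.1).
#'
#' @param beta,probes,annot as in [promoter_mean_beta()].
#' @param groups two-level factor (control first, case second).
#' @param p_cut,effect_cut significance thresholds.
#' @return a `differential_table` with columns `feature_id, effect, t_mod, p,
#'   p_adj, significant`; genes without promoter probes are reported in the
#'   `dropped` attribute.
#' @export
diff_methylation <- function(beta, probes, annot, groups, p_cut = 0.05, effect_cut = 0.1) {
  pm <- promoter_mean_beta(beta, probes, annot)
  tab <- finish_differential(moderated_t_test(pm, groups), p_cut, effect_cut)
  attr(tab, "dropped") <- attr(pm, "dropped")
  tab
}

#' Differential expression
#'
#' Moderated t on a log2 expression matrix followed by Benjamini-Hochberg
#' adjustment; effect = log2 fold change (case minus control). A gene is
#' significant when `p_adj <= p_cut` and `|log2FC| >= effect_cut` (defaults
#' 0.01 and 0.5).
#'
#' @param expr gene x sample log2 expression matrix.
#' @param groups two-level factor (control first, case second).
#' @param p_cut,effect_cut significance thresholds.
#' @return a `differential_table`.
#' @export
diff_expression <- function(expr, groups, p_cut = 0.01, effect_cut = 0.5) {
  if (any(!is.finite(as.matrix(expr))))
    stopf("expression matrix must be finite (impute or drop missing values upstream)")
  finish_differential(moderated_t_test(expr, groups), p_cut, effect_cut)
}
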