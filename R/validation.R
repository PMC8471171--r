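# Quantification of validation assays: bisulfite clone methylation and
# conversion rate, delta-delta-Ct relative expression, ChIP percent-input,
# and dual-luciferase relative promoter activity.

#' Bisulfite clone call matrix
#'
#' @param calls clone x CpG-site matrix of binary methylation calls (1 =
#'   methylated).
#' @param converted,total per-clone counts of converted and total non-CpG
#'   cytosines (for the conversion-rate QC); optional.
#' @return a `clone_matrix` object.
#' @export
clone_matrix <- function(calls, converted = NULL, total = NULL) {
  calls <- as.matrix(calls)
  if (length(calls) == 0L) stopf("clone matrix must have >= 1 clone and >= 1 site")
  if (!all(calls %in% c(0L, 1L))) stopf("clone calls must be 0/1")
  if (!is.null(converted) || !is.null(total)) {
    if (is.null(converted) || is.null(total) ||
        length(converted) != nrow(calls) || length(total) != nrow(calls))
      stopf("'converted' and 'total' must both be given, one value per clone")
    if (any(converted > total) || any(converted < 0)) stopf("need 0 <= converted <= total")
  }
  structure(list(calls = calls, converted = converted, total = total),
            class = "clone_matrix")
}

#' @export
print.clone_matrix <- function(x, ...) {
  s <- clone_methylation_summary(x)
  cat(sprintf("Bisulfite clones: %d clones x %d CpG sites, overall methylation %.1f%%\n",
              nrow(x$calls), ncol(x$calls), s$overall_percent))
  invisible(x)
}

#' Summarise clone methylation per CpG and overall
#'
#' @param clones a [clone_matrix()].
#' @return list with `per_cpg_percent` (100 x column means) and
#'   `overall_percent` (100 x grand mean of all calls).
#' @export
clone_methylation_summary <- function(clones) {
  if (!inherits(clones, "clone_matrix")) stopf("need a clone_matrix object")
  list(per_cpg_percent = 100 * colMeans(clones$calls),
       overall_percent = 100 * mean(clones$calls))
}

#' Bisulfite conversion rate per clone
#'
#' The conversion rate of a clone is the percentage of its non-CpG cytosines
#' read as converted. Clones below the pass threshold are flagged; when
#' `exclude = TRUE` the returned `calls_passing` matrix retains only passing
#' clones (for re-summarising).
#'
#' @param clones a [clone_matrix()] carrying conversion counts.
#' @param pass_threshold minimum percent conversion to pass (default 95).
#' @param exclude drop failing clones from `calls_passing` (default FALSE).
#' @return list with `rate_percent` (per clone), `pass` (logical) and
#'   `calls_passing`.
#' @export
conversion_rate <- function(clones, pass_threshold = 95, exclude = FALSE) {
  if (!inherits(clones, "clone_matrix")) stopf("need a clone_matrix object")
  if (is.null(clones$converted)) stopf("clone matrix carries no conversion counts")
  if (any(clones$total == 0)) stopf("conversion rate undefined with 0 non-CpG cytosines")
  rate <- 100 * clones$converted / clones$total
  pass <- rate >= pass_threshold
  keep <- if (exclude) pass else rep(TRUE, length(pass))
  list(rate_percent = setNames(rate, rownames(clones$calls)),
       pass = setNames(pass, rownames(clones$calls)),
       calls_passing = clones$calls[keep, , drop = FALSE])
}

#' Relative expression by the delta-delta-Ct method
#'
#' Technical-replicate Ct values are combined per (condition, gene), then
#' `dCt = Ct_target - Ct_housekeeping` within each condition,
#' `ddCt = dCt_condition - dCt_reference`, and the reported fold change is
#' `2^(-ddCt)` of each non-reference condition versus the reference.
#'
#' @param ct long-format table with columns `condition, gene, ct` (and
#'   optionally `replicate`).
#' @param housekeeping name of the housekeeping gene (must be measured in
#'   every condition).
#' @param reference_condition the condition folds are expressed against.
#' @param combine how to combine replicate Cts: "mean" (default) or "median".
#' @return data.frame `condition, gene, dct, ddct, fold` for every
#'   non-housekeeping gene and non-reference condition.
#' @export
ddct <- function(ct, housekeeping, reference_condition, combine = c("mean", "median")) {
  combine <- match.arg(combine)
  need <- c("condition", "gene", "ct")
  if (!all(need %in% names(ct))) stopf("ct table needs columns: %s", paste(need, collapse = ", "))
  if (any(!is.finite(ct$ct) | ct$ct <= 0)) stopf("Ct values must be finite and > 0")
  fun <- if (combine == "mean") mean else median
  agg <- aggregate(ct$ct, by = list(condition = ct$condition, gene = ct$gene),
                   FUN = fun)
  names(agg)[3L] <- "ct"
  conditions <- unique(agg$condition)
  if (!reference_condition %in% conditions) stopf("reference condition '%s' absent", reference_condition)
  hk <- agg[agg$gene == housekeeping, ]
  if (nrow(hk) != length(conditions))
    stopf("housekeeping gene '%s' must be measured in every condition", housekeeping)
  hk_ct <- setNames(hk$ct, hk$condition)
  tg <- agg[agg$gene != housekeeping, ]
  tg$dct <- tg$ct - hk_ct[tg$condition]
  ref <- tg[tg$condition == reference_condition, ]
  ref_dct <- setNames(ref$dct, ref$gene)
  out <- tg[tg$condition != reference_condition, ]
  if (any(!out$gene %in% names(ref_dct)))
    stopf("every target gene must be measured in the reference condition")
  out$ddct <- out$dct - ref_dct[out$gene]
  out$fold <- 2^(-out$ddct)
  rownames(out) <- NULL
  out[, c("condition", "gene", "dct", "ddct", "fold")]
}

#' ChIP enrichment as percent of input
#'
#' The input Ct is first adjusted for the fraction of chromatin used as
#' input, `adjusted = ct_input - log2(1 / input_fraction)`, and the
#' enrichment reported as `100 * 2^(adjusted - ct_ip)`. With
#' `input_fraction = 1` this reduces to `100 * 2^(ct_input - ct_ip)`.
#' Replicate rows per (region, antibody) are averaged on the percent scale.
#'
#' @param chip table with columns `target_region, antibody, ct_ip, ct_input,
#'   input_fraction` (input_fraction in (0, 1]).
#' @return data.frame `target_region, antibody, percent_input` (mean over
#'   replicate rows).
#' @export
percent_input <- function(chip) {
  need <- c("target_region", "antibody", "ct_ip", "ct_input", "input_fraction")
  if (!all(need %in% names(chip))) stopf("chip table needs columns: %s", paste(need, collapse = ", "))
  if (any(chip$input_fraction <= 0 | chip$input_fraction > 1))
    stopf("input_fraction must lie in (0, 1]")
  adjusted <- chip$ct_input - log2(1 / chip$input_fraction)
  pct <- 100 * 2^(adjusted - chip$ct_ip)
  agg <- aggregate(pct, by = list(target_region = chip$target_region,
                                  antibody = chip$antibody), FUN = mean)
  names(agg)[3L] <- "percent_input"
  agg[order(agg$target_region, agg$antibody), , drop = FALSE]
}

#' Relative promoter activity from dual-luciferase readings
#'
#' Per well, activity is firefly / renilla luminescence; within each
#' condition the reported fold is the mean activity of the promoter
#' construct over the mean activity of the empty control construct.
#'
#' @param luc table with columns `construct` (values including
#'   `empty_control`), `condition`, `firefly`, `renilla` (> 0).
#' @param control_construct name of the empty/control construct.
#' @return data.frame `condition, construct, fold` for each non-control
#'   construct and condition.
#' @export
luciferase_relative <- function(luc, control_construct = "empty_control") {
  need <- c("construct", "condition", "firefly", "renilla")
  if (!all(need %in% names(luc))) stopf("luciferase table needs columns: %s", paste(need, collapse = ", "))
  if (any(luc$renilla <= 0)) stopf("renilla readings must be > 0")
  luc$activity <- luc$firefly / luc$renilla
  out <- list()
  for (cond in unique(luc$condition)) {
    sub <- luc[luc$condition == cond, ]
    ctrl <- sub$activity[sub$construct == control_construct]
    if (length(ctrl) == 0L)
      stopf("condition '%s' lacks the control construct '%s'", cond, control_construct)
    for (cons in setdiff(unique(sub$construct), control_construct)) {
      out[[length(out) + 1L]] <- data.frame(
        condition = cond, construct = cons,
        fold = mean(sub$activity[sub$construct == cons]) / mean(ctrl),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
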