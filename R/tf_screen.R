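# Scoring of protein-microarray incubations with methylated vs unmethylated
# DNA fragments: positivity thresholds from negative-control spots,
# methylation-preference ratios, protein-expression QC from terminal-tag
# stains, and ranking of methyl-preferring candidates.

SCAN_COLUMNS <- c("spot_id", "tf_id", "construct", "replicate",
                  "mfi_meth", "mfi_unmeth", "tag_n", "tag_c")

validate_scan <- function(scan) {
  missing_cols <- setdiff(SCAN_COLUMNS, names(scan))
  if (length(missing_cols) > 0)
    stopf("scan table lacks columns: %s", paste(missing_cols, collapse = ", "))
  num <- c("mfi_meth", "mfi_unmeth", "tag_n", "tag_c")
  if (any(vapply(scan[num], function(x) any(!is.finite(x) | x < 0), logical(1))))
    stopf("MFI and tag values must be finite and >= 0")
  if (sum(scan$construct == "negative_control") < 2L)
    stopf("scan must contain >= 2 negative-control spots")
  scan
}

#' Positivity threshold from negative-control spots
#'
#' The threshold for a positive fluorescence signal is the mean of the
#' negative-control MFIs plus four sample standard deviations.
#'
#' @param neg_mfis numeric vector of negative-control MFIs (>= 2 values).
#' @param n_sd number of standard deviations above the mean (default 4).
#' @return the threshold, a single fluorescence value (>= mean of inputs).
#' @export
positivity_threshold <- function(neg_mfis, n_sd = 4) {
  if (length(neg_mfis) < 2L)
    stopf("need >= 2 negative-control values (sample SD is undefined otherwise)")
  if (any(!is.finite(neg_mfis))) stopf("negative-control MFIs must be finite")
  mean(neg_mfis) + n_sd * sd(neg_mfis)
}

#' Screen a TF microarray for methylation-preferring binders
#'
#' Per TF, replicate spots are collapsed by the median in every channel.
#' Positivity thresholds are computed per channel (methylated, unmethylated,
#' and both tag stains) from the negative-control spots as mean + 4 SD. The
#' methylation-preference ratio is computed after flooring each binding
#' channel at its threshold, which keeps ratios finite and conservative when
#' the weaker channel is below background. Classes:
#' \describe{
#'   \item{not_expressed}{both tag-stain signals below `expression_floor`
#'     times their thresholds;}
#'   \item{non_binder}{expressed but neither binding channel positive;}
#'   \item{methyl_preferring}{methylated channel positive and
#'     meth/unmeth ratio >= `ratio_cutoff`;}
#'   \item{unmethyl_preferring}{the symmetric case;}
#'   \item{non_discriminating}{positive but below the ratio cutoff either way.}
#' }
#' Methyl-preferring TFs are ranked by descending ratio, ties broken by
#' descending methylated-channel MFI, then tf_id.
#'
#' @param scan spot table with columns `spot_id, tf_id, construct, replicate,
#'   mfi_meth, mfi_unmeth, tag_n, tag_c`; negative-control spots have
#'   `construct == "negative_control"`.
#' @param ratio_cutoff minimum preference ratio (default 2).
#' @param expression_floor fraction of the tag threshold a tag signal must
#'   reach for the protein to count as expressed (default 1).
#' @param top_k how many methyl-preferring TFs the `top` attribute reports
#'   (default 15).
#' @return a `screen_result` data.frame, one row per TF: `tf_id, construct,
#'   mfi_meth, mfi_unmeth, tag_n, tag_c, positive_meth, positive_unmeth,
#'   ratio_meth_over_unmeth, class, rank`; attributes `thresholds` (named
#'   vector for all four channels) and `top` (the top_k methyl-preferring rows).
#' @export
tf_screen <- function(scan, ratio_cutoff = 2, expression_floor = 1, top_k = 15L) {
  scan <- validate_scan(scan)
  ratio_cutoff <- assert_number(ratio_cutoff, "ratio_cutoff", min = 1)
  expression_floor <- assert_number(expression_floor, "expression_floor", min = 0)
  top_k <- assert_count(top_k, "top_k")

  neg <- scan[scan$construct == "negative_control", ]
  thr <- c(meth = positivity_threshold(neg$mfi_meth),
           unmeth = positivity_threshold(neg$mfi_unmeth),
           tag_n = positivity_threshold(neg$tag_n),
           tag_c = positivity_threshold(neg$tag_c))

  tf <- scan[scan$construct != "negative_control", ]
  agg <- function(v) tapply(v, tf$tf_id, median)
  res <- data.frame(tf_id = sort(unique(tf$tf_id)), stringsAsFactors = FALSE)
  res$construct <- tapply(tf$construct, tf$tf_id, function(x) x[1L])[res$tf_id]
  for (col in c("mfi_meth", "mfi_unmeth", "tag_n", "tag_c"))
    res[[col]] <- as.numeric(agg(tf[[col]])[res$tf_id])

  res$positive_meth <- res$mfi_meth > thr[["meth"]]
  res$positive_unmeth <- res$mfi_unmeth > thr[["unmeth"]]
  floored_m <- pmax(res$mfi_meth, thr[["meth"]])
  floored_u <- pmax(res$mfi_unmeth, thr[["unmeth"]])
  res$ratio_meth_over_unmeth <- floored_m / floored_u

  expressed <- res$tag_n >= expression_floor * thr[["tag_n"]] |
    res$tag_c >= expression_floor * thr[["tag_c"]]
  cls <- rep("non_discriminating", nrow(res))
  cls[res$positive_meth & res$ratio_meth_over_unmeth >= ratio_cutoff] <- "methyl_preferring"
  cls[res$positive_unmeth & 1 / res$ratio_meth_over_unmeth >= ratio_cutoff] <- "unmethyl_preferring"
  cls[!res$positive_meth & !res$positive_unmeth] <- "non_binder"
  cls[!expressed] <- "not_expressed"
  res$class <- cls

  res$rank <- NA_integer_
  mp <- which(res$class == "methyl_preferring")
  if (length(mp) > 0) {
    ord <- mp[order(-res$ratio_meth_over_unmeth[mp], -res$mfi_meth[mp], res$tf_id[mp])]
    res$rank[ord] <- seq_along(ord)
  }

  class(res) <- c("screen_result", "data.frame")
  attr(res, "thresholds") <- thr
  attr(res, "ratio_cutoff") <- ratio_cutoff
  attr(res, "top") <- res[!is.na(res$rank) & res$rank <= top_k, , drop = FALSE][
    order(res$rank[!is.na(res$rank) & res$rank <= top_k]), , drop = FALSE]
  res
}

#' @export
print.screen_result <- function(x, ...) {
  cat(sprintf("TF screen: %d TFs; classes: %s\n", nrow(x),
              paste(sprintf("%s=%d", names(table(x$class)), table(x$class)), collapse = ", ")))
  top <- attr(x, "top")
  if (nrow(top) > 0) {
    cat("Top methyl-preferring TFs:\n")
    print.data.frame(top[, c("tf_id", "mfi_meth", "mfi_unmeth",
                             "ratio_meth_over_unmeth", "rank")], row.names = FALSE, ...)
  }
  invisible(x)
}

#' Protein-expression QC from terminal-tag stains
#'
#' A spotted protein counts as expressed full length when both its N- and
#' C-terminal tag-stain signals exceed their negative-control-derived
#' positivity thresholds (a missing C-terminal signal indicates a truncated
#' product).
#'
#' @param scan spot table as in [tf_screen()].
#' @return data.frame `tf_id, tag_n, tag_c, expressed_full_length`.
#' @export
expression_qc <- function(scan) {
  scan <- validate_scan(scan)
  neg <- scan[scan$construct == "negative_control", ]
  thr_n <- positivity_threshold(neg$tag_n)
  thr_c <- positivity_threshold(neg$tag_c)
  tf <- scan[scan$construct != "negative_control", ]
  ids <- sort(unique(tf$tf_id))
  tag_n <- as.numeric(tapply(tf$tag_n, tf$tf_id, median)[ids])
  tag_c <- as.numeric(tapply(tf$tag_c, tf$tf_id, median)[ids])
  data.frame(tf_id = ids, tag_n = tag_n, tag_c = tag_c,
             expressed_full_length = tag_n > thr_n & tag_c > thr_c,
             stringsAsFactors = FALSE)
}
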