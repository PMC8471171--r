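# Joint classification of promoter-methylation and expression changes into
# the four quadrants (hyper/hypo methylation x up/down expression), and
# nomination of candidate direct targets from knockdown panels.

#' Classify genes into methylation/expression quadrants
#'
#' Inner-joins a differential-methylation and a differential-expression table
#' on gene id and assigns each gene to a quadrant when, and only when, it is
#' significant in both layers: `hyper_up` (delta beta > 0, log2FC > 0),
#' `hyper_down` (> 0, < 0), `hypo_up` (< 0, > 0), `hypo_down` (< 0, < 0).
#' Genes failing either significance call — or with a delta beta of exactly 0,
#' whose direction is undefined — get quadrant `none`.
#'
#' @param meth a `differential_table` from [diff_methylation()] (effect =
#'   delta beta).
#' @param expr a `differential_table` from [diff_expression()] (effect =
#'   log2FC).
#' @return list with `records` (data.frame `gene_id, delta_beta, log2fc,
#'   meth_significant, expr_significant, quadrant`) and `counts` (named
#'   vector `total, hyper_up, hyper_down, hypo_up, hypo_down`, where `total`
#'   counts genes in any quadrant). An empty join warns and returns zero rows.
#' @export
classify_quadrants <- function(meth, expr) {
  shared <- intersect(meth$feature_id, expr$feature_id)
  if (length(shared) == 0L) {
    warning("no shared gene ids between the methylation and expression tables")
    records <- data.frame(gene_id = character(0), delta_beta = numeric(0),
                          log2fc = numeric(0), meth_significant = logical(0),
                          expr_significant = logical(0), quadrant = character(0),
                          stringsAsFactors = FALSE)
    counts <- setNames(rep(0L, 5L), c("total", QUADRANTS))
    return(list(records = records, counts = counts))
  }
  im <- match(shared, meth$feature_id)
  ie <- match(shared, expr$feature_id)
  db <- meth$effect[im]
  fc <- expr$effect[ie]
  ms <- meth$significant[im]
  es <- expr$significant[ie]
  quadrant <- rep("none", length(shared))
  both <- ms & es & db != 0 & fc != 0
  quadrant[both & db > 0 & fc > 0] <- "hyper_up"
  quadrant[both & db > 0 & fc < 0] <- "hyper_down"
  quadrant[both & db < 0 & fc > 0] <- "hypo_up"
  quadrant[both & db < 0 & fc < 0] <- "hypo_down"
  records <- data.frame(gene_id = shared, delta_beta = db, log2fc = fc,
                        meth_significant = ms, expr_significant = es,
                        quadrant = quadrant, stringsAsFactors = FALSE)
  counts <- c(total = sum(quadrant != "none"),
              vapply(QUADRANTS, function(q) sum(quadrant == q), integer(1)))
  list(records = records, counts = counts)
}

#' Genes consistently down-regulated across knockdown panels
#'
#' Intersects, over one differential table per cell line (knockdown vs
#' control), the sets of genes that are significant with a negative log2 fold
#' change. With a single panel this is just that panel's down set.
#'
#' @param panels list of `differential_table`s (>= 1), one per cell line.
#' @return character vector of consistently down-regulated gene ids.
#' @export
knockdown_intersection <- function(panels) {
  if (!is.list(panels) || length(panels) == 0L) stopf("'panels' must be a non-empty list")
  down_sets <- lapply(panels, function(tab) {
    tab$feature_id[tab$significant & tab$effect < 0]
  })
  sort(Reduce(intersect, down_sets))
}

#' Candidate direct targets: consistently down AND promoter-hypermethylated
#'
#' Filters a consistently-down gene set to the genes whose promoters are
#' significantly hypermethylated (delta beta > 0) in the differential
#' methylation table — the pattern expected of genes directly activated by a
#' methylation-preferring transcription factor.
#'
#' @param consistent_down character vector from [knockdown_intersection()].
#' @param meth a `differential_table` from [diff_methylation()].
#' @return character vector of candidate gene ids.
#' @export
candidate_direct_targets <- function(consistent_down, meth) {
  hyper <- meth$feature_id[meth$significant & meth$effect > 0]
  sort(intersect(consistent_down, hyper))
}
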