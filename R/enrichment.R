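# Overrepresentation and gene set enrichment.
#
# fisher_overrep: one-sided (overrepresentation) Fisher exact test per set,
# i.e. the hypergeometric upper tail of the 2x2 study/set table, with BH
# control. gsea: weighted Kolmogorov-Smirnov running-sum enrichment with a
# gene-label permutation null, Broad-style NES and sign-pooled FDR q.

#' Fisher's exact overrepresentation analysis
#'
#' For every gene set, builds the 2x2 table of study/non-study against
#' set/non-set membership within the universe and computes the one-sided
#' Fisher exact p-value for overrepresentation (the hypergeometric
#' probability of at least the observed overlap), then adjusts across sets
#' by Benjamini-Hochberg.
#'
#' @param study character vector of genes of interest (must be contained in
#'   the universe).
#' @param universe character vector of all scorable genes.
#' @param collection named list of gene sets (character vectors); members
#'   outside the universe are ignored, sets with no member in the universe
#'   are dropped.
#' @param p_cut significance threshold on the adjusted p (default 0.05).
#' @return data.frame `set_id, overlap, set_size, study_size, universe_size,
#'   odds_ratio, p, p_adj, significant`, sorted by p.
#' @export
fisher_overrep <- function(study, universe, collection, p_cut = 0.05) {
  study <- unique(as.character(study))
  universe <- unique(as.character(universe))
  if (!all(study %in% universe)) stopf("'study' must be a subset of 'universe'")
  if (!is.list(collection) || is.null(names(collection)))
    stopf("'collection' must be a named list of gene sets")
  N <- length(universe)
  n <- length(study)
  rows <- lapply(names(collection), function(id) {
    members <- intersect(unique(collection[[id]]), universe)
    K <- length(members)
    if (K == 0L) return(NULL)
    k <- length(intersect(study, members))
    # hypergeometric upper tail P(X >= k) = one-sided Fisher p
    p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    a <- k; b <- n - k; c2 <- K - k; d2 <- N - K - b
    or <- (a * d2) / max(b * c2, .Machine$double.xmin)
    data.frame(set_id = id, overlap = k, set_size = K, study_size = n,
               universe_size = N, odds_ratio = or, p = p,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) stopf("no gene set overlaps the universe")
  out <- do.call(rbind, rows)
  out$p_adj <- bh_adjust(out$p)
  out$significant <- out$p_adj <= p_cut
  out <- out[order(out$p), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Weighted KS running-sum enrichment score of one set against a ranked list.
# scores must be sorted in the ranking order; hit weights are |score|^weight
# normalised to 1, misses decrement 1/(N - Nh).
running_es <- function(in_set, scores, weight) {
  N <- length(scores)
  nh <- sum(in_set)
  if (nh == 0L || nh == N) return(NA_real_)
  w <- abs(scores)^weight
  hit_norm <- sum(w[in_set])
  if (hit_norm == 0) {
    # all hit scores zero: fall back to unweighted increments
    inc <- ifelse(in_set, 1 / nh, -1 / (N - nh))
  } else {
    inc <- ifelse(in_set, w / hit_norm, -1 / (N - nh))
  }
  rs <- cumsum(inc)
  # extremum = running-sum value of largest magnitude; on (near-)ties the
  # earliest position wins, which keeps the sign well defined
  m <- max(abs(rs))
  rs[which(abs(rs) >= m - 1e-12)[1L]]
}

#' Gene set enrichment analysis (weighted running-sum statistic)
#'
#' Ranks genes by score (decreasing), computes per set the weighted
#' Kolmogorov-Smirnov running-sum enrichment score (hit increments
#' proportional to |score|^weight, miss decrements 1/(N - Nh); ES is the
#' running-sum extremum), and calibrates it against a gene-label permutation
#' null: for each permutation the set labels are reassigned to a random gene
#' subset of the same size. NES = ES divided by the mean |null ES| of the
#' same sign; p is the (+1-corrected) fraction of same-sign null ES at least
#' as extreme; q is a Broad-style FDR computed within the positive and
#' negative pools from the pooled null NES distribution. A set is significant
#' when NES > 1, p <= 0.05 and q <= 0.25.
#'
#' @param ranked named numeric vector: gene-level scores (e.g. moderated t
#'   from a knockdown-vs-control fit); names are unique gene ids.
#' @param collection named list of gene sets; sets with no member in the
#'   ranked list are skipped with a warning.
#' @param weight exponent on |score| for hit increments (default 1; 0 gives
#'   the classic unweighted KS statistic).
#' @param n_perm number of label permutations (default 1000).
#' @param seed integer RNG seed for the permutations.
#' @return data.frame `set_id, size, es, nes, p, q, direction, significant`
#'   where direction is `enriched_in_control` for positive ES (set members
#'   concentrate at the top of the ranking) and `enriched_in_kd` otherwise.
#' @export
gsea <- function(ranked, collection, weight = 1, n_perm = 1000L, seed) {
  if (is.null(names(ranked)) || anyDuplicated(names(ranked)))
    stopf("'ranked' must be a named vector with unique gene ids")
  if (!is.list(collection) || is.null(names(collection)))
    stopf("'collection' must be a named list of gene sets")
  weight <- assert_number(weight, "weight", min = 0)
  n_perm <- assert_count(n_perm, "n_perm")
  seed <- assert_count(seed, "seed", min = 0L)

  ord <- order(ranked, decreasing = TRUE)
  scores <- as.numeric(ranked[ord])
  genes <- names(ranked)[ord]
  N <- length(genes)

  keep <- names(collection)[vapply(collection, function(s) any(s %in% genes), logical(1))]
  skipped <- setdiff(names(collection), keep)
  if (length(skipped) > 0)
    warning(sprintf("skipping %d set(s) with no member in the ranked list: %s",
                    length(skipped), paste(skipped, collapse = ", ")))
  if (length(keep) == 0L) stopf("no gene set overlaps the ranked list")

  set.seed(seed)
  sizes <- vapply(keep, function(id) sum(genes %in% collection[[id]]), integer(1))
  es <- vapply(keep, function(id) running_es(genes %in% collection[[id]], scores, weight),
               numeric(1))

  # one permutation null per distinct set size
  null_by_size <- list()
  for (k in sort(unique(sizes))) {
    nes_null <- vapply(seq_len(n_perm), function(i) {
      in_set <- logical(N)
      in_set[sample.int(N, k)] <- TRUE
      running_es(in_set, scores, weight)
    }, numeric(1))
    null_by_size[[as.character(k)]] <- nes_null
  }

  nes <- p <- numeric(length(keep))
  null_nes_pool <- list()
  for (i in seq_along(keep)) {
    nulls <- null_by_size[[as.character(sizes[i])]]
    same <- nulls[sign(nulls) == sign(es[i]) & nulls != 0]
    mean_abs <- if (length(same) > 0) mean(abs(same)) else mean(abs(nulls))
    nes[i] <- es[i] / mean_abs
    p[i] <- (1 + sum(abs(same) >= abs(es[i]))) / (length(same) + 1)
    pos <- nulls[nulls > 0]; neg <- nulls[nulls < 0]
    null_nes_pool[[i]] <- c(if (length(pos) > 0) pos / mean(pos) else numeric(0),
                            if (length(neg) > 0) neg / mean(abs(neg)) else numeric(0))
  }
  pool <- unlist(null_nes_pool)

  q <- vapply(seq_along(keep), function(i) {
    if (nes[i] >= 0) {
      num <- mean(pool[pool >= 0] >= nes[i])
      den <- mean(nes[nes >= 0] >= nes[i])
    } else {
      num <- mean(pool[pool < 0] <= nes[i])
      den <- mean(nes[nes < 0] <= nes[i])
    }
    if (!is.finite(den) || den == 0) return(1)
    min(1, num / den)
  }, numeric(1))

  out <- data.frame(set_id = keep, size = sizes, es = es, nes = nes, p = p, q = q,
                    direction = ifelse(es >= 0, "enriched_in_control", "enriched_in_kd"),
                    significant = nes > 1 & p <= 0.05 & q <= 0.25,
                    stringsAsFactors = FALSE)
  out <- out[order(-abs(out$nes)), , drop = FALSE]
  rownames(out) <- NULL
  out
}
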