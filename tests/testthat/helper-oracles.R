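# Independent brute-force oracles, deliberately written as direct loops over
# definitions so they share no code path with the package implementations.

# Benjamini-Hochberg step-up by the formula: p * m / rank, cumulative min
# from the largest rank down, capped at 1.
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  cummin_val <- 1
  for (i in m:1) {
    val <- min(1, p[o[i]] * m / i)
    cummin_val <- min(cummin_val, val)
    adj[o[i]] <- cummin_val
  }
  adj
}

# ordinary pooled-variance two-sample t and its two-sided p
pooled_t_brute <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  sp2 <- (sum((x - mean(x))^2) + sum((y - mean(y))^2)) / (n1 + n2 - 2)
  tt <- (mean(y) - mean(x)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = tt, p = 2 * pt(-abs(tt), df = n1 + n2 - 2))
}

# hypergeometric upper tail P(overlap >= k) by direct summation
hyper_tail_brute <- function(k, set_size, study_size, universe_size) {
  upper <- min(set_size, study_size)
  if (k > upper) return(0)
  sum(vapply(k:upper, function(i)
    dhyper(i, set_size, universe_size - set_size, study_size), numeric(1)))
}

# GSEA running-sum enrichment score by a direct element-by-element loop
es_brute <- function(genes_ranked, scores_ranked, set_members, weight) {
  N <- length(genes_ranked)
  hits <- genes_ranked %in% set_members
  nh <- sum(hits)
  denom_hit <- sum(abs(scores_ranked[hits])^weight)
  rs <- 0; best <- 0
  for (i in seq_len(N)) {
    if (hits[i]) {
      rs <- rs + if (denom_hit > 0) abs(scores_ranked[i])^weight / denom_hit else 1 / nh
    } else {
      rs <- rs - 1 / (N - nh)
    }
    # earliest extremum wins on near-ties (matching the stated convention)
    if (abs(rs) > abs(best) + 1e-12) best <- rs
  }
  best
}

# brute-force PWM window score: sum of log2(emission / background) letter by
# letter over a character vector window
pwm_score_brute <- function(window_chars, prob, background) {
  s <- 0
  for (j in seq_along(window_chars))
    s <- s + log2(prob[window_chars[j], j] / background[[window_chars[j]]])
  s
}

revcomp_chars <- function(chars) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", M = "G")
  rev(unname(comp[chars]))
}

# small random differential matrix with groups, for oracle comparisons
sim_toy_matrix <- function(n_feat, n_per_group, seed, effect = 0, sd = 1) {
  set.seed(seed)
  mat <- matrix(rnorm(n_feat * 2 * n_per_group, sd = sd), n_feat)
  mat[, (n_per_group + 1):(2 * n_per_group)] <-
    mat[, (n_per_group + 1):(2 * n_per_group)] + effect
  rownames(mat) <- sprintf("f%03d", seq_len(n_feat))
  colnames(mat) <- sprintf("s%02d", seq_len(2 * n_per_group))
  list(mat = mat,
       groups = factor(rep(c("control", "case"), each = n_per_group),
                       levels = c("control", "case")))
}

# minimal TF-array scan table builder for hand-crafted screen cases
toy_scan <- function(tf_rows, neg_mfi = c(90, 95, 100, 105, 110)) {
  tf <- do.call(rbind, lapply(names(tf_rows), function(id) {
    v <- tf_rows[[id]]
    data.frame(spot_id = paste0("s_", id), tf_id = id, construct = "dbd",
               replicate = 1L, mfi_meth = v[["meth"]], mfi_unmeth = v[["unmeth"]],
               tag_n = v[["tag_n"]], tag_c = v[["tag_c"]],
               stringsAsFactors = FALSE)
  }))
  neg <- data.frame(spot_id = sprintf("neg%d", seq_along(neg_mfi)), tf_id = "NEG",
                    construct = "negative_control", replicate = 1L,
                    mfi_meth = neg_mfi, mfi_unmeth = neg_mfi,
                    tag_n = neg_mfi, tag_c = neg_mfi, stringsAsFactors = FALSE)
  rbind(tf, neg)
}
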