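# Promoter aggregation, the moderated t, BH adjustment, and the
# significance wrappers.

test_that("promoter mean beta averages in-window probes with half-open edges", {
  annot <- data.frame(gene_id = "g1", chrom = "chr1", strand = "+", tss = 2000L)
  probes <- data.frame(probe_id = c("p1", "p2", "p3", "edge"),
                       chrom = "chr1",
                       pos = c(600L, 1500L, 2400L, 2500L))  # edge sits at tss+500
  beta <- matrix(c(0.2, 0.4, 0.6, 0.9,
                   0.5, 0.5, 0.5, 0.9), ncol = 2,
                 dimnames = list(probes$probe_id, c("s1", "s2")))
  pm <- promoter_mean_beta(beta, probes, annot)
  expect_equal(unname(pm["g1", "s1"]), 0.4)   # edge probe excluded (half-open)
  expect_equal(unname(pm["g1", "s2"]), 0.5)

  # brute-force window membership agrees with the overlap computation
  win <- promoter_windows(annot)
  manual <- probes$pos >= win$start & probes$pos < win$end
  expect_equal(unname(pm["g1", "s1"]), mean(beta[manual, "s1"]))

  # output bounded by min/max of in-window probes
  expect_gte(pm["g1", "s1"], min(beta[manual, "s1"]))
  expect_lte(pm["g1", "s1"], max(beta[manual, "s1"]))
})

test_that("promoter windows are strand-oriented and genes without probes are dropped", {
  annot <- data.frame(gene_id = c("plus", "minus", "empty"), chrom = "chr1",
                      strand = c("+", "-", "+"), tss = c(2000L, 2000L, 99000L))
  win <- promoter_windows(annot)
  expect_equal(win$start[win$gene_id == "plus"], 500L)
  expect_equal(win$end[win$gene_id == "plus"], 2500L)
  expect_equal(win$start[win$gene_id == "minus"], 1500L)
  expect_equal(win$end[win$gene_id == "minus"], 3500L)

  probes <- data.frame(probe_id = c("a", "b"), chrom = "chr1", pos = c(600L, 3000L))
  beta <- matrix(c(0.3, 0.7), ncol = 1, dimnames = list(c("a", "b"), "s1"))
  pm <- promoter_mean_beta(beta, probes, annot)
  expect_equal(attr(pm, "dropped"), "empty")
  expect_equal(rownames(pm), c("plus", "minus"))

  far <- data.frame(gene_id = "g", chrom = "chr1", strand = "+", tss = 99000L)
  expect_error(promoter_mean_beta(beta, probes, far), "no probe")
})

test_that("moderated t reduces to the ordinary pooled t at d0 = 0", {
  toy <- sim_toy_matrix(6, 3, seed = 21, effect = 0.8)
  res <- moderated_t_test(toy$mat, toy$groups, d0 = 0)
  for (i in seq_len(nrow(toy$mat))) {
    ref <- pooled_t_brute(toy$mat[i, 1:3], toy$mat[i, 4:6])
    expect_equal(res$t_mod[i], ref$t, tolerance = 1e-12)
    expect_equal(res$p[i], ref$p, tolerance = 1e-12)
  }
  expect_equal(res$effect, rowMeans(toy$mat[, 4:6]) - rowMeans(toy$mat[, 1:3]),
               ignore_attr = TRUE)
})

test_that("fitted prior and moderated t agree with the limma oracle", {
  skip_if_not_installed("limma")
  set.seed(7)
  n <- 300
  mat <- matrix(rnorm(n * 10, sd = rep(sqrt(1 / rgamma(n, 4, 4)), 10)), n, 10)
  mat[1:30, 6:10] <- mat[1:30, 6:10] + 1
  rownames(mat) <- sprintf("f%03d", seq_len(n))
  groups <- factor(rep(c("control", "case"), each = 5), levels = c("control", "case"))
  mine <- moderated_t_test(mat, groups)
  fit <- limma::eBayes(limma::lmFit(mat, stats::model.matrix(~groups)))
  expect_equal(attr(mine, "d0"), unname(fit$df.prior), tolerance = 1e-8)
  expect_equal(attr(mine, "s02"), unname(fit$s2.prior), tolerance = 1e-8)
  expect_equal(mine$t_mod, unname(fit$t[, 2]), tolerance = 1e-10)
  expect_equal(mine$p, unname(fit$p.value[, 2]), tolerance = 1e-10)
})

test_that("posterior variance interpolates monotonically between s2 and the prior", {
  toy <- sim_toy_matrix(50, 4, seed = 31)
  t_ord <- moderated_t_test(toy$mat, toy$groups, d0 = 0)
  t_fit <- moderated_t_test(toy$mat, toy$groups)
  t_inf <- moderated_t_test(toy$mat, toy$groups, d0 = Inf)
  # recover s2_post from t: s2_post = (effect / t)^2 / (1/n1 + 1/n2)
  s2_of <- function(res) (res$effect / res$t_mod)^2 / (1 / 4 + 1 / 4)
  s2 <- s2_of(t_ord); s2p <- s2_of(t_fit); s20 <- s2_of(t_inf)
  expect_true(all(s2p >= pmin(s2, s20) - 1e-12))
  expect_true(all(s2p <= pmax(s2, s20) + 1e-12))
  expect_true(is.infinite(attr(t_inf, "df_total")))
})

test_that("degenerate inputs: identical groups, constant features, all-zero variance", {
  mat <- matrix(rep(c(1, 2, 3, 4), each = 6), nrow = 4, byrow = TRUE,
                dimnames = list(paste0("f", 1:4), paste0("s", 1:6)))
  groups <- factor(rep(c("control", "case"), each = 3), levels = c("control", "case"))
  expect_warning(res <- moderated_t_test(mat, groups), "zero within-group variance")
  expect_equal(res$effect, rep(0, 4))
  expect_equal(res$t_mod, rep(0, 4))
  expect_equal(res$p, rep(1, 4))

  # identical case/control values per feature (with variance): effect 0, p 1
  toy <- sim_toy_matrix(5, 3, seed = 41)
  same <- cbind(toy$mat[, 1:3], toy$mat[, 1:3])
  colnames(same) <- paste0("s", 1:6)
  res2 <- moderated_t_test(same, groups)
  expect_equal(res2$effect, rep(0, 5))
  expect_equal(res2$p, rep(1, 5))
})

test_that("moderated t holds its nominal type-I error on null features", {
  toy <- sim_toy_matrix(500, 5, seed = 99, effect = 0)
  res <- moderated_t_test(toy$mat, toy$groups)
  rate <- mean(res$p <= 0.05)
  margin <- 3 * sqrt(0.05 * 0.95 / 500)       # ~0.029
  expect_lt(abs(rate - 0.05), margin)
})

test_that("bh_adjust matches the step-up formula and brute force on random lists", {
  expect_equal(bh_adjust(0.05), 0.05)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(13)
  for (i in 1:20) {
    p <- runif(sample(1:50, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, bh_brute(p), tolerance = 1e-12)
    expect_true(all(adj >= p))
    expect_true(all(adj <= 1))
  }
})

test_that("significance flags follow the stated thresholds exactly", {
  # strong p-value but |effect| below the cutoff is not significant
  toy <- sim_toy_matrix(60, 20, seed = 55, effect = 0.4, sd = 0.1)
  tab <- diff_expression(toy$mat, toy$groups)      # p_adj tiny, |log2FC| = 0.4 < 0.5
  expect_true(all(tab$p_adj < 1e-6))
  expect_false(any(tab$significant))
  tab2 <- diff_expression(toy$mat, toy$groups, effect_cut = 0.3)
  expect_true(all(tab2$significant))
  # flags reproducible from (effect, p_adj) and the thresholds alone
  expect_equal(tab2$significant, tab2$p_adj <= 0.01 & abs(tab2$effect) >= 0.3)
  # p_adj >= p and monotone in the rank of p
  expect_true(all(tab$p_adj >= tab$p))
  o <- order(tab$p)
  expect_true(all(diff(tab$p_adj[o]) >= -1e-15))
})

test_that("differential methylation recovers planted promoter effects and respects the delta-beta cutoff", {
  sim <- gen_methylome_transcriptome(sim_config(n_genes = 100L, seed = 17L))
  tab <- diff_methylation(sim$beta, sim$probes, sim$annot, sim$groups)
  hyper <- sim$truth$gene_id[sim$truth$planted_delta_beta > 0]
  called <- tab$feature_id[tab$significant & tab$effect > 0]
  expect_gte(mean(hyper %in% called), 0.9)

  # sub-cutoff planted effect (delta beta = 0.09) is never significant,
  # regardless of p
  sim2 <- gen_methylome_transcriptome(
    sim_config(n_genes = 100L, delta_beta_effect = 0.09, beta_noise_sd = 0.1,
               n_per_group = 20L, seed = 18L))
  tab2 <- diff_methylation(sim2$beta, sim2$probes, sim2$annot, sim2$groups)
  planted <- sim2$truth$gene_id[sim2$truth$planted_delta_beta != 0]
  expect_false(any(tab2$significant[tab2$feature_id %in% planted]))

  # identical groups: nothing significant
  null_sim <- gen_methylome_transcriptome(
    sim_config(n_genes = 100L, delta_beta_effect = 0, log2fc_effect = 0, seed = 19L))
  tab3 <- diff_methylation(null_sim$beta, null_sim$probes, null_sim$annot, null_sim$groups)
  expect_equal(sum(tab3$significant), 0L)
})
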