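# Bisulfite clone summaries, conversion QC, delta-delta-Ct, ChIP
# percent-input and luciferase quantification.

test_that("clone methylation summary: counts to percents", {
  # 10 clones x 5 sites with 29 methylated calls -> 58% overall
  calls <- matrix(0L, 10, 5, dimnames = list(sprintf("c%02d", 1:10), sprintf("CpG%d", 1:5)))
  calls[cbind(rep(1:10, 5)[1:29], rep(1:5, each = 10)[1:29])] <- 1L
  expect_equal(sum(calls), 29)
  s <- clone_methylation_summary(clone_matrix(calls))
  expect_equal(s$overall_percent, 58)

  # 17 of 50 calls -> 34%
  calls34 <- matrix(0L, 10, 5)
  calls34[cbind(rep(1:10, 5)[1:17], rep(1:5, each = 10)[1:17])] <- 1L
  expect_equal(clone_methylation_summary(clone_matrix(calls34))$overall_percent, 34)

  zero <- clone_matrix(matrix(0L, 4, 3))
  s0 <- clone_methylation_summary(zero)
  expect_equal(s0$overall_percent, 0)
  expect_equal(unname(s0$per_cpg_percent), c(0, 0, 0))

  # with complete clones, overall equals the mean of per-CpG percents
  set.seed(8)
  rnd <- clone_matrix(matrix(rbinom(40, 1, 0.5), 8, 5))
  sr <- clone_methylation_summary(rnd)
  expect_equal(sr$overall_percent, mean(sr$per_cpg_percent))
  expect_true(all(sr$per_cpg_percent >= 0 & sr$per_cpg_percent <= 100))

  expect_error(clone_matrix(matrix(numeric(0), 0, 0)), ">= 1")
  expect_error(clone_matrix(matrix(c(0, 2), 1)), "0/1")
})

test_that("adding an all-methylated clone never decreases the overall percent", {
  set.seed(9)
  for (i in 1:5) {
    calls <- matrix(rbinom(30, 1, runif(1)), 6, 5)
    before <- clone_methylation_summary(clone_matrix(calls))$overall_percent
    after <- clone_methylation_summary(clone_matrix(rbind(calls, rep(1L, 5))))$overall_percent
    expect_gte(after, before)
  }
})

test_that("conversion rate per clone with pass flags and optional exclusion", {
  calls <- matrix(rbinom(15, 1, 0.5), 3, 5,
                  dimnames = list(c("c1", "c2", "c3"), NULL))
  cm <- clone_matrix(calls, converted = c(95, 100, 97), total = c(100, 100, 100))
  cr <- conversion_rate(cm, pass_threshold = 98)
  expect_equal(unname(cr$rate_percent), c(95, 100, 97))
  expect_equal(unname(cr$pass), c(FALSE, TRUE, FALSE))
  expect_equal(nrow(cr$calls_passing), 3L)   # exclusion off by default

  cr_ex <- conversion_rate(cm, pass_threshold = 98, exclude = TRUE)
  expect_equal(rownames(cr_ex$calls_passing), "c2")

  all_conv <- clone_matrix(calls, converted = c(100, 100, 100), total = c(100, 100, 100))
  expect_true(all(conversion_rate(all_conv)$pass))
  expect_error(conversion_rate(clone_matrix(calls)), "no conversion counts")
  bad <- clone_matrix(calls, converted = c(0, 0, 0), total = c(0, 0, 0))
  expect_error(conversion_rate(bad), "undefined")
})

test_that("delta-delta-Ct recovers fold changes and its invariances", {
  ct <- function(cond, gene, vals) data.frame(condition = cond, gene = gene,
                                              replicate = seq_along(vals), ct = vals)
  # identical Cts everywhere -> fold 1
  tab <- rbind(ct("control", "HK", c(20, 20)), ct("case", "HK", c(20, 20)),
               ct("control", "T", c(25, 25)), ct("case", "T", c(25, 25)))
  expect_equal(ddct(tab, "HK", "control")$fold, 1)

  # target 25 -> 24 cycles with constant housekeeping: fold 2 in the case
  tab2 <- rbind(ct("control", "HK", 20), ct("case", "HK", 20),
                ct("control", "T", 25), ct("case", "T", 24))
  res2 <- ddct(tab2, "HK", "control")
  expect_equal(res2$fold, 2)
  expect_equal(res2$ddct, -1)

  # shifting housekeeping Cts by +1 in both conditions leaves the fold alone
  tab3 <- tab2; tab3$ct[tab3$gene == "HK"] <- tab3$ct[tab3$gene == "HK"] + 1
  expect_equal(ddct(tab3, "HK", "control")$fold, 2)

  # a global constant shift of every Ct leaves the fold alone
  tab4 <- tab2; tab4$ct <- tab4$ct + 3
  expect_equal(ddct(tab4, "HK", "control")$fold, 2)

  # replicate combination: mean vs median
  tab5 <- rbind(ct("control", "HK", c(20, 20, 20)), ct("case", "HK", c(20, 20, 20)),
                ct("control", "T", c(25, 25, 25)), ct("case", "T", c(23, 24, 28)))
  expect_equal(ddct(tab5, "HK", "control")$fold, 2^(25 - 25))  # mean 25
  expect_equal(ddct(tab5, "HK", "control", combine = "median")$fold, 2)

  expect_error(ddct(tab2[tab2$gene != "HK", ], "HK", "control"), "housekeeping")
  expect_error(ddct(tab2, "HK", "baseline"), "reference")
})

test_that("ChIP percent-input applies the dilution adjustment", {
  chip <- data.frame(target_region = "promoter", antibody = "specific",
                     ct_ip = 20, ct_input = 25, input_fraction = 0.01)
  res <- percent_input(chip)
  expect_equal(res$percent_input, 100 * 2^((25 - log2(100)) - 20))
  expect_equal(res$percent_input, 32.0, tolerance = 0.05)

  # ct_ip equal to the adjusted input Ct -> 100%
  chip2 <- data.frame(target_region = "promoter", antibody = "specific",
                      ct_ip = 25 - log2(100), ct_input = 25, input_fraction = 0.01)
  expect_equal(percent_input(chip2)$percent_input, 100)

  # input_fraction 1 reduces to 100 * 2^(ct_input - ct_ip)
  chip3 <- data.frame(target_region = "promoter", antibody = "igg",
                      ct_ip = 24, ct_input = 22, input_fraction = 1)
  expect_equal(percent_input(chip3)$percent_input, 100 * 2^(22 - 24))

  expect_error(percent_input(transform(chip, input_fraction = 0)), "input_fraction")

  # planted enrichment: specific antibody above IgG at the promoter
  v <- gen_validation_data(seed = 6)
  pin <- percent_input(v$chip)
  prom <- pin[pin$target_region == "promoter", ]
  expect_gt(prom$percent_input[prom$antibody == "specific"],
            prom$percent_input[prom$antibody == "igg"])
})

test_that("luciferase folds normalise by renilla and by the empty control", {
  luc <- data.frame(construct = c("promoter", "promoter", "empty_control", "empty_control"),
                    condition = "control",
                    firefly = c(1000, 1100, 500, 520),
                    renilla = c(100, 110, 100, 104))
  res <- luciferase_relative(luc)
  expect_equal(res$fold, mean(c(10, 10)) / mean(c(5, 5)))

  # promoter wells identical to control wells -> fold 1
  luc1 <- luc; luc1$firefly <- 500; luc1$renilla <- 100
  expect_equal(luciferase_relative(luc1)$fold, 1)

  # doubling firefly doubles the fold
  luc2 <- luc; luc2$firefly[luc2$construct == "promoter"] <-
    2 * luc2$firefly[luc2$construct == "promoter"]
  expect_equal(luciferase_relative(luc2)$fold, 2 * res$fold)

  # planted knockdown halving is recovered from generated data
  v <- gen_validation_data(list(luc_noise_cv = 0), seed = 10)
  lr <- luciferase_relative(v$luciferase)
  expect_equal(lr$fold[lr$condition == "kd"] / lr$fold[lr$condition == "control"],
               0.5, tolerance = 1e-12)

  expect_error(luciferase_relative(luc[luc$construct == "promoter", ]), "control construct")
  expect_error(luciferase_relative(transform(luc, renilla = 0)), "renilla")
})
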