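# Extended-alphabet encoding, PWM scanning, and exact p-values.

simple_pwm <- function(cons, strong = 0.84, bg = NULL) {
  prob <- matrix((1 - strong) / 4, nrow = 5, ncol = length(cons),
                 dimnames = list(c("A", "C", "G", "T", "M"), NULL))
  for (j in seq_along(cons)) prob[cons[j], j] <- strong
  methyl_pwm(prob, background = bg)
}

test_that("methylation encoding marks the CpG cytosine symmetrically on both strands", {
  pr <- methyl_promoter("g", "ACGT", methyl_mask = 1L)
  enc <- encode_methylation(pr)
  expect_equal(enc$plus, "AMGT")
  # revcomp("ACGT") = "ACGT"; the partner cytosine of the methylated CpG sits
  # at reverse index 1, so the minus strand reads AMGT too
  expect_equal(enc$minus, "AMGT")

  # mask given at the G of the CpG normalises to the C position
  pr_g <- methyl_promoter("g", "ACGT", methyl_mask = 2L)
  expect_equal(pr_g$methyl_mask, 1L)
  expect_equal(encode_methylation(pr_g)$plus, "AMGT")

  pr0 <- methyl_promoter("g", "ACGTTT")
  enc0 <- encode_methylation(pr0)
  expect_equal(enc0$plus, "ACGTTT")
  expect_equal(enc0$minus, paste(revcomp_chars(strsplit("ACGTTT", "")[[1]]), collapse = ""))

  expect_error(methyl_promoter("g", "CAAA", methyl_mask = 0L), "CpG context")
  expect_error(methyl_promoter("g", "ACGT", methyl_mask = 9L), "inside")
  expect_error(methyl_promoter("g", "ACGN"), "A/C/G/T")
})

test_that("a width-1 motif scores every window and a wide motif returns empty", {
  pwm <- simple_pwm("A", strong = 0.97)
  pr <- methyl_promoter("g", "AAAA")
  hits <- scan_motif(pr, pwm, p_threshold = 0.5)
  # 4 plus-strand hits with equal scores; minus strand (TTTT) scores too low
  expect_equal(nrow(hits), 4L)
  expect_true(all(hits$strand == "+"))
  expect_equal(length(unique(hits$score)), 1L)
  expect_setequal(hits$start, 0:3)

  wide <- simple_pwm(rep("A", 10))
  expect_warning(empty <- scan_motif(pr, wide), "width")
  expect_equal(nrow(empty), 0L)
})

test_that("best hit equals the brute-force maximum over all windows and strands", {
  set.seed(42)
  chars <- sample(c("A", "C", "G", "T"), 50, replace = TRUE)
  seqstr <- paste(chars, collapse = "")
  cg <- which(chars[-50] == "C" & chars[-1] == "G")
  mask <- if (length(cg) > 0) (cg - 1L)[1:min(2, length(cg))] else integer(0)
  pr <- methyl_promoter("g", seqstr, methyl_mask = mask)
  pwm <- simple_pwm(c("M", "G", "A", "T"))
  hits <- scan_motif(pr, pwm, p_threshold = 1)

  enc <- encode_methylation(pr)
  best <- -Inf
  for (strand_seq in c(enc$plus, enc$minus)) {
    sc <- strsplit(strand_seq, "")[[1]]
    for (i in 1:(50 - 4 + 1))
      best <- max(best, pwm_score_brute(sc[i:(i + 3)], pwm$prob, pwm$background))
  }
  expect_equal(max(hits$score), best, tolerance = 2e-3)  # integerization granularity
  # every window on both strands was tested
  expect_equal(nrow(hits), 2L * (50 - 4 + 1))
})

test_that("an M-heavy column scores higher on the methylated copy of a sequence", {
  seqstr <- "TTACGGAATT"
  masked <- methyl_promoter("g", seqstr, methyl_mask = 3L)
  unmasked <- methyl_promoter("g", seqstr)
  pwm <- simple_pwm(c("M", "G", "G", "A"))
  h_m <- scan_motif(masked, pwm, p_threshold = 1)
  h_u <- scan_motif(unmasked, pwm, p_threshold = 1)
  at <- function(h) h$score[h$start == 3 & h$strand == "+"]
  expect_gt(at(h_m), at(h_u))
})

test_that("DP p-values equal brute-force enumeration over all extended-alphabet words", {
  pwm <- simple_pwm(c("M", "G", "A"), strong = 0.7)
  tab <- exact_pvalue_table(pwm, granularity = 1e-3)
  si <- tab$int_scores
  letters5 <- c("A", "C", "G", "T", "M")
  words <- expand.grid(l1 = letters5, l2 = letters5, l3 = letters5,
                       stringsAsFactors = FALSE)
  w_score <- si[cbind(match(words$l1, letters5), 1)] +
    si[cbind(match(words$l2, letters5), 2)] +
    si[cbind(match(words$l3, letters5), 3)]
  w_prob <- pwm$background[words$l1] * pwm$background[words$l2] * pwm$background[words$l3]
  for (s in sort(unique(w_score))) {
    p_enum <- sum(w_prob[w_score >= s])
    p_dp <- promethex:::lookup_pvalue(tab, s)
    expect_equal(p_dp, p_enum, tolerance = 1e-12)
  }
  # monotone non-increasing tail
  expect_true(all(diff(tab$tail) <= 1e-15))
  # uniform pwm = background: every score 0, p(0) = 1
  flat <- methyl_pwm(matrix(0.2, 5, 3, dimnames = list(letters5, NULL)))
  ftab <- exact_pvalue_table(flat)
  expect_equal(promethex:::lookup_pvalue(ftab, 0L), 1)
})

test_that("scanning the reverse complement mirrors hits with flipped strands", {
  set.seed(11)
  chars <- sample(c("A", "C", "G", "T"), 40, replace = TRUE)
  chars[10:11] <- c("C", "G")
  pr <- methyl_promoter("g", paste(chars, collapse = ""), methyl_mask = 9L)
  rc <- revcomp_chars(chars)
  rc[rc == "M"] <- "C"   # plain base string for the reverse complement
  # methylated CpG at plus positions 9-10 maps to rc positions 40-1-10 = 29 (C)
  pr_rc <- methyl_promoter("g", paste(rc, collapse = ""), methyl_mask = 29L)

  pwm <- simple_pwm(c("M", "G", "A"))
  h_fwd <- scan_motif(pr, pwm, p_threshold = 1)
  h_rc <- scan_motif(pr_rc, pwm, p_threshold = 1)
  # a plus-strand hit at start s in the original appears as a minus-strand
  # hit at start L - w - s in the reverse complement
  key_fwd <- sort(paste(ifelse(h_fwd$strand == "+", "-", "+"),
                        40 - 3 - h_fwd$start, round(h_fwd$score, 6)))
  key_rc <- sort(paste(h_rc$strand, h_rc$start, round(h_rc$score, 6)))
  expect_equal(key_fwd, key_rc)
})

test_that("with no methylation and the C mass split over C and M the scan reduces to 4 letters", {
  set.seed(12)
  chars <- sample(c("A", "C", "G", "T"), 30, replace = TRUE)
  pr <- methyl_promoter("g", paste(chars, collapse = ""))
  prob4 <- matrix(runif(4 * 3, 0.05, 1), nrow = 4,
                  dimnames = list(c("A", "C", "G", "T"), NULL))
  prob4 <- sweep(prob4, 2, colSums(prob4), "/")
  # split the C emission (and the C background) evenly over C and M: on a
  # methylation-free sequence the log-odds of every letter are unchanged
  prob5 <- rbind(prob4[c("A", "G", "T"), ], C = prob4["C", ] / 2, M = prob4["C", ] / 2)
  pwm <- methyl_pwm(prob5, background = c(A = 0.25, G = 0.25, T = 0.25, C = 0.125, M = 0.125),
                    pseudocount = 0)
  hits <- scan_motif(pr, pwm, p_threshold = 1)

  # independent 4-letter scan with uniform background
  enc <- list(plus = chars, minus = revcomp_chars(chars))
  bg4 <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
  for (strand in c("+", "-")) {
    sc <- if (strand == "+") enc$plus else enc$minus
    for (i in 1:(30 - 3 + 1)) {
      win <- sc[i:(i + 2)]
      ref <- sum(vapply(1:3, function(j) log2(prob4[win[j], j] / bg4[win[j]]), numeric(1)))
      start <- if (strand == "+") i - 1L else 30 - 3 - (i - 1L)
      got <- hits$score[hits$strand == strand & hits$start == start]
      expect_lt(abs(got - ref), 2e-3)   # within the integerization bin
    }
  }
})

test_that("window q-values match brute-force BH over all tested windows", {
  set.seed(13)
  chars <- sample(c("A", "C", "G", "T"), 25, replace = TRUE)
  pr <- methyl_promoter("g", paste(chars, collapse = ""))
  pwm <- simple_pwm(c("G", "A", "T"))
  hits <- scan_motif(pr, pwm, p_threshold = 1)
  # BH is equivariant under row reordering, so brute force on the returned
  # p's must reproduce the returned q's
  expect_equal(hits$q, bh_brute(hits$p), tolerance = 1e-12)
  expect_true(all(diff(hits$p) >= -1e-15))  # sorted by p
})
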