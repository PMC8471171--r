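# Synthetic-data generators with planted ground truth. Every input the
# pipeline consumes can be generated here, so all downstream stages are
# testable without any external download. All generators take an explicit
# seed; none touches the global RNG state it did not set itself.

QUADRANTS <- c("hyper_up", "hyper_down", "hypo_up", "hypo_down")

#' Simulation configuration for the methylome/transcriptome generator
#'
#' Bundles and validates the parameters of [gen_methylome_transcriptome()].
#' Defaults describe a two-group case/control design with promoter-level
#' methylation effects of |delta beta| = 0.3, expression effects of
#' |log2FC| = 1.5, and 20 samples per group — a regime in which the planted
#' hyper-up genes are recoverable by the differential stage.
#'
#' @param n_genes number of genes.
#' @param n_cpg_per_promoter CpG probes placed inside each promoter window.
#' @param n_per_group samples per condition (case and control).
#' @param delta_beta_effect absolute planted promoter methylation difference
#'   (beta-value scale, case minus control).
#' @param log2fc_effect absolute planted expression difference (log2 units).
#' @param beta_noise_sd per-CpG, per-sample noise SD on the logit scale.
#' @param expr_noise_sd per-gene, per-sample noise SD on the log2 scale.
#' @param quadrant_proportions named fractions of genes planted in each of
#'   the four methylation/expression quadrants (`hyper_up`, `hyper_down`,
#'   `hypo_up`, `hypo_down`); must sum to at most 1. The remainder are null
#'   genes with no planted effect.
#' @param na_rate fraction of beta/expression entries set missing (default 0).
#' @param seed integer RNG seed (mandatory; there is no global-state default).
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_genes = 200L,
                       n_cpg_per_promoter = 5L,
                       n_per_group = 20L,
                       delta_beta_effect = 0.3,
                       log2fc_effect = 1.5,
                       beta_noise_sd = 0.5,
                       expr_noise_sd = 0.5,
                       quadrant_proportions = c(hyper_up = 0.10, hyper_down = 0.05,
                                                hypo_up = 0.05, hypo_down = 0.05),
                       na_rate = 0,
                       seed) {
  n_genes <- assert_count(n_genes, "n_genes")
  n_cpg_per_promoter <- assert_count(n_cpg_per_promoter, "n_cpg_per_promoter")
  n_per_group <- assert_count(n_per_group, "n_per_group", min = 2L)
  delta_beta_effect <- assert_number(delta_beta_effect, "delta_beta_effect", 0, 0.45)
  log2fc_effect <- assert_number(log2fc_effect, "log2fc_effect", 0)
  beta_noise_sd <- assert_number(beta_noise_sd, "beta_noise_sd", 0)
  expr_noise_sd <- assert_number(expr_noise_sd, "expr_noise_sd", 0)
  na_rate <- assert_number(na_rate, "na_rate", 0, 0.5)
  if (missing(seed)) stopf("'seed' is required; generators keep no global random state")
  seed <- assert_count(seed, "seed", min = 0L)
  if (is.null(names(quadrant_proportions)) ||
      !all(names(quadrant_proportions) %in% QUADRANTS))
    stopf("quadrant_proportions must be named with a subset of: %s",
          paste(QUADRANTS, collapse = ", "))
  qp <- setNames(rep(0, 4L), QUADRANTS)
  qp[names(quadrant_proportions)] <- quadrant_proportions
  if (any(qp < 0) || sum(qp) > 1 + 1e-12)
    stopf("quadrant_proportions must be non-negative and sum to <= 1")
  structure(list(n_genes = n_genes, n_cpg_per_promoter = n_cpg_per_promoter,
                 n_per_group = n_per_group, delta_beta_effect = delta_beta_effect,
                 log2fc_effect = log2fc_effect, beta_noise_sd = beta_noise_sd,
                 expr_noise_sd = expr_noise_sd, quadrant_proportions = qp,
                 na_rate = na_rate, seed = seed),
            class = "sim_config")
}

# deterministic quadrant assignment: round(prop * n) genes per quadrant,
# assigned in gene-index order, remainder null
assign_quadrants <- function(n_genes, proportions) {
  counts <- round(proportions * n_genes)
  if (sum(counts) > n_genes) stopf("quadrant proportions allocate more genes than exist")
  quadrant <- rep("null", n_genes)
  at <- 1L
  for (q in QUADRANTS) {
    k <- counts[[q]]
    if (k > 0) quadrant[at:(at + k - 1L)] <- q
    at <- at + k
  }
  quadrant
}

#' Generate a paired methylome/transcriptome dataset with planted effects
#'
#' Emulates a two-group (case vs control) study in which some promoters are
#' differentially methylated and some genes differentially expressed, with a
#' configurable fraction planted in each methylation/expression quadrant.
#' Beta values are produced per CpG as `plogis(qlogis(group mean) + noise)`,
#' clamped to `[1e-4, 1 - 1e-4]`, which keeps them in the open unit interval
#' with mean-dependent variance as on real methylation arrays. The case-group
#' promoter mean is shifted by the planted delta beta, and case-group
#' expression by the planted log2 fold change.
#'
#' @param config a [sim_config()].
#' @return a list with elements
#'   \describe{
#'     \item{beta}{CpG-probe x sample matrix of beta values.}
#'     \item{probes}{data.frame `probe_id, chrom, pos` (0-based coordinates).}
#'     \item{expr}{gene x sample matrix of log2 expression.}
#'     \item{annot}{gene annotation `gene_id, chrom, strand, tss`.}
#'     \item{groups}{factor `control`/`case` aligned to the sample columns.}
#'     \item{truth}{planted-truth table: `gene_id, planted_delta_beta,
#'       planted_log2fc, planted_quadrant, planted_kd_down`.}
#'   }
#' @export
gen_methylome_transcriptome <- function(config) {
  if (!inherits(config, "sim_config")) stopf("'config' must be built by sim_config()")
  cf <- config
  set.seed(cf$seed)

  n <- cf$n_genes
  k <- cf$n_cpg_per_promoter
  m <- cf$n_per_group
  samples <- c(sprintf("ctrl_%02d", seq_len(m)), sprintf("case_%02d", seq_len(m)))
  groups <- factor(rep(c("control", "case"), each = m), levels = c("control", "case"))

  quadrant <- assign_quadrants(n, cf$quadrant_proportions)
  # a quadrant label requires both planted effects to be real: with either
  # effect size at 0 no gene is planted and the whole truth table is null
  if (cf$delta_beta_effect == 0 || cf$log2fc_effect == 0)
    quadrant <- rep("null", n)
  d_beta <- ifelse(quadrant %in% c("hyper_up", "hyper_down"), cf$delta_beta_effect,
                   ifelse(quadrant %in% c("hypo_up", "hypo_down"), -cf$delta_beta_effect, 0))
  lfc <- ifelse(quadrant %in% c("hyper_up", "hypo_up"), cf$log2fc_effect,
                ifelse(quadrant %in% c("hyper_down", "hypo_down"), -cf$log2fc_effect, 0))

  gene_id <- sprintf("gene%04d", seq_len(n))
  truth <- data.frame(gene_id = gene_id,
                      planted_delta_beta = d_beta,
                      planted_log2fc = lfc,
                      planted_quadrant = quadrant,
                      planted_kd_down = FALSE,
                      stringsAsFactors = FALSE)

  # annotation: one TSS per gene, all probes inside the strand-oriented
  # -1500/+500 promoter window
  strand <- rep(c("+", "-"), length.out = n)
  tss <- 5000L + (seq_len(n) - 1L) * 10000L
  annot <- data.frame(gene_id = gene_id, chrom = "chr1", strand = strand,
                      tss = tss, stringsAsFactors = FALSE)
  win <- promoter_windows(annot)
  pos <- unlist(lapply(seq_len(n), function(i) {
    win$start[i] + floor((seq_len(k) - 0.5) / k * (win$end[i] - win$start[i]))
  }))
  probes <- data.frame(probe_id = sprintf("cg%06d", seq_len(n * k)),
                       chrom = "chr1", pos = as.integer(pos),
                       stringsAsFactors = FALSE)

  # control-group promoter means leave headroom for the planted shift
  base <- numeric(n)
  up_m <- d_beta >= 0
  base[up_m] <- runif(sum(up_m), 0.20, 0.50)
  base[!up_m] <- runif(sum(!up_m), 0.50, 0.80)
  mu <- cbind(control = base, case = pmin(pmax(base + d_beta, 1e-3), 1 - 1e-3))

  beta <- matrix(NA_real_, nrow = n * k, ncol = 2L * m,
                 dimnames = list(probes$probe_id, samples))
  for (g in seq_len(n)) {
    rows <- ((g - 1L) * k + 1L):(g * k)
    mus <- rep(mu[g, as.integer(groups)], each = k)
    eps <- rnorm(k * 2L * m, sd = cf$beta_noise_sd)
    beta[rows, ] <- plogis(qlogis(mus) + eps)
  }
  beta <- pmin(pmax(beta, 1e-4), 1 - 1e-4)

  base_expr <- runif(n, 3, 10)
  shift <- outer(lfc, as.integer(groups) - 1L)     # case columns get the planted log2FC
  expr <- base_expr + shift + matrix(rnorm(n * 2L * m, sd = cf$expr_noise_sd), n, 2L * m)
  dimnames(expr) <- list(gene_id, samples)

  if (cf$na_rate > 0) {
    beta[runif(length(beta)) < cf$na_rate] <- NA_real_
    expr[runif(length(expr)) < cf$na_rate] <- NA_real_
  }

  list(beta = beta, probes = probes, expr = expr, annot = annot,
       groups = groups, truth = truth, config = cf)
}

#' Generate a protein-microarray screen with planted methyl-preferring binders
#'
#' Emulates a TF microarray incubated with a methylated and an unmethylated
#' version of the same DNA fragment. Negative-control spots carry background
#' fluorescence in all channels. Planted methyl-preferring binders receive a
#' methylated-channel MFI equal to `preference_fold` times their
#' unmethylated-channel MFI, with both above the positivity threshold; a
#' fraction of the remaining TFs bind both fragments equally
#' (non-discriminating) and the rest do not bind. All expressed spots carry
#' N- and C-terminal tag-stain signal.
#'
#' @param n_tf number of transcription-factor spots (distinct TFs).
#' @param n_neg number of negative-control spots (>= 2, needed for the SD).
#' @param n_methyl_binders number of planted methyl-preferring TFs (<= n_tf).
#' @param preference_fold ratio of methylated over unmethylated signal for
#'   planted binders (>= 1).
#' @param noise_cv multiplicative coefficient of variation applied per
#'   replicate and channel.
#' @param seed integer RNG seed.
#' @param n_replicates spots per TF (collapsed by median downstream).
#' @param frac_nondiscriminating fraction of non-planted TFs that bind both
#'   fragments equally well.
#' @return list with `scan` (long-format spot table with columns `spot_id,
#'   tf_id, construct, replicate, mfi_meth, mfi_unmeth, tag_n, tag_c`),
#'   `binders` (planted methyl-preferring tf_ids) and `truth`.
#' @export
gen_tf_array <- function(n_tf, n_neg, n_methyl_binders, preference_fold,
                         noise_cv, seed, n_replicates = 2L,
                         frac_nondiscriminating = 0.15) {
  n_tf <- assert_count(n_tf, "n_tf")
  n_neg <- assert_count(n_neg, "n_neg")
  if (n_neg < 2L) stopf("n_neg must be >= 2 (the positivity threshold needs a sample SD)")
  n_methyl_binders <- assert_count(n_methyl_binders, "n_methyl_binders", min = 0L)
  if (n_methyl_binders > n_tf) stopf("n_methyl_binders must be <= n_tf")
  preference_fold <- assert_number(preference_fold, "preference_fold", min = 1)
  noise_cv <- assert_number(noise_cv, "noise_cv", 0, 1)
  n_replicates <- assert_count(n_replicates, "n_replicates")
  seed <- assert_count(seed, "seed", min = 0L)
  set.seed(seed)

  bg_mean <- 100; bg_sd <- 10; tag_level <- 3000
  tf_id <- sprintf("TF%03d", seq_len(n_tf))
  binders <- tf_id[seq_len(n_methyl_binders)]
  rest <- setdiff(tf_id, binders)
  n_nd <- round(frac_nondiscriminating * length(rest))
  nondisc <- if (n_nd > 0) rest[seq_len(n_nd)] else character(0)
  construct <- ifelse(seq_len(n_tf) %% 20L == 0L, "full_length", "dbd")

  noisy <- function(x) x * (1 + rnorm(length(x), sd = noise_cv))
  base_unmeth <- setNames(runif(n_tf, 400, 800), tf_id)

  rows <- vector("list", n_tf * n_replicates + n_neg * n_replicates)
  ri <- 1L
  for (r in seq_len(n_replicates)) {
    mfi_meth <- mfi_unmeth <- rnorm(n_tf, bg_mean, bg_sd)     # non-binder default
    is_b <- tf_id %in% binders
    is_nd <- tf_id %in% nondisc
    mfi_unmeth[is_b] <- noisy(base_unmeth[is_b])
    mfi_meth[is_b] <- noisy(preference_fold * base_unmeth[is_b])
    both <- noisy(runif(n_tf, 500, 1500))
    mfi_unmeth[is_nd] <- noisy(both[is_nd])
    mfi_meth[is_nd] <- noisy(both[is_nd])
    rows[[ri]] <- data.frame(
      spot_id = sprintf("spot_%s_r%d", tf_id, r), tf_id = tf_id,
      construct = construct, replicate = r,
      mfi_meth = pmax(mfi_meth, 0), mfi_unmeth = pmax(mfi_unmeth, 0),
      tag_n = pmax(noisy(rep(tag_level, n_tf)), 0),
      tag_c = pmax(noisy(rep(tag_level, n_tf)), 0),
      stringsAsFactors = FALSE)
    ri <- ri + 1L
    rows[[ri]] <- data.frame(
      spot_id = sprintf("neg_%03d_r%d", seq_len(n_neg), r), tf_id = "NEG",
      construct = "negative_control", replicate = r,
      mfi_meth = pmax(rnorm(n_neg, bg_mean, bg_sd), 0),
      mfi_unmeth = pmax(rnorm(n_neg, bg_mean, bg_sd), 0),
      tag_n = pmax(rnorm(n_neg, bg_mean, bg_sd), 0),
      tag_c = pmax(rnorm(n_neg, bg_mean, bg_sd), 0),
      stringsAsFactors = FALSE)
    ri <- ri + 1L
  }
  scan <- do.call(rbind, rows)
  truth <- data.frame(tf_id = tf_id, methyl_binder = tf_id %in% binders,
                      stringsAsFactors = FALSE)
  list(scan = scan, binders = binders, truth = truth)
}

#' Generate knockdown-vs-control expression panels across cell lines
#'
#' Emulates siRNA knockdown experiments in several cell lines: a consistent
#' set of genes is down-shifted in every line, and each line additionally has
#' its own private set of down-shifted genes. The intersection of the
#' per-line down-regulated sets therefore equals the planted consistent set.
#'
#' @param n_cell_lines number of cell lines.
#' @param n_genes genes per panel.
#' @param n_down_consistent genes down-regulated in every line.
#' @param per_line_extra_down genes down-regulated in exactly one line each.
#' @param log2fc_effect magnitude of the down-shift (log2 units, > 0).
#' @param seed integer RNG seed.
#' @param n_per_group samples per condition within each line.
#' @param expr_noise_sd log2-scale noise SD.
#' @return list with `panels` (one element per line: `expr` matrix, `groups`
#'   factor with levels control/knockdown, `cell_line`) and `truth`
#'   (`gene_id, planted_kd_down`).
#' @export
gen_knockdown_panel <- function(n_cell_lines, n_genes, n_down_consistent,
                                per_line_extra_down, log2fc_effect, seed,
                                n_per_group = 5L, expr_noise_sd = 0.25) {
  n_cell_lines <- assert_count(n_cell_lines, "n_cell_lines")
  n_genes <- assert_count(n_genes, "n_genes")
  n_down_consistent <- assert_count(n_down_consistent, "n_down_consistent", min = 0L)
  per_line_extra_down <- assert_count(per_line_extra_down, "per_line_extra_down", min = 0L)
  if (n_down_consistent > n_genes) stopf("n_down_consistent must be <= n_genes")
  needed <- n_down_consistent + n_cell_lines * per_line_extra_down
  if (needed > n_genes) stopf("not enough genes for the planted down sets (%d needed)", needed)
  log2fc_effect <- assert_number(log2fc_effect, "log2fc_effect", min = 0)
  n_per_group <- assert_count(n_per_group, "n_per_group", min = 2L)
  expr_noise_sd <- assert_number(expr_noise_sd, "expr_noise_sd", min = 0)
  seed <- assert_count(seed, "seed", min = 0L)
  set.seed(seed)

  gene_id <- sprintf("gene%04d", seq_len(n_genes))
  consistent <- if (n_down_consistent > 0) gene_id[seq_len(n_down_consistent)] else character(0)
  groups <- factor(rep(c("control", "knockdown"), each = n_per_group),
                   levels = c("control", "knockdown"))
  base <- runif(n_genes, 3, 10)

  panels <- vector("list", n_cell_lines)
  at <- n_down_consistent
  for (l in seq_len(n_cell_lines)) {
    extra <- if (per_line_extra_down > 0) gene_id[(at + 1L):(at + per_line_extra_down)] else character(0)
    at <- at + per_line_extra_down
    down <- c(consistent, extra)
    shift <- ifelse(gene_id %in% down, -log2fc_effect, 0)
    expr <- base + outer(shift, as.integer(groups) - 1L) +
      matrix(rnorm(n_genes * 2L * n_per_group, sd = expr_noise_sd), n_genes)
    dimnames(expr) <- list(gene_id,
                           sprintf("line%d_%s_%d", l, rep(c("ctrl", "kd"), each = n_per_group),
                                   rep(seq_len(n_per_group), 2L)))
    panels[[l]] <- list(expr = expr, groups = groups, cell_line = sprintf("line%d", l),
                        planted_down = down)
  }
  truth <- data.frame(gene_id = gene_id, planted_kd_down = gene_id %in% consistent,
                      stringsAsFactors = FALSE)
  list(panels = panels, truth = truth)
}

#' Generate validation-assay inputs encoding known ground truth
#'
#' Produces the four validation-assay tables from declared truths: bisulfite
#' clone calls are Bernoulli draws from per-CpG methylation fractions; qPCR
#' Ct values are `base_ct - log2(abundance) + noise` so that a true fold
#' change is recovered by the delta-delta-Ct method; ChIP Ct pairs encode a
#' true percent-input enrichment; luciferase well pairs encode true
#' promoter-activity ratios.
#'
#' @param spec a list of truths with (all optional, defaults shown in
#'   [default_validation_spec()]): `cpg_fractions`, `n_clones`,
#'   `conversion_rate`, `n_non_cpg`, `fold_changes` (named, case vs control),
#'   `housekeeping`, `n_ct_replicates`, `ct_noise_sd`, `chip` (data.frame
#'   `target_region, antibody, percent_input`), `input_fraction`,
#'   `luciferase_activity` (data.frame `construct, condition, activity`),
#'   `n_wells`, `luc_noise_cv`.
#' @param seed integer RNG seed.
#' @return list with `clones` (a [clone_matrix()]), `ct` (CtTable), `chip`
#'   (ChipTable) and `luciferase` (LuciferaseTable) data.frames.
#' @export
gen_validation_data <- function(spec = list(), seed) {
  seed <- assert_count(seed, "seed", min = 0L)
  sp <- modifyList(default_validation_spec(), spec)
  if (any(sp$cpg_fractions < 0 | sp$cpg_fractions > 1))
    stopf("cpg_fractions must lie in [0, 1]")
  if (sp$conversion_rate < 0 || sp$conversion_rate > 1)
    stopf("conversion_rate must lie in [0, 1]")
  set.seed(seed)

  n_cpg <- length(sp$cpg_fractions)
  calls <- matrix(rbinom(sp$n_clones * n_cpg, 1L, rep(sp$cpg_fractions, each = sp$n_clones)),
                  nrow = sp$n_clones,
                  dimnames = list(sprintf("clone%02d", seq_len(sp$n_clones)),
                                  sprintf("CpG%d", seq_len(n_cpg))))
  converted <- rbinom(sp$n_clones, sp$n_non_cpg, sp$conversion_rate)
  clones <- clone_matrix(calls, converted = converted, total = rep(sp$n_non_cpg, sp$n_clones))

  genes <- c(names(sp$fold_changes), sp$housekeeping)
  base_ct <- setNames(runif(length(genes), 18, 26), genes)
  ct_rows <- list()
  for (cond in c("control", "case")) {
    for (g in genes) {
      ab <- if (g == sp$housekeeping || cond == "control") 1 else sp$fold_changes[[g]]
      ct_rows[[length(ct_rows) + 1L]] <- data.frame(
        sample = cond, condition = cond, gene = g,
        replicate = seq_len(sp$n_ct_replicates),
        ct = base_ct[[g]] - log2(ab) + rnorm(sp$n_ct_replicates, sd = sp$ct_noise_sd),
        stringsAsFactors = FALSE)
    }
  }
  ct <- do.call(rbind, ct_rows)

  chip <- sp$chip
  chip$input_fraction <- sp$input_fraction
  chip$ct_input <- runif(nrow(chip), 23, 26)
  adj <- chip$ct_input - log2(1 / chip$input_fraction)
  chip$ct_ip <- adj - log2(chip$percent_input / 100) + rnorm(nrow(chip), sd = sp$ct_noise_sd)
  chip <- chip[, c("target_region", "antibody", "ct_ip", "ct_input", "input_fraction",
                   "percent_input")]
  names(chip)[names(chip) == "percent_input"] <- "true_percent_input"

  la <- sp$luciferase_activity
  luc_rows <- lapply(seq_len(nrow(la)), function(i) {
    renilla <- 1e5 * (1 + rnorm(sp$n_wells, sd = sp$luc_noise_cv))
    firefly <- 0.1 * la$activity[i] * renilla * (1 + rnorm(sp$n_wells, sd = sp$luc_noise_cv))
    data.frame(construct = la$construct[i], condition = la$condition[i],
               well = seq_len(sp$n_wells), firefly = firefly, renilla = renilla,
               stringsAsFactors = FALSE)
  })
  luciferase <- do.call(rbind, luc_rows)

  list(clones = clones, ct = ct, chip = chip, luciferase = luciferase)
}

#' Default truths for [gen_validation_data()]
#'
#' The defaults mirror a typical validation round: five promoter CpGs at
#' ~58% methylation read out over ten clones, a two-fold expression change
#' against an HPRT1 housekeeping control, promoter ChIP enrichment well above
#' an upstream control region and IgG background, and a knockdown that halves
#' promoter-driven luciferase activity.
#'
#' @return a list of truth parameters.
#' @export
default_validation_spec <- function() {
  list(
    cpg_fractions = c(0.6, 0.6, 0.6, 0.5, 0.6),
    n_clones = 10L,
    conversion_rate = 0.99,
    n_non_cpg = 50L,
    fold_changes = c(ALDH1A3 = 2),
    housekeeping = "HPRT1",
    n_ct_replicates = 3L,
    ct_noise_sd = 0.05,
    chip = data.frame(
      target_region = c("promoter", "promoter", "upstream_5kb_control", "upstream_5kb_control"),
      antibody = c("specific", "igg", "specific", "igg"),
      percent_input = c(5, 0.5, 0.5, 0.4),
      stringsAsFactors = FALSE),
    input_fraction = 0.01,
    luciferase_activity = data.frame(
      construct = c("promoter", "empty_control", "promoter", "empty_control"),
      condition = c("control", "control", "kd", "kd"),
      activity = c(4, 1, 2, 1),
      stringsAsFactors = FALSE),
    n_wells = 3L,
    luc_noise_cv = 0.03
  )
}
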