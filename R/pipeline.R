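# Stage orchestration: deterministic end-to-end runs over files on disk,
# driven by a validated config (YAML or list), with a JSON manifest per
# stage recording parameters, seeds and input checksums.

PIPELINE_STAGES <- c("simulate", "diff", "integrate", "screen", "scan",
                     "enrich", "validate", "all")

#' Default pipeline configuration
#'
#' All stage thresholds under their conventional defaults: differential
#' methylation at adjusted p <= 0.05 with |delta beta| >= 0.1; differential
#' expression at adjusted p <= 0.01 with |log2FC| >= 0.5; array positivity at
#' negative-control mean + 4 SD with preference-ratio cutoff 2 and top-15
#' reporting; GSEA significance at NES > 1, p <= 0.05, q <= 0.25; Fisher
#' overrepresentation at adjusted p <= 0.05; motif hits at p <= 1e-4.
#'
#' @param seed integer seed used by every stochastic stage.
#' @param outdir output directory.
#' @return nested config list, YAML-serialisable.
#' @export
default_run_config <- function(seed = 1L, outdir = "promethex_out") {
  list(
    seed = as.integer(seed),
    outdir = outdir,
    sim = list(
      n_genes = 200L, n_cpg_per_promoter = 5L, n_per_group = 20L,
      delta_beta_effect = 0.3, log2fc_effect = 1.5,
      beta_noise_sd = 0.5, expr_noise_sd = 0.5,
      quadrant_proportions = list(hyper_up = 0.10, hyper_down = 0.05,
                                  hypo_up = 0.05, hypo_down = 0.05),
      tf = list(n_tf = 100L, n_neg = 20L, n_methyl_binders = 5L,
                preference_fold = 8, noise_cv = 0.1),
      kd = list(n_cell_lines = 3L, n_down_consistent = 10L,
                per_line_extra_down = 5L, log2fc_effect = 2)
    ),
    methylation = list(p_cut = 0.05, effect_cut = 0.1),
    expression = list(p_cut = 0.01, effect_cut = 0.5),
    screen = list(ratio_cutoff = 2, expression_floor = 1, top_k = 15L),
    motif = list(p_threshold = 1e-4, granularity = 1e-3),
    gsea = list(weight = 1, n_perm = 1000L),
    fisher = list(p_cut = 0.05)
  )
}

validate_config_keys <- function(user, default, path = "") {
  unknown <- setdiff(names(user), names(default))
  if (length(unknown) > 0)
    stopf("unknown config key(s): %s", paste0(path, unknown, collapse = ", "))
  for (k in names(user)) {
    if (is.list(default[[k]]) && !is.null(names(default[[k]])) &&
        k != "quadrant_proportions") {
      if (!is.list(user[[k]])) stopf("config key '%s%s' must be a mapping", path, k)
      validate_config_keys(user[[k]], default[[k]], paste0(path, k, "."))
    }
  }
  invisible(TRUE)
}

load_run_config <- function(config) {
  default <- default_run_config()
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stopf("config file '%s' not found", config)
    config <- yaml::read_yaml(config)
  }
  if (is.null(config)) config <- list()
  if (!is.list(config)) stopf("config must be a list or a YAML file path")
  validate_config_keys(config, default)
  modifyList(default, config)
}

stage_dir <- function(cf, stage) {
  d <- file.path(cf$outdir, stage)
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  d
}

write_manifest <- function(cf, stage, inputs, outputs) {
  manifest <- list(
    stage = stage,
    package_version = as.character(utils::packageVersion("promethex")),
    seed = cf$seed,
    parameters = cf[setdiff(names(cf), "outdir")],
    input_md5 = {
      present <- inputs[file.exists(inputs)]
      as.list(setNames(tools::md5sum(present), basename(present)))
    },
    outputs = outputs
  )
  path <- file.path(cf$outdir, sprintf("manifest_%s.json", stage))
  write_json_summary(manifest, path)
  path
}

# demo methylation-preferring motif (an NFAT-like GGAAA core preceded by a
# methylated CpG) used by the simulate/scan stages
demo_methyl_pwm <- function() {
  cons <- c("M", "G", "G", "A", "A", "A")
  prob <- matrix(0.04, nrow = 5L, ncol = length(cons),
                 dimnames = list(M_ALPHABET, NULL))
  for (j in seq_along(cons)) prob[cons[j], j] <- 0.84
  methyl_pwm(prob)
}

sim_stage <- function(cf) {
  d <- stage_dir(cf, "sim")
  qp <- unlist(cf$sim$quadrant_proportions)
  config <- sim_config(n_genes = cf$sim$n_genes,
                       n_cpg_per_promoter = cf$sim$n_cpg_per_promoter,
                       n_per_group = cf$sim$n_per_group,
                       delta_beta_effect = cf$sim$delta_beta_effect,
                       log2fc_effect = cf$sim$log2fc_effect,
                       beta_noise_sd = cf$sim$beta_noise_sd,
                       expr_noise_sd = cf$sim$expr_noise_sd,
                       quadrant_proportions = qp,
                       seed = cf$seed)
  sim <- gen_methylome_transcriptome(config)
  write_matrix_tsv(sim$beta, file.path(d, "beta.tsv"))
  write_table_tsv(sim$probes, file.path(d, "probes.tsv"))
  write_matrix_tsv(sim$expr, file.path(d, "expr.tsv"))
  write_table_tsv(sim$annot, file.path(d, "tss.tsv"))
  write_bed(promoter_windows(sim$annot), file.path(d, "promoters.bed"))
  write_table_tsv(data.frame(sample = colnames(sim$beta), group = as.character(sim$groups)),
                  file.path(d, "groups.tsv"))
  write_table_tsv(sim$truth, file.path(d, "truth.tsv"))

  tf <- gen_tf_array(cf$sim$tf$n_tf, cf$sim$tf$n_neg, cf$sim$tf$n_methyl_binders,
                     cf$sim$tf$preference_fold, cf$sim$tf$noise_cv, seed = cf$seed + 1L)
  write_table_tsv(tf$scan, file.path(d, "tf_scan.tsv"))
  write_table_tsv(tf$truth, file.path(d, "tf_truth.tsv"))

  kd <- gen_knockdown_panel(cf$sim$kd$n_cell_lines, cf$sim$n_genes,
                            cf$sim$kd$n_down_consistent, cf$sim$kd$per_line_extra_down,
                            cf$sim$kd$log2fc_effect, seed = cf$seed + 2L)
  for (i in seq_along(kd$panels))
    write_matrix_tsv(kd$panels[[i]]$expr, file.path(d, sprintf("kd_line%d_expr.tsv", i)))
  kd_groups <- do.call(rbind, lapply(kd$panels, function(p)
    data.frame(sample = colnames(p$expr), group = as.character(p$groups))))
  write_table_tsv(kd_groups, file.path(d, "kd_groups.tsv"))
  write_table_tsv(kd$truth, file.path(d, "kd_truth.tsv"))

  # gene sets for the enrichment stage: the planted consistently-down set
  # plus size-matched random sets
  set.seed(cf$seed + 3L)
  genes <- kd$truth$gene_id
  planted <- genes[kd$truth$planted_kd_down]
  collection <- c(list(PLANTED_DOWN = planted),
                  setNames(lapply(1:5, function(i) sample(genes, max(length(planted), 10L))),
                           sprintf("RANDOM_%d", 1:5)))
  write_gmt(collection, file.path(d, "gene_sets.gmt"))

  # promoter sequence with a planted methylated binding site for motif scanning
  set.seed(cf$seed + 4L)
  L <- 500L
  seq_chars <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  site <- c("C", "G", "G", "A", "A", "A")   # CpG then the GGAAA core
  at <- c(101L, 301L)
  for (s in at) seq_chars[s:(s + length(site) - 1L)] <- site
  promoter_seq <- paste(seq_chars, collapse = "")
  write_fasta(setNames(promoter_seq, "ALDH_promoter_synthetic"), file.path(d, "promoter.fa"))
  mask <- data.frame(gene_id = "mCpG", chrom = "ALDH_promoter_synthetic",
                     start = at - 1L, end = at, strand = "+")
  write_bed(mask, file.path(d, "methyl_mask.bed"))
  write_meme_pwm(demo_methyl_pwm(), file.path(d, "motif.meme"), name = "NFAT_like_methyl")

  val <- gen_validation_data(seed = cf$seed + 5L)
  write_matrix_tsv(val$clones$calls, file.path(d, "clone_calls.tsv"))
  write_table_tsv(data.frame(clone_id = rownames(val$clones$calls),
                             converted = val$clones$converted, total = val$clones$total),
                  file.path(d, "clone_conversion.tsv"))
  write_table_tsv(val$ct, file.path(d, "qpcr_ct.tsv"))
  write_table_tsv(val$chip, file.path(d, "chip_ct.tsv"))
  write_table_tsv(val$luciferase, file.path(d, "luciferase.tsv"))

  write_manifest(cf, "simulate", character(0), list.files(d))
}

read_groups <- function(path, samples) {
  g <- read_table_tsv(path)
  if (!all(c("sample", "group") %in% names(g))) stopf("groups table needs sample, group")
  factor(g$group[match(samples, g$sample)], levels = unique(g$group))
}

diff_stage <- function(cf) {
  sd_ <- file.path(cf$outdir, "sim")
  d <- stage_dir(cf, "diff")
  beta <- read_matrix_tsv(file.path(sd_, "beta.tsv"))
  probes <- read_table_tsv(file.path(sd_, "probes.tsv"))
  annot <- read_table_tsv(file.path(sd_, "tss.tsv"))
  expr <- read_matrix_tsv(file.path(sd_, "expr.tsv"))
  groups <- read_groups(file.path(sd_, "groups.tsv"), colnames(beta))

  meth <- diff_methylation(beta, probes, annot, groups,
                           p_cut = cf$methylation$p_cut, effect_cut = cf$methylation$effect_cut)
  expr_tab <- diff_expression(expr, groups,
                              p_cut = cf$expression$p_cut, effect_cut = cf$expression$effect_cut)
  write_table_tsv(as.data.frame(meth), file.path(d, "diff_methylation.tsv"))
  write_table_tsv(as.data.frame(expr_tab), file.path(d, "diff_expression.tsv"))

  kd_files <- list.files(sd_, pattern = "^kd_line\\d+_expr\\.tsv$", full.names = TRUE)
  kd_groups_path <- file.path(sd_, "kd_groups.tsv")
  for (f in kd_files) {
    kexpr <- read_matrix_tsv(f)
    kgroups <- read_groups(kd_groups_path, colnames(kexpr))
    tab <- diff_expression(kexpr, kgroups,
                           p_cut = cf$expression$p_cut, effect_cut = cf$expression$effect_cut)
    write_table_tsv(as.data.frame(tab),
                    file.path(d, sub("_expr\\.tsv$", "_diff.tsv", basename(f))))
  }
  write_manifest(cf, "diff",
                 c(file.path(sd_, c("beta.tsv", "probes.tsv", "tss.tsv", "expr.tsv",
                                    "groups.tsv")), kd_files),
                 list.files(d))
}

integrate_stage <- function(cf) {
  dd <- file.path(cf$outdir, "diff")
  d <- stage_dir(cf, "integrate")
  meth <- read_table_tsv(file.path(dd, "diff_methylation.tsv"))
  expr <- read_table_tsv(file.path(dd, "diff_expression.tsv"))
  cls <- classify_quadrants(meth, expr)
  write_table_tsv(cls$records, file.path(d, "integration.tsv"))
  write_table_tsv(cls$records[, c("gene_id", "delta_beta", "log2fc", "quadrant")],
                  file.path(d, "scatter.tsv"))
  write_json_summary(as.list(cls$counts), file.path(d, "quadrant_counts.json"))

  kd_files <- list.files(dd, pattern = "^kd_line\\d+_diff\\.tsv$", full.names = TRUE)
  if (length(kd_files) > 0) {
    panels <- lapply(kd_files, read_table_tsv)
    consistent <- knockdown_intersection(panels)
    targets <- candidate_direct_targets(consistent, meth)
    write_table_tsv(data.frame(gene_id = consistent), file.path(d, "consistent_down.tsv"))
    write_table_tsv(data.frame(gene_id = targets), file.path(d, "candidate_targets.tsv"))
  }
  write_manifest(cf, "integrate",
                 c(file.path(dd, c("diff_methylation.tsv", "diff_expression.tsv")), kd_files),
                 list.files(d))
}

screen_stage <- function(cf) {
  sd_ <- file.path(cf$outdir, "sim")
  d <- stage_dir(cf, "screen")
  scan <- read_table_tsv(file.path(sd_, "tf_scan.tsv"))
  res <- tf_screen(scan, ratio_cutoff = cf$screen$ratio_cutoff,
                   expression_floor = cf$screen$expression_floor, top_k = cf$screen$top_k)
  qc <- expression_qc(scan)
  write_table_tsv(as.data.frame(res), file.path(d, "screen_results.tsv"))
  write_table_tsv(qc, file.path(d, "expression_qc.tsv"))
  write_json_summary(list(classes = as.list(table(res$class)),
                          thresholds = as.list(attr(res, "thresholds")),
                          top = attr(res, "top")$tf_id),
                     file.path(d, "screen_summary.json"))
  write_manifest(cf, "screen", file.path(sd_, "tf_scan.tsv"), list.files(d))
}

scan_stage <- function(cf) {
  sd_ <- file.path(cf$outdir, "sim")
  d <- stage_dir(cf, "scan")
  seqs <- read_fasta(file.path(sd_, "promoter.fa"))
  pwm <- read_meme_pwm(file.path(sd_, "motif.meme"))
  hits <- list()
  for (nm in names(seqs)) {
    mask <- read_methyl_mask_bed(file.path(sd_, "methyl_mask.bed"), seq_name = nm)
    prom <- methyl_promoter(nm, seqs[[nm]], methyl_mask = mask)
    hits[[nm]] <- scan_motif(prom, pwm, p_threshold = cf$motif$p_threshold,
                             granularity = cf$motif$granularity)
  }
  hits <- do.call(rbind, hits)
  write_table_tsv(hits, file.path(d, "motif_hits.tsv"))
  if (nrow(hits) > 0)
    write_bed(data.frame(gene_id = sprintf("hit%d", seq_len(nrow(hits))),
                         chrom = hits$gene_id, start = hits$start, end = hits$end,
                         strand = hits$strand),
              file.path(d, "motif_hits.bed"))
  write_manifest(cf, "scan",
                 file.path(sd_, c("promoter.fa", "methyl_mask.bed", "motif.meme")),
                 list.files(d))
}

enrich_stage <- function(cf) {
  sd_ <- file.path(cf$outdir, "sim")
  dd <- file.path(cf$outdir, "diff")
  id <- file.path(cf$outdir, "integrate")
  d <- stage_dir(cf, "enrich")
  collection <- read_gmt(file.path(sd_, "gene_sets.gmt"))

  kd_files <- list.files(dd, pattern = "^kd_line1_diff\\.tsv$", full.names = TRUE)
  ranked_tab <- read_table_tsv(kd_files[1L])
  # ranking metric: moderated t of control vs knockdown (positive = higher in control)
  ranked <- setNames(-ranked_tab$t_mod, ranked_tab$feature_id)
  gs <- gsea(ranked, collection, weight = cf$gsea$weight, n_perm = cf$gsea$n_perm,
             seed = cf$seed + 6L)
  write_table_tsv(gs, file.path(d, "gsea.tsv"))

  consistent <- read_table_tsv(file.path(id, "consistent_down.tsv"))$gene_id
  universe <- ranked_tab$feature_id
  fo <- fisher_overrep(as.character(consistent), universe, collection,
                       p_cut = cf$fisher$p_cut)
  write_table_tsv(fo, file.path(d, "fisher_overrep.tsv"))
  write_manifest(cf, "enrich",
                 c(file.path(sd_, "gene_sets.gmt"), kd_files,
                   file.path(id, "consistent_down.tsv")),
                 list.files(d))
}

validate_stage <- function(cf) {
  sd_ <- file.path(cf$outdir, "sim")
  d <- stage_dir(cf, "validate")
  calls <- read_matrix_tsv(file.path(sd_, "clone_calls.tsv"))
  conv <- read_table_tsv(file.path(sd_, "clone_conversion.tsv"))
  clones <- clone_matrix(calls, converted = conv$converted, total = conv$total)
  meth_summary <- clone_methylation_summary(clones)
  conv_rate <- conversion_rate(clones)
  ct <- read_table_tsv(file.path(sd_, "qpcr_ct.tsv"))
  folds <- ddct(ct, housekeeping = "HPRT1", reference_condition = "control")
  chip <- read_table_tsv(file.path(sd_, "chip_ct.tsv"))
  pin <- percent_input(chip)
  luc <- read_table_tsv(file.path(sd_, "luciferase.tsv"))
  lr <- luciferase_relative(luc)

  write_table_tsv(folds, file.path(d, "ddct_folds.tsv"))
  write_table_tsv(pin, file.path(d, "chip_percent_input.tsv"))
  write_table_tsv(lr, file.path(d, "luciferase_folds.tsv"))
  write_json_summary(list(
    clone_overall_percent = meth_summary$overall_percent,
    clone_per_cpg_percent = meth_summary$per_cpg_percent,
    conversion_rate_percent = conv_rate$rate_percent,
    conversion_pass = conv_rate$pass
  ), file.path(d, "bisulfite_summary.json"))
  write_manifest(cf, "validate",
                 file.path(sd_, c("clone_calls.tsv", "clone_conversion.tsv", "qpcr_ct.tsv",
                                  "chip_ct.tsv", "luciferase.tsv")),
                 list.files(d))
}

#' Run one pipeline stage (or all of them)
#'
#' Stages read their inputs from, and write their outputs under,
#' `config$outdir` (`sim/`, `diff/`, `integrate/`, `screen/`, `scan/`,
#' `enrich/`, `validate/`); each stage writes a JSON manifest recording the
#' package version, seed, parameters and input checksums. No stage mutates
#' its inputs, and re-running a stage overwrites only that stage's outputs.
#' Identical configs (including the seed) produce identical outputs.
#'
#' @param stage one of `simulate`, `diff`, `integrate`, `screen`, `scan`,
#'   `enrich`, `validate`, `all`.
#' @param config a config list ([default_run_config()] supplies defaults and
#'   the full key set; unknown keys are rejected) or the path of a YAML file.
#' @return the resolved config, invisibly.
#' @export
run_pipeline <- function(stage = "all", config = default_run_config()) {
  stage <- match.arg(stage, PIPELINE_STAGES)
  cf <- load_run_config(config)
  dir.create(cf$outdir, recursive = TRUE, showWarnings = FALSE)
  stages <- if (stage == "all")
    c("simulate", "diff", "integrate", "screen", "scan", "enrich", "validate") else stage
  for (s in stages) {
    switch(s,
           simulate = sim_stage(cf),
           diff = diff_stage(cf),
           integrate = integrate_stage(cf),
           screen = screen_stage(cf),
           scan = scan_stage(cf),
           enrich = enrich_stage(cf),
           validate = validate_stage(cf))
  }
  invisible(cf)
}
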