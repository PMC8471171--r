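# Readers/writers for the plain-text formats the pipeline exchanges:
# feature x sample TSV matrices, BED promoter/mask annotation, FASTA
# promoter sequences, MEME-like PWM text (with optional M column), GMT gene
# set collections, and JSON summaries.

#' Write / read a feature x sample matrix as TSV
#'
#' The first column (`feature_id`) holds rownames; remaining columns are
#' samples with a header row of sample ids.
#'
#' @param mat numeric matrix with row and column names.
#' @param path file path.
#' @return `read_matrix_tsv` returns the matrix; writers return the path
#'   invisibly.
#' @export
write_matrix_tsv <- function(mat, path) {
  df <- data.frame(feature_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L || names(df)[1L] != "feature_id")
    stopf("'%s' is not a feature x sample TSV (expected a 'feature_id' first column)", path)
  mat <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(mat)) stopf("'%s' contains non-numeric sample columns", path)
  rownames(mat) <- df$feature_id
  mat
}

#' Write / read a plain data.frame as TSV
#' @param df data.frame.
#' @param path file path.
#' @export
write_table_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_table_tsv
#' @export
read_table_tsv <- function(path) {
  read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}

#' Write / read promoter windows as 6-column BED
#'
#' BED is 0-based half-open; the name column carries the gene id and the
#' score column is 0.
#'
#' @param windows data.frame `gene_id, chrom, start, end, strand` as from
#'   [promoter_windows()].
#' @param path file path.
#' @export
write_bed <- function(windows, path) {
  gr <- GenomicRanges::GRanges(
    windows$chrom,
    IRanges::IRanges(start = windows$start + 1L, end = windows$end),
    strand = windows$strand)
  names(gr) <- windows$gene_id
  GenomicRanges::mcols(gr)$score <- 0
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' @rdname write_bed
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  data.frame(gene_id = if (!is.null(gr$name)) gr$name else as.character(seq_along(gr)),
             chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             stringsAsFactors = FALSE)
}

#' Write / read promoter FASTA via Biostrings
#' @param sequences named character vector of DNA sequences.
#' @param path file path.
#' @export
write_fasta <- function(sequences, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(sequences), path)
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' Read / write gene-set collections in GMT format
#'
#' Reading delegates to [fgsea::gmtPathways()]; writing emits one line per
#' set: id, description ("na"), then members, tab-separated.
#'
#' @param collection named list of character vectors.
#' @param path file path.
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' @rdname read_gmt
#' @export
write_gmt <- function(collection, path) {
  lines <- vapply(names(collection), function(id) {
    paste(c(id, "na", collection[[id]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write / read a methylation-aware PWM as MEME-like text
#'
#' The text carries a `MOTIF` line, optional `Background letter frequencies`
#' line over the extended alphabet, and a `letter-probability matrix` header
#' (`alength= 5`) followed by one row per motif position in A C G T M order.
#' A 4-letter matrix (`alength= 4`) is accepted on read; its M emission then
#' equals the C emission.
#'
#' @param pwm a [methyl_pwm()].
#' @param path file path.
#' @param name motif name for the `MOTIF` line.
#' @export
write_meme_pwm <- function(pwm, path, name = "motif1") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME-like version 4 (extended alphabet ACGTM)", "",
               sprintf("MOTIF %s", name),
               paste("Background letter frequencies:",
                     paste(sprintf("%s %.6f", M_ALPHABET, pwm$background), collapse = " ")),
               sprintf("letter-probability matrix: alength= 5 w= %d", pwm$width)), con)
  for (j in seq_len(pwm$width))
    writeLines(paste(sprintf("%.6f", pwm$prob[, j]), collapse = " "), con)
  invisible(path)
}

#' @rdname write_meme_pwm
#' @export
read_meme_pwm <- function(path) {
  lines <- readLines(path)
  bg <- NULL
  bg_i <- grep("^Background letter frequencies", lines)
  if (length(bg_i) > 0) {
    toks <- strsplit(sub("^Background letter frequencies:?\\s*", "", lines[bg_i[1L]]),
                     "\\s+")[[1]]
    if (length(toks) %% 2L == 0L && length(toks) > 0L) {
      letters_ <- toks[seq(1, length(toks), by = 2)]
      vals <- as.numeric(toks[seq(2, length(toks), by = 2)])
      bg <- setNames(vals, toupper(letters_))
      if (!all(M_ALPHABET %in% names(bg))) {
        if (all(c("A", "C", "G", "T") %in% names(bg)) && !"M" %in% names(bg))
          bg <- c(bg, M = unname(bg[["C"]]))
      }
      bg <- bg[M_ALPHABET]
    }
  }
  hdr_i <- grep("^letter-probability matrix", lines)
  if (length(hdr_i) == 0L) stopf("'%s' has no letter-probability matrix header", path)
  hdr <- lines[hdr_i[1L]]
  alength <- as.integer(sub(".*alength=\\s*(\\d+).*", "\\1", hdr))
  w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", hdr))
  if (!alength %in% c(4L, 5L)) stopf("alength must be 4 or 5, got %d", alength)
  rows <- lines[(hdr_i[1L] + 1L):(hdr_i[1L] + w)]
  prob <- vapply(rows, function(l) as.numeric(strsplit(trimws(l), "\\s+")[[1]]),
                 numeric(alength))
  dimnames(prob) <- list(if (alength == 5L) M_ALPHABET else c("A", "C", "G", "T"), NULL)
  # the stored matrix already carries its pseudocount; renormalise only
  methyl_pwm(prob, background = bg, pseudocount = 0)
}

#' Read a methylated-CpG mask from BED
#'
#' Expects single-base BED features (0-based half-open) marking methylated
#' cytosine positions; returns the 0-based positions for the named sequence,
#' relative to `offset`.
#'
#' @param path BED file path.
#' @param seq_name sequence/chromosome name to extract (default: all rows).
#' @param offset 0-based start of the target sequence on that chromosome.
#' @export
read_methyl_mask_bed <- function(path, seq_name = NULL, offset = 0L) {
  bed <- read_bed(path)
  if (!is.null(seq_name)) bed <- bed[bed$chrom == seq_name, , drop = FALSE]
  as.integer(bed$start) - as.integer(offset)
}

#' Write a list/summary as JSON
#' @param x a list of scalars/vectors.
#' @param path file path.
#' @export
write_json_summary <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
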