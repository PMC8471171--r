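# Methylation-aware PWM scanning. Sequences are encoded over the extended
# alphabet {A, C, G, T, M}, where M is 5-methylcytosine in CpG context;
# CpG methylation is treated as symmetric, so the complementary cytosine on
# the minus strand is likewise M. Windows are scored as sum log2(emission /
# background) and p-values are exact tail probabilities of the window score
# under the background model, computed by dynamic programming on an
# integerized score grid (the classic FIMO construction).

M_ALPHABET <- c("A", "C", "G", "T", "M")
COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", M = "G")

#' Promoter sequence with a methylated-CpG mask
#'
#' @param gene_id gene identifier.
#' @param sequence DNA string over A/C/G/T.
#' @param methyl_mask integer vector of 0-based positions of methylated
#'   cytosines. Each position must sit in CpG context: either the C of a CpG
#'   (C followed by G) or the plus-strand G whose minus-strand partner C is
#'   methylated (G preceded by C). Masks are normalised to the plus-strand C
#'   position of each CpG.
#' @param offset 0-based genomic start of the sequence (for reporting).
#' @return a `methyl_promoter` object.
#' @export
methyl_promoter <- function(gene_id, sequence, methyl_mask = integer(0), offset = 0L) {
  sequence <- toupper(as.character(sequence))
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  if (!all(chars %in% c("A", "C", "G", "T")))
    stopf("sequence must contain only A/C/G/T")
  L <- length(chars)
  methyl_mask <- as.integer(methyl_mask)
  if (any(methyl_mask < 0 | methyl_mask >= L))
    stopf("methyl mask positions must lie inside the sequence")
  # normalise each masked position to the C of its CpG
  norm <- integer(0)
  for (p in methyl_mask) {
    if (chars[p + 1L] == "C" && p + 2L <= L && chars[p + 2L] == "G") {
      norm <- c(norm, p)
    } else if (chars[p + 1L] == "G" && p >= 1L && chars[p] == "C") {
      norm <- c(norm, p - 1L)
    } else {
      stopf("masked position %d is not in CpG context", p)
    }
  }
  structure(list(gene_id = as.character(gene_id), sequence = sequence,
                 methyl_mask = sort(unique(norm)), offset = as.integer(offset)),
            class = "methyl_promoter")
}

#' Encode a promoter over the extended methylation alphabet, per strand
#'
#' On the plus strand every masked CpG cytosine becomes M. The minus-strand
#' encoding is the reverse complement in which the cytosine pairing the
#' plus-strand G of each methylated CpG is likewise M (CpG methylation is
#' symmetric).
#'
#' @param promoter a [methyl_promoter()].
#' @return list with character strings `plus` and `minus` (minus written
#'   5' to 3').
#' @export
encode_methylation <- function(promoter) {
  if (!inherits(promoter, "methyl_promoter")) stopf("need a methyl_promoter object")
  chars <- strsplit(promoter$sequence, "", fixed = TRUE)[[1]]
  L <- length(chars)
  plus <- chars
  if (length(promoter$methyl_mask) > 0)
    plus[promoter$methyl_mask + 1L] <- "M"
  minus <- rev(unname(COMPLEMENT[chars]))
  # plus-strand G of a methylated CpG at c-position p sits at p+1; its
  # minus-strand partner C lands at reverse index L-1-(p+1) (0-based)
  if (length(promoter$methyl_mask) > 0)
    minus[L - 1L - promoter$methyl_mask] <- "M"
  list(plus = paste(plus, collapse = ""), minus = paste(minus, collapse = ""))
}

#' Methylation-aware position weight matrix
#'
#' @param prob numeric matrix of emission probabilities: either 5 rows named
#'   A, C, G, T, M (columns = motif positions) or 4 rows A, C, G, T, in which
#'   case the M emission is set equal to the C emission (the motif is
#'   indifferent to methylation).
#' @param background named probabilities over the extended alphabet (strictly
#'   positive, summing to 1); default uniform 0.2 per letter.
#' @param pseudocount added to every emission before renormalising (keeps
#'   log-odds finite; default 1e-4).
#' @return a `methyl_pwm` with elements `prob` (5 x width), `background`,
#'   `width` and `log_odds` (log2 emission/background).
#' @export
methyl_pwm <- function(prob, background = NULL, pseudocount = 1e-4) {
  prob <- as.matrix(prob)
  if (is.null(rownames(prob))) stopf("'prob' needs rownames over the alphabet")
  rownames(prob) <- toupper(rownames(prob))
  if (identical(sort(rownames(prob)), sort(c("A", "C", "G", "T")))) {
    prob <- rbind(prob, M = prob["C", , drop = FALSE])
    rownames(prob)[5L] <- "M"
  }
  if (!identical(sort(rownames(prob)), sort(M_ALPHABET)))
    stopf("'prob' rows must be A, C, G, T (and optionally M)")
  prob <- prob[M_ALPHABET, , drop = FALSE]
  if (any(prob < 0)) stopf("emission probabilities must be >= 0")
  prob <- sweep(prob + pseudocount, 2L, colSums(prob + pseudocount), "/")
  if (any(abs(colSums(prob) - 1) > 1e-9))
    stopf("each motif position must sum to 1")
  if (is.null(background)) background <- setNames(rep(0.2, 5L), M_ALPHABET)
  background <- background[M_ALPHABET]
  if (any(is.na(background)) || any(background <= 0))
    stopf("background must be strictly positive over A, C, G, T, M")
  background <- background / sum(background)
  structure(list(prob = prob, background = background, width = ncol(prob),
                 log_odds = log2(sweep(prob, 1L, background, "/"))),
            class = "methyl_pwm")
}

#' @export
print.methyl_pwm <- function(x, ...) {
  cat(sprintf("Methylation-aware PWM, width %d\n", x$width))
  print(round(x$prob, 3), ...)
  invisible(x)
}

# integerized per-position scores (units of 'granularity' bits)
integer_scores <- function(pwm, granularity) {
  round(pwm$log_odds / granularity)
}

#' Exact p-value table for PWM window scores
#'
#' Computes `p(s) = P(window score >= s)` under the background model by
#' dynamic programming: per-position log-odds scores are integerized at the
#' given granularity and their distributions convolved across positions,
#' weighting each letter by its background probability. The resulting tail
#' is exact for the integerized scores (which [scan_motif()] also uses, so
#' scores and p-values are mutually consistent) and monotone non-increasing.
#'
#' @param pwm a [methyl_pwm()].
#' @param granularity score-bin width in bits (default 1e-3).
#' @return a `pwm_pvalue_table`: list with `granularity`, integer score grid
#'   `grid`, tail probabilities `tail`, and the integerized per-position
#'   score matrix `int_scores`.
#' @export
exact_pvalue_table <- function(pwm, granularity = 1e-3) {
  if (!inherits(pwm, "methyl_pwm")) stopf("need a methyl_pwm object")
  granularity <- assert_number(granularity, "granularity")
  if (granularity <= 0) stopf("granularity must be > 0")
  si <- integer_scores(pwm, granularity)
  bg <- pwm$background

  lo <- 0L; hi <- 0L
  dist <- 1          # probability over integer scores lo..hi
  for (j in seq_len(pwm$width)) {
    smin <- min(si[, j]); smax <- max(si[, j])
    new_lo <- lo + smin; new_hi <- hi + smax
    new <- numeric(new_hi - new_lo + 1L)
    for (a in M_ALPHABET) {
      s <- si[a, j]
      idx <- (lo + s - new_lo + 1L):(hi + s - new_lo + 1L)
      new[idx] <- new[idx] + dist * bg[[a]]
    }
    dist <- new; lo <- new_lo; hi <- new_hi
  }
  tail <- rev(cumsum(rev(dist)))
  tail <- pmin(tail, 1)
  structure(list(granularity = granularity, grid = lo:hi, tail = tail,
                 int_scores = si, width = pwm$width),
            class = "pwm_pvalue_table")
}

# p-value of integer scores against a pwm_pvalue_table
lookup_pvalue <- function(table, int_score) {
  idx <- int_score - table$grid[1L] + 1L
  idx <- pmin(pmax(idx, 1L), length(table$tail))
  p <- table$tail[idx]
  p[int_score > table$grid[length(table$grid)]] <- 0
  p[int_score < table$grid[1L]] <- 1
  pmax(p, .Machine$double.xmin)
}

score_windows <- function(encoded, int_scores, width) {
  chars <- strsplit(encoded, "", fixed = TRUE)[[1]]
  idx <- match(chars, M_ALPHABET)
  n_win <- length(chars) - width + 1L
  if (n_win < 1L) return(integer(0))
  total <- integer(n_win)
  for (k in seq_len(width)) {
    total <- total + int_scores[cbind(idx[k:(k + n_win - 1L)], k)]
  }
  total
}

#' Scan a promoter with a methylation-aware PWM
#'
#' Scores every window on both strands of the methylation-encoded promoter
#' as the sum of log2(emission/background) terms, assigns each window the
#' exact p-value of its score under the background model, reports hits with
#' p below the threshold (sorted by p, then position), and attaches BH
#' q-values computed over all tested windows.
#'
#' @param promoter a [methyl_promoter()].
#' @param pwm a [methyl_pwm()].
#' @param p_threshold report windows with p <= this value (default 1e-4).
#' @param granularity score integerization bin in bits (default 1e-3).
#' @return data.frame `gene_id, start, end, strand, score, p, q` (start
#'   0-based in plus-strand sequence coordinates plus the promoter offset,
#'   end exclusive; score in bits). A motif wider than the sequence warns
#'   and returns zero rows.
#' @export
scan_motif <- function(promoter, pwm, p_threshold = 1e-4, granularity = 1e-3) {
  if (!inherits(promoter, "methyl_promoter")) stopf("need a methyl_promoter object")
  if (!inherits(pwm, "methyl_pwm")) stopf("need a methyl_pwm object")
  L <- nchar(promoter$sequence)
  w <- pwm$width
  empty <- data.frame(gene_id = character(0), start = integer(0), end = integer(0),
                      strand = character(0), score = numeric(0), p = numeric(0),
                      q = numeric(0), stringsAsFactors = FALSE)
  if (w > L) {
    warning(sprintf("motif width %d exceeds sequence length %d", w, L))
    return(empty)
  }
  enc <- encode_methylation(promoter)
  tab <- exact_pvalue_table(pwm, granularity)
  si <- tab$int_scores

  sp <- score_windows(enc$plus, si, w)
  sm <- score_windows(enc$minus, si, w)
  n_win <- L - w + 1L
  starts_plus <- 0:(n_win - 1L)
  starts_minus <- L - w - (0:(n_win - 1L))   # minus window j maps to plus start L-w-j

  all_int <- c(sp, sm)
  all_p <- lookup_pvalue(tab, all_int)
  all_q <- bh_adjust(all_p)
  hits <- data.frame(
    gene_id = promoter$gene_id,
    start = promoter$offset + c(starts_plus, starts_minus),
    end = promoter$offset + c(starts_plus, starts_minus) + w,
    strand = rep(c("+", "-"), each = n_win),
    score = all_int * tab$granularity,
    p = all_p, q = all_q,
    stringsAsFactors = FALSE)
  hits <- hits[hits$p <= p_threshold, , drop = FALSE]
  hits <- hits[order(hits$p, hits$start), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}
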