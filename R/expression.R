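#' Compute FPKM from fragment counts
#'
#' Fragments per kilobase of exon per million mapped reads:
#' `fpkm = fragments / ((mapped_reads / 1e6) * (exon_length_bp / 1e3))`.
#'
#' @param fragments non-negative fragment counts (vector, possibly named by
#'   gene).
#' @param exon_length_bp positive exon lengths in base pairs.
#' @param mapped_reads total mapped reads in the sample (scalar > 0).
#' @return numeric FPKM values, same names as `fragments`.
#' @examples
#' compute_fpkm(c(gA = 10), 1000, 1e6)   # 10
#' compute_fpkm(100, 2000, 1e7)          # 5
#' @export
compute_fpkm <- function(fragments, exon_length_bp, mapped_reads) {
  if (length(mapped_reads) != 1L || !is.finite(mapped_reads) ||
      mapped_reads <= 0) {
    stop("mapped_reads must be a single positive count", call. = FALSE)
  }
  if (any(exon_length_bp <= 0)) {
    stop("exon lengths must be positive", call. = FALSE)
  }
  if (any(fragments < 0)) stop("fragment counts must be >= 0", call. = FALSE)
  fragments / ((mapped_reads / 1e6) * (exon_length_bp / 1e3))
}

#' Read a gene x sample FPKM table
#'
#' TSV with first column `gene_id` and one column per sample.
#'
#' @param path TSV file.
#' @return numeric matrix (genes x samples) with dimnames.
#' @export
read_expression <- function(path) {
  df <- read_tsv(path)
  if (names(df)[1L] != "gene_id") {
    stop("expression table must start with a 'gene_id' column", call. = FALSE)
  }
  if (anyDuplicated(df$gene_id)) stop("duplicate gene_id", call. = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df$gene_id
  storage.mode(m) <- "double"
  if (any(m < 0)) stop("FPKM values must be >= 0", call. = FALSE)
  m
}

#' Discretize expression into high/moderate/low states
#'
#' Per sample, genes in the top `high_q` fraction of expression are called
#' high (+1), genes in the bottom `low_q` fraction low (-1), and the rest
#' moderate (0). Cutoffs are empirical order statistics with
#' `k = ceiling(q * n)`: the high cutoff is the k-th largest value, the low
#' cutoff the k-th smallest. The rule is rank-based, so any strictly
#' monotone transform of a sample leaves the states unchanged.
#'
#' Ties: a cutoff value shared by more genes than the nominal fraction
#' admits drops the tied genes back to moderate, so each extreme class has
#' at most `ceiling(q * n)` members (exactly that many when values are
#' distinct). In the degenerate all-equal sample every gene is moderate.
#'
#' @param table numeric genes x samples matrix (or a single named vector).
#' @param low_q,high_q extreme fractions; defaults 0.15 and 0.15, the
#'   conventional highest-15\%/lowest-15\% rule. Must satisfy
#'   `low_q + high_q < 1`.
#' @return object of class `expression_states`: list with `states` (integer
#'   genes x samples matrix in `{-1, 0, 1}`), `cutoffs` (per-sample low and
#'   high cutoff values, FPKM units), `low_q`, `high_q`.
#' @examples
#' m <- cbind(s1 = c(1:20))
#' rownames(m) <- paste0("g", 1:20)
#' discretize(m)$states[18:20, 1]  # the top three genes are +1
#' @export
discretize <- function(table, low_q = 0.15, high_q = 0.15) {
  if (is.null(dim(table))) {
    table <- matrix(table, ncol = 1L,
                    dimnames = list(names(table), "sample"))
  }
  if (!(low_q > 0 && high_q > 0 && low_q + high_q < 1)) {
    stop("need 0 < low_q, 0 < high_q and low_q + high_q < 1", call. = FALSE)
  }
  n <- nrow(table)
  if (n < ceiling(1 / min(low_q, high_q))) {
    warning("fewer than ", ceiling(1 / min(low_q, high_q)),
            " genes: quantile cutoffs may coincide")
  }
  states <- matrix(0L, n, ncol(table), dimnames = dimnames(table))
  cutoffs <- data.frame(sample = colnames(table),
                        low_cutoff = NA_real_, high_cutoff = NA_real_,
                        stringsAsFactors = FALSE)
  k_hi <- ceiling(high_q * n)
  k_lo <- ceiling(low_q * n)
  for (j in seq_len(ncol(table))) {
    v <- table[, j]
    sv <- sort(v)
    c_lo <- sv[k_lo]
    c_hi <- sv[n - k_hi + 1L]
    hi <- if (sum(v >= c_hi) <= k_hi) v >= c_hi else v > c_hi
    lo <- if (sum(v <= c_lo) <= k_lo) v <= c_lo else v < c_lo
    s <- integer(n)
    s[hi] <- 1L
    s[lo] <- -1L
    s[hi & lo] <- 0L  # degenerate overlap: no evidence either way
    states[, j] <- s
    cutoffs$low_cutoff[j] <- c_lo
    cutoffs$high_cutoff[j] <- c_hi
  }
  structure(list(states = states, cutoffs = cutoffs,
                 low_q = low_q, high_q = high_q),
            class = "expression_states")
}

#' @export
print.expression_states <- function(x, ...) {
  cat("Expression states: ", nrow(x$states), " genes x ", ncol(x$states),
      " samples (low ", x$low_q * 100, "%, high ", x$high_q * 100, "%)\n",
      sep = "")
  tab <- apply(x$states, 2L, function(s) table(factor(s, c(-1, 0, 1))))
  rownames(tab) <- c("low", "moderate", "high")
  print(tab)
  invisible(x)
}

#' Write gene states as TSV (`gene_id  sample  state`)
#' @param states an `expression_states` object.
#' @param path output path.
#' @param header optional comment lines.
#' @export
write_states <- function(states, path, header = character()) {
  m <- states$states
  df <- data.frame(gene_id = rep(rownames(m), ncol(m)),
                   sample = rep(colnames(m), each = nrow(m)),
                   state = as.integer(m), stringsAsFactors = FALSE)
  write_tsv(df, path, header)
}

#' Per-gene expression fold changes between two samples
#'
#' `fc = (fpkm2 + pseudocount) / (fpkm1 + pseudocount)`. Genes with
#' `fc > up_threshold` (default 2) are called up-regulated, genes with
#' `fc < down_threshold` (default 0.5) down-regulated, the rest unchanged.
#' The default pseudocount of 1 guards against zero FPKM; `pseudocount = 0`
#' gives the literal ratio.
#'
#' @param table genes x samples FPKM matrix.
#' @param sample1,sample2 column names; fold change is sample2 over sample1.
#' @param pseudocount added to both values before the ratio.
#' @param up_threshold,down_threshold call thresholds.
#' @return data frame `gene_id`, `fpkm1`, `fpkm2`, `fc`, `call`.
#' @export
gene_fold_changes <- function(table, sample1, sample2, pseudocount = 1,
                              up_threshold = 2, down_threshold = 0.5) {
  for (s in c(sample1, sample2)) {
    if (!s %in% colnames(table)) {
      stop("unknown sample id: ", s, call. = FALSE)
    }
  }
  f1 <- table[, sample1]
  f2 <- table[, sample2]
  fc <- (f2 + pseudocount) / (f1 + pseudocount)
  call <- ifelse(fc > up_threshold, "up",
                 ifelse(fc < down_threshold, "down", "unchanged"))
  data.frame(gene_id = rownames(table), fpkm1 = unname(f1),
             fpkm2 = unname(f2), fc = unname(fc), call = unname(call),
             stringsAsFactors = FALSE)
}
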