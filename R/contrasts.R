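#' All pairwise differential-expression contrasts between isolations
#'
#' Runs one contrast per unordered pair of isolations and returns normalized
#' log2 fold changes with BH-adjusted p-values.  Two engines are available:
#'
#' * `"deseq2"` (default): a single negative-binomial GLM fit across all
#'   isolations via [DESeq2::DESeq()], Wald contrasts per pair.  Fold
#'   changes are median-of-ratios normalized; `padj` is DESeq2's BH value
#'   (genes filtered out by DESeq2, `padj = NA`, are treated as
#'   not significant).
#' * `"welch"`: a self-contained two-sided Welch t-test per gene on
#'   `log2(TPM + pseudocount)` across replicates, with
#'   `log2FC = log2(mean TPM_a + pc) - log2(mean TPM_b + pc)` and BH
#'   adjustment within each contrast.  When both groups have zero variance
#'   and equal means the p-value is 1.
#'
#' Externally computed contrast tables (e.g. from another DESeq2 run) can be
#' loaded with [read_contrast_table()] and passed straight to
#' [classify_genes()].
#'
#' @param counts A `count_matrix` or a counts tibble (`gene_id`,
#'   `length_bp`, sample columns).
#' @param samples Sample sheet tibble (`sample`, `isolation`, `replicate`);
#'   taken from `counts` when it is a `count_matrix`.
#' @param engine `"deseq2"` or `"welch"`.
#' @param pseudocount Pseudocount for the Welch engine's TPM log transform.
#' @return A tibble with `gene_id`, `contrast` (`"a_vs_b"`), `iso_a`,
#'   `iso_b`, `log2fc` (positive = higher in `iso_a`), `pvalue`, `p_adj`.
#' @export
pairwise_contrasts <- function(counts, samples = NULL,
                               engine = c("deseq2", "welch"),
                               pseudocount = 1) {
  engine <- match.arg(engine)
  if (inherits(counts, "count_matrix")) {
    if (is.null(samples)) samples <- counts$samples
    counts <- counts$counts
  }
  if (is.null(samples)) stop("`samples` sheet is required")
  iso <- sort(unique(samples$isolation))
  if (length(iso) < 2) stop("need at least two isolations")
  reps <- table(samples$isolation)
  if (engine == "welch" && any(reps < 2)) {
    stop("welch engine needs >= 2 replicates per isolation")
  }
  sample_cols <- setdiff(names(counts), c("gene_id", "length_bp"))
  missing <- setdiff(samples$sample, sample_cols)
  if (length(missing)) {
    stop("samples missing from count matrix: ",
         paste(missing, collapse = ", "))
  }
  pairs <- utils::combn(iso, 2)
  switch(engine,
         deseq2 = .contrasts_deseq2(counts, samples, pairs),
         welch = .contrasts_welch(counts, samples, pairs, pseudocount))
}

.contrasts_deseq2 <- function(counts, samples, pairs) {
  mat <- as.matrix(counts[, samples$sample])
  storage.mode(mat) <- "integer"
  rownames(mat) <- counts$gene_id
  coldata <- data.frame(isolation = factor(samples$isolation))
  dds <- suppressMessages(DESeq2::DESeqDataSetFromMatrix(
    countData = mat, colData = coldata, design = ~isolation))
  dds <- suppressMessages(DESeq2::DESeq(dds, quiet = TRUE))
  purrr::map_dfr(seq_len(ncol(pairs)), function(k) {
    a <- pairs[1, k]; b <- pairs[2, k]
    r <- DESeq2::results(dds, contrast = c("isolation", a, b))
    tibble::tibble(
      gene_id = rownames(r),
      contrast = paste0(a, "_vs_", b),
      iso_a = a, iso_b = b,
      log2fc = ifelse(is.na(r$log2FoldChange), 0, r$log2FoldChange),
      pvalue = ifelse(is.na(r$pvalue), 1, r$pvalue),
      p_adj = ifelse(is.na(r$padj), 1, r$padj)
    )
  })
}

.contrasts_welch <- function(counts, samples, pairs, pseudocount) {
  tpm <- compute_tpm(counts)
  tpm_wide <- tidyr::pivot_wider(tpm, names_from = "sample",
                                 values_from = "tpm")
  gene_id <- tpm_wide$gene_id
  tm <- as.matrix(tpm_wide[, -1])
  lt <- log2(tm + pseudocount)
  purrr::map_dfr(seq_len(ncol(pairs)), function(k) {
    a <- pairs[1, k]; b <- pairs[2, k]
    sa <- samples$sample[samples$isolation == a]
    sb <- samples$sample[samples$isolation == b]
    xa <- lt[, sa, drop = FALSE]; xb <- lt[, sb, drop = FALSE]
    na <- ncol(xa); nb <- ncol(xb)
    ma <- rowMeans(xa); mb <- rowMeans(xb)
    va <- apply(xa, 1, stats::var); vb <- apply(xb, 1, stats::var)
    se2 <- va / na + vb / nb
    tstat <- (ma - mb) / sqrt(se2)
    df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
    p <- 2 * stats::pt(-abs(tstat), df)
    # degenerate cases: no variance anywhere
    zero_var <- se2 == 0
    p[zero_var & ma == mb] <- 1
    p[zero_var & ma != mb] <- 0
    p[is.na(p)] <- 1
    lfc <- log2(rowMeans(tm[, sa, drop = FALSE]) + pseudocount) -
      log2(rowMeans(tm[, sb, drop = FALSE]) + pseudocount)
    tibble::tibble(
      gene_id = gene_id,
      contrast = paste0(a, "_vs_", b),
      iso_a = a, iso_b = b,
      log2fc = lfc,
      pvalue = p,
      p_adj = stats::p.adjust(p, method = "BH")
    )
  })
}

#' Read or write a contrast table in the package TSV schema
#'
#' The schema is `gene_id`, `contrast` (`"a_vs_b"`), `log2fc`, `p_adj`
#' (optionally `pvalue`, `iso_a`, `iso_b`).  Missing `iso_a`/`iso_b` are
#' recovered from the contrast string.
#'
#' @param path TSV path.
#' @param x Contrast tibble from [pairwise_contrasts()].
#' @return A validated contrast tibble.
#' @export
read_contrast_table <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE)
  need <- c("gene_id", "contrast", "log2fc", "p_adj")
  if (!all(need %in% names(x))) {
    stop("contrast table must have columns: ", paste(need, collapse = ", "))
  }
  if (!all(c("iso_a", "iso_b") %in% names(x))) {
    parts <- stringr::str_split_fixed(x$contrast, "_vs_", 2)
    x$iso_a <- parts[, 1]
    x$iso_b <- parts[, 2]
  }
  if (any(x$p_adj < 0 | x$p_adj > 1, na.rm = TRUE)) {
    stop("p_adj outside [0, 1]")
  }
  x
}

#' @rdname read_contrast_table
#' @export
write_contrast_table <- function(x, path) {
  readr::write_tsv(x, path)
  invisible(path)
}
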