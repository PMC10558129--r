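#' Classify genes by the pairwise-contrast expression rules
#'
#' Applies the rule set used to define the gene classes:
#'
#' * `neoblast`: `log2fc > 1` and `p_adj < 0.05` versus **every** other
#'   isolation;
#' * a tissue class (`brain`, `epidermis`, `intestine`): the same holds for
#'   that tissue versus every other isolation including the neoblasts;
#' * `constitutive`: mean TPM above `expressed_tpm` in every isolation and
#'   **no** contrast involving the gene satisfies `|log2fc| > 1` and
#'   `p_adj < 0.05`;
#' * everything else: `unclassified`.
#'
#' All inequalities are strict, so a gene at exactly `log2fc = 1` in one
#' required contrast is not classified.  Genes absent from any contrast are
#' `unclassified` with a warning.  The reported `expression_bin` is the
#' [bin_expression()] bin of the gene's best (highest mean TPM) isolation.
#'
#' @param contrasts Contrast tibble from [pairwise_contrasts()] or
#'   [read_contrast_table()] covering all isolation pairs.
#' @param tpm Long TPM tibble from [compute_tpm()].
#' @param samples Sample sheet (`sample`, `isolation`).
#' @param lfc_threshold Fold-change threshold on the log2 scale.
#' @param alpha Adjusted p-value threshold.
#' @param expressed_tpm Mean-TPM threshold for "expressed in an isolation".
#' @param focal_classes Classes to call (default: the four specific classes).
#' @return A tibble with `gene_id`, `class`, `expression_bin`.
#' @export
classify_genes <- function(contrasts, tpm, samples,
                           lfc_threshold = 1, alpha = 0.05,
                           expressed_tpm = 10,
                           focal_classes = c("brain", "epidermis",
                                             "intestine", "neoblast")) {
  iso <- sort(unique(samples$isolation))
  mt <- mean_tpm_by_isolation(tpm, samples)
  gene_ids <- sort(unique(mt$gene_id))

  in_contrasts <- unique(contrasts$gene_id)
  absent <- setdiff(gene_ids, in_contrasts)
  if (length(absent)) {
    warning(length(absent),
            " gene(s) absent from the contrast table; left unclassified")
  }

  # gene x contrast signed fold change / significance lookup
  key <- function(a, b) paste0(a, "_vs_", b)
  sig_tbl <- contrasts |>
    dplyr::mutate(sig = abs(.data$log2fc) > lfc_threshold &
                    .data$p_adj < alpha)
  sig_any <- sig_tbl |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(any_sig = any(.data$sig), .groups = "drop")

  class <- stats::setNames(rep("unclassified", length(gene_ids)), gene_ids)

  for (cl in focal_classes) {
    others <- setdiff(iso, cl)
    if (!cl %in% iso) next
    ok <- stats::setNames(rep(TRUE, length(gene_ids)), gene_ids)
    covered <- stats::setNames(rep(TRUE, length(gene_ids)), gene_ids)
    for (o in others) {
      cc <- contrasts[contrasts$contrast == key(cl, o), ]
      flip <- 1
      if (!nrow(cc)) {
        cc <- contrasts[contrasts$contrast == key(o, cl), ]
        flip <- -1
      }
      if (!nrow(cc)) stop("missing contrast between ", cl, " and ", o)
      up <- stats::setNames(flip * cc$log2fc > lfc_threshold &
                              cc$p_adj < alpha, cc$gene_id)
      here <- gene_ids %in% names(up)
      covered <- covered & here
      ok[here] <- ok[here] & up[gene_ids[here]]
      ok[!here] <- FALSE
    }
    class[ok & covered] <- cl
  }

  min_tpm <- mt |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(min_tpm = min(.data$mean_tpm), .groups = "drop")
  const <- min_tpm$gene_id[min_tpm$min_tpm > expressed_tpm]
  never_sig <- sig_any$gene_id[!sig_any$any_sig]
  is_const <- gene_ids %in% const & gene_ids %in% never_sig &
    gene_ids %in% in_contrasts
  class[is_const & class == "unclassified"] <- "constitutive"

  best <- mt |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(best_tpm = max(.data$mean_tpm), .groups = "drop")
  tibble::tibble(
    gene_id = gene_ids,
    class = unname(class[gene_ids]),
    expression_bin = .tpm_bin(best$best_tpm[match(gene_ids,
                                                  best$gene_id)])
  )
}

#' One-shot expression classification
#'
#' Convenience wrapper: TPM, pairwise contrasts, and the classification
#' rules in one call, returning a fitted-object-style result with
#' [generics::tidy()] / [generics::glance()] / [ggplot2::autoplot()]
#' methods.
#'
#' @inheritParams pairwise_contrasts
#' @inheritParams classify_genes
#' @param ... Passed to [classify_genes()].
#' @return A `gene_classification` object (list with `classes`,
#'   `contrasts`, `tpm`, `samples`, `engine`).
#' @export
classify_expression <- function(counts, samples = NULL,
                                engine = c("deseq2", "welch"),
                                pseudocount = 1, ...) {
  engine <- match.arg(engine)
  if (inherits(counts, "count_matrix") && is.null(samples)) {
    samples <- counts$samples
  }
  tpm <- compute_tpm(counts)
  contrasts <- pairwise_contrasts(counts, samples, engine = engine,
                                  pseudocount = pseudocount)
  classes <- classify_genes(contrasts, tpm, samples, ...)
  structure(list(classes = classes, contrasts = contrasts, tpm = tpm,
                 samples = samples, engine = engine),
            class = "gene_classification")
}

#' @export
print.gene_classification <- function(x, ...) {
  cat("<gene_classification> engine:", x$engine, "\n")
  print(table(x$classes$class))
  invisible(x)
}

#' Tidy a gene classification
#'
#' @param x A `gene_classification` from [classify_expression()].
#' @param ... Unused.
#' @return `tidy()`: the per-gene class table; `glance()`: a one-row
#'   summary with class counts.
#' @method tidy gene_classification
#' @export
tidy.gene_classification <- function(x, ...) {
  x$classes
}

#' @rdname tidy.gene_classification
#' @method glance gene_classification
#' @export
glance.gene_classification <- function(x, ...) {
  counts <- table(factor(x$classes$class,
                         levels = stemchrom_gene_classes()))
  out <- tibble::as_tibble(as.list(counts))
  dplyr::bind_cols(
    tibble::tibble(n_genes = nrow(x$classes), engine = x$engine), out)
}

#' @rdname tidy.gene_classification
#' @param object A `gene_classification`.
#' @method autoplot gene_classification
#' @export
autoplot.gene_classification <- function(object, ...) {
  df <- object$classes |>
    dplyr::count(.data$class, .data$expression_bin)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$class, y = .data$n,
                                   fill = .data$expression_bin)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "gene class", y = "genes",
                  fill = "expression bin") +
    ggplot2::theme_minimal()
}
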