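#' Per-gene binned signal around the TSS
#'
#' Counts fragments overlapping fixed-width bins in a strand-oriented window
#' around every TSS (upstream negative) and scales counts to RPKM
#' (`count * 1e9 / (bin_bp * library_size)`).  This is the per-gene matrix
#' underlying [tss_metaprofile()]; it is exported so callers can compute
#' per-gene statistics such as the position of maximum signal.
#'
#' @param fragments Fragment tibble (0-based half-open) with `sample`.
#' @param genes Gene tibble with `gene_id`, `contig`, `tss`, `strand` (and
#'   optionally `class`).
#' @param half_width Half window width in bp.
#' @param bin_width Bin size in bp; must divide `2 * half_width`.
#' @param library_size Optional named per-sample totals.
#' @param contig_lengths Optional named contig lengths; windows beyond the
#'   contig are truncated with a warning.
#' @return A tibble with `gene_id`, `sample`, `position` (bin center,
#'   bp relative to TSS), `count`, `rpkm`.
#' @export
tss_signal_matrix <- function(fragments, genes, half_width = 1000,
                              bin_width = 10, library_size = NULL,
                              contig_lengths = NULL) {
  centers <- tibble::tibble(id = genes$gene_id, contig = genes$contig,
                            center = genes$tss, strand = genes$strand)
  out <- .binned_window_counts(fragments, centers, half_width, bin_width,
                               library_size, contig_lengths)
  names(out)[names(out) == "id"] <- "gene_id"
  out
}

#' TSS metaprofile per gene class
#'
#' Mean RPKM-scaled binned coverage over the TSS +/- `half_width` window,
#' averaged across the genes of each class, with minus-strand genes flipped
#' so that upstream positions are negative.
#'
#' @inheritParams tss_signal_matrix
#' @param by Column of `genes` to average within (default `"class"`;
#'   use `NULL` for a single profile).
#' @return A `tss_profile` tibble: `class`, `sample`, `position`,
#'   `mean_rpkm`.
#' @export
tss_metaprofile <- function(fragments, genes, half_width = 1000,
                            bin_width = 10, library_size = NULL,
                            contig_lengths = NULL, by = "class") {
  mat <- tss_signal_matrix(fragments, genes, half_width, bin_width,
                           library_size, contig_lengths)
  grp <- if (is.null(by)) rep("all", nrow(genes)) else genes[[by]]
  mat$class <- grp[match(mat$gene_id, genes$gene_id)]
  prof <- mat |>
    dplyr::group_by(.data$class, .data$sample, .data$position) |>
    dplyr::summarise(mean_rpkm = mean(.data$rpkm), .groups = "drop")
  class(prof) <- c("tss_profile", class(prof))
  prof
}

#' Position of maximum TSS-proximal signal per gene
#'
#' Per-gene argmax of the binned TSS window signal; ties are broken toward
#' the bin closest to the TSS.
#'
#' @inheritParams tss_signal_matrix
#' @param sample Optional sample to restrict to.
#' @return Tibble `gene_id`, `sample`, `argmax_position`, `max_rpkm`.
#' @export
tss_argmax <- function(fragments, genes, half_width = 1000, bin_width = 10,
                       library_size = NULL, sample = NULL) {
  mat <- tss_signal_matrix(fragments, genes, half_width, bin_width,
                           library_size)
  if (!is.null(sample)) mat <- mat[mat$sample %in% sample, ]
  mat |>
    dplyr::group_by(.data$gene_id, .data$sample) |>
    dplyr::arrange(dplyr::desc(.data$rpkm), abs(.data$position),
                   .by_group = TRUE) |>
    dplyr::summarise(argmax_position = dplyr::first(.data$position),
                     max_rpkm = dplyr::first(.data$rpkm),
                     .groups = "drop")
}

#' Plot a TSS (or motif-centered) metaprofile
#'
#' @param object A `tss_profile` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot tss_profile
#' @export
autoplot.tss_profile <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$position, y = .data$mean_rpkm,
                               color = .data$class)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~sample, scales = "free_y") +
    ggplot2::labs(x = "position relative to TSS (bp)", y = "mean RPKM",
                  color = "gene class") +
    ggplot2::theme_minimal()
}

#' Accessibility profile centered on motif instances
#'
#' Mean RPKM-scaled binned coverage in a window centered on genomic motif
#' hits, oriented by motif strand.
#'
#' @param hits Genomic hits from [motif_hits_genome()] (columns `contig`,
#'   `center`, `strand`).
#' @param fragments Fragment tibble with `sample`.
#' @param half_width,bin_width Window geometry in bp.
#' @param library_size Optional named per-sample totals.
#' @return A `tss_profile` tibble with `class = motif`, `sample`,
#'   `position`, `mean_rpkm`.  Empty hits give an empty, flagged profile.
#' @export
motif_accessibility_profile <- function(hits, fragments, half_width = 500,
                                        bin_width = 10,
                                        library_size = NULL) {
  if (!nrow(hits)) {
    warning("no motif hits; empty profile")
    out <- tibble::tibble(class = character(), sample = character(),
                          position = numeric(), mean_rpkm = numeric())
    class(out) <- c("tss_profile", class(out))
    return(out)
  }
  centers <- tibble::tibble(id = paste0("hit", seq_len(nrow(hits))),
                            contig = hits$contig, center = hits$center,
                            strand = hits$strand)
  mat <- .binned_window_counts(fragments, centers, half_width, bin_width,
                               library_size)
  prof <- mat |>
    dplyr::group_by(.data$sample, .data$position) |>
    dplyr::summarise(mean_rpkm = mean(.data$rpkm), .groups = "drop") |>
    dplyr::mutate(class = "motif", .before = 1)
  class(prof) <- c("tss_profile", class(prof))
  prof
}
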