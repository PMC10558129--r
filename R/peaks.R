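#' log2 ATAC / H3K4me3 signal ratio per gene
#'
#' `log2((atac + pc) / (k4 + pc))` on RPKM values computed over the same
#' 2-kb TSS-centered window (see [window_rpkm()]).
#'
#' @param atac_rpkm,k4_rpkm Tibbles with `gene_id` and `rpkm` (e.g. from
#'   [window_rpkm()]), one row per gene.
#' @param pseudocount Added to both signals before the ratio.
#' @return Tibble `gene_id`, `atac_rpkm`, `k4_rpkm`, `log2_ratio`.
#' @export
atac_h3k4_ratio <- function(atac_rpkm, k4_rpkm, pseudocount = 1) {
  if (any(atac_rpkm$rpkm < 0) || any(k4_rpkm$rpkm < 0)) {
    stop("RPKM values must be non-negative")
  }
  x <- dplyr::inner_join(
    dplyr::select(atac_rpkm, "gene_id", atac_rpkm = "rpkm"),
    dplyr::select(k4_rpkm, "gene_id", k4_rpkm = "rpkm"),
    by = "gene_id")
  dplyr::mutate(x, log2_ratio = log2((.data$atac_rpkm + pseudocount) /
                                       (.data$k4_rpkm + pseudocount)))
}

#' Replicate-consensus peaks
#'
#' A consensus peak is the union of mutually overlapping (>= 1 bp) peaks
#' that are present in all replicates; it is retained only if every member
#' peak has `neg_log10_p` strictly greater than `min_neg_log10_p`.
#'
#' @param peaks Peak tibble with `contig`, `start`, `end` (0-based
#'   half-open), `summit` (offset from `start`), `neg_log10_p`,
#'   `replicate`.
#' @param n_replicates Number of replicates that must support a peak.
#' @param min_neg_log10_p Score threshold (strict inequality).
#' @return Consensus peak tibble `contig`, `start`, `end`, `summit`,
#'   `neg_log10_p` (minimum over members), `n_members`.
#' @export
consensus_peaks <- function(peaks, n_replicates = 3, min_neg_log10_p = 4) {
  if (!nrow(peaks)) {
    return(tibble::tibble(contig = character(), start = integer(),
                          end = integer(), summit = integer(),
                          neg_log10_p = numeric(), n_members = integer()))
  }
  if (length(unique(peaks$replicate)) < n_replicates) {
    # a replicate with no peaks at all means no consensus is possible
    return(consensus_peaks(peaks[0, ], n_replicates, min_neg_log10_p))
  }
  out <- purrr::map_dfr(unique(peaks$contig), function(ct) {
    p <- peaks[peaks$contig == ct, ]
    ir <- .iranges0(p$start, p$end)
    red <- IRanges::reduce(ir, min.gapwidth = 0L)
    hit <- IRanges::findOverlaps(ir, red)
    grp <- S4Vectors_subjectHits(hit)
    purrr::map_dfr(seq_along(red), function(g) {
      members <- p[grp == g, ]
      if (length(unique(members$replicate)) < n_replicates) return(NULL)
      if (!all(members$neg_log10_p > min_neg_log10_p)) return(NULL)
      best <- members[which.max(members$neg_log10_p), ]
      st <- min(members$start)
      tibble::tibble(contig = ct, start = st, end = max(members$end),
                     summit = as.integer(best$start + best$summit - st),
                     neg_log10_p = min(members$neg_log10_p),
                     n_members = nrow(members))
    })
  })
  if (!nrow(out)) out <- consensus_peaks(peaks[0, ], n_replicates,
                                         min_neg_log10_p)
  dplyr::arrange(out, .data$contig, .data$start)
}

# thin indirection so the IRanges Hits accessor has one home
S4Vectors_subjectHits <- function(hit) {
  as.data.frame(hit)$subjectHits
}

#' Assign peaks to genomic features
#'
#' Assigns each peak, by its summit position, to one of `promoter`, `exon`,
#' `intron`, `TE`, `intergenic` with that priority.  The promoter is the
#' strand-aware 2-kb window upstream of the TSS, `[TSS - promoter_bp,
#' TSS)`.
#'
#' @param peaks Peak tibble with `contig`, `start`, `summit` (offset).
#' @param genes Gene tibble (`gene_id`, `contig`, `start`, `end`, `strand`,
#'   `tss`; 1-based inclusive).
#' @param exons Exon tibble (`contig`, `start`, `end`; 1-based inclusive).
#' @param repeats Repeat tibble (`contig`, `start`, `end`; 1-based
#'   inclusive).
#' @param promoter_bp Promoter window width.
#' @param contig_lengths Optional named contig lengths for bounds checking.
#' @return `peaks` with an added `feature` column.
#' @export
assign_feature <- function(peaks, genes, exons, repeats,
                           promoter_bp = 2000, contig_lengths = NULL) {
  summit1 <- peaks$start + peaks$summit + 1L  # 1-based summit position
  if (!is.null(contig_lengths)) {
    len <- contig_lengths[peaks$contig]
    if (any(summit1 < 1 | summit1 > len)) {
      stop("peak summit outside contig bounds")
    }
  }
  in_any <- function(contig, pos, tab) {
    if (is.null(tab) || !nrow(tab)) return(rep(FALSE, length(pos)))
    vapply(seq_along(pos), function(i) {
      any(tab$contig == contig[i] & tab$start <= pos[i] &
            tab$end >= pos[i])
    }, logical(1))
  }
  prom <- tibble::tibble(
    contig = genes$contig,
    start = ifelse(genes$strand == "+", genes$tss - promoter_bp,
                   genes$tss + 1L),
    end = ifelse(genes$strand == "+", genes$tss - 1L,
                 genes$tss + promoter_bp)
  )
  is_prom <- in_any(peaks$contig, summit1, prom)
  is_exon <- in_any(peaks$contig, summit1, exons)
  is_gene <- in_any(peaks$contig, summit1, genes)
  is_te <- in_any(peaks$contig, summit1, repeats)
  feature <- dplyr::case_when(
    is_prom ~ "promoter",
    is_exon ~ "exon",
    is_gene ~ "intron",
    is_te ~ "TE",
    TRUE ~ "intergenic"
  )
  dplyr::mutate(peaks, feature = feature)
}

#' Region of maximum promoter signal
#'
#' For each gene, finds the coverage bin with maximum RPKM within the
#' strand-aware `[TSS - window_bp, TSS)` promoter window.  The region is
#' reported only when its value strictly exceeds `min_rpkm`; ties are broken
#' toward the bin closest to the TSS.
#'
#' @param coverage Binned coverage tibble from [bin_coverage()] (`contig`,
#'   `start`, `end`, `rpkm`; 0-based half-open bins).
#' @param genes Gene tibble with `gene_id`, `contig`, `tss`, `strand`.
#' @param window_bp Promoter window width.
#' @param min_rpkm Threshold the maximum must exceed (strictly).
#' @return Tibble `gene_id`, `position` (bin center relative to TSS),
#'   `rpkm`, one row per gene that has a qualifying region.
#' @export
max_signal_region <- function(coverage, genes, window_bp = 2000,
                              min_rpkm = 10) {
  purrr::map_dfr(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    tss0 <- g$tss - 1L
    if (g$strand == "+") {
      lo <- tss0 - window_bp; hi <- tss0
    } else {
      lo <- tss0 + 1L; hi <- tss0 + window_bp + 1L
    }
    bins <- coverage[coverage$contig == g$contig &
                       coverage$end > lo & coverage$start < hi, ]
    if (!nrow(bins)) return(NULL)
    mid0 <- (bins$start + bins$end) / 2 - 0.5
    rel <- if (g$strand == "+") mid0 - tss0 else tss0 - mid0
    best <- order(-bins$rpkm, abs(rel))[1]
    if (bins$rpkm[best] <= min_rpkm) return(NULL)
    tibble::tibble(gene_id = g$gene_id, position = rel[best],
                   rpkm = bins$rpkm[best])
  })
}

#' Write / read peak tables (narrowPeak-compatible columns)
#'
#' Columns: contig, start, end, name, score, strand, neg_log10_p, summit.
#'
#' @param peaks Peak tibble.
#' @param path File path.
#' @return The path / a peak tibble.
#' @export
write_peaks <- function(peaks, path) {
  out <- tibble::tibble(
    contig = peaks$contig, start = peaks$start, end = peaks$end,
    name = if ("name" %in% names(peaks)) peaks$name else
      paste0("peak", seq_len(nrow(peaks))),
    score = 0L, strand = ".",
    neg_log10_p = peaks$neg_log10_p,
    summit = peaks$summit
  )
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}

#' @rdname write_peaks
#' @param replicate Replicate id to attach.
#' @export
read_peaks <- function(path, replicate = 1L) {
  x <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE)
  tibble::tibble(contig = x[[1]], start = x[[2]], end = x[[3]],
                 summit = x[[8]], neg_log10_p = x[[7]],
                 replicate = replicate)
}
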