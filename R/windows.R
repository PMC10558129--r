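#' Strand-aware TSS windows
#'
#' Builds genomic windows around gene TSSs in the 0-based half-open
#' convention used for fragments.  `upstream = 2000, downstream = 0` gives
#' the promoter window \[TSS-2000, TSS); `upstream = downstream = 1000`
#' gives the 2-kb window centered on the TSS.
#'
#' @param genes Gene tibble with `gene_id`, `contig`, `tss` (1-based
#'   position of the first transcribed base), `strand`.
#' @param upstream,downstream Window extent in bp (upstream of / from the
#'   TSS base, strand-aware).
#' @return Tibble `gene_id`, `contig`, `start`, `end` (0-based half-open),
#'   `strand`.
#' @export
tss_windows <- function(genes, upstream = 2000, downstream = 0) {
  tss0 <- genes$tss - 1L
  plus <- genes$strand == "+"
  start <- ifelse(plus, tss0 - upstream, tss0 - downstream + 1L)
  end <- ifelse(plus, tss0 + downstream, tss0 + upstream + 1L)
  tibble::tibble(gene_id = genes$gene_id, contig = genes$contig,
                 start = as.integer(start), end = as.integer(end),
                 strand = genes$strand)
}

# IRanges from 0-based half-open coordinates
.iranges0 <- function(start, end) {
  IRanges::IRanges(start = start + 1L, end = end)
}

# count fragments overlapping each window by >= 1 bp, per sample
.window_counts <- function(fragments, windows, samples = NULL) {
  if (!"sample" %in% names(fragments)) fragments$sample <- "all"
  if (is.null(samples)) samples <- unique(fragments$sample)
  if (!length(samples)) samples <- "all"
  win_idx <- seq_len(nrow(windows))
  out <- purrr::map_dfr(samples, function(sm) {
    fr <- fragments[fragments$sample == sm, ]
    counts <- integer(nrow(windows))
    for (ct in unique(windows$contig)) {
      wsel <- windows$contig == ct
      fsel <- fr$contig == ct
      if (!any(wsel)) next
      q <- .iranges0(windows$start[wsel], windows$end[wsel])
      s <- .iranges0(fr$start[fsel], fr$end[fsel])
      counts[wsel] <- IRanges::countOverlaps(q, s, minoverlap = 1L)
    }
    tibble::tibble(window = win_idx, sample = sm, count = counts)
  })
  out
}

#' RPKM over genomic windows
#'
#' `RPKM = count * 1e9 / (window_bp * library_size)`, where a fragment is
#' counted if it overlaps the window by at least 1 bp.
#'
#' @param fragments Fragment tibble with `contig`, `start`, `end` (0-based
#'   half-open) and optionally `sample`.
#' @param windows Window tibble from [tss_windows()] (or any tibble with
#'   `contig`, `start`, `end` and an id column such as `gene_id`).
#' @param library_size Named vector of total fragments per sample; defaults
#'   to the per-sample totals of `fragments`.
#' @return A tibble with the window id columns plus `sample`, `count`,
#'   `rpkm`.
#' @export
window_rpkm <- function(fragments, windows, library_size = NULL) {
  lib <- .library_sizes(fragments, library_size)
  counts <- .window_counts(fragments, windows, samples = names(lib))
  width <- windows$end - windows$start
  if (any(width <= 0)) stop("windows must have positive width")
  id_cols <- intersect(c("gene_id", "window_id"), names(windows))
  out <- dplyr::bind_cols(
    windows[counts$window, id_cols, drop = FALSE],
    counts[, c("sample", "count")]
  )
  out$rpkm <- unname(out$count * 1e9 /
    (width[counts$window] * lib[out$sample]))
  tibble::as_tibble(out)
}

.library_sizes <- function(fragments, library_size = NULL) {
  if (!"sample" %in% names(fragments)) fragments$sample <- "all"
  if (is.null(library_size)) {
    tab <- table(fragments$sample)
    library_size <- stats::setNames(as.numeric(tab), names(tab))
  }
  if (!length(library_size)) {
    stop("cannot infer library sizes from an empty fragment set")
  }
  if (any(library_size <= 0)) stop("library size must be positive")
  library_size
}

# binned, strand-oriented coverage matrix around center positions:
# one row per (id, sample, position), count = fragments overlapping the bin
.binned_window_counts <- function(fragments, centers, half_width = 1000,
                                  bin_width = 10, library_size = NULL,
                                  contig_lengths = NULL) {
  stopifnot((2 * half_width) %% bin_width == 0)
  lib <- .library_sizes(fragments, library_size)
  if (!"sample" %in% names(fragments)) fragments$sample <- "all"
  rs <- seq(-half_width, half_width - bin_width, by = bin_width)
  n_bins <- length(rs)
  n_ctr <- nrow(centers)
  center0 <- rep(centers$center - 1L, each = n_bins)
  plus <- rep(centers$strand == "+", each = n_bins)
  rel <- rep(rs, n_ctr)
  bstart <- ifelse(plus, center0 + rel, center0 - rel - bin_width + 1L)
  bins <- tibble::tibble(
    id = rep(centers$id, each = n_bins),
    contig = rep(centers$contig, each = n_bins),
    start = as.integer(bstart),
    end = as.integer(bstart + bin_width),
    position = rel + bin_width / 2
  )
  if (!is.null(contig_lengths)) {
    len <- contig_lengths[bins$contig]
    if (any(bins$start < 0 | bins$end > len)) {
      warning("window(s) extend beyond contig bounds; truncated")
      bins$start <- pmax(bins$start, 0L)
      bins$end <- pmin(bins$end, as.integer(len))
      bins <- bins[bins$end > bins$start, ]
    }
  }
  counts <- .window_counts(fragments, bins)
  out <- dplyr::bind_cols(bins[counts$window, c("id", "position")], counts)
  out$rpkm <- unname(out$count * 1e9 / (bin_width * lib[out$sample]))
  tibble::as_tibble(out[, c("id", "sample", "position", "count", "rpkm")])
}

#' Binned genome-wide coverage in RPKM
#'
#' @param fragments Fragment tibble (0-based half-open) with optional
#'   `sample` column.
#' @param contig_lengths Named vector of contig lengths.
#' @param bin_width Bin size in bp.
#' @param library_size Optional named per-sample totals.
#' @return Tibble `contig`, `start`, `end`, `sample`, `count`, `rpkm`.
#' @export
bin_coverage <- function(fragments, contig_lengths, bin_width = 50,
                         library_size = NULL) {
  lib <- .library_sizes(fragments, library_size)
  bins <- purrr::map_dfr(names(contig_lengths), function(ct) {
    starts <- seq(0L, contig_lengths[[ct]] - 1L, by = bin_width)
    tibble::tibble(contig = ct, start = as.integer(starts),
                   end = as.integer(pmin(starts + bin_width,
                                         contig_lengths[[ct]])))
  })
  counts <- .window_counts(fragments, bins)
  out <- dplyr::bind_cols(bins[counts$window, ], counts[, c("sample",
                                                            "count")])
  out$rpkm <- unname(out$count * 1e9 /
    ((out$end - out$start) * lib[out$sample]))
  tibble::as_tibble(out)
}
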