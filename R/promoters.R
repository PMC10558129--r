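#' Extract strand-aware promoter sequences
#'
#' Returns the window around each TSS read 5'->3' on the coding strand
#' (minus-strand genes are reverse-complemented), covering relative
#' positions `[-upstream, downstream - 1]` where position 0 is the TSS base.
#' So `upstream = 500, downstream = 0` is the 500 nt upstream of the TSS
#' and `upstream = 40, downstream = 41` is the TSS +/- 40 nt window.
#' Windows that run off a contig are padded with `N` (keeping positions
#' aligned) and flagged.
#'
#' @param genome A [Biostrings::DNAStringSet].
#' @param genes Gene tibble with `gene_id`, `contig`, `tss`, `strand` (and
#'   optionally `class`, carried through).
#' @param upstream,downstream Window extent in bases (see above).
#' @return Tibble `gene_id`, `class` (if present), `seq`, `upstream`,
#'   `downstream`, `truncated`.
#' @export
extract_promoters <- function(genome, genes, upstream = 2000,
                              downstream = 0) {
  stopifnot(upstream + downstream > 0)
  contig_len <- stats::setNames(Biostrings::width(genome), names(genome))
  seqs <- character(nrow(genes))
  trunc <- logical(nrow(genes))
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    if (g$strand == "+") {
      lo <- g$tss - upstream; hi <- g$tss + downstream - 1L
    } else {
      lo <- g$tss - downstream + 1L; hi <- g$tss + upstream
    }
    clo <- max(lo, 1L); chi <- min(hi, contig_len[[g$contig]])
    if (chi < clo) {
      s <- ""
    } else {
      s <- as.character(Biostrings::subseq(genome[[g$contig]], clo, chi))
    }
    pad_left <- clo - lo; pad_right <- hi - chi
    trunc[i] <- pad_left > 0 || pad_right > 0
    s <- paste0(strrep("N", pad_left), s, strrep("N", pad_right))
    if (g$strand == "-") {
      s <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(s)))
    }
    seqs[i] <- s
  }
  out <- tibble::tibble(gene_id = genes$gene_id, seq = seqs,
                        upstream = as.integer(upstream),
                        downstream = as.integer(downstream),
                        truncated = trunc)
  if ("class" %in% names(genes)) {
    out <- dplyr::mutate(out, class = genes$class, .after = "gene_id")
  }
  if (any(trunc)) warning(sum(trunc), " window(s) truncated at contig edge")
  out
}

#' Positional base composition around the TSS
#'
#' Per-position A/C/G/T fractions (over non-N bases) and the AT fraction,
#' optionally per gene class.  Positions are labeled relative to the TSS
#' (`-upstream ... downstream - 1`, 0 = TSS base).
#'
#' @param promoters Output of [extract_promoters()]; all sequences must
#'   share one window spec.
#' @param by Optional grouping column of `promoters` (e.g. `"class"`).
#' @return Tibble `class`, `position`, `a`, `c`, `g`, `t`, `at`, `n_seqs`.
#'   Positions where every sequence has `N` carry `NaN` fractions and are
#'   flagged with a warning.
#' @export
composition_profile <- function(promoters, by = NULL) {
  stopifnot(nrow(promoters) >= 1)
  lens <- nchar(promoters$seq)
  if (length(unique(lens)) != 1) {
    stop("all promoter sequences must have equal length")
  }
  positions <- seq(-promoters$upstream[1],
                   promoters$downstream[1] - 1L)
  grp <- if (is.null(by)) rep("all", nrow(promoters)) else promoters[[by]]
  out <- purrr::map_dfr(unique(grp), function(cl) {
    m <- do.call(rbind, strsplit(promoters$seq[grp == cl], ""))
    counts <- vapply(c("A", "C", "G", "T"), function(b) {
      colSums(m == b)
    }, numeric(ncol(m)))
    informative <- rowSums(counts)
    fr <- counts / informative
    tibble::tibble(class = cl, position = positions,
                   a = fr[, "A"], c = fr[, "C"], g = fr[, "G"],
                   t = fr[, "T"], at = fr[, "A"] + fr[, "T"],
                   n_seqs = sum(grp == cl))
  })
  if (any(!is.finite(out$at))) {
    warning("position(s) with only N bases; fractions undefined there")
  }
  out
}

#' Aggregate AT content of a relative-position window
#'
#' @param promoters Output of [extract_promoters()].
#' @param from,to Relative positions (inclusive) to aggregate over.
#' @param by Optional grouping column.
#' @return Tibble `class`, `at_fraction` over all bases of all sequences in
#'   the window.
#' @export
at_content <- function(promoters, from = -200, to = -1, by = NULL) {
  up <- promoters$upstream[1]
  i0 <- from + up + 1L; i1 <- to + up + 1L
  stopifnot(i0 >= 1, i1 <= nchar(promoters$seq[1]))
  sub <- substr(promoters$seq, i0, i1)
  grp <- if (is.null(by)) rep("all", nrow(promoters)) else promoters[[by]]
  purrr::map_dfr(unique(grp), function(cl) {
    s <- paste(sub[grp == cl], collapse = "")
    ch <- strsplit(s, "")[[1]]
    inf <- ch %in% c("A", "C", "G", "T")
    tibble::tibble(class = cl,
                   at_fraction = mean(ch[inf] %in% c("A", "T")))
  })
}
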