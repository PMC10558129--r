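#' Count maximal T-runs per promoter
#'
#' Counts maximal runs of `T` of length at least `min_len` on the coding
#' strand (a run of 7 counts once, not as overlapping shorter runs).
#'
#' @param promoters Output of [extract_promoters()] (or any tibble with
#'   `gene_id` and `seq`).
#' @param min_len Minimum run length (>= 2).
#' @return Tibble `gene_id`, `n_stretches`, `total_t_in_stretches`.
#' @export
t_stretch_counts <- function(promoters, min_len = 5) {
  if (min_len < 2) stop("min_len must be >= 2")
  tb <- .seq_tbl(promoters)
  counts <- purrr::map2_dfr(tb$id, tb$seq, function(id, s) {
    r <- rle(strsplit(s, "")[[1]] == "T")
    runs <- r$lengths[r$values & r$lengths >= min_len]
    tibble::tibble(gene_id = id, n_stretches = length(runs),
                   total_t_in_stretches = sum(runs))
  })
  counts
}

#' Compare T-stretch frequency between gene classes
#'
#' Per-gene maximal T-run counts plus pairwise two-sided rank-sum
#' (Wilcoxon) tests between classes with Bonferroni correction.
#'
#' @inheritParams t_stretch_counts
#' @param class_table Tibble with `gene_id`, `class`.
#' @return List with `counts` (per-gene, with class) and `tests`
#'   (`class_a`, `class_b`, `p_value`, `p_bonferroni`).
#' @export
t_stretch_stats <- function(promoters, class_table, min_len = 5) {
  counts <- t_stretch_counts(promoters, min_len) |>
    dplyr::left_join(class_table, by = "gene_id")
  cls <- sort(unique(counts$class))
  tests <- NULL
  if (length(cls) >= 2) {
    pairs <- utils::combn(cls, 2)
    tests <- purrr::map_dfr(seq_len(ncol(pairs)), function(k) {
      a <- counts$n_stretches[counts$class == pairs[1, k]]
      b <- counts$n_stretches[counts$class == pairs[2, k]]
      p <- suppressWarnings(stats::wilcox.test(a, b)$p.value)
      tibble::tibble(class_a = pairs[1, k], class_b = pairs[2, k],
                     p_value = p)
    })
    tests$p_bonferroni <- pmin(1, tests$p_value * nrow(tests))
  }
  list(counts = counts, tests = tests)
}

#' Count k-mers over a sequence set
#'
#' Overlapping occurrences on the coding strand only; windows containing a
#' non-ACGT letter are skipped.
#'
#' @param seqs Character vector or tibble with `seq`.
#' @param k k-mer length.
#' @return Named integer vector of counts (observed k-mers only), with an
#'   attribute `n_positions` giving the number of valid windows scanned.
#' @export
count_kmers <- function(seqs, k) {
  tb <- .seq_tbl(seqs)
  acc <- vector("list", nrow(tb))
  n_pos <- 0L
  for (i in seq_along(tb$seq)) {
    s <- tb$seq[i]
    L <- nchar(s)
    if (L < k) next
    km <- substring(s, 1:(L - k + 1L), k:L)
    km <- km[!stringr::str_detect(km, "[^ACGT]")]
    n_pos <- n_pos + length(km)
    acc[[i]] <- km
  }
  out <- table(unlist(acc))
  res <- stats::setNames(as.integer(out), names(out))
  attr(res, "n_positions") <- n_pos
  res
}

#' k-mer enrichment of promoters against a background set
#'
#' Observed counts are overlapping occurrences over all foreground
#' sequences (coding strand only).  Expected counts come from the
#' background's per-position k-mer frequency times the number of foreground
#' positions; `log2_enrichment = log2((obs + pc) / (exp + pc))` and the
#' p-value is an upper binomial tail at the background frequency, BH
#' adjusted across k-mers.
#'
#' @param promoters Foreground sequences (tibble with `seq` or character
#'   vector).
#' @param background Background sequences in the same form.
#' @param k k-mer length (default 9, nonamers).
#' @param pseudocount Stabilizer for the enrichment ratio.
#' @return Tibble `kmer`, `observed`, `expected`, `log2_enrichment`,
#'   `p_value`, `p_adj`, ranked by significance then enrichment.
#' @export
kmer_enrichment <- function(promoters, background, k = 9,
                            pseudocount = 0.5) {
  fg <- count_kmers(promoters, k)
  bg <- count_kmers(background, k)
  n_fg <- attr(fg, "n_positions")
  n_bg <- attr(bg, "n_positions")
  if (!n_bg) stop("empty background")
  if (!n_fg) stop("no foreground positions of length k")
  kmers <- union(names(fg), names(bg))
  obs <- ifelse(kmers %in% names(fg), fg[kmers], 0L)
  bgc <- ifelse(kmers %in% names(bg), bg[kmers], 0L)
  expected <- (bgc / n_bg) * n_fg
  enr <- log2((obs + pseudocount) / (expected + pseudocount))
  # the p-value uses a half-count frequency floor so k-mers unseen in the
  # background cannot claim a zero p-value
  freq <- pmin((bgc + 0.5) / (n_bg + 0.5), 1)
  p <- stats::pbinom(obs - 1, n_fg, freq, lower.tail = FALSE)
  tibble::tibble(kmer = kmers, observed = as.integer(obs),
                 expected = expected, log2_enrichment = enr,
                 p_value = p,
                 p_adj = stats::p.adjust(p, method = "BH")) |>
    dplyr::arrange(.data$p_value, dplyr::desc(.data$log2_enrichment),
                   dplyr::desc(.data$observed))
}

#' Scan for maximal perfect tandem repeat arrays
#'
#' Finds maximal perfect tandem arrays of period `unit_len` with at least
#' `min_units` full units.  An array is reported once, at its maximal
#' extent (the extent may include a partial trailing unit; `n_units` counts
#' full units).  Arrays whose unit contains only A and T are flagged.
#'
#' @param promoters Sequences (tibble with `gene_id`/`id` and `seq`, or a
#'   character vector).
#' @param unit_len Repeat unit length (e.g. 2 or 3).
#' @param min_units Minimum number of full units.
#' @return Tibble `gene_id`, `start`, `end` (1-based inclusive within the
#'   sequence), `unit`, `n_units`, `at_only`.
#' @export
tandem_repeat_scan <- function(promoters, unit_len = 3, min_units = 3) {
  stopifnot(unit_len >= 1, min_units >= 2)
  tb <- .seq_tbl(promoters)
  u <- unit_len
  out <- purrr::map2_dfr(tb$id, tb$seq, function(id, s) {
    L <- nchar(s)
    if (L < u * min_units) return(NULL)
    ch <- strsplit(s, "")[[1]]
    eq <- ch[seq_len(L - u)] == ch[seq_len(L - u) + u] &
      ch[seq_len(L - u)] %in% c("A", "C", "G", "T")
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- which(r$values)
    out <- purrr::map_dfr(keep, function(j) {
      span_start <- starts[j]
      span_end <- ends[j] + u  # last position matching the period
      n_units <- (span_end - span_start + 1L) %/% u
      if (n_units < min_units) return(NULL)
      unit <- substr(s, span_start, span_start + u - 1L)
      tibble::tibble(gene_id = id, start = span_start,
                     end = span_end, unit = unit,
                     n_units = as.integer(n_units),
                     at_only = !grepl("[^AT]", unit))
    })
    out
  })
  if (!nrow(out)) {
    out <- tibble::tibble(gene_id = character(), start = integer(),
                          end = integer(), unit = character(),
                          n_units = integer(), at_only = logical())
  }
  out
}
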