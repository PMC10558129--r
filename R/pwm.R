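#' Read a position weight matrix in minimal MEME text format
#'
#' Parses the small MEME dialect used for the PWM fixtures shipped with the
#' package: a `MOTIF` line followed by a `letter-probability matrix:` header
#' and one row of A/C/G/T probabilities per motif position, with an optional
#' `Background letter frequencies` block.  Only the first motif of a file is
#' returned.
#'
#' @param path Path to a MEME-format text file.
#' @return A `pwm` object: list with `name`, `mat` (4 x width probability
#'   matrix, rows A/C/G/T; columns sum to 1), and `bg` (named background
#'   frequencies).
#' @export
read_meme_pwm <- function(path) {
  lines <- readLines(path)
  bg <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
  bg_at <- grep("^Background letter frequencies", lines)
  if (length(bg_at)) {
    toks <- strsplit(trimws(lines[bg_at[1] + 1L]), "\\s+")[[1]]
    vals <- as.numeric(toks[seq(2, length(toks), by = 2)])
    names(vals) <- toks[seq(1, length(toks), by = 2)]
    bg <- vals[c("A", "C", "G", "T")]
  }
  m_at <- grep("^MOTIF", lines)
  if (!length(m_at)) stop("no MOTIF entry in ", path)
  name <- strsplit(trimws(lines[m_at[1]]), "\\s+")[[1]][2]
  h_at <- grep("^letter-probability matrix:", lines)
  h_at <- h_at[h_at > m_at[1]][1]
  w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", lines[h_at]))
  rows <- lines[(h_at + 1L):(h_at + w)]
  mat <- t(vapply(rows, function(r) {
    as.numeric(strsplit(trimws(r), "\\s+")[[1]])
  }, numeric(4)))
  dimnames(mat) <- NULL
  mat <- t(mat)
  rownames(mat) <- c("A", "C", "G", "T")
  new_pwm(mat, bg = bg, name = name)
}

#' Construct or derive PWMs
#'
#' `new_pwm()` validates a probability matrix into a `pwm` object;
#' `pwm_consensus()` returns the per-column argmax string;
#' `reverse_complement_pwm()` reverses the columns and complements the rows;
#' `stemchrom_pwm()` loads one of the fixture motifs shipped with the
#' package (`"planted_tf"`, `"inr"`, `"tata"`).  The Inr and TATA fixtures
#' are editable placeholders, not empirically derived motifs.
#'
#' @param mat 4 x width matrix of per-position base probabilities, rows
#'   A/C/G/T; every column must sum to 1 (tolerance 1e-9).
#' @param bg Named background frequencies for A, C, G, T.
#' @param name Motif name.
#' @return A `pwm` object.
#' @export
new_pwm <- function(mat, bg = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                    name = "pwm") {
  stopifnot(is.matrix(mat), nrow(mat) == 4)
  if (is.null(rownames(mat))) rownames(mat) <- c("A", "C", "G", "T")
  mat <- mat[c("A", "C", "G", "T"), , drop = FALSE]
  if (ncol(mat) < 4) stop("PWM must have length >= 4")
  if (any(abs(colSums(mat) - 1) > 1e-9)) {
    stop("every PWM column must sum to 1")
  }
  bg <- bg[c("A", "C", "G", "T")]
  structure(list(name = name, mat = mat, bg = bg / sum(bg)), class = "pwm")
}

#' @rdname new_pwm
#' @param pwm A `pwm` object.
#' @export
pwm_consensus <- function(pwm) {
  paste(rownames(pwm$mat)[apply(pwm$mat, 2, which.max)], collapse = "")
}

#' @rdname new_pwm
#' @export
reverse_complement_pwm <- function(pwm) {
  mat <- pwm$mat[c("T", "G", "C", "A"), rev(seq_len(ncol(pwm$mat)))]
  rownames(mat) <- c("A", "C", "G", "T")
  bg <- pwm$bg[c("T", "G", "C", "A")]
  names(bg) <- c("A", "C", "G", "T")
  new_pwm(mat, bg = bg, name = paste0(pwm$name, "_rc"))
}

#' @rdname new_pwm
#' @param which Fixture motif name.
#' @export
stemchrom_pwm <- function(which = c("planted_tf", "inr", "tata")) {
  which <- match.arg(which)
  read_meme_pwm(system.file("extdata", "pwm", paste0(which, ".meme"),
                            package = "stemchrom", mustWork = TRUE))
}

#' @export
print.pwm <- function(x, ...) {
  cat("<pwm>", x$name, "width", ncol(x$mat),
      "consensus", pwm_consensus(x), "\n")
  invisible(x)
}

# log2-odds score matrix; zero cells floored at `floor` before the log
.pwm_logodds <- function(pwm, floor = 1e-3) {
  log2(pmax(pwm$mat, floor) / pwm$bg)
}

#' Exact PWM score threshold for a p-value
#'
#' Enumerates the exact distribution of the log-odds score of a random
#' sequence drawn from the PWM's background model (positions independent)
#' and returns the smallest threshold `s` with `P(score >= s) <= p`.
#'
#' @param pwm A `pwm` object.
#' @param p Tail probability.
#' @param digits Scores are accumulated on a grid rounded to this many
#'   decimals to keep the enumeration exact and finite.
#' @return A scalar score threshold.
#' @export
pwm_score_threshold <- function(pwm, p = 1e-3, digits = 6) {
  stopifnot(p > 0, p <= 1)
  S <- round(.pwm_logodds(pwm), digits)
  dist <- c(`0` = 1)
  for (j in seq_len(ncol(S))) {
    vals <- as.numeric(names(dist))
    new_vals <- round(rep(vals, each = 4) + rep(S[, j], length(vals)),
                      digits)
    new_p <- rep(dist, each = 4) * rep(pwm$bg, length(vals))
    agg <- tapply(new_p, new_vals, sum)
    dist <- as.numeric(agg)
    names(dist) <- names(agg)
  }
  vals <- as.numeric(names(dist))
  o <- order(vals, decreasing = TRUE)
  vals <- vals[o]
  prob <- dist[o]
  # merge numerically split ties (independent roundings of mathematically
  # equal sums differ by ~1e-6) so a tie group is never cut in half
  cluster <- cumsum(c(TRUE, diff(vals) < -1e-5))
  cl_min <- tapply(vals, cluster, min)
  cl_tail <- cumsum(tapply(prob, cluster, sum))
  ok <- which(cl_tail <= p + 1e-12)
  if (!length(ok)) return(max(vals) + 1e-9)
  # small margin keeps boundary instances (scored without rounding) in
  cl_min[[max(ok)]] - 5e-6
}

.seq_tbl <- function(seqs) {
  if (is.data.frame(seqs)) {
    id_col <- intersect(c("gene_id", "id", "contig"), names(seqs))[1]
    if (is.na(id_col) || !"seq" %in% names(seqs)) {
      stop("sequence table needs an id column (gene_id/id/contig) and `seq`")
    }
    tibble::tibble(id = seqs[[id_col]], seq = toupper(seqs$seq))
  } else {
    ids <- names(seqs)
    if (is.null(ids)) ids <- as.character(seq_along(seqs))
    tibble::tibble(id = ids, seq = toupper(unname(seqs)))
  }
}

.revcomp_string <- function(s) {
  vapply(s, function(x) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", x), "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# score every offset of one sequence against a log-odds matrix; NA where the
# window contains a non-ACGT letter
.score_offsets <- function(chars_idx, S) {
  w <- ncol(S)
  L <- length(chars_idx)
  if (L < w) return(numeric(0))
  n_off <- L - w + 1L
  sc <- numeric(n_off)
  for (j in seq_len(w)) {
    sc <- sc + S[cbind(chars_idx[j:(j + n_off - 1L)], j)]
  }
  sc
}

#' Scan sequences with a PWM
#'
#' Computes the log2-odds score of the motif against the background model at
#' every offset of every sequence and reports hits at or above a threshold.
#' The threshold is either given directly (`score_threshold`) or derived from
#' a p-value by exact enumeration of the background score distribution
#' (`p_threshold`, the default route).  Sequences shorter than the motif
#' yield no hits.  With `both_strands = TRUE` the reverse complement of each
#' sequence is scanned as well and hits are reported with strand `"-"` at
#' their forward-strand offset.
#'
#' @param seqs A tibble with an id column and a `seq` column, or a (named)
#'   character vector.
#' @param pwm A `pwm` object.
#' @param score_threshold Minimum log2-odds score for a hit.
#' @param p_threshold Tail p-value used to derive the threshold when
#'   `score_threshold` is `NULL`.
#' @param both_strands Also scan the reverse complement.
#' @param floor Probability floor applied to zero PWM cells.
#' @return A tibble with columns `id`, `offset` (1-based start of the match
#'   within the sequence, forward-strand coordinates), `strand`, `score`.
#' @export
scan_pwm <- function(seqs, pwm, score_threshold = NULL, p_threshold = 1e-3,
                     both_strands = FALSE, floor = 1e-3) {
  stopifnot(inherits(pwm, "pwm"))
  tb <- .seq_tbl(seqs)
  if (is.null(score_threshold)) {
    score_threshold <- pwm_score_threshold(pwm, p_threshold)
  }
  S <- .pwm_logodds(pwm, floor)
  w <- ncol(S)
  base_idx <- c(A = 1L, C = 2L, G = 3L, T = 4L)
  scan_one <- function(id, s, strand) {
    ci <- base_idx[strsplit(s, "")[[1]]]
    sc <- .score_offsets(ci, S)
    hit <- which(!is.na(sc) & sc >= score_threshold)
    if (!length(hit)) return(NULL)
    off <- hit
    if (strand == "-") off <- nchar(s) - (hit + w - 1L) + 1L
    tibble::tibble(id = id, offset = as.integer(off), strand = strand,
                   score = sc[hit])
  }
  out <- purrr::map2_dfr(tb$id, tb$seq, scan_one, strand = "+")
  if (both_strands) {
    rc <- .revcomp_string(tb$seq)
    out <- dplyr::bind_rows(out,
                            purrr::map2_dfr(tb$id, rc, scan_one,
                                            strand = "-"))
  }
  if (!nrow(out)) {
    out <- tibble::tibble(id = character(), offset = integer(),
                          strand = character(), score = numeric())
  }
  dplyr::arrange(out, .data$id, .data$offset)
}

#' Scan a genome for motif instances on both strands
#'
#' Convenience wrapper around [scan_pwm()] for genome-coordinate hits, e.g.
#' to center accessibility profiles on motif instances.
#'
#' @param genome A [Biostrings::DNAStringSet].
#' @inheritParams scan_pwm
#' @return A tibble with `contig`, `start` (1-based), `strand`, `score`, and
#'   `center` (1-based position of the motif midpoint).
#' @export
motif_hits_genome <- function(genome, pwm, score_threshold = NULL,
                              p_threshold = 1e-4) {
  seqs <- stats::setNames(as.character(genome), names(genome))
  hits <- scan_pwm(seqs, pwm, score_threshold = score_threshold,
                   p_threshold = p_threshold, both_strands = TRUE)
  w <- ncol(pwm$mat)
  tibble::tibble(contig = hits$id, start = hits$offset,
                 strand = hits$strand, score = hits$score,
                 center = hits$offset + as.integer(w %/% 2))
}

#' Percentage of genes carrying a motif, per gene class
#'
#' @param hits [scan_pwm()] output where `id` is a gene id (e.g. hits on
#'   TSS +/- 40 windows).
#' @param class_table Tibble with `gene_id` and `class` covering the scanned
#'   gene universe.
#' @return A tibble with `class`, `n_genes`, `n_with_hit`, `percent`.
#'   Classes with no genes are flagged with `NaN` and a warning.
#' @export
motif_class_frequency <- function(hits, class_table) {
  stopifnot(all(c("gene_id", "class") %in% names(class_table)))
  with_hit <- unique(hits$id)
  out <- class_table |>
    dplyr::group_by(class = .data$class) |>
    dplyr::summarise(
      n_genes = dplyr::n(),
      n_with_hit = sum(.data$gene_id %in% with_hit),
      .groups = "drop"
    ) |>
    dplyr::mutate(percent = 100 * .data$n_with_hit / .data$n_genes)
  if (any(out$n_genes == 0)) warning("empty gene class; percent undefined")
  out
}
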