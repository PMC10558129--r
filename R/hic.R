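#' Simulate a Hi-C contact matrix with planted compartments
#'
#' Builds a symmetric binned contact matrix on one contig: expected counts
#' follow a power-law distance decay, multiplied by `hic_boost` for bin
#' pairs in the same planted compartment (a checkerboard of alternating
#' blocks of `hic_block_bins` bins), Poisson-sampled and symmetrized.  A
#' `strip_fraction` of bins is turned into near-zero-coverage "white
#' strips" (their expected counts are scaled down 50-fold), emulating
#' assembly regions without Hi-C coverage.
#'
#' @param plan A [simulation_plan()].
#' @return A `contact_matrix`: list with `mat` (dense symmetric matrix),
#'   `bins` (tibble `bin`, `contig`, `start`), `bin_size`, and `truth`
#'   (tibble `bin`, `compartment` in A/B, `is_strip`).
#' @export
simulate_contacts <- function(plan) {
  stopifnot(inherits(plan, "simulation_plan"))
  n <- plan$hic_bins
  .with_stage_seed(plan, "hic", {
    block <- (seq_len(n) - 1L) %/% plan$hic_block_bins
    comp <- ifelse(block %% 2L == 0L, "A", "B")
    n_strip <- round(plan$strip_fraction * n)
    strips <- if (n_strip > 0) sort(sample.int(n, n_strip)) else integer(0)
    d <- abs(outer(seq_len(n), seq_len(n), "-"))
    expected <- plan$hic_depth / (d + 1)^plan$hic_decay_exponent
    same <- outer(comp, comp, "==")
    expected[same] <- expected[same] * plan$hic_boost
    scale <- rep(1, n)
    scale[strips] <- 0.02
    expected <- expected * outer(scale, scale)
    up <- upper.tri(expected, diag = TRUE)
    counts <- matrix(0, n, n)
    counts[up] <- stats::rpois(sum(up), expected[up])
    counts <- counts + t(counts) - diag(diag(counts))
    bins <- tibble::tibble(bin = seq_len(n), contig = "contig_hic",
                           start = (seq_len(n) - 1L) * plan$hic_bin_size)
    # companions emulating the study's bin-level annotations: the A
    # compartment is twice as accessible; genic bases are uniform across
    # compartments (no planted genic enrichment)
    accessibility <- tibble::tibble(
      bin = seq_len(n),
      value = stats::rlnorm(n, log(ifelse(comp == "A", 2, 1)), 0.2))
    features <- tibble::tibble(
      bin = seq_len(n), family = "gene",
      bases = round(stats::runif(n, 0.4, 0.6) * plan$hic_bin_size))
    structure(list(
      mat = counts, bins = bins, bin_size = plan$hic_bin_size,
      accessibility = accessibility, features = features,
      truth = tibble::tibble(bin = seq_len(n), compartment = comp,
                             is_strip = seq_len(n) %in% strips)
    ), class = "contact_matrix")
  })
}

#' Write / read contacts as COO triplets
#'
#' Text format: `bin_i TAB bin_j TAB count` for the upper triangle, plus a
#' `bins.tsv` side file.
#'
#' @param contacts A `contact_matrix`.
#' @param dir Output directory.
#' @return The directory / a `contact_matrix` (without truth).
#' @export
write_contacts <- function(contacts, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  m <- contacts$mat
  up <- which(upper.tri(m, diag = TRUE) & m > 0, arr.ind = TRUE)
  readr::write_tsv(tibble::tibble(bin_i = up[, 1], bin_j = up[, 2],
                                  count = m[up]),
                   file.path(dir, "contacts.coo"), col_names = FALSE)
  readr::write_tsv(contacts$bins, file.path(dir, "bins.tsv"))
  invisible(dir)
}

#' @rdname write_contacts
#' @export
read_contacts <- function(dir) {
  coo <- readr::read_tsv(file.path(dir, "contacts.coo"),
                         col_names = c("bin_i", "bin_j", "count"),
                         show_col_types = FALSE)
  bins <- readr::read_tsv(file.path(dir, "bins.tsv"),
                          show_col_types = FALSE)
  n <- nrow(bins)
  m <- matrix(0, n, n)
  m[cbind(coo$bin_i, coo$bin_j)] <- coo$count
  m[cbind(coo$bin_j, coo$bin_i)] <- coo$count
  structure(list(mat = m, bins = bins,
                 bin_size = diff(bins$start[1:2]), truth = NULL),
            class = "contact_matrix")
}

#' Knight-Ruiz-style matrix balancing
#'
#' Symmetric diagonal balancing: finds a positive scaling vector `x` such
#' that `diag(x) %*% M %*% diag(x)` has equal row sums, by fixed-point
#' iteration (`x <- x / sqrt(rowsums)`), stopping when the coefficient of
#' variation of the row sums drops below `tol`.
#'
#' @param mat Symmetric non-negative matrix with strictly positive row
#'   sums (drop zero rows first, see [drop_white_strips()]).
#' @param tol Convergence tolerance on the row-sum coefficient of
#'   variation.
#' @param max_iter Maximum iterations; non-convergence is an error naming
#'   the iteration count.
#' @return List with `balanced` (matrix), `scaling` (vector `x`),
#'   `iterations`, `cv`.
#' @export
kr_balance <- function(mat, tol = 1e-6, max_iter = 3000) {
  stopifnot(is.matrix(mat), nrow(mat) == ncol(mat))
  if (max(abs(mat - t(mat))) > 1e-9) stop("matrix must be symmetric")
  rs <- rowSums(mat)
  if (any(rs <= 0)) stop("zero row sums present; drop white strips first")
  n <- nrow(mat)
  x <- rep(1, n)
  cv <- Inf
  for (it in seq_len(max_iter)) {
    r <- x * (mat %*% x)[, 1]
    cv <- stats::sd(r) / mean(r)
    if (is.na(cv)) cv <- 0  # 1x1 matrix
    if (cv < tol) {
      balanced <- mat * outer(x, x)
      return(list(balanced = balanced, scaling = x, iterations = it - 1L,
                  cv = cv))
    }
    x <- x / sqrt(r / mean(r))
  }
  stop("KR balancing did not converge after ", max_iter,
       " iterations (cv = ", signif(cv, 3), ")")
}

#' Remove low-coverage rows/columns ("white strips")
#'
#' Drops every bin whose row sum is zero, plus bins whose row sum falls
#' below `min_coverage_frac` times the median nonzero row sum.  Returns the
#' reduced matrix together with the index map needed to reallocate results
#' to original coordinates.
#'
#' @param mat Symmetric contact matrix.
#' @param min_coverage_frac Fraction of the median nonzero row sum below
#'   which a bin is considered uncovered.
#' @return List with `mat` (reduced), `keep` (original indices retained),
#'   `dropped` (original indices removed).
#' @export
drop_white_strips <- function(mat, min_coverage_frac = 0.05) {
  rs <- rowSums(mat)
  nz <- rs[rs > 0]
  if (!length(nz)) stop("all bins have zero coverage")
  thr <- min_coverage_frac * stats::median(nz)
  keep <- which(rs > 0 & rs >= thr)
  if (!length(keep)) stop("all bins dropped as white strips")
  list(mat = mat[keep, keep, drop = FALSE], keep = keep,
       dropped = setdiff(seq_len(nrow(mat)), keep))
}

#' Observed-over-expected transform
#'
#' Divides each entry by the mean of its `|i - j|` diagonal.  Diagonals
#' with zero mean produce zero entries (flagged with a warning).
#'
#' @param mat Square (balanced) matrix.
#' @return O/E matrix of the same shape.
#' @export
observed_over_expected <- function(mat) {
  n <- nrow(mat)
  d <- abs(row(mat) - col(mat))
  means <- tapply(as.vector(mat), as.vector(d), mean)
  expected <- matrix(means[as.character(d)], n, n)
  out <- mat / expected
  if (any(expected == 0)) {
    warning("diagonal(s) with zero mean; O/E set to 0 there")
    out[expected == 0] <- 0
  }
  out
}

#' Compartment eigenvector with reallocation over dropped bins
#'
#' First eigenvector (largest eigenvalue) of the Pearson correlation matrix
#' of the O/E rows, written back to the original bin coordinates with `NA`
#' at dropped (white-strip) bins.
#'
#' @param oe O/E matrix on the strip-free bins.
#' @param keep Original indices of the retained bins (from
#'   [drop_white_strips()]).
#' @param n_bins Total number of original bins.
#' @return Tibble `bin`, `eigenvector`, `label` (`"A"` for positive,
#'   `"B"` for negative, `NA` at dropped bins; signs are provisional until
#'   [orient_compartments()]).
#' @export
compartment_eigenvector <- function(oe, keep = seq_len(nrow(oe)),
                                    n_bins = max(keep)) {
  if (nrow(oe) < 2) stop("need at least two retained bins")
  cm <- suppressWarnings(stats::cor(oe))
  if (any(!is.finite(cm))) {
    stop("degenerate correlation matrix (constant O/E rows)")
  }
  ev <- eigen(cm, symmetric = TRUE)$vectors[, 1]
  # deterministic sign convention pre-orientation: positive sum
  if (sum(ev) < 0) ev <- -ev
  full <- rep(NA_real_, n_bins)
  full[keep] <- ev
  tibble::tibble(bin = seq_len(n_bins), eigenvector = full,
                 label = dplyr::case_when(is.na(full) ~ NA_character_,
                                          full >= 0 ~ "A", TRUE ~ "B"))
}

#' Call A/B compartments from a contact matrix
#'
#' Full pipeline per contig: white-strip removal, KR balancing, O/E,
#' Pearson-correlation eigenvector, reallocation to original bins.
#'
#' @param contacts A `contact_matrix` (or plain matrix).
#' @param min_coverage_frac Passed to [drop_white_strips()].
#' @param tol,max_iter Passed to [kr_balance()].
#' @return A `compartment_track` tibble: `bin`, `contig`, `start`,
#'   `eigenvector`, `label`.
#' @export
call_compartments <- function(contacts, min_coverage_frac = 0.05,
                              tol = 1e-6, max_iter = 3000) {
  if (inherits(contacts, "contact_matrix")) {
    mat <- contacts$mat
    bins <- contacts$bins
  } else {
    mat <- contacts
    bins <- tibble::tibble(bin = seq_len(nrow(mat)), contig = "contig_1",
                           start = 0L)
  }
  out <- purrr::map_dfr(unique(bins$contig), function(ct) {
    sel <- which(bins$contig == ct)
    m <- mat[sel, sel, drop = FALSE]
    ws <- drop_white_strips(m, min_coverage_frac)
    bal <- kr_balance(ws$mat, tol = tol, max_iter = max_iter)
    oe <- observed_over_expected(bal$balanced)
    tr <- compartment_eigenvector(oe, keep = ws$keep,
                                  n_bins = length(sel))
    dplyr::bind_cols(bins[sel, ], tr[, c("eigenvector", "label")])
  })
  class(out) <- c("compartment_track", class(out))
  out
}

#' Orient compartment signs by accessibility and compute feature enrichment
#'
#' Flips the eigenvector sign (per contig) so that the positive side has
#' the higher mean accessibility; the positive side is then the A
#' compartment.  If accessibility is missing for more than half of the
#' retained bins, orientation falls back to gene density (with a warning),
#' using `genes`.
#'
#' Feature enrichment for a family `f` in compartment `C` is the fraction
#' of `f`'s annotated bases lying in `C` divided by `C`'s share of the
#' labeled genome, so a uniformly distributed feature scores 1.0 in both
#' compartments.
#'
#' @param track A `compartment_track` from [call_compartments()].
#' @param accessibility Tibble `bin`, `value` (e.g. mean ATAC RPKM per
#'   bin).
#' @param features Optional tibble `bin`, `family`, `bases` giving
#'   annotated bases per bin and family (see [features_per_bin()]).
#' @param genes Optional tibble `bin`, `value` of gene counts per bin for
#'   the fallback orientation.
#' @return List with `track` (oriented), `enrichment` (tibble `family`,
#'   `compartment`, `enrichment`), `gene_density` (per-compartment mean of
#'   `genes`, if given).
#' @export
orient_and_enrich <- function(track, accessibility, features = NULL,
                              genes = NULL) {
  out <- track
  for (ct in unique(track$contig)) {
    sel <- which(track$contig == ct & !is.na(track$eigenvector))
    acc <- accessibility$value[match(track$bin[sel], accessibility$bin)]
    use <- !is.na(acc)
    if (mean(use) < 0.5) {
      warning("accessibility missing for >50% of retained bins; ",
              "orienting by gene density")
      if (is.null(genes)) stop("no gene density available for fallback")
      acc <- genes$value[match(track$bin[sel], genes$bin)]
      use <- !is.na(acc)
    }
    pos <- out$eigenvector[sel] >= 0
    if (mean(acc[use & pos]) < mean(acc[use & !pos])) {
      flip <- which(track$contig == ct)
      out$eigenvector[flip] <- -out$eigenvector[flip]
    }
  }
  out$label <- dplyr::case_when(
    is.na(out$eigenvector) ~ NA_character_,
    out$eigenvector >= 0 ~ "A",
    TRUE ~ "B")
  enrichment <- NULL
  if (!is.null(features)) {
    lab <- out$label[match(features$bin, out$bin)]
    labeled_bins <- table(out$label[!is.na(out$label)])
    share <- labeled_bins / sum(labeled_bins)
    enrichment <- features |>
      dplyr::mutate(compartment = lab) |>
      dplyr::filter(!is.na(.data$compartment)) |>
      dplyr::group_by(.data$family, .data$compartment) |>
      dplyr::summarise(bases = sum(.data$bases), .groups = "drop_last") |>
      dplyr::mutate(frac = .data$bases / sum(.data$bases)) |>
      dplyr::ungroup() |>
      dplyr::mutate(enrichment = .data$frac /
                      as.numeric(share[.data$compartment])) |>
      dplyr::select("family", "compartment", "enrichment")
  }
  gene_density <- NULL
  if (!is.null(genes)) {
    lab <- out$label[match(genes$bin, out$bin)]
    gene_density <- tibble::tibble(
      compartment = names(split(genes$value, lab)),
      mean_genes = vapply(split(genes$value, lab), mean, numeric(1)))
  }
  list(track = out, enrichment = enrichment, gene_density = gene_density)
}

#' Tabulate annotated feature bases per Hi-C bin
#'
#' @param intervals Tibble `contig`, `start`, `end` (1-based inclusive),
#'   `family`.
#' @param bins Bin tibble (`bin`, `contig`, `start`) with `bin_size`.
#' @param bin_size Bin size in bp.
#' @return Tibble `bin`, `family`, `bases`.
#' @export
features_per_bin <- function(intervals, bins, bin_size) {
  purrr::map_dfr(seq_len(nrow(bins)), function(i) {
    b <- bins[i, ]
    lo <- b$start + 1L; hi <- b$start + bin_size
    sel <- intervals$contig == b$contig & intervals$start <= hi &
      intervals$end >= lo
    if (!any(sel)) return(NULL)
    ov <- pmin(intervals$end[sel], hi) - pmax(intervals$start[sel], lo) + 1L
    tibble::tibble(bin = b$bin, family = intervals$family[sel],
                   bases = ov) |>
      dplyr::group_by(.data$bin, .data$family) |>
      dplyr::summarise(bases = sum(.data$bases), .groups = "drop")
  })
}

#' Plot a compartment track
#'
#' @param object A `compartment_track`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot compartment_track
#' @export
autoplot.compartment_track <- function(object, ...) {
  df <- object[!is.na(object$eigenvector), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bin, y = .data$eigenvector,
                                   fill = .data$label)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~contig, scales = "free_x") +
    ggplot2::labs(x = "bin", y = "compartment eigenvector",
                  fill = "compartment") +
    ggplot2::theme_minimal()
}
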