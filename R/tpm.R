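#' Transcripts per million
#'
#' TPM for sample `j` is `1e6 * rate / sum(rate)` with
#' `rate = count / length_bp`, so every sample's TPM column sums to one
#' million.
#'
#' @param counts Either a `count_matrix` (from [simulate_counts()] /
#'   [read_counts()]) or a tibble with `gene_id`, `length_bp`, and one
#'   numeric column per sample.
#' @return A long tibble with `gene_id`, `sample`, `tpm`.
#' @examples
#' tb <- tibble::tibble(gene_id = c("a", "b"), length_bp = c(1000, 2000),
#'                      s1 = c(10, 20))
#' compute_tpm(tb)  # both genes 5e5
#' @export
compute_tpm <- function(counts) {
  if (inherits(counts, "count_matrix")) counts <- counts$counts
  stopifnot(all(c("gene_id", "length_bp") %in% names(counts)))
  if (any(counts$length_bp <= 0)) stop("gene lengths must be positive")
  sample_cols <- setdiff(names(counts), c("gene_id", "length_bp"))
  if (!length(sample_cols)) stop("no sample columns found")
  long <- tidyr::pivot_longer(counts, dplyr::all_of(sample_cols),
                              names_to = "sample", values_to = "count")
  long <- dplyr::mutate(long, rate = .data$count / .data$length_bp)
  totals <- long |>
    dplyr::group_by(.data$sample) |>
    dplyr::summarise(total = sum(.data$rate), .groups = "drop")
  bad <- totals$sample[totals$total == 0]
  if (length(bad)) {
    stop("sample(s) with zero total rate: ", paste(bad, collapse = ", "))
  }
  long |>
    dplyr::left_join(totals, by = "sample") |>
    dplyr::mutate(tpm = 1e6 * .data$rate / .data$total) |>
    dplyr::select("gene_id", "sample", "tpm")
}

#' Per-isolation mean TPM
#'
#' @param tpm Long TPM tibble from [compute_tpm()].
#' @param samples Sample sheet with `sample` and `isolation`.
#' @return Tibble `gene_id`, `isolation`, `mean_tpm`.
#' @export
mean_tpm_by_isolation <- function(tpm, samples) {
  tpm |>
    dplyr::left_join(samples[, c("sample", "isolation")], by = "sample") |>
    dplyr::group_by(.data$gene_id, .data$isolation) |>
    dplyr::summarise(mean_tpm = mean(.data$tpm), .groups = "drop")
}

#' Bin genes by expression level
#'
#' Genes are binned by mean TPM in one isolation: `high` above 30 TPM,
#' `expressed` between 10 and 30 TPM, `weak` below 10 TPM.  Boundary values
#' (exactly 10 or exactly 30) fall in the middle `expressed` bin so the bins
#' are exhaustive.
#'
#' @param tpm Long TPM tibble from [compute_tpm()].
#' @param samples Sample sheet with `sample` and `isolation`.
#' @param isolation Which isolation to bin in.
#' @return Tibble `gene_id`, `mean_tpm`, `expression_bin`.
#' @export
bin_expression <- function(tpm, samples, isolation) {
  stopifnot(isolation %in% samples$isolation)
  mt <- mean_tpm_by_isolation(tpm, samples)
  mt <- mt[mt$isolation == isolation, ]
  tibble::tibble(
    gene_id = mt$gene_id,
    mean_tpm = mt$mean_tpm,
    expression_bin = .tpm_bin(mt$mean_tpm)
  )
}

.tpm_bin <- function(x) {
  dplyr::case_when(
    x > 30 ~ "high",
    x < 10 ~ "weak",
    TRUE ~ "expressed"
  )
}
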