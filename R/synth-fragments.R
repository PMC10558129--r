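#' Per-promoter fragment template intensities
#'
#' Expected fragment counts per promoter and assay used by
#' [simulate_fragments()], at nominal depth (i.e. when
#' `plan$fragment_depth` is `NULL`).  The templates encode the planted
#' promoter architectures:
#'
#' * tissue-specific genes: a strong short-fragment (sub-nucleosomal)
#'   enrichment centered ~200 bp upstream of the TSS, present only in the
#'   matching isolation;
#' * constitutive genes (all isolations) and neoblast genes (neoblast
#'   isolation only): a milder TSS-centered short-fragment enrichment plus
#'   nucleosome-sized fragments whose midpoints are phased at -180 and
#'   +120 bp;
#' * H3K4me3 fragments enriched downstream of the TSS, stronger for
#'   constitutive/neoblast than for tissue genes.
#'
#' @return A tibble with columns `arch` (tissue / stem-like), `assay`,
#'   `component`, `mean_count`, `center`, `sd`, `len_min`, `len_max`.
#' @export
fragment_templates <- function() {
  tibble::tribble(
    ~arch,     ~assay,     ~component, ~mean_count, ~center, ~sd, ~len_min, ~len_max,
    "tissue",  "ATAC",     "nfr",      200,         -200,    50,  50,       119,
    "stem",    "ATAC",     "tss",      120,         0,       30,  50,       119,
    "stem",    "ATAC",     "nuc_m1",   40,          -180,    20,  150,      250,
    "stem",    "ATAC",     "nuc_p1",   40,          120,     20,  150,      250,
    "tissue",  "H3K4me3",  "body",     80,          300,     150, 150,      250,
    "stem",    "H3K4me3",  "body",     200,         300,     150, 150,      250
  )
}

# background fragment rate per bp per sample
.bg_rate <- function(assay) if (assay == "ATAC") 0.005 else 0.002

#' Simulate chromatin fragments with planted promoter architecture
#'
#' Generates deduplicated-fragment-style BED3 intervals for one assay across
#' all five isolations (one sample per isolation), by drawing
#' Poisson-distributed fragment counts around the class templates of
#' [fragment_templates()] plus a uniform genomic background.  Fragments
#' extending past a contig end are clipped.
#'
#' @param plan A [simulation_plan()].
#' @param bundle A `genome_bundle` from [simulate_genome()].
#' @param assay `"ATAC"` or `"H3K4me3"`.
#' @return A tibble with `contig`, `start`, `end` (0-based half-open),
#'   `length`, `sample`, `isolation`, `assay`.
#' @export
simulate_fragments <- function(plan, bundle, assay = c("ATAC", "H3K4me3")) {
  assay <- match.arg(assay)
  stopifnot(inherits(bundle, "genome_bundle"))
  genes <- bundle$genes
  contig_len <- stats::setNames(Biostrings::width(bundle$genome),
                                names(bundle$genome))
  genome_bp <- sum(contig_len)
  tmpl <- fragment_templates()
  tmpl <- tmpl[tmpl$assay == assay, ]
  iso <- stemchrom_isolations()
  tissue_classes <- c("brain", "epidermis", "intestine")

  # scale all intensities so the expected per-sample total matches
  # plan$fragment_depth (if set)
  implied <- genome_bp * .bg_rate(assay)
  if (nrow(genes)) {
    arch_of <- ifelse(genes$class %in% tissue_classes, "tissue",
                      ifelse(genes$class %in% c("constitutive", "neoblast"),
                             "stem", NA))
    per_arch <- tapply(tmpl$mean_count, tmpl$arch, sum)
    implied <- implied +
      sum(per_arch[stats::na.omit(arch_of)], na.rm = TRUE) / length(iso) *
      2  # rough average across isolations; scaling only needs to be stable
  }
  s <- if (is.null(plan$fragment_depth)) 1 else plan$fragment_depth / implied

  stage <- if (assay == "ATAC") "atac" else "h3k4"
  .with_stage_seed(plan, stage, {
    rows <- list()
    emit <- function(contig, gcenter, len, sample, isolation) {
      if (!length(gcenter)) return()
      start <- as.integer(round(gcenter - len / 2))
      end <- as.integer(start + len)
      # clip to contig bounds
      cl <- contig_len[contig]
      start <- pmax(start, 0L)
      end <- pmin(end, as.integer(cl))
      keep <- end > start
      rows[[length(rows) + 1L]] <<- tibble::tibble(
        contig = contig[keep], start = start[keep], end = end[keep],
        sample = sample, isolation = isolation)
    }
    for (is_name in iso) {
      sample <- paste0(is_name, "_", assay)
      # promoter templates
      if (nrow(genes)) {
        for (r in seq_len(nrow(tmpl))) {
          tm <- tmpl[r, ]
          active <- if (tm$arch == "tissue") {
            genes$class %in% tissue_classes & genes$class == is_name
          } else {
            genes$class == "constitutive" |
              (genes$class == "neoblast" & is_name == "neoblast")
          }
          # tissue genes keep a basal H3K4me3 signal off-isolation
          basal <- tm$arch == "tissue" & tm$assay == "H3K4me3" &
            genes$class %in% tissue_classes & genes$class != is_name
          mean_counts <- numeric(nrow(genes))
          mean_counts[active] <- tm$mean_count * s
          mean_counts[basal] <- 5 * s
          sel <- which(mean_counts > 0)
          if (!length(sel)) next
          n <- stats::rpois(length(sel), mean_counts[sel])
          gi <- rep(sel, n)
          if (!length(gi)) next
          rel <- stats::rnorm(length(gi), tm$center, tm$sd)
          len <- round(stats::runif(length(gi), tm$len_min, tm$len_max))
          tss0 <- genes$tss[gi] - 1L
          gc <- ifelse(genes$strand[gi] == "+", tss0 + rel, tss0 - rel)
          emit(genes$contig[gi], gc, len, sample, is_name)
        }
      }
      # uniform background
      for (ct in names(contig_len)) {
        n_bg <- stats::rpois(1, contig_len[[ct]] * .bg_rate(assay) * s)
        if (n_bg == 0) next
        gc <- stats::runif(n_bg, 0, contig_len[[ct]])
        lmin <- if (assay == "ATAC") 50 else 150
        len <- round(stats::runif(n_bg, lmin, 250))
        emit(rep(ct, n_bg), gc, len, sample, is_name)
      }
    }
    out <- if (length(rows)) dplyr::bind_rows(rows) else
      tibble::tibble(contig = character(), start = integer(),
                     end = integer(), sample = character(),
                     isolation = character())
    out$length <- out$end - out$start
    out$assay <- assay
    dplyr::arrange(out, .data$contig, .data$start, .data$end)[
      , c("contig", "start", "end", "length", "sample", "isolation",
          "assay")]
  })
}

#' Write / read fragments as BED3 (+ sample column)
#'
#' @param fragments Fragment tibble.
#' @param path Output TSV/BED path.
#' @return The path / a fragment tibble.
#' @export
write_fragments <- function(fragments, path) {
  readr::write_tsv(fragments[, c("contig", "start", "end", "sample")],
                   path, col_names = FALSE)
  invisible(path)
}

#' @rdname write_fragments
#' @param sample,isolation,assay Metadata to attach when the BED file does
#'   not carry them.
#' @export
read_fragments <- function(path, sample = NULL, isolation = NA_character_,
                           assay = NA_character_) {
  x <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE)
  names(x)[1:3] <- c("contig", "start", "end")
  if (ncol(x) >= 4) names(x)[4] <- "sample"
  if (!is.null(sample)) x$sample <- sample
  if (!"sample" %in% names(x)) x$sample <- "all"
  x$length <- x$end - x$start
  x$isolation <- isolation
  x$assay <- assay
  tibble::as_tibble(x)
}
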