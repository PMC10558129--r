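#' Simulate a replicated gene x sample count matrix
#'
#' Draws negative-binomial counts for `n_replicates` replicates of the five
#' cell isolations.  Class genes have a `fold_change`-times higher mean in
#' their matching isolation; constitutive genes have equal (high) means
#' everywhere; unclassified genes are weakly expressed everywhere.  Base
#' count means are drawn log-normally around class-typical levels
#' (specific ~80, constitutive ~200, unclassified ~0.5 expected counts), and
#' gene lengths uniformly in 0.5-3 kb.
#'
#' @param plan A [simulation_plan()].
#' @param class_table Optional precomputed [simulate_class_table()] output.
#' @return A `count_matrix` object: list with `counts` (tibble: `gene_id`,
#'   `length_bp`, one column per sample), `samples` (tibble: `sample`,
#'   `isolation`, `replicate`), and `truth` (the class table).
#' @export
simulate_counts <- function(plan, class_table = NULL) {
  stopifnot(inherits(plan, "simulation_plan"))
  if (is.null(class_table)) class_table <- simulate_class_table(plan)
  iso <- stemchrom_isolations()
  n_rep <- plan$n_replicates
  samples <- tibble::tibble(
    sample = paste0(rep(iso, each = n_rep), "_r", rep(seq_len(n_rep),
                                                      length(iso))),
    isolation = rep(iso, each = n_rep),
    replicate = rep(seq_len(n_rep), length(iso))
  )
  ng <- nrow(class_table)
  .with_stage_seed(plan, "counts", {
    length_bp <- sample(500:3000, ng, replace = TRUE)
    base <- numeric(ng)
    cl <- class_table$class
    spec <- cl %in% c("brain", "epidermis", "intestine", "neoblast")
    base[spec] <- stats::rlnorm(sum(spec), log(80), 0.4)
    base[cl == "constitutive"] <- stats::rlnorm(sum(cl == "constitutive"),
                                                log(200), 0.4)
    base[cl == "unclassified"] <- stats::rlnorm(sum(cl == "unclassified"),
                                                log(0.5), 0.3)
    mu <- matrix(base, ng, length(iso), dimnames = list(NULL, iso))
    for (k in c("brain", "epidermis", "intestine", "neoblast")) {
      mu[cl == k, k] <- base[cl == k] * plan$fold_change
    }
    draw <- function(m) {
      if (plan$nb_dispersion < 1e-8) stats::rpois(length(m), m)
      else stats::rnbinom(length(m), mu = m, size = 1 / plan$nb_dispersion)
    }
    counts <- vapply(seq_len(nrow(samples)), function(j) {
      draw(mu[, samples$isolation[j]])
    }, numeric(ng))
    colnames(counts) <- samples$sample
    out <- tibble::as_tibble(counts)
    out <- dplyr::bind_cols(
      tibble::tibble(gene_id = class_table$gene_id,
                     length_bp = as.integer(length_bp)),
      out
    )
    structure(list(counts = out, samples = samples,
                   truth = class_table),
              class = "count_matrix")
  })
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("<count_matrix>", nrow(x$counts), "genes x", nrow(x$samples),
      "samples (", length(unique(x$samples$isolation)), "isolations )\n")
  invisible(x)
}

#' Write / read a count matrix as TSV
#'
#' The counts table is written as `gene_id`, `length_bp`, one column per
#' sample; the sample sheet as `sample`, `isolation`, `replicate`.
#'
#' @param x A `count_matrix`.
#' @param dir Output directory.
#' @return `write_counts()` the directory, invisibly; `read_counts()` a
#'   `count_matrix` (without planted truth).
#' @export
write_counts <- function(x, dir) {
  stopifnot(inherits(x, "count_matrix"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(x$counts, file.path(dir, "counts.tsv"))
  readr::write_tsv(x$samples, file.path(dir, "samples.tsv"))
  if (!is.null(x$truth)) {
    readr::write_tsv(x$truth, file.path(dir, "classes_truth.tsv"))
  }
  invisible(dir)
}

#' @rdname write_counts
#' @export
read_counts <- function(dir) {
  counts <- readr::read_tsv(file.path(dir, "counts.tsv"),
                            show_col_types = FALSE)
  samples <- readr::read_tsv(file.path(dir, "samples.tsv"),
                             show_col_types = FALSE)
  structure(list(counts = counts, samples = samples, truth = NULL),
            class = "count_matrix")
}
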