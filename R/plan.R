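#' Cell isolations and gene classes
#'
#' The five cell isolations profiled by the experimental design (four
#' differentiated tissues plus the neoblast stem-cell fraction) and the six
#' gene classes assigned by the expression rules. The pharynx participates
#' only as a contrast group; no pharynx-specific gene class is called.
#'
#' @format Character vectors.
#' @name stemchrom-classes
NULL

#' @rdname stemchrom-classes
#' @export
stemchrom_isolations <- function() {
  c("brain", "epidermis", "intestine", "neoblast", "pharynx")
}

#' @rdname stemchrom-classes
#' @export
stemchrom_gene_classes <- function() {
  c("brain", "epidermis", "intestine", "neoblast", "constitutive",
    "unclassified")
}

#' Build a simulation plan
#'
#' A simulation plan collects every tunable parameter of the synthetic-data
#' generator in one validated object.  The same plan (same seed included)
#' always regenerates byte-identical artifacts, so downstream analyses can be
#' tested against planted ground truth.
#'
#' The defaults describe the study conditions the generator emulates: a
#' genome with ~70% AT content, constitutive/stem promoters whose
#' \[-200, 0\] window reaches 92% AT with a T bias and poly(dT) tracts,
#' tissue promoters with an upstream nucleosome-free region around -200 bp
#' plus AT trinucleotide tandem repeats, fourfold expression enrichment of
#' class genes in their matching isolation, three replicates of five cell
#' isolations, two-compartment checkerboard Hi-C contact maps with
#' low-coverage "white strips", and image stacks of Gaussian cell blobs with
#' known colony membership.
#'
#' @param seed Integer seed; every generator routes its randomness through
#'   this value (plus a fixed per-stage offset) so artifacts are reproducible
#'   independent of call order.
#' @param n_genes_per_class Named integer vector giving the number of genes
#'   to plant per class; names must be a subset of
#'   [stemchrom_gene_classes()].
#' @param genome_at_fraction Background genome AT fraction in \[0, 1\].
#' @param promoter_at_fraction_constitutive Target AT fraction of the
#'   \[-200, 0\] window of constitutive and neoblast promoters.
#' @param promoter_t_bias Probability that an AT base in the constitutive
#'   promoter window is T rather than A (the "T over A" bias).
#' @param tss_window_bp Width of the promoter window used downstream (bp).
#' @param fragment_depth Expected fragments per sample for fragment
#'   generation; `NULL` keeps the per-promoter template intensities at their
#'   nominal values (see [fragment_templates()]).
#' @param nb_dispersion Negative-binomial dispersion of simulated counts
#'   (variance = mu + dispersion * mu^2); values below 1e-8 fall back to
#'   Poisson noise.
#' @param fold_change Expression fold change of a class gene in its matching
#'   isolation.
#' @param n_replicates Replicates per isolation.
#' @param gene_length_bp Length of each simulated gene body (bp).
#' @param hic_bins Number of Hi-C bins (>= 20).
#' @param hic_bin_size Hi-C bin size in bp.
#' @param hic_block_bins Compartment block length in bins (checkerboard
#'   period).
#' @param hic_boost Multiplicative contact boost for same-compartment bin
#'   pairs.
#' @param hic_decay_exponent Power-law exponent of contact distance decay.
#' @param hic_depth Expected contact count at distance one bin.
#' @param strip_fraction Fraction of Hi-C bins turned into near-zero
#'   coverage strips.
#' @param image_voxel_um Named numeric vector `c(x=, y=, z=)` of voxel
#'   calibration in micrometers (default: the 10x objective calibration,
#'   2.76 x 2.76 x 7 um).
#'
#' @return An object of class `simulation_plan` (a validated named list).
#' @examples
#' plan <- simulation_plan(seed = 1, n_genes_per_class = c(brain = 5,
#'   constitutive = 5))
#' plan
#' @export
simulation_plan <- function(seed = 1L,
                            n_genes_per_class = c(
                              brain = 150L, epidermis = 150L,
                              intestine = 150L, neoblast = 150L,
                              constitutive = 200L, unclassified = 200L),
                            genome_at_fraction = 0.70,
                            promoter_at_fraction_constitutive = 0.92,
                            promoter_t_bias = 0.65,
                            tss_window_bp = 2000L,
                            fragment_depth = NULL,
                            nb_dispersion = 0.1,
                            fold_change = 4,
                            n_replicates = 3L,
                            gene_length_bp = 1000L,
                            hic_bins = 100L,
                            hic_bin_size = 50000L,
                            hic_block_bins = 10L,
                            hic_boost = 2,
                            hic_decay_exponent = 1,
                            hic_depth = 60,
                            strip_fraction = 0.10,
                            image_voxel_um = c(x = 2.76, y = 2.76, z = 7)) {
  stopifnot(length(seed) == 1, is.finite(seed))
  seed <- as.integer(seed)
  if (is.null(names(n_genes_per_class)) ||
      !all(names(n_genes_per_class) %in% stemchrom_gene_classes())) {
    stop("`n_genes_per_class` must be named with gene classes: ",
         paste(stemchrom_gene_classes(), collapse = ", "))
  }
  n_genes_per_class <- vapply(n_genes_per_class, as.integer, integer(1))
  if (any(n_genes_per_class < 0)) stop("gene counts must be non-negative")
  for (fr in c(genome_at_fraction, promoter_at_fraction_constitutive,
               promoter_t_bias, strip_fraction)) {
    if (!is.numeric(fr) || fr < 0 || fr > 1) {
      stop("all fractions must lie in [0, 1]")
    }
  }
  stopifnot(tss_window_bp > 0, gene_length_bp > 0, n_replicates >= 1,
            nb_dispersion >= 0, fold_change > 0,
            hic_bins >= 20, hic_bin_size > 0, hic_block_bins >= 1,
            hic_boost > 0, hic_depth > 0)
  if (!is.null(fragment_depth)) stopifnot(fragment_depth >= 0)
  if (!all(c("x", "y", "z") %in% names(image_voxel_um)) ||
      any(image_voxel_um <= 0)) {
    stop("`image_voxel_um` must be a named positive vector c(x=, y=, z=)")
  }
  plan <- list(
    seed = seed,
    n_genes_per_class = n_genes_per_class,
    genome_at_fraction = genome_at_fraction,
    promoter_at_fraction_constitutive = promoter_at_fraction_constitutive,
    promoter_t_bias = promoter_t_bias,
    tss_window_bp = as.integer(tss_window_bp),
    fragment_depth = fragment_depth,
    nb_dispersion = nb_dispersion,
    fold_change = fold_change,
    n_replicates = as.integer(n_replicates),
    gene_length_bp = as.integer(gene_length_bp),
    hic_bins = as.integer(hic_bins),
    hic_bin_size = as.integer(hic_bin_size),
    hic_block_bins = as.integer(hic_block_bins),
    hic_boost = hic_boost,
    hic_decay_exponent = hic_decay_exponent,
    hic_depth = hic_depth,
    strip_fraction = strip_fraction,
    image_voxel_um = image_voxel_um[c("x", "y", "z")]
  )
  structure(plan, class = "simulation_plan")
}

#' @export
print.simulation_plan <- function(x, ...) {
  cat("<simulation_plan>\n")
  cat("  seed:", x$seed, "\n")
  cat("  genes:", paste(names(x$n_genes_per_class), x$n_genes_per_class,
                        sep = "=", collapse = ", "), "\n")
  cat("  genome AT:", x$genome_at_fraction,
      "| constitutive promoter AT:", x$promoter_at_fraction_constitutive,
      "\n")
  cat("  counts: fold change", x$fold_change, ", dispersion",
      x$nb_dispersion, ",", x$n_replicates, "replicates x 5 isolations\n")
  cat("  Hi-C:", x$hic_bins, "bins of", x$hic_bin_size, "bp, boost",
      x$hic_boost, ", strip fraction", x$strip_fraction, "\n")
  cat("  voxel (um):", paste(names(x$image_voxel_um), x$image_voxel_um,
                             sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Write or read a simulation plan as plain text
#'
#' Plans serialize to a key/value YAML file so a run's conditions travel with
#' its artifacts.
#'
#' @param plan A [simulation_plan()].
#' @param path File path.
#' @return `read_plan()` returns a `simulation_plan`; `write_plan()` returns
#'   `path` invisibly.
#' @export
write_plan <- function(plan, path) {
  stopifnot(inherits(plan, "simulation_plan"))
  x <- unclass(plan)
  x$n_genes_per_class <- as.list(x$n_genes_per_class)
  x$image_voxel_um <- as.list(x$image_voxel_um)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_plan
#' @export
read_plan <- function(path) {
  x <- yaml::read_yaml(path)
  x$n_genes_per_class <- unlist(x$n_genes_per_class)
  x$image_voxel_um <- unlist(x$image_voxel_um)
  do.call(simulation_plan, x)
}

# Stage-specific seeds: every generator is reproducible in isolation, so
# artifact identity does not depend on the order generators are called in.
.stage_seed <- function(plan, stage) {
  offsets <- c(genome = 101L, counts = 211L, atac = 307L, h3k4 = 401L,
               hic = 503L, stack = 601L)
  if (!stage %in% names(offsets)) stop("unknown stage: ", stage)
  (as.integer(plan$seed) + offsets[[stage]]) %% .Machine$integer.max
}

.with_stage_seed <- function(plan, stage, code) {
  withr::with_seed(.stage_seed(plan, stage), code)
}
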