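make_counts <- function(mat, lengths = rep(1000L, nrow(mat)),
                        iso = NULL, reps = NULL) {
  samples <- tibble::tibble(
    sample = colnames(mat),
    isolation = iso %||% rep("iso", ncol(mat)),
    replicate = reps %||% seq_len(ncol(mat)))
  counts <- dplyr::bind_cols(
    tibble::tibble(gene_id = paste0("g", seq_len(nrow(mat))),
                   length_bp = lengths),
    tibble::as_tibble(mat))
  list(counts = counts, samples = samples)
}

test_that("TPM normalizes rates to one million per sample", {
  tb <- tibble::tibble(gene_id = c("a", "b"),
                       length_bp = c(1000L, 2000L), s1 = c(10, 20))
  tpm <- compute_tpm(tb)
  expect_equal(tpm$tpm, c(5e5, 5e5))
  one <- tibble::tibble(gene_id = "a", length_bp = 700L, s1 = 3)
  expect_equal(compute_tpm(one)$tpm, 1e6)
  # random 50 x 4 matrix: per-sample sums hit 1e6 to relative 1e-6
  set.seed(1)
  m <- matrix(rpois(200, 30), 50, 4,
              dimnames = list(NULL, paste0("s", 1:4)))
  x <- make_counts(m, lengths = sample(500:3000, 50, TRUE))
  tpm <- compute_tpm(x$counts)
  sums <- tapply(tpm$tpm, tpm$sample, sum)
  expect_true(all(abs(sums - 1e6) < 1e6 * 1e-6))
  # direct-summation oracle for one entry
  rate <- m[, 1] / x$counts$length_bp
  expect_equal(tpm$tpm[tpm$sample == "s1"][7], 1e6 * rate[7] / sum(rate))
})

test_that("a sample with zero total rate fails, naming the sample", {
  tb <- tibble::tibble(gene_id = c("a", "b"), length_bp = c(1000L, 1000L),
                       good = c(1, 2), dead = c(0, 0))
  expect_error(compute_tpm(tb), "dead")
})

test_that("welch contrasts match their stated arithmetic", {
  # gene 1 has TPM exactly 40 in iso A and 10 in iso B
  m <- cbind(a1 = c(40, 999960), a2 = c(40, 999960),
             b1 = c(10, 999990), b2 = c(10, 999990))
  x <- make_counts(m, iso = c("A", "A", "B", "B"), reps = c(1, 2, 1, 2))
  res <- pairwise_contrasts(x$counts, x$samples, engine = "welch")
  g1 <- res[res$gene_id == "g1", ]
  expect_equal(g1$log2fc, log2(41 / 11), tolerance = 1e-8)
  # zero variance, unequal means: p -> 0
  expect_equal(g1$pvalue, 0)
  # identical replicate vectors in both groups
  m2 <- cbind(a1 = c(5, 7), a2 = c(5, 7), b1 = c(5, 7), b2 = c(5, 7))
  x2 <- make_counts(m2, iso = c("A", "A", "B", "B"), reps = c(1, 2, 1, 2))
  res2 <- pairwise_contrasts(x2$counts, x2$samples, engine = "welch")
  expect_true(all(res2$log2fc == 0))
  expect_true(all(res2$p_adj == 1))
})

test_that("welch p-values agree with stats::t.test on noisy data", {
  set.seed(11)
  m <- matrix(rnbinom(40 * 6, mu = 50, size = 5), 40, 6,
              dimnames = list(NULL, paste0("s", 1:6)))
  x <- make_counts(m, iso = rep(c("A", "B"), each = 3),
                   reps = rep(1:3, 2))
  res <- pairwise_contrasts(x$counts, x$samples, engine = "welch")
  tpm <- compute_tpm(x$counts)
  lt <- log2(matrix(tpm$tpm[order(tpm$sample, tpm$gene_id)], 40)[
    order(order(paste0("g", 1:40))), ] + 1)
  # recompute with t.test for a handful of genes
  wide <- tidyr::pivot_wider(tpm, names_from = "sample",
                             values_from = "tpm")
  wide <- wide[match(paste0("g", 1:40), wide$gene_id), ]
  for (g in c(1, 13, 27)) {
    a <- log2(as.numeric(wide[g, c("s1", "s2", "s3")]) + 1)
    b <- log2(as.numeric(wide[g, c("s4", "s5", "s6")]) + 1)
    expect_equal(res$pvalue[res$gene_id == paste0("g", g)],
                 stats::t.test(a, b)$p.value, tolerance = 1e-10)
  }
  # BH within the contrast matches manual step-up on our own p-values
  p <- res$pvalue
  n <- length(p)
  o <- order(p)
  stepup <- numeric(n)
  stepup[o] <- rev(cummin(rev(p[o] * n / seq_len(n))))
  expect_equal(res$p_adj, pmin(stepup, 1))
})

test_that("planted fold-change direction is recovered by welch log2FC", {
  plan <- simulation_plan(seed = 21, nb_dispersion = 0.05, fold_change = 4,
                          n_genes_per_class = c(brain = 150, neoblast = 150,
                                                constitutive = 150,
                                                unclassified = 150))
  cm <- simulate_counts(plan)
  res <- pairwise_contrasts(cm, engine = "welch")
  truth <- cm$truth
  ok <- c()
  for (cl in c("brain", "neoblast")) {
    gid <- truth$gene_id[truth$class == cl]
    sub <- res[res$gene_id %in% gid &
                 (res$iso_a == cl | res$iso_b == cl), ]
    signed <- ifelse(sub$iso_a == cl, sub$log2fc, -sub$log2fc)
    ok <- c(ok, signed > 0)
  }
  expect_gte(mean(ok), 0.99)
})

test_that("classification rules apply strict thresholds", {
  iso <- c("brain", "epidermis", "intestine", "neoblast", "pharynx")
  pairs <- utils::combn(iso, 2)
  base <- purrr::map_dfr(seq_len(ncol(pairs)), function(k) {
    tibble::tibble(gene_id = c("up", "edge", "flat"),
                   contrast = paste0(pairs[1, k], "_vs_", pairs[2, k]),
                   iso_a = pairs[1, k], iso_b = pairs[2, k],
                   log2fc = 0, p_adj = 1)
  })
  # "up": neoblast gene, +2 vs all others; "edge": exactly 1.0 in one
  # required contrast, passing elsewhere
  fix <- function(df, gene, cl, lfc_all, one_edge = FALSE) {
    sel <- df$gene_id == gene & (df$iso_a == cl | df$iso_b == cl)
    df$log2fc[sel] <- ifelse(df$iso_a[sel] == cl, lfc_all, -lfc_all)
    df$p_adj[sel] <- 0.001
    if (one_edge) {
      first <- which(sel)[1]
      df$log2fc[first] <- ifelse(df$iso_a[first] == cl, 1.0, -1.0)
    }
    df
  }
  contrasts <- fix(base, "up", "neoblast", 2)
  contrasts <- fix(contrasts, "edge", "brain", 2, one_edge = TRUE)
  tpm <- tidyr::expand_grid(
    gene_id = c("up", "edge", "flat"),
    sample = paste0(rep(iso, each = 2), "_r", rep(1:2, 5))) |>
    dplyr::mutate(tpm = 50)
  samples <- tibble::tibble(sample = unique(tpm$sample),
                            isolation = rep(iso, each = 2),
                            replicate = rep(1:2, 5))
  cls <- classify_genes(contrasts, tpm, samples)
  expect_equal(cls$class[cls$gene_id == "up"], "neoblast")
  expect_equal(cls$class[cls$gene_id == "edge"], "unclassified")
  # "flat": expressed everywhere, no significant contrast -> constitutive
  expect_equal(cls$class[cls$gene_id == "flat"], "constitutive")
  # a gene absent from the contrasts is unclassified with a warning
  tpm2 <- dplyr::bind_rows(tpm, tidyr::expand_grid(
    gene_id = "ghost", sample = samples$sample) |>
      dplyr::mutate(tpm = 50))
  expect_warning(cls2 <- classify_genes(contrasts, tpm2, samples),
                 "absent")
  expect_equal(cls2$class[cls2$gene_id == "ghost"], "unclassified")
})

test_that("expression bins respect the 10/30 TPM boundaries", {
  tpm <- tibble::tibble(gene_id = paste0("g", 1:4),
                        sample = "a_r1", tpm = c(31, 5, 30, 10))
  samples <- tibble::tibble(sample = "a_r1", isolation = "a",
                            replicate = 1)
  bins <- bin_expression(tpm, samples, "a")
  expect_equal(bins$expression_bin, c("high", "weak", "expressed",
                                      "expressed"))
})

test_that("classification is invariant to uniform scaling of a sample", {
  plan <- small_plan(seed = 31)
  cm <- simulate_counts(plan)
  before <- classify_expression(cm, engine = "welch")$classes
  scaled <- cm$counts
  scaled$brain_r2 <- scaled$brain_r2 * 10
  after <- classify_expression(
    structure(list(counts = scaled, samples = cm$samples, truth = NULL),
              class = "count_matrix"), engine = "welch")$classes
  expect_identical(before, after)
})

test_that("null simulations rarely leak into specific classes (welch)", {
  leak <- vapply(1:5, function(s) {
    plan <- simulation_plan(
      seed = 100 + s, fold_change = 1,
      n_genes_per_class = c(brain = 100, epidermis = 100, intestine = 100,
                            neoblast = 100, constitutive = 100,
                            unclassified = 100))
    cls <- classify_expression(simulate_counts(plan),
                               engine = "welch")$classes
    mean(!cls$class %in% c("constitutive", "unclassified"))
  }, numeric(1))
  expect_true(all(leak <= 0.05))
})

test_that("contrast tables round-trip through the TSV schema", {
  x <- tibble::tibble(gene_id = c("g1", "g2"),
                      contrast = "brain_vs_neoblast",
                      iso_a = "brain", iso_b = "neoblast",
                      log2fc = c(1.5, -0.3), pvalue = c(0.01, 0.7),
                      p_adj = c(0.02, 0.8))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_contrast_table(x, path)
  back <- read_contrast_table(path)
  expect_equal(back$log2fc, x$log2fc)
  # iso columns recovered from the contrast string when missing
  readr::write_tsv(x[, c("gene_id", "contrast", "log2fc", "p_adj")], path)
  back2 <- read_contrast_table(path)
  expect_equal(back2$iso_a, c("brain", "brain"))
})
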