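rand_seq <- function(n, len, probs = c(A = 0.3, C = 0.2, G = 0.2, T = 0.3)) {
  vapply(seq_len(n), function(i) {
    paste(sample(names(probs), len, replace = TRUE, prob = probs),
          collapse = "")
  }, character(1))
}

test_that("promoter extraction is strand-aware with position -1 at the TSS", {
  genome <- Biostrings::DNAStringSet(c(c1 = "AAACCC"))
  plus <- tibble::tibble(gene_id = "p", contig = "c1", tss = 4L,
                         strand = "+")
  expect_equal(extract_promoters(genome, plus, upstream = 3)$seq, "AAA")
  minus <- tibble::tibble(gene_id = "m", contig = "c1", tss = 3L,
                          strand = "-")
  expect_equal(extract_promoters(genome, minus, upstream = 3)$seq, "GGG")
  # truncation at the contig edge pads with N and flags
  expect_warning(tr <- extract_promoters(genome, plus, upstream = 10),
                 "truncated")
  expect_true(tr$truncated)
  expect_equal(nchar(tr$seq), 10)
  expect_match(tr$seq, "^N+AAA$")
})

test_that("extraction round-trips against the genome substring", {
  set.seed(3)
  genome <- Biostrings::DNAStringSet(c(c1 = rand_seq(1, 3000)))
  genes <- tibble::tibble(gene_id = c("p", "m"), contig = "c1",
                          tss = c(1200L, 2100L), strand = c("+", "-"))
  prom <- extract_promoters(genome, genes, upstream = 100, downstream = 20)
  raw <- as.character(genome[[1]])
  expect_equal(prom$seq[1], substr(raw, 1100, 1219))
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(substr(raw, 2081, 2200))))
  expect_equal(prom$seq[2], rc)
})

test_that("composition profiles sum to one and flag all-N positions", {
  prom <- tibble::tibble(gene_id = c("a", "b"),
                         seq = c("AAAA", "AAAA"),
                         upstream = 2L, downstream = 2L,
                         truncated = FALSE)
  cp <- composition_profile(prom)
  expect_true(all(cp$a == 1))
  expect_equal(cp$position, c(-2, -1, 0, 1))
  alt <- tibble::tibble(gene_id = c("a", "b"), seq = c("ATAT", "ATAT"),
                        upstream = 2L, downstream = 2L, truncated = FALSE)
  ca <- composition_profile(alt)
  expect_equal(ca$a, c(1, 0, 1, 0))
  expect_equal(ca$t, c(0, 1, 0, 1))
  expect_true(all(abs(ca$a + ca$c + ca$g + ca$t - 1) < 1e-12))
  nn <- tibble::tibble(gene_id = "a", seq = "ANTA", upstream = 2L,
                       downstream = 2L, truncated = TRUE)
  expect_warning(cn <- composition_profile(nn), "N bases")
  expect_true(is.nan(cn$at[2]))
})

test_that("T-stretch counting finds maximal runs only", {
  tb <- tibble::tibble(gene_id = "g", seq = "TTTTTATTTTTT")
  expect_equal(t_stretch_counts(tb, min_len = 5)$n_stretches, 2L)
  expect_equal(t_stretch_counts(tibble::tibble(gene_id = "g",
                                               seq = "AAAAAAA"),
                                min_len = 5)$n_stretches, 0L)
  expect_error(t_stretch_counts(tb, min_len = 1), "min_len")
  set.seed(7)
  seqs <- rand_seq(100, 120, probs = c(A = .2, C = .1, G = .1, T = .6))
  got <- t_stretch_counts(tibble::tibble(gene_id = paste0("g", 1:100),
                                         seq = seqs), min_len = 5)
  want <- vapply(seqs, oracle_t_runs, integer(1), min_len = 5,
                 USE.NAMES = FALSE)
  expect_equal(got$n_stretches, want)
})

test_that("t_stretch_stats runs class comparisons with Bonferroni", {
  ct <- tibble::tibble(gene_id = paste0("g", 1:40),
                       class = rep(c("brain", "constitutive"), each = 20))
  seqs <- c(rand_seq(20, 100, c(A = .35, C = .15, G = .15, T = .35)),
            rand_seq(20, 100, c(A = .25, C = .04, G = .04, T = .67)))
  st <- t_stretch_stats(tibble::tibble(gene_id = ct$gene_id, seq = seqs),
                        ct, min_len = 5)
  expect_equal(nrow(st$tests), 1)
  expect_true(st$tests$p_bonferroni >= st$tests$p_value)
  expect_lt(st$tests$p_value, 0.05)
})

test_that("k-mer counts equal the exhaustive sliding-window oracle", {
  set.seed(9)
  seqs <- rand_seq(5, 25)
  got <- count_kmers(seqs, 4)
  want <- oracle_kmer_counts(seqs, 4)
  want <- want[order(names(want))]
  expect_equal(as.integer(want), as.integer(got[names(want)]))
  expect_equal(sum(got), sum(want))
})

test_that("k-mer enrichment ranks a planted nonamer first", {
  set.seed(13)
  bg <- rand_seq(50, 120)
  fg <- rand_seq(50, 120)
  planted <- "GACGTCATG"
  fg <- vapply(fg, function(s) {
    at <- sample(1:100, 1)
    paste0(substr(s, 1, at - 1), planted, substr(s, at + 9, 120))
  }, character(1), USE.NAMES = FALSE)
  km <- kmer_enrichment(fg, bg, k = 9)
  expect_equal(km$kmer[1], planted)
  expect_lt(km$p_adj[1], 1e-10)
  # background == foreground: enrichments near zero
  km0 <- kmer_enrichment(bg, bg, k = 6)
  expect_lt(max(abs(km0$log2_enrichment)), 0.25)
  expect_error(kmer_enrichment(fg, character(0), k = 9), "background")
})

test_that("enrichment keeps type-I behavior under resampled backgrounds", {
  set.seed(17)
  frac_sig <- vapply(1:20, function(i) {
    fg <- rand_seq(20, 80)
    bg <- rand_seq(40, 80)
    km <- kmer_enrichment(fg, bg, k = 4)
    mean(km$p_adj < 0.05 & km$log2_enrichment > 0)
  }, numeric(1))
  expect_lte(mean(frac_sig), 0.05)
})

test_that("tandem repeat arrays match the stated conventions", {
  one <- tandem_repeat_scan(c(g = "ATTATTATT"), unit_len = 3,
                            min_units = 3)
  expect_equal(nrow(one), 1)
  expect_equal(one$n_units, 3L)
  expect_true(one$at_only)
  expect_equal(c(one$start, one$end), c(1L, 9L))
  none <- tandem_repeat_scan(c(g = "ACGACG"), unit_len = 3, min_units = 3)
  expect_equal(nrow(none), 0)
  mixed <- tandem_repeat_scan(c(g = "TTACGACGACGTT"), unit_len = 3,
                              min_units = 3)
  expect_equal(nrow(mixed), 1)
  expect_false(mixed$at_only)
})

test_that("tandem arrays agree with the brute-force finder", {
  set.seed(19)
  seqs <- c(rand_seq(40, 60, c(A = .4, C = .1, G = .1, T = .4)),
            paste0("AC", strrep("TAT", 5), "GG"),
            paste0(strrep("AT", 6), "CC"))
  for (u in c(2, 3)) {
    got <- tandem_repeat_scan(stats::setNames(seqs,
                                              paste0("s", seq_along(seqs))),
                              unit_len = u, min_units = 3)
    for (i in seq_along(seqs)) {
      want <- oracle_tandem_arrays(seqs[i], u, 3)
      sub <- got[got$gene_id == paste0("s", i), ]
      if (is.null(want)) {
        expect_equal(nrow(sub), 0)
      } else {
        expect_equal(sub$start, want$start)
        expect_equal(sub$end, want$end)
        expect_equal(sub$n_units, want$n_units)
      }
    }
  }
})

test_that("PWM scanning matches exhaustive scoring", {
  pwm <- stemchrom_pwm("planted_tf")
  cons <- pwm_consensus(pwm)
  h <- scan_pwm(c(x = cons), pwm, score_threshold = -100)
  expect_equal(h$offset[which.max(h$score)], 1L)
  # uniform PWM against uniform background scores 0 everywhere
  uni <- new_pwm(matrix(0.25, 4, 6,
                        dimnames = list(c("A", "C", "G", "T"), NULL)))
  hu <- scan_pwm(c(x = "ACGTACGTAC"), uni, score_threshold = -100)
  expect_true(all(hu$score == 0))
  # exhaustive oracle on random sequences, including an N
  set.seed(23)
  seqs <- rand_seq(10, 30)
  seqs[3] <- paste0(substr(seqs[3], 1, 10), "N", substr(seqs[3], 12, 30))
  got <- scan_pwm(stats::setNames(seqs, paste0("s", 1:10)), pwm,
                  score_threshold = 2)
  for (i in 1:10) {
    want <- oracle_pwm_scores(seqs[i], pwm$mat, pwm$bg)
    w_hit <- which(!is.na(want) & want >= 2)
    sub <- got[got$id == paste0("s", i), ]
    expect_equal(sub$offset, as.integer(w_hit))
    expect_equal(sub$score, want[w_hit], tolerance = 1e-12)
  }
  # a sequence shorter than the motif yields no hits and no error
  expect_equal(nrow(scan_pwm(c(s = "ACG"), pwm, score_threshold = -100)),
               0)
})

test_that("reverse-complement scanning is symmetric", {
  pwm <- stemchrom_pwm("inr")
  set.seed(29)
  s <- rand_seq(1, 40)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  fwd <- scan_pwm(c(x = s), pwm, score_threshold = -100)
  rev <- scan_pwm(c(x = rc), reverse_complement_pwm(pwm),
                  score_threshold = -100)
  expect_equal(fwd$score, rev(rev$score), tolerance = 1e-12)
})

test_that("score thresholds match brute-force tail enumeration", {
  m <- matrix(c(.7, .1, .1, .1,
                .1, .6, .2, .1,
                .25, .25, .25, .25,
                .1, .1, .1, .7,
                .4, .3, .2, .1), 4, 5,
              dimnames = list(c("A", "C", "G", "T"), NULL))
  pwm <- new_pwm(m, bg = c(A = .3, C = .2, G = .2, T = .3))
  S <- round(log2(pmax(m, 1e-3) / pwm$bg), 6)
  grid <- expand.grid(rep(list(1:4), 5))
  sc <- round(apply(grid, 1, function(ix) sum(S[cbind(ix, 1:5)])), 5)
  pr <- apply(grid, 1, function(ix) prod(pwm$bg[ix]))
  agg <- tapply(pr, sc, sum)
  vals <- sort(as.numeric(names(agg)), decreasing = TRUE)
  tail_p <- cumsum(agg[as.character(vals)])
  for (p in c(0.05, 0.01, 0.001)) {
    ok <- tail_p <= p + 1e-9
    want <- if (any(ok)) min(vals[ok]) else max(vals) + 1e-9
    expect_equal(pwm_score_threshold(pwm, p), want, tolerance = 1e-4)
  }
})

test_that("motif class frequencies are simple percentages", {
  ct <- tibble::tibble(gene_id = paste0("g", 1:10),
                       class = rep("brain", 10))
  hits <- tibble::tibble(id = c("g1", "g1", "g2", "g7"), offset = 1L,
                         strand = "+", score = 5)
  mf <- motif_class_frequency(hits, ct)
  expect_equal(mf$percent, 30)
  none <- motif_class_frequency(hits[0, ], ct)
  expect_equal(none$percent, 0)
})

test_that("planted Inr frequencies are recovered within five points", {
  plan <- simulation_plan(seed = 43, n_genes_per_class = c(
    brain = 50, constitutive = 50, unclassified = 20))
  b <- simulate_genome(plan)
  prom <- extract_promoters(b$genome, b$genes, upstream = 40,
                            downstream = 41)
  hits <- scan_pwm(prom, stemchrom_pwm("inr"), p_threshold = 1e-4)
  mf <- motif_class_frequency(hits, b$truth$class_table)
  planted <- b$truth$motifs[b$truth$motifs$kind == "inr", ]
  planted_pct <- 100 * vapply(mf$class, function(cl) {
    ids <- b$truth$class_table$gene_id[b$truth$class_table$class == cl]
    mean(ids %in% planted$gene_id)
  }, numeric(1))
  sel <- mf$class %in% c("constitutive", "brain")
  expect_true(all(abs(mf$percent[sel] - planted_pct[sel]) <= 5))
  expect_equal(mf$percent[mf$class == "constitutive"], 100)
})

test_that("motif-centered accessibility profiles behave", {
  hits <- tibble::tibble(contig = "c1", center = 3000L, strand = "+")
  fr <- uniform_frags(6000)
  prof <- motif_accessibility_profile(hits, fr, half_width = 500)
  expect_lt(max(prof$mean_rpkm) / min(prof$mean_rpkm), 1.05)
  expect_warning(
    empty <- motif_accessibility_profile(hits[0, ], fr),
    "no motif hits")
  expect_equal(nrow(empty), 0)
  # a single hit reproduces that locus's own coverage
  fr2 <- frag_tbl(c(2800, 3100), c(2900, 3200))
  p1 <- motif_accessibility_profile(hits, fr2, half_width = 500)
  direct <- tss_signal_matrix(
    fr2, tibble::tibble(gene_id = "g", contig = "c1", tss = 3000L,
                        strand = "+"), half_width = 500)
  expect_equal(p1$mean_rpkm, direct$rpkm)
})
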