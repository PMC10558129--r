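test_that("window RPKM follows count * 1e9 / (bp * library)", {
  win <- tibble::tibble(gene_id = "g", contig = "c1", start = 1000L,
                        end = 3000L, strand = "+")
  fr <- frag_tbl(1500, 1600)
  out <- window_rpkm(fr, win, library_size = c(s1 = 1e6))
  expect_equal(out$rpkm, 0.5)
  out0 <- window_rpkm(frag_tbl(integer(0), integer(0)), win,
                      library_size = c(s1 = 1e6))
  expect_equal(out0$rpkm, 0)
  expect_error(window_rpkm(fr, win, library_size = c(s1 = 0)), "positive")
})

test_that("overlap counting matches the brute-force oracle", {
  set.seed(2)
  fr <- frag_tbl(start = sample(0:5000, 100),
                 end = 0)  # placeholder
  fr$end <- fr$start + sample(20:300, 100, replace = TRUE)
  fr$length <- fr$end - fr$start
  wins <- tibble::tibble(gene_id = paste0("w", 1:15), contig = "c1",
                         start = sample(0:4800, 15),
                         end = 0L)
  wins$end <- wins$start + sample(100:800, 15, replace = TRUE)
  out <- window_rpkm(fr, wins, library_size = c(s1 = 1e6))
  for (i in seq_len(nrow(wins))) {
    expect_equal(out$count[out$gene_id == wins$gene_id[i]],
                 oracle_overlap_count(fr$start, fr$end,
                                      wins$start[i], wins$end[i]))
  }
  # additivity over disjoint fragment subsets
  half <- fr[1:50, ]; rest <- fr[51:100, ]
  c1 <- window_rpkm(half, wins, library_size = c(s1 = 1e6))$count
  c2 <- window_rpkm(rest, wins, library_size = c(s1 = 1e6))$count
  expect_equal(c1 + c2, out$count)
})

test_that("TSS metaprofiles are flat under uniform coverage", {
  genes <- tibble::tibble(gene_id = "g1", contig = "c1", tss = 3000L,
                          strand = "+", class = "x")
  fr <- uniform_frags(6000)
  prof <- tss_metaprofile(fr, genes)
  expect_lt(max(prof$mean_rpkm) / min(prof$mean_rpkm), 1.05)
})

test_that("minus-strand genes are flipped so upstream is negative", {
  genes <- tibble::tibble(gene_id = "g1", contig = "c1", tss = 3000L,
                          strand = "-", class = "x")
  # a fragment 150 bp 5' of a minus-strand TSS lies at larger coordinates
  fr <- frag_tbl(3000 + 150 - 5, 3000 + 150 + 5)
  prof <- tss_metaprofile(fr, genes)
  hot <- prof$position[prof$mean_rpkm > 0]
  expect_true(all(hot <= -130 & hot >= -170))
  # gene-order invariance of the metaprofile
  genes2 <- tibble::tibble(gene_id = c("a", "b"), contig = "c1",
                           tss = c(3000L, 9000L), strand = c("+", "-"),
                           class = "x")
  fr2 <- dplyr::bind_rows(frag_tbl(2800, 2900), frag_tbl(9100, 9200))
  p1 <- tss_metaprofile(fr2, genes2)
  p2 <- tss_metaprofile(fr2, genes2[2:1, ])
  expect_equal(p1, p2)
})

test_that("planted architectures separate by per-gene argmax", {
  plan <- simulation_plan(seed = 41, n_genes_per_class = c(
    brain = 25, constitutive = 25, unclassified = 5))
  b <- simulate_genome(plan)
  fr <- simulate_fragments(plan, b, "ATAC")
  tis <- tss_argmax(fr[fr$isolation == "brain", ],
                    b$genes[b$genes$class == "brain", ])
  stem <- tss_argmax(fr[fr$isolation == "neoblast", ],
                     b$genes[b$genes$class == "constitutive", ])
  expect_gte(mean(tis$argmax_position >= -300 &
                    tis$argmax_position <= -100), 0.95)
  expect_gte(mean(abs(stem$argmax_position) <= 50), 0.95)
})

test_that("ATAC/H3K4me3 log-ratio follows its formula", {
  a <- tibble::tibble(gene_id = c("g1", "g2"), rpkm = c(4, 7))
  k <- tibble::tibble(gene_id = c("g1", "g2"), rpkm = c(16, 7))
  r <- atac_h3k4_ratio(a, k, pseudocount = 1)
  expect_equal(r$log2_ratio, c(log2(5 / 17), 0))
  expect_error(atac_h3k4_ratio(dplyr::mutate(a, rpkm = -1), k),
               "non-negative")
})

test_that("consensus peaks require all replicates above the score cutoff", {
  pk <- function(rep, p, start = 100L, end = 200L) {
    tibble::tibble(contig = "c1", start = start, end = end,
                   summit = 50L, neg_log10_p = p, replicate = rep)
  }
  three <- dplyr::bind_rows(pk(1, 5), pk(2, 6), pk(3, 7))
  out <- consensus_peaks(three)
  expect_equal(nrow(out), 1)
  expect_equal(c(out$start, out$end), c(100L, 200L))
  # present in only 2 of 3 replicates
  expect_equal(nrow(consensus_peaks(dplyr::bind_rows(pk(1, 5), pk(2, 6)))),
               0)
  # one member at exactly the cutoff fails the strict inequality
  expect_equal(nrow(consensus_peaks(dplyr::bind_rows(pk(1, 5), pk(2, 4),
                                                     pk(3, 7)))), 0)
  # consensus of identical replicate sets returns the original intervals
  a <- dplyr::bind_rows(pk(1, 9, 100L, 200L), pk(1, 8, 500L, 640L))
  all3 <- dplyr::bind_rows(a, dplyr::mutate(a, replicate = 2),
                           dplyr::mutate(a, replicate = 3))
  out3 <- consensus_peaks(all3)
  expect_equal(out3[, c("start", "end")], a[, c("start", "end")])
  # an empty replicate kills every consensus
  expect_equal(nrow(consensus_peaks(a)), 0)
})

test_that("feature assignment follows the stated priority", {
  genes <- tibble::tibble(gene_id = "g1", contig = "c1", start = 5001L,
                          end = 7000L, strand = "+", tss = 5001L)
  exons <- tibble::tibble(gene_id = "g1", contig = "c1",
                          start = c(5001L, 6701L), end = c(5300L, 7000L))
  repeats <- tibble::tibble(contig = "c1", start = 5100L, end = 5400L,
                            family = "LTR")
  mk_peak <- function(pos) {
    tibble::tibble(contig = "c1", start = pos - 50L, end = pos + 50L,
                   summit = 50L)
  }
  # summit 500 bp upstream of the plus-strand TSS -> promoter
  expect_equal(assign_feature(mk_peak(4501L), genes, exons,
                              repeats)$feature, "promoter")
  # summit inside an exon that also lies in a repeat -> exon wins
  expect_equal(assign_feature(mk_peak(5150L), genes, exons,
                              repeats)$feature, "exon")
  expect_equal(assign_feature(mk_peak(6000L), genes, exons,
                              repeats)$feature, "intron")
  expect_error(assign_feature(mk_peak(99999L), genes, exons, repeats,
                              contig_lengths = c(c1 = 10000)), "bounds")
})

test_that("feature assignment matches a hand-enumerated oracle", {
  set.seed(5)
  genes <- tibble::tibble(gene_id = c("g1", "g2"), contig = "c1",
                          start = c(3001L, 9001L), end = c(5000L, 11000L),
                          strand = c("+", "-"),
                          tss = c(3001L, 11000L))
  exons <- tibble::tibble(gene_id = c("g1", "g1", "g2"), contig = "c1",
                          start = c(3001L, 4501L, 9001L),
                          end = c(3400L, 5000L, 9500L))
  repeats <- tibble::tibble(contig = "c1", start = c(6000L, 4400L),
                            end = c(6500L, 4600L), family = "TE")
  summits <- sample(1:14000, 20)
  peaks <- tibble::tibble(contig = "c1", start = summits - 1L,
                          end = summits + 1L, summit = 1L)
  got <- assign_feature(peaks, genes, exons, repeats,
                        promoter_bp = 2000)$feature
  oracle <- vapply(summits, function(p) {
    in_prom <- (p >= 1001 && p <= 3000) || (p >= 11001 && p <= 13000)
    in_exon <- any(p >= exons$start & p <= exons$end)
    in_gene <- any(p >= genes$start & p <= genes$end)
    in_te <- any(p >= repeats$start & p <= repeats$end)
    if (in_prom) "promoter" else if (in_exon) "exon" else
      if (in_gene) "intron" else if (in_te) "TE" else "intergenic"
  }, character(1))
  expect_equal(got, oracle)
})

test_that("max signal region applies threshold and tie rules", {
  genes <- tibble::tibble(gene_id = "g1", contig = "c1", tss = 3001L,
                          strand = "+")
  cov <- tibble::tibble(contig = "c1",
                        start = seq(0L, 2950L, by = 50L),
                        end = seq(50L, 3000L, by = 50L),
                        rpkm = 0)
  hot <- cov
  hot$rpkm[hot$start == 2700L] <- 12  # bin center 2725, ~ -275 from TSS
  out <- max_signal_region(hot, genes)
  expect_equal(out$rpkm, 12)
  expect_lt(abs(out$position - (-275)), 26)
  weak <- cov
  weak$rpkm[weak$start == 2700L] <- 8
  expect_equal(nrow(max_signal_region(weak, genes)), 0)
  tie <- cov
  tie$rpkm[tie$start %in% c(2600L, 2850L)] <- 12
  out_tie <- max_signal_region(tie, genes)
  expect_lt(abs(out_tie$position - (-125)), 26)  # closest to the TSS wins
})

test_that("nucleosome occupancy proxy filters, smooths, and normalizes", {
  genes <- tibble::tibble(gene_id = "g1", contig = "c1", tss = 3001L,
                          strand = "+", class = "x")
  short <- frag_tbl(seq(2000, 4000, by = 20), seq(2000, 4000, by = 20) + 80)
  expect_warning(occ0 <- nucleosome_occupancy(short, genes),
                 "no nucleosomal")
  expect_true(all(occ0$occupancy == 0))
  # uniform nucleosomal fragments give a flat normalized profile ~ 1
  unif <- frag_tbl(seq(1500, 4500, by = 3), seq(1500, 4500, by = 3) + 200)
  occ1 <- nucleosome_occupancy(unif, genes)
  mid <- occ1$occupancy[abs(occ1$position) <= 600]
  expect_true(all(abs(mid - 1) < 0.1))
  # planted phasing: midpoints exactly at -180 and +120
  mids <- rep(c(3000 - 180, 3000 + 120), each = 300) +
    round(rnorm(600, 0, 15))
  phased <- frag_tbl(mids - 100, mids + 100)
  flank <- frag_tbl(seq(1500, 4500, by = 12), seq(1500, 4500, by = 12) +
                      200)
  occ2 <- nucleosome_occupancy(dplyr::bind_rows(phased, flank), genes)
  modes <- profile_modes(occ2[abs(occ2$position) < 400, ], n = 2)
  expect_lt(abs(sort(modes$position)[1] - (-180)), 30)
  expect_lt(abs(sort(modes$position)[2] - 120), 30)
})
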