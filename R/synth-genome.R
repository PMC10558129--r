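#' Assign gene classes for a simulation
#'
#' Draws the planted class label of every simulated gene.  The assignment is
#' deterministic in the plan seed and shared by all generators, so counts can
#' be simulated without building a genome and vice versa.
#'
#' @param plan A [simulation_plan()].
#' @return A tibble with columns `gene_id` and `class`.
#' @export
simulate_class_table <- function(plan) {
  stopifnot(inherits(plan, "simulation_plan"))
  classes <- rep(names(plan$n_genes_per_class), plan$n_genes_per_class)
  n <- length(classes)
  if (n == 0) {
    return(tibble::tibble(gene_id = character(), class = character()))
  }
  withr::with_seed((plan$seed + 97L) %% .Machine$integer.max, {
    classes <- sample(classes)
  })
  tibble::tibble(
    gene_id = sprintf("g%05d", seq_len(n)),
    class = classes
  )
}

# AT trinucleotide units with both letters represented (tandem-repeat pool
# for tissue-specific promoters).
.at_trinucleotide_units <- function() {
  c("AAT", "ATA", "TAA", "ATT", "TAT", "TTA")
}

# Per-promoter fragment template intensities; see fragment_templates().
.sample_background <- function(n, at_fraction) {
  p_at <- at_fraction / 2
  p_cg <- (1 - at_fraction) / 2
  sample(c("A", "T", "C", "G"), n, replace = TRUE,
         prob = c(p_at, p_at, p_cg, p_cg))
}

# Sample one motif instance from a PWM (per-column draw).  When
# `min_score` is given, draws are rejected until the instance's log-odds
# score reaches it (planted instances emulate functional, high-affinity
# sites); after `tries` rejections the consensus is planted.
.sample_pwm_instance <- function(pwm, min_score = NULL, tries = 200) {
  S <- .pwm_logodds(pwm)
  idx <- seq_len(nrow(pwm$mat))
  for (t in seq_len(tries)) {
    draw <- apply(pwm$mat, 2, function(col) sample(idx, 1, prob = col))
    if (is.null(min_score)) break
    if (sum(S[cbind(draw, seq_along(draw))]) >= min_score) break
    if (t == tries) draw <- apply(S, 2, which.max)
  }
  rownames(pwm$mat)[draw]
}

.revcomp_chars <- function(x) {
  rev(unname(c(A = "T", C = "G", G = "C", T = "A", N = "N")[x]))
}

#' Simulate a genome with planted promoter architectures
#'
#' Builds a background genome (i.i.d. bases with the plan's AT fraction) and
#' plants class-specific promoter sequence features:
#'
#' * tissue-specific genes (brain/epidermis/intestine) receive one sampled
#'   transcription-factor PWM instance in \[-300, -100\] relative to the TSS
#'   and two AT trinucleotide tandem-repeat arrays further upstream;
#' * constitutive and neoblast genes have their \[-200, -1\] window rewritten
#'   to the plan's AT fraction with a T bias, at least two poly(dT) runs
#'   (length >= 6), and an Initiator (Inr) PWM instance spanning the TSS;
#' * 10% of tissue-specific promoters also carry an Inr instance;
#' * unclassified genes are plain background.
#'
#' Genes are laid out on two contigs in fixed-size slots wide enough that
#' promoter windows and profile windows never overlap a neighboring gene, on
#' randomly drawn strands (minus-strand features are reverse-complemented
#' into the genome).  Each gene has two exons separated by one intron when
#' the gene body is at least 1 kb.  Repeat (TE) intervals with family labels
#' are scattered in the intergenic buffer.
#'
#' @param plan A [simulation_plan()].
#' @param class_table Optional precomputed [simulate_class_table()] output.
#' @return A `genome_bundle`: list with `genome` (a
#'   [Biostrings::DNAStringSet]), `genes`, `exons`, `repeats` tibbles
#'   (1-based inclusive coordinates; `tss` is the first transcribed base),
#'   and `truth` (class table plus planted motif records).
#' @export
simulate_genome <- function(plan, class_table = NULL) {
  stopifnot(inherits(plan, "simulation_plan"))
  if (is.null(class_table)) class_table <- simulate_class_table(plan)
  n_genes <- nrow(class_table)
  w <- plan$tss_window_bp
  glen <- plan$gene_length_bp
  slot <- 2L * w + glen + 1000L

  inr_pwm <- stemchrom_pwm("inr")
  tf_pwm <- stemchrom_pwm("planted_tf")
  # planted instances must score at least as high as a stringent scan
  # threshold, emulating functional high-affinity sites
  inr_min <- pwm_score_threshold(inr_pwm, 1e-4)
  tf_min <- pwm_score_threshold(tf_pwm, 1e-4)

  .with_stage_seed(plan, "genome", {
    if (n_genes == 0) {
      seqs <- paste0(.sample_background(10000L, plan$genome_at_fraction),
                     collapse = "")
      genome <- Biostrings::DNAStringSet(stats::setNames(seqs, "contig_1"))
      return(structure(list(
        genome = genome,
        genes = tibble::tibble(gene_id = character(), contig = character(),
                               start = integer(), end = integer(),
                               strand = character(), tss = integer(),
                               class = character()),
        exons = tibble::tibble(gene_id = character(), contig = character(),
                               start = integer(), end = integer()),
        repeats = tibble::tibble(contig = character(), start = integer(),
                                 end = integer(), family = character()),
        truth = list(class_table = class_table,
                     motifs = tibble::tibble())
      ), class = "genome_bundle"))
    }

    contig_of <- rep(c("contig_1", "contig_2"), length.out = n_genes)
    contig_of <- sort(contig_of)
    slot_index <- stats::ave(seq_len(n_genes), contig_of,
                             FUN = seq_along) - 1L
    strands <- sample(c("+", "-"), n_genes, replace = TRUE)

    contig_len <- vapply(split(slot_index, contig_of), function(ix) {
      (max(ix) + 1L) * slot + slot %/% 2L
    }, integer(1))
    chars <- lapply(contig_len, .sample_background,
                    at_fraction = plan$genome_at_fraction)

    offset <- slot_index * slot
    start <- offset + w + 1L
    end <- start + glen - 1L
    tss <- ifelse(strands == "+", start, end)

    genes <- tibble::tibble(
      gene_id = class_table$gene_id,
      contig = contig_of,
      start = as.integer(start),
      end = as.integer(end),
      strand = strands,
      tss = as.integer(tss),
      class = class_table$class
    )

    # write `seq_chars` (coding-strand letters) at relative positions
    # rel .. rel+len-1 (rel 0 = TSS base, negative = upstream)
    write_rel <- function(ct, tss_i, strand, rel, seq_chars) {
      len <- length(seq_chars)
      if (strand == "+") {
        pos <- tss_i + rel + seq_len(len) - 1L
        chars[[ct]][pos] <<- seq_chars
      } else {
        pos <- tss_i - rel - len + seq_len(len)
        chars[[ct]][pos] <<- .revcomp_chars(seq_chars)
      }
    }

    motif_rows <- list()
    record <- function(gene_id, kind, rel, seq) {
      motif_rows[[length(motif_rows) + 1L]] <<-
        tibble::tibble(gene_id = gene_id, kind = kind,
                       rel_start = as.integer(rel), seq = seq)
    }

    tissue_classes <- c("brain", "epidermis", "intestine")
    at_frac <- plan$promoter_at_fraction_constitutive
    t_bias <- plan$promoter_t_bias

    for (i in seq_len(n_genes)) {
      cl <- genes$class[i]
      ct <- genes$contig[i]
      s <- genes$strand[i]
      t0 <- genes$tss[i]
      if (cl %in% tissue_classes) {
        inst <- .sample_pwm_instance(tf_pwm, tf_min)
        rel <- sample(seq(-300L, -100L - length(inst) + 1L), 1)
        write_rel(ct, t0, s, rel, inst)
        record(genes$gene_id[i], "tf", rel, paste(inst, collapse = ""))
        arr_rel <- c(-500L, -430L) + sample(0:10, 2, replace = TRUE)
        for (r in arr_rel) {
          unit <- sample(.at_trinucleotide_units(), 1)
          n_units <- sample(4:8, 1)
          arr <- strsplit(strrep(unit, n_units), "")[[1]]
          write_rel(ct, t0, s, r, arr)
          record(genes$gene_id[i], "repeat", r, paste(arr, collapse = ""))
        }
        if (stats::runif(1) < 0.10) {
          inst <- .sample_pwm_instance(inr_pwm, inr_min)
          write_rel(ct, t0, s, -2L, inst)
          record(genes$gene_id[i], "inr", -2L, paste(inst, collapse = ""))
        }
      } else if (cl %in% c("constitutive", "neoblast")) {
        region_len <- 200L
        n_runs <- sample(2:3, 1)
        run_lens <- sample(6:12, n_runs, replace = TRUE)
        # non-overlapping run placements inside the region
        gaps <- region_len - sum(run_lens)
        cuts <- sort(sample.int(gaps, n_runs))
        run_starts <- cuts + c(0L, cumsum(run_lens))[seq_len(n_runs)]
        is_run <- rep(FALSE, region_len)
        is_sep <- rep(FALSE, region_len)
        for (j in seq_len(n_runs)) {
          is_run[run_starts[j] + seq_len(run_lens[j]) - 1L] <- TRUE
          # flank each planted run with an A so runs stay distinct maximal
          # runs regardless of the random fill
          for (p in c(run_starts[j] - 1L, run_starts[j] + run_lens[j])) {
            if (p >= 1L && p <= region_len) is_sep[p] <- TRUE
          }
        }
        is_sep <- is_sep & !is_run
        n_free <- sum(!is_run & !is_sep)
        n_at_total <- ceiling(region_len * at_frac)
        n_at_free <- max(0L, min(n_free,
                                 n_at_total - sum(run_lens) - sum(is_sep)))
        free_letters <- c(
          ifelse(stats::runif(n_at_free) < t_bias, "T", "A"),
          sample(c("C", "G"), n_free - n_at_free, replace = TRUE)
        )
        free_letters <- sample(free_letters)
        region <- character(region_len)
        region[is_run] <- "T"
        region[is_sep] <- "A"
        region[!is_run & !is_sep] <- free_letters
        write_rel(ct, t0, s, -region_len, region)
        for (j in seq_len(n_runs)) {
          record(genes$gene_id[i], "polyT",
                 run_starts[j] - 1L - region_len,
                 strrep("T", run_lens[j]))
        }
        inst <- .sample_pwm_instance(inr_pwm, inr_min)
        write_rel(ct, t0, s, -2L, inst)
        record(genes$gene_id[i], "inr", -2L, paste(inst, collapse = ""))
      }
    }

    # exons: two exons of 300 bp flanking a 400 bp intron when the gene
    # body allows, otherwise a single exon spanning the gene
    exons <- purrr::map_dfr(seq_len(n_genes), function(i) {
      g <- genes[i, ]
      if (glen >= 1000L) {
        if (g$strand == "+") {
          tibble::tibble(gene_id = g$gene_id, contig = g$contig,
                         start = c(g$start, g$end - 299L),
                         end = c(g$start + 299L, g$end))
        } else {
          tibble::tibble(gene_id = g$gene_id, contig = g$contig,
                         start = c(g$end - 299L, g$start),
                         end = c(g$end, g$start + 299L))
        }
      } else {
        tibble::tibble(gene_id = g$gene_id, contig = g$contig,
                       start = g$start, end = g$end)
      }
    })

    # TE intervals in the intergenic buffer at the tail of each slot
    families <- c("LTR/Gypsy", "LINE/CR1", "DNA/TcMar")
    rep_rows <- purrr::map_dfr(seq_len(n_genes), function(i) {
      if (stats::runif(1) > 0.5) return(NULL)
      buf_start <- offset[i] + 2L * w + glen + 1L
      len <- sample(150:700, 1)
      st <- buf_start + sample.int(1000L - len, 1)
      tibble::tibble(contig = contig_of[i], start = as.integer(st),
                     end = as.integer(st + len - 1L),
                     family = sample(families, 1))
    })

    genome <- Biostrings::DNAStringSet(vapply(chars, paste0,
                                              character(1), collapse = ""))
    names(genome) <- names(chars)
    motifs <- if (length(motif_rows)) dplyr::bind_rows(motif_rows) else
      tibble::tibble()

    structure(list(
      genome = genome,
      genes = genes,
      exons = exons,
      repeats = rep_rows,
      truth = list(class_table = class_table, motifs = motifs)
    ), class = "genome_bundle")
  })
}

#' @export
print.genome_bundle <- function(x, ...) {
  cat("<genome_bundle>\n")
  cat("  contigs:", length(x$genome), "(",
      sum(Biostrings::width(x$genome)), "bp )\n")
  cat("  genes:", nrow(x$genes), "| repeats:", nrow(x$repeats), "\n")
  if (nrow(x$genes)) {
    print(table(x$genes$class))
  }
  invisible(x)
}

#' Write a genome bundle to standard files
#'
#' Writes the genome FASTA, a GFF3 gene annotation (1-based inclusive), a
#' BED6 repeat annotation (0-based half-open), the planted class table, and
#' the planted motif records.
#'
#' @param bundle A `genome_bundle` from [simulate_genome()].
#' @param dir Output directory (created if missing).
#' @return The directory path, invisibly.
#' @export
write_genome_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "genome_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Biostrings::writeXStringSet(bundle$genome, file.path(dir, "genome.fa"))
  g <- bundle$genes
  gff <- c("##gff-version 3")
  if (nrow(g)) {
    gene_lines <- sprintf("%s\tstemchrom\tgene\t%d\t%d\t.\t%s\t.\tID=%s;class=%s",
                          g$contig, g$start, g$end, g$strand, g$gene_id,
                          g$class)
    e <- dplyr::left_join(bundle$exons,
                          g[, c("gene_id", "strand")], by = "gene_id")
    exon_lines <- sprintf("%s\tstemchrom\texon\t%d\t%d\t.\t%s\t.\tParent=%s",
                          e$contig, e$start, e$end, e$strand, e$gene_id)
    gff <- c(gff, gene_lines, exon_lines)
  }
  writeLines(gff, file.path(dir, "genes.gff3"))
  r <- bundle$repeats
  if (nrow(r)) {
    readr::write_tsv(
      tibble::tibble(contig = r$contig, start = r$start - 1L, end = r$end,
                     name = r$family, score = 0L, strand = "."),
      file.path(dir, "repeats.bed"), col_names = FALSE)
  } else {
    file.create(file.path(dir, "repeats.bed"))
  }
  readr::write_tsv(bundle$truth$class_table, file.path(dir, "classes.tsv"))
  if (nrow(bundle$truth$motifs)) {
    readr::write_tsv(bundle$truth$motifs, file.path(dir, "motifs.tsv"))
  }
  invisible(dir)
}
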