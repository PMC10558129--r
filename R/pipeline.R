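#' Plant a default field of cell colonies
#'
#' Lays out colony centers on a widely spaced grid (inter-center gaps far
#' above the clustering cutoff) and places each colony's cells on a
#' jittered in-plane grid with `cell_spacing_um` spacing, so that (a)
#' within a colony every cell chains to its neighbors at well under the
#' 50-um cutoff, (b) cells never sit so close that their segmented objects
#' merge, and (c) different colonies never come near the cutoff.
#'
#' @param plan A [simulation_plan()].
#' @param colony_cells Integer vector: cells per planted colony (each
#'   colony at most 16 cells).
#' @param dims Stack dimensions (voxels) the field must fit into.
#' @param cell_spacing_um In-plane grid spacing between cells of a colony.
#' @param jitter_um Uniform positional jitter applied per cell.
#' @return Tibble `cell`, `x`, `y`, `z` (um), `colony`.
#' @export
simulate_colony_field <- function(plan, colony_cells = c(3, 5, 9),
                                  dims = c(z = 8, y = 96, x = 96),
                                  cell_spacing_um = 26, jitter_um = 2) {
  stopifnot(all(colony_cells >= 1), all(colony_cells <= 16),
            cell_spacing_um < 50 - 2 * jitter_um)
  vox <- plan$image_voxel_um
  field <- c(x = (dims[["x"]] - 1) * vox[["x"]],
             y = (dims[["y"]] - 1) * vox[["y"]],
             z = (dims[["z"]] - 1) * vox[["z"]])
  k <- length(colony_cells)
  half_extent <- 1.5 * cell_spacing_um + jitter_um  # up to 4x4 cell grid
  margin <- half_extent + 8
  gx <- ceiling(sqrt(k))
  gy <- ceiling(k / gx)
  cx <- seq(margin, field[["x"]] - margin, length.out = max(gx, 2))[1:gx]
  cy <- seq(margin, field[["y"]] - margin, length.out = max(gy, 2))[1:gy]
  centers <- expand.grid(x = cx, y = cy)[seq_len(k), ]
  min_gap <- suppressWarnings(min(stats::dist(centers)))
  if (is.finite(min_gap) && min_gap - 2 * half_extent <= 50) {
    stop("field too small to separate ", k, " colonies unambiguously")
  }
  withr::with_seed((plan$seed + 602L) %% .Machine$integer.max, {
    purrr::map_dfr(seq_len(k), function(j) {
      n <- colony_cells[j]
      side <- ceiling(sqrt(n))
      gpos <- expand.grid(
        gx = seq_len(side) - (side + 1) / 2,
        gy = seq_len(side) - (side + 1) / 2)[seq_len(n), ]
      tibble::tibble(
        x = centers$x[j] + gpos$gx * cell_spacing_um +
          stats::runif(n, -jitter_um, jitter_um),
        y = centers$y[j] + gpos$gy * cell_spacing_um +
          stats::runif(n, -jitter_um, jitter_um),
        z = field[["z"]] / 2 + stats::runif(n, -7, 7),
        colony = j)
    }) |>
      dplyr::mutate(cell = dplyr::row_number(), .before = 1)
  })
}

#' Default pipeline configuration
#'
#' The parameter defaults are the analysis constants used throughout the
#' package: 2-kb promoter windows, TSS +/- 1 kb profiles, TSS +/- 40 nt
#' motif windows, expression bins at 10 and 30 TPM, |log2FC| > 1 with
#' adjusted p < 0.05, replicate-consensus peaks at -log10 p > 4, 50-kb Hi-C
#' bins, and a 50-um colony cutoff.
#'
#' @return A nested named list (see [run_pipeline()]).
#' @export
default_run_config <- function() {
  list(
    seed = 1L,
    stages = c("simulate", "classify", "chromatin", "seqfeat",
               "compartments", "colonies", "report"),
    engine = "deseq2",
    plan = list(),
    params = list(
      promoter_bp = 2000,
      profile_half_width = 1000,
      profile_bin_width = 10,
      motif_half_window = 40,
      expressed_tpm = 10,
      high_tpm = 30,
      lfc_threshold = 1,
      alpha = 0.05,
      min_neg_log10_p = 4,
      hic_min_coverage_frac = 0.05,
      colony_cutoff_um = 50,
      colony_n = 3,
      colony_f = 1.5,
      colony_cells = c(3, 5, 9)
    )
  )
}

.merge_config <- function(user, defaults, path = "") {
  if (is.null(user)) return(defaults)
  unknown <- setdiff(names(user), names(defaults))
  if (path == "" && "plan" %in% names(user)) {
    plan_ok <- names(formals(simulation_plan))
    bad <- setdiff(names(user$plan), plan_ok)
    if (length(bad)) {
      stop("unknown plan key(s): ", paste(bad, collapse = ", "))
    }
  }
  if (length(unknown)) {
    stop("unknown config key(s)", if (nzchar(path)) paste0(" in ", path),
         ": ", paste(unknown, collapse = ", "))
  }
  for (k in names(user)) {
    if (k == "plan") {
      defaults$plan <- user$plan
    } else if (is.list(defaults[[k]]) && is.list(user[[k]])) {
      defaults[[k]] <- .merge_config(user[[k]], defaults[[k]],
                                     paste0(path, k, "/"))
    } else {
      defaults[[k]] <- user[[k]]
    }
  }
  defaults
}

.fmt <- function(x) {
  if (is.numeric(x)) sprintf("%.6g", x) else as.character(x)
}

.md_table <- function(df) {
  cells <- vapply(df, function(col) vapply(col, .fmt, character(1)),
                  character(nrow(df)))
  if (nrow(df) == 1) cells <- matrix(cells, nrow = 1)
  header <- paste("|", paste(names(df), collapse = " | "), "|")
  sep <- paste("|", paste(rep("---", ncol(df)), collapse = " | "), "|")
  body <- apply(cells, 1, function(r) paste("|", paste(r, collapse = " | "),
                                            "|"))
  c(header, sep, body)
}

#' Run the synthetic analysis pipeline
#'
#' Orchestrates the package's stages over a configuration: `simulate`
#' (genome, counts, fragments, Hi-C contacts, colony stack), `classify`
#' (TPM, pairwise contrasts, class rules), `chromatin` (TSS metaprofiles,
#' per-gene signal argmax, ATAC/H3K4me3 ratios, nucleosome occupancy),
#' `seqfeat` (composition, T-stretches, nonamer enrichment, motif
#' frequencies), `compartments` (white-strip-corrected A/B calling),
#' `colonies` (detection, clustering, counts), and `report` (a
#' deterministic markdown summary juxtaposing the stage outputs).  All
#' randomness derives from the single config seed; running twice with the
#' same config yields byte-identical artifacts.
#'
#' @param config Path to a YAML config file, or a (possibly partial)
#'   config list; see [default_run_config()].  Unknown keys are rejected
#'   before any stage runs.
#' @param outdir Output directory for artifacts, resolved config, report,
#'   and log.
#' @param seed Optional seed overriding the config seed.
#' @return Invisibly, a list of in-memory stage results (including
#'   `report_path`).
#' @export
run_pipeline <- function(config = NULL, outdir, seed = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- .merge_config(config, default_run_config())
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(cfg, file.path(outdir, "resolved_config.yaml"))
  logf <- file.path(outdir, "run.log")
  log <- function(...) {
    cat(format(Sys.time(), "%Y-%m-%d %H:%M:%S"), "|", ..., "\n",
        file = logf, append = TRUE)
  }
  p <- cfg$params
  plan <- do.call(simulation_plan, c(list(seed = cfg$seed), cfg$plan))
  st <- new.env(parent = emptyenv())
  need <- function(name, artifact) {
    if (!exists(name, envir = st)) {
      stop("missing artifact '", artifact,
           "': run the 'simulate' stage first")
    }
    get(name, envir = st)
  }
  report <- list()
  add_report <- function(title, lines) {
    report[[length(report) + 1L]] <<- c(paste("##", title), "", lines, "")
  }

  for (stage in cfg$stages) {
    log("stage:", stage)
    switch(stage,
      simulate = {
        st$bundle <- simulate_genome(plan)
        st$counts <- simulate_counts(plan, st$bundle$truth$class_table)
        st$atac <- simulate_fragments(plan, st$bundle, "ATAC")
        st$k4 <- simulate_fragments(plan, st$bundle, "H3K4me3")
        st$contacts <- simulate_contacts(plan)
        st$field <- simulate_colony_field(plan, p$colony_cells)
        st$stack <- simulate_colony_stack(
          plan, st$field[, c("x", "y", "z")],
          colony_cutoff_um = p$colony_cutoff_um)
        write_genome_bundle(st$bundle, file.path(outdir, "genome"))
        write_counts(st$counts, file.path(outdir, "expression"))
        write_fragments(st$atac, file.path(outdir, "atac_fragments.bed"))
        write_fragments(st$k4, file.path(outdir, "h3k4me3_fragments.bed"))
        write_contacts(st$contacts, file.path(outdir, "hic"))
        write_image_stack(st$stack, file.path(outdir, "colony_stack.tif"))
      },
      classify = {
        counts <- if (exists("counts", envir = st)) st$counts else {
          cdir <- file.path(outdir, "expression")
          if (!file.exists(file.path(cdir, "counts.tsv"))) {
            stop("missing artifact 'expression/counts.tsv': run the ",
                 "'simulate' stage first or provide it")
          }
          read_counts(cdir)
        }
        st$counts <- counts
        st$fit <- classify_expression(
          counts, engine = cfg$engine,
          lfc_threshold = p$lfc_threshold, alpha = p$alpha,
          expressed_tpm = p$expressed_tpm)
        readr::write_tsv(st$fit$classes,
                         file.path(outdir, "gene_classes.tsv"))
        readr::write_tsv(st$fit$contrasts,
                         file.path(outdir, "contrasts.tsv"))
        sum_tbl <- glance(st$fit)
        if (!is.null(counts$truth)) {
          truth <- counts$truth
          called <- st$fit$classes
          m <- dplyr::inner_join(truth, called, by = "gene_id",
                                 suffix = c("_true", "_called"))
          sum_tbl$label_recovery <-
            mean(m$class_true == m$class_called)
        }
        add_report("Gene classification", .md_table(sum_tbl))
      },
      chromatin = {
        bundle <- need("bundle", "genome")
        atac <- need("atac", "atac_fragments.bed")
        k4 <- need("k4", "h3k4me3_fragments.bed")
        genes <- bundle$genes
        prof <- tss_metaprofile(atac, genes,
                                half_width = p$profile_half_width,
                                bin_width = p$profile_bin_width)
        readr::write_tsv(prof, file.path(outdir, "tss_metaprofile.tsv"))
        # per-gene argmax in the gene's matching isolation
        argmax <- purrr::map_dfr(
          intersect(unique(genes$class),
                    c("brain", "epidermis", "intestine", "neoblast",
                      "constitutive")),
          function(cl) {
            gsel <- genes[genes$class == cl, ]
            iso <- if (cl == "constitutive") "neoblast" else cl
            am <- tss_argmax(atac[atac$isolation == iso, ], gsel,
                             half_width = p$profile_half_width,
                             bin_width = p$profile_bin_width)
            am$class <- cl
            am
          })
        st$argmax <- argmax
        arch <- argmax |>
          dplyr::mutate(arch = ifelse(.data$class %in%
                                        c("constitutive", "neoblast"),
                                      "stem-like", "tissue")) |>
          dplyr::group_by(.data$arch) |>
          dplyr::summarise(
            n = dplyr::n(),
            upstream_peak = mean(.data$argmax_position >= -300 &
                                   .data$argmax_position <= -100),
            tss_centered = mean(abs(.data$argmax_position) <= 50),
            .groups = "drop")
        add_report("Promoter architecture (per-gene ATAC argmax)",
                   .md_table(arch))
        # log2(ATAC / H3K4me3) over the 2-kb TSS-centered window
        win <- tss_windows(genes, upstream = p$promoter_bp / 2,
                           downstream = p$promoter_bp / 2)
        ratios <- purrr::map_dfr(
          unique(genes$class), function(cl) {
            gsel <- genes$class == cl
            iso <- if (cl %in% c("brain", "epidermis", "intestine",
                                 "neoblast")) cl else "neoblast"
            a <- window_rpkm(atac[atac$isolation == iso, ], win[gsel, ])
            k <- window_rpkm(k4[k4$isolation == iso, ], win[gsel, ])
            r <- atac_h3k4_ratio(a, k)
            r$class <- cl
            r
          })
        st$ratios <- ratios
        readr::write_tsv(ratios, file.path(outdir, "atac_h3k4_ratio.tsv"))
        rat <- ratios |>
          dplyr::group_by(.data$class) |>
          dplyr::summarise(median_log2_ratio =
                             stats::median(.data$log2_ratio),
                           .groups = "drop")
        add_report("log2(ATAC / H3K4me3), matching isolation",
                   .md_table(rat))
        occ <- nucleosome_occupancy(
          atac[atac$isolation == "neoblast", ], genes,
          half_width = p$profile_half_width)
        st$occupancy <- occ
        readr::write_tsv(occ, file.path(outdir,
                                        "nucleosome_occupancy.tsv"))
        if ("constitutive" %in% occ$class) {
          oc <- occ[occ$class == "constitutive" &
                      abs(occ$position) <= 400, ]
          up <- profile_modes(oc[oc$position < 0, ], n = 1)
          dn <- profile_modes(oc[oc$position > 0, ], n = 1)
          add_report("Constitutive nucleosome phasing (modes)",
                     .md_table(tibble::tibble(
                       minus_one_bp = up$position[1],
                       plus_one_bp = dn$position[1])))
        }
      },
      seqfeat = {
        bundle <- need("bundle", "genome")
        genes <- bundle$genes
        prom500 <- extract_promoters(bundle$genome, genes,
                                     upstream = 500, downstream = 500)
        comp <- composition_profile(prom500, by = "class")
        readr::write_tsv(comp, file.path(outdir, "composition.tsv"))
        at_near <- at_content(prom500, from = -200, to = -1, by = "class")
        add_report("AT fraction in [-200, 0) by class",
                   .md_table(at_near))
        promu <- extract_promoters(bundle$genome, genes, upstream = 500,
                                   downstream = 0)
        ts <- t_stretch_stats(promu, bundle$truth$class_table)
        readr::write_tsv(ts$counts, file.path(outdir, "t_stretches.tsv"))
        tmed <- ts$counts |>
          dplyr::group_by(.data$class) |>
          dplyr::summarise(mean_stretches = mean(.data$n_stretches),
                           .groups = "drop")
        add_report("Poly(dT) stretches (>=5 nt) per 500-bp promoter",
                   .md_table(tmed))
        tissue <- promu[genes$class %in% c("brain", "epidermis",
                                           "intestine"), ]
        constit <- promu[genes$class == "constitutive", ]
        if (nrow(tissue) && nrow(constit)) {
          km <- kmer_enrichment(tissue, constit, k = 9)
          readr::write_tsv(utils::head(km, 50),
                           file.path(outdir, "nonamer_enrichment.tsv"))
          add_report("Top nonamers, tissue vs constitutive promoters",
                     .md_table(utils::head(km, 5)))
        }
        hw <- p$motif_half_window
        prom40 <- extract_promoters(bundle$genome, genes, upstream = hw,
                                    downstream = hw + 1)
        freq <- purrr::map_dfr(c("inr", "tata"), function(mname) {
          hits <- scan_pwm(prom40, stemchrom_pwm(mname),
                           p_threshold = 1e-4)
          mf <- motif_class_frequency(hits, bundle$truth$class_table)
          mf$motif <- mname
          mf
        })
        readr::write_tsv(freq, file.path(outdir, "motif_frequency.tsv"))
        add_report("Motif frequency over TSS window (%)",
                   .md_table(freq[, c("motif", "class", "percent")]))
      },
      compartments = {
        contacts <- need("contacts", "hic")
        track <- call_compartments(contacts,
                                   min_coverage_frac =
                                     p$hic_min_coverage_frac)
        oriented <- orient_and_enrich(track, contacts$accessibility,
                                      features = contacts$features)
        st$compartments <- oriented
        readr::write_tsv(oriented$track,
                         file.path(outdir, "compartments.tsv"))
        if (!is.null(oriented$enrichment)) {
          readr::write_tsv(oriented$enrichment,
                           file.path(outdir,
                                     "compartment_enrichment.tsv"))
        }
        smry <- oriented$track |>
          dplyr::count(.data$label)
        if (!is.null(contacts$truth)) {
          m <- dplyr::inner_join(oriented$track, contacts$truth,
                                 by = "bin")
          kept <- !is.na(m$label)
          smry <- tibble::tibble(
            a_bins = sum(oriented$track$label == "A", na.rm = TRUE),
            b_bins = sum(oriented$track$label == "B", na.rm = TRUE),
            na_bins = sum(is.na(oriented$track$label)),
            label_accuracy = mean(m$label[kept] ==
                                    m$compartment[kept]))
        }
        add_report("A/B compartments", .md_table(smry))
      },
      colonies = {
        stack <- need("stack", "colony_stack.tif")
        objs <- detect_objects(stack, n = p$colony_n, f = p$colony_f,
                               mode = "3D")
        cent <- object_centroids(objs)
        cols <- cluster_colonies(cent, cutoff_um = p$colony_cutoff_um)
        st$colonies <- cols
        readr::write_tsv(cols, file.path(outdir, "colonies.tsv"))
        sizes <- colony_sizes(cols)
        readr::write_tsv(sizes, file.path(outdir, "colony_sizes.tsv"))
        smry <- tibble::tibble(
          n_cells = nrow(cols), n_colonies = nrow(sizes),
          sizes = paste(sort(sizes$n_cells), collapse = ","))
        if (!is.null(stack$truth)) {
          planted <- sort(as.integer(table(stack$truth$colony)))
          smry$planted_sizes <- paste(planted, collapse = ",")
        }
        add_report("Colonies", .md_table(smry))
      },
      report = {
        hdr <- c("# stemchrom pipeline report", "",
                 paste("seed:", cfg$seed), "")
        writeLines(c(hdr, unlist(report)),
                   file.path(outdir, "report.md"))
      },
      stop("unknown stage: ", stage)
    )
  }
  st$report_path <- file.path(outdir, "report.md")
  invisible(as.list(st))
}
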