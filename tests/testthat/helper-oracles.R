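# Independent brute-force oracles used to validate the package's optimized
# implementations.  These deliberately use naive enumeration and stay
# independent of the code paths they check.

# fragments overlapping a window by >= 1 bp (0-based half-open coordinates)
oracle_overlap_count <- function(frag_start, frag_end, win_start, win_end) {
  n <- 0L
  for (i in seq_along(frag_start)) {
    lo <- max(frag_start[i], win_start)
    hi <- min(frag_end[i], win_end)
    if (hi - lo >= 1) n <- n + 1L
  }
  n
}

# maximal T-runs of length >= min_len via regex
oracle_t_runs <- function(seq, min_len) {
  m <- gregexpr(paste0("T{", min_len, ",}"), seq)[[1]]
  if (m[1] == -1) 0L else length(m)
}

# overlapping k-mer counts by explicit position loop
oracle_kmer_counts <- function(seqs, k) {
  counts <- list()
  for (s in seqs) {
    if (nchar(s) < k) next
    for (i in seq_len(nchar(s) - k + 1)) {
      km <- substr(s, i, i + k - 1)
      if (grepl("[^ACGT]", km)) next
      counts[[km]] <- (counts[[km]] %||% 0L) + 1L
    }
  }
  unlist(counts)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# maximal perfect tandem arrays: an array is a maximal stretch of positions
# where the letter repeats with period u (evaluated position by position,
# independently of the rle-based implementation)
oracle_tandem_arrays <- function(s, u, min_units) {
  L <- nchar(s)
  ch <- strsplit(s, "")[[1]]
  periodic <- logical(max(L - u, 0))
  for (i in seq_len(max(L - u, 0))) {
    periodic[i] <- ch[i] == ch[i + u] && ch[i] %in% c("A", "C", "G", "T")
  }
  res <- NULL
  i <- 1L
  while (i <= length(periodic)) {
    if (!periodic[i]) {
      i <- i + 1L
      next
    }
    j <- i
    while (j < length(periodic) && periodic[j + 1L]) j <- j + 1L
    span_end <- j + u
    n_units <- (span_end - i + 1L) %/% u
    if (n_units >= min_units) {
      res <- rbind(res, data.frame(start = i, end = span_end,
                                   n_units = n_units))
    }
    i <- j + 1L
  }
  res
}

# exhaustive PWM scoring of one sequence (log2 odds, floor 1e-3)
oracle_pwm_scores <- function(s, mat, bg) {
  S <- log2(pmax(mat, 1e-3) / bg)
  w <- ncol(mat)
  ch <- strsplit(s, "")[[1]]
  L <- length(ch)
  if (L < w) return(numeric(0))
  out <- numeric(L - w + 1)
  for (o in seq_len(L - w + 1)) {
    sc <- 0
    for (j in seq_len(w)) {
      b <- ch[o + j - 1]
      if (!b %in% rownames(S)) {
        sc <- NA_real_
        break
      }
      sc <- sc + S[b, j]
    }
    out[o] <- sc
  }
  out
}

# per-diagonal observed/expected by explicit loops
oracle_oe <- function(m) {
  n <- nrow(m)
  out <- matrix(0, n, n)
  for (d in 0:(n - 1)) {
    vals <- c()
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (abs(i - j) == d) vals <- c(vals, m[i, j])
      }
    }
    mu <- mean(vals)
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (abs(i - j) == d) out[i, j] <- if (mu == 0) 0 else m[i, j] / mu
      }
    }
  }
  out
}

# Sinkhorn iteration oracle for symmetric balancing (independent update
# scheme: alternate row/column scalings of the rectangular view)
oracle_sinkhorn <- function(m, iters = 5000) {
  r <- rep(1, nrow(m))
  c_ <- rep(1, ncol(m))
  for (i in seq_len(iters)) {
    r <- 1 / (m %*% c_)[, 1]
    c_ <- 1 / (t(m) %*% r)[, 1]
  }
  sqrt(r * c_)  # symmetric scaling
}

# transitive closure partition from pairwise distances (< cutoff merges)
oracle_partition <- function(coords, cutoff) {
  n <- nrow(coords)
  lab <- seq_len(n)
  d <- as.matrix(stats::dist(coords))
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (i != j && d[i, j] < cutoff && lab[j] != lab[i]) {
          new <- min(lab[i], lab[j])
          lab[lab == lab[i] | lab == lab[j]] <- new
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  match(lab, unique(lab))
}

# canonical form of a partition for comparison
canonical_partition <- function(lab) {
  match(lab, unique(lab))
}

# two labelings over the same element order induce the same partition iff
# their first-occurrence canonical forms match
same_partition <- function(a, b) {
  identical(canonical_partition(a), canonical_partition(b))
}

# small helper: fragment tibble constructor
frag_tbl <- function(start, end, contig = "c1", sample = "s1",
                     isolation = "brain", assay = "ATAC") {
  tibble::tibble(contig = contig, start = as.integer(start),
                 end = as.integer(end), length = as.integer(end - start),
                 sample = sample, isolation = isolation, assay = assay)
}

# uniformly tiled fragments giving flat coverage over [0, len)
uniform_frags <- function(len, step = 5, frag_len = 50, contig = "c1",
                          sample = "s1") {
  starts <- seq(0L, len - frag_len, by = step)
  frag_tbl(starts, starts + frag_len, contig = contig, sample = sample)
}

small_plan <- function(seed = 1, ...) {
  simulation_plan(
    seed = seed,
    n_genes_per_class = c(brain = 8, epidermis = 8, intestine = 8,
                          neoblast = 8, constitutive = 10,
                          unclassified = 8),
    ...)
}
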