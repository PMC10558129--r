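#' Simulate a calibrated image stack with planted cell colonies
#'
#' Renders Gaussian intensity blobs at the given physical centroid
#' positions on top of a realistic confocal background — i.i.d. Gaussian
#' detector noise plus sparse single-voxel "hot pixel" (salt) noise — using
#' the plan's voxel calibration.  The blob peak amplitude is
#' `snr` times the total background standard deviation
#' (`sqrt(noise_sd^2 + salt_fraction * salt_amplitude^2)`).  The planted
#' colony membership (connected components of pairwise centroid distance <
#' `colony_cutoff_um`) is recorded as ground truth.
#'
#' @param plan A [simulation_plan()] (provides seed and voxel calibration).
#' @param centroids_um Matrix or tibble with columns `x`, `y`, `z`
#'   (micrometers); may have zero rows for a pure-noise stack.
#' @param radius_um Gaussian sigma of each blob in micrometers (scalar or
#'   per-blob); must be at least the in-plane voxel size.
#' @param snr Blob peak amplitude in units of the total background
#'   standard deviation.
#' @param dims Stack dimensions `c(z=, y=, x=)` in voxels.
#' @param noise_sd Gaussian detector noise standard deviation.
#' @param salt_fraction Fraction of voxels carrying hot-pixel noise.
#' @param salt_amplitude Hot-pixel amplitude (in `noise_sd` units, these
#'   are isolated single-voxel spikes removed by the object size filter).
#' @param colony_cutoff_um Distance defining planted colony membership.
#' @param channel Channel label.
#' @return An `image_stack` with `truth`: tibble `cell`, `x`, `y`, `z`,
#'   `colony`.
#' @export
simulate_colony_stack <- function(plan, centroids_um,
                                  radius_um = 6, snr = 8,
                                  dims = c(z = 8, y = 96, x = 96),
                                  noise_sd = 1, salt_fraction = 0.01,
                                  salt_amplitude = 15 * noise_sd,
                                  colony_cutoff_um = 50,
                                  channel = "marker") {
  stopifnot(inherits(plan, "simulation_plan"))
  vox <- plan$image_voxel_um
  cen <- as.data.frame(centroids_um)
  if (nrow(cen) && !all(c("x", "y", "z") %in% names(cen))) {
    names(cen)[1:3] <- c("x", "y", "z")
  }
  radius_um <- rep(radius_um, length.out = max(1, nrow(cen)))
  if (nrow(cen) && any(radius_um < min(vox[c("x", "y")]))) {
    stop("blob radius below the in-plane voxel size")
  }
  field <- c(x = (dims[["x"]] - 1) * vox[["x"]],
             y = (dims[["y"]] - 1) * vox[["y"]],
             z = (dims[["z"]] - 1) * vox[["z"]])
  if (nrow(cen) && any(cen$x < 0 | cen$x > field[["x"]] |
                       cen$y < 0 | cen$y > field[["y"]] |
                       cen$z < 0 | cen$z > field[["z"]])) {
    stop("centroid(s) outside the imaged field")
  }
  .with_stage_seed(plan, "stack", {
    a <- array(stats::rnorm(prod(dims), 0, noise_sd),
               dim = c(dims[["z"]], dims[["y"]], dims[["x"]]))
    n_salt <- round(salt_fraction * prod(dims))
    if (n_salt > 0) {
      idx <- sample.int(prod(dims), n_salt)
      a[idx] <- a[idx] + salt_amplitude
    }
    bg_sd <- sqrt(noise_sd^2 + salt_fraction * salt_amplitude^2)
    if (nrow(cen)) {
      zc <- (seq_len(dims[["z"]]) - 1) * vox[["z"]]
      yc <- (seq_len(dims[["y"]]) - 1) * vox[["y"]]
      xc <- (seq_len(dims[["x"]]) - 1) * vox[["x"]]
      for (i in seq_len(nrow(cen))) {
        dz2 <- (zc - cen$z[i])^2
        dy2 <- (yc - cen$y[i])^2
        dx2 <- (xc - cen$x[i])^2
        blob <- snr * bg_sd *
          exp(-(outer(outer(dz2, dy2, "+"), dx2, "+")) /
                (2 * radius_um[i]^2))
        a <- a + blob
      }
    }
    truth <- NULL
    if (nrow(cen)) {
      cl <- cluster_colonies(
        tibble::tibble(object_id = seq_len(nrow(cen)),
                       x_um = cen$x, y_um = cen$y, z_um = cen$z),
        cutoff_um = colony_cutoff_um)
      truth <- tibble::tibble(cell = seq_len(nrow(cen)), x = cen$x,
                              y = cen$y, z = cen$z,
                              colony = cl$colony_id)
    }
    structure(list(data = a, voxel_um = vox, channel = channel,
                   truth = truth), class = "image_stack")
  })
}

#' Write / read an image stack as multi-page TIFF
#'
#' Intensities are affinely rescaled to `[0, 1]` for 32-bit float TIFF
#' storage; segmentation is invariant to this rescaling because both the
#' Laplacian filter and the `mean + f * sd` threshold are affine-equivariant.
#'
#' @param stack An `image_stack`.
#' @param path TIFF path.
#' @param voxel_um Voxel calibration to attach on read.
#' @return The path / an `image_stack`.
#' @export
write_image_stack <- function(stack, path) {
  a <- stack$data
  rng <- range(a)
  if (diff(rng) == 0) rng[2] <- rng[1] + 1
  scaled <- (a - rng[1]) / (rng[2] - rng[1])
  pages <- lapply(seq_len(dim(a)[1]), function(z) scaled[z, , ])
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  invisible(path)
}

#' @rdname write_image_stack
#' @export
read_image_stack <- function(path, voxel_um = c(x = 1, y = 1, z = 1)) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  a <- array(0, dim = c(length(pages), nrow(pages[[1]]),
                        ncol(pages[[1]])))
  for (z in seq_along(pages)) a[z, , ] <- pages[[z]]
  structure(list(data = a, voxel_um = voxel_um, channel = "tiff",
                 truth = NULL), class = "image_stack")
}
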