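# windowed sums along the first axis of a matrix (rows = axis)
.win_sum_cols <- function(m, r) {
  n <- nrow(m)
  cs <- apply(m, 2, cumsum)
  if (!is.matrix(cs)) cs <- matrix(cs, nrow = n)
  hi <- pmin(seq_len(n) + r, n)
  lo <- pmax(seq_len(n) - r, 1L)
  top <- cs[hi, , drop = FALSE]
  bottom <- rbind(0, cs)[lo, , drop = FALSE]
  top - bottom
}

# windowed sum along one axis of a 3d array
.box_sum_axis <- function(a, axis, r) {
  if (r == 0) return(a)
  d <- dim(a)
  perm <- c(axis, setdiff(1:3, axis))
  ap <- aperm(a, perm)
  m <- matrix(ap, nrow = d[axis])
  s <- .win_sum_cols(m, r)
  ap <- array(s, dim = d[perm])
  aperm(ap, order(perm))
}

.axis_counts <- function(len, r) {
  pmin(seq_len(len) + r, len) - pmax(seq_len(len) - r, 1L) + 1L
}

#' Blob-enhancing Laplacian filter
#'
#' Center-minus-neighborhood-mean filter of radius `n` (kernel extent
#' `2n + 1` per in-plane axis), the contrast-enhancement step applied
#' before thresholded object detection.  In `"3D"` mode the neighborhood
#' also extends along z with a radius scaled by the voxel anisotropy
#' (`round(n * voxel_x / voxel_z)`); in `"2D"` mode each slice is filtered
#' independently.  The filter removes any constant offset (the response to
#' a constant image is exactly zero, edges included, because the local mean
#' is normalized by the actual neighborhood size).
#'
#' @param stack An `image_stack` (list with `data` array `(z, y, x)` and
#'   `voxel_um`), or a plain 2D/3D array (unit voxels assumed).
#' @param n Neighborhood radius in pixels (>= 1).
#' @param mode `"3D"` or `"2D"`.
#' @return An `image_stack` with filtered data.
#' @export
laplacian_enhance <- function(stack, n, mode = c("3D", "2D")) {
  mode <- match.arg(mode)
  stack <- .as_image_stack(stack)
  a <- stack$data
  d <- dim(a)
  stopifnot(n >= 1)
  if (n > (min(d[2], d[3]) - 1) %/% 2) {
    stop("neighborhood radius n exceeds the image half-extent")
  }
  rz <- 0L
  if (mode == "3D" && d[1] > 1) {
    rz <- as.integer(round(n * stack$voxel_um[["x"]] /
                             stack$voxel_um[["z"]]))
    rz <- min(rz, d[1] - 1L)
  }
  s <- .box_sum_axis(a, 3, n)
  s <- .box_sum_axis(s, 2, n)
  if (rz > 0) s <- .box_sum_axis(s, 1, rz)
  counts <- outer(outer(.axis_counts(d[1], rz), .axis_counts(d[2], n)),
                  .axis_counts(d[3], n))
  dim(counts) <- d
  stack$data <- a - s / counts
  stack$channel <- paste0(stack$channel, "_enhanced")
  stack
}

.as_image_stack <- function(x) {
  if (inherits(x, "image_stack")) return(x)
  a <- as.array(x)
  if (length(dim(a)) == 2) a <- array(a, dim = c(1, dim(a)))
  structure(list(data = a, voxel_um = c(x = 1, y = 1, z = 1),
                 channel = "raw", truth = NULL), class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$data)
  cat("<image_stack>", x$channel, ":", d[1], "x", d[2], "x", d[3],
      "(z,y,x), voxel", paste(x$voxel_um, collapse = "x"), "um\n")
  invisible(x)
}

# connected-component labels of a logical mask; 26-connectivity in 3D,
# 8-connectivity per slice in 2D mode
.label_components <- function(mask, mode = c("3D", "2D")) {
  mode <- match.arg(mode)
  d <- dim(mask)
  fg <- which(mask)
  if (!length(fg)) {
    return(tibble::tibble(object_id = integer(), z = integer(),
                          y = integer(), x = integer()))
  }
  coords <- arrayInd(fg, d)
  dz <- if (mode == "3D") -1:1 else 0L
  offs <- expand.grid(dz = dz, dy = -1:1, dx = -1:1)
  offs <- offs[!(offs$dz == 0 & offs$dy == 0 & offs$dx == 0), ]
  edges <- list()
  for (k in seq_len(nrow(offs))) {
    nz <- coords[, 1] + offs$dz[k]
    ny <- coords[, 2] + offs$dy[k]
    nx <- coords[, 3] + offs$dx[k]
    ok <- nz >= 1 & nz <= d[1] & ny >= 1 & ny <= d[2] &
      nx >= 1 & nx <= d[3]
    nl <- (nx[ok] - 1L) * d[1] * d[2] + (ny[ok] - 1L) * d[1] + nz[ok]
    j <- match(nl, fg)
    has <- !is.na(j)
    if (any(has)) {
      edges[[length(edges) + 1L]] <- cbind(which(ok)[has], j[has])
    }
  }
  g <- igraph::make_empty_graph(n = length(fg), directed = FALSE)
  if (length(edges)) {
    em <- do.call(rbind, edges)
    g <- igraph::add_edges(g, t(em))
  }
  comp <- igraph::components(g)$membership
  tibble::tibble(object_id = as.integer(comp),
                 z = coords[, 1] - 1L, y = coords[, 2] - 1L,
                 x = coords[, 3] - 1L)
}

#' Threshold segmentation of a filtered stack
#'
#' Thresholds the (typically Laplacian-enhanced, see [laplacian_enhance()])
#' image at `mean + f * sd` of the filtered intensities and labels
#' connected components above the threshold (8-connectivity within slices
#' in 2D mode, 26-connectivity in 3D).  Components smaller than `min_size`
#' voxels are discarded.  An empty object set is a valid result.
#'
#' @param stack A filtered `image_stack` (or array).
#' @param f Threshold factor: `t = mean + f * sd`.
#' @param mode `"3D"` (objects span slices) or `"2D"` (objects are
#'   per-slice).
#' @param min_size Minimum object size in voxels.
#' @return An `object_set`: list with `objects` (tibble `object_id`,
#'   `n_voxels`), `voxels` (tibble `object_id`, `z`, `y`, `x`; 0-based),
#'   `voxel_um`, `threshold`.
#' @export
segment_objects <- function(stack, f, mode = c("3D", "2D"),
                            min_size = 8) {
  mode <- match.arg(mode)
  stopifnot(f > 0)
  stack <- .as_image_stack(stack)
  a <- stack$data
  thr <- mean(a) + f * stats::sd(a)
  vox <- .label_components(a > thr, mode)
  if (nrow(vox)) {
    sizes <- table(vox$object_id)
    keep <- as.integer(names(sizes)[sizes >= min_size])
    vox <- vox[vox$object_id %in% keep, ]
    # renumber 1..k in first-voxel order
    vox$object_id <- as.integer(factor(vox$object_id,
                                       levels = unique(vox$object_id)))
  }
  objects <- vox |>
    dplyr::count(.data$object_id, name = "n_voxels")
  structure(list(objects = objects, voxels = vox,
                 voxel_um = stack$voxel_um, threshold = thr),
            class = "object_set")
}

#' @export
print.object_set <- function(x, ...) {
  cat("<object_set>", nrow(x$objects), "objects,",
      sum(x$objects$n_voxels), "voxels, threshold",
      signif(x$threshold, 4), "\n")
  invisible(x)
}

#' Enhance and segment in one call
#'
#' @inheritParams laplacian_enhance
#' @inheritParams segment_objects
#' @return An `object_set`.
#' @export
detect_objects <- function(stack, n, f, mode = c("3D", "2D"),
                           min_size = 8) {
  mode <- match.arg(mode)
  segment_objects(laplacian_enhance(stack, n, mode), f, mode, min_size)
}

#' Physical centroids of segmented objects
#'
#' Intensity-unweighted mean of the 0-based voxel indices, multiplied by
#' the per-axis voxel size, in micrometers.
#'
#' @param objects An `object_set` from [segment_objects()].
#' @return Tibble `object_id`, `x_um`, `y_um`, `z_um`, `n_voxels`.
#' @export
object_centroids <- function(objects) {
  v <- objects$voxels
  if (!nrow(v)) {
    return(tibble::tibble(object_id = integer(), x_um = numeric(),
                          y_um = numeric(), z_um = numeric(),
                          n_voxels = integer()))
  }
  vox <- objects$voxel_um
  v |>
    dplyr::group_by(.data$object_id) |>
    dplyr::summarise(x_um = mean(.data$x) * vox[["x"]],
                     y_um = mean(.data$y) * vox[["y"]],
                     z_um = mean(.data$z) * vox[["z"]],
                     n_voxels = dplyr::n(), .groups = "drop")
}

#' Group cells into colonies by centroid distance
#'
#' Colonies are the connected components of the graph whose edges join
#' centroids at Euclidean distance strictly less than `cutoff_um`
#' (transitive closure: chains of close cells merge into one colony; a
#' pair at exactly the cutoff stays split).
#'
#' @param centroids Tibble with `object_id`, `x_um`, `y_um`, and optionally
#'   `z_um`.
#' @param cutoff_um Distance cutoff in micrometers.
#' @return A `colony_set`: tibble `object_id`, `x_um`, `y_um`, `z_um`,
#'   `colony_id`, `colony_size`.
#' @export
cluster_colonies <- function(centroids, cutoff_um = 50) {
  stopifnot(cutoff_um > 0)
  n <- nrow(centroids)
  if (!"z_um" %in% names(centroids)) centroids$z_um <- 0
  out <- centroids
  if (n == 0) {
    out$colony_id <- integer(0)
    out$colony_size <- integer(0)
  } else {
    m <- as.matrix(centroids[, c("x_um", "y_um", "z_um")])
    dm <- as.matrix(stats::dist(m))
    adj <- dm < cutoff_um
    adj[lower.tri(adj, diag = TRUE)] <- FALSE
    ed <- which(adj, arr.ind = TRUE)
    g <- igraph::make_empty_graph(n = n, directed = FALSE)
    if (nrow(ed)) g <- igraph::add_edges(g, t(ed))
    memb <- igraph::components(g)$membership
    out$colony_id <- as.integer(memb)
    sizes <- table(memb)
    out$colony_size <- as.integer(sizes[as.character(memb)])
  }
  class(out) <- c("colony_set", class(out))
  out
}

#' Colony size table
#'
#' @param colonies A `colony_set` from [cluster_colonies()].
#' @return Tibble `colony_id`, `n_cells`.
#' @export
colony_sizes <- function(colonies) {
  colonies |>
    dplyr::count(.data$colony_id, name = "n_cells") |>
    tibble::as_tibble()
}

#' Marker abundance normalized to nuclei counts
#'
#' `abundance = detected marker objects / detected DAPI nuclei`, the
#' per-image normalization used to compare stainings across animals.
#'
#' @param marker_objects,dapi_objects `object_set`s segmented on the same
#'   field (marker channel and DAPI channel).
#' @return One-row tibble `n_marker`, `n_dapi`, `abundance`.  Zero DAPI
#'   objects give `NA` abundance with a warning.
#' @export
density_and_counts <- function(marker_objects, dapi_objects) {
  n_m <- nrow(marker_objects$objects)
  n_d <- nrow(dapi_objects$objects)
  ab <- if (n_d == 0) {
    warning("zero DAPI objects; abundance undefined")
    NA_real_
  } else n_m / n_d
  tibble::tibble(n_marker = n_m, n_dapi = n_d, abundance = ab)
}

#' Plot detected colonies
#'
#' @param object A `colony_set`.
#' @param ... Unused.
#' @return A ggplot of centroids colored by colony.
#' @method autoplot colony_set
#' @export
autoplot.colony_set <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$x_um, y = .data$y_um,
                               color = factor(.data$colony_id))) +
    ggplot2::geom_point() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (um)", y = "y (um)", color = "colony") +
    ggplot2::theme_minimal()
}
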