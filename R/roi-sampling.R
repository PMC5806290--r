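# Random sampling of consecutive-voxel groups from an ROI.

#' Sample groups of consecutive ROI voxels from an R2* map
#'
#' Reproduces the group-sampling scheme used for the voting ensemble: the
#' valid ROI voxels of a plane are linearised in scan order (row-major by
#' default, i.e. reading each image row left to right; invalid voxels are
#' skipped), and `n_groups` runs of `group_size` consecutive positions are
#' drawn with replacement from all start offsets admitting a full run.
#' Groups may overlap. Deterministic under `seed`.
#'
#' @param map an `r2star_map`, or a plain numeric matrix of R2* values.
#' @param mask logical matrix of analyzable voxels (kidney parenchyma with
#'   collecting system and cysts excluded). Combined with the map's own
#'   validity mask when `map` is an `r2star_map`.
#' @param n_groups number of groups to draw (default 100 per plane).
#' @param group_size voxels per group (default 100).
#' @param seed optional integer seed.
#' @param order `"row"` (row-major, default) or `"col"` (column-major)
#'   linearisation.
#'
#' @return An object of class `voxel_group_set`: list with `values`
#'   (`n_groups x group_size` matrix, one group per row), `start` (start
#'   offsets in the linearised ROI), `group_size`, `order` and `n_valid`.
#' @export
#' @examples
#' m <- matrix(rnorm(400, 20), 20, 20)
#' g <- sample_voxel_groups(m, matrix(TRUE, 20, 20), n_groups = 5,
#'                          group_size = 50, seed = 1)
#' dim(g$values)
sample_voxel_groups <- function(map, mask, n_groups = 100L, group_size = 100L,
                                seed = NULL, order = c("row", "col")) {
  order <- match.arg(order)
  if (inherits(map, "r2star_map")) {
    values <- map$values
    mask <- mask & map$valid
  } else {
    values <- map
  }
  stopifnot(is.matrix(values), is.logical(mask),
            all(dim(mask) == dim(values)))
  if (order == "row") {
    lin <- as.vector(t(values))[as.vector(t(mask))]
  } else {
    lin <- as.vector(values)[as.vector(mask)]
  }
  n_valid <- length(lin)
  if (n_valid < group_size) {
    stop(sprintf("ROI has %d valid voxels; %d are needed per group",
                 n_valid, group_size), call. = FALSE)
  }
  n_starts <- n_valid - group_size + 1L
  starts <- with_seed(seed, sample.int(n_starts, n_groups, replace = TRUE))
  vals <- matrix(NA_real_, n_groups, group_size)
  for (g in seq_len(n_groups)) {
    vals[g, ] <- lin[starts[g]:(starts[g] + group_size - 1L)]
  }
  structure(list(values = vals, start = starts, group_size = group_size,
                 order = order, n_valid = n_valid),
            class = "voxel_group_set")
}

#' @export
print.voxel_group_set <- function(x, ...) {
  cat(sprintf("voxel_group_set: %d groups of %d consecutive voxels (%s-major, ROI %d voxels)\n",
              nrow(x$values), x$group_size, x$order, x$n_valid))
  invisible(x)
}
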