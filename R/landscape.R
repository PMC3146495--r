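#' Build a binary-habitat landscape of equally sized, equally spaced patches
#'
#' Constructs a rectangular grid landscape of two habitat classes: optimal
#' vole habitat, arranged as `n_patches` congruent square patches centred on
#' a regular \eqn{\sqrt{n} \times \sqrt{n}} lattice, embedded in a matrix of
#' unsuitable (but freely traversable) habitat. The total optimal area is
#' held at `habitat_fraction` of the landscape while the number of patches
#' varies, so fragmentation can be manipulated without changing habitat
#' amount.
#'
#' Cell coordinates are 0-based integers with the origin at the bottom-left
#' corner; cell `(x, y)` spans metres `[x, x+1) * cell_size_m` horizontally.
#' Patch `(i, j)` (0-based lattice indices, row-major patch ids) has its
#' left edge at `round((i + 0.5) * W/k - s/2)` where `k = sqrt(n_patches)`
#' and `s` is the patch side in cells, so layouts are exactly reproducible.
#'
#' @param width_m,height_m Landscape dimensions in metres.
#' @param habitat_fraction Fraction of total area that is optimal habitat
#'   (in (0, 1); the study design uses 0.015).
#' @param n_patches Number of patches; must be a perfect square (1, 9, 25,
#'   100 in the study design).
#' @param cell_size_m Cell edge length in metres (1 m in the full-scale
#'   design; 10 m for desk-scale runs).
#'
#' @return An object of class `vole_landscape`: a list with the grid
#'   dimensions, the realised habitat fraction, a `patch` integer matrix
#'   (`height` rows x `width` cols, entry -1 for matrix habitat, else the
#'   0-based patch id), the patch side in cells, and a tibble of patch
#'   bounding boxes.
#' @examples
#' land <- build_landscape(2450, 2450, 0.015, n_patches = 9, cell_size_m = 10)
#' land$patch_side_cells # 10 cells = 100 m
#' @export
build_landscape <- function(width_m, height_m, habitat_fraction, n_patches,
                            cell_size_m = 1) {
  stopifnot(width_m > 0, height_m > 0, cell_size_m > 0)
  if (length(n_patches) != 1L || n_patches < 1 ||
      sqrt(n_patches) %% 1 != 0) {
    abort("`n_patches` must be a perfect square >= 1.")
  }
  if (habitat_fraction <= 0 || habitat_fraction >= 1) {
    abort("`habitat_fraction` must lie in (0, 1).")
  }
  W <- as.integer(round(width_m / cell_size_m))
  H <- as.integer(round(height_m / cell_size_m))
  k <- as.integer(sqrt(n_patches))
  side <- as.integer(round(sqrt(habitat_fraction * W * H / n_patches)))
  if (side < 1) {
    abort("Patch side is below one cell; decrease `n_patches` or `cell_size_m`.")
  }
  if (side > floor(W / k) || side > floor(H / k)) {
    abort("Patches do not fit on the lattice at this fragmentation level.")
  }
  patch <- matrix(-1L, nrow = H, ncol = W)
  boxes <- vector("list", n_patches)
  for (j in seq_len(k) - 1L) {
    for (i in seq_len(k) - 1L) {
      x0 <- as.integer(round((i + 0.5) * W / k - side / 2))
      y0 <- as.integer(round((j + 0.5) * H / k - side / 2))
      x0 <- max(0L, min(W - side, x0))
      y0 <- max(0L, min(H - side, y0))
      id <- j * k + i
      patch[(y0 + 1):(y0 + side), (x0 + 1):(x0 + side)] <- id
      boxes[[id + 1L]] <- tibble(
        patch = id, x0 = x0, y0 = y0,
        x1 = x0 + side - 1L, y1 = y0 + side - 1L
      )
    }
  }
  structure(
    list(
      width_m = W * cell_size_m, height_m = H * cell_size_m,
      cell_size_m = cell_size_m, width = W, height = H,
      n_patches = as.integer(n_patches),
      nominal_fraction = habitat_fraction,
      habitat_fraction = n_patches * side^2 / (W * H),
      patch_side_cells = side,
      patch = patch,
      patches = bind_rows(boxes)
    ),
    class = "vole_landscape"
  )
}

#' @export
print.vole_landscape <- function(x, ...) {
  cat(sprintf(
    "<vole_landscape> %g x %g m (%d x %d cells of %g m)\n",
    x$width_m, x$height_m, x$width, x$height, x$cell_size_m
  ))
  cat(sprintf(
    "  %d patch(es) of %d x %d cells; optimal habitat %.3f%% (nominal %.3f%%)\n",
    x$n_patches, x$patch_side_cells, x$patch_side_cells,
    100 * x$habitat_fraction, 100 * x$nominal_fraction
  ))
  invisible(x)
}

#' Habitat class at cell coordinates
#'
#' @param landscape A [build_landscape()] object.
#' @param x,y Integer cell coordinates (0-based, origin bottom-left);
#'   vectorised and recycled.
#' @return Character vector, `"optimal"` or `"matrix"`.
#' @examples
#' land <- build_landscape(100, 100, 0.01, 1)
#' habitat_at(land, 50, 50)
#' @export
habitat_at <- function(landscape, x, y) {
  stopifnot(inherits(landscape, "vole_landscape"))
  n <- max(length(x), length(y))
  x <- rep_len(as.integer(x), n)
  y <- rep_len(as.integer(y), n)
  if (any(x < 0 | x >= landscape$width | y < 0 | y >= landscape$height)) {
    abort("Coordinates out of bounds.")
  }
  ifelse(landscape$patch[cbind(y + 1L, x + 1L)] >= 0L, "optimal", "matrix")
}

#' Patch id at cell coordinates (-1 for matrix habitat)
#' @inheritParams habitat_at
#' @return Integer vector of 0-based patch ids, -1 in the matrix.
#' @export
patch_at <- function(landscape, x, y) {
  stopifnot(inherits(landscape, "vole_landscape"))
  n <- max(length(x), length(y))
  x <- rep_len(as.integer(x), n)
  y <- rep_len(as.integer(y), n)
  if (any(x < 0 | x >= landscape$width | y < 0 | y >= landscape$height)) {
    abort("Coordinates out of bounds.")
  }
  landscape$patch[cbind(y + 1L, x + 1L)]
}

#' Fraction of habitat patches occupied by at least one vole
#'
#' @param landscape A [build_landscape()] object.
#' @param positions Data frame with integer cell columns `x` and `y`
#'   (vole locations); may be empty.
#' @return A single number in \[0, 1\]: occupied patches / total patches.
#'   The unoccupied fraction reported in fragmentation diagnostics is
#'   `1 - patch_occupancy(...)`.
#' @export
patch_occupancy <- function(landscape, positions) {
  stopifnot(inherits(landscape, "vole_landscape"))
  if (is.null(positions) || nrow(positions) == 0L) {
    return(0)
  }
  ids <- patch_at(landscape, positions$x, positions$y)
  length(unique(ids[ids >= 0L])) / landscape$n_patches
}

#' @describeIn build_landscape One row per cell: `x`, `y`, `patch`,
#'   `habitat`.
#' @param x A `vole_landscape` object.
#' @param ... Unused.
#' @export
as_tibble.vole_landscape <- function(x, ...) {
  grid <- expand.grid(x = seq_len(x$width) - 1L, y = seq_len(x$height) - 1L)
  pid <- as.vector(t(x$patch)) # row y+1 of the matrix is y; transpose -> x fastest
  tibble(
    x = grid$x, y = grid$y, patch = pid,
    habitat = ifelse(pid >= 0L, "optimal", "matrix")
  )
}

#' Write / read a landscape header as JSON
#'
#' The raster itself is not stored: layouts are deterministic functions of
#' the header parameters, so [read_landscape()] rebuilds the grid exactly.
#'
#' @param landscape A `vole_landscape`.
#' @param path File path for the JSON header.
#' @return `write_landscape()` returns `path` invisibly; `read_landscape()`
#'   returns the rebuilt `vole_landscape`.
#' @export
write_landscape <- function(landscape, path) {
  stopifnot(inherits(landscape, "vole_landscape"))
  hdr <- landscape[c(
    "width_m", "height_m", "cell_size_m", "n_patches", "nominal_fraction"
  )]
  jsonlite::write_json(hdr, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_landscape
#' @export
read_landscape <- function(path) {
  hdr <- jsonlite::read_json(path, simplifyVector = TRUE)
  build_landscape(
    hdr$width_m, hdr$height_m, hdr$nominal_fraction,
    hdr$n_patches, hdr$cell_size_m
  )
}
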