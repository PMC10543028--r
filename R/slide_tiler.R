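# Slide tiling: tissue detection by Sobel gradients, fixed-grid partitioning,
# low-gradient tile removal, color normalization and resizing.

#' Construct a slide image
#'
#' Wraps an RGB pixel array with the identifiers and acquisition metadata the
#' pipeline tracks. Pixels are expected in `[0, 255]` with channels in RGB
#' order; slides are taken as already scanned at the nominal magnification
#' (20x by default) — no pyramid resampling is performed.
#'
#' @param pixels numeric array `H x W x 3` in `[0, 255]`.
#' @param slide_id,patient_id identifiers; every tile produced from the slide
#'   inherits both, which is what keeps patient-level cross-validation splits
#'   leakage-free downstream.
#' @param magnification nominal objective power.
#' @param preparation one of `"FFPE"`, `"FF"`, `"synthetic"`.
#' @return an object of class `slide_image`.
#' @export
slide_image <- function(pixels, slide_id, patient_id = slide_id,
                        magnification = 20, preparation = c("synthetic", "FFPE", "FF")) {
  preparation <- match.arg(preparation)
  if (length(dim(pixels)) != 3L || dim(pixels)[3L] != 3L) {
    stop_input("slide pixels must be an H x W x 3 array")
  }
  if (min(pixels) < 0 || max(pixels) > 255) {
    stop_input("slide pixels must lie in [0, 255]")
  }
  structure(list(slide_id = as.character(slide_id),
                 patient_id = as.character(patient_id),
                 pixels = pixels, magnification = magnification,
                 preparation = preparation),
            class = "slide_image")
}

#' @export
print.slide_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<slide_image> %s (patient %s), %d x %d px, %sx, %s\n",
              x$slide_id, x$patient_id, d[1], d[2], x$magnification, x$preparation))
  invisible(x)
}

# Luminance-weighted grayscale: 0.299 R + 0.587 G + 0.114 B.
slide_gray <- function(pixels) {
  0.299 * pixels[, , 1L] + 0.587 * pixels[, , 2L] + 0.114 * pixels[, , 3L]
}

#' Per-pixel Sobel gradient magnitude
#'
#' Tissue detection operates on a weighted gradient magnitude: the slide is
#' converted to luminance-weighted grayscale and convolved with the two 3x3
#' Sobel kernels; the map is `sqrt(gx^2 + gy^2)` per pixel. Borders are
#' handled by edge replication.
#'
#' @param image a [slide_image()].
#' @return an `H x W` matrix of non-negative gradient magnitudes.
#' @export
compute_gradient_map <- function(image) {
  stopifnot(inherits(image, "slide_image"))
  d <- dim(image$pixels)
  if (d[1L] < 3L || d[2L] < 3L) {
    stop_input("slide %s is smaller than the 3x3 Sobel kernel", image$slide_id)
  }
  g <- slide_gray(image$pixels)
  H <- nrow(g); W <- ncol(g)
  p <- matrix(0, H + 2L, W + 2L)                       # replicate-padded
  p[2:(H + 1L), 2:(W + 1L)] <- g
  p[1L, ] <- p[2L, ]; p[H + 2L, ] <- p[H + 1L, ]
  p[, 1L] <- p[, 2L]; p[, W + 2L] <- p[, W + 1L]
  ri <- 2:(H + 1L); ci <- 2:(W + 1L)
  # Sobel x: column differences weighted 1-2-1 across rows.
  gx <- (p[ri - 1L, ci + 1L] + 2 * p[ri, ci + 1L] + p[ri + 1L, ci + 1L]) -
        (p[ri - 1L, ci - 1L] + 2 * p[ri, ci - 1L] + p[ri + 1L, ci - 1L])
  gy <- (p[ri + 1L, ci - 1L] + 2 * p[ri + 1L, ci] + p[ri + 1L, ci + 1L]) -
        (p[ri - 1L, ci - 1L] + 2 * p[ri - 1L, ci] + p[ri - 1L, ci + 1L])
  sqrt(gx^2 + gy^2)
}

#' Partition a slide into non-overlapping tiles
#'
#' Lays a fixed grid of `tile_edge x tile_edge` blocks from the slide origin;
#' remainder pixels at the right and bottom edges are discarded, so exactly
#' `floor(H/tile_edge) * floor(W/tile_edge)` tiles are produced.
#'
#' @param image a [slide_image()].
#' @param tile_edge tile side length in pixels (512 for 20x whole-slide runs).
#' @return a `tile_set`; empty (with a warning) when the slide is smaller
#'   than one tile.
#' @export
tile_slide <- function(image, tile_edge = 512L) {
  stopifnot(inherits(image, "slide_image"), tile_edge >= 1L)
  d <- dim(image$pixels)
  nr <- d[1L] %/% tile_edge
  nc <- d[2L] %/% tile_edge
  if (nr == 0L || nc == 0L) {
    warning(sprintf("slide %s (%d x %d) is smaller than one %d-px tile; empty tile set",
                    image$slide_id, d[1L], d[2L], tile_edge))
    tiles <- list()
  } else {
    tiles <- vector("list", nr * nc)
    k <- 0L
    for (i in seq_len(nr) - 1L) {
      for (j in seq_len(nc) - 1L) {
        k <- k + 1L
        rows <- (i * tile_edge + 1L):((i + 1L) * tile_edge)
        cols <- (j * tile_edge + 1L):((j + 1L) * tile_edge)
        tiles[[k]] <- list(grid_row = i, grid_col = j,
                           pixels = image$pixels[rows, cols, , drop = FALSE],
                           frac_low_gradient = NA_real_, retained = TRUE)
      }
    }
  }
  structure(list(slide_id = image$slide_id, patient_id = image$patient_id,
                 tiles = tiles,
                 tiling_params = list(tile_edge = as.integer(tile_edge),
                                      gradient_threshold = NA_real_,
                                      resize_edge = NA_integer_)),
            class = "tile_set")
}

#' @export
length.tile_set <- function(x) length(x$tiles)

#' @export
print.tile_set <- function(x, ...) {
  cat(sprintf("<tile_set> slide %s: %d tiles (%d retained), edge %d\n",
              x$slide_id, length(x$tiles),
              sum(vapply(x$tiles, `[[`, logical(1), "retained")),
              x$tiling_params$tile_edge))
  invisible(x)
}

#' Remove background tiles by the low-gradient rule
#'
#' A tile is removed when strictly more than half of its pixels have weighted
#' gradient magnitude below `threshold` (so a tile with exactly half its
#' pixels below threshold is retained). The fraction is recorded on every
#' tile, and removed tiles stay in the set with `retained = FALSE` so the
#' manifest documents the decision.
#'
#' @param tiles a `tile_set` from [tile_slide()].
#' @param gradient_map matrix from [compute_gradient_map()] on the same slide.
#' @param threshold gradient threshold; the whole-slide default is 15, with
#'   10-20 the sensible range depending on image quality.
#' @return the `tile_set` with `frac_low_gradient` and `retained` filled in.
#' @export
filter_tiles <- function(tiles, gradient_map, threshold = 15) {
  stopifnot(inherits(tiles, "tile_set"), threshold > 0)
  edge <- tiles$tiling_params$tile_edge
  need_r <- max(vapply(tiles$tiles, `[[`, integer(1), "grid_row"), -1L) + 1L
  need_c <- max(vapply(tiles$tiles, `[[`, integer(1), "grid_col"), -1L) + 1L
  if (length(tiles$tiles) > 0 &&
      (nrow(gradient_map) < need_r * edge || ncol(gradient_map) < need_c * edge)) {
    stop_input("gradient map (%d x %d) is not aligned with the %d-px tile grid",
               nrow(gradient_map), ncol(gradient_map), edge)
  }
  tiles$tiles <- lapply(tiles$tiles, function(tl) {
    rows <- (tl$grid_row * edge + 1L):((tl$grid_row + 1L) * edge)
    cols <- (tl$grid_col * edge + 1L):((tl$grid_col + 1L) * edge)
    frac <- mean(gradient_map[rows, cols] < threshold)
    tl$frac_low_gradient <- frac
    tl$retained <- frac <= 0.5
    tl
  })
  tiles$tiling_params$gradient_threshold <- threshold
  tiles
}

#' Subset a tile set to its retained tiles
#' @param tiles a `tile_set`.
#' @return the `tile_set` containing retained tiles only.
#' @export
retained_tiles <- function(tiles) {
  stopifnot(inherits(tiles, "tile_set"))
  tiles$tiles <- Filter(function(tl) isTRUE(tl$retained), tiles$tiles)
  tiles
}

#' Tile manifest
#'
#' @param tiles a `tile_set`.
#' @return a data.frame with one row per tile: `slide_id`, `patient_id`,
#'   `grid_row`, `grid_col`, `frac_low_gradient`, `retained`.
#' @export
tile_manifest <- function(tiles) {
  stopifnot(inherits(tiles, "tile_set"))
  data.frame(
    slide_id = rep(tiles$slide_id, length(tiles$tiles)),
    patient_id = rep(tiles$patient_id, length(tiles$tiles)),
    grid_row = vapply(tiles$tiles, `[[`, integer(1), "grid_row"),
    grid_col = vapply(tiles$tiles, `[[`, integer(1), "grid_col"),
    frac_low_gradient = vapply(tiles$tiles, `[[`, numeric(1), "frac_low_gradient"),
    retained = vapply(tiles$tiles, `[[`, logical(1), "retained"),
    stringsAsFactors = FALSE
  )
}

#' Resize retained tiles
#'
#' Bilinear resampling of each retained tile to `edge x edge` (224 by
#' default, the standard input size of image-classification backbones).
#' Already-sized tiles pass through unchanged.
#'
#' @param tiles a `tile_set` (tiles must be square).
#' @param edge output side length.
#' @return the `tile_set` with retained tiles resized.
#' @export
resize_tiles <- function(tiles, edge = 224L) {
  stopifnot(inherits(tiles, "tile_set"), edge >= 1L)
  tiles$tiles <- lapply(tiles$tiles, function(tl) {
    if (!isTRUE(tl$retained)) return(tl)
    d <- dim(tl$pixels)
    if (d[1L] != d[2L]) stop_input("tile (%d,%d) is not square", tl$grid_row, tl$grid_col)
    if (d[1L] == edge) return(tl)
    img <- EBImage::Image(aperm(tl$pixels, c(2L, 1L, 3L)) / 255, colormode = "Color")
    out <- EBImage::resize(img, w = edge, h = edge)
    px <- aperm(EBImage::imageData(out), c(2L, 1L, 3L)) * 255
    px[px < 0] <- 0; px[px > 255] <- 255
    tl$pixels <- px
    tl
  })
  tiles$tiling_params$resize_edge <- as.integer(edge)
  tiles
}

# Rotate a slide's pixel array counter-clockwise by 0/90/180/270 degrees.
rotate_slide <- function(image, degrees) {
  stopifnot(inherits(image, "slide_image"), degrees %in% c(0, 90, 180, 270))
  px <- image$pixels
  rot90 <- function(a) {
    # counter-clockwise quarter turn: new[i, j] = old[j, W + 1 - i]
    aperm(a[, rev(seq_len(dim(a)[2L])), , drop = FALSE], c(2L, 1L, 3L))
  }
  k <- degrees / 90
  while (k > 0) { px <- rot90(px); k <- k - 1 }
  out <- image
  out$pixels <- px
  out
}
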