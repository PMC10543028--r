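# Stain color normalization. Default is Reinhard mean/variance matching in
# CIE Lab (a perceptual space); Macenko stain-vector normalization is an
# optional backend; "identity" passes tiles through untouched, which is the
# right choice for synthetic cohorts whose color channels carry signal.

#' Default Reinhard reference statistics
#'
#' Per-channel Lab means and standard deviations of a typical well-stained
#' H&E field, used as the bundled normalization target when no cohort-specific
#' reference is supplied.
#'
#' @return list with `mean` and `sd`, each length-3 (L, a, b).
#' @export
reinhard_reference <- function() {
  list(mean = c(65, 22, -12), sd = c(14, 9, 6))
}

# Lab statistics of one RGB tile (pixels in [0, 255]).
tile_lab <- function(pixels) {
  rgb <- cbind(as.vector(pixels[, , 1L]), as.vector(pixels[, , 2L]),
               as.vector(pixels[, , 3L])) / 255
  grDevices::convertColor(rgb, from = "sRGB", to = "Lab")
}

reinhard_tile <- function(pixels, reference) {
  lab <- tile_lab(pixels)
  mu <- colMeans(lab)
  s <- apply(lab, 2L, sd)
  if (any(s == 0)) {
    warning("degenerate tile (zero channel variance); returned unchanged")
    return(pixels)
  }
  lab2 <- sweep(sweep(sweep(sweep(lab, 2L, mu, "-"), 2L, s, "/"),
                      2L, reference$sd, "*"), 2L, reference$mean, "+")
  rgb <- grDevices::convertColor(lab2, from = "Lab", to = "sRGB")
  rgb[rgb < 0] <- 0; rgb[rgb > 1] <- 1
  out <- pixels
  out[, , 1L] <- matrix(rgb[, 1L], dim(pixels)[1L]) * 255
  out[, , 2L] <- matrix(rgb[, 2L], dim(pixels)[1L]) * 255
  out[, , 3L] <- matrix(rgb[, 3L], dim(pixels)[1L]) * 255
  out
}

# Reference H&E stain vectors (hematoxylin, eosin rows) and the standard
# maximum-concentration targets used by Macenko-style normalization.
macenko_reference <- function() {
  list(stains = rbind(c(0.5626, 0.7201, 0.4062),
                      c(0.2159, 0.8012, 0.5581)),
       max_conc = c(1.9705, 1.0308))
}

macenko_tile <- function(pixels, reference, beta = 0.15, alpha = 1) {
  d <- dim(pixels)
  I <- cbind(as.vector(pixels[, , 1L]), as.vector(pixels[, , 2L]),
             as.vector(pixels[, , 3L]))
  od <- -log((I + 1) / 256)                       # optical density
  keep <- rowSums(od > beta) == 3L
  if (sum(keep) < 10 || sd(od[keep, 1L]) == 0) {
    warning("degenerate tile for stain estimation; returned unchanged")
    return(pixels)
  }
  e <- eigen(stats::cov(od[keep, , drop = FALSE]), symmetric = TRUE)
  v <- e$vectors[, 1:2]                           # top-2 OD plane
  proj <- od[keep, , drop = FALSE] %*% v
  phi <- atan2(proj[, 2L], proj[, 1L])
  lo <- quantile(phi, alpha / 100); hi <- quantile(phi, 1 - alpha / 100)
  s1 <- v %*% c(cos(lo), sin(lo))
  s2 <- v %*% c(cos(hi), sin(hi))
  if (s1[1L] < 0) s1 <- -s1
  if (s2[1L] < 0) s2 <- -s2
  stains <- if (s1[1L] > s2[1L]) rbind(t(s1), t(s2)) else rbind(t(s2), t(s1))
  conc <- t(qr.solve(t(stains), t(od)))           # pixel stain concentrations
  maxc <- apply(conc, 2L, quantile, 0.99)
  maxc[maxc <= 0] <- 1e-6
  conc <- sweep(conc, 2L, reference$max_conc / maxc, "*")
  od2 <- conc %*% reference$stains
  I2 <- 256 * exp(-od2) - 1
  I2[I2 < 0] <- 0; I2[I2 > 255] <- 255
  out <- pixels
  out[, , 1L] <- matrix(I2[, 1L], d[1L])
  out[, , 2L] <- matrix(I2[, 2L], d[1L])
  out[, , 3L] <- matrix(I2[, 3L], d[1L])
  out
}

#' Color-normalize retained tiles
#'
#' Deterministic stain normalization applied tile-by-tile to the retained
#' tiles of a set. `"reinhard"` matches per-channel Lab mean and standard
#' deviation to the reference; `"macenko"` re-projects optical densities onto
#' reference H&E stain vectors; `"identity"` returns tiles unchanged (for
#' synthetic cohorts). Degenerate tiles (zero channel variance) are returned
#' unchanged with a warning.
#'
#' @param tiles a `tile_set`.
#' @param reference reference statistics: [reinhard_reference()] or
#'   [macenko_reference()] shaped lists; defaults to the bundled reference of
#'   the chosen method.
#' @param method `"reinhard"`, `"macenko"`, or `"identity"`.
#' @return the `tile_set` with retained tiles normalized.
#' @export
normalize_color <- function(tiles, reference = NULL,
                            method = c("reinhard", "macenko", "identity")) {
  stopifnot(inherits(tiles, "tile_set"))
  method <- match.arg(method)
  if (method == "identity") return(tiles)
  if (is.null(reference)) {
    reference <- if (method == "reinhard") reinhard_reference() else macenko_reference()
  }
  tiles$tiles <- lapply(tiles$tiles, function(tl) {
    if (!isTRUE(tl$retained)) return(tl)
    tl$pixels <- if (method == "reinhard") {
      reinhard_tile(tl$pixels, reference)
    } else {
      macenko_tile(tl$pixels, reference)
    }
    tl
  })
  tiles
}
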