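# Convenience wrappers chaining tiler -> color normalization -> resize ->
# feature extraction, slide by slide, so whole cohorts can be featurized
# without holding all tile pixels in memory at once.

#' Featurize one slide
#'
#' Runs the full tile pipeline on a slide: gradient map, fixed-grid tiling,
#' low-gradient tile removal, color normalization, resize, feature
#' extraction.
#'
#' @param slide a [slide_image()].
#' @param tile_edge tile side in pixels.
#' @param threshold gradient threshold for tissue retention.
#' @param resize_edge output tile side for the feature backend.
#' @param color_norm normalization method passed to [normalize_color()].
#' @param backend,backend_fun feature backend passed to [extract_features()].
#' @return list with `features` (a `feature_matrix` of the slide's retained
#'   tiles) and `manifest` (the per-tile decision table); `features` is NULL
#'   when no tile is retained.
#' @export
slide_features <- function(slide, tile_edge = 512L, threshold = 15,
                           resize_edge = 224L, color_norm = "reinhard",
                           backend = "texture", backend_fun = NULL) {
  gm <- compute_gradient_map(slide)
  ts <- tile_slide(slide, tile_edge)
  ts <- filter_tiles(ts, gm, threshold)
  manifest <- tile_manifest(ts)
  ts <- retained_tiles(ts)
  if (length(ts) == 0L) return(list(features = NULL, manifest = manifest))
  ts <- normalize_color(ts, method = color_norm)
  ts <- resize_tiles(ts, resize_edge)
  list(features = extract_features(ts, backend = backend, backend_fun = backend_fun),
       manifest = manifest)
}

#' Featurize a cohort of slides
#'
#' @param slides list of [slide_image()] objects.
#' @param ... passed to [slide_features()].
#' @return list with `features` (stacked `feature_matrix` across slides,
#'   manifest order) and `manifest`.
#' @export
cohort_features <- function(slides, ...) {
  parts <- lapply(slides, slide_features, ...)
  feats <- Filter(Negate(is.null), lapply(parts, `[[`, "features"))
  if (!length(feats)) stop_input("no slide contributed a retained tile")
  features <- feature_matrix(
    do.call(rbind, lapply(feats, strip_fm)),
    do.call(rbind, lapply(feats, tile_info)),
    backend_tag = attr(feats[[1L]], "backend_tag")
  )
  list(features = features,
       manifest = do.call(rbind, lapply(parts, `[[`, "manifest")))
}
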