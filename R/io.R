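# Readers and writers for the pipeline's external formats: counts (TSV /
# MatrixMarket), gene sets (GMT), drug GI networks (JSON), label and
# survival tables (TSV), PNG slides and tile manifests.

#' Read a genes x samples count matrix from TSV
#'
#' Expects a header row of sample identifiers and gene identifiers in the
#' first column.
#'
#' @param path TSV file.
#' @return integer matrix with gene rownames and sample colnames.
#' @export
read_counts_tsv <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", row.names = 1L,
                   check.names = FALSE)
  as.matrix(df)
}

#' Write a genes x samples matrix to TSV
#' @param mat matrix with dimnames.
#' @param path output file.
#' @export
write_matrix_tsv <- function(mat, path) {
  df <- data.frame(gene_id = rownames(mat), as.data.frame(mat, check.names = FALSE),
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read counts from MatrixMarket with gene/sample sidecar lists
#'
#' @param mtx path to the `.mtx` file.
#' @param genes,samples paths to one-identifier-per-line sidecar files
#'   (rows, columns).
#' @return integer matrix.
#' @export
read_counts_mtx <- function(mtx, genes, samples) {
  m <- as.matrix(Matrix::readMM(mtx))
  rownames(m) <- readLines(genes)
  colnames(m) <- readLines(samples)
  m
}

#' Read gene sets from a GMT file
#'
#' @param path GMT file (set name, description, then member genes, tab
#'   separated).
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1L]]
    parts[-(1:2)]
  })
  names(sets) <- vapply(lines, function(l) strsplit(l, "\t", fixed = TRUE)[[1L]][1L], "")
  sets
}

#' Read a drug GI network from JSON
#'
#' Schema: `{"drug": str, "targets": [str], "sl_partners": [str],
#' "sr_partners": [str]}`.
#'
#' @param path JSON file.
#' @return a [gi_network()].
#' @export
read_gi_network <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  gi_network(j$drug, targets = j$targets %||% character(),
             sl_partners = j$sl_partners %||% character(),
             sr_partners = j$sr_partners %||% character())
}

#' Write a drug GI network to JSON
#' @param network a [gi_network()].
#' @param path output file.
#' @export
write_gi_network <- function(network, path) {
  jsonlite::write_json(unclass(network), path, auto_unbox = TRUE, pretty = TRUE)
}

#' Read a two-column label table
#'
#' @param path TSV with columns `patient_id` and `response` (0/1).
#' @return named 0/1 vector.
#' @export
read_labels_tsv <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  setNames(as.integer(df$response), df$patient_id)
}

#' Read a survival table
#'
#' @param path TSV with columns `patient_id`, `time`, `event`.
#' @return data.frame.
#' @export
read_survival_tsv <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Read a slide from PNG
#'
#' @param path PNG file.
#' @param slide_id,patient_id identifiers (default from the filename).
#' @param ... passed to [slide_image()].
#' @return a [slide_image()].
#' @export
read_slide_png <- function(path, slide_id = sub("\\.png$", "", basename(path)),
                           patient_id = slide_id, ...) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 2L) px <- array(rep(px, 3L), c(dim(px), 3L))
  slide_image(px[, , 1:3, drop = FALSE] * 255, slide_id, patient_id, ...)
}

#' Write a slide to PNG
#' @param slide a [slide_image()].
#' @param path output file.
#' @export
write_slide_png <- function(slide, path) {
  png::writePNG(slide$pixels / 255, path)
}

#' Write a synthetic cohort to a directory
#'
#' Emits the cohort in the exact formats the pipeline consumes: PNG slides
#' plus a slide manifest TSV, a counts TSV, and a truth JSON (latent
#' factors, driven genes, loadings).
#'
#' @param cohort result of [generate_cohort()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(file.path(dir, "slides"), recursive = TRUE, showWarnings = FALSE)
  man <- do.call(rbind, lapply(cohort$slides, function(s) {
    path <- file.path("slides", paste0(s$slide_id, ".png"))
    write_slide_png(s, file.path(dir, path))
    data.frame(slide_id = s$slide_id, patient_id = s$patient_id, path = path,
               stringsAsFactors = FALSE)
  }))
  write.table(man, file.path(dir, "slides.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write_matrix_tsv(cohort$counts, file.path(dir, "counts.tsv"))
  jsonlite::write_json(
    list(driven_genes = cohort$truth$driven_genes,
         z = cohort$truth$z, loadings = cohort$truth$loadings,
         library_factors = cohort$truth$library_factors),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Write a tile manifest TSV
#' @param manifest data.frame from [tile_manifest()].
#' @param path output file.
#' @export
write_tile_manifest <- function(manifest, path) {
  write.table(manifest, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
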