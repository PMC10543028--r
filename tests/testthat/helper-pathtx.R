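# Shared fixtures, all built in code at test time.

# Uniform gray slide.
gray_slide <- function(h = 8, w = 8, value = 128, id = "S1", patient = "P1") {
  slide_image(array(value, c(h, w, 3)), id, patient)
}

# Vertical black/white step edge at column `at`.
step_slide <- function(h = 8, w = 8, at = w / 2, id = "S1") {
  px <- array(0, c(h, w, 3))
  px[, (at + 1):w, ] <- 255
  slide_image(px, id)
}

# Checkerboard of sq-px squares. Note a 1-px checkerboard is invisible to a
# 3x3 Sobel kernel (the +/-1 offsets skip exactly one period), so
# gradient-based tests use sq = 2.
checker_slide <- function(h = 16, w = 16, lo = 0, hi = 255, id = "S1", sq = 1) {
  m <- outer(seq_len(h), seq_len(w),
             function(i, j) ifelse((((i - 1) %/% sq) + ((j - 1) %/% sq)) %% 2 == 0, hi, lo))
  slide_image(array(rep(m, 3), c(h, w, 3)), id)
}

# Deterministic pseudo-random RGB slide.
noise_slide <- function(h = 32, w = 32, seed = 1, id = "S1", patient = "P1") {
  set.seed(seed)
  slide_image(array(sample(0:255, h * w * 3, replace = TRUE), c(h, w, 3)), id, patient)
}

# Small feature matrix with tile lineage for n tiles spread over slides /
# patients; d defaults to the compressed width.
toy_features <- function(n = 12, d = 512, n_slides = 4, n_patients = 2, seed = 1) {
  set.seed(seed)
  slides <- rep(sprintf("S%d", seq_len(n_slides)), length.out = n)
  patients <- sprintf("P%d", (match(slides, unique(slides)) - 1) %% n_patients + 1)
  info <- data.frame(tile_id = sprintf("t%02d", seq_len(n)),
                     slide_id = slides, patient_id = patients,
                     stringsAsFactors = FALSE)
  feature_matrix(matrix(rnorm(n * d), n, d), info, backend_tag = "toy")
}

# Reference Sobel magnitude by direct per-pixel convolution with replicated
# borders (the brute-force oracle).
sobel_oracle <- function(gray) {
  H <- nrow(gray); W <- ncol(gray)
  kx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3)      # columns of kx vary across x
  ky <- t(kx)
  at <- function(i, j) gray[min(max(i, 1), H), min(max(j, 1), W)]
  out <- matrix(0, H, W)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    gx <- 0; gy <- 0
    for (di in -1:1) for (dj in -1:1) {
      gx <- gx + kx[di + 2, dj + 2] * at(i + di, j + dj)
      gy <- gy + ky[di + 2, dj + 2] * at(i + di, j + dj)
    }
    out[i, j] <- sqrt(gx^2 + gy^2)
  }
  out
}

# Fast training settings for unit tests.
fast_config <- function(seed = 1, ...) {
  args <- list(learning_rate = 3e-3, batch_size = 32L, max_epochs = 30L,
               patience = 10L, seed = seed)
  do.call(training_config, utils::modifyList(args, list(...)))
}

make_tranche <- function(genes, index = 0L) {
  structure(list(tranche_index = index, gene_ids = genes,
                 median_range = c(NA_real_, NA_real_)),
            class = "gene_tranche")
}
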