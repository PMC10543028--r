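# Seeded synthetic cohorts: slides whose tile textures deterministically
# encode per-patient latent factors, expression driven by those factors at a
# configurable signal-to-noise ratio, GI networks over the driven genes,
# and response labels drawn from the true matching score. Every pipeline
# stage is exercisable on these cohorts with a known ground truth.

#' Specify a synthetic cohort
#'
#' The generator emulates matched (slide, bulk expression, response) cohorts:
#' each patient carries latent factors `z`; slide textures encode `z` in
#' their channel intensities (striped gratings keep every tile above the
#' tissue-detection gradient threshold); driven genes follow
#' `log mu_g + sqrt(snr) sigma (u_g . z) + sigma eps` on the natural-log
#' scale, so the image-predictable correlation of a driven gene is
#' `sqrt(snr/(1+snr))`; null genes are independent of `z`. Counts are
#' Poisson draws of the exponentiated log-expression under per-sample
#' library-size factors, so the expressed-gene filter and CPM normalization
#' are exercised realistically.
#'
#' @param n_patients number of patients.
#' @param slides_per_patient slides per patient.
#' @param slide_dim `c(H, W)` slide size in pixels.
#' @param tile_edge tile edge the slides are sized for (the texture period
#'   divides it).
#' @param n_genes total genes.
#' @param n_driven_genes genes driven by the latent factors
#'   (<= `n_genes`).
#' @param n_latent_factors latent dimensionality (at most 3; each factor is
#'   encoded in one color channel).
#' @param snr per-gene variance ratio of image-driven signal to biological
#'   noise.
#' @param noise_sd biological noise standard deviation on the natural-log
#'   scale.
#' @param seed integer fixing every downstream draw.
#' @return a `synthetic_cohort_spec`.
#' @export
synthetic_cohort_spec <- function(n_patients = 40L, slides_per_patient = 1L,
                                  slide_dim = c(64L, 64L), tile_edge = 32L,
                                  n_genes = 200L, n_driven_genes = 50L,
                                  n_latent_factors = 3L, snr = 4,
                                  noise_sd = 0.25, seed = 1L) {
  stopifnot(n_patients >= 1, slides_per_patient >= 1, n_genes >= 1,
            n_driven_genes <= n_genes, n_driven_genes >= 0,
            n_latent_factors >= 1, snr >= 0, noise_sd > 0)
  if (n_latent_factors > 3L) {
    stop_input("at most 3 latent factors (one per color channel)")
  }
  if (any(slide_dim < tile_edge)) {
    stop_input("slide (%d x %d) too small for one %d-px tile",
               slide_dim[1], slide_dim[2], tile_edge)
  }
  structure(list(n_patients = as.integer(n_patients),
                 slides_per_patient = as.integer(slides_per_patient),
                 slide_dim = as.integer(slide_dim), tile_edge = as.integer(tile_edge),
                 n_genes = as.integer(n_genes),
                 n_driven_genes = as.integer(n_driven_genes),
                 n_latent_factors = as.integer(n_latent_factors),
                 snr = snr, noise_sd = noise_sd, seed = as.integer(seed)),
            class = "synthetic_cohort_spec")
}

# Striped texture slide encoding z in per-channel base intensity. The
# square-wave grating (period 4 px, amplitude 40) keeps the Sobel gradient
# high everywhere so all tiles pass tissue detection.
synth_slide <- function(z, slide_id, patient_id, dims, seed) {
  with_seed(seed, {
    H <- dims[1L]; W <- dims[2L]
    stripe <- ifelse((((seq_len(W) - 1L) %/% 2L) %% 2L) == 0L, 1, -1)
    base <- rep(128, 3)
    base[seq_along(z)] <- 128 + 55 * tanh(z / 1.5)
    px <- array(0, c(H, W, 3))
    for (c in 1:3) {
      layer <- matrix(base[c], H, W) +
        matrix(stripe * 40, H, W, byrow = TRUE) +
        matrix(rnorm(H * W, 0, 2), H, W)
      px[, , c] <- pmin(pmax(round(layer), 0), 255)
    }
    slide_image(px, slide_id, patient_id, preparation = "synthetic")
  })
}

#' Generate a synthetic cohort
#'
#' @param spec a [synthetic_cohort_spec()].
#' @param truth optional `truth` record from a previous [generate_cohort()]
#'   call: the new cohort then shares that cohort's gene model (baselines
#'   `log_mu`, loadings, driven genes) but draws fresh patients — the way an
#'   external evaluation cohort relates to a training cohort.
#' @return list with `slides` (list of [slide_image()]), `counts` (genes x
#'   patients integer matrix) and `truth` (latent factors `z`, loadings,
#'   `driven_genes`, `log_mu`, the noiseless image-predictable log
#'   expression, library factors, and the spec) — everything an acceptance
#'   test needs to check recovery against the planted signal.
#' @export
generate_cohort <- function(spec, truth = NULL) {
  stopifnot(inherits(spec, "synthetic_cohort_spec"))
  k <- spec$n_latent_factors
  n <- spec$n_patients
  g <- spec$n_genes
  if (!is.null(truth)) {
    stopifnot(length(truth$log_mu) == g, ncol(truth$loadings) == k)
  }

  core <- with_seed(spec$seed, {
    z <- matrix(rnorm(k * n), k, n,
                dimnames = list(NULL, sprintf("P%03d", seq_len(n))))
    genes <- sprintf("G%04d", seq_len(g))
    if (is.null(truth)) {
      log_mu <- runif(g, log(50), log(2000))
      driven <- if (spec$n_driven_genes > 0) genes[seq_len(spec$n_driven_genes)] else character()
      loadings <- matrix(0, g, k, dimnames = list(genes, NULL))
      if (length(driven)) {
        u <- matrix(rnorm(length(driven) * k), length(driven), k)
        u <- u / sqrt(rowSums(u^2))
        loadings[driven, ] <- u
      }
    } else {
      log_mu <- truth$log_mu
      driven <- truth$driven_genes
      loadings <- truth$loadings
    }
    signal <- sqrt(spec$snr) * spec$noise_sd * (loadings %*% z)
    noiseless <- matrix(log_mu, g, n) + signal
    dimnames(noiseless) <- list(genes, colnames(z))
    eps <- matrix(rnorm(g * n, 0, spec$noise_sd), g, n)
    libf <- exp(rnorm(n, 0, 0.1))
    lambda <- exp(noiseless + eps) * rep(libf, each = g)
    counts <- matrix(rpois(g * n, lambda), g, n, dimnames = dimnames(noiseless))
    list(z = z, log_mu = log_mu, driven = driven, loadings = loadings,
         noiseless = noiseless, counts = counts, libf = libf)
  })

  patients <- colnames(core$z)
  slides <- list()
  for (p in seq_len(n)) {
    for (s in seq_len(spec$slides_per_patient)) {
      sid <- sprintf("%s_S%d", patients[p], s)
      slides[[sid]] <- synth_slide(core$z[, p], sid, patients[p], spec$slide_dim,
                                   derive_seed(spec$seed, p * 37L + s))
    }
  }

  list(slides = slides, counts = core$counts,
       truth = list(z = core$z, loadings = core$loadings,
                    driven_genes = core$driven, log_mu = core$log_mu,
                    noiseless = core$noiseless, library_factors = core$libf,
                    spec = spec))
}

#' Generate a drug GI network over driven genes
#'
#' Samples disjoint SL and SR partner sets from the cohort's driven genes
#' and stores each patient's true matching score (computed on the noiseless
#' image-predictable expression) in the returned object.
#'
#' @param truth the `truth` record of [generate_cohort()].
#' @param n_sl,n_sr partner counts (their sum must be >= 1 and at most the
#'   number of driven genes).
#' @param seed integer seed.
#' @param drug drug name for the network.
#' @return a [gi_network()] with attribute `true_ems` (named vector of true
#'   per-patient matching scores).
#' @export
generate_gi_network <- function(truth, n_sl = 8L, n_sr = 4L, seed = 1L,
                                drug = "synthetic-drug") {
  if (n_sl + n_sr < 1L) stop_input("need at least one partner")
  if (n_sl + n_sr > length(truth$driven_genes)) {
    stop_input("%d partners requested but only %d driven genes exist",
               n_sl + n_sr, length(truth$driven_genes))
  }
  partners <- with_seed(seed, sample(truth$driven_genes, n_sl + n_sr))
  net <- gi_network(drug, targets = "SYNTH-TARGET",
                    sl_partners = if (n_sl > 0) partners[seq_len(n_sl)] else character(),
                    sr_partners = if (n_sr > 0) partners[n_sl + seq_len(n_sr)] else character())
  true_ems <- score_cohort(truth$noiseless, net)
  attr(net, "true_ems") <- setNames(true_ems$ems, true_ems$patient_id)
  net
}

#' Generate response labels from true matching scores
#'
#' `label ~ Bernoulli(plogis(slope * ems + intercept))`, seeded.
#'
#' @param true_ems named numeric vector of matching scores.
#' @param slope,intercept logistic response model parameters.
#' @param seed integer seed.
#' @return named 0/1 vector.
#' @export
generate_response <- function(true_ems, slope = 4, intercept = -2, seed = 1L) {
  with_seed(seed, {
    setNames(rbinom(length(true_ems), 1L, plogis(slope * true_ems + intercept)),
             names(true_ems))
  })
}
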