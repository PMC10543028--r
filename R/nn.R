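# Minimal dense-network engine used by the autoencoder, the per-tranche
# multi-task regressors and the direct classifier. Single hidden ReLU layer
# with inverted dropout, Adam updates, minibatch training and patience-based
# early stopping that restores the best-validation weights.

relu <- function(x) {
  x[x < 0] <- 0
  x
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# Seeded uniform fan-in initialization: U(-1/sqrt(fan_in), 1/sqrt(fan_in)).
nn_new <- function(sizes) {
  L <- length(sizes) - 1L
  W <- vector("list", L)
  b <- vector("list", L)
  for (l in seq_len(L)) {
    lim <- 1 / sqrt(sizes[l])
    W[[l]] <- matrix(runif(sizes[l] * sizes[l + 1L], -lim, lim), sizes[l], sizes[l + 1L])
    b[[l]] <- runif(sizes[l + 1L], -lim, lim)
  }
  structure(list(W = W, b = b, sizes = sizes), class = "pathtx_nn")
}

nn_forward <- function(net, X, output = "linear") {
  L <- length(net$W)
  a <- X
  for (l in seq_len(L)) {
    a <- sweep(a %*% net$W[[l]], 2L, net$b[[l]], "+")
    if (l < L) a <- relu(a)
  }
  if (output == "sigmoid") a <- sigmoid(a)
  a
}

adam_state <- function(net) {
  lapply(seq_along(net$W), function(l) {
    list(mW = net$W[[l]] * 0, vW = net$W[[l]] * 0,
         mb = net$b[[l]] * 0, vb = net$b[[l]] * 0)
  })
}

# One Adam minibatch step on a single-hidden-layer net. Returns updated
# net/optimizer state. `yb` has one column per output unit.
nn_step <- function(net, opt, xb, yb, lr, dropout, output, t) {
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  n <- nrow(xb)

  z1 <- sweep(xb %*% net$W[[1L]], 2L, net$b[[1L]], "+")
  a1 <- relu(z1)
  if (dropout > 0) {
    mask <- matrix(runif(length(a1)) >= dropout, nrow(a1), ncol(a1)) / (1 - dropout)
    a1 <- a1 * mask
  }
  z2 <- sweep(a1 %*% net$W[[2L]], 2L, net$b[[2L]], "+")
  out <- if (output == "sigmoid") sigmoid(z2) else z2

  # MSE (linear) and BCE (sigmoid) both reduce to (out - y)/N at the logits.
  dz2 <- (out - yb) / (n * ncol(yb))
  if (output == "linear") dz2 <- 2 * dz2

  gW2 <- crossprod(a1, dz2)
  gb2 <- colSums(dz2)
  da1 <- tcrossprod(dz2, net$W[[2L]])
  if (dropout > 0) da1 <- da1 * mask
  dz1 <- da1 * (z1 > 0)
  gW1 <- crossprod(xb, dz1)
  gb1 <- colSums(dz1)

  grads <- list(list(W = gW1, b = gb1), list(W = gW2, b = gb2))
  for (l in 1:2) {
    opt[[l]]$mW <- beta1 * opt[[l]]$mW + (1 - beta1) * grads[[l]]$W
    opt[[l]]$vW <- beta2 * opt[[l]]$vW + (1 - beta2) * grads[[l]]$W^2
    opt[[l]]$mb <- beta1 * opt[[l]]$mb + (1 - beta1) * grads[[l]]$b
    opt[[l]]$vb <- beta2 * opt[[l]]$vb + (1 - beta2) * grads[[l]]$b^2
    mhW <- opt[[l]]$mW / (1 - beta1^t); vhW <- opt[[l]]$vW / (1 - beta2^t)
    mhb <- opt[[l]]$mb / (1 - beta1^t); vhb <- opt[[l]]$vb / (1 - beta2^t)
    net$W[[l]] <- net$W[[l]] - lr * mhW / (sqrt(vhW) + eps)
    net$b[[l]] <- net$b[[l]] - lr * mhb / (sqrt(vhb) + eps)
  }
  list(net = net, opt = opt)
}

# Mean per-output-column Pearson correlation between predictions and targets;
# columns constant in either vector are skipped. Falls back to negative MSE
# when no column admits a correlation.
metric_gene_cor <- function(pred, y) {
  px <- sweep(pred, 2L, colMeans(pred))
  py <- sweep(y, 2L, colMeans(y))
  sp <- colSums(px^2)
  sy <- colSums(py^2)
  ok <- sp > 0 & sy > 0              # single-row validation: no correlation
  if (!any(ok)) return(-mean((pred - y)^2))
  mean(colSums(px * py)[ok] / sqrt(sp[ok] * sy[ok]))
}

# Train a single-hidden-layer network. `metric` is maximized on the
# validation pair; "neg_mse" for the autoencoder/classifier, "gene_cor" for
# the expression regressors (the early-stopping rule of the training
# procedure: stop when the average per-gene validation correlation has not
# improved for `patience` consecutive epochs, cap at `max_epochs`, return the
# best-epoch weights).
nn_train <- function(x, y, hidden, config, val_x, val_y,
                     metric = c("neg_mse", "gene_cor"),
                     output = c("linear", "sigmoid")) {
  metric <- match.arg(metric)
  output <- match.arg(output)
  stopifnot(nrow(x) == nrow(y), nrow(val_x) == nrow(val_y))

  with_seed(config$seed, {
    net <- nn_new(c(ncol(x), hidden, ncol(y)))
    opt <- adam_state(net)
    best <- list(metric = -Inf, net = net, epoch = 0L)
    history <- numeric(0)
    t <- 0L
    stall <- 0L
    epochs_run <- 0L

    for (epoch in seq_len(config$max_epochs)) {
      epochs_run <- epoch
      idx <- sample.int(nrow(x))
      starts <- seq(1L, length(idx), by = config$batch_size)
      for (s in starts) {
        rows <- idx[s:min(s + config$batch_size - 1L, length(idx))]
        t <- t + 1L
        st <- nn_step(net, opt, x[rows, , drop = FALSE], y[rows, , drop = FALSE],
                      config$learning_rate, config$dropout, output, t)
        net <- st$net; opt <- st$opt
      }
      vp <- nn_forward(net, val_x, output)
      m <- if (metric == "gene_cor") metric_gene_cor(vp, val_y) else -mean((vp - val_y)^2)
      history <- c(history, m)
      if (m > best$metric + 1e-12) {
        best <- list(metric = m, net = net, epoch = epoch)
        stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= config$patience) break
      }
    }

    structure(list(net = best$net, best_metric = best$metric,
                   best_epoch = best$epoch, epochs_run = epochs_run,
                   history = history, metric = metric, output = output,
                   config = config),
              class = "pathtx_nn_fit")
  })
}
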