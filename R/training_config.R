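#' Training configuration
#'
#' Shared optimizer/early-stopping settings for the autoencoder, the
#' per-tranche regressors and the direct classifier. Defaults are the
#' production values: Adam at learning rate 1e-4, minibatches of 32 tiles,
#' at most 500 epochs with patience 50 on the validation metric, dropout 0.2.
#' Desk-scale runs (tests, vignette) pass smaller `max_epochs`/`patience`.
#'
#' @param learning_rate Adam learning rate.
#' @param batch_size tiles per minibatch.
#' @param max_epochs hard cap on training epochs.
#' @param patience epochs without validation improvement before stopping.
#' @param dropout dropout probability on the hidden layer during training.
#' @param seed integer seed fixing initialization, batch order and dropout.
#' @return a `training_config` list.
#' @export
training_config <- function(learning_rate = 1e-4, batch_size = 32L,
                            max_epochs = 500L, patience = 50L,
                            dropout = 0.2, seed = 1L) {
  stopifnot(learning_rate > 0, batch_size >= 1, max_epochs >= 1,
            patience >= 1, patience < max_epochs, dropout >= 0, dropout < 1)
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 dropout = dropout, seed = as.integer(seed)),
            class = "training_config")
}
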