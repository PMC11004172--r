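#' EverFlow configuration
#'
#' EverFlow is a compact 1-D convolutional architecture for per-event
#' cytometry classification. Each event is treated as a length-12,
#' single-channel signal in fixed panel order, passed through a stack of
#' Flow Blocks (1-D convolution -> batch normalization -> ReLU -> optional
#' max-pooling), then adaptive average pooling and a linear softmax head
#' over the 16 cell classes. The default configuration has exactly three
#' convolutional layers, three batch-normalization layers and two
#' max-pooling stages, and trains with the Ranger optimizer (RAdam +
#' Lookahead) at learning rate 5e-3 for at most 75 epochs.
#'
#' @param n_flow_blocks Number of Flow Blocks (>= 1).
#' @param conv_channels Convolution widths, one per block.
#' @param kernel_size Odd kernel size.
#' @param pool_blocks Integer indices of blocks followed by max-pooling.
#' @param learning_rate Optimizer learning rate.
#' @param max_epochs Epoch cap.
#' @param optimizer `"ranger"` or `"adam"` (fallback at the same rate).
#' @param batch_size Mini-batch size.
#' @param seed RNG seed for initialization, splits and shuffling.
#' @param class_weighting `"inverse-frequency"` (default; the cell classes
#'   are heavily imbalanced) or `"none"`.
#' @param patience Early-stop patience (epochs without validation
#'   improvement).
#' @return An `everflow_config`.
#' @export
everflow_config <- function(n_flow_blocks = 3L,
                            conv_channels = c(32L, 64L, 128L),
                            kernel_size = 3L,
                            pool_blocks = c(1L, 2L),
                            learning_rate = 5e-3,
                            max_epochs = 75L,
                            optimizer = c("ranger", "adam"),
                            batch_size = 256L,
                            seed = 1L,
                            class_weighting = c("inverse-frequency", "none"),
                            patience = 10L) {
  optimizer <- match.arg(optimizer)
  class_weighting <- match.arg(class_weighting)
  if (n_flow_blocks < 1L) stop_config("need at least one Flow Block")
  if (length(conv_channels) != n_flow_blocks)
    stop_config("conv_channels must have one width per Flow Block")
  if (kernel_size %% 2L == 0L) stop_config("kernel_size must be odd")
  if (length(pool_blocks) && !all(pool_blocks %in% seq_len(n_flow_blocks)))
    stop_config("pool_blocks indices outside 1..n_flow_blocks")
  structure(list(n_flow_blocks = as.integer(n_flow_blocks),
                 conv_channels = as.integer(conv_channels),
                 kernel_size = as.integer(kernel_size),
                 pool_blocks = as.integer(pool_blocks),
                 learning_rate = learning_rate,
                 max_epochs = as.integer(max_epochs),
                 optimizer = optimizer,
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed),
                 class_weighting = class_weighting,
                 patience = as.integer(patience)),
            class = "everflow_config")
}

#' Build an (untrained) EverFlow event classifier
#'
#' @param config An [everflow_config()].
#' @param signal_length Input signal length (12 panel channels).
#' @return An `event_classifier` with random initial weights.
#' @export
build_everflow <- function(config = everflow_config(), signal_length = 12L) {
  set.seed(config$seed)
  layers <- list()
  in_ch <- 1L
  L <- signal_length
  for (i in seq_len(config$n_flow_blocks)) {
    pad <- (config$kernel_size - 1L) %/% 2L
    if (config$kernel_size > L + 2L * pad)
      stop_config(sprintf(
        "kernel size %d exceeds the signal length %d remaining after pooling",
        config$kernel_size, L))
    layers <- c(layers, list(
      layer_conv1d(in_ch, config$conv_channels[i], config$kernel_size),
      layer_bn(config$conv_channels[i], ndim = 2L),
      layer_relu()))
    in_ch <- config$conv_channels[i]
    if (i %in% config$pool_blocks) {
      if (L < 2L)
        stop_config("signal too short for another max-pooling stage")
      layers <- c(layers, list(layer_maxpool1d(2L)))
      L <- L %/% 2L
    }
  }
  layers <- c(layers, list(layer_gap1d(),
                           layer_linear(in_ch, length(cell_types()))))
  structure(list(config = config, layers = layers,
                 class_order = cell_types(), signal_length = signal_length,
                 history = NULL, trained = FALSE),
            class = "event_classifier")
}

#' Layer census of an event classifier
#'
#' Counts convolutional, batch-normalization and max-pooling layers — the
#' structural signature of the architecture (3/3/2 under the defaults).
#'
#' @param model An `event_classifier` (or a `patient_classifier`).
#' @return Named integer vector of layer counts.
#' @export
model_layer_census <- function(model) {
  layer_census(model$layers)
}

#' @export
print.event_classifier <- function(x, ...) {
  cz <- model_layer_census(x)
  cat(sprintf("<event_classifier> EverFlow: %d conv1d / %d batch-norm / %d max-pool; %s\n",
              cz["conv1d"], cz["bn"], cz["maxpool1d"],
              if (x$trained) "trained" else "untrained"))
  invisible(x)
}

events_to_signal <- function(x) {
  x <- as.matrix(x)
  array(x, c(nrow(x), 1L, ncol(x)))
}

#' Train the Phase II per-event cell-type classifier
#'
#' Trains EverFlow on pooled, transformed events (cell types amalgamated
#' across patients) with cross-entropy loss, optional inverse-frequency
#' class weights, and early stopping on a stratified 10% validation split.
#'
#' @param events Numeric matrix of transformed events (rows) x 12 channels,
#'   as produced by [transform_events()].
#' @param labels Per-event cell-type labels aligned to `events` rows.
#' @param config An [everflow_config()].
#' @param verbose Print per-epoch progress.
#' @return A trained `event_classifier` with `history`.
#' @export
train_event_classifier <- function(events, labels,
                                   config = everflow_config(),
                                   verbose = FALSE) {
  events <- as.matrix(events)
  if (ncol(events) != 12L)
    stop_panel_mismatch("events must have 12 channels")
  if (length(labels) != nrow(events))
    stop_alignment("labels must align to event rows")
  check_labels(labels)
  if (length(unique(labels)) < 2L)
    stop_degenerate("need at least two cell classes to train")
  model <- build_everflow(config, signal_length = ncol(events))
  y <- match(labels, model$class_order)
  cw <- NULL
  if (config$class_weighting == "inverse-frequency") {
    tab <- tabulate(y, nbins = length(model$class_order))
    cw <- ifelse(tab > 0, sum(tab) / (sum(tab > 0) * pmax(tab, 1)), 1)
  }
  fit <- train_network(model$layers, events_to_signal(events), y,
                       n_classes = length(model$class_order),
                       lr = config$learning_rate,
                       max_epochs = config$max_epochs,
                       batch_size = config$batch_size,
                       optimizer = config$optimizer,
                       class_weights = cw,
                       patience = config$patience,
                       seed = config$seed, verbose = verbose)
  model$layers <- fit$layers
  model$history <- fit$history
  model$trained <- TRUE
  model
}

#' Classify events with a trained EverFlow model
#'
#' @param model Trained `event_classifier`.
#' @param em An [event_matrix()] in instrument units (transformed
#'   internally), or an already-transformed numeric matrix.
#' @param chunk_size Events scored per forward pass.
#' @return List: `labels` (argmax, ties to the lowest class index) and
#'   `prob` (n x 16 matrix, rows summing to 1).
#' @export
classify_events <- function(model, em, chunk_size = 8192L) {
  stopifnot(inherits(model, "event_classifier"))
  x <- if (inherits(em, "event_matrix")) transform_events(em) else as.matrix(em)
  if (ncol(x) != 12L)
    stop_panel_mismatch("expected 12 channels of event data")
  n <- nrow(x)
  prob <- matrix(NA_real_, n, length(model$class_order),
                 dimnames = list(NULL, model$class_order))
  for (s in seq(1L, n, by = chunk_size)) {
    ix <- s:min(s + chunk_size - 1L, n)
    fw <- nn_forward(model$layers, events_to_signal(x[ix, , drop = FALSE]),
                     training = FALSE)
    prob[ix, ] <- softmax_rows(fw$out)
  }
  labels <- model$class_order[max.col(prob, ties.method = "first")]
  list(labels = labels, prob = prob)
}

#' Per-class recall of per-event predictions
#'
#' @param labels_true,labels_pred Aligned per-event label vectors.
#' @return Named 16-vector of recalls; classes absent from `labels_true`
#'   are `NA` (not applicable), never `NaN`.
#' @export
per_class_recall <- function(labels_true, labels_pred) {
  if (length(labels_true) != length(labels_pred))
    stop_alignment("label vectors must align")
  check_labels(labels_true); check_labels(labels_pred)
  cls <- cell_types()
  out <- stats::setNames(rep(NA_real_, length(cls)), cls)
  for (k in cls) {
    sel <- labels_true == k
    if (any(sel)) out[k] <- mean(labels_pred[sel] == k)
  }
  out
}

#' Save or load a model checkpoint
#'
#' Checkpoints are self-describing: config, class order and weights travel
#' together, so a loaded model classifies identically.
#'
#' @param model An `event_classifier` or `patient_classifier`.
#' @param path Checkpoint path.
#' @return `path` (save) or the model (load).
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop_dependency(paste0("no checkpoint at ", path))
  readRDS(path)
}
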