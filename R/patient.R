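# Patient-level 5-class diagnosis.
#
# Phase I consumes the raw event cloud: each sample is rendered into a
# fixed-size stack of 2-D density histograms over the canonical ALOT gating
# views, then classified with a residual CNN. Phase III consumes the
# AI-derived cellular composition (16 fractions, optionally + 192 per-class
# channel medians) through a matched residual stack on 1-D feature input.

#' Default channel pairs for density rendering
#'
#' The six 2-D projections a human gater would inspect on an ALOT tube:
#' CD45 x SSC-A, CD34 x CD45, CD19 x CyCD79a, CyCD3 x SmCD3, CyMPO x SSC-A,
#' CD7 x SmCD3.
#'
#' @return List of character pairs of panel channel names.
#' @export
default_density_pairs <- function() {
  list(c("CD45-KrO", "SSC-A"),
       c("CD34-PerCP-Cy5.5", "CD45-KrO"),
       c("CD19-PC7", "CyCD79a-PE"),
       c("CyCD3-PacB", "SmCD3-APCH7"),
       c("CyMPO-FITC", "SSC-A"),
       c("CD7-APC", "SmCD3-APCH7"))
}

# fixed per-channel histogram ranges in transformed space, so images are
# comparable across patients: arcsinh fluorescence in [0, 6.5], unit-range
# scatter in [0, 1]
channel_range <- function(channel, panel = alot_panel()) {
  role <- panel$roles[match(channel, panel$names)]
  if (is.na(role)) stop_panel_mismatch(paste0("unknown channel: ", channel))
  if (role == "fluorescence") c(0, 6.5) else c(0, 1)
}

#' Render a sample's event cloud as a density image
#'
#' For each channel pair, a `bins x bins` 2-D histogram of the transformed
#' events on fixed ranges (raw counts sum to the event count per plane),
#' followed by `log1p` and unit-max scaling. Deterministic and invariant to
#' event order.
#'
#' @param em An [event_matrix()] (transformed internally).
#' @param pairs List of channel-name pairs; default the six ALOT views.
#' @param bins Bins per axis (default 64).
#' @param normalize One of `"log1p-unit-max"` (default) or `"counts"`.
#' @return A `density_image`: list with `planes` (P x bins x bins array),
#'   `pair_list`, `bins`, `normalization`, `sample_id`.
#' @export
render_density_image <- function(em, pairs = default_density_pairs(),
                                 bins = 64L,
                                 normalize = c("log1p-unit-max", "counts")) {
  normalize <- match.arg(normalize)
  x <- transform_events(em)
  planes <- array(0, c(length(pairs), bins, bins))
  for (p in seq_along(pairs)) {
    pr <- pairs[[p]]
    if (!all(pr %in% colnames(x)))
      stop_panel_mismatch(paste0("density pair references unknown channel: ",
                                 paste(pr, collapse = " x ")))
    bx <- bin_index(x[, pr[1]], channel_range(pr[1], em$panel), bins)
    by <- bin_index(x[, pr[2]], channel_range(pr[2], em$panel), bins)
    tab <- table(factor(bx, levels = seq_len(bins)),
                 factor(by, levels = seq_len(bins)))
    planes[p, , ] <- as.matrix(tab)
  }
  if (normalize == "log1p-unit-max") {
    for (p in seq_along(pairs)) {
      pl <- log1p(planes[p, , ])
      mx <- max(pl)
      planes[p, , ] <- if (mx > 0) pl / mx else pl
    }
  }
  structure(list(planes = planes, pair_list = pairs, bins = as.integer(bins),
                 normalization = normalize, sample_id = em$sample_id),
            class = "density_image")
}

bin_index <- function(v, range, bins) {
  i <- floor((v - range[1]) / (range[2] - range[1]) * bins) + 1L
  pmin(pmax(i, 1L), bins)
}

#' Patient-classifier configuration
#'
#' @param variant `"resnet_tiny"` (desk-scale default, ~10 weighted layers)
#'   or `"resnet50"` (the 50-weight-layer bottleneck stack).
#' @param learning_rate,max_epochs,batch_size,optimizer,seed,patience As in
#'   [everflow_config()]; the training protocol is shared across phases.
#' @param bins,pairs Density-image geometry (Phase I).
#' @return A `patient_config`.
#' @export
patient_config <- function(variant = c("resnet_tiny", "resnet50"),
                           learning_rate = 5e-3, max_epochs = 75L,
                           batch_size = 16L,
                           optimizer = c("ranger", "adam"),
                           seed = 1L, patience = 10L,
                           bins = 64L, pairs = default_density_pairs()) {
  variant <- match.arg(variant)
  optimizer <- match.arg(optimizer)
  structure(list(variant = variant, learning_rate = learning_rate,
                 max_epochs = as.integer(max_epochs),
                 batch_size = as.integer(batch_size), optimizer = optimizer,
                 seed = as.integer(seed), patience = as.integer(patience),
                 bins = as.integer(bins), pairs = pairs),
            class = "patient_config")
}

# residual 2-D block: conv-bn-relu-conv-bn (+ projection shortcut on shape
# change), final ReLU applied by the block wrapper
res2d_block <- function(in_ch, out_ch, stride) {
  body <- list(layer_conv2d(in_ch, out_ch, 3L, stride = stride),
               layer_bn(out_ch, ndim = 3L),
               layer_relu(),
               layer_conv2d(out_ch, out_ch, 3L),
               layer_bn(out_ch, ndim = 3L))
  shortcut <- if (stride != 1L || in_ch != out_ch)
    list(layer_conv2d(in_ch, out_ch, 1L, stride = stride, pad = 0L),
         layer_bn(out_ch, ndim = 3L))
  else list()
  layer_residual(body, shortcut)
}

# bottleneck block (1x1 reduce, 3x3, 1x1 expand), the ResNet-50 unit
bottleneck2d_block <- function(in_ch, mid_ch, out_ch, stride) {
  body <- list(layer_conv2d(in_ch, mid_ch, 1L, pad = 0L),
               layer_bn(mid_ch, ndim = 3L), layer_relu(),
               layer_conv2d(mid_ch, mid_ch, 3L, stride = stride),
               layer_bn(mid_ch, ndim = 3L), layer_relu(),
               layer_conv2d(mid_ch, out_ch, 1L, pad = 0L),
               layer_bn(out_ch, ndim = 3L))
  shortcut <- if (stride != 1L || in_ch != out_ch)
    list(layer_conv2d(in_ch, out_ch, 1L, stride = stride, pad = 0L),
         layer_bn(out_ch, ndim = 3L))
  else list()
  layer_residual(body, shortcut)
}

build_patient_cnn <- function(variant, in_ch, n_classes = 5L) {
  if (variant == "resnet_tiny") {
    layers <- list(
      layer_conv2d(in_ch, 8L, 3L, stride = 2L),
      layer_bn(8L, ndim = 3L), layer_relu(),
      res2d_block(8L, 16L, stride = 2L),
      res2d_block(16L, 32L, stride = 2L),
      layer_gap2d(),
      layer_linear(32L, n_classes))
  } else {
    widths <- list(c(64L, 256L), c(128L, 512L), c(256L, 1024L), c(512L, 2048L))
    reps <- c(3L, 4L, 6L, 3L)
    layers <- list(layer_conv2d(in_ch, 64L, 7L, stride = 2L, pad = 3L),
                   layer_bn(64L, ndim = 3L), layer_relu())
    ch <- 64L
    for (s in seq_along(reps)) {
      for (r in seq_len(reps[s])) {
        stride <- if (r == 1L && s > 1L) 2L else 1L
        layers <- c(layers, list(
          bottleneck2d_block(ch, widths[[s]][1], widths[[s]][2], stride)))
        ch <- widths[[s]][2]
      }
    }
    layers <- c(layers, list(layer_gap2d(), layer_linear(ch, n_classes)))
  }
  layers
}

# residual dense stack for 1-D feature input (Phase III)
res_dense_block <- function(width) {
  layer_residual(list(layer_linear(width, width), layer_bn(width, ndim = 1L),
                      layer_relu(),
                      layer_linear(width, width), layer_bn(width, ndim = 1L)))
}

build_patient_mlp <- function(variant, in_dim, n_classes = 5L, width = 64L) {
  n_blocks <- if (variant == "resnet_tiny") 2L else 16L
  layers <- list(layer_linear(in_dim, width), layer_bn(width, ndim = 1L),
                 layer_relu())
  for (b in seq_len(n_blocks)) layers <- c(layers, list(res_dense_block(width)))
  c(layers, list(layer_linear(width, n_classes)))
}

#' Count weighted layers of a patient classifier
#'
#' Convolutional plus fully-connected layers on the main path (shortcut
#' projections excluded), the convention behind names like "50-layer".
#'
#' @param model A `patient_classifier`.
#' @return Integer count.
#' @export
n_weight_layers <- function(model) {
  count <- function(layers) {
    s <- 0L
    for (l in layers) {
      if (l$type %in% c("conv1d", "conv2d", "linear")) s <- s + 1L
      if (l$type == "residual") s <- s + count(l$body)
    }
    s
  }
  count(model$layers)
}

new_patient_classifier <- function(layers, input_mode, config, extra = list()) {
  structure(c(list(layers = layers, input_mode = input_mode, config = config,
                   class_order = diagnosis_levels(), history = NULL,
                   trained = FALSE), extra),
            class = "patient_classifier")
}

#' @export
print.patient_classifier <- function(x, ...) {
  cat(sprintf("<patient_classifier> %s on %s input: %d weighted layers; %s\n",
              x$config$variant, x$input_mode, n_weight_layers(x),
              if (x$trained) "trained" else "untrained"))
  invisible(x)
}

manifest_density_images <- function(manifest, config) {
  ims <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    em <- read_fcs(manifest$fcs_path[i])
    ims[[i]] <- render_density_image(em, pairs = config$pairs,
                                     bins = config$bins)
  }
  x <- array(0, c(length(ims), length(config$pairs), config$bins, config$bins))
  for (i in seq_along(ims)) x[i, , , ] <- ims[[i]]$planes
  x
}

#' Train the Phase I patient classifier from raw event clouds
#'
#' Renders every manifest sample into a density image and fits the residual
#' CNN over the five diagnosis groups.
#'
#' @param manifest Manifest data.frame ([read_manifest()]) or path; only the
#'   rows given in `train_ids` (if any) are used.
#' @param config A [patient_config()].
#' @param train_ids Optional sample_id subset.
#' @param verbose Print per-epoch progress.
#' @return A trained `patient_classifier` (`input_mode = "density_image"`).
#' @export
train_phase1 <- function(manifest, config = patient_config(),
                         train_ids = NULL, verbose = FALSE) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  if (!is.null(train_ids))
    manifest <- manifest[manifest$sample_id %in% train_ids, , drop = FALSE]
  if (length(unique(manifest$diagnosis)) < 2L)
    stop_degenerate("need at least two diagnoses to train")
  x <- manifest_density_images(manifest, config)
  y <- match(manifest$diagnosis, diagnosis_levels())
  set.seed(config$seed)
  layers <- build_patient_cnn(config$variant, in_ch = length(config$pairs))
  fit <- train_network(layers, x, y, n_classes = 5L,
                       lr = config$learning_rate,
                       max_epochs = config$max_epochs,
                       batch_size = config$batch_size,
                       optimizer = config$optimizer,
                       patience = config$patience,
                       seed = config$seed, verbose = verbose)
  model <- new_patient_classifier(fit$layers, "density_image", config)
  model$history <- fit$history
  model$trained <- TRUE
  model
}

#' Train the Phase III patient classifier from composition features
#'
#' @param features Numeric matrix, one row per patient: 16 composition
#'   fractions, or 16 + 192 with per-class channel summaries (see
#'   [composition_features()]).
#' @param diagnoses Character vector of [diagnosis_levels()] per row.
#' @param with_summaries Whether `features` includes the 192 channel
#'   summaries (checked against the feature dimension).
#' @param config A [patient_config()].
#' @param verbose Print per-epoch progress.
#' @return A trained `patient_classifier` (`input_mode = "composition"` or
#'   `"composition+summaries"`).
#' @export
train_phase3 <- function(features, diagnoses, with_summaries = FALSE,
                         config = patient_config(), verbose = FALSE) {
  features <- as.matrix(features)
  expected <- if (with_summaries) 16L + 192L else 16L
  if (ncol(features) != expected)
    stop_config(sprintf("expected %d features (with_summaries=%s), got %d",
                        expected, with_summaries, ncol(features)))
  if (nrow(features) != length(diagnoses))
    stop_alignment("one diagnosis per feature row required")
  if (length(unique(diagnoses)) < 2L)
    stop_degenerate("need at least two diagnoses to train")
  y <- match(diagnoses, diagnosis_levels())
  set.seed(config$seed)
  layers <- build_patient_mlp(config$variant, in_dim = ncol(features))
  fit <- train_network(layers, features, y, n_classes = 5L,
                       lr = config$learning_rate,
                       max_epochs = config$max_epochs,
                       batch_size = config$batch_size,
                       optimizer = config$optimizer,
                       patience = config$patience,
                       seed = config$seed, verbose = verbose)
  mode <- if (with_summaries) "composition+summaries" else "composition"
  model <- new_patient_classifier(fit$layers, mode, config)
  model$history <- fit$history
  model$trained <- TRUE
  model
}

#' Predict a patient's diagnosis
#'
#' @param model Trained `patient_classifier`.
#' @param input A [render_density_image()] result (density-image models) or
#'   a feature vector/matrix (composition models).
#' @return For a single sample, list with `label` and `prob` (5-vector,
#'   summing to 1; argmax ties go to the lowest class index). For a feature
#'   matrix, list with `labels` and `prob` matrix.
#' @export
predict_patient <- function(model, input) {
  stopifnot(inherits(model, "patient_classifier"))
  if (model$input_mode == "density_image") {
    if (!inherits(input, "density_image"))
      stop_config("this model expects a density_image input")
    d <- dim(input$planes)
    if (d[1] != length(model$config$pairs) || d[2] != model$config$bins)
      stop_panel_mismatch("density image geometry does not match the model")
    x <- array(input$planes, c(1L, d))
  } else {
    x <- if (is.null(dim(input))) matrix(input, nrow = 1) else as.matrix(input)
    want <- if (model$input_mode == "composition") 16L else 208L
    if (ncol(x) != want)
      stop_config(sprintf("this model expects %d features, got %d",
                          want, ncol(x)))
  }
  fw <- nn_forward(model$layers, x, training = FALSE)
  prob <- softmax_rows(fw$out)
  colnames(prob) <- model$class_order
  labels <- model$class_order[max.col(prob, ties.method = "first")]
  if (nrow(prob) == 1L) list(label = labels[1], prob = prob[1, ])
  else list(labels = labels, prob = prob)
}
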