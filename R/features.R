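#' Transform raw intensities for modeling
#'
#' Fluorescence channels get the variance-stabilizing transform
#' `asinh(x / cofactor)` (cofactor 150, the usual choice for conventional
#' fluorescence cytometry); scatter channels are scaled linearly to `[0, 1]`
#' by a fixed instrument range so that images and features are comparable
#' across samples.
#'
#' @param em An [event_matrix()], or a bare numeric matrix in panel order.
#' @param panel Channel panel (used when `em` is a bare matrix).
#' @param cofactor arcsinh cofactor for fluorescence channels.
#' @param scatter_range Full-scale instrument range for scatter channels.
#' @return Numeric matrix of transformed intensities, same shape and order.
#' @export
transform_events <- function(em, panel = alot_panel(), cofactor = 150,
                             scatter_range = 262144) {
  if (inherits(em, "event_matrix")) {
    panel <- em$panel
    x <- em$values
  } else {
    x <- as.matrix(em)
  }
  if (ncol(x) != length(panel$names))
    stop_panel_mismatch("matrix width does not match the panel")
  sc <- which(panel$roles == "scatter")
  fl <- which(panel$roles == "fluorescence")
  if (any(x[, sc] < 0))
    stop_format("negative scatter intensities are outside the instrument range")
  out <- x
  out[, fl] <- asinh(x[, fl] / cofactor)
  out[, sc] <- x[, sc] / scatter_range
  colnames(out) <- panel$names
  out
}

# inverse of transform_events, used by the simulator to emit instrument units
untransform_events <- function(x, panel = alot_panel(), cofactor = 150,
                               scatter_range = 262144) {
  sc <- which(panel$roles == "scatter")
  fl <- which(panel$roles == "fluorescence")
  out <- x
  out[, fl] <- sinh(x[, fl]) * cofactor
  out[, sc] <- x[, sc] * scatter_range
  out
}

#' Cellular composition of a sample
#'
#' Counts per-event labels into the fixed 16-class order and returns exact
#' class fractions. The composition is the Phase III patient-level feature
#' vector.
#'
#' @param labels Character vector of per-event labels from [cell_types()].
#' @param sample_id Optional sample identifier.
#' @return A `composition_vector`: list with `sample_id`, `fractions`
#'   (16-vector summing to 1), and `counts` (16-vector of integers).
#' @export
composition_vector <- function(labels, sample_id = NA_character_) {
  if (!length(labels)) stop_format("empty label vector")
  check_labels(labels)
  cls <- cell_types()
  counts <- as.integer(table(factor(labels, levels = cls)))
  structure(list(sample_id = sample_id,
                 fractions = stats::setNames(counts / length(labels), cls),
                 counts = stats::setNames(counts, cls)),
            class = "composition_vector")
}

#' @export
print.composition_vector <- function(x, ...) {
  cat(sprintf("<composition_vector> sample '%s', %d events\n",
              x$sample_id, sum(x$counts)))
  nz <- x$fractions[x$fractions > 0]
  print(round(nz, 4))
  invisible(x)
}

#' Per-class channel summaries
#'
#' For each of the 16 cell classes, the column-wise median of the transformed
#' intensities of that class's events: a fixed-shape 16 x 12 matrix. Classes
#' absent from the sample get a zero row and a `FALSE` presence flag rather
#' than imputed values, so downstream models can learn absence.
#'
#' @param em An [event_matrix()] (transformed internally).
#' @param labels Per-event labels aligned to `em` rows.
#' @return List with `summary` (16 x 12 matrix of medians) and `present`
#'   (logical 16-vector).
#' @export
channel_summaries <- function(em, labels) {
  x <- transform_events(em)
  if (length(labels) != nrow(x))
    stop_alignment(sprintf("%d labels for %d events", length(labels), nrow(x)))
  check_labels(labels)
  cls <- cell_types()
  out <- matrix(0, nrow = length(cls), ncol = ncol(x),
                dimnames = list(cls, colnames(x)))
  present <- stats::setNames(rep(FALSE, length(cls)), cls)
  for (k in seq_along(cls)) {
    rows <- labels == cls[k]
    if (any(rows)) {
      out[k, ] <- apply(x[rows, , drop = FALSE], 2, stats::median)
      present[k] <- TRUE
    }
  }
  list(summary = out, present = present)
}

#' Assemble the Phase III feature vector for one sample
#'
#' Either the 16 composition fractions alone, or those fractions concatenated
#' with the flattened 16 x 12 per-class median summary (16 + 192 = 208
#' features).
#'
#' @param comp A [composition_vector()].
#' @param summaries Optional result of [channel_summaries()].
#' @return Named numeric feature vector.
#' @export
composition_features <- function(comp, summaries = NULL) {
  stopifnot(inherits(comp, "composition_vector"))
  feats <- comp$fractions
  if (!is.null(summaries)) {
    s <- t(summaries$summary)  # flatten class-major: 12 channels per class
    nm <- as.vector(outer(colnames(summaries$summary),
                          rownames(summaries$summary),
                          function(ch, cl) paste(cl, ch, sep = ".")))
    feats <- c(feats, stats::setNames(as.vector(s), nm))
  }
  feats
}
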