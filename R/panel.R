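#' The ALOT channel panel
#'
#' The acute leukemia orientation tube (ALOT) is an 8-antibody EuroFlow
#' screening panel. Each acquired event carries 12 channels: eight
#' fluorescence intensities (marker-fluorochrome pairs) plus four light
#' scatter parameters (FSC-A, FSC-H, SSC-A, SSC-H).
#'
#' @param names Character vector of 12 unique channel identifiers.
#' @param roles Character vector tagging each channel `"fluorescence"` or
#'   `"scatter"`; exactly 8 fluorescence and 4 scatter channels are required.
#' @return A `channel_panel` object.
#' @export
channel_panel <- function(names, roles) {
  if (length(names) != 12L || length(roles) != 12L)
    stop_panel_mismatch("a channel panel has exactly 12 channels")
  if (anyDuplicated(names))
    stop_panel_mismatch("channel names must be unique")
  if (!all(roles %in% c("fluorescence", "scatter")))
    stop_panel_mismatch("roles must be 'fluorescence' or 'scatter'")
  if (sum(roles == "fluorescence") != 8L || sum(roles == "scatter") != 4L)
    stop_panel_mismatch("panel must have 8 fluorescence and 4 scatter channels")
  structure(list(names = as.character(names), roles = as.character(roles)),
            class = "channel_panel")
}

#' @describeIn channel_panel The standard ALOT panel in fixed acquisition
#'   order: CyCD3-PacB, CD45-KrO, CyMPO-FITC, CyCD79a-PE, CD34-PerCP-Cy5.5,
#'   CD19-PC7, CD7-APC, SmCD3-APCH7, then FSC-A, FSC-H, SSC-A, SSC-H.
#' @export
alot_panel <- function() {
  channel_panel(
    names = c("CyCD3-PacB", "CD45-KrO", "CyMPO-FITC", "CyCD79a-PE",
              "CD34-PerCP-Cy5.5", "CD19-PC7", "CD7-APC", "SmCD3-APCH7",
              "FSC-A", "FSC-H", "SSC-A", "SSC-H"),
    roles = c(rep("fluorescence", 8), rep("scatter", 4))
  )
}

# Case-insensitive substring aliases used to map vendor $PnS/$PnN values onto
# panel channels. First column: panel name; remaining entries: accepted
# substrings (lower case).
panel_alias_table <- function() {
  list(
    "CyCD3-PacB"       = c("cycd3", "cd3-pacb", "cd3 pacb", "cd3-v450", "pacific blue cd3"),
    "CD45-KrO"         = c("cd45", "kro", "krome orange"),
    "CyMPO-FITC"       = c("mpo", "cympo"),
    "CyCD79a-PE"       = c("cd79a", "cycd79a"),
    "CD34-PerCP-Cy5.5" = c("cd34"),
    "CD19-PC7"         = c("cd19"),
    "CD7-APC"          = c("cd7-apc", "cd7 apc", "cd7apc", "cd7"),
    "SmCD3-APCH7"      = c("smcd3", "cd3-apch7", "cd3 apc-h7", "cd3-apc-h7"),
    "FSC-A"            = c("fsc-a", "fsc a", "fsca"),
    "FSC-H"            = c("fsc-h", "fsc h", "fsch"),
    "SSC-A"            = c("ssc-a", "ssc a", "ssca"),
    "SSC-H"            = c("ssc-h", "ssc h", "ssch")
  )
}

#' The 16 ALOT cell-type labels
#'
#' Nine physiological populations, a debris class, and six pathological
#' populations, in the fixed order used throughout the package (class index
#' 1..16 is stable; model outputs, composition vectors and summary matrices
#' all follow it).
#'
#' @return Character vector of the 16 class names.
#' @export
cell_types <- function() {
  c("B-lym", "T-lym", "Neu", "Mono", "Ery", "Eos", "NK",
    "CD34posM", "CD34posB", "debris",
    "AML-CD34pos", "AML-CD34neg", "B-ALL-CD34pos", "B-ALL-CD34neg",
    "T-ALL", "BCLPD")
}

#' @describeIn cell_types The nine physiological cell types.
#' @export
physiological_types <- function() cell_types()[1:9]

#' @describeIn cell_types The six pathological cell types.
#' @export
pathological_types <- function() cell_types()[11:16]

#' The five patient diagnosis groups
#'
#' Fixed order: Normal, AML, B-ALL, Complex (possible myelodysplasia,
#' recommended for follow-up with a dedicated AML/MDS tube), Other
#' (T-ALL, lymphoma, myeloma and other diagnoses).
#'
#' @return Character vector of length 5.
#' @export
diagnosis_levels <- function() c("Normal", "AML", "B-ALL", "Complex", "Other")

#' Build an event matrix
#'
#' An `event_matrix` holds one sample's events-by-channel intensity matrix in
#' instrument units, together with its channel panel. Intensities must be
#' finite; event count is capped (250,000 by default, the usual ALOT
#' acquisition stop).
#'
#' @param sample_id Sample identifier string.
#' @param values Numeric matrix, `n_events x 12`, finite, columns in panel
#'   order.
#' @param panel A [channel_panel()]; defaults to [alot_panel()].
#' @param max_events Hard cap on rows.
#' @return An `event_matrix`.
#' @export
event_matrix <- function(sample_id, values, panel = alot_panel(),
                         max_events = 250000L) {
  values <- as.matrix(values)
  if (!is.numeric(values) || ncol(values) != 12L)
    stop_panel_mismatch("event values must be a numeric matrix with 12 columns")
  if (nrow(values) < 1L)
    stop_format("an event matrix needs at least one event")
  if (nrow(values) > max_events)
    stop_cap_exceeded(sprintf("%d events exceed the cap of %d",
                              nrow(values), max_events))
  if (!all(is.finite(values)))
    stop_format("event intensities must be finite (no NA/NaN/Inf)")
  colnames(values) <- panel$names
  structure(list(sample_id = as.character(sample_id),
                 values = values, panel = panel),
            class = "event_matrix")
}

#' @export
print.event_matrix <- function(x, ...) {
  cat(sprintf("<event_matrix> sample '%s': %d events x %d channels\n",
              x$sample_id, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @export
dim.event_matrix <- function(x) dim(x$values)

n_events <- function(em) nrow(em$values)

check_labels <- function(labels) {
  bad <- setdiff(unique(labels), cell_types())
  if (length(bad))
    stop_unknown_label(paste0("unknown cell-type label(s): ",
                              paste(bad, collapse = ", ")))
  invisible(labels)
}
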