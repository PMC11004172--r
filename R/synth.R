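# Synthetic ALOT cohort simulator. Each cell type is a Gaussian cluster in
# transformed space (arcsinh for fluorescence, unit-range for scatter),
# truncated at zero; each diagnosis is a Dirichlet prior over the 16-class
# composition. This gives every downstream stage a fully reproducible,
# label-complete stand-in for patient data.

#' Build a cell-type intensity template
#'
#' @param label One of [cell_types()].
#' @param location Numeric 12-vector of mean transformed intensity.
#' @param scale Positive 12-vector of per-channel standard deviations.
#' @param correlation Optional 12 x 12 symmetric positive-definite channel
#'   correlation matrix (identity when `NULL`).
#' @return A `cell_type_template`.
#' @export
cell_type_template <- function(label, location, scale, correlation = NULL) {
  stopifnot(label %in% cell_types(), length(location) == 12L,
            length(scale) == 12L)
  if (any(scale <= 0)) stop_config("template scale must be positive")
  if (!is.null(correlation)) {
    if (!isSymmetric(unname(correlation)) ||
        any(eigen(correlation, symmetric = TRUE, only.values = TRUE)$values <= 0))
      stop_config("correlation must be symmetric positive-definite")
  }
  structure(list(label = label, location = as.numeric(location),
                 scale = as.numeric(scale), correlation = correlation),
            class = "cell_type_template")
}

# transformed-space intensity levels for fluorescence (arcsinh units) and
# scatter (fraction of full range)
FL_NEG <- 0.4; FL_DIM <- 2.2; FL_POS <- 4.2; FL_HI <- 5.2
FL_SD <- 0.35; SC_SD <- 0.05

tmpl_loc <- function(CyCD3 = FL_NEG, CD45 = FL_NEG, MPO = FL_NEG,
                     CD79a = FL_NEG, CD34 = FL_NEG, CD19 = FL_NEG,
                     CD7 = FL_NEG, SmCD3 = FL_NEG,
                     FSCA = 0.35, FSCH = 0.33, SSCA = 0.15, SSCH = 0.14) {
  c(CyCD3, CD45, MPO, CD79a, CD34, CD19, CD7, SmCD3, FSCA, FSCH, SSCA, SSCH)
}

CD34_CHANNEL <- 5L

#' Default ALOT cell-type templates
#'
#' Sixteen templates encoding canonical ALOT marker logic: T cells
#' SmCD3+/CyCD3+/CD7+/CD45-high, B cells CD19+/CyCD79a+/CD45-high,
#' neutrophils MPO+/SSC-high, erythroid CD45-negative/low-scatter, NK
#' CD7+/SmCD3-, myeloid and B precursors CD34+/CD45-dim, T-ALL
#' CyCD3+/CD7+/SmCD3-/CD45-negative, and so on. The deliberately hard cases
#' — BCLPD overlapping mature B cells, and CD34-negative blasts overlapping
#' their physiological counterparts — sit at a distance controlled by
#' `separation`: 1 is the default (moderately separated) geometry; values
#' near 0 collapse each pathological template onto its physiological
#' confounder.
#'
#' @param separation Non-negative scalar scaling the offset of the
#'   confusable pathological templates from their anchors.
#' @return Named list of 16 [cell_type_template()]s in [cell_types()] order.
#' @export
default_templates <- function(separation = 1) {
  if (separation < 0) stop_config("separation must be non-negative")
  sd12 <- c(rep(FL_SD, 8), rep(SC_SD, 4))
  loc <- list(
    "B-lym" = tmpl_loc(CD45 = FL_HI, CD79a = FL_POS, CD19 = FL_POS),
    "T-lym" = tmpl_loc(CyCD3 = FL_POS, CD45 = FL_HI, CD7 = FL_POS,
                       SmCD3 = FL_POS),
    "Neu"   = tmpl_loc(CD45 = 4.0, MPO = FL_POS,
                       FSCA = 0.55, FSCH = 0.52, SSCA = 0.65, SSCH = 0.62),
    "Mono"  = tmpl_loc(CD45 = 5.0, MPO = FL_DIM,
                       FSCA = 0.60, FSCH = 0.57, SSCA = 0.35, SSCH = 0.33),
    "Ery"   = tmpl_loc(FSCA = 0.18, FSCH = 0.17, SSCA = 0.08, SSCH = 0.08),
    "Eos"   = tmpl_loc(CD45 = FL_POS, MPO = 3.2,
                       FSCA = 0.55, FSCH = 0.52, SSCA = 0.85, SSCH = 0.82),
    "NK"    = tmpl_loc(CD45 = FL_HI, CD7 = FL_POS, SSCA = 0.16, SSCH = 0.15),
    "CD34posM" = tmpl_loc(CD45 = FL_DIM, MPO = 3.0, CD34 = FL_POS,
                          FSCA = 0.45, FSCH = 0.43, SSCA = 0.30, SSCH = 0.28),
    "CD34posB" = tmpl_loc(CD45 = FL_DIM, CD79a = 3.6, CD34 = FL_POS,
                          CD19 = 3.8,
                          FSCA = 0.30, FSCH = 0.28, SSCA = 0.14, SSCH = 0.13),
    "debris" = tmpl_loc(CyCD3 = 0.8, CD45 = 0.8, MPO = 0.8, CD79a = 0.8,
                        CD34 = 0.8, CD19 = 0.8, CD7 = 0.8, SmCD3 = 0.8,
                        FSCA = 0.06, FSCH = 0.06, SSCA = 0.05, SSCH = 0.05)
  )
  scl <- lapply(loc, function(l) sd12)
  scl[["debris"]] <- c(rep(0.8, 8), rep(0.04, 4))

  # Pathological templates are anchored on their clinical confounders and
  # pulled away by `separation`: CD34+ blasts on the physiological CD34+
  # precursor, CD34- blasts on the mature population they get mistaken for
  # (monocytic cells for AML, mature B cells for B-ALL). At separation 1
  # each CD34- blast equals its CD34+ counterpart except on CD34; as
  # separation -> 0 every blast collapses onto its confounder.
  delta_aml <- tmpl_loc(MPO = 0.5, CD7 = 0.8, FSCA = 0.06, FSCH = 0.06,
                        SSCA = 0.12, SSCH = 0.12) -
               tmpl_loc()
  loc[["AML-CD34pos"]] <- loc[["CD34posM"]] + separation * delta_aml
  aml_neg_target <- loc[["AML-CD34pos"]]
  aml_neg_target[CD34_CHANNEL] <- FL_NEG
  loc[["AML-CD34neg"]] <- if (separation == 1) aml_neg_target else
    loc[["Mono"]] + separation * (aml_neg_target - loc[["Mono"]])

  delta_ball <- tmpl_loc(CD45 = -0.9, CD79a = 0.6, CD19 = 0.5,
                         FSCA = 0.05, FSCH = 0.05) - tmpl_loc()
  loc[["B-ALL-CD34pos"]] <- loc[["CD34posB"]] + separation * delta_ball
  ball_neg_target <- loc[["B-ALL-CD34pos"]]
  ball_neg_target[CD34_CHANNEL] <- FL_NEG
  loc[["B-ALL-CD34neg"]] <- if (separation == 1) ball_neg_target else
    loc[["B-lym"]] + separation * (ball_neg_target - loc[["B-lym"]])

  loc[["T-ALL"]] <- tmpl_loc(CyCD3 = 3.6, CD45 = 0.5, CD34 = FL_DIM,
                             CD7 = 3.8,
                             FSCA = 0.32, FSCH = 0.30, SSCA = 0.14,
                             SSCH = 0.13)

  delta_bclpd <- tmpl_loc(CD45 = -1.2, CD19 = 0.7, FSCA = -0.03) - tmpl_loc()
  loc[["BCLPD"]] <- loc[["B-lym"]] + separation * delta_bclpd

  for (p in pathological_types()) scl[[p]] <- sd12
  lapply(stats::setNames(cell_types(), cell_types()), function(cl)
    cell_type_template(cl, loc[[cl]], scl[[cl]]))
}

#' Draw events from a cell-type template
#'
#' Samples a truncated-at-zero Gaussian in transformed space and
#' back-transforms to instrument units. Deterministic given `seed`.
#'
#' @param template A [cell_type_template()].
#' @param n Number of events (>= 1).
#' @param seed Integer RNG seed.
#' @param noise_sd_multiplier Scales all template standard deviations;
#'   0 collapses every event onto the template location.
#' @param panel Channel panel.
#' @return List with `values` (n x 12 instrument-unit matrix) and `labels`
#'   (constant character vector).
#' @export
sample_events <- function(template, n, seed = 1L, noise_sd_multiplier = 1,
                          panel = alot_panel()) {
  if (n <= 0) stop_config("n must be >= 1")
  set.seed(seed)
  z <- matrix(stats::rnorm(n * 12L), nrow = n)
  if (!is.null(template$correlation)) {
    z <- z %*% chol(template$correlation)
  }
  x <- sweep(z, 2, template$scale * noise_sd_multiplier, `*`)
  x <- sweep(x, 2, template$location, `+`)
  x <- pmax(x, 0)  # transformed intensities are non-negative
  vals <- untransform_events(x, panel = panel)
  list(values = vals, labels = rep(template$label, n))
}

#' Diagnosis phenotype: a Dirichlet prior over cell composition
#'
#' @param diagnosis One of [diagnosis_levels()].
#' @param composition_alpha Named non-negative 16-vector of Dirichlet
#'   concentrations in [cell_types()] order; zero excludes a class.
#' @return A `phenotype_spec`.
#' @export
phenotype_spec <- function(diagnosis, composition_alpha) {
  stopifnot(diagnosis %in% diagnosis_levels())
  a <- rep(0, 16); names(a) <- cell_types()
  a[names(composition_alpha)] <- composition_alpha
  if (any(a < 0) || !any(a > 0))
    stop_config("composition_alpha needs at least one positive entry")
  structure(list(diagnosis = diagnosis, composition_alpha = a),
            class = "phenotype_spec")
}

#' Default diagnosis phenotypes
#'
#' Normal marrow/blood is neutrophil-dominated with rare CD34+ precursors;
#' AML and B-ALL carry a large blast burden (mostly CD34-positive);
#' Complex is a Normal-like composition with an abnormal CD34+ myeloid
#' excess (the possible-myelodysplasia group); Other mixes T-ALL and mature
#' B-cell neoplasm (BCLPD) compositions.
#'
#' @return Named list of [phenotype_spec()]s, one per diagnosis.
#' @export
default_phenotypes <- function() {
  list(
    Normal = phenotype_spec("Normal", c(
      "B-lym" = 6, "T-lym" = 12, "Neu" = 40, "Mono" = 6, "Ery" = 8,
      "Eos" = 2, "NK" = 2, "CD34posM" = 0.5, "CD34posB" = 0.3,
      "debris" = 8)),
    AML = phenotype_spec("AML", c(
      "B-lym" = 3, "T-lym" = 6, "Neu" = 15, "Mono" = 4, "Ery" = 5,
      "Eos" = 1, "NK" = 1, "CD34posM" = 1, "CD34posB" = 0.2, "debris" = 6,
      "AML-CD34pos" = 20, "AML-CD34neg" = 8)),
    "B-ALL" = phenotype_spec("B-ALL", c(
      "B-lym" = 2, "T-lym" = 5, "Neu" = 12, "Mono" = 3, "Ery" = 4,
      "Eos" = 1, "NK" = 1, "CD34posM" = 0.5, "CD34posB" = 0.3, "debris" = 5,
      "B-ALL-CD34pos" = 22, "B-ALL-CD34neg" = 8)),
    Complex = phenotype_spec("Complex", c(
      "B-lym" = 6, "T-lym" = 12, "Neu" = 35, "Mono" = 6, "Ery" = 8,
      "Eos" = 2, "NK" = 2, "CD34posM" = 6, "CD34posB" = 0.5, "debris" = 8)),
    Other = phenotype_spec("Other", c(
      "B-lym" = 4, "T-lym" = 8, "Neu" = 20, "Mono" = 4, "Ery" = 6,
      "Eos" = 1, "NK" = 2, "CD34posM" = 0.5, "CD34posB" = 0.3, "debris" = 6,
      "T-ALL" = 10, "BCLPD" = 8))
  )
}

#' Simulator configuration
#'
#' @param n_patients_per_diagnosis Named integer vector (subset of
#'   [diagnosis_levels()]).
#' @param n_events Events per patient (default 20,000; hard cap 250,000).
#' @param seed Global integer seed; per-patient seeds derive from it via a
#'   counter scheme so each patient is independently reproducible.
#' @param templates List of 16 [cell_type_template()]s.
#' @param phenotypes Named list of [phenotype_spec()]s.
#' @param noise_sd_multiplier Global noise scale.
#' @return A `sim_config`.
#' @export
sim_config <- function(n_patients_per_diagnosis = c(Normal = 64, AML = 41,
                                                    "B-ALL" = 43,
                                                    Complex = 60, Other = 33),
                       n_events = 20000L, seed = 1L,
                       templates = default_templates(),
                       phenotypes = default_phenotypes(),
                       noise_sd_multiplier = 1) {
  if (n_events > 250000L) stop_cap_exceeded("n_events exceeds the 250,000 cap")
  if (n_events < 1L) stop_config("n_events must be >= 1")
  if (!all(names(n_patients_per_diagnosis) %in% diagnosis_levels()))
    stop_unknown_label("unknown diagnosis in n_patients_per_diagnosis")
  structure(list(n_patients_per_diagnosis = n_patients_per_diagnosis,
                 n_events = as.integer(n_events), seed = as.integer(seed),
                 templates = templates, phenotypes = phenotypes,
                 noise_sd_multiplier = noise_sd_multiplier),
            class = "sim_config")
}

# counter-based per-patient seed stream; stays below 2^31-1
patient_seed <- function(global_seed, index) {
  m <- 2147483647
  as.integer((((global_seed %% m) * 48271) %% m + (index * 69621) %% m) %% m)
}

rdirichlet1 <- function(alpha) {
  g <- ifelse(alpha > 0, stats::rgamma(length(alpha), shape = alpha), 0)
  g / sum(g)
}

#' Simulate one patient
#'
#' Draws a composition from the phenotype's Dirichlet prior, class counts
#' from a multinomial, per-class events from the templates, and shuffles the
#' events with a recorded permutation.
#'
#' @param spec A [phenotype_spec()].
#' @param n_events Events to generate.
#' @param seed Integer seed.
#' @param templates Cell-type templates.
#' @param noise_sd_multiplier Noise scale.
#' @param sample_id Sample identifier.
#' @return List: `em` ([event_matrix()]), `labels`, `diagnosis`,
#'   `composition` (the drawn Dirichlet fractions), `permutation`.
#' @export
simulate_patient <- function(spec, n_events = 20000L, seed = 1L,
                             templates = default_templates(),
                             noise_sd_multiplier = 1,
                             sample_id = "sim") {
  stopifnot(inherits(spec, "phenotype_spec"))
  set.seed(seed)
  p <- rdirichlet1(spec$composition_alpha)
  counts <- as.integer(stats::rmultinom(1, n_events, p))
  names(counts) <- cell_types()
  vals <- matrix(0, nrow = n_events, ncol = 12L)
  labels <- character(n_events)
  at <- 1L
  for (k in which(counts > 0)) {
    frag <- sample_events(templates[[cell_types()[k]]], counts[k],
                          seed = patient_seed(seed, k),
                          noise_sd_multiplier = noise_sd_multiplier)
    idx <- at:(at + counts[k] - 1L)
    vals[idx, ] <- frag$values
    labels[idx] <- frag$labels
    at <- at + counts[k]
  }
  set.seed(patient_seed(seed, 17L))
  perm <- sample.int(n_events)
  list(em = event_matrix(sample_id, vals[perm, , drop = FALSE]),
       labels = labels[perm], diagnosis = spec$diagnosis,
       composition = p, permutation = perm)
}

#' Simulate a full cohort to disk
#'
#' Writes one FCS file and one label sidecar per patient, a manifest CSV
#' (`sample_id,fcs_path,label_path,diagnosis`), and a JSON config snapshot
#' including the seed. Byte-identical across runs with the same config.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory (created if needed).
#' @return Path to the manifest CSV.
#' @export
simulate_cohort <- function(config, out_dir) {
  stopifnot(inherits(config, "sim_config"))
  ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop_io(paste0("cannot create ", out_dir))
  rows <- list()
  i <- 0L
  for (dx in names(config$n_patients_per_diagnosis)) {
    for (j in seq_len(config$n_patients_per_diagnosis[[dx]])) {
      i <- i + 1L
      sid <- sprintf("S%04d_%s", i, gsub("-", "", dx))
      sim <- simulate_patient(config$phenotypes[[dx]],
                              n_events = config$n_events,
                              seed = patient_seed(config$seed, i),
                              templates = config$templates,
                              noise_sd_multiplier = config$noise_sd_multiplier,
                              sample_id = sid)
      fcs <- paste0(sid, ".fcs"); lab <- paste0(sid, "_labels.csv")
      write_fcs(sim$em, file.path(out_dir, fcs))
      write_label_sidecar(sim$labels, file.path(out_dir, lab))
      rows[[i]] <- data.frame(sample_id = sid, fcs_path = fcs,
                              label_path = lab, diagnosis = dx)
    }
  }
  manifest <- do.call(rbind, rows)
  mpath <- file.path(out_dir, "manifest.csv")
  utils::write.csv(manifest, mpath, row.names = FALSE, quote = FALSE)
  snap <- list(seed = config$seed, n_events = config$n_events,
               n_patients_per_diagnosis = as.list(config$n_patients_per_diagnosis),
               noise_sd_multiplier = config$noise_sd_multiplier,
               templates = lapply(config$templates, function(t)
                 list(label = t$label, location = t$location, scale = t$scale)),
               phenotypes = lapply(config$phenotypes, function(p)
                 list(diagnosis = p$diagnosis,
                      composition_alpha = as.list(p$composition_alpha))))
  jsonlite::write_json(snap, file.path(out_dir, "sim_config.json"),
                       auto_unbox = TRUE, digits = NA)
  mpath
}
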