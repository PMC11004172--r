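# Shared fixture builders. Everything is generated in code at test time.

random_event_matrix <- function(n = 50, seed = 1, sample_id = "fix") {
  set.seed(seed)
  vals <- cbind(matrix(abs(rnorm(n * 8)) * 300, n, 8),      # fluorescence
                matrix(runif(n * 4, 0, 262144), n, 4))      # scatter
  event_matrix(sample_id, vals)
}

# pooled transformed events drawn from the default templates
draw_class_events <- function(classes, n_per_class, seed = 1,
                              templates = default_templates()) {
  xs <- list(); ys <- list()
  for (i in seq_along(classes)) {
    frag <- sample_events(templates[[classes[i]]], n_per_class,
                          seed = seed + i)
    xs[[i]] <- transform_events(frag$values)
    ys[[i]] <- frag$labels
  }
  list(events = do.call(rbind, xs), labels = unlist(ys))
}

# in-memory synthetic cohort: list of simulate_patient() results
draw_cohort <- function(patients_per_class, n_events, seed = 1,
                        templates = default_templates(),
                        phenotypes = default_phenotypes()) {
  out <- list()
  i <- 0L
  for (dx in names(phenotypes)) {
    for (j in seq_len(patients_per_class)) {
      i <- i + 1L
      out[[i]] <- simulate_patient(
        phenotypes[[dx]], n_events = n_events,
        seed = everflow:::patient_seed(seed, i),
        templates = templates,
        sample_id = sprintf("S%03d", i))
    }
  }
  out
}

# published-cohort-shaped 241-patient manifest (no files, splitting only)
manifest_241 <- function() {
  counts <- c(Normal = 64, AML = 41, "B-ALL" = 43, Complex = 60, Other = 33)
  data.frame(
    sample_id = sprintf("P%03d", seq_len(sum(counts))),
    fcs_path = "none.fcs", label_path = "none.csv",
    diagnosis = rep(names(counts), counts))
}
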