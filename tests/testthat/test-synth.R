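test_that("default templates encode the ALOT marker logic", {
  tm <- default_templates()
  cd45 <- 2L
  expect_lt(tm[["T-ALL"]]$location[cd45], tm[["T-lym"]]$location[cd45])
  # CD34-negative AML differs from CD34-positive AML only on CD34
  same <- tm[["AML-CD34neg"]]$location == tm[["AML-CD34pos"]]$location
  expect_identical(which(!same), 5L)
  same_b <- tm[["B-ALL-CD34neg"]]$location == tm[["B-ALL-CD34pos"]]$location
  expect_identical(which(!same_b), 5L)
  # all 16 locations pairwise distinct
  locs <- t(vapply(tm, function(t) t$location, numeric(12)))
  expect_equal(nrow(unique(locs)), 16)
  # knob collapses the hard cases onto their anchors
  tm0 <- default_templates(separation = 0)
  expect_equal(tm0[["BCLPD"]]$location, tm0[["B-lym"]]$location)
  expect_equal(tm0[["AML-CD34pos"]]$location, tm0[["CD34posM"]]$location)
})

test_that("sample_events is deterministic and matches its template", {
  tm <- default_templates()
  a <- sample_events(tm[["Neu"]], 500, seed = 9)
  b <- sample_events(tm[["Neu"]], 500, seed = 9)
  expect_identical(a$values, b$values)
  expect_true(all(a$labels == "Neu"))
  # CLT: per-channel mean within ~3 standard errors of the closed-form
  # truncated-Gaussian mean E[max(X,0)] = mu*pnorm(mu/sd) + sd*dnorm(mu/sd)
  big <- sample_events(tm[["Neu"]], 10000, seed = 10)
  x <- transform_events(big$values)
  mu <- tm[["Neu"]]$location; sd <- tm[["Neu"]]$scale
  trunc_mean <- mu * pnorm(mu / sd) + sd * dnorm(mu / sd)
  se <- sd / sqrt(10000)
  expect_true(all(abs(colMeans(x) - trunc_mean) <= 3.5 * se))
  # zero noise collapses onto the location vector
  z <- sample_events(tm[["Neu"]], 5, seed = 1, noise_sd_multiplier = 0)
  zt <- transform_events(z$values)
  expect_equal(unname(zt[1, ]), tm[["Neu"]]$location, tolerance = 1e-8)
  expect_error(sample_events(tm[["Neu"]], 0), class = "ef_config_error")
})

test_that("simulate_patient draws composition, counts and labels coherently", {
  # one-hot alpha: every event is Neu
  spec <- phenotype_spec("Normal", c(Neu = 5))
  sim <- simulate_patient(spec, n_events = 200, seed = 3)
  expect_true(all(sim$labels == "Neu"))

  # empirical composition tracks the drawn Dirichlet composition
  sim2 <- simulate_patient(default_phenotypes()$AML, n_events = 20000,
                           seed = 11)
  emp <- composition_vector(sim2$labels)$fractions
  p <- sim2$composition
  bound <- 3 * sqrt(p * (1 - p) / 20000) + 1e-9
  expect_true(all(abs(emp - p) <= bound))
  expect_equal(sum(emp), 1)
  expect_equal(nrow(sim2$em$values), 20000)
})

test_that("AML patients essentially always carry blast events", {
  # P(no blast) = E[(1-p_blast)^n] under the Dirichlet prior; Monte Carlo
  # over the prior is the oracle for the configured alphas
  alpha <- default_phenotypes()$AML$composition_alpha
  blast <- c("AML-CD34pos", "AML-CD34neg")
  set.seed(42)
  pb <- replicate(2000, {
    g <- ifelse(alpha > 0, rgamma(length(alpha), alpha), 0)
    sum(g[blast]) / sum(g)
  })
  p_none <- mean((1 - pb)^20000)
  expect_lt(p_none, 0.001)
  # and an actual draw contains blasts
  sim <- simulate_patient(default_phenotypes()$AML, 20000, seed = 5)
  expect_gt(sum(sim$labels %in% blast), 0)
})

test_that("simulate_cohort writes a reproducible on-disk cohort", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  cfg <- sim_config(n_patients_per_diagnosis = c(Normal = 2, AML = 2),
                    n_events = 300, seed = 7)
  m1 <- simulate_cohort(cfg, d1)
  m2 <- simulate_cohort(cfg, d2)
  df <- read_manifest(m1)
  expect_equal(nrow(df), 4)
  expect_true(all(file.exists(df$fcs_path)))
  # byte-identical sidecars and FCS across runs with the same seed
  for (f in list.files(d1)) {
    if (f == "manifest.csv" || grepl("json$", f)) next
    expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                     readBin(file.path(d2, f), "raw", 1e6), label = f)
  }
  # labels align with FCS rows
  em <- read_fcs(df$fcs_path[1])
  labels <- read_label_sidecar(df$label_path[1], nrow(em$values))
  expect_equal(length(labels), 300)
  expect_true(all(labels %in% cell_types()))
})

test_that("a published-cohort-shaped simulation has 241 manifest rows", {
  d <- withr::local_tempdir()
  cfg <- sim_config(n_events = 20)  # tiny events; the row count is the point
  m <- simulate_cohort(cfg, d)
  expect_equal(nrow(read_manifest(m)), 241)
})

test_that("neutrophils dominate the physiological composition", {
  alpha <- default_phenotypes()$Normal$composition_alpha
  phys <- alpha[physiological_types()]
  expect_identical(names(which.max(phys)), "Neu")
})

test_that("a quadratic-discriminant oracle learns the simulator", {
  skip_if_not_installed("MASS")
  tr <- draw_class_events(cell_types(), 1000, seed = 100)
  te <- draw_class_events(cell_types(), 300, seed = 900)
  fit <- MASS::qda(tr$events, grouping = factor(tr$labels))
  pred <- as.character(predict(fit, te$events)$class)
  phys <- te$labels %in% physiological_types()
  acc <- mean(pred[phys] == te$labels[phys])
  expect_gte(acc, 0.95)
})
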