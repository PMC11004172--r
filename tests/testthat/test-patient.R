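test_that("density rendering conserves counts and normalizes to unit max", {
  # all events identical -> one nonzero bin per plane, value 1 after scaling
  vals <- matrix(rep(c(rep(100, 8), rep(1e5, 4)), each = 25), 25, 12)
  em <- event_matrix("const", vals)
  di <- render_density_image(em, bins = 32)
  for (p in 1:6) {
    plane <- di$planes[p, , ]
    expect_equal(sum(plane > 0), 1)
    expect_equal(max(plane), 1)
  }
  # raw counts per plane equal the event count
  em2 <- random_event_matrix(500, seed = 6)
  raw <- render_density_image(em2, bins = 16, normalize = "counts")
  for (p in 1:6) expect_equal(sum(raw$planes[p, , ]), 500)
  expect_error(
    render_density_image(em2, pairs = list(c("CD45-KrO", "nope"))),
    class = "ef_panel_mismatch")
})

test_that("histograms match a double-loop binning oracle", {
  for (rep in 1:20) {
    em <- random_event_matrix(sample(30:120, 1), seed = 3000 + rep)
    di <- render_density_image(em, bins = 8, normalize = "counts")
    x <- transform_events(em)
    for (p in sample(1:6, 2)) {
      pr <- di$pair_list[[p]]
      rng1 <- everflow:::channel_range(pr[1])
      rng2 <- everflow:::channel_range(pr[2])
      oracle <- matrix(0, 8, 8)
      for (i in seq_len(nrow(x))) {
        bx <- min(max(floor((x[i, pr[1]] - rng1[1]) /
                              (rng1[2] - rng1[1]) * 8) + 1, 1), 8)
        by <- min(max(floor((x[i, pr[2]] - rng2[1]) /
                              (rng2[2] - rng2[1]) * 8) + 1, 1), 8)
        oracle[bx, by] <- oracle[bx, by] + 1
      }
      expect_equal(di$planes[p, , ], oracle)
    }
  }
})

test_that("density rendering is permutation-invariant", {
  em <- random_event_matrix(200, seed = 8)
  di1 <- render_density_image(em, bins = 16)
  perm <- sample(200)
  em2 <- event_matrix(em$sample_id, em$values[perm, ])
  expect_equal(render_density_image(em2, bins = 16)$planes, di1$planes)
})

test_that("model variants have the expected weighted-layer depth", {
  cfg_t <- patient_config(variant = "resnet_tiny")
  mt <- everflow:::new_patient_classifier(
    everflow:::build_patient_cnn("resnet_tiny", 6), "density_image", cfg_t)
  expect_equal(n_weight_layers(mt), 6)  # stem + 2x2 block convs + head
  cfg_f <- patient_config(variant = "resnet50")
  mf <- everflow:::new_patient_classifier(
    everflow:::build_patient_cnn("resnet50", 6), "density_image", cfg_f)
  expect_equal(n_weight_layers(mf), 50)  # the canonical 50-layer count
})

test_that("toy one-hot compositions are perfectly separable", {
  # each diagnosis gets a distinct one-hot composition
  n <- 40
  dx <- rep(diagnosis_levels(), length.out = n)
  feats <- matrix(0, n, 16)
  for (i in seq_len(n)) feats[i, match(dx[i], diagnosis_levels())] <- 1
  cfg <- patient_config(seed = 4, max_epochs = 40, batch_size = 8)
  m <- train_phase3(feats, dx, config = cfg)
  pred <- predict_patient(m, feats)
  expect_identical(pred$labels, dx)
  expect_equal(unname(rowSums(pred$prob)), rep(1, n), tolerance = 1e-6)
})

test_that("composition-only prediction ignores the event count", {
  labels <- c(rep("Neu", 30), rep("AML-CD34pos", 20))
  comp1 <- composition_features(composition_vector(labels))
  comp2 <- composition_features(composition_vector(rep(labels, 2)))
  expect_equal(comp1, comp2)  # duplicating every event leaves fractions alone
  set.seed(5)
  feats <- matrix(runif(30 * 16), 30, 16)
  dx <- rep(diagnosis_levels(), 6)
  m <- train_phase3(feats, dx,
                    config = patient_config(seed = 1, max_epochs = 3,
                                            batch_size = 8))
  p1 <- predict_patient(m, comp1)
  p2 <- predict_patient(m, comp2)
  expect_identical(p1$label, p2$label)
  expect_equal(p1$prob, p2$prob)
})

test_that("adding channel summaries never hurts training accuracy", {
  set.seed(6)
  cohort <- draw_cohort(patients_per_class = 6, n_events = 400, seed = 33)
  f16 <- t(vapply(cohort, function(p)
    composition_features(composition_vector(p$labels)), numeric(16)))
  f208 <- t(vapply(cohort, function(p)
    composition_features(composition_vector(p$labels),
                         channel_summaries(p$em, p$labels)), numeric(208)))
  dx <- vapply(cohort, `[[`, character(1), "diagnosis")
  # compare at convergence: no early stop within the epoch budget
  cfg <- patient_config(seed = 9, max_epochs = 150, batch_size = 8,
                        patience = 150)
  m16 <- train_phase3(f16, dx, config = cfg)
  m208 <- train_phase3(f208, dx, with_summaries = TRUE, config = cfg)
  acc16 <- mean(predict_patient(m16, f16)$labels == dx)
  acc208 <- mean(predict_patient(m208, f208)$labels == dx)
  expect_gte(acc208, acc16)
})

test_that("feature dimension mismatches are rejected", {
  feats <- matrix(runif(10 * 16), 10, 16)
  dx <- rep(diagnosis_levels(), 2)
  expect_error(train_phase3(feats, dx, with_summaries = TRUE),
               class = "ef_config_error")
  m <- train_phase3(feats, dx,
                    config = patient_config(seed = 2, max_epochs = 2,
                                            batch_size = 4))
  expect_error(predict_patient(m, runif(208)), class = "ef_config_error")
})

test_that("duplicate inputs give identical predictions", {
  set.seed(10)
  feats <- matrix(runif(20 * 16), 20, 16)
  dx <- rep(diagnosis_levels(), 4)
  m <- train_phase3(feats, dx,
                    config = patient_config(seed = 3, max_epochs = 3,
                                            batch_size = 4))
  a <- predict_patient(m, feats[1, ])
  b <- predict_patient(m, feats[1, ])
  expect_identical(a, b)
})
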