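test_that("metrics follow their confusion-matrix definitions", {
  cm <- rbind(c(85, 15), c(39, 61))  # rows: true malignant, true benign
  dimnames(cm) <- list(c("malignant", "benign"), c("malignant", "benign"))
  m <- class_metrics(cm, positive = "malignant")
  expect_equal(m$sensitivity, 0.85)
  expect_equal(m$specificity, 0.61)
  expect_equal(m$accuracy, 0.73)
  perfect <- diag(c(10, 10)); dimnames(perfect) <- dimnames(cm)
  mp <- class_metrics(perfect, positive = "malignant")
  expect_equal(unlist(mp), c(accuracy = 1, sensitivity = 1, specificity = 1))
  allpos <- rbind(c(10, 0), c(10, 0)); dimnames(allpos) <- dimnames(cm)
  ma <- class_metrics(allpos, positive = "malignant")
  expect_equal(unlist(ma), c(accuracy = 0.5, sensitivity = 1, specificity = 0))
})

test_that("stratified splits preserve class proportions within one sample", {
  labels <- rep(c("a", "b", "c"), c(30, 20, 10))
  sp <- stratified_split(labels, 0.7, seed = 4)
  expect_equal(sort(c(sp$train, sp$test)), seq_along(labels))
  for (cl in c("a", "b", "c")) {
    got <- sum(labels[sp$train] == cl)
    want <- 0.7 * sum(labels == cl)
    expect_lte(abs(got - want), 1)
  }
  # both sides keep at least one sample of a tiny class
  sp2 <- stratified_split(c("a", "a", "b", "b"), 0.7, seed = 1)
  expect_true(all(table(c("a", "a", "b", "b")[sp2$test]) >= 1))
})

test_that("studies are deterministic under a fixed seed", {
  w <- gen_wings(wing_spec(n_classes = 3, n_per_class = 4, width = 120,
                           height = 54, delta = 5, seed = 6))
  r1 <- tidy(run_wing_study(w, order = 10, k = 6, cv_folds = 3, seed = 7))
  r2 <- tidy(run_wing_study(w, order = 10, k = 6, cv_folds = 3, seed = 7))
  expect_identical(r1, r2)
  m <- gen_masses(mass_spec(n_benign = 12, n_malignant = 12, size = 48, seed = 8))
  s1 <- suppressWarnings(run_mass_study(m, km_order = 12, gpzm_order = 6,
                                        working_size = 48, n_repeats = 2, seed = 9))
  s2 <- suppressWarnings(run_mass_study(m, km_order = 12, gpzm_order = 6,
                                        working_size = 48, n_repeats = 2, seed = 9))
  expect_identical(s1$per_repeat, s2$per_repeat)
})

test_that("fitted models depend only on training rows (no test leakage)", {
  set.seed(33)
  n <- 24
  Xkm <- matrix(rnorm(n * 40), n, 40)
  Xgp <- matrix(abs(rnorm(n * 12)), n, 12)
  labels <- rep(c("benign", "malignant"), each = n / 2)
  tr <- c(1:9, 13:21)
  fit1 <- orthomoments:::mass_image_fit(Xkm[tr, ], Xgp[tr, ], labels[tr], 0.1, 0.95)
  # corrupt everything outside the training rows
  Xkm2 <- Xkm; Xkm2[-tr, ] <- 99
  Xgp2 <- Xgp; Xgp2[-tr, ] <- 99
  labels2 <- labels; labels2[-tr] <- "flipped"
  fit2 <- orthomoments:::mass_image_fit(Xkm2[tr, ], Xgp2[tr, ], labels2[tr], 0.1, 0.95)
  expect_identical(serialize(fit1, NULL), serialize(fit2, NULL))
  # and the projection of a fixed query is unchanged
  q <- orthomoments:::mass_image_project(fit1, Xkm[22:24, ], Xgp[22:24, ])
  q2 <- orthomoments:::mass_image_project(fit2, Xkm[22:24, ], Xgp[22:24, ])
  expect_identical(q, q2)
})

test_that("mass study reports all models with mean ± SE formatting", {
  m <- gen_masses(mass_spec(n_benign = 12, n_malignant = 12, size = 48, seed = 10))
  st <- suppressWarnings(run_mass_study(m, km_order = 12, gpzm_order = 6,
                                        working_size = 48, n_repeats = 3, seed = 11))
  expect_setequal(unique(st$summary$model), c("image", "I", "II", "III", "IV"))
  expect_equal(nrow(st$per_repeat), 5 * 3)
  fm <- format(st)
  expect_true(all(grepl("^\\d+\\.\\d ± \\d+\\.\\d$", fm$formatted)))
  expect_true(all(st$summary$se >= 0))
  expect_true(all(st$summary$mean >= 0 & st$summary$mean <= 1))
  # standard error uses sd / sqrt(n_repeats)
  acc <- dplyr::filter(st$per_repeat, model == "image")$accuracy
  se <- dplyr::filter(st$summary, model == "image", metric == "accuracy")$se
  expect_equal(se, sd(acc) / sqrt(3), tolerance = 1e-12)
})

test_that("one-hot expert encoding uses the fixed vocabularies", {
  tabs <- orthomoments:::default_expert_tables()
  d <- tibble::tibble(assessment = c("4", "2"), shape = c("oval", "irregular"),
                      margin = c("spiculated", "obscured"), density = c("2", "3"),
                      subtlety = c("5", "1"))
  E <- orthomoments:::onehot_expert(d, tabs, c("assessment", "shape"))
  expect_equal(ncol(E), 7 + 4)
  expect_equal(sum(E[1, ]), 2)  # one level active per feature
  expect_equal(E[1, "assessment_4"], 1, ignore_attr = TRUE)
  expect_equal(E[2, "shape_irregular"], 1, ignore_attr = TRUE)
})

test_that("wing study tidy output exposes both arms and both evaluations", {
  w <- gen_wings(wing_spec(n_classes = 3, n_per_class = 4, width = 120,
                           height = 54, delta = 6, seed = 12))
  ws <- run_wing_study(w, order = 10, k = 6, cv_folds = 3, seed = 13)
  td <- tidy(ws)
  expect_equal(nrow(td), 4)
  expect_setequal(td$arm, c("moment", "landmark"))
  expect_setequal(td$evaluation, c("training", "cv"))
  expect_true(all(td$total == 12))
  expect_true(all(td$lower <= td$mean & td$mean <= td$upper))
})
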