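# End-to-end study orchestration: classification metrics, stratified
# splits, the multi-class wing study (moment-invariant arm vs landmark
# arm, Bayesian accuracy summaries), and the two-class mass study
# (KM + GPZM image features, P(mal), and the four expert-feature fusion
# models evaluated over repeated 70/30 splits).

#' Classification metrics from a confusion matrix
#'
#' Accuracy is trace/total. For two-class problems with a designated
#' positive class, sensitivity = TP/(TP+FN) and specificity = TN/(TN+FP);
#' they are `NA` when the relevant true class is empty or for multi-class
#' input.
#'
#' @param confusion square count matrix, true classes in rows; dimnames
#'   give the labels.
#' @param positive positive class label (for sensitivity/specificity).
#' @return a one-row tibble with `accuracy`, `sensitivity`, `specificity`.
#' @export
class_metrics <- function(confusion, positive = NULL) {
  m <- as.matrix(confusion)
  if (nrow(m) != ncol(m)) stop_arg("confusion matrix must be square")
  if (any(m < 0)) stop_arg("confusion matrix entries must be non-negative")
  acc <- sum(diag(m)) / sum(m)
  sens <- spec <- NA_real_
  if (nrow(m) == 2 && !is.null(positive)) {
    labs <- rownames(m) %||% colnames(m)
    if (is.null(labs) || !positive %in% labs) stop_arg("positive class not found in dimnames")
    pos <- which(labs == positive); neg <- setdiff(1:2, pos)
    if (sum(m[pos, ]) > 0) sens <- m[pos, pos] / sum(m[pos, ])
    if (sum(m[neg, ]) > 0) spec <- m[neg, neg] / sum(m[neg, ])
  }
  tibble(accuracy = acc, sensitivity = sens, specificity = spec)
}

confusion_matrix <- function(truth, pred, levels = sort(unique(c(truth, pred)))) {
  table(factor(truth, levels), factor(pred, levels))
}

#' Stratified train/test split
#'
#' Samples `round(train_fraction * n_c)` training indices within each
#' class (clamped so both sides keep at least one sample when the class
#' has >= 2), preserving class proportions to within one sample.
#'
#' @param labels class label vector.
#' @param train_fraction fraction for training (default 0.7).
#' @param seed integer seed.
#' @return list with integer vectors `train` and `test`.
#' @export
stratified_split <- function(labels, train_fraction = 0.7, seed = 1) {
  if (train_fraction <= 0 || train_fraction >= 1) stop_arg("train_fraction must be in (0, 1)")
  idx <- with_seed(seed, {
    unlist(lapply(unique(labels), function(cl) {
      w <- which(labels == cl)
      n_tr <- round(train_fraction * length(w))
      if (length(w) >= 2) n_tr <- min(max(n_tr, 1), length(w) - 1)
      sample(w, n_tr)
    }))
  })
  list(train = sort(idx), test = sort(setdiff(seq_along(labels), idx)))
}

# stratified k folds (vector of fold assignments)
stratified_folds <- function(labels, k, seed) {
  fold <- integer(length(labels))
  with_seed(seed, {
    for (cl in unique(labels)) {
      w <- sample(which(labels == cl))
      fold[w] <- rep_len(seq_len(k), length(w))
    }
  })
  fold
}

# ---------------------------------------------------------------------------
# Wing study

#' Run the multi-class wing study
#'
#' Extracts pose-normalized Krawtchouk moment invariants, fits the
#' Z-score / Q-mode PCA / Fisher LDA pipeline and the Gaussian kernel
#' discriminant, and reports the training-set confusion matrix with its
#' Bayesian posterior accuracy, plus a stratified cross-validated
#' confusion matrix (fitted fold-wise, no leakage). The same report is
#' produced for the landmark-coordinate comparison arm.
#'
#' @param wings tibble from [gen_wings()] (or equivalent with `label`,
#'   `image`, `landmarks` columns).
#' @param order Krawtchouk invariant order (default 200, giving `order^2`
#'   features).
#' @param p Krawtchouk weight parameter.
#' @param k retained principal components for the moment arm (default 60);
#'   clamped to the sample count and to at least `s - 1`.
#' @param k_landmark retained components for the landmark arm (default 15).
#' @param mass_fraction pose-normalization scale target.
#' @param cv_folds stratified cross-validation fold count (default 5).
#' @param bandwidth,priors passed to [kd_fit()].
#' @param seed integer seed for fold assignment.
#' @return a `wing_study` object; see [tidy.wing_study()].
#' @export
run_wing_study <- function(wings, order = 200, p = 0.5, k = 60,
                           k_landmark = 15, mass_fraction = 0.25,
                           cv_folds = 5, bandwidth = "scott",
                           priors = "empirical", seed = 1) {
  stopifnot(all(c("label", "image", "landmarks") %in% names(wings)))
  labels <- as.character(wings$label)
  n <- length(labels)
  s <- length(unique(labels))
  X_mom <- t(vapply(wings$image, km_invariant_features, numeric(order^2),
                    order = order, p = p, mass_fraction = mass_fraction))
  X_lm <- landmark_features(wings$landmarks)
  run_arm <- function(X, k_arm) {
    k_eff <- min(k_arm, n - 1, ncol(X))
    k_eff <- max(k_eff, s - 1)
    fs <- feature_space_fit(X, labels, select_fraction = NULL, k = k_eff)
    Ztr <- predict(fs, X)
    kd <- kd_fit(Ztr, labels, bandwidth = bandwidth, priors = priors)
    pred_tr <- predict(kd, Ztr)$.pred
    cm_tr <- confusion_matrix(labels, pred_tr, sort(unique(labels)))
    # fold-wise refit for the cross-validated estimate
    fold <- stratified_folds(labels, cv_folds, seed)
    pred_cv <- character(n)
    for (f in seq_len(cv_folds)) {
      tr <- fold != f; te <- fold == f
      if (!any(te)) next
      k_f <- max(min(k_eff, sum(tr) - 1), s - 1)
      fs_f <- feature_space_fit(X[tr, , drop = FALSE], labels[tr], k = k_f)
      kd_f <- kd_fit(predict(fs_f, X[tr, , drop = FALSE]), labels[tr],
                     bandwidth = bandwidth, priors = priors)
      pred_cv[te] <- predict(kd_f, predict(fs_f, X[te, , drop = FALSE]))$.pred
    }
    cm_cv <- confusion_matrix(labels, pred_cv, sort(unique(labels)))
    list(confusion = cm_tr,
         posterior = do.call(posterior_accuracy, as.list(accuracy_from_confusion(cm_tr))),
         cv_confusion = cm_cv,
         cv_posterior = do.call(posterior_accuracy, as.list(accuracy_from_confusion(cm_cv))),
         model = fs, kd = kd)
  }
  res <- list(moment = run_arm(X_mom, k), landmark = run_arm(X_lm, k_landmark),
              config = list(order = order, p = p, k = k, k_landmark = k_landmark,
                            cv_folds = cv_folds, seed = seed, n = n, s = s))
  class(res) <- "wing_study"
  res
}

#' @export
print.wing_study <- function(x, ...) {
  cat("Wing study (", x$config$n, " specimens, ", x$config$s, " classes)\n", sep = "")
  cat("  moment arm   training: ", format(x$moment$posterior),
      "   CV: ", format(x$moment$cv_posterior), "\n", sep = "")
  cat("  landmark arm training: ", format(x$landmark$posterior),
      "   CV: ", format(x$landmark$cv_posterior), "\n", sep = "")
  invisible(x)
}

#' Tidy a wing study report
#'
#' @param x a `wing_study`.
#' @param ... unused.
#' @return tibble with one row per (arm, evaluation) pair: posterior mean
#'   accuracy and credible bounds.
#' @exportS3Method
tidy.wing_study <- function(x, ...) {
  grab <- function(arm, eval, pa) {
    dplyr::mutate(tidy(pa), arm = arm, evaluation = eval, .before = 1)
  }
  dplyr::bind_rows(
    grab("moment", "training", x$moment$posterior),
    grab("moment", "cv", x$moment$cv_posterior),
    grab("landmark", "training", x$landmark$posterior),
    grab("landmark", "cv", x$landmark$cv_posterior)
  )
}

# ---------------------------------------------------------------------------
# Mass study

# one-hot encode the expert features with a fixed vocabulary
onehot_expert <- function(data, tables, features) {
  cols <- lapply(features, function(nm) {
    lev <- tables[[nm]]$levels
    m <- outer(as.character(data[[nm]]), lev, `==`) * 1
    colnames(m) <- paste0(nm, "_", lev)
    m
  })
  do.call(cbind, cols)
}

# image-arm model: per-block Z-score + t-selection on KM and GPZM features,
# concatenation, Q-mode PCA, LDA. Fit uses training rows only.
mass_image_fit <- function(Xkm, Xgp, labels, select_fraction, beta) {
  fit_block <- function(X) {
    sc <- zscore_fit(X)
    Xs <- zscore_apply(X, sc)
    sel <- t_select(Xs, labels, select_fraction)
    list(scaler = sc, sel = sel, X = Xs[, sel, drop = FALSE])
  }
  bk <- fit_block(Xkm)
  bg <- fit_block(Xgp)
  Xsel <- cbind(bk$X, bg$X)
  pca <- qmode_pca(Xsel, beta = beta)
  k <- max(pca$k, length(unique(labels)) - 1)
  lda <- lda_fit(pca$scores[, seq_len(k), drop = FALSE], labels)
  list(km = bk[c("scaler", "sel")], gp = bg[c("scaler", "sel")],
       pca = pca, k = k, lda = lda)
}

mass_image_project <- function(model, Xkm, Xgp) {
  a <- zscore_apply(Xkm, model$km$scaler)[, model$km$sel, drop = FALSE]
  b <- zscore_apply(Xgp, model$gp$scaler)[, model$gp$sel, drop = FALSE]
  V <- pca_project(cbind(a, b), model$pca, k = model$k)
  lda_project(V, model$lda)
}

#' Run the two-class mass study
#'
#' Images are resized to `working_size`, min-max normalized and histogram
#' equalized; Krawtchouk and generalized pseudo-Zernike feature blocks are
#' extracted once per image. Each repeat draws a stratified
#' `train_fraction` split and fits, on the training rows only: per-block
#' Z-score + top-`select_fraction` |t| selection, Q-mode PCA at variance
#' threshold `beta`, Fisher LDA, and the Gaussian kernel discriminant.
#' P(mal) for the test rows comes from that model; P(mal) for the training
#' rows is produced out-of-fold (`oof_folds`-fold refits within the
#' training set) so the fusion models never see in-sample densities. Four
#' fusion models are then fit with the kernel discriminant on one-hot
#' expert features: (I) all five expert features + P(mal); (II) all five
#' expert features; (III) assessment replaced by P(mal); (IV) neither
#' assessment nor P(mal).
#'
#' @param masses tibble from [gen_masses()].
#' @param km_order Krawtchouk moment order for the image features.
#' @param gpzm_order generalized pseudo-Zernike order.
#' @param alpha GPZM side parameter.
#' @param working_size image side length used for feature extraction.
#' @param select_fraction per-block t-selection fraction (default 0.01).
#' @param beta PCA cumulative-variance threshold (default 0.95).
#' @param train_fraction training fraction per repeat (default 0.7).
#' @param n_repeats number of random split instances (default 10).
#' @param oof_folds folds for out-of-fold training P(mal).
#' @param bandwidth,priors passed to [kd_fit()].
#' @param positive positive class (default "malignant").
#' @param expert_tables vocabulary for one-hot encoding (defaults to the
#'   generator's tables).
#' @param seed integer seed.
#' @return a `mass_study` object with `$per_repeat` and `$summary`
#'   tibbles; see [tidy.mass_study()].
#' @export
run_mass_study <- function(masses, km_order = 64, gpzm_order = 12, alpha = 0,
                           working_size = 128, select_fraction = 0.01,
                           beta = 0.95, train_fraction = 0.7, n_repeats = 10,
                           oof_folds = 5, bandwidth = "scott",
                           priors = "empirical", positive = "malignant",
                           expert_tables = default_expert_tables(), seed = 1) {
  stopifnot(all(c("label", "image") %in% names(masses)))
  labels <- as.character(masses$label)
  lev <- sort(unique(labels))
  imgs <- lapply(masses$image, function(im) {
    hist_equalize(normalize_minmax(resize_image(im, working_size, working_size)))
  })
  Xkm <- km_feature_matrix(imgs, km_order)
  Xgp <- gpzm_feature_matrix(imgs, gpzm_order, alpha)
  has_expert <- all(c("assessment", "shape", "margin", "density", "subtlety") %in%
                      names(masses))
  expert_all <- c("assessment", "shape", "margin", "density", "subtlety")
  expert_noassess <- setdiff(expert_all, "assessment")
  model_defs <- list(I = list(expert = expert_all, pmal = TRUE),
                     II = list(expert = expert_all, pmal = FALSE),
                     III = list(expert = expert_noassess, pmal = TRUE),
                     IV = list(expert = expert_noassess, pmal = FALSE))

  per_repeat <- list()
  for (r in seq_len(n_repeats)) {
    sp <- stratified_split(labels, train_fraction, substream_seed(seed, r))
    tr <- sp$train; te <- sp$test
    img_model <- mass_image_fit(Xkm[tr, , drop = FALSE], Xgp[tr, , drop = FALSE],
                                labels[tr], select_fraction, beta)
    Ztr <- mass_image_project(img_model, Xkm[tr, , drop = FALSE], Xgp[tr, , drop = FALSE])
    Zte <- mass_image_project(img_model, Xkm[te, , drop = FALSE], Xgp[te, , drop = FALSE])
    kd <- kd_fit(Ztr, labels[tr], bandwidth = bandwidth, priors = priors)
    pred_te <- predict(kd, Zte)
    cm <- confusion_matrix(labels[te], pred_te$.pred, lev)
    rows <- dplyr::mutate(class_metrics(cm, positive), model = "image", instance = r)

    if (has_expert) {
      pmal_te <- pred_te[[paste0(".prob_", positive)]]
      # out-of-fold P(mal) for training rows
      pmal_tr <- numeric(length(tr))
      fold <- stratified_folds(labels[tr], oof_folds, substream_seed(seed, 1000 + r))
      for (f in seq_len(oof_folds)) {
        fi <- fold != f; fo <- fold == f
        if (!any(fo)) next
        m_f <- mass_image_fit(Xkm[tr[fi], , drop = FALSE], Xgp[tr[fi], , drop = FALSE],
                              labels[tr[fi]], select_fraction, beta)
        kd_f <- kd_fit(mass_image_project(m_f, Xkm[tr[fi], , drop = FALSE],
                                          Xgp[tr[fi], , drop = FALSE]),
                       labels[tr[fi]], bandwidth = bandwidth, priors = priors)
        pmal_tr[fo] <- kd_positive_prob(
          kd_f, mass_image_project(m_f, Xkm[tr[fo], , drop = FALSE],
                                   Xgp[tr[fo], , drop = FALSE]), positive)
      }
      for (mid in names(model_defs)) {
        def <- model_defs[[mid]]
        Etr <- onehot_expert(masses[tr, ], expert_tables, def$expert)
        Ete <- onehot_expert(masses[te, ], expert_tables, def$expert)
        if (def$pmal) {
          Etr <- cbind(Etr, pmal = pmal_tr)
          Ete <- cbind(Ete, pmal = pmal_te)
        }
        kd_m <- kd_fit(Etr, labels[tr], bandwidth = bandwidth, priors = priors)
        cm_m <- confusion_matrix(labels[te], predict(kd_m, Ete)$.pred, lev)
        rows <- dplyr::bind_rows(rows, dplyr::mutate(class_metrics(cm_m, positive),
                                                     model = mid, instance = r))
      }
    }
    per_repeat[[r]] <- rows
  }
  per_repeat <- dplyr::bind_rows(per_repeat) |>
    dplyr::select("model", "instance", "accuracy", "sensitivity", "specificity")
  summary <- per_repeat |>
    tidyr::pivot_longer(c("accuracy", "sensitivity", "specificity"),
                        names_to = "metric", values_to = "value") |>
    dplyr::group_by(.data$model, .data$metric) |>
    dplyr::summarise(mean = mean(.data$value),
                     se = sd(.data$value) / sqrt(dplyr::n()),
                     n_repeats = dplyr::n(), .groups = "drop")
  structure(list(per_repeat = per_repeat, summary = summary,
                 config = list(km_order = km_order, gpzm_order = gpzm_order,
                               alpha = alpha, working_size = working_size,
                               select_fraction = select_fraction, beta = beta,
                               train_fraction = train_fraction,
                               n_repeats = n_repeats, seed = seed,
                               positive = positive)),
            class = "mass_study")
}

#' Format mass-study metrics as "mean ± SE" percentages
#'
#' @param x a `mass_study`.
#' @param ... unused.
#' @return tibble with `model`, `metric`, and `formatted` ("84.6 ± 1.2").
#' @export
format.mass_study <- function(x, ...) {
  dplyr::mutate(x$summary,
                formatted = sprintf("%.1f ± %.1f", 100 * .data$mean, 100 * .data$se)) |>
    dplyr::select("model", "metric", "formatted")
}

#' @export
print.mass_study <- function(x, ...) {
  cat("Mass study:", x$config$n_repeats, "random split instances\n")
  print(as.data.frame(format(x)), row.names = FALSE)
  invisible(x)
}

#' Tidy a mass study report
#' @param x a `mass_study`.
#' @param ... unused.
#' @return the per-model summary tibble (mean and standard error of each
#'   metric over the split instances).
#' @exportS3Method
tidy.mass_study <- function(x, ...) x$summary

#' @exportS3Method
glance.mass_study <- function(x, ...) {
  img <- dplyr::filter(x$summary, .data$model == "image", .data$metric == "accuracy")
  tibble(n_repeats = x$config$n_repeats,
         image_accuracy = img$mean, image_accuracy_se = img$se)
}
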