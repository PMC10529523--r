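#' Train the solid/cystic patch classifier
#'
#' Random-forest ensemble on the 36 AR texture features. Grouped
#' cross-validation accuracy is computed with nodules as groups, so no
#' nodule contributes patches to both a training and a validation fold.
#'
#' @param features Numeric matrix, one row per patch.
#' @param labels Character or factor patch labels, `"solid"`/`"cystic"`.
#' @param group_ids Per-patch nodule identifier (for grouped CV).
#' @param seed Integer seed making training deterministic.
#' @param n_trees Number of trees (default 200).
#' @param cv_folds Number of grouped CV folds (default 5, capped at the
#'   number of groups).
#' @return A list of class `region_model` with the fitted forest, the
#'   feature layout version, the training seed and `cv_accuracy`.
#' @export
train_region_model <- function(features, labels, group_ids,
                               seed = 1L, n_trees = 200L, cv_folds = 5L) {
  features <- as.matrix(features)
  labels <- factor(as.character(labels), levels = c("solid", "cystic"))
  stopifnot(nrow(features) == length(labels),
            length(group_ids) == length(labels))
  if (anyNA(labels)) stop("labels must be 'solid' or 'cystic'", call. = FALSE)
  tab <- table(labels)
  if (any(tab == 0)) {
    stop("training data must contain both classes", call. = FALSE)
  }
  if (any(tab < 20)) {
    warning("fewer than 20 patches in a class; classifier may be unstable")
  }

  cv <- grouped_cv_predictions(features, labels, group_ids,
                               seed = seed, n_trees = n_trees,
                               cv_folds = cv_folds)
  rf <- with_seed(seed, randomForest::randomForest(
    x = features, y = labels, ntree = as.integer(n_trees)))
  structure(list(forest = rf,
                 feature_layout_version = FEATURE_LAYOUT_VERSION,
                 training_seed = as.integer(seed),
                 cv_accuracy = mean(cv$predicted == cv$label),
                 cv_predictions = cv),
            class = "region_model")
}

# Out-of-fold patch predictions under grouped (by nodule) cross-validation.
grouped_cv_predictions <- function(features, labels, group_ids,
                                   seed = 1L, n_trees = 200L, cv_folds = 5L) {
  groups <- unique(group_ids)
  k <- max(2L, min(as.integer(cv_folds), length(groups)))
  fold_of_group <- with_seed(seed + 7L, {
    stats::setNames(rep_len(seq_len(k), length(groups))[sample.int(length(groups))],
                    as.character(groups))
  })
  fold <- fold_of_group[as.character(group_ids)]
  pred <- factor(rep(NA_character_, length(labels)), levels = levels(labels))
  for (f in seq_len(k)) {
    test_idx <- which(fold == f)
    train_idx <- which(fold != f)
    if (length(test_idx) == 0) next
    if (nlevels(droplevels(labels[train_idx])) < 2) {
      stop("a CV training fold lost one class entirely; use more groups",
           call. = FALSE)
    }
    rf <- with_seed(seed + f, randomForest::randomForest(
      x = features[train_idx, , drop = FALSE], y = labels[train_idx],
      ntree = as.integer(n_trees)))
    pred[test_idx] <- predict(rf, features[test_idx, , drop = FALSE])
  }
  data.frame(group_id = group_ids, label = labels, predicted = pred,
             fold = as.integer(fold))
}

#' Predict patch classes with a trained region model
#'
#' @param model A `region_model`.
#' @param features Feature matrix (rows = patches) or list of
#'   [texture_patch()] objects.
#' @param ... Passed to [patch_feature_matrix()] when `features` is a
#'   patch list.
#' @return Factor of `"solid"`/`"cystic"` predictions.
#' @export
predict_patch_classes <- function(model, features, ...) {
  stopifnot(inherits(model, "region_model"))
  if (is.list(features) && !is.data.frame(features) && !is.matrix(features)) {
    features <- patch_feature_matrix(features, ...)
  }
  features <- as.matrix(features)
  trained_vars <- rownames(model$forest$importance)
  if (ncol(features) != length(trained_vars)) {
    stop(sprintf("feature count %d does not match the model's %d (layout %s)",
                 ncol(features), length(trained_vars),
                 model$feature_layout_version), call. = FALSE)
  }
  # columns are matched by position: the feature layout version pins the
  # ordering, while column names differ between descriptive and f01.. forms
  colnames(features) <- trained_vars
  predict(model$forest, features)
}

#' Estimate a nodule's cystic percentage from its patches
#'
#' Patch-count aggregation of the classifier output:
#' `100 * n_cystic / n_patches`; the solid percentage is the complement.
#'
#' @param model A `region_model`.
#' @param patches Non-empty list of [texture_patch()] objects, or a
#'   precomputed feature matrix.
#' @param nodule_id Identifier carried into the result.
#' @param ... Passed to [patch_feature_matrix()].
#' @return A list of class `cystic_estimate`: `nodule_id`,
#'   `cystic_percent` in \[0, 100\], `n_patches`.
#' @export
estimate_cystic_percentage <- function(model, patches, nodule_id = NA, ...) {
  n <- if (is.matrix(patches)) nrow(patches) else length(patches)
  if (n == 0) {
    stop("no patches inside the nodule: cannot estimate composition",
         call. = FALSE)
  }
  pred <- predict_patch_classes(model, patches, ...)
  structure(list(nodule_id = nodule_id,
                 cystic_percent = 100 * mean(pred == "cystic"),
                 n_patches = length(pred)),
            class = "cystic_estimate")
}

#' Recovery error of cystic-percentage estimates on known phantoms
#'
#' Applies a trained model to each synthetic nodule and compares the
#' estimated cystic percentage with the phantom truth.
#'
#' @param truths List of `synthetic_nodule` objects (>= 5).
#' @param model A `region_model`.
#' @param config A [run_config()].
#' @return A list with `mae_points` (mean absolute error, percentage
#'   points) and `per_nodule` (data.frame of truth, estimate, residual).
#' @export
evaluate_recovery <- function(truths, model, config = run_config()) {
  stopifnot(length(truths) >= 5)
  rows <- lapply(truths, function(nod) {
    patches <- extract_patches(nod$image, nod$nodule_mask,
                               patch_size_px = config$patch_size_px,
                               stride_px = config$stride_px,
                               min_inside_fraction = config$min_inside_fraction)
    est <- estimate_cystic_percentage(model, patches,
                                      nodule_id = nod$nodule_id %||% NA,
                                      ar_order = config$ar_order,
                                      band_edges = config$band_edges)
    data.frame(nodule_id = est$nodule_id,
               true_pct = 100 * nod$cystic_fraction_true,
               estimated_pct = est$cystic_percent,
               n_patches = est$n_patches)
  })
  per_nodule <- do.call(rbind, rows)
  per_nodule$residual <- per_nodule$estimated_pct - per_nodule$true_pct
  list(mae_points = mean(abs(per_nodule$residual)), per_nodule = per_nodule)
}

#' End-to-end recovery on a synthetic suite with held-out estimates
#'
#' Builds the labelled feature table over all nodules, runs grouped
#' cross-validation (nodules as groups), and forms every nodule's cystic
#' percentage from the out-of-fold patch predictions only, so no nodule is
#' estimated by a forest that saw its own patches.
#'
#' @param truths List of `synthetic_nodule` objects.
#' @param config A [run_config()].
#' @param seed Integer seed for fold assignment and forests.
#' @return A list: `cv_accuracy` (grouped patch accuracy), `mae_points`,
#'   `per_nodule` data.frame, and the pooled `feature_table`.
#' @export
recover_cystic_suite <- function(truths, config = run_config(), seed = config$seed) {
  tabs <- lapply(truths, nodule_feature_table, config = config)
  tab <- do.call(rbind, tabs)
  feat_cols <- grep("^f[0-9]+$", names(tab), value = TRUE)
  labels <- factor(tab$label, levels = c("solid", "cystic"))
  cv <- grouped_cv_predictions(as.matrix(tab[feat_cols]), labels,
                               tab$nodule_id, seed = seed,
                               n_trees = config$rf_trees)
  truth_pct <- vapply(truths, function(t) 100 * t$cystic_fraction_true, numeric(1))
  ids <- vapply(truths, function(t) t$nodule_id %||% NA_integer_, integer(1))
  per_nodule <- do.call(rbind, lapply(seq_along(ids), function(i) {
    sel <- cv$group_id == ids[i]
    data.frame(nodule_id = ids[i],
               true_pct = truth_pct[i],
               estimated_pct = 100 * mean(cv$predicted[sel] == "cystic"),
               n_patches = sum(sel))
  }))
  per_nodule$residual <- per_nodule$estimated_pct - per_nodule$true_pct
  list(cv_accuracy = mean(cv$predicted == cv$label),
       mae_points = mean(abs(per_nodule$residual)),
       per_nodule = per_nodule,
       feature_table = tab)
}
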