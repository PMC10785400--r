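#' Stacked-ensemble configuration
#'
#' Defaults follow common AutoML practice: three complementary base
#' learners (gradient-boosted trees, random forest, regularised
#' logistic), each bagged over stratified bootstrap resamples, stacked
#' for two layers with 5-fold out-of-fold predictions, and a logistic
#' meta-learner giving calibrated probabilities. Class imbalance (one
#' positive voxel per target against dozens of negatives) is handled by
#' balanced class weights in every learner.
#'
#' @param base_learners Subset of `c("gbt", "rf", "glmnet")`.
#' @param bags_per_learner Bootstrap bags averaged per learner
#'   (default 5).
#' @param stack_layers Stacking depth (default 2).
#' @param folds_for_oof Folds for out-of-fold predictions (default 5).
#' @param validation_fraction Fraction of targets held out by
#'   [split_by_target()] (default 0.2).
#' @param seed RNG seed; all per-fit seeds are derived from it.
#' @return A `vd_stack_config` list.
#' @export
stack_config <- function(base_learners = c("gbt", "rf", "glmnet"),
                         bags_per_learner = 5, stack_layers = 2,
                         folds_for_oof = 5, validation_fraction = 0.2,
                         seed = 1) {
  base_learners <- match.arg(base_learners, several.ok = TRUE)
  if (validation_fraction <= 0 || validation_fraction >= 1) {
    abort("validation_fraction must be in (0, 1)")
  }
  if (folds_for_oof < 2) abort("folds_for_oof must be >= 2")
  if (stack_layers < 1) abort("stack_layers must be >= 1")
  structure(list(base_learners = base_learners,
                 bags_per_learner = as.integer(bags_per_learner),
                 stack_layers = as.integer(stack_layers),
                 folds_for_oof = as.integer(folds_for_oof),
                 validation_fraction = validation_fraction,
                 seed = as.integer(seed)),
            class = "vd_stack_config")
}

# ---- base-learner registry ----------------------------------------------

fit_base_learner <- function(kind, x, y, w, seed) {
  switch(kind,
    gbt = {
      dm <- xgboost::xgb.DMatrix(x, label = y, weight = w)
      booster <- xgboost::xgb.train(
        params = list(objective = "binary:logistic", max_depth = 4,
                      eta = 0.1, nthread = 1, seed = seed),
        data = dm, nrounds = 60, verbose = 0)
      list(kind = "gbt", model = booster)
    },
    rf = {
      yf <- factor(y, levels = c(0, 1))
      cw <- as.numeric(length(y) / (2 * pmax(table(yf), 1)))
      names(cw) <- levels(yf)
      fit <- ranger::ranger(x = as.data.frame(x), y = yf, probability = TRUE,
                            num.trees = 150, class.weights = cw,
                            seed = seed, num.threads = 1)
      list(kind = "rf", model = fit)
    },
    glmnet = {
      # small-class warning is expected here: one positive voxel per target,
      # with the imbalance handled through the balanced weights
      fit <- suppressWarnings(
        glmnet::glmnet(x, y, family = "binomial", weights = w,
                       alpha = 0, lambda = 0.05, standardize = TRUE))
      list(kind = "glmnet", model = fit)
    },
    abort(paste0("unknown base learner: ", kind))
  )
}

predict_base_learner <- function(fit, x) {
  p <- switch(fit$kind,
    gbt = predict(fit$model, xgboost::xgb.DMatrix(x)),
    rf = predict(fit$model, data = as.data.frame(x),
                 num.threads = 1)$predictions[, "1"],
    glmnet = as.numeric(predict(fit$model, newx = x, type = "response"))
  )
  pmin(pmax(as.numeric(p), 0), 1)
}

# stratified bootstrap keeps both classes present in every bag
bagged_fit <- function(kind, x, y, w, bags, seed) {
  models <- vector("list", bags)
  for (b in seq_len(bags)) {
    set.seed(seed + 7919L * b)
    idx <- unlist(lapply(split(seq_along(y), y), function(rows) {
      sample(rows, length(rows), replace = TRUE)
    }), use.names = FALSE)
    models[[b]] <- fit_base_learner(kind, x[idx, , drop = FALSE], y[idx],
                                    w[idx], seed = seed + b)
  }
  structure(list(kind = kind, models = models), class = "vd_bagged")
}

predict_bagged <- function(bag, x) {
  rowMeans(vapply(bag$models, predict_base_learner, numeric(nrow(x)), x = x))
}

balanced_weights <- function(y) {
  tab <- table(factor(y, levels = c(0, 1)))
  as.numeric(length(y) / (2 * pmax(tab, 1)))[y + 1]
}

grouped_folds <- function(groups, k, seed) {
  ug <- sort(unique(groups))
  k <- min(k, length(ug))
  set.seed(seed)
  assignment <- setNames(sample(rep_len(seq_len(k), length(ug))), ug)
  assignment[as.character(groups)]
}

# ---- target-level data handling -----------------------------------------

#' Split feature tables into training and validation sets by target
#'
#' The split is at target granularity — all voxels of one target land
#' on the same side — so no validation voxel can leak into training.
#'
#' @param tables Named or unnamed list of voxel feature tables (one per
#'   target).
#' @param fraction Fraction of targets held out (default 0.2).
#' @param seed RNG seed.
#' @return List with elements `train` and `validation`.
#' @export
split_by_target <- function(tables, fraction = 0.2, seed = 1) {
  if (length(tables) < 2) abort("need at least 2 targets to split")
  set.seed(seed)
  n_val <- max(1L, round(fraction * length(tables)))
  if (n_val >= length(tables)) n_val <- length(tables) - 1L
  val_idx <- sort(sample(length(tables), n_val))
  list(train = tables[-val_idx], validation = tables[val_idx])
}

#' Remove training targets structurally similar to benchmark targets
#'
#' Given precomputed pairwise structural-similarity scores (e.g.
#' TM-scores, computed externally), drops every training target whose
#' similarity to any benchmark target strictly exceeds the threshold;
#' a score exactly at the threshold is kept.
#'
#' @param targets Character vector of training target ids.
#' @param benchmark Character vector of benchmark/held-out target ids.
#' @param similarity Data frame with columns `target`, `benchmark`,
#'   `score` covering every (target, benchmark) pair.
#' @param threshold Removal threshold (default 0.5).
#' @return The retained training target ids.
#' @export
dedup_by_similarity <- function(targets, benchmark, similarity,
                                threshold = 0.5) {
  need <- tidyr::expand_grid(target = targets, benchmark = benchmark)
  have <- dplyr::semi_join(need, similarity, by = c("target", "benchmark"))
  if (nrow(have) < nrow(need)) {
    miss <- dplyr::anti_join(need, similarity, by = c("target", "benchmark"))
    abort(paste0("similarity scores missing for pair(s): ",
                 paste(paste0("(", miss$target, ",", miss$benchmark, ")"),
                       collapse = " ")))
  }
  bad <- similarity |>
    dplyr::filter(.data$target %in% targets, .data$benchmark %in% benchmark,
                  .data$score > threshold) |>
    dplyr::pull(.data$target) |>
    unique()
  setdiff(targets, bad)
}

# ---- training -----------------------------------------------------------

#' Train the voxel-scoring stacked classifier
#'
#' Layer 1 fits each base learner bagged over stratified bootstrap
#' resamples; out-of-fold predictions of layer k (folds drawn at target
#' granularity) are appended to the features of layer k+1; a logistic
#' meta-learner on the final layer's out-of-fold predictions produces a
#' calibrated binding-site probability in \[0, 1\]. Deterministic given
#' the config seed.
#'
#' @param train_tables List of labelled, imputed, feature-selected voxel
#'   tables.
#' @param config A [stack_config()].
#' @param validation_tables Optional held-out tables for the training
#'   report (AUROC, log-loss, top-1 site hit rate).
#' @param column_means Optional imputation means to bundle for
#'   inference-time imputation.
#' @return A `vd_site_scorer`.
#' @export
train_site_scorer <- function(train_tables, config = stack_config(),
                              validation_tables = NULL, column_means = NULL) {
  big <- dplyr::bind_rows(train_tables)
  feats <- feature_cols(big)
  x <- as.matrix(big[, feats, drop = FALSE])
  if (any(is.na(x))) abort("training tables contain missing values; impute first")
  y <- as.integer(big$label == "positive")
  if (length(unique(y)) < 2) abort("training data must contain both classes")
  w <- balanced_weights(y)
  groups <- big$target_id

  layers <- vector("list", config$stack_layers)
  cur_x <- x
  for (layer in seq_len(config$stack_layers)) {
    lseed <- config$seed + 1000L * layer
    fold_of <- grouped_folds(groups, config$folds_for_oof, lseed)
    oof <- matrix(NA_real_, nrow(cur_x), length(config$base_learners),
                  dimnames = list(NULL, config$base_learners))
    full <- list()
    for (li in seq_along(config$base_learners)) {
      kind <- config$base_learners[li]
      for (f in sort(unique(fold_of))) {
        tr <- fold_of != f
        bag <- bagged_fit(kind, cur_x[tr, , drop = FALSE], y[tr], w[tr],
                          config$bags_per_learner,
                          seed = lseed + 100L * li + f)
        oof[!tr, li] <- predict_bagged(bag, cur_x[!tr, , drop = FALSE])
      }
      full[[kind]] <- bagged_fit(kind, cur_x, y, w, config$bags_per_learner,
                                 seed = lseed + 100L * li)
    }
    layers[[layer]] <- list(learners = full)
    cur_x <- cbind(cur_x, oof)
    colnames(cur_x) <- c(colnames(cur_x)[seq_len(ncol(cur_x) - ncol(oof))],
                         paste0(".stack", layer, "_", config$base_learners))
  }
  # meta-learner: logistic model on the final layer's OOF predictions
  last_oof <- cur_x[, paste0(".stack", config$stack_layers, "_",
                             config$base_learners), drop = FALSE]
  meta_df <- as.data.frame(last_oof)
  names(meta_df) <- config$base_learners
  meta_fit <- suppressWarnings(
    glm(y ~ ., data = cbind(y = y, meta_df), family = binomial(), weights = w))
  meta_coef <- coef(meta_fit)
  meta_coef[is.na(meta_coef)] <- 0

  model <- structure(
    list(config = config, selected_features = feats,
         column_means = column_means, layers = layers,
         meta_coef = meta_coef, training_report = NULL),
    class = "vd_site_scorer")
  if (!is.null(validation_tables)) {
    model$training_report <- validation_report(model, validation_tables)
  }
  model
}

scorer_forward <- function(model, x) {
  cur_x <- x
  for (li in seq_along(model$layers)) {
    layer <- model$layers[[li]]
    preds <- vapply(model$config$base_learners, function(kind) {
      predict_bagged(layer$learners[[kind]], cur_x)
    }, numeric(nrow(cur_x)))
    if (nrow(cur_x) == 1L) preds <- matrix(
      preds, nrow = 1, dimnames = list(NULL, model$config$base_learners))
    colnames(preds) <- paste0(".stack", li, "_", model$config$base_learners)
    cur_x <- cbind(cur_x, preds)
  }
  last <- cur_x[, ncol(cur_x) - rev(seq_along(model$config$base_learners)) + 1,
                drop = FALSE]
  eta <- model$meta_coef[1] + as.numeric(last %*% model$meta_coef[-1])
  pmin(pmax(stats::plogis(eta), 0), 1)
}

#' Score voxels with a trained site scorer
#'
#' @param model A `vd_site_scorer`.
#' @param table A voxel feature table whose feature columns match the
#'   model's selected features (missing cells are imputed with the
#'   bundled training means).
#' @return The table's voxel metadata plus a `score` column in \[0, 1\]
#'   and `total_pose_count` (used downstream as a ranking tie-break).
#' @export
score_voxels <- function(model, table) {
  stopifnot(inherits(model, "vd_site_scorer"))
  if (!is.null(model$column_means)) {
    table <- apply_impute(table, model$column_means)
  }
  missing <- setdiff(model$selected_features, names(table))
  if (length(missing) > 0) {
    abort(paste0("table is missing model feature column(s): ",
                 paste(missing, collapse = ", ")))
  }
  x <- as.matrix(table[, model$selected_features, drop = FALSE])
  if (any(is.na(x))) abort("table contains missing values and no imputation means are bundled")
  cc <- count_cols(table)
  cnt <- if (length(cc) > 0) rowSums(as.matrix(table[, cc, drop = FALSE]),
                                     na.rm = TRUE) else rep(0, nrow(table))
  out <- table[, intersect(meta_cols, names(table))]
  out$total_pose_count <- cnt
  out$score <- scorer_forward(model, x)
  out
}

validation_report <- function(model, validation_tables) {
  scored <- purrr::map(validation_tables, ~ score_voxels(model, .x))
  big <- dplyr::bind_rows(scored)
  y <- as.integer(big$label == "positive")
  p <- pmin(pmax(big$score, 1e-12), 1 - 1e-12)
  auroc <- if (length(unique(y)) == 2) {
    as.numeric(pROC::auc(pROC::roc(y, big$score, quiet = TRUE,
                                   direction = "<", levels = c(0, 1))))
  } else NA_real_
  top1 <- vapply(scored, function(s) {
    if (!any(s$label == "positive")) return(NA)
    best <- which.max(s$score)
    s$label[best] == "positive"
  }, logical(1))
  tibble::tibble(
    n_validation_targets = length(validation_tables),
    n_voxels = nrow(big),
    auroc = auroc,
    log_loss = -mean(y * log(p) + (1 - y) * log(1 - p)),
    top1_hit_rate = mean(top1, na.rm = TRUE)
  )
}

#' @export
print.vd_site_scorer <- function(x, ...) {
  cat(sprintf("<vd_site_scorer> %d features, %d layer(s) of {%s} x %d bags\n",
              length(x$selected_features), x$config$stack_layers,
              paste(x$config$base_learners, collapse = ", "),
              x$config$bags_per_learner))
  if (!is.null(x$training_report)) {
    cat(sprintf("  validation: AUROC %.3f, log-loss %.3f, top-1 hit rate %.2f (%d targets)\n",
                x$training_report$auroc, x$training_report$log_loss,
                x$training_report$top1_hit_rate,
                x$training_report$n_validation_targets))
  }
  invisible(x)
}

#' @rdname train_site_scorer
#' @param x,object A `vd_site_scorer`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.vd_site_scorer <- function(x, ...) {
  tibble::tibble(term = names(x$meta_coef),
                 estimate = as.numeric(x$meta_coef))
}

#' @rdname train_site_scorer
#' @exportS3Method generics::glance
glance.vd_site_scorer <- function(x, ...) {
  rep <- x$training_report
  tibble::tibble(
    n_features = length(x$selected_features),
    stack_layers = x$config$stack_layers,
    bags_per_learner = x$config$bags_per_learner,
    auroc = if (is.null(rep)) NA_real_ else rep$auroc,
    log_loss = if (is.null(rep)) NA_real_ else rep$log_loss,
    top1_hit_rate = if (is.null(rep)) NA_real_ else rep$top1_hit_rate
  )
}

# ---- serialization ------------------------------------------------------

#' Save or load a trained site scorer
#'
#' The bundle is a directory holding the config and feature metadata as
#' JSON plus the fitted learners (gradient-boosted boosters are
#' converted to raw bytes so the bundle survives sessions). Loading
#' reproduces identical scores.
#'
#' @param model A `vd_site_scorer`.
#' @param dir Bundle directory.
#' @return `load_site_scorer()` returns the model; `save_site_scorer()`
#'   returns `dir` invisibly.
#' @export
save_site_scorer <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(
    list(config = unclass(model$config),
         selected_features = model$selected_features,
         column_means = as.list(model$column_means %||% list()),
         meta_coef = as.list(model$meta_coef)),
    file.path(dir, "scorer.json"), auto_unbox = TRUE, digits = NA)
  layers <- purrr::map(model$layers, function(layer) {
    purrr::map(layer$learners, function(bag) {
      bag$models <- purrr::map(bag$models, function(m) {
        if (m$kind == "gbt") m$model <- xgboost::xgb.save.raw(m$model)
        m
      })
      bag
    })
  })
  saveRDS(layers, file.path(dir, "learners.rds"))
  if (!is.null(model$training_report)) {
    jsonlite::write_json(model$training_report,
                         file.path(dir, "training_report.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  invisible(dir)
}

#' @rdname save_site_scorer
#' @export
load_site_scorer <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "scorer.json"))
  layers_raw <- readRDS(file.path(dir, "learners.rds"))
  layers <- purrr::map(layers_raw, function(learners) {
    list(learners = purrr::map(learners, function(bag) {
      bag$models <- purrr::map(bag$models, function(m) {
        if (m$kind == "gbt") m$model <- xgboost::xgb.load.raw(m$model)
        m
      })
      structure(bag, class = "vd_bagged")
    }))
  })
  cfg <- meta$config
  config <- stack_config(
    base_learners = unlist(cfg$base_learners),
    bags_per_learner = cfg$bags_per_learner,
    stack_layers = cfg$stack_layers, folds_for_oof = cfg$folds_for_oof,
    validation_fraction = cfg$validation_fraction, seed = cfg$seed)
  cm <- unlist(meta$column_means)
  report <- if (file.exists(file.path(dir, "training_report.json"))) {
    tibble::as_tibble(jsonlite::fromJSON(file.path(dir, "training_report.json")))
  } else NULL
  structure(
    list(config = config,
         selected_features = unlist(meta$selected_features),
         column_means = if (length(cm) > 0) cm else NULL,
         layers = layers,
         meta_coef = unlist(meta$meta_coef),
         training_report = report),
    class = "vd_site_scorer")
}

#' Fit the full selection + scoring pipeline on labelled tables
#'
#' Convenience orchestration: splits targets 80/20, fits imputation
#' means on the training side, runs Boruta on the imputed training
#' voxels, trains the stacked scorer on the selected features and
#' reports validation metrics on the held-out targets. The returned
#' scorer bundles the imputation means, so it can score raw
#' (unimputed, unselected) feature tables directly.
#'
#' @param tables List of labelled voxel feature tables, one per target.
#' @param boruta A [boruta_config()].
#' @param stack A [stack_config()].
#' @param keep_tentative Passed to [apply_selection()].
#' @return A `vd_site_scorer` with an extra `boruta` element holding
#'   the feature decisions.
#' @export
fit_site_pipeline <- function(tables, boruta = boruta_config(),
                              stack = stack_config(), keep_tentative = FALSE) {
  split <- split_by_target(tables, stack$validation_fraction, stack$seed)
  means <- fit_impute(split$train)
  train_imp <- purrr::map(split$train, ~ apply_impute(.x, means))
  big <- dplyr::bind_rows(train_imp)
  decisions <- boruta_select(big[, feature_cols(big)],
                             big$label == "positive", boruta)
  train_sel <- purrr::map(train_imp, ~ apply_selection(.x, decisions,
                                                       keep_tentative))
  val_sel <- purrr::map(split$validation, function(tb) {
    apply_selection(apply_impute(tb, means), decisions, keep_tentative)
  })
  model <- train_site_scorer(train_sel, stack, validation_tables = val_sel,
                             column_means = means)
  model$boruta <- decisions
  model$target_split <- list(
    train = unname(purrr::map_chr(split$train, ~ .x$target_id[1])),
    validation = unname(purrr::map_chr(split$validation, ~ .x$target_id[1]))
  )
  model
}
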