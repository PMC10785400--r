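#' Boruta configuration
#'
#' @param max_iterations Maximum shadow-comparison iterations
#'   (default 100).
#' @param alpha Two-sided binomial test level (default 0.05).
#' @param ensemble_size Trees in the random-forest importance model
#'   (default 200).
#' @param seed RNG seed.
#' @return A `vd_boruta_config` list.
#' @export
boruta_config <- function(max_iterations = 100, alpha = 0.05,
                          ensemble_size = 200, seed = 1) {
  if (alpha <= 0 || alpha >= 1) abort("alpha must be in (0, 1)")
  if (max_iterations < 1) abort("max_iterations must be >= 1")
  structure(list(max_iterations = as.integer(max_iterations), alpha = alpha,
                 ensemble_size = as.integer(ensemble_size),
                 seed = as.integer(seed)),
            class = "vd_boruta_config")
}

#' Boruta shadow-feature selection
#'
#' Each iteration appends one column-shuffled "shadow" copy of every
#' still-undecided feature, fits a class-weighted random forest, and
#' credits a real feature with a hit when its impurity importance
#' exceeds the maximum shadow importance. A two-sided binomial test of
#' hits against Binomial(trials, 1/2) then confirms features that beat
#' their shadows consistently and rejects those that do not; features
#' still undecided after `max_iterations` remain tentative. The
#' procedure is deterministic given the seed. No multiple-testing
#' correction is applied across features (the canonical algorithm's
#' behaviour).
#'
#' @param x Data frame or matrix of fully-imputed features.
#' @param y Binary labels (two classes required): factor, or anything
#'   coercible; the rarer class is treated via balanced class weights.
#' @param config A [boruta_config()].
#' @return A `vd_boruta` tibble with columns `feature`, `status`
#'   (`confirmed`/`rejected`/`tentative`), `hits`, `trials`,
#'   `mean_importance`.
#' @export
boruta_select <- function(x, y, config = boruta_config()) {
  x <- as.data.frame(x)
  if (any(!vapply(x, is.numeric, logical(1))) ||
      any(!is.finite(as.matrix(x)))) {
    abort("x must be numeric and fully imputed (no missing/non-finite values)")
  }
  y <- as.factor(y)
  if (nlevels(droplevels(y)) != 2) abort("y must contain exactly two classes")
  y <- droplevels(y)
  feats <- names(x)
  status <- setNames(rep("tentative", length(feats)), feats)
  hits <- setNames(rep(0L, length(feats)), feats)
  imp_sum <- setNames(rep(0, length(feats)), feats)
  trials <- 0L
  cw <- as.numeric(length(y) / (2 * table(y)))
  names(cw) <- levels(y)

  set.seed(config$seed)
  for (iter in seq_len(config$max_iterations)) {
    undecided <- feats[status == "tentative"]
    if (length(undecided) == 0) break
    live <- feats[status != "rejected"]
    shadows <- lapply(x[undecided], sample)
    names(shadows) <- paste0(".shadow_", undecided)
    design <- cbind(x[live], as.data.frame(shadows))
    fit <- ranger::ranger(
      x = design, y = y, num.trees = config$ensemble_size,
      importance = "impurity", class.weights = cw,
      seed = config$seed + iter, num.threads = 1
    )
    imp <- fit$variable.importance
    shadow_max <- max(imp[names(shadows)])
    real_imp <- imp[live]
    imp_sum[live] <- imp_sum[live] + real_imp
    trials <- trials + 1L
    hits[undecided] <- hits[undecided] +
      as.integer(real_imp[undecided] > shadow_max)
    for (f in undecided) {
      p <- binom.test(hits[[f]], trials, p = 0.5,
                      alternative = "two.sided")$p.value
      if (p < config$alpha) {
        status[[f]] <- if (hits[[f]] > trials / 2) "confirmed" else "rejected"
      }
    }
  }
  out <- tibble::tibble(
    feature = feats,
    status = unname(status[feats]),
    hits = unname(hits[feats]),
    trials = trials,
    mean_importance = unname(imp_sum[feats]) / pmax(trials, 1L)
  )
  class(out) <- c("vd_boruta", class(out))
  attr(out, "config") <- config
  out
}

#' @export
print.vd_boruta <- function(x, ...) {
  cat(sprintf("<vd_boruta> %d features: %d confirmed, %d rejected, %d tentative (%d trials)\n",
              nrow(x), sum(x$status == "confirmed"), sum(x$status == "rejected"),
              sum(x$status == "tentative"), max(x$trials)))
  NextMethod()
}

#' @rdname boruta_select
#' @exportS3Method generics::tidy
tidy.vd_boruta <- function(x, ...) {
  tibble::as_tibble(unclass(x)[c("feature", "status", "hits", "trials",
                                 "mean_importance")])
}

#' @rdname boruta_select
#' @exportS3Method generics::glance
glance.vd_boruta <- function(x, ...) {
  tibble::tibble(
    n_features = nrow(x),
    n_confirmed = sum(x$status == "confirmed"),
    n_rejected = sum(x$status == "rejected"),
    n_tentative = sum(x$status == "tentative"),
    trials = max(x$trials)
  )
}

#' Plot Boruta feature importances by decision
#'
#' @param object A `vd_boruta` result.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.vd_boruta <- function(object, ...) {
  df <- dplyr::arrange(tidy(object), .data$mean_importance)
  df$feature <- factor(df$feature, levels = df$feature)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean_importance, y = .data$feature,
                                   fill = .data$status)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "mean impurity importance", y = NULL,
                  title = "Boruta feature decisions") +
    ggplot2::theme_minimal()
}

#' One-way ANOVA F-scores of features against the voxel label
#'
#' Classic equal-variance one-way F statistic between the positive and
#' negative voxel groups, used to report the relative discriminative
#' power of selected features. Conventions for degenerate inputs: a
#' feature constant everywhere scores 0; a feature with between-group
#' separation but zero within-group variance scores `Inf` capped at
#' `cap`.
#'
#' @param x Data frame or matrix of features.
#' @param y Binary labels.
#' @param cap Sentinel replacing infinite F (default `1e12`).
#' @return A tibble with columns `feature`, `f_score`, sorted
#'   decreasing.
#' @export
anova_f_scores <- function(x, y, cap = 1e12) {
  x <- as.data.frame(x)
  y <- droplevels(as.factor(y))
  if (nlevels(y) != 2) abort("y must contain exactly two classes")
  f <- vapply(x, function(v) {
    if (var(v) == 0) return(0)
    groups <- split(v, y)
    if (all(vapply(groups, function(g) length(g) < 2 || var(g) == 0, logical(1)))) {
      means <- vapply(groups, mean, numeric(1))
      return(if (isTRUE(all.equal(means[1], means[2]))) 0 else Inf)
    }
    unname(oneway.test(v ~ y, var.equal = TRUE)$statistic)
  }, numeric(1))
  f[is.infinite(f)] <- cap
  f[is.na(f)] <- 0
  dplyr::arrange(tibble::tibble(feature = names(f), f_score = unname(f)),
                 dplyr::desc(.data$f_score))
}

#' Keep the Boruta-selected feature columns of a voxel table
#'
#' @param table A voxel feature table.
#' @param decisions A `vd_boruta` result covering the table's feature
#'   columns.
#' @param keep_tentative Keep tentative features too (default `FALSE`).
#' @return The table restricted to metadata plus selected features.
#' @export
apply_selection <- function(table, decisions, keep_tentative = FALSE) {
  wanted <- if (keep_tentative) c("confirmed", "tentative") else "confirmed"
  sel <- decisions$feature[decisions$status %in% wanted]
  missing <- setdiff(feature_cols(table), decisions$feature)
  if (length(missing) > 0) {
    abort(paste0("decisions do not cover column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (length(sel) == 0) abort("no features selected; refusing to emit an empty design matrix")
  keep <- c(intersect(meta_cols, names(table)), intersect(names(table), sel))
  out <- table[, keep]
  attr(out, "grid") <- attr(table, "grid")
  out
}
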