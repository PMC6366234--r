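# Uplift suitability: presence/absence assembly, random-forest ensemble with
# cross-validation, ROC/TSS metrics and the range-masked binary map.

STATIC_CONTINUOUS <- c("dem", "slope", "aspect", "roughness", "tpi",
                       "slope_unevenness", "aspect_unevenness", "ndvi")
DYNAMIC_LAYERS <- c("thermal_uplift", "orographic_uplift")

framework_layers <- function(framework) {
  switch(framework,
         static = c(STATIC_CONTINUOUS, "urban_footprint", "land_use"),
         dynamic = DYNAMIC_LAYERS,
         combined = c(STATIC_CONTINUOUS, "urban_footprint", "land_use",
                      DYNAMIC_LAYERS),
         stop("framework must be static, dynamic or combined", call. = FALSE))
}

# Extract the predictor matrix for a framework at point locations.
# Categorical land use is one-hot encoded (one 0/1 column per class) so the
# forest can attribute importance per class.
extract_predictors <- function(stack, x, y, framework) {
  lays <- framework_layers(framework)
  miss <- setdiff(lays, names(stack$layers))
  if (length(miss))
    stop("stack lacks layers: ", paste(miss, collapse = ", "), call. = FALSE)
  out <- data.frame(row.names = seq_along(x))
  for (nm in setdiff(lays, "land_use"))
    out[[nm]] <- raster_extract(stack$layers[[nm]], x, y)
  if ("land_use" %in% lays) {
    lu <- raster_extract(stack$layers$land_use, x, y)
    lev <- stack$layers$land_use$levels
    for (i in seq_along(lev))
      out[[paste0("land_use_", lev[i])]] <- as.numeric(lu == i)
  }
  out
}

#' Assemble presence/absence uplift observations with predictors
#'
#' Presences are soaring-event centroids, absences flapping-burst locations.
#' Predictor values are extracted from the stack according to the modelling
#' framework (`static`: terrain, NDVI, land use, urban footprint;
#' `dynamic`: thermal and orographic uplift potential; `combined`: both).
#' Observations with any missing predictor are dropped (count in attribute
#' `"n_dropped"`); the min/max of every continuous predictor over the
#' retained observations is recorded in attribute `"training_ranges"` for
#' later extrapolation masking.
#'
#' @param events soaring events from [extract_soaring_events()].
#' @param flaps absence observations from [select_flapping()].
#' @param stack a `uls_stack` covering the observation locations.
#' @param framework `"static"`, `"dynamic"` or `"combined"`.
#' @return data.frame with `presence` (1/0), `x`, `y` and one column per
#'   predictor; attributes `framework`, `training_ranges`, `n_dropped`.
#' @export
assemble_observations <- function(events, flaps, stack,
                                  framework = "static") {
  pts <- rbind(
    data.frame(presence = rep(1L, nrow(events)), x = events$x, y = events$y),
    data.frame(presence = rep(0L, nrow(flaps)), x = flaps$x, y = flaps$y))
  pred <- extract_predictors(stack, pts$x, pts$y, framework)
  keep <- stats::complete.cases(pred)
  n_dropped <- sum(!keep)
  if (n_dropped)
    message(n_dropped, " observations dropped for missing predictors")
  obs <- cbind(pts[keep, ], pred[keep, , drop = FALSE])
  if (!any(obs$presence == 1) || !any(obs$presence == 0))
    stop("need both presences and absences after filtering", call. = FALSE)
  cont <- intersect(framework_layers(framework),
                    c(STATIC_CONTINUOUS, DYNAMIC_LAYERS))
  ranges <- lapply(cont, function(nm) range(obs[[nm]]))
  names(ranges) <- cont
  attr(obs, "framework") <- framework
  attr(obs, "training_ranges") <- ranges
  attr(obs, "n_dropped") <- n_dropped
  obs
}

#' ROC AUC (trapezoidal)
#'
#' Area under the receiver operating characteristic computed by the
#' trapezoidal rule, with scores oriented so that higher scores indicate
#' presence.
#'
#' @param labels 0/1 vector.
#' @param scores numeric score vector.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(labels, scores) {
  r <- pROC::roc(labels, scores, levels = c(0, 1), direction = "<",
                 quiet = TRUE)
  as.numeric(pROC::auc(r))
}

#' Sensitivity, specificity and TSS at a threshold
#'
#' Presence is predicted where `scores >= threshold`. Sensitivity is the
#' proportion of presences correctly classified, specificity the proportion
#' of absences, and the true skill statistic is
#' sensitivity + specificity - 1.
#'
#' @param labels 0/1 vector (both classes present).
#' @param scores numeric scores.
#' @param threshold classification cut.
#' @return named vector `c(sensitivity, specificity, tss)`.
#' @export
confusion_metrics <- function(labels, scores, threshold) {
  if (length(unique(labels)) < 2)
    stop("metrics undefined: only one class in labels", call. = FALSE)
  pred <- scores >= threshold
  sens <- sum(pred & labels == 1) / sum(labels == 1)
  spec <- sum(!pred & labels == 0) / sum(labels == 0)
  c(sensitivity = sens, specificity = spec, tss = sens + spec - 1)
}

#' Threshold maximizing the true skill statistic
#'
#' Scans the grid of observed score values; ties are broken towards the
#' larger threshold.
#'
#' @inheritParams confusion_metrics
#' @return the maximizing threshold.
#' @export
max_tss_threshold <- function(labels, scores) {
  if (length(unique(labels)) < 2)
    stop("threshold undefined: only one class in labels", call. = FALSE)
  cand <- sort(unique(scores))
  tss <- vapply(cand, function(t)
    confusion_metrics(labels, scores, t)[["tss"]], numeric(1))
  best <- max(tss)
  cand[max(which(tss == best))]
}

#' Fit the random-forest uplift suitability model with cross-validation
#'
#' Runs `n_runs` independent 90/10 splits. Each run trains a regression
#' forest (500 trees) on the 0/1 response, so predictions are uplift
#' probabilities, and is evaluated on the held-out 10%: train and test ROC
#' AUC, and sensitivity/specificity/TSS at the run's max-TSS threshold. A
#' split that leaves a single class in the test set is redrawn with an
#' incremented sub-seed. Variable importances (accuracy decrease `%IncMSE`
#' and node-purity increase) are averaged across runs; the ensemble
#' threshold is the mean of the per-run max-TSS thresholds.
#'
#' @param obs observations from [assemble_observations()].
#' @param seed master seed; run `r` uses `seed + r`.
#' @param n_runs number of train/test partitions.
#' @param test_frac held-out fraction.
#' @param prevalence optional presence:absence ratio; absences are resampled
#'   to `n_presences / prevalence` before splitting.
#' @param ntree trees per forest.
#' @return object of class `uls_rf_ensemble`: `forests`, `metrics`
#'   (per-run data.frame), `threshold`, `importance`, `framework`,
#'   `training_ranges`, `predictors`.
#' @export
fit_rf_cv <- function(obs, seed = 1, n_runs = 10, test_frac = 0.10,
                      prevalence = NULL, ntree = 500) {
  pred_cols <- setdiff(names(obs), c("presence", "x", "y"))
  if (nrow(obs) < 100 || length(unique(obs$presence)) < 2)
    stop("need >= 100 observations with both classes", call. = FALSE)
  if (!is.null(prevalence)) {
    pres <- which(obs$presence == 1); abs_ <- which(obs$presence == 0)
    n_abs <- max(1L, round(length(pres) / prevalence))
    set.seed(seed)
    abs_ <- sample(abs_, n_abs, replace = n_abs > length(abs_))
    obs <- obs[c(pres, abs_), ]
  }
  n <- nrow(obs)
  X <- obs[, pred_cols, drop = FALSE]
  y <- obs$presence
  forests <- vector("list", n_runs)
  rows <- vector("list", n_runs)
  imp <- NULL
  for (r in seq_len(n_runs)) {
    sub <- 0L
    repeat {
      set.seed(seed + r + 1000L * sub)
      test <- sample(n, max(1, round(test_frac * n)))
      if (length(unique(y[test])) == 2 &&
          length(unique(y[-test])) == 2) break
      sub <- sub + 1L
      message("run ", r, ": single-class split, redrawing (", sub, ")")
    }
    rf <- withCallingHandlers(
      randomForest::randomForest(
        x = X[-test, , drop = FALSE], y = y[-test],
        ntree = ntree, mtry = max(1, floor(sqrt(length(pred_cols)))),
        importance = TRUE),
      # regression trees on the 0/1 response are intentional: predictions
      # are probabilities
      warning = function(w) {
        if (grepl("five or fewer unique values", conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
    sc_test <- stats::predict(rf, X[test, , drop = FALSE])
    sc_train <- stats::predict(rf)   # out-of-bag scores for the training side
    thr <- max_tss_threshold(y[test], sc_test)
    cm <- confusion_metrics(y[test], sc_test, thr)
    rows[[r]] <- data.frame(
      run = r,
      auc_train = roc_auc(y[-test], sc_train),
      auc_test = roc_auc(y[test], sc_test),
      threshold = thr,
      sensitivity = cm[["sensitivity"]], specificity = cm[["specificity"]],
      tss = cm[["tss"]])
    forests[[r]] <- rf
    im <- randomForest::importance(rf)
    imp <- if (is.null(imp)) im else imp + im
  }
  metrics <- do.call(rbind, rows)
  structure(list(
    forests = forests, metrics = metrics,
    threshold = mean(metrics$threshold),
    importance = imp / n_runs,
    framework = attr(obs, "framework"),
    training_ranges = attr(obs, "training_ranges"),
    predictors = pred_cols, n_obs = n),
    class = "uls_rf_ensemble")
}

#' @export
print.uls_rf_ensemble <- function(x, ...) {
  cat(sprintf("<uls_rf_ensemble> %s framework, %d runs, %d obs\n",
              x$framework, nrow(x$metrics), x$n_obs))
  cat(sprintf("  mean test AUC %.3f, threshold %.3f, TSS %.3f\n",
              mean(x$metrics$auc_test), x$threshold, mean(x$metrics$tss)))
  invisible(x)
}

#' Predict the uplift suitability map from a fitted ensemble
#'
#' Cells with any continuous predictor missing or outside its training range
#' are left unclassified (the forest does not extrapolate); elsewhere the
#' probability is the cell-wise mean over the ensemble's forests and the
#' binary layer applies the ensemble's max-TSS threshold.
#'
#' @param ensemble a `uls_rf_ensemble`.
#' @param stack a `uls_stack` providing the ensemble's predictor layers.
#' @return object of class `uls_suitability`: `probability` and `binary`
#'   `uls_raster`s (binary: 1 suitable, 0 unsuitable, NA unclassified),
#'   `mask` (TRUE where unclassified) and `threshold`.
#' @export
predict_map <- function(ensemble, stack) {
  fw <- ensemble$framework
  cc <- raster_coords(stack$layers[[1]])
  pred <- extract_predictors(stack, cc$x, cc$y, fw)
  ok <- stats::complete.cases(pred)
  for (nm in names(ensemble$training_ranges)) {
    rg <- ensemble$training_ranges[[nm]]
    ok <- ok & !is.na(pred[[nm]]) & pred[[nm]] >= rg[1] & pred[[nm]] <= rg[2]
  }
  prob <- rep(NA_real_, nrow(pred))
  if (any(ok)) {
    Xok <- pred[ok, ensemble$predictors, drop = FALSE]
    ps <- vapply(ensemble$forests, function(rf) stats::predict(rf, Xok),
                 numeric(sum(ok)))
    prob[ok] <- rowMeans(ps)
  }
  g <- stack$grid
  pm <- matrix(NA_real_, g$nrow, g$ncol)
  pm[cbind(cc$row, cc$col)] <- prob
  bm <- matrix(NA_real_, g$nrow, g$ncol)
  bm[cbind(cc$row, cc$col)] <- ifelse(is.na(prob), NA,
                                      as.numeric(prob >= ensemble$threshold))
  mk <- function(v) uls_raster(v, stack$layers[[1]]$xmin,
                               stack$layers[[1]]$ymin, g$res)
  structure(list(probability = mk(pm), binary = mk(bm),
                 mask = mk(matrix(as.numeric(is.na(pm)), g$nrow, g$ncol)),
                 threshold = ensemble$threshold),
            class = "uls_suitability")
}

#' @export
print.uls_suitability <- function(x, ...) {
  v <- x$binary$values
  cat(sprintf(paste0("<uls_suitability> threshold %.3f; %.1f%% suitable, ",
                     "%.1f%% unsuitable, %.1f%% unclassified\n"),
              x$threshold, 100 * mean(v == 1, na.rm = TRUE) * mean(!is.na(v)),
              100 * mean(v == 0, na.rm = TRUE) * mean(!is.na(v)),
              100 * mean(is.na(v))))
  invisible(x)
}
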