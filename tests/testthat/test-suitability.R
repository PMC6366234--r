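# Presence/absence metrics, TSS thresholding, AUC, the cross-validated
# forest, and map prediction with extrapolation masking.

test_that("confusion metrics match hand-computed confusion matrices", {
  # perfect scores at threshold 0.5
  expect_equal(unname(confusion_metrics(c(0, 0, 1, 1), c(0, 0, 1, 1), 0.5)),
               c(1, 1, 1))
  # TP=83 FN=17 TN=69 FP=31 -> sens 0.83, spec 0.69, TSS 0.52
  labels <- c(rep(1, 100), rep(0, 100))
  scores <- c(rep(0.9, 83), rep(0.1, 17), rep(0.1, 69), rep(0.9, 31))
  expect_equal(unname(confusion_metrics(labels, scores, 0.5)),
               c(0.83, 0.69, 0.52))
  # all scores 1: sens 1, spec 0, TSS 0
  expect_equal(unname(confusion_metrics(c(0, 1), c(1, 1), 0.5)), c(1, 0, 0))
  expect_error(confusion_metrics(c(1, 1), c(0.5, 0.7), 0.5), "one class")
})

test_that("max-TSS threshold scans observed scores, ties to the larger cut", {
  # separable case: any cut in (0.2, 0.8] is perfect; the scanned grid
  # returns 0.8
  expect_equal(max_tss_threshold(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9)), 0.8)
  # anti-ordered labels: best TSS is 0 at a degenerate cut
  lab <- c(1, 1, 0, 0); sc <- c(0.1, 0.2, 0.8, 0.9)
  thr <- max_tss_threshold(lab, sc)
  expect_equal(confusion_metrics(lab, sc, thr)[["tss"]], 0)
  expect_error(max_tss_threshold(c(1, 1), c(0.1, 0.9)), "one class")
})

test_that("threshold and AUC match exhaustive / rank-statistic oracles", {
  set.seed(51)
  for (rep_ in 1:40) {
    n <- sample(10:200, 1)
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) next
    scores <- round(runif(n), sample(c(1, 2, 6), 1))  # allow heavy ties
    # exhaustive scan over all observed cuts
    cand <- sort(unique(scores))
    tss <- sapply(cand, function(t) {
      pred <- scores >= t
      sum(pred & labels == 1) / sum(labels == 1) +
        sum(!pred & labels == 0) / sum(labels == 0) - 1
    })
    best <- cand[max(which(tss == max(tss)))]
    expect_identical(max_tss_threshold(labels, scores), best)
    # trapezoidal AUC equals the Mann-Whitney statistic / (n1 n0)
    s1 <- scores[labels == 1]; s0 <- scores[labels == 0]
    u <- sum(outer(s1, s0, ">")) + 0.5 * sum(outer(s1, s0, "=="))
    expect_equal(roc_auc(labels, scores), u / (length(s1) * length(s0)),
                 tolerance = 1e-9)
  }
})

test_that("observation assembly extracts per-framework predictors and ranges", {
  L <- tiny_landscape()
  stack <- landscape_stack(L)
  set.seed(52)
  ev <- data.frame(x = runif(300, 500, 7500), y = runif(300, 500, 7500))
  fl <- data.frame(x = runif(40, 500, 7500), y = runif(40, 500, 7500))
  obs <- assemble_observations(ev, fl, stack, "static")
  expect_setequal(unique(obs$presence), c(0, 1))
  expect_true(all(c("dem", "slope", "roughness", "ndvi",
                    "land_use_water", "urban_footprint") %in% names(obs)))
  rg <- attr(obs, "training_ranges")
  expect_equal(unname(rg$dem), range(obs$dem))
  # dynamic framework: exactly the two uplift potentials
  obd <- assemble_observations(ev, fl, stack, "dynamic")
  expect_setequal(setdiff(names(obd), c("presence", "x", "y")),
                  c("thermal_uplift", "orographic_uplift"))
  # a point outside the grid has missing predictors and is dropped
  ev2 <- rbind(ev, data.frame(x = -500, y = -500))
  expect_message(ob2 <- assemble_observations(ev2, fl, stack, "static"),
                 "dropped")
  expect_equal(attr(ob2, "n_dropped"), nrow(ev2) + nrow(fl) - nrow(ob2))
  expect_error(assemble_observations(ev[0, ], fl, stack, "static"), "presence")
})

test_that("a forest on shuffled labels is indistinguishable from chance", {
  set.seed(53)
  n <- 2000
  obs <- data.frame(presence = rbinom(n, 1, 0.5),
                    x = runif(n), y = runif(n),
                    a = rnorm(n), b = rnorm(n), c = rnorm(n))
  attr(obs, "framework") <- "static"
  attr(obs, "training_ranges") <- list(a = c(-4, 4))
  rf <- fit_rf_cv(obs, seed = 2, n_runs = 5, ntree = 200)
  expect_lt(abs(mean(rf$metrics$auc_test) - 0.5), 0.05)
})

test_that("the forest recovers a planted logistic dependence and its drivers", {
  set.seed(54)
  n <- 1500
  d <- data.frame(roughness = rnorm(n), dem = rnorm(n), ndvi = rnorm(n),
                  junk1 = rnorm(n), junk2 = rnorm(n))
  p <- plogis(1.6 * d$roughness + 1.2 * d$dem - 0.8 * d$ndvi)
  obs <- cbind(presence = rbinom(n, 1, p), x = runif(n), y = runif(n), d)
  attr(obs, "framework") <- "static"
  attr(obs, "training_ranges") <- lapply(d, range)
  rf <- fit_rf_cv(obs, seed = 3, n_runs = 5, ntree = 300)
  expect_gte(mean(rf$metrics$auc_test), 0.80)
  imp <- sort(rf$importance[, 1], decreasing = TRUE)
  expect_true(all(c("roughness", "dem") %in% names(imp)[1:3]))
  expect_true(all(rf$metrics$threshold > 0 & rf$metrics$threshold < 1))
  # prevalence manipulation changes the class balance before splitting
  rf2 <- fit_rf_cv(obs, seed = 3, n_runs = 2, ntree = 100, prevalence = 5)
  expect_equal(round(rf2$n_obs), sum(obs$presence == 1) +
                 round(sum(obs$presence == 1) / 5))
})

test_that("map prediction masks extrapolation and missing predictors", {
  L <- tiny_landscape()
  stack <- landscape_stack(L)
  set.seed(55)
  ev <- data.frame(x = runif(400, 500, 7500), y = runif(400, 500, 7500))
  fl <- data.frame(x = runif(60, 500, 7500), y = runif(60, 500, 7500))
  obs <- assemble_observations(ev, fl, stack, "static")
  rf <- fit_rf_cv(obs, seed = 4, n_runs = 3, ntree = 100)
  # shrink one training range artificially: cells beyond it must be masked
  rf$training_ranges$dem[2] <- unname(quantile(obs$dem, 0.8))
  map <- predict_map(rf, stack)
  cc <- raster_coords(stack$layers$dem)
  dem <- stack$layers$dem$values[cbind(cc$row, cc$col)]
  prob <- map$probability$values[cbind(cc$row, cc$col)]
  expect_true(all(is.na(prob[!is.na(dem) & dem > rf$training_ranges$dem[2]])))
  # classified cells lie within every training range
  ok <- !is.na(prob)
  for (nm in names(rf$training_ranges)) {
    v <- stack$layers[[nm]]$values[cbind(cc$row, cc$col)]
    rg <- rf$training_ranges[[nm]]
    expect_true(all(v[ok] >= rg[1] & v[ok] <= rg[2]), label = nm)
  }
  # binary layer applies the ensemble threshold outside the mask
  bin <- map$binary$values[cbind(cc$row, cc$col)]
  expect_equal(bin[ok], as.numeric(prob[ok] >= map$threshold))
  expect_true(all(is.na(bin[!ok])))
})
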