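# Fix metrics, 15 s segments, EMbC-style classification, label smoothing,
# soaring-event extraction.

test_that("fix metrics follow their definitions", {
  # constant height: vertical speed zero everywhere defined
  b <- make_burst(x = seq(0, 140, 10), y = rep(0, 15), h = rep(100, 15))
  m <- compute_fix_metrics(b)
  expect_true(all(m$vspeed[-15] == 0))
  expect_true(is.na(m$vspeed[15]))

  # heights 100, 102.5 at 1 s spacing: vertical speed 2.5 m/s
  b2 <- make_burst(x = c(0, 10, 20), y = c(0, 0, 0), h = c(100, 102.5, 105))
  expect_equal(compute_fix_metrics(b2)$vspeed[1], 2.5)

  # due-east then due-north step: 90 degree turn at the middle fix
  b3 <- make_burst(x = c(0, 10, 10), y = c(0, 0, 10), h = rep(100, 3))
  m3 <- compute_fix_metrics(b3)
  expect_equal(m3$turn[2], 90)
  expect_true(is.na(m3$turn[1]) && is.na(m3$turn[3]))

  # duplicate timestamps are rejected
  b4 <- b3; b4$timestamp[2] <- b4$timestamp[1]
  expect_error(compute_fix_metrics(b4), "duplicate")
  expect_error(compute_fix_metrics(b3[1:2, ]), "3 fixes")

  # lon/lat fall back to a local projection about the burst centroid
  b5 <- b3; b5$x <- NULL; b5$y <- NULL
  b5$lon <- 8 + c(0, 10, 10) / (111320 * cos(44 * pi / 180))
  b5$lat <- 44 + c(0, 0, 10) / 111320
  expect_equal(compute_fix_metrics(b5)$turn[2], 90, tolerance = 1e-3)
})

test_that("segment construction: counts, circle turning, straight climbs", {
  # 120 s burst -> 8 segments of 15 s
  n <- 120
  b <- make_burst(x = seq_len(n) * 10, y = rep(0, n), h = rep(100, n))
  s <- build_segments(compute_fix_metrics(b))
  expect_equal(nrow(s), 8)
  expect_true(all(s$duration == 15))

  # a uniform 24 deg/s circle: interior segments sum to ~360
  th <- (0:(n - 1)) * 24 * pi / 180
  bc <- make_burst(x = 30 * cos(th), y = 30 * sin(th), h = 100 + 0.5 * (0:(n - 1)))
  sc <- build_segments(compute_fix_metrics(bc))
  expect_true(all(abs(sc$cum_turn[2:7] - 360) < 1))
  expect_equal(sc$mean_vspeed[3], 0.5, tolerance = 1e-9)

  # straight constant climb: zero turning, mean vspeed = climb rate
  bs <- make_burst(x = seq_len(n) * 12, y = seq_len(n) * 3, h = 100 + 1.4 * seq_len(n))
  ss <- build_segments(compute_fix_metrics(bs))
  expect_true(all(ss$cum_turn < 1e-9))
  expect_true(all(abs(ss$mean_vspeed - 1.4) < 1e-9))

  # bursts shorter than 120 s are ineligible
  expect_null(build_segments(compute_fix_metrics(b[1:100, ])))
})

test_that("EMbC recovers four well-separated quadrant clusters", {
  set.seed(31)
  n <- 125
  segs <- data.frame(
    mean_vspeed = c(rnorm(n, 2, 0.3), rnorm(n, 2, 0.3),
                    rnorm(n, -2, 0.3), rnorm(n, -2, 0.3)),
    cum_turn = abs(c(rnorm(n, 360, 30), rnorm(n, 30, 15),
                     rnorm(n, 360, 30), rnorm(n, 30, 15))))
  truth <- rep(c("circular_soaring", "linear_soaring",
                 "circular_soaring", "gliding"), each = n)
  out <- embc_classify(segs)
  expect_gte(mean(out$behaviour == truth), 0.95)
  fit <- attr(out, "embc_fit")
  expect_true(fit$converged)
  expect_true(fit$delim_turn > 100 && fit$delim_turn < 320)
})

test_that("single-regime and degenerate inputs behave as documented", {
  set.seed(32)
  # all low-turning, descending: everything is gliding
  segs <- data.frame(mean_vspeed = runif(60, -3, -0.5),
                     cum_turn = runif(60, 0, 10))
  expect_true(all(embc_classify(segs)$behaviour == "gliding"))
  # all high-turning, ascending: everything is circular soaring
  segs2 <- data.frame(mean_vspeed = runif(60, 0.5, 3),
                      cum_turn = runif(60, 330, 400))
  expect_true(all(embc_classify(segs2)$behaviour == "circular_soaring"))
  # degenerate inputs
  expect_error(embc_classify(segs[1:10, ]), "20")
  segs3 <- data.frame(mean_vspeed = rep(1, 30), cum_turn = runif(30, 0, 400))
  expect_error(embc_classify(segs3), "variance")
})

test_that("the label smoother relabels only doubly-isolated segments", {
  S <- "circular_soaring"; G <- "gliding"; L <- "linear_soaring"
  expect_equal(smooth_labels(c(S, S, G, S, S)), c(S, S, S, S, S))
  expect_equal(smooth_labels(c(S, S, S)), c(S, S, S))          # homogeneous
  expect_equal(smooth_labels(c(S, G, G, S)), c(S, G, G, S))    # agrees once
  # tie in the modal vote keeps the original label
  expect_equal(smooth_labels(c(S, G, L, G, S))[3], L)
  # edge segments have a single neighbour: never relabelled
  expect_equal(smooth_labels(c(G, S, S)), c(G, S, S))
})

test_that("two smoother passes reach a fixed point on all short sequences", {
  labs <- c("circular_soaring", "gliding", "linear_soaring")
  grid <- expand.grid(rep(list(1:3), 7))
  for (i in seq_len(nrow(grid))) {
    x <- labs[as.integer(grid[i, ])]
    s2 <- smooth_labels(smooth_labels(x))
    expect_identical(smooth_labels(s2), s2)
  }
})

test_that("soaring events pool soaring, merge short gaps and drop short runs", {
  t0 <- as.POSIXct("2014-08-01 08:00:00", tz = "UTC")
  mkseg <- function(i, beh) data.frame(
    individual = "b1", burst_id = "r1", seg = i,
    t_start = t0 + (i - 1) * 15, t_end = t0 + i * 15 - 1, duration = 15,
    mean_vspeed = ifelse(beh == "gliding", -1.5, 1.5), cum_turn = 100,
    n_fix = 15, x = i * 100, y = 0, behaviour = beh)
  segs <- do.call(rbind, lapply(seq_len(12), function(i) mkseg(i,
    c("circular_soaring", "circular_soaring", "linear_soaring",  # run 1: 45 s
      "gliding", "gliding",                                      # 30 s gap
      "circular_soaring", "circular_soaring", "circular_soaring",# run 2: 45 s
      "gliding", "gliding", "gliding", "gliding")[i])))
  ev <- extract_soaring_events(segs)
  # 30 s gap < 60 s: both runs merge into a single event of 90 s soaring
  expect_equal(nrow(ev), 1)
  expect_equal(ev$duration, 90)
  expect_equal(ev$n_seg, 6)
  # centroid is the fix-weighted mean of member segment positions
  expect_equal(ev$x, mean(c(1:3, 6:8) * 100))

  # a single 15 s soaring segment is not an event (> 30 s rule)
  one <- rbind(mkseg(1, "circular_soaring"), mkseg(2, "gliding"))
  expect_equal(nrow(extract_soaring_events(one)), 0)
  # a 45 s run alone is one event
  run3 <- do.call(rbind, lapply(1:3, function(i) mkseg(i, "linear_soaring")))
  ev3 <- extract_soaring_events(run3)
  expect_equal(nrow(ev3), 1)
  expect_equal(ev3$duration, 45)
  # runs separated by >= 60 s stay separate events
  far <- do.call(rbind, lapply(seq_len(11), function(i) mkseg(i,
    c(rep("circular_soaring", 3), rep("gliding", 4),
      rep("circular_soaring", 3), "gliding")[i])))
  expect_equal(nrow(extract_soaring_events(far)), 2)
})

test_that("segment time is conserved through the pipeline", {
  sim <- tiny_sim()
  segs <- segment_bursts(sim$gps)
  gb <- sim$gps[!is.na(sim$gps$burst_id), ]
  per_burst <- tapply(as.numeric(gb$timestamp), gb$burst_id,
                      function(t) max(t) - min(t) + 1)
  dropped <- sum(per_burst %% 15) + sum(per_burst[per_burst < 120])
  expect_equal(sum(segs$duration), sum(per_burst) - dropped)
})
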