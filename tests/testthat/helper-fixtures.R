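# Shared fixtures, memoized so expensive simulations run once per session.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_env))
    assign(key, force(expr), envir = .fixture_env)
  get(key, envir = .fixture_env)
}

# Standard fixture: the full pipeline on the default study conditions
# (landscape seed 42, 20 birds, 4 days), writing all outputs.
std_pipeline <- function() {
  memo("std_pipeline", {
    out <- file.path(tempdir(), "uls_std_pipeline")
    t0 <- Sys.time()
    res <- suppressWarnings(suppressMessages(
      run_pipeline(seed = 42, out_dir = out, quiet = TRUE)))
    attr(res, "elapsed_min") <-
      as.numeric(difftime(Sys.time(), t0, units = "mins"))
    res
  })
}

std_out_dir <- function() {
  std_pipeline()
  file.path(tempdir(), "uls_std_pipeline")
}

# Small simulation for unit tests: 6 birds, 1 day.
tiny_sim <- function() {
  memo("tiny_sim", {
    L <- tiny_landscape()
    simulate_tracks(L, n_birds = 6, seed = 7,
                    schedule = schedule_config(n_days = 1))
  })
}

tiny_landscape <- function() {
  memo("tiny_landscape", generate_landscape(11, shape = c(80, 80)))
}

# Random ACC burst: sinusoid + noise, arbitrary offsets per axis.
random_burst <- function(n = 40) {
  amp <- stats::runif(3, 0, 2)
  off <- stats::rnorm(3, 0, 1)
  fr <- stats::runif(3, 0.5, 5)
  tt <- seq_len(n) / 10.54
  m <- sapply(1:3, function(a)
    off[a] + amp[a] * sin(2 * pi * fr[a] * tt) + stats::rnorm(n, 0, 0.1))
  colnames(m) <- c("x", "y", "z")
  m
}

# Brute-force ODBA statistics, written independently of compute_odba.
odba_oracle <- function(m) {
  out <- numeric(6)
  n <- nrow(m)
  dyn <- matrix(0, n, 3)
  for (a in 1:3) {
    st <- sum(m[, a]) / n
    for (i in seq_len(n)) dyn[i, a] <- abs(m[i, a] - st)
  }
  odba <- numeric(n)
  for (i in seq_len(n)) odba[i] <- dyn[i, 1] + dyn[i, 2] + dyn[i, 3]
  c(mean(odba), sum(odba), stats::sd(odba),
    mean(dyn[, 3]), sum(dyn[, 3]), stats::sd(dyn[, 3]))
}

# A GPS burst data.frame from raw vectors (1 Hz).
make_burst <- function(x, y, h, t0 = as.POSIXct("2014-08-01 08:00:00",
                                                tz = "UTC")) {
  n <- length(x)
  data.frame(individual = "b1", burst_id = "b1_r1",
             timestamp = t0 + seq_len(n) - 1,
             x = x, y = y, height_ellipsoid = h,
             ground_speed = c(sqrt(diff(x)^2 + diff(y)^2), NA))
}

# Independent sliding-window oracle for the terrain derivatives.
terrain_oracle <- function(z, res) {
  nr <- nrow(z); nc <- ncol(z)
  slope <- aspect <- rough <- tpi <- matrix(NA_real_, nr, nc)
  for (i in 2:(nr - 1)) for (j in 2:(nc - 1)) {
    w <- z[(i - 1):(i + 1), (j - 1):(j + 1)]
    if (anyNA(w)) next
    a <- w[1, 1]; b <- w[1, 2]; cc <- w[1, 3]
    d <- w[2, 1];               f <- w[2, 3]
    g <- w[3, 1]; h <- w[3, 2]; ii <- w[3, 3]
    dzdx <- ((cc + 2 * f + ii) - (a + 2 * d + g)) / (8 * res)
    dzdy <- ((a + 2 * b + cc) - (g + 2 * h + ii)) / (8 * res)
    slope[i, j] <- atan(sqrt(dzdx^2 + dzdy^2)) * 180 / pi
    if (slope[i, j] > 0)
      aspect[i, j] <- (atan2(-dzdx, -dzdy) * 180 / pi) %% 360
    rough[i, j] <- max(w) - min(w)
    tpi[i, j] <- w[2, 2] - mean(w[-5])
  }
  list(slope = slope, aspect = aspect, roughness = rough, tpi = tpi)
}

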