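test_that("image normalization maps 8-bit intensities onto [0,1]", {
  img <- tiny_image()
  norm <- normalize_image(img)
  expect_equal(norm[img == 255], 1)
  expect_equal(norm[img == 0], 0)
  expect_equal(norm[2, 1], 204 / 255)
  expect_equal(norm[1, 2], 0.2)
  expect_true(all(order(as.vector(norm)) == order(as.vector(img))))
  expect_error(normalize_image(matrix(-1)), "0, 255")
})

test_that("time grid discretizes the window and rejects misaligned steps", {
  g <- time_grid(20, 0.5)
  expect_equal(g$n_steps, 40L)
  expect_equal(g$times[1], 0)
  expect_equal(g$times[40], 19.5)
  expect_error(time_grid(10, 0.3), "integer multiple")
})

test_that("rate mapping scales intensity to Hz and is bounded by 63.75", {
  expect_equal(rate_coding_rate(255, rate_params(4)), 63.75)
  expect_equal(rate_coding_rate(0), 0)
  expect_equal(max(rate_coding_rate(0:255)), 63.75)
})

test_that("rate encoding matches the Bernoulli-sum oracle in mean count", {
  # oracle: sum of n_steps Bernoulli(rate*dt) draws has mean rate*window
  set.seed(11)
  grid <- time_grid(100, 0.5)
  img <- matrix(255, 1, 1)
  n_rep <- 2000
  counts <- replicate(n_rep, sum(encode_rate(img, rate_params(4), grid)$spikes))
  p <- 63.75 * 0.5 / 1000
  expected <- p * grid$n_steps               # 6.375
  se <- sqrt(grid$n_steps * p * (1 - p) / n_rep)
  expect_equal(expected, 6.375)
  expect_lt(abs(mean(counts) - expected), 3 * se)
  # dark pixel stays silent; reproducibility under a fixed seed
  expect_equal(sum(encode_rate(matrix(0, 1, 1), grid = grid)$spikes), 0)
  r1 <- withr::with_seed(5, encode_rate(tiny_image(), grid = grid))
  r2 <- withr::with_seed(5, encode_rate(tiny_image(), grid = grid))
  expect_identical(r1$spikes, r2$spikes)
})

test_that("rate encoding refuses probabilities above one", {
  expect_error(
    encode_rate(matrix(255, 1, 1), rate_params(0.01), time_grid(10, 0.5)),
    "probability"
  )
})

test_that("TTFS threshold decays exponentially from theta0", {
  p <- ttfs_params(tau_th = 6)
  expect_equal(ttfs_threshold(0, p), 1)
  expect_equal(ttfs_threshold(6, p), exp(-1))
  expect_gt(ttfs_threshold(6, p), ttfs_threshold(12, p))
  ts <- seq(0, 20, by = 0.5)
  expect_true(all(diff(ttfs_threshold(ts, p)) < 0))
})

test_that("TTFS spike weight favors early spikes and stays in (0,1]", {
  p <- ttfs_params(tau_s = 15)
  expect_equal(spike_weight_ttfs(0, p), 1)
  expect_equal(spike_weight_ttfs(15, p), exp(-1))
  expect_gt(spike_weight_ttfs(5, p), spike_weight_ttfs(10, p))
  w <- spike_weight_ttfs(seq(0, 100, 0.5), p)
  expect_true(all(w > 0 & w <= 1))
})

test_that("TTFS emits one spike at the first strict threshold crossing", {
  grid <- time_grid(20, 0.5)
  # P = exp(-1) crosses theta0*exp(-t/6) exactly at t = 6; first strict
  # crossing on the grid is 6.5 ms
  r <- encode_ttfs(matrix(exp(-1), 1, 1), ttfs_params(), grid)
  expect_equal(grid$times[which(r$spikes[1, ])], 6.5)
  # P = 0 never crosses a positive threshold
  r0 <- encode_ttfs(matrix(0, 1, 1), ttfs_params(), grid)
  expect_equal(sum(r0$spikes), 0)
  # every representable intensity emits at most one spike
  all_p <- matrix((0:255) / 255, ncol = 1)
  rall <- encode_ttfs(all_p, ttfs_params(), grid)
  counts <- rowSums(rall$spikes)
  expect_true(all(counts <= 1))
  expect_equal(max(counts), 1)
  # determinism
  expect_identical(rall$spikes, encode_ttfs(all_p, ttfs_params(), grid)$spikes)
})

test_that("phase spike weight is periodic with period 8 over (0, 1]", {
  p <- phase_params()
  expect_equal(spike_weight_phase(1, p), 0.5)
  expect_equal(spike_weight_phase(8, p), 2^-8)
  expect_equal(spike_weight_phase(9, p), 0.5)
  t <- 1:64
  w <- spike_weight_phase(t, p)
  expect_equal(w[t], w[((t - 1) %% 8) + 1])
  expect_true(all(w > 0 & w <= 1))
})

test_that("phase encoding emits the binary expansion MSB-first, cyclically", {
  grid <- time_grid(24, 1)
  r255 <- encode_phase(matrix(255, 1, 1), grid = grid)
  expect_true(all(r255$spikes[1, ]))
  r1 <- encode_phase(matrix(1, 1, 1), grid = grid)
  expect_equal(which(r1$spikes[1, ]), c(8L, 16L, 24L))
  expect_equal(r1$spike_weight[8], 2^-8)
  r170 <- encode_phase(matrix(170, 1, 1), grid = grid)
  expect_equal(which(r170$spikes[1, 1:8]), c(1L, 3L, 5L, 7L))
  expect_equal(which(r170$spikes[1, 9:16]), c(1L, 3L, 5L, 7L))
  expect_error(encode_phase(matrix(256, 1, 1), grid = grid), "8 bits")
})

test_that("burst spike count is the ceiling of n_max * P", {
  p <- burst_params(n_max = 5)
  expect_equal(burst_spike_count(1, p), 5L)
  expect_equal(burst_spike_count(0, p), 0L)
  expect_equal(burst_spike_count(0.41, p), 3L)
  P <- seq(0, 1, by = 0.01)
  expect_true(all(diff(burst_spike_count(P, p)) >= 0))
  expect_true(all(burst_spike_count(P[P > 0], p) > 0))
})

test_that("burst ISI shrinks with intensity and is confined to [t_min, t_max]", {
  p <- burst_params(n_max = 5, t_max = 10, t_min = 2)
  expect_equal(burst_isi(1, p), 2)
  expect_equal(burst_isi(0.5, p), 6)
  # single-spike bursts fall back to t_max
  expect_equal(burst_isi(0.1, p), 10)
  P <- seq(0, 1, by = 0.01)
  isi <- burst_isi(P, p)
  expect_true(all(isi >= 2 & isi <= 10))
  expect_true(all(diff(isi) <= 0))
})

test_that("burst encoding places N_s spikes ISI apart from t = 0", {
  grid <- time_grid(20, 0.5)
  r <- encode_burst(matrix(1, 1, 1), burst_params(), grid)
  expect_equal(grid$times[which(r$spikes[1, ])], c(0, 2, 4, 6, 8))
  # the whole burst fits before 20 ms for any intensity
  all_p <- matrix((0:255) / 255, ncol = 1)
  rall <- encode_burst(all_p, burst_params(), grid)
  expect_true(all(rall$spikes[, grid$times >= 20] == FALSE))
  last_spike <- apply(rall$spikes, 1, function(s) {
    k <- which(s)
    if (length(k)) grid$times[max(k)] else NA_real_
  })
  expect_lt(max(last_spike, na.rm = TRUE), 20)
  # silent for P = 0, deterministic otherwise
  expect_equal(sum(encode_burst(matrix(0, 1, 1), grid = grid)$spikes), 0)
  expect_identical(rall$spikes,
                   encode_burst(all_p, burst_params(), grid)$spikes)
})

test_that("spike totals over random images order phase > rate > burst > ttfs", {
  set.seed(202)
  totals <- matrix(0, 100, 4, dimnames = list(NULL, c("phase", "rate", "burst", "ttfs")))
  grid100 <- time_grid(100, 0.5)
  for (i in 1:100) {
    img <- random_image(8)
    totals[i, "phase"] <- sum(encode(img, "phase")$spikes)
    totals[i, "rate"] <- sum(encode_rate(img, rate_params(4), grid100)$spikes)
    totals[i, "burst"] <- sum(encode(img, "burst")$spikes)
    totals[i, "ttfs"] <- sum(encode(img, "ttfs")$spikes)
  }
  m <- colMeans(totals)
  expect_gt(m["phase"], m["rate"])
  expect_gt(m["rate"], m["burst"])
  expect_gt(m["burst"], m["ttfs"])
  # TTFS is bounded by one spike per input
  expect_true(all(totals[, "ttfs"] <= 64))
})

test_that("rasters round-trip through the event-list CSV format", {
  set.seed(3)
  r <- encode(tiny_image(), "phase")
  ev <- raster_events(r)
  expect_equal(nrow(ev), sum(r$spikes))
  path <- withr::local_tempfile(fileext = ".csv")
  write_spike_events(r, path)
  back <- read_spike_events(path)
  expect_equal(back$neuron, ev$neuron)
  expect_equal(back$time_ms, ev$time_ms)
  expect_equal(back$weight, ev$weight)
  expect_equal(attr(back, "scheme"), "phase")
  expect_error(read_spike_events(withr::local_tempfile(lines = "x,y")),
               "v1 event file")
})
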