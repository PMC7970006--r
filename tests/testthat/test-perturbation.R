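test_that("AWGN by SNR hits the target noise power", {
  set.seed(51)
  # constant image: noise s.d. = a / sqrt(snr) before clipping
  a <- 100
  img <- matrix(a, 50, 50)
  snr <- 9.5
  noisy <- awgn_by_snr(img, snr)
  expect_equal(dim(noisy), dim(img))
  expect_true(all(noisy >= 0 & noisy <= 255))
  expect_equal(sd(noisy - img), a / sqrt(snr), tolerance = 0.05)
  # Monte-Carlo: empirical SNR within 5% of the target
  snr_hat <- mean(replicate(200, {
    n <- awgn_by_snr(img, snr)
    mean(img^2) / mean((n - img)^2)
  }))
  expect_lt(abs(snr_hat - snr) / snr, 0.05)
  expect_error(awgn_by_snr(matrix(0, 3, 3), 10), "blank image")
})

test_that("AWGN by sigma adds the stated deviation on interior pixels", {
  set.seed(52)
  img <- matrix(128, 80, 80)
  expect_identical(awgn_by_sigma(img, 0), img)
  noisy <- awgn_by_sigma(img, 25)
  interior <- img > 0 & img < 255 & noisy > 0 & noisy < 255
  expect_equal(sd((noisy - img)[interior]), 25, tolerance = 0.1)
  big <- awgn_by_sigma(img, 500)
  expect_true(all(big >= 0 & big <= 255))
})

test_that("motion blur smears an impulse along the motion line", {
  expect_equal(motion_blur_kernel(1), matrix(1, 1, 1))
  k <- motion_blur_kernel(5, 15)
  expect_equal(sum(k), 1)
  # uniform image unchanged in the interior (kernel is mean-preserving)
  img <- matrix(100, 11, 11)
  blurred <- motion_blur(img, 5, 15)
  expect_equal(blurred[4:8, 4:8], img[4:8, 4:8], tolerance = 1e-9)
  # impulse response: support spans ~5 px along a 15-degree CCW line
  imp <- matrix(0, 11, 11); imp[6, 6] <- 255
  resp <- motion_blur(imp, 5, 15)
  on <- which(resp > 1, arr.ind = TRUE)
  expect_gte(diff(range(on[, 2])) + 1, 4)   # horizontal extent ~length
  expect_lte(diff(range(on[, 1])) + 1, 3)   # shallow 15-degree rise
  expect_equal(sum(resp), 255, tolerance = 1e-6)
  # blur with length 1 is the identity
  expect_equal(motion_blur(imp, 1), imp)
})

test_that("reduced-contrast AWGN rescales about the mean before noising", {
  set.seed(53)
  img <- matrix(c(50, 100, 150, 250), 20, 20)
  m <- mean(img)
  scaled <- m + (img - m) * 0.5
  # contrast range halves before the noise stage
  expect_equal(diff(range(scaled)), diff(range(img)) * 0.5)
  # composition order matters: rescale-then-noise != noise-then-rescale
  withr::with_seed(9, a <- reduced_contrast_awgn(img, 0.5, 12))
  withr::with_seed(9, {
    b <- awgn_by_snr(img, 12)
    b <- mean(b) + (b - mean(b)) * 0.5
  })
  expect_false(isTRUE(all.equal(a, b)))
  # identity limit: full contrast, near-infinite SNR
  near_id <- reduced_contrast_awgn(img, 1, 1e12)
  expect_equal(near_id, img, tolerance = 1e-3)
})

test_that("programming noise scales with the fixed-point precision", {
  set.seed(54)
  eps <- 2^-8
  cfg <- prog_noise_config(sigma_pct = 0.5, epsilon = eps)
  expect_identical(programming_noise(0.25, prog_noise_config(0, eps)), 0.25)
  draws <- programming_noise(rep(0.25, 1e5), cfg)
  expect_equal(sd(draws), 0.5 * eps, tolerance = 0.02)
  expect_equal(mean(draws), 0.25, tolerance = 3 * 0.5 * eps / sqrt(1e5))
  # precision improves with bit width
  expect_lt(quant_config(12)$epsilon, quant_config(8)$epsilon)
})

test_that("SAF mask counts follow the binomial expectation", {
  set.seed(55)
  saf <- sample_saf_mask(c(784, 100), saf_config(0.2, on_ratio = 0.5))
  n_fault <- sum(saf$mask)
  expect_equal(n_fault, round(0.2 * 78400))
  n_on <- sum(saf$values == 1, na.rm = TRUE)
  # on count is half the faults by construction; positions are random
  expect_equal(n_on, round(0.5 * n_fault))
  # the *location* of stuck-on faults is uniform: count in the first half
  # of the matrix is binomial(n_on, 1/2)
  first_half <- sum(saf$values[seq_len(39200)] == 1, na.rm = TRUE)
  expect_lt(abs(first_half - n_on / 2), 3 * sqrt(n_on * 0.25))
  # extremes
  expect_equal(sum(sample_saf_mask(c(10, 10), saf_config(0))$mask), 0)
  all_on <- sample_saf_mask(c(10, 10), saf_config(1, on_ratio = 1))
  expect_true(all(all_on$mask))
  expect_true(all(all_on$values == 1))
})

test_that("stuck-at-fault synapses survive training unchanged", {
  set.seed(56)
  saf <- sample_saf_mask(c(16, 4), saf_config(0.25, on_ratio = 0.5))
  W <- matrix(runif(64), 16, 4)
  W2 <- apply_saf(W, saf)
  expect_identical(W2[!saf$mask], W[!saf$mask])
  expect_equal(W2[saf$mask], saf$values[saf$mask])
  # a full training epoch leaves the stuck values in place
  cfg <- scheme_config("burst", coupling = coupling_params(input_gain = 1))
  topo <- build_topology(16, 4, cfg$coupling)
  topo$saf <- saf
  topo$W <- apply_saf(topo$W, saf)
  for (i in 1:5) {
    res <- run_window(random_image(4), cfg, topo, mode = "train")
    topo <- res$topo
  }
  expect_equal(topo$W[saf$mask], saf$values[saf$mask])
})

test_that("perturbed images remain valid 8-bit images", {
  set.seed(57)
  img <- random_image(10)
  for (kind in c("awgn_snr", "awgn_sigma", "motion_blur",
                 "reduced_contrast_awgn")) {
    out <- switch(kind,
      awgn_snr = perturb_image(img, kind, snr = 9.5),
      awgn_sigma = perturb_image(img, kind, sigma = 40),
      motion_blur = perturb_image(img, kind),
      reduced_contrast_awgn = perturb_image(img, kind))
    expect_equal(dim(out), dim(img))
    expect_true(all(out >= 0 & out <= 255))
  }
  expect_identical(perturb_image(img, "none"), img)
})
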