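test_that("topology wiring follows the winner-take-all pattern", {
  set.seed(7)
  topo <- build_topology(784, 100)
  expect_equal(dim(topo$W), c(784L, 100L))
  expect_true(all(topo$W > 0 & topo$W < 1))
  expect_equal(topo$n_inh, topo$n_exc)
  # lateral inhibition reaches all-but-self: 100 * 99 connections
  expect_equal(topo$n_inh * (topo$n_exc - 1), 9900L)
  expect_false(any(topo$prune_mask))
})

test_that("synaptic input sums weighted spikes only at firing steps", {
  W <- matrix(c(0.3, 0.7, 0.1, 0.2), 2, 2)
  expect_equal(synaptic_input(c(0, 0), 1, W), c(0, 0))
  expect_equal(synaptic_input(c(1, 0), 1, W), c(0.3, 0.1))
  # two spikes, weights 0.3/0.7 onto one target, spike weight 0.5
  expect_equal(synaptic_input(c(1, 1), 0.5, W)[1], 0.5)
})

test_that("LIF membrane leaks toward rest and fires at threshold", {
  lif <- lif_params(tau_m = 10, v_th = 0.5)
  syn <- synapse_params(30)
  # leak only: v decays toward v_rest geometrically
  st <- lif_step(v = 0.4, g_e = 0, g_i = 0, refrac = 0L, z_e = 0,
                 lif = lif, syn = syn, dt = 0.5)
  expect_equal(st$v, 0.4 + 0.05 * (-0.4))
  expect_false(st$fired)
  # crossing the threshold fires and resets
  st2 <- lif_step(v = 0.49, g_e = 0, g_i = 0, refrac = 0L, z_e = 5,
                  lif = lif, syn = syn, dt = 0.5)
  expect_true(st2$fired)
  expect_equal(st2$v, lif$v_reset)
  expect_equal(st2$refrac, 4L)
})

test_that("constant drive settles on the fixed point of the discrete map", {
  # oracle: v* solves v* = v* + (dt/tau_m)(-(v* - v_rest) + g*)  =>  v* = g*
  lif <- lif_params(tau_m = 10, v_th = 1e6)  # threshold out of reach
  syn <- synapse_params(30)
  g_star <- 0.3
  decay <- exp(-0.5 / 30)
  v <- 0
  g <- 0
  for (k in 1:4000) {
    st <- lif_step(v, g, 0, 0L, z_e = g_star * (1 - decay), lif = lif,
                   syn = syn, dt = 0.5)
    v <- st$v; g <- st$g_e
  }
  expect_equal(v, g_star, tolerance = 1e-3)
})

test_that("threshold adaptation increments on spikes and decays between", {
  ad <- adapt_params(theta_plus = 0.008, theta_decay = 100)
  th <- adapt_threshold(rep(0, 3), c(FALSE, TRUE, FALSE), ad, 0.5)
  expect_equal(th, c(0, 0.008, 0))
  th2 <- adapt_threshold(th, rep(FALSE, 3), ad, 0.5)
  expect_equal(th2[2], 0.008 * exp(-0.5 / 100))
  expect_true(all(th2 <= th))
})

test_that("a window over a blank image produces no excitatory spikes", {
  set.seed(21)
  cfg <- scheme_config("ttfs")
  topo <- build_topology(16, 4)
  res <- run_window(matrix(0, 4, 4), cfg, topo, mode = "infer")
  expect_equal(res$trace$output_spikes, 0)
  expect_equal(res$trace$input_spikes, 0)
  expect_equal(res$trace$sops, 0)
})

test_that("run_window is deterministic for deterministic encoders", {
  set.seed(22)
  cfg <- scheme_config("burst", coupling = coupling_params(input_gain = 1))
  topo <- build_topology(16, 4, cfg$coupling)
  img <- tiny_image()
  r1 <- run_window(img, cfg, topo, mode = "train")
  r2 <- run_window(img, cfg, topo, mode = "train")
  expect_identical(r1$trace$per_neuron_counts, r2$trace$per_neuron_counts)
  expect_identical(r1$topo$W, r2$topo$W)
  expect_identical(r1$trace$sops, r2$trace$sops)
})

test_that("strong lateral inhibition lets one neuron dominate the window", {
  set.seed(23)
  cfg <- scheme_config("ttfs")
  topo <- build_topology(16, 4, coupling_params(w_ei = 15, w_ie = 5,
                                                input_gain = 1.5))
  img <- matrix(0, 4, 4); img[2, 2:3] <- 255  # one bright blob
  res <- run_window(img, cfg, topo, mode = "infer")
  counts <- res$trace$per_neuron_counts
  expect_gt(max(counts), 0)
  expect_gte(max(counts), sum(counts) - max(counts))
})

test_that("without inhibition the output rate is monotone in intensity", {
  set.seed(24)
  cfg <- scheme_config("burst",
                       coupling = coupling_params(w_ie = 0, input_gain = 0.1))
  topo <- build_topology(9, 3, cfg$coupling)
  topo$W[] <- 0.5
  counts <- vapply(c(40, 120, 255), function(int) {
    res <- run_window(matrix(int, 3, 3), cfg, topo, mode = "infer")
    sum(res$trace$per_neuron_counts)
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
  expect_gt(counts[3], counts[1])
})

test_that("SOP accounting matches a brute-force event recount", {
  set.seed(25)
  cfg <- scheme_config("burst", coupling = coupling_params(input_gain = 1))
  topo <- build_topology(16, 4, cfg$coupling)
  topo$prune_mask[1:5, 1] <- TRUE   # some pruned synapses reduce fan-out
  img <- tiny_image()
  res <- run_window(img, cfg, topo, mode = "train")
  # independent recount: every input spike traverses that row's unpruned
  # synapses; every exc spike its single inh synapse; every inh spike
  # n_exc - 1 lateral synapses; every written weight one update
  grid <- time_grid(cfg$train_window, cfg$dt)
  raster <- encode(img, "burst", grid = grid)
  fan_out <- rowSums(!topo$prune_mask)
  sop_in <- sum(rowSums(raster$spikes) * fan_out)
  sop_exc <- res$trace$output_spikes
  sop_inh <- res$trace$inh_spikes * (topo$n_exc - 1)
  expect_equal(res$trace$sops,
               sop_in + sop_exc + sop_inh + res$trace$n_updates)
})

test_that("inference leaves weights untouched and training changes them", {
  set.seed(26)
  cfg <- scheme_config("ttfs", coupling = coupling_params(input_gain = 2))
  topo <- build_topology(16, 4, cfg$coupling)
  img <- tiny_image()
  inf <- run_window(img, cfg, topo, mode = "infer")
  expect_identical(inf$topo$W, topo$W)
  tr <- run_window(img, cfg, topo, mode = "train")
  expect_false(identical(tr$topo$W, topo$W))
  expect_true(all(tr$topo$W >= 0 & tr$topo$W <= 1))
})

test_that("checkpoints round-trip weights and thresholds exactly", {
  set.seed(27)
  topo <- build_topology(16, 4)
  theta <- runif(4)
  path <- withr::local_tempfile(fileext = ".rds")
  checkpoint_save(topo, theta, path)
  back <- checkpoint_load(path)
  expect_identical(back$topo$W, topo$W)
  expect_identical(back$theta, theta)
  saveRDS(list(format = "other"), path)
  expect_error(checkpoint_load(path), "checkpoint")
})
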