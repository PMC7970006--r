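#' Additive white Gaussian noise at a target signal-to-noise ratio
#'
#' Adds zero-mean Gaussian noise whose variance equals the mean signal
#' power of the clean image divided by `snr` (a linear power ratio, not
#' dB), then clips to \[0, 255\]. Emulates background clutter.
#'
#' @param img Numeric matrix of intensities in \[0, 255\].
#' @param snr Linear signal-to-noise power ratio (> 0).
#' @param db Set `TRUE` to interpret `snr` in decibels instead.
#' @return Noisy image, same shape, clipped to \[0, 255\].
#' @export
awgn_by_snr <- function(img, snr = 9.5, db = FALSE) {
  stopifnot(snr > 0)
  if (db) snr <- 10^(snr / 10)
  power <- mean(img^2)
  if (power == 0) stop("blank image: signal power is zero", call. = FALSE)
  sigma <- sqrt(power / snr)
  awgn_by_sigma(img, sigma)
}

#' Additive white Gaussian noise with a fixed standard deviation
#'
#' @param img Numeric matrix of intensities in \[0, 255\].
#' @param sigma Noise standard deviation in intensity units (>= 0).
#' @return Noisy image clipped to \[0, 255\].
#' @export
awgn_by_sigma <- function(img, sigma) {
  stopifnot(sigma >= 0)
  if (sigma == 0) return(img)
  out <- img + matrix(stats::rnorm(length(img), sd = sigma),
                      nrow(img), ncol(img))
  pmin(pmax(out, 0), 255)
}

#' Linear motion-blur kernel
#'
#' Rasterizes a line of the given length and angle (degrees,
#' counterclockwise) with bilinear sub-pixel weighting and normalizes it to
#' unit sum, emulating a linear camera motion.
#'
#' @param length Blur extent in pixels (>= 1).
#' @param angle Motion angle in degrees, counterclockwise.
#' @return A square kernel matrix of odd size summing to 1.
#' @export
motion_blur_kernel <- function(length = 5, angle = 15) {
  stopifnot(length >= 1)
  if (length == 1) return(matrix(1, 1, 1))
  half <- (length - 1) / 2
  size <- 2 * ceiling(half) + 1
  centre <- ceiling(half) + 1
  k <- matrix(0, size, size)
  theta <- angle * pi / 180
  # sample the segment finely; deposit each sample with bilinear weights
  ts <- seq(-half, half, length.out = 8 * length)
  for (t in ts) {
    x <- centre + t * cos(theta)
    y <- centre - t * sin(theta)   # row index grows downward; CCW angle
    x0 <- floor(x); y0 <- floor(y)
    fx <- x - x0; fy <- y - y0
    for (off in list(c(0, 0, (1 - fx) * (1 - fy)), c(0, 1, fx * (1 - fy)),
                     c(1, 0, (1 - fx) * fy), c(1, 1, fx * fy))) {
      r <- y0 + off[1]; cc <- x0 + off[2]
      if (r >= 1 && r <= size && cc >= 1 && cc <= size) {
        k[r, cc] <- k[r, cc] + off[3]
      }
    }
  }
  k / sum(k)
}

#' Motion blur
#'
#' Convolves the image with [motion_blur_kernel()] (zero-padded borders),
#' preserving size and mean intensity in the interior.
#'
#' @param img Numeric matrix of intensities.
#' @param length Blur extent in pixels.
#' @param angle Motion angle in degrees, counterclockwise.
#' @return Blurred image, same shape.
#' @export
motion_blur <- function(img, length = 5, angle = 15) {
  k <- motion_blur_kernel(length, angle)
  half <- (dim(k)[1] - 1) / 2
  out <- matrix(0, nrow(img), ncol(img))
  # shift-and-add over kernel cells; zero padding outside the image
  for (r in seq_len(nrow(k))) {
    for (cc in seq_len(ncol(k))) {
      w <- k[r, cc]
      if (w == 0) next
      dr <- r - 1 - half; dc <- cc - 1 - half
      src_r <- seq_len(nrow(img)) + dr
      src_c <- seq_len(ncol(img)) + dc
      ok_r <- src_r >= 1 & src_r <= nrow(img)
      ok_c <- src_c >= 1 & src_c <= ncol(img)
      out[ok_r, ok_c] <- out[ok_r, ok_c] +
        w * img[src_r[ok_r], src_c[ok_c], drop = FALSE]
    }
  }
  pmin(pmax(out, 0), 255)
}

#' Reduced-contrast image with additive noise
#'
#' Rescales intensities about the image mean by `contrast_scale`, then
#' applies [awgn_by_snr()]. Emulates background clutter under a significant
#' change in lighting conditions.
#'
#' @param img Numeric matrix of intensities in \[0, 255\].
#' @param contrast_scale Contrast fraction in (0, 1\].
#' @param snr Linear signal-to-noise power ratio for the added noise.
#' @return Perturbed image clipped to \[0, 255\].
#' @export
reduced_contrast_awgn <- function(img, contrast_scale = 0.5, snr = 12) {
  stopifnot(contrast_scale > 0, contrast_scale <= 1)
  m <- mean(img)
  scaled <- pmin(pmax(m + (img - m) * contrast_scale, 0), 255)
  awgn_by_snr(scaled, snr)
}

#' Apply a named input perturbation
#'
#' Dispatcher over the input-noise models, for configuration-driven use.
#'
#' @param img Numeric matrix of intensities in \[0, 255\].
#' @param kind One of `"awgn_snr"`, `"awgn_sigma"`, `"motion_blur"`,
#'   `"reduced_contrast_awgn"`, `"none"`.
#' @param ... Parameters passed to the corresponding function.
#' @return Perturbed image.
#' @export
perturb_image <- function(img, kind = c("none", "awgn_snr", "awgn_sigma",
                                        "motion_blur",
                                        "reduced_contrast_awgn"), ...) {
  kind <- match.arg(kind)
  switch(kind,
    none = img,
    awgn_snr = awgn_by_snr(img, ...),
    awgn_sigma = awgn_by_sigma(img, ...),
    motion_blur = motion_blur(img, ...),
    reduced_contrast_awgn = reduced_contrast_awgn(img, ...)
  )
}

#' Programming-noise settings and hook
#'
#' Writing a weight into an analog synaptic device incurs Gaussian
#' programming noise with standard deviation `sigma_pct * epsilon`, where
#' `epsilon` is the fixed-point precision of the device and `sigma_pct`
#' the noise level as a fraction of it. During training the noise is added
#' to each quantized weight update; post-training it is added once to each
#' quantized weight at device mapping.
#'
#' @param sigma_pct Noise level as a fraction of the precision (in
#'   \[0, 1\]).
#' @param epsilon Fixed-point precision (> 0), e.g. `quant_config(bits)$epsilon`.
#' @return `prog_noise_config()`: an object of class `prog_noise_config`.
#' @export
prog_noise_config <- function(sigma_pct, epsilon) {
  stopifnot(sigma_pct >= 0, sigma_pct <= 1, epsilon > 0)
  structure(list(sigma_pct = sigma_pct, epsilon = epsilon),
            class = "prog_noise_config")
}

#' @rdname prog_noise_config
#' @param delta_q Quantized update value(s).
#' @param cfg A `prog_noise_config`.
#' @return `programming_noise()`: `delta_q` plus Gaussian noise of s.d.
#'   `sigma_pct * epsilon`, same shape.
#' @export
programming_noise <- function(delta_q, cfg) {
  if (cfg$sigma_pct == 0) return(delta_q)
  out <- delta_q + stats::rnorm(length(delta_q),
                                sd = cfg$sigma_pct * cfg$epsilon)
  if (is.matrix(delta_q)) dim(out) <- dim(delta_q)
  out
}

#' @rdname prog_noise_config
#' @return `make_prog_noise_hook()`: a function of one matrix argument for
#'   use in [update_hooks()].
#' @export
make_prog_noise_hook <- function(cfg) {
  force(cfg)
  function(delta) programming_noise(delta, cfg)
}

#' Stuck-at-fault settings
#'
#' A fraction `fault_rate` of synaptic devices is frozen before training
#' starts: a share `on_ratio` of them stuck at the high conductance state
#' (`w_on`) and the rest at the low state (`w_off`).
#'
#' @param fault_rate Fraction of synapses faulted, in \[0, 1\].
#' @param on_ratio Fraction of faulted synapses stuck on, in \[0, 1\].
#' @param w_on,w_off Stuck weight values (the weight bounds by default).
#' @return An object of class `saf_config`.
#' @export
saf_config <- function(fault_rate, on_ratio = 0.5, w_on = 1, w_off = 0) {
  stopifnot(fault_rate >= 0, fault_rate <= 1, on_ratio >= 0, on_ratio <= 1)
  structure(list(fault_rate = fault_rate, on_ratio = on_ratio,
                 w_on = w_on, w_off = w_off), class = "saf_config")
}

#' Sample a stuck-at-fault mask
#'
#' Selects a uniformly random `fault_rate` fraction of positions as
#' faulted; of those, the first `on_ratio` share (of a random permutation)
#' is stuck on at `w_on`, the rest stuck off at `w_off`.
#'
#' @param dim Integer vector `c(n_input, n_exc)` — weight-matrix shape.
#' @param cfg A [saf_config()].
#' @return List of class `saf_mask` with logical matrix `mask` and numeric
#'   matrix `values` (stuck values at faulted positions, `NA` elsewhere).
#' @export
sample_saf_mask <- function(dim, cfg) {
  n <- prod(dim)
  n_fault <- round(cfg$fault_rate * n)
  idx <- sample.int(n, n_fault)
  n_on <- round(cfg$on_ratio * n_fault)
  mask <- matrix(FALSE, dim[1], dim[2])
  values <- matrix(NA_real_, dim[1], dim[2])
  mask[idx] <- TRUE
  values[idx[seq_len(n_on)]] <- cfg$w_on
  if (n_fault > n_on) values[idx[(n_on + 1):n_fault]] <- cfg$w_off
  structure(list(mask = mask, values = values), class = "saf_mask")
}

#' Clamp stuck-at-fault synapses
#'
#' Overwrites faulted entries with their stuck value; called after every
#' weight update so that faults persist through training. Non-faulted
#' entries are untouched.
#'
#' @param W Weight matrix.
#' @param saf A `saf_mask` from [sample_saf_mask()].
#' @return `W` with faulted entries clamped.
#' @export
apply_saf <- function(W, saf) {
  stopifnot(all(dim(W) == dim(saf$mask)))
  W[saf$mask] <- saf$values[saf$mask]
  W
}
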