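# run body with a private RNG stream seeded by `seed`, restoring the caller's
# stream afterwards
with_local_seed <- function(seed, body) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  body()
}

#' Synthetic sparse-stroke dataset specification
#'
#' Describes an MNIST-like synthetic task: per class, a fixed sparse stroke
#' template (mostly-zero background, a bright connected stroke covering at
#' most 30% of the pixels); each sample is the template with Gaussian
#' intensity jitter on the stroke pixels, clipped to \[0, 255\]. The
#' background stays exactly zero, as in the handwritten-digit data this
#' emulates. Deterministic per seed and class-balanced.
#'
#' @param n_classes Number of classes.
#' @param image_size Pixels per side.
#' @param n_train,n_test Sample counts.
#' @param stroke_intensity Template stroke intensity in \[0, 255\].
#' @param jitter_sigma Gaussian intensity jitter (s.d., intensity units)
#'   applied to stroke pixels.
#' @param stroke_dropout Probability that an individual stroke pixel is
#'   omitted from a given sample, emulating the stroke-shape/thickness
#'   variability of handwriting (images stay centered, as in the
#'   preprocessed digit datasets this mimics).
#' @param shift_max Maximum per-sample translation in pixels (uniform
#'   integer offset per axis; 0 by default since the emulated datasets are
#'   centered).
#' @param seed RNG seed for templates and jitter.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_classes = 3, image_size = 10, n_train = 60,
                           n_test = 30, stroke_intensity = 220,
                           jitter_sigma = 20, stroke_dropout = 0.2,
                           shift_max = 0, seed = 42) {
  stopifnot(n_classes >= 2, image_size >= 4, n_train > 0, n_test > 0,
            stroke_intensity >= 1, stroke_intensity <= 255,
            jitter_sigma >= 0, stroke_dropout >= 0, stroke_dropout < 1,
            shift_max >= 0)
  structure(list(n_classes = as.integer(n_classes),
                 image_size = as.integer(image_size),
                 n_train = as.integer(n_train), n_test = as.integer(n_test),
                 stroke_intensity = stroke_intensity,
                 jitter_sigma = jitter_sigma,
                 stroke_dropout = stroke_dropout,
                 shift_max = as.integer(shift_max), seed = seed),
            class = "synthetic_spec")
}

# one connected stroke as a set of cells: a 4-neighbour random walk,
# deduplicated, of roughly `target` cells
random_stroke <- function(size, target) {
  pos <- c(sample(2:(size - 1), 1), sample(2:(size - 1), 1))
  cells <- matrix(pos, 1, 2)
  dirs <- rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  dir <- dirs[sample(4, 1), ]
  while (nrow(unique(cells)) < target) {
    if (runif(1) < 0.25) dir <- dirs[sample(4, 1), ]
    nxt <- pmin(pmax(pos + dir, 1), size)
    if (all(nxt == pos)) dir <- -dir else pos <- nxt
    cells <- rbind(cells, pos)
  }
  unique(cells)
}

# class templates: a base stroke shared by every class (as handwritten
# digits share most of their ink) plus a smaller class-specific stroke that
# carries the distinguishing signal; total ink capped at 30% of the pixels
make_templates <- function(n_classes, size, intensity, max_frac = 0.3) {
  npx <- size^2
  base_target <- round(0.12 * npx)
  class_target <- min(round(0.08 * npx), floor(max_frac * npx) - base_target)
  base <- random_stroke(size, base_target)
  class_cells <- list()
  distinct_ok <- function(a, b) {
    shared <- sum(apply(a, 1, function(r) any(b[, 1] == r[1] & b[, 2] == r[2])))
    shared < 0.4 * min(nrow(a), nrow(b))
  }
  for (k in seq_len(n_classes)) {
    for (try in 1:200) {
      cand <- random_stroke(size, class_target)
      if (all(vapply(class_cells, distinct_ok, logical(1), b = cand))) break
    }
    class_cells[[k]] <- cand
  }
  lapply(class_cells, function(cc) {
    tpl <- matrix(0, size, size)
    tpl[base] <- intensity
    tpl[cc] <- intensity
    tpl
  })
}

#' Generate a synthetic sparse-stroke dataset
#'
#' Draws the class templates — a base stroke shared by all classes plus a
#' smaller class-specific stroke per class (class strokes are redrawn until
#' pairwise distinct), so classes overlap the way handwritten digits share
#' ink while remaining separable — then samples class-balanced train/test
#' images as template plus stroke-pixel jitter and dropout.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `templates` (list of matrices), `train`/`test` (each a
#'   list with `images`, an `size x size x n` array, and `labels`, integer
#'   class ids `0:(K-1)`).
#' @export
generate_synthetic <- function(spec) {
  with_local_seed(spec$seed, function() {
    K <- spec$n_classes
    templates <- make_templates(K, spec$image_size, spec$stroke_intensity)
    shift_image <- function(img, dr, dc) {
      out <- matrix(0, nrow(img), ncol(img))
      src_r <- seq_len(nrow(img)) - dr
      src_c <- seq_len(ncol(img)) - dc
      ok_r <- src_r >= 1 & src_r <= nrow(img)
      ok_c <- src_c >= 1 & src_c <= ncol(img)
      out[ok_r, ok_c] <- img[src_r[ok_r], src_c[ok_c]]
      out
    }
    sample_set <- function(n) {
      labels <- (seq_len(n) - 1L) %% K
      images <- array(0, c(spec$image_size, spec$image_size, n))
      for (i in seq_len(n)) {
        tpl <- templates[[labels[i] + 1L]]
        img <- tpl
        on_px <- tpl > 0
        img[on_px] <- img[on_px] + rnorm(sum(on_px), sd = spec$jitter_sigma)
        if (spec$stroke_dropout > 0) {
          drop <- on_px & (matrix(runif(length(img)), nrow(img)) <
                             spec$stroke_dropout)
          img[drop] <- 0
        }
        if (spec$shift_max > 0) {
          sh <- sample(seq(-spec$shift_max, spec$shift_max), 2, replace = TRUE)
          img <- shift_image(img, sh[1], sh[2])
        }
        images[, , i] <- round(pmin(pmax(img, 0), 255))
      }
      list(images = images, labels = labels)
    }
    list(templates = templates,
         train = sample_set(spec$n_train),
         test = sample_set(spec$n_test))
  })
}

#' Read / write IDX files
#'
#' The big-endian binary container used by MNIST-style datasets: a 4-byte
#' magic number (two zero bytes, a type code, the number of dimensions),
#' one 32-bit big-endian integer per dimension, then the data. Only the
#' unsigned-byte type (code 0x08) is supported, which covers image and
#' label files.
#'
#' @param path File path.
#' @return `read_idx()`: an array of the stored dimensions (a vector for
#'   1-D label files). `write_idx()`: `path`, invisibly.
#' @export
read_idx <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "integer", 4, size = 1, signed = FALSE)
  if (length(magic) < 4 || magic[1] != 0 || magic[2] != 0) {
    stop("bad IDX magic number at offset 0 in ", path, call. = FALSE)
  }
  if (magic[3] != 0x08) {
    stop(sprintf("unsupported IDX type code 0x%02x at offset 2 (only ubyte 0x08)",
                 magic[3]), call. = FALSE)
  }
  ndim <- magic[4]
  dims <- readBin(con, "integer", ndim, size = 4, endian = "big")
  n <- prod(dims)
  data <- readBin(con, "integer", n, size = 1, signed = FALSE)
  if (length(data) < n) {
    stop(sprintf("truncated IDX file: expected %d bytes of data, got %d",
                 n, length(data)), call. = FALSE)
  }
  if (ndim == 1) return(data)
  # row-major storage: last dimension varies fastest
  array(data, dim = rev(dims)) |> aperm(rev(seq_len(ndim)))
}

#' @rdname read_idx
#' @param x Integer array (values 0-255) or vector to store.
#' @export
write_idx <- function(x, path) {
  dims <- dim(x) %||% length(x)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0, 0, 0x08, length(dims))), con)
  writeBin(as.integer(dims), con, size = 4, endian = "big")
  flat <- if (is.null(dim(x))) x else as.vector(aperm(x, rev(seq_along(dims))))
  writeBin(as.raw(as.integer(flat)), con)
  invisible(path)
}

#' Save / load a network checkpoint
#'
#' Versioned checkpoint of everything that persists across images: the
#' input weights, pruning mask, stuck-at-fault state, and the adaptive
#' threshold offsets. Round-trips exactly.
#'
#' @param topo An `snn_topology`.
#' @param theta Adaptive threshold offsets.
#' @param path File path.
#' @return `checkpoint_save()`: `path` invisibly; `checkpoint_load()`: a
#'   list with `topo` and `theta`.
#' @export
checkpoint_save <- function(topo, theta, path) {
  saveRDS(list(format = "spikecoding-checkpoint", version = 1L,
               topo = topo, theta = theta), path)
  invisible(path)
}

#' @rdname checkpoint_save
#' @export
checkpoint_load <- function(path) {
  x <- readRDS(path)
  if (!identical(x$format, "spikecoding-checkpoint") || x$version != 1L) {
    stop("not a version-1 spikecoding checkpoint: ", path, call. = FALSE)
  }
  x[c("topo", "theta")]
}
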