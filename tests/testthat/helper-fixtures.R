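# small shared fixtures, built in code

# a deterministic 4x4 test image with a spread of intensities
tiny_image <- function() {
  matrix(c(0, 51, 102, 153,
           204, 255, 128, 64,
           32, 16, 8, 4,
           2, 1, 200, 100), 4, 4, byrow = TRUE)
}

# random 8-bit image of a given side length
random_image <- function(size = 10) {
  matrix(sample(0:255, size^2, replace = TRUE), size, size)
}

# desk-scale experiment config shared by the slower end-to-end tests
desk_spec <- function(...) synthetic_spec(...)

# memoized store for expensive acceptance-scale runs, shared across tests
.run_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .run_cache)) {
    assign(key, force(expr), envir = .run_cache)
  }
  get(key, envir = .run_cache)
}
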