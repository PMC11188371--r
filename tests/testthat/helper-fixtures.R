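# shared fixtures, built once per session and memoised

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_env)) assign(key, expr, envir = .fixture_env)
  get(key, envir = .fixture_env)
}

# rasterised disk mask of radius r centred in a (2r+21)^2 canvas
disk_mask <- function(r, pad = 10) {
  n <- 2 * r + 2 * pad + 1
  c0 <- r + pad + 1
  outer(seq_len(n), seq_len(n), function(y, x) (y - c0)^2 + (x - c0)^2 <= r^2)
}

# rasterised axis-aligned ellipse mask (semi-axes a >= b), optional rotation
ellipse_mask <- function(a, b, theta = 0, pad = 10) {
  n <- 2 * a + 2 * pad + 1
  c0 <- a + pad + 1
  outer(seq_len(n), seq_len(n), function(y, x) {
    dx <- x - c0; dy <- y - c0
    u <- dx * cos(theta) + dy * sin(theta)
    v <- -dx * sin(theta) + dy * cos(theta)
    (u / a)^2 + (v / b)^2 <= 1
  })
}

square_mask <- function(side, pad = 10) {
  n <- side + 2 * pad
  m <- matrix(FALSE, n, n)
  m[(pad + 1):(pad + side), (pad + 1):(pad + side)] <- TRUE
  m
}

# small in-memory synthetic dataset shared across test files
fixture_dataset <- function(n = 60, seed = 5, noise_sd = NULL) {
  law <- if (is.null(noise_sd)) allometric_law() else
    allometric_law(noise_sd = noise_sd)
  memo(sprintf("ds_%d_%d_%s", n, seed, format(law$noise_sd)),
       generate_dataset(n, law, seed = seed))
}

# the benchmark-scale corpus used by the acceptance checks: written to a
# per-session tempdir (full-resolution images are too large to keep in RAM)
fixture_benchmark <- function() {
  memo("bench376", {
    dir <- file.path(tempdir(), "fw_bench376")
    generate_dataset(376, allometric_law(), seed = 101, out_dir = dir)
    list(dir = dir,
         manifest = read.csv(file.path(dir, "manifest.csv")))
  })
}

# 28x28 single-channel inputs for the benchmark corpus
fixture_benchmark_images <- function() {
  bench <- fixture_benchmark()
  memo("bench376_imgs", lapply(bench$manifest$sample_id, function(id)
    prepare_image_input(png::readPNG(
      file.path(bench$dir, "images", paste0(id, ".png"))))))
}

count_components_for_test <- function(mask) {
  max(EBImage::bwlabel(EBImage::Image(t(mask * 1))))
}
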