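# Shared fixture builders. Everything is generated in code at test time;
# nothing is read from stored binaries.

# a deterministic pseudo-random tile (no RNG state touched)
lcg_tile <- function(h, w, channels = 1, seed = 1) {
  n <- h * w * channels
  x <- numeric(n)
  s <- seed
  for (i in seq_len(n)) {
    s <- (1103515245 * s + 12345) %% 2^31
    x[i] <- s %% 256
  }
  if (channels == 1) tile_image(matrix(x, h, w))
  else tile_image(array(x, c(h, w, channels)))
}

# random tile via R's RNG under a fixed seed
random_tile <- function(h, w, channels = 1, seed = 1) {
  withr::with_seed(seed, {
    x <- sample(0:255, h * w * channels, replace = TRUE)
    if (channels == 1) tile_image(matrix(x, h, w))
    else tile_image(array(x, c(h, w, channels)))
  })
}

# write a tiny class/patient tree of constant-valued tiles; returns root
# (a fresh session-tempdir subdirectory; cleaned up with the session)
make_tree <- function(spec, size = 8, value = 100) {
  root <- tempfile("tree")
  dir.create(root)
  for (cl in names(spec)) {
    patients <- spec[[cl]]
    for (p in names(patients)) {
      for (i in seq_len(patients[[p]])) {
        write_tile(tile_image(matrix(value, size, size)),
                   file.path(root, cl, p, sprintf("t%02d.png", i)))
      }
    }
  }
  root
}

# brute-force Otsu oracle: maximise between-class variance by explicit loop
otsu_oracle <- function(values) {
  best_t <- NA_integer_
  best_v <- -Inf
  n <- length(values)
  for (t in 0:255) {
    lo <- values[values < t]
    hi <- values[values >= t]
    if (length(lo) == 0 || length(hi) == 0) next
    w0 <- length(lo) / n
    w1 <- length(hi) / n
    v <- w0 * w1 * (mean(lo) - mean(hi))^2
    if (v > best_v + 1e-12) {
      best_v <- v
      best_t <- t
    }
  }
  best_t
}

# O(n^2) pairwise AUC oracle with half credit for ties
auc_oracle <- function(true_labels, probs) {
  pos <- probs[true_labels == "immature"]
  neg <- probs[true_labels == "mature"]
  s <- 0
  for (p in pos) for (q in neg) {
    s <- s + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  s / (length(pos) * length(neg))
}

pixels_of <- function(img) {
  a <- unclass(img)
  attr(a, "source_path") <- NULL
  class(a) <- NULL
  a
}
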