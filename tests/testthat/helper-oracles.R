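# Naive reference implementations, kept deliberately independent of the
# package's vectorised code paths: everything here is scalar double loops.

random_image <- function(h, w, label = NA_character_, source_id = "rnd") {
  labeled_image(array(runif(h * w * 3, 0, 255), dim = c(h, w, 3)),
                label = label, source_id = source_id)
}

# per-block mean via an explicit pixel loop
oracle_block_mean <- function(block) {
  sums <- c(0, 0, 0)
  n <- 0L
  for (i in seq_len(dim(block)[1])) {
    for (j in seq_len(dim(block)[2])) {
      for (k in 1:3) sums[k] <- sums[k] + block[i, j, k]
      n <- n + 1L
    }
  }
  sums / n
}

# feature vector assembled block by block, row-major, RGB interleaved
oracle_featurize <- function(image, n_w, n_h) {
  px <- image$pixels
  h <- dim(px)[1]; w <- dim(px)[2]
  stopifnot(h %% n_h == 0, w %% n_w == 0)
  bh <- h %/% n_h; bw <- w %/% n_w
  out <- numeric(0)
  for (r in seq_len(n_h)) {
    for (c in seq_len(n_w)) {
      block <- px[((r - 1) * bh + 1):(r * bh), ((c - 1) * bw + 1):(c * bw), , drop = FALSE]
      out <- c(out, oracle_block_mean(block))
    }
  }
  out
}

oracle_cosine <- function(x, y) {
  dot <- 0; xx <- 0; yy <- 0
  for (i in seq_along(x)) {
    dot <- dot + x[i] * y[i]
    xx <- xx + x[i]^2
    yy <- yy + y[i]^2
  }
  dot / sqrt(xx * yy)
}

# element-wise column mean over a label's vectors
oracle_centroid <- function(vectors) {
  n <- length(vectors)
  len <- length(vectors[[1]])
  out <- numeric(len)
  for (j in seq_len(len)) {
    s <- 0
    for (i in seq_len(n)) s <- s + vectors[[i]][j]
    out[j] <- s / n
  }
  out
}

# small feature tibble from raw vectors
feature_table <- function(vectors, labels, ids = sprintf("img%02d", seq_along(vectors))) {
  tibble::tibble(source_id = ids, label = labels, feature = vectors)
}

# tiny array binders used by the tiling test
abind_cols <- function(...) {
  parts <- list(...)
  out <- array(0, dim = c(dim(parts[[1]])[1], sum(vapply(parts, function(p) dim(p)[2], 0L)), 3))
  at <- 0L
  for (p in parts) {
    out[, (at + 1):(at + dim(p)[2]), ] <- p
    at <- at + dim(p)[2]
  }
  out
}
abind_rows <- function(...) {
  parts <- list(...)
  out <- array(0, dim = c(sum(vapply(parts, function(p) dim(p)[1], 0L)), dim(parts[[1]])[2], 3))
  at <- 0L
  for (p in parts) {
    out[(at + 1):(at + dim(p)[1]), , ] <- p
    at <- at + dim(p)[1]
  }
  out
}
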