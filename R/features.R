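#' Block grids
#'
#' A block grid partitions an image into `n_w` equal divisions across the
#' width and `n_h` down the height, giving `n_w * n_h` rectangular blocks.
#' Every grid used on real data divides its region exactly (e.g. a 1080 x 1350
#' region under an 8 x 10 grid gives 80 blocks of 135 x 135 pixels); strict
#' mode therefore requires exact divisibility, and a permissive mode that
#' truncates remainder rows/columns is available behind `strict = FALSE` in
#' the segmentation functions.
#'
#' @param n_w Number of divisions across the width (>= 1).
#' @param n_h Number of divisions down the height (>= 1).
#' @return An object of class `block_grid`.
#' @examples
#' block_grid(8, 10)            # 80 blocks
#' parse_grid("27x20")          # region-3 grid, 540 blocks
#' @export
block_grid <- function(n_w, n_h) {
  n_w <- as.integer(n_w); n_h <- as.integer(n_h)
  if (is.na(n_w) || is.na(n_h) || n_w < 1L || n_h < 1L) {
    stop("grid divisions must be integers >= 1", call. = FALSE)
  }
  structure(list(n_w = n_w, n_h = n_h), class = "block_grid")
}

#' @rdname block_grid
#' @param x For `parse_grid()`, a string `"<n_w>x<n_h>"`; for the methods, a
#'   `block_grid`.
#' @export
parse_grid <- function(x) {
  if (inherits(x, "block_grid")) return(x)
  parts <- strsplit(tolower(x), "x", fixed = TRUE)[[1L]]
  if (length(parts) != 2L) stop(sprintf("malformed grid '%s'", x), call. = FALSE)
  block_grid(as.integer(parts[[1L]]), as.integer(parts[[2L]]))
}

#' @export
format.block_grid <- function(x, ...) sprintf("%dx%d", x$n_w, x$n_h)

#' @export
print.block_grid <- function(x, ...) {
  cat(sprintf("<block_grid> %d x %d (%d blocks)\n", x$n_w, x$n_h, n_blocks(x)))
  invisible(x)
}

#' @rdname block_grid
#' @param grid A `block_grid`.
#' @export
n_blocks <- function(grid) grid$n_w * grid$n_h

check_divisible <- function(h, w, grid, strict = TRUE) {
  rem_w <- w %% grid$n_w
  rem_h <- h %% grid$n_h
  if (strict && (rem_w != 0L || rem_h != 0L)) {
    stop(sprintf(
      "grid %s does not divide a %d x %d image: remainder %d px in width, %d px in height",
      format(grid), w, h, rem_w, rem_h), call. = FALSE)
  }
  c(bh = h %/% grid$n_h, bw = w %/% grid$n_w)
}

#' Segment an image into grid blocks
#'
#' Returns the blocks of `image` under `grid` in row-major order (top-left to
#' bottom-right), each a `(H/n_h) x (W/n_w) x 3` array. The blocks tile the
#' image without gap or overlap. Intended for inspection and small images; the
#' feature path ([featurize()]) aggregates without materialising blocks.
#'
#' @param image A [labeled_image()].
#' @param grid A [block_grid()] or grid string.
#' @param strict Require exact divisibility (default); otherwise remainder
#'   rows/columns at the right and bottom edges are dropped.
#' @return List of `n_w * n_h` pixel arrays, row-major.
#' @export
segment <- function(image, grid, strict = TRUE) {
  stopifnot(inherits(image, "labeled_image"))
  grid <- parse_grid(grid)
  bs <- check_divisible(img_height(image), img_width(image), grid, strict)
  bh <- bs[["bh"]]; bw <- bs[["bw"]]
  px <- image$pixels
  out <- vector("list", n_blocks(grid))
  k <- 1L
  for (r in seq_len(grid$n_h)) {
    rows <- ((r - 1L) * bh + 1L):(r * bh)
    for (c in seq_len(grid$n_w)) {
      cols <- ((c - 1L) * bw + 1L):(c * bw)
      out[[k]] <- px[rows, cols, , drop = FALSE]
      k <- k + 1L
    }
  }
  out
}

#' Mean RGB of one block
#'
#' Per-channel arithmetic mean over all pixels of a block, in floating point.
#'
#' @param block An h x w x 3 pixel array (as produced by [segment()]).
#' @return Named numeric vector `c(R, G, B)`, each in \[0, 255\].
#' @export
block_mean <- function(block) {
  if (!is.array(block) || length(dim(block)) != 3L || dim(block)[3L] != 3L ||
      prod(dim(block)[1:2]) == 0L) {
    stop("`block` must be a nonempty h x w x 3 array", call. = FALSE)
  }
  c(R = mean(block[, , 1L]), G = mean(block[, , 2L]), B = mean(block[, , 3L]))
}

# Per-channel block means without materialising blocks. Column-major reshape
# sums runs of bh rows within each image column, then the transposed reshape
# sums runs of bw columns; entry [c, r] of the result is the sum over block
# (row r, col c), so as.vector() yields row-major block order directly.
block_channel_means <- function(ch, n_h, n_w, bh, bw) {
  h_used <- n_h * bh; w_used <- n_w * bw
  ch <- ch[seq_len(h_used), seq_len(w_used), drop = FALSE]
  row_sums <- matrix(colSums(matrix(ch, nrow = bh)), nrow = n_h, ncol = w_used)
  sums <- matrix(colSums(matrix(t(row_sums), nrow = bw)), nrow = n_w, ncol = n_h)
  as.vector(sums) / (bh * bw)
}

#' Build a block-mean feature vector
#'
#' Segments `image` under `grid`, takes each block's mean RGB, and
#' concatenates the triplets in row-major block order into a single vector of
#' length `3 * n_w * n_h`. Entries stay floating point; no rounding is applied
#' before [reconstruct()]. A 1080 x 1350 region-1 image under an 8 x 10 grid
#' yields 80 blocks of 135 x 135 pixels and a 240-entry vector.
#'
#' @inheritParams segment
#' @return Numeric vector of length `3 * n_w * n_h` with attributes `grid`
#'   (grid string) and `region` (the image's region name if known).
#' @export
featurize <- function(image, grid, strict = TRUE) {
  stopifnot(inherits(image, "labeled_image"))
  grid <- parse_grid(grid)
  bs <- check_divisible(img_height(image), img_width(image), grid, strict)
  means <- vapply(1:3, function(k) {
    block_channel_means(image$pixels[, , k], grid$n_h, grid$n_w, bs[["bh"]], bs[["bw"]])
  }, numeric(n_blocks(grid)))
  v <- as.numeric(t(means))  # interleave R,G,B per block
  attr(v, "grid") <- format(grid)
  attr(v, "region") <- attr(image, "region")
  v
}

#' Featurize a table of images
#'
#' Tidy wrapper over [crop()] + [featurize()]: takes a manifest-style tibble
#' with an `image` list-column, optionally crops every image to `region`, and
#' appends the feature vectors as a `feature` list-column.
#'
#' @param data Tibble with columns `source_id`, `label` and list-column
#'   `image` (see [read_manifest()], [generate_dataset()]).
#' @param grid A [block_grid()] or grid string such as `"8x10"`.
#' @param region Optional [region_spec()] applied to every image first.
#' @param strict Require exact divisibility of the (cropped) image by `grid`.
#' @return `data` without the `image` column, plus columns `region`, `grid`
#'   and list-column `feature`.
#' @export
featurize_images <- function(data, grid, region = NULL, strict = TRUE) {
  stopifnot(is.data.frame(data), "image" %in% names(data))
  grid <- parse_grid(grid)
  region_name <- if (is.null(region)) "full" else region$name
  feats <- purrr::map(data$image, function(img) {
    if (!is.null(region)) img <- crop(img, region)
    featurize(img, grid, strict = strict)
  })
  out <- dplyr::select(data, -"image")
  out$region <- region_name
  out$grid <- format(grid)
  out$feature <- feats
  tibble::as_tibble(out)
}

#' Reconstruct a block-averaged image from a feature vector
#'
#' Inverts [featurize()] up to within-block detail: each output block is
#' filled with its (rounded) mean RGB triplet. At a one-pixel-per-block grid
#' the reconstruction equals the source image exactly (the means are single
#' integer pixel values).
#'
#' @param vector Feature vector from [featurize()] (or any numeric vector of
#'   length `3 * n_w * n_h`).
#' @param grid The [block_grid()] the vector was built with; defaults to the
#'   vector's `grid` attribute.
#' @param out_width,out_height Output size in pixels; must be divisible by the
#'   grid.
#' @return A [labeled_image()].
#' @export
reconstruct <- function(vector, out_width, out_height, grid = attr(vector, "grid")) {
  if (is.null(grid)) stop("`grid` is required when the vector carries no grid attribute",
                          call. = FALSE)
  grid <- parse_grid(grid)
  if (length(vector) != 3L * n_blocks(grid)) {
    stop(sprintf("vector length %d inconsistent with grid %s (expected %d)",
                 length(vector), format(grid), 3L * n_blocks(grid)), call. = FALSE)
  }
  bs <- check_divisible(as.integer(out_height), as.integer(out_width), grid, strict = TRUE)
  px <- array(0, dim = c(out_height, out_width, 3L))
  ones <- matrix(1, bs[["bh"]], bs[["bw"]])
  for (k in 1:3) {
    # de-interleave channel k, reshape row-major block order to n_h x n_w
    means <- matrix(vector[seq(k, length(vector), by = 3L)],
                    nrow = grid$n_h, ncol = grid$n_w, byrow = TRUE)
    px[, , k] <- kronecker(means, ones)
  }
  labeled_image(pmin(pmax(round(px), 0), 255), source_id = "<reconstructed>")
}

#' Concatenate feature vectors from two regions
#'
#' Joins two feature tables by `source_id` and concatenates each image's
#' vectors end to end, so composite region-2 + region-3 features can be
#' classified like any other vector. Images present in only one table are
#' rejected.
#'
#' @param a,b Feature tibbles from [featurize_images()].
#' @return A feature tibble whose `feature` vectors have length
#'   `len(a) + len(b)` and whose `region`/`grid` columns join the parts with
#'   `"+"`.
#' @export
concat_features <- function(a, b) {
  stopifnot(is.data.frame(a), is.data.frame(b),
            "feature" %in% names(a), "feature" %in% names(b))
  if (nrow(a) == 0L || nrow(b) == 0L) {
    stop("cannot concatenate an empty feature table", call. = FALSE)
  }
  only_a <- setdiff(a$source_id, b$source_id)
  only_b <- setdiff(b$source_id, a$source_id)
  if (length(only_a) > 0L || length(only_b) > 0L) {
    stop(sprintf("source ids do not match: %s",
                 paste(c(only_a, only_b), collapse = ", ")), call. = FALSE)
  }
  idx <- match(a$source_id, b$source_id)
  out <- a
  out$feature <- purrr::map2(a$feature, b$feature[idx], c)
  out$region <- paste(a$region, b$region[idx], sep = "+")
  out$grid <- paste(a$grid, b$grid[idx], sep = "+")
  out
}

#' Write / read feature tables as CSV
#'
#' One row per image with columns `source_id`, `label`, `split` (if present),
#' `region`, `grid`, then `v_000` ... `v_{n-1}`. A JSON sidecar
#' (`<path>.json`) records the grid/region metadata.
#'
#' @param features Feature tibble from [featurize_images()].
#' @param path Output CSV path.
#' @export
write_features <- function(features, path) {
  lens <- lengths(features$feature)
  if (length(unique(lens)) != 1L) {
    stop("all feature vectors must share one length to be written", call. = FALSE)
  }
  mat <- do.call(rbind, features$feature)
  colnames(mat) <- sprintf("v_%03d", seq_len(ncol(mat)) - 1L)
  meta_cols <- intersect(c("source_id", "label", "split", "region", "grid"),
                         names(features))
  out <- cbind(as.data.frame(features[meta_cols]), as.data.frame(mat))
  utils::write.csv(out, path, row.names = FALSE)
  jsonlite::write_json(
    list(grid = unique(features$grid), region = unique(features$region),
         n_features = ncol(mat), n_images = nrow(out)),
    paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  vcols <- grep("^v_\\d+$", names(df), value = TRUE)
  meta <- tibble::as_tibble(df[setdiff(names(df), vcols)])
  meta$feature <- lapply(seq_len(nrow(df)), function(i) as.numeric(df[i, vcols]))
  meta
}
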