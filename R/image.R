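#' Labelled plasma images
#'
#' A `labeled_image` wraps an H x W x 3 numeric array of 8-bit RGB channel
#' intensities (stored as doubles in \[0, 255\]) together with an optional
#' category label and a provenance string (usually the source file name).
#' All user-facing sizes are quoted width x height, the convention used
#' throughout for region and grid dimensions; the pixel array itself is
#' indexed `[row, column, channel]`.
#'
#' @param pixels Numeric H x W x 3 array with values in \[0, 255\].
#' @param label Optional category identifier string (see [parse_label()]);
#'   `NA` for an unlabeled test image.
#' @param source_id Provenance string, e.g. the file name.
#' @return An object of class `labeled_image`.
#' @export
labeled_image <- function(pixels, label = NA_character_, source_id = "<memory>") {
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3L] != 3L) {
    stop("`pixels` must be an H x W x 3 array", call. = FALSE)
  }
  if (dim(pixels)[1L] < 1L || dim(pixels)[2L] < 1L) {
    stop("image must be at least 1 x 1", call. = FALSE)
  }
  rng <- range(pixels)
  if (is.na(rng[1L]) || rng[1L] < 0 || rng[2L] > 255) {
    stop("channel values must lie in [0, 255] and contain no NA", call. = FALSE)
  }
  if (!is.na(label)) label <- render_label(label)  # validates
  structure(
    list(pixels = pixels, label = label, source_id = source_id),
    class = "labeled_image"
  )
}

#' @export
print.labeled_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<labeled_image> %d x %d (W x H), label: %s, source: %s\n",
              d[2L], d[1L], ifelse(is.na(x$label), "<none>", x$label), x$source_id))
  invisible(x)
}

#' @export
dim.labeled_image <- function(x) dim(x$pixels)

img_height <- function(img) dim(img$pixels)[1L]
img_width <- function(img) dim(img$pixels)[2L]

#' Read a plasma image from disk
#'
#' PNG is the canonical lossless format. JPEG input is accepted (phone-camera
#' frames) via the EBImage package when installed, with a warning that lossy
#' compression may perturb block means. Alpha channels are dropped; grayscale
#' images are rejected because the feature vectors are defined on RGB.
#'
#' @param path File path (`.png`, `.jpg`/`.jpeg`).
#' @param label Optional category identifier. By default the label is taken
#'   from a file name of the form `"<label>_<replicate>.png"` when it parses,
#'   else left missing.
#' @return A [labeled_image()].
#' @export
read_image <- function(path, label = NULL) {
  if (!file.exists(path)) stop(sprintf("no such image file: '%s'", path), call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    px <- png::readPNG(path)
  } else if (ext %in% c("jpg", "jpeg")) {
    if (!requireNamespace("EBImage", quietly = TRUE)) {
      stop("reading JPEG requires the EBImage package", call. = FALSE)
    }
    warning(sprintf("'%s' is JPEG: lossy compression may perturb block means", path),
            call. = FALSE)
    eb <- EBImage::readImage(path)
    px <- aperm(EBImage::imageData(eb), c(2L, 1L, 3L))
  } else {
    stop(sprintf("unsupported image format '.%s' (use PNG or JPEG)", ext), call. = FALSE)
  }
  if (length(dim(px)) == 2L) {
    stop(sprintf("'%s' is grayscale; the method is defined on RGB images", path),
         call. = FALSE)
  }
  if (dim(px)[3L] == 4L) px <- px[, , 1:3, drop = FALSE]  # drop alpha
  if (dim(px)[3L] != 3L) {
    stop(sprintf("'%s' has %d channels; expected RGB", path, dim(px)[3L]), call. = FALSE)
  }
  if (is.null(label)) label <- label_from_filename(path)
  labeled_image(px * 255, label = label, source_id = basename(path))
}

label_from_filename <- function(path) {
  stem <- tools::file_path_sans_ext(basename(path))
  candidate <- sub("_.*$", "", stem)
  out <- tryCatch(render_label(candidate), error = function(e) NA_character_)
  out
}

#' Write a plasma image as lossless PNG
#'
#' @param image A [labeled_image()].
#' @param path Output path (`.png`).
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  stopifnot(inherits(image, "labeled_image"))
  png::writePNG(image$pixels / 255, target = path)
  invisible(path)
}

#' Define a rectangular crop region
#'
#' A region is a named crop rectangle in source-frame pixel coordinates:
#' `left`/`top` give the 0-based offset of its top-left corner, `width` and
#' `height` its extent. Coordinates are half-open (`[left, left + width)`),
#' so a full-extent region of an image is `region_spec("full", 0, 0, W, H)`.
#'
#' @param name Region name, e.g. `"region1"`.
#' @param left,top 0-based pixel offsets of the top-left corner.
#' @param width,height Region extent in pixels (positive).
#' @return An object of class `region_spec`.
#' @export
region_spec <- function(name, left, top, width, height) {
  left <- as.integer(left); top <- as.integer(top)
  width <- as.integer(width); height <- as.integer(height)
  if (left < 0L || top < 0L) stop("region offsets must be >= 0", call. = FALSE)
  if (width < 1L || height < 1L) stop("region width and height must be >= 1", call. = FALSE)
  structure(list(name = name, left = left, top = top, width = width, height = height),
            class = "region_spec")
}

#' @export
print.region_spec <- function(x, ...) {
  cat(sprintf("<region_spec> %s: %d x %d at (left = %d, top = %d)\n",
              x$name, x$width, x$height, x$left, x$top))
  invisible(x)
}

#' Crop an image to a region
#'
#' Pixel values are copied unchanged and the label is preserved. A region
#' extending beyond the image bounds is rejected, reporting the overflow.
#'
#' @param image A [labeled_image()].
#' @param region A [region_spec()].
#' @return A [labeled_image()] of dimensions `region$height` x `region$width`.
#' @export
crop <- function(image, region) {
  stopifnot(inherits(image, "labeled_image"), inherits(region, "region_spec"))
  h <- img_height(image); w <- img_width(image)
  over_w <- region$left + region$width - w
  over_h <- region$top + region$height - h
  if (over_w > 0L || over_h > 0L) {
    stop(sprintf(
      "region '%s' exceeds image bounds by %d px in width and %d px in height",
      region$name, max(over_w, 0L), max(over_h, 0L)), call. = FALSE)
  }
  rows <- (region$top + 1L):(region$top + region$height)
  cols <- (region$left + 1L):(region$left + region$width)
  labeled_image(image$pixels[rows, cols, , drop = FALSE],
                label = image$label,
                source_id = image$source_id)
}

#' Default region geometry for original camera frames
#'
#' The three crops used on real 1080 x 1920 portrait frames: region 1
#' (1080 x 1350) removes the top and bottom black background and is centered
#' vertically; region 2 (360 x 324) encloses the central plasma observation
#' window; region 3 (540 x 400) sits in the faint bottom reflection band.
#' Only the region sizes are fixed by the acquisition protocol; the offsets of
#' regions 2 and 3 are configurable (see [regions_from_yaml()]) and default to
#' horizontally centered placements.
#'
#' @param frame_width,frame_height Source frame size in pixels.
#' @return Named list of [region_spec()]s.
#' @export
default_regions <- function(frame_width = 1080, frame_height = 1920) {
  r1_top <- (frame_height - 1350L) %/% 2L
  list(
    region1 = region_spec("region1", (frame_width - 1080L) %/% 2L, r1_top, 1080L, 1350L),
    region2 = region_spec("region2", (frame_width - 360L) %/% 2L, r1_top + 500L, 360L, 324L),
    region3 = region_spec("region3", (frame_width - 540L) %/% 2L, r1_top + 1350L - 450L,
                          540L, 400L)
  )
}

#' Read / write region configurations
#'
#' Regions are serialised as a YAML list of entries with fields `name`,
#' `left`, `top`, `width`, `height`.
#'
#' @param path YAML file path.
#' @return `regions_from_yaml()`: named list of [region_spec()]s.
#' @export
regions_from_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  out <- lapply(raw, function(r) {
    region_spec(r$name, r$left, r$top, r$width, r$height)
  })
  names(out) <- vapply(out, `[[`, "", "name")
  out
}

#' @rdname regions_from_yaml
#' @param regions Named list of [region_spec()]s.
#' @export
regions_to_yaml <- function(regions, path) {
  yaml::write_yaml(lapply(unname(regions), unclass), path)
  invisible(path)
}

#' Read an image manifest
#'
#' A manifest is a CSV with columns `source_id`, `label`, `split`
#' (`train`/`test`); `source_id` entries are image file names resolved
#' relative to `dir`.
#'
#' @param path Manifest CSV path.
#' @param dir Directory holding the images; defaults to the manifest's
#'   directory.
#' @param load Read the pixel data into an `image` list-column (default TRUE).
#' @return A tibble with columns `source_id`, `label`, `split` and, when
#'   `load = TRUE`, `image` (list of [labeled_image()]s).
#' @export
read_manifest <- function(path, dir = dirname(path), load = TRUE) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("source_id", "label", "split")
  missing_cols <- setdiff(required, names(m))
  if (length(missing_cols) > 0L) {
    stop(sprintf("manifest '%s' lacks column(s): %s", path,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  if (!all(m$split %in% c("train", "test"))) {
    stop("manifest `split` must be 'train' or 'test'", call. = FALSE)
  }
  m <- tibble::as_tibble(m[required])
  if (load) {
    m$image <- purrr::map2(m$source_id, m$label, function(f, lab) {
      read_image(file.path(dir, f), label = lab)
    })
  }
  m
}
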