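#' Synthetic plasma-image configuration
#'
#' Defines a seeded generator for synthetic plasma frames that emulate the
#' structure the classifier relies on: a dark background, one or two vertical
#' Gaussian-profile light columns in the central plasma area with a
#' category-specific RGB hue, a deterministic additive hue shift per inlet
#' pressure step, a faint blurred reflection band at the bottom of the frame,
#' and i.i.d. Gaussian pixel noise per replicate. It does not attempt
#' physically realistic plasma emission; it reproduces the geometry and
#' color statistics the method exploits.
#'
#' The default canvas is 216 x 270 (width x height), an exact 1/5 scale of
#' the real region-1 crop, so the standard grids (1x1, 4x5, 8x10, ...) divide
#' it integrally. The default analyte palette deliberately gives benzene (B,
#' two narrow columns) and the benzene/pentane mixture (BC, one wide
#' off-center column) the same base hue: their whole-image mean colors are
#' then parallel by construction, so a 1x1 whole-image grid cannot separate
#' them (cosine similarity is scale-invariant) while any finer grid can —
#' the generator's analogue of the poor whole-image baseline.
#'
#' @param width,height Canvas size in pixels (width x height).
#' @param analytes Tibble describing the palette; see [synth_analytes()].
#' @param pressures Inlet pressures to enumerate (Psi).
#' @param n_train,n_test Replicates per category and split.
#' @param noise_sigma Per-pixel, per-channel Gaussian noise SD in channel
#'   units (default 2).
#' @param pressure_shift Additive RGB shift per pressure step (channel units).
#' @param col_sd Column Gaussian SD as a fraction of the width.
#' @param row_center,row_sd Vertical envelope center/SD as fractions of the
#'   height.
#' @param reflection_frac Height fraction of the bottom reflection band.
#' @param reflection_scale Intensity scale of the reflection in (0, 1); 0
#'   disables the band.
#' @param reflection_blur Widening factor applied to the column SD in the
#'   reflection band.
#' @param min_color_separation Minimum pairwise Euclidean distance (channel
#'   units) required between distinct analyte base colors; analytes declared
#'   as mean-color twins are exempt.
#' @param seed Integer seed consumed by [generate_dataset()].
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(width = 216, height = 270,
                         analytes = synth_analytes(),
                         pressures = PRESSURES_PSI,
                         n_train = 5, n_test = 1,
                         noise_sigma = 2,
                         pressure_shift = c(6, -4, 8),
                         col_sd = 12 / 216,
                         row_center = 120 / 270, row_sd = 45 / 270,
                         reflection_frac = 0.2, reflection_scale = 0.15,
                         reflection_blur = 2.5,
                         min_color_separation = 40,
                         seed = 1L) {
  stopifnot(width >= 4, height >= 4, n_train >= 1, n_test >= 1,
            noise_sigma >= 0, length(pressure_shift) == 3L,
            reflection_frac >= 0, reflection_frac < 1,
            reflection_scale >= 0, reflection_scale < 1)
  cfg <- structure(
    list(width = as.integer(width), height = as.integer(height),
         analytes = analytes, pressures = as.integer(pressures),
         n_train = as.integer(n_train), n_test = as.integer(n_test),
         noise_sigma = noise_sigma, pressure_shift = pressure_shift,
         col_sd = col_sd, row_center = row_center, row_sd = row_sd,
         reflection_frac = reflection_frac, reflection_scale = reflection_scale,
         reflection_blur = reflection_blur,
         min_color_separation = min_color_separation,
         seed = as.integer(seed)),
    class = "synth_config")
  check_color_separation(cfg)
  cfg
}

#' Default synthetic analyte palette
#'
#' One row per analyte: base RGB hue, the horizontal centers of its light
#' columns (fractions of the width), a width multiplier for the column SD,
#' and an optional `mean_color_twin` naming the analyte it deliberately
#' shares its base hue with.
#'
#' @return A tibble with columns `analyte`, `r`, `g`, `b`, `centers`
#'   (list-column), `width_scale`, `mean_color_twin`.
#' @export
synth_analytes <- function() {
  tibble::tibble(
    analyte = c("C", "B", "A", "BC", "AC", "AB"),
    r = c(165, 90, 225, 90, 230, 120),
    g = c(120, 210, 150, 210, 210, 200),
    b = c(215, 120, 70, 120, 100, 230),
    # BC carries one double-width off-center column with the same total
    # intensity mass and hue as B's two narrow columns: whole-image mean
    # colors stay parallel (the 1x1 collision) while any finer grid sees
    # the different column layout.
    centers = list(0.5, c(0.36, 0.64), 0.5, 0.39, 0.5, c(0.36, 0.64)),
    width_scale = c(1, 1, 1, 2, 1, 1),
    mean_color_twin = c(NA, "BC", NA, "B", NA, NA)
  )
}

#' Helium-plasma generator preset
#'
#' Pure helium plasma images differ only subtly across inlet pressures: the
#' preset uses a single lilac-to-white hue family, a pressure shift and a
#' noise level each 10x smaller than the VOC defaults, and more training
#' replicates, mimicking the much tighter within-category similarity of real
#' helium frames.
#'
#' @param ... Overrides passed to [synth_config()].
#' @export
helium_synth_config <- function(...) {
  he <- tibble::tibble(
    analyte = "He", r = 205, g = 190, b = 220,
    centers = list(0.5), width_scale = 1, mean_color_twin = NA_character_
  )
  defaults <- list(analytes = he, n_train = 6, n_test = 1,
                   noise_sigma = 0.2, pressure_shift = c(0.6, -0.4, 0.8))
  args <- utils::modifyList(defaults, list(...))
  do.call(synth_config, args)
}

check_color_separation <- function(cfg) {
  a <- cfg$analytes
  if (nrow(a) < 2L) return(invisible(TRUE))
  cols <- as.matrix(a[, c("r", "g", "b")])
  for (i in seq_len(nrow(a) - 1L)) {
    for (j in (i + 1L):nrow(a)) {
      twin <- identical(a$mean_color_twin[[i]], a$analyte[[j]]) ||
        identical(a$mean_color_twin[[j]], a$analyte[[i]])
      d <- sqrt(sum((cols[i, ] - cols[j, ])^2))
      if (!twin && d < cfg$min_color_separation) {
        stop(sprintf(
          "base colors of '%s' and '%s' are %.1f channel units apart (< %.1f)",
          a$analyte[[i]], a$analyte[[j]], d, cfg$min_color_separation),
          call. = FALSE)
      }
    }
  }
  invisible(TRUE)
}

# noiseless intensity field (height x width, peak ~1) for one analyte row
render_intensity <- function(cfg, arow) {
  w <- cfg$width; h <- cfg$height
  x <- seq_len(w)
  sd_px <- cfg$col_sd * w * arow$width_scale
  profile <- rowSums(vapply(arow$centers[[1L]], function(cf) {
    exp(-((x - cf * w)^2) / (2 * sd_px^2))
  }, numeric(w)))
  rows <- seq_len(h)
  envelope <- exp(-((rows - cfg$row_center * h)^2) / (2 * (cfg$row_sd * h)^2))
  intensity <- outer(envelope, profile)
  if (cfg$reflection_frac > 0) {
    band_h <- max(1L, round(cfg$reflection_frac * h))
    band_rows <- (h - band_h + 1L):h
    blur_sd <- sd_px * cfg$reflection_blur
    blurred <- rowSums(vapply(arow$centers[[1L]], function(cf) {
      exp(-((x - cf * w)^2) / (2 * blur_sd^2))
    }, numeric(w)))
    # the band replaces whatever envelope tail reaches it, so a zero scale
    # leaves it genuinely dark
    intensity[band_rows, ] <- matrix(cfg$reflection_scale * blurred,
                                     nrow = band_h, ncol = w, byrow = TRUE)
  }
  intensity
}

category_color <- function(cfg, label) {
  lab <- parse_label(label)
  arow <- cfg$analytes[cfg$analytes$analyte == lab$analyte, ]
  if (nrow(arow) == 0L) {
    stop(sprintf("label '%s' not present in generator config", render_label(lab)),
         call. = FALSE)
  }
  step <- match(lab$pressure_psi, sort(cfg$pressures)) - 1L
  list(arow = arow,
       rgb = pmin(pmax(c(arow$r, arow$g, arow$b) + step * cfg$pressure_shift, 0), 255))
}

#' Generate one synthetic plasma image
#'
#' Renders the deterministic noiseless frame for `label` and adds i.i.d.
#' Gaussian pixel noise drawn from R's current RNG stream (or from `seed`
#' when given), clipping to \[0, 255\]. Two calls with the same config, label
#' and RNG state produce bit-identical images.
#'
#' @param config A [synth_config()].
#' @param label Category identifier, e.g. `"B-20"`.
#' @param seed Optional integer; when given, the RNG is seeded locally.
#' @param source_id Provenance string for the resulting image.
#' @return A [labeled_image()].
#' @export
generate_image <- function(config, label, seed = NULL, source_id = NULL) {
  stopifnot(inherits(config, "synth_config"))
  if (!is.null(seed)) set.seed(seed)
  cc <- category_color(config, label)
  intensity <- render_intensity(config, cc$arow)
  px <- array(0, dim = c(config$height, config$width, 3L))
  for (k in 1:3) px[, , k] <- cc$rgb[[k]] * intensity
  if (config$noise_sigma > 0) {
    px <- px + stats::rnorm(length(px), mean = 0, sd = config$noise_sigma)
  }
  labeled_image(pmin(pmax(px, 0), 255),
                label = label,
                source_id = source_id %||% sprintf("%s_mem", render_label(label)))
}

#' Generate a full synthetic dataset
#'
#' Enumerates every category of the config (analytes x pressures, canonical
#' order), renders `n_train + n_test` noisy replicates of each, and returns a
#' manifest tibble with the images as a list-column. The split follows the
#' real protocol: a handful of training replicates and one held-out test
#' image per category by default. When `dir` is given the images are also
#' written as PNG files plus a `manifest.csv` compatible with
#' [read_manifest()]. The whole dataset is a deterministic function of
#' `(config, config$seed)`.
#'
#' @param config A [synth_config()].
#' @param dir Optional output directory for PNGs and the manifest CSV.
#' @return Tibble with columns `source_id`, `label`, `split`, `image`.
#' @export
generate_dataset <- function(config, dir = NULL) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  labels <- enumerate_categories(config$analytes$analyte, config$pressures)
  reps <- config$n_train + config$n_test
  rows <- purrr::map(labels, function(lab) {
    purrr::map(seq_len(reps), function(r) {
      sid <- sprintf("%s_%02d.png", lab, r)
      list(source_id = sid, label = lab,
           split = if (r <= config$n_train) "train" else "test",
           image = generate_image(config, lab, source_id = sid))
    })
  })
  rows <- purrr::flatten(rows)
  manifest <- tibble::tibble(
    source_id = purrr::map_chr(rows, "source_id"),
    label = purrr::map_chr(rows, "label"),
    split = purrr::map_chr(rows, "split"),
    image = purrr::map(rows, "image")
  )
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    purrr::walk2(manifest$image, manifest$source_id,
                 function(img, sid) write_image(img, file.path(dir, sid)))
    utils::write.csv(manifest[c("source_id", "label", "split")],
                     file.path(dir, "manifest.csv"), row.names = FALSE)
  }
  manifest
}

#' Region analogues for the synthetic canvas
#'
#' Scaled counterparts of the three crops used on real frames: `full` is the
#' whole canvas (region-1 analogue), `center` a crop centered on the plasma
#' columns (region-2 analogue), `bottom` a strip inside the reflection band
#' (region-3 analogue). On the default 216 x 270 canvas these are 216 x 270,
#' 120 x 90 and 216 x 40, chosen so the standard grid ratios divide exactly.
#'
#' @param config A [synth_config()].
#' @return Named list of [region_spec()]s.
#' @export
synth_regions <- function(config = synth_config()) {
  w <- config$width; h <- config$height
  cw <- round(w * 5 / 9); ch <- round(h / 3)
  c_top <- round(config$row_center * h - ch / 2)
  bh <- round(h * 40 / 270)
  b_top <- h - bh - round(h * 10 / 270)
  list(
    full = region_spec("full", 0L, 0L, w, h),
    center = region_spec("center", (w - cw) %/% 2L, c_top, cw, ch),
    bottom = region_spec("bottom", 0L, b_top, w, bh)
  )
}
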