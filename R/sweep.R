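#' Block-count sweep over regions and grids
#'
#' Reproduces the structure of the accuracy-versus-resolution experiment: for
#' every (region, grid) combination the training images are featurized and a
#' centroid model fitted, the held-out test images classified, and one result
#' row emitted with block geometry, accuracy, wall time and the
#' misclassification list. Rows are ordered by region then ascending block
#' count. Wall times are reported for orientation only; they are
#' hardware-dependent and never part of any assertion.
#'
#' @param data Manifest tibble with columns `source_id`, `label`, `split` and
#'   list-column `image` (from [generate_dataset()] or [read_manifest()]).
#' @param regions Named list of [region_spec()]s (e.g. [synth_regions()]);
#'   `NULL` entries mean "use the image as-is".
#' @param grids Named list mapping each region name to a character vector of
#'   grid strings (`"8x10"`, ...). Must be nonempty for every region.
#' @param strict Passed to [featurize_images()].
#' @return Tibble with one row per (region, grid): `region`, `grid`,
#'   `n_blocks`, `block_w`, `block_h`, `accuracy`, `accuracy_pct`, `time_s`,
#'   `misclassified` (list-column of tibbles `source_id`, `label`,
#'   `predicted`).
#' @export
run_sweep <- function(data, regions, grids, strict = TRUE) {
  stopifnot(is.data.frame(data), all(c("split", "image") %in% names(data)))
  if (length(grids) == 0L || any(lengths(grids) == 0L)) {
    stop("`grids` must list at least one grid per region", call. = FALSE)
  }
  missing_regions <- setdiff(names(grids), names(regions))
  if (length(missing_regions) > 0L) {
    stop(sprintf("grids given for unknown region(s): %s",
                 paste(missing_regions, collapse = ", ")), call. = FALSE)
  }
  train <- dplyr::filter(data, .data$split == "train")
  test <- dplyr::filter(data, .data$split == "test")
  if (nrow(train) == 0L || nrow(test) == 0L) {
    stop("sweep needs both train and test images", call. = FALSE)
  }
  rows <- purrr::map(names(grids), function(rname) {
    region <- regions[[rname]]
    gs <- unique(grids[[rname]])
    gs <- gs[order(vapply(gs, function(g) n_blocks(parse_grid(g)), 0))]
    purrr::map(gs, function(g) {
      grid <- parse_grid(g)
      t0 <- proc.time()[["elapsed"]]
      model <- fit_centroids(featurize_images(train, grid, region, strict = strict))
      ev <- evaluate(featurize_images(test, grid, region, strict = strict), model)
      elapsed <- proc.time()[["elapsed"]] - t0
      ref <- if (is.null(region)) dim(data$image[[1L]]$pixels) else c(region$height, region$width)
      nb <- n_blocks(grid)
      bw <- ref[[2L]] %/% grid$n_w
      bh <- ref[[1L]] %/% grid$n_h
      tibble::tibble(
        region = rname, grid = format(grid), n_blocks = nb,
        block_w = bw, block_h = bh,
        accuracy = ev$accuracy, accuracy_pct = ev$accuracy_pct,
        time_s = elapsed,
        misclassified = list(ev$misclassified)
      )
    })
  })
  dplyr::bind_rows(purrr::flatten(rows))
}

#' Write a sweep results table as CSV
#'
#' Flattens the `misclassified` list-column into `"label->predicted"` pairs
#' separated by `"; "`, mirroring the tabular misclassification reports.
#'
#' @param results Tibble from [run_sweep()].
#' @param path Output CSV path.
#' @export
write_sweep <- function(results, path) {
  flat <- results
  flat$misclassified <- vapply(results$misclassified, function(m) {
    if (nrow(m) == 0L) "" else paste(sprintf("%s->%s", m$label, m$predicted),
                                     collapse = "; ")
  }, "")
  utils::write.csv(flat, path, row.names = FALSE)
  invisible(path)
}

#' Read a sweep specification from YAML
#'
#' The YAML maps region names to an entry with the region rectangle
#' (`left`, `top`, `width`, `height`; omit for "whole image") and a `grids`
#' list of grid strings.
#'
#' @param path YAML path.
#' @return List with elements `regions` (named list of [region_spec()]s or
#'   `NULL`) and `grids` (named list of character vectors).
#' @export
sweep_from_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  regions <- lapply(names(raw), function(nm) {
    r <- raw[[nm]]
    if (is.null(r$width)) NULL else region_spec(nm, r$left %||% 0L, r$top %||% 0L,
                                                r$width, r$height)
  })
  names(regions) <- names(raw)
  grids <- lapply(raw, function(r) as.character(r$grids))
  if (any(lengths(grids) == 0L)) stop("every region needs a nonempty `grids` list",
                                      call. = FALSE)
  list(regions = regions, grids = grids)
}
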