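#' Category labels for plasma images
#'
#' Each plasma image category is identified by an analyte code crossed with a
#' GC inlet pressure, rendered as `"<analyte>-<pressure>"` (e.g. `"AC-24"`).
#' The six VOC codes are `C` (n-pentane), `B` (benzene), `A` (acetone) and the
#' binary mixtures `BC`, `AC`, `AB`; `He` denotes pure helium plasma. The four
#' inlet pressures are 17, 20, 24 and 27 Psi, giving 24 VOC categories (plus
#' four helium categories).
#'
#' @name voc-labels
NULL

# canonical analyte order: single compounds then mixtures, as tabulated
VOC_ANALYTES <- c("C", "B", "A", "BC", "AC", "AB")
ALL_ANALYTES <- c(VOC_ANALYTES, "He")
PRESSURES_PSI <- c(17L, 20L, 24L, 27L)

#' Parse a category identifier
#'
#' Splits an identifier such as `"AC-24"` into its analyte code and inlet
#' pressure, validating both parts.
#'
#' @param identifier Character scalar, `"<analyte>-<pressure>"`.
#' @return An object of class `voc_label`: a list with elements `analyte`
#'   (character) and `pressure_psi` (integer). `format()` renders it back to
#'   the identical identifier string.
#' @examples
#' parse_label("AC-24")
#' format(parse_label("C-17"))
#' @seealso [enumerate_categories()], [render_label()]
#' @export
parse_label <- function(identifier) {
  if (!is.character(identifier) || length(identifier) != 1L || is.na(identifier)) {
    stop("`identifier` must be a single character string", call. = FALSE)
  }
  parts <- strsplit(identifier, "-", fixed = TRUE)[[1L]]
  if (length(parts) != 2L) {
    stop(sprintf("malformed identifier '%s': expected '<analyte>-<pressure>'", identifier),
         call. = FALSE)
  }
  analyte <- parts[[1L]]
  if (!analyte %in% ALL_ANALYTES) {
    stop(sprintf("unknown analyte code '%s' in '%s' (expected one of %s)",
                 analyte, identifier, paste(ALL_ANALYTES, collapse = ", ")),
         call. = FALSE)
  }
  pressure <- suppressWarnings(as.integer(parts[[2L]]))
  if (is.na(pressure) || !pressure %in% PRESSURES_PSI ||
      parts[[2L]] != as.character(pressure)) {
    stop(sprintf("unknown pressure '%s' in '%s' (expected one of %s)",
                 parts[[2L]], identifier, paste(PRESSURES_PSI, collapse = ", ")),
         call. = FALSE)
  }
  structure(list(analyte = analyte, pressure_psi = pressure), class = "voc_label")
}

#' Render a category label back to its identifier string
#'
#' @param label A `voc_label` (from [parse_label()]) or a character identifier,
#'   which is validated and returned unchanged.
#' @return Character scalar such as `"AC-24"`.
#' @export
render_label <- function(label) {
  if (is.character(label)) label <- parse_label(label)
  stopifnot(inherits(label, "voc_label"))
  sprintf("%s-%d", label$analyte, label$pressure_psi)
}

#' @export
format.voc_label <- function(x, ...) render_label(x)

#' @export
print.voc_label <- function(x, ...) {
  cat("<voc_label> ", render_label(x), "\n", sep = "")
  invisible(x)
}

#' Enumerate category labels
#'
#' Forms the Cartesian product of analyte codes and inlet pressures in the
#' canonical deterministic order: analytes in tabulated column order
#' (C, B, A, BC, AC, AB, He), pressures ascending. The default arguments
#' enumerate the full 24-category VOC scheme.
#'
#' @param analytes Character vector of analyte codes.
#' @param pressures Integer vector of inlet pressures (Psi).
#' @return Character vector of identifiers, e.g. `"C-17"`, `"C-20"`, ...
#' @examples
#' length(enumerate_categories())  # 24
#' enumerate_categories("He")      # the four helium categories
#' @export
enumerate_categories <- function(analytes = VOC_ANALYTES, pressures = PRESSURES_PSI) {
  if (length(analytes) == 0L) stop("`analytes` must be nonempty", call. = FALSE)
  if (length(pressures) == 0L) stop("`pressures` must be nonempty", call. = FALSE)
  bad <- setdiff(analytes, ALL_ANALYTES)
  if (length(bad) > 0L) {
    stop(sprintf("unknown analyte code(s): %s", paste(bad, collapse = ", ")), call. = FALSE)
  }
  if (!all(pressures %in% PRESSURES_PSI)) {
    stop(sprintf("unknown pressure(s): %s",
                 paste(setdiff(pressures, PRESSURES_PSI), collapse = ", ")), call. = FALSE)
  }
  analytes <- ALL_ANALYTES[ALL_ANALYTES %in% analytes]
  pressures <- sort(unique(as.integer(pressures)))
  as.vector(t(outer(analytes, pressures, function(a, p) sprintf("%s-%d", a, p))))
}

#' Order labels canonically
#'
#' Sorts identifiers by analyte column order then ascending pressure; used for
#' deterministic centroid ordering and argmax tie-breaking.
#'
#' @param labels Character vector of identifiers.
#' @return The same labels, canonically ordered.
#' @export
order_labels <- function(labels) {
  parsed <- lapply(labels, parse_label)
  a <- match(vapply(parsed, `[[`, "", "analyte"), ALL_ANALYTES)
  p <- vapply(parsed, `[[`, 0L, "pressure_psi")
  labels[order(a, p)]
}
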