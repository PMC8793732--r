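# Measurement data model and CSV schema.
#
# A column series is the unit of analysis: the ordered per-vertebra facet
# measurements of one specimen. Stored as a data.frame subclass so base
# subsetting, printing and write.csv work, with specimen-level metadata
# (specimen id, taxon, units) kept in attributes.

.SCHEMA_COLS <- c("specimen_id", "taxon", "element_label", "serial_index",
                  "region", "facet", "convention", "vertical", "horizontal",
                  "centrum_length", "units")

.REGIONS <- c("cervical", "dorsal")
.FACETS <- c("posterior", "anterior")
.CONVENTIONS <- c("midline", "maximum")

#' Construct a vertebral column series
#'
#' Bundles the ordered per-vertebra articular-facet measurements of one
#' specimen, the unit on which serial-variation metrics are computed.
#'
#' @param measurements data.frame with columns `element_label`,
#'   `serial_index`, `region`, `facet`, `convention`, `vertical`,
#'   `horizontal` and optionally `centrum_length`. `vertical` and
#'   `horizontal` are the facet extents in any unit that is consistent
#'   within the specimen (mm, image pixels, ...); `serial_index` is the
#'   1-based anatomical position (C1 = atlas), strictly increasing.
#' @param specimen_id,taxon identifying metadata.
#' @param units free-text unit tag (default `"arbitrary"`); never converted.
#' @param allow_mixed_facets permit measurements taken on different facets or
#'   conventions within one series (default `FALSE`: mixing is an error).
#' @return An object of class `column_series` (a data.frame, rows sorted by
#'   `serial_index`).
#' @examples
#' column_series(
#'   data.frame(element_label = c("C2", "C3"), serial_index = c(2, 3),
#'              region = "cervical", facet = "posterior",
#'              convention = "midline", vertical = c(10, 11),
#'              horizontal = c(12, 12)),
#'   specimen_id = "demo")
#' @seealso [read_measurements], [load_fixture], [serial_variation]
#' @export
column_series <- function(measurements, specimen_id, taxon = NA_character_,
                          units = "arbitrary", allow_mixed_facets = FALSE) {
  m <- as.data.frame(measurements)
  if (is.null(m$centrum_length)) m$centrum_length <- NA_real_
  needed <- setdiff(.SCHEMA_COLS, c("specimen_id", "taxon", "units"))
  missing_cols <- setdiff(needed, names(m))
  if (length(missing_cols))
    stop("missing measurement columns: ", paste(missing_cols, collapse = ", "))
  m <- m[order(m$serial_index), needed, drop = FALSE]
  rownames(m) <- NULL
  m$serial_index <- as.integer(m$serial_index)
  for (col in c("vertical", "horizontal", "centrum_length"))
    m[[col]] <- as.numeric(m[[col]])

  validate_measurements(m, specimen_id, allow_mixed_facets)

  structure(m,
            class = c("column_series", "data.frame"),
            specimen_id = as.character(specimen_id),
            taxon = as.character(taxon),
            units = as.character(units))
}

validate_measurements <- function(m, specimen_id, allow_mixed_facets) {
  id <- as.character(specimen_id)
  bad <- which(!is.finite(m$vertical) | m$vertical <= 0 |
               !is.finite(m$horizontal) | m$horizontal <= 0)
  if (length(bad))
    stop(sprintf("specimen '%s': non-positive facet extent at element(s) %s",
                 id, paste(m$element_label[bad], collapse = ", ")))
  bad_cl <- which(!is.na(m$centrum_length) & m$centrum_length <= 0)
  if (length(bad_cl))
    stop(sprintf("specimen '%s': non-positive centrum_length at element(s) %s",
                 id, paste(m$element_label[bad_cl], collapse = ", ")))
  if (anyDuplicated(m$serial_index))
    stop(sprintf("specimen '%s': duplicate serial_index %s", id,
                 paste(unique(m$serial_index[duplicated(m$serial_index)]),
                       collapse = ", ")))
  if (any(m$serial_index < 1L))
    stop(sprintf("specimen '%s': serial_index must be >= 1", id))
  if (!all(m$region %in% .REGIONS))
    stop(sprintf("specimen '%s': region must be one of %s", id,
                 paste(.REGIONS, collapse = ", ")))
  if (!all(m$facet %in% .FACETS))
    stop(sprintf("specimen '%s': facet must be one of %s", id,
                 paste(.FACETS, collapse = ", ")))
  if (!all(m$convention %in% .CONVENTIONS))
    stop(sprintf("specimen '%s': convention must be one of %s", id,
                 paste(.CONVENTIONS, collapse = ", ")))
  prefix <- substr(m$element_label, 1, 1)
  expected <- ifelse(m$region == "cervical", "C", "D")
  if (any(prefix != expected))
    stop(sprintf("specimen '%s': element_label prefix disagrees with region at %s",
                 id, paste(m$element_label[prefix != expected], collapse = ", ")))
  if (!allow_mixed_facets) {
    if (length(unique(m$facet)) > 1L)
      stop(sprintf("specimen '%s': mixed facet values (use allow_mixed_facets = TRUE to permit)",
                   id))
    if (length(unique(m$convention)) > 1L)
      stop(sprintf("specimen '%s': mixed convention values (use allow_mixed_facets = TRUE to permit)",
                   id))
  }
  invisible(m)
}

#' @export
print.column_series <- function(x, ...) {
  cat(sprintf("Column series: %s (%s), %d vertebrae [%s], units: %s\n",
              attr(x, "specimen_id"), attr(x, "taxon"), nrow(x),
              paste(range_labels(x), collapse = "-"), attr(x, "units")))
  print(as.data.frame(x), ...)
  invisible(x)
}

range_labels <- function(x) x$element_label[c(1L, nrow(x))]

#' @export
as.data.frame.column_series <- function(x, ...) {
  d <- data.frame(specimen_id = attr(x, "specimen_id"),
                  taxon = attr(x, "taxon"),
                  unclass_df(x),
                  units = attr(x, "units"),
                  stringsAsFactors = FALSE)
  d[, .SCHEMA_COLS]
}

unclass_df <- function(x) {
  class(x) <- "data.frame"
  x
}

#' Read vertebral measurements from CSV
#'
#' Reads the package's measurement CSV schema (header
#' `specimen_id,taxon,element_label,serial_index,region,facet,convention,vertical,horizontal,centrum_length,units`)
#' and returns one validated [column_series] per specimen, rows sorted by
#' `serial_index` regardless of input order.
#'
#' @param path CSV file path.
#' @param allow_mixed_facets passed to [column_series].
#' @return Named list of `column_series` (names are specimen ids, in order of
#'   first appearance in the file).
#' @examples
#' tab <- system.file("extdata", "table1.csv", package = "vertcol")
#' series <- read_measurements(tab)
#' names(series)
#' @export
read_measurements <- function(path, allow_mixed_facets = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(serial_index = "integer"))
  missing_cols <- setdiff(.SCHEMA_COLS, names(raw))
  if (length(missing_cols))
    stop("CSV is missing schema column(s): ", paste(missing_cols, collapse = ", "))
  ids <- unique(raw$specimen_id)
  out <- lapply(ids, function(id) {
    rows <- raw[raw$specimen_id == id, , drop = FALSE]
    units <- unique(rows$units)
    if (length(units) > 1L)
      stop(sprintf("specimen '%s': inconsistent units tag", id))
    column_series(rows, specimen_id = id, taxon = rows$taxon[1L],
                  units = units, allow_mixed_facets = allow_mixed_facets)
  })
  stats::setNames(out, ids)
}

#' Write vertebral measurements to CSV
#'
#' Inverse of [read_measurements]: writes one or more column series in the
#' package CSV schema so that reading the file back reproduces the input.
#'
#' @param series a `column_series` or a (possibly empty) list of them.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(series, path) {
  if (inherits(series, "column_series")) series <- list(series)
  rows <- if (length(series)) {
    do.call(rbind, lapply(series, as.data.frame))
  } else {
    stats::setNames(as.data.frame(matrix(nrow = 0, ncol = length(.SCHEMA_COLS))),
                    .SCHEMA_COLS)
  }
  utils::write.csv(rows, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

.FIXTURE_IDS <- c(giraffe = "giraffe", monitor = "monitor",
                  alligator = "alligator", ostrich = "ostrich",
                  diplodocus_cm84 = "CM 84",
                  giraffatitan_mbr2180 = "MB.R.2180")

#' Load a bundled measured cervical series
#'
#' Returns the raw vertical/horizontal facet extents of one of the six
#' bundled comparison specimens, verbatim from the published measurement
#' table: a young juvenile giraffe (C2-C7), a savannah monitor (C3-C7), a
#' juvenile alligator (C5-D2, anterior facets), an ostrich (C5-C11, maximum
#' extents), *Diplodocus carnegii* CM 84 (C2-C15) and *Giraffatitan brancai*
#' MB.R.2180 (C2-C7).
#'
#' @param name one of `"giraffe"`, `"monitor"`, `"alligator"`, `"ostrich"`,
#'   `"diplodocus_cm84"`, `"giraffatitan_mbr2180"`.
#' @return A [column_series].
#' @examples
#' load_fixture("giraffatitan_mbr2180")
#' @export
load_fixture <- function(name) {
  if (length(name) != 1L || !name %in% names(.FIXTURE_IDS))
    stop("unknown fixture '", paste(name, collapse = ","), "'; valid names: ",
         paste(names(.FIXTURE_IDS), collapse = ", "))
  path <- system.file("extdata", "table1.csv", package = "vertcol")
  read_measurements(path)[[.FIXTURE_IDS[[name]]]]
}

#' Names of the bundled measurement fixtures
#' @return Character vector of names accepted by [load_fixture].
#' @export
fixture_names <- function() names(.FIXTURE_IDS)
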