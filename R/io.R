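# Readers and writers for setup collections.
#
# Native XML dialect (UTF-8):
#   <setups>
#     <setup id="acqua4" clinic="acqua">
#       <instrument id="scalpel" label="Scalpel" x="100" y="200" angle="45"/>
#     </setup>
#   </setups>
#
# Deposited archives in the wild use undocumented element/attribute names, so
# the reader takes an `xml_dialect()` mapping: the foreign dialect can be
# adapted without code changes.

#' Describe an XML dialect for setup files
#'
#' The native writer always emits the default dialect; the reader accepts any
#' mapping of element and attribute names, so foreign files following the same
#' shape (a root of setup elements, each holding one element per placed
#' instrument) can be ingested by renaming only.
#'
#' @param root,setup,instrument element names.
#' @param setup_id,clinic attribute names on the setup element.
#' @param instrument_id,label,x,y,angle attribute names on the instrument
#'   element.
#' @param default_clinic clinic id to assume when the clinic attribute is
#'   absent (some archives encode the clinic in the file name instead);
#'   `NULL` makes a missing clinic attribute an error.
#' @return A named list of class `xml_dialect`.
#' @export
xml_dialect <- function(root = "setups", setup = "setup",
                        instrument = "instrument",
                        setup_id = "id", clinic = "clinic",
                        instrument_id = "id", label = "label",
                        x = "x", y = "y", angle = "angle",
                        default_clinic = NULL) {
  structure(
    list(root = root, setup = setup, instrument = instrument,
         setup_id = setup_id, clinic = clinic, instrument_id = instrument_id,
         label = label, x = x, y = y, angle = angle,
         default_clinic = default_clinic),
    class = "xml_dialect"
  )
}

xml_attr_required <- function(node, attr, what) {
  v <- xml2::xml_attr(node, attr)
  if (is.na(v)) {
    abort_parse("missing attribute '%s' on <%s> element", attr,
                xml2::xml_name(node))
  }
  v
}

parse_numeric_attr <- function(value, attr, setup_id) {
  out <- suppressWarnings(as.numeric(value))
  if (is.na(out)) {
    abort_parse("setup '%s': attribute '%s' value '%s' is not numeric",
                setup_id, attr, value)
  }
  out
}

#' Read a setup collection from XML
#'
#' Parses a setup file in the dialect described by `dialect` (by default the
#' native one, see [xml_dialect()]). Angles are normalized to `[0, 360)`;
#' placements outside the 1920 x 1080 px surface raise a validation error
#' naming the setup and instrument. Placement order within a setup is
#' preserved.
#'
#' @param path path to an XML file.
#' @param dialect an [xml_dialect()] mapping.
#' @return A [setup_collection()].
#' @seealso [write_setups_xml()], [read_setups_csv()]
#' @export
read_setups_xml <- function(path, dialect = xml_dialect()) {
  if (!file.exists(path)) abort_io("file not found: %s", path)
  doc <- tryCatch(
    xml2::read_xml(path),
    error = function(e) abort_parse("malformed XML in '%s': %s",
                                    path, conditionMessage(e))
  )
  if (xml2::xml_name(doc) != dialect$root) {
    abort_parse("expected root element <%s>, found <%s>",
                dialect$root, xml2::xml_name(doc))
  }
  setup_nodes <- xml2::xml_find_all(doc, paste0("./", dialect$setup))
  setups <- lapply(setup_nodes, function(node) {
    sid <- xml_attr_required(node, dialect$setup_id, "setup")
    clinic <- xml2::xml_attr(node, dialect$clinic)
    if (is.na(clinic)) {
      if (is.null(dialect$default_clinic)) {
        abort_parse("setup '%s': missing attribute '%s'", sid, dialect$clinic)
      }
      clinic <- dialect$default_clinic
    }
    inst_nodes <- xml2::xml_find_all(node, paste0("./", dialect$instrument))
    iid <- vapply(inst_nodes, xml_attr_required, character(1L),
                  dialect$instrument_id, "instrument")
    lab <- vapply(inst_nodes, function(n) {
      v <- xml2::xml_attr(n, dialect$label)
      if (is.na(v)) xml2::xml_attr(n, dialect$instrument_id) else v
    }, character(1L))
    num <- function(attr) {
      vapply(seq_along(inst_nodes), function(i) {
        parse_numeric_attr(xml_attr_required(inst_nodes[[i]], attr, "instrument"),
                           attr, sid)
      }, numeric(1L))
    }
    df <- data.frame(instrument_id = iid, label = lab,
                     x = num(dialect$x), y = num(dialect$y),
                     angle = num(dialect$angle), stringsAsFactors = FALSE)
    table_setup(sid, clinic, df)
  })
  setup_collection(setups)
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  gsub("\"", "&quot;", x, fixed = TRUE)
}

# %.17g round-trips doubles exactly through the decimal representation.
fmt_num <- function(x) sprintf("%.17g", x)

#' Write a setup collection to XML
#'
#' Serializes in the native dialect. Numeric attributes are written with
#' enough digits that `read_setups_xml(write_setups_xml(c))` reproduces the
#' collection exactly.
#'
#' @param collection a [setup_collection()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_setups_xml <- function(collection, path) {
  stopifnot(inherits(collection, "setup_collection"))
  lines <- c("<?xml version=\"1.0\" encoding=\"UTF-8\"?>", "<setups>")
  for (s in collection$setups) {
    lines <- c(lines, sprintf("  <setup id=\"%s\" clinic=\"%s\">",
                              xml_escape(s$setup_id), xml_escape(s$clinic_id)))
    p <- s$placements
    if (nrow(p) > 0L) {
      lines <- c(lines, sprintf(
        "    <instrument id=\"%s\" label=\"%s\" x=\"%s\" y=\"%s\" angle=\"%s\"/>",
        xml_escape(p$instrument_id), xml_escape(p$label),
        fmt_num(p$x), fmt_num(p$y), fmt_num(p$angle)))
    }
    lines <- c(lines, "  </setup>")
  }
  lines <- c(lines, "</setups>")
  ok <- tryCatch({
    writeLines(lines, path, useBytes = TRUE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) abort_io("cannot write '%s'", path)
  invisible(path)
}

CSV_COLUMNS <- c("setup_id", "clinic_id", "instrument_id", "label",
                 "x", "y", "angle")

#' Read a setup collection from CSV
#'
#' Expects the header `setup_id,clinic_id,instrument_id,label,x,y,angle`, one
#' placement per row. Validation matches the XML reader. Setups with zero
#' placements cannot be represented in this flat format.
#'
#' @param path path to a CSV file.
#' @return A [setup_collection()].
#' @export
read_setups_csv <- function(path) {
  if (!file.exists(path)) abort_io("file not found: %s", path)
  df <- tryCatch(
    utils::read.csv(path, colClasses = "character", check.names = FALSE),
    error = function(e) abort_parse("cannot parse CSV '%s': %s",
                                    path, conditionMessage(e))
  )
  missing_cols <- setdiff(CSV_COLUMNS, names(df))
  if (length(missing_cols) > 0L) {
    abort_parse("CSV '%s' missing column(s): %s", path,
                paste(missing_cols, collapse = ", "))
  }
  for (col in c("x", "y", "angle")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & nzchar(trimws(df[[col]])) | is.na(v))
    if (length(bad) > 0L) {
      abort_parse("CSV '%s' row %d: column '%s' value '%s' is not numeric",
                  path, bad[1L], col, df[[col]][bad[1L]])
    }
    df[[col]] <- v
  }
  collection_from_flat(df)
}

#' Write a setup collection to CSV
#'
#' @param collection a [setup_collection()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_setups_csv <- function(collection, path) {
  stopifnot(inherits(collection, "setup_collection"))
  df <- as.data.frame(collection)
  for (col in c("x", "y", "angle")) df[[col]] <- fmt_num(df[[col]])
  ok <- tryCatch({
    utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) abort_io("cannot write '%s'", path)
  invisible(path)
}

# Dispatch on extension; used by the CLI.
read_setups_auto <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    xml = read_setups_xml(path),
    csv = read_setups_csv(path),
    abort_io("cannot infer format of '%s' (expected .xml or .csv)", path)
  )
}
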