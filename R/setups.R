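# Data model: instrument placements, table setups, setup collections.
#
# A placement lives on the 1920 x 1080 px virtual table surface (origin
# top-left, x rightward, y downward). Orientation is in degrees,
# counter-clockwise positive, normalized to [0, 360) on ingest; the
# similarity metric only ever uses differences of angles, so the choice of
# reference direction is immaterial as long as it is fixed.

SURFACE_WIDTH <- 1920
SURFACE_HEIGHT <- 1080

PLACEMENT_COLUMNS <- c("instrument_id", "label", "x", "y", "angle")

#' Build a placement table
#'
#' Constructs the placement data frame held by a [table_setup()]: one row per
#' instrument instance on the table, with the canonical instrument identity
#' used for cross-table matching, a free-text display label, the x/y position
#' in pixels and the orientation angle in degrees.
#'
#' Angles are normalized to `[0, 360)`; positions outside the
#' 1920 x 1080 px surface are rejected. The same `instrument_id` may occur on
#' several rows (the recording surface allows duplicate and stacked
#' instruments); the metric matches such instances by optimal assignment.
#'
#' @param instrument_id character vector of canonical instrument identities.
#' @param x,y numeric positions in pixels, `0 <= x <= 1920`, `0 <= y <= 1080`.
#' @param angle numeric orientation in degrees; any finite value is accepted
#'   and reduced modulo 360.
#' @param label optional display names; defaults to `instrument_id`.
#' @return A data frame with columns `instrument_id`, `label`, `x`, `y`,
#'   `angle`.
#' @examples
#' placements("scalpel", x = 100, y = 200, angle = 45)
#' @export
placements <- function(instrument_id = character(), x = numeric(),
                       y = numeric(), angle = numeric(),
                       label = instrument_id) {
  df <- data.frame(
    instrument_id = as.character(instrument_id),
    label = as.character(label),
    x = as.numeric(x),
    y = as.numeric(y),
    angle = as.numeric(angle),
    stringsAsFactors = FALSE
  )
  validate_placements(df)
}

validate_placements <- function(df, setup_id = "<unnamed>") {
  stopifnot(is.data.frame(df))
  missing_cols <- setdiff(PLACEMENT_COLUMNS, names(df))
  if (length(missing_cols) > 0L) {
    abort_validation("placements missing column(s): %s",
                     paste(missing_cols, collapse = ", "))
  }
  df <- df[, PLACEMENT_COLUMNS, drop = FALSE]
  rownames(df) <- NULL
  if (nrow(df) == 0L) return(df)
  if (anyNA(df$x) || anyNA(df$y) || anyNA(df$angle) ||
      !all(is.finite(df$x)) || !all(is.finite(df$y)) ||
      !all(is.finite(df$angle))) {
    abort_validation("setup '%s': non-finite coordinate or angle", setup_id)
  }
  bad <- which(df$x < 0 | df$x > SURFACE_WIDTH |
               df$y < 0 | df$y > SURFACE_HEIGHT)
  if (length(bad) > 0L) {
    abort_validation(
      "setup '%s': instrument '%s' at (%g, %g) outside the %d x %d surface",
      setup_id, df$instrument_id[bad[1L]], df$x[bad[1L]], df$y[bad[1L]],
      SURFACE_WIDTH, SURFACE_HEIGHT)
  }
  df$angle <- df$angle %% 360
  df
}

#' Create a table setup
#'
#' A table setup is one recorded arrangement: the placements laid out by one
#' participant (scrub nurse), tagged with the clinic the participant belongs
#' to. It is the unit compared by [table_similarity()].
#'
#' @param setup_id character scalar, unique within a collection
#'   (e.g. `"acqua4"`).
#' @param clinic_id character scalar naming the clinic (e.g. `"acqua"`).
#' @param placements a placement data frame from [placements()]; may be empty
#'   (a valid degenerate setup).
#' @return An object of class `table_setup`.
#' @examples
#' table_setup("s1", "clinicA", placements("forceps", 10, 20, 90))
#' @export
table_setup <- function(setup_id, clinic_id, placements = NULL) {
  if (!is.character(setup_id) || length(setup_id) != 1L || !nzchar(setup_id)) {
    abort_validation("setup_id must be a non-empty string")
  }
  if (!is.character(clinic_id) || length(clinic_id) != 1L || !nzchar(clinic_id)) {
    abort_validation("clinic_id must be a non-empty string")
  }
  if (is.null(placements)) {
    placements <- placements()
  }
  placements <- validate_placements(placements, setup_id = setup_id)
  structure(
    list(setup_id = setup_id, clinic_id = clinic_id, placements = placements),
    class = "table_setup"
  )
}

#' @export
print.table_setup <- function(x, ...) {
  cat(sprintf("<table_setup> %s (clinic %s), %d instrument(s)\n",
              x$setup_id, x$clinic_id, nrow(x$placements)))
  if (nrow(x$placements) > 0L) print(utils::head(x$placements, 10L))
  invisible(x)
}

#' Create a setup collection
#'
#' Bundles table setups (with unique ids) for matrix computation, clinic
#' attribution and serialization. The clinic set is derived from the setups.
#'
#' @param setups a list of [table_setup()] objects.
#' @return An object of class `setup_collection` with elements `setups`
#'   (named by setup id, insertion order preserved) and `clinics` (sorted
#'   unique clinic ids).
#' @examples
#' a <- table_setup("s1", "c1", placements("knife", 5, 5, 0))
#' b <- table_setup("s2", "c1", placements("knife", 9, 8, 10))
#' setup_collection(list(a, b))
#' @export
setup_collection <- function(setups = list()) {
  if (inherits(setups, "table_setup")) setups <- list(setups)
  if (!is.list(setups) || !all(vapply(setups, inherits, logical(1L), "table_setup"))) {
    abort_validation("setups must be a list of table_setup objects")
  }
  ids <- vapply(setups, `[[`, character(1L), "setup_id")
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L) {
    abort_validation("duplicate setup_id in collection: %s",
                     paste(unique(dup), collapse = ", "))
  }
  names(setups) <- ids
  clinics <- sort(unique(vapply(setups, `[[`, character(1L), "clinic_id")))
  structure(list(setups = setups, clinics = clinics),
            class = "setup_collection")
}

#' @export
print.setup_collection <- function(x, ...) {
  cat(sprintf("<setup_collection> %d setup(s) across %d clinic(s)\n",
              length(x$setups), length(x$clinics)))
  if (length(x$setups) > 0L) {
    tab <- table(vapply(x$setups, `[[`, character(1L), "clinic_id"))
    for (cl in names(tab)) cat(sprintf("  %s: %d\n", cl, tab[[cl]]))
  }
  invisible(x)
}

#' @export
length.setup_collection <- function(x) length(x$setups)

collection_ids <- function(c) names(c$setups)

collection_clinic_of <- function(c) {
  vapply(c$setups, `[[`, character(1L), "clinic_id")
}

get_setup <- function(c, setup_id) {
  s <- c$setups[[setup_id]]
  if (is.null(s)) abort_validation("unknown setup_id '%s'", setup_id)
  s
}

#' Convert between a setup collection and a flat data frame
#'
#' One row per placement, with `setup_id` and `clinic_id` repeated; the same
#' layout as the CSV interchange format.
#'
#' @param x a `setup_collection`.
#' @param ... unused.
#' @return A data frame with columns `setup_id`, `clinic_id`,
#'   `instrument_id`, `label`, `x`, `y`, `angle`.
#' @export
as.data.frame.setup_collection <- function(x, ...) {
  if (length(x$setups) == 0L) {
    return(data.frame(setup_id = character(), clinic_id = character(),
                      instrument_id = character(), label = character(),
                      x = numeric(), y = numeric(), angle = numeric(),
                      stringsAsFactors = FALSE))
  }
  rows <- lapply(x$setups, function(s) {
    n <- nrow(s$placements)
    cbind(
      data.frame(setup_id = rep(s$setup_id, n),
                 clinic_id = rep(s$clinic_id, n),
                 stringsAsFactors = FALSE),
      s$placements
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Inverse of as.data.frame.setup_collection; `extra` carries setups with no
# placements (which a flat table cannot represent).
collection_from_flat <- function(df, empty_setups = NULL) {
  stopifnot(is.data.frame(df))
  setups <- list()
  if (nrow(df) > 0L) {
    idx <- split(seq_len(nrow(df)), factor(df$setup_id, levels = unique(df$setup_id)))
    setups <- lapply(names(idx), function(id) {
      rows <- df[idx[[id]], , drop = FALSE]
      clinic <- unique(rows$clinic_id)
      if (length(clinic) != 1L) {
        abort_validation("setup '%s' assigned to multiple clinics: %s",
                         id, paste(clinic, collapse = ", "))
      }
      table_setup(id, clinic, rows[, PLACEMENT_COLUMNS, drop = FALSE])
    })
  }
  setup_collection(c(setups, empty_setups))
}
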