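# Aggregation of closed yes/no questionnaire responses per clinic.
#
# Raw per-participant answers are not needed: the unit of input is the
# per-clinic yes-count together with the clinic's participant count.
# Conditional questions ("Q1.1 applies & ...") keep ALL participants in the
# denominator — a participant whose gating answer was "no" counts as "no"
# here too — so percentages are non-increasing along a dependency chain.

#' Question specifications
#'
#' @param df data frame with columns `question_id`, `text` and `depends_on`
#'   (semicolon-separated ids of questions that must be answered yes for this
#'   one to apply; empty for unconditional questions). Dependencies must
#'   precede their dependents.
#' @return A data frame of class `question_specs` with `depends_on` parsed
#'   into a list column.
#' @export
question_specs <- function(df) {
  stopifnot(is.data.frame(df))
  need <- c("question_id", "text", "depends_on")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0L) {
    abort_validation("question specs missing column(s): %s",
                     paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(df$question_id)) {
    abort_validation("duplicate question_id in specs")
  }
  deps <- lapply(as.character(df$depends_on), function(d) {
    d <- trimws(strsplit(d, ";", fixed = TRUE)[[1L]])
    d[nzchar(d)]
  })
  seen <- character()
  for (i in seq_len(nrow(df))) {
    unknown <- setdiff(deps[[i]], seen)
    if (length(unknown) > 0L) {
      abort_validation("question '%s' depends on '%s', which does not precede it",
                       df$question_id[i], unknown[1L])
    }
    seen <- c(seen, df$question_id[i])
  }
  out <- data.frame(question_id = as.character(df$question_id),
                    text = as.character(df$text), stringsAsFactors = FALSE)
  out$depends_on <- deps
  class(out) <- c("question_specs", "data.frame")
  out
}

#' Per-clinic yes-counts
#'
#' @param df data frame with columns `clinic_id`, `question_id`, `yes_count`,
#'   `n` (participants in the clinic). `n` must be constant within a clinic
#'   and `0 <= yes_count <= n`.
#' @return A data frame of class `response_counts`.
#' @export
response_counts <- function(df) {
  stopifnot(is.data.frame(df))
  need <- c("clinic_id", "question_id", "yes_count", "n")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0L) {
    abort_validation("response counts missing column(s): %s",
                     paste(missing_cols, collapse = ", "))
  }
  df$yes_count <- as.numeric(df$yes_count)
  df$n <- as.numeric(df$n)
  if (anyNA(df$yes_count) || anyNA(df$n)) {
    abort_validation("non-numeric yes_count or n in response counts")
  }
  if (any(df$yes_count < 0 | df$yes_count > df$n)) {
    bad <- which(df$yes_count < 0 | df$yes_count > df$n)[1L]
    abort_validation("clinic '%s', question '%s': yes_count %g outside [0, %g]",
                     df$clinic_id[bad], df$question_id[bad],
                     df$yes_count[bad], df$n[bad])
  }
  per_clinic_n <- tapply(df$n, df$clinic_id, function(v) length(unique(v)))
  if (any(per_clinic_n > 1L)) {
    abort_validation("clinic '%s' reported with inconsistent participant counts",
                     names(per_clinic_n)[per_clinic_n > 1L][1L])
  }
  if (anyDuplicated(df[, c("clinic_id", "question_id")])) {
    abort_validation("duplicate clinic/question pair in response counts")
  }
  out <- df[, need]
  rownames(out) <- NULL
  class(out) <- c("response_counts", "data.frame")
  out
}

counts_cell <- function(r, clinic, q) {
  row <- r[r$clinic_id == clinic & r$question_id == q, , drop = FALSE]
  if (nrow(row) == 0L) {
    abort_validation("no count for clinic '%s', question '%s'", clinic, q)
  }
  row
}

#' Percent agreement within one clinic
#'
#' `100 * yes_count / n` for the clinic; unrounded (round at presentation).
#'
#' @param r a [response_counts()] data frame.
#' @param clinic,q clinic and question ids.
#' @return Percentage in `[0, 100]`.
#' @export
clinic_percent <- function(r, clinic, q) {
  stopifnot(inherits(r, "response_counts"))
  row <- counts_cell(r, clinic, q)
  100 * row$yes_count / row$n
}

#' Percent agreement over all clinics
#'
#' Participant-weighted: `100 * sum(yes_counts) / sum(n)`. With equal clinic
#' sizes this equals the unweighted mean of the clinic percentages.
#'
#' @param r a [response_counts()] data frame.
#' @param q a question id present for every clinic.
#' @return Percentage in `[0, 100]`.
#' @export
total_percent <- function(r, q) {
  stopifnot(inherits(r, "response_counts"))
  rows <- r[r$question_id == q, , drop = FALSE]
  if (nrow(rows) == 0L) abort_validation("unknown question_id '%s'", q)
  missing_clinics <- setdiff(unique(r$clinic_id), rows$clinic_id)
  if (length(missing_clinics) > 0L) {
    abort_validation("question '%s' missing counts for clinic '%s'",
                     q, missing_clinics[1L])
  }
  if (sum(rows$n) == 0) abort_validation("zero participants for question '%s'", q)
  100 * sum(rows$yes_count) / sum(rows$n)
}

validate_dependencies <- function(specs, r) {
  for (i in seq_len(nrow(specs))) {
    q <- specs$question_id[i]
    for (dep in specs$depends_on[[i]]) {
      for (cl in unique(r$clinic_id)) {
        yq <- counts_cell(r, cl, q)$yes_count
        yd <- counts_cell(r, cl, dep)$yes_count
        if (yq > yd) {
          abort_validation(
            "clinic '%s': question '%s' has more yes answers (%g) than its dependency '%s' (%g)",
            cl, q, yq, dep, yd)
        }
      }
    }
  }
  invisible(TRUE)
}

#' Render questionnaire percentage tables
#'
#' One row per question with per-clinic and participant-weighted total
#' percentages, one-decimal rounding at this presentation step. Dependent
#' questions are annotated with their gating chain. Counts violating chain
#' monotonicity raise a validation error. Optionally writes
#' `questions.csv`/`questions.txt` under `out_dir`.
#'
#' @param specs a [question_specs()] data frame.
#' @param r a [response_counts()] data frame covering every spec question.
#' @param out_dir optional output directory.
#' @return Invisibly, a list with `csv` (per-question percentages, full
#'   precision) and `text` (formatted lines).
#' @export
render_question_tables <- function(specs, r, out_dir = NULL) {
  stopifnot(inherits(specs, "question_specs"), inherits(r, "response_counts"))
  validate_dependencies(specs, r)
  clinics <- sort(unique(r$clinic_id))
  if (nrow(specs) == 0L) {
    csv <- data.frame(question_id = character(), text = character())
    lines <- character()
  } else {
    pct <- lapply(specs$question_id, function(q) {
      c(vapply(clinics, function(cl) clinic_percent(r, cl, q), numeric(1L)),
        total = total_percent(r, q))
    })
    csv <- cbind(
      data.frame(question_id = specs$question_id, text = specs$text,
                 depends_on = vapply(specs$depends_on, paste,
                                     character(1L), collapse = ";"),
                 stringsAsFactors = FALSE),
      do.call(rbind, pct)
    )
    rownames(csv) <- NULL
    chain <- vapply(seq_len(nrow(specs)), function(i) {
      d <- specs$depends_on[[i]]
      if (length(d) == 0L) specs$question_id[i]
      else paste(c(paste0(d, " applies"), specs$question_id[i]), collapse = " & ")
    }, character(1L))
    header <- c("question", clinics, "total")
    body <- lapply(seq_len(nrow(specs)), function(i) {
      c(chain[i], vapply(pct[[i]], fmt1, character(1L)))
    })
    tab <- rbind(header, do.call(rbind, body))
    widths <- apply(nchar(tab), 2L, max)
    lines <- apply(tab, 1L, function(rw) {
      paste(mapply(formatC, rw, width = widths, MoreArgs = list(flag = "-")),
            collapse = "  ")
    })
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(csv, file.path(out_dir, "questions.csv"),
                     row.names = FALSE)
    writeLines(lines, file.path(out_dir, "questions.txt"))
  }
  invisible(list(csv = csv, text = lines))
}

#' Read question specs from CSV
#'
#' Columns `question_id,text,depends_on` (`depends_on` semicolon-separated).
#'
#' @param path CSV file path.
#' @return A [question_specs()] data frame.
#' @export
read_question_specs <- function(path) {
  if (!file.exists(path)) abort_io("file not found: %s", path)
  df <- utils::read.csv(path, colClasses = "character")
  question_specs(df)
}

#' Read per-clinic yes-counts from CSV
#'
#' Columns `clinic_id,question_id,yes_count,n`.
#'
#' @param path CSV file path.
#' @return A [response_counts()] data frame.
#' @export
read_question_counts <- function(path) {
  if (!file.exists(path)) abort_io("file not found: %s", path)
  df <- tryCatch(utils::read.csv(path),
                 error = function(e) abort_parse("cannot parse CSV '%s': %s",
                                                path, conditionMessage(e)))
  for (col in c("yes_count", "n")) {
    if (col %in% names(df)) {
      v <- suppressWarnings(as.numeric(df[[col]]))
      bad <- which(is.na(v))
      if (length(bad) > 0L) {
        abort_parse("CSV '%s' row %d: column '%s' is not numeric",
                    path, bad[1L], col)
      }
    }
  }
  response_counts(df)
}
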