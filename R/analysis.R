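# Leave-one-out clinic attribution.
#
# For each setup, remove it, compute the mean similarity score between it and
# the remaining setups of every clinic (its own clinic mean uses its
# remaining clinic-mates), and predict the clinic with the lowest mean. The
# per-setup total is the count-weighted mean over all non-self scores by
# default (not the mean of clinic means; with unequal clinic sizes the two
# differ, so the strategy is injectable).

#' Per-clinic average similarity for one setup
#'
#' Means of `table_similarity(target, other)` over the other setups, grouped
#' by clinic, plus the total mean over all others.
#'
#' @param target a setup id present in `collection`, or a [table_setup()]
#'   whose id is.
#' @param collection a [setup_collection()].
#' @param w a [metric_weights()] object.
#' @param normalization passed to [table_similarity()].
#' @param total_strategy `"pooled"` (default): total = mean over all non-self
#'   scores, count-weighted; `"clinic_mean"`: unweighted mean of the clinic
#'   means.
#' @return A list with `setup_id`, `clinic_id`, `per_clinic` (named numeric,
#'   one mean per clinic) and `total`.
#' @export
clinic_averages <- function(target, collection, w = metric_weights(),
                            normalization = "union",
                            total_strategy = c("pooled", "clinic_mean")) {
  stopifnot(inherits(collection, "setup_collection"))
  total_strategy <- match.arg(total_strategy)
  if (inherits(target, "table_setup")) target <- target$setup_id
  target_setup <- get_setup(collection, target)
  others <- collection$setups[setdiff(collection_ids(collection), target)]
  if (length(others) == 0L) {
    abort_validation("collection has no setups besides '%s'", target)
  }
  scores <- vapply(others, function(s) {
    table_similarity(target_setup, s, w, normalization)
  }, numeric(1L))
  clinics_of_others <- vapply(others, `[[`, character(1L), "clinic_id")
  missing_clinics <- setdiff(collection$clinics, clinics_of_others)
  if (length(missing_clinics) > 0L) {
    abort_validation("clinic '%s' has no setups left after removing '%s'",
                     missing_clinics[1L], target)
  }
  per_clinic <- vapply(collection$clinics, function(cl) {
    mean(scores[clinics_of_others == cl])
  }, numeric(1L))
  total <- switch(total_strategy,
                  pooled = mean(scores),
                  clinic_mean = mean(per_clinic))
  list(setup_id = target, clinic_id = target_setup$clinic_id,
       per_clinic = per_clinic, total = total)
}

# Row-wise clinic means from a precomputed similarity matrix (one pass for
# the whole LOOCV; identical numbers to clinic_averages, cheaper).
averages_from_matrix <- function(M, clinic_of, total_strategy = "pooled") {
  ids <- rownames(M)
  clinics <- sort(unique(clinic_of))
  lapply(ids, function(id) {
    others <- setdiff(ids, id)
    scores <- M[id, others]
    oc <- clinic_of[others]
    per_clinic <- vapply(clinics, function(cl) mean(scores[oc == cl]),
                         numeric(1L))
    total <- if (total_strategy == "pooled") mean(scores) else mean(per_clinic)
    list(setup_id = id, clinic_id = clinic_of[[id]],
         per_clinic = per_clinic, total = total)
  })
}

#' Leave-one-out clinic attribution
#'
#' Classifies every setup by removing it, computing its per-clinic mean
#' similarity against the remaining setups, and predicting the clinic with
#' the lowest mean (lower score = more similar). A tie in the minimum is
#' reported as ambiguous (all tied clinics listed, separated by `"|"`) and
#' counted as incorrect unless the true clinic is the unique minimum.
#'
#' @param collection a [setup_collection()] with at least two clinics, each
#'   holding at least two setups.
#' @inheritParams clinic_averages
#' @return A data frame of class `loocv_result` with one row per setup:
#'   `setup_id`, `true_clinic`, `predicted_clinic`, `ambiguous`, `correct`,
#'   one `mean_<clinic>` column per clinic, and `total`. Attributes
#'   `n_correct`, `accuracy` and `weights` summarize the run.
#' @examples
#' cfg <- simulation_config(n_clinics = 2, nurses_per_clinic = 2,
#'                          n_instruments = 3, sigma_xy = 0, sigma_angle = 0,
#'                          p_drop = 0, p_extra = 0, seed = 7)
#' res <- loocv_classify(simulate_study(cfg))
#' attr(res, "accuracy")
#' @export
loocv_classify <- function(collection, w = metric_weights(),
                           normalization = "union",
                           total_strategy = c("pooled", "clinic_mean")) {
  stopifnot(inherits(collection, "setup_collection"))
  total_strategy <- match.arg(total_strategy)
  w <- as_metric_weights(w)
  clinic_of <- collection_clinic_of(collection)
  if (length(collection$clinics) < 2L) {
    abort_validation("LOOCV requires at least 2 clinics")
  }
  counts <- table(clinic_of)
  small <- names(counts)[counts < 2L]
  if (length(small) > 0L) {
    abort_validation("clinic '%s' has fewer than 2 setups; every clinic must keep one after removal",
                     small[1L])
  }
  M <- similarity_matrix(collection, w, normalization)
  avgs <- averages_from_matrix(unclass(M), clinic_of, total_strategy)
  rows <- lapply(avgs, function(a) {
    mins <- names(a$per_clinic)[a$per_clinic == min(a$per_clinic)]
    ambiguous <- length(mins) > 1L
    correct <- !ambiguous && mins == a$clinic_id
    cbind(
      data.frame(setup_id = a$setup_id, true_clinic = a$clinic_id,
                 predicted_clinic = paste(mins, collapse = "|"),
                 ambiguous = ambiguous, correct = correct,
                 stringsAsFactors = FALSE),
      as.data.frame(as.list(stats::setNames(a$per_clinic,
                                            paste0("mean_", names(a$per_clinic))))),
      data.frame(total = a$total)
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out,
            class = c("loocv_result", "data.frame"),
            n_correct = sum(out$correct),
            accuracy = mean(out$correct),
            weights = w,
            normalization = normalization,
            total_strategy = total_strategy)
}

#' Accuracy of a leave-one-out run
#'
#' @param results a `loocv_result` from [loocv_classify()].
#' @return Fraction of setups attributed to their true clinic.
#' @export
loocv_accuracy <- function(results) {
  stopifnot(inherits(results, "loocv_result"))
  mean(results$correct)
}

#' @export
print.loocv_result <- function(x, ...) {
  cat(sprintf("<loocv_result> %d/%d correct (%.1f%%)\n",
              attr(x, "n_correct"), nrow(x), 100 * attr(x, "accuracy")))
  print(as.data.frame(x), ...)
  invisible(x)
}

#' Most representative setup of a collection
#'
#' The setup minimizing the mean similarity score against all other setups
#' (the table most similar to all other tables). Ties are broken
#' lexicographically by setup id and reported.
#'
#' @inheritParams loocv_classify
#' @return A list with `setup_id`, `total` (its all-others mean score) and
#'   `tied` (ids sharing the minimum, including the winner).
#' @export
most_representative <- function(collection, w = metric_weights(),
                                normalization = "union") {
  stopifnot(inherits(collection, "setup_collection"))
  if (length(collection$setups) < 2L) {
    abort_validation("most_representative requires at least 2 setups")
  }
  M <- unclass(similarity_matrix(collection, w, normalization))
  n <- nrow(M)
  totals <- rowSums(M) / (n - 1L)   # diagonal is 0: mean over the others
  best <- min(totals)
  tied <- sort(names(totals)[totals == best])
  list(setup_id = tied[1L], total = best, tied = tied)
}

fmt1 <- function(x) sprintf("%.1f", x)

#' Render the leave-one-out report
#'
#' Produces the per-setup attribution table: one row per setup with the
#' per-clinic mean similarities and the total mean, rounded to one decimal
#' at this presentation step only. Correct attributions are flagged `yes`,
#' incorrect ones `NO`, and the most representative setup (lowest total)
#' is starred. Optionally writes `table1.csv` (machine-readable, full
#' precision) and `table1.txt` (formatted) under `out_dir`.
#'
#' @param results a `loocv_result` from [loocv_classify()].
#' @param out_dir optional output directory (created if needed).
#' @return Invisibly, a list with `csv` (data frame) and `text` (character
#'   lines).
#' @export
render_table1 <- function(results, out_dir = NULL) {
  stopifnot(inherits(results, "loocv_result"))
  if (nrow(results) == 0L) abort_validation("no results to render")
  mean_cols <- grep("^mean_", names(results), value = TRUE)
  clinics <- sub("^mean_", "", mean_cols)
  rep_id <- results$setup_id[which.min(results$total)]

  csv <- as.data.frame(results)[, c("setup_id", "true_clinic",
                                    "predicted_clinic", "correct",
                                    mean_cols, "total")]

  header <- c("setup", clinics, "total", "predicted", "correct")
  body <- lapply(seq_len(nrow(results)), function(i) {
    star <- if (results$setup_id[i] == rep_id) "*" else ""
    c(paste0(results$setup_id[i], star),
      vapply(mean_cols, function(cl) fmt1(results[[cl]][i]), character(1L)),
      fmt1(results$total[i]),
      results$predicted_clinic[i],
      if (results$correct[i]) "yes" else "NO")
  })
  tab <- rbind(header, do.call(rbind, body))
  widths <- apply(nchar(tab), 2L, max)
  lines <- apply(tab, 1L, function(r) {
    paste(mapply(formatC, r, width = widths, MoreArgs = list(flag = "-")),
          collapse = "  ")
  })
  lines <- c(lines, "",
             sprintf("accuracy: %d/%d (%s%%)", attr(results, "n_correct"),
                     nrow(results), fmt1(100 * attr(results, "accuracy"))),
             sprintf("most representative: %s (total %s)",
                     rep_id, fmt1(min(results$total))),
             "(* lowest total mean; lower scores = more similar)")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(csv, file.path(out_dir, "table1.csv"), row.names = FALSE)
    writeLines(lines, file.path(out_dir, "table1.txt"))
  }
  invisible(list(csv = csv, text = lines))
}
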