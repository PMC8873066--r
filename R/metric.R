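# Table similarity metric.
#
# For two setups A and B, every instrument identity present on either table
# contributes one per-instrument score s_inst:
#
#   s_inst = w_trans * d_trans + w_rot * d_rot   if matched on both tables
#   s_inst = w_miss                              if present on only one table
#
# with d_trans the Euclidean position distance in pixels and d_rot the
# minimal angular difference in degrees (range [0, 180]). The table score
# s_tab is the normalized sum of the s_inst values: 0 for identical setups,
# larger values for less similar setups. The normalization denominator is
# configurable (see `normalization` below) because "normalized sum" admits
# more than one reading; the default divides by the size of the matching
# universe (matched pairs count once, each unmatched instance counts once),
# making s_tab a per-instrument average comparable across table sizes.
#
# Duplicate instances of one identity are matched min(m, n) at a time by
# minimum-total-cost assignment on w_trans*d_trans + w_rot*d_rot; the
# |m - n| leftover instances each count as missing once.

#' Metric weights
#'
#' The triple configuring the influence of translational deviation (per
#' pixel), rotational deviation (per degree) and missing instruments (flat
#' penalty, in score units) on the table similarity score. The study defaults
#' are `w_trans = 1`, `w_rot = 1`, `w_miss = 1000`.
#'
#' @param w_trans,w_rot,w_miss finite non-negative reals.
#' @return An object of class `metric_weights`.
#' @examples
#' metric_weights()
#' metric_weights(w_miss = 500)
#' @export
metric_weights <- function(w_trans = 1, w_rot = 1, w_miss = 1000) {
  w <- c(w_trans = as.numeric(w_trans), w_rot = as.numeric(w_rot),
         w_miss = as.numeric(w_miss))
  if (anyNA(w) || !all(is.finite(w)) || any(w < 0)) {
    abort_validation("metric weights must be finite and non-negative")
  }
  structure(as.list(w), class = "metric_weights")
}

#' @export
print.metric_weights <- function(x, ...) {
  cat(sprintf("<metric_weights> w_trans=%g w_rot=%g w_miss=%g\n",
              x$w_trans, x$w_rot, x$w_miss))
  invisible(x)
}

as_metric_weights <- function(w) {
  if (inherits(w, "metric_weights")) return(w)
  if (is.numeric(w) && length(w) == 3L) {
    return(metric_weights(w[[1L]], w[[2L]], w[[3L]]))
  }
  abort_validation("weights must be a metric_weights object or numeric triple")
}

#' Translational distance between two placements
#'
#' Euclidean distance in pixels between instrument positions; on the
#' 1920 x 1080 surface the range is `[0, sqrt(1920^2 + 1080^2)]`, about
#' 2202.9 px.
#'
#' @param a,b placements (any list or one-row data frame with `x` and `y`),
#'   or numeric vectors of x-positions/y-positions for the vectorized form
#'   `trans_distance(xa, ya, xb, yb)` — see `rot_distance` for the scalar
#'   convention used throughout.
#' @return Distance(s) in pixels.
#' @examples
#' trans_distance(list(x = 0, y = 0), list(x = 3, y = 4)) # 5
#' @export
trans_distance <- function(a, b) {
  sqrt((a$x - b$x)^2 + (a$y - b$y)^2)
}

trans_distance_xy <- function(xa, ya, xb, yb) {
  sqrt((xa - xb)^2 + (ya - yb)^2)
}

#' Rotational distance between two angles
#'
#' The minimal angle (degrees) needed to rotate one instrument into the
#' other's orientation: `min(|a - b|, 360 - |a - b|)`, range `[0, 180]`.
#' Vectorized.
#'
#' @param angle_a,angle_b angles in degrees, `[0, 360)`.
#' @return Angular distance(s) in degrees.
#' @examples
#' rot_distance(10, 350) # 20
#' @export
rot_distance <- function(angle_a, angle_b) {
  d <- abs(angle_a - angle_b)
  pmin(d, 360 - d)
}

# Canonical ordering of the argument pair: the whole score computation is run
# on (first, second) ordered by content, so s_tab(A, B) and s_tab(B, A)
# execute identical arithmetic and agree bitwise even when optimal
# assignments are tied.
setup_content_key <- function(s) {
  p <- s$placements
  paste(s$setup_id, s$clinic_id,
        paste(p$instrument_id, fmt_num(p$x), fmt_num(p$y), fmt_num(p$angle),
              collapse = ";"),
        sep = "|")
}

all_injections <- function(m, n) {
  # all ordered selections of m distinct targets out of n, in lexicographic
  # order of the selected index vectors; deterministic
  if (m == 0L) return(list(integer()))
  out <- list()
  rec <- function(prefix, remaining) {
    if (length(prefix) == m) {
      out[[length(out) + 1L]] <<- prefix
      return(invisible())
    }
    for (t in remaining) rec(c(prefix, t), setdiff(remaining, t))
  }
  rec(integer(), seq_len(n))
  out
}

# Optimal assignment of the m rows of cost (m <= n) to distinct columns,
# minimizing total cost, by exhaustive enumeration (duplicate multiplicities
# on a real tray are tiny). Returns the first-encountered optimal injection.
solve_assignment <- function(cost) {
  m <- nrow(cost); n <- ncol(cost)
  stopifnot(m <= n)
  if (m == 1L) return(which.min(cost[1L, ]))
  n_inj <- prod(n - seq_len(m) + 1)
  if (n_inj > 5e5) {
    abort_validation(
      "too many duplicate instances of one instrument (%d x %d) for exact matching",
      m, n)
  }
  injections <- all_injections(m, n)
  best <- NULL; best_cost <- Inf
  for (inj in injections) {
    tc <- sum(cost[cbind(seq_len(m), inj)])
    if (tc < best_cost) {
      best_cost <- tc
      best <- inj
    }
  }
  best
}

empty_scores <- function() {
  data.frame(instrument_id = character(), status = character(),
             d_trans = numeric(), d_rot = numeric(), s_inst = numeric(),
             stringsAsFactors = FALSE)
}

# Per-identity matching for one instrument id with pa (instances on first
# table) and pb (on second); returns score rows.
match_one_identity <- function(id, pa, pb, w) {
  m <- nrow(pa); n <- nrow(pb)
  if (m == 0L || n == 0L) {
    k <- max(m, n)
    return(data.frame(instrument_id = rep(id, k),
                      status = rep("missing", k),
                      d_trans = rep(NA_real_, k), d_rot = rep(NA_real_, k),
                      s_inst = rep(w$w_miss, k), stringsAsFactors = FALSE))
  }
  swap <- m > n
  small <- if (swap) pb else pa
  big <- if (swap) pa else pb
  k <- nrow(small)
  dt <- outer(seq_len(k), seq_len(nrow(big)), function(i, j) {
    trans_distance_xy(small$x[i], small$y[i], big$x[j], big$y[j])
  })
  dr <- outer(seq_len(k), seq_len(nrow(big)), function(i, j) {
    rot_distance(small$angle[i], big$angle[j])
  })
  cost <- w$w_trans * dt + w$w_rot * dr
  inj <- solve_assignment(cost)
  matched <- data.frame(
    instrument_id = rep(id, k), status = rep("matched", k),
    d_trans = dt[cbind(seq_len(k), inj)],
    d_rot = dr[cbind(seq_len(k), inj)],
    s_inst = cost[cbind(seq_len(k), inj)],
    stringsAsFactors = FALSE)
  n_miss <- nrow(big) - k
  if (n_miss > 0L) {
    matched <- rbind(matched, data.frame(
      instrument_id = rep(id, n_miss), status = rep("missing", n_miss),
      d_trans = rep(NA_real_, n_miss), d_rot = rep(NA_real_, n_miss),
      s_inst = rep(w$w_miss, n_miss), stringsAsFactors = FALSE))
  }
  matched
}

#' Per-instrument similarity scores for a pair of setups
#'
#' Computes the matching universe of two setups and one score row per element
#' of it: instruments present on both tables are matched (duplicate instances
#' by minimum-total-cost assignment) and scored
#' `w_trans * d_trans + w_rot * d_rot`; each instance present on exactly one
#' table is scored `w_miss` once. Rows are ordered by `instrument_id`, then
#' assignment order, and the result is invariant under swapping `a` and `b`.
#'
#' @param a,b [table_setup()] objects.
#' @param w a [metric_weights()] object.
#' @return A data frame with columns `instrument_id`, `status`
#'   (`"matched"`/`"missing"`), `d_trans` (px), `d_rot` (deg) and `s_inst`
#'   (`NA` distances for missing instruments).
#' @examples
#' a <- table_setup("a", "c1", placements("I1", 0, 0, 0))
#' b <- table_setup("b", "c2", placements("I1", 3, 4, 20))
#' instrument_scores(a, b, metric_weights()) # s_inst = 5 + 20 = 25
#' @export
instrument_scores <- function(a, b, w = metric_weights()) {
  stopifnot(inherits(a, "table_setup"), inherits(b, "table_setup"))
  w <- as_metric_weights(w)
  if (setup_content_key(b) < setup_content_key(a)) {
    tmp <- a; a <- b; b <- tmp
  }
  pa <- a$placements; pb <- b$placements
  ids <- sort(unique(c(pa$instrument_id, pb$instrument_id)))
  if (length(ids) == 0L) return(empty_scores())

  if (!anyDuplicated(pa$instrument_id) && !anyDuplicated(pb$instrument_id)) {
    # fast path: at most one instance per identity on each table
    ia <- match(ids, pa$instrument_id)
    ib <- match(ids, pb$instrument_id)
    matched <- !is.na(ia) & !is.na(ib)
    dt <- dr <- rep(NA_real_, length(ids))
    dt[matched] <- trans_distance_xy(pa$x[ia[matched]], pa$y[ia[matched]],
                                     pb$x[ib[matched]], pb$y[ib[matched]])
    dr[matched] <- rot_distance(pa$angle[ia[matched]], pb$angle[ib[matched]])
    s <- ifelse(matched, w$w_trans * dt + w$w_rot * dr, w$w_miss)
    return(data.frame(instrument_id = ids,
                      status = ifelse(matched, "matched", "missing"),
                      d_trans = dt, d_rot = dr, s_inst = s,
                      stringsAsFactors = FALSE))
  }

  parts <- lapply(ids, function(id) {
    match_one_identity(id,
                       pa[pa$instrument_id == id, , drop = FALSE],
                       pb[pb$instrument_id == id, , drop = FALSE],
                       w)
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

#' Table similarity score
#'
#' The normalized sum of the per-instrument scores of [instrument_scores()].
#' A value of 0 indicates identical setups; higher values indicate decreased
#' similarity. The metric is symmetric — `table_similarity(a, b, w)` equals
#' `table_similarity(b, a, w)` bitwise — because the summation runs in a
#' canonical order independent of argument order.
#'
#' @param a,b [table_setup()] objects; at least one must contain an
#'   instrument.
#' @param w a [metric_weights()] object.
#' @param normalization denominator of the normalized sum:
#'   `"union"` (default) divides by the size of the matching universe
#'   (matched pairs once, unmatched instances once), `"max_size"` by the
#'   larger table's instrument count, `"matched_only"` by the number of
#'   matched pairs (penalties stay in the numerator). The strategy is
#'   injectable so reference data can be calibrated against either reading.
#' @return A non-negative score (score units).
#' @examples
#' w <- metric_weights()
#' a <- table_setup("a", "c1", placements("I1", 0, 0, 0))
#' b <- table_setup("b", "c2", placements("I1", 3, 4, 20))
#' table_similarity(a, b, w)  # 25
#' table_similarity(a, a, w)  # 0
#' @export
table_similarity <- function(a, b, w = metric_weights(),
                             normalization = c("union", "max_size",
                                               "matched_only")) {
  normalization <- match.arg(normalization)
  scores <- instrument_scores(a, b, w)
  if (nrow(scores) == 0L) {
    abort_validation("similarity of two empty setups ('%s', '%s') is undefined",
                     a$setup_id, b$setup_id)
  }
  denom <- switch(normalization,
    union = nrow(scores),
    max_size = max(nrow(a$placements), nrow(b$placements)),
    matched_only = sum(scores$status == "matched")
  )
  if (denom == 0L) {
    abort_validation("normalization '%s' undefined for setups '%s', '%s' (no matched instruments)",
                     normalization, a$setup_id, b$setup_id)
  }
  # sort before summing: the accumulation order is a function of the score
  # multiset only, making symmetry exact in floating point
  sum(sort(scores$s_inst)) / denom
}

#' Pairwise similarity matrix of a collection
#'
#' Symmetric matrix with zero diagonal; entry (i, j) is
#' `table_similarity(setup_i, setup_j, w)`.
#'
#' @param collection a [setup_collection()] with at least two setups.
#' @inheritParams table_similarity
#' @return A numeric matrix of class `similarity_matrix` with setup ids as
#'   dimnames and the clinic assignment in attribute `clinic_id`.
#' @export
similarity_matrix <- function(collection, w = metric_weights(),
                              normalization = c("union", "max_size",
                                                "matched_only")) {
  stopifnot(inherits(collection, "setup_collection"))
  normalization <- match.arg(normalization)
  ids <- collection_ids(collection)
  n <- length(ids)
  if (n < 2L) abort_validation("similarity_matrix requires at least 2 setups")
  M <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      s <- table_similarity(collection$setups[[i]], collection$setups[[j]],
                            w, normalization)
      M[i, j] <- s
      M[j, i] <- s
    }
  }
  structure(M, class = c("similarity_matrix", class(M)),
            clinic_id = collection_clinic_of(collection))
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat(sprintf("<similarity_matrix> %d x %d\n", nrow(x), ncol(x)))
  y <- x
  attr(y, "clinic_id") <- NULL
  print(round(unclass(y), 1), ...)
  invisible(x)
}
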