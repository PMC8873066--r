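# Shared fixtures and an independent brute-force oracle for the metric.

# terse setup builder: ts("a", "c1", "I1", 0, 0, 0, "I2", 10, 20, 90)
ts <- function(setup_id, clinic_id, ...) {
  v <- list(...)
  stopifnot(length(v) %% 4 == 0)
  if (length(v) == 0) return(table_setup(setup_id, clinic_id))
  m <- matrix(v, ncol = 4, byrow = TRUE)
  table_setup(setup_id, clinic_id, placements(
    instrument_id = unlist(m[, 1]),
    x = as.numeric(unlist(m[, 2])),
    y = as.numeric(unlist(m[, 3])),
    angle = as.numeric(unlist(m[, 4]))
  ))
}

# Independent oracle: recomputes s_tab straight from the definition, with a
# recursive min-cost matching, no code shared with the package internals.
oracle_min_match <- function(A, B, w) {
  # A, B: data frames of instances of ONE identity; returns min total cost of
  # matching min(m, n) pairs
  if (nrow(A) > nrow(B)) { tmp <- A; A <- B; B <- tmp }
  if (nrow(A) == 0) return(0)
  best <- Inf
  for (j in seq_len(nrow(B))) {
    dt <- sqrt((A$x[1] - B$x[j])^2 + (A$y[1] - B$y[j])^2)
    da <- abs(A$angle[1] - B$angle[j])
    dr <- min(da, 360 - da)
    cost <- w$w_trans * dt + w$w_rot * dr +
      oracle_min_match(A[-1, , drop = FALSE], B[-j, , drop = FALSE], w)
    if (cost < best) best <- cost
  }
  best
}

oracle_s_tab <- function(a, b, w, normalization = "union") {
  pa <- a$placements; pb <- b$placements
  ids <- sort(unique(c(pa$instrument_id, pb$instrument_id)))
  total <- 0
  universe <- 0
  matched <- 0
  for (id in ids) {
    A <- pa[pa$instrument_id == id, , drop = FALSE]
    B <- pb[pb$instrument_id == id, , drop = FALSE]
    m <- nrow(A); n <- nrow(B)
    total <- total + oracle_min_match(A, B, w) + abs(m - n) * w$w_miss
    universe <- universe + max(m, n)
    matched <- matched + min(m, n)
  }
  denom <- switch(normalization,
                  union = universe,
                  max_size = max(nrow(pa), nrow(pb)),
                  matched_only = matched)
  total / denom
}

# random valid setup with optional duplicate identities
random_setup <- function(setup_id, clinic_id, n_instruments,
                         id_pool = sprintf("I%d", 1:6)) {
  ids <- sample(id_pool, n_instruments, replace = TRUE)
  table_setup(setup_id, clinic_id, placements(
    instrument_id = ids,
    x = runif(n_instruments, 0, 1920),
    y = runif(n_instruments, 0, 1080),
    angle = runif(n_instruments, 0, 360)
  ))
}

random_collection <- function(n_setups, n_clinics = 2, max_instruments = 6) {
  setups <- lapply(seq_len(n_setups), function(i) {
    random_setup(sprintf("s%d", i), sprintf("c%d", 1 + (i %% n_clinics)),
                 sample(1:max_instruments, 1))
  })
  setup_collection(setups)
}
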