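# Synthetic multi-clinic setup generator.
#
# Stated world: each clinic has an archetype layout (its habitual "standard"
# setup of a shared instrument set); a nurse reproduces the archetype with
# isotropic Gaussian positional jitter (clipped to the surface), wrapped-
# Gaussian angular jitter, independent Bernoulli dropout of archetype
# instruments and occasional non-archetype extras at uniform positions. The
# noise model is a deliberate minimal stand-in with interpretable parameters,
# not an empirical fit.

#' Simulation configuration
#'
#' Defaults mirror the study scale (3 clinics, 5 nurses per clinic) and an
#' instrument count on the order of a FESS tray. Jitter magnitudes describe a
#' clinic with a clear but hand-laid standard: positional SD of 15 px on a
#' 1920 x 1080 surface, angular SD of 10 degrees, 5% instrument dropout and
#' no extras unless requested.
#'
#' @param n_clinics number of clinics (archetypes).
#' @param nurses_per_clinic setups sampled per clinic.
#' @param n_instruments instruments per archetype.
#' @param sigma_xy positional jitter SD, pixels (per axis).
#' @param sigma_angle angular jitter SD, degrees (wrapped into `[0, 360)`).
#' @param p_drop probability a nurse omits an archetype instrument.
#' @param p_extra controls non-archetype extras: each nurse adds
#'   `Binomial(n_instruments, p_extra)` unique extra instruments at uniform
#'   positions and angles.
#' @param archetype_separation minimum distance (px) between the positions of
#'   corresponding instruments in any two clinic archetypes; 0 lets
#'   archetypes coincide.
#' @param shared_archetype if `TRUE`, every clinic uses one identical
#'   archetype (the no-between-clinic-signal condition; overrides
#'   `archetype_separation`).
#' @param seed integer seed making generation reproducible.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_clinics = 3, nurses_per_clinic = 5,
                              n_instruments = 20, sigma_xy = 15,
                              sigma_angle = 10, p_drop = 0.05, p_extra = 0,
                              archetype_separation = 300,
                              shared_archetype = FALSE, seed = 42) {
  cfg <- list(n_clinics = as.integer(n_clinics),
              nurses_per_clinic = as.integer(nurses_per_clinic),
              n_instruments = as.integer(n_instruments),
              sigma_xy = as.numeric(sigma_xy),
              sigma_angle = as.numeric(sigma_angle),
              p_drop = as.numeric(p_drop), p_extra = as.numeric(p_extra),
              archetype_separation = as.numeric(archetype_separation),
              shared_archetype = isTRUE(shared_archetype),
              seed = as.integer(seed))
  if (cfg$n_clinics < 1L || cfg$nurses_per_clinic < 1L || cfg$n_instruments < 1L) {
    abort_validation("counts must be >= 1")
  }
  if (cfg$sigma_xy < 0 || cfg$sigma_angle < 0) {
    abort_validation("jitter SDs must be >= 0")
  }
  if (cfg$p_drop < 0 || cfg$p_drop > 1 || cfg$p_extra < 0 || cfg$p_extra > 1) {
    abort_validation("probabilities must lie in [0, 1]")
  }
  if (cfg$archetype_separation < 0) {
    abort_validation("archetype_separation must be >= 0")
  }
  structure(cfg, class = "simulation_config")
}

clip <- function(v, lo, hi) pmin(pmax(v, lo), hi)

# n_clinics positions for one instrument with pairwise distance >= sep
sample_separated_positions <- function(n, sep, max_tries = 10000L) {
  for (try in seq_len(max_tries)) {
    x <- stats::runif(n, 0, SURFACE_WIDTH)
    y <- stats::runif(n, 0, SURFACE_HEIGHT)
    if (n == 1L || min(stats::dist(cbind(x, y))) >= sep) {
      return(cbind(x = x, y = y))
    }
  }
  abort_validation(
    "cannot place %d clinic variants %g px apart on the %d x %d surface",
    n, sep, SURFACE_WIDTH, SURFACE_HEIGHT)
}

#' Generate clinic archetype layouts
#'
#' All archetypes share one instrument identity set; for every instrument the
#' clinic-specific positions are at least `archetype_separation` px apart
#' pairwise (rejection-sampled; infeasible separations raise an error).
#' Angles are uniform. With `shared_archetype = TRUE` a single layout is
#' replicated for all clinics. Reproducible from `cfg$seed`.
#'
#' @param cfg a [simulation_config()].
#' @return A list of `clinic_archetype` objects (`clinic_id` plus a placement
#'   data frame).
#' @export
generate_archetypes <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(cfg$seed)
  ids <- sprintf("inst%02d", seq_len(cfg$n_instruments))
  clinics <- sprintf("clinic%d", seq_len(cfg$n_clinics))
  n_layouts <- if (cfg$shared_archetype) 1L else cfg$n_clinics
  sep <- if (cfg$shared_archetype) 0 else cfg$archetype_separation
  pos <- lapply(seq_len(cfg$n_instruments), function(k) {
    sample_separated_positions(n_layouts, sep)
  })
  angles <- matrix(stats::runif(n_layouts * cfg$n_instruments, 0, 360),
                   nrow = n_layouts)
  lapply(seq_along(clinics), function(ci) {
    li <- if (cfg$shared_archetype) 1L else ci
    structure(
      list(clinic_id = clinics[ci],
           placements = placements(
             instrument_id = ids,
             x = vapply(pos, function(p) p[li, "x"], numeric(1L)),
             y = vapply(pos, function(p) p[li, "y"], numeric(1L)),
             angle = angles[li, ])),
      class = "clinic_archetype")
  })
}

#' Sample a setup collection from archetypes
#'
#' Draws `nurses_per_clinic` setups per clinic: archetype positions plus
#' isotropic Gaussian jitter (SD `sigma_xy`, clipped to the surface), angles
#' plus wrapped-Gaussian jitter (SD `sigma_angle`), Bernoulli(p_drop)
#' dropout per archetype instrument, and uniform-placed extra instruments.
#' Setup ids follow the `<clinic><index>` convention (e.g. `"clinic1"` yields
#' `"clinic1_3"`). Reproducible from `cfg$seed`.
#'
#' @param archetypes output of [generate_archetypes()].
#' @param cfg a [simulation_config()].
#' @return A [setup_collection()].
#' @export
sample_collection <- function(archetypes, cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(cfg$seed + 1L)
  setups <- list()
  for (arch in archetypes) {
    base <- arch$placements
    for (nurse in seq_len(cfg$nurses_per_clinic)) {
      sid <- sprintf("%s_%d", arch$clinic_id, nurse)
      keep <- stats::runif(nrow(base)) >= cfg$p_drop
      p <- base[keep, , drop = FALSE]
      if (nrow(p) > 0L) {
        p$x <- clip(p$x + stats::rnorm(nrow(p), 0, cfg$sigma_xy),
                    0, SURFACE_WIDTH)
        p$y <- clip(p$y + stats::rnorm(nrow(p), 0, cfg$sigma_xy),
                    0, SURFACE_HEIGHT)
        p$angle <- (p$angle + stats::rnorm(nrow(p), 0, cfg$sigma_angle)) %% 360
      }
      n_extra <- stats::rbinom(1L, cfg$n_instruments, cfg$p_extra)
      if (n_extra > 0L) {
        extra_ids <- sprintf("extra_%s_%d", sid, seq_len(n_extra))
        p <- rbind(p, placements(
          instrument_id = extra_ids,
          x = stats::runif(n_extra, 0, SURFACE_WIDTH),
          y = stats::runif(n_extra, 0, SURFACE_HEIGHT),
          angle = stats::runif(n_extra, 0, 360)))
      }
      setups[[sid]] <- table_setup(sid, arch$clinic_id, p)
    }
  }
  setup_collection(unname(setups))
}

#' Generate a complete synthetic study
#'
#' Convenience wrapper: [generate_archetypes()] then [sample_collection()].
#'
#' @param cfg a [simulation_config()].
#' @return A [setup_collection()].
#' @examples
#' col <- simulate_study(simulation_config(seed = 1))
#' length(col)
#' @export
simulate_study <- function(cfg) {
  sample_collection(generate_archetypes(cfg), cfg)
}

#' Characterize LOOCV accuracy over a configuration grid
#'
#' For each configuration, repeatedly simulates a study (replicate r uses
#' seed `cfg$seed + r`), runs [loocv_classify()] and records the accuracy;
#' reports the per-configuration mean and SD. Deterministic given the
#' configuration seeds.
#'
#' @param cfg_grid a list of [simulation_config()] objects (a single config
#'   is accepted).
#' @param replicates simulated studies per configuration.
#' @param w a [metric_weights()] object.
#' @return A data frame with one row per configuration: the noise parameters,
#'   `mean_accuracy`, `sd_accuracy` and `replicates`. Attribute
#'   `accuracies` holds the per-replicate matrix (configs x replicates).
#' @export
characterize_accuracy <- function(cfg_grid, replicates = 20,
                                  w = metric_weights()) {
  if (inherits(cfg_grid, "simulation_config")) cfg_grid <- list(cfg_grid)
  stopifnot(length(cfg_grid) > 0L, replicates >= 1L)
  acc <- matrix(NA_real_, nrow = length(cfg_grid), ncol = replicates)
  for (ci in seq_along(cfg_grid)) {
    cfg <- cfg_grid[[ci]]
    stopifnot(inherits(cfg, "simulation_config"))
    for (r in seq_len(replicates)) {
      cfg_r <- cfg
      cfg_r$seed <- cfg$seed + r
      res <- loocv_classify(simulate_study(cfg_r), w)
      acc[ci, r] <- loocv_accuracy(res)
    }
  }
  out <- do.call(rbind, lapply(seq_along(cfg_grid), function(ci) {
    cfg <- cfg_grid[[ci]]
    data.frame(n_clinics = cfg$n_clinics,
               nurses_per_clinic = cfg$nurses_per_clinic,
               n_instruments = cfg$n_instruments,
               sigma_xy = cfg$sigma_xy, sigma_angle = cfg$sigma_angle,
               p_drop = cfg$p_drop, p_extra = cfg$p_extra,
               archetype_separation = cfg$archetype_separation,
               shared_archetype = cfg$shared_archetype,
               seed = cfg$seed,
               mean_accuracy = mean(acc[ci, ]),
               sd_accuracy = stats::sd(acc[ci, ]),
               replicates = replicates)
  }))
  structure(out, accuracies = acc)
}
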