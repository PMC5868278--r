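lognormal_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  rlnorm(n, meanlog = 0, sdlog = sqrt(log(1 + cv^2)))
}

#' Simulate a dual-luciferase readthrough plate
#'
#' For each replicate, emits a test (TGA) well whose firefly reading is the
#' control level scaled by the true readthrough efficiency, and a sense
#' (TGG) control well. Multiplicative lognormal noise (median 1,
#' coefficient of variation `cv`) is applied independently to every
#' luminescence reading, reflecting that luminescence is positive with
#' noise that scales with signal.
#'
#' @param true_efficiency True readthrough efficiency as a fraction in
#'   `[0, 1]`.
#' @param n_replicates Biological replicates per variant (default 12).
#' @param cv Coefficient of variation of the per-reading noise.
#' @param construct,batch Labels for the construct and transfection batch.
#' @param base_firefly,base_renilla Noiseless control luminescence levels.
#' @param seed Optional integer seed.
#' @return A plate tibble with columns `batch`, `construct`, `variant`,
#'   `treatment`, `dose`, `replicate`, `firefly`, `renilla`.
#' @examples
#' sim_plate(0.067, n_replicates = 3, cv = 0, seed = 1)
#' @export
sim_plate <- function(true_efficiency, n_replicates = 12L, cv = 0.1,
                      construct = "construct", batch = "plate1",
                      base_firefly = 1e6, base_renilla = 2e5, seed = NULL) {
  assert_fraction(true_efficiency, "true_efficiency")
  assert_count(n_replicates, "n_replicates")
  if (!is.numeric(cv) || cv < 0) stop_validation("`cv` must be >= 0")
  with_seed_maybe(seed, {
    n <- n_replicates
    tga <- tibble(
      batch = batch, construct = construct, variant = "TGA",
      treatment = "none", dose = NA_real_, replicate = seq_len(n),
      firefly = base_firefly * true_efficiency * lognormal_noise(n, cv),
      renilla = base_renilla * lognormal_noise(n, cv)
    )
    tgg <- tibble(
      batch = batch, construct = construct, variant = "TGG",
      treatment = "none", dose = NA_real_, replicate = seq_len(n),
      firefly = base_firefly * lognormal_noise(n, cv),
      renilla = base_renilla * lognormal_noise(n, cv)
    )
    bind_rows(tga, tgg)
  })
}

#' Simulate a transactivation plate with planted fold-changes
#'
#' Emits vehicle and stimulated wells for each construct, with the
#' stimulated firefly level scaled by the planted fold-change and lognormal
#' noise on every reading.
#'
#' @param folds Named numeric vector: planted transactivation fold per
#'   construct (1 = no response).
#' @param n_replicates Replicates per arm (default 4).
#' @param cv Per-reading coefficient of variation.
#' @param dose Stimulation dose recorded in the table (default 1e-9, i.e.
#'   1 nM).
#' @param seed Optional seed.
#' @return A plate tibble with `treatment` in `vehicle`/`stimulated`.
#' @export
sim_transactivation <- function(folds, n_replicates = 4L, cv = 0.1,
                                dose = 1e-9, seed = NULL) {
  assert_count(n_replicates, "n_replicates")
  with_seed_maybe(seed, {
    rows <- lapply(names(folds), function(con) {
      n <- n_replicates
      base_f <- 5e5
      base_r <- 2e5
      bind_rows(
        tibble(batch = "plate1", construct = con, variant = "VDRE",
               treatment = "vehicle", dose = 0, replicate = seq_len(n),
               firefly = base_f * lognormal_noise(n, cv),
               renilla = base_r * lognormal_noise(n, cv)),
        tibble(batch = "plate1", construct = con, variant = "VDRE",
               treatment = "stimulated", dose = dose, replicate = seq_len(n),
               firefly = base_f * folds[[con]] * lognormal_noise(n, cv),
               renilla = base_r * lognormal_noise(n, cv))
      )
    })
    bind_rows(rows)
  })
}

#' Simulate sigmoidal dose-response curves
#'
#' Four-parameter logistic responses on a log-spaced dose grid with
#' multiplicative lognormal noise:
#' `response = floor + (top - floor) / (1 + (ec50 / dose)^hill)`.
#'
#' @param ec50s Named numeric vector of EC50s (> 0), one curve each.
#' @param hill Hill slope (finite, > 0).
#' @param fold_range Ratio of the top to the floor response (floor is 1).
#' @param noise_cv Coefficient of variation of per-reading noise.
#' @param doses Dose grid; defaults to 13 log-spaced doses spanning
#'   1e-12 to 1e-6 (molar, a typical calcitriol titration range).
#' @param n_replicates Replicates per dose (default 8).
#' @param seed Optional seed.
#' @return Tibble with `curve_id`, `dose`, `replicate`, `response`.
#' @export
sim_dose_response <- function(ec50s, hill = 1, fold_range = 6, noise_cv = 0.05,
                              doses = 10^seq(-12, -6, length.out = 13),
                              n_replicates = 8L, seed = NULL) {
  if (any(ec50s <= 0)) stop_validation("`ec50s` must be > 0")
  if (!is.finite(hill) || hill <= 0) stop_validation("`hill` must be finite and > 0")
  if (fold_range <= 1) stop_validation("`fold_range` must be > 1")
  assert_count(n_replicates, "n_replicates")
  if (is.null(names(ec50s))) names(ec50s) <- paste0("curve", seq_along(ec50s))
  floor_ <- 1
  top <- fold_range
  with_seed_maybe(seed, {
    rows <- lapply(names(ec50s), function(id) {
      grid <- tidyr::expand_grid(dose = doses, replicate = seq_len(n_replicates))
      mu <- floor_ + (top - floor_) / (1 + (ec50s[[id]] / grid$dose)^hill)
      tibble(curve_id = id, dose = grid$dose, replicate = grid$replicate,
             response = mu * lognormal_noise(nrow(grid), noise_cv))
    })
    bind_rows(rows)
  })
}
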