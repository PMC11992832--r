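#' Specification of a synthetic cohort
#'
#' Defines the population distributions from which synthetic participants
#' are drawn. Each participant is a vector of generative parameters: a
#' baseline RT, a saturating practice speed-up, a saturating high-vs-low
#' triplet RT advantage (the learning trajectory), an accuracy model
#' (baseline log-odds, per-block decline, high-vs-low log-odds advantage),
#' motor facilitation on trills/repetitions, an OCI-R total score, and
#' moderation coefficients that scale the learning asymptotes with the
#' standardized OCI-R score (zero by default: OC tendencies do not modulate
#' learning unless asked to).
#'
#' Defaults emulate the observed task statistics: block-level mean RTs
#' drifting from ~375 ms toward ~349 ms, accuracy declining from ~92% to
#' ~90% across 25 blocks with a triplet accuracy advantage growing to
#' ~3.5 percentage points, an RT learning asymptote around 10 ms, and OCI-R
#' totals distributed like the study samples (study 1: mean 20.72, SD
#' 11.30; study 2: mean 14.24, SD 11.73; clamped to 0-72 and rounded).
#'
#' @param n_participants Cohort size.
#' @param study `"study1"` or `"study2"`; sets the OCI-R distribution.
#' @param means,sds Named numeric vectors overriding population means and
#'   SDs of the participant parameters (see Details for names).
#' @param ocir_mean,ocir_sd OCI-R population moments (defaults per study).
#' @param noise_family `"shifted_lognormal"` (default; right-skewed,
#'   median-zero residuals) or `"normal"`.
#' @param lognorm_shape Log-scale SD of the shifted-lognormal residual
#'   (default 0.4).
#' @param retention Fraction of the trained (sequence A) advantage retained
#'   on `HL` triplets during reversed-sequence blocks; 1 = full retention.
#' @param seed Default seed used by [sample_cohort()].
#'
#' @details Parameter names (population means / SDs): `mu_rt` (375/30 ms),
#' `sigma_rt` (60/10 ms residual scale), `practice_amp` (26/8 ms),
#' `practice_rate` (8/0 blocks), `learn_asym` (10/4 ms), `learn_rate`
#' (2/0 epochs), `acc_base` (2.4/0.3 log-odds), `acc_drift` (0.011/0.004
#' log-odds per block), `acc_learn_asym` (0.35/0.10 log-odds), `motor_facil`
#' (15/5 ms), `theta_rt` (0/0), `theta_acc` (0/0). Scale parameters are
#' truncated at zero when drawn.
#'
#' @return An object of class `asrt_cohort_spec`.
#' @export
cohort_spec <- function(n_participants,
                        study = c("study1", "study2"),
                        means = NULL, sds = NULL,
                        ocir_mean = NULL, ocir_sd = NULL,
                        noise_family = c("shifted_lognormal", "normal"),
                        lognorm_shape = 0.4,
                        retention = 1.0,
                        seed = 1L) {
  study <- match.arg(study)
  noise_family <- match.arg(noise_family)
  n_participants <- as.integer(n_participants)
  stopifnot(n_participants >= 1)

  def_means <- c(mu_rt = 375, sigma_rt = 60, practice_amp = 26,
                 practice_rate = 8, learn_asym = 10, learn_rate = 2,
                 acc_base = 2.4, acc_drift = 0.011, acc_learn_asym = 0.35,
                 motor_facil = 15, theta_rt = 0, theta_acc = 0)
  def_sds <- c(mu_rt = 30, sigma_rt = 10, practice_amp = 8,
               practice_rate = 0, learn_asym = 4, learn_rate = 0,
               acc_base = 0.3, acc_drift = 0.004, acc_learn_asym = 0.10,
               motor_facil = 5, theta_rt = 0, theta_acc = 0)
  if (!is.null(means)) {
    bad <- setdiff(names(means), names(def_means))
    if (length(bad)) abort(paste("Unknown parameter:", paste(bad, collapse = ", ")),
                           class = "asrt_config_error")
    def_means[names(means)] <- means
  }
  if (!is.null(sds)) {
    bad <- setdiff(names(sds), names(def_sds))
    if (length(bad)) abort(paste("Unknown parameter:", paste(bad, collapse = ", ")),
                           class = "asrt_config_error")
    def_sds[names(sds)] <- sds
  }
  if (any(def_sds < 0)) {
    abort("Population SDs must be non-negative.", class = "asrt_config_error")
  }
  ocir_mean <- ocir_mean %||% switch(study, study1 = 20.72, study2 = 14.24)
  ocir_sd <- ocir_sd %||% switch(study, study1 = 11.30, study2 = 11.73)
  if (ocir_sd <= 0) abort("`ocir_sd` must be positive.",
                          class = "asrt_config_error")

  structure(list(
    n_participants = n_participants, study = study,
    means = def_means, sds = def_sds,
    ocir_mean = ocir_mean, ocir_sd = ocir_sd,
    noise_family = noise_family, lognorm_shape = lognorm_shape,
    retention = retention, seed = seed
  ), class = "asrt_cohort_spec")
}

#' @export
print.asrt_cohort_spec <- function(x, ...) {
  cat("<asrt_cohort_spec> n =", x$n_participants, "|", x$study,
      sprintf("| OCI-R %.2f (%.2f) | noise %s\n",
              x$ocir_mean, x$ocir_sd, x$noise_family))
  invisible(x)
}

#' Draw a cohort of synthetic participants
#'
#' Samples `n_participants` parameter vectors from the population
#' distributions of a [cohort_spec()]. Scale parameters (`sigma_rt`,
#' `practice_amp`, `practice_rate`, `learn_rate`, `acc_drift`,
#' `acc_learn_asym`, `motor_facil`) are truncated at zero; OCI-R totals are
#' drawn normal, rounded to integers and clamped to the attainable 0-72
#' range. `z_ocir`, the OCI-R score standardized by the population moments,
#' is the covariate that the moderation coefficients `theta_rt`/`theta_acc`
#' multiply.
#'
#' @param spec An [cohort_spec()].
#' @param seed Seed (defaults to `spec$seed`).
#' @return A tibble with one row per participant: `participant_id`, all
#'   generative parameters, `ocir` and `z_ocir`.
#' @export
sample_cohort <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "asrt_cohort_spec"))
  n <- spec$n_participants
  nonneg <- c("sigma_rt", "practice_amp", "practice_rate", "learn_rate",
              "acc_drift", "acc_learn_asym", "motor_facil")
  withr::with_seed(seed, {
    draws <- lapply(names(spec$means), function(p) {
      x <- rnorm(n, spec$means[[p]], spec$sds[[p]])
      if (p %in% nonneg) x <- pmax(x, 0)
      if (p == "learn_rate" || p == "practice_rate") x <- pmax(x, 1e-6)
      x
    })
    names(draws) <- names(spec$means)
    rng <- ocir_range()
    ocir <- pmin(pmax(round(rnorm(n, spec$ocir_mean, spec$ocir_sd)),
                      rng[1]), rng[2])
    tibble(
      participant_id = sprintf("P%03d", seq_len(n)),
      !!!draws,
      ocir = as.integer(ocir),
      z_ocir = (ocir - spec$ocir_mean) / spec$ocir_sd
    )
  })
}
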