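#' Expected high-vs-low RT advantage at a given epoch
#'
#' The generative learning trajectory: the RT penalty (ms) on
#' low-probability trials at 5-block epoch `t` for a participant with
#' learning asymptote `learn_asym`, growth constant `learn_rate` and
#' OCI-R moderation `theta_rt` at standardized score `z_ocir`,
#' `delta(t) = learn_asym * (1 + theta_rt * z_ocir) * (1 - exp(-t / learn_rate))`.
#' Exposed so recovery studies can compare estimated learning scores with
#' their generative truth.
#'
#' @param epoch Epoch index (1-based, 5-block bins).
#' @param learn_asym Asymptotic advantage (ms).
#' @param learn_rate Epoch-scale growth constant.
#' @param theta Moderation coefficient (default 0).
#' @param z_ocir Standardized OCI-R score (default 0).
#' @return Numeric vector of expected advantages (ms).
#' @export
learning_delta <- function(epoch, learn_asym, learn_rate,
                           theta = 0, z_ocir = 0) {
  learn_asym * (1 + theta * z_ocir) * (1 - exp(-epoch / learn_rate))
}

#' Simulate one participant's responses on a classified stream
#'
#' Generates first-response RT and correctness for every stimulus of a
#' classified stream. The mean RT is
#' `mu_rt - practice_amp * (1 - exp(-(block - 1) / practice_rate))
#'  + delta(t) * I(low) - motor_facil * I(trill or repetition)`,
#' where `delta(t)` is the epoch-level learning trajectory
#' ([learning_delta()]) and `I(low)` marks low-probability trials under the
#' phase's own sequence. Residual noise has median zero (shifted-lognormal
#' by default, normal optionally) and RTs are floored at 1 ms. Correctness
#' is Bernoulli with log-odds
#' `acc_base - acc_drift * (block - 1) + a(t) * I(high)`, with `a(t)` the
#' analogous accuracy trajectory. During reversed-sequence (B) blocks the
#' learning term applies to the B-defined categories (`LH` triplets are the
#' B-high trials) while a `retention` fraction of the A-trained advantage
#' still applies to `HL` triplets, so Old and New knowledge contrasts have
#' known generative values. Practice blocks (block index below 1) receive
#' no learning term. Only first responses are generated, matching the
#' analysis convention; incorrect responses still carry an RT.
#'
#' @param stream A classified stream ([classify_triplets()]); for designs
#'   with B blocks the interference labels must be present.
#' @param params A single-row ParticipantParams tibble (one row of
#'   [sample_cohort()] output).
#' @param seed Integer seed.
#' @param noise_family,lognorm_shape,retention Noise and retention options,
#'   normally taken from the [cohort_spec()].
#' @param epoch_width Blocks per epoch for the learning trajectory
#'   (default 5).
#' @return A TrialRecord tibble: the stream columns plus `participant_id`,
#'   `rt_ms`, `correct` and `ocir`.
#' @export
simulate_trials <- function(stream, params, seed,
                            noise_family = c("shifted_lognormal", "normal"),
                            lognorm_shape = 0.4,
                            retention = 1.0,
                            epoch_width = 5) {
  noise_family <- match.arg(noise_family)
  if (!all(c("triplet_category", "transition_kind") %in% names(stream))) {
    abort("Stream must be classified first (see classify_triplets()).",
          class = "asrt_precondition_error")
  }
  if (nrow(params) != 1) abort("`params` must be a single participant row.")
  b_block <- !is.na(stream$sequence_label) & stream$sequence_label == "B"
  if (any(b_block) &&
      all(stream$interference_label[b_block] == "not_applicable")) {
    abort("B-phase blocks present but no interference labels: classify with the interference pattern.",
          class = "asrt_precondition_error")
  }

  n <- nrow(stream)
  block <- stream$block
  analyzable <- block >= 1
  epoch <- ifelse(analyzable, ceiling(block / epoch_width), NA_real_)

  delta <- ifelse(analyzable,
                  learning_delta(epoch, params$learn_asym, params$learn_rate,
                                 params$theta_rt, params$z_ocir), 0)
  a_t <- ifelse(analyzable,
                learning_delta(epoch, params$acc_learn_asym, params$learn_rate,
                               params$theta_acc, params$z_ocir), 0)

  # low/high indicators under the phase's own sequence: in B blocks the
  # B-defined high trials are exactly the LH triplets
  low_phase <- ifelse(b_block,
                      stream$interference_label %in% c("HL", "LL"),
                      stream$triplet_category == "low")
  high_phase <- ifelse(b_block,
                       stream$interference_label == "LH",
                       stream$triplet_category == "high")
  hl <- b_block & stream$interference_label == "HL"
  motor <- stream$transition_kind %in% c("trill", "repetition")

  mean_rt <- params$mu_rt -
    params$practice_amp * (1 - exp(-(block - 1) / params$practice_rate)) +
    delta * low_phase - retention * delta * hl -
    params$motor_facil * motor

  log_odds <- params$acc_base - params$acc_drift * (block - 1) +
    a_t * high_phase + retention * a_t * hl

  withr::with_seed(seed, {
    noise <- switch(noise_family,
      normal = rnorm(n, 0, params$sigma_rt),
      shifted_lognormal = {
        s <- lognorm_shape
        scale <- params$sigma_rt / sqrt((exp(s^2) - 1) * exp(s^2))
        scale * (rlnorm(n, 0, s) - 1)
      })
    out <- stream
    out$participant_id <- params$participant_id
    out$rt_ms <- pmax(mean_rt + noise, 1)
    out$correct <- rbinom(n, 1, plogis(log_odds))
    out$ocir <- params$ocir
    out
  })
}

#' Simulate a full cohort on a task design
#'
#' Draws a cohort from a [cohort_spec()], generates an independent
#' classified stimulus stream per participant (random elements differ
#' across participants, as in the real task), and simulates all responses.
#' Per-participant seeds are derived deterministically from `seed` with
#' [derive_seed()], so the whole dataset is reproducible.
#'
#' @param design An [design_spec()].
#' @param spec An [cohort_spec()].
#' @param seed Global seed (defaults to `spec$seed`).
#' @return A list of class `asrt_cohort_sim`: `trials` (TrialRecord tibble
#'   for all participants) and `participants` (the sampled parameter table,
#'   for recovery scoring).
#' @export
simulate_cohort <- function(design, spec, seed = spec$seed) {
  stopifnot(inherits(design, "asrt_design"), inherits(spec, "asrt_cohort_spec"))
  cohort <- sample_cohort(spec, seed = derive_seed(seed, "cohort"))
  interference <- if (!is.null(design$pattern_b)) design$pattern_b else NULL
  trials <- lapply(seq_len(nrow(cohort)), function(i) {
    stream <- generate_stream(design,
                              seed = derive_seed(seed, paste0("stream_", i)))
    stream <- classify_triplets(stream, design$pattern, interference)
    simulate_trials(stream, cohort[i, ],
                    seed = derive_seed(seed, paste0("responses_", i)),
                    noise_family = spec$noise_family,
                    lognorm_shape = spec$lognorm_shape,
                    retention = spec$retention)
  })
  structure(list(trials = dplyr::bind_rows(trials), participants = cohort),
            class = "asrt_cohort_sim")
}

#' @export
print.asrt_cohort_sim <- function(x, ...) {
  cat("<asrt_cohort_sim>", nrow(x$participants), "participants,",
      nrow(x$trials), "trials\n")
  invisible(x)
}
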