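test_that("cohort sampling is reproducible, clamped and centered", {
  spec <- cohort_spec(5, study = "study1", seed = 42)
  c1 <- sample_cohort(spec)
  c2 <- sample_cohort(spec)
  expect_identical(c1, c2)
  expect_identical(nrow(c1), 5L)

  big <- sample_cohort(cohort_spec(10000, study = "study1"), seed = 1)
  expect_true(all(big$ocir >= 0 & big$ocir <= 72))
  expect_true(all(big$ocir == round(big$ocir)))
  # truncation shifts the mean by < 0.5 at these moments
  expect_lt(abs(mean(big$ocir) - 20.72), 0.5)
  expect_true(all(big$sigma_rt >= 0))

  expect_error(cohort_spec(5, sds = c(mu_rt = -1)),
               class = "asrt_config_error")
  expect_error(cohort_spec(5, means = c(nonsense = 1)),
               class = "asrt_config_error")
})

noise_free_params <- function(...) {
  spec <- cohort_spec(1, means = c(mu_rt = 400, sigma_rt = 0,
                                   practice_amp = 0, learn_asym = 0,
                                   motor_facil = 0, acc_base = 30,
                                   acc_drift = 0, acc_learn_asym = 0, ...),
                      sds = setNames(rep(0, 12), names(cohort_spec(1)$means)),
                      noise_family = "normal")
  sample_cohort(spec, seed = 1)
}

test_that("noise-free degenerate simulation returns the baseline RT everywhere", {
  d <- design_spec("study1", n_blocks = 3, practice_blocks = 0)
  s <- classify_triplets(generate_stream(d, seed = 2), d$pattern)
  params <- noise_free_params()
  trials <- simulate_trials(s, params, seed = 7, noise_family = "normal")
  expect_identical(nrow(trials), nrow(s)) # first responses only
  expect_true(all(trials$rt_ms == 400))
  expect_true(all(trials$correct == 1L)) # log-odds 30
})

test_that("simulation requires a classified stream", {
  d <- design_spec("study1", n_blocks = 2, practice_blocks = 0)
  s <- generate_stream(d, seed = 2)
  expect_error(simulate_trials(s, noise_free_params(), seed = 1),
               class = "asrt_precondition_error")
})

test_that("median low-high RT difference tracks the learning trajectory", {
  # many repetitions of one block keep practice fixed while epochs vary
  d <- design_spec("study1", n_blocks = 25, practice_blocks = 0)
  s <- classify_triplets(generate_stream(d, seed = 31), d$pattern)
  spec <- cohort_spec(1, means = c(learn_asym = 30, practice_amp = 0,
                                   motor_facil = 0, sigma_rt = 40),
                      sds = setNames(rep(0, 12),
                                     names(cohort_spec(1)$means)))
  params <- sample_cohort(spec, seed = 5)
  trials <- simulate_trials(s, params, seed = 9,
                            noise_family = "shifted_lognormal")
  defined <- trials[trials$triplet_category %in% c("high", "low") &
                      !trials$transition_kind %in% c("trill", "repetition"), ]
  defined$epoch <- ceiling(defined$block / 5)
  diffs <- tapply(seq_len(nrow(defined)), defined$epoch, function(i) {
    dd <- defined[i, ]
    median(dd$rt_ms[dd$triplet_category == "low"]) -
      median(dd$rt_ms[dd$triplet_category == "high"])
  })
  truth <- learning_delta(1:5, 30, params$learn_rate)
  # ~400 low trials per epoch: Monte-Carlo error of a median difference
  # at sigma 40 is a few ms
  expect_true(all(abs(diffs - truth) < 8))
  expect_gt(diffs[5], diffs[1])
})

test_that("null accuracy learning leaves high and low accuracy equal", {
  d <- design_spec("study1", n_blocks = 10, practice_blocks = 0)
  s <- classify_triplets(generate_stream(d, seed = 4), d$pattern)
  spec <- cohort_spec(1, means = c(acc_learn_asym = 0, acc_drift = 0,
                                   acc_base = 1.0),
                      sds = setNames(rep(0, 12),
                                     names(cohort_spec(1)$means)))
  params <- sample_cohort(spec, seed = 2)
  trials <- simulate_trials(s, params, seed = 3)
  acc <- tapply(trials$correct, trials$triplet_category, mean)
  expect_lt(abs(acc[["high"]] - acc[["low"]]), 0.08)
})

test_that("increasing the learning asymptote increases the learning score", {
  d <- design_spec("study1", n_blocks = 10)
  score_at <- function(asym) {
    spec <- cohort_spec(6, means = c(learn_asym = asym),
                        sds = c(learn_asym = 0), seed = 8)
    sim <- simulate_cohort(d, spec, seed = 8)
    rt_f <- filter_trials(sim$trials, analysis = "rt")
    acc_f <- filter_trials(sim$trials, analysis = "accuracy")
    mean(learning_scores(aggregate_cells(rt_f, acc_f))$rt_learning)
  }
  expect_gt(score_at(40), score_at(0))
})

test_that("cohort simulation is deterministic and exports true parameters", {
  sim1 <- small_sim()
  d <- design_spec("study1", n_blocks = 10)
  sim2 <- simulate_cohort(d, cohort_spec(8, seed = 101), seed = 101)
  expect_identical(sim1$trials, sim2$trials)
  expect_identical(sim1$participants, sim2$participants)
  expect_setequal(unique(sim1$trials$participant_id),
                  sim1$participants$participant_id)
})
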