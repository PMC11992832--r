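test_that("epoch assignment bins blocks by fives with a phase offset", {
  expect_identical(assign_epoch(7), 2L)
  expect_identical(assign_epoch(25), 5L)
  expect_identical(assign_epoch(1:25), rep(1:5, each = 5))
  # interference phase: blocks 16-30 with 15 preceding blocks
  expect_identical(assign_epoch(16, phase_offset = 15), 1L)
  expect_identical(assign_epoch(c(20, 21, 25, 26, 30), phase_offset = 15),
                   c(1L, 2L, 2L, 3L, 3L))
  expect_error(assign_epoch(15, phase_offset = 15),
               class = "asrt_precondition_error")
  expect_error(assign_epoch(0), class = "asrt_precondition_error")
})

hand_cells <- function() {
  # two participants, one epoch, hand-set values
  trials <- tibble::tibble(
    participant_id = rep(c("P1", "P2"), c(7, 4)),
    block = 1L,
    rt_ms = c(300, 310, 320, 355, 365, 350, 360, 400, 410, 395, 405),
    correct = c(1L, 1L, 0L, 1L, 1L, 1L, 0L, 1L, 1L, 0L, 1L),
    triplet_category = c(rep("high", 3), rep("low", 4),
                         rep("high", 2), rep("low", 2)),
    interference_label = "not_applicable"
  )
  trials
}

test_that("cell aggregation reproduces hand-computed medians and accuracies", {
  trials <- hand_cells()
  cells <- aggregate_cells(trials, trials, keying = "category")
  p1_high <- cells[cells$participant_id == "P1" & cells$key == "high", ]
  expect_identical(p1_high$median_rt, 310)  # median of {300, 310, 320}
  expect_identical(p1_high$mean_acc, 2 / 3)
  expect_identical(p1_high$n_rt, 3L)
  p1_low <- cells[cells$participant_id == "P1" & cells$key == "low", ]
  expect_identical(p1_low$median_rt, 357.5)
  expect_identical(p1_low$mean_acc, 0.75)  # {1,1,1,0}
})

test_that("learning scores use the low-minus-high / high-minus-low convention", {
  cells <- tibble::tibble(
    participant_id = "P1", epoch = 1L, key = c("high", "low"),
    median_rt = c(350, 360), n_rt = c(10L, 10L),
    mean_acc = c(0.95, 0.90), n_acc = c(12L, 12L))
  sc <- learning_scores(cells, per_epoch = TRUE)
  expect_identical(sc$rt_learning, 10)
  expect_equal(sc$acc_learning, 0.05)

  # identical cells give a null score
  cells$median_rt <- c(355, 355)
  cells$mean_acc <- c(0.9, 0.9)
  sc <- learning_scores(cells, per_epoch = TRUE)
  expect_identical(sc$rt_learning, 0)
  expect_identical(sc$acc_learning, 0)
})

test_that("the averaged score is the unweighted epoch mean", {
  diffs <- c(2, 4, 6, 8, 10)
  cells <- tibble::tibble(
    participant_id = "P1", epoch = rep(1:5, each = 2),
    key = rep(c("high", "low"), 5),
    median_rt = as.numeric(rbind(rep(350, 5), 350 + diffs)),
    n_rt = 5L, mean_acc = 0.9, n_acc = 6L)
  sc <- learning_scores(cells)
  expect_identical(sc$rt_learning, 6)
})

test_that("a missing epoch or cell yields a missing averaged score", {
  cells <- tibble::tibble(
    participant_id = rep(c("P1", "P2"), c(4, 3)),
    epoch = c(1L, 1L, 2L, 2L, 1L, 1L, 2L),
    key = c("high", "low", "high", "low", "high", "low", "high"),
    median_rt = c(300, 310, 300, 312, 400, 420, 395),
    n_rt = 5L, mean_acc = 0.9, n_acc = 6L)
  sc <- learning_scores(cells)
  expect_identical(sc$rt_learning[sc$participant_id == "P1"], 11)
  expect_true(is.na(sc$rt_learning[sc$participant_id == "P2"]))
})

test_that("knowledge scores contrast HL and LH against the LL baseline", {
  cells <- tibble::tibble(
    participant_id = "P1", epoch = 1L, key = c("HL", "LH", "LL"),
    median_rt = c(354, 363, 363), n_rt = 20L,
    mean_acc = c(0.93, 0.90, 0.90), n_acc = 25L)
  ks <- knowledge_scores(cells, per_epoch = TRUE)
  expect_identical(ks$old_rt, 9)   # LL - HL
  expect_identical(ks$new_rt, 0)   # LH equals the LL baseline
  expect_equal(ks$old_acc, 0.03)
  expect_identical(ks$new_acc, 0)
})

test_that("scores are invariant to trial order and RT translation", {
  trials <- hand_cells()
  shuffled <- trials[sample.int(nrow(trials)), ]
  expect_identical(aggregate_cells(trials, trials),
                   aggregate_cells(shuffled, shuffled))
  shifted <- trials
  shifted$rt_ms <- shifted$rt_ms + 250
  sc0 <- learning_scores(aggregate_cells(trials, trials), per_epoch = TRUE)
  sc1 <- learning_scores(aggregate_cells(shifted, shifted), per_epoch = TRUE)
  expect_identical(sc0$rt_learning, sc1$rt_learning)
})

test_that("interference keying restricts to HL/LH/LL cells", {
  sim_design <- design_spec("study2")
  stream <- classify_triplets(generate_stream(sim_design, seed = 6),
                              sim_design$pattern, sim_design$pattern_b)
  spec <- cohort_spec(1, study = "study2", seed = 6)
  trials <- simulate_trials(stream, sample_cohort(spec), seed = 6)
  interference <- trials[trials$block >= 16, ]
  rt_f <- filter_trials(interference, analysis = "rt")
  acc_f <- filter_trials(interference, analysis = "accuracy")
  cells <- aggregate_cells(rt_f, acc_f, keying = "interference",
                           phase_offset = 15)
  expect_setequal(unique(cells$key), c("HL", "LH", "LL"))
  expect_setequal(unique(cells$epoch), 1:3)
  ks <- knowledge_scores(cells)
  expect_identical(nrow(ks), 1L)
  expect_true(is.finite(ks$old_rt) && is.finite(ks$new_rt))
})
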