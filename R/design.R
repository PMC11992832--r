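#' Task design specification
#'
#' Describes one study design: how many blocks, how each block is built
#' (repetitions of the eight-element pattern/random alternation), which
#' sequence governs which block range, and how many all-random practice
#' blocks precede the task.
#'
#' Two stock layouts are provided. `"study1"` is a single learning phase of
#' 25 blocks under sequence A. `"study2"` is 15 learning-phase blocks under
#' A, then an interference phase of blocks 16-20 (A), 21-25 (the reversed
#' sequence B, introduced without warning), and 26-30 (A again). With the
#' default 10 repetitions per block each block holds 80 stimuli.
#'
#' @param study `"study1"` or `"study2"`.
#' @param pattern The trained [asrt_pattern()] (sequence A). Defaults to
#'   `(2, 4, 3, 1)`.
#' @param reps_per_block Repetitions of the eight-element sequence per
#'   block (default 10, i.e. 80 trials per block).
#' @param practice_blocks Number of all-random lead-in blocks, flagged
#'   non-analyzable (default 2).
#' @param start_phase `"pattern_first"` (default; blocks open with a pattern
#'   element, as in the canonical `2-r-4-r-...` notation) or
#'   `"random_first"`.
#' @param delay_min Metadata only: the between-phase delay in minutes for
#'   the two-phase layout (no behavioral consequence).
#' @param n_blocks Optional block-count override for the single-phase
#'   (`"study1"`) layout, used for reduced-size simulation studies; the
#'   stock layout is 25 blocks.
#'
#' @return An object of class `asrt_design` with elements `study`,
#'   `pattern`, `pattern_b` (reversal, two-phase layout only),
#'   `reps_per_block`, `trials_per_block`, `practice_blocks`, `start_phase`,
#'   and `phase_layout`, a tibble with columns `phase`, `first_block`,
#'   `last_block`, `sequence_label`.
#' @examples
#' design_spec("study2")
#' @export
design_spec <- function(study = c("study1", "study2"),
                        pattern = asrt_pattern(c(2, 4, 3, 1)),
                        reps_per_block = 10,
                        practice_blocks = 2,
                        start_phase = c("pattern_first", "random_first"),
                        delay_min = 46.2, n_blocks = NULL) {
  study <- match.arg(study)
  start_phase <- match.arg(start_phase)
  if (!is_asrt_pattern(pattern)) pattern <- asrt_pattern(pattern)
  reps_per_block <- as.integer(reps_per_block)
  practice_blocks <- as.integer(practice_blocks)
  stopifnot(reps_per_block >= 1, practice_blocks >= 0)

  if (!is.null(n_blocks) && study != "study1") {
    abort("`n_blocks` can only override the single-phase (study1) layout.",
          class = "asrt_invalid_design")
  }
  layout <- switch(study,
    study1 = tibble(
      phase = "learning", first_block = 1L,
      last_block = as.integer(n_blocks %||% 25L),
      sequence_label = pattern$label),
    study2 = tibble(
      phase = c("learning", "interference", "interference", "interference"),
      first_block = c(1L, 16L, 21L, 26L),
      last_block = c(15L, 20L, 25L, 30L),
      sequence_label = c("A", "A", "B", "A"))
  )
  validate_phase_layout(layout)

  structure(list(
    study = study,
    pattern = pattern,
    pattern_b = if (study == "study2") reverse_pattern(pattern) else NULL,
    reps_per_block = reps_per_block,
    trials_per_block = reps_per_block * 8L,
    practice_blocks = practice_blocks,
    start_phase = start_phase,
    phase_layout = layout,
    delay_min = delay_min
  ), class = "asrt_design")
}

validate_phase_layout <- function(layout) {
  if (any(layout$first_block > layout$last_block)) {
    abort("Invalid phase layout: empty block range.",
          class = "asrt_invalid_design")
  }
  covered <- unlist(Map(seq, layout$first_block, layout$last_block))
  if (anyDuplicated(covered)) {
    abort("Invalid phase layout: overlapping block ranges.",
          class = "asrt_invalid_design")
  }
  if (!identical(sort(covered), seq_len(max(layout$last_block)))) {
    abort("Invalid phase layout: block ranges must tile 1..max without gaps.",
          class = "asrt_invalid_design")
  }
  invisible(layout)
}

#' @export
print.asrt_design <- function(x, ...) {
  cat("<asrt_design> ", x$study, ": ",
      max(x$phase_layout$last_block), " blocks x ",
      x$trials_per_block, " trials (+", x$practice_blocks,
      " practice), pattern A = ",
      paste(x$pattern$order, collapse = "-"), "\n", sep = "")
  for (i in seq_len(nrow(x$phase_layout))) {
    r <- x$phase_layout[i, ]
    cat(sprintf("  blocks %2d-%2d  %-12s sequence %s\n",
                r$first_block, r$last_block, r$phase, r$sequence_label))
  }
  invisible(x)
}

#' Exact triplet-category probability budget
#'
#' Closed-form marginal probabilities that an interior trial (the third or
#' later trial of a block) ends each triplet category, under a valid pattern
#' and uniformly random `r` elements. Because roles alternate, a trial and
#' the trial two back share the same role: a pattern-ending trial always
#' completes a high-probability triplet (probability 1), while a
#' random-ending trial does so with probability 1/4. Halving over the two
#' roles gives 50% pattern-ending high, 12.5% random-ending high and 37.5%
#' random-ending low; 62.5% of interior trials in total end a
#' high-probability triplet.
#'
#' @param pattern An [asrt_pattern()].
#' @return A tibble with columns `category` (`"high"`/`"low"`), `ending`
#'   (`"pattern_ending"`/`"random_ending"`) and `probability`, plus an
#'   attribute `totals` with named elements `high` and `low`.
#' @export
expected_triplet_probabilities <- function(pattern = asrt_pattern(c(2, 4, 3, 1))) {
  succ <- successor_map(pattern)
  # a single 4-cycle can never coincide with its own inverse
  stopifnot(!any(succ[succ] == seq_len(4)))
  tab <- tibble(
    category = c("high", "high", "low"),
    ending = c("pattern_ending", "random_ending", "random_ending"),
    probability = c(1 / 2, 1 / 2 * 1 / 4, 1 / 2 * 3 / 4)
  )
  attr(tab, "totals") <- c(high = 5 / 8, low = 3 / 8)
  tab
}

#' Enumerate interference triplet-type pairs and check HH impossibility
#'
#' For the interference design every triplet is relabelled by whether its
#' (first, third) position pair is high-probability under the trained
#' sequence A, under the interference sequence (by default the reversal B),
#' both, or neither: `HL` (high under A only), `LH` (high under B only),
#' `LL` (neither) and the forbidden `HH` (both). When the interference
#' sequence is the true reversal, `HH` would require a position pair that is
#' both a successor and a predecessor pair of a single 4-cycle, which cannot
#' exist, so the function asserts an HH count of zero; a nonzero count
#' signals a non-reversal interference pattern and raises a
#' `asrt_design_violation` error carrying the report.
#'
#' @param pattern_a The trained [asrt_pattern()].
#' @param interference_pattern The interference pattern; defaults to
#'   `reverse_pattern(pattern_a)`.
#' @return A list of class `asrt_interference_report` with elements `pairs`
#'   (a 16-row tibble: `first`, `third`, `label`) and `counts` (named counts
#'   for HL, LH, LL, HH). The reversal always yields 4 HL, 4 LH and 8 LL
#'   pair types.
#' @export
validate_interference <- function(pattern_a = asrt_pattern(c(2, 4, 3, 1)),
                                  interference_pattern = NULL) {
  if (!is_asrt_pattern(pattern_a)) pattern_a <- asrt_pattern(pattern_a)
  if (is.null(interference_pattern)) {
    interference_pattern <- reverse_pattern(pattern_a)
  }
  succ_a <- successor_map(pattern_a)
  succ_b <- successor_map(interference_pattern)
  grid <- expand.grid(first = 1:4, third = 1:4)
  high_a <- succ_a[grid$first] == grid$third
  high_b <- succ_b[grid$first] == grid$third
  label <- dplyr::case_when(
    high_a & high_b ~ "HH",
    high_a ~ "HL",
    high_b ~ "LH",
    TRUE ~ "LL"
  )
  pairs <- tibble(first = grid$first, third = grid$third, label = label)
  counts <- vapply(c("HL", "LH", "LL", "HH"),
                   function(l) sum(label == l), integer(1))
  report <- structure(list(pairs = pairs, counts = counts),
                      class = "asrt_interference_report")
  if (counts[["HH"]] > 0) {
    abort(
      sprintf(paste0("Interference pattern is not a reversal of the trained ",
                     "sequence: %d 'HH' pair types found."), counts[["HH"]]),
      class = "asrt_design_violation", report = report)
  }
  report
}

#' @export
print.asrt_interference_report <- function(x, ...) {
  cat("<asrt_interference_report> pair types:",
      paste(names(x$counts), x$counts, sep = "=", collapse = ", "), "\n")
  invisible(x)
}
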