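#' Generate an ASRT stimulus stream
#'
#' Builds the full trial-by-trial stimulus sequence for a design: per block,
#' `reps_per_block` repetitions of the eight-element alternation in which
#' pattern elements cycle through the phase's pattern sequence and random
#' elements are drawn independently and uniformly from the four positions.
#' Practice blocks are all-random and carry non-positive block indices
#' (0, -1, ...) with `phase = "practice"` so that analyzable blocks are
#' numbered 1..N, matching the block factor used in analysis. Every block
#' starts at the same point of the cycle (`order[1]`) because 10 repetitions
#' of the 8-element sequence close the cycle exactly.
#'
#' @param design An [design_spec()].
#' @param seed Integer seed; the stream is reproducible given the seed.
#' @return A tibble with one row per stimulus: `block`, `idx` (1-based
#'   within block), `position` (1-4), `role` (`"pattern"`/`"random"`),
#'   `phase`, `sequence_label`.
#' @export
generate_stream <- function(design, seed) {
  stopifnot(inherits(design, "asrt_design"))
  if (missing(seed) || is.null(seed)) {
    abort("`seed` is required: streams must be reproducible.")
  }
  tpb <- design$trials_per_block
  layout <- design$phase_layout

  n_per_phase <- layout$last_block - layout$first_block + 1L
  task_blocks <- seq_len(max(layout$last_block))
  practice <- design$practice_blocks
  block_plan <- list(
    block = c(if (practice > 0) seq(1L - practice, 0L), task_blocks),
    phase = c(rep("practice", practice), rep(layout$phase, n_per_phase)),
    sequence_label = c(rep(NA_character_, practice),
                       rep(layout$sequence_label, n_per_phase)))

  patterns <- list(A = design$pattern,
                   B = design$pattern_b %||% reverse_pattern(design$pattern))
  pattern_first <- identical(design$start_phase, "pattern_first")

  # flat construction: rows are block-major with idx increasing, so the
  # per-block pattern cycle can be laid down with rep()
  nb <- length(block_plan$block)
  block <- rep(block_plan$block, each = tpb)
  phase <- rep(block_plan$phase, each = tpb)
  seq_label <- rep(block_plan$sequence_label, each = tpb)
  idx <- rep.int(seq_len(tpb), nb)
  is_pattern <- if (pattern_first) idx %% 2L == 1L else idx %% 2L == 0L
  is_pattern[phase == "practice"] <- FALSE
  per_block_pattern <- sum(if (pattern_first) seq_len(tpb) %% 2L == 1L
                           else seq_len(tpb) %% 2L == 0L)

  position <- integer(nb * tpb)
  for (lab in c("A", "B")) {
    sel <- is_pattern & !is.na(seq_label) & seq_label == lab
    if (any(sel)) {
      cycle <- rep_len(patterns[[lab]]$order, per_block_pattern)
      position[sel] <- rep(cycle, sum(sel) / per_block_pattern)
    }
  }
  withr::with_seed(seed, {
    position[!is_pattern] <- sample(1:4, sum(!is_pattern), replace = TRUE)
  })
  tibble(block = block, idx = idx, position = position,
         role = ifelse(is_pattern, "pattern", "random"),
         phase = phase, sequence_label = seq_label)
}

#' Classify every trial of a stream by its triplet
#'
#' Each trial from the third one of a block onward is the final element of a
#' triplet: the window of positions at trials `n - 2`, `n - 1`, `n` within
#' the same block (windows never cross block boundaries; the first two
#' trials of a block are `"undefined"`). A trial is `"high"` if its position
#' is the cyclic successor, under `reference_pattern`, of the position two
#' trials back, otherwise `"low"`. The ending records the role of the final
#' trial; pattern-ending trials are always high under the generating
#' sequence. Transition kind marks repetitions (`a-a-a`) and trills
#' (`a-b-a`), which carry motor-level facilitation and are removed before
#' analysis. When `interference_pattern` is supplied each defined triplet is
#' additionally labelled `HL` (high under the reference only), `LH` (high
#' under the interference pattern only) or `LL` (neither); `HH` is
#' impossible for a true reversal and raises `asrt_design_violation` if
#' encountered.
#'
#' @param stream A stream tibble from [generate_stream()] (block-ordered).
#' @param reference_pattern The [asrt_pattern()] defining `"high"`
#'   (sequence A).
#' @param interference_pattern Optional interference [asrt_pattern()]
#'   (sequence B) for the `HL`/`LH`/`LL` relabelling.
#' @return The stream with columns `triplet_category`, `triplet_ending`,
#'   `transition_kind` (all `"undefined"` for the first two trials of each
#'   block) and `interference_label` (`"not_applicable"` where undefined or
#'   when no interference pattern is supplied).
#' @export
classify_triplets <- function(stream, reference_pattern,
                              interference_pattern = NULL) {
  req <- c("block", "idx", "position")
  if (!all(req %in% names(stream))) {
    abort(paste("Stream lacks required columns:",
                paste(setdiff(req, names(stream)), collapse = ", ")),
          class = "asrt_schema_error")
  }
  succ_a <- successor_map(reference_pattern)
  n <- nrow(stream)
  p3 <- stream$position
  p2 <- dplyr::lag(p3, 1)
  p1 <- dplyr::lag(p3, 2)
  same_block <- stream$block == dplyr::lag(stream$block, 2) &
    stream$idx >= 3
  defined <- !is.na(same_block) & same_block

  high_a <- defined & succ_a[pmax(p1, 1L)] == p3
  category <- ifelse(defined, ifelse(high_a, "high", "low"), "undefined")
  ending <- ifelse(defined, paste0(stream$role, "_ending"), "undefined")
  transition <- ifelse(!defined, "undefined",
                ifelse(p1 == p2 & p2 == p3, "repetition",
                ifelse(p1 == p3 & p1 != p2, "trill", "other")))

  if (!is.null(interference_pattern)) {
    succ_b <- successor_map(interference_pattern)
    high_b <- defined & succ_b[pmax(p1, 1L)] == p3
    if (any(high_a & high_b)) {
      abort("'HH' triplet encountered: interference pattern is not a reversal.",
            class = "asrt_design_violation")
    }
    interference <- ifelse(!defined, "not_applicable",
                    ifelse(high_a, "HL",
                    ifelse(high_b, "LH", "LL")))
  } else {
    interference <- rep("not_applicable", n)
  }

  stream$triplet_category <- category
  stream$triplet_ending <- ending
  stream$interference_label <- interference
  stream$transition_kind <- transition
  stream
}
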