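#' Map a block index to its epoch
#'
#' Epochs are consecutive `width`-block bins: epoch
#' `ceiling((block - phase_offset) / width)`. For the single-phase layout
#' (offset 0, width 5) blocks 1-5 are epoch 1 and block 25 is epoch 5; for
#' the interference phase use `phase_offset = 15` so that blocks 16-20,
#' 21-25 and 26-30 become epochs 1-3.
#'
#' @param block Integer block index (must lie above `phase_offset`).
#' @param width Blocks per epoch (default 5).
#' @param phase_offset Number of blocks preceding the phase (default 0).
#' @return Integer epoch ids.
#' @export
assign_epoch <- function(block, width = 5, phase_offset = 0) {
  if (any(is.na(block)) || any(block <= phase_offset)) {
    abort("`block` outside the design for this phase offset.",
          class = "asrt_precondition_error")
  }
  as.integer(ceiling((block - phase_offset) / width))
}

#' Aggregate filtered trials into participant x epoch x triplet cells
#'
#' Builds the cell table from which learning and knowledge scores derive:
#' per-cell median RT from the RT-filtered dataset and per-cell mean
#' accuracy from the accuracy-filtered dataset. Cells are keyed either by
#' triplet category (`"high"`/`"low"`) or by interference label
#' (`"HL"`/`"LH"`/`"LL"`; `LL` cells contain only triplets low under both
#' sequences by construction). Empty cells are simply absent, never
#' imputed; downstream scores for affected participant-epochs come out
#' missing.
#'
#' @param rt_trials RT-analysis trials ([filter_trials()] with
#'   `analysis = "rt"`).
#' @param acc_trials Accuracy-analysis trials (`analysis = "accuracy"`).
#' @param keying `"category"` or `"interference"`.
#' @param epoch_width,phase_offset Passed to [assign_epoch()]; use
#'   `phase_offset = 15` for the interference phase.
#' @return A CellTable tibble: `participant_id`, `epoch`, `key`,
#'   `median_rt`, `n_rt`, `mean_acc`, `n_acc`.
#' @export
aggregate_cells <- function(rt_trials, acc_trials,
                            keying = c("category", "interference"),
                            epoch_width = 5, phase_offset = 0) {
  keying <- match.arg(keying)
  if (inherits(rt_trials, "asrt_filtered")) rt_trials <- rt_trials$trials
  if (inherits(acc_trials, "asrt_filtered")) acc_trials <- acc_trials$trials

  prep <- function(df) {
    key <- switch(keying,
      category = df$triplet_category,
      interference = df$interference_label)
    keep <- key %in% switch(keying,
      category = c("high", "low"),
      interference = c("HL", "LH", "LL"))
    df <- df[keep, , drop = FALSE]
    df$key <- key[keep]
    df$epoch <- assign_epoch(df$block, epoch_width, phase_offset)
    df
  }

  rt_cells <- prep(rt_trials) |>
    group_by(.data$participant_id, .data$epoch, .data$key) |>
    summarise(median_rt = median(.data$rt_ms), n_rt = dplyr::n(),
              .groups = "drop")
  acc_cells <- prep(acc_trials) |>
    group_by(.data$participant_id, .data$epoch, .data$key) |>
    summarise(mean_acc = mean(.data$correct), n_acc = dplyr::n(),
              .groups = "drop")
  dplyr::full_join(rt_cells, acc_cells,
                   by = c("participant_id", "epoch", "key")) |>
    arrange(.data$participant_id, .data$epoch, .data$key)
}

score_from_cells <- function(cells, minuend, subtrahend, prefix) {
  widen <- function(value) {
    w <- cells |>
      select("participant_id", "epoch", "key", dplyr::all_of(value)) |>
      pivot_wider(names_from = "key", values_from = dplyr::all_of(value))
    for (k in c(minuend, subtrahend)) {
      if (!k %in% names(w)) w[[k]] <- NA_real_
    }
    w
  }
  wide_rt <- widen("median_rt")
  wide_acc <- widen("mean_acc")
  out <- dplyr::full_join(
    wide_rt |> select("participant_id", "epoch",
                      rt_minu = dplyr::all_of(minuend),
                      rt_subt = dplyr::all_of(subtrahend)),
    wide_acc |> select("participant_id", "epoch",
                       acc_minu = dplyr::all_of(minuend),
                       acc_subt = dplyr::all_of(subtrahend)),
    by = c("participant_id", "epoch"))
  # positive = learning/knowledge in the conventional direction
  out[[paste0(prefix, "_rt")]] <- out$rt_subt - out$rt_minu
  out[[paste0(prefix, "_acc")]] <- out$acc_minu - out$acc_subt
  out |> select(-"rt_minu", -"rt_subt", -"acc_minu", -"acc_subt")
}

average_over_epochs <- function(per_epoch, value_cols) {
  epochs <- sort(unique(per_epoch$epoch))
  per_epoch |>
    group_by(.data$participant_id) |>
    summarise(dplyr::across(dplyr::all_of(value_cols), ~ {
      if (length(.x) < length(epochs) || anyNA(.x)) NA_real_ else mean(.x)
    }), .groups = "drop")
}

#' Probabilistic-learning difference scores
#'
#' Per participant and epoch, the learning scores
#' `rt_learning = median_rt(low) - median_rt(high)` and
#' `acc_learning = mean_acc(high) - mean_acc(low)` (both signed so that
#' positive means learning in the conventional direction), optionally
#' averaged over epochs with an unweighted mean. A participant whose cell
#' table misses any epoch (or any cell within an epoch) gets a missing
#' averaged score.
#'
#' @param cells A category-keyed CellTable from [aggregate_cells()].
#' @param per_epoch If `TRUE` return the per-epoch table; otherwise
#'   (default) the participant-level epoch-averaged scores.
#' @return A ScoreTable tibble: `participant_id`, (`epoch`,) `rt_learning`,
#'   `acc_learning`.
#' @export
learning_scores <- function(cells, per_epoch = FALSE) {
  if (!all(cells$key %in% c("high", "low"))) {
    abort("`cells` must be keyed by triplet category (high/low).",
          class = "asrt_precondition_error")
  }
  tab <- score_from_cells(cells, "high", "low", "learning")
  names(tab)[names(tab) == "learning_rt"] <- "rt_learning"
  names(tab)[names(tab) == "learning_acc"] <- "acc_learning"
  if (per_epoch) return(tab)
  average_over_epochs(tab, c("rt_learning", "acc_learning"))
}

#' Old- and New-knowledge scores for the interference phase
#'
#' From interference-keyed cells (blocks 16-30 of the two-phase design):
#' Old knowledge contrasts `HL` against `LL`
#' (`old_rt = median_rt(LL) - median_rt(HL)`,
#' `old_acc = mean_acc(HL) - mean_acc(LL)`) and quantifies the resistance
#' of the trained regularity to the interfering one; New knowledge
#' contrasts `LH` against `LL` analogously and quantifies acquisition of
#' the reversed regularity. Positive values mean knowledge in the
#' conventional direction.
#'
#' @param cells An interference-keyed CellTable from [aggregate_cells()].
#' @param per_epoch If `TRUE` return per-epoch scores (interference epochs
#'   1-3); otherwise the epoch-averaged participant-level table.
#' @return A tibble: `participant_id`, (`epoch`,) `old_rt`, `old_acc`,
#'   `new_rt`, `new_acc`.
#' @export
knowledge_scores <- function(cells, per_epoch = FALSE) {
  if (!all(cells$key %in% c("HL", "LH", "LL"))) {
    abort("`cells` must be keyed by interference label (HL/LH/LL).",
          class = "asrt_precondition_error")
  }
  old <- score_from_cells(cells, "HL", "LL", "old")
  new <- score_from_cells(cells, "LH", "LL", "new")
  tab <- dplyr::left_join(old, new, by = c("participant_id", "epoch"))
  if (per_epoch) return(tab)
  average_over_epochs(tab, c("old_rt", "old_acc", "new_rt", "new_acc"))
}
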