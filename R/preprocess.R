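#' Trial-exclusion configuration
#'
#' The standard ASRT trial-exclusion rules: keep first responses only, drop
#' RTs below `rt_min` or above `rt_max` (strict inequalities: trials at
#' exactly 150 or 1000 ms are retained), drop RTs outside each
#' participant's median +/- `mad_k` raw median absolute deviations
#' (unscaled MAD, no 1.4826 normal-consistency factor), drop repetitions
#' and trills, drop the first two trials of every block (they belong to no
#' identified triplet), and - for the RT analysis only - drop incorrect
#' responses.
#'
#' @param rt_min,rt_max RT range bounds in ms (defaults 150 and 1000).
#' @param mad_k MAD multiplier (default 3).
#' @param drop_trills,drop_repetitions,drop_first_two Logical toggles for
#'   the corresponding rules.
#' @param rule_order Order in which rules are applied (and in which the
#'   audit attributes removals: a trial is counted at the first rule that
#'   removes it). The removed set is order-independent for every rule
#'   except `rt_mad`, whose bounds are computed on the survivors of the
#'   rules before it.
#' @return An object of class `asrt_filter_config`.
#' @export
filter_config <- function(rt_min = 150, rt_max = 1000, mad_k = 3,
                          drop_trills = TRUE, drop_repetitions = TRUE,
                          drop_first_two = TRUE,
                          rule_order = c("practice", "nonfirst_response",
                                         "rt_range", "rt_mad", "repetition",
                                         "trill", "first_two")) {
  if (!(rt_min < rt_max)) abort("`rt_min` must be below `rt_max`.",
                                class = "asrt_config_error")
  if (mad_k <= 0) abort("`mad_k` must be positive.",
                        class = "asrt_config_error")
  known <- c("practice", "nonfirst_response", "rt_range", "rt_mad",
             "repetition", "trill", "first_two")
  if (anyDuplicated(rule_order) || !all(rule_order %in% known)) {
    abort(paste("`rule_order` must be distinct rules among:",
                paste(known, collapse = ", ")),
          class = "asrt_config_error")
  }
  structure(list(rt_min = rt_min, rt_max = rt_max, mad_k = mad_k,
                 drop_trills = drop_trills,
                 drop_repetitions = drop_repetitions,
                 drop_first_two = drop_first_two,
                 rule_order = rule_order),
            class = "asrt_filter_config")
}

#' Raw-MAD outlier bounds
#'
#' Bounds `median(x) +/- k * median(|x - median(x)|)` using the raw
#' (unscaled) median absolute deviation.
#'
#' @param rts Numeric vector of RTs (ms); must be nonempty.
#' @param k Multiplier (default 3).
#' @return Numeric `c(low, high)`.
#' @examples
#' mad_bounds(c(300, 310, 320, 330, 1000)) # (290, 350)
#' @export
mad_bounds <- function(rts, k = 3) {
  if (length(rts) == 0 || all(is.na(rts))) {
    abort("`rts` must be a nonempty numeric vector.",
          class = "asrt_precondition_error")
  }
  m <- median(rts, na.rm = TRUE)
  mad0 <- median(abs(rts - m), na.rm = TRUE)
  c(m - k * mad0, m + k * mad0)
}

#' Apply the trial-exclusion pipeline
#'
#' Applies the exclusion rules of a [filter_config()] in a fixed order,
#' each rule operating on the survivors of the previous ones: practice
#' trials; non-first responses (when a `first_response` column is present);
#' the RT range rule; the per-participant MAD rule (bounds computed on each
#' participant's surviving trials); repetitions; trills; the first two
#' trials of each block; and, for `analysis = "rt"` only, incorrect
#' responses. Each removed trial is counted once, at the first rule that
#' removes it. The RT dataset is therefore always a subset of the accuracy
#' dataset for the same input.
#'
#' @param records A TrialRecord tibble (classified, with `rt_ms`, `correct`,
#'   `participant_id`).
#' @param config An [filter_config()].
#' @param analysis `"accuracy"` or `"rt"`.
#' @return A list of class `asrt_filtered`: `trials` (surviving records) and
#'   `audit` (an `asrt_filter_audit`: per-rule and per-participant removal
#'   counts and fractions; counts reconcile exactly with input minus output).
#' @export
filter_trials <- function(records, config = filter_config(),
                          analysis = c("accuracy", "rt")) {
  analysis <- match.arg(analysis)
  stopifnot(inherits(config, "asrt_filter_config"))
  req <- c("participant_id", "block", "idx", "rt_ms", "correct",
           "transition_kind")
  missing_cols <- setdiff(req, names(records))
  if (length(missing_cols)) {
    abort(paste("Records lack required columns:",
                paste(missing_cols, collapse = ", ")),
          class = "asrt_schema_error")
  }

  n_input <- nrow(records)
  audit_rows <- list()
  drop_rule <- function(df, rule, remove) {
    remove <- !is.na(remove) & remove
    per_part <- df$participant_id[remove]
    audit_rows[[rule]] <<- tibble(
      rule = rule, n_removed = sum(remove),
      fraction_of_input = sum(remove) / max(n_input, 1L),
      by_participant = list(table(per_part)))
    df[!remove, , drop = FALSE]
  }

  out <- records
  for (rule in config$rule_order) {
    out <- switch(rule,
      practice = if ("phase" %in% names(out)) {
        drop_rule(out, "practice", out$phase == "practice")
      } else out,
      nonfirst_response = if ("first_response" %in% names(out)) {
        drop_rule(out, "nonfirst_response", !out$first_response)
      } else out,
      rt_range = drop_rule(out, "rt_range",
                           out$rt_ms < config$rt_min |
                             out$rt_ms > config$rt_max),
      rt_mad = {
        mad_out <- out |>
          group_by(.data$participant_id) |>
          mutate(.mad_drop = {
            b <- mad_bounds(.data$rt_ms, config$mad_k)
            .data$rt_ms < b[1] | .data$rt_ms > b[2]
          }) |>
          ungroup()
        res <- drop_rule(mad_out, "rt_mad", mad_out$.mad_drop)
        res$.mad_drop <- NULL
        res
      },
      repetition = if (config$drop_repetitions) {
        drop_rule(out, "repetition", out$transition_kind == "repetition")
      } else out,
      trill = if (config$drop_trills) {
        drop_rule(out, "trill", out$transition_kind == "trill")
      } else out,
      first_two = if (config$drop_first_two) {
        drop_rule(out, "first_two", out$idx <= 2)
      } else out)
  }
  # incorrect responses are excluded from the RT analysis only, always last
  if (analysis == "rt") {
    out <- drop_rule(out, "incorrect", out$correct == 0)
  }

  audit_tab <- dplyr::bind_rows(audit_rows)
  audit <- structure(list(
    analysis = analysis, n_input = n_input, n_output = nrow(out),
    rules = audit_tab,
    total_removed = n_input - nrow(out),
    fraction_removed = (n_input - nrow(out)) / max(n_input, 1L)
  ), class = "asrt_filter_audit")
  stopifnot(sum(audit_tab$n_removed) == audit$total_removed)

  structure(list(trials = out, audit = audit), class = "asrt_filtered")
}

#' @export
print.asrt_filter_audit <- function(x, ...) {
  cat(sprintf("<asrt_filter_audit> %s dataset: %d -> %d trials (%.2f%% removed)\n",
              x$analysis, x$n_input, x$n_output, 100 * x$fraction_removed))
  for (i in seq_len(nrow(x$rules))) {
    cat(sprintf("  %-18s %6d (%5.2f%%)\n", x$rules$rule[i],
                x$rules$n_removed[i], 100 * x$rules$fraction_of_input[i]))
  }
  invisible(x)
}

#' Serialize a filter audit to JSON
#'
#' @param audit An `asrt_filter_audit`.
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return The JSON string, invisibly when written to a file.
#' @export
audit_json <- function(audit, path = NULL) {
  stopifnot(inherits(audit, "asrt_filter_audit"))
  payload <- list(
    analysis = audit$analysis, n_input = audit$n_input,
    n_output = audit$n_output, total_removed = audit$total_removed,
    fraction_removed = audit$fraction_removed,
    rules = lapply(seq_len(nrow(audit$rules)), function(i) {
      list(rule = audit$rules$rule[i],
           n_removed = audit$rules$n_removed[i],
           fraction_of_input = audit$rules$fraction_of_input[i],
           by_participant = as.list(audit$rules$by_participant[[i]]))
    }))
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(json)
}
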