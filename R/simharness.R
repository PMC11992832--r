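#' Simulation harness: type-I error and power over an effect grid
#'
#' Runs the whole pipeline - simulate a cohort, apply the trial filters,
#' compute difference scores, run the difference-score correlations and
#' (optionally) the trial-level mixed models - for every row of an effect
#' grid and every replicate, and records per-test rejection indicators at
#' level `alpha`. With all moderation coefficients at zero this calibrates
#' the type-I error of the OCI-R tests (nominal 5%); varying `learn_asym`
#' traces the power of the triplet-type tests.
#'
#' Mixed models in the harness use fast settings by design: Wald
#' chi-square Type III tests for RT (asymptotically equivalent to the
#' Satterthwaite F at trial-level sample sizes), a `(TripletType |
#' participant)` random structure, and binomial cell aggregation with
#' `nAGQ = 0` for accuracy.
#'
#' @param design An [design_spec()].
#' @param base_spec A [cohort_spec()] providing population defaults.
#' @param grid A data frame of parameter overrides, one simulation
#'   condition per row; columns must be population-mean names (e.g.
#'   `learn_asym`, `theta_rt`, `theta_acc`). A single all-default condition
#'   when `NULL`.
#' @param n_reps Replicates per condition.
#' @param seed Global seed; replicate seeds are derived with
#'   [derive_seed()].
#' @param tests Which tests to run: any of `"pearson_rt"`, `"pearson_acc"`
#'   (difference-score correlations with OCI-R), `"rt_model"`,
#'   `"acc_model"` (trial-level models; terms `triplet` and
#'   `triplet:ocir_c` are recorded).
#' @param alpha Rejection level (default 0.05).
#' @return A list of class `asrt_design_sim`: `raw` (one row per replicate
#'   x test x term: `p_value`, `reject`, `error`) and `rates` (rejection
#'   rates with exact binomial 95% confidence intervals).
#' @export
run_design_sim <- function(design, base_spec, grid = NULL, n_reps = 100,
                           seed = 1,
                           tests = c("pearson_rt", "pearson_acc"),
                           alpha = 0.05) {
  stopifnot(inherits(design, "asrt_design"),
            inherits(base_spec, "asrt_cohort_spec"))
  if (is.null(grid)) grid <- tibble(.condition = 1L)
  grid <- as_tibble(grid)
  if (!".condition" %in% names(grid)) {
    grid$.condition <- seq_len(nrow(grid))
  }
  tests <- match.arg(tests, c("pearson_rt", "pearson_acc", "rt_model",
                              "acc_model"), several.ok = TRUE)
  par_cols <- setdiff(names(grid), ".condition")
  bad <- setdiff(par_cols, names(base_spec$means))
  if (length(bad)) {
    abort(paste("Unknown grid parameters:", paste(bad, collapse = ", ")),
          class = "asrt_config_error")
  }

  rows <- list()
  for (g in seq_len(nrow(grid))) {
    spec_g <- base_spec
    for (p in par_cols) spec_g$means[[p]] <- grid[[p]][g]
    for (r in seq_len(n_reps)) {
      rep_seed <- derive_seed(seed, paste0("cond", g, "_rep", r))
      res <- tryCatch(
        sim_one_replicate(design, spec_g, rep_seed, tests),
        error = function(e) tibble(test = "error", term = NA_character_,
                                   p_value = NA_real_,
                                   error = conditionMessage(e)))
      res$condition <- grid$.condition[g]
      res$rep <- r
      rows[[length(rows) + 1L]] <- res
    }
  }
  raw <- dplyr::bind_rows(rows)
  if (!"error" %in% names(raw)) raw$error <- NA_character_
  raw$reject <- !is.na(raw$p_value) & raw$p_value < alpha

  rates <- raw |>
    filter(is.na(.data$error)) |>
    group_by(.data$condition, .data$test, .data$term) |>
    summarise(n = dplyr::n(), n_reject = sum(.data$reject),
              rate = mean(.data$reject), .groups = "drop")
  cis <- Map(function(k, n) stats::binom.test(k, n)$conf.int,
             rates$n_reject, rates$n)
  rates$ci_low <- vapply(cis, `[`, numeric(1), 1)
  rates$ci_high <- vapply(cis, `[`, numeric(1), 2)

  structure(list(raw = raw, rates = rates, grid = grid, alpha = alpha),
            class = "asrt_design_sim")
}

sim_one_replicate <- function(design, spec, rep_seed, tests) {
  sim <- simulate_cohort(design, spec, seed = rep_seed)
  out <- list()

  need_scores <- any(c("pearson_rt", "pearson_acc") %in% tests)
  rt_f <- filter_trials(sim$trials, analysis = "rt")
  acc_f <- filter_trials(sim$trials, analysis = "accuracy")

  if (need_scores) {
    cells <- aggregate_cells(rt_f, acc_f, keying = "category")
    scores <- learning_scores(cells)
    scores <- dplyr::left_join(
      scores,
      dplyr::distinct(sim$participants, .data$participant_id, .data$ocir),
      by = "participant_id")
    if ("pearson_rt" %in% tests) {
      ct <- pearson_test(scores$rt_learning, scores$ocir)
      out$pearson_rt <- tibble(test = "pearson_rt", term = "ocir",
                               p_value = ct$p_value)
    }
    if ("pearson_acc" %in% tests) {
      ct <- pearson_test(scores$acc_learning, scores$ocir)
      out$pearson_acc <- tibble(test = "pearson_acc", term = "ocir",
                                p_value = ct$p_value)
    }
  }
  if ("rt_model" %in% tests) {
    fit <- fit_rt_model(rt_f, model_spec("log_rt", random = "no_time_slope",
                                         ddf = "asymptotic"))
    keep <- fit$anova$term %in% c("triplet", "triplet:ocir_c")
    out$rt_model <- tibble(test = "rt_model", term = fit$anova$term[keep],
                           p_value = fit$anova$p_value[keep])
  }
  if ("acc_model" %in% tests) {
    fit <- fit_accuracy_model(acc_f,
                              model_spec("accuracy",
                                         random = "no_time_slope"),
                              aggregate = TRUE, nagq = 0L,
                              lrt_terms = c("triplet", "triplet:ocir_c"))
    out$acc_model <- tibble(test = "acc_model", term = fit$anova$term,
                            p_value = fit$anova$p_value)
  }
  res <- dplyr::bind_rows(out)
  res$error <- NA_character_
  res
}

#' @export
print.asrt_design_sim <- function(x, ...) {
  cat("<asrt_design_sim> alpha =", x$alpha, "\n")
  print(as.data.frame(x$rates), digits = 3)
  invisible(x)
}
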