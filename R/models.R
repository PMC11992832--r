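#' Mixed-model specification
#'
#' Captures the trial-level model structure: outcome, the fixed part
#' `Time * TripletType * OCIR` (OCI-R mean-centered, continuous; factors
#' coded sum-to-zero so Type III tests are valid), the random part (by
#' default per-participant intercept with correlated slopes for Time and
#' TripletType), and the inference type (Type III F tests for RT models,
#' likelihood-ratio tests for accuracy models). The random structure names
#' the top rung of the convergence ladder: `"full"`
#' `(Time + Triplet | participant)`, `"no_corr"` (uncorrelated),
#' `"no_time_slope"` `(Triplet | participant)`, `"intercept_only"`.
#'
#' @param outcome `"log_rt"` or `"accuracy"`.
#' @param random Starting random-effects structure.
#' @param ddf Denominator-df method for RT Type III tests:
#'   `"satterthwaite"` (default) or `"asymptotic"` (Wald chi-square, much
#'   faster; equivalent at large residual df).
#' @param epoch_width,phase_offset Epoch (Time factor) construction, see
#'   [assign_epoch()].
#' @param keying `"category"` (high/low triplets) or `"interference"`
#'   (HL/LH/LL relabelling).
#' @param triplet_levels Which triplet levels enter the model; defaults to
#'   `c("high", "low")` for category keying; for interference models use
#'   e.g. `c("HL", "LL")` (Old knowledge) or `c("LH", "LL")` (New
#'   knowledge).
#' @return An object of class `asrt_model_spec`.
#' @export
model_spec <- function(outcome = c("log_rt", "accuracy"),
                       random = c("full", "no_corr", "no_time_slope",
                                  "intercept_only"),
                       ddf = c("satterthwaite", "asymptotic"),
                       epoch_width = 5, phase_offset = 0,
                       keying = c("category", "interference"),
                       triplet_levels = NULL) {
  outcome <- match.arg(outcome)
  keying <- match.arg(keying)
  if (is.null(triplet_levels)) {
    triplet_levels <- if (keying == "category") c("high", "low")
                      else c("HL", "LL")
  }
  structure(list(outcome = outcome, random = match.arg(random),
                 ddf = match.arg(ddf), epoch_width = epoch_width,
                 phase_offset = phase_offset, keying = keying,
                 triplet_levels = triplet_levels),
            class = "asrt_model_spec")
}

random_ladder <- c("full", "no_corr", "no_time_slope", "intercept_only")

random_term <- function(structure) {
  switch(structure,
    full = "(time + triplet | participant_id)",
    no_corr = "(time + triplet || participant_id)",
    no_time_slope = "(triplet | participant_id)",
    intercept_only = "(1 | participant_id)")
}

prepare_model_data <- function(trials, spec) {
  if (inherits(trials, "asrt_filtered")) trials <- trials$trials
  key <- switch(spec$keying,
    category = trials$triplet_category,
    interference = trials$interference_label)
  keep <- key %in% spec$triplet_levels
  d <- trials[keep, , drop = FALSE]
  d$triplet <- factor(key[keep], levels = spec$triplet_levels)
  epoch <- assign_epoch(d$block, spec$epoch_width, spec$phase_offset)
  d$time <- factor(epoch, levels = sort(unique(epoch)))
  # mean-center OCI-R at the participant level, one value per participant
  ppl <- dplyr::distinct(d, .data$participant_id, .data$ocir)
  d$ocir_c <- d$ocir - mean(ppl$ocir)
  if (nlevels(d$time) < 1 || nlevels(droplevels(d$triplet)) < 2) {
    abort("Insufficient factor levels after subsetting for the model.",
          class = "asrt_precondition_error")
  }
  d
}

sum_contrasts <- function(data) {
  list(time = stats::contr.sum(nlevels(data$time)),
       triplet = stats::contr.sum(nlevels(data$triplet)))
}

fit_with_ladder <- function(fitter, start) {
  start_i <- match(start, random_ladder)
  for (i in seq(start_i, length(random_ladder))) {
    res <- fitter(random_ladder[i])
    if (res$converged || i == length(random_ladder)) {
      res$ladder <- random_ladder[i]
      return(res)
    }
  }
}

converged_ok <- function(model) {
  msgs <- unlist(model@optinfo$conv$lme4$messages)
  length(msgs) == 0 || !any(grepl("failed to converge", msgs, fixed = TRUE))
}

tidy_anova3 <- function(at) {
  if (all(c("NumDF", "DenDF") %in% colnames(at))) {
    tibble(term = rownames(at), statistic = at[, "F value"],
           df1 = at[, "NumDF"], df2 = at[, "DenDF"],
           p_value = at[, "Pr(>F)"], test = "F")
  } else {
    tibble(term = rownames(at), statistic = at[, "Chisq"],
           df1 = at[, "Df"], df2 = NA_real_,
           p_value = at[, "Pr(>Chisq)"], test = "Chisq")
  }
}

new_asrt_fit <- function(model, spec, anova_tab, ladder, singular, data) {
  vc <- as.data.frame(lme4::VarCorr(model))
  fe <- lme4::fixef(model)
  r2 <- tryCatch(nakagawa_r2(model), error = function(e) NULL)
  structure(list(
    model = model, spec = spec, anova = anova_tab,
    fixef = tibble(term = names(fe), estimate = unname(fe)),
    varcor = tibble(vc),
    ladder = ladder, converged = converged_ok(model), singular = singular,
    r2 = r2,
    n_obs = nrow(data),
    n_participants = dplyr::n_distinct(data$participant_id)
  ), class = "asrt_fit")
}

#' @export
print.asrt_fit <- function(x, ...) {
  cat("<asrt_fit> ", x$spec$outcome, " model | ", x$n_obs, " trials, ",
      x$n_participants, " participants | random: ", x$ladder,
      if (x$singular) " (singular)" else "", "\n", sep = "")
  print(as.data.frame(x$anova), digits = 4)
  if (!is.null(x$r2)) {
    cat(sprintf("R2 marginal %.3f, conditional %.3f; adjusted ICC %.3f\n",
                x$r2$marginal, x$r2$conditional, x$r2$icc_adjusted))
  }
  invisible(x)
}

#' Trial-level linear mixed model for (log) reaction time
#'
#' Fits `log(RT) ~ Time * TripletType * OCIR + (Time + TripletType |
#' participant)` by REML, with sum-to-zero factor coding and the
#' mean-centered continuous OCI-R score, and reports Type III tests per
#' fixed term (Satterthwaite F by default; Wald chi-square with
#' `ddf = "asymptotic"`). On non-convergence a fixed simplification ladder
#' is descended - drop the random-effect correlations, then the Time slope,
#' then all slopes - and the final structure is recorded in the result.
#'
#' @param trials RT-filtered trials ([filter_trials()] output or its
#'   `$trials`).
#' @param spec An [model_spec()]; defaults to the log-RT spec.
#' @return An `asrt_fit`: the `lmerMod`, the Type III table (`$anova`),
#'   fixed effects, variance components, the convergence-ladder position,
#'   and Nakagawa R-squared with adjusted ICC.
#' @export
fit_rt_model <- function(trials, spec = model_spec("log_rt")) {
  stopifnot(identical(spec$outcome, "log_rt"))
  d <- prepare_model_data(trials, spec)
  ctr <- sum_contrasts(d)
  use_sat <- identical(spec$ddf, "satterthwaite")
  fitter <- function(structure) {
    f <- as.formula(paste("log(rt_ms) ~ time * triplet * ocir_c +",
                          random_term(structure)))
    ctrl <- lme4::lmerControl(optimizer = "nloptwrap",
                              calc.derivs = use_sat,
                              check.conv.singular = "ignore")
    model <- withCallingHandlers(
      if (use_sat) {
        lmerTest::lmer(f, data = d, REML = TRUE, contrasts = ctr,
                       control = ctrl)
      } else {
        lme4::lmer(f, data = d, REML = TRUE, contrasts = ctr,
                   control = ctrl)
      },
      warning = function(w) invokeRestart("muffleWarning"))
    list(model = model, converged = converged_ok(model))
  }
  res <- fit_with_ladder(fitter, spec$random)
  model <- res$model
  at <- if (use_sat) {
    stats::anova(model, type = 3)
  } else {
    car::Anova(model, type = 3)
  }
  new_asrt_fit(model, spec, tidy_anova3(at), res$ladder,
               lme4::isSingular(model), d)
}

#' Trial-level generalized linear mixed model for accuracy
#'
#' Fits the logit-link mixed model `Accuracy ~ Time * TripletType * OCIR +
#' (Time + TripletType | participant)` and tests each fixed term by a
#' likelihood-ratio comparison of nested fits (the model with and without
#' the term, all else equal). With `aggregate = TRUE` trials are collapsed
#' to binomial counts per participant x Time x TripletType cell before
#' fitting - the same fixed structure at a fraction of the cost, used by
#' the simulation harness; the choice is recorded in the result. Constant
#' outcomes (all correct or all incorrect) raise an explicit separation
#' error rather than fitting silently.
#'
#' @param trials Accuracy-filtered trials.
#' @param spec An [model_spec()] with `outcome = "accuracy"`.
#' @param aggregate Collapse to binomial cell counts before fitting.
#' @param nagq Integration points for `glmer` (passed as `nAGQ`; 0 is a
#'   faster approximation used by the harness).
#' @param lrt_terms Fixed terms to test by LRT; `NULL` (default) tests all
#'   seven. Restricting the set skips the corresponding reduced fits.
#' @return An `asrt_fit` with an `$anova` table of likelihood-ratio
#'   chi-square tests.
#' @export
fit_accuracy_model <- function(trials, spec = model_spec("accuracy"),
                               aggregate = FALSE, nagq = 1L,
                               lrt_terms = NULL) {
  stopifnot(identical(spec$outcome, "accuracy"))
  d <- prepare_model_data(trials, spec)
  if (var(d$correct) == 0) {
    abort("Outcome is constant (complete separation): accuracy model not estimable.",
          class = "asrt_separation_error")
  }
  ctr <- sum_contrasts(d)
  if (aggregate) {
    d <- d |>
      group_by(.data$participant_id, .data$time, .data$triplet,
               .data$ocir_c) |>
      summarise(n_correct = sum(.data$correct), n_total = dplyr::n(),
                .groups = "drop")
    lhs <- "cbind(n_correct, n_total - n_correct)"
  } else {
    lhs <- "correct"
  }
  fixed <- "time * triplet * ocir_c"
  # Sum-to-zero fixed-effect columns, so that dropping one term's columns
  # while keeping the others yields the marginal (Type-III-style) LRT; a
  # formula update would be re-absorbed by the remaining interactions.
  mm <- stats::model.matrix(as.formula(paste("~", fixed)), d,
                            contrasts.arg = ctr)
  asgn <- attr(mm, "assign")
  terms_to_test <- attr(stats::terms(as.formula(paste("~", fixed))),
                        "term.labels")
  coef_names <- paste0(".b", seq_len(ncol(mm)))
  colnames(mm) <- coef_names
  d <- dplyr::bind_cols(d, as_tibble(mm))

  fit_cols <- function(cols, structure) {
    f <- as.formula(paste(lhs, "~ 0 +", paste(cols, collapse = " + "),
                          "+", random_term(structure)))
    withCallingHandlers(
      lme4::glmer(f, data = d, family = stats::binomial(), nAGQ = nagq,
                  control = lme4::glmerControl(
                    optimizer = "bobyqa",
                    check.conv.singular = "ignore")),
      warning = function(w) invokeRestart("muffleWarning"))
  }
  # the full model keeps the factor parameterization (emmeans needs it);
  # reduced models are refit on the explicit columns with the term removed
  fitter <- function(structure) {
    f <- as.formula(paste(lhs, "~", fixed, "+", random_term(structure)))
    model <- withCallingHandlers(
      lme4::glmer(f, data = d, family = stats::binomial(), contrasts = ctr,
                  nAGQ = nagq,
                  control = lme4::glmerControl(
                    optimizer = "bobyqa",
                    check.conv.singular = "ignore")),
      warning = function(w) invokeRestart("muffleWarning"))
    list(model = model, converged = converged_ok(model))
  }
  res <- fit_with_ladder(fitter, spec$random)
  model <- res$model

  test_idx <- if (is.null(lrt_terms)) seq_along(terms_to_test) else {
    bad <- setdiff(lrt_terms, terms_to_test)
    if (length(bad)) abort(paste("Unknown terms:", paste(bad, collapse = ", ")))
    match(lrt_terms, terms_to_test)
  }
  lrt <- lapply(test_idx, function(j) {
    reduced <- fit_cols(coef_names[asgn != j], res$ladder)
    cmp <- stats::anova(reduced, model)
    tibble(term = terms_to_test[j], statistic = cmp$Chisq[2],
           df1 = cmp$Df[2], df2 = NA_real_,
           p_value = cmp$`Pr(>Chisq)`[2], test = "LRT")
  })
  fit <- new_asrt_fit(model, spec, dplyr::bind_rows(lrt), res$ladder,
                      lme4::isSingular(model), d)
  fit$aggregated <- aggregate
  fit
}

#' Sidak-adjusted pairwise cell contrasts on the response scale
#'
#' Estimated marginal cell means are regridded to the response scale
#' (milliseconds for the log-RT model, probability of a correct response
#' for the accuracy model) and all pairwise differences are tested with
#' Sidak adjustment over the family of contrasts.
#'
#' @param fit An `asrt_fit`.
#' @param specs Factors defining the cells, e.g. `~ time`, `~ triplet` or
#'   `~ time * triplet` (default).
#' @param df_method Degrees-of-freedom method for the underlying
#'   `emmeans` grid of a linear mixed model: `"satterthwaite"` (default)
#'   or `"asymptotic"`.
#' @return A tibble: `contrast`, `estimate` (response-scale difference),
#'   `se`, `p_value` (unadjusted), `p_sidak`, and the family size `m`.
#' @export
cell_contrasts <- function(fit, specs = ~ time * triplet,
                           df_method = c("satterthwaite", "asymptotic")) {
  stopifnot(inherits(fit, "asrt_fit"))
  df_method <- match.arg(df_method)
  emm <- emmeans::emmeans(fit$model, specs = specs, lmer.df = df_method)
  rg <- emmeans::regrid(emm, transform = "response")
  prs <- as.data.frame(emmeans::contrast(rg, method = "pairwise",
                                         adjust = "none"))
  stat_col <- intersect(c("t.ratio", "z.ratio"), names(prs))[1]
  out <- tibble(
    contrast = as.character(prs$contrast),
    estimate = prs$estimate, se = prs$SE,
    statistic = prs[[stat_col]],
    p_value = prs$p.value
  )
  out$m <- nrow(out)
  out$p_sidak <- sidak_adjust(out$p_value, m = nrow(out))
  out
}

#' Nakagawa marginal and conditional R-squared
#'
#' Variance-explained summaries for mixed models: marginal R2 =
#' `var_fixed / (var_fixed + var_random + var_resid)` (fixed effects only),
#' conditional R2 adds the random-effect variance to the numerator, and
#' the adjusted ICC is `var_random / (var_random + var_resid)`. For a
#' fitted model, `var_fixed` is the variance of the fixed-effect linear
#' predictor and `var_random` the mean per-observation random-effect
#' variance (which accommodates random slopes); for logit models the
#' residual variance is the latent-scale constant `pi^2 / 3`.
#'
#' @param object A fitted `merMod`/`asrt_fit`, or the fixed-effect variance
#'   component (numeric) when supplying components directly.
#' @param var_random,var_resid Random-effect and residual variance
#'   components for the numeric interface.
#' @param ... Unused.
#' @return A list: `marginal`, `conditional`, `icc_adjusted`, `components`.
#' @examples
#' nakagawa_r2(1, var_random = 1, var_resid = 2) # marginal .25, conditional .5
#' @export
nakagawa_r2 <- function(object, ...) UseMethod("nakagawa_r2")

#' @rdname nakagawa_r2
#' @export
nakagawa_r2.numeric <- function(object, var_random, var_resid, ...) {
  var_fixed <- object
  if (any(c(var_fixed, var_random, var_resid) < 0)) {
    abort("Variance components must be non-negative.",
          class = "asrt_precondition_error")
  }
  denom <- var_fixed + var_random + var_resid
  list(marginal = var_fixed / denom,
       conditional = (var_fixed + var_random) / denom,
       icc_adjusted = var_random / (var_random + var_resid),
       components = c(var_fixed = var_fixed, var_random = var_random,
                      var_resid = var_resid))
}

#' @rdname nakagawa_r2
#' @export
nakagawa_r2.merMod <- function(object, ...) {
  beta <- lme4::fixef(object)
  x <- lme4::getME(object, "X")
  var_fixed <- var(as.numeric(x %*% beta))
  lambdat <- lme4::getME(object, "Lambdat")
  zt <- lme4::getME(object, "Zt")
  disp <- stats::sigma(object)^2
  # per-observation random-effect variance z_i' (sigma^2 L'L) z_i
  v <- Matrix::colSums((lambdat %*% zt)^2) * disp
  var_random <- mean(v)
  var_resid <- if (inherits(object, "glmerMod")) {
    fam <- stats::family(object)
    if (fam$family == "binomial" && fam$link == "logit") pi^2 / 3
    else abort("Only binomial-logit GLMMs are supported.")
  } else {
    stats::sigma(object)^2
  }
  nakagawa_r2(var_fixed, var_random = var_random, var_resid = var_resid)
}

#' @rdname nakagawa_r2
#' @export
nakagawa_r2.asrt_fit <- function(object, ...) nakagawa_r2(object$model, ...)

#' Serialize a fit to JSON
#'
#' Estimates, per-term tests, variance components, convergence-ladder
#' position and R-squared summaries in a machine-readable form.
#'
#' @param fit An `asrt_fit`.
#' @param path Optional output path; when `NULL` the JSON string is
#'   returned.
#' @return JSON string (invisibly when written).
#' @export
fit_json <- function(fit, path = NULL) {
  stopifnot(inherits(fit, "asrt_fit"))
  payload <- list(
    outcome = fit$spec$outcome,
    n_obs = fit$n_obs, n_participants = fit$n_participants,
    random_structure = fit$ladder, converged = fit$converged,
    singular = fit$singular,
    fixed_effects = fit$fixef, tests = fit$anova,
    variance_components = fit$varcor,
    r2 = fit$r2[c("marginal", "conditional", "icc_adjusted")]
  )
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                           dataframe = "rows")
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(json)
}
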