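#' TrialRecord column schema
#'
#' The canonical tidy trial table: one row per first response. Used by
#' [read_trials()]/[write_trials()] for validation.
#'
#' @return A named character vector mapping column names to types
#'   (`"character"`, `"integer"`, `"double"`).
#' @export
trial_schema <- function() {
  c(participant_id = "character", block = "integer", idx = "integer",
    position = "integer", role = "character", phase = "character",
    sequence_label = "character", triplet_category = "character",
    triplet_ending = "character", interference_label = "character",
    transition_kind = "character", rt_ms = "double", correct = "integer",
    ocir = "integer")
}

validate_trials <- function(df, file = "<data>") {
  schema <- trial_schema()
  missing_cols <- setdiff(names(schema), names(df))
  extra_cols <- setdiff(names(df), names(schema))
  problems <- character()
  if (length(missing_cols)) {
    problems <- c(problems, paste("missing columns:",
                                  paste(missing_cols, collapse = ", ")))
  }
  if (length(extra_cols)) {
    problems <- c(problems, paste("unexpected columns:",
                                  paste(extra_cols, collapse = ", ")))
  }
  if (!length(missing_cols) && nrow(df) > 0) {
    bad_row <- function(mask, what) {
      if (any(mask, na.rm = TRUE)) {
        rows <- which(mask)
        paste0(what, " at row", if (length(rows) > 1) "s" else "", " ",
               paste(head(rows, 5), collapse = ", "),
               if (length(rows) > 5) sprintf(" (+%d more)", length(rows) - 5))
      }
    }
    problems <- c(problems,
      bad_row(!df$correct %in% c(0L, 1L), "correct not in {0,1}"),
      bad_row(!is.na(df$rt_ms) & df$rt_ms <= 0, "rt_ms not positive"),
      bad_row(!df$position %in% 1:4, "position not in 1..4"),
      bad_row(!df$role %in% c("pattern", "random"), "invalid role"),
      bad_row(!is.na(df$ocir) & (df$ocir < 0 | df$ocir > 72),
              "ocir outside 0..72"))
  }
  problems <- problems[!vapply(problems, is.null, logical(1))]
  if (length(problems)) {
    abort(paste0("Schema violations in ", file, ":\n  ",
                 paste(unlist(problems), collapse = "\n  ")),
          class = "asrt_schema_error")
  }
  invisible(df)
}

#' Read / write the tidy trial-record CSV
#'
#' Lossless round-trip of the TrialRecord table with schema validation;
#' violations are reported with offending row numbers. `write_trials()`
#' also writes a JSON sidecar (`<path>.meta.json`) recording the package
#' version and a content hash, so every output file documents its
#' provenance without breaking strict CSV parsing.
#'
#' @param path CSV file path.
#' @param records A TrialRecord tibble.
#' @param sidecar Write the provenance sidecar (default `TRUE`).
#' @return `read_trials()`: the validated tibble. `write_trials()`: `path`,
#'   invisibly.
#' @export
read_trials <- function(path) {
  schema <- trial_schema()
  col_spec <- do.call(readr::cols, lapply(schema, function(t) switch(t,
    character = readr::col_character(), integer = readr::col_integer(),
    double = readr::col_double())))
  df <- suppressWarnings(
    readr::read_csv(path, col_types = col_spec, progress = FALSE))
  prob <- readr::problems(df)
  if (nrow(prob) > 0) {
    abort(paste0("Unparseable values in ", path, " at rows: ",
                 paste(head(unique(prob$row), 10), collapse = ", ")),
          class = "asrt_schema_error")
  }
  validate_trials(df, file = path)
}

#' @rdname read_trials
#' @export
write_trials <- function(records, path, sidecar = TRUE) {
  validate_trials(as_tibble(records))
  readr::write_csv(records[, names(trial_schema())], path, progress = FALSE)
  if (sidecar) {
    meta <- list(
      package = "asrtlearn",
      version = as.character(utils::packageVersion("asrtlearn")),
      n_rows = nrow(records),
      content_hash = content_hash(records))
    writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE),
               paste0(path, ".meta.json"))
  }
  invisible(path)
}

# order-sensitive checksum of the serialized table; dependency-free and fast
content_hash <- function(df) {
  con <- textConnection("hash_buffer", "w", local = TRUE)
  utils::write.csv(df, con, row.names = FALSE)
  close(con)
  x <- utf8ToInt(paste(hash_buffer, collapse = "\n"))
  m <- 2147483587
  h <- sum((x * (seq_along(x) %% 9973 + 1)) %% m) %% m
  sprintf("chk:%08x", as.integer(h))
}

#' Read a run configuration (YAML or JSON)
#'
#' A run configuration mirrors the constructor arguments of the pipeline
#' stages under the sections `design`, `cohort`, `filter`, `model` and
#' `simulation`, plus a global `seed`. Stage seeds are derived from the
#' global seed with [derive_seed()].
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A named list with at least a `seed` element.
#' @export
read_run_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  if (is.null(cfg$seed)) cfg$seed <- 1L
  cfg
}
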