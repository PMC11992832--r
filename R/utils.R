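#' Derive a stage seed from a global seed
#'
#' Every stochastic stage of the pipeline draws its seed deterministically
#' from the global run seed and a stage name, so stages can be re-run in
#' isolation and still reproduce an end-to-end run. The derivation is a
#' small polynomial string hash folded with the seed modulo a prime below
#' 2^31; it is stable across platforms and R versions.
#'
#' @param seed Integer global seed.
#' @param stage Character stage name, e.g. `"participant_7"`.
#' @return An integer in `[0, 2^31)` usable with [set.seed()].
#' @export
derive_seed <- function(seed, stage) {
  m <- 2147483587 # prime < 2^31
  h <- 0
  for (ch in utf8ToInt(as.character(stage))) {
    h <- (h * 31 + ch) %% m
  }
  as.integer((h * 1103 + as.numeric(seed) %% m * 8191) %% m)
}

#' OCI-R total-score range
#'
#' The Obsessive-Compulsive Inventory-Revised has 18 items each rated on a
#' 0-4 scale, so total scores span 0 to 72.
#'
#' @param n_items Number of items (18).
#' @param max_rating Maximum item rating (4).
#' @return Integer vector `c(min, max)` of attainable total scores.
#' @export
ocir_range <- function(n_items = 18L, max_rating = 4L) {
  c(0L, as.integer(n_items) * as.integer(max_rating))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
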