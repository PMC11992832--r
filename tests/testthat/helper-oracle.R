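# Independent brute-force triplet labeling: walks every length-3 window
# within each block and derives the labels directly from the pattern order
# written as a doubled cycle, without using the package's successor map.
oracle_classify <- function(stream, order_a, order_b = NULL) {
  follows <- function(ord, a, b) {
    doubled <- c(ord, ord)
    any(vapply(seq_len(4), function(i) {
      doubled[i] == a && doubled[i + 1] == b
    }, logical(1)))
  }
  n <- nrow(stream)
  cat_out <- character(n)
  end_out <- character(n)
  tran_out <- character(n)
  intf_out <- character(n)
  for (i in seq_len(n)) {
    if (stream$idx[i] <= 2) {
      cat_out[i] <- "undefined"
      end_out[i] <- "undefined"
      tran_out[i] <- "undefined"
      intf_out[i] <- "not_applicable"
      next
    }
    stopifnot(stream$block[i - 2] == stream$block[i])
    p <- stream$position[(i - 2):i]
    hi_a <- follows(order_a, p[1], p[3])
    cat_out[i] <- if (hi_a) "high" else "low"
    end_out[i] <- paste0(stream$role[i], "_ending")
    tran_out[i] <- if (p[1] == p[2] && p[2] == p[3]) "repetition"
                   else if (p[1] == p[3] && p[1] != p[2]) "trill"
                   else "other"
    if (is.null(order_b)) {
      intf_out[i] <- "not_applicable"
    } else {
      hi_b <- follows(order_b, p[1], p[3])
      stopifnot(!(hi_a && hi_b))
      intf_out[i] <- if (hi_a) "HL" else if (hi_b) "LH" else "LL"
    }
  }
  list(category = cat_out, ending = end_out, transition = tran_out,
       interference = intf_out)
}

# Minimal hand-built classified TrialRecord table for filter/scoring tests.
toy_records <- function() {
  tibble::tibble(
    participant_id = "P001",
    block = 1L,
    idx = 1:10,
    # pattern rows (odd) follow the (2,4,3,1) cycle; labels verified by hand
    position = c(2L, 1L, 4L, 2L, 3L, 2L, 1L, 1L, 2L, 3L),
    role = rep(c("pattern", "random"), 5),
    phase = "learning",
    sequence_label = "A",
    triplet_category = c("undefined", "undefined", "high", "high", "high",
                         "low", "high", "low", "high", "low"),
    triplet_ending = c("undefined", "undefined", rep(c("pattern_ending",
                                                       "random_ending"), 4)),
    interference_label = "not_applicable",
    transition_kind = c("undefined", "undefined", "other", "other", "other",
                        "trill", "other", "other", "other", "other"),
    # row 3: too fast (100 ms); row 5: too slow (1200 ms); row 6: trill;
    # rows 1-2: block-initial; row 9: incorrect; rest clean and clustered
    # so the MAD rule removes nothing
    rt_ms = c(330, 335, 100, 340, 1200, 338, 332, 336, 334, 339),
    correct = c(1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L, 0L, 1L),
    ocir = 20L
  )
}

# Fast small simulated cohort shared across tests (built once per run).
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      design <- design_spec("study1", n_blocks = 10)
      spec <- cohort_spec(8, seed = 101)
      cache <<- simulate_cohort(design, spec, seed = 101)
    }
    cache
  }
})
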