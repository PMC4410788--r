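# inter-response interval extraction and prefiltering ---------------------

EXCLUSION_REASONS <- c("none", "prefilter", "outlier", "missing_neighbor",
                       "unassigned", "sync_phase")

new_iri_series <- function(df, session) {
  df <- tibble::as_tibble(df)
  attr(df, "condition") <- session$condition
  attr(df, "target_interval_ms") <- session$target_interval_ms
  attr(df, "participant_id") <- session$participant_id
  attr(df, "group") <- session$group
  class(df) <- c("iri_series", class(df))
  df
}

# preserve attributes when subassigning through generic verbs
reflag <- function(iri, idx, reason) {
  iri$valid[idx] <- FALSE
  iri$exclusion_reason[idx] <- reason
  iri
}

# Anchored incremental stimulus assignment for paced tapping.  The first tap
# is anchored to the nearest onset (ties toward the earlier stimulus); each
# later tap advances the last assigned slot by the rounded number of target
# intervals spanned since that tap.  Tracking the produced sequence rather
# than absolute clock time keeps slot numbers consecutive for participants
# whose drift accumulates beyond half an interval, while still exposing
# double taps (zero advance) and skipped slots (advance >= 2).
assign_stimulus <- function(taps, onsets, target) {
  n <- length(taps)
  n_stim <- length(onsets)
  slot <- rep(NA_integer_, n)
  d <- abs(onsets - taps[1])
  slot[1] <- which.min(d)[1]  # which.min returns the first (earlier) on ties
  base_t <- taps[1]
  base_s <- slot[1]
  if (n >= 2L) {
    for (j in 2:n) {
      inc <- round((taps[j] - base_t) / target)
      cand <- base_s + inc
      if (inc >= 1 && cand <= n_stim) {
        slot[j] <- as.integer(cand)
        base_t <- taps[j]
        base_s <- slot[j]
      }  # inc == 0: double-tap candidate; cand > n_stim: after the train
    }
  }
  slot
}

#' Extract inter-response intervals from a session
#'
#' Forms `I_j = t_j - t_(j-1)` for consecutive recorded taps and assigns each
#' interval the stimulus index of its terminating tap.  Externally paced: the
#' first tap is anchored to the nearest stimulus onset (ties toward the
#' earlier stimulus) and later taps advance the slot by the rounded number of
#' target intervals spanned, so slowly drifting participants keep consecutive
#' slot numbers; taps that advance the slot by zero (double-tap candidates) or
#' fall beyond the stimulus train are flagged `unassigned`, as are the
#' intervals touching them.  Self paced: taps in the synchronization phase (up
#' to half an interval after the last pacing tone) are flagged `sync_phase`;
#' continuation taps are indexed ordinally with the same gap-based
#' advancement, so an unrecorded tap does not compress the trend axis.  Gaps
#' longer than 1.5 times the target interval are flagged `missing_neighbor`
#' and never emitted as one long interval.
#'
#' @param session A [tap_session()].
#' @return A tibble of class `iri_series` with columns `tap_index` (ordinal of
#'   the terminating tap), `stimulus_index`, `iri_ms`, `valid`,
#'   `exclusion_reason`.
#' @export
compute_iri <- function(session) {
  stopifnot(inherits(session, "tap_session"))
  taps <- session$tap_times_ms
  if (length(taps) < 2L)
    wk_stop("wktap_too_few_taps", "participant %s (%s): need at least 2 taps",
            session$participant_id, session$condition)
  target <- session$target_interval_ms
  n <- length(taps)
  iri <- tibble::tibble(
    tap_index = 2:n,
    stimulus_index = NA_integer_,
    iri_ms = diff(taps),
    valid = TRUE,
    exclusion_reason = "none")

  if (session$condition == "externally_paced") {
    slot <- assign_stimulus(taps, session$stimulus_onsets_ms, target)
    iri$stimulus_index <- slot[iri$tap_index]
    bad <- is.na(slot[iri$tap_index]) | is.na(slot[iri$tap_index - 1L])
    iri <- reflag(iri, which(bad), "unassigned")
  } else {
    cutoff <- max(session$stimulus_onsets_ms) + target / 2
    is_sync <- taps <= cutoff
    cont <- which(!is_sync)
    # ordinal continuation index, advancing across unrecorded-tap gaps
    ord <- integer(n)
    if (length(cont)) {
      ord[cont[1]] <- 1L
      if (length(cont) > 1L) {
        steps <- pmax(1, round(diff(taps[cont]) / target))
        ord[cont[-1]] <- 1L + cumsum(steps)
      }
    }
    term_sync <- is_sync[iri$tap_index]
    spans_phase <- !is_sync[iri$tap_index] & is_sync[iri$tap_index - 1L]
    iri <- reflag(iri, which(term_sync | spans_phase), "sync_phase")
    keep <- !term_sync & !spans_phase
    iri$stimulus_index[keep] <- ord[iri$tap_index[keep]]
  }

  long_gap <- iri$iri_ms > 1.5 * target
  iri <- reflag(iri, which(long_gap), "missing_neighbor")
  new_iri_series(iri, session)
}

#' Remove atypical early responses
#'
#' Marks the intervals formed by the first two taps (externally paced) or
#' first seven taps (self paced) as `prefilter`, i.e. the first 2 or 7 valid
#' intervals of the series; removing the first k taps of a train removes
#' exactly its first k intervals.
#'
#' @param iri An `iri_series` from [compute_iri()].
#' @param condition Condition; defaults to the series' own.
#' @param n_remove Override for the number of initial taps removed.
#' @param min_remaining Minimum number of analysable intervals required.
#' @return The series with prefilter flags applied.
#' @export
prefilter <- function(iri, condition = NULL, n_remove = NULL,
                      min_remaining = 10L) {
  stopifnot(inherits(iri, "iri_series"))
  condition <- match.arg(condition %||% attr(iri, "condition"), CONDITIONS)
  k <- n_remove %||% if (condition == "externally_paced") 2L else 7L
  first_valid <- head(which(iri$valid), k)
  iri <- reflag(iri, first_valid, "prefilter")
  if (sum(iri$valid) < min_remaining)
    wk_stop("wktap_too_few_taps",
            "too few taps: %d analysable intervals remain after prefiltering (need >= %d)",
            sum(iri$valid), min_remaining)
  iri
}
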