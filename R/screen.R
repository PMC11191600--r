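# Composing per-receptor threshold probability profiles into the two
# screening metrics and running the funnel:
#   activity score   = P(active at or below 10 nM on the target receptor)
#   selectivity score = P(active at 10 nM on D4) x prod over off-targets
#                       of P(not active at 1000 nM) -- the probability of
#                       two-orders-of-magnitude selectivity if the four
#                       predictions are treated as independent. Because the
#                       score multiplies several independent predictions,
#                       per-prediction error accumulates in it.

#' Screening funnel configuration
#'
#' @param activity_cutoff molecules with activity score at or above this
#'   move forward (default 0.8; the comparison is `>=`).
#' @param selectivity_cutoff preferred molecules additionally have a
#'   selectivity score exceeding this (default 0.4; the comparison is
#'   strict `>`).
#' @param n_select number of candidates to acquire (default 89).
#' @param selectivity_mode `"product"` (default) multiplies the three
#'   off-target inactivity probabilities; `"min"` uses only the worst
#'   off-target.
#' @return object of class `funnel_config`.
#' @export
funnel_config <- function(activity_cutoff = 0.8, selectivity_cutoff = 0.4,
                          n_select = 89L,
                          selectivity_mode = c("product", "min")) {
  assert_prob(activity_cutoff, "activity_cutoff")
  assert_prob(selectivity_cutoff, "selectivity_cutoff")
  stopifnot(n_select >= 1)
  structure(list(
    activity_cutoff = activity_cutoff,
    selectivity_cutoff = selectivity_cutoff,
    n_select = as.integer(n_select),
    selectivity_mode = match.arg(selectivity_mode)
  ), class = "funnel_config")
}

profile_prob <- function(profile, threshold) {
  col <- paste0("p_", format(threshold, scientific = FALSE))
  if (!col %in% names(profile)) {
    stop("profile is missing the ", threshold, " nM threshold", call. = FALSE)
  }
  profile[[col]]
}

#' Activity score of a target-receptor profile
#'
#' The probability that a molecule is active on D4 at or below 10 nM:
#' the 10 nM entry of its D4 threshold profile.
#'
#' @param profile_d4 profile rows from [predict_profiles()] for receptor
#'   D4 (data.frame with `p_*` columns).
#' @return numeric vector of probabilities.
#' @export
activity_score <- function(profile_d4) {
  if (!all(profile_d4$receptor == "D4")) {
    stop("activity_score expects D4 profiles", call. = FALSE)
  }
  profile_prob(profile_d4, 10)
}

#' Selectivity score from four receptor profiles
#'
#' Composes the probability of a molecule being active at 10 nM on D4 and
#' simultaneously not active at 1000 nM on each of D2, D3 and D5 (two
#' orders of magnitude). In product mode (default):
#' `P_D4,10 * (1 - P_D2,1000) * (1 - P_D3,1000) * (1 - P_D5,1000)`;
#' in min mode the product over off-targets is replaced by the single
#' worst `1 - P_r,1000`.
#'
#' @param profiles named list with elements `D2`, `D3`, `D4`, `D5`, each a
#'   profile data.frame from [predict_profiles()] (rows aligned across
#'   receptors).
#' @param mode `"product"` or `"min"`.
#' @return numeric vector of selectivity scores in [0, 1].
#' @export
selectivity_score <- function(profiles, mode = c("product", "min")) {
  mode <- match.arg(mode)
  if (!all(RECEPTORS %in% names(profiles))) {
    stop("profiles must contain all of D2, D3, D4, D5", call. = FALSE)
  }
  p_on <- profile_prob(profiles$D4, 10)
  off <- vapply(c("D2", "D3", "D5"),
                function(r) profile_prob(profiles[[r]], 1000),
                numeric(length(p_on)))
  if (is.null(dim(off))) off <- matrix(off, nrow = 1)
  assert_prob(p_on, "P_D4,10nM")
  assert_prob(off, "off-target P_1000nM")
  if (mode == "product") {
    p_on * apply(1 - off, 1, prod)
  } else {
    p_on * apply(1 - off, 1, min)
  }
}

#' Score a library through the screening funnel
#'
#' Predicts all four receptor profiles (streamed in batches of
#' `batch_size` molecules, so memory stays bounded on large decks),
#' composes activity and selectivity scores, applies the funnel cutoffs
#' and ranks: activity passers first, ordered by selectivity score
#' descending (ties: activity score descending, then `mol_id`); molecules
#' failing the activity cutoff follow, ordered by activity score
#' descending (ties: `mol_id`). Ranks are unique and contiguous.
#'
#' @param models named list of four `receptor_model`s (`D2`...`D5`), all
#'   sharing one featurization config.
#' @param features feature matrix of the library to screen.
#' @param funnel a [funnel_config()].
#' @param batch_size molecules scored per batch (default 5000).
#' @return data.frame of class `screening_scores`: `mol_id`,
#'   `activity_score`, `selectivity_score`, `passed_activity`,
#'   `passed_selectivity`, `rank`, in rank order.
#' @export
screen_library <- function(models, features, funnel = funnel_config(),
                           batch_size = 5000L) {
  stopifnot(all(RECEPTORS %in% names(models)))
  hashes <- vapply(models[RECEPTORS], `[[`, character(1),
                   "feature_config_hash")
  if (length(unique(hashes)) != 1) {
    stop("the four models were trained on different featurization configs")
  }
  if (nrow(features) == 0) stop("empty library", call. = FALSE)
  n <- nrow(features)
  starts <- seq(1, n, by = batch_size)
  act <- sel <- numeric(n)
  ids <- character(n)
  for (s in starts) {
    idx <- s:min(s + batch_size - 1, n)
    Xb <- features[idx, , drop = FALSE]
    attr(Xb, "config_hash") <- attr(features, "config_hash")
    prof <- lapply(models[RECEPTORS], predict_profiles, features = Xb)
    act[idx] <- activity_score(prof$D4)
    sel[idx] <- selectivity_score(prof, mode = funnel$selectivity_mode)
    ids[idx] <- prof$D4$mol_id
  }
  passed_a <- act >= funnel$activity_cutoff
  passed_s <- sel > funnel$selectivity_cutoff
  ord <- order(!passed_a,                       # passers first
               ifelse(passed_a, -sel, 0),       # passers: selectivity desc
               -act,                            # then activity desc
               ids, method = "radix")
  out <- data.frame(
    mol_id = ids, activity_score = act, selectivity_score = sel,
    passed_activity = passed_a, passed_selectivity = passed_s,
    stringsAsFactors = FALSE
  )[ord, ]
  out$rank <- seq_len(n)
  rownames(out) <- NULL
  class(out) <- c("screening_scores", "data.frame")
  out
}

#' Select acquisition candidates from ranked scores
#'
#' Two-tier priority mirroring "preference" in the funnel: first, in rank
#' order, molecules passing both the activity and selectivity cutoffs;
#' then, if fewer than `n_select`, molecules passing activity alone, until
#' `n_select` ids are collected (fewer if the funnel passes fewer).
#'
#' @param scores ranked scores from [screen_library()].
#' @param funnel a [funnel_config()].
#' @return character vector of up to `n_select` molecule ids.
#' @export
select_candidates <- function(scores, funnel = funnel_config()) {
  s <- scores[order(scores$rank), ]
  tier1 <- s$mol_id[s$passed_activity & s$passed_selectivity]
  tier2 <- s$mol_id[s$passed_activity & !s$passed_selectivity]
  utils::head(c(tier1, tier2), funnel$n_select)
}
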