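# Funnel performance against synthetic ground truth: hit rates at the two
# single-point inhibition tiers (>50% and >85% at 10 uM), the fraction of
# truly 100-fold D4-selective molecules among the selected, and enrichment
# of each over the screened library's base rate.

truth_for <- function(ids, truth) {
  i <- match(ids, truth$mol_id)
  if (anyNA(i)) {
    stop("ids missing from truth manifest: ",
         paste(utils::head(ids[is.na(i)], 5), collapse = ", "),
         call. = FALSE)
  }
  truth[i, , drop = FALSE]
}

#' Evaluate a candidate selection against ground truth
#'
#' Hit definitions come from the one-site occupancy model at 10 uM
#' ([percent_inhibition()] of the true D4 IC50): a molecule is a tier-1
#' hit above 50% inhibition and a tier-2 hit above 85%. Selectivity is
#' ground truth: at least a 100-fold margin (two orders of magnitude) of
#' every off-target IC50 over the D4 IC50. Base rates are computed over
#' the screened deck (the rows of `scores`), so enrichment factors are
#' selected-set rate divided by deck rate. An empty selection reports all
#' rates and enrichments as `NA` (an explicit undefined sentinel, never
#' 0).
#'
#' @param scores ranked deck scores from [screen_library()].
#' @param selected_ids candidate ids from [select_candidates()].
#' @param truth ground-truth manifest (see [make_benchmark()]); must cover
#'   every screened and selected id.
#' @return list of class `funnel_report`: counts `n_screened`,
#'   `n_passed_activity`, `n_passed_both`, `n_selected`; rates
#'   `hit_rate_50`, `hit_rate_85`, `selective_rate`; deck base rates
#'   `base_rate_50`, `base_rate_85`, `base_rate_selective`; enrichments
#'   `enrichment_factor_50`, `enrichment_factor_85`,
#'   `enrichment_selective`.
#' @export
evaluate_selection <- function(scores, selected_ids, truth) {
  deck <- truth_for(scores$mol_id, truth)
  base_50 <- mean(deck$percent_inhibition_10uM > 50)
  base_85 <- mean(deck$percent_inhibition_10uM > 85)
  base_sel <- mean(deck$is_selective_100x)
  n_sel <- length(selected_ids)
  if (n_sel == 0) {
    rate_50 <- rate_85 <- rate_sel <- NA_real_
  } else {
    st <- truth_for(selected_ids, truth)
    rate_50 <- mean(st$percent_inhibition_10uM > 50)
    rate_85 <- mean(st$percent_inhibition_10uM > 85)
    rate_sel <- mean(st$is_selective_100x)
  }
  enr <- function(rate, base) {
    if (is.na(rate)) NA_real_ else if (base == 0) Inf else rate / base
  }
  structure(list(
    n_screened = nrow(scores),
    n_passed_activity = sum(scores$passed_activity),
    n_passed_both = sum(scores$passed_activity & scores$passed_selectivity),
    n_selected = n_sel,
    hit_rate_50 = rate_50, hit_rate_85 = rate_85,
    selective_rate = rate_sel,
    base_rate_50 = base_50, base_rate_85 = base_85,
    base_rate_selective = base_sel,
    enrichment_factor_50 = enr(rate_50, base_50),
    enrichment_factor_85 = enr(rate_85, base_85),
    enrichment_selective = enr(rate_sel, base_sel)
  ), class = "funnel_report")
}

#' @export
print.funnel_report <- function(x, ...) {
  cat(sprintf(
    paste0("<funnel_report> screened %d | passed activity %d | passed ",
           "both %d | selected %d\n"),
    x$n_screened, x$n_passed_activity, x$n_passed_both, x$n_selected))
  fmt <- function(v) if (is.na(v)) "undefined" else sprintf("%.3f", v)
  cat("  hit rate >50%:", fmt(x$hit_rate_50),
      "(deck", sprintf("%.3f", x$base_rate_50),
      "-> enrichment", fmt(x$enrichment_factor_50), ")\n")
  cat("  hit rate >85%:", fmt(x$hit_rate_85),
      "(deck", sprintf("%.3f", x$base_rate_85),
      "-> enrichment", fmt(x$enrichment_factor_85), ")\n")
  cat("  100-fold selective:", fmt(x$selective_rate),
      "(deck", sprintf("%.4f", x$base_rate_selective),
      "-> enrichment", fmt(x$enrichment_selective), ")\n")
  invisible(x)
}

#' Per-off-target selectivity breakdown of a selection
#'
#' For each off-target receptor, the fraction of selected molecules with
#' a true >= 100-fold potency margin over that receptor alone, next to
#' the fraction selective against all three at once. Single-off-target
#' fractions always contain the all-three fraction (set containment); the
#' gap between them is the funnel's characteristic failure mode --
#' molecules selective against one subtype but not all.
#'
#' @param selected_ids candidate ids.
#' @param truth ground-truth manifest.
#' @return data.frame with rows `D2`, `D3`, `D5`, `all`, columns
#'   `receptor` and `fraction_selective`.
#' @export
per_offtarget_selectivity_breakdown <- function(selected_ids, truth) {
  st <- truth_for(selected_ids, truth)
  frac <- function(off_col) {
    mean(st$pIC50_D4 - st[[off_col]] >= 2)
  }
  data.frame(
    receptor = c("D2", "D3", "D5", "all"),
    fraction_selective = c(frac("pIC50_D2"), frac("pIC50_D3"),
                           frac("pIC50_D5"), mean(st$is_selective_100x)),
    stringsAsFactors = FALSE
  )
}

#' Null distribution of enrichment under random selection
#'
#' Draws `n_rep` uniformly random selections of `n_select` deck molecules
#' and returns the mean and standard error of their tier-1 enrichment
#' factor; under random selection the expectation is 1.
#'
#' @param scores deck scores (defines the deck).
#' @param truth ground-truth manifest.
#' @param n_select selection size (default 89).
#' @param n_rep resamples (default 1000).
#' @param seed integer seed.
#' @return list: `mean_enrichment_50`, `se`, `n_rep`.
#' @export
random_selection_null <- function(scores, truth, n_select = 89L,
                                  n_rep = 1000L, seed = 1) {
  deck <- truth_for(scores$mol_id, truth)
  base_50 <- mean(deck$percent_inhibition_10uM > 50)
  hits <- deck$percent_inhibition_10uM > 50
  enr <- with_seed(seed, vapply(seq_len(n_rep), function(i) {
    mean(hits[sample.int(nrow(deck), n_select)]) / base_50
  }, numeric(1)))
  list(mean_enrichment_50 = mean(enr),
       se = stats::sd(enr) / sqrt(n_rep),
       n_rep = n_rep)
}
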