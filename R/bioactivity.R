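# Converting confirmatory potency measurements (IC50 / Ki / Kd in nM, with
# censoring qualifiers) into per-threshold active/inactive/unknown labels.
# The five activity thresholds are fixed: a molecule is "active at t" when
# its potency is at or below t nM (inclusive boundary).

#' The five activity thresholds, in nM
#' @return numeric vector `c(1, 10, 100, 1000, 10000)`.
#' @export
activity_thresholds <- function() c(1, 10, 100, 1000, 10000)

RECEPTORS <- c("D2", "D3", "D4", "D5")
ENDPOINTS <- c("Ki", "Kd", "IC50")  # in precedence order
QUALIFIERS <- c("eq", "lt", "gt")

validate_measurements <- function(m) {
  need <- c("mol_id", "receptor", "endpoint", "value_nM", "qualifier")
  stopifnot(is.data.frame(m), all(need %in% names(m)))
  if (nrow(m) == 0) stop("empty measurement set", call. = FALSE)
  if (!all(m$receptor %in% RECEPTORS)) stop("receptor must be one of D2/D3/D4/D5")
  if (!all(m$endpoint %in% ENDPOINTS)) stop("endpoint must be IC50, Ki or Kd")
  if (!all(m$qualifier %in% QUALIFIERS)) stop("qualifier must be eq, lt or gt")
  if (!all(is.finite(m$value_nM) & m$value_nM > 0)) stop("value_nM must be > 0")
  invisible(m)
}

#' Consensus potency for one molecule x receptor
#'
#' Aggregates replicate confirmatory measurements into a single value and
#' censoring qualifier. Endpoint precedence is Ki > Kd > IC50 (binding
#' constants are assay-concentration independent); within the chosen
#' endpoint, uncensored (`eq`) values are combined by geometric mean
#' (potencies are log-normal by convention). If only censored values exist,
#' the least informative consistent bound is returned: the largest
#' upper bound as `lt`, or the smallest lower bound as `gt`; when both
#' directions are present and consistent (every `gt` bound below every
#' `lt` bound) the `lt` side is kept, since the labels it licenses are
#' implied by the upper bound alone. A `lt` bound at or below a `gt` bound
#' is contradictory and sets `conflict = TRUE` (all labels then `unknown`).
#'
#' @param measurements data.frame of measurements for a single
#'   `mol_id` x `receptor` (columns `mol_id`, `receptor`, `endpoint`,
#'   `value_nM`, `qualifier`).
#' @return list: `mol_id`, `receptor`, `endpoint`, `value_nM`, `qualifier`,
#'   `conflict`.
#' @export
consensus_potency <- function(measurements) {
  validate_measurements(measurements)
  if (length(unique(measurements$mol_id)) != 1 ||
      length(unique(measurements$receptor)) != 1) {
    stop("consensus_potency expects one mol_id x receptor group")
  }
  ep <- ENDPOINTS[min(match(measurements$endpoint, ENDPOINTS))]
  m <- measurements[measurements$endpoint == ep, ]
  out <- list(mol_id = m$mol_id[1], receptor = m$receptor[1], endpoint = ep,
              value_nM = NA_real_, qualifier = NA_character_,
              conflict = FALSE)
  eqv <- m$value_nM[m$qualifier == "eq"]
  if (length(eqv)) {
    # round the geometric mean to 12 significant digits so that exact
    # replicate values sit exactly on label-threshold boundaries
    out$value_nM <- if (length(eqv) == 1) eqv else {
      signif(exp(mean(log(eqv))), 12)
    }
    out$qualifier <- "eq"
    return(out)
  }
  lt <- m$value_nM[m$qualifier == "lt"]
  gt <- m$value_nM[m$qualifier == "gt"]
  if (length(lt) && length(gt) && min(lt) <= max(gt)) {
    out$conflict <- TRUE
    return(out)
  }
  if (length(lt)) {
    out$value_nM <- max(lt)
    out$qualifier <- "lt"
  } else {
    out$value_nM <- min(gt)
    out$qualifier <- "gt"
  }
  out
}

#' Threshold labels from one consensus potency
#'
#' Expands a consensus (value, qualifier) into the five per-threshold
#' labels. With `qualifier = "eq"` and potency p: `active` at every
#' threshold t with p <= t (boundary inclusive: p equal to t is active),
#' `inactive` where p > t. A lower bound (`gt` v) licenses `inactive` at
#' t <= v and leaves t > v `unknown`; an upper bound (`lt` v) licenses
#' `active` at t >= v and leaves t < v `unknown`. A conflicted consensus
#' yields all `unknown`.
#'
#' @param consensus list as returned by [consensus_potency()].
#' @param thresholds the activity thresholds (nM); fixed default
#'   [activity_thresholds()].
#' @return data.frame: `mol_id`, `receptor`, `threshold_nM`, `label`
#'   (one row per threshold).
#' @export
build_threshold_labels <- function(consensus,
                                   thresholds = activity_thresholds()) {
  t <- thresholds
  lab <- if (isTRUE(consensus$conflict)) {
    rep("unknown", length(t))
  } else if (consensus$qualifier == "eq") {
    ifelse(consensus$value_nM <= t, "active", "inactive")
  } else if (consensus$qualifier == "gt") {
    ifelse(t <= consensus$value_nM, "inactive", "unknown")
  } else if (consensus$qualifier == "lt") {
    ifelse(t >= consensus$value_nM, "active", "unknown")
  } else {
    stop("qualifier must be eq, lt or gt")
  }
  data.frame(
    mol_id = consensus$mol_id, receptor = consensus$receptor,
    threshold_nM = t, label = lab, stringsAsFactors = FALSE
  )
}

#' Threshold labels for a whole measurement table
#'
#' Groups a long measurement table by molecule and receptor, forms the
#' consensus per group ([consensus_potency()]) and expands it into labels
#' ([build_threshold_labels()]). Every molecule x receptor pair present in
#' the table yields exactly five rows; receptors without measurements for
#' a molecule are simply absent (training masks them as unknown).
#'
#' @param measurements long data.frame of [consensus_potency()] columns.
#' @return long data.frame of labels.
#' @export
threshold_labels <- function(measurements) {
  validate_measurements(measurements)
  key <- paste(measurements$mol_id, measurements$receptor, sep = "\r")
  parts <- split(measurements, key)
  out <- lapply(parts, function(g) build_threshold_labels(consensus_potency(g)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Read a measurement CSV
#'
#' Columns: `mol_id`, `receptor` (D2|D3|D4|D5), `endpoint` (IC50|Ki|Kd),
#' `value_nM`, `qualifier` (eq|lt|gt).
#' @param path CSV file.
#' @return validated data.frame.
#' @export
read_measurements <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_measurements(m)
  m
}

#' Write a measurement table as CSV (deterministic byte output)
#' @param measurements validated measurement data.frame.
#' @param path output file.
#' @export
write_measurements <- function(measurements, path) {
  validate_measurements(measurements)
  lines <- c(
    "mol_id,receptor,endpoint,value_nM,qualifier",
    sprintf("%s,%s,%s,%.10g,%s", measurements$mol_id, measurements$receptor,
            measurements$endpoint, measurements$value_nM,
            measurements$qualifier)
  )
  writeLines(lines, path)
  invisible(path)
}
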