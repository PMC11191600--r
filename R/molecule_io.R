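# Reading, standardizing and writing molecule libraries. Parsing and
# canonicalization are delegated to OpenBabel via ChemmineR/ChemmineOB;
# this module owns the standardization policy: keep the largest covalent
# fragment, neutralize simple protonation states, canonicalize, preserve
# stereo annotations as given. Tautomers are left alone.

# Batch SMILES -> canonical SMILES through OpenBabel. Returns a character
# vector aligned with the input; entries that failed to parse are NA.
canonicalize_smiles <- function(smiles, neutralize = TRUE) {
  n <- length(smiles)
  if (n == 0) return(character(0))
  inp <- paste(paste(smiles, seq_len(n)), collapse = "\n")
  args <- list("SMI", "CAN", inp)
  if (neutralize) {
    args$options <- data.frame(names = "neutralize", args = "",
                               stringsAsFactors = FALSE)
  }
  out <- tryCatch(
    do.call(ChemmineOB::convertFormat, args),
    error = function(e) ""
  )
  res <- rep(NA_character_, n)
  lines <- strsplit(out, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(lines)]
  if (length(lines)) {
    parts <- strsplit(lines, "[\t ]+")
    can <- vapply(parts, `[`, character(1), 1)
    idx <- suppressWarnings(as.integer(vapply(parts, function(p) {
      if (length(p) >= 2) p[length(p)] else NA_character_
    }, character(1))))
    ok <- !is.na(idx) & nzchar(can) & !is.na(can)
    res[idx[ok]] <- can[ok]
  }
  res
}

# Heavy-atom counts of a batch of (valid) SMILES.
heavy_atom_counts <- function(smiles) {
  sdf <- smiles_to_sdfset(smiles)
  ab <- ChemmineR::atomblock(sdf)
  if (!is.list(ab)) ab <- list(ab)
  vapply(ab, nrow, integer(1))
}

# Largest covalent fragment of each raw SMILES (ties broken by the
# lexicographically smallest canonical string, for determinism).
largest_fragment <- function(smiles) {
  has_salt <- grepl(".", smiles, fixed = TRUE)
  out <- smiles
  for (i in which(has_salt)) {
    frs <- strsplit(smiles[i], ".", fixed = TRUE)[[1]]
    frs <- frs[nzchar(frs)]
    can <- canonicalize_smiles(frs, neutralize = FALSE)
    if (all(is.na(can))) next
    ok <- which(!is.na(can))
    sizes <- heavy_atom_counts(can[ok])
    best <- ok[sizes == max(sizes)]
    out[i] <- frs[best[order(can[best])[1]]]
  }
  out
}

#' Standardize molecule records
#'
#' Applies the package's standardization policy to each record: keep the
#' largest covalent fragment (salt stripping), neutralize simple
#' protonation states where valence allows, and emit the canonical
#' structure string. Stereo annotations present in the input are preserved;
#' tautomers are not canonicalized. The operation is idempotent: feeding
#' canonical output back in returns it unchanged.
#'
#' @param records data.frame with columns `mol_id` and `smiles_raw` (a
#'   `smiles_canonical` column, if present, is recomputed).
#' @return the records with `smiles_canonical` filled in.
#' @export
standardize <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("mol_id", "smiles_raw") %in% names(records)))
  frag <- largest_fragment(records$smiles_raw)
  can <- canonicalize_smiles(frag, neutralize = TRUE)
  if (anyNA(can)) {
    stop("unparseable structure for mol_id: ",
         paste(records$mol_id[is.na(can)], collapse = ", "), call. = FALSE)
  }
  records$smiles_canonical <- can
  records
}

# Id collision policy: first occurrence keeps the id, later ones get
# "-2", "-3", ... appended. Never silently drops data.
disambiguate_ids <- function(ids) {
  dup <- duplicated(ids)
  if (any(dup)) {
    occ <- stats::ave(seq_along(ids), ids, FUN = seq_along)
    ids[occ > 1] <- paste0(ids[occ > 1], "-", occ[occ > 1])
    message(sum(dup), " duplicate mol_id(s) disambiguated with -k suffixes")
    # suffixing can itself collide with a pre-existing id; recurse until fixed
    if (anyDuplicated(ids)) ids <- disambiguate_ids(ids)
  }
  ids
}

#' Load a molecule library
#'
#' Reads a library from a SMILES line file, a CSV, or an SDF, standardizes
#' every entry ([standardize()]), skips and counts unparseable entries,
#' and disambiguates duplicate ids with `-2`, `-3`, ... suffixes.
#' Duplicate *structures* under distinct ids are retained (screening decks
#' legitimately contain them); a dedup report of repeated canonical
#' structures is attached as attribute `"dedup_report"`.
#'
#' @param path input file.
#' @param format one of `"smiles-list"` (one SMILES per line, optional
#'   second whitespace-separated token used as id), `"csv"` (required
#'   columns `mol_id`, `smiles`), `"sdf"` (id from `sdf_id_field`, default
#'   the title line).
#' @param source_tag free-text provenance tag stored on every record.
#' @param sdf_id_field SDF data field holding the id; `NULL` = title line.
#' @return data.frame of records: `mol_id`, `smiles_raw`,
#'   `smiles_canonical`, `source_tag`; attributes `n_skipped` and
#'   `dedup_report`.
#' @export
load_library <- function(path, format = c("csv", "smiles-list", "sdf"),
                         source_tag = basename(path), sdf_id_field = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (format == "csv") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (!all(c("mol_id", "smiles") %in% names(df))) {
      stop("CSV library must have columns mol_id, smiles", call. = FALSE)
    }
    ids <- as.character(df$mol_id)
    raw <- as.character(df$smiles)
  } else if (format == "smiles-list") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    toks <- strsplit(trimws(lines), "[\t ]+")
    raw <- vapply(toks, `[`, character(1), 1)
    ids <- vapply(seq_along(toks), function(i) {
      if (length(toks[[i]]) >= 2) toks[[i]][2] else sprintf("M%06d", i)
    }, character(1))
  } else {
    sdf <- ChemmineR::read.SDFset(path)
    ids <- if (is.null(sdf_id_field)) {
      ChemmineR::sdfid(sdf)
    } else {
      vapply(ChemmineR::datablock(sdf), function(d) {
        if (sdf_id_field %in% names(d)) d[[sdf_id_field]] else NA_character_
      }, character(1))
    }
    ids[is.na(ids) | !nzchar(ids)] <-
      sprintf("M%06d", which(is.na(ids) | !nzchar(ids)))
    raw <- unname(vapply(
      as.character(suppressWarnings(ChemmineR::sdf2smiles(sdf))),
      function(s) strsplit(s, "[\t ]")[[1]][1], character(1)
    ))
  }
  frag <- largest_fragment(raw)
  can <- canonicalize_smiles(frag, neutralize = TRUE)
  bad <- is.na(can)
  if (all(bad)) stop("zero parseable molecules in ", path, call. = FALSE)
  if (any(bad)) {
    message(sum(bad), " unparseable entr",
            if (sum(bad) == 1) "y" else "ies", " skipped: ",
            paste(utils::head(ids[bad], 10), collapse = ", "))
  }
  rec <- data.frame(
    mol_id = disambiguate_ids(ids[!bad]),
    smiles_raw = raw[!bad],
    smiles_canonical = can[!bad],
    source_tag = source_tag,
    stringsAsFactors = FALSE
  )
  tab <- table(rec$smiles_canonical)
  dupes <- tab[tab > 1]
  attr(rec, "dedup_report") <- data.frame(
    smiles_canonical = names(dupes),
    n_copies = as.integer(dupes),
    stringsAsFactors = FALSE
  )
  attr(rec, "n_skipped") <- sum(bad)
  rec
}

#' Write a molecule library as CSV
#'
#' Companion to [load_library()] (CSV dialect): a round trip preserves the
#' multiset of canonical structure strings exactly.
#'
#' @param records data.frame from [load_library()] / [standardize()].
#' @param path output file.
#' @export
write_library <- function(records, path) {
  stopifnot(nrow(records) > 0)
  lines <- c("mol_id,smiles",
             paste(records$mol_id, records$smiles_canonical, sep = ","))
  writeLines(lines, path)
  invisible(path)
}

#' Write screening scores as CSV
#'
#' Fixed header `mol_id,activity_score,selectivity_score,passed_activity,`
#' `passed_selectivity,rank`; rows in rank order; byte-identical output for
#' identical input (numbers are formatted with 10 significant digits,
#' independent of locale or options).
#'
#' @param scores data.frame from [screen_library()].
#' @param path output file.
#' @export
write_scores <- function(scores, path) {
  stopifnot(is.data.frame(scores), nrow(scores) > 0)
  need <- c("mol_id", "activity_score", "selectivity_score",
            "passed_activity", "passed_selectivity", "rank")
  stopifnot(all(need %in% names(scores)))
  s <- scores[order(scores$rank), need]
  lines <- c(
    paste(need, collapse = ","),
    sprintf("%s,%.10g,%.10g,%s,%s,%d",
            s$mol_id, s$activity_score, s$selectivity_score,
            ifelse(s$passed_activity, "TRUE", "FALSE"),
            ifelse(s$passed_selectivity, "TRUE", "FALSE"),
            as.integer(s$rank))
  )
  writeLines(lines, path)
  invisible(path)
}
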