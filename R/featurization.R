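#' Featurization settings for hashed circular fingerprints
#'
#' All models in the pipeline consume fixed-length binary substructure
#' fingerprints: every atom-centred environment up to `radius` bonds is
#' assigned a deterministic 32-bit identifier (FNV-1a over the atom's
#' element, heavy-atom degree, formal charge, bond-order sum and ring flag,
#' then iteratively over sorted neighbour environments), and identifiers are
#' folded modulo `n_bits`. Identical canonical structures always map to
#' identical bit vectors, across sessions and machines.
#'
#' @param radius integer, number of bond-expansion iterations around each
#'   atom (default 2, i.e. environments of diameter 4).
#' @param n_bits integer, folded fingerprint length (default 2048).
#' @param descriptor_hook optional function(smiles) returning a fixed-length
#'   numeric block appended to the fingerprint; off by default. The hook's
#'   declared `hook_id` attribute participates in the config hash.
#' @return object of class `fp_config` with a `config_hash` identifying the
#'   settings; feature matrices and trained models carry this hash and
#'   refuse to mix.
#' @examples
#' cfg <- fp_config()
#' cfg$config_hash
#' @export
fp_config <- function(radius = 2L, n_bits = 2048L, descriptor_hook = NULL) {
  stopifnot(radius >= 0, n_bits >= 8)
  hook_id <- if (is.null(descriptor_hook)) "none" else {
    id <- attr(descriptor_hook, "hook_id")
    if (is.null(id)) stop("descriptor_hook must carry a 'hook_id' attribute")
    id
  }
  cfg <- list(
    radius = as.integer(radius),
    n_bits = as.integer(n_bits),
    descriptor_hook = descriptor_hook,
    config_hash = hash_string(
      paste("circular-fp", radius, n_bits, hook_id, sep = "|")
    )
  )
  class(cfg) <- "fp_config"
  cfg
}

# Convert SMILES to an SDFset in chunks (ChemmineOB round-trips through
# OpenBabel; chunking keeps peak memory flat on large decks).
smiles_to_sdfset <- function(smiles, chunk = 2000L) {
  parts <- split(smiles, ceiling(seq_along(smiles) / chunk))
  sets <- lapply(parts, function(p) {
    suppressWarnings(ChemmineR::smiles2sdf(p))
  })
  out <- sets[[1]]
  if (length(sets) > 1) for (i in 2:length(sets)) {
    out <- suppressWarnings(c(out, sets[[i]]))
  }
  ChemmineR::cid(out) <- paste0("m", seq_along(out))
  out
}

# Core of the fingerprint: per-atom environment identifiers on a flat
# library graph. Returns a list of per-iteration identifier vectors
# (iteration 0 .. radius), each aligned with graph$mol.
atom_environment_ids <- function(graph, radius) {
  ids <- hash_rows(cbind(
    graph$z, graph$degree, graph$charge + 16, graph$valsum, graph$in_ring
  ))
  out <- vector("list", radius + 1)
  out[[1]] <- ids
  if (radius == 0 || length(graph$e_from) == 0) {
    if (radius > 0) for (i in 2:(radius + 1)) {
      out[[i]] <- hash_rows(cbind(i - 1, out[[i - 1]]))
    }
    return(out)
  }
  nb_center <- c(graph$e_from, graph$e_to)
  nb_other <- c(graph$e_to, graph$e_from)
  nb_order <- c(graph$e_order, graph$e_order)
  n_tot <- length(graph$mol)
  for (it in seq_len(radius)) {
    prev <- out[[it]]
    h <- hash_rows(cbind(it, prev))
    # absorb neighbour (bond order, environment id) pairs in canonical order
    o <- order(nb_center, nb_order, prev[nb_other])
    ctr <- nb_center[o]
    ord_s <- nb_order[o]
    nid_s <- prev[nb_other[o]]
    rank <- sequence(rle(ctr)$lengths)
    for (r in seq_len(max(rank))) {
      sel <- rank == r
      a <- ctr[sel]
      h[a] <- fnv_step(fnv_step(h[a], ord_s[sel]), nid_s[sel])
    }
    out[[it + 1]] <- h
  }
  out
}

#' Fingerprint a molecule library
#'
#' Maps standardized molecules to a sparse binary feature matrix. The whole
#' library is processed as one block-diagonal molecular graph, so cost is a
#' few vectorized passes rather than a per-molecule loop; row i of the
#' result equals [featurize_molecule()] applied to record i.
#'
#' @param records data.frame of molecule records with columns `mol_id` and
#'   `smiles_canonical` (see [load_library()]).
#' @param config an [fp_config()].
#' @return a `Matrix::dgCMatrix` of 0/1 values, one row per record
#'   (rownames = `mol_id`), `config$n_bits` columns, with attribute
#'   `config_hash`.
#' @export
featurize_library <- function(records, config = fp_config()) {
  stopifnot(is.data.frame(records),
            all(c("mol_id", "smiles_canonical") %in% names(records)))
  if (nrow(records) == 0) stop("empty record set")
  bad <- !vapply(records$smiles_canonical,
                 function(s) is.character(s) && nzchar(s), logical(1))
  if (any(bad)) {
    stop("unparseable records: ",
         paste(records$mol_id[bad], collapse = ", "))
  }
  sdf <- tryCatch(
    smiles_to_sdfset(records$smiles_canonical),
    error = function(e) stop("failed to parse library for featurization: ",
                             conditionMessage(e), call. = FALSE)
  )
  if (length(sdf) != nrow(records)) {
    stop("featurization parse failure; molecule count mismatch")
  }
  graph <- library_graph(sdf, records$smiles_canonical)
  env_ids <- atom_environment_ids(graph, config$radius)
  mol <- rep(graph$mol, length(env_ids))
  bit <- unlist(env_ids, use.names = FALSE) %% config$n_bits
  key <- mol * config$n_bits + bit
  keep <- !duplicated(key)
  X <- Matrix::sparseMatrix(
    i = mol[keep], j = bit[keep] + 1, x = 1,
    dims = c(nrow(records), config$n_bits)
  )
  rownames(X) <- records$mol_id
  if (!is.null(config$descriptor_hook)) {
    extra <- t(vapply(records$smiles_canonical, config$descriptor_hook,
                      config$descriptor_hook(records$smiles_canonical[1])))
    X <- cbind(X, Matrix::Matrix(extra, sparse = TRUE))
  }
  attr(X, "config_hash") <- config$config_hash
  X
}

#' Fingerprint a single molecule
#'
#' @param smiles_canonical canonical structure string (see [standardize()]).
#' @param config an [fp_config()].
#' @param mol_id optional identifier carried into the result.
#' @return list with `mol_id`, `bits` (numeric 0/1 vector of length
#'   `n_bits`), `n_bits` and `config_hash`.
#' @export
featurize_molecule <- function(smiles_canonical, config = fp_config(),
                               mol_id = NA_character_) {
  X <- featurize_library(
    data.frame(mol_id = "x", smiles_canonical = smiles_canonical,
               stringsAsFactors = FALSE),
    config
  )
  list(mol_id = mol_id, bits = as.numeric(X[1, ]), n_bits = ncol(X),
       config_hash = config$config_hash)
}

#' Jaccard/Tanimoto similarity of two binary fingerprints
#' @param a,b numeric 0/1 vectors of equal length.
#' @return similarity in [0, 1].
#' @export
tanimoto <- function(a, b) {
  stopifnot(length(a) == length(b))
  inter <- sum(a > 0 & b > 0)
  uni <- sum(a > 0 | b > 0)
  if (uni == 0) return(0)
  inter / uni
}

#' Ring-framework scaffold keys
#'
#' Reduces each molecule to its ring systems plus linkers (iteratively
#' deleting terminal heavy atoms) and hashes the remaining atoms' circular
#' environments into an order-independent key. Molecules sharing a core
#' framework share a key; fully acyclic molecules all map to `"acyclic"`.
#' Used by scaffold-aware train/validation splitting.
#'
#' @param records data.frame with `mol_id`, `smiles_canonical`.
#' @return character vector of keys, one per record.
#' @export
scaffold_key <- function(records) {
  sdf <- smiles_to_sdfset(records$smiles_canonical)
  graph <- library_graph(sdf, records$smiles_canonical)
  n_tot <- length(graph$mol)
  alive <- rep(TRUE, n_tot)
  ef <- graph$e_from
  et <- graph$e_to
  eo <- graph$e_order
  repeat {
    deg <- tabulate(c(ef, et), nbins = n_tot)
    term <- alive & deg <= 1
    if (!any(term)) break
    alive[term] <- FALSE
    keep <- !(term[ef] | term[et])
    ef <- ef[keep]; et <- et[keep]; eo <- eo[keep]
  }
  keys <- rep("acyclic", length(sdf))
  has_core <- tapply(alive, graph$mol, any)
  core_mols <- which(as.logical(has_core))
  if (length(core_mols)) {
    sub <- list(
      mol = graph$mol[alive],
      z = graph$z[alive],
      charge = graph$charge[alive],
      degree = tabulate(c(ef, et), nbins = n_tot)[alive],
      valsum = {
        vs <- rep(0, n_tot)
        if (length(ef)) {
          s <- tapply(c(eo, eo), c(ef, et), sum)
          vs[as.integer(names(s))] <- s
        }
        vs[alive]
      },
      in_ring = graph$in_ring[alive],
      e_from = match(ef, which(alive)),
      e_to = match(et, which(alive)),
      e_order = eo
    )
    ids <- atom_environment_ids(sub, 2L)
    final <- ids[[3]]
    for (m in core_mols) {
      v <- sort(final[sub$mol == m])
      keys[m] <- paste0("fw-", hex32(hash_rows(matrix(v, nrow = 1))))
    }
  }
  keys
}

#' Persist a feature matrix as a sparse on-disk table
#'
#' Writes `<stem>.mtx` (MatrixMarket sparse coordinates) plus a
#' `<stem>.json` sidecar manifest holding the molecule ids and the
#' featurization config hash; [read_feature_matrix()] refuses to load a
#' table whose manifest hash differs from the requested config.
#'
#' @param X matrix from [featurize_library()].
#' @param stem file path without extension.
#' @return invisibly, the two file paths.
#' @export
write_feature_matrix <- function(X, stem) {
  mtx <- paste0(stem, ".mtx")
  man <- paste0(stem, ".json")
  Matrix::writeMM(methods::as(X, "CsparseMatrix"), mtx)
  jsonlite::write_json(
    list(mol_id = rownames(X), n_bits = ncol(X),
         config_hash = attr(X, "config_hash")),
    man, auto_unbox = TRUE
  )
  invisible(c(mtx, man))
}

#' @rdname write_feature_matrix
#' @param config the [fp_config()] the caller expects the table to match.
#' @export
read_feature_matrix <- function(stem, config) {
  man <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  if (!identical(man$config_hash, config$config_hash)) {
    stop("feature table config hash ", man$config_hash,
         " does not match requested config ", config$config_hash)
  }
  X <- methods::as(Matrix::readMM(paste0(stem, ".mtx")) * 1, "CsparseMatrix")
  rownames(X) <- man$mol_id
  attr(X, "config_hash") <- man$config_hash
  X
}
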