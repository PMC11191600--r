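# Internal arithmetic and graph helpers shared by featurization and the
# synthetic-library generator. All hashing is plain 32-bit FNV-1a computed
# with exact modular arithmetic on doubles, so fingerprints are identical
# across sessions, platforms and process restarts.

FNV_OFFSET <- 2166136261
FNV_PRIME <- 16777619
TWO32 <- 2^32

# XOR of two vectors of non-negative doubles < 2^32, via 16-bit halves
# (R's bitwXor only covers signed 32-bit integers).
xor32 <- function(a, b) {
  ah <- a %/% 65536L
  al <- a %% 65536L
  bh <- b %/% 65536L
  bl <- b %% 65536L
  bitwXor(as.integer(ah), as.integer(bh)) * 65536 +
    bitwXor(as.integer(al), as.integer(bl))
}

# (a * FNV_PRIME) mod 2^32 without exceeding 2^53: split a into 16-bit halves.
mulprime32 <- function(a) {
  ah <- a %/% 65536
  al <- a %% 65536
  (((ah * FNV_PRIME) %% 65536) * 65536 + al * FNV_PRIME) %% TWO32
}

# One FNV-1a absorption step, vectorized over h and v.
fnv_step <- function(h, v) mulprime32(xor32(h, v %% TWO32))

#' Hash rows of a non-negative integer matrix to 32-bit values
#'
#' Applies FNV-1a column by column, so each row's hash depends on the whole
#' tuple and on column order. Used for atom-environment identifiers,
#' featurization config hashes and scaffold keys.
#'
#' @param m numeric matrix (or vector, treated as one column) of
#'   non-negative values below 2^32.
#' @return numeric vector of hashes in [0, 2^32).
#' @keywords internal
hash_rows <- function(m) {
  if (is.null(dim(m))) m <- matrix(m, ncol = 1)
  h <- rep(FNV_OFFSET, nrow(m))
  for (j in seq_len(ncol(m))) h <- fnv_step(h, m[, j])
  h
}

# Render a hash value (double in [0, 2^32)) as 8 hex digits.
hex32 <- function(h) {
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

# Deterministic hash of a character scalar (config hashes, scaffold ids).
hash_string <- function(s) {
  v <- utf8ToInt(s)
  h <- FNV_OFFSET
  for (x in v) h <- fnv_step(h, x)
  hex32(h)
}

# Atomic numbers for symbols OpenBabel emits in small-molecule SDFs; unknown
# symbols fall back to a deterministic hash-derived code so featurization
# never aborts on exotic elements.
ELEMENT_Z <- c(
  H = 1, B = 5, C = 6, N = 7, O = 8, F = 9, Na = 11, Mg = 12, Al = 13,
  Si = 14, P = 15, S = 16, Cl = 17, K = 19, Ca = 20, Zn = 30, Se = 34,
  Br = 35, I = 53
)

# Element and formal charge of a one-atom SMILES like "C", "O", "[Na+]",
# "[NH4+]"; NULL if the string is not a single-atom SMILES.
parse_single_atom <- function(smi) {
  m <- regmatches(
    smi,
    regexec("^\\[?([A-Z][a-z]?)H?[0-9]*([+-]?)([0-9]*)\\]?$", smi)
  )[[1]]
  if (length(m) == 0) return(NULL)
  chg <- if (m[3] == "") 0 else if (m[4] == "") 1 else as.integer(m[4])
  if (m[3] == "-") chg <- -chg
  list(element = m[2], charge = chg)
}

element_to_z <- function(sym) {
  z <- unname(ELEMENT_Z[sym])
  miss <- is.na(z)
  if (any(miss)) {
    z[miss] <- vapply(sym[miss], function(s) {
      200 + strtoi(substr(hash_string(s), 1, 4), 16L) %% 1000
    }, numeric(1))
  }
  z
}

#' Flatten an SDFset into one block-diagonal molecular graph
#'
#' Atoms of all molecules are concatenated with global indices; edges never
#' cross molecules, so whole-library fingerprinting is a handful of
#' vectorized passes instead of a per-molecule loop. Ring membership is
#' computed once for the union graph: an atom is in a ring iff it has an
#' incident non-bridge edge.
#'
#' @param sdfset a `ChemmineR::SDFset`.
#' @return list with per-atom vectors `mol`, `z`, `charge`, `degree`,
#'   `valsum` (sum of bond orders), `in_ring`, the per-molecule atom counts
#'   `n_atoms`, and edge vectors `e_from`, `e_to`, `e_order` (each edge once).
#' @keywords internal
library_graph <- function(sdfset, smiles = NULL) {
  k <- length(sdfset)
  abs_ <- ChemmineR::atomblock(sdfset)
  bbs <- ChemmineR::bondblock(sdfset)
  if (k == 1 && !is.list(abs_)) {
    abs_ <- list(abs_)
    bbs <- list(bbs)
  }
  n_atoms <- vapply(abs_, nrow, integer(1))
  offset <- c(0L, cumsum(n_atoms))[seq_len(k)]
  per_mol <- lapply(seq_len(k), function(i) {
    a <- abs_[[i]]
    sym <- sub("_.*$", "", rownames(a))
    code <- if ("C6" %in% colnames(a)) a[, "C6"] else rep(0, nrow(a))
    # ChemmineR cannot represent single-atom molecules (the atom row is
    # mangled); recover element and charge from the canonical SMILES
    if (nrow(a) == 1 && !grepl("^[A-Za-z]", sym[1])) {
      sa <- if (!is.null(smiles)) parse_single_atom(smiles[i]) else NULL
      if (is.null(sa)) {
        sym <- "C"
        code <- 0
      } else {
        sym <- sa$element
        code <- if (sa$charge == 0) 0 else 4 - sa$charge
      }
    }
    list(sym = sym, code = code)
  })
  sym <- unlist(lapply(per_mol, `[[`, "sym"), use.names = FALSE)
  chg_code <- unlist(lapply(per_mol, `[[`, "code"), use.names = FALSE)
  charge <- ifelse(chg_code == 0, 0, 4 - chg_code)

  e_from <- e_to <- e_order <- vector("list", k)
  for (i in seq_len(k)) {
    bb <- bbs[[i]]
    if (is.null(bb) || length(bb) < 3) next  # single-atom molecule
    if (is.null(dim(bb))) bb <- matrix(bb, nrow = 1)
    if (nrow(bb) == 0 || ncol(bb) < 3) next
    e_from[[i]] <- bb[, 1] + offset[i]
    e_to[[i]] <- bb[, 2] + offset[i]
    e_order[[i]] <- bb[, 3]
  }
  e_from <- as.numeric(unlist(e_from, use.names = FALSE))
  e_to <- as.numeric(unlist(e_to, use.names = FALSE))
  e_order <- as.numeric(unlist(e_order, use.names = FALSE))

  n_tot <- sum(n_atoms)
  degree <- tabulate(c(e_from, e_to), nbins = n_tot)
  valsum <- rep(0, n_tot)
  if (length(e_from)) {
    vs <- tapply(c(e_order, e_order), c(e_from, e_to), sum)
    valsum[as.integer(names(vs))] <- vs
  }

  in_ring <- rep(FALSE, n_tot)
  if (length(e_from)) {
    g <- igraph::make_graph(rbind(e_from, e_to), n = n_tot, directed = FALSE)
    br <- igraph::bridges(g)
    cyc <- rep(TRUE, length(e_from))
    cyc[as.integer(br)] <- FALSE
    ring_atoms <- unique(c(e_from[cyc], e_to[cyc]))
    in_ring[ring_atoms] <- TRUE
  }

  list(
    mol = rep(seq_len(k), n_atoms),
    z = element_to_z(sym),
    charge = charge,
    degree = degree,
    valsum = valsum,
    in_ring = in_ring,
    n_atoms = n_atoms,
    e_from = e_from,
    e_to = e_to,
    e_order = e_order
  )
}

# Stop unless all values are finite probabilities.
assert_prob <- function(x, what) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stop(what, " must be probabilities in [0, 1]", call. = FALSE)
  }
  invisible(x)
}

# Run an expression with a locally seeded RNG, restoring the caller's
# RNG state afterwards so library code never perturbs user randomness.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
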