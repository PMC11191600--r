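# Synthetic chemistry benchmark: assembles drug-like molecules from a
# fragment grammar (amine-bearing cores with north acyl/aryl and south
# benzylic/heteroaryl caps, including the piperidine-amide and
# 2,7-diazaspiro[3.5]nonane chemotypes), assigns each molecule true
# per-receptor potencies from a latent linear structure-activity map with
# a shared cross-receptor component, and simulates noisy, censored
# confirmatory assay measurements. Every downstream stage of the funnel is
# thereby testable against exact ground truth.

# Aryl building blocks, written for attachment at the first ring atom.
# Ring-closure digits 8/9 never collide with the cores' digits 1/2.
default_aryls <- function() {
  subs <- c("F", "Cl", "C", "OC")
  c(
    "c8ccccc8",
    sprintf("c8ccc(%s)cc8", subs),   # para
    sprintf("c8cccc(%s)c8", subs),   # meta
    sprintf("c8c(%s)cccc8", subs),   # ortho
    "c8ccco8",                       # furan-2-yl
    "c8cccs8",                       # thiophen-2-yl
    "c8ccncc8",                      # pyridin-4-yl
    "c8cccnc8",                      # pyridin-3-yl
    "c8ccc9ccccc9c8",                # naphthalen-2-yl
    "c8ccc9OCOc9c8"                  # benzodioxol-5-yl
  )
}

#' Fragment grammar for synthetic library assembly
#'
#' Cores are SMILES templates with `{N}` (north) and `{S}` (south)
#' attachment markers; caps are fragments written from their attachment
#' atom. The default grammar crosses eight saturated amine cores (two
#' orientations of the 2,7-diazaspiro[3.5]nonane motif, 3- and
#' 4-substituted piperidines, pyrrolidine, azepane, azetidine, piperazine)
#' with acyl / sulfonyl / benzylic north caps and benzylic / arylethyl /
#' aryl south caps over a substituted (hetero)aryl set -- about 30,000
#' enumerable products. Every core and cap is parse-checked at
#' construction.
#'
#' @param cores character vector of core templates (must contain `{N}` and
#'   `{S}`).
#' @param north_caps,south_caps character vectors of cap fragments; the
#'   empty string (south only) means an unsubstituted attachment.
#' @return object of class `fragment_grammar`.
#' @export
fragment_grammar <- function(cores = NULL, north_caps = NULL,
                             south_caps = NULL) {
  ar <- default_aryls()
  # attachment markers always follow an atom, so a cap's first atom is the
  # attachment atom
  if (is.null(cores)) cores <- c(
    "C1CC2(CN(C2){N})CCN1{S}",    # 2,7-diazaspiro[3.5]nonane, N-acyl azetidine
    "C1CC2(CN(C2){S})CCN1{N}",    # same spiro core, caps swapped
    "C1CC({S})CCN1{N}",           # 4-substituted piperidine
    "C1C({S})CCCN1{N}",           # 3-substituted piperidine
    "C1C({S})CCN1{N}",            # 3-substituted pyrrolidine
    "C1CC({S})CCCN1{N}",          # 4-substituted azepane
    "C1C({S})CN1{N}",             # 3-substituted azetidine
    "C1CN({S})CCN1{N}"            # piperazine
  )
  if (is.null(north_caps)) north_caps <- c(
    paste0("C(=O)", ar),          # aryl amides
    paste0("S(=O)(=O)", ar),      # aryl sulfonamides
    paste0("C", ar),              # benzylic
    "C(C)=O", "C(=O)CC", "C(=O)C8CC8", "S(C)(=O)=O", "C"
  )
  if (is.null(south_caps)) south_caps <- c(
    paste0("C", ar),              # benzylic
    paste0("CC", ar),             # arylethyl
    ar,                           # direct aryl
    "", "C", "CC", "CC8CC8"
  )
  stopifnot(length(cores) >= 1, length(north_caps) >= 1,
            length(south_caps) >= 1,
            all(grepl("{N}", cores, fixed = TRUE)),
            all(grepl("{S}", cores, fixed = TRUE)))
  g <- structure(list(cores = cores, north_caps = north_caps,
                      south_caps = south_caps),
                 class = "fragment_grammar")
  validate_grammar(g)
  g
}

assemble_product <- function(core, north, south) {
  s <- sub("{N}", north, core, fixed = TRUE)
  if (nzchar(south)) {
    sub("{S}", south, s, fixed = TRUE)
  } else {
    gsub("{S}", "", sub("({S})", "", s, fixed = TRUE), fixed = TRUE)
  }
}

# Parse-check every core against the first caps and every cap against the
# first core; names the offending fragment on failure.
validate_grammar <- function(g) {
  check <- function(smiles, what, frags) {
    ok <- !is.na(canonicalize_smiles(smiles))
    if (!all(ok)) {
      stop("unparseable grammar product from ", what, ": ",
           paste(frags[!ok], collapse = ", "), call. = FALSE)
    }
  }
  check(vapply(g$cores, assemble_product,
               north = g$north_caps[1], south = g$south_caps[1],
               character(1)), "core", g$cores)
  check(vapply(g$north_caps, function(nc)
    assemble_product(g$cores[1], nc, g$south_caps[1]), character(1)),
    "north cap", g$north_caps)
  check(vapply(g$south_caps, function(sc)
    assemble_product(g$cores[1], g$north_caps[1], sc), character(1)),
    "south cap", g$south_caps)
  invisible(g)
}

#' Generate a synthetic molecule library
#'
#' Samples the core x north x south grid uniformly without replacement (a
#' seeded permutation of the full grid, assembled and standardized in
#' chunks; products whose canonical structures collide are dropped, so the
#' library is unique by structure). If the grid is exhausted before `n`
#' unique molecules are found, further molecules are drawn with
#' replacement under substituent perturbation (chain homologation of the
#' south cap), which always yields parseable products. Deterministic per
#' seed.
#'
#' @param grammar a [fragment_grammar()].
#' @param n number of molecules.
#' @param seed integer seed.
#' @return molecule records data.frame (`mol_id` = `SYN-000001`, ...,
#'   `smiles_raw` the assembled string, `smiles_canonical`, `source_tag`).
#' @export
generate_library <- function(grammar, n, seed = 17) {
  stopifnot(inherits(grammar, "fragment_grammar"), n >= 1)
  nc <- length(grammar$cores)
  nn <- length(grammar$north_caps)
  ns <- length(grammar$south_caps)
  total <- nc * nn * ns
  perm <- with_seed(seed, sample.int(total))
  seen <- character(0)
  raw_out <- can_out <- character(0)
  pos <- 1L
  round <- 0L
  chunk <- max(1000L, min(5000L, n))
  while (length(can_out) < n) {
    if (pos > total) {
      round <- round + 1L
      pos <- 1L
      if (round > 25L) stop("grammar capacity exhausted", call. = FALSE)
    }
    idx <- perm[pos:min(pos + chunk - 1L, total)]
    pos <- pos + length(idx)
    ci <- ((idx - 1L) %% nc) + 1L
    ni <- (((idx - 1L) %/% nc) %% nn) + 1L
    si <- ((idx - 1L) %/% (nc * nn)) + 1L
    south <- grammar$south_caps[si]
    if (round > 0L) south <- paste0(strrep("C", round), south)
    raw <- mapply(assemble_product, grammar$cores[ci],
                  grammar$north_caps[ni], south, USE.NAMES = FALSE)
    can <- canonicalize_smiles(raw, neutralize = TRUE)
    if (anyNA(can)) {
      bad <- which(is.na(can))[1]
      stop("unparseable grammar product from core '",
           grammar$cores[ci[bad]], "' + north '",
           grammar$north_caps[ni[bad]], "' + south '", south[bad], "'",
           call. = FALSE)
    }
    fresh <- !(can %in% seen) & !duplicated(can)
    seen <- c(seen, can[fresh])
    raw_out <- c(raw_out, raw[fresh])
    can_out <- c(can_out, can[fresh])
  }
  data.frame(
    mol_id = sprintf("SYN-%06d", seq_len(n)),
    smiles_raw = raw_out[seq_len(n)],
    smiles_canonical = can_out[seq_len(n)],
    source_tag = "synthetic-grammar",
    stringsAsFactors = FALSE
  )
}

#' Latent structure-activity map with cross-receptor correlation
#'
#' Ground-truth potency is linear in fingerprint bits. For each molecule
#' with bit vector x (per-molecule normalized projections
#' z_w = x.w / sqrt(|x|), so each z is a unit-variance structural score):
#'
#'   pIC50_r = bias_r + shared_scale * z_shared + private_scale_r * z_r
#'
#' The shared component drives all four receptors and makes potencies
#' correlated across receptors; D4's private component (scale
#' `d4_private_scale`) is what true selectivity can come from, so the
#' fraction of molecules that are >= 100-fold D4-selective is small and
#' exactly computable from the stored truth. Defaults (bias 3.1, shared
#' 2.4, D4 private 1.2, off-target private 1.0, noise 0.3 log units) give
#' a realistic potency spread of about 2.8 log units, roughly a quarter of
#' the deck active at 10 uM on D4, and a 1-3 percent 100-fold-selective
#' fraction.
#'
#' @param config [fp_config()] the weights are drawn for.
#' @param bias named per-receptor intercepts (pIC50 units).
#' @param shared_component_scale,d4_private_scale,offtarget_private_scale
#'   standard deviations (log10 units) of the structural components.
#' @param noise_sd assay noise (log10 units) used by the simulator.
#' @param seed integer; weight vectors are drawn deterministically.
#' @return object of class `latent_potency_model`.
#' @export
latent_potency_model <- function(config = fp_config(),
                                 bias = c(D2 = 3.1, D3 = 3.1,
                                          D4 = 3.1, D5 = 3.1),
                                 shared_component_scale = 2.4,
                                 d4_private_scale = 1.2,
                                 offtarget_private_scale = 1.0,
                                 noise_sd = 0.3, seed = 17) {
  stopifnot(all(RECEPTORS %in% names(bias)))
  nb <- config$n_bits
  w <- with_seed(seed, list(
    shared = stats::rnorm(nb),
    D2 = stats::rnorm(nb), D3 = stats::rnorm(nb),
    D4 = stats::rnorm(nb), D5 = stats::rnorm(nb)
  ))
  structure(list(
    weights = w, bias = bias[RECEPTORS],
    shared_component_scale = shared_component_scale,
    d4_private_scale = d4_private_scale,
    offtarget_private_scale = offtarget_private_scale,
    noise_sd = noise_sd, seed = seed,
    config_hash = config$config_hash, n_bits = nb,
    center = c(shared = 0, D2 = 0, D3 = 0, D4 = 0, D5 = 0),
    comp_scale = c(shared = 1, D2 = 1, D3 = 1, D4 = 1, D5 = 1)
  ), class = "latent_potency_model")
}

# Raw (uncalibrated) structural components, one column per weight vector.
latent_components <- function(features, model) {
  norm <- sqrt(pmax(1, Matrix::rowSums(features != 0)))
  Wm <- cbind(model$weights$shared, model$weights$D2, model$weights$D3,
              model$weights$D4, model$weights$D5)
  Z <- as.matrix(features %*% Wm) / norm
  colnames(Z) <- c("shared", RECEPTORS)
  Z
}

#' Standardize a latent model's components against a reference library
#'
#' Molecules assembled from a shared fragment pool have correlated bits,
#' so the raw projections are neither centred nor unit-variance across a
#' library. Calibration stores, per component, the reference library's
#' mean and standard deviation in the model; potency assignment then uses
#' the standardized components, so the stated component scales are exact
#' log10 standard deviations over that chemical space. The calibrated
#' model remains a deterministic per-molecule function.
#'
#' @param model a [latent_potency_model()].
#' @param features feature matrix of the reference library.
#' @return the model with `center` and `comp_scale` filled in.
#' @export
calibrate_latent_model <- function(model, features) {
  Z <- latent_components(features, model)
  model$center <- colMeans(Z)
  s <- apply(Z, 2, stats::sd)
  s[!is.finite(s) | s == 0] <- 1
  model$comp_scale <- s
  model
}

#' True per-receptor potencies for featurized molecules
#'
#' @param features feature matrix ([featurize_library()]) built with the
#'   config the model was drawn for.
#' @param model a [latent_potency_model()].
#' @return matrix of true pIC50 (-log10 molar IC50), one row per molecule
#'   (rownames = mol_id), columns `D2`, `D3`, `D4`, `D5`.
#' @export
assign_latent_potency <- function(features, model) {
  stopifnot(inherits(model, "latent_potency_model"))
  if (ncol(features) != model$n_bits) {
    stop("feature width ", ncol(features), " does not match the latent ",
         "model's ", model$n_bits, " bits", call. = FALSE)
  }
  if (!is.null(attr(features, "config_hash")) &&
      !identical(attr(features, "config_hash"), model$config_hash)) {
    stop("feature config hash does not match the latent model", call. = FALSE)
  }
  Z <- latent_components(features, model)
  Z <- sweep(sweep(Z, 2, model$center), 2, model$comp_scale, "/")
  scale_r <- c(D2 = model$offtarget_private_scale,
               D3 = model$offtarget_private_scale,
               D4 = model$d4_private_scale,
               D5 = model$offtarget_private_scale)
  out <- vapply(RECEPTORS, function(r) {
    model$bias[[r]] + model$shared_component_scale * Z[, "shared"] +
      scale_r[[r]] * Z[, r]
  }, numeric(nrow(features)))
  if (is.null(dim(out))) out <- matrix(out, nrow = 1,
                                       dimnames = list(NULL, RECEPTORS))
  rownames(out) <- rownames(features)
  out
}

#' Simulate one confirmatory assay measurement
#'
#' Measured log-potency is the true value plus Normal(0, `noise_sd`) (log10
#' units); the resulting IC50 in nM is censored to `censor_range`: below
#' the lower limit it is reported as (`lt`, lo), above the upper limit as
#' (`gt`, hi), otherwise as an uncensored `eq` value.
#'
#' @param true_pIC50 numeric vector of true -log10 molar potencies.
#' @param mol_id,receptor identifiers, recycled along `true_pIC50`.
#' @param noise_sd assay noise in log10 units.
#' @param censor_range c(lo, hi) reporting window in nM.
#' @param seed integer seed.
#' @return measurement data.frame (endpoint `IC50`).
#' @export
simulate_confirmatory_assay <- function(true_pIC50, mol_id, receptor,
                                        noise_sd = 0.3,
                                        censor_range = c(1, 10000),
                                        seed = 1) {
  stopifnot(length(censor_range) == 2, all(censor_range > 0),
            censor_range[1] < censor_range[2])
  n <- length(true_pIC50)
  noise <- if (noise_sd > 0) {
    with_seed(seed, stats::rnorm(n, sd = noise_sd))
  } else rep(0, n)
  meas_nM <- 10^(9 - (true_pIC50 + noise))
  qualifier <- ifelse(meas_nM < censor_range[1], "lt",
                      ifelse(meas_nM > censor_range[2], "gt", "eq"))
  value <- pmin(pmax(meas_nM, censor_range[1]), censor_range[2])
  data.frame(
    mol_id = rep_len(mol_id, n), receptor = rep_len(receptor, n),
    endpoint = "IC50", value_nM = value, qualifier = qualifier,
    stringsAsFactors = FALSE
  )
}

#' One-site percent inhibition at a ligand concentration
#'
#' Fractional receptor occupancy by a competing ligand at concentration
#' `conc_nM` with half-maximal concentration `ic50_nM`:
#' `100 * conc / (conc + ic50)`. By construction equals 50 when the ligand
#' is at its IC50 and approaches 100 as the IC50 vanishes.
#'
#' @param ic50_nM half-maximal inhibitory concentration (nM).
#' @param conc_nM ligand concentration (nM); default 10 uM, the
#'   single-point screening concentration.
#' @return percent inhibition in [0, 100].
#' @export
percent_inhibition <- function(ic50_nM, conc_nM = 10000) {
  if (any(ic50_nM <= 0) || any(conc_nM <= 0)) {
    stop("ic50_nM and conc_nM must be positive", call. = FALSE)
  }
  100 * conc_nM / (conc_nM + ic50_nM)
}

#' Cheng-Prusoff conversion of IC50 to Ki
#'
#' For competitive inhibition in a radioligand displacement assay:
#' `Ki = IC50 / (1 + [L] / Kd)` with radioligand concentration `[L]` and
#' its dissociation constant `Kd`. Always below the IC50 for positive
#' ligand concentration.
#'
#' @param ic50_nM measured IC50 (nM).
#' @param ligand_conc_nM radioligand concentration (nM).
#' @param ligand_kd_nM radioligand Kd (nM).
#' @return Ki in nM.
#' @export
cheng_prusoff_ki <- function(ic50_nM, ligand_conc_nM, ligand_kd_nM) {
  if (any(ic50_nM <= 0) || any(ligand_conc_nM < 0) ||
      any(ligand_kd_nM <= 0)) {
    stop("concentrations must be positive", call. = FALSE)
  }
  ic50_nM / (1 + ligand_conc_nM / ligand_kd_nM)
}

#' Benchmark configuration
#'
#' @param n_train labeled molecules with simulated confirmatory
#'   measurements on all four receptors (default 2000).
#' @param n_screen screening-deck size, structurally disjoint from the
#'   training set (default 20000).
#' @param grammar a [fragment_grammar()].
#' @param fp an [fp_config()].
#' @param noise_sd,censor_range assay simulation settings (defaults 0.3
#'   log units and the 1--10,000 nM span of the label thresholds).
#' @param latent named list of overrides passed to
#'   [latent_potency_model()].
#' @return list of class `benchmark_config`.
#' @export
benchmark_config <- function(n_train = 2000L, n_screen = 20000L,
                             grammar = NULL, fp = fp_config(),
                             noise_sd = 0.3, censor_range = c(1, 10000),
                             latent = list()) {
  structure(list(
    n_train = as.integer(n_train), n_screen = as.integer(n_screen),
    grammar = grammar, fp = fp, noise_sd = noise_sd,
    censor_range = censor_range, latent = latent
  ), class = "benchmark_config")
}

#' Build the synthetic screening benchmark
#'
#' Generates `n_train + n_screen` unique molecules, featurizes them,
#' draws the latent potency model, assigns true per-receptor potencies,
#' simulates censored confirmatory measurements for the training
#' molecules (all four receptors), and assembles the ground-truth
#' manifest. Training structures and deck structures are disjoint by
#' construction (the library is unique by canonical structure). Fully
#' reproducible per seed.
#'
#' @param config a [benchmark_config()].
#' @param seed integer master seed (default 17); the latent model and the
#'   assay simulation derive their own sub-seeds from it.
#' @return list of class `screening_benchmark`: `records_train`,
#'   `records_screen`, `features_train`, `features_screen`,
#'   `measurements`, `truth` (mol_id, split, pIC50_D2..D5,
#'   percent_inhibition_10uM, min_fold_selectivity, is_selective_100x),
#'   `latent_model`, `fp`, `seed`.
#' @export
make_benchmark <- function(config = benchmark_config(), seed = 17) {
  grammar <- if (is.null(config$grammar)) fragment_grammar() else
    config$grammar
  n_total <- config$n_train + config$n_screen
  capacity <- length(grammar$cores) * length(grammar$north_caps) *
    length(grammar$south_caps) * 26
  if (n_total > capacity) {
    stop("requested ", n_total, " molecules exceed grammar capacity")
  }
  records <- generate_library(grammar, n_total, seed = seed)
  X <- featurize_library(records, config$fp)
  latent_args <- utils::modifyList(
    list(config = config$fp, noise_sd = config$noise_sd, seed = seed + 1L),
    config$latent
  )
  latent <- do.call(latent_potency_model, latent_args)
  latent <- calibrate_latent_model(latent, X)
  truth_p <- assign_latent_potency(X, latent)

  i_train <- seq_len(config$n_train)
  i_screen <- config$n_train + seq_len(config$n_screen)
  meas <- do.call(rbind, lapply(seq_along(RECEPTORS), function(k) {
    r <- RECEPTORS[k]
    simulate_confirmatory_assay(
      truth_p[i_train, r], records$mol_id[i_train], r,
      noise_sd = config$noise_sd, censor_range = config$censor_range,
      seed = seed + 1L + k
    )
  }))
  rownames(meas) <- NULL

  off <- truth_p[, c("D2", "D3", "D5"), drop = FALSE]
  margin <- truth_p[, "D4"] - apply(off, 1, max)
  truth <- data.frame(
    mol_id = records$mol_id,
    split = c(rep("train", config$n_train), rep("screen", config$n_screen)),
    pIC50_D2 = truth_p[, "D2"], pIC50_D3 = truth_p[, "D3"],
    pIC50_D4 = truth_p[, "D4"], pIC50_D5 = truth_p[, "D5"],
    percent_inhibition_10uM =
      percent_inhibition(10^(9 - truth_p[, "D4"]), 10000),
    min_fold_selectivity = 10^margin,
    is_selective_100x = margin >= 2,
    stringsAsFactors = FALSE
  )
  rownames(truth) <- NULL

  subset_features <- function(i) {
    Xi <- X[i, , drop = FALSE]
    attr(Xi, "config_hash") <- attr(X, "config_hash")
    Xi
  }
  structure(list(
    records_train = records[i_train, ],
    records_screen = records[i_screen, ],
    features_train = subset_features(i_train),
    features_screen = subset_features(i_screen),
    measurements = meas,
    truth = truth,
    latent_model = latent,
    fp = config$fp,
    seed = seed
  ), class = "screening_benchmark")
}

#' Write a benchmark's tables to a directory
#'
#' Emits `train_library.csv`, `screen_library.csv` (molecule_io CSV
#' dialect), `measurements.csv` (bioactivity dialect) and
#' `truth_manifest.csv`. Output bytes are identical for identical seeds.
#'
#' @param benchmark a `screening_benchmark`.
#' @param dir output directory (created if missing).
#' @return invisibly, the file paths.
#' @export
write_benchmark <- function(benchmark, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p1 <- file.path(dir, "train_library.csv")
  p2 <- file.path(dir, "screen_library.csv")
  p3 <- file.path(dir, "measurements.csv")
  p4 <- file.path(dir, "truth_manifest.csv")
  write_library(benchmark$records_train, p1)
  write_library(benchmark$records_screen, p2)
  write_measurements(benchmark$measurements, p3)
  tr <- benchmark$truth
  writeLines(c(
    paste0("mol_id,split,pIC50_D2,pIC50_D3,pIC50_D4,pIC50_D5,",
           "percent_inhibition_10uM,min_fold_selectivity,is_selective_100x"),
    sprintf("%s,%s,%.10g,%.10g,%.10g,%.10g,%.10g,%.10g,%s",
            tr$mol_id, tr$split, tr$pIC50_D2, tr$pIC50_D3, tr$pIC50_D4,
            tr$pIC50_D5, tr$percent_inhibition_10uM,
            tr$min_fold_selectivity,
            ifelse(tr$is_selective_100x, "TRUE", "FALSE"))
  ), p4)
  invisible(c(p1, p2, p3, p4))
}
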