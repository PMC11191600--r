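# Shared fixtures, built lazily once per test run, and independent oracles
# used by several files.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# 2 cores x 3 caps x 3 caps = 18 enumerable products.
tiny_grammar <- function() {
  fragment_grammar(
    cores = c("C1CC2(CN(C2){N})CCN1{S}", "C1CC({S})CCN1{N}"),
    north_caps = c("C(=O)c8ccccc8", "C(=O)c8ccc(F)cc8", "Cc8ccccc8"),
    south_caps = c("Cc8ccccc8", "Cc8ccncc8", "C")
  )
}

# ~60 diverse molecules with fingerprints, for property-style loops.
sample_molecules <- function() {
  fixture("sample_molecules", function() {
    lib <- generate_library(fragment_grammar(), 60, seed = 41)
    X <- featurize_library(lib, fp_config())
    list(records = lib, features = X, config = fp_config())
  })
}

# A small but complete benchmark for pipeline tests (cheap: ~500 molecules).
small_benchmark <- function() {
  fixture("small_benchmark", function() {
    make_benchmark(benchmark_config(n_train = 300L, n_screen = 400L),
                   seed = 23)
  })
}

# The default-scale campaign used by the acceptance suite: benchmark at the
# published defaults (2000 train / 20000 deck, seed 17), labels, an 80/20
# split, the four receptor models and the screened deck.
acceptance_campaign <- function() {
  fixture("acceptance_campaign", function() {
    bm <- make_benchmark(benchmark_config(), seed = 17)
    labs <- threshold_labels(bm$measurements)
    sp <- split_dataset(bm$features_train, labs, "random", 0.8, seed = 170)
    models <- lapply(stats::setNames(nm = c("D2", "D3", "D4", "D5")),
                     function(r) {
      train_receptor_model(bm$features_train, labs, r, qsar_hyperparams(),
                           seed = 170, train_ids = sp$train,
                           validation_ids = sp$validation)
    })
    scores <- screen_library(models, bm$features_screen, funnel_config())
    list(benchmark = bm, labels = labs, split = sp, models = models,
         scores = scores)
  })
}

# Independent FNV-1a reimplementation (scalar, explicit byte-free integer
# absorption) used as the featurization oracle; deliberately written
# differently from the package's vectorized version.
oracle_fnv <- function(values) {
  h <- 2166136261
  for (v in values) {
    # xor via binary expansion
    bits_h <- as.integer(intToBits(as.integer(h %% 2^31)))[1:31]
    hi_h <- h %/% 2^31
    bits_v <- as.integer(intToBits(as.integer(v %% 2^31)))[1:31]
    hi_v <- v %/% 2^31
    x <- sum((bits_h != bits_v) * 2^(0:30)) + ((hi_h + hi_v) %% 2) * 2^31
    # multiply by the FNV prime mod 2^32 using 8-bit limbs; the shifted
    # prime is reduced first so every product stays exactly representable
    limbs <- c(x %% 256, (x %/% 256) %% 256, (x %/% 65536) %% 256,
               (x %/% 16777216) %% 256)
    acc <- 0
    for (k in 0:3) {
      shifted_prime <- (16777619 * 256^k) %% 2^32
      acc <- (acc + limbs[k + 1] * shifted_prime) %% 2^32
    }
    h <- acc
  }
  h
}

# Exact isotonic-projection oracle for 5-vectors: enumerate all contiguous
# block partitions, keep those whose block means are nondecreasing, return
# the feasible fit with minimal squared error.
oracle_isotonic <- function(y) {
  n <- length(y)
  best <- NULL
  best_sse <- Inf
  for (mask in 0:(2^(n - 1) - 1)) {
    cuts <- which(bitwAnd(mask, 2^(0:(n - 2))) > 0)
    bounds <- c(0, cuts, n)
    fit <- numeric(n)
    means <- numeric(length(bounds) - 1)
    for (b in seq_len(length(bounds) - 1)) {
      i <- (bounds[b] + 1):bounds[b + 1]
      means[b] <- mean(y[i])
      fit[i] <- means[b]
    }
    if (is.unsorted(means)) next
    sse <- sum((y - fit)^2)
    if (sse < best_sse - 1e-15) {
      best_sse <- sse
      best <- fit
    }
  }
  best
}

# Literal threshold labeler: tests p <= t directly, with censoring
# semantics spelled out case by case.
oracle_labeler <- function(value, qualifier, thresholds) {
  vapply(thresholds, function(t) {
    if (qualifier == "eq") {
      if (value <= t) "active" else "inactive"
    } else if (qualifier == "gt") {
      # true potency exceeds `value`: anything at or below t <= value is
      # ruled out; above the bound we cannot tell
      if (t <= value) "inactive" else "unknown"
    } else {
      # true potency is below `value`: active wherever t >= value
      if (t >= value) "active" else "unknown"
    }
  }, character(1))
}

# A handcrafted receptor model whose activity profile is a known function
# of fingerprint bit `bit`: hidden unit = that bit, task logits =
# base + slope * bit.
toy_model <- function(receptor, bit, base, slope, n_bits = 64,
                      hash = "toycfg") {
  par <- list(
    W1 = matrix(0, n_bits, 1), b1 = 0,
    W2 = matrix(slope, 1, 5), b2 = base
  )
  par$W1[bit, 1] <- 1
  structure(list(
    version = "selscreen-model-1", receptor = receptor,
    feature_config_hash = hash, tasks = activity_thresholds(),
    parameters = par, masked_tasks = rep(FALSE, 5),
    masked_prevalence = rep(0.5, 5), calibration = NULL,
    training_manifest = list(seed = 0)
  ), class = "receptor_model")
}

toy_features <- function(bits_on, n = 64, hash = "toycfg") {
  X <- Matrix::sparseMatrix(
    i = rep(seq_along(bits_on), lengths(bits_on)),
    j = unlist(bits_on), x = 1,
    dims = c(length(bits_on), n)
  )
  rownames(X) <- sprintf("T%03d", seq_along(bits_on))
  attr(X, "config_hash") <- hash
  X
}
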