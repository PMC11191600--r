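# Per-receptor multitask threshold classifiers. One model per receptor
# predicts, for every molecule, the five probabilities
# P(potency <= t) for t in {1, 10, 100, 1000, 10000} nM, sharing a hidden
# representation across the five threshold tasks. Unknown labels are
# masked out of the loss; class imbalance is handled by inverse-frequency
# weighting; predicted probability vectors are made coherent (nondecreasing
# in t, as probabilities of nested events must be) by isotonic projection.

#' Hyperparameters of the multitask threshold classifier
#'
#' A small shared-trunk feed-forward network: one ReLU hidden layer over
#' the fingerprint bits, five sigmoid task heads, masked
#' inverse-class-frequency-weighted cross-entropy, full-batch Adam.
#'
#' @param hidden hidden layer width (default 32).
#' @param epochs full-batch Adam steps (default 300).
#' @param lr learning rate (default 0.02).
#' @param l2 L2 penalty on weights (default 1e-5).
#' @return list of hyperparameters.
#' @export
qsar_hyperparams <- function(hidden = 32L, epochs = 300L, lr = 0.02,
                             l2 = 1e-5) {
  stopifnot(hidden >= 1, epochs >= 1, lr > 0, l2 >= 0)
  list(hidden = as.integer(hidden), epochs = as.integer(epochs),
       lr = lr, l2 = l2)
}

# Long label table -> n x 5 matrix in {1, 0, NA}, rows aligned with mol_ids.
label_matrix <- function(labels, receptor, mol_ids) {
  l <- labels[labels$receptor == receptor & labels$mol_id %in% mol_ids, ]
  th <- activity_thresholds()
  Y <- matrix(NA_real_, length(mol_ids), length(th),
              dimnames = list(mol_ids, paste0("p_", th)))
  if (nrow(l)) {
    i <- match(l$mol_id, mol_ids)
    j <- match(l$threshold_nM, th)
    v <- ifelse(l$label == "active", 1,
                ifelse(l$label == "inactive", 0, NA_real_))
    Y[cbind(i, j)] <- v
  }
  Y
}

#' Train/validation split
#'
#' @param features feature matrix from [featurize_library()] (rownames are
#'   molecule ids).
#' @param labels long label table ([threshold_labels()]); only used to
#'   restrict the split to labeled molecules.
#' @param strategy `"random"`, or `"scaffold"` to keep molecules sharing a
#'   ring-framework key ([scaffold_key()]) on the same side.
#' @param fraction fraction of molecules on the training side.
#' @param seed integer; splits are deterministic given the seed.
#' @param records molecule records (required for `strategy = "scaffold"`).
#' @return list with character vectors `train` and `validation`.
#' @export
split_dataset <- function(features, labels, strategy = c("random", "scaffold"),
                          fraction = 0.8, seed = 1, records = NULL) {
  strategy <- match.arg(strategy)
  ids <- intersect(rownames(features), unique(labels$mol_id))
  if (length(ids) < 20) stop("need at least 20 labeled molecules to split")
  n_train <- round(fraction * length(ids))
  if (strategy == "random") {
    train <- with_seed(seed, sample(ids, n_train))
  } else {
    if (is.null(records)) stop("scaffold strategy requires `records`")
    rec <- records[match(ids, records$mol_id), ]
    keys <- scaffold_key(rec)
    groups <- split(ids, keys)
    ord <- with_seed(seed, sample(seq_along(groups)))
    train <- character(0)
    for (g in ord) {
      if (length(train) >= n_train) break
      train <- c(train, groups[[g]])
    }
  }
  list(train = sort(train), validation = sort(setdiff(ids, train)))
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# Forward pass; X sparse or dense, returns list(H, P).
mlp_forward <- function(X, par) {
  H <- as.matrix(X %*% par$W1)
  H <- sweep(H, 2, par$b1, "+")
  H[H < 0] <- 0
  Z <- H %*% par$W2
  Z <- sweep(Z, 2, par$b2, "+")
  list(H = H, P = sigmoid(Z))
}

#' Area under the ROC curve
#'
#' Thin wrapper over `pROC` with fixed direction (higher score = more
#' likely active).
#' @param score numeric predictions.
#' @param label 0/1 vector.
#' @return AUROC, or `NA` if only one class is present.
#' @export
auroc <- function(score, label) {
  ok <- !is.na(label) & !is.na(score)
  y <- label[ok]
  if (length(unique(y)) < 2) return(NA_real_)
  as.numeric(pROC::auc(pROC::roc(
    response = y, predictor = score[ok],
    levels = c(0, 1), direction = "<", quiet = TRUE
  )))
}

#' Train one receptor's multitask threshold classifier
#'
#' Fits the shared-trunk network on all molecules of `features` that carry
#' at least one non-`unknown` label for `receptor`. A task with no actives
#' or no inactives in the training labels is masked: it contributes
#' nothing to the loss and predicts its Laplace-smoothed training
#' prevalence as a constant. Training is deterministic for a fixed seed.
#'
#' @param features feature matrix (training rows are selected by id).
#' @param labels long label table for (at least) this receptor.
#' @param receptor `"D2"`, `"D3"`, `"D4"` or `"D5"`.
#' @param hyperparams [qsar_hyperparams()].
#' @param seed integer seed for weight initialization.
#' @param train_ids,validation_ids optional id vectors (e.g. from
#'   [split_dataset()]); default trains on every labeled molecule.
#'   Validation molecules are excluded from training and per-task
#'   validation AUROCs are recorded in the manifest.
#' @return object of class `receptor_model`.
#' @export
train_receptor_model <- function(features, labels, receptor,
                                 hyperparams = qsar_hyperparams(), seed = 1,
                                 train_ids = NULL, validation_ids = NULL) {
  stopifnot(receptor %in% RECEPTORS)
  all_ids <- intersect(rownames(features),
                       unique(labels$mol_id[labels$receptor == receptor]))
  if (is.null(train_ids)) train_ids <- setdiff(all_ids, validation_ids)
  train_ids <- intersect(train_ids, all_ids)
  Y <- label_matrix(labels, receptor, train_ids)
  known <- !is.na(Y)
  keep <- rowSums(known) > 0
  train_ids <- train_ids[keep]
  Y <- Y[keep, , drop = FALSE]
  known <- known[keep, , drop = FALSE]
  X <- features[train_ids, , drop = FALSE]
  n <- nrow(X); d <- ncol(X); k <- ncol(Y)

  n_pos <- colSums(Y == 1, na.rm = TRUE)
  n_neg <- colSums(Y == 0, na.rm = TRUE)
  masked <- n_pos < 1 | n_neg < 1
  if (all(masked)) stop("all threshold tasks are masked (single-class)")
  if (any(masked)) {
    warning("masked single-class task(s) at thresholds ",
            paste(activity_thresholds()[masked], collapse = ", "), " nM")
  }
  # inverse-class-frequency weights, mean 1 over known labels of each task
  w_pos <- ifelse(masked, 0, (n_pos + n_neg) / (2 * pmax(n_pos, 1)))
  w_neg <- ifelse(masked, 0, (n_pos + n_neg) / (2 * pmax(n_neg, 1)))
  W <- matrix(0, n, k)
  W[known & !is.na(Y) & Y == 1] <- rep(w_pos, each = n)[known & Y == 1]
  W[known & !is.na(Y) & Y == 0] <- rep(w_neg, each = n)[known & Y == 0]
  Ymask <- Y
  Ymask[is.na(Ymask)] <- 0

  hp <- hyperparams
  scale1 <- sqrt(2 / max(1, mean(Matrix::rowSums(X != 0))))
  par <- with_seed(seed, list(
    W1 = matrix(stats::rnorm(d * hp$hidden, sd = scale1), d, hp$hidden),
    b1 = rep(0, hp$hidden),
    W2 = matrix(stats::rnorm(hp$hidden * k, sd = sqrt(1 / hp$hidden)),
                hp$hidden, k),
    b2 = rep(0, k)
  ))
  adam <- list(m = lapply(par, function(p) p * 0),
               v = lapply(par, function(p) p * 0))
  b1m <- 0.9; b2m <- 0.999; eps <- 1e-8
  denom <- sum(W)
  Xt <- Matrix::t(X)
  for (it in seq_len(hp$epochs)) {
    fw <- mlp_forward(X, par)
    dZ <- (fw$P - Ymask) * W / denom
    g <- list(
      W1 = NULL, b1 = NULL,
      W2 = crossprod(fw$H, dZ) + hp$l2 * par$W2,
      b2 = colSums(dZ)
    )
    dH <- dZ %*% t(par$W2)
    dH[fw$H <= 0] <- 0
    g$W1 <- as.matrix(Xt %*% dH) + hp$l2 * par$W1
    g$b1 <- colSums(dH)
    for (p in names(par)) {
      adam$m[[p]] <- b1m * adam$m[[p]] + (1 - b1m) * g[[p]]
      adam$v[[p]] <- b2m * adam$v[[p]] + (1 - b2m) * g[[p]]^2
      mhat <- adam$m[[p]] / (1 - b1m^it)
      vhat <- adam$v[[p]] / (1 - b2m^it)
      par[[p]] <- par[[p]] - hp$lr * mhat / (sqrt(vhat) + eps)
    }
  }

  prevalence <- (n_pos + 0.5) / (n_pos + n_neg + 1)
  model <- structure(list(
    version = "selscreen-model-1",
    receptor = receptor,
    feature_config_hash = attr(features, "config_hash"),
    tasks = activity_thresholds(),
    parameters = par,
    masked_tasks = masked,
    masked_prevalence = prevalence,
    calibration = NULL,
    training_manifest = list(
      seed = seed, n_train = n, hyperparams = hp[c("hidden", "epochs",
                                                   "lr", "l2")],
      n_pos = n_pos, n_neg = n_neg,
      split = if (is.null(validation_ids)) "all-data" else
        sprintf("%d train / %d validation", n, length(validation_ids)),
      validation_auroc = rep(NA_real_, k)
    )
  ), class = "receptor_model")

  if (!is.null(validation_ids)) {
    vids <- intersect(validation_ids, all_ids)
    Yv <- label_matrix(labels, receptor, vids)
    Xv <- features[vids, , drop = FALSE]
    attr(Xv, "config_hash") <- attr(features, "config_hash")
    Pv <- predict_profiles(model, Xv)
    pm <- as.matrix(Pv[, paste0("p_", activity_thresholds())])
    model$training_manifest$validation_auroc <-
      vapply(seq_len(k), function(j) auroc(pm[, j], Yv[, j]), numeric(1))
  }
  model
}

#' @export
print.receptor_model <- function(x, ...) {
  cat("<receptor_model>", x$receptor, "| tasks:",
      paste(x$tasks, collapse = "/"), "nM | features:",
      x$feature_config_hash, "\n")
  va <- x$training_manifest$validation_auroc
  if (!all(is.na(va))) {
    cat("  validation AUROC:",
        paste(sprintf("%s nM %.3f", x$tasks, va), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Make five threshold probabilities coherent
#'
#' The events "active at or below t" are nested in t, so their
#' probabilities must be nondecreasing. Raw per-task outputs are replaced
#' by their least-squares nondecreasing (isotonic, equal-weight,
#' pool-adjacent-violators) projection. The projection is idempotent and
#' leaves already-monotone input untouched.
#'
#' @param raw numeric vector of 5 probabilities ordered by threshold, or a
#'   matrix with 5 columns (row-wise projection).
#' @return object of the same shape, monotone along thresholds.
#' @export
enforce_threshold_monotonicity <- function(raw) {
  assert_prob(raw, "raw threshold probabilities")
  # block averaging can leave float dust a few ulp outside [0,1]; the true
  # projection of probabilities is a probability, so clamp it back
  if (is.matrix(raw)) {
    t(apply(raw, 1, function(r) pmin(1, pmax(0, stats::isoreg(r)$yf))))
  } else {
    pmin(1, pmax(0, stats::isoreg(raw)$yf))
  }
}

#' Predict threshold probability profiles
#'
#' Runs the trained network on a feature matrix and returns, per molecule,
#' the five monotone probabilities P(active at or below t). Refuses to mix
#' featurization configs.
#'
#' @param model a `receptor_model`.
#' @param features feature matrix built with the same [fp_config()] as the
#'   model (checked via the config hash).
#' @return data.frame: `mol_id`, `receptor`, and columns `p_1`, `p_10`,
#'   `p_100`, `p_1000`, `p_10000`.
#' @export
predict_profiles <- function(model, features) {
  stopifnot(inherits(model, "receptor_model"))
  if (!identical(attr(features, "config_hash"), model$feature_config_hash)) {
    stop("feature config hash mismatch: model ", model$feature_config_hash,
         " vs features ", attr(features, "config_hash"), call. = FALSE)
  }
  P <- mlp_forward(features, model$parameters)$P
  if (any(model$masked_tasks)) {
    for (j in which(model$masked_tasks)) P[, j] <- model$masked_prevalence[j]
  }
  P <- enforce_threshold_monotonicity(P)
  out <- data.frame(
    mol_id = rownames(features), receptor = model$receptor,
    stringsAsFactors = FALSE
  )
  colnames(P) <- paste0("p_", activity_thresholds())
  cbind(out, as.data.frame(P))
}

#' Save / load a trained receptor model archive
#'
#' One versioned file holding parameters, the training manifest and the
#' featurization config hash. Predictions after a save/load round trip are
#' bit-identical.
#'
#' @param model a `receptor_model`.
#' @param path archive file path.
#' @export
save_receptor_model <- function(model, path) {
  stopifnot(inherits(model, "receptor_model"))
  saveRDS(model, path, version = 3)
  invisible(path)
}

#' @rdname save_receptor_model
#' @export
load_receptor_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "receptor_model") ||
      !identical(model$version, "selscreen-model-1")) {
    stop("not a selscreen model archive: ", path, call. = FALSE)
  }
  model
}
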