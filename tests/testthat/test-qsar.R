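# Deterministic features for separable-task tests: bit 1 marks actives,
# bit 2 inactives, with a few shared nuisance bits.
separable_fixture <- function(n = 200, seed = 5) {
  set.seed(seed)
  active <- rep(c(TRUE, FALSE), length.out = n)
  bits <- lapply(seq_len(n), function(i) {
    noise <- sample(10:64, 6)
    c(if (active[i]) 1L else 2L, noise)
  })
  X <- toy_features(bits)
  ids <- rownames(X)
  m <- data.frame(
    mol_id = ids, receptor = "D4", endpoint = "IC50",
    value_nM = ifelse(active, 5, 5000), qualifier = "eq",
    stringsAsFactors = FALSE
  )
  list(X = X, labels = threshold_labels(m), ids = ids, active = active)
}

test_that("splits are disjoint, sized, and deterministic per seed", {
  fx <- separable_fixture()
  s1 <- split_dataset(fx$X, fx$labels, "random", 0.8, seed = 3)
  s2 <- split_dataset(fx$X, fx$labels, "random", 0.8, seed = 3)
  s3 <- split_dataset(fx$X, fx$labels, "random", 0.8, seed = 4)
  expect_identical(s1, s2)
  expect_false(identical(s1$train, s3$train))
  expect_length(intersect(s1$train, s1$validation), 0)
  expect_equal(length(s1$train), 160)
  expect_setequal(c(s1$train, s1$validation), fx$ids)
  expect_error(split_dataset(fx$X[1:10, ], fx$labels, "random"),
               "at least 20")
})

test_that("scaffold splits never straddle a ring framework", {
  recs <- rbind(
    data.frame(mol_id = sprintf("benz%02d", 1:12),
               smiles_canonical = sprintf("%sc1ccccc1",
                                          strrep("C", 1:12))),
    data.frame(mol_id = sprintf("naph%02d", 1:12),
               smiles_canonical = sprintf("%sc1ccc2ccccc2c1",
                                          strrep("C", 1:12)))
  )
  X <- featurize_library(recs, fp_config())
  m <- data.frame(mol_id = recs$mol_id, receptor = "D4", endpoint = "IC50",
                  value_nM = 50, qualifier = "eq")
  labs <- threshold_labels(m)
  sp <- split_dataset(X, labs, "scaffold", 0.5, seed = 1, records = recs)
  fam <- function(ids) unique(substr(ids, 1, 4))
  expect_length(intersect(fam(sp$train), fam(sp$validation)), 0)
})

test_that("isotonic enforcement matches the exact partition oracle", {
  expect_equal(enforce_threshold_monotonicity(c(0.1, 0.3, 0.5, 0.7, 0.9)),
               c(0.1, 0.3, 0.5, 0.7, 0.9))
  expect_equal(enforce_threshold_monotonicity(c(0.9, 0.5, 0.7, 0.8, 0.9)),
               c(0.7, 0.7, 0.7, 0.8, 0.9))
  expect_equal(enforce_threshold_monotonicity(c(1, 0, 0, 0, 0)),
               rep(0.2, 5))
  set.seed(2)
  for (i in 1:200) {
    y <- stats::runif(5)
    fit <- enforce_threshold_monotonicity(y)
    expect_equal(fit, oracle_isotonic(y), tolerance = 1e-12)
    expect_equal(enforce_threshold_monotonicity(fit), fit)  # idempotent
  }
  expect_error(enforce_threshold_monotonicity(c(0.1, 1.2, 0.3, 0.4, 0.5)),
               "probabilities")
})

test_that("a linearly separable task reaches validation AUROC 1", {
  fx <- separable_fixture()
  sp <- split_dataset(fx$X, fx$labels, "random", 0.7, seed = 9)
  m <- suppressWarnings(train_receptor_model(
    fx$X, fx$labels, "D4", qsar_hyperparams(), seed = 1,
    train_ids = sp$train, validation_ids = sp$validation))
  au <- m$training_manifest$validation_auroc
  # the 10 nM task separates actives (5 nM) from inactives (5000 nM)
  expect_equal(au[[2]], 1)
})

test_that("training and prediction are deterministic and serializable", {
  fx <- separable_fixture()
  m1 <- suppressWarnings(train_receptor_model(fx$X, fx$labels, "D4",
                                              seed = 42))
  m2 <- suppressWarnings(train_receptor_model(fx$X, fx$labels, "D4",
                                              seed = 42))
  p1 <- predict_profiles(m1, fx$X)
  expect_identical(p1, predict_profiles(m2, fx$X))

  f <- withr::local_tempfile(fileext = ".rds")
  save_receptor_model(m1, f)
  expect_identical(predict_profiles(load_receptor_model(f), fx$X), p1)
  suppressWarnings(
    expect_error(load_receptor_model(withr::local_tempfile(fileext = ".rds")))
  )
})

test_that("profiles are monotone, in [0,1], and batch-invariant", {
  fx <- separable_fixture()
  m <- suppressWarnings(train_receptor_model(fx$X, fx$labels, "D4",
                                             seed = 7))
  p <- predict_profiles(m, fx$X)
  pm <- as.matrix(p[, paste0("p_", activity_thresholds())])
  expect_true(all(pm >= 0 & pm <= 1))
  expect_true(all(apply(pm, 1, function(r) all(diff(r) >= -1e-12))))
  # batch == per-molecule
  one <- fx$X[3, , drop = FALSE]
  attr(one, "config_hash") <- attr(fx$X, "config_hash")
  expect_equal(unname(as.numeric(predict_profiles(m, one)[1, -(1:2)])),
               unname(as.numeric(p[3, -(1:2)])))
  # an active training molecule scores high at permissive thresholds
  act_id <- fx$ids[fx$active][1]
  row <- p[p$mol_id == act_id, ]
  expect_gte(row$p_10000, row$p_1)
  expect_gte(row$p_10000, 0.5)
})

test_that("feature-config mismatches are refused", {
  fx <- separable_fixture()
  m <- suppressWarnings(train_receptor_model(fx$X, fx$labels, "D4",
                                             seed = 1))
  Xbad <- fx$X
  attr(Xbad, "config_hash") <- "other"
  expect_error(predict_profiles(m, Xbad), "config hash mismatch")
})

test_that("single-class tasks are masked with a warning, not fatal", {
  fx <- separable_fixture()
  # every molecule active at 10000 nM (values 5 and 5000 both <= 10000):
  # that task is single-class and must be masked
  expect_warning(
    train_receptor_model(fx$X, fx$labels, "D4", seed = 1),
    "masked"
  )
  m <- suppressWarnings(train_receptor_model(fx$X, fx$labels, "D4", seed = 1))
  expect_true(m$masked_tasks[5])
  p <- predict_profiles(m, fx$X)
  expect_true(all(p$p_10000 >= 0 & p$p_10000 <= 1))
})
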