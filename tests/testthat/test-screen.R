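profile_df <- function(receptor, probs) {
  out <- data.frame(mol_id = sprintf("m%02d", seq_len(nrow(probs))),
                    receptor = receptor, stringsAsFactors = FALSE)
  colnames(probs) <- paste0("p_", activity_thresholds())
  cbind(out, as.data.frame(probs))
}

four_profiles <- function(d4_10, d2_1000, d3_1000, d5_1000) {
  n <- length(d4_10)
  mk <- function(p1000, p10 = p1000 / 2) {
    cbind(p10 / 2, p10, pmin(1, p1000), pmin(1, p1000), pmin(1, p1000))
  }
  list(
    D2 = profile_df("D2", mk(d2_1000)),
    D3 = profile_df("D3", mk(d3_1000)),
    D4 = profile_df("D4", cbind(d4_10 / 2, d4_10, pmin(1, d4_10 + 0.01),
                                pmin(1, d4_10 + 0.02), pmin(1, d4_10 + 0.03))),
    D5 = profile_df("D5", mk(d5_1000))
  )
}

test_that("the activity score is the 10 nM entry of the D4 profile", {
  p <- profile_df("D4", matrix(c(0.1, 0.6, 0.8, 0.9, 0.95), 1))
  expect_equal(activity_score(p), 0.6)
  expect_equal(activity_score(profile_df("D4", matrix(0, 1, 5))), 0)
  expect_equal(activity_score(profile_df("D4", matrix(1, 1, 5))), 1)
  expect_error(activity_score(profile_df("D2", matrix(0, 1, 5))), "D4")
})

test_that("selectivity composes target activity with off-target inactivity", {
  pr <- four_profiles(0.9, 0, 0, 0)
  expect_equal(selectivity_score(pr), 0.9)          # no off-target penalty
  pr2 <- four_profiles(0.9, 1, 0, 0)
  expect_equal(selectivity_score(pr2), 0)           # certain off-target hit
  pr3 <- four_profiles(0.9, 0.5, 0.5, 0.5)
  expect_equal(selectivity_score(pr3), 0.9 * 0.5^3) # = 0.1125
  expect_equal(selectivity_score(pr3, mode = "min"), 0.9 * 0.5)
  expect_error(selectivity_score(pr3[c("D2", "D4")]), "D2, D3, D4, D5")
})

test_that("selectivity is bounded by activity and responds monotonically", {
  set.seed(31)
  for (i in 1:200) {
    a <- stats::runif(1)
    off <- stats::runif(3)
    pr <- four_profiles(a, off[1], off[2], off[3])
    s <- selectivity_score(pr)
    expect_lte(s, a + 1e-12)
    # raising an off-target probability never raises selectivity
    worse <- pmin(1, off + stats::runif(3, 0, 0.2))
    expect_lte(selectivity_score(four_profiles(a, worse[1], worse[2],
                                               worse[3])), s + 1e-12)
    # raising target activity never lowers it
    expect_gte(selectivity_score(four_profiles(min(1, a + 0.1), off[1],
                                               off[2], off[3])), s - 1e-12)
  }
})

test_that("screening ranks passers by selectivity with tie-breaks", {
  # bit 2 drives D4 activity; bit 3 drives D2 off-target activity
  X <- toy_features(list(c(2L), c(2L, 3L), c(4L), c(2L, 5L)))
  models <- list(
    D2 = toy_model("D2", 3, base = rep(-6, 5), slope = 12),
    D3 = toy_model("D3", 60, base = rep(-6, 5), slope = 0),
    D4 = toy_model("D4", 2, base = rep(-2, 5), slope = 6),
    D5 = toy_model("D5", 61, base = rep(-6, 5), slope = 0)
  )
  sc <- screen_library(models, X, funnel_config(activity_cutoff = 0.5))
  expect_equal(nrow(sc), 4)
  expect_equal(sc$rank, 1:4)
  # molecules T001 and T004 share D4 bit and clean off-targets; T002 has
  # the D2 liability, T003 is inactive
  expect_setequal(sc$mol_id[1:2], c("T001", "T004"))
  expect_equal(sc$mol_id[3], "T002")
  expect_equal(sc$mol_id[4], "T003")
  expect_false(sc$passed_activity[sc$mol_id == "T003"])
  expect_lt(sc$selectivity_score[sc$mol_id == "T002"],
            sc$selectivity_score[sc$mol_id == "T001"])
  # equal scores fall back to lexicographic ids
  expect_equal(sc$mol_id[1], "T001")
})

test_that("screening is invariant to batch size", {
  sm <- sample_molecules()
  set.seed(3)
  X <- sm$features
  models <- lapply(stats::setNames(nm = c("D2", "D3", "D4", "D5")),
                   function(r) {
    toy_model(r, sample(2048, 1), base = seq(-2, 2, length.out = 5),
              slope = 2, n_bits = 2048, hash = sm$config$config_hash)
  })
  s1 <- screen_library(models, X, funnel_config(), batch_size = 7L)
  s2 <- screen_library(models, X, funnel_config(), batch_size = 10000L)
  expect_identical(s1, s2)
})

test_that("cutoff comparisons are >= for activity and > for selectivity", {
  X <- toy_features(list(c(2L)))
  # logit 0 -> probability exactly 0.5 everywhere
  models <- lapply(stats::setNames(nm = c("D2", "D3", "D4", "D5")),
                   function(r) toy_model(r, 60, base = rep(0, 5), slope = 0))
  sc <- screen_library(models, X,
                       funnel_config(activity_cutoff = 0.5,
                                     selectivity_cutoff = 0.0625))
  expect_true(sc$passed_activity)          # 0.5 >= 0.5
  expect_false(sc$passed_selectivity)      # 0.5 * 0.5^3 = 0.0625, not > it
})

test_that("candidate selection applies two-tier preference", {
  mk_scores <- function(n_both, n_act_only, n_fail) {
    n <- n_both + n_act_only + n_fail
    data.frame(
      mol_id = sprintf("c%04d", seq_len(n)),
      activity_score = stats::runif(n, 0.8, 1),
      selectivity_score = c(stats::runif(n_both, 0.5, 1),
                            stats::runif(n_act_only, 0, 0.3),
                            stats::runif(n_fail, 0, 0.3)),
      passed_activity = rep(c(TRUE, TRUE, FALSE),
                            c(n_both, n_act_only, n_fail)),
      passed_selectivity = rep(c(TRUE, FALSE, FALSE),
                               c(n_both, n_act_only, n_fail)),
      rank = seq_len(n)
    )
  }
  set.seed(8)
  s1 <- mk_scores(100, 0, 10)
  sel1 <- select_candidates(s1, funnel_config())
  expect_length(sel1, 89)
  expect_equal(sel1, s1$mol_id[1:89])

  s2 <- mk_scores(50, 200, 10)
  sel2 <- select_candidates(s2, funnel_config())
  expect_length(sel2, 89)
  expect_equal(sum(sel2 %in% s2$mol_id[1:50]), 50)   # all dual passers
  expect_equal(sel2[51:89], s2$mol_id[51:89])        # best activity-only

  s3 <- mk_scores(0, 0, 30)
  expect_length(select_candidates(s3, funnel_config()), 0)
})
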