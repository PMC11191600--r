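test_that("library generation is deterministic and exhausts small grids", {
  g <- tiny_grammar()
  lib1 <- generate_library(g, 18, seed = 3)
  lib2 <- generate_library(g, 18, seed = 3)
  expect_identical(lib1, lib2)
  # 2 x 3 x 3 grid -> all 18 products distinct
  expect_equal(length(unique(lib1$smiles_canonical)), 18)
  expect_equal(lib1$mol_id, sprintf("SYN-%06d", 1:18))

  one <- generate_library(g, 1, seed = 5)
  expect_equal(nrow(one), 1)
  expect_false(is.na(one$smiles_canonical))

  # beyond the grid, homologated products keep the library unique
  lib3 <- generate_library(g, 25, seed = 3)
  expect_equal(length(unique(lib3$smiles_canonical)), 25)
})

test_that("grammar construction rejects unparseable fragments by name", {
  expect_error(
    fragment_grammar(cores = c("C1CC({S})CCN1{N}"),
                     north_caps = c("C(=O)c8ccccc8", "C(=O)qq"),
                     south_caps = "C"),
    "north cap"
  )
})

test_that("zero weights collapse the potency map to its bias", {
  sm <- sample_molecules()
  lm <- latent_potency_model(sm$config, bias = c(D2 = 6, D3 = 6,
                                                 D4 = 6, D5 = 6), seed = 2)
  lm$weights <- lapply(lm$weights, function(w) w * 0)
  P <- assign_latent_potency(sm$features, lm)
  expect_true(all(P == 6))
  expect_error(assign_latent_potency(sm$features[, 1:100], lm), "bits")
})

test_that("without a private D4 component selectivity all but vanishes", {
  sm <- sample_molecules()
  big <- fixture("sel_null_lib", function() {
    lib <- generate_library(fragment_grammar(), 1500, seed = 43)
    featurize_library(lib, fp_config())
  })
  lm <- latent_potency_model(sm$config, d4_private_scale = 0, seed = 2)
  lm <- calibrate_latent_model(lm, big)
  P <- assign_latent_potency(big, lm)
  marg <- P[, "D4"] - pmax(P[, "D2"], P[, "D3"], P[, "D5"])
  expect_lt(mean(marg >= 2), 0.005)
})

test_that("assay simulation respects noise and censoring", {
  exact <- simulate_confirmatory_assay(7, "m", "D4", noise_sd = 0,
                                       censor_range = c(1, 10000))
  expect_equal(exact$value_nM, 100)         # pIC50 7 -> 100 nM
  expect_equal(exact$qualifier, "eq")
  expect_equal(exact$endpoint, "IC50")

  hot <- simulate_confirmatory_assay(10, "m", "D4", noise_sd = 0)
  expect_equal(hot$qualifier, "lt")         # 0.1 nM below the 1 nM floor
  expect_equal(hot$value_nM, 1)
  cold <- simulate_confirmatory_assay(4, "m", "D4", noise_sd = 0)
  expect_equal(cold$qualifier, "gt")        # 100 uM above the ceiling
  expect_equal(cold$value_nM, 10000)

  mc <- simulate_confirmatory_assay(rep(6, 10000), "m", "D4",
                                    noise_sd = 0.3,
                                    censor_range = c(1e-6, 1e12), seed = 9)
  sdev <- stats::sd(log10(mc$value_nM))
  se <- 0.3 / sqrt(2 * (10000 - 1))
  expect_lt(abs(sdev - 0.3), 3 * se)
})

test_that("one-site occupancy behaves like its closed form", {
  expect_equal(percent_inhibition(10000, 10000), 50)
  expect_gt(percent_inhibition(1e-9, 10000), 99.999)
  # solve 100c/(c+x) = 85 at c = 10 uM -> x = 10000 * 15/85
  expect_equal(percent_inhibition(10000 * 15 / 85, 10000), 85)
  expect_lt(abs(percent_inhibition(1764.7, 10000) - 85), 0.1)
  # strictly decreasing in ic50, increasing in concentration
  ic <- sort(stats::runif(50, 1, 1e5))
  expect_true(all(diff(percent_inhibition(ic, 1e4)) < 0))
  cc <- sort(stats::runif(50, 1, 1e5))
  expect_true(all(diff(percent_inhibition(1e3, cc)) > 0))
  expect_error(percent_inhibition(-1, 10), "positive")
})

test_that("Cheng-Prusoff conversion is bounded and hits its limits", {
  expect_equal(cheng_prusoff_ki(84, 0, 1), 84)    # no radioligand: Ki = IC50
  set.seed(12)
  ic <- stats::runif(100, 0.1, 1e5)
  conc <- stats::runif(100, 0.1, 1e4)
  kd <- stats::runif(100, 0.1, 1e4)
  expect_true(all(cheng_prusoff_ki(ic, conc, kd) < ic))
  # assay ratio [L]/Kd fitted from the printed 84 -> 23 nM pair transfers
  # to the other printed pairs within assay rounding
  ratio <- 84 / 23 - 1
  expect_lt(abs(cheng_prusoff_ki(28, ratio, 1) - 7.6) / 7.6, 0.1)
  expect_lt(abs(cheng_prusoff_ki(62, ratio, 1) - 17) / 17, 0.1)
  expect_lt(abs(cheng_prusoff_ki(210, ratio, 1) - 59) / 59, 0.1)
})

test_that("benchmarks have stated sizes, no leakage, and exact manifests", {
  bm <- small_benchmark()
  expect_equal(nrow(bm$records_train), 300)
  expect_equal(nrow(bm$records_screen), 400)
  expect_equal(nrow(bm$measurements), 300 * 4)
  expect_equal(nrow(bm$truth), 700)
  # no structure leaks from training into the deck
  expect_length(intersect(bm$records_train$smiles_canonical,
                          bm$records_screen$smiles_canonical), 0)
  # manifest selectivity class equals recomputation from stored potencies
  marg <- bm$truth$pIC50_D4 -
    pmax(bm$truth$pIC50_D2, bm$truth$pIC50_D3, bm$truth$pIC50_D5)
  expect_equal(bm$truth$is_selective_100x, marg >= 2)
  expect_equal(bm$truth$min_fold_selectivity, 10^marg)
  expect_equal(bm$truth$percent_inhibition_10uM,
               percent_inhibition(10^(9 - bm$truth$pIC50_D4), 10000))
  # measured values are consistent with truth + noise + censoring
  m <- bm$measurements[bm$measurements$qualifier == "eq", ]
  tr <- bm$truth[match(m$mol_id, bm$truth$mol_id), ]
  tmat <- as.matrix(tr[, paste0("pIC50_", c("D2", "D3", "D4", "D5"))])
  true_p <- tmat[cbind(seq_len(nrow(m)),
                       match(m$receptor, c("D2", "D3", "D4", "D5")))]
  resid <- log10(m$value_nM) - (9 - true_p)
  expect_lt(max(abs(resid)), 0.3 * 5)
  # judge the noise scale away from the censoring boundaries, where the
  # eq-conditioning does not truncate the residual distribution
  inner <- true_p > 6 & true_p < 8
  expect_gt(sum(inner), 30)
  expect_lt(abs(stats::sd(resid[inner]) - 0.3), 0.08)
})

test_that("identical seeds give byte-identical benchmark files", {
  cfg <- benchmark_config(n_train = 40L, n_screen = 60L)
  d1 <- file.path(withr::local_tempdir(), "a")
  d2 <- file.path(withr::local_tempdir(), "b")
  write_benchmark(make_benchmark(cfg, seed = 5), d1)
  write_benchmark(make_benchmark(cfg, seed = 5), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
})
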