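test_that("relative activity is firefly over Renilla, rejecting bad rows", {
  plate <- tibble::tibble(batch = "b", construct = "c", variant = "TGA",
                          treatment = "none", dose = NA_real_,
                          replicate = 1:3,
                          firefly = c(200, 100, 50),
                          renilla = c(100, 0, 25))
  out <- suppressWarnings(relative_activity(plate))
  expect_equal(out$rel_activity, c(2, 2))
  rej <- attr(out, "rejected")
  expect_identical(rej$reason, "nonpositive_renilla")
  # batch result equals the row-wise oracle
  plate2 <- sim_plate(0.05, n_replicates = 6, cv = 0.2, seed = 9)
  out2 <- relative_activity(plate2)
  expect_equal(out2$rel_activity,
               vapply(seq_len(nrow(plate2)),
                      function(i) plate2$firefly[i] / plate2$renilla[i], 0))
})

test_that("noiseless plates recover the planted efficiency exactly", {
  plate <- sim_plate(0.067, n_replicates = 12, cv = 0, seed = 1)
  eff <- readthrough_efficiency(plate)
  expect_equal(unlist(eff$efficiencies), rep(6.7, 12), tolerance = 1e-12)
  expect_equal(eff$median, 6.7, tolerance = 1e-12)
  # test rows identical to control rows give 100%
  ctrl <- plate[plate$variant == "TGG", ]
  test_same <- dplyr::mutate(ctrl, variant = "TGA")
  expect_equal(readthrough_efficiency(dplyr::bind_rows(test_same, ctrl))$median,
               100, tolerance = 1e-12)
})

test_that("noisy plates recover the efficiency within the noise tolerance", {
  plate <- sim_plate(0.067, n_replicates = 12, cv = 0.1, seed = 3)
  eff <- readthrough_efficiency(plate)
  expect_lt(abs(eff$median - 6.7) / 6.7, 0.20)
})

test_that("efficiencies are invariant to instrument scale", {
  plate <- sim_plate(0.03, n_replicates = 8, cv = 0.15, seed = 5)
  scaled <- dplyr::mutate(plate, firefly = firefly * 37.5,
                          renilla = renilla * 0.004)
  expect_equal(readthrough_efficiency(plate)$efficiencies,
               readthrough_efficiency(scaled)$efficiencies, tolerance = 1e-12)
})

test_that("the efficiency estimator is median-consistent under lognormal noise", {
  for (cv in c(0.05, 0.1, 0.2)) {
    meds <- vapply(1:150, function(s) {
      readthrough_efficiency(sim_plate(0.067, 12, cv, seed = 10000 + s))$median
    }, 0)
    expect_lt(abs(median(meds) - 6.7) / 6.7, 0.05)
  }
})

test_that("paired normalization mode matches replicate-wise division", {
  plate <- sim_plate(0.1, n_replicates = 5, cv = 0.1, seed = 11)
  eff <- readthrough_efficiency(plate, mode = "paired")
  tga <- plate[plate$variant == "TGA", ]
  tgg <- plate[plate$variant == "TGG", ]
  oracle <- 100 * (tga$firefly / tga$renilla) / (tgg$firefly / tgg$renilla)
  expect_equal(unlist(eff$efficiencies), oracle, tolerance = 1e-12)
})

test_that("missing controls are an error", {
  plate <- sim_plate(0.05, n_replicates = 3, cv = 0, seed = 2)
  expect_error(readthrough_efficiency(plate[plate$variant == "TGA", ]),
               class = "readthrough_data_error")
})

test_that("box statistics follow the type-7 / 1.5 IQR conventions", {
  b <- boxplot_stats(1:5)
  expect_equal(b$median, 3)
  expect_equal(b$q25, 2)
  expect_equal(b$q75, 4)
  same <- boxplot_stats(rep(4.2, 7))
  expect_equal(same$q25, same$q75)
  expect_length(same$outliers[[1]], 0)
  set.seed(13)
  x <- rlnorm(200, 0, 0.6)
  bs <- boxplot_stats(x)
  expect_equal(bs$q25, quantile7(x, 0.25), tolerance = 1e-12)
  expect_equal(bs$median, quantile7(x, 0.5), tolerance = 1e-12)
  expect_equal(bs$q75, quantile7(x, 0.75), tolerance = 1e-12)
  # conservation: outliers plus whisker-interior values = input multiset
  inside <- x[x >= bs$whisker_lo & x <= bs$whisker_hi]
  expect_identical(sort(c(inside, bs$outliers[[1]])), sort(x))
  expect_error(boxplot_stats(numeric(0)), class = "readthrough_data_error")
})

test_that("transactivation fold-changes recover planted responses", {
  same <- sim_transactivation(c(wt = 1), n_replicates = 6, cv = 0, seed = 1)
  expect_equal(transactivation_fold(same)$fold, 1, tolerance = 1e-12)
  planted <- sim_transactivation(c(wt = 6, mutant = 1), n_replicates = 4,
                                 cv = 0.1, seed = 21)
  tf <- transactivation_fold(planted)
  expect_gt(tf$fold[tf$construct == "wt"], 5)
  expect_lt(tf$fold[tf$construct == "wt"], 7)
  expect_lt(abs(tf$fold[tf$construct == "mutant"] - 1), 0.35)
  # missing vehicle arm errors
  stim_only <- planted[planted$treatment == "stimulated", ]
  expect_error(transactivation_fold(stim_only),
               class = "readthrough_data_error")
})
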