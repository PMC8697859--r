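test_that("generation is deterministic and byte-identical per seed", {
  d1 <- tempfile(); d2 <- tempfile()
  generate_dataset(synth_config(n_molecules = 40, seed = 19), out_dir = d1)
  generate_dataset(synth_config(n_molecules = 40, seed = 19), out_dir = d2)
  f1 <- readLines(file.path(d1, "data.csv"))
  f2 <- readLines(file.path(d2, "data.csv"))
  expect_identical(f1, f2)
  d3 <- tempfile()
  generate_dataset(synth_config(n_molecules = 40, seed = 20), out_dir = d3)
  expect_false(identical(f1, readLines(file.path(d3, "data.csv"))))
})

test_that("noiseless distances fall mostly in the physical window", {
  ds <- generate_dataset(synth_config(n_molecules = 200, seed = 31))
  tr <- attr(ds, "truth")
  expect_gte(mean(tr$Re_true >= 1.4 & tr$Re_true <= 3.8), 0.8)
  expect_true(all(tr$Re_true >= 0.8 & tr$Re_true <= 4.5))
  expect_true(all(tr$we_true > 0))
  expect_true(all(tr$D0_true > 0))
})

test_that("noise injection is unbiased", {
  ds <- generate_dataset(synth_config(n_molecules = 250, seed = 41,
                                      noise_Re = 0.05))
  tr <- attr(ds, "truth")
  bias <- mean(ds$Re - tr$Re_true)
  expect_lt(abs(bias), 3 * 0.05 / sqrt(250))
})

test_that("fixtures mirror the constants-table coverage proportions", {
  dir <- tempfile()
  paths <- make_fixture("standard", seed = 11, dir = dir)
  ds <- attr(paths, "dataset")
  expect_equal(nrow(ds), 250)
  # binomial 4-sigma bands around the nominal coverages
  expect_true(abs(sum(!is.na(ds$D0)) - 187.5) < 4 * sqrt(250 * .75 * .25))
  expect_true(abs(sum(!is.na(ds$Re_A)) - 125) < 4 * sqrt(250 * .25))
  expect_true(all(file.exists(paths)))
  # tiny fixture loads back through the CSV path with zero warnings
  dir2 <- tempfile()
  make_fixture("tiny", seed = 11, dir = dir2)
  expect_no_warning(
    ds2 <- suppressMessages(load_dataset(file.path(dir2, "data.csv"))))
  expect_equal(nrow(ds2), 40)
  # regeneration under the same seed is idempotent
  dir3 <- tempfile()
  make_fixture("tiny", seed = 11, dir = dir3)
  expect_identical(readLines(file.path(dir2, "data.csv")),
                   readLines(file.path(dir3, "data.csv")))
})

test_that("generated formulas parse back to the sampled atoms", {
  ds <- generate_dataset(synth_config(n_molecules = 60, seed = 51))
  for (i in seq_len(nrow(ds))) {
    p <- parse_diatomic_formula(ds$formula[i])
    expect_equal(p$atom1$symbol, ds$atom1[i])
    expect_equal(p$atom2$symbol, ds$atom2[i])
  }
})

test_that("truth models satisfy their defining relations", {
  # badger_exact: Re^3 we^2 m constant on the noiseless truth
  ds <- badger_ds()
  tr <- attr(ds, "truth")
  v <- tr$Re_true^3 * tr$we_true^2 * ds$m
  expect_lt(sd(v) / mean(v), 1e-12)
  # parr_exact: Z1 Z2 = A exp(xi Re) exactly
  dsp <- generate_dataset(synth_config(n_molecules = 50, noise_Re = 0,
                                       seed = 6, truth = "parr_exact"))
  trp <- attr(dsp, "truth")
  expect_equal(dsp$Z1 * dsp$Z2, 10 * exp(2 * trp$Re_true), tolerance = 1e-10)
  # binding truth is consistent with the D_e/D_0 conversion (rows where
  # the positivity floor on D_0 did not engage)
  k <- spectro_constants$cm1_to_eV
  De_back <- trp$D0_true + trp$we_true * k / 2 - 0.01 * trp$we_true * k / 4
  free <- trp$D0_true > 0.051
  expect_true(any(free))
  expect_equal(De_back[free], trp$De_true[free], tolerance = 1e-10)
})

test_that("configuration invariants are enforced", {
  expect_error(synth_config(n_molecules = 10), "n_molecules")
  expect_error(synth_config(pool = c("H", "C", "N")), "pool")
  expect_error(generate_dataset(synth_config(n_molecules = 250,
                                             pool = c("H", "C", "N", "O",
                                                      "F", "Cl", "Br", "S",
                                                      "P", "Na"))),
               "unique pairs")
})
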