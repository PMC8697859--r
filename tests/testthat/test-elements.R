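test_that("formula parsing handles isotopes, ambiguity and bad tokens", {
  p <- parse_diatomic_formula("NaK")
  expect_equal(p$atom1$symbol, "Na")
  expect_equal(p$atom2$symbol, "K")

  p <- parse_diatomic_formula("DF")
  expect_equal(p$atom1$symbol, "D")
  expect_equal(p$atom1$mass, 2.014102, tolerance = 1e-4)
  expect_equal(p$atom1$Z, 1)

  # two-letter first token wins when both splits are valid
  p <- parse_diatomic_formula("CoS")
  expect_equal(p$atom1$symbol, "Co")
  p <- parse_diatomic_formula("COs")
  expect_equal(c(p$atom1$symbol, p$atom2$symbol), c("C", "Os"))

  expect_error(parse_diatomic_formula("QZr"), "unknown symbol")
  expect_error(parse_diatomic_formula("NN"), "homonuclear")
  expect_error(parse_diatomic_formula("X"), "parse")
})

test_that("parse after format is the identity over random element pairs", {
  tab <- element_table()
  set.seed(101)
  for (i in 1:200) {
    pair <- sample(tab$symbol, 2)
    f <- paste0(pair[1], pair[2])
    p <- tryCatch(parse_diatomic_formula(f), error = function(e) e)
    expect_false(inherits(p, "error"), info = f)
    expect_equal(c(p$atom1$symbol, p$atom2$symbol), pair,
                 info = f)
  }
})

test_that("hydrogen isotopes carry distinct masses but shared chemistry", {
  tab <- element_table()
  expect_equal(tab["D", "Z"], 1)
  expect_equal(tab["T", "Z"], 1)
  expect_equal(tab["D", "group"], 1)
  expect_equal(tab["D", "mass"], 2.014, tolerance = 1e-3)
  expect_equal(tab["T", "mass"], 3.016, tolerance = 1e-3)
  expect_true(all(tab$group >= 1 & tab$group <= 18))
  expect_true(all(tab$period >= 1 & tab$period <= 7))
})

test_that("reduced mass obeys symmetry, bounds and closed forms", {
  expect_equal(reduced_mass(2, 2), 1)
  expect_equal(reduced_mass(1.00783, 18.99840), 0.95706, tolerance = 1e-5)
  set.seed(7)
  m1 <- runif(50, 0.5, 250); m2 <- runif(50, 0.5, 250)
  expect_equal(reduced_mass(m1, m2), reduced_mass(m2, m1))
  expect_true(all(reduced_mass(m1, m2) <= pmin(m1, m2)))
  # monotone approach to the light mass as the heavy one grows
  expect_equal(reduced_mass(3, 1e12), 3, tolerance = 1e-10)
  expect_error(reduced_mass(-1, 2), "positive")
})

test_that("dissociation energy converts vibrational terms correctly", {
  expect_equal(dissociation_energy(1, 0, 0), 1)
  expect_equal(dissociation_energy(0, 2000, 0), 0.12398, tolerance = 1e-4)
  expect_equal(dissociation_energy(4, 2990, 52), 4 + 0.18536 - 0.00161,
               tolerance = 1e-4)
  # monotone in each argument
  expect_gt(dissociation_energy(2, 1000, 10), dissociation_energy(1, 1000, 10))
  expect_gt(dissociation_energy(1, 2000, 10), dissociation_energy(1, 1000, 10))
  expect_lt(dissociation_energy(1, 1000, 50), dissociation_energy(1, 1000, 10))
  expect_error(dissociation_energy(1, 1000, NA), "wexe")
  expect_warning(dissociation_energy(1, 1000, NA, missing_wexe = "zero"),
                 "treated as 0")
})

test_that("radius ratio is the bond-type indicator", {
  expect_equal(radius_ratio(1.0, 0.5, 0.5), 1.0)
  expect_equal(radius_ratio(2.0, 0.5, 0.5), 2.0)
  expect_gt(radius_ratio(0.9, 0.25, 0.5), 0)
  expect_error(radius_ratio(1, NA, 0.5), "radius")
})

test_that("dataset loading validates columns and reports bad rows", {
  tmp <- tempfile(fileext = ".csv")
  writeLines(c("formula,Re,we,wexe,D0",
               "NaK,3.50,124.0,0.5,0.6",
               "HF,0.917,4138.3,89.9,5.87",
               "CsI,3.31,119.2,0.25,3.36"), tmp)
  ds <- suppressMessages(load_dataset(tmp))
  expect_s3_class(ds, "spectro_dataset")
  expect_equal(nrow(ds), 3)
  expect_equal(ds["NaK", "m"],
               reduced_mass(element_record("Na")$mass,
                            element_record("K")$mass))

  writeLines(c("formula,Re,we", "NaK,3.5,124", "ClCl,2.0,560",
               "LiH,1.6,1405"), tmp)
  expect_warning(ds2 <- suppressMessages(load_dataset(tmp)), "homonuclear")
  expect_equal(nrow(ds2), 2)
  expect_error(suppressMessages(load_dataset(tmp, strict = TRUE)),
               "homonuclear")

  writeLines(c("formula,we", "NaK,124"), tmp)
  expect_error(suppressMessages(load_dataset(tmp)), "Re")
})

test_that("A-state rows pivot into wide columns on load", {
  tmp <- tempfile(fileext = ".csv")
  writeLines(c("formula,state,Re,we",
               "NaK,X,3.50,124.0",
               "NaK,A,3.80,105.0",
               "LiH,X,1.60,1405.0"), tmp)
  ds <- suppressMessages(load_dataset(tmp))
  expect_equal(nrow(ds), 2)
  expect_equal(ds["NaK", "Re_A"], 3.80)
  expect_equal(ds["NaK", "we_A"], 105.0)
  expect_true(is.na(ds["LiH", "Re_A"]))
})

test_that("valence electron counts follow the block convention", {
  expect_equal(valence_electrons(element_record("Na")), 1L)   # s block
  expect_equal(valence_electrons(element_record("Cl")), 7L)   # p block
  expect_equal(valence_electrons(element_record("Fe")), 8L)   # d block
  expect_equal(valence_electrons(element_record("Ce")), 3L)   # f block
  expect_equal(valence_electrons(element_record("He")), 2L)
})
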