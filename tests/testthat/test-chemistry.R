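test_that("monoisotopic masses reproduce the printed modification deltas", {
  expect_equal(monoisotopic_mass(parse_formula("C2H2O")), 42.010565,
               tolerance = 1e-5 / 42)
  expect_equal(monoisotopic_mass(parse_formula("H2O")), 18.010565,
               tolerance = 1e-5 / 18)
  expect_identical(monoisotopic_mass(composition()), 0.0)
  expect_error(monoisotopic_mass(composition(C = 1, Zz = 2)), "Zz")
})

test_that("composition arithmetic is element-wise and never goes negative", {
  a <- parse_formula("C2H3NO")
  b <- parse_formula("CH2")
  s <- comp_add(a, b)
  expect_equal(unclass(s)[["C"]], 3L)
  expect_equal(unclass(s)[["H"]], 5L)
  d <- comp_subtract(s, b)
  expect_equal(sort(names(d)), sort(names(a)))
  expect_error(comp_subtract(b, a), "negative")
  expect_error(composition(C = -1), "non-negative")
})

test_that("peptide masses are additive over modification deltas", {
  m0 <- peptide_mass("KSAPATGGVK")
  expect_equal(m0, 914.518530, tolerance = 1e-4 / 914)
  ac <- modified_peptide("KSAPATGGVK",
                         data.frame(pos = 1, name = "Acetyl (K)"))
  expect_equal(ac$mass - m0, 42.010565, tolerance = 1e-5 / 42)
  me3 <- modified_peptide("KSAPATGGVK",
                          data.frame(pos = 1, name = "Trimethyl (K)"))
  expect_lt(abs(me3$mass - ac$mass - 0.036385), 1e-6)
  expect_error(peptide_mass(""), "empty")
  expect_error(modified_peptide("KSAPATGGVK",
                                data.frame(pos = 2, name = "Acetyl (K)")),
               "not allowed")
})

test_that("every registry delta reproduces the printed value to 1e-5 Da", {
  printed <- c("Carbamidomethyl (C)" = 57.021464, "Acetyl (K)" = 42.010565,
               "Methyl (K)" = 14.015650, "Dimethyl (K)" = 28.031300,
               "Trimethyl (K)" = 42.046950, "Methyl (R)" = 14.015650,
               "Dimethyl (R)" = 28.031300, "Deamidated (R)" = 0.984016,
               "Phospho (ST)" = 79.966331, "Oxidation (M)" = 15.994915)
  reg <- default_modifications()
  expect_setequal(names(reg), names(printed))
  for (nm in names(printed)) {
    expect_lt(abs(reg[[nm]]$delta_mass - printed[[nm]]), 1e-5)
  }
})

test_that("isotope envelopes agree with the polynomial-expansion oracle", {
  # single carbon: A1/A0 is the 13C/12C abundance ratio
  env_c <- isotope_distribution(composition(C = 1))
  expect_equal(env_c$abundances[2] / env_c$abundances[1], 0.0107 / 0.9893,
               tolerance = 1e-10)
  # monoisotopic element: single peak
  expect_equal(isotope_distribution(composition(P = 1))$abundances, 1.0)
  # peptide-scale compositions against the atom-by-atom oracle
  for (comp in list(peptide_composition("KSAPATGGVK"),
                    parse_formula("C10H15N3O6S2"),
                    parse_formula("C39H70N12O13"))) {
    got <- isotope_distribution(comp)$abundances
    want <- envelope_oracle(comp)
    expect_equal(length(got), length(want))
    expect_true(all(abs(got - want) < 1e-6))
  }
  expect_error(isotope_distribution(composition()), "empty")
  expect_error(isotope_distribution(composition(C = 5), floor = 1.5), "floor")
})

test_that("envelope truncation keeps a single maximal peak above the floor", {
  env <- isotope_distribution(peptide_composition("KSAPATGGVK"), floor = 1e-3)
  expect_equal(sum(env$abundances == 1), 1)
  expect_true(all(env$abundances >= 0 & env$abundances <= 1))
  expect_gte(env$abundances[length(env$abundances)], 1e-3)
})

test_that("envelope similarity is a cosine: scale-invariant and symmetric", {
  th <- isotope_distribution(peptide_composition("KSAPATGGVK"))
  expect_equal(envelope_similarity(th, th$abundances * 7.3), 1.0)
  expect_equal(envelope_similarity(c(1, 0, 0), c(0, 1, 0)), 0.0)
  # perturbed envelope against a direct cosine computed here
  obs <- th$abundances[1:4] * 1.1
  direct <- sum(th$abundances[1:4] * obs) /
    sqrt(sum(th$abundances[1:4]^2) * sum(obs^2))
  expect_equal(envelope_similarity(th$abundances[1:4], obs), direct,
               tolerance = 1e-12)
  set.seed(42)
  for (i in 1:20) {
    a <- runif(sample(3:6, 1)); b <- runif(sample(3:6, 1))
    expect_equal(envelope_similarity(a, b), envelope_similarity(b, a))
    expect_equal(envelope_similarity(a * runif(1, 0.1, 10), b),
                 envelope_similarity(a, b), tolerance = 1e-12)
  }
  expect_error(envelope_similarity(c(1, 0.5), c(0, 0)), "zero")
})

test_that("fragment ions carry modification deltas on the right side", {
  pep <- modified_peptide("KSAPATGGVK",
                          data.frame(pos = 1, name = "Acetyl (K)"))
  unmod <- modified_peptide("KSAPATGGVK")
  fi_mod <- fragment_ions(pep)
  fi_un <- fragment_ions(unmod)
  b <- fi_mod$type == "b"
  # every b ion contains residue 1 and is shifted by the acetyl delta
  expect_true(all(abs(fi_mod$mz[b] - fi_un$mz[b] - 42.010565) < 1e-5))
  # y ions up to y9 exclude residue 1: unshifted
  y_small <- fi_mod$type == "y" & fi_mod$index < 10
  expect_true(all(abs(fi_mod$mz[y_small] - fi_un$mz[y_small]) < 1e-9))
})

test_that("the registry round-trips through its plain-text serialization", {
  reg <- default_modifications()
  path <- tempfile(fileext = ".tsv")
  write_modification_registry(reg, path)
  back <- read_modification_registry(path)
  expect_identical(names(back), names(reg))
  for (nm in names(reg)) {
    expect_equal(back[[nm]]$delta_mass, reg[[nm]]$delta_mass)
    expect_identical(back[[nm]]$targets, reg[[nm]]$targets)
    expect_identical(back[[nm]]$fixed, reg[[nm]]$fixed)
  }
})
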