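# Adduct chemistry: formulas, compositions, species, delta grouping,
# covering sequence.

test_that("formula arithmetic is exact and guarded", {
  h2o <- chem_formula(c(H = 2, O = 1))
  ump <- parse_formula("C9H13N2O9P")
  expect_equal(formula_mass(h2o), 18.01056, tolerance = 1e-5)
  expect_equal(formula_mass(ump), 324.03587, tolerance = 1e-5)
  expect_identical(formula_mass(chem_formula()), 0.0)

  s <- formula_add(ump, h2o)
  expect_identical(formula_subtract(s, h2o)$counts, ump$counts)
  expect_error(formula_subtract(h2o, ump), "negative")
  expect_error(chem_formula(c(Xx = 1)), "unknown element")
  expect_error(chem_formula(c(C = 2), heavy = c(C = 3)), "exceeds")
})

test_that("heavy isotopes carry the published mass differences", {
  light <- chem_formula(c(C = 9, N = 2))
  heavy <- chem_formula(c(C = 9, N = 2), heavy = c(C = 9, N = 2))
  expect_equal(formula_mass(heavy) - formula_mass(light),
               9 * ORACLE_D13C + 2 * ORACLE_D15N, tolerance = 1e-4)
})

test_that("composition enumeration matches the worked examples", {
  ucucu <- enumerate_compositions("UCUCU", 1, 4)
  expect_length(ucucu, 6)
  expect_setequal(names(ucucu), c("U1", "C1", "C1U1", "C1U2", "C2U1", "C2U2"))

  cgcuu <- enumerate_compositions("CGCUU", 1, 4)
  expect_length(cgcuu, 11)
  expect_setequal(names(cgcuu),
                  c("C1", "G1", "U1", "C1G1", "C1U1", "U2", "C2G1",
                    "C1G1U1", "C1U2", "C2G1U1", "C1G1U2"))

  expect_identical(names(enumerate_compositions("A", 1, 1)), "A1")
  expect_error(enumerate_compositions("UCXU", 1, 2), "invalid base 'X' at position 3")
  expect_error(enumerate_compositions("", 1, 1), "empty")
  expect_error(enumerate_compositions("ACG", 1, 5), "exceeds")
})

test_that("composition enumeration equals brute force on random sequences", {
  set.seed(11)
  for (i in 1:200) {
    len <- sample(4:30, 1)
    rna <- random_rna(len)
    max_len <- sample(seq_len(min(4, len)), 1)
    got <- names(enumerate_compositions(rna, 1, max_len))
    expect_identical(sort(got), oracle_compositions(rna, 1, max_len),
                     info = rna)
  }
})

test_that("built-in nucleotide and loss masses match independent summation", {
  for (b in c("A", "C", "G", "U")) {
    sp <- build_adduct_species(parse_comp_tag(b))
    expect_equal(sp$light_mass_da, oracle_sum_mass(as.list(ORACLE_NMP[[b]])),
                 tolerance = 1e-4, info = b)
  }
  losses <- default_losses()
  expect_equal(formula_mass(losses[["-H2O"]]$formula_delta), 18.010565,
               tolerance = 1e-4)
  expect_equal(formula_mass(losses[["-HPO3"]]$formula_delta), 79.966331,
               tolerance = 1e-4)
  expect_equal(formula_mass(losses[["-H3PO4"]]$formula_delta), 97.976896,
               tolerance = 1e-4)
})

test_that("adduct species reproduce the worked mass/delta examples", {
  scheme <- labeling_scheme("metabolic_13C15N")
  u <- build_adduct_species(parse_comp_tag("U"), scheme = scheme)
  expect_equal(u$light_mass_da, 324.0359, tolerance = 1e-4)
  expect_equal(u$delta_mass_da, 11.0243, tolerance = 1e-4)

  u_loss <- build_adduct_species(parse_comp_tag("U"),
                                 default_losses()[["-HPO3"]], scheme)
  expect_equal(u_loss$light_mass_da, 244.0695, tolerance = 1e-4)
  expect_equal(u_loss$delta_mass_da, 11.0243, tolerance = 1e-4)

  cu <- build_adduct_species(parse_comp_tag("C1U1"), scheme = scheme)
  expect_equal(cu$light_mass_da, 324.03587 + 323.05185 - 18.01056,
               tolerance = 1e-4)
  expect_equal(cu$delta_mass_da, 18 * ORACLE_D13C + 5 * ORACLE_D15N,
               tolerance = 1e-4)
})

test_that("delta consistency and scheme conventions hold across species", {
  schemes <- list(labeling_scheme("none"),
                  labeling_scheme("metabolic_13C15N"),
                  labeling_scheme("ribose_13C"),
                  labeling_scheme("phosphate_18O"))
  comps <- enumerate_compositions("UGCAUGU", 1, 4)
  for (scheme in schemes) {
    for (comp in comps) {
      sp <- build_adduct_species(comp, scheme = scheme)
      expect_equal(sp$delta_mass_da,
                   formula_mass(sp$heavy_formula) - formula_mass(sp$light_formula),
                   tolerance = 1e-12)
      expect_gte(sp$delta_mass_da, 0)
      if (scheme$name == "none") expect_identical(sp$delta_mass_da, 0)
      if (scheme$name == "ribose_13C") {
        expect_equal(sp$delta_mass_da, comp_length(comp) * 5 * ORACLE_D13C,
                     tolerance = 1e-4)
      }
      if (scheme$name == "phosphate_18O") {
        expect_equal(sp$delta_mass_da, 2.00425, tolerance = 1e-4)
      }
    }
  }
})

test_that("5'-OH terminus variant subtracts one HPO3", {
  a <- build_adduct_species(parse_comp_tag("U"))
  b <- build_adduct_species(parse_comp_tag("U"), terminus = "5p_OH")
  expect_equal(a$light_mass_da - b$light_mass_da, 79.96633, tolerance = 1e-4)
})

test_that("grouping by delta partitions species and is order-stable", {
  scheme <- labeling_scheme("metabolic_13C15N")
  species <- enumerate_adduct_species("UCUCU", scheme, losses = list(loss_spec("none")))
  groups <- group_by_delta(species)
  expect_length(groups, 6)  # all six UCUCU compositions have distinct deltas
  expect_identical(vapply(groups, function(g) g$delta_mass_da, numeric(1)),
                   sort(vapply(groups, function(g) g$delta_mass_da, numeric(1))))
  # partition: every species in exactly one group
  n_in_groups <- sum(vapply(groups, function(g) length(g$species), integer(1)))
  expect_identical(n_in_groups, length(species))
  # stable under permutation of the input
  set.seed(5)
  groups2 <- group_by_delta(sample(species))
  expect_identical(adduct_table(groups), adduct_table(groups2))

  # unlabeled scheme collapses to one zero-delta group
  sp_none <- enumerate_adduct_species("UCUCU", labeling_scheme("none"),
                                      losses = list(loss_spec("none")))
  g_none <- group_by_delta(sp_none)
  expect_length(g_none, 1)
  expect_identical(g_none[[1]]$delta_mass_da, 0)

  # species closer than the tolerance share a group
  s1 <- build_adduct_species(parse_comp_tag("U"), scheme = scheme)
  s2 <- s1
  s2$delta_mass_da <- s1$delta_mass_da + 5e-5
  expect_length(group_by_delta(list(s1, s2), tol_da = 1e-4), 1)
})

test_that("covering RNA passes its own coverage check and is reproducible", {
  s1 <- generate_covering_rna(1)
  expect_length(enumerate_compositions(s1, 1, 1), 4)

  s2 <- generate_covering_rna(2, c("A", "C"))
  expect_setequal(names(enumerate_compositions(s2, 1, 2)),
                  c("A1", "C1", "A2", "A1C1", "C2"))

  s4 <- generate_covering_rna(4)
  expect_length(enumerate_compositions(s4, 1, 4), 69)  # 4+10+20+35 multisets
  expect_identical(s4, generate_covering_rna(4))
})

test_that("adduct table serializes with six-decimal masses", {
  species <- enumerate_adduct_species("UC", labeling_scheme("metabolic_13C15N"),
                                      max_len = 2)
  groups <- group_by_delta(species)
  path <- tempfile(fileext = ".tsv")
  on.exit(unlink(path))
  write_adduct_table(groups, path)
  back <- data.table::fread(path, sep = "\t")
  expect_identical(names(back),
                   c("composition", "loss", "light_mass_da", "heavy_mass_da",
                     "delta_mass_da", "group_id"))
  expect_equal(sort(unique(back$composition)),
               sort(names(enumerate_compositions("UC", 1, 2))))
})
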