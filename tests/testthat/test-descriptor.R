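test_that("local dipole moment is bond length times absolute charge difference", {
  expect_equal(local_dipole(1.2342, 0.224, -0.288), 0.6319104,
               tolerance = 1e-9)
  expect_equal(local_dipole(1.7, 0.13, 0.13), 0)
  expect_equal(local_dipole(2.0, 0.1, -0.1), 0.4)
  expect_error(local_dipole(0, 0.1, -0.1), "positive")
  expect_error(local_dipole(-1.2, 0.1, -0.1), "positive")
})

test_that("dipolar factor uses a base-10 logarithm and handles limits", {
  expect_equal(dipolar_function(2.6790, 0.63191), 1.7193, tolerance = 1e-4)
  expect_equal(dipolar_function(0, 0.5), 1)
  for (m in c(0.1, 1, 7)) {
    expect_equal(dipolar_function(9 * m, m), 2)   # 1 + log10(10)
  }
  expect_error(dipolar_function(1.5, 0), "singular")
  expect_error(dipolar_function(-1, 0.5), "non-negative")
  # strictly increasing in mu for fixed mu_f
  mus <- seq(0, 5, by = 0.25)
  vals <- vapply(mus, dipolar_function, numeric(1), mu_f = 0.6319)
  expect_true(all(diff(vals) > 0))
  expect_true(all(vals >= 1))
})

test_that("charge-to-SET mapping supports coefficients and overrides", {
  co <- data.frame(category = c("CH3", "CH2"),
                   slope = c(-1, 2), intercept = c(1, 0.5))
  m <- set_map(coefficients = co)
  expect_equal(set_from_charge(0, "CH3", m), 1)      # intercept at q = 0
  expect_equal(set_from_charge(0.1, "CH3", m), 0.9)
  expect_error(set_from_charge(0.1, "CH", m), "no coefficients")
  expect_error(set_from_charge(2, "CH3", m), "non-positive")

  m2 <- set_map(coefficients = co, overrides = c("3" = 0.9892))
  expect_equal(set_from_charge(NA, "CH3", m2, index = 3), 0.9892)
  expect_equal(set_from_charge(0, "CH3", m2, index = 1), 1)
  expect_error(set_map(overrides = c("1" = -0.5)), "positive")

  co_dom <- data.frame(category = "CH3", slope = -1, intercept = 1,
                       q_min = -0.3, q_max = 0.3)
  m3 <- set_map(coefficients = co_dom)
  expect_error(set_from_charge(0.5, "CH3", m3), "domain")
})

test_that("dipolar scaling applies only to the heteroatom neighbourhood", {
  g <- parse_structure("CCC(=O)CCC")
  expect_equal(dipole_scaled_atoms(g), c(3L, 4L))
  sets <- c(0.9892, 0.9998, 0.2268, 1.1346, 0.9998, 0.8988, 0.9998)
  ctx <- dipolar_context(2.6790, 1.2342, 0.224, -0.288)
  eff <- effective_sets(g, sets, ctx)
  expect_equal(eff[c(1, 2, 5, 6, 7)], sets[c(1, 2, 5, 6, 7)])
  expect_equal(eff[3], sets[3] * ctx$a_mu)
  expect_equal(eff[4], sets[4] * ctx$a_mu)
  # apolar: identity
  expect_equal(effective_sets(g, sets, NULL), sets)
  expect_error(effective_sets(g, sets[1:3], ctx), "one SET value per atom")
  expect_error(effective_sets(g, c(-1, sets[-1]), NULL), "non-positive")
})

test_that("3-hexanone reference decomposition is reproduced at display precision", {
  res <- compute_descriptor(hexanone_smi(), hexanone_state())
  ref <- hexanone_reference
  expect_equal(res$mu_f, ref$mu_f, tolerance = 1e-4)
  expect_equal(res$a_mu, ref$a_mu, tolerance = 1e-4)
  expect_equal(round(res$per_atom, 4), ref$contributions)
  expect_true(all(abs(res$per_atom - ref$contributions) <= 1e-4))
  expect_equal(displayed_total(res), ref$total)
  expect_equal(res$total, sum(res$per_atom))
  expect_equal(res$scaled_atoms, c(3L, 4L))
})

test_that("atom contributions are own value plus log10 of neighbours", {
  g <- parse_structure("CCC(=O)CCC")
  res <- compute_descriptor(hexanone_smi(), hexanone_state())
  eff <- res$effective_set
  # oxygen: self + log of the carbonyl carbon only
  expect_equal(atom_contribution(4, g, eff), eff[4] + log10(eff[3]))
  # mid-chain carbon: two neighbour terms
  expect_equal(atom_contribution(2, g, eff),
               eff[2] + log10(eff[1]) + log10(eff[3]))
  # isolated atom: empty neighbour sum
  single <- mol_graph("C", NULL)
  expect_equal(atom_contribution(1, single, 0.77), 0.77)
  expect_equal(total_iset(single, 0.77)$total, 0.77)
})

test_that("unit SET values make the total count atoms", {
  for (smi in c("CCCC", "CC(C)C", "CCCCCC")) {
    g <- parse_structure(smi)
    bd <- total_iset(g, rep(1, n_atoms(g)))
    expect_equal(bd$total, n_atoms(g), info = smi)
  }
})

test_that("ethanol pipeline matches a hand-evaluated aggregation", {
  g <- parse_structure("CCO")
  st <- list(
    name = "ethanol-synthetic", dipole_debye = 1.69,
    polar_group = list(carbon = 2, heteroatom = 3,
                       bond_length_angstrom = 1.41),
    atoms = data.frame(index = 1:3, element = c("C", "C", "O"),
                       net_charge_e = c(NA, 0.028, -0.328),
                       set_value = c(0.97, 1.01, 1.08))
  )
  res <- compute_descriptor(g, st)
  # spreadsheet-style evaluation, kept deliberately explicit
  mu_f <- 1.41 * abs(0.028 - (-0.328))
  a_mu <- 1 + log10(1 + 1.69 / mu_f)
  e1 <- 0.97; e2 <- 1.01 * a_mu; e3 <- 1.08 * a_mu
  expected <- (e1 + log10(e2)) + (e2 + log10(e1) + log10(e3)) +
    (e3 + log10(e2))
  expect_equal(res$total, expected, tolerance = 1e-12)
  expect_equal(res$a_mu, a_mu)
})

test_that("structure/state mismatches are rejected", {
  st <- read_state(hexanone_state())
  expect_error(compute_descriptor(parse_structure("CCO"), st), "mismatch")
  st_bad <- st
  st_bad$atoms$element[4] <- "N"
  expect_error(compute_descriptor(parse_structure("CCC(=O)CCC"), st_bad),
               "element symbols disagree")
  st_nopolar <- st
  st_nopolar$polar_group <- NULL
  expect_error(compute_descriptor(parse_structure("CCC(=O)CCC"), st_nopolar),
               "polar_group")
})

test_that("total is invariant under atom relabeling", {
  for (seed in 1:8) {
    m <- synth_molecule(synth_spec(sample(3:8, 1), "branched",
                                   heteroatom_position = 2, seed = seed))
    eff <- effective_sets(m$graph, m$states$set_value, m$ctx)
    bd <- total_iset(m$graph, eff)
    perm <- sample(n_atoms(m$graph))
    gp <- permute_graph(m$graph, perm)
    effp <- numeric(length(eff)); effp[perm] <- eff
    bdp <- total_iset(gp, effp)
    expect_equal(bdp$total, bd$total, tolerance = 1e-12)
    expect_equal(unname(bdp$per_atom[perm]), unname(bd$per_atom),
                 tolerance = 1e-12)
  }
})

test_that("aggregation agrees with an edge-sum evaluator and scaling identity", {
  set.seed(42)
  for (rep in 1:10) {
    n <- sample(2:8, 1)
    m <- synth_molecule(synth_spec(n, "branched", seed = rep))
    eff <- m$states$set_value
    bd <- total_iset(m$graph, eff)
    expect_equal(bd$total, brute_iset(m$graph, eff), tolerance = 1e-12)
    # scaling all SET values by k shifts the total by the linear terms
    # plus (sum of degrees) * log10(k) = 2 * n_bonds * log10(k)
    k <- runif(1, 0.5, 2)
    shift <- (k - 1) * sum(eff) + 2 * nrow(m$graph$bonds) * log10(k)
    expect_equal(total_iset(m$graph, k * eff)$total, bd$total + shift,
                 tolerance = 1e-10)
  }
})

test_that("polar-group selection strategies behave as documented", {
  # ethyl acetate: two oxygens; the carbonyl strategy picks the C=O pair
  g <- parse_structure("CCOC(C)=O")
  cls <- classify_atoms(g)
  n <- n_atoms(g)
  o_idx <- which(cls$category == "heteroatom")
  deg <- vapply(o_idx, function(i) length(atom_neighbors(g, i)), 1L)
  o_ester <- o_idx[deg == 2]      # bridging ester oxygen
  o_carbonyl <- o_idx[deg == 1]   # double-bonded oxygen
  c_carbonyl <- atom_neighbors(g, o_carbonyl)[1]
  c_ester <- setdiff(atom_neighbors(g, o_ester), c_carbonyl)[1]
  charges <- rep(NA_real_, n)
  charges[c_ester] <- 0.02; charges[c_carbonyl] <- 0.30
  charges[o_ester] <- -0.35; charges[o_carbonyl] <- -0.35
  st <- list(
    name = "ethyl-acetate-synthetic", dipole_debye = 1.9,
    polar_group = list(
      list(carbon = c_ester, heteroatom = o_ester,
           bond_length_angstrom = 1.43),
      list(carbon = c_carbonyl, heteroatom = o_carbonyl,
           bond_length_angstrom = 1.23)
    ),
    atoms = data.frame(index = seq_len(n), element = cls$element,
                       net_charge_e = charges, set_value = rep(0.95, n))
  )
  # identify which polar group the carbonyl strategy used via mu_f
  res <- compute_descriptor(g, st, mu_f_strategy = "carbonyl")
  expect_equal(res$mu_f, 1.23 * abs(0.30 - (-0.35)), tolerance = 1e-12)
  res_first <- compute_descriptor(g, st, mu_f_strategy = "first")
  expect_equal(res_first$mu_f, 1.43 * abs(0.02 - (-0.35)), tolerance = 1e-12)
})
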