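test_that("SMILES parsing yields the expected heavy-atom graphs", {
  cases <- list(
    list(smi = "CCC(=O)CCC", atoms = 7, bonds = 6,
         elements = c(C = 6, O = 1)),
    list(smi = "CC", atoms = 2, bonds = 1, elements = c(C = 2)),
    list(smi = "C1CC1", atoms = 3, bonds = 3, elements = c(C = 3))
  )
  for (cs in cases) {
    g <- parse_structure(cs$smi)
    expect_equal(n_atoms(g), cs$atoms, info = cs$smi)
    expect_equal(nrow(g$bonds), cs$bonds, info = cs$smi)
    counts <- table(g$atoms$element)
    expect_equal(counts[names(cs$elements)], cs$elements,
                 ignore_attr = TRUE, info = cs$smi)
  }
  named <- parse_structure("CCC(=O)CCC 3-hexanone")
  expect_equal(named$name, "3-hexanone")
  expect_error(parse_structure("not_a_smiles((", format = "smiles"),
               "unparseable")
})

test_that("graph construction enforces its invariants", {
  expect_error(mol_graph(c("C", "H"), rbind(c(1, 2))), "hydrogen")
  expect_error(mol_graph(c("C", "C"), rbind(c(1, 1))), "self-bond")
  expect_error(mol_graph(c("C", "C"), rbind(c(1, 3))), "existing atoms")
  expect_error(mol_graph(c("C", "C"), rbind(c(1, 2), c(2, 1))), "duplicate")
  expect_error(mol_graph(c("C", "C", "C"), rbind(c(1, 2))), "disconnected")
  # single atoms are valid molecules
  expect_equal(n_atoms(mol_graph("C", NULL)), 1)
})

test_that("atom classification follows heavy-neighbour count and element", {
  eth <- classify_atoms(parse_structure("CC"))
  expect_equal(eth$category, c("CH3", "CH3"))

  etoh <- classify_atoms(parse_structure("CCO"))
  expect_equal(etoh$category, c("CH3", "CH2", "heteroatom"))
  expect_equal(etoh$hetero_adjacent, c(FALSE, TRUE, FALSE))

  hex <- classify_atoms(parse_structure("CCC(=O)CCC"))
  expect_equal(hex$category[3], "CH")       # carbonyl carbon: 3 heavy nbrs
  expect_true(hex$hetero_adjacent[3])
  expect_equal(hex$category[4], "heteroatom")
  expect_false(any(hex$hetero_adjacent[c(1, 5, 6, 7)]))

  quat <- classify_atoms(parse_structure("CC(C)(C)C"))
  expect_equal(sum(quat$category == "C_quaternary"), 1)
})

test_that("neighbour queries are sorted and validated", {
  g <- parse_structure("CCC(=O)CCC")
  expect_equal(atom_neighbors(g, 3), c(2L, 4L, 5L))
  expect_equal(atom_neighbors(parse_structure("CC"), 1), 2L)
  expect_equal(atom_neighbors(path_graph(3), 2), c(1L, 3L))
  expect_error(atom_neighbors(g, 9), "unknown atom index")
  expect_error(atom_neighbors(g, 0), "unknown atom index")
})

test_that("parse -> serialize -> parse round-trips the graph", {
  for (smi in c("CCC(=O)CCC", "CC(C)(C)CO", "C1CCCCC1", "CCOC(C)=O")) {
    g <- parse_structure(smi)
    g2 <- parse_structure(mol_to_sdf(g), format = "sdf")
    expect_equal(n_atoms(g2), n_atoms(g), info = smi)
    expect_equal(sort(g2$atoms$element), sort(g$atoms$element), info = smi)
    key <- function(gr) sort(paste(gr$bonds$i, gr$bonds$j))
    expect_equal(key(g2), key(g), info = smi)
  }
})

test_that("classification is invariant under atom relabeling", {
  for (seed in 1:5) {
    m <- synth_molecule(synth_spec(7, "branched", heteroatom_position = 4,
                                   seed = seed))
    perm <- sample(7)
    gp <- permute_graph(m$graph, perm)
    expect_equal(sort(classify_atoms(gp)$category),
                 sort(classify_atoms(m$graph)$category))
  }
})

test_that("acyclic hydrocarbons have n - 1 bonds", {
  for (n in c(2, 5, 9)) {
    expect_equal(nrow(path_graph(n)$bonds), n - 1)
    g <- synth_molecule(synth_spec(n, "branched", seed = n))$graph
    expect_equal(nrow(g$bonds), n - 1)
  }
})

test_that("structure files are read record by record", {
  smi_file <- tempfile(fileext = ".smi")
  writeLines(c("CC ethane", "CCO ethanol"), smi_file)
  gs <- read_structures(smi_file)
  expect_length(gs, 2)
  expect_equal(names(gs), c("ethane", "ethanol"))
  expect_equal(n_atoms(gs$ethanol), 3)

  sdf_file <- tempfile(fileext = ".sdf")
  writeLines(paste(mol_to_sdf(gs$ethane), "$$$$",
                   mol_to_sdf(gs$ethanol), "$$$$", sep = "\n"), sdf_file)
  gs2 <- read_structures(sdf_file)
  expect_length(gs2, 2)
  expect_equal(vapply(gs2, n_atoms, 1L), vapply(gs, n_atoms, 1L),
               ignore_attr = TRUE)
  unlink(c(smi_file, sdf_file))
})

test_that("explicit hydrogens are collapsed before graph construction", {
  # ethanol with explicit hydrogens in the atom block
  g <- parse_structure("[H]C([H])([H])C([H])([H])O[H]", format = "smiles")
  expect_equal(n_atoms(g), 3)
  expect_equal(sort(g$atoms$element), c("C", "C", "O"))
  expect_equal(nrow(g$bonds), 2)
})
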