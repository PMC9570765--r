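test_that("Burden matrix follows the off-diagonal convention", {
  one <- mol_graph(tibble::tibble(element = "C", charge = 0L, h_count = 4L),
                   NULL)
  expect_equal(build_burden_matrix(one, 0.7), matrix(0.7))
  # ethane: single bond, both atoms terminal -> 0.1 * 1 + 0.01
  ethane <- mol_from_smiles("CC")
  B <- build_burden_matrix(ethane, c(0.2, 0.4))
  expect_equal(B, matrix(c(0.2, 0.11, 0.11, 0.4), 2))
  expect_error(build_burden_matrix(ethane, 1:3),
               class = "sibcut_error_contract")
})

test_that("Burden matrix equals the brute-force pairwise constructor", {
  set.seed(5)
  for (smi in c("CCO", "C1=CC=CC=C1", "CC(=O)NC1=CC=CC=C1", "C1=CC=CO1",
                "CC(C)(C)CO")) {
    mol <- mol_from_smiles(smi)
    w <- rnorm(nrow(mol$atoms))
    expect_equal(build_burden_matrix(mol, w), oracle_burden(mol, w))
  }
})

test_that("eigen summaries match closed forms and stay sorted", {
  expect_equal(bcut_from_matrix(matrix(2.5)), rep(2.5, 4))
  # symmetric 2x2: eigenvalues a -/+ |c|, thirds interpolate linearly
  a <- 0.4; cc <- -0.3
  expect_equal(bcut_from_matrix(matrix(c(a, cc, cc, a), 2)),
               c(a - abs(cc), a - abs(cc) / 3, a + abs(cc) / 3, a + abs(cc)))
  expect_error(bcut_from_matrix(matrix(c(1, 2, 3, 4), 2)),
               class = "sibcut_error_contract")
})

test_that("eigen summaries agree with an independent solver oracle", {
  set.seed(9)
  for (n in c(2, 3, 5, 12, 27, 50)) {
    A <- matrix(rnorm(n * n), n)
    B <- (A + t(A)) / 2
    expect_equal(bcut_from_matrix(B), oracle_bcut_summary(B),
                 tolerance = 1e-9)
  }
})

test_that("bcut_vector composes the three weighting schemes", {
  # lone neutral carbon: zero charge, methane's single-atom contributions
  v <- bcut_vector(mol_from_smiles("C"))
  expect_equal(names(v), c(paste0("BCUT_PEOE_", 0:3),
                           paste0("BCUT_SLOGP_", 0:3),
                           paste0("BCUT_SMR_", 0:3)))
  expect_equal(unname(v[1:4]), rep(0, 4), tolerance = 1e-6)
  expect_equal(unname(v[5:8]), rep(0.6361, 4), tolerance = 1e-4)
  expect_equal(unname(v[9:12]), rep(6.731, 4), tolerance = 1e-3)
})

test_that("within each property the four summaries are nondecreasing", {
  smis <- c("CCO", "C1=CC=NC=C1", "CC(N)=O", "NC(=O)N",
            "OCC1OC(n2cnc3c(N)ncnc32)C(O)C1O")
  for (smi in smis) {
    v <- bcut_vector(mol_from_smiles(smi))
    for (block in list(1:4, 5:8, 9:12)) {
      expect_true(all(diff(v[block]) >= -1e-12), label = smi)
    }
  }
})

test_that("bcut_vector is invariant under heavy-atom reindexing", {
  mol <- mol_from_smiles("CC(=O)NC1=CC=CC=C1")
  v <- bcut_vector(mol)
  set.seed(21)
  for (rep in 1:3) {
    vp <- bcut_vector(permute_mol(mol, sample(nrow(mol$atoms))))
    expect_equal(vp, v, tolerance = 1e-10)
  }
})

test_that("descriptor tables are built deterministically from structures", {
  empty <- build_descriptor_table(tibble::tibble(symbol = character(),
                                                 mol = list()))
  expect_equal(nrow(empty), 0L)
  expect_equal(names(empty)[1], "NT")

  st <- read_structures(system.file("extdata", "natural_nucleosides.smi",
                                    package = "sibcut"))
  tab <- build_descriptor_table(st)
  expect_equal(dim(tab), c(5L, 13L))
  expect_equal(names(tab), c("NT", paste0("BCUT_PEOE_", 0:3),
                             paste0("BCUT_SLOGP_", 0:3),
                             paste0("BCUT_SMR_", 0:3)))
  # presentation order does not change content
  tab2 <- build_descriptor_table(st[c(3, 1, 5, 2, 4), ])
  expect_equal(dplyr::arrange(tab2, NT), dplyr::arrange(tab, NT))
  expect_error(build_descriptor_table(st[c(1, 1), ]),
               class = "sibcut_error_input")
})
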