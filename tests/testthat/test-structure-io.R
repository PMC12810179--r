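minimal_pdb <- paste(
  "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
  "ATOM      2  CA  ALA A   1       1.500   0.000   0.000  1.00  0.00           C",
  "ATOM      3  C1'   A B   1       5.000   0.000   0.000  1.00  0.00           C",
  "ATOM      4  N1    A B   1       6.500   0.000   0.000  1.00  0.00           N",
  "END", sep = "\n")

test_that("a minimal two-residue complex parses into one protein and one RNA group", {
  x <- parse_structure(minimal_pdb)
  expect_s3_class(x, "panther_structure")
  expect_equal(sum(x$groups$kind == "amino_acid"), 1)
  expect_equal(sum(x$groups$kind == "nucleotide"), 1)
  expect_equal(n_frames(x), 1)
  expect_equal(nrow(x$atoms), 4)
  # masses from elements, parameters from the bundled table
  expect_true(all(x$atoms$mass > 0))
  expect_false(anyNA(x$atoms$sigma))
})

test_that("MODEL blocks become frames with identical atom ordering", {
  multi <- paste("MODEL     1", minimal_pdb, "ENDMDL",
                 "MODEL     2",
                 gsub("0\\.000   0\\.000   0\\.000", "1.000   0.000   0.000",
                      minimal_pdb),
                 "ENDMDL", "END", sep = "\n")
  x <- parse_structure(multi)
  expect_equal(n_frames(x), 2)
  expect_equal(x$xyz[2, , 1], x$xyz[2, , 2])    # unchanged atom
  expect_equal(x$xyz[1, 1, 2] - x$xyz[1, 1, 1], 1)  # shifted atom
})

test_that("malformed ATOM lines raise an error naming the line", {
  bad <- sub("1\\.500", "x.xxx", minimal_pdb)
  expect_error(parse_structure(bad), "line 2")
  short <- paste("ATOM      1  N   ALA A   1", minimal_pdb, sep = "\n")
  expect_error(parse_structure(short), "line 1")
})

test_that("nonstandard residues are skipped with a warning; all-nonstandard input fails", {
  het <- sub("END",
             paste("ATOM      5  O   HOH C   1       9.000   9.000   9.000  1.00  0.00           O",
                   "END", sep = "\n"),
             minimal_pdb)
  expect_warning(x <- parse_structure(het), "HOH")
  expect_equal(nrow(x$atoms), 4)
  protein_only <- paste(strsplit(minimal_pdb, "\n")[[1]][1:2], collapse = "\n")
  expect_error(parse_structure(protein_only), "at least one")
})

test_that("center of mass matches identity, symmetry and a hand-weighted sum", {
  # single atom: COM is the atom
  x1 <- two_atom_structure(5)
  expect_equal(center_of_mass(x1, 1), c(0, 0, 0))
  # equal masses at (0,0,0) and (2,0,0): midpoint
  g <- list(
    list(resid = "GLY", chain = "A", resno = 1,
         atoms = data.frame(name = c("CA", "CB"), element = "C",
                            x = c(0, 2), y = 0, z = 0, charge = 0,
                            eps = 0.1, sigma = 3, mass = 12)),
    list(resid = "A", chain = "B", resno = 1,
         atoms = data.frame(name = "C2", element = "C", x = 50, y = 0, z = 0,
                            charge = 0, eps = 0.1, sigma = 3, mass = 12)))
  expect_equal(center_of_mass(make_structure(g), 1), c(1, 0, 0))
  # unequal masses: independent weighted mean
  set.seed(4)
  m <- runif(4, 5, 30)
  xyz <- matrix(runif(12, -3, 3), 4, 3)
  g[[1]]$atoms <- data.frame(name = c("CA", "CB", "CG", "CD"), element = "C",
                             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                             charge = 0, eps = 0.1, sigma = 3, mass = m)
  expect_equal(center_of_mass(make_structure(g), 1),
               colSums(xyz * m) / sum(m), tolerance = 1e-12)
})

test_that("find_pairs applies an inclusive COM cutoff and matches a brute-force scan", {
  x <- two_atom_structure(11.9)
  expect_equal(nrow(find_pairs(x, cutoff = 12)), 1)
  x <- two_atom_structure(12.1)
  expect_equal(nrow(find_pairs(x, cutoff = 12)), 0)
  # boundary is inclusive: unit masses keep the COM arithmetic exact
  xb <- make_structure(list(
    list(resid = "ALA", chain = "A", resno = 1,
         atoms = data.frame(name = "CA", element = "C", x = 0, y = 0, z = 0,
                            charge = 0, eps = 0.1, sigma = 3, mass = 1)),
    list(resid = "A", chain = "B", resno = 1,
         atoms = data.frame(name = "C2", element = "C", x = 12, y = 0, z = 0,
                            charge = 0, eps = 0.1, sigma = 3, mass = 1))))
  expect_equal(nrow(find_pairs(xb, cutoff = 12)), 1)
  for (seed in 1:5) {
    x <- random_structure(seed, n_protein = 4, n_rna = 4)
    got <- find_pairs(x, cutoff = 12)
    ora <- oracle_find_pairs(x, cutoff = 12)
    expect_equal(nrow(got), nrow(ora))
    expect_setequal(paste(got$p_group, got$r_group),
                    paste(ora$p, ora$r))
    expect_equal(sort(got$com_distance), sort(ora$d), tolerance = 1e-12)
  }
})

test_that("bond-vector hydrogen placement counts at 3.4 A and excludes at 3.6 A", {
  mk <- function(dist_NA) make_structure(list(
    list(resid = "ALA", chain = "A", resno = 1,
         atoms = data.frame(name = c("N", "CA"), element = c("N", "C"),
                            x = c(0, -1.5), y = 0, z = 0, charge = 0,
                            eps = 0.1, sigma = 3, mass = c(14, 12))),
    list(resid = "A", chain = "B", resno = 1,
         atoms = data.frame(name = "N1", element = "N", x = dist_NA, y = 0,
                            z = 0, charge = 0, eps = 0.1, sigma = 3,
                            mass = 14))))
  expect_equal(count_hbonds(mk(4.4), 1, 2), 1)  # placed H at 1.0: H...A 3.4
  expect_equal(count_hbonds(mk(4.6), 1, 2), 0)  # H...A 3.6 > 3.5
})

test_that("an explicit hydrogen at a 100-degree D-H...A angle is excluded", {
  ang <- 100 * pi / 180
  A <- c(1, 0, 0) + 3.0 * c(cos(ang), sin(ang), 0)
  x <- make_structure(list(
    list(resid = "ALA", chain = "A", resno = 1,
         atoms = data.frame(name = c("N", "H"), element = c("N", "H"),
                            x = c(0, 1), y = 0, z = 0, charge = 0, eps = 0.1,
                            sigma = 3, mass = c(14, 1))),
    list(resid = "A", chain = "B", resno = 1,
         atoms = data.frame(name = "N1", element = "N", x = A[1], y = A[2],
                            z = A[3], charge = 0, eps = 0.1, sigma = 3,
                            mass = 14))))
  expect_equal(count_hbonds(x, 1, 2), 0)
  # a linear explicit hydrogen at the same H...A distance is counted
  x2 <- make_structure(list(
    list(resid = "ALA", chain = "A", resno = 1,
         atoms = data.frame(name = c("N", "H"), element = c("N", "H"),
                            x = c(0, 1), y = 0, z = 0, charge = 0, eps = 0.1,
                            sigma = 3, mass = c(14, 1))),
    list(resid = "A", chain = "B", resno = 1,
         atoms = data.frame(name = "N1", element = "N", x = 4, y = 0, z = 0,
                            charge = 0, eps = 0.1, sigma = 3, mass = 14))))
  expect_equal(count_hbonds(x2, 1, 2), 1)
})

test_that("with placed hydrogens detection reduces to the distance test on random geometries", {
  crit <- hbond_criteria()
  set.seed(11)
  for (i in 1:25) {
    d <- runif(1, 1.2, 6.5)
    dirv <- rnorm(3); dirv <- dirv / sqrt(sum(dirv^2))
    x <- make_structure(list(
      list(resid = "SER", chain = "A", resno = 1,
           atoms = data.frame(name = "OG", element = "O", x = 0, y = 0, z = 0,
                              charge = 0, eps = 0.1, sigma = 3, mass = 16)),
      list(resid = "U", chain = "B", resno = 1,
           atoms = data.frame(name = "O4", element = "O", x = d * dirv[1],
                              y = d * dirv[2], z = d * dirv[3], charge = 0,
                              eps = 0.1, sigma = 3, mass = 16))))
    expected <- as.integer(d - crit$placed_bond_length < crit$max_h_acceptor_dist)
    expect_equal(count_hbonds(x, 1, 2, crit), expected)
  }
})

test_that("a zero maximum H...acceptor distance never counts a bond", {
  x <- two_atom_structure(3)
  crit <- hbond_criteria(max_h_acceptor_dist = 0)
  expect_equal(count_hbonds(x, 1, 2, crit), 0)
  b <- gen_complex(seed = 3)
  pr <- find_pairs(b$structure)
  for (k in seq_len(nrow(pr)))
    expect_equal(count_hbonds(b$structure, pr$p_group[k], pr$r_group[k],
                              crit), 0)
})

test_that("serialize-then-parse round-trips groups and coordinates", {
  b <- gen_complex(seed = 9, n_protein = 4, n_rna = 3,
                   pairs = data.frame(com_distance = c(6, 7.5, 10),
                                      hbonds = c(1, 1, 0)))
  x <- b$structure
  y <- parse_structure(write_structure_pdb(x), pdb_id = x$pdb_id)
  expect_equal(y$groups$type_code, x$groups$type_code)
  expect_equal(y$groups$kind, x$groups$kind)
  expect_equal(nrow(y$atoms), nrow(x$atoms))
  expect_equal(y$xyz, x$xyz, tolerance = 1e-9)  # coords already at 1e-3
})

test_that("the bundled parameter TSV matches the in-code defaults", {
  path <- system.file("extdata", "default_params.tsv", package = "panther")
  expect_true(nzchar(path))
  p <- read_parameter_table(path)
  d <- default_parameter_table()
  expect_equal(p$entries, d$entries)
  # parsing with the file-backed table gives identical energies
  b <- gen_complex(seed = 8)
  x1 <- parse_structure(b$pdb, params = p)
  x2 <- parse_structure(b$pdb, params = d)
  pr <- find_pairs(x1)
  expect_equal(pair_energy(x1, pr$p_group[1], pr$r_group[1], p)$e_total,
               pair_energy(x2, pr$p_group[1], pr$r_group[1], d)$e_total)
})

test_that("pair identification is invariant to atom order within groups", {
  x <- random_structure(21, n_protein = 3, n_rna = 3)
  perm <- sample(nrow(x$atoms))
  x2 <- panther_structure(x$atoms[perm, ],
                          x$xyz[perm, , , drop = FALSE], pdb_id = x$pdb_id)
  p1 <- find_pairs(x); p2 <- find_pairs(x2)
  expect_equal(p1$com_distance, p2$com_distance, tolerance = 1e-12)
  expect_equal(p1[c("chain_p", "res_p", "chain_r", "res_r")],
               p2[c("chain_p", "res_p", "chain_r", "res_r")])
})
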