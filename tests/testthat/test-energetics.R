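test_that("Lennard-Jones energy is zero at sigma and -eps at the minimum", {
  x <- two_atom_structure(3.0, eps = c(0.1, 0.1), sigma = c(3, 3))
  expect_equal(lj_energy(x, 1, 2), 0, tolerance = 1e-12)
  x <- two_atom_structure(3.0 * 2^(1 / 6))
  expect_equal(lj_energy(x, 1, 2), -0.1, tolerance = 1e-12)
})

test_that("Coulomb energy matches the closed form and is symmetric under group swap", {
  x <- two_atom_structure(3.320636, charge = c(1, -1))
  expect_equal(coulomb_energy(x, 1, 2), -100, tolerance = 1e-9)
  set.seed(8)
  for (i in 1:20) {
    q <- runif(2, -1, 1); r <- runif(1, 1.5, 12)
    x <- two_atom_structure(r, charge = q)
    expect_equal(coulomb_energy(x, 1, 2), 332.0636 * q[1] * q[2] / r,
                 tolerance = 1e-12)
    expect_identical(coulomb_energy(x, 1, 2), coulomb_energy(x, 2, 1))
  }
  # zero charge contributes nothing
  x <- two_atom_structure(4, charge = c(0, 0.7))
  expect_identical(coulomb_energy(x, 1, 2), 0)
  # dielectric scales the electrostatics down
  p2 <- default_parameter_table(dielectric = 4)
  x <- two_atom_structure(4, charge = c(0.5, -0.5))
  expect_equal(coulomb_energy(x, 1, 2, p2),
               coulomb_energy(x, 1, 2) / 4, tolerance = 1e-12)
})

test_that("pair energy equals the naive double-loop oracle on random groups", {
  for (seed in 1:10) {
    x <- random_structure(seed, n_protein = 1, n_rna = 1,
                          atoms_per_group = sample(2:4, 1))
    got <- pair_energy(x, 1, 2)
    ora <- oracle_pair_energy(x, 1, 2)
    expect_equal(got$e_vdw, ora$e_vdw, tolerance = 1e-12)
    expect_equal(got$e_elec, ora$e_elec, tolerance = 1e-12)
    expect_identical(got$e_total, got$e_vdw + got$e_elec)
  }
})

test_that("coincident atoms raise a clash error", {
  x <- two_atom_structure(0)
  expect_error(pair_energy(x, 1, 2), "clash")
})

test_that("energy is additive over a partition of one group", {
  x <- random_structure(31, n_protein = 1, n_rna = 2, atoms_per_group = 3)
  # treat the two RNA groups as a partition of one combined partner
  joint <- make_structure(list(
    list(resid = x$groups$type_code[1], chain = "A", resno = 1,
         atoms = data.frame(name = c("CA", "CB", "CG"), element = "C",
                            x = x$xyz[1:3, 1, 1], y = x$xyz[1:3, 2, 1],
                            z = x$xyz[1:3, 3, 1],
                            charge = x$atoms$charge[1:3],
                            eps = x$atoms$eps[1:3],
                            sigma = x$atoms$sigma[1:3],
                            mass = x$atoms$mass[1:3])),
    list(resid = "A", chain = "B", resno = 1,
         atoms = data.frame(name = paste0("C", 1:6), element = "C",
                            x = x$xyz[4:9, 1, 1], y = x$xyz[4:9, 2, 1],
                            z = x$xyz[4:9, 3, 1],
                            charge = x$atoms$charge[4:9],
                            eps = x$atoms$eps[4:9],
                            sigma = x$atoms$sigma[4:9],
                            mass = x$atoms$mass[4:9]))))
  split_sum <- pair_energy(x, 1, 2)$e_total + pair_energy(x, 1, 3)$e_total
  expect_equal(pair_energy(joint, 1, 2)$e_total, split_sum,
               tolerance = 1e-10)
})

# helper: split LJ into repulsive/attractive sums with the oracle loop
attr_lj_parts <- function(x) {
  ai <- group_atoms(x, 1); aj <- group_atoms(x, 2)
  rep_s <- att_s <- 0
  for (a in ai) for (b in aj) {
    r <- sqrt(sum((x$xyz[a, , 1] - x$xyz[b, , 1])^2))
    eps <- sqrt(x$atoms$eps[a] * x$atoms$eps[b])
    sig <- (x$atoms$sigma[a] + x$atoms$sigma[b]) / 2
    rep_s <- rep_s + 4 * eps * (sig / r)^12
    att_s <- att_s - 4 * eps * (sig / r)^6
  }
  list(rep = rep_s, att = att_s)
}

test_that("components scale with distance as 1/r (Coulomb) and r^-12/r^-6 (LJ)", {
  set.seed(5)
  for (i in 1:5) {
    lambda <- runif(1, 1.2, 2.5)
    x <- random_structure(100 + i, n_protein = 1, n_rna = 1)
    x2 <- x
    x2$xyz <- x$xyz * lambda
    e1 <- pair_energy(x, 1, 2)
    e2 <- pair_energy(x2, 1, 2)
    expect_equal(e2$e_elec, e1$e_elec / lambda, tolerance = 1e-10)
    # decompose LJ into its two power laws via two evaluations
    rep1 <- attr_lj_parts(x)
    expect_equal(attr_lj_parts(x2)$rep, rep1$rep / lambda^12, tolerance = 1e-8)
    expect_equal(attr_lj_parts(x2)$att, rep1$att / lambda^6, tolerance = 1e-8)
  }
})

test_that("analyzed frame blocks follow the window/skip pattern", {
  s <- window_scheme(window = 10, skip = 40)
  expect_length(analyzed_frames(10000, s), 200)
  expect_length(analyzed_frames(9, s), 0)
  b <- analyzed_frames(60, s)
  expect_equal(b, list(1:10, 51:60))
  # trailing partial window discarded
  expect_length(analyzed_frames(59, s), 1)
  # degenerate scheme: every frame analyzed
  expect_equal(analyzed_frames(4, window_scheme(window = 2, skip = 0)),
               list(1:2, 3:4))
})

test_that("a constant-geometry trajectory reproduces the static pair energy", {
  b <- gen_complex(seed = 6)
  tr <- gen_trajectory(b, n_frames = 60, persistence = c(1, 1))
  dec <- decompose_trajectory(tr$structure)
  expect_true(all(dec$retained))
  pr <- find_pairs(b$structure)
  for (k in seq_len(nrow(dec))) {
    static <- pair_energy(b$structure, dec$p_group[k], dec$r_group[k])
    expect_equal(dec$mean_local_energy[k], static$e_total, tolerance = 1e-10)
    wm <- attr(dec, "window_means")[[dec$pair_id[k]]]
    expect_true(all(abs(wm$mean_energy - static$e_total) < 1e-10))
  }
})

test_that("persistence filtering is inclusive at the threshold", {
  b <- gen_complex(seed = 2)
  # 960 frames -> 20 windows -> 200 analyzed frames
  tr <- gen_trajectory(b, n_frames = 960, persistence = c(139 / 200, 140 / 200))
  dec <- decompose_trajectory(tr$structure, compute_hbonds = FALSE)
  dec <- dec[order(dec$res_p), ]
  expect_equal(dec$presence_fraction, c(0.695, 0.700))
  expect_equal(dec$retained, c(FALSE, TRUE))
})

test_that("window means average only present frames", {
  b <- gen_complex(seed = 2)
  # pair 2 present in the first analyzed half only
  tr <- gen_trajectory(b, n_frames = 100, persistence = c(1, 0.5))
  dec <- decompose_trajectory(tr$structure, compute_hbonds = FALSE)
  p2 <- dec[dec$res_p == 2, ]
  expect_equal(p2$presence_fraction, 0.5)
  wm <- attr(dec, "window_means")[[p2$pair_id]]
  expect_equal(wm$window, 1)  # second window has no present frames
  expect_false(p2$retained)
})

test_that("decomposition requires at least one complete window", {
  b <- gen_complex(seed = 2)
  x <- b$structure
  x$xyz <- array(rep(x$xyz, 5), dim = c(nrow(x$atoms), 3, 5))
  expect_error(decompose_trajectory(x), "window")
})
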