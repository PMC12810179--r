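# Independent oracles and hand-built structure helpers. The physics oracle
# is a deliberately naive double loop, kept separate from the package's
# vectorized implementation.

# Structure with explicitly supplied per-atom parameters: a list of groups,
# each list(resid, chain, resno, atoms = data.frame(name, element, x, y, z,
# charge, eps, sigma, mass)).
make_structure <- function(groups, pdb_id = "test") {
  atoms <- do.call(rbind, lapply(groups, function(g) {
    data.frame(name = g$atoms$name, element = g$atoms$element,
               resid = g$resid, chain = g$chain, resno = g$resno,
               charge = g$atoms$charge, eps = g$atoms$eps,
               sigma = g$atoms$sigma, mass = g$atoms$mass,
               stringsAsFactors = FALSE)
  }))
  xyz <- as.matrix(do.call(rbind, lapply(groups, function(g)
    g$atoms[, c("x", "y", "z")])))
  dimnames(xyz) <- NULL
  panther_structure(atoms, xyz, pdb_id = pdb_id)
}

# one single-atom protein group + one single-atom RNA group at distance r
two_atom_structure <- function(r, eps = c(0.1, 0.1), sigma = c(3, 3),
                               charge = c(0, 0)) {
  make_structure(list(
    list(resid = "ALA", chain = "A", resno = 1,
         atoms = data.frame(name = "CA", element = "C", x = 0, y = 0, z = 0,
                            charge = charge[1], eps = eps[1],
                            sigma = sigma[1], mass = 12.011)),
    list(resid = "A", chain = "B", resno = 1,
         atoms = data.frame(name = "C2", element = "C", x = r, y = 0, z = 0,
                            charge = charge[2], eps = eps[2],
                            sigma = sigma[2], mass = 12.011))
  ))
}

# random multi-atom structure with random nonbonded parameters
random_structure <- function(seed, n_protein = 2, n_rna = 2,
                             atoms_per_group = 3) {
  set.seed(seed)
  mk_group <- function(kind, idx) {
    center <- runif(3, -6, 6)
    n <- atoms_per_group
    if (kind == "protein") {
      resid <- sample(aa_vocabulary(), 1)
      names <- c("CA", "CB", "CG", "CD", "CE")[seq_len(n)]
    } else {
      resid <- sample(nt_vocabulary(), 1)
      names <- c("C2", "C4", "C5", "C6", "C8")[seq_len(n)]
    }
    list(resid = resid,
         chain = if (kind == "protein") "A" else "B",
         resno = idx,
         atoms = data.frame(
           name = names, element = "C",
           x = center[1] + runif(n, -1, 1),
           y = center[2] + runif(n, -1, 1),
           z = center[3] + runif(n, -1, 1),
           charge = runif(n, -0.8, 0.8),
           eps = runif(n, 0.02, 0.3),
           sigma = runif(n, 2.5, 3.8),
           mass = runif(n, 10, 20)))
  }
  groups <- c(lapply(seq_len(n_protein), function(i) mk_group("protein", i)),
              lapply(seq_len(n_rna), function(i) mk_group("rna", i)))
  make_structure(groups)
}

# naive double-loop Lennard-Jones + Coulomb oracle (Lorentz-Berthelot)
oracle_pair_energy <- function(x, gi, gj, frame = 1, k_e = 332.0636,
                               dielectric = 1) {
  ai <- group_atoms(x, gi)
  aj <- group_atoms(x, gj)
  e_vdw <- 0
  e_elec <- 0
  for (a in ai) {
    for (b in aj) {
      dr <- x$xyz[a, , frame] - x$xyz[b, , frame]
      r <- sqrt(sum(dr * dr))
      eps <- sqrt(x$atoms$eps[a] * x$atoms$eps[b])
      sig <- (x$atoms$sigma[a] + x$atoms$sigma[b]) / 2
      e_vdw <- e_vdw + 4 * eps * ((sig / r)^12 - (sig / r)^6)
      e_elec <- e_elec + k_e * x$atoms$charge[a] * x$atoms$charge[b] /
        (dielectric * r)
    }
  }
  list(e_vdw = e_vdw, e_elec = e_elec, e_total = e_vdw + e_elec)
}

# brute-force all-pairs COM scan
oracle_find_pairs <- function(x, frame = 1, cutoff = 12) {
  g <- x$groups
  out <- list()
  for (p in g$id[g$kind == "amino_acid"]) {
    for (r in g$id[g$kind == "nucleotide"]) {
      d <- sqrt(sum((center_of_mass(x, p, frame) -
                       center_of_mass(x, r, frame))^2))
      if (d <= cutoff) out[[length(out) + 1]] <- c(p, r, d)
    }
  }
  if (!length(out)) return(data.frame(p = integer(0), r = integer(0),
                                      d = numeric(0)))
  m <- do.call(rbind, out)
  data.frame(p = m[, 1], r = m[, 2], d = m[, 3])
}

# closed-form normalized exponential-decay weights
oracle_weights <- function(d, r0 = 9) {
  w <- exp(-d / r0)
  w / sum(w)
}
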