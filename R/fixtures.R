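# Synthetic complexes, trajectories and feature tables with known ground
# truth. Geometry is built from small residue templates recentred so that
# planted COM distances hold exactly (to PDB writing precision); hydrogen
# bond truth is derived by the generator's own donor/acceptor bookkeeping,
# and the feature-table energy functions are deliberately unrelated to the
# package's Lennard-Jones/Coulomb code so recovery tests cannot silently
# reuse the physics implementation.

#' @noRd
.tmpl_protein <- function() {
  data.frame(name = c("N", "CA", "C", "O", "CB"),
             element = c("N", "C", "C", "O", "C"),
             x = c(1.8, 0.5, -0.7, -1.8, 0.6),
             y = c(0.0, 0.6, -0.3, 0.2, 2.1),
             z = c(0.0, 0.0, 0.4, 0.6, 0.1),
             stringsAsFactors = FALSE)
}

#' @noRd
.tmpl_rna <- function() {
  data.frame(name = c("C1'", "N9", "C2", "N1"),
             element = c("C", "N", "C", "N"),
             x = c(1.5, 0.5, -1.2, -2.2),
             y = c(0.8, 0.0, -0.9, 0.0),
             z = c(0.0, 0.0, 0.0, 0.0),
             stringsAsFactors = FALSE)
}

#' @noRd
.recenter <- function(tmpl) {
  m <- unname(ELEMENT_MASS[tmpl$element])
  com <- c(sum(tmpl$x * m), sum(tmpl$y * m), sum(tmpl$z * m)) / sum(m)
  tmpl$x <- tmpl$x - com[1]; tmpl$y <- tmpl$y - com[2]; tmpl$z <- tmpl$z - com[3]
  tmpl
}

#' @noRd
.fixture_energy <- function(d, hb, params = c(A = 20, L = 6, hb_coef = 1.5)) {
  -params[["A"]] * exp(-d / params[["L"]]) - params[["hb_coef"]] * hb
}

#' Generate a synthetic protein-RNA complex with known ground truth
#'
#' Residue groups are placed on a wide grid (40 A spacing) so only the
#' requested pairs interact; pair \code{i} couples protein group \code{i} to
#' RNA group \code{i} at exactly the requested COM distance. Each protein
#' group is a 5-atom amino-acid template whose backbone N (a donor) faces
#' its RNA partner; each RNA group is a 4-atom adenine-like base whose N1
#' acceptor either faces the protein (to plant one hydrogen bond) or is
#' rotated away (zero hydrogen bonds). The manifest records the planted COM
#' distances, the generator's own hydrogen-bond truth, and per-pair ground
#' truth energies from a documented exponential-decay function (unrelated to
#' the package's physics code).
#'
#' @param n_protein,n_rna group counts; both must be >= 1.
#' @param pairs data.frame with one row per planted pair: columns
#'   \code{com_distance} (Angstrom) and \code{hbonds} (0 or 1). At most
#'   \code{min(n_protein, n_rna)} rows.
#' @param seed integer; fixes the residue-type sampling so repeated calls
#'   are byte-identical.
#' @param pdb_id complex identifier.
#' @param chain_p,chain_r chain identifiers.
#' @return list with \code{pdb} (PDB text), \code{structure}
#'   (parsed-equivalent \code{panther_structure}), and \code{manifest}.
#' @export
gen_complex <- function(n_protein = 3, n_rna = 2,
                        pairs = data.frame(com_distance = c(7, 8),
                                           hbonds = c(1, 0)),
                        seed = 1L, pdb_id = "SYN001",
                        chain_p = "A", chain_r = "B") {
  if (n_protein < 1 || n_rna < 1)
    stop_domain("need at least one protein and one RNA group")
  n_pairs <- nrow(pairs)
  if (n_pairs > min(n_protein, n_rna))
    stop_domain("more planted pairs (%d) than available groups", n_pairs)
  tp <- .recenter(.tmpl_protein())
  tr <- .recenter(.tmpl_rna())
  a_p <- tp$x[tp$name == "N"]       # donor offset toward +x
  a_r <- -tr$x[tr$name == "N1"]     # acceptor offset toward -x (positive)

  set.seed(seed)
  aa_codes <- sample(AA3, n_protein, replace = TRUE)

  place <- function(tmpl, com) {
    cbind(tmpl$x + com[1], tmpl$y + com[2], tmpl$z + com[3])
  }
  atoms <- list(); coords <- list()
  # protein groups on a y-grid
  p_com <- lapply(seq_len(n_protein), function(g) c(0, 40 * (g - 1), 0))
  for (g in seq_len(n_protein)) {
    atoms[[length(atoms) + 1]] <- data.frame(
      name = tp$name, element = tp$element, resid = aa_codes[g],
      chain = chain_p, resno = g, stringsAsFactors = FALSE)
    coords[[length(coords) + 1]] <- place(tp, p_com[[g]])
  }
  # RNA groups: planted partners, then spectators far away
  truth <- data.frame(pair = integer(0), res_p = integer(0),
                      res_r = integer(0), aa = character(0),
                      nt = character(0), com_distance = numeric(0),
                      hbonds = integer(0), true_energy = numeric(0))
  for (j in seq_len(n_rna)) {
    if (j <= n_pairs) {
      d <- pairs$com_distance[j]
      want_hb <- pairs$hbonds[j]
      if (d <= 0) stop_domain("com_distance must be > 0")
      sep_face <- d - a_p - a_r
      sep_away <- d - a_p + a_r
      if (want_hb == 1) {
        if (!(sep_face > 1.2 && sep_face < 4.4))
          stop_domain("infeasible geometry: cannot plant an H-bond at COM distance %.2f A", d)
        t_use <- tr
      } else {
        if (sep_away < 4.6)
          stop_domain("infeasible geometry: cannot avoid an H-bond at COM distance %.2f A", d)
        t_use <- tr
        t_use$x <- -t_use$x   # rotate base so N1 points away
      }
      com <- c(d, 40 * (j - 1), 0)
      xyzj <- place(t_use, com)
      # generator's own H-bond truth: placed-H criterion on its donor/acceptor
      dDA <- sqrt(sum((xyzj[t_use$name == "N1", ] -
                         (place(tp, p_com[[j]])[tp$name == "N", ]))^2))
      hb_true <- as.integer(dDA > 1.0 && (dDA - 1.0) < 3.5)
      if (hb_true != want_hb)
        stop_domain("internal geometry inconsistency for pair %d", j)
      truth <- rbind(truth, data.frame(
        pair = j, res_p = j, res_r = j, aa = aa_codes[j], nt = "A",
        com_distance = d, hbonds = hb_true,
        true_energy = .fixture_energy(d, hb_true)))
    } else {
      com <- c(300, 40 * (j - 1), 200)
      xyzj <- place(tr, com)
      t_use <- tr
    }
    atoms[[length(atoms) + 1]] <- data.frame(
      name = tr$name, element = tr$element, resid = "A",
      chain = chain_r, resno = j, stringsAsFactors = FALSE)
    coords[[length(coords) + 1]] <- xyzj
  }
  atoms_df <- do.call(rbind, atoms)
  xyz <- do.call(rbind, coords)
  # write at PDB precision first so text and structure agree exactly
  xyz <- round(xyz, 3)
  x <- panther_structure(atoms_df, xyz, pdb_id = pdb_id,
                         params = default_parameter_table())
  manifest <- list(seed = seed, pdb_id = pdb_id,
                   n_protein_groups = n_protein, n_rna_groups = n_rna,
                   chain_p = chain_p, chain_r = chain_r,
                   pairs = truth,
                   energy_fun = "exp_decay",
                   energy_params = c(A = 20, L = 6, hb_coef = 1.5),
                   noise_sd = 0)
  list(pdb = write_structure_pdb(x), structure = x, manifest = manifest)
}

#' Generate a synthetic trajectory with controlled pair persistence
#'
#' Replicates a generated complex across frames; in frames where a planted
#' pair is scheduled absent, its RNA group is displaced 500 A away so its
#' COM distance exceeds any sensible cutoff. Presence is controlled exactly
#' on the analyzed frames of \code{scheme}: a target fraction \code{f} puts
#' the pair inside the cutoff in the first \code{f * n_analyzed} analyzed
#' frames (an error if that is not an integer, since the fraction would be
#' unreachable). Frames outside analyzed windows mirror the absent state.
#'
#' @param base result of [gen_complex()].
#' @param n_frames trajectory length.
#' @param persistence numeric vector of target presence fractions, one per
#'   planted pair.
#' @param scheme [window_scheme()] defining the analyzed frames.
#' @param jitter_sd optional Gaussian coordinate jitter (Angstrom) applied
#'   per frame; default 0 keeps per-frame energies exactly constant.
#' @param seed RNG seed for the jitter.
#' @return list with \code{structure} (multi-frame) and \code{manifest}
#'   (base manifest plus realized presence fractions).
#' @export
gen_trajectory <- function(base, n_frames, persistence,
                           scheme = window_scheme(), jitter_sd = 0,
                           seed = 1L) {
  x <- base$structure
  man <- base$manifest
  n_pairs <- nrow(man$pairs)
  if (length(persistence) != n_pairs)
    stop_domain("persistence must have one entry per planted pair (%d)", n_pairs)
  blocks <- analyzed_frames(n_frames, scheme)
  if (!length(blocks)) stop_domain("n_frames too small for one full window")
  af <- unlist(blocks)
  n_af <- length(af)
  k <- persistence * n_af
  if (any(abs(k - round(k)) > 1e-9))
    stop_domain("unreachable presence fraction(s): %s over %d analyzed frames",
                paste(persistence[abs(k - round(k)) > 1e-9], collapse = ", "),
                n_af)
  k <- as.integer(round(k))

  xyz <- array(rep(x$xyz[, , 1], n_frames),
               dim = c(nrow(x$atoms), 3, n_frames))
  present_frames <- lapply(k, function(ki) af[seq_len(ki)])
  for (p in seq_len(n_pairs)) {
    rgrp <- which(x$groups$kind == "nucleotide" &
                    x$groups$resno == man$pairs$res_r[p])
    idx <- group_atoms(x, x$groups$id[rgrp])
    absent <- setdiff(seq_len(n_frames), present_frames[[p]])
    xyz[idx, 3, absent] <- xyz[idx, 3, absent] + 500
  }
  if (jitter_sd > 0) {
    set.seed(seed)
    xyz <- xyz + array(stats::rnorm(length(xyz), 0, jitter_sd), dim = dim(xyz))
  }
  xt <- x
  xt$xyz <- xyz
  man$trajectory <- list(n_frames = n_frames, n_analyzed = n_af,
                         target_persistence = persistence,
                         realized_persistence = k / n_af,
                         jitter_sd = jitter_sd, seed = seed)
  list(structure = xt, manifest = man)
}

#' Generate a synthetic feature table from a known energy function
#'
#' Draws interaction features (amino-acid type, base type, COM distance
#' uniform on 3-12 A, hydrogen-bond count 0-3) and computes
#' \code{local_energy = f(aa, nt, distance, hbonds) + Normal(0, noise_sd)}.
#' The generating functions are documented closed forms independent of the
#' package's physics code:
#' \describe{
#'   \item{linear}{additive: amino-acid and base offsets plus
#'     \code{-0.8 * distance - 1.5 * hbonds}.}
#'   \item{nonlinear_interaction}{a base-type-dependent Morse-like decay in
#'     distance whose equilibrium distance and depth shift with amino-acid
#'     type (an aa-by-distance interaction), plus \code{-1.5 * hbonds}.}
#'   \item{hbond_dominant}{\code{-2.5 * hbonds - 0.15 * distance}.}
#' }
#'
#' @param n number of records.
#' @param generator one of \code{"linear"}, \code{"nonlinear_interaction"},
#'   \code{"hbond_dominant"}.
#' @param noise_sd Gaussian noise SD in kcal/mol, default 0.5.
#' @param seed RNG seed.
#' @param noise_feature add a pure-noise numeric column \code{noise_feat}
#'   (standard normal, unused by the energy function) for importance-null
#'   tests.
#' @return list with \code{records} and \code{manifest} (generator id,
#'   parameters, seed, noise_sd).
#' @export
gen_feature_table <- function(n, generator = c("linear",
                                               "nonlinear_interaction",
                                               "hbond_dominant"),
                              noise_sd = 0.5, seed = 1L,
                              noise_feature = FALSE) {
  generator <- match.arg(generator)
  set.seed(seed)
  aa <- sample(AA3, n, replace = TRUE)
  nt <- sample(NT1, n, replace = TRUE)
  d <- stats::runif(n, 3, 12)
  hb <- sample(0:3, n, replace = TRUE, prob = c(0.45, 0.30, 0.17, 0.08))

  aa_scale <- stats::setNames(seq(0, 1, length.out = 20), AA3)
  aa_lin <- stats::setNames(seq(-1.5, 1.5, length.out = 20), AA3)
  nt_lin <- c(A = 0.5, C = -0.3, G = 0.8, U = -0.6)
  nt_depth <- c(A = 8, C = 6, G = 10, U = 7)

  f <- switch(generator,
    linear = -6 + aa_lin[aa] + nt_lin[nt] - 0.8 * d - 1.5 * hb,
    nonlinear_interaction = {
      d0 <- 2 + 2 * aa_scale[aa]
      depth <- nt_depth[nt] * (0.5 + aa_scale[aa])
      depth * ((1 - exp(-0.6 * (d - d0)))^2 - 1) - 1.5 * hb
    },
    hbond_dominant = -2.5 * hb - 0.15 * d
  )
  e <- unname(f) + stats::rnorm(n, 0, noise_sd)
  records <- data.frame(complex_id = "synthetic", aa = aa, nt = nt,
                        com_distance = d, hbonds = hb,
                        local_energy = e, stringsAsFactors = FALSE)
  if (noise_feature) records$noise_feat <- stats::rnorm(n)
  manifest <- list(generator = generator, n = n, noise_sd = noise_sd,
                   seed = seed,
                   params = list(aa_scale = aa_scale, aa_lin = aa_lin,
                                 nt_lin = nt_lin, nt_depth = nt_depth,
                                 hb_coef = 1.5),
                   true_signal = unname(f))
  list(records = records, manifest = manifest)
}

#' Oracle model returning generator ground-truth energies
#'
#' Builds a lookup model from one or more [gen_complex()] results; its
#' predictions for a record are the manifest's \code{true_energy} for the
#' matching (complex, protein residue, RNA residue) triple. Used to test the
#' scoring integration independently of any fitted regression.
#'
#' @param bases a single [gen_complex()] result or a list of them.
#' @return an object usable with [predict_local_energies()] and
#'   [score_complex()].
#' @export
oracle_model <- function(bases) {
  if (!is.null(bases$manifest)) bases <- list(bases)
  tab <- do.call(rbind, lapply(bases, function(b) {
    p <- b$manifest$pairs
    data.frame(key = paste(b$manifest$pdb_id, p$res_p, p$res_r, sep = "|"),
               energy = p$true_energy, stringsAsFactors = FALSE)
  }))
  structure(list(table = tab), class = "panther_oracle_model")
}

#' @export
predict_local_energies.panther_oracle_model <- function(model, records) {
  if (!nrow(records)) return(numeric(0))
  key <- paste(records$complex_id, records$res_p, records$res_r, sep = "|")
  m <- match(key, model$table$key)
  if (anyNA(m))
    stop_domain("oracle model has no ground truth for: %s",
                paste(unique(key[is.na(m)]), collapse = ", "))
  model$table$energy[m]
}
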