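#' Pairwise Lennard-Jones energy between two residue groups
#'
#' Sum over all atom pairs (a in group i, b in group j) of
#' \code{4*eps_ab*((sigma_ab/r_ab)^12 - (sigma_ab/r_ab)^6)}, kcal/mol.
#' Pair parameters come from the table's combining rules
#' (Lorentz-Berthelot by default: geometric-mean eps, arithmetic-mean sigma).
#' No atom-level distance cutoff is applied: group-pair selection happens
#' upstream at the center-of-mass level.
#'
#' @param x a \code{panther_structure} whose atoms carry eps/sigma.
#' @param group_i,group_j group ids.
#' @param params a [parameter_table()] supplying combining rules, dielectric
#'   and the Coulomb constant.
#' @param frame frame index.
#' @return kcal/mol.
#' @export
lj_energy <- function(x, group_i, group_j, params = default_parameter_table(),
                      frame = 1) {
  pe <- pair_energy_core(x, group_i, group_j, params, frame, what = "vdw")
  pe$e_vdw
}

#' Pairwise Coulomb energy between two residue groups
#'
#' Sum over all atom pairs of \code{k_e * q_a * q_b / (eps_r * r_ab)} with
#' \code{k_e} the table's \code{coulomb_constant} (default 332.0636
#' kcal A mol^-1 e^-2) and \code{eps_r} its relative dielectric constant.
#'
#' @inheritParams lj_energy
#' @return kcal/mol.
#' @export
coulomb_energy <- function(x, group_i, group_j,
                           params = default_parameter_table(), frame = 1) {
  pe <- pair_energy_core(x, group_i, group_j, params, frame, what = "elec")
  pe$e_elec
}

#' Total pairwise local interaction energy
#'
#' \code{E_ij = E_vdw,ij + E_elec,ij}: each component computed once over the
#' same atom-pair distances, the total being their exact sum.
#'
#' @inheritParams lj_energy
#' @return list with \code{e_vdw}, \code{e_elec}, \code{e_total} (kcal/mol).
#' @export
pair_energy <- function(x, group_i, group_j,
                        params = default_parameter_table(), frame = 1) {
  pair_energy_core(x, group_i, group_j, params, frame, what = "both")
}

#' @noRd
pair_energy_core <- function(x, group_i, group_j, params, frame, what) {
  stopifnot(inherits(x, "panther_structure"))
  ai <- group_atoms(x, group_i)
  aj <- group_atoms(x, group_j)
  xyz <- x$xyz[, , frame, drop = FALSE][, , 1]
  if (is.null(dim(xyz))) xyz <- matrix(xyz, ncol = 3)
  D <- cross_dist(xyz[ai, , drop = FALSE], xyz[aj, , drop = FALSE])
  if (any(D == 0))
    stop_domain("clashing atoms: zero interatomic distance between groups %s and %s",
                group_i, group_j)
  at <- x$atoms
  e_vdw <- e_elec <- 0
  if (what %in% c("vdw", "both")) {
    eps_i <- at$eps[ai]; eps_j <- at$eps[aj]
    sig_i <- at$sigma[ai]; sig_j <- at$sigma[aj]
    if (anyNA(eps_i) || anyNA(eps_j) || anyNA(sig_i) || anyNA(sig_j))
      stop_domain("atoms lack LJ parameters; extend the parameter table")
    eps_ab <- outer(eps_i, eps_j, params$combine_eps)
    sig_ab <- outer(sig_i, sig_j, params$combine_sigma)
    sr6 <- (sig_ab / D)^6
    e_vdw <- sum(4 * eps_ab * (sr6^2 - sr6))
  }
  if (what %in% c("elec", "both")) {
    q_i <- at$charge[ai]; q_j <- at$charge[aj]
    if (anyNA(q_i) || anyNA(q_j))
      stop_domain("atoms lack partial charges; extend the parameter table")
    e_elec <- params$coulomb_constant *
      sum(outer(q_i, q_j) / (params$dielectric * D))
  }
  list(e_vdw = e_vdw, e_elec = e_elec, e_total = e_vdw + e_elec)
}

#' Trajectory windowing scheme
#'
#' Defaults follow the decorrelation scheme used throughout the package:
#' energies are averaged over 10-frame windows separated by 40 skipped
#' frames, pairs are identified at a 12 A center-of-mass cutoff, and a pair
#' is retained only if present in at least 70 percent of analyzed frames
#' (inclusive threshold).
#'
#' @param window frames per averaging window (N), default 10.
#' @param skip frames skipped between windows, default 40.
#' @param persistence_threshold retention fraction, default 0.70.
#' @param r_cut COM cutoff in Angstrom, default 12.
#' @export
window_scheme <- function(window = 10, skip = 40,
                          persistence_threshold = 0.70, r_cut = 12) {
  if (window < 1 || skip < 0) stop_domain("require window >= 1 and skip >= 0")
  if (!(persistence_threshold > 0 && persistence_threshold <= 1))
    stop_domain("persistence_threshold must lie in (0, 1]")
  if (r_cut <= 0) stop_domain("r_cut must be > 0")
  structure(list(window = window, skip = skip,
                 persistence_threshold = persistence_threshold, r_cut = r_cut),
            class = "panther_window_scheme")
}

#' Analyzed frame blocks of a window/skip scheme
#'
#' Window blocks start at frame 1 and repeat every \code{window + skip}
#' frames; a trailing block shorter than \code{window} is discarded. With the
#' defaults (10/40), a 10,000-frame trajectory yields 200 blocks.
#'
#' @param total_frames trajectory length.
#' @param scheme a [window_scheme()].
#' @return list of integer vectors of 1-based frame indices.
#' @export
analyzed_frames <- function(total_frames, scheme = window_scheme()) {
  stopifnot(total_frames >= 0)
  stride <- scheme$window + scheme$skip
  starts <- seq(1L, by = stride,
                length.out = max(0L, (total_frames + scheme$skip) %/% stride))
  starts <- starts[starts + scheme$window - 1L <= total_frames]
  lapply(starts, function(s) seq.int(s, s + scheme$window - 1L))
}

#' Decompose a trajectory into per-pair time-averaged local energies
#'
#' For every amino-acid/nucleotide pair that comes within \code{r_cut}
#' (COM-COM) in any analyzed frame: presence is recorded per analyzed frame;
#' window means of the pairwise energy are taken over present frames only
#' (windows with no presence are excluded); \code{presence_fraction} is the
#' share of analyzed frames with the pair inside the cutoff; the pair is
#' retained iff \code{presence_fraction >= persistence_threshold}; and
#' \code{mean_local_energy} is the mean of the window means. Optionally the
#' presence-weighted mean COM distance and hydrogen-bond count are recorded
#' as trajectory-mode features.
#'
#' @param x a multi-frame \code{panther_structure}.
#' @param params [parameter_table()] (combining rules, dielectric).
#' @param scheme a [window_scheme()].
#' @param criteria [hbond_criteria()] for the per-frame H-bond counts.
#' @param compute_hbonds logical; set FALSE to skip H-bond counting.
#' @return a \code{panther_decomposition}: data.frame with one row per
#'   candidate pair (columns pair_id, chain_p, res_p, aa, chain_r, res_r, nt,
#'   n_windows, presence_fraction, retained, mean_e_vdw, mean_e_elec,
#'   mean_local_energy, mean_com_distance, mean_hbonds) carrying the
#'   per-window mean series as attribute \code{"window_means"}.
#' @export
decompose_trajectory <- function(x, params = default_parameter_table(),
                                 scheme = window_scheme(),
                                 criteria = hbond_criteria(),
                                 compute_hbonds = TRUE) {
  stopifnot(inherits(x, "panther_structure"))
  blocks <- analyzed_frames(n_frames(x), scheme)
  if (!length(blocks))
    stop_domain("trajectory too short: no complete %d-frame window", scheme$window)
  af <- unlist(blocks)
  g <- x$groups
  pid <- g$id[g$kind == "amino_acid"]
  rid <- g$id[g$kind == "nucleotide"]

  # COM distances for all candidate pairs in every analyzed frame
  dists <- array(NA_real_, dim = c(length(pid), length(rid), length(af)))
  for (k in seq_along(af)) {
    pc <- group_coms(x, pid, af[k])
    rc <- group_coms(x, rid, af[k])
    dists[, , k] <- cross_dist(pc, rc)
  }
  present <- dists <= scheme$r_cut
  ever <- which(apply(present, c(1, 2), any), arr.ind = TRUE)
  if (!nrow(ever)) ever <- matrix(integer(0), ncol = 2)

  frame_of <- af
  block_of <- rep(seq_along(blocks), vapply(blocks, length, 1L))

  rows <- vector("list", nrow(ever))
  wm_list <- vector("list", nrow(ever))
  for (q in seq_len(nrow(ever))) {
    i <- ever[q, 1]; j <- ever[q, 2]
    pg <- pid[i]; rg <- rid[j]
    pres <- present[i, j, ]
    wf <- numeric(0); wv <- numeric(0); we <- numeric(0)
    for (b in seq_along(blocks)) {
      sel <- which(block_of == b & pres)
      if (!length(sel)) next
      ev <- ee <- numeric(length(sel))
      for (s in seq_along(sel)) {
        pe <- pair_energy_core(x, pg, rg, params, frame_of[sel[s]], "both")
        ev[s] <- pe$e_vdw; ee[s] <- pe$e_elec
      }
      wf <- c(wf, b); wv <- c(wv, mean(ev)); we <- c(we, mean(ee))
    }
    hb <- NA_real_
    if (compute_hbonds && any(pres)) {
      sel <- which(pres)
      hb <- mean(vapply(sel, function(s)
        count_hbonds(x, pg, rg, criteria, frame_of[s]), numeric(1)))
    }
    pf <- mean(pres)
    rows[[q]] <- data.frame(
      pair_id = sprintf("%s%s-%s%s", g$chain[pg], g$seq_index[pg],
                        g$chain[rg], g$seq_index[rg]),
      p_group = pg, r_group = rg,
      chain_p = g$chain[pg], res_p = g$seq_index[pg], aa = g$type_code[pg],
      chain_r = g$chain[rg], res_r = g$seq_index[rg], nt = g$type_code[rg],
      n_windows = length(wf),
      presence_fraction = pf,
      retained = pf >= scheme$persistence_threshold,
      mean_e_vdw = if (length(wv)) mean(wv) else NA_real_,
      mean_e_elec = if (length(we)) mean(we) else NA_real_,
      mean_local_energy = if (length(wv)) mean(wv + we) else NA_real_,
      mean_com_distance = mean(dists[i, j, ][pres]),
      mean_hbonds = hb,
      stringsAsFactors = FALSE)
    wm_list[[q]] <- data.frame(window = wf, mean_e_vdw = wv, mean_e_elec = we,
                               mean_energy = wv + we)
  }
  out <- if (length(rows)) do.call(rbind, rows) else data.frame()
  if (nrow(out)) {
    ord <- order(out$chain_p, g$resno[out$p_group], out$chain_r,
                 g$resno[out$r_group])
    out <- out[ord, , drop = FALSE]
    wm_list <- wm_list[ord]
    rownames(out) <- NULL
    names(wm_list) <- out$pair_id
  }
  attr(out, "window_means") <- wm_list
  attr(out, "scheme") <- scheme
  attr(out, "pdb_id") <- x$pdb_id
  attr(out, "n_analyzed_frames") <- length(af)
  class(out) <- c("panther_decomposition", class(out))
  out
}

#' Write a trajectory decomposition as CSV
#'
#' @param decomp result of [decompose_trajectory()].
#' @param path output file.
#' @export
write_decomposition_csv <- function(decomp, path) {
  cols <- c("pair_id", "aa", "nt", "n_windows", "presence_fraction",
            "retained", "mean_e_vdw", "mean_e_elec", "mean_local_energy",
            "mean_com_distance", "mean_hbonds")
  df <- as.data.frame(decomp)[, cols, drop = FALSE]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
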