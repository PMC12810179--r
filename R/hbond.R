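#' Geometric hydrogen-bond criteria
#'
#' Distance and angle windows used by [count_hbonds()]. The hydrogen-acceptor
#' distance must be strictly below \code{max_h_acceptor_dist}; the
#' donor-H...acceptor angle, measured at the hydrogen (180 degrees = linear),
#' must lie within \code{[min_angle, max_angle]}. When a structure carries no
#' explicit hydrogen on a donor, one is placed at \code{placed_bond_length}
#' along the donor-to-acceptor unit vector (bond-vector placement); by
#' construction this makes the angle exactly 180 degrees, so for placed
#' hydrogens detection reduces to the distance test.
#'
#' @param max_h_acceptor_dist Angstrom, default 3.5.
#' @param min_angle,max_angle degrees, default window 120 to 180.
#' @param placed_bond_length Angstrom, default 1.0 (typical N-H / O-H).
#' @export
hbond_criteria <- function(max_h_acceptor_dist = 3.5,
                           min_angle = 120,
                           max_angle = 180,
                           placed_bond_length = 1.0) {
  if (!(min_angle > 0 && min_angle <= max_angle && max_angle <= 180))
    stop_domain("require 0 < min_angle <= max_angle <= 180")
  if (max_h_acceptor_dist < 0 || placed_bond_length <= 0)
    stop_domain("hydrogen-bond distances must be positive")
  structure(list(max_h_acceptor_dist = max_h_acceptor_dist,
                 min_angle = min_angle, max_angle = max_angle,
                 placed_bond_length = placed_bond_length),
            class = "panther_hbond_criteria")
}

# Donor/acceptor assignment: N/O heavy atoms bearing (or chemically implying)
# an H are donors; N/O atoms with lone pairs are acceptors. Residue keys
# "PROT" and "RNA" match any amino acid / any nucleotide; specific codes add
# side-chain or base atoms. Editable via options not needed: pass a modified
# table to count_hbonds().

.hb_table <- function() {
  d <- function(residue, atoms) data.frame(residue = residue, atom = atoms)
  donors <- rbind(
    d("PROT", "N"),
    d("ARG", c("NE", "NH1", "NH2")), d("ASN", "ND2"), d("GLN", "NE2"),
    d("HIS", c("ND1", "NE2")), d("LYS", "NZ"), d("SER", "OG"),
    d("THR", "OG1"), d("TRP", "NE1"), d("TYR", "OH"),
    d("RNA", "O2'"),
    d("A", "N6"), d("C", "N4"), d("G", c("N1", "N2")), d("U", "N3")
  )
  acceptors <- rbind(
    d("PROT", c("O", "OXT")),
    d("ASP", c("OD1", "OD2")), d("GLU", c("OE1", "OE2")),
    d("ASN", "OD1"), d("GLN", "OE1"), d("HIS", c("ND1", "NE2")),
    d("SER", "OG"), d("THR", "OG1"), d("TYR", "OH"),
    d("RNA", c("OP1", "OP2", "O1P", "O2P", "O5'", "O3'", "O4'", "O2'")),
    d("A", c("N1", "N3", "N7")), d("G", c("O6", "N3", "N7")),
    d("C", c("O2", "N3")), d("U", c("O2", "O4"))
  )
  list(donors = donors, acceptors = acceptors)
}

#' Default donor/acceptor atom table
#'
#' data.frames of heavy-atom names flagged as hydrogen-bond donors and
#' acceptors, keyed by residue code with the wildcards \code{"PROT"} (any
#' amino acid) and \code{"RNA"} (any nucleotide). Pass an edited copy to
#' [parse_structure()] to change the assignment.
#' @export
default_hbond_table <- function() .hb_table()

#' @noRd
flag_donors_acceptors <- function(atoms, hb_table = default_hbond_table()) {
  match_tab <- function(tab) {
    hit <- rep(FALSE, nrow(atoms))
    is_prot <- atoms$kind == "amino_acid"
    is_rna  <- atoms$kind == "nucleotide"
    key <- paste(atoms$resid, atoms$name)
    hit <- hit | key %in% paste(tab$residue, tab$atom)
    wp <- tab[tab$residue == "PROT", "atom"]
    wr <- tab[tab$residue == "RNA", "atom"]
    hit <- hit | (is_prot & atoms$name %in% wp)
    hit <- hit | (is_rna & atoms$name %in% wr)
    hit
  }
  atoms$donor <- match_tab(hb_table$donors)
  atoms$acceptor <- match_tab(hb_table$acceptors)
  atoms
}

#' Count geometric hydrogen bonds between two residue groups
#'
#' Enumerates donor/acceptor heavy-atom pairs across the two groups in both
#' directions (group-i donors against group-j acceptors and vice versa). For
#' donors carrying explicit hydrogens (element H within 1.25 A of the donor)
#' the real hydrogen geometry is tested; otherwise a hydrogen is placed by
#' the bond-vector method, \code{placed_bond_length} along the donor-acceptor
#' unit vector. A donor-acceptor pair counts once if any of its hydrogens
#' satisfies both the H...acceptor distance and the D-H...A angle window.
#'
#' @param x a \code{panther_structure}.
#' @param group_i,group_j group ids (rows of \code{x$groups}).
#' @param criteria a [hbond_criteria()] object.
#' @param frame frame index, default 1.
#' @return integer count >= 0.
#' @export
count_hbonds <- function(x, group_i, group_j,
                         criteria = hbond_criteria(), frame = 1) {
  stopifnot(inherits(x, "panther_structure"))
  xyz <- x$xyz[, , frame, drop = FALSE][, , 1]
  if (is.null(dim(xyz))) xyz <- matrix(xyz, ncol = 3)
  ai <- group_atoms(x, group_i)
  aj <- group_atoms(x, group_j)
  n <- count_dir(x, xyz, ai, aj, criteria) + count_dir(x, xyz, aj, ai, criteria)
  n
}

#' @noRd
count_dir <- function(x, xyz, don_idx, acc_idx, crit) {
  atoms <- x$atoms
  donors <- don_idx[atoms$donor[don_idx]]
  accs <- acc_idx[atoms$acceptor[acc_idx]]
  if (!length(donors) || !length(accs)) return(0L)
  # explicit hydrogens within the donor's own group
  hyd <- don_idx[atoms$element[don_idx] == "H"]
  total <- 0L
  for (d in donors) {
    D <- xyz[d, ]
    dh <- if (length(hyd)) hyd[sqrt(colSums((t(xyz[hyd, , drop = FALSE]) - D)^2)) < 1.25] else integer(0)
    for (a in accs) {
      A <- xyz[a, ]
      dDA <- sqrt(sum((A - D)^2))
      if (dDA <= 0) next
      if (length(dh)) {
        ok <- FALSE
        for (h in dh) {
          H <- xyz[h, ]
          dHA <- sqrt(sum((A - H)^2))
          if (dHA >= crit$max_h_acceptor_dist || dHA == 0) next
          v1 <- D - H; v2 <- A - H
          cosang <- sum(v1 * v2) / (sqrt(sum(v1^2)) * sqrt(sum(v2^2)))
          ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
          if (ang >= crit$min_angle && ang <= crit$max_angle) { ok <- TRUE; break }
        }
        if (ok) total <- total + 1L
      } else {
        if (dDA <= crit$placed_bond_length) next
        dHA <- dDA - crit$placed_bond_length  # H on the D->A segment
        # bond-vector placement is linear by construction: angle = 180
        if (dHA < crit$max_h_acceptor_dist &&
            crit$min_angle <= 180 && 180 <= crit$max_angle)
          total <- total + 1L
      }
    }
  }
  total
}
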