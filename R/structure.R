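#' Construct a protein-RNA complex structure object
#'
#' Low-level constructor used by [parse_structure()] and by the synthetic
#' generators; also convenient for building hand-specified configurations in
#' tests and examples. Residue groups (the units between which local energies
#' are defined) are derived from \code{(chain, resno, insert, resid)}; protein
#' groups are ordered before RNA groups, each sorted by chain then residue
#' number.
#'
#' @param atoms data.frame with columns \code{name}, \code{element},
#'   \code{resid} (3-letter amino-acid code or 1-letter base code),
#'   \code{chain}, \code{resno}; optional \code{insert}, \code{charge},
#'   \code{eps}, \code{sigma}, \code{mass}.
#' @param xyz coordinates: an \code{n_atoms x 3} matrix (single frame) or an
#'   \code{n_atoms x 3 x n_frames} array.
#' @param pdb_id identifier carried through to records and scores.
#' @param params optional [parameter_table()] used to fill charges, LJ
#'   parameters and masses not already present in \code{atoms}.
#' @param hb_table donor/acceptor table, see [default_hbond_table()].
#' @return object of class \code{panther_structure} with elements
#'   \code{atoms}, \code{groups}, \code{xyz}, \code{pdb_id}.
#' @export
panther_structure <- function(atoms, xyz, pdb_id = "complex",
                              params = NULL,
                              hb_table = default_hbond_table()) {
  stopifnot(is.data.frame(atoms), nrow(atoms) > 0)
  if (is.null(atoms$insert)) atoms$insert <- ""
  atoms$insert[is.na(atoms$insert)] <- ""
  if (length(dim(xyz)) == 2) xyz <- array(xyz, dim = c(dim(xyz), 1L))
  stopifnot(length(dim(xyz)) == 3, dim(xyz)[1] == nrow(atoms), dim(xyz)[2] == 3)
  if (!all(is.finite(xyz))) stop_domain("coordinates must be finite")

  kind <- ifelse(atoms$resid %in% AA3, "amino_acid",
                 ifelse(atoms$resid %in% NT1, "nucleotide", NA))
  drop <- is.na(kind)
  if (any(drop)) {
    warning(sprintf("skipping %d atom(s) in nonstandard residue(s): %s",
                    sum(drop), paste(unique(atoms$resid[drop]), collapse = ", ")))
    atoms <- atoms[!drop, , drop = FALSE]
    xyz <- xyz[!drop, , , drop = FALSE]
    kind <- kind[!drop]
  }
  if (!nrow(atoms)) stop_domain("no standard protein or RNA residues found")
  atoms$kind <- kind

  if (is.null(atoms$charge) || !is.null(params)) {
    for (f in c("charge", "eps", "sigma", "mass"))
      if (is.null(atoms[[f]])) atoms[[f]] <- NA_real_
    if (!is.null(params)) {
      filled <- assign_parameters(atoms[c("name", "element", "resid")], params)
      for (f in c("charge", "eps", "sigma", "mass")) {
        take <- is.na(atoms[[f]])
        atoms[[f]][take] <- filled[[f]][take]
      }
    }
  }
  if (is.null(atoms$mass)) atoms$mass <- NA_real_
  mm <- is.na(atoms$mass)
  atoms$mass[mm] <- unname(ELEMENT_MASS[atoms$element[mm]])
  if (any(is.na(atoms$mass) | atoms$mass <= 0))
    stop_domain("every atom needs a positive mass (unknown element?)")

  atoms <- flag_donors_acceptors(atoms, hb_table)

  # group key in input order, then reorder: protein first, by chain/resno
  key <- paste(atoms$kind, atoms$chain, atoms$resno, atoms$insert, atoms$resid,
               sep = "|")
  ord_groups <- unique(data.frame(kind = atoms$kind, chain = atoms$chain,
                                  resno = atoms$resno, insert = atoms$insert,
                                  resid = atoms$resid, key = key,
                                  stringsAsFactors = FALSE))
  ord_groups <- ord_groups[order(ord_groups$kind == "nucleotide",
                                 ord_groups$chain, ord_groups$resno,
                                 ord_groups$insert), , drop = FALSE]
  if (!any(ord_groups$kind == "amino_acid") ||
      !any(ord_groups$kind == "nucleotide"))
    stop_domain("structure must contain at least one protein residue and one RNA nucleotide")

  groups <- data.frame(
    id = seq_len(nrow(ord_groups)),
    kind = ord_groups$kind,
    type_code = ord_groups$resid,
    chain = ord_groups$chain,
    seq_index = paste0(ord_groups$resno, ord_groups$insert),
    resno = ord_groups$resno,
    stringsAsFactors = FALSE
  )
  atoms$group <- match(key, ord_groups$key)
  group_idx <- split(seq_len(nrow(atoms)), atoms$group)
  group_idx <- group_idx[as.character(groups$id)]

  structure(list(pdb_id = pdb_id, atoms = atoms, groups = groups,
                 xyz = xyz, group_idx = group_idx),
            class = "panther_structure")
}

#' @export
print.panther_structure <- function(x, ...) {
  cat(sprintf("panther_structure '%s': %d atoms, %d protein + %d RNA groups, %d frame(s)\n",
              x$pdb_id, nrow(x$atoms),
              sum(x$groups$kind == "amino_acid"),
              sum(x$groups$kind == "nucleotide"),
              n_frames(x)))
  invisible(x)
}

#' Number of frames in a structure
#' @param x a \code{panther_structure}.
#' @export
n_frames <- function(x) dim(x$xyz)[3]

#' Atom indices of a residue group
#' @param x a \code{panther_structure}.
#' @param group group id.
#' @export
group_atoms <- function(x, group) {
  idx <- x$group_idx[[group]]
  if (is.null(idx) || !length(idx)) stop_domain("empty or unknown group %s", group)
  idx
}

#' Parse a protein-RNA complex from PDB text or file
#'
#' Reads standard fixed-width PDB (ATOM/HETATM/MODEL/ENDMDL records); each
#' MODEL block becomes one frame with identical atom ordering. Atoms in
#' residues outside the 20 standard amino acids and the four ribonucleotides
#' are skipped with a warning. Parameters (charge, LJ, mass) are assigned
#' from \code{params} where the table covers the atom.
#'
#' @param pdb PDB-format text (any string containing a newline), or a path.
#' @param params a [parameter_table()]; default [default_parameter_table()].
#' @param pdb_id identifier; defaults to the file base name or "complex".
#' @param hb_table donor/acceptor assignment table.
#' @return a \code{panther_structure}.
#' @export
parse_structure <- function(pdb, params = default_parameter_table(),
                            pdb_id = NULL,
                            hb_table = default_hbond_table()) {
  if (length(pdb) == 1 && !grepl("\n", pdb)) {
    path <- pdb
    if (!file.exists(path)) stop_domain("no such file: %s", path)
    pdb_id <- pdb_id %||% sub("\\.(pdb|ent)$", "", basename(path))
    lines <- readLines(path, warn = FALSE)
  } else {
    lines <- unlist(strsplit(paste(pdb, collapse = "\n"), "\n", fixed = TRUE))
    pdb_id <- pdb_id %||% "complex"
  }
  validate_atom_lines(lines)
  tf <- tempfile(fileext = ".pdb")
  on.exit(unlink(tf), add = TRUE)
  writeLines(lines, tf)
  prs <- bio3d::read.pdb(tf, multi = TRUE, verbose = FALSE)

  at <- prs$atom
  if (!nrow(at)) stop_domain("no ATOM records found")
  element <- trimws(at$elesy %||% "")
  blank <- is.na(element) | element == ""
  element[blank] <- element_from_name(at$elety[blank])
  atoms <- data.frame(name = trimws(at$elety),
                      element = element,
                      resid = trimws(at$resid),
                      chain = ifelse(is.na(at$chain), "", at$chain),
                      resno = at$resno,
                      insert = ifelse(is.na(at$insert), "", at$insert),
                      stringsAsFactors = FALSE)
  nfr <- if (is.matrix(prs$xyz)) nrow(prs$xyz) else 1L
  xyz <- array(NA_real_, dim = c(nrow(atoms), 3, nfr))
  xm <- if (is.matrix(prs$xyz)) prs$xyz else matrix(prs$xyz, nrow = 1)
  if (ncol(xm) != 3 * nrow(atoms))
    stop_domain("inconsistent PDB: %d coordinates for %d atoms (records after END, or truncated MODEL block?)",
                ncol(xm), nrow(atoms))
  for (f in seq_len(nfr))
    xyz[, , f] <- matrix(xm[f, ], ncol = 3, byrow = TRUE)

  panther_structure(atoms, xyz, pdb_id = pdb_id, params = params,
                    hb_table = hb_table)
}

#' @noRd
validate_atom_lines <- function(lines) {
  is_atom <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(is_atom)) stop_domain("no ATOM records found")
  idx <- which(is_atom)
  for (i in idx) {
    ln <- lines[i]
    if (nchar(ln) < 54)
      stop_domain("malformed ATOM line %d: too short (%d chars)", i, nchar(ln))
    coords <- suppressWarnings(as.numeric(c(substr(ln, 31, 38),
                                            substr(ln, 39, 46),
                                            substr(ln, 47, 54))))
    if (any(is.na(coords)))
      stop_domain("malformed ATOM line %d: unreadable coordinates", i)
  }
  invisible(TRUE)
}

#' Serialize a structure back to PDB text
#'
#' Fixed-width ATOM records, one MODEL block per frame when multi-frame.
#' Coordinates are written at the PDB's 3-decimal precision.
#'
#' @param x a \code{panther_structure}.
#' @param frames frames to write; default all.
#' @return character scalar of PDB text.
#' @export
write_structure_pdb <- function(x, frames = seq_len(n_frames(x))) {
  stopifnot(inherits(x, "panther_structure"))
  atoms <- x$atoms
  multi <- length(frames) > 1
  out <- character(0)
  serial <- seq_len(nrow(atoms))
  for (f in frames) {
    if (multi) out <- c(out, sprintf("MODEL     %4d", match(f, frames)))
    xyzf <- x$xyz[, , f]
    nm <- ifelse(nchar(atoms$name) < 4, paste0(" ", atoms$name), atoms$name)
    recs <- sprintf("ATOM  %5d %-4s %-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                    serial, nm, atoms$resid, atoms$chain, atoms$resno,
                    atoms$insert, xyzf[, 1], xyzf[, 2], xyzf[, 3],
                    1.00, 0.00, atoms$element)
    out <- c(out, recs, if (multi) "ENDMDL")
  }
  paste(c(out, "END", ""), collapse = "\n")
}

#' Center of mass of a residue group
#'
#' Mass-weighted mean of the group's atom coordinates at one frame.
#'
#' @param x a \code{panther_structure}.
#' @param group group id.
#' @param frame frame index.
#' @return numeric length-3 vector, Angstrom.
#' @export
center_of_mass <- function(x, group, frame = 1) {
  idx <- group_atoms(x, group)
  m <- x$atoms$mass[idx]
  if (any(m <= 0)) stop_domain("center_of_mass requires positive masses")
  xyz <- x$xyz[idx, , frame, drop = FALSE][, , 1, drop = TRUE]
  if (is.null(dim(xyz))) xyz <- matrix(xyz, ncol = 3)
  colSums(xyz * m) / sum(m)
}

#' @noRd
group_coms <- function(x, ids, frame = 1) {
  t(vapply(ids, function(g) center_of_mass(x, g, frame), numeric(3)))
}

#' Interface pairs within a center-of-mass cutoff
#'
#' Every (amino acid, nucleotide) group pair whose COM-COM distance is less
#' than or equal to \code{cutoff} (the boundary is inclusive). Ordered by
#' protein chain/residue then RNA chain/residue, so output is deterministic
#' and independent of atom ordering.
#'
#' @param x a \code{panther_structure}.
#' @param frame frame index.
#' @param cutoff Angstrom; default 12.
#' @return data.frame with columns p_group, r_group, chain_p, res_p, aa,
#'   chain_r, res_r, nt, com_distance. Zero rows allowed.
#' @export
find_pairs <- function(x, frame = 1, cutoff = 12) {
  stopifnot(inherits(x, "panther_structure"))
  if (cutoff <= 0) stop_domain("cutoff must be > 0")
  g <- x$groups
  pid <- g$id[g$kind == "amino_acid"]
  rid <- g$id[g$kind == "nucleotide"]
  pc <- group_coms(x, pid, frame)
  rc <- group_coms(x, rid, frame)
  d <- cross_dist(pc, rc)
  hit <- which(d <= cutoff, arr.ind = TRUE)
  if (!nrow(hit)) {
    return(data.frame(p_group = integer(0), r_group = integer(0),
                      chain_p = character(0), res_p = character(0),
                      aa = character(0), chain_r = character(0),
                      res_r = character(0), nt = character(0),
                      com_distance = numeric(0), stringsAsFactors = FALSE))
  }
  p <- pid[hit[, 1]]; r <- rid[hit[, 2]]
  out <- data.frame(
    p_group = p, r_group = r,
    chain_p = g$chain[p], res_p = g$seq_index[p], aa = g$type_code[p],
    chain_r = g$chain[r], res_r = g$seq_index[r], nt = g$type_code[r],
    com_distance = d[hit], stringsAsFactors = FALSE)
  ord <- order(out$chain_p, g$resno[out$p_group], out$chain_r,
               g$resno[out$r_group])
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}
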