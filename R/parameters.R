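#' Nonbonded parameter table
#'
#' Holds the per-atom parameters needed for pairwise energy calculations:
#' partial charge (elementary charge units), Lennard-Jones well depth
#' \code{eps} (kcal/mol), zero-crossing distance \code{sigma} (Angstrom), and
#' mass (amu), together with the global relative dielectric constant and the
#' Coulomb conversion constant.
#'
#' Rows are matched to atoms with decreasing specificity: an exact
#' \code{(residue, atom)} row first, then a \code{residue == "*"} row matching
#' the atom name in any residue, then a \code{residue == "element"} row
#' matching the element symbol. Each field (charge, eps, sigma, mass) is taken
#' from the most specific row in which it is non-missing, so a charge-only
#' override row can sit on top of element-level LJ defaults.
#'
#' @param entries data.frame with columns \code{residue}, \code{atom},
#'   \code{charge}, \code{eps}, \code{sigma}, \code{mass}.
#' @param dielectric relative permittivity used in the Coulomb term; must be
#'   positive. Defaults to 1 (the trained regression absorbs overall scale).
#' @param coulomb_constant conversion constant k_e in kcal A mol^-1 e^-2.
#' @param combine_eps,combine_sigma combining rules producing pair parameters
#'   from per-atom values; defaults are Lorentz-Berthelot (geometric mean for
#'   eps, arithmetic mean for sigma). Override to supply pre-combined rules.
#' @return object of class \code{panther_params}.
#' @export
parameter_table <- function(entries,
                            dielectric = 1.0,
                            coulomb_constant = 332.0636,
                            combine_eps = function(ea, eb) sqrt(ea * eb),
                            combine_sigma = function(sa, sb) (sa + sb) / 2) {
  stopifnot(is.data.frame(entries))
  need <- c("residue", "atom", "charge", "eps", "sigma", "mass")
  miss <- setdiff(need, names(entries))
  if (length(miss))
    stop_domain("parameter table lacks column(s): %s", paste(miss, collapse = ", "))
  if (!is.numeric(dielectric) || dielectric <= 0)
    stop_domain("dielectric must be > 0")
  bad <- !is.na(entries$sigma) & entries$sigma <= 0
  if (any(bad))
    stop_domain("all sigma values must be > 0")
  structure(list(entries = entries[need],
                 dielectric = dielectric,
                 coulomb_constant = coulomb_constant,
                 combine_eps = combine_eps,
                 combine_sigma = combine_sigma),
            class = "panther_params")
}

#' Bundled generic parameter set
#'
#' A compact, element-based nonbonded parameter set covering the 20 standard
#' amino acids and the four ribonucleotides: element-level Lennard-Jones
#' depths/radii and masses, plus name-level partial charges for backbone,
#' phosphate, sugar and base heteroatoms. These are generic magnitudes in the
#' range of common biomolecular force fields, not any published force field;
#' they give physically shaped (repulsive core, attractive tail,
#' charge-signed) energies whose absolute scale the downstream regression
#' model absorbs. Replace via [read_parameter_table()] for production work
#' with a real force field.
#'
#' @inheritParams parameter_table
#' @return \code{panther_params} object.
#' @export
default_parameter_table <- function(dielectric = 1.0) {
  ele <- data.frame(
    residue = "element",
    atom   = c("H", "C", "N", "O", "P", "S"),
    charge = 0,
    eps    = c(0.0157, 0.0860, 0.1700, 0.2100, 0.2000, 0.2500),
    sigma  = c(2.00, 3.40, 3.25, 2.96, 3.74, 3.56),
    mass   = c(1.008, 12.011, 14.007, 15.999, 30.974, 32.06)
  )
  chg <- function(atom, charge)
    data.frame(residue = "*", atom = atom, charge = charge,
               eps = NA_real_, sigma = NA_real_, mass = NA_real_)
  charges <- rbind(
    # protein backbone
    chg("N", -0.40), chg("CA", 0.05), chg("C", 0.55), chg("O", -0.55),
    chg("OXT", -0.55), chg("CB", 0.00),
    # charged / polar side-chain termini
    chg("NZ", 0.30), chg("NE", -0.30), chg("NH1", 0.30), chg("NH2", 0.30),
    chg("OD1", -0.55), chg("OD2", -0.55), chg("OE1", -0.55), chg("OE2", -0.55),
    chg("OG", -0.45), chg("OG1", -0.45), chg("OH", -0.45),
    chg("ND1", -0.30), chg("ND2", -0.60), chg("NE1", -0.30), chg("NE2", -0.30),
    chg("SG", -0.10), chg("SD", -0.10),
    # nucleotide phosphate and sugar
    chg("P", 1.10), chg("OP1", -0.70), chg("OP2", -0.70),
    chg("O1P", -0.70), chg("O2P", -0.70),
    chg("O5'", -0.45), chg("O3'", -0.45), chg("O4'", -0.35), chg("O2'", -0.45),
    chg("C1'", 0.10), chg("C2'", 0.05), chg("C3'", 0.05), chg("C4'", 0.05),
    chg("C5'", 0.05),
    # base heteroatoms
    chg("N1", -0.30), chg("N3", -0.30), chg("N7", -0.30), chg("N9", -0.05),
    chg("N2", -0.60), chg("N4", -0.60), chg("N6", -0.60),
    chg("O2", -0.50), chg("O4", -0.50), chg("O6", -0.50)
  )
  parameter_table(rbind(charges, ele), dielectric = dielectric)
}

#' Read / write a parameter table
#'
#' Plain TSV with columns residue, atom, charge, eps, sigma, mass; the global
#' keys are passed separately (or read from a JSON sidecar via
#' \code{dielectric}/\code{coulomb_constant} arguments).
#'
#' @param path file path.
#' @inheritParams parameter_table
#' @export
read_parameter_table <- function(path, dielectric = 1.0,
                                 coulomb_constant = 332.0636) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  parameter_table(tab, dielectric = dielectric,
                  coulomb_constant = coulomb_constant)
}

#' @rdname read_parameter_table
#' @param params a \code{panther_params} object.
#' @export
write_parameter_table <- function(params, path) {
  stopifnot(inherits(params, "panther_params"))
  utils::write.table(params$entries, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Assign charges, LJ parameters and masses to an atom table.
#'
#' @param atoms data.frame with columns name, element, resid.
#' @param params panther_params.
#' @return atoms with columns charge, eps, sigma, mass filled where covered.
#' @noRd
assign_parameters <- function(atoms, params) {
  e <- params$entries
  key_exact <- paste(e$residue, e$atom, sep = "|")
  key_star  <- e$atom[e$residue == "*"]
  star      <- e[e$residue == "*", , drop = FALSE]
  elem      <- e[e$residue == "element", , drop = FALSE]

  n <- nrow(atoms)
  out <- data.frame(charge = rep(NA_real_, n), eps = NA_real_,
                    sigma = NA_real_, mass = NA_real_)
  fill <- function(out, rows, idx) {
    for (f in c("charge", "eps", "sigma", "mass")) {
      take <- is.na(out[[f]][idx]) & !is.na(rows[[f]])
      out[[f]][idx[take]] <- rows[[f]][take]
    }
    out
  }
  # most specific: (residue, atom)
  m <- match(paste(atoms$resid, atoms$name, sep = "|"), key_exact)
  has <- which(!is.na(m))
  if (length(has)) out <- fill(out, e[m[has], , drop = FALSE], has)
  # any-residue atom-name rows
  m <- match(atoms$name, star$atom)
  has <- which(!is.na(m))
  if (length(has)) out <- fill(out, star[m[has], , drop = FALSE], has)
  # element fallback
  m <- match(atoms$element, elem$atom)
  has <- which(!is.na(m))
  if (length(has)) out <- fill(out, elem[m[has], , drop = FALSE], has)
  # mass fallback from the built-in element masses
  mm <- is.na(out$mass)
  out$mass[mm] <- unname(ELEMENT_MASS[atoms$element[mm]])
  cbind(atoms, out)
}
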