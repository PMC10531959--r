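#' Read a protonated protein-ligand complex from a PDB file
#'
#' Parses a PDB file and splits it into receptor and ligand atom tables.
#' The ligand must be present as a single HETATM residue carrying explicit
#' hydrogen atoms: the intermolecular restraints are measured from the
#' ligand protons, so an un-protonated X-ray structure must be protonated
#' with an external tool before use.
#'
#' @param path Path to a PDB file.
#' @param ligand_residue_name Three-letter (or PDB het-code) residue name of
#'   the ligand.
#' @return An object of class `nmr2_complex`: a list with tibbles `receptor`
#'   and `ligand` (columns `residue_number`, `residue_name`, `atom`,
#'   `element`, `x`, `y`, `z`), all coordinates in Angstrom in the fixed
#'   receptor frame.
#' @export
read_complex <- function(path, ligand_residue_name) {
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  elem <- at$elesy
  if (is.null(elem) || all(is.na(elem)) || all(elem == "")) {
    elem <- sub("^[0-9']*", "", at$elety)
    elem <- toupper(substr(elem, 1, 1))
  }
  elem <- toupper(trimws(elem))
  atoms <- tibble(
    residue_number = at$resno,
    residue_name = trimws(at$resid),
    chain = ifelse(is.na(at$chain), "", at$chain),
    atom = trimws(at$elety),
    element = elem,
    x = at$x, y = at$y, z = at$z,
    hetero = at$type == "HETATM"
  )
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z))) {
    abort("non-finite coordinates in PDB file")
  }
  lig <- dplyr::filter(atoms, .data$residue_name == ligand_residue_name)
  if (nrow(lig) == 0) {
    abort(paste0("ligand residue '", ligand_residue_name, "' not found in ", path))
  }
  copies <- dplyr::distinct(lig, .data$chain, .data$residue_number)
  if (nrow(copies) > 1) {
    abort(paste0("ambiguous ligand: ", nrow(copies), " copies of residue '",
                 ligand_residue_name, "' present; extract one copy first"))
  }
  if (!any(lig$element == "H")) {
    abort(paste0("ligand '", ligand_residue_name, "' carries no hydrogen atoms; ",
                 "protonate the structure (e.g. with reduce or openbabel) first"))
  }
  rec <- dplyr::filter(atoms, .data$residue_name != ligand_residue_name)
  new_complex(
    receptor = dplyr::select(rec, -"hetero"),
    ligand = dplyr::select(lig, -"hetero")
  )
}

#' Construct a complex from atom tables
#'
#' Builds an `nmr2_complex` directly from receptor and ligand atom tibbles
#' (columns `residue_number`, `residue_name`, `atom`, `element`, `x`, `y`,
#' `z`). Used by the synthetic benchmark generator and useful for
#' programmatic fixtures.
#'
#' @param receptor,ligand Atom tibbles.
#' @return An `nmr2_complex`.
#' @export
new_complex <- function(receptor, ligand) {
  structure(list(receptor = as_tibble(receptor), ligand = as_tibble(ligand)),
            class = "nmr2_complex")
}

#' @export
print.nmr2_complex <- function(x, ...) {
  cat("<nmr2_complex> receptor:", nrow(x$receptor), "atoms; ligand:",
      nrow(x$ligand), "atoms (", sum(x$ligand$element == "H"), "protons )\n")
  invisible(x)
}

#' Binding-site methyl groups of a complex
#'
#' Returns every methyl carbon of an ALA/VAL/LEU/ILE/THR/MET residue whose
#' carbon lies within `cutoff` of any ligand proton. These methyls are the
#' trilateration beacons of the restraint network; distances are always
#' measured to the methyl carbon, never to its rotor protons.
#'
#' @param complex An `nmr2_complex`.
#' @param cutoff Distance cutoff in Angstrom from any ligand proton to the
#'   methyl carbon (default 7).
#' @return A tibble of methyl sites: `site_id`, `residue_number`,
#'   `residue_type`, `methyl_atom_name`, `x`, `y`, `z`, ordered by residue
#'   number then atom name.
#' @export
find_binding_site_methyls <- function(complex, cutoff = 7) {
  stopifnot(inherits(complex, "nmr2_complex"), cutoff > 0)
  protons <- ligand_protons(complex)
  cand <- dplyr::inner_join(
    complex$receptor, .methyl_table,
    by = c("residue_name" = "residue_type", "atom" = "methyl_atom_name"),
    keep = TRUE
  )
  if (nrow(cand) == 0 || nrow(protons) == 0) {
    return(empty_methyl_tbl())
  }
  pm <- coords_matrix(protons)
  cm <- coords_matrix(cand)
  # min distance of each candidate carbon to any ligand proton
  mind <- apply(cm, 1, function(c) min(sqrt(colSums((t(pm) - c)^2))))
  keep <- cand[mind <= cutoff, , drop = FALSE]
  out <- tibble(
    residue_number = keep$residue_number,
    residue_type = keep$residue_type,
    methyl_atom_name = keep$methyl_atom_name,
    x = keep$x, y = keep$y, z = keep$z
  )
  out <- dplyr::arrange(out, .data$residue_number, .data$methyl_atom_name)
  out$site_id <- paste0(out$residue_type, out$residue_number, ":",
                        out$methyl_atom_name)
  dplyr::select(out, "site_id", dplyr::everything())
}

empty_methyl_tbl <- function() {
  tibble(site_id = character(), residue_number = integer(),
         residue_type = character(), methyl_atom_name = character(),
         x = double(), y = double(), z = double())
}

#' Ligand protons of a complex
#'
#' All hydrogen atoms of the ligand, each reported as an individual proton
#' (rotor protons are never collapsed to pseudo-atoms).
#'
#' @param complex An `nmr2_complex`.
#' @return A tibble: `proton_id`, `parent_heavy_atom`, `x`, `y`, `z`,
#'   ordered by atom name.
#' @export
ligand_protons <- function(complex) {
  stopifnot(inherits(complex, "nmr2_complex"))
  h <- dplyr::filter(complex$ligand, .data$element == "H")
  heavy <- dplyr::filter(complex$ligand, .data$element != "H")
  parent <- rep(NA_character_, nrow(h))
  if (nrow(heavy) > 0 && nrow(h) > 0) {
    hm <- coords_matrix(h)
    km <- coords_matrix(heavy)
    parent <- apply(hm, 1, function(p) {
      heavy$atom[which.min(colSums((t(km) - p)^2))]
    })
  }
  out <- tibble(proton_id = h$atom, parent_heavy_atom = parent,
                x = h$x, y = h$y, z = h$z)
  dplyr::arrange(out, .data$proton_id)
}

#' Write methyl sites to JSON
#'
#' @param sites A methyl-site tibble from [find_binding_site_methyls()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_methyl_sites <- function(sites, path) {
  jsonlite::write_json(sites, path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' Read methyl sites from JSON
#'
#' @param path Path written by [write_methyl_sites()].
#' @return A methyl-site tibble.
#' @export
read_methyl_sites <- function(path) {
  as_tibble(jsonlite::read_json(path, simplifyVector = TRUE))
}
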