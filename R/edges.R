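#' Hydrogen-bonding edge definitions
#'
#' Per-base edge atom sets in the Leontis-Westhof taxonomy, annotated as
#' hydrogen-bond donors (with the names of their attached hydrogens) or
#' acceptors. The arginine guanidinium group is carried as an additional
#' "edge" with donors NE, NH1 and NH2, plus the backbone amide donor N.
#'
#' Edge sets used:
#' * C  Watson-Crick: N4 (donor), N3, O2 (acceptors)
#' * G  Watson-Crick: N1, N2 (donors), O6 (acceptor); Hoogsteen: O6, N7 (acceptors)
#' * A  Watson-Crick: N6 (donor), N1 (acceptor); Hoogsteen: N6 (donor), N7 (acceptor)
#' * U  Watson-Crick: N3 (donor), O2, O4 (acceptors)
#' * ARG guanidinium: NE, NH1, NH2 (donors); backbone: N (donor)
#'
#' Hydrogen names follow the PDB chemical component dictionary
#' (H41/H42, H61/H62, H21/H22, H1, H3, HE, HH11/HH12, HH21/HH22, H).
#'
#' @return A tibble with columns `resname`, `edge`, `atom`, `role`
#'   (`"donor"`/`"acceptor"`) and `hydrogens` (comma-separated hydrogen atom
#'   names, empty for acceptors).
#' @export
edge_table <- function() {
  tibble::tribble(
    ~resname, ~edge,         ~atom,  ~role,      ~hydrogens,
    "C",      "WC",          "N4",   "donor",    "H41,H42",
    "C",      "WC",          "N3",   "acceptor", "",
    "C",      "WC",          "O2",   "acceptor", "",
    "G",      "WC",          "N1",   "donor",    "H1",
    "G",      "WC",          "N2",   "donor",    "H21,H22",
    "G",      "WC",          "O6",   "acceptor", "",
    "G",      "Hoogsteen",   "O6",   "acceptor", "",
    "G",      "Hoogsteen",   "N7",   "acceptor", "",
    "A",      "WC",          "N6",   "donor",    "H61,H62",
    "A",      "WC",          "N1",   "acceptor", "",
    "A",      "Hoogsteen",   "N6",   "donor",    "H61,H62",
    "A",      "Hoogsteen",   "N7",   "acceptor", "",
    "U",      "WC",          "N3",   "donor",    "H3",
    "U",      "WC",          "O2",   "acceptor", "",
    "U",      "WC",          "O4",   "acceptor", "",
    "ARG",    "guanidinium", "NE",   "donor",    "HE",
    "ARG",    "guanidinium", "NH1",  "donor",    "HH11,HH12",
    "ARG",    "guanidinium", "NH2",  "donor",    "HH21,HH22",
    "ARG",    "backbone",    "N",    "donor",    "H"
  )
}

#' Ring atom sets used for base-stacking centres of mass
#'
#' Purine rings are the fused 9-atom system, pyrimidine rings the 6-atom
#' system; exocyclic atoms are excluded. The planar guanidinium group of
#' arginine is treated as a 4-atom "ring" (CZ, NE, NH1, NH2) so that
#' base/guanidinium pi stacking can be measured with the same metric.
#'
#' @param resname Residue name (`"A"`, `"C"`, `"G"`, `"U"` or `"ARG"`).
#' @return Character vector of heavy-atom names.
#' @export
ring_atoms <- function(resname) {
  purine <- c("N1", "C2", "N3", "C4", "C5", "C6", "N7", "C8", "N9")
  pyrimidine <- c("N1", "C2", "N3", "C4", "C5", "C6")
  switch(resname,
    A = purine, G = purine,
    C = pyrimidine, U = pyrimidine,
    ARG = c("CZ", "NE", "NH1", "NH2"),
    rlang::abort(
      sprintf("no ring definition for residue type '%s'", resname),
      class = "car_classification_error"
    )
  )
}

#' Backbone atom names for RMSD selections
#'
#' @param kind `"protein"` (N, CA, C, O) or `"nucleic"` (P, O5', C5', C4',
#'   C3', O3').
#' @return Character vector of atom names.
#' @export
backbone_atoms <- function(kind = c("protein", "nucleic")) {
  kind <- match.arg(kind)
  if (kind == "protein") c("N", "CA", "C", "O") else c("P", "O5'", "C5'", "C4'", "C3'", "O3'")
}

# Standard atomic masses (u) for mass-weighted centres of heavy atoms.
ATOMIC_MASS <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, P = 30.974, S = 32.06)

atom_masses <- function(elements) {
  m <- ATOMIC_MASS[toupper(elements)]
  if (any(is.na(m))) {
    rlang::abort(
      paste0("no atomic mass for element(s): ", paste(unique(elements[is.na(m)]), collapse = ", ")),
      class = "car_geometry_error"
    )
  }
  unname(m)
}

# Is this residue type a purine / pyrimidine / amino acid in our vocabulary?
is_nucleotide <- function(resname) resname %in% c("A", "C", "G", "U")
is_purine <- function(resname) resname %in% c("A", "G")

# Donor/acceptor candidates for a structure: all edge-table entries present
# plus common off-edge sites (sugar O2' donor/acceptor, phosphate OP1/OP2
# acceptors) so that off-edge hydrogen bonding is seen, not silently dropped.
#' Enumerate hydrogen-bond donor and acceptor candidates in a structure
#'
#' Donors and acceptors are drawn from [edge_table()] for every residue whose
#' type is known there, extended with the nucleotide sugar O2' hydroxyl
#' (donor and acceptor) and the phosphate oxygens OP1/OP2 (acceptors), which
#' participate in off-edge contacts.
#'
#' @param s A [car_structure].
#' @return A list with tibbles `donors` and `acceptors`, each with columns
#'   `chain`, `resno`, `resname`, `atom` (and `hydrogens` for donors).
#' @export
hbond_candidates <- function(s) {
  res <- dplyr::distinct(s, .data$chain, .data$resno, .data$resname)
  et <- edge_table()
  base <- res |>
    dplyr::inner_join(et, by = "resname", relationship = "many-to-many") |>
    dplyr::semi_join(s, by = c("chain", "resno", "atom"))
  nuc <- dplyr::filter(res, is_nucleotide(.data$resname))
  extra_d <- nuc |>
    dplyr::mutate(edge = "off-edge", atom = "O2'", role = "donor", hydrogens = "HO2'")
  extra_a <- dplyr::bind_rows(
    dplyr::mutate(nuc, atom = "O2'"),
    dplyr::mutate(nuc, atom = "OP1"),
    dplyr::mutate(nuc, atom = "OP2")
  ) |>
    dplyr::mutate(edge = "off-edge", role = "acceptor", hydrogens = "")
  extra <- dplyr::bind_rows(extra_d, extra_a) |>
    dplyr::semi_join(s, by = c("chain", "resno", "atom"))
  all <- dplyr::bind_rows(base, extra) |>
    dplyr::distinct(.data$chain, .data$resno, .data$resname, .data$atom, .data$role, .data$hydrogens)
  list(
    donors = all |>
      dplyr::filter(.data$role == "donor") |>
      dplyr::select("chain", "resno", "resname", "atom", "hydrogens"),
    acceptors = all |>
      dplyr::filter(.data$role == "acceptor") |>
      dplyr::distinct(.data$chain, .data$resno, .data$resname, .data$atom)
  )
}
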