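#' Atomic structure and trajectory containers
#'
#' A `car_structure` is a tibble of atoms with one row per atom and columns
#' `chain`, `resno`, `resname`, `atom`, `element`, `x`, `y`, `z`. Residue
#' identity is always the pair (`chain`, `resno`) using the author numbering
#' of the source file; no renumbering is ever performed silently.
#'
#' @param atoms A data frame with the columns listed above. `resno` is coerced
#'   to integer, coordinates to double.
#' @return A tibble of class `car_structure`.
#' @export
car_structure <- function(atoms) {
  needed <- c("chain", "resno", "resname", "atom", "element", "x", "y", "z")
  missing <- setdiff(needed, names(atoms))
  if (length(missing) > 0) {
    rlang::abort(
      paste0("atom table is missing columns: ", paste(missing, collapse = ", ")),
      class = "car_format_error"
    )
  }
  atoms <- tibble::as_tibble(atoms)[needed]
  atoms$resno <- as.integer(atoms$resno)
  atoms$x <- as.double(atoms$x)
  atoms$y <- as.double(atoms$y)
  atoms$z <- as.double(atoms$z)
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
    rlang::abort("non-finite coordinates in atom table", class = "car_format_error")
  }
  dup <- atoms |>
    dplyr::count(.data$chain, .data$resno, .data$atom) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    rlang::abort(
      paste0(
        "duplicated atom names within a residue: ",
        paste(paste0(dup$chain, ":", dup$resno, "/", dup$atom), collapse = ", ")
      ),
      class = "car_format_error"
    )
  }
  class(atoms) <- c("car_structure", class(tibble::tibble()))
  atoms
}

#' @export
print.car_structure <- function(x, ...) {
  nres <- nrow(dplyr::distinct(x, .data$chain, .data$resno))
  cat(sprintf(
    "<car_structure> %d atoms, %d residues, %d chain(s)\n",
    nrow(x), nres, length(unique(x$chain))
  ))
  NextMethod()
}

#' Coordinate matrix of a structure
#'
#' @param s A `car_structure`.
#' @return A numeric matrix with one row per atom and columns x, y, z.
#' @export
coords <- function(s) {
  as.matrix(s[, c("x", "y", "z")])
}

#' Replace the coordinates of a structure
#'
#' @param s A `car_structure`.
#' @param xyz A matrix with one row per atom (same order as `s`) or a numeric
#'   vector of length `3 * nrow(s)` in x1,y1,z1,x2,... order.
#' @return The structure with coordinates replaced.
#' @export
set_coords <- function(s, xyz) {
  if (is.vector(xyz)) xyz <- matrix(xyz, ncol = 3, byrow = TRUE)
  stopifnot(nrow(xyz) == nrow(s), ncol(xyz) == 3)
  s$x <- xyz[, 1]
  s$y <- xyz[, 2]
  s$z <- xyz[, 3]
  s
}

#' Extract one residue from a structure
#'
#' @param s A `car_structure`.
#' @param chain Chain identifier.
#' @param resno Author residue number.
#' @return A `car_structure` containing just that residue's atoms.
#' @export
residue_atoms <- function(s, chain, resno) {
  out <- dplyr::filter(s, .data$chain == !!chain, .data$resno == !!resno)
  if (nrow(out) == 0) {
    rlang::abort(
      sprintf("residue %s:%s not found", chain, resno),
      class = "car_lookup_error"
    )
  }
  out
}

#' Read-out of a chain's residue sequence
#'
#' Single-letter codes are the residue names themselves for standard
#' ribonucleotides (A, C, G, U).
#'
#' @param s A `car_structure`.
#' @param chain Chain identifier.
#' @return Character vector of residue names in residue-number order.
#' @export
chain_sequence <- function(s, chain) {
  s |>
    dplyr::filter(.data$chain == !!chain) |>
    dplyr::distinct(.data$resno, .data$resname) |>
    dplyr::arrange(.data$resno) |>
    dplyr::pull(.data$resname)
}

#' Trajectory container
#'
#' A `car_trajectory` bundles a fixed topology (`car_structure`) with an
#' `n_frames x (3 * n_atoms)` coordinate matrix (x1,y1,z1,x2,... per row, the
#' bio3d `xyz` convention) and a sampling rate in frames per nanosecond.
#'
#' @param topology A `car_structure` giving the fixed atom order.
#' @param xyz Coordinate matrix, one row per frame.
#' @param frames_per_ns Positive sampling rate.
#' @return An object of class `car_trajectory`.
#' @export
car_trajectory <- function(topology, xyz, frames_per_ns = 100) {
  if (!inherits(topology, "car_structure")) topology <- car_structure(topology)
  if (is.vector(xyz)) xyz <- matrix(xyz, nrow = 1)
  if (ncol(xyz) != 3 * nrow(topology)) {
    rlang::abort("xyz width does not match 3 * atom count", class = "car_format_error")
  }
  if (nrow(xyz) == 0) {
    rlang::abort("trajectory has zero frames", class = "car_empty_trajectory_error")
  }
  if (!all(is.finite(xyz))) {
    rlang::abort("non-finite trajectory coordinates", class = "car_format_error")
  }
  if (!is.numeric(frames_per_ns) || length(frames_per_ns) != 1 || frames_per_ns <= 0) {
    rlang::abort("frames_per_ns must be a positive number", class = "car_format_error")
  }
  structure(
    list(topology = topology, xyz = unname(as.matrix(xyz)), frames_per_ns = frames_per_ns),
    class = "car_trajectory"
  )
}

#' @export
print.car_trajectory <- function(x, ...) {
  cat(sprintf(
    "<car_trajectory> %d frames, %d atoms, %g frames/ns\n",
    n_frames(x), nrow(x$topology), x$frames_per_ns
  ))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj A `car_trajectory`.
#' @return Integer frame count.
#' @export
n_frames <- function(traj) nrow(traj$xyz)

#' Extract one frame of a trajectory as a structure
#'
#' @param traj A `car_trajectory`.
#' @param i Frame index (1-based).
#' @return A `car_structure` with that frame's coordinates.
#' @export
frame_structure <- function(traj, i) {
  if (i < 1 || i > n_frames(traj)) {
    rlang::abort(sprintf("frame index %d out of range", i), class = "car_index_error")
  }
  set_coords(traj$topology, traj$xyz[i, ])
}
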