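#' Read an atomic structure from a PDB file
#'
#' Reads ATOM/HETATM records, preserving author chain identifiers and residue
#' numbers verbatim. For multi-model files a single model can be selected.
#' Element symbols are taken from columns 77-78 when present and otherwise
#' inferred from the atom name.
#'
#' @param path Path to a PDB file.
#' @param model_index Optional 1-based model number for multi-model files;
#'   defaults to the first model.
#' @return A [car_structure] tibble.
#' @export
read_structure <- function(path, model_index = NULL) {
  pdb <- read_pdb_checked(path)
  n_models <- nrow(pdb$xyz)
  idx <- model_index %||% 1L
  if (idx < 1 || idx > n_models) {
    rlang::abort(
      sprintf("model %d requested but file has %d model(s)", idx, n_models),
      class = "car_index_error"
    )
  }
  pdb_to_structure(pdb, idx)
}

#' Read a multi-model PDB file as a trajectory
#'
#' Every MODEL record becomes one frame; the first model supplies the
#' topology. Atom count and order must be identical across models.
#'
#' @param path Path to a multi-model PDB file.
#' @param frames_per_ns Sampling rate to attach to the trajectory (the PDB
#'   format does not carry one). Default 100, the rate at which snapshots were
#'   collected in the simulations this package analyses.
#' @return A [car_trajectory].
#' @export
read_trajectory <- function(path, frames_per_ns = 100) {
  pdb <- read_pdb_checked(path)
  car_trajectory(pdb_to_structure(pdb, 1L), pdb$xyz, frames_per_ns = frames_per_ns)
}

read_pdb_checked <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(paste0("file not found: ", path), class = "car_format_error")
  }
  pdb <- tryCatch(
    bio3d::read.pdb(path, multi = TRUE, verbose = FALSE),
    error = function(e) {
      rlang::abort(
        paste0("could not parse PDB file: ", conditionMessage(e)),
        class = "car_format_error"
      )
    }
  )
  if (nrow(pdb$atom) == 0) {
    rlang::abort("PDB file contains no atoms", class = "car_format_error")
  }
  pdb
}

pdb_to_structure <- function(pdb, model_index) {
  a <- pdb$atom
  elesy <- a$elesy
  blank <- is.na(elesy) | elesy == ""
  if (any(blank)) elesy[blank] <- guess_element(a$elety[blank])
  xyz <- matrix(pdb$xyz[model_index, ], ncol = 3, byrow = TRUE)
  car_structure(tibble::tibble(
    chain = ifelse(is.na(a$chain), " ", a$chain),
    resno = a$resno,
    resname = a$resid,
    atom = a$elety,
    element = elesy,
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]
  ))
}

# Element from a PDB atom name: strip digits/primes, take the leading letter;
# two-letter handling is unnecessary for the biomolecular atoms handled here.
guess_element <- function(atom_name) {
  core <- sub("^[0-9']*", "", atom_name)
  toupper(substr(core, 1, 1))
}

#' Write a structure to a single-model PDB file
#'
#' @param s A [car_structure].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(s, path) {
  write_trajectory(car_trajectory(s, matrix(t(coords(s)), nrow = 1)), path,
    single_model = TRUE
  )
}

#' Write a trajectory as a multi-model PDB file
#'
#' One MODEL record per frame, atom order preserved. Coordinates are stored
#' in the fixed 8.3 PDB columns, so a round trip through [read_structure()]
#' reproduces them to 0.001 Angstrom.
#'
#' @param traj A [car_trajectory].
#' @param path Output path.
#' @param single_model Write bare ATOM records without MODEL/ENDMDL wrappers
#'   (used for one-frame structures).
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path, single_model = FALSE) {
  if (!inherits(traj, "car_trajectory")) {
    rlang::abort("expected a car_trajectory", class = "car_format_error")
  }
  top <- traj$topology
  bio3d::write.pdb(
    file = path,
    xyz = traj$xyz,
    resno = top$resno,
    chain = top$chain,
    resid = top$resname,
    elety = top$atom,
    elesy = top$element,
    end = TRUE
  )
  if (single_model) {
    # bio3d always wraps multi-row xyz in MODEL records; strip for 1 frame
    lines <- readLines(path)
    keep <- !grepl("^(MODEL|ENDMDL)", lines)
    writeLines(lines[keep], path)
  }
  invisible(path)
}

# rRNA landmark numbering between E. coli 16S and S. cerevisiae 18S.
# The decoding-centre landmarks used throughout: C1054 (yeast C1274),
# A1196 (yeast A1427), and the 530-loop anchor G530 (yeast G577).
ECOLI_YEAST_MAP <- tibble::tibble(
  ecoli = c(1054L, 1196L, 530L),
  yeast = c(1274L, 1427L, 577L),
  base = c("C", "A", "G")
)

#' Map rRNA landmark residue numbers between E. coli 16S and yeast 18S
#'
#' Helix-34 and 530-loop landmarks are conventionally quoted in E. coli 16S
#' numbering even when the structure is the yeast ribosome; this maps between
#' the two conventions for the landmarks this package uses.
#'
#' @param n Residue number.
#' @param direction `"ecoli_to_yeast"` or `"yeast_to_ecoli"`.
#' @return The partner residue number (integer).
#' @export
#' @examples
#' map_numbering(1054, "ecoli_to_yeast") # 1274
map_numbering <- function(n, direction = c("ecoli_to_yeast", "yeast_to_ecoli")) {
  direction <- match.arg(direction)
  from <- if (direction == "ecoli_to_yeast") ECOLI_YEAST_MAP$ecoli else ECOLI_YEAST_MAP$yeast
  to <- if (direction == "ecoli_to_yeast") ECOLI_YEAST_MAP$yeast else ECOLI_YEAST_MAP$ecoli
  hit <- match(as.integer(n), from)
  if (any(is.na(hit))) {
    rlang::abort(
      sprintf("residue number %s is not a mapped landmark", paste(n[is.na(hit)], collapse = ", ")),
      class = "car_lookup_error"
    )
  }
  to[hit]
}

#' The landmark numbering table
#' @return Tibble with columns `ecoli`, `yeast`, `base`.
#' @export
numbering_table <- function() ECOLI_YEAST_MAP
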