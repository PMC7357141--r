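#' Select a radius shell of residues around an anchor residue
#'
#' A residue is kept when any of its atoms lies within `radius` Angstrom of
#' any atom of the anchor residue (any-atom rule, so partially overlapping
#' residues are retained). Within each chain, gaps of at most `gap_fill_max`
#' intervening residues between kept segments are then filled, reducing the
#' number of artificial chain breaks. Every remaining segment terminus that is
#' not a native chain terminus is recorded as a break point, and each break
#' point gets one cap record (terminal-residue capping is bookkeeping here;
#' cap atoms are the MD engine's job).
#'
#' @param s A [car_structure].
#' @param anchor Anchor residue, either `"chain:resno"` (e.g. `"A:530"`) or a
#'   list/vector with elements `chain` and `resno`. The conventional anchor
#'   for decoding-centre subsystems is the G530 nucleotide of the 530 loop.
#' @param radius Shell radius in Angstrom (default 40).
#' @param gap_fill_max Maximum number of intervening residues merged between
#'   kept segments of the same chain (default 10).
#' @return An object of class `car_selection`: list with `residues` (tibble
#'   `chain`, `resno`, `resname`), `segments` (tibble `chain`, `start`,
#'   `end`), `break_points` (tibble `chain`, `resno`, `terminus`),
#'   `cap_records`, and the spec used.
#' @export
select_shell <- function(s, anchor, radius = 40, gap_fill_max = 10) {
  stopifnot(radius > 0, gap_fill_max >= 0)
  anc <- parse_residue_id(anchor)
  anchor_atoms <- dplyr::filter(s, .data$chain == anc$chain, .data$resno == anc$resno)
  if (nrow(anchor_atoms) == 0) {
    rlang::abort(
      sprintf("anchor residue %s:%s not found", anc$chain, anc$resno),
      class = "car_lookup_error"
    )
  }
  axyz <- coords(anchor_atoms)
  xyz <- coords(s)
  # min distance of each atom to any anchor atom
  d2min <- rep(Inf, nrow(xyz))
  for (k in seq_len(nrow(axyz))) {
    d2 <- (xyz[, 1] - axyz[k, 1])^2 + (xyz[, 2] - axyz[k, 2])^2 + (xyz[, 3] - axyz[k, 3])^2
    d2min <- pmin(d2min, d2)
  }
  hit <- s[d2min <= radius^2, ] |>
    dplyr::distinct(.data$chain, .data$resno)
  if (nrow(hit) == 0) {
    rlang::abort("no residues within the shell radius", class = "car_degenerate_selection_error")
  }

  all_res <- s |>
    dplyr::distinct(.data$chain, .data$resno, .data$resname) |>
    dplyr::arrange(.data$chain, .data$resno)
  kept <- dplyr::semi_join(all_res, hit, by = c("chain", "resno"))

  # gap filling: per chain, in residue-existence order, merge segments whose
  # gap (count of intervening residues present in s) is <= gap_fill_max
  filled <- all_res |>
    dplyr::group_by(.data$chain) |>
    dplyr::group_modify(function(df, key) {
      sel <- df$resno %in% kept$resno[kept$chain == key$chain]
      if (!any(sel)) {
        return(df[0, ])
      }
      idx <- which(sel)
      take <- rep(FALSE, nrow(df))
      take[idx] <- TRUE
      runs <- split(idx, cumsum(c(1, diff(idx) > 1)))
      for (r in seq_len(length(runs) - 1)) {
        gap_lo <- max(runs[[r]]) + 1
        gap_hi <- min(runs[[r + 1]]) - 1
        if (gap_hi - gap_lo + 1 <= gap_fill_max) take[gap_lo:gap_hi] <- TRUE
      }
      df[take, ]
    }) |>
    dplyr::ungroup()

  segments <- filled |>
    dplyr::left_join(
      all_res |>
        dplyr::group_by(.data$chain) |>
        dplyr::mutate(ord = dplyr::row_number()) |>
        dplyr::ungroup(),
      by = c("chain", "resno", "resname")
    ) |>
    dplyr::group_by(.data$chain) |>
    dplyr::mutate(seg = cumsum(c(1, diff(.data$ord) > 1))) |>
    dplyr::group_by(.data$chain, .data$seg) |>
    dplyr::summarise(start = min(.data$resno), end = max(.data$resno), .groups = "drop") |>
    dplyr::select("chain", "start", "end")

  native <- all_res |>
    dplyr::group_by(.data$chain) |>
    dplyr::summarise(first = min(.data$resno), last = max(.data$resno), .groups = "drop")
  bp <- segments |>
    dplyr::left_join(native, by = "chain") |>
    dplyr::reframe(
      chain = rep(.data$chain, 2),
      resno = c(.data$start, .data$end),
      terminus = rep(c("N_or_5prime", "C_or_3prime"), each = dplyr::n()),
      native_end = c(.data$start == .data$first, .data$end == .data$last)
    ) |>
    dplyr::filter(!.data$native_end) |>
    dplyr::select("chain", "resno", "terminus") |>
    dplyr::arrange(.data$chain, .data$resno)

  structure(
    list(
      residues = filled,
      segments = segments,
      break_points = bp,
      cap_records = dplyr::mutate(bp, cap = "terminal_residue"),
      anchor = anc, radius = radius, gap_fill_max = gap_fill_max
    ),
    class = "car_selection"
  )
}

#' @export
print.car_selection <- function(x, ...) {
  cat(sprintf(
    "<car_selection> %d residues in %d segment(s) over %d chain(s); %d break point(s)\n",
    nrow(x$residues), nrow(x$segments), length(unique(x$segments$chain)),
    nrow(x$break_points)
  ))
  invisible(x)
}

parse_residue_id <- function(x) {
  if (is.character(x) && length(x) == 1 && grepl(":", x)) {
    parts <- strsplit(x, ":", fixed = TRUE)[[1]]
    return(list(chain = parts[1], resno = as.integer(parts[2])))
  }
  x <- as.list(x)
  if (!all(c("chain", "resno") %in% names(x))) {
    rlang::abort("anchor must be 'chain:resno' or have elements chain and resno",
      class = "car_config_error"
    )
  }
  list(chain = as.character(x$chain), resno = as.integer(x$resno))
}

#' Build an onion-shell restraint mask from a selection
#'
#' Partitions the selected residues into an unrestrained core and a restrained
#' outer "onion shell" (selection minus core) held at a positional restraint
#' weight, by default 20 kcal/mol/A^2.
#'
#' @param sel A `car_selection` from [select_shell()].
#' @param core Tibble with columns `chain`, `resno` (or character vector of
#'   `"chain:resno"`) naming the unrestrained residues; must be a subset of
#'   the selection.
#' @param weight Restraint weight in kcal/mol/A^2 (default 20).
#' @return An object of class `car_restraint_mask`: list with `restrained`,
#'   `unrestrained` residue tibbles and `weight`.
#' @export
build_restraint_mask <- function(sel, core, weight = 20) {
  stopifnot(inherits(sel, "car_selection"), weight > 0)
  core <- normalise_residue_table(core)
  outside <- dplyr::anti_join(core, sel$residues, by = c("chain", "resno"))
  if (nrow(outside) > 0) {
    rlang::abort(
      paste0(
        "core residues outside the selection: ",
        paste(paste0(outside$chain, ":", outside$resno), collapse = ", ")
      ),
      class = "car_consistency_error"
    )
  }
  restrained <- dplyr::anti_join(sel$residues, core, by = c("chain", "resno"))
  if (nrow(restrained) == 0) {
    rlang::warn("core equals selection: restrained set is empty")
  }
  structure(
    list(
      restrained = restrained[, c("chain", "resno")],
      unrestrained = dplyr::semi_join(
        sel$residues, core,
        by = c("chain", "resno")
      )[, c("chain", "resno")],
      weight = weight
    ),
    class = "car_restraint_mask"
  )
}

#' @export
print.car_restraint_mask <- function(x, ...) {
  cat(sprintf(
    "<car_restraint_mask> %d restrained, %d unrestrained, %g kcal/mol/A^2\n",
    nrow(x$restrained), nrow(x$unrestrained), x$weight
  ))
  invisible(x)
}

#' Default unrestrained core: residues within an inner radius of the anchor
#'
#' @param s The full [car_structure] the selection came from.
#' @param sel A `car_selection`.
#' @param inner_radius Inner radius in Angstrom.
#' @return Tibble of core residues (`chain`, `resno`).
#' @export
core_by_radius <- function(s, sel, inner_radius) {
  inner <- select_shell(s,
    anchor = sel$anchor, radius = inner_radius,
    gap_fill_max = 0
  )
  dplyr::semi_join(inner$residues, sel$residues, by = c("chain", "resno"))[, c("chain", "resno")]
}

#' Check the buffer between the onion shell and residues of interest
#'
#' Verifies that no restrained residue is an immediate chain neighbour
#' (residue number +/- 1 on the same chain) of any residue of interest, i.e.
#' that at least one unrestrained residue buffers each one from the shell.
#'
#' @param mask A `car_restraint_mask`.
#' @param residues Tibble `chain`, `resno` (or `"chain:resno"` strings) of the
#'   residues that must be buffered.
#' @return TRUE if the buffer holds, otherwise FALSE (with the offending
#'   residues as attribute `violations`).
#' @export
check_buffer <- function(mask, residues) {
  residues <- normalise_residue_table(residues)
  neigh <- dplyr::bind_rows(
    dplyr::mutate(residues, resno = .data$resno - 1L),
    residues,
    dplyr::mutate(residues, resno = .data$resno + 1L)
  )
  bad <- dplyr::semi_join(mask$restrained, neigh, by = c("chain", "resno"))
  structure(nrow(bad) == 0, violations = bad)
}

normalise_residue_table <- function(x) {
  if (is.character(x)) {
    x <- purrr::map_dfr(x, function(id) tibble::as_tibble(parse_residue_id(id)))
  }
  x <- tibble::as_tibble(x)
  x$resno <- as.integer(x$resno)
  dplyr::distinct(x[, c("chain", "resno")])
}

#' Serialize a restraint mask
#'
#' @param mask A `car_restraint_mask`.
#' @param format `"json"` for an engine-agnostic JSON document or `"ambmask"`
#'   for an AMBER-style residue mask string over the restrained residue
#'   numbers (AMBER masks carry no chain, so numbers are pooled).
#' @return A character scalar.
#' @export
render_mask <- function(mask, format = c("json", "ambmask")) {
  format <- match.arg(format)
  if (format == "json") {
    return(jsonlite::toJSON(
      list(
        weight_kcal_mol_A2 = mask$weight,
        restrained = mask$restrained,
        unrestrained = mask$unrestrained
      ),
      auto_unbox = TRUE, digits = NA
    ))
  }
  nums <- sort(unique(mask$restrained$resno))
  if (length(nums) == 0) {
    return(":")
  }
  runs <- split(nums, cumsum(c(1, diff(nums) > 1)))
  parts <- vapply(runs, function(r) {
    if (length(r) == 1) as.character(r) else paste0(min(r), "-", max(r))
  }, character(1))
  paste0(":", paste(parts, collapse = ","))
}

#' Substitute a nucleotide base in place
#'
#' Replaces the base of a target ribonucleotide with another standard base,
#' mimicking template-based residue growth: sugar and phosphate atoms always
#' keep their coordinates; base atoms shared by name between the old and the
#' new base keep their coordinates when both bases belong to the same family
#' (purine-purine or pyrimidine-pyrimidine, `policy = "shared"`); atoms
#' present only in the new base are grown in from an idealized template
#' positioned on the residue's glycosidic frame (glycosidic nitrogen, the
#' C1'-N glycosidic bond direction, and the original base-plane normal), so
#' the base plane's orientation relative to the backbone is preserved.
#'
#' @param s A [car_structure].
#' @param target Residue to substitute, `"chain:resno"` or list with `chain`
#'   and `resno`.
#' @param new_base One of `"A"`, `"C"`, `"G"`, `"U"`.
#' @param templates Idealized residue templates, default [car_templates()].
#' @param policy `"shared"` (default): same-family shared-name base atoms keep
#'   coordinates; `"all_new"`: every base atom is rebuilt from the template.
#' @return The modified [car_structure]; no atom outside the target residue
#'   moves.
#' @export
substitute_nucleotide <- function(s, target, new_base,
                                  templates = car_templates(),
                                  policy = c("shared", "all_new")) {
  policy <- match.arg(policy)
  if (!new_base %in% c("A", "C", "G", "U")) {
    rlang::abort("new_base must be one of A, C, G, U", class = "car_type_error")
  }
  tgt <- parse_residue_id(target)
  res <- residue_atoms(s, tgt$chain, tgt$resno)
  old_base <- res$resname[1]
  if (!is_nucleotide(old_base)) {
    rlang::abort(
      sprintf("target %s:%s is %s, not a ribonucleotide", tgt$chain, tgt$resno, old_base),
      class = "car_type_error"
    )
  }
  if (old_base == new_base) {
    return(s)
  }

  old_glyc <- if (is_purine(old_base)) "N9" else "N1"
  new_glyc <- if (is_purine(new_base)) "N9" else "N1"
  need <- c(old_glyc, "C1'")
  if (!all(need %in% res$atom)) {
    rlang::abort(
      sprintf(
        "target residue lacks glycosidic anchor atom(s): %s",
        paste(setdiff(need, res$atom), collapse = ", ")
      ),
      class = "car_geometry_error"
    )
  }

  # local frame on the existing residue: origin at glycosidic N, x along
  # N -> C1', z the base-plane normal (sign chosen consistently vs x)
  frame_old <- glycosidic_frame(res, old_glyc, ring_atoms(old_base))
  tpl <- dplyr::filter(templates, .data$resname == new_base)
  frame_tpl <- glycosidic_frame(
    dplyr::rename(tpl, chain = "resname"), # any grouping; only coords used
    new_glyc, ring_atoms(new_base),
    coords_only = TRUE, atoms = tpl$atom,
    xyz = as.matrix(tpl[, c("x", "y", "z")])
  )

  base_atoms_old <- base_atom_names(res$atom)
  base_atoms_new <- base_atom_names(tpl$atom)
  same_family <- is_purine(old_base) == is_purine(new_base)
  shared <- if (policy == "shared" && same_family) {
    intersect(base_atoms_old, base_atoms_new)
  } else {
    character(0)
  }

  # transform template base atoms into the old residue's glycosidic frame
  tpl_xyz <- as.matrix(tpl[, c("x", "y", "z")])
  local <- sweep(tpl_xyz, 2, frame_tpl$origin) %*% t(frame_tpl$axes)
  placed <- sweep(local %*% frame_old$axes, 2, frame_old$origin, "+")

  keep_rows <- res[!res$atom %in% setdiff(base_atoms_old, shared), ]
  grow_names <- setdiff(base_atoms_new, shared)
  grow_idx <- match(grow_names, tpl$atom)
  grown <- tibble::tibble(
    chain = tgt$chain, resno = tgt$resno, resname = new_base,
    atom = grow_names, element = tpl$element[grow_idx],
    x = placed[grow_idx, 1], y = placed[grow_idx, 2], z = placed[grow_idx, 3]
  )
  keep_rows$resname <- new_base

  rest <- dplyr::filter(s, !(.data$chain == tgt$chain & .data$resno == tgt$resno))
  pos <- which(s$chain == tgt$chain & s$resno == tgt$resno)[1]
  before <- s[seq_len(pos - 1), ]
  before <- dplyr::filter(before, !(.data$chain == tgt$chain & .data$resno == tgt$resno))
  after <- dplyr::anti_join(rest, before,
    by = c("chain", "resno", "atom")
  )
  car_structure(dplyr::bind_rows(before, keep_rows, grown, after))
}

# Base (non-sugar, non-phosphate) atom names, hydrogens included.
base_atom_names <- function(atoms) {
  sugar_phos <- grepl("'", atoms, fixed = TRUE) |
    atoms %in% c("P", "OP1", "OP2", "OP3", "HOP3", "HOP2")
  atoms[!sugar_phos]
}

glycosidic_frame <- function(res, glyc, ring, coords_only = FALSE,
                             atoms = NULL, xyz = NULL) {
  if (!coords_only) {
    atoms <- res$atom
    xyz <- coords(res)
  }
  origin <- xyz[match(glyc, atoms), ]
  c1 <- xyz[match("C1'", atoms), ]
  ring_xyz <- xyz[match(ring, atoms), , drop = FALSE]
  ring_xyz <- ring_xyz[stats::complete.cases(ring_xyz), , drop = FALSE]
  if (any(is.na(origin)) || any(is.na(c1)) || nrow(ring_xyz) < 3) {
    rlang::abort("cannot build glycosidic frame: anchor or ring atoms missing",
      class = "car_geometry_error"
    )
  }
  x <- c1 - origin
  x <- x / sqrt(sum(x^2))
  z <- plane_normal(ring_xyz)
  # orient the normal consistently relative to the glycosidic bond:
  # pick the sign that makes the frame right-handed with a fixed reference
  ref <- ring_xyz[1, ] - origin
  if (sum(z * pracma_cross(x, ref)) < 0) z <- -z
  z <- z - sum(z * x) * x
  z <- z / sqrt(sum(z^2))
  y <- pracma_cross(z, x)
  list(origin = origin, axes = rbind(x, y, z))
}

pracma_cross <- function(a, b) {
  c(
    a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1]
  )
}

# Best-fit plane normal of a set of points (smallest principal axis).
plane_normal <- function(xyz) {
  cen <- colMeans(xyz)
  sv <- svd(sweep(xyz, 2, cen))
  n <- sv$v[, 3]
  n / sqrt(sum(n^2))
}

#' Base-plane normal of a residue
#'
#' @param frame A [car_structure].
#' @param chain,resno Residue identifier.
#' @return Unit normal vector of the best-fit plane through the ring atoms.
#' @export
base_plane_normal <- function(frame, chain, resno) {
  res <- residue_atoms(frame, chain, resno)
  ring <- ring_atoms(res$resname[1])
  xyz <- coords(res)[match(ring, res$atom), , drop = FALSE]
  if (anyNA(xyz)) {
    rlang::abort("ring atoms missing for base-plane normal", class = "car_geometry_error")
  }
  plane_normal(xyz)
}
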