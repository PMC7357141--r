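#' Detect hydrogen bonds in one frame
#'
#' A hydrogen bond is recorded when the donor-heavy-atom to acceptor-heavy-atom
#' distance is below `dist_cutoff` and the donor-H-acceptor angle (vertex at
#' the hydrogen) is at least `angle_cutoff`, for at least one hydrogen attached
#' to the donor. These are the cpptraj-style criteria used throughout the
#' package (defaults 3.0 Angstrom, 135 degrees). Pairs within the same residue
#' are excluded. If one donor satisfies the criteria through several
#' hydrogens, the hydrogen with the widest angle is reported.
#'
#' Hydrogens are located geometrically: hydrogen atoms of the donor's residue
#' within 1.25 Angstrom of the donor heavy atom. A donor with no attached
#' hydrogen in the structure raises a missing-hydrogen diagnostic rather than
#' being skipped, because structures without explicit hydrogens cannot support
#' the angle criterion.
#'
#' @param frame A [car_structure] (one frame).
#' @param donors Tibble of donor heavy atoms with columns `chain`, `resno`,
#'   `atom` (optionally `resname`). Default: all donors from
#'   [hbond_candidates()].
#' @param acceptors Tibble of acceptor atoms, same columns. Default from
#'   [hbond_candidates()].
#' @param dist_cutoff Heavy-atom distance cutoff in Angstrom.
#' @param angle_cutoff Donor-H-acceptor angle cutoff in degrees.
#' @param hydrogen_map Optional donor-to-hydrogen connectivity tibble from
#'   [hydrogen_topology()], normally computed on a trajectory's topology so
#'   that coordinate noise in a frame cannot detach a hydrogen from its donor.
#'   Default: inferred geometrically from `frame` itself.
#' @return Tibble of events: donor/acceptor chain, resno, resname, atom, the
#'   hydrogen used, `distance` (Angstrom) and `angle` (degrees).
#' @export
detect_hbonds <- function(frame, donors = NULL, acceptors = NULL,
                          dist_cutoff = 3.0, angle_cutoff = 135,
                          hydrogen_map = NULL) {
  if (is.null(donors) || is.null(acceptors)) {
    cand <- hbond_candidates(frame)
    donors <- donors %||% cand$donors
    acceptors <- acceptors %||% cand$acceptors
  }
  empty <- tibble::tibble(
    donor_chain = character(), donor_resno = integer(), donor_resname = character(),
    donor_atom = character(), hydrogen = character(),
    acceptor_chain = character(), acceptor_resno = integer(),
    acceptor_resname = character(), acceptor_atom = character(),
    distance = double(), angle = double()
  )
  if (nrow(donors) == 0 || nrow(acceptors) == 0 || nrow(frame) == 0) {
    return(empty)
  }
  don <- locate_atoms(frame, donors, "donor")
  acc <- locate_atoms(frame, acceptors, "acceptor")
  dh <- attach_hydrogens(frame, don, hydrogen_map)

  # all donor-H x acceptor combinations, same-residue pairs excluded
  grid <- tidyr::crossing(di = seq_len(nrow(dh)), ai = seq_len(nrow(acc)))
  d <- dh[grid$di, ]
  a <- acc[grid$ai, ]
  same <- d$chain == a$chain & d$resno == a$resno
  d <- d[!same, ]
  a <- a[!same, ]
  if (nrow(d) == 0) {
    return(empty)
  }
  dx <- cbind(d$x, d$y, d$z)
  hx <- cbind(d$hx, d$hy, d$hz)
  ax <- cbind(a$x, a$y, a$z)
  dist_da <- sqrt(rowSums((dx - ax)^2))
  v1 <- dx - hx
  v2 <- ax - hx
  cosang <- rowSums(v1 * v2) /
    pmax(sqrt(rowSums(v1^2)) * sqrt(rowSums(v2^2)), .Machine$double.eps)
  ang <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
  ok <- dist_da < dist_cutoff & ang >= angle_cutoff
  if (!any(ok)) {
    return(empty)
  }
  tibble::tibble(
    donor_chain = d$chain[ok], donor_resno = d$resno[ok],
    donor_resname = d$resname[ok], donor_atom = d$atom[ok],
    hydrogen = d$hydrogen[ok],
    acceptor_chain = a$chain[ok], acceptor_resno = a$resno[ok],
    acceptor_resname = a$resname[ok], acceptor_atom = a$atom[ok],
    distance = dist_da[ok], angle = ang[ok]
  ) |>
    dplyr::group_by(
      .data$donor_chain, .data$donor_resno, .data$donor_atom,
      .data$acceptor_chain, .data$acceptor_resno, .data$acceptor_atom
    ) |>
    dplyr::slice_max(.data$angle, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::arrange(
      .data$donor_chain, .data$donor_resno, .data$donor_atom,
      .data$acceptor_chain, .data$acceptor_resno, .data$acceptor_atom
    )
}

# Join a candidate table against the frame to pick up coordinates/resname.
locate_atoms <- function(frame, spec, what) {
  spec <- tibble::as_tibble(spec)
  spec$resno <- as.integer(spec$resno)
  cols <- intersect(c("chain", "resno", "atom"), names(spec))
  if (length(cols) < 3) {
    rlang::abort(
      sprintf("%s table needs columns chain, resno, atom", what),
      class = "car_config_error"
    )
  }
  out <- dplyr::inner_join(
    spec[, cols],
    frame[, c("chain", "resno", "resname", "atom", "x", "y", "z")],
    by = c("chain", "resno", "atom")
  )
  dplyr::distinct(out, .data$chain, .data$resno, .data$atom, .keep_all = TRUE)
}

# Expand donors to one row per attached hydrogen: either from an explicit
# connectivity map, or geometrically (element H within 1.25 A, same residue).
# Errors if any donor heavy atom ends up with no hydrogen.
attach_hydrogens <- function(frame, don, hydrogen_map = NULL) {
  if (!is.null(hydrogen_map)) {
    hyd_xyz <- dplyr::select(frame,
      chain = "chain", resno = "resno", hydrogen = "atom",
      hx = "x", hy = "y", hz = "z"
    )
    out <- don |>
      dplyr::inner_join(hydrogen_map,
        by = c("chain", "resno", "atom"),
        relationship = "many-to-many"
      ) |>
      dplyr::inner_join(hyd_xyz, by = c("chain", "resno", "hydrogen"))
  } else {
    hyd <- dplyr::filter(frame, toupper(.data$element) == "H")
    out <- dplyr::inner_join(
      don,
      dplyr::select(hyd,
        chain = "chain", resno = "resno", hydrogen = "atom",
        hx = "x", hy = "y", hz = "z"
      ),
      by = c("chain", "resno"), relationship = "many-to-many"
    )
    out <- dplyr::filter(
      out,
      (.data$x - .data$hx)^2 + (.data$y - .data$hy)^2 + (.data$z - .data$hz)^2 <= 1.25^2
    )
  }
  orphan <- dplyr::anti_join(don, out, by = c("chain", "resno", "atom"))
  if (nrow(orphan) > 0) {
    rlang::abort(
      paste0(
        "donor atom(s) without attached hydrogens (explicit hydrogens are ",
        "required for hydrogen-bond detection): ",
        paste(paste0(orphan$chain, ":", orphan$resno, "/", orphan$atom), collapse = ", ")
      ),
      class = "car_missing_hydrogen_error"
    )
  }
  out
}

#' Donor-hydrogen connectivity of a structure
#'
#' Maps every potential donor heavy atom to its attached hydrogens (element H,
#' same residue, within 1.25 Angstrom). Computed once on a trajectory's
#' topology (or any reference frame) this map makes hydrogen-bond detection
#' robust to per-frame coordinate noise, which in a real force field cannot
#' break a covalent N-H/O-H bond.
#'
#' @param s A [car_structure] with physically sensible donor-H distances.
#' @return Tibble with columns `chain`, `resno`, `atom` (donor heavy atom)
#'   and `hydrogen`.
#' @export
hydrogen_topology <- function(s) {
  heavies <- dplyr::filter(s, toupper(.data$element) %in% c("N", "O"))
  hyd <- dplyr::filter(s, toupper(.data$element) == "H")
  out <- dplyr::inner_join(
    heavies,
    dplyr::select(hyd,
      chain = "chain", resno = "resno", hydrogen = "atom",
      hx = "x", hy = "y", hz = "z"
    ),
    by = c("chain", "resno"), relationship = "many-to-many"
  )
  out |>
    dplyr::filter(
      (.data$x - .data$hx)^2 + (.data$y - .data$hy)^2 + (.data$z - .data$hz)^2 <= 1.25^2
    ) |>
    dplyr::select("chain", "resno", "atom", "hydrogen")
}

#' Classify hydrogen-bond events by base-pairing edge
#'
#' Each event's donor and acceptor atom is assigned to the Watson-Crick or
#' Hoogsteen edge of its residue (or "guanidinium"/"backbone" for arginine).
#' Atoms that sit on both edges (adenine N6, guanine O6) are disambiguated
#' geometrically: the edge whose heavy-atom centre of mass lies closest to the
#' partner atom wins. Atoms on no defined edge are labelled "off-edge";
#' residue types absent from the edge table are labelled "unclassified".
#'
#' @param events Event tibble from [detect_hbonds()].
#' @param frame The [car_structure] the events were detected in (needed for
#'   the geometric disambiguation).
#' @param edges Edge definition tibble, default [edge_table()].
#' @return `events` with `donor_edge` and `acceptor_edge` columns appended.
#' @export
classify_edge <- function(events, frame, edges = edge_table()) {
  if (nrow(events) == 0) {
    return(dplyr::mutate(events, donor_edge = character(), acceptor_edge = character()))
  }
  events$donor_edge <- vapply(seq_len(nrow(events)), function(i) {
    assign_edge(
      frame, edges,
      events$donor_chain[i], events$donor_resno[i], events$donor_resname[i],
      events$donor_atom[i], "donor",
      partner = c(events$acceptor_chain[i], events$acceptor_resno[i], events$acceptor_atom[i])
    )
  }, character(1))
  events$acceptor_edge <- vapply(seq_len(nrow(events)), function(i) {
    assign_edge(
      frame, edges,
      events$acceptor_chain[i], events$acceptor_resno[i], events$acceptor_resname[i],
      events$acceptor_atom[i], "acceptor",
      partner = c(events$donor_chain[i], events$donor_resno[i], events$donor_atom[i])
    )
  }, character(1))
  events
}

assign_edge <- function(frame, edges, chain, resno, resname, atom, role, partner) {
  hits <- edges |>
    dplyr::filter(
      .data$resname == !!resname, .data$atom == !!atom, .data$role == !!role
    )
  if (!resname %in% edges$resname && !is_nucleotide(resname)) {
    return("unclassified")
  }
  if (nrow(hits) == 0) {
    return("off-edge")
  }
  if (nrow(hits) == 1) {
    return(hits$edge[1])
  }
  # ambiguous atom: pick the edge whose COM is nearest the partner atom
  p <- dplyr::filter(
    frame,
    .data$chain == partner[1], .data$resno == as.integer(partner[2]),
    .data$atom == partner[3]
  )
  if (nrow(p) != 1) {
    return(hits$edge[1])
  }
  dists <- vapply(hits$edge, function(e) {
    com <- edge_com(frame, chain, resno, e, edges)
    sqrt(sum((com - c(p$x, p$y, p$z))^2))
  }, double(1))
  hits$edge[which.min(dists)]
}

#' Per-frame edge-pair bond counts
#'
#' @param classified Output of [classify_edge()], optionally with a `frame`
#'   column when events from several frames are pooled.
#' @return Tibble of counts per (donor residue, acceptor residue, donor edge,
#'   acceptor edge) and frame if present.
#' @export
edge_bond_counts <- function(classified) {
  keys <- intersect(
    c(
      "frame", "donor_chain", "donor_resno", "donor_resname", "donor_edge",
      "acceptor_chain", "acceptor_resno", "acceptor_resname", "acceptor_edge"
    ),
    names(classified)
  )
  dplyr::count(classified, dplyr::across(dplyr::all_of(keys)), name = "n_bonds")
}

# Mass-weighted centre of the heavy atoms of one edge of one residue.
edge_com <- function(frame, chain, resno, edge, edges = edge_table()) {
  res <- residue_atoms(frame, chain, resno)
  resname <- res$resname[1]
  if (edge == "ring") {
    names <- ring_atoms(resname)
  } else {
    names <- edges |>
      dplyr::filter(.data$resname == !!resname, .data$edge == !!edge) |>
      dplyr::pull(.data$atom) |>
      unique()
    if (length(names) == 0) {
      rlang::abort(
        sprintf("residue type '%s' has no edge '%s'", resname, edge),
        class = "car_geometry_error"
      )
    }
  }
  atoms_com(res, names, sprintf("%s:%s %s edge", chain, resno, edge))
}

atoms_com <- function(res, names, label) {
  sel <- res[match(names, res$atom), ]
  if (anyNA(sel$atom)) {
    rlang::abort(
      sprintf(
        "%s is missing atom(s): %s", label,
        paste(names[is.na(sel$atom)], collapse = ", ")
      ),
      class = "car_geometry_error"
    )
  }
  m <- atom_masses(sel$element)
  c(
    sum(m * sel$x), sum(m * sel$y), sum(m * sel$z)
  ) / sum(m)
}

#' Centre-of-mass distance between two base-pairing edges
#'
#' The distance between the mass-weighted centres of the donor and acceptor
#' heavy atoms of each edge, the metric used for base-pair separation
#' time-courses.
#'
#' @param frame A [car_structure].
#' @param chain_a,resno_a,edge_a First residue and its edge name.
#' @param chain_b,resno_b,edge_b Second residue and its edge name.
#' @param edges Edge definitions, default [edge_table()].
#' @return Distance in Angstrom.
#' @export
edge_distance <- function(frame, chain_a, resno_a, edge_a,
                          chain_b, resno_b, edge_b, edges = edge_table()) {
  ca <- edge_com(frame, chain_a, resno_a, edge_a, edges)
  cb <- edge_com(frame, chain_b, resno_b, edge_b, edges)
  sqrt(sum((ca - cb)^2))
}

#' Minimum guanidinium-edge distance of an arginine to a partner edge
#'
#' The guanidinium group presents two donor pairs, NE/NH1 and NE/NH2. The
#' distance reported per frame is the smaller of the two distances from the
#' centres of mass of those pairs to the partner edge's centre of mass; ties
#' resolve to the NE/NH1 pair.
#'
#' @param frame A [car_structure].
#' @param arg_chain,arg_resno The arginine residue.
#' @param partner_chain,partner_resno,partner_edge The partner residue edge.
#' @return Distance in Angstrom, with attribute `branch` recording which
#'   donor pair ("NE,NH1" or "NE,NH2") was closer.
#' @export
guanidinium_edge_distance <- function(frame, arg_chain, arg_resno,
                                      partner_chain, partner_resno, partner_edge) {
  arg <- residue_atoms(frame, arg_chain, arg_resno)
  com1 <- atoms_com(arg, c("NE", "NH1"), sprintf("%s:%s NE,NH1", arg_chain, arg_resno))
  com2 <- atoms_com(arg, c("NE", "NH2"), sprintf("%s:%s NE,NH2", arg_chain, arg_resno))
  pc <- edge_com(frame, partner_chain, partner_resno, partner_edge)
  d1 <- sqrt(sum((com1 - pc)^2))
  d2 <- sqrt(sum((com2 - pc)^2))
  if (d1 <= d2) {
    structure(d1, branch = "NE,NH1")
  } else {
    structure(d2, branch = "NE,NH2")
  }
}

#' Base-stacking distance between two residues
#'
#' Distance between the mass-weighted centres of the heavy ring atoms
#' (purine 9-ring, pyrimidine 6-ring, arginine guanidinium CZ/NE/NH1/NH2).
#' Stacked bases read 3-4 Angstrom; a configurable threshold (default 4.5)
#' classifies a pair as stacked.
#'
#' @param frame A [car_structure].
#' @param chain_a,resno_a First residue.
#' @param chain_b,resno_b Second residue.
#' @return Distance in Angstrom.
#' @export
stacking_distance <- function(frame, chain_a, resno_a, chain_b, resno_b) {
  ca <- edge_com(frame, chain_a, resno_a, "ring")
  cb <- edge_com(frame, chain_b, resno_b, "ring")
  sqrt(sum((ca - cb)^2))
}

#' Is a pair stacked?
#' @param distance Ring centre-of-mass distance in Angstrom.
#' @param threshold Stacking threshold, default 4.5 Angstrom (midpoint of the
#'   observed stacked band below 4 and unstacked band above 5).
#' @return Logical.
#' @export
is_stacked <- function(distance, threshold = 4.5) distance < threshold

#' Backbone RMSD time course of a trajectory
#'
#' Per-frame root-mean-square deviation of backbone atoms (protein N/CA/C/O,
#' nucleic P/O5'/C5'/C4'/C3'/O3') relative to a reference structure, after
#' optimal least-squares rigid-body superposition on those atoms (disable
#' with `fit = FALSE` for a raw coordinate RMSD).
#'
#' @param traj A [car_trajectory].
#' @param reference A [car_structure]; default is the trajectory's first
#'   frame.
#' @param selection Optional tibble with columns `chain`, `resno` restricting
#'   the residues used; default all residues.
#' @param fit Superpose before measuring (default TRUE).
#' @return A series tibble with columns `pair`, `metric`, `frame`, `ns`,
#'   `value`.
#' @export
backbone_rmsd <- function(traj, reference = NULL, selection = NULL, fit = TRUE) {
  top <- traj$topology
  reference <- reference %||% frame_structure(traj, 1)
  res <- dplyr::distinct(top, .data$chain, .data$resno, .data$resname)
  if (!is.null(selection)) {
    selection <- dplyr::mutate(tibble::as_tibble(selection), resno = as.integer(.data$resno))
    res <- dplyr::semi_join(res, selection, by = c("chain", "resno"))
    if (nrow(res) == 0) {
      rlang::abort("selection matches no residues", class = "car_selection_error")
    }
  }
  res$kind <- ifelse(is_nucleotide(res$resname), "nucleic", "protein")
  wanted <- res |>
    dplyr::rowwise() |>
    dplyr::reframe(
      chain = .data$chain, resno = .data$resno,
      atom = backbone_atoms(.data$kind)
    )
  idx_top <- match_atom_rows(top, wanted)
  idx_ref <- match_atom_rows(reference, wanted)
  keep <- !is.na(idx_top) & !is.na(idx_ref)
  if (!any(keep)) {
    rlang::abort(
      "no backbone atoms shared between trajectory and reference",
      class = "car_selection_error"
    )
  }
  idx_top <- idx_top[keep]
  idx_ref <- idx_ref[keep]
  xyz_cols <- as.vector(rbind(3 * idx_top - 2, 3 * idx_top - 1, 3 * idx_top))
  ref_xyz <- as.vector(t(coords(reference)[idx_ref, , drop = FALSE]))
  mob <- traj$xyz[, xyz_cols, drop = FALSE]
  if (fit) {
    mob <- bio3d::fit.xyz(ref_xyz, mob,
      fixed.inds = seq_along(ref_xyz),
      mobile.inds = seq_along(ref_xyz)
    )
    if (is.vector(mob)) mob <- matrix(mob, nrow = 1)
  }
  dev <- sweep(mob, 2, ref_xyz)
  vals <- sqrt(rowSums(dev^2) / (length(ref_xyz) / 3))
  new_series(tibble::tibble(
    pair = "backbone", metric = "rmsd",
    frame = seq_len(n_frames(traj)),
    ns = (seq_len(n_frames(traj)) - 1) / traj$frames_per_ns,
    value = as.double(vals)
  ), frames_per_ns = traj$frames_per_ns)
}

match_atom_rows <- function(s, wanted) {
  key_s <- paste(s$chain, s$resno, s$atom, sep = "\r")
  key_w <- paste(wanted$chain, wanted$resno, wanted$atom, sep = "\r")
  match(key_w, key_s)
}

new_series <- function(df, frames_per_ns) {
  attr(df, "frames_per_ns") <- frames_per_ns
  class(df) <- unique(c("car_series", class(df)))
  df
}

#' Extract per-frame metric series from a trajectory
#'
#' For each pair specification, computes a per-frame time course at the given
#' stride. Supported metrics:
#' * `"hbond_count"`: number of hydrogen bonds between the two residues
#'   (either direction); if `edge_a`/`edge_b` are given, only bonds whose
#'   atoms lie on those edges are counted.
#' * `"edge_distance"`: [edge_distance()] between `edge_a` and `edge_b`.
#' * `"guanidinium_distance"`: [guanidinium_edge_distance()] with residue A
#'   the arginine and edge_b the partner edge.
#' * `"stacking_distance"`: [stacking_distance()].
#'
#' @param traj A [car_trajectory].
#' @param pairs Tibble with columns `pair` (label), `metric`, `chain_a`,
#'   `resno_a`, `chain_b`, `resno_b` and optionally `edge_a`, `edge_b`.
#' @param stride Keep every `stride`-th frame (default 1). The effective
#'   sampling rate `frames_per_ns / stride` is recorded on the result so time
#'   axes stay in ns.
#' @param dist_cutoff,angle_cutoff Hydrogen-bond criteria passed through to
#'   [detect_hbonds()].
#' @return A `car_series` tibble: `pair`, `metric`, `frame`, `ns`, `value`.
#' @export
series_extract <- function(traj, pairs, stride = 1,
                           dist_cutoff = 3.0, angle_cutoff = 135) {
  pairs <- tibble::as_tibble(pairs)
  if (nrow(pairs) == 0) {
    rlang::abort("empty pair specification", class = "car_config_error")
  }
  if (!all(c("pair", "metric", "chain_a", "resno_a", "chain_b", "resno_b") %in% names(pairs))) {
    rlang::abort(
      "pairs needs columns pair, metric, chain_a, resno_a, chain_b, resno_b",
      class = "car_config_error"
    )
  }
  if (!"edge_a" %in% names(pairs)) pairs$edge_a <- NA_character_
  if (!"edge_b" %in% names(pairs)) pairs$edge_b <- NA_character_
  stopifnot(stride >= 1)
  frames <- seq(1, n_frames(traj), by = stride)

  # restrict hydrogen-bond candidates to residues named in the specs
  res_used <- dplyr::bind_rows(
    dplyr::select(pairs, chain = "chain_a", resno = "resno_a"),
    dplyr::select(pairs, chain = "chain_b", resno = "resno_b")
  ) |>
    dplyr::mutate(resno = as.integer(.data$resno)) |>
    dplyr::distinct()
  need_hb <- any(pairs$metric == "hbond_count")
  if (need_hb) {
    top_sub <- dplyr::semi_join(traj$topology, res_used, by = c("chain", "resno"))
    cand <- hbond_candidates(top_sub)
    hmap <- hydrogen_topology(top_sub)
  }

  out <- purrr::map_dfr(frames, function(fi) {
    fr <- frame_structure(traj, fi)
    ev <- NULL
    if (need_hb) {
      sub <- dplyr::semi_join(fr, res_used, by = c("chain", "resno"))
      ev <- detect_hbonds(sub, cand$donors, cand$acceptors,
        dist_cutoff = dist_cutoff, angle_cutoff = angle_cutoff,
        hydrogen_map = hmap
      )
    }
    purrr::map_dfr(seq_len(nrow(pairs)), function(i) {
      p <- pairs[i, ]
      val <- switch(p$metric,
        hbond_count = pair_hbond_count(ev, fr, p),
        edge_distance = edge_distance(
          fr, p$chain_a, p$resno_a, p$edge_a, p$chain_b, p$resno_b, p$edge_b
        ),
        guanidinium_distance = as.double(guanidinium_edge_distance(
          fr, p$chain_a, p$resno_a, p$chain_b, p$resno_b, p$edge_b
        )),
        stacking_distance = stacking_distance(
          fr, p$chain_a, p$resno_a, p$chain_b, p$resno_b
        ),
        rlang::abort(
          sprintf("unknown metric '%s'", p$metric),
          class = "car_config_error"
        )
      )
      tibble::tibble(
        pair = p$pair, metric = p$metric, frame = fi,
        ns = (fi - 1) / traj$frames_per_ns, value = val
      )
    })
  })
  new_series(out, frames_per_ns = traj$frames_per_ns / stride)
}

pair_hbond_count <- function(events, frame, p) {
  if (is.null(events) || nrow(events) == 0) {
    return(0)
  }
  fwd <- events$donor_chain == p$chain_a & events$donor_resno == p$resno_a &
    events$acceptor_chain == p$chain_b & events$acceptor_resno == p$resno_b
  rev <- events$donor_chain == p$chain_b & events$donor_resno == p$resno_b &
    events$acceptor_chain == p$chain_a & events$acceptor_resno == p$resno_a
  ev <- events[fwd | rev, ]
  if (nrow(ev) == 0) {
    return(0)
  }
  if (!is.na(p$edge_a) || !is.na(p$edge_b)) {
    et <- edge_table()
    on_edge <- function(resname, atom, edge) {
      is.na(edge) | atom %in% et$atom[et$resname == resname & et$edge == edge]
    }
    keep <- vapply(seq_len(nrow(ev)), function(j) {
      if (fwd[fwd | rev][j]) {
        on_edge(ev$donor_resname[j], ev$donor_atom[j], p$edge_a) &&
          on_edge(ev$acceptor_resname[j], ev$acceptor_atom[j], p$edge_b)
      } else {
        on_edge(ev$donor_resname[j], ev$donor_atom[j], p$edge_b) &&
          on_edge(ev$acceptor_resname[j], ev$acceptor_atom[j], p$edge_a)
      }
    }, logical(1))
    ev <- ev[keep, ]
  }
  as.double(nrow(ev))
}

#' Pool a series into fixed-width time bins
#'
#' Frames are pooled into consecutive non-overlapping bins of `bin_ns`
#' nanoseconds; each bin's value is the mean over its member frames. A
#' trailing partial bin is kept and flagged. Because every frame lands in
#' exactly one bin, the frame-count-weighted mean of bin means equals the
#' overall series mean exactly.
#'
#' @param series A `car_series` tibble (needs `ns` and `value`).
#' @param bin_ns Bin width in nanoseconds (default 1).
#' @return Tibble with `pair`, `metric`, `bin`, `ns_start`, `value` (bin
#'   mean), `n_frames`, and `partial` flag.
#' @export
bin_series <- function(series, bin_ns = 1) {
  stopifnot(bin_ns > 0)
  out <- series |>
    dplyr::mutate(bin = floor(.data$ns / bin_ns)) |>
    dplyr::group_by(.data$pair, .data$metric, .data$bin) |>
    dplyr::summarise(
      ns_start = .data$bin[1] * bin_ns,
      value = mean(.data$value),
      n_frames = dplyr::n(),
      .groups = "drop_last"
    ) |>
    dplyr::mutate(partial = .data$n_frames < max(.data$n_frames)) |>
    dplyr::ungroup()
  fpn <- attr(series, "frames_per_ns")
  if (!is.null(fpn)) {
    full <- bin_ns * fpn
    out$partial <- out$n_frames < full
  }
  out
}
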