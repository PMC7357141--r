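# Shared fixtures and independent oracles for the test suite.

# A straight single-chain "helix" of n pseudo-nucleotide residues spaced
# `spacing` Angstrom apart along x; three heavy atoms per residue.
make_helix <- function(n, chain = "A", spacing = 3.8, resno_start = 1) {
  purrr::map_dfr(seq_len(n), function(i) {
    x0 <- (i - 1) * spacing
    tibble::tibble(
      chain = chain,
      resno = resno_start + i - 1L,
      resname = "U",
      atom = c("P", "C4'", "N1"),
      element = c("P", "C", "N"),
      x = c(x0, x0 + 1.0, x0 + 0.5),
      y = c(0, 0, 1.2),
      z = 0
    )
  }) |>
    car_structure()
}

# Minimal donor(N-H)/acceptor(O) system: donor residue A:1, acceptor B:2.
# The acceptor is placed at donor-acceptor distance `d` with donor-H-acceptor
# angle `theta_deg` (vertex at H; 180 = collinear). N at origin, H at (1,0,0).
make_triplet <- function(d = 2.9, theta_deg = 180) {
  theta <- theta_deg * pi / 180
  hd <- c(-1, 0, 0) # H -> D direction
  ha_dir <- c(-cos(theta), sin(theta), 0) # H -> A at angle theta from H -> D
  # |HA| solving |DA| = d given |DH| = 1:
  r <- cos(theta) + sqrt(cos(theta)^2 + d^2 - 1)
  a <- c(1, 0, 0) + r * ha_dir
  car_structure(tibble::tibble(
    chain = c("A", "A", "B"),
    resno = c(1L, 1L, 2L),
    resname = c("X", "X", "Y"),
    atom = c("N", "H", "O"),
    element = c("N", "H", "O"),
    x = c(0, 1, a[1]), y = c(0, 0, a[2]), z = c(0, 0, a[3])
  ))
}

triplet_donors <- tibble::tibble(chain = "A", resno = 1L, atom = "N")
triplet_acceptors <- tibble::tibble(chain = "B", resno = 2L, atom = "O")

has_triplet_bond <- function(d, theta_deg = 180, dist_cutoff = 3.0, angle_cutoff = 135) {
  ev <- detect_hbonds(make_triplet(d, theta_deg), triplet_donors, triplet_acceptors,
    dist_cutoff = dist_cutoff, angle_cutoff = angle_cutoff
  )
  nrow(ev) == 1
}

# Independent brute-force hydrogen-bond oracle: explicit double loop over all
# donor/acceptor pairs and all hydrogens, no shared code with detect_hbonds.
# `hydrogen_names` optionally fixes donor->hydrogen connectivity (a named list
# keyed by "chain:resno:atom"); otherwise hydrogens are found geometrically.
brute_hbonds <- function(frame, donors, acceptors, dist_cutoff = 3.0,
                         angle_cutoff = 135, hydrogen_names = NULL) {
  df <- as.data.frame(frame)
  out <- list()
  for (i in seq_len(nrow(donors))) {
    drow <- df[df$chain == donors$chain[i] & df$resno == donors$resno[i] &
      df$atom == donors$atom[i], ]
    if (nrow(drow) != 1) next
    res_h <- df[df$chain == drow$chain & df$resno == drow$resno &
      toupper(df$element) == "H", ]
    if (is.null(hydrogen_names)) {
      hs <- res_h[sqrt((res_h$x - drow$x)^2 + (res_h$y - drow$y)^2 +
        (res_h$z - drow$z)^2) <= 1.25, ]
    } else {
      key <- paste(drow$chain, drow$resno, drow$atom, sep = ":")
      hs <- res_h[res_h$atom %in% hydrogen_names[[key]], ]
    }
    for (j in seq_len(nrow(acceptors))) {
      arow <- df[df$chain == acceptors$chain[j] & df$resno == acceptors$resno[j] &
        df$atom == acceptors$atom[j], ]
      if (nrow(arow) != 1) next
      if (arow$chain == drow$chain && arow$resno == drow$resno) next
      dda <- sqrt((drow$x - arow$x)^2 + (drow$y - arow$y)^2 + (drow$z - arow$z)^2)
      if (dda >= dist_cutoff) next
      best_ang <- -Inf
      for (k in seq_len(nrow(hs))) {
        v1 <- c(drow$x - hs$x[k], drow$y - hs$y[k], drow$z - hs$z[k])
        v2 <- c(arow$x - hs$x[k], arow$y - hs$y[k], arow$z - hs$z[k])
        ang <- acos(max(min(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2)), 1), -1)) * 180 / pi
        if (ang > best_ang) best_ang <- ang
      }
      if (best_ang >= angle_cutoff) {
        out[[length(out) + 1]] <- data.frame(
          donor_chain = drow$chain, donor_resno = drow$resno, donor_atom = drow$atom,
          acceptor_chain = arow$chain, acceptor_resno = arow$resno,
          acceptor_atom = arow$atom
        )
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(
      donor_chain = character(), donor_resno = integer(), donor_atom = character(),
      acceptor_chain = character(), acceptor_resno = integer(),
      acceptor_atom = character()
    ))
  }
  res <- do.call(rbind, out)
  res[order(
    res$donor_chain, res$donor_resno, res$donor_atom,
    res$acceptor_chain, res$acceptor_resno, res$acceptor_atom
  ), , drop = FALSE]
}

bond_keys <- function(ev) {
  sort(paste(
    ev$donor_chain, ev$donor_resno, ev$donor_atom,
    ev$acceptor_chain, ev$acceptor_resno, ev$acceptor_atom
  ))
}

# Independent brute-force shell-membership oracle: all-atom double loop.
brute_shell_residues <- function(s, anchor_chain, anchor_resno, radius) {
  df <- as.data.frame(s)
  anc <- df[df$chain == anchor_chain & df$resno == anchor_resno, ]
  keep <- list()
  for (res in split(df, paste(df$chain, df$resno))) {
    found <- FALSE
    for (i in seq_len(nrow(res))) {
      for (j in seq_len(nrow(anc))) {
        d <- sqrt((res$x[i] - anc$x[j])^2 + (res$y[i] - anc$y[j])^2 +
          (res$z[i] - anc$z[j])^2)
        if (d <= radius) {
          found <- TRUE
          break
        }
      }
      if (found) break
    }
    if (found) {
      keep[[length(keep) + 1]] <- data.frame(chain = res$chain[1], resno = res$resno[1])
    }
  }
  res <- do.call(rbind, keep)
  res[order(res$chain, res$resno), , drop = FALSE]
}

# Mass-weighted centre-of-mass oracle over named atoms of one residue.
brute_com <- function(frame, chain, resno, atoms) {
  masses <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, P = 30.974)
  df <- as.data.frame(frame)
  rows <- df[df$chain == chain & df$resno == resno & df$atom %in% atoms, ]
  m <- masses[toupper(rows$element)]
  c(sum(m * rows$x), sum(m * rows$y), sum(m * rows$z)) / sum(m)
}
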