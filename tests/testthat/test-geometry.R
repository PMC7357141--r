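test_that("the reverse-Hoogsteen A:C pair yields exactly its two defining bonds", {
  p <- make_pair("tWH_AC")
  ev <- detect_hbonds(p)
  expect_equal(nrow(ev), 2)
  got <- sort(paste(ev$donor_resname, ev$donor_atom, ev$acceptor_resname, ev$acceptor_atom))
  expect_equal(got, sort(c("A N6 C N3", "C N4 A N7")))
  # translated 10 A apart: nothing
  moved <- p
  bsel <- moved$chain == "B"
  moved$x[bsel] <- moved$x[bsel] + 10
  expect_equal(nrow(detect_hbonds(moved)), 0)
})

test_that("the Watson-Crick G:C pair yields its three bonds, matching the brute-force oracle", {
  p <- make_pair("WC_GC")
  cand <- hbond_candidates(p)
  ev <- detect_hbonds(p, cand$donors, cand$acceptors)
  expect_equal(nrow(ev), 3)
  expect_setequal(
    paste(ev$donor_atom, ev$acceptor_atom),
    c("N1 N3", "N2 O2", "N4 O6")
  )
  oracle <- brute_hbonds(p, cand$donors, cand$acceptors)
  expect_equal(bond_keys(ev), bond_keys(oracle))
})

test_that("detection equals the brute-force oracle on noisy fixtures", {
  base <- make_car_fixture("GCU")
  cand <- hbond_candidates(base)
  # donor-H connectivity fixed from the clean topology on both routes
  hmap <- hydrogen_topology(base)
  hnames <- split(hmap$hydrogen, paste(hmap$chain, hmap$resno, hmap$atom, sep = ":"))
  for (i in 1:20) {
    noisy <- withr::with_seed(100 + i, {
      set_coords(base, coords(base) + matrix(rnorm(3 * nrow(base), sd = 0.15), ncol = 3))
    })
    ev <- detect_hbonds(noisy, cand$donors, cand$acceptors, hydrogen_map = hmap)
    oracle <- brute_hbonds(noisy, cand$donors, cand$acceptors, hydrogen_names = hnames)
    expect_equal(bond_keys(ev), bond_keys(oracle))
  }
})

test_that("distance and angle cutoffs are sharp at 3.0 A and 135 degrees", {
  expect_true(has_triplet_bond(2.999))
  expect_false(has_triplet_bond(3.001))
  expect_true(has_triplet_bond(2.8, 135.1))
  expect_false(has_triplet_bond(2.8, 134.9))
})

test_that("structures without donor hydrogens raise a diagnostic", {
  s <- make_triplet()
  s_noh <- car_structure(dplyr::filter(s, atom != "H"))
  expect_error(
    detect_hbonds(s_noh, triplet_donors, triplet_acceptors),
    class = "car_missing_hydrogen_error"
  )
})

test_that("edge classification puts the A:C pair on (Hoogsteen, WC) and O2' off-edge", {
  p <- make_pair("tWH_AC")
  ev <- classify_edge(detect_hbonds(p), p)
  a_donor <- ev[ev$donor_resname == "A", ]
  expect_equal(a_donor$donor_edge, "Hoogsteen")
  expect_equal(a_donor$acceptor_edge, "WC")
  c_donor <- ev[ev$donor_resname == "C", ]
  expect_equal(c_donor$donor_edge, "WC")
  expect_equal(c_donor$acceptor_edge, "Hoogsteen")
  counts <- edge_bond_counts(ev)
  expect_equal(sum(counts$n_bonds), 2)

  # a WC G:C event set classifies both sides as WC
  g <- make_pair("WC_GC")
  evg <- classify_edge(detect_hbonds(g), g)
  expect_true(all(evg$donor_edge == "WC"))
  expect_true(all(evg$acceptor_edge == "WC"))

  # an O2' donor is off-edge
  fake <- tibble::tibble(
    donor_chain = "A", donor_resno = 1L, donor_resname = "G", donor_atom = "O2'",
    hydrogen = "HO2'", acceptor_chain = "B", acceptor_resno = 2L,
    acceptor_resname = "C", acceptor_atom = "O2", distance = 2.9, angle = 170
  )
  cls <- classify_edge(fake, g)
  expect_equal(cls$donor_edge, "off-edge")

  # empty event list stays empty with the classification columns added
  e0 <- classify_edge(detect_hbonds(make_helix(1)), make_helix(1))
  expect_equal(nrow(e0), 0)
  expect_true(all(c("donor_edge", "acceptor_edge") %in% names(e0)))
})

test_that("edge distances are rigid-motion faithful and match a COM oracle", {
  p <- make_pair("tWH_AC")
  # identical edges superposed -> 0
  expect_equal(edge_distance(p, "A", 1, "WC", "A", 1, "WC"), 0)
  # rigid +3 x translation of a copy of residue A as a new chain
  a <- residue_atoms(p, "A", 1)
  a2 <- a
  a2$chain <- "Q"
  a2$x <- a2$x + 3
  s2 <- car_structure(dplyr::bind_rows(a, a2))
  expect_equal(edge_distance(s2, "A", 1, "WC", "Q", 1, "WC"), 3, tolerance = 1e-12)
  # oracle: mass-weighted COM over the edge atom names
  et <- edge_table()
  a_atoms <- unique(et$atom[et$resname == "A" & et$edge == "Hoogsteen"])
  c_atoms <- unique(et$atom[et$resname == "C" & et$edge == "WC"])
  com_a <- brute_com(p, "A", 1, a_atoms)
  com_c <- brute_com(p, "B", 2, c_atoms)
  expect_equal(
    edge_distance(p, "A", 1, "Hoogsteen", "B", 2, "WC"),
    sqrt(sum((com_a - com_c)^2)),
    tolerance = 1e-9
  )
  expect_error(edge_distance(p, "A", 1, "guanidinium", "B", 2, "WC"),
    class = "car_geometry_error"
  )
})

test_that("the guanidinium minimum-edge rule picks the closer donor pair with NE,NH1 ties", {
  fx <- make_car_fixture("GCU")
  d <- guanidinium_edge_distance(fx, "S", 146, "M", 5, "WC")
  arg <- residue_atoms(fx, "S", 146)
  com1 <- brute_com(fx, "S", 146, c("NE", "NH1"))
  com2 <- brute_com(fx, "S", 146, c("NE", "NH2"))
  et <- edge_table()
  pc <- brute_com(fx, "M", 5, unique(et$atom[et$resname == "C" & et$edge == "WC"]))
  d1 <- sqrt(sum((com1 - pc)^2))
  d2 <- sqrt(sum((com2 - pc)^2))
  expect_equal(as.double(d), min(d1, d2), tolerance = 1e-9)
  expect_equal(attr(d, "branch"), if (d1 <= d2) "NE,NH1" else "NE,NH2")

  # symmetric tie: partner edge equidistant from both pairs
  # build a tiny symmetric system: an arginine and a C whose WC edge COM lies
  # on the guanidinium symmetry plane is hard to arrange exactly, so test the
  # tie rule directly on a partner placed at the midpoint geometry
  mid <- (com1 + com2) / 2
  cres <- residue_atoms(fx, "M", 5)
  shift <- mid - brute_com(fx, "M", 5, unique(et$atom[et$resname == "C" & et$edge == "WC"]))
  cres2 <- set_coords(cres, sweep(coords(cres), 2, shift, "+"))
  s2 <- car_structure(dplyr::bind_rows(arg, cres2))
  d_tie <- guanidinium_edge_distance(s2, "S", 146, "M", 5, "WC")
  expect_equal(attr(d_tie, "branch"), "NE,NH1")
})

test_that("stacking distance reproduces constructed rises and rigid geometry", {
  fx <- make_car_fixture("GCU")
  expect_equal(stacking_distance(fx, "R", 1054, "R", 1196), 3.7, tolerance = 0.01)
  expect_true(is_stacked(stacking_distance(fx, "R", 1054, "R", 1196)))
  expect_equal(stacking_distance(fx, "R", 1054, "R", 1054), 0)
  # coplanar parallel rings displaced 3.5 along the shared normal
  a <- residue_atoms(fx, "R", 1054)
  b <- a
  b$chain <- "Q"
  n <- base_plane_normal(fx, "R", 1054)
  b <- set_coords(b, sweep(coords(b), 2, 3.5 * n, "+"))
  s <- car_structure(dplyr::bind_rows(a, b))
  expect_equal(stacking_distance(s, "R", 1054, "Q", 1054), 3.5, tolerance = 1e-9)
  expect_error(stacking_distance(fx, "R", 1054, "T", 99), class = "car_lookup_error")
})

test_that("backbone RMSD is zero under rigid motion and d/sqrt(n) for a single displacement", {
  fx <- make_car_fixture("GCU")
  base_xyz <- as.vector(t(coords(fx)))
  # frames: identical, then rigidly rotated+translated
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  moved <- as.vector(t(sweep(coords(fx) %*% t(R), 2, c(5, -3, 2), "+")))
  traj <- car_trajectory(fx, rbind(base_xyz, base_xyz, moved), frames_per_ns = 100)
  rms <- backbone_rmsd(traj)
  expect_equal(rms$value, c(0, 0, 0), tolerance = 1e-6)

  # closed form without superposition: one backbone atom displaced by d
  sel <- tibble::tibble(chain = "R", resno = c(1054, 1196))
  top <- traj$topology
  bb_n <- sum(top$chain == "R" & top$atom %in% c("P", "O5'", "C5'", "C4'", "C3'", "O3'"))
  i <- which(top$chain == "R" & top$resno == 1054 & top$atom == "P")
  d <- 1.7
  disp <- coords(fx)
  disp[i, 1] <- disp[i, 1] + d
  traj2 <- car_trajectory(fx, rbind(base_xyz, as.vector(t(disp))), frames_per_ns = 100)
  rms2 <- backbone_rmsd(traj2, reference = fx, selection = sel, fit = FALSE)
  expect_equal(rms2$value[1], 0, tolerance = 1e-9)
  expect_equal(rms2$value[2], d / sqrt(bb_n), tolerance = 1e-9)
  expect_error(
    backbone_rmsd(traj2, selection = tibble::tibble(chain = "Z", resno = 1)),
    class = "car_selection_error"
  )
})
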