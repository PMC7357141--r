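test_that("idealized pairs satisfy their defining bond lists and open pairs have none", {
  au <- make_pair("WC_AU")
  ev <- detect_hbonds(au)
  expect_setequal(paste(ev$donor_atom, ev$acceptor_atom), c("N6 O4", "N3 N1"))
  expect_true(all(abs(ev$distance - 2.9) < 0.15))
  open <- make_pair("tWH_AC", target_distance = 5.0)
  expect_equal(nrow(detect_hbonds(open)), 0)
  expect_error(make_pair("WC_XX"), class = "car_spec_error")
})

test_that("every template donor carries explicit hydrogens", {
  tpl <- car_templates()
  et <- edge_table()
  donors <- dplyr::filter(et, role == "donor")
  for (i in seq_len(nrow(donors))) {
    res <- dplyr::filter(tpl, resname == donors$resname[i])
    hs <- strsplit(donors$hydrogens[i], ",")[[1]]
    expect_true(all(hs %in% res$atom),
      label = paste(donors$resname[i], donors$atom[i], "hydrogens present")
    )
    heavy <- res[res$atom == donors$atom[i], ]
    for (h in hs) {
      hrow <- res[res$atom == h, ]
      d <- sqrt((heavy$x - hrow$x)^2 + (heavy$y - hrow$y)^2 + (heavy$z - hrow$z)^2)
      expect_lt(d, 1.25)
    }
  }
})

test_that("the CAR fixture realises its constructed geometry for a GCN +1 codon", {
  fx <- make_car_fixture("GCU")
  ev <- classify_edge(detect_hbonds(fx), fx)
  key <- paste(ev$donor_chain, ev$donor_resno, ev$acceptor_chain, ev$acceptor_resno)
  # C1054:G1 (WC:WC, 3 bonds) and A1196:C2 (Hoogsteen:WC, 2 bonds), nothing else
  expect_equal(sum(key %in% c("M 4 R 1054", "R 1054 M 4")), 3)
  expect_equal(sum(key %in% c("M 5 R 1196", "R 1196 M 5")), 2)
  expect_equal(nrow(ev), 5)
  a_ev <- ev[ev$donor_chain == "R" & ev$donor_resno == 1196, ]
  expect_equal(a_ev$donor_edge, "Hoogsteen")
  # stack rises inside the 3.5-4.0 band
  expect_gte(stacking_distance(fx, "R", 1054, "R", 1196), 3.5)
  expect_lte(stacking_distance(fx, "R", 1054, "R", 1196), 4.0)
  expect_gte(stacking_distance(fx, "R", 1196, "S", 146), 3.5)
  expect_lte(stacking_distance(fx, "R", 1196, "S", 146), 4.0)
  expect_gte(stacking_distance(fx, "R", 1054, "T", 34), 3.5)
  expect_lte(stacking_distance(fx, "R", 1054, "T", 34), 4.0)
})

test_that("a purine at +1 position 2 removes the A1196 pairing at construction", {
  gcu <- make_car_fixture("GCU")
  ggu <- make_car_fixture("GGU")
  count_a1196 <- function(fx) {
    ev <- detect_hbonds(fx)
    sum((ev$donor_chain == "R" & ev$donor_resno == 1196) |
      (ev$acceptor_chain == "R" & ev$acceptor_resno == 1196))
  }
  expect_lte(count_a1196(ggu), count_a1196(gcu))
  expect_equal(count_a1196(ggu), 0)
  # the G2 edge sits at least 4 A from the A1196 Hoogsteen edge
  expect_gte(edge_distance(ggu, "R", 1196, "Hoogsteen", "M", 5, "WC"), 4)
  expect_error(make_car_fixture("GXU"), class = "car_spec_error")
})

test_that("trajectories are deterministic in the seed and exact at sigma zero", {
  base <- make_pair("tWH_AC")
  spec <- trajectory_spec(20, noise_sigma = 0.1, seed = 9)
  t1 <- make_trajectory(base, spec)
  t2 <- make_trajectory(base, spec)
  expect_identical(t1$xyz, t2$xyz)
  t3 <- make_trajectory(base, trajectory_spec(20, noise_sigma = 0.1, seed = 10))
  expect_false(identical(t1$xyz, t3$xyz))

  quiet <- make_trajectory(base, trajectory_spec(5, noise_sigma = 0, seed = 1))
  for (i in 1:5) {
    expect_equal(coords(frame_structure(quiet, i)), coords(base), ignore_attr = TRUE)
  }
  gt <- attr(t1, "ground_truth")
  expect_equal(gt$seed, 9L)
  expect_equal(gt$noise_sigma, 0.1)
})

test_that("trajectory specs validate their schedules", {
  base <- make_pair("tWH_AC")
  expect_error(
    trajectory_spec(10, schedule = tibble::tibble(
      chain_a = "A", resno_a = 1, chain_b = "B", resno_b = 2,
      from = 5, to = 20, formed = FALSE
    )),
    class = "car_spec_error"
  )
  bad_pair <- trajectory_spec(10, schedule = tibble::tibble(
    chain_a = "A", resno_a = 1, chain_b = "Z", resno_b = 9,
    from = 1, to = 5, formed = FALSE
  ))
  expect_error(make_trajectory(base, bad_pair), class = "car_spec_error")
})

test_that("scripted schedules are recovered from noisy trajectories at 95%+", {
  base <- make_pair("tWH_AC")
  spec <- trajectory_spec(
    n_frames = 200, frames_per_ns = 100, noise_sigma = 0.1,
    schedule = tibble::tibble(
      chain_a = "A", resno_a = 1L, chain_b = "B", resno_b = 2L,
      from = 101L, to = 200L, formed = FALSE
    ),
    seed = 77
  )
  traj <- make_trajectory(base, spec)
  states <- scripted_states(traj, "A", 1, "B", 2)
  recovered <- recover_schedule(traj, "A", 1, "B", 2)
  expect_gte(mean(recovered == states), 0.95)
  # the raw bond-count series alone also tracks the script closely: formed
  # frames can transiently lose both bonds to noise, broken frames never gain
  ser <- series_extract(traj, tibble::tibble(
    pair = "AC", metric = "hbond_count",
    chain_a = "A", resno_a = 1L, chain_b = "B", resno_b = 2L
  ))
  expect_gte(mean((ser$value > 0) == states), 0.90)
  expect_true(all(ser$value[101:200] == 0))
})

test_that("mean bond count decays monotonically with coordinate noise", {
  base <- make_pair("tWH_AC")
  means <- vapply(c(0, 0.1, 0.3, 0.6), function(sig) {
    traj <- make_trajectory(base, trajectory_spec(
      n_frames = 200, noise_sigma = sig, seed = 123
    ))
    ser <- series_extract(traj, tibble::tibble(
      pair = "AC", metric = "hbond_count",
      chain_a = "A", resno_a = 1L, chain_b = "B", resno_b = 2L
    ))
    mean(ser$value)
  }, double(1))
  expect_equal(means[1], 2)
  expect_true(all(diff(means) <= 0))
})
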