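single_atom <- function(element = "C", x = 0, y = 0, z = 0, seq = 1L,
                        chain = "X") {
  tibble::tibble(
    record = "ATOM", atom_name = element, element = element,
    x = x, y = y, z = z, residue_name = "CLU", residue_seq = seq,
    chain_id = chain, altloc = "", occupancy = 1, structure_id = "s"
  )
}

test_that("an isolated atom recovers the analytic sphere area", {
  s <- shrake_rupley(single_atom("C"))
  analytic <- 4 * pi * (1.70 + 1.40)^2
  expect_lt(abs(s$total_area - analytic) / analytic, 0.01)
  # disjoint atoms are additive
  two <- dplyr::bind_rows(single_atom("C"),
                          single_atom("S", x = 100, seq = 2L))
  s2 <- shrake_rupley(two)
  expect_equal(s2$total_area,
               4 * pi * (1.70 + 1.4)^2 + 4 * pi * (1.80 + 1.4)^2,
               tolerance = 1e-6)
  expect_error(shrake_rupley(single_atom()[0, ]), "empty")
})

test_that("two overlapping atoms match the analytic spherical-cap area", {
  r1 <- 1.70 + 1.4
  r2 <- 1.55 + 1.4
  for (d in c(2.0, 3.0, 4.5)) {
    pair <- dplyr::bind_rows(single_atom("C"),
                             single_atom("N", x = d, seq = 2L))
    got <- shrake_rupley(pair)$total_area
    want <- two_sphere_area(r1, r2, d)
    expect_lt(abs(got - want) / want, 0.02)
  }
})

test_that("adding occluders never increases any atom's area", {
  cl <- random_atom_cluster(8, box = 5, seed = 101)
  base <- shrake_rupley(cl)$per_atom$area
  extra <- dplyr::bind_rows(cl, random_atom_cluster(4, box = 5, seed = 202) |>
                              dplyr::mutate(residue_seq = residue_seq + 100L))
  grown <- shrake_rupley(extra)$per_atom$area[seq_along(base)]
  expect_true(all(grown <= base + 1e-9))
})

test_that("doubling the point lattice changes totals by less than 0.5%", {
  cl <- random_atom_cluster(10, box = 6, seed = 7)
  a1 <- shrake_rupley(cl, n_sphere_points = 960)$total_area
  a2 <- shrake_rupley(cl, n_sphere_points = 1920)$total_area
  expect_lt(abs(a1 - a2) / a2, 0.005)
})

test_that("SASA is invariant under rigid transforms to lattice tolerance", {
  cl <- random_atom_cluster(10, box = 6, seed = 13)
  a1 <- shrake_rupley(cl)$total_area
  moved <- transform_structure(cl, rot_about(c(3, 1, -2), 51), c(5, -7, 2))
  a2 <- shrake_rupley(moved)$total_area
  expect_lt(abs(a1 - a2) / a1, 0.01)
})

test_that("heme exposure shrinks monotonically with added context", {
  fil <- make_filament(n_subunits = 3, hemes_per_subunit = 8)
  lone <- heme_sasa(dplyr::filter(fil, chain_id == "B", residue_seq == 6),
                    "B", 6)
  in_subunit <- heme_sasa(fil, "B", 6, context_chains = "B")
  in_filament <- heme_sasa(fil, "B", 6)
  expect_gt(lone, in_subunit)
  expect_gte(in_subunit, in_filament)
  # the pendant heme is far more exposed than a mid-chain heme
  buried <- heme_sasa(fil, "B", 3)
  expect_gt(in_filament, buried)
  expect_error(heme_sasa(fil, "B", 99), "no heme")
  expect_error(heme_sasa(fil, "B", 6, context_chains = "A"),
               "own chain")
})

test_that("buried interface area matches geometry and conventions", {
  # two far-apart subunits bury nothing
  a <- single_atom("C", chain = "A")
  b <- single_atom("C", x = 100, seq = 2L, chain = "B")
  far <- buried_interface_area(dplyr::bind_rows(a, b), "A", "B")
  expect_equal(far$buried_area, 0, tolerance = 1e-9)
  # touching-sphere dimer: per-side burial equals the analytic cap loss
  d <- 3.0
  ab <- dplyr::bind_rows(a, single_atom("C", x = d, seq = 2L, chain = "B"))
  got <- buried_interface_area(ab, "A", "B")
  r <- 1.70 + 1.4
  want <- (2 * 4 * pi * r^2 - two_sphere_area(r, r, d)) / 2
  expect_lt(abs(got$buried_area - want) / want, 0.02)
  # total convention is exactly twice per-side
  tot <- buried_interface_area(ab, "A", "B", per_side = FALSE)
  expect_equal(tot$buried_area, 2 * got$buried_area)
  expect_error(buried_interface_area(ab, "A", "A"), "disjoint")
  expect_error(buried_interface_area(ab, "A", "C"), "non-empty")
})

test_that("per-heme areas sum their atoms and tidy methods expose them", {
  fil <- make_filament(n_subunits = 1, hemes_per_subunit = 3,
                       branch_positions = list())
  res <- shrake_rupley(fil)
  by_hand <- res$per_atom |>
    dplyr::group_by(residue_seq) |>
    dplyr::summarise(area = sum(area))
  expect_equal(res$per_heme$area, by_hand$area)
  expect_equal(tidy(res), res$per_heme)
  gl <- glance(res)
  expect_equal(gl$n_atoms, 75L)
  expect_equal(gl$probe_radius, 1.4)
})
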