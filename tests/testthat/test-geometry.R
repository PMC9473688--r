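test_that("minimum ring distance matches construction and brute force", {
  a <- ideal_porphyrin()
  # pure translation along the plane normal: corresponding atoms realize it
  b <- transform_ring(ideal_porphyrin(residue_seq = 2), diag(3), c(0, 0, 4))
  expect_equal(min_ring_distance(a, b), 4.0)
  # coincident rings with distinct ids: distance zero; same id: error
  b0 <- ideal_porphyrin(residue_seq = 2)
  expect_equal(min_ring_distance(a, b0), 0.0)
  expect_error(min_ring_distance(a, ideal_porphyrin()), "self-pair")
  # randomly moved pairs agree with the exhaustive 625-distance double loop
  set.seed(42)
  for (k in 1:5) {
    b <- transform_ring(ideal_porphyrin(residue_seq = 2),
                        rot_about(random_axis(), runif(1, 0, 180)),
                        rnorm(3, sd = 6))
    expect_equal(min_ring_distance(a, b),
                 brute_min_dist(ring_xyz(a), ring_xyz(b)),
                 tolerance = 1e-10)
    expect_equal(min_ring_distance(a, b), min_ring_distance(b, a))
  }
})

test_that("ring superposition recovers exact rigid transforms", {
  a <- ideal_porphyrin()
  s0 <- superpose_rings(a, a)
  expect_equal(s0$rotation, diag(3), tolerance = 1e-9)
  expect_lt(s0$rmsd, 1e-9)
  set.seed(7)
  for (k in 1:5) {
    r0 <- rot_about(random_axis(), runif(1, 0, 180))
    t0 <- rnorm(3, sd = 10)
    b <- transform_ring(ideal_porphyrin(residue_seq = 2), r0, t0)
    s <- superpose_rings(a, b)
    expect_lt(norm(s$rotation - r0, "F"), 1e-6)
    expect_equal(s$translation, t0, tolerance = 1e-6, ignore_attr = TRUE)
    expect_lt(s$rmsd, 1e-6)
  }
})

test_that("superposition rmsd matches the quaternion oracle on noisy pairs", {
  set.seed(11)
  a <- ideal_porphyrin()
  for (k in 1:10) {
    r0 <- rot_about(random_axis(), runif(1, 0, 180))
    coords <- ring_xyz(a) %*% t(r0) +
      matrix(rnorm(3, sd = 5), 25, 3, byrow = TRUE) +
      matrix(rnorm(75, sd = 0.05), 25, 3)
    b <- porphyrin_ring(coords, residue_seq = 2)
    s <- superpose_rings(a, b)
    expect_equal(s$rmsd, quaternion_rmsd(ring_xyz(a), coords),
                 tolerance = 1e-6)
  }
})

test_that("rotation_angle matches the closed form and rejects non-rotations", {
  expect_equal(rotation_angle(diag(3)), 0)
  expect_equal(rotation_angle(rot_about(c(0, 0, 1), 90)), 90)
  set.seed(3)
  for (k in 1:5) {
    expect_equal(rotation_angle(rot_about(random_axis(), 180)), 180,
                 tolerance = 1e-9)
  }
  expect_equal(rotation_angle(rot_about(c(2, -1, 0.5), 73.2)), 73.2,
               tolerance = 1e-9)
  expect_error(rotation_angle(diag(c(1, 1, -1))), "not a proper rotation")
  expect_error(rotation_angle(2 * diag(3)), "not a proper rotation")
  expect_error(rotation_angle(matrix(0, 2, 2)), "3 x 3")
})

test_that("theta is symmetric in the pair and invariant under common rigid moves", {
  set.seed(19)
  a <- ideal_porphyrin()
  for (k in 1:5) {
    b <- transform_ring(ideal_porphyrin(residue_seq = 2),
                        rot_about(random_axis(), runif(1, 0, 180)),
                        rnorm(3, sd = 5))
    th_ab <- superpose_rings(a, b)$theta
    th_ba <- superpose_rings(b, a)$theta
    expect_equal(th_ab, th_ba, tolerance = 1e-9)
    g <- rot_about(random_axis(), runif(1, 0, 180))
    tg <- rnorm(3, sd = 8)
    th_moved <- superpose_rings(transform_ring(a, g, tg),
                                transform_ring(b, g, tg))$theta
    expect_equal(th_ab, th_moved, tolerance = 1e-6)
  }
})

test_that("motif classification follows the angle thresholds", {
  expect_equal(classify_motif(0), "parallel")
  expect_equal(classify_motif(39.9), "parallel")
  expect_equal(classify_motif(180), "antiparallel")
  expect_equal(classify_motif(140.1), "antiparallel")
  expect_equal(classify_motif(90, plane_angle = 90), "T_shaped")
  expect_equal(classify_motif(120, plane_angle = 60), "T_shaped")
  expect_equal(classify_motif(56), "intermediate")
  expect_equal(classify_motif(90, plane_angle = 0), "intermediate")
  expect_error(classify_motif(181), "\\[0, 180\\]")
  expect_error(classify_motif(-1), "\\[0, 180\\]")
})

test_that("contact_pairs applies the distance cutoff and sorts output", {
  a <- ideal_porphyrin()
  far <- transform_ring(ideal_porphyrin(residue_seq = 2), diag(3),
                        c(0, 0, 10))
  expect_equal(nrow(contact_pairs(list(a, far), cutoff = 6)), 0L)
  # linear chain of 5 rings at 4 A spacing: 4 contacting pairs
  chain <- make_filament(n_subunits = 1, hemes_per_subunit = 5,
                         chain_spacing = 4, branch_positions = list())
  cp <- contact_pairs(extract_hemes(chain))
  expect_equal(nrow(cp), 4L)
  expect_equal(cp$seq_a, 1:4)
  expect_equal(cp$seq_b, 2:5)
  expect_equal(cp$min_distance, rep(4, 4), tolerance = 1e-9)
})

test_that("pruned superposition drops outliers and never worsens the rmsd", {
  set.seed(23)
  p <- matrix(rnorm(60, sd = 5), 20, 3)
  s_id <- pruned_superposition(p, p)
  expect_equal(s_id$rmsd, 0)
  expect_equal(s_id$n_pairs_used, 20L)
  # 20 matched points + 5 displaced outliers are pruned back to the core
  r0 <- rot_about(random_axis(), 40)
  q <- p %*% t(r0) + matrix(c(3, -2, 1), 20, 3, byrow = TRUE)
  p_out <- rbind(p, matrix(rnorm(15, sd = 5), 5, 3))
  q_out <- rbind(q, matrix(rnorm(15, sd = 5), 5, 3) + 10)
  s <- pruned_superposition(p_out, q_out)
  expect_equal(s$n_pairs_used, 20L)
  expect_equal(sort(s$kept), 1:20)
  expect_lt(s$rmsd, 1e-6)
  # survivors' rmsd is never larger than the unpruned fit
  noisy_q <- q + matrix(rnorm(60, sd = 0.3), 20, 3)
  full <- pruned_superposition(p, noisy_q, prune_factor = 1e9)
  pruned <- pruned_superposition(p, noisy_q, prune_factor = 2)
  expect_lte(pruned$rmsd, full$rmsd)
  expect_equal(full$n_pairs_used, 20L)
  expect_error(pruned_superposition(p[1:3, ], q[1:3, ]), "at least 4")
})
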