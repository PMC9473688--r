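# Independent reference implementations used to validate the package's own
# geometry and surface code. These deliberately use different algorithms
# from the implementation (Horn's quaternion method instead of Kabsch SVD,
# explicit double loops instead of matrix algebra, Monte-Carlo rejection
# sampling instead of the lattice).

# Horn's closed-form quaternion superposition: returns the least-squares
# rmsd of mapping p onto q (n x 3 each, rows corresponding), computed from
# the largest eigenvalue of the 4x4 key matrix.
quaternion_rmsd <- function(p, q) {
  p0 <- sweep(p, 2, colMeans(p))
  q0 <- sweep(q, 2, colMeans(q))
  m <- t(p0) %*% q0
  sxx <- m[1, 1]; sxy <- m[1, 2]; sxz <- m[1, 3]
  syx <- m[2, 1]; syy <- m[2, 2]; syz <- m[2, 3]
  szx <- m[3, 1]; szy <- m[3, 2]; szz <- m[3, 3]
  n4 <- matrix(c(
    sxx + syy + szz, syz - szy,       szx - sxz,        sxy - syx,
    syz - szy,       sxx - syy - szz, sxy + syx,        szx + sxz,
    szx - sxz,       sxy + syx,      -sxx + syy - szz,  syz + szy,
    sxy - syx,       szx + sxz,       syz + szy,       -sxx - syy + szz
  ), 4, 4, byrow = TRUE)
  lmax <- max(eigen(n4, symmetric = TRUE, only.values = TRUE)$values)
  msd <- (sum(p0^2) + sum(q0^2) - 2 * lmax) / nrow(p)
  sqrt(max(msd, 0))
}

# Brute-force minimum cross distance: explicit double loop over all pairs.
brute_min_dist <- function(p, q) {
  best <- Inf
  for (i in seq_len(nrow(p))) {
    for (j in seq_len(nrow(q))) {
      d <- sqrt(sum((p[i, ] - q[j, ])^2))
      if (d < best) best <- d
    }
  }
  best
}

# Monte-Carlo SASA by rejection sampling: n_samples uniform points on each
# atom's expanded sphere, counting those outside all other expanded
# spheres.
mc_sasa <- function(atoms, probe_radius = 1.4, n_samples = 1e5) {
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  rad <- unname(hemewire::vdw_radii()[toupper(atoms$element)])
  rad[is.na(rad)] <- 1.70
  rad <- rad + probe_radius
  n <- nrow(xyz)
  total <- 0
  for (i in seq_len(n)) {
    u <- matrix(stats::rnorm(3 * n_samples), ncol = 3)
    u <- u / sqrt(rowSums(u^2))
    pts <- sweep(u * rad[i], 2, xyz[i, ], `+`)
    ok <- rep(TRUE, n_samples)
    for (j in seq_len(n)[-i]) {
      ok <- ok & rowSums(sweep(pts, 2, xyz[j, ])^2) >= rad[j]^2
    }
    total <- total + 4 * pi * rad[i]^2 * mean(ok)
  }
  total
}

# Analytic accessible area of two intersecting spheres of expanded radii
# r1, r2 at centre distance d: each sphere loses a spherical cap.
two_sphere_area <- function(r1, r2, d) {
  if (d >= r1 + r2) return(4 * pi * (r1^2 + r2^2))
  x <- (d^2 + r1^2 - r2^2) / (2 * d)
  h1 <- r1 - x
  h2 <- r2 - (d - x)
  4 * pi * r1^2 - 2 * pi * r1 * h1 + 4 * pi * r2^2 - 2 * pi * r2 * h2
}

# Random proper rotation from a uniform random axis and given angle.
random_axis <- function() {
  v <- stats::rnorm(3)
  v / sqrt(sum(v^2))
}

rot_about <- function(axis, deg) {
  u <- axis / sqrt(sum(axis^2))
  th <- deg * pi / 180
  k <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * k + (1 - cos(th)) * (k %*% k)
}

# Coordinates of a ring / structure as plain matrices.
ring_xyz <- function(ring) ring$coords
atoms_xyz <- function(atoms) as.matrix(atoms[, c("x", "y", "z")])

# Location where deposited PDB/EMDB coordinate files would live if a user
# fetches them (they are not distributed with the package).
deposited_path <- function(id) {
  testthat::test_path("deposited", paste0(id, ".pdb"))
}
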