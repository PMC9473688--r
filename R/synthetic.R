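#' Generate a heme pair with controlled geometry
#'
#' Places a second idealized porphyrin ring at a designed rotation angle
#' and offset from a first one, so the whole distance/angle analysis chain
#' can be validated against known ground truth. Ring B is the ideal ring
#' rotated by `theta` degrees about `rotation_axis` and then translated by
#' `lateral_offset` along x plus `normal_offset` along z; when
#' `target_min_distance` is given the translation magnitude is instead
#' solved by root finding so that the achieved minimum edge-to-edge
#' distance equals the target.
#'
#' @param theta Designed rotation angle, degrees in \[0, 180\].
#' @param rotation_axis Rotation axis (default x, an in-plane axis, so
#'   `theta = 180` produces a flipped, antiparallel ring).
#' @param normal_offset,lateral_offset Translation components, angstroms.
#' @param target_min_distance Optional minimum ring distance to achieve
#'   along the offset direction (solved to ~1e-10 angstroms).
#' @return Atom tibble with two HEC residues (chain A, residues 1 and 2)
#'   and a `ground_truth` attribute: list with the designed `theta`,
#'   `rotation_axis`, achieved `min_distance` and `translation`. Retrieve
#'   it with [ground_truth()] before reshaping the tibble.
#' @export
make_pair <- function(theta, rotation_axis = c(1, 0, 0), normal_offset = 0,
                      lateral_offset = 0, target_min_distance = NULL) {
  if (!is.finite(theta) || theta < 0 || theta > 180) {
    abort("`theta` must lie in [0, 180] degrees.")
  }
  if (normal_offset < 0 || lateral_offset < 0) {
    abort("offsets must be non-negative.")
  }
  ring_a <- ideal_porphyrin(chain_id = "A", residue_seq = 1L)
  r <- rot_axis(rotation_axis, theta)
  b0 <- transform_ring(ideal_porphyrin(chain_id = "A", residue_seq = 2L), r)
  v <- c(lateral_offset, 0, normal_offset)
  if (!is.null(target_min_distance)) {
    if (target_min_distance < 0) abort("`target_min_distance` must be >= 0.")
    dir <- if (sqrt(sum(v^2)) < 1e-12) c(0, 0, 1) else v / sqrt(sum(v^2))
    f <- function(s) {
      bb <- transform_ring(b0, translation = s * dir)
      min_ring_distance(ring_a, bb) - target_min_distance
    }
    hi <- target_min_distance + 30
    if (f(hi) < 0) abort("`target_min_distance` is not attainable.")
    s <- if (f(0) >= 0) 0 else uniroot(f, c(0, hi), tol = 1e-12)$root
    v <- s * dir
  }
  ring_b <- transform_ring(b0, translation = v)
  out <- rings_to_structure(list(ring_a, ring_b), structure_id = "pair")
  attr(out, "ground_truth") <- list(
    theta = theta, rotation_axis = rotation_axis,
    min_distance = min_ring_distance(ring_a, ring_b), translation = v
  )
  out
}

#' Generate a toy multiheme filament with known topology
#'
#' Builds an idealized cytochrome-filament heme array: each subunit is a
#' stack of porphyrin rings along the helical (z) axis at `chain_spacing`,
#' with consecutive rings alternating between an in-plane 180-degree flip
#' (antiparallel pair) and a 90-degree turn; positions listed in
#' `branch_positions` become pendant rings hanging off the preceding chain
#' heme at a designed minimum distance, emulating a branched heme that is
#' close to exactly one chain heme. Subunits are replicated by the
#' rise/twist screw operation; the gap across the subunit interface is
#' solved so that the terminal hemes of adjacent subunits sit at
#' `interface_pair_distance` (and the rise implied by that gap is
#' recorded). Supplying `rise` directly instead fixes the screw and the
#' achieved interface distance is whatever that geometry gives.
#'
#' Because the ideal ring is geometrically four-fold symmetric, the
#' designed spacings are realized *exactly* by the minimum edge-to-edge
#' distances, which makes generator-to-analyzer round trips meaningful at
#' tight tolerance.
#'
#' @param n_subunits Number of subunits (>= 1). Chains are named A, B, ...
#' @param hemes_per_subunit Total hemes per subunit, branches included.
#' @param chain_spacing Minimum ring distance between consecutive chain
#'   hemes, angstroms.
#' @param branch_positions List of `c(position, distance)` pairs: the heme
#'   at `position` (1-based within the subunit) becomes a pendant attached
#'   to the closest preceding chain heme at minimum ring distance
#'   `distance`.
#' @param twist Twist per subunit, degrees.
#' @param interface_pair_distance Designed minimum ring distance between
#'   the last chain heme of one subunit and the first of the next; used to
#'   derive the rise when `rise` is `NULL`.
#' @param rise Optional rise per subunit, angstroms; overrides the
#'   interface-distance solve.
#' @return Atom tibble with a `ground_truth` attribute: list with
#'   `main_chain` (heme ids in order), `branches` (tibble `heme`,
#'   `attachment`, `distance`), `chain_spacing`, `interface_distance`,
#'   `rise`, `twist`, `n_subunits`, `hemes_per_subunit`.
#' @export
make_filament <- function(n_subunits = 3L, hemes_per_subunit = 8L,
                          chain_spacing = 4.5,
                          branch_positions = list(c(6, 4.6)),
                          twist = -158.2, interface_pair_distance = 4.5,
                          rise = NULL) {
  if (n_subunits < 1L) abort("`n_subunits` must be >= 1.")
  if (chain_spacing <= 0) abort("`chain_spacing` must be positive.")
  if (hemes_per_subunit < 1L) abort("`hemes_per_subunit` must be >= 1.")
  branch_idx <- if (length(branch_positions)) {
    vapply(branch_positions, function(b) as.integer(b[1L]), integer(1))
  } else integer(0)
  branch_dist <- if (length(branch_positions)) {
    vapply(branch_positions, function(b) as.numeric(b[2L]), numeric(1))
  } else numeric(0)
  if (any(branch_idx <= 1L) || any(branch_idx > hemes_per_subunit)) {
    abort("branch positions must lie in 2..hemes_per_subunit.")
  }
  chain_idx <- setdiff(seq_len(hemes_per_subunit), branch_idx)
  m <- length(chain_idx)
  if (m < 1L) abort("at least one chain heme is required.")

  # orientations along the chain: alternate flip (antiparallel) / quarter
  # turn so adjacent pairs exercise more than one rotation angle
  flip_x <- rot_axis(c(1, 0, 0), 180)
  quarter <- rot_z(90)
  orient <- vector("list", m)
  orient[[1L]] <- diag(3)
  if (m > 1L) {
    for (j in 2L:m) {
      step <- if (j %% 2L == 0L) flip_x else quarter
      orient[[j]] <- step %*% orient[[j - 1L]]
    }
  }

  # one subunit: chain hemes stacked on the z axis
  base <- ideal_porphyrin()
  subunit <- vector("list", hemes_per_subunit)
  z_of <- numeric(m)
  for (j in seq_len(m)) {
    z_of[j] <- (j - 1L) * chain_spacing
    subunit[[chain_idx[j]]] <- transform_ring(
      porphyrin_ring(base$coords, "A", chain_idx[j]),
      orient[[j]], c(0, 0, z_of[j])
    )
  }
  # pendant branches: coplanar offset along +x from the attachment heme,
  # offset solved so the minimum ring distance equals the design
  attach_idx <- integer(length(branch_idx))
  for (k in seq_along(branch_idx)) {
    prev_chain <- chain_idx[chain_idx < branch_idx[k]]
    attach <- prev_chain[length(prev_chain)]
    attach_idx[k] <- attach
    a_ring <- subunit[[attach]]
    b0 <- porphyrin_ring(base$coords, "A", branch_idx[k])
    f <- function(dx) {
      bb <- transform_ring(b0, flip_x, a_ring$fe + c(dx, 0, 0))
      min_ring_distance(a_ring, bb) - branch_dist[k]
    }
    dx <- uniroot(f, c(0, branch_dist[k] + 30), tol = 1e-12)$root
    subunit[[branch_idx[k]]] <-
      transform_ring(b0, flip_x, a_ring$fe + c(dx, 0, 0))
  }

  # rise: either given, or solved so the interface pair hits its design
  top <- subunit[[chain_idx[m]]]
  bottom0 <- subunit[[chain_idx[1L]]]
  interface_gap <- NULL
  if (is.null(rise)) {
    if (n_subunits > 1L || !is.null(interface_pair_distance)) {
      f <- function(g) {
        bb <- transform_ring(bottom0, rot_z(twist),
                             c(0, 0, z_of[m] + g))
        min_ring_distance(top, bb) - interface_pair_distance
      }
      hi <- interface_pair_distance + 30
      lo <- 1e-3
      if (f(lo) > 0) {
        abort("`interface_pair_distance` is not attainable with this twist.")
      }
      interface_gap <- uniroot(f, c(lo, hi), tol = 1e-12)$root
      rise <- z_of[m] + interface_gap
    } else {
      rise <- z_of[m] + chain_spacing
    }
  }
  params <- helical_params(rise, twist)

  unit_atoms <- rings_to_structure(subunit, structure_id = "filament")
  atoms <- if (n_subunits == 1L) {
    unit_atoms
  } else {
    fil <- expand_filament(unit_atoms, params, n_subunits)
    fil$chain_id <- LETTERS[fil$copy_index + 1L]
    fil$copy_index <- NULL
    fil
  }
  if (n_subunits == 1L) atoms$chain_id <- "A"

  chains <- LETTERS[seq_len(n_subunits)]
  main_chain <- as.vector(t(outer(chains, chain_idx, paste, sep = ":")))
  achieved_interface <- if (n_subunits > 1L) {
    hs <- extract_hemes(atoms)
    ra <- hs$ring[[match(paste0("A:", chain_idx[m]),
                         paste0(hs$chain_id, ":", hs$residue_seq))]]
    rb <- hs$ring[[match(paste0("B:", chain_idx[1L]),
                         paste0(hs$chain_id, ":", hs$residue_seq))]]
    min_ring_distance(ra, rb)
  } else NA_real_
  branches <- tibble(
    heme = as.vector(t(outer(chains, branch_idx, paste, sep = ":"))),
    attachment = as.vector(t(outer(chains, attach_idx, paste, sep = ":"))),
    distance = rep(branch_dist, times = n_subunits)
  )
  attr(atoms, "ground_truth") <- list(
    main_chain = main_chain, branches = branches,
    chain_spacing = chain_spacing, interface_distance = achieved_interface,
    rise = rise, twist = twist, n_subunits = n_subunits,
    hemes_per_subunit = hemes_per_subunit
  )
  atoms
}

#' Ground truth attached to a generated structure
#'
#' @param atoms Tibble returned by [make_pair()] or [make_filament()].
#' @return The ground-truth list, or `NULL` if absent. dplyr verbs may
#'   drop attributes, so read the ground truth before reshaping.
#' @export
ground_truth <- function(atoms) {
  attr(atoms, "ground_truth", exact = TRUE)
}

#' Write a generated structure plus its ground-truth sidecar
#'
#' @param atoms Generated atom tibble carrying a ground-truth attribute.
#' @param path Output PDB path; the sidecar is written next to it as
#'   `<path>.json` (requires \pkg{jsonlite}).
#' @return `path`, invisibly.
#' @export
write_synthetic <- function(atoms, path) {
  write_pdb(atoms, path)
  gt <- ground_truth(atoms)
  if (!is.null(gt)) {
    if (!requireNamespace("jsonlite", quietly = TRUE)) {
      warn("jsonlite not available; ground-truth sidecar not written.")
    } else {
      jsonlite::write_json(gt, paste0(path, ".json"), auto_unbox = TRUE,
                           digits = NA)
    }
  }
  invisible(path)
}

#' Random atom cluster for surface-area validation
#'
#' A small cluster of atoms with mixed elements at uniform random
#' positions in a cube, used to validate the Shrake-Rupley implementation
#' against Monte-Carlo and analytic references.
#'
#' @param n_atoms Number of atoms.
#' @param box Cube edge length, angstroms.
#' @param elements Elements to sample from.
#' @param seed Seed for reproducibility (`NULL` leaves the RNG state
#'   alone).
#' @return Atom tibble of single-atom residues on chain X.
#' @export
random_atom_cluster <- function(n_atoms = 10L, box = 6,
                                elements = c("C", "N", "O", "S"),
                                seed = 20220905L) {
  if (!is.null(seed)) set.seed(seed)
  tibble(
    record = "ATOM",
    atom_name = paste0("X", seq_len(n_atoms)),
    element = sample(elements, n_atoms, replace = TRUE),
    x = stats::runif(n_atoms, 0, box),
    y = stats::runif(n_atoms, 0, box),
    z = stats::runif(n_atoms, 0, box),
    residue_name = "CLU",
    residue_seq = seq_len(n_atoms),
    chain_id = "X",
    altloc = "",
    occupancy = 1,
    structure_id = "cluster"
  )
}
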