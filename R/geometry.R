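#' Minimum edge-to-edge distance between two porphyrin rings
#'
#' The smallest Euclidean distance over all 25 x 25 atom pairs of the two
#' porphyrin cores, regardless of atom type — the "edge-to-edge" distance
#' used to define heme contacts.
#'
#' @param a,b [porphyrin_ring()] objects with distinct heme identities.
#' @return Distance in angstroms (non-negative, symmetric in `a`, `b`).
#' @export
min_ring_distance <- function(a, b) {
  stopifnot(inherits(a, "porphyrin_ring"), inherits(b, "porphyrin_ring"))
  if (heme_id(a) == heme_id(b)) {
    abort("self-pair: the two rings have the same heme identity.")
  }
  sqrt(min_cross_dist2(a$coords, b$coords))
}

# Squared minimum cross distance between two coordinate sets.
min_cross_dist2 <- function(p, q) {
  d2 <- outer(rowSums(p^2), rep(1, nrow(q))) +
    outer(rep(1, nrow(p)), rowSums(q^2)) - 2 * p %*% t(q)
  max(min(d2), 0)
}

# Kabsch least-squares rigid superposition of P onto Q (n x 3 each):
# q ~ R p + t with det(R) = +1. Returns list(rotation, translation, rmsd).
kabsch <- function(p, q) {
  pc <- colMeans(p); qc <- colMeans(q)
  p0 <- sweep(p, 2L, pc); q0 <- sweep(q, 2L, qc)
  h <- t(p0) %*% q0
  sv <- svd(h)
  d <- sign(det(sv$v %*% t(sv$u)))
  r <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  tr <- qc - as.numeric(r %*% pc)
  fit <- p %*% t(r) + matrix(tr, nrow(p), 3L, byrow = TRUE)
  list(rotation = r, translation = tr,
       rmsd = sqrt(mean(rowSums((q - fit)^2))), fitted = fit)
}

#' Superpose one porphyrin ring onto another
#'
#' Least-squares rigid superposition (proper rotation only) of ring `a`'s
#' 25 atoms onto ring `b`'s, with correspondence by canonical atom name
#' (FE to FE, NA to NA, ...). The name-based correspondence is what makes
#' the rotation angle well defined: the chemically distinct pyrrole rings
#' A-D break the porphyrin's geometric pseudo-symmetry.
#'
#' @param a,b [porphyrin_ring()] objects.
#' @return A `ring_superposition`: list with `rotation` (3 x 3),
#'   `translation`, `rmsd` (angstroms), `n_pairs_used` (25), `theta`
#'   (rotation angle, degrees) and `kept` (indices used).
#' @export
superpose_rings <- function(a, b) {
  stopifnot(inherits(a, "porphyrin_ring"), inherits(b, "porphyrin_ring"))
  fit <- kabsch(a$coords, b$coords)
  new_superposition(fit$rotation, fit$translation, fit$rmsd, 25L, 1:25)
}

new_superposition <- function(rotation, translation, rmsd, n, kept) {
  structure(
    list(rotation = rotation, translation = translation, rmsd = rmsd,
         n_pairs_used = as.integer(n), theta = rotation_angle(rotation),
         kept = kept),
    class = "ring_superposition"
  )
}

#' @export
print.ring_superposition <- function(x, ...) {
  cat(sprintf(
    "<ring_superposition> rmsd = %.4f A over %d atom pairs, theta = %.2f deg\n",
    x$rmsd, x$n_pairs_used, x$theta))
  invisible(x)
}

#' Rotation angle of a rotation matrix
#'
#' The angle theta = arccos((tr(R) - 1) / 2), in degrees, of a proper
#' rotation matrix. Applied to the superposition matrix between two
#' porphyrin rings it is the heme-pair orientation statistic: 0 deg means
#' the rings are perfectly parallel, 180 deg perfectly antiparallel
#' (flipped). The half-trace cosine is clamped into \[-1, 1\] and the angle
#' is evaluated as atan2(|sin theta|, cos theta) — algebraically identical
#' to its arccosine but numerically stable at 0 and 180 deg, where the
#' bare arccosine loses half the working precision.
#'
#' @param rotation 3 x 3 orthonormal matrix with det +1 (tolerance 1e-6).
#' @return Angle in degrees, in \[0, 180\].
#' @export
rotation_angle <- function(rotation) {
  r <- as.matrix(rotation)
  if (!is.numeric(r) || any(dim(r) != c(3L, 3L)) || any(!is.finite(r))) {
    abort("`rotation` must be a finite 3 x 3 numeric matrix.")
  }
  if (max(abs(crossprod(r) - diag(3))) > 1e-6 || abs(det(r) - 1) > 1e-6) {
    abort("`rotation` is not a proper rotation matrix (orthonormal, det +1).")
  }
  ct <- pmin(1, pmax(-1, (sum(diag(r)) - 1) / 2))
  # |sin theta| from the antisymmetric part of R
  st <- sqrt((r[3, 2] - r[2, 3])^2 + (r[1, 3] - r[3, 1])^2 +
               (r[2, 1] - r[1, 2])^2) / 2
  atan2(st, ct) * 180 / pi
}

#' Classify the packing motif of a heme pair
#'
#' Discretizes the rotation angle (and ring-plane angle) into the packing
#' classes seen in heme-pair surveys: `parallel` (theta < 40 deg),
#' `antiparallel` (theta > 140 deg), `T_shaped` (ring planes roughly
#' perpendicular: plane angle in \[60, 120\] deg), otherwise
#' `intermediate`. The numeric bounds are this package's discretization of
#' qualitative orientation clusters and can be tightened by the caller.
#'
#' @param theta Rotation angle(s), degrees in \[0, 180\].
#' @param plane_angle Angle(s) between the two ring-plane normals, degrees
#'   in \[0, 180\]. Defaults to `theta`, exact when the pair differs by a
#'   pure tilt about an in-plane axis.
#' @return Character vector of motif labels.
#' @export
classify_motif <- function(theta, plane_angle = theta) {
  if (any(!is.finite(theta)) || any(theta < 0 | theta > 180)) {
    abort("`theta` must lie in [0, 180] degrees.")
  }
  dplyr::case_when(
    theta < 40 ~ "parallel",
    theta > 140 ~ "antiparallel",
    plane_angle >= 60 & plane_angle <= 120 ~ "T_shaped",
    TRUE ~ "intermediate"
  )
}

#' Contact pairs among a set of porphyrin rings
#'
#' All unordered ring pairs whose minimum edge-to-edge distance does not
#' exceed `cutoff`, each annotated with the superposition rotation, the
#' rotation angle theta, the ring-plane angle, and the packing motif.
#'
#' @param hemes Heme tibble from [extract_hemes()] (a `ring` list-column),
#'   or a bare list of [porphyrin_ring()] objects.
#' @param cutoff Contact cutoff on the minimum ring distance, angstroms.
#' @return Tibble sorted by (chain_a, seq_a, chain_b, seq_b) with columns
#'   `chain_a`, `seq_a`, `resname_a`, `chain_b`, `seq_b`, `resname_b`,
#'   `min_distance`, `theta`, `plane_angle`, `motif`, `rmsd`, and
#'   list-columns `rotation`, `translation`. Zero rows when no pair is in
#'   contact (or fewer than two rings are supplied).
#' @export
contact_pairs <- function(hemes, cutoff = 6.0) {
  rings <- as_ring_list(hemes)
  ord <- order(map_chr(rings, function(r) r$chain_id),
               map_dbl(rings, function(r) r$residue_seq))
  rings <- rings[ord]
  n <- length(rings)
  out <- list()
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        d <- min_ring_distance(rings[[i]], rings[[j]])
        if (d > cutoff) next
        sup <- superpose_rings(rings[[i]], rings[[j]])
        pa <- plane_angle(rings[[i]], rings[[j]])
        out[[length(out) + 1L]] <- tibble(
          chain_a = rings[[i]]$chain_id, seq_a = rings[[i]]$residue_seq,
          resname_a = rings[[i]]$residue_name,
          chain_b = rings[[j]]$chain_id, seq_b = rings[[j]]$residue_seq,
          resname_b = rings[[j]]$residue_name,
          min_distance = d, theta = sup$theta, plane_angle = pa,
          motif = classify_motif(sup$theta, pa), rmsd = sup$rmsd,
          rotation = list(sup$rotation), translation = list(sup$translation)
        )
      }
    }
  }
  if (length(out) == 0L) {
    return(tibble(
      chain_a = character(), seq_a = integer(), resname_a = character(),
      chain_b = character(), seq_b = integer(), resname_b = character(),
      min_distance = numeric(), theta = numeric(), plane_angle = numeric(),
      motif = character(), rmsd = numeric(),
      rotation = list(), translation = list()
    ))
  }
  dplyr::bind_rows(out)
}

as_ring_list <- function(hemes) {
  if (inherits(hemes, "porphyrin_ring")) return(list(hemes))
  if (is.data.frame(hemes)) {
    if (!"ring" %in% names(hemes)) {
      abort("heme tibble must carry a `ring` list-column (see extract_hemes()).")
    }
    return(hemes$ring)
  }
  if (is.list(hemes) && all(map_lgl(hemes, inherits, "porphyrin_ring"))) {
    return(hemes)
  }
  abort("`hemes` must be porphyrin rings or a tibble with a `ring` column.")
}

# Angle between the ring-plane normals, degrees in [0, 180].
plane_angle <- function(a, b) {
  ct <- sum(a$normal * b$normal)
  acos(pmin(1, pmax(-1, ct))) * 180 / pi
}

#' Pruned best-subset superposition
#'
#' Iteratively superposes two coordinate sets with a given one-to-one
#' correspondence, dropping atom pairs whose residual exceeds
#' `prune_factor` times the current RMSD, and refitting until no pair is
#' dropped or fewer than four pairs would remain. Reports the final RMSD
#' and the number of surviving pairs — the "best aligned subset" summary
#' used for comparing globally dissimilar structures that share a
#' conserved core.
#'
#' @param coords_a,coords_b N x 3 coordinate matrices (N >= 4), row i of
#'   `coords_a` corresponding to row i of `coords_b`.
#' @param prune_factor Residual threshold as a multiple of the current
#'   RMSD.
#' @return A `ring_superposition` with `n_pairs_used` the surviving count
#'   and `kept` the surviving row indices.
#' @export
pruned_superposition <- function(coords_a, coords_b, prune_factor = 2.0) {
  p <- as.matrix(coords_a); q <- as.matrix(coords_b)
  if (nrow(p) != nrow(q) || ncol(p) != 3L || ncol(q) != 3L) {
    abort("`coords_a` and `coords_b` must be N x 3 with equal N.")
  }
  if (nrow(p) < 4L) abort("need at least 4 corresponding atom pairs.")
  active <- seq_len(nrow(p))
  repeat {
    fit <- kabsch(p[active, , drop = FALSE], q[active, , drop = FALSE])
    resid <- sqrt(rowSums((q[active, , drop = FALSE] - fit$fitted)^2))
    if (fit$rmsd < 1e-12) break
    drop <- resid > prune_factor * fit$rmsd
    if (!any(drop) || sum(!drop) < 4L) break
    active <- active[!drop]
  }
  new_superposition(fit$rotation, fit$translation, fit$rmsd,
                    length(active), active)
}
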