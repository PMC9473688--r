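#' Canonical porphyrin-ring atom names
#'
#' The 25 non-hydrogen atoms of the porphyrin core of a heme (HEC or HEM),
#' in the fixed order used throughout the package: the iron, the four
#' pyrrole nitrogens, the sixteen pyrrole carbons and the four methine
#' (meso) carbons. Vinyl and propionate substituents are excluded.
#'
#' @return Character vector of length 25.
#' @export
porphyrin_atoms <- function() {
  c("FE", "NA", "NB", "NC", "ND",
    "C1A", "C2A", "C3A", "C4A",
    "C1B", "C2B", "C3B", "C4B",
    "C1C", "C2C", "C3C", "C4C",
    "C1D", "C2D", "C3D", "C4D",
    "CHA", "CHB", "CHC", "CHD")
}

#' Construct a porphyrin-ring object
#'
#' Low-level constructor. `coords` must hold the 25 canonical atoms in the
#' order of [porphyrin_atoms()]. The ring-plane normal is the least-squares
#' plane normal of the 24 non-iron atoms, with its sign fixed by the
#' NA->C1A x NA->C1B cross-product convention so that the normal is
#' reproducible for a given atom labelling.
#'
#' @param coords 25 x 3 numeric matrix, angstroms, canonical atom order.
#' @param chain_id,residue_seq,residue_name Identity of the parent heme
#'   residue (`residue_name` is `"HEC"` or `"HEM"`).
#' @return An object of class `porphyrin_ring`: a list with elements
#'   `coords` (25 x 3, rownames = atom names), `fe` (Fe position),
#'   `normal` (unit plane normal), `chain_id`, `residue_seq`,
#'   `residue_name`.
#' @export
porphyrin_ring <- function(coords, chain_id = "A", residue_seq = 1L,
                           residue_name = "HEC") {
  coords <- as.matrix(coords)
  if (!is.numeric(coords) || nrow(coords) != 25L || ncol(coords) != 3L) {
    abort("`coords` must be a 25 x 3 numeric matrix in canonical atom order.")
  }
  if (any(!is.finite(coords))) {
    abort("ring coordinates must be finite.")
  }
  if (!residue_name %in% c("HEC", "HEM")) {
    abort("`residue_name` must be \"HEC\" or \"HEM\".")
  }
  rownames(coords) <- porphyrin_atoms()
  structure(
    list(
      coords = coords,
      fe = coords[1L, ],
      normal = ring_plane_normal(coords),
      chain_id = as.character(chain_id),
      residue_seq = as.integer(residue_seq),
      residue_name = residue_name
    ),
    class = "porphyrin_ring"
  )
}

#' @export
print.porphyrin_ring <- function(x, ...) {
  cat(sprintf("<porphyrin_ring> %s %s:%d  Fe = (%.2f, %.2f, %.2f)\n",
              x$residue_name, x$chain_id, x$residue_seq,
              x$fe[1], x$fe[2], x$fe[3]))
  invisible(x)
}

heme_id <- function(ring) {
  paste0(ring$chain_id, ":", ring$residue_seq)
}

# Least-squares plane normal of the 24 non-Fe ring atoms (SVD), signed by
# the NA->C1A x NA->C1B convention.
ring_plane_normal <- function(coords) {
  pts <- coords[-1L, , drop = FALSE]
  ctr <- colMeans(pts)
  sv <- svd(sweep(pts, 2L, ctr))
  n <- sv$v[, 3L]
  na <- coords["NA", ]
  ref <- cross3(coords["C1A", ] - na, coords["C1B", ] - na)
  if (sum(n * ref) < 0) n <- -n
  n / sqrt(sum(n^2))
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Idealized planar porphyrin ring
#'
#' Builds a flat, geometrically four-fold-symmetric porphyrin core: Fe at
#' the origin, pyrrole nitrogens 2.00 angstroms from Fe along +/-x and
#' +/-y, alpha/beta pyrrole carbons and meso carbons at idealized radii,
#' all in the z = 0 plane. Because the coordinates have exact C4 geometric
#' symmetry, in-plane quarter-turns and in-plane flips map the atom set
#' onto itself, which makes generated stacking distances exact.
#'
#' @inheritParams porphyrin_ring
#' @return A [porphyrin_ring()] with plane normal +z.
#' @export
ideal_porphyrin <- function(chain_id = "A", residue_seq = 1L,
                            residue_name = "HEC") {
  deg <- pi / 180
  pol <- function(r, theta_deg) {
    c(r * cos(theta_deg * deg), r * sin(theta_deg * deg), 0)
  }
  base <- c(A = 0, B = 90, C = 180, D = 270)
  coords <- matrix(0, 25L, 3L)
  rownames(coords) <- porphyrin_atoms()
  coords["FE", ] <- c(0, 0, 0)
  for (k in names(base)) {
    phi <- base[[k]]
    coords[paste0("N", k), ]  <- pol(2.00, phi)
    coords[paste0("C1", k), ] <- pol(3.05, phi - 23.0)
    coords[paste0("C2", k), ] <- pol(4.25, phi - 16.5)
    coords[paste0("C3", k), ] <- pol(4.25, phi + 16.5)
    coords[paste0("C4", k), ] <- pol(3.05, phi + 23.0)
  }
  coords["CHA", ] <- pol(3.45, -45)
  coords["CHB", ] <- pol(3.45, 45)
  coords["CHC", ] <- pol(3.45, 135)
  coords["CHD", ] <- pol(3.45, 225)
  porphyrin_ring(coords, chain_id, residue_seq, residue_name)
}

#' Convert porphyrin rings to an atom table
#'
#' Assembles one or more rings into the standard atom tibble used by the
#' I/O and surface modules, with one HETATM row per ring atom.
#'
#' @param rings A `porphyrin_ring` or a list of them.
#' @param structure_id Identifier recorded in the `structure_id` column.
#' @return Atom tibble (see [read_structure()] for the column contract).
#' @export
rings_to_structure <- function(rings, structure_id = "synthetic") {
  if (inherits(rings, "porphyrin_ring")) rings <- list(rings)
  rows <- purrr::map(rings, function(r) {
    tibble(
      record = "HETATM",
      atom_name = porphyrin_atoms(),
      element = ifelse(porphyrin_atoms() == "FE", "FE",
                       substr(porphyrin_atoms(), 1L, 1L)),
      x = unname(r$coords[, 1L]),
      y = unname(r$coords[, 2L]),
      z = unname(r$coords[, 3L]),
      residue_name = r$residue_name,
      residue_seq = r$residue_seq,
      chain_id = r$chain_id,
      altloc = "",
      occupancy = 1,
      structure_id = structure_id
    )
  })
  dplyr::bind_rows(rows)
}

# Apply a rigid transform (rotation then translation) to a ring.
transform_ring <- function(ring, rotation = diag(3), translation = c(0, 0, 0)) {
  coords <- ring$coords %*% t(rotation)
  coords <- sweep(coords, 2L, translation, `+`)
  porphyrin_ring(coords, ring$chain_id, ring$residue_seq, ring$residue_name)
}
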