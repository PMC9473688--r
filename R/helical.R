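#' Helical symmetry parameters
#'
#' Rise (axial translation per subunit, angstroms) and twist (rotation per
#' subunit, degrees, signed for handedness) of a 1-start helical polymer.
#' The helical axis is fixed to z by convention.
#'
#' @param rise Rise per subunit, angstroms (> 0).
#' @param twist Twist per subunit, degrees (0 < |twist| <= 180).
#' @return A `helical_params` object.
#' @examples
#' helical_params(rise = 58.1, twist = -158.2) |> pitch()
#' @export
helical_params <- function(rise, twist) {
  if (!is.finite(rise) || rise <= 0) abort("`rise` must be positive.")
  if (!is.finite(twist) || twist == 0 || abs(twist) > 180) {
    abort("`twist` must be non-zero with |twist| <= 180 degrees.")
  }
  structure(list(rise = rise, twist = twist, axis = c(0, 0, 1)),
            class = "helical_params")
}

#' @export
print.helical_params <- function(x, ...) {
  cat(sprintf("<helical_params> rise %.2f A, twist %.2f deg (pitch %.1f A)\n",
              x$rise, x$twist, pitch(x)))
  invisible(x)
}

#' 1-start helical pitch
#'
#' The axial length of one full turn of the 1-start helix:
#' `rise * 360 / |twist|`. Invariant to the handedness (sign of twist).
#'
#' @param params A [helical_params()] object.
#' @return Pitch in angstroms.
#' @export
pitch <- function(params) {
  stopifnot(inherits(params, "helical_params"))
  params$rise * 360 / abs(params$twist)
}

#' Predicted layer-line positions of a helical filament
#'
#' In the power spectrum of a 1-start helical filament the meridional
#' layer line sits at 1/rise and the near-equatorial 1-start layer line at
#' 1/pitch.
#'
#' @param params A [helical_params()] object.
#' @return Tibble with `pitch` (angstroms), `meridional_position` and
#'   `one_start_position` (reciprocal angstroms).
#' @export
layer_lines <- function(params) {
  p <- pitch(params)
  tibble(pitch = p,
         meridional_position = 1 / params$rise,
         one_start_position = 1 / p)
}

# Rotation about z by `deg` degrees.
rot_z <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), sin(th), 0,
           -sin(th), cos(th), 0,
           0, 0, 1), 3L, 3L)
}

# Rotation about an arbitrary unit axis by `deg` degrees (Rodrigues).
rot_axis <- function(axis, deg) {
  u <- axis / sqrt(sum(axis^2))
  th <- deg * pi / 180
  k <- matrix(c(0, u[3], -u[2],
                -u[3], 0, u[1],
                u[2], -u[1], 0), 3L, 3L)
  diag(3) + sin(th) * k + (1 - cos(th)) * (k %*% k)
}

#' Expand an asymmetric unit into a helical filament
#'
#' Applies the screw operation of a 1-start helix: copy `i` is the input
#' rotated about z by `i * twist` degrees and translated by `i * rise`
#' angstroms along z. Copies are indexed relative to `center_index`, so a
#' three-copy expansion with `center_index = 1` places one copy below and
#' one above the unchanged central subunit. Chain ids are suffixed with
#' the copy index (use [write_pdb()]'s automatic remapping for file
#' output).
#'
#' @param atoms Atom tibble of the asymmetric unit.
#' @param params A [helical_params()] object.
#' @param n_copies Number of subunit copies (>= 1).
#' @param center_index Which copy keeps the input coordinates (0-based).
#' @return Atom tibble of the filament with an added `copy_index` column.
#'   A warning is raised if any inter-copy atom pair falls below 1
#'   angstrom (steric clash in the generated model).
#' @export
expand_filament <- function(atoms, params, n_copies, center_index = 0L) {
  stopifnot(inherits(params, "helical_params"))
  if (n_copies < 1L) abort("`n_copies` must be >= 1.")
  idx <- seq(0L, n_copies - 1L) - as.integer(center_index)
  copies <- purrr::map(idx, function(i) {
    out <- transform_structure(atoms, rot_z(i * params$twist),
                               c(0, 0, i * params$rise))
    out$copy_index <- i
    if (n_copies > 1L) out$chain_id <- paste0(out$chain_id, "_", i)
    out
  })
  fil <- dplyr::bind_rows(copies)
  if (n_copies > 1L && nrow(atoms) <= 5000L) {
    for (k in seq_len(n_copies - 1L)) {
      a <- as.matrix(copies[[k]][, c("x", "y", "z")])
      b <- as.matrix(copies[[k + 1L]][, c("x", "y", "z")])
      if (min_cross_dist2(a, b) < 1) {
        warn("inter-copy atomic clash (< 1 A) in expanded filament.")
        break
      }
    }
  }
  fil
}
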