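#' Read a macromolecular structure into an atom tibble
#'
#' Parses a PDB or mmCIF file (via \pkg{bio3d}) into the flat atom table
#' used throughout the package. Hydrogens are dropped. When a file carries
#' alternate conformers, the highest-occupancy conformer of each atom is
#' kept (ties broken in favour of altloc `"A"`, then alphabetically).
#' Only the first model of multi-model files is read.
#'
#' @param path Path to a structure file.
#' @param format `"auto"` (by file extension), `"pdb"` or `"mmcif"`.
#' @return A tibble with one row per atom and columns `record`
#'   (ATOM/HETATM), `atom_name`, `element`, `x`, `y`, `z` (angstroms),
#'   `residue_name`, `residue_seq`, `chain_id`, `altloc`, `occupancy`,
#'   `structure_id`.
#' @examples
#' pdb <- tempfile(fileext = ".pdb")
#' make_pair(theta = 90, normal_offset = 5) |> write_pdb(pdb)
#' read_structure(pdb)
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    abort(sprintf("structure file not found: %s", path))
  }
  if (format == "auto") {
    ext <- tolower(sub(".*\\.", "", sub("\\.gz$", "", path)))
    format <- if (ext %in% c("cif", "mmcif")) "mmcif" else "pdb"
  }
  # bio3d's readers emit advisory warnings (cif reader beta note,
  # unparsed helix/sheet records) that are irrelevant to atom extraction
  parsed <- tryCatch(
    suppressWarnings(
      if (format == "mmcif") bio3d::read.cif(path, verbose = FALSE)
      else bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
    ),
    error = function(e) {
      abort(sprintf("could not parse '%s' as %s: %s",
                    path, format, conditionMessage(e)))
    }
  )
  at <- parsed$atom
  if (is.null(at) || nrow(at) == 0L) {
    abort(sprintf("could not parse '%s' as %s: no atom records found.",
                  path, format))
  }
  element <- toupper(trimws(ifelse(is.na(at$elesy) | at$elesy == "",
                                   guess_element(at$elety), at$elesy)))
  atoms <- tibble(
    record = at$type,
    atom_name = trimws(at$elety),
    element = element,
    x = at$x, y = at$y, z = at$z,
    residue_name = trimws(at$resid),
    residue_seq = as.integer(at$resno),
    chain_id = ifelse(is.na(at$chain), "", as.character(at$chain)),
    altloc = ifelse(is.na(at$alt), "", as.character(at$alt)),
    occupancy = ifelse(is.na(at$o), 1, at$o),
    structure_id = sub("\\.[^.]*(\\.gz)?$", "", basename(path))
  )
  atoms <- dplyr::filter(atoms, !.data$element %in% c("H", "D"))
  resolve_altlocs(atoms)
}

# Fallback element assignment from the atom name when the element column
# is absent (common in minimal PDB files).
guess_element <- function(atom_name) {
  nm <- toupper(trimws(atom_name))
  two <- substr(nm, 1L, 2L)
  ifelse(two %in% c("FE", "ZN", "MG", "MN", "CU", "NI", "CL", "BR"),
         two, substr(nm, 1L, 1L))
}

# Keep one conformer per (chain, residue, atom): highest occupancy,
# ties resolved toward altloc "A" (then alphabetically), preserving
# original atom order.
resolve_altlocs <- function(atoms) {
  atoms$.row <- seq_len(nrow(atoms))
  out <- atoms |>
    dplyr::group_by(.data$chain_id, .data$residue_seq,
                    .data$residue_name, .data$atom_name) |>
    dplyr::arrange(dplyr::desc(.data$occupancy), .data$altloc,
                   .by_group = TRUE) |>
    dplyr::slice(1L) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$.row)
  out$.row <- NULL
  out
}

#' Extract canonical porphyrin rings from a structure
#'
#' Finds every HEC/HEM residue carrying all 25 canonical porphyrin-core
#' atoms ([porphyrin_atoms()]) and returns one ring per residue. Hemes
#' with any canonical atom missing are skipped with a warning rather than
#' imputed, so downstream geometry never mixes measured and invented
#' atoms.
#'
#' @param atoms Atom tibble from [read_structure()] or a generator.
#' @return A tibble with one row per complete heme: `chain_id`,
#'   `residue_seq`, `residue_name`, and a `ring` list-column of
#'   [porphyrin_ring()] objects, sorted by (chain, residue number).
#'   Zero rows when the structure has no hemes.
#' @export
extract_hemes <- function(atoms) {
  hem <- dplyr::filter(atoms, .data$residue_name %in% c("HEC", "HEM"))
  empty <- tibble(chain_id = character(), residue_seq = integer(),
                  residue_name = character(), ring = list())
  if (nrow(hem) == 0L) return(empty)
  canon <- porphyrin_atoms()
  grp <- hem |>
    dplyr::group_by(.data$chain_id, .data$residue_seq, .data$residue_name) |>
    dplyr::group_split()
  rows <- list()
  skipped <- character()
  for (g in grp) {
    g <- g[!duplicated(g$atom_name), ]
    idx <- match(canon, g$atom_name)
    key <- paste0(g$chain_id[1], ":", g$residue_seq[1])
    if (anyNA(idx)) {
      skipped <- c(skipped, key)
      next
    }
    coords <- as.matrix(g[idx, c("x", "y", "z")])
    rows[[length(rows) + 1L]] <- tibble(
      chain_id = g$chain_id[1],
      residue_seq = as.integer(g$residue_seq[1]),
      residue_name = g$residue_name[1],
      ring = list(porphyrin_ring(coords, g$chain_id[1], g$residue_seq[1],
                                 g$residue_name[1]))
    )
  }
  if (length(skipped) > 0L) {
    warn(sprintf("skipped %d heme(s) with missing porphyrin-core atoms: %s",
                 length(skipped), paste(skipped, collapse = ", ")))
  }
  if (length(rows) == 0L) return(empty)
  dplyr::bind_rows(rows) |>
    dplyr::arrange(.data$chain_id, .data$residue_seq)
}

#' Write an atom tibble to a PDB file
#'
#' Coordinates are written at the PDB format's three-decimal precision, so
#' `read_structure(write_pdb(x, f))` reproduces them to 1e-3 angstroms.
#' Chain identifiers longer than one character (e.g. from
#' [expand_filament()]) are remapped to single letters with a warning.
#'
#' @param atoms Non-empty atom tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(atoms, path) {
  if (is.null(atoms) || nrow(atoms) == 0L) {
    abort("cannot write an empty structure.")
  }
  chains <- atoms$chain_id
  if (any(nchar(chains) != 1L)) {
    pool <- c(LETTERS, letters, as.character(0:9))
    u <- unique(chains)
    if (length(u) > length(pool)) {
      abort("too many chains to remap onto single-character PDB chain ids.")
    }
    map <- stats::setNames(pool[seq_along(u)], u)
    chains <- unname(map[chains])
    warn("chain ids remapped to single characters for PDB output.")
  }
  rec <- if ("record" %in% names(atoms)) atoms$record
         else ifelse(atoms$residue_name %in% c("HEC", "HEM"),
                     "HETATM", "ATOM")
  bio3d::write.pdb(
    file = path,
    xyz = as.numeric(t(as.matrix(atoms[, c("x", "y", "z")]))),
    type = rec,
    resno = atoms$residue_seq,
    resid = atoms$residue_name,
    eleno = seq_len(nrow(atoms)),
    elety = atoms$atom_name,
    chain = chains,
    o = atoms$occupancy,
    b = rep(0, nrow(atoms)),
    elesy = atoms$element
  )
  invisible(path)
}

#' Apply a rigid-body transform to an atom tibble
#'
#' @param atoms Atom tibble.
#' @param rotation 3 x 3 rotation matrix.
#' @param translation Length-3 translation vector (angstroms).
#' @return The transformed atom tibble.
#' @export
transform_structure <- function(atoms, rotation = diag(3),
                                translation = c(0, 0, 0)) {
  xyz <- as.matrix(atoms[, c("x", "y", "z")]) %*% t(rotation)
  xyz <- sweep(xyz, 2L, translation, `+`)
  atoms$x <- xyz[, 1L]; atoms$y <- xyz[, 2L]; atoms$z <- xyz[, 3L]
  atoms
}
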