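#' Survey heme-pair geometry over a corpus of structures
#'
#' Runs the contact-pair analysis over every structure file supplied and
#' concatenates the results into one tidy table — the batch form of the
#' distance/orientation survey. Pairs are intra-structure only (the first
#' model of multi-model files is used); unreadable files are skipped with
#' a warning. Row order is deterministic: input order, then (chain,
#' residue) within each structure, so re-running the survey reproduces the
#' table byte for byte.
#'
#' @param paths Character vector of PDB/mmCIF file paths, or a directory
#'   (searched non-recursively for `.pdb`/`.cif` files, sorted).
#' @param cutoff Contact cutoff on the minimum ring distance, angstroms.
#' @return Tibble with one row per contacting heme pair: `structure_id`,
#'   `chain_a`, `seq_a`, `resname_a`, `chain_b`, `seq_b`, `resname_b`,
#'   `min_distance`, `theta`, `plane_angle`, `motif`.
#' @export
survey <- function(paths, cutoff = 6.0) {
  if (length(paths) == 1L && dir.exists(paths)) {
    paths <- sort(list.files(paths, pattern = "\\.(pdb|ent|cif|mmcif)$",
                             full.names = TRUE, ignore.case = TRUE))
  }
  if (length(paths) == 0L) abort("no structure files supplied.")
  rows <- list()
  n_ok <- 0L
  for (p in paths) {
    atoms <- tryCatch(read_structure(p), error = function(e) {
      warn(sprintf("skipping unreadable file '%s': %s", p,
                   conditionMessage(e)))
      NULL
    })
    if (is.null(atoms)) next
    n_ok <- n_ok + 1L
    hemes <- extract_hemes(atoms)
    if (nrow(hemes) < 2L) next
    pr <- contact_pairs(hemes, cutoff = cutoff)
    if (nrow(pr) == 0L) next
    pr$structure_id <- atoms$structure_id[1L]
    rows[[length(rows) + 1L]] <- pr
  }
  if (n_ok == 0L) abort("no readable structure files in the corpus.")
  cols <- c("structure_id", "chain_a", "seq_a", "resname_a",
            "chain_b", "seq_b", "resname_b", "min_distance", "theta",
            "plane_angle", "motif")
  if (length(rows) == 0L) {
    out <- tibble(structure_id = character(), chain_a = character(),
                  seq_a = integer(), resname_a = character(),
                  chain_b = character(), seq_b = integer(),
                  resname_b = character(), min_distance = numeric(),
                  theta = numeric(), plane_angle = numeric(),
                  motif = character())
    return(out)
  }
  dplyr::bind_rows(rows)[, cols]
}

#' Histogram of heme-pair rotation angles
#'
#' Counts survey rows into fixed-width angle bins `[k w, (k+1) w)`.
#'
#' @param rows Survey tibble with a `theta` column (non-empty).
#' @param bin_width Bin width, degrees.
#' @return Tibble `bin_start`, `bin_end`, `count`; counts sum to
#'   `nrow(rows)`.
#' @export
angle_histogram <- function(rows, bin_width = 10) {
  if (nrow(rows) == 0L) abort("cannot histogram an empty pair table.")
  breaks <- seq(0, 180 + bin_width, by = bin_width)
  bin <- findInterval(rows$theta, breaks, rightmost.closed = FALSE)
  tb <- table(factor(bin, levels = seq_len(length(breaks) - 1L)))
  tibble(bin_start = breaks[-length(breaks)],
         bin_end = breaks[-1L],
         count = as.integer(tb))
}

#' Flag geometrically rare heme pairs
#'
#' Heme pairs with rotation angles in the 50-90 degree band normally sit
#' at edge-to-edge distances of 6 angstroms or more; a pair in that band
#' at a short distance is a rare, tight perpendicular-ish packing. This
#' adds a logical `rare` column marking rows with `theta` in
#' `[theta_low, theta_high]` and `min_distance < distance_max`.
#'
#' @param rows Survey tibble.
#' @param theta_low,theta_high Rotation-angle band, degrees.
#' @param distance_max Distance threshold, angstroms.
#' @return `rows` with an added `rare` column.
#' @export
rare_pair_flags <- function(rows, theta_low = 50, theta_high = 90,
                            distance_max = 5.0) {
  dplyr::mutate(
    rows,
    rare = .data$theta >= theta_low & .data$theta <= theta_high &
      .data$min_distance < distance_max
  )
}

#' Write a heme-pair table as TSV
#'
#' @param rows Survey or contact-pair tibble.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_pairs_tsv <- function(rows, path) {
  keep <- !vapply(rows, is.list, logical(1))
  write.table(rows[, keep], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Orientation-distance map of heme pairs
#'
#' Scatter of rotation angle against minimum ring distance, coloured by
#' packing motif — the standard view of heme-pair packing space in which
#' orientation clusters appear as dense bands.
#'
#' @param rows Survey tibble.
#' @param cutoff Optional distance cutoff drawn as a reference line.
#' @return A ggplot object.
#' @export
plot_orientation_map <- function(rows, cutoff = NULL) {
  p <- ggplot2::ggplot(rows, ggplot2::aes(
    x = .data$min_distance, y = .data$theta, colour = .data$motif)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::scale_y_continuous(limits = c(0, 180),
                                breaks = seq(0, 180, 45)) +
    ggplot2::labs(x = "minimum ring distance (Å)",
                  y = expression(theta ~ "(degrees)"),
                  colour = "motif") +
    ggplot2::theme_minimal()
  if (!is.null(cutoff)) {
    p <- p + ggplot2::geom_vline(xintercept = cutoff, linetype = "dashed")
  }
  p
}

#' Histogram plot of heme-pair rotation angles
#'
#' @param rows Survey tibble.
#' @param bin_width Bin width, degrees.
#' @return A ggplot object.
#' @export
plot_angle_histogram <- function(rows, bin_width = 10) {
  h <- angle_histogram(rows, bin_width)
  ggplot2::ggplot(h, ggplot2::aes(x = .data$bin_start + bin_width / 2,
                                  y = .data$count)) +
    ggplot2::geom_col(width = bin_width, fill = "grey30") +
    ggplot2::labs(x = expression(theta ~ "(degrees)"), y = "pairs") +
    ggplot2::theme_minimal()
}
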