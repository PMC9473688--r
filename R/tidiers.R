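#' Tidy a ring superposition
#'
#' @param x A `ring_superposition`.
#' @param ... Unused.
#' @return One-row tibble with `theta`, `rmsd`, `n_pairs_used` and the
#'   translation components.
#' @method tidy ring_superposition
#' @export
tidy.ring_superposition <- function(x, ...) {
  tibble(theta = x$theta, rmsd = x$rmsd, n_pairs_used = x$n_pairs_used,
         tx = x$translation[1], ty = x$translation[2],
         tz = x$translation[3])
}

#' @rdname tidy.ring_superposition
#' @method glance ring_superposition
#' @export
glance.ring_superposition <- function(x, ...) {
  tibble(rmsd = x$rmsd, n_pairs_used = x$n_pairs_used, theta = x$theta)
}

#' Tidy a heme graph
#'
#' @param x A [heme_graph()].
#' @param ... Unused.
#' @return Edge tibble with `from`, `to`, `min_distance`, `theta`,
#'   `motif` and an `on_main_chain` flag marking edges between consecutive
#'   main-chain hemes.
#' @method tidy heme_graph
#' @export
tidy.heme_graph <- function(x, ...) {
  ed <- as_tibble(igraph::as_data_frame(x$graph, what = "edges"))
  mc <- x$main_chain
  step <- character(0)
  if (length(mc) > 1L) {
    a <- mc[-length(mc)]; b <- mc[-1L]
    step <- paste(pmin(a, b), pmax(a, b))
  }
  ed$on_main_chain <- paste(pmin(ed$from, ed$to),
                            pmax(ed$from, ed$to)) %in% step
  ed
}

#' @rdname tidy.heme_graph
#' @method glance heme_graph
#' @export
glance.heme_graph <- function(x, ...) {
  tibble(
    n_hemes = igraph::vcount(x$graph),
    n_contacts = igraph::ecount(x$graph),
    chain_length = length(x$main_chain),
    n_branches = length(unique(x$branches$heme)),
    n_isolated = length(x$isolated)
  )
}

#' Tidy a SASA result
#'
#' @param x A `sasa_result` from [shrake_rupley()].
#' @param ... Unused.
#' @return The per-heme area tibble (`tidy`), or a one-row summary
#'   (`glance`).
#' @method tidy sasa_result
#' @export
tidy.sasa_result <- function(x, ...) {
  x$per_heme
}

#' @rdname tidy.sasa_result
#' @method glance sasa_result
#' @export
glance.sasa_result <- function(x, ...) {
  tibble(total_area = x$total_area, n_atoms = nrow(x$per_atom),
         n_hemes = nrow(x$per_heme), probe_radius = x$probe_radius,
         n_sphere_points = x$n_sphere_points)
}

#' Plot per-heme solvent exposure
#'
#' @param object A `sasa_result`.
#' @param ... Unused.
#' @return A ggplot bar chart of per-heme solvent-exposed area.
#' @method autoplot sasa_result
#' @export
autoplot.sasa_result <- function(object, ...) {
  ph <- object$per_heme
  ph$heme <- paste0(ph$chain_id, ":", ph$residue_seq)
  ggplot2::ggplot(ph, ggplot2::aes(x = stats::reorder(.data$heme,
                                                      .data$area),
                                   y = .data$area)) +
    ggplot2::geom_col(fill = "firebrick") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = expression("solvent-exposed area (" *
                                             ring(A)^2 * ")")) +
    ggplot2::theme_minimal()
}

#' Plot a heme contact graph
#'
#' Fe positions are not stored in the graph, so the layout is topological
#' (main chain laid out left to right, branches offset).
#'
#' @param object A [heme_graph()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot heme_graph
#' @export
autoplot.heme_graph <- function(object, ...) {
  ed <- tidy(object)
  mc <- object$main_chain
  pos <- tibble(name = mc, px = seq_along(mc), py = 0)
  br <- unique(object$branches[, c("heme", "attachment")])
  if (nrow(br) > 0L) {
    pos <- dplyr::bind_rows(pos, tibble(
      name = br$heme,
      px = match(br$attachment, mc),
      py = seq_len(nrow(br))
    ))
  }
  others <- setdiff(igraph::V(object$graph)$name, pos$name)
  if (length(others) > 0L) {
    pos <- dplyr::bind_rows(pos, tibble(
      name = others, px = seq_along(others), py = -1))
  }
  seg <- ed |>
    dplyr::left_join(pos, by = c(from = "name")) |>
    dplyr::rename(x = "px", y = "py") |>
    dplyr::left_join(pos, by = c(to = "name")) |>
    dplyr::rename(xend = "px", yend = "py")
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = seg, ggplot2::aes(
      x = .data$x, y = .data$y, xend = .data$xend, yend = .data$yend,
      linetype = !.data$on_main_chain)) +
    ggplot2::geom_label(data = pos, ggplot2::aes(
      x = .data$px, y = .data$py, label = .data$name)) +
    ggplot2::guides(linetype = "none") +
    ggplot2::theme_void()
}
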