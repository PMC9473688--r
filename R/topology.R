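#' Build the heme contact graph
#'
#' Turns a contact-pair table into an undirected simple graph whose nodes
#' are heme identifiers (`"chain:residue"`) and whose edges carry the
#' minimum ring distance, rotation angle and motif. Parallel edges are
#' collapsed keeping the smallest distance.
#'
#' @param pairs Contact-pair tibble from [contact_pairs()] or [survey()].
#' @return An \pkg{igraph} undirected graph with edge attributes
#'   `min_distance`, `theta`, `motif` and vertex attributes `chain_id`,
#'   `residue_seq`.
#' @export
build_graph <- function(pairs) {
  if (nrow(pairs) == 0L) {
    return(igraph::make_empty_graph(n = 0, directed = FALSE))
  }
  ida <- paste0(pairs$chain_a, ":", pairs$seq_a)
  idb <- paste0(pairs$chain_b, ":", pairs$seq_b)
  key <- ifelse(ida < idb, paste(ida, idb), paste(idb, ida))
  ed <- tibble(from = pmin(ida, idb), to = pmax(ida, idb),
               min_distance = pairs$min_distance, theta = pairs$theta,
               motif = pairs$motif, key = key) |>
    dplyr::group_by(.data$key) |>
    dplyr::arrange(.data$min_distance, .by_group = TRUE) |>
    dplyr::slice(1L) |>
    dplyr::ungroup() |>
    dplyr::select(-"key") |>
    dplyr::arrange(.data$from, .data$to)
  verts <- sort(unique(c(ed$from, ed$to)))
  vt <- tibble(
    name = verts,
    chain_id = sub(":.*$", "", verts),
    residue_seq = as.integer(sub("^.*:", "", verts))
  )
  igraph::graph_from_data_frame(ed, directed = FALSE, vertices = vt)
}

# Deterministic sort key for heme node names "chain:seq".
node_order <- function(names) {
  order(sub(":.*$", "", names), as.integer(sub("^.*:", "", names)))
}

#' Trace the main heme chain through a contact graph
#'
#' The main chain is defined as the longest simple path in the largest
#' connected component, found exhaustively when that component has at most
#' `exhaustive_limit` nodes and by a double-sweep (diameter path)
#' heuristic otherwise. Ties are broken deterministically by
#' (chain, residue number). If no simple path covers at least half the
#' component a warning is issued (cyclic packing) and the best path is
#' returned anyway.
#'
#' @param graph Graph from [build_graph()].
#' @param exhaustive_limit Component size up to which the longest simple
#'   path is found by exhaustive search.
#' @return Character vector of heme ids in path order (possibly empty).
#' @export
trace_main_chain <- function(graph, exhaustive_limit = 24L) {
  n <- igraph::vcount(graph)
  if (n == 0L) return(character())
  comp <- igraph::components(graph)
  big <- which.max(comp$csize)
  members <- igraph::V(graph)$name[comp$membership == big]
  sub <- igraph::induced_subgraph(graph, members)
  nm <- igraph::V(sub)$name
  if (length(nm) == 1L) return(nm)
  ordkey <- integer(length(nm))
  ordkey[node_order(nm)] <- seq_along(nm)
  adj <- igraph::as_adj_list(sub)
  adj <- lapply(adj, function(v) {
    idx <- as.integer(v)
    idx[order(ordkey[idx])]
  })
  if (length(nm) <= exhaustive_limit) {
    best <- longest_simple_path(adj, ordkey)
  } else {
    d1 <- igraph::distances(sub)
    u <- which(d1 == max(d1[is.finite(d1)]), arr.ind = TRUE)[1L, ]
    best <- as.integer(igraph::shortest_paths(
      sub, from = u[1L], to = u[2L])$vpath[[1L]])
  }
  if (length(best) < length(nm) / 2) {
    warn("no simple path covers half of the largest component; returning best path.")
  }
  if (ordkey[best[1L]] > ordkey[best[length(best)]]) best <- rev(best)
  nm[best]
}

# Exhaustive longest simple path by DFS over all simple paths.
# `adj` is an adjacency list of integer indices (neighbours pre-sorted by
# ordkey); ties between equally long paths break toward the
# lexicographically smallest ordkey sequence after canonical orientation.
longest_simple_path <- function(adj, ordkey) {
  n <- length(adj)
  best <- integer(0)
  canonical <- function(path) {
    if (ordkey[path[1L]] > ordkey[path[length(path)]]) rev(path) else path
  }
  better <- function(cand, cur) {
    if (length(cand) != length(cur)) return(length(cand) > length(cur))
    a <- ordkey[canonical(cand)]; b <- ordkey[canonical(cur)]
    cmp <- which(a != b)
    length(cmp) > 0L && a[cmp[1L]] < b[cmp[1L]]
  }
  visited <- logical(n)
  path <- integer(n)
  dfs <- function(v, depth) {
    visited[v] <<- TRUE
    path[depth] <<- v
    extended <- FALSE
    for (w in adj[[v]]) {
      if (!visited[w]) {
        extended <- TRUE
        dfs(w, depth + 1L)
      }
    }
    if (!extended) {
      cand <- path[seq_len(depth)]
      if (better(cand, best)) best <<- cand
    }
    visited[v] <<- FALSE
  }
  starts <- seq_len(n)[order(ordkey)]
  for (s in starts) dfs(s, 1L)
  canonical(best)
}

#' Branched (off-chain) hemes
#'
#' Hemes that are not part of the main chain, with the heme(s) they attach
#' to. A degree-1 off-chain heme — the classic branched heme hanging off a
#' filament's central chain — is reported with its unique neighbour;
#' off-chain hemes of higher degree are reported once per attachment.
#'
#' @param graph Graph from [build_graph()].
#' @param main_chain Path from [trace_main_chain()]; computed if missing.
#' @return Tibble with columns `heme`, `attachment`, `min_distance`,
#'   `degree`. Zero rows for a purely linear chain.
#' @export
branch_hemes <- function(graph, main_chain = NULL) {
  if (is.null(main_chain)) main_chain <- trace_main_chain(graph)
  empty <- tibble(heme = character(), attachment = character(),
                  min_distance = numeric(), degree = integer())
  if (igraph::vcount(graph) == 0L) return(empty)
  off <- setdiff(igraph::V(graph)$name, main_chain)
  off <- off[igraph::degree(graph, off) > 0]
  if (length(off) == 0L) return(empty)
  rows <- purrr::map(off, function(v) {
    nb <- igraph::neighbors(graph, v)
    eid <- igraph::get_edge_ids(graph, rbind(rep(v, length(nb)), nb$name))
    tibble(heme = v, attachment = nb$name,
           min_distance = igraph::E(graph)$min_distance[eid],
           degree = length(nb))
  })
  res <- dplyr::bind_rows(rows)
  as_tibble(res[node_order(res$heme), ])
}

#' Full heme-chain topology of a structure
#'
#' Convenience wrapper: builds the contact graph, traces the main chain
#' and detects branches in one call.
#'
#' @param pairs Contact-pair tibble from [contact_pairs()].
#' @return A `heme_graph` object: list with `graph` (igraph),
#'   `main_chain` (heme ids in order), `branches` (tibble), `isolated`
#'   (degree-0 nodes; always empty for contact-derived graphs).
#' @export
heme_graph <- function(pairs) {
  g <- build_graph(pairs)
  mc <- trace_main_chain(g)
  structure(
    list(graph = g, main_chain = mc, branches = branch_hemes(g, mc),
         isolated = igraph::V(g)$name[igraph::degree(g) == 0]),
    class = "heme_graph"
  )
}

#' @export
print.heme_graph <- function(x, ...) {
  cat(sprintf("<heme_graph> %d hemes, %d contacts; main chain %d, branches %d\n",
              igraph::vcount(x$graph), igraph::ecount(x$graph),
              length(x$main_chain), nrow(x$branches)))
  if (length(x$main_chain) > 0)
    cat("  main chain:", paste(x$main_chain, collapse = " - "), "\n")
  invisible(x)
}

#' Export a heme graph as an edge-list TSV
#'
#' @param graph Graph from [build_graph()] or a `heme_graph`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_edge_tsv <- function(graph, path) {
  if (inherits(graph, "heme_graph")) graph <- graph$graph
  ed <- igraph::as_data_frame(graph, what = "edges")
  write.table(ed, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a heme graph in DOT format for visualization
#'
#' @inheritParams write_edge_tsv
#' @return `path`, invisibly.
#' @export
write_dot <- function(graph, path) {
  if (inherits(graph, "heme_graph")) graph <- graph$graph
  igraph::write_graph(graph, path, format = "dot")
  invisible(path)
}
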