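linear_chain_pairs <- function(n, spacing = 4.5) {
  fil <- make_filament(n_subunits = 1, hemes_per_subunit = n,
                       chain_spacing = spacing, branch_positions = list())
  contact_pairs(extract_hemes(fil))
}

test_that("build_graph collapses pairs into a simple contact graph", {
  g0 <- build_graph(contact_pairs(list(ideal_porphyrin())))
  expect_equal(igraph::vcount(g0), 0L)
  cp <- linear_chain_pairs(4)
  g <- build_graph(cp)
  expect_equal(igraph::vcount(g), 4L)
  expect_equal(igraph::ecount(g), 3L)
  # duplicated pair rows collapse keeping the smallest distance
  dup <- dplyr::bind_rows(cp, dplyr::mutate(cp[1, ], min_distance = 1.0))
  gd <- build_graph(dup)
  expect_equal(igraph::ecount(gd), 3L)
  eid <- igraph::get_edge_ids(gd, c("A:1", "A:2"))
  expect_equal(igraph::E(gd)$min_distance[eid], 1.0)
})

test_that("main-chain tracing finds the full linear chain with no branches", {
  g <- build_graph(linear_chain_pairs(6))
  mc <- trace_main_chain(g)
  expect_equal(mc, paste0("A:", 1:6))
  expect_equal(nrow(branch_hemes(g, mc)), 0L)
})

test_that("a pendant heme is detected as a branch off the main chain", {
  # 7 chain hemes + 1 pendant attached at chain position 5 (heme ids keep
  # their subunit numbering: the pendant is heme 6, attached to heme 5)
  fil <- make_filament(n_subunits = 1, hemes_per_subunit = 8,
                       branch_positions = list(c(6, 4.6)))
  hg <- heme_graph(contact_pairs(extract_hemes(fil)))
  expect_equal(hg$main_chain, paste0("A:", c(1:5, 7:8)))
  expect_equal(nrow(hg$branches), 1L)
  expect_equal(hg$branches$heme, "A:6")
  expect_equal(hg$branches$attachment, "A:5")
  expect_equal(hg$branches$min_distance, 4.6, tolerance = 1e-9)
  expect_equal(hg$branches$degree, 1L)
})

test_that("adding a pendant heme never shortens the main chain", {
  plain <- heme_graph(contact_pairs(extract_hemes(
    make_filament(n_subunits = 1, hemes_per_subunit = 7,
                  branch_positions = list()))))
  branched <- heme_graph(contact_pairs(extract_hemes(
    make_filament(n_subunits = 1, hemes_per_subunit = 8,
                  branch_positions = list(c(6, 4.6))))))
  expect_gte(length(branched$main_chain), length(plain$main_chain))
})

test_that("bridged filaments yield a k*m main chain with no branches", {
  fil <- make_filament(n_subunits = 3, hemes_per_subunit = 5,
                       branch_positions = list(),
                       interface_pair_distance = 4.5)
  hg <- heme_graph(contact_pairs(extract_hemes(fil)))
  expect_equal(length(hg$main_chain), 15L)
  expect_equal(nrow(hg$branches), 0L)
  expect_equal(hg$main_chain[1:5], paste0("A:", 1:5))
})

test_that("topology is invariant under rigid transforms and relabeling", {
  fil <- make_filament(n_subunits = 2, hemes_per_subunit = 8)
  hg1 <- heme_graph(contact_pairs(extract_hemes(fil)))
  moved <- transform_structure(fil, rot_about(c(1, 1, 0), 65), c(-3, 9, 1))
  hg2 <- heme_graph(contact_pairs(extract_hemes(moved)))
  expect_equal(hg1$main_chain, hg2$main_chain)
  expect_equal(hg1$branches, hg2$branches)
  # relabeling chains permutes ids but not the shape of the topology
  relab <- dplyr::mutate(fil, chain_id = ifelse(chain_id == "A", "Q", "P"))
  hg3 <- heme_graph(contact_pairs(extract_hemes(relab)))
  expect_equal(length(hg3$main_chain), length(hg1$main_chain))
  expect_equal(nrow(hg3$branches), nrow(hg1$branches))
})

test_that("tidy and glance summarise the heme graph", {
  hg <- heme_graph(contact_pairs(extract_hemes(make_filament())))
  td <- tidy(hg)
  expect_true(all(c("from", "to", "min_distance", "on_main_chain") %in%
                    names(td)))
  expect_equal(sum(td$on_main_chain), length(hg$main_chain) - 1L)
  gl <- glance(hg)
  expect_equal(gl$n_hemes, 24L)
  expect_equal(gl$chain_length, 21L)
  expect_equal(gl$n_branches, 3L)
})

test_that("graph exports produce edge-list TSV and DOT files", {
  hg <- heme_graph(linear_chain_pairs(4))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  dot <- withr::local_tempfile(fileext = ".dot")
  write_edge_tsv(hg, tsv)
  ed <- utils::read.delim(tsv)
  expect_equal(nrow(ed), 3L)
  write_dot(hg, dot)
  expect_true(any(grepl("graph", readLines(dot))))
})
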