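# shared analysed benchmark for the graph tests
bench_graph <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      bs <- benchmark_system(seed = 42, n_frames = 300)
      al <- align_ensemble(bs$ensemble)
      ev <- rbind(detect_events(al, "hbond"),
                  detect_events(al, "salt_bridge"),
                  detect_events(al, "metal_coord"))
      sites <- cluster_water_sites(al)
      cache <<- list(al = al, ev = ev, sites = sites,
                     graph = build_graph(al, ev, sites),
                     truth = bs$truth)
    }
    cache
  }
})

test_that("an inert residue chain becomes nodes plus covalent adjacency", {
  frames <- list(structure_model(data.frame(
    name = rep(c("N", "CA", "C", "O"), 3),
    res_name = rep(c("GLY", "ALA", "GLY"), each = 4),
    res_seq = rep(101:103, each = 4), chain = "A",
    x = rep(c(0, 20, 40), each = 4) + c(0, 1.5, 2.2, 3.5),
    y = rep(c(0, 1, 0), each = 4), z = 0, stringsAsFactors = FALSE)))
  e <- md_ensemble(frames); e$aligned <- TRUE
  g <- build_graph(e, detect_events(e, "hbond"), list())
  expect_equal(igraph::vcount(g), 3)
  expect_equal(igraph::ecount(g), 2)
  expect_true(all(igraph::E(g)$kind == "covalent_adjacent"))
})

test_that("the planted ligand-to-cluster path is found exactly", {
  b <- bench_graph()
  p <- find_path(b$graph, "LIG:N1", c("Cu3047", "Cu3048", "Cu3049"))
  expect_true(p$found)
  expect_equal(p$hops, 6)            # 7 nodes
  expect_length(p$nodes, 7)
  expect_equal(p$nodes, b$truth$path_nodes)
  expect_equal(format_path(p),
               "N1(+)…Asp1025-His1026-Cu3052-Cys1021-His1022-Cu3048")
  expect_equal(p$n_water_sites, 0)
})

test_that("the water-mediated route to Cu3047 runs through a site node", {
  b <- bench_graph()
  p <- find_path(b$graph, "LIG:N1", "Cu3047")
  expect_true(p$found)
  expect_equal(p$hops, 7)
  expect_equal(p$n_water_sites, 1)
  expect_match(format_path(p), "…WS[0-9]+…")
  # the site on the path is the planted bridge site next to Cu3047
  site_node <- p$nodes[grepl("^WS", p$nodes)]
  site <- b$sites[[which(vapply(b$sites, `[[`, "", "site_id") == site_node)]]
  expect_lt(sqrt(sum((site$centroid -
                        c(14, -2, 4))^2)), 1.0)
})

test_that("zero-hop, missing-node and disconnected cases behave", {
  b <- bench_graph()
  p0 <- find_path(b$graph, "LIG:N1", "LIG:N1")
  expect_true(p0$found)
  expect_equal(p0$hops, 0)
  expect_equal(format_path(p0), "N1(+)")
  expect_error(find_path(b$graph, "nope", "Cu3047"), "argument")
  expect_error(find_path(b$graph, "LIG:N1", character()), "argument")
  # forbidding metal coordination cuts every route to the coppers
  pf <- find_path(b$graph, "LIG:N1", "Cu3048",
                  forbidden_kinds = "metal_coord")
  expect_false(pf$found)
  pm <- find_path(b$graph, "LIG:N1", "Cu3048", max_hops = 3)
  expect_false(pm$found)
})

test_that("raising the edge occupancy floor prunes sub-threshold edges", {
  b <- bench_graph()
  g50 <- build_graph(b$al, b$ev, b$sites, occ_min = 50)
  g90 <- build_graph(b$al, b$ev, b$sites, occ_min = 90)
  el <- igraph::as_data_frame(g50)
  sub <- el$kind == "hbond" & el$of_percent < 90
  expect_equal(igraph::ecount(g90), igraph::ecount(g50) - sum(sub))
  # brute-force recount of surviving hbond edges
  el90 <- igraph::as_data_frame(g90)
  expect_true(all(el90$of_percent[el90$kind == "hbond"] >= 90))
})

test_that("events naming atoms absent from the ensemble are rejected", {
  b <- bench_graph()
  bad <- b$ev[1, ]
  bad$atom_a <- "A:GLY:9999:CA"
  expect_error(build_graph(b$al, rbind(b$ev, bad), b$sites),
               "graph-consistency")
})

test_that("find_path hop counts equal exhaustive BFS on random graphs", {
  for (s in 1:30) {
    rg <- random_test_graph(n = sample(8:30, 1), p = 0.12, seed = 900 + s)
    nodes <- rg$nodes
    src <- nodes[1]
    tgt <- nodes[c(length(nodes), length(nodes) - 2)]
    want <- oracle_bfs_hops(rg$edges, src, tgt)
    got <- find_path(rg$graph, src, tgt)
    if (is.finite(want)) {
      expect_true(got$found)
      expect_equal(got$hops, as.integer(want))
      # every consecutive pair really is an edge
      for (i in seq_len(got$hops))
        expect_true(igraph::are_adjacent(rg$graph, got$nodes[i],
                                         got$nodes[i + 1]))
    } else expect_false(got$found)
  }
})

test_that("among equal-hop paths the bottleneck occupancy decides, then ids", {
  ed <- data.frame(a = c("s", "m1", "s", "m2", "s", "m3"),
                   b = c("m1", "t", "m2", "t", "m3", "t"),
                   kind = "hbond", distance = 3,
                   of_percent = c(60, 60, 95, 80, 95, 80),
                   stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(
    ed, directed = FALSE,
    vertices = data.frame(id = c("s", "m1", "m2", "m3", "t"),
                          label = c("s", "m1", "m2", "m3", "t"),
                          type = "residue"))
  p <- find_path(g, "s", "t")
  expect_equal(p$hops, 2)
  expect_equal(p$min_of_percent, 80)
  expect_equal(p$nodes[2], "m2")   # m2 < m3 lexicographically at equal score
})

test_that("adding an edge never lengthens a shortest path", {
  rg <- random_test_graph(n = 15, p = 0.15, seed = 5)
  d0 <- igraph::distances(rg$graph)
  g2 <- igraph::add_edges(rg$graph, c("n01", "n15"),
                          attr = list(kind = "hbond", distance = 3,
                                      of_percent = 99))
  d1 <- igraph::distances(g2)
  expect_true(all(d1 <= d0 + 1e-9))
})
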