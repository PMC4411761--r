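test_that("shortest channels equal exhaustive enumeration on random graphs", {
  for (seed in 301:320) {
    net <- rand_graph_network(sample(5:9, 1), seed)
    nodes <- networkNodes(net)$tet
    pair <- sample(nodes, 2)
    oracle <- all_simple_paths_costs(net, pair[1], pair[2])
    ch <- shortestChannel(net, pair[1], pair[2])
    if (is.null(oracle)) {
      expect_null(ch)
      next
    }
    cost <- AlphaPore:::.channel_cost(net, ch)
    expect_equal(cost, min(oracle[, "cost"]), tolerance = 1e-9,
                 info = paste("seed", seed))
    # Bellman-Ford agreement
    expect_equal(cost, bellman_ford_cost(net, pair[1], pair[2]),
                 tolerance = 1e-9)
  }
})

test_that("degenerate channel requests are rejected", {
  net <- rand_graph_network(6, 7)
  expect_error(shortestChannel(net, 3, 3), "degenerate")
  expect_error(shortestChannel(net, 3, 999), "pruned network")
})

test_that("channel objects are geometrically consistent", {
  tb <- tube_fixture()
  for (ch in tb$tm) {
    n <- length(ch@nodePath)
    expect_length(ch@triPath, n - 1)
    expect_equal(nrow(ch@centerline), 2L * n - 1L)
    # consecutive tets share the listed triangle
    for (i in seq_len(n - 1)) {
      tt <- tb$tri@triTets[ch@triPath[i], ]
      expect_setequal(tt, ch@nodePath[i:(i + 1)])
    }
    expect_gt(ch@bottleneckRadius, 0)
    expect_gt(ch@length, 0)
    # feasibility: all crossed triangles outside the alpha complex
    expect_true(all(tb$tri@triAlpha[ch@triPath] > 0))
  }
})

test_that("iterated extraction returns edge-disjoint channels and stops", {
  # graph with exactly two edge-disjoint s-t paths
  nodes <- data.frame(tet = 1:4, x = c(0, 1, 1, 2), y = c(0, 1, -1, 0),
                      z = 0, width = 1)
  edges <- data.frame(tri = 1:4,
                      from = c(1, 2, 1, 3), to = c(2, 4, 3, 4),
                      length = c(1, 1, 2, 2), width = 1)
  net <- assembleNetwork(nodes, edges)
  chs <- disjointChannels(net, 1, 4, count = 3)
  expect_length(chs, 2L)
  expect_length(intersect(chs[[1]]@triPath, chs[[2]]@triPath), 0L)
  # first channel equals plain Dijkstra
  expect_equal(chs[[1]]@nodePath, shortestChannel(net, 1, 4)@nodePath)

  # property on random graphs: pairwise triangle-disjoint, first = Dijkstra
  for (seed in 331:336) {
    net <- rand_graph_network(8, seed)
    nodes <- networkNodes(net)$tet
    pair <- sample(nodes, 2)
    ch0 <- shortestChannel(net, pair[1], pair[2])
    if (is.null(ch0)) next
    chs <- disjointChannels(net, pair[1], pair[2], count = 4)
    expect_equal(chs[[1]]@nodePath, ch0@nodePath)
    tris <- lapply(chs, function(c) c@triPath)
    if (length(tris) > 1) {
      for (i in seq_len(length(tris) - 1))
        for (j in seq(i + 1, length(tris)))
          expect_length(intersect(tris[[i]], tris[[j]]), 0L)
    }
  }
})

test_that("the widest path tree satisfies the bottleneck property", {
  # 4-cycle with widths 1..4 drops the width-1 edge
  nodes <- data.frame(tet = 1:4, x = c(0, 1, 1, 0), y = c(0, 0, 1, 1),
                      z = 0, width = 1)
  edges <- data.frame(tri = 1:4, from = c(1, 2, 3, 4), to = c(2, 3, 4, 1),
                      length = 1, width = c(1, 2, 3, 4))
  net <- assembleNetwork(nodes, edges)
  wt <- widestPathTree(net)
  expect_equal(nrow(wt@edges), 3L)
  expect_false(1 %in% wt@edges$tri)

  for (seed in 341:352) {
    net <- rand_graph_network(sample(6:10, 1), seed)
    wt <- widestPathTree(net)
    e <- wt@edges
    nodes <- networkNodes(net)$tet
    # tree edge count = nodes - components
    g <- igraph::graph_from_data_frame(
      data.frame(from = as.character(e$from), to = as.character(e$to)),
      directed = FALSE, vertices = data.frame(name = as.character(nodes)))
    expect_equal(nrow(e),
                 length(nodes) - igraph::components(g)$no)
    # bottleneck property vs exhaustive enumeration
    pair <- sample(nodes, 2)
    oracle <- all_simple_paths_costs(net, pair[1], pair[2])
    if (is.null(oracle)) next
    sp <- igraph::shortest_paths(g, as.character(pair[1]),
                                 to = as.character(pair[2]),
                                 output = "vpath")$vpath[[1]]
    if (length(sp) == 0) next
    ids <- as.integer(names(sp))
    ekey <- paste(pmin(e$from, e$to), pmax(e$from, e$to))
    want <- paste(pmin(ids[-length(ids)], ids[-1]),
                  pmax(ids[-length(ids)], ids[-1]))
    treeMin <- min(e$width[match(want, ekey)])
    expect_equal(treeMin, max(oracle[, "minw"]), tolerance = 1e-12,
                 info = paste("seed", seed))
  }
})

test_that("tree pruning leaves exactly the paths between important nodes", {
  # star: centre 1, leaves 2..5; keeping two leaves keeps the path
  nodes <- data.frame(tet = 1:5, x = 0, y = 0, z = 0, width = 1)
  nodes$x <- c(0, 1, -1, 0, 0); nodes$y <- c(0, 0, 0, 1, -1)
  edges <- data.frame(tri = 1:4, from = 1L, to = 2:5, length = 1, width = 1)
  net <- assembleNetwork(nodes, edges)
  wt <- widestPathTree(net)
  pr <- pruneTree(wt, important = c(2L, 4L))
  expect_setequal(pr@nodes, c(1L, 2L, 4L))
  expect_setequal(pr@edges$tri, c(1L, 3L))
  # important = all nodes leaves the tree unchanged
  pr2 <- pruneTree(wt, important = 1:5)
  expect_setequal(pr2@edges$tri, wt@edges$tri)

  # pruned tree equals the union of pairwise tree paths
  for (seed in 361:364) {
    net <- rand_graph_network(9, seed)
    wt <- widestPathTree(net)
    nodes <- networkNodes(net)$tet
    imp <- sample(nodes, 3)
    pr <- pruneTree(wt, imp)
    g <- igraph::graph_from_data_frame(
      data.frame(from = as.character(wt@edges$from),
                 to = as.character(wt@edges$to), tri = wt@edges$tri),
      directed = FALSE, vertices = data.frame(name = as.character(nodes)))
    want <- integer(0)
    for (i in 1:2) for (j in seq(i + 1, 3)) {
      p <- suppressWarnings(igraph::shortest_paths(
        g, as.character(imp[i]), to = as.character(imp[j]),
        output = "epath"))$epath[[1]]
      want <- union(want, igraph::E(g)$tri[as.integer(p)])
    }
    expect_setequal(pr@edges$tri, want)
  }
})

test_that("important pores cover endpoint pairs and collapse duplicates", {
  # k = 2 gives exactly one pore when connected
  br <- barrel_fixture()
  expect_length(importantPores(br$net, br$eps, k = 2), 1L)
  # C(4, 2) upper bound
  expect_lte(length(importantPores(br$net, br$eps, k = 4)), 6L)
  # tube: top pore connects opposite ends
  tb <- tube_fixture()
  pores <- importantPores(tb$net, tb$eps)
  expect_length(pores, 1L)
  z <- pores[[1]]@centerline[c(1, nrow(pores[[1]]@centerline)), 3]
  expect_lt(min(z), 5); expect_gt(max(z), 35)
})

test_that("channel JSON export carries path, centerline and radii", {
  tb <- tube_fixture()
  ch <- tb$tm[[1]]
  f <- tempfile(fileext = ".json")
  writeChannelJSON(ch, f)
  back <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(back$nodes, ch@nodePath)
  expect_equal(back$bottleneck_radius, ch@bottleneckRadius,
               tolerance = 1e-12)
  expect_equal(nrow(back$centerline), nrow(ch@centerline))
})
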