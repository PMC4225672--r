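test_that("association follows the 1/d^2 rule on a path and 0 across components", {
  path <- tnet(c("a", "b"), c("b", "c"))
  am <- association_matrix(path)
  expect_equal(am$association["a", "b"], 1)
  expect_equal(am$association["a", "c"], 0.25)
  expect_equal(diag(am$association), c(a = 1, b = 1, c = 1))

  two <- tnet(c("a", "c"), c("b", "d"))
  am2 <- association_matrix(two)
  expect_equal(am2$association["a", "c"], 0)
  expect_equal(am2$association["a", "d"], 0)
  expect_equal(am2$association["a", "b"], 1)
})

test_that("shortest-path distances equal a Floyd-Warshall oracle", {
  for (s in 1:8) {
    net <- rand_digraph(10, sample(8:20, 1), seed = s)
    am <- association_matrix(net)
    d_oracle <- oracle_apsp(net)
    expect_equal(am$distance[rownames(d_oracle), colnames(d_oracle)],
                 d_oracle)
    # symmetry and value range of the association
    expect_equal(am$association, t(am$association))
    expect_true(all(am$association >= 0 & am$association <= 1))
    # s = 1 iff i = j or d = 1
    expect_equal(am$association == 1, am$distance <= 1)
  }
})

test_that("adding an edge never decreases any association", {
  for (s in 1:5) {
    net <- rand_digraph(8, 10, seed = s)
    am1 <- association_matrix(net)
    pool <- expand.grid(from = net$nodes$id, to = net$nodes$id,
                        stringsAsFactors = FALSE)
    pool <- pool[pool$from != pool$to, ]
    present <- paste(net$edges$regulator, net$edges$target)
    pool <- pool[!paste(pool$from, pool$to) %in% present, ]
    add <- pool[withr::with_seed(s, sample(nrow(pool), 1)), ]
    net2 <- trn(dplyr::bind_rows(
      net$edges, tibble::tibble(regulator = add$from, target = add$to,
                                mode = "unknown", evidence = "unknown")))
    am2 <- association_matrix(net2)
    ids <- am1$nodes
    expect_true(all(am2$association[ids, ids] >= am1$association[ids, ids] - 1e-12))
  }
})

test_that("average-linkage clustering separates two planted cliques at the auto cut", {
  # two 4-cliques {a,b,c,d} and {e,f,g,h} joined by the single edge c->e
  cl <- tnet(c("a", "a", "a", "b", "b", "c", "e", "e", "e", "f", "f", "g", "c"),
             c("b", "c", "d", "c", "d", "d", "f", "g", "h", "g", "h", "h", "e"))
  part <- cluster_modules(cl)
  expect_equal(max(part$assignment$module), 2)
  m <- setNames(part$assignment$module, part$assignment$node)
  expect_equal(length(unique(m[c("a", "b", "c", "d")])), 1)
  expect_equal(length(unique(m[c("e", "f", "g", "h")])), 1)
  expect_false(m[["a"]] == m[["e"]])

  # merge heights are non-decreasing (ultrametric average linkage)
  expect_true(all(diff(part$merge_tree$height) >= -1e-12))
})

test_that("explicit cuts are honored and over-large cuts error", {
  cl <- tnet(c("a", "a", "b", "c"), c("b", "c", "c", "d"))
  part <- cluster_modules(cl, cut = 3)
  expect_equal(max(part$assignment$module), 3)
  expect_error(cluster_modules(cl, cut = 10), class = "trntopo_cut_error")
})

test_that("disconnected components become their own modules, kept apart from the cut", {
  net <- trn(tibble::tibble(
    regulator = c("a", "a", "b", "x"), target = c("b", "c", "c", "y")),
    isolated_nodes = tibble::tibble(id = "lone", class = "TF"))
  part <- cluster_modules(net)
  m <- setNames(part$assignment$module, part$assignment$node)
  # the triangle is the clustered component; {x,y} and {lone} are appended
  expect_equal(length(unique(m[c("a", "b", "c")])), 1)
  expect_equal(length(part$component_modules), 2)
  expect_false(m[["x"]] %in% m[c("a", "b", "c")])
  expect_false(m[["lone"]] %in% c(m[c("a", "b", "c")], m[["x"]]))
  # contiguous 1-based module indices over all nodes
  expect_setequal(unique(part$assignment$module),
                  seq_len(max(part$assignment$module)))
})

test_that("the merge tree exports as Newick with branch lengths", {
  cl <- tnet(c("a", "a", "b", "e", "e", "f", "c"),
             c("b", "c", "c", "f", "g", "g", "e"))
  part <- cluster_modules(cl)
  f <- withr::local_tempfile(fileext = ".nwk")
  write_merge_tree(part, f)
  phy <- ape::read.tree(f)
  expect_setequal(phy$tip.label, c("a", "b", "c", "e", "f", "g"))
  expect_true(all(phy$edge.length >= 0))
})

test_that("Girvan-Newman removes the bridge of a barbell first and splits it in two", {
  barbell <- tnet(c("a", "b", "a", "d", "e", "d", "c"),
                  c("b", "c", "c", "e", "f", "f", "d"))
  part <- cluster_girvan_newman(barbell)
  first <- sort(unlist(part$removal_order[1, ]))
  expect_equal(unname(first), c("c", "d"))
  expect_equal(max(part$assignment$module), 2)
  m <- setNames(part$assignment$module, part$assignment$node)
  expect_equal(length(unique(m[c("a", "b", "c")])), 1)
  expect_equal(length(unique(m[c("d", "e", "f")])), 1)
})

test_that("both methods recover a planted two-block structure exactly", {
  sim <- simulate_trn(trn_spec(
    n_regulators = 16, n_targets = 30, n_modules = 2,
    intra_module_edge_prob = 0.8, inter_module_edge_prob = 0.02,
    n_planted_ff = 0, n_planted_cff = 0, include_hub = FALSE, seed = 21))
  sub <- regulator_subnetwork(sim$network)
  truth <- sim$truth$modules
  for (part in list(cluster_modules(sub, cut = 2),
                    cluster_girvan_newman(sub, cut = 2))) {
    merged <- dplyr::inner_join(part$assignment, truth, by = "node")
    expect_equal(oracle_ari(merged$module.x, merged$module.y), 1)
  }
})

test_that("partition comparison matches the contingency-table ARI oracle", {
  for (s in 1:6) {
    withr::with_seed(s, {
      nodes <- sprintf("g%02d", 1:40)
      pa <- tibble::tibble(node = nodes, module = sample(1:4, 40, replace = TRUE))
      pb <- tibble::tibble(node = nodes, module = sample(1:5, 40, replace = TRUE))
    })
    a <- read_write_partition(pa)
    b <- read_write_partition(pb)
    cmp <- compare_partitions(a, b)
    merged <- dplyr::inner_join(pa, pb, by = "node")
    expect_equal(cmp$ari, oracle_ari(merged$module.x, merged$module.y),
                 tolerance = 1e-12)
  }
})

test_that("comparison reports identity, refinement relations, and incomparability", {
  nodes <- letters[1:9]
  p1 <- tibble::tibble(node = nodes, module = rep(1:3, each = 3))
  same <- compare_partitions(read_write_partition(p1), read_write_partition(p1))
  expect_equal(same$ari, 1)
  expect_true(all(same$relations$relation[same$relations$module_a ==
                                          same$relations$module_b] == "equal"))

  # split module 3 into two -> the original module is a superset of both parts
  p2 <- tibble::tibble(node = nodes, module = c(1, 1, 1, 2, 2, 2, 3, 4, 4))
  cmp <- compare_partitions(read_write_partition(p1), read_write_partition(p2))
  expect_lt(cmp$ari, 1)
  rel3 <- cmp$relations[cmp$relations$module_a == 3 & cmp$relations$n_shared > 0, ]
  expect_true(all(rel3$relation == "superset"))

  p3 <- tibble::tibble(node = paste0("z", 1:5), module = rep(1, 5))
  expect_error(compare_partitions(read_write_partition(p1),
                                  read_write_partition(p3)),
               class = "trntopo_incomparable_partitions_error")

  p4 <- tibble::tibble(node = c(nodes[1:6], "extra"), module = rep(1:7)[1:7])
  expect_warning(compare_partitions(read_write_partition(p1),
                                    read_write_partition(p4)),
                 class = "trntopo_partial_overlap")
})

test_that("partitions round-trip through the TSV exchange format", {
  pa <- tibble::tibble(node = sprintf("g%02d", 1:12),
                       module = rep(1:3, each = 4))
  part <- read_write_partition(pa)
  expect_equal(part$method, "external")
  expect_equal(part$assignment$module, pa$module)
  expect_equal(part$assignment$node, pa$node)
})
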