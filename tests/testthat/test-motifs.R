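test_that("minimal FF and CFF graphs are classified exactly once and disjointly", {
  ff <- find_motifs(tnet(c("a", "b", "a"), c("b", "c", "c")))
  expect_equal(nrow(ff), 1)
  expect_equal(ff$motif_type, "FF")
  expect_equal(ff[, c("master", "local", "target")],
               tibble::tibble(master = "a", local = "b", target = "c"))

  cff <- find_motifs(tnet(c("a", "b", "b", "a"), c("b", "a", "c", "c")))
  expect_equal(nrow(cff), 1)
  expect_equal(cff$motif_type, "CFF")

  # the mutual edge makes the triple CFF, never FF as well
  expect_false("FF" %in% cff$motif_type)
})

test_that("extra edges within a triple disqualify it (induced-subgraph matching)", {
  # FF plus feedback C->A
  none <- find_motifs(tnet(c("a", "b", "a", "c"), c("b", "c", "c", "a")))
  expect_equal(nrow(none), 0)
  # FF plus C->B
  none2 <- find_motifs(tnet(c("a", "b", "a", "c"), c("b", "c", "c", "b")))
  expect_equal(nrow(none2), 0)
  # self-loops are ignored: FF still found when A autoregulates
  ff <- find_motifs(tnet(c("a", "b", "a", "a"), c("b", "c", "c", "a")))
  expect_equal(nrow(ff), 1)
})

test_that("enumeration matches the exhaustive all-triples oracle on every 3-node digraph", {
  # all 2^6 = 64 labeled digraphs on {a, b, c} without self-loops
  pairs <- expand.grid(from = c("a", "b", "c"), to = c("a", "b", "c"),
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$from != pairs$to, ]
  for (mask in 0:63) {
    sel <- as.logical(bitwAnd(mask, 2^(0:5)))
    if (!any(sel)) next
    net <- tnet(pairs$from[sel], pairs$to[sel])
    expect_same_motifs(find_motifs(net), oracle_motifs(net))
  }
})

test_that("enumeration matches the oracle on random digraphs up to 8 nodes", {
  for (s in 1:12) {
    n <- sample(4:8, 1)
    net <- rand_digraph(n, sample(5:(n * (n - 1)), 1), seed = s)
    expect_same_motifs(find_motifs(net), oracle_motifs(net))
  }
})

test_that("motif counts are invariant under node relabeling", {
  net <- rand_digraph(8, 20, seed = 42)
  relabel <- setNames(sprintf("z%02d", seq_len(n_nodes(net))),
                      sample(net$nodes$id))
  net2 <- tnet(unname(relabel[net$edges$regulator]),
               unname(relabel[net$edges$target]))
  expect_equal(table(find_motifs(net)$motif_type),
               table(find_motifs(net2)$motif_type))
})

test_that("switching preserves every node's (in, out) degree pair", {
  for (s in 1:5) {
    net <- rand_digraph(12, 30, seed = s)
    r <- switching_null(net, n_swaps_per_edge = 20, seed = s)
    for (dir in c("in", "out")) {
      expect_equal(degree_stats(r, dir)$degrees[names(degree_stats(net, dir)$degrees)],
                   degree_stats(net, dir)$degrees)
    }
    expect_equal(n_edges(r), n_edges(net))
    expect_equal(n_nodes(r), n_nodes(net))
  }
  # self-loops stay in place
  loopy <- tnet(c("a", "a", "b", "c"), c("a", "b", "c", "d"))
  r <- switching_null(loopy, 10, seed = 1)
  expect_true(any(r$edges$regulator == "a" & r$edges$target == "a"))
})

test_that("a 2-swappable-edge graph yields the original or the single valid swap", {
  net <- tnet(c("a", "c"), c("b", "d"))
  for (s in 1:10) {
    r <- switching_null(net, 10, seed = s)
    got <- sort(paste(r$edges$regulator, r$edges$target))
    expect_true(identical(got, c("a b", "c d")) ||
                identical(got, c("a d", "c b")))
  }
  tiny <- tnet("a", "b")
  expect_warning(same <- switching_null(tiny, 10, seed = 1),
                 class = "trntopo_unswappable")
  expect_identical(same$edges, tiny$edges)
})

test_that("randomization explores different wirings across seeds while degrees stay fixed", {
  sim <- simulate_trn(trn_spec(n_regulators = 20, n_targets = 60,
                               n_modules = 2, intra_module_edge_prob = 0.2,
                               inter_module_edge_prob = 0.05,
                               n_planted_ff = 10, n_planted_cff = 0,
                               include_hub = FALSE, seed = 8))
  net <- sim$network
  counts <- vapply(1:30, function(s) {
    r <- switching_null(net, 20, seed = s)
    sum(find_motifs(r)$motif_type == "FF")
  }, numeric(1))
  expect_gt(stats::var(counts), 0)
})

test_that("planted feed-forward excess is flagged significant, with sane p-values", {
  sim <- simulate_trn(trn_spec(n_regulators = 30, n_targets = 80,
                               n_modules = 3, intra_module_edge_prob = 0.05,
                               inter_module_edge_prob = 0.02,
                               n_planted_ff = 30, n_planted_cff = 0,
                               include_hub = FALSE, seed = 11))
  sig <- motif_significance(sim$network, n_random = 200,
                            n_swaps_per_edge = 20, seed = 5)
  ff <- sig[sig$motif_type == "FF", ]
  expect_true(ff$significant)
  expect_lt(ff$p_value, 0.01)
  expect_gt(ff$z_score, 2)
  # empirical p-values carry the +1 pseudocount: never exactly 0
  expect_true(all(sig$p_value >= 1 / 201))
  expect_true(all(sig$p_value <= 1))
  expect_warning(motif_significance(sim$network, n_random = 20, seed = 1),
                 class = "trntopo_few_randomizations")
})

test_that("pair summaries count distinct targets per regulator pair", {
  # one master, two locals, 3 shared targets each
  net <- tnet(c("m", "m", rep("l1", 3), rep("l2", 3), rep("m", 6)),
              c("l1", "l2", paste0("t", 1:3), paste0("u", 1:3),
                paste0("t", 1:3), paste0("u", 1:3)))
  inst <- find_motifs(net)
  summ <- ff_pair_summary(inst)
  expect_equal(nrow(summ), 2)
  expect_equal(summ$n_targets, c(3, 3))
  expect_equal(summ$master_module, c("unassigned", "unassigned"))

  # module indices renumber to byte-order of smallest member: l1's module
  # becomes 1, m's becomes 2
  part <- read_write_partition(
    tibble::tibble(node = c("m", "l1"), module = c(1, 2)))
  summ2 <- ff_pair_summary(inst, part)
  expect_equal(summ2$master_module, c("2", "2"))
  expect_setequal(summ2$local_module, c("1", "unassigned"))

  single <- ff_pair_summary(find_motifs(tnet(c("a", "b", "a"), c("b", "c", "c"))))
  expect_equal(single$n_targets, 1)
})

test_that("embedding fractions separate intra- from inter-module motifs", {
  # 3 intra-module FFs (m1, l1 in module 1) + 1 inter-module FF (m1, l2)
  net <- tnet(c("m1", rep("l1", 3), rep("m1", 3), "m1", "l2", "m1"),
              c("l1", paste0("t", 1:3), paste0("t", 1:3), "l2", "x1", "x1"))
  inst <- find_motifs(net)
  expect_equal(nrow(inst), 4)
  part <- read_write_partition(tibble::tibble(
    node = c("m1", "l1", "l2"), module = c(1, 1, 2)))
  emb <- motif_embedding(inst, part)
  expect_equal(emb$fraction_embedded, 0.75)
  expect_equal(emb$n_embedded + emb$n_cross_talk, emb$n_total)
  ct <- attr(emb, "cross_talk")
  expect_equal(nrow(ct), 1)
  expect_equal(ct$local, "l2")

  # single-module partition: everything embedded
  all_one <- read_write_partition(tibble::tibble(
    node = c("m1", "l1", "l2"), module = c(1, 1, 1)))
  expect_equal(motif_embedding(inst, all_one)$fraction_embedded, 1)

  # uncovered regulators count as cross-talk, with a warning
  partial <- read_write_partition(tibble::tibble(node = "m1", module = 1))
  expect_warning(emb2 <- motif_embedding(inst, partial),
                 class = "trntopo_unassigned_regulators")
  expect_equal(emb2$fraction_embedded, 0)
})

test_that("role profiles classify master-dominant, local-dominant, and mixed regulators", {
  single <- regulator_roles(find_motifs(tnet(c("a", "b", "a"), c("b", "c", "c"))))
  expect_equal(single$n_master[single$regulator == "a"], 1)
  expect_equal(single$n_local[single$regulator == "a"], 0)
  expect_equal(single$role[single$regulator == "a"], "master")
  expect_equal(single$role[single$regulator == "b"], "local")

  # chain of two overlapping FFs sharing the middle regulator b:
  # a->b->c (target t1 for (a,b)) and b->c with target t2 for (b,c)
  chain <- tnet(c("a", "b", "a", "b", "c", "b"),
                c("b", "t1", "t1", "c", "t2", "t2"))
  roles <- regulator_roles(find_motifs(chain))
  expect_equal(roles$role[roles$regulator == "b"], "mixed")
})
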