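# Fixture builders and independent brute-force oracles. The oracles are
# deliberately naive (adjacency matrices, Floyd-Warshall, exhaustive triple
# scans, the contingency-table ARI formula) and share no code with the
# package's implementations.

tnet <- function(from, to, ...) {
  trn(tibble::tibble(regulator = from, target = to, ...))
}

# Random simple digraph on n named nodes with m edges (no self-loops).
rand_digraph <- function(n, m, seed, loops = FALSE) {
  withr::with_seed(seed, {
    ids <- sprintf("n%02d", seq_len(n))
    pairs <- expand.grid(from = ids, to = ids, stringsAsFactors = FALSE)
    if (!loops) pairs <- pairs[pairs$from != pairs$to, ]
    take <- pairs[sample(nrow(pairs), min(m, nrow(pairs))), ]
    tnet(take$from, take$to)
  })
}

adjacency_of <- function(net) {
  ids <- sort(net$nodes$id, method = "radix")
  a <- matrix(0L, length(ids), length(ids), dimnames = list(ids, ids))
  for (i in seq_len(nrow(net$edges))) {
    a[net$edges$regulator[i], net$edges$target[i]] <- 1L
  }
  a
}

# Degree oracle: row/column sums of the adjacency matrix (a self-loop adds
# one to each direction).
oracle_degrees <- function(net, direction) {
  a <- adjacency_of(net)
  switch(direction,
    out = rowSums(a),
    `in` = colSums(a),
    total = rowSums(a) + colSums(a))
}

# All-pairs shortest paths on the undirected simple projection by
# Floyd-Warshall.
oracle_apsp <- function(net) {
  a <- adjacency_of(net)
  u <- pmax(a, t(a))
  diag(u) <- 0
  n <- nrow(u)
  d <- ifelse(u == 1, 1, Inf)
  diag(d) <- 0
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      d[i, ] <- pmin(d[i, ], d[i, k] + d[k, ])
    }
  }
  d
}

# Exhaustive induced-subgraph FF/CFF scan over all ordered node triples.
# CFF triples are canonicalized to the byte-smaller regulator as master.
oracle_motifs <- function(net) {
  a <- adjacency_of(net)
  diag(a) <- 0L
  ids <- rownames(a)
  out <- list()
  n <- length(ids)
  for (A in seq_len(n)) for (B in seq_len(n)) for (C in seq_len(n)) {
    if (A == B || B == C || A == C) next
    ff <- a[A, B] == 1 && a[B, C] == 1 && a[A, C] == 1 &&
      a[B, A] == 0 && a[C, A] == 0 && a[C, B] == 0
    cff <- a[A, B] == 1 && a[B, A] == 1 && a[B, C] == 1 && a[A, C] == 1 &&
      a[C, A] == 0 && a[C, B] == 0 && A < B
    if (ff) {
      out[[length(out) + 1]] <- data.frame(
        motif_type = "FF", master = ids[A], local = ids[B], target = ids[C])
    } else if (cff) {
      out[[length(out) + 1]] <- data.frame(
        motif_type = "CFF", master = ids[A], local = ids[B], target = ids[C])
    }
  }
  if (length(out) == 0) {
    return(data.frame(motif_type = character(), master = character(),
                      local = character(), target = character()))
  }
  res <- do.call(rbind, out)
  res[order(res$motif_type, res$master, res$local, res$target,
            method = "radix"), , drop = FALSE]
}

# Adjusted Rand index straight from the contingency-table formula.
oracle_ari <- function(x, y) {
  tab <- table(x, y)
  comb2 <- function(v) sum(v * (v - 1) / 2)
  sum_ij <- comb2(as.vector(tab))
  sum_a <- comb2(rowSums(tab))
  sum_b <- comb2(colSums(tab))
  n2 <- comb2(sum(tab))
  expected <- sum_a * sum_b / n2
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}

motif_key <- function(d) paste(d$motif_type, d$master, d$local, d$target)

expect_same_motifs <- function(found, expected) {
  expect_setequal(motif_key(found), motif_key(expected))
  expect_equal(nrow(found), nrow(expected))
}

# Build an external trn_partition by round-tripping through the TSV format.
read_write_partition <- function(df) {
  f <- tempfile(fileext = ".tsv")
  on.exit(unlink(f))
  utils::write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
  read_partition(f)
}
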