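#' Shortest-path association matrix
#'
#' Computes, over the undirected projection of the network, the shortest-path
#' length `d_ij` between every pair of genes and the association function
#' `s_ij = 1 / d_ij^2`. The association amplifies close relationships and
#' damps remote ones: `s = 1` for direct neighbours, `1/4` at distance 2,
#' `1/9` at distance 3, and exactly 0 for unreachable pairs. The diagonal is
#' 1 by convention. Node order is byte-wise lexicographic, making the matrix
#' deterministic.
#'
#' @param net A non-empty [trn] object.
#' @return A `trn_assoc` object: list with `nodes` (ordered ids),
#'   `distance` (matrix of hop counts, `Inf` when unreachable), and
#'   `association` (matrix in `[0, 1]`).
#' @examples
#' net <- trn(tibble::tibble(regulator = c("a", "b"), target = c("b", "c")))
#' association_matrix(net)$association
#' @export
association_matrix <- function(net) {
  stopifnot(inherits(net, "trn"))
  if (n_nodes(net) == 0) {
    trn_abort("Cannot compute associations on an empty network.",
      "empty_network_error")
  }
  g <- igraph::as_undirected(igraph::simplify(as_igraph(net)), mode = "collapse")
  ord <- trn_sort(igraph::V(g)$name)
  d <- igraph::distances(g, v = ord, to = ord)
  s <- 1 / d^2
  s[is.infinite(d)] <- 0
  diag(s) <- 1
  structure(list(nodes = ord, distance = d, association = s),
            class = "trn_assoc")
}

#' @export
print.trn_assoc <- function(x, ...) {
  cat(sprintf("<trn_assoc> %d nodes, %d unreachable pairs\n",
              length(x$nodes), sum(is.infinite(x$distance)) / 2))
  invisible(x)
}

new_trn_partition <- function(assignment, method, cut, merge_tree = NULL,
                              component_modules = integer(), extra = list()) {
  structure(
    c(list(assignment = assignment, method = method, cut = cut,
           merge_tree = merge_tree, component_modules = component_modules),
      extra),
    class = "trn_partition"
  )
}

#' @export
print.trn_partition <- function(x, ...) {
  n_mod <- max(x$assignment$module)
  cat(sprintf("<trn_partition> %s: %d nodes in %d modules (%s)\n",
              x$method, nrow(x$assignment), n_mod, x$cut))
  if (length(x$component_modules)) {
    cat(sprintf("  %d module(s) are disconnected components kept apart from the cut\n",
                length(x$component_modules)))
  }
  invisible(x)
}

#' @export
tidy.trn_partition <- function(x, ...) x$assignment

# Renumber modules 1..k in byte-order of each module's smallest member.
renumber_modules <- function(assignment) {
  assignment <- assignment[order(assignment$node, method = "radix"), ]
  firsts <- assignment %>%
    group_by(.data$module) %>%
    summarise(first_node = min(.data$node), .groups = "drop")
  firsts <- firsts[order(firsts$first_node, method = "radix"), ]
  remap <- setNames(seq_len(nrow(firsts)), firsts$module)
  assignment$module <- unname(remap[as.character(assignment$module)])
  assignment
}

#' Detect modules by average-linkage clustering of the association matrix
#'
#' Runs hierarchical agglomerative average-linkage (UPGMA) clustering on the
#' dissimilarity `D = 1 - s`, where `s` is the `1/d^2` shortest-path
#' association, and cuts the resulting dendrogram into modules. Only the
#' largest connected component is clustered: unreachable nodes have
#' association exactly 0 to everything and would merge arbitrarily, so every
#' other connected component is kept as its own module, appended after the
#' cut modules and reported separately via `component_modules`.
#'
#' @param x A [trn] object or a precomputed [association_matrix()] result.
#' @param cut Either `"auto"` (cut at the largest gap between consecutive
#'   merge heights, with the gap between the last merge and the maximum
#'   dissimilarity 1 standing for the single-module cut) or an explicit
#'   module count for the clustered component.
#' @return A `trn_partition` with the per-node assignment (tibble `node`,
#'   `module`; indices contiguous from 1), the `hclust` merge tree, and the
#'   indices of disconnected-component modules.
#' @seealso [cluster_girvan_newman()], [compare_partitions()],
#'   [write_merge_tree()]
#' @export
cluster_modules <- function(x, cut = "auto") {
  assoc <- if (inherits(x, "trn")) association_matrix(x) else x
  stopifnot(inherits(assoc, "trn_assoc"))
  nodes <- assoc$nodes

  # Connected components from finite distances.
  comp <- rep(NA_integer_, length(nodes))
  cid <- 0L
  for (i in seq_along(nodes)) {
    if (is.na(comp[i])) {
      cid <- cid + 1L
      comp[is.finite(assoc$distance[i, ])] <- cid
    }
  }
  sizes <- tabulate(comp)
  main <- which(sizes == max(sizes))[1]
  main_idx <- which(comp == main)
  n_main <- length(main_idx)

  if (is.numeric(cut) && cut > n_main) {
    trn_abort(sprintf(
      "Requested %d modules but the clustered component has only %d nodes.",
      cut, n_main), "cut_error")
  }

  if (n_main == 1) {
    h <- NULL
    main_assign <- tibble(node = nodes[main_idx], module = 1L)
    k <- 1L
    cut_desc <- "single-node component"
  } else {
    d_main <- stats::as.dist(1 - assoc$association[main_idx, main_idx])
    h <- stats::hclust(d_main, method = "average")
    k <- if (identical(cut, "auto")) largest_gap_k(h$height) else as.integer(cut)
    membership <- stats::cutree(h, k = k)
    main_assign <- tibble(node = nodes[main_idx], module = as.integer(membership))
    cut_desc <- if (identical(cut, "auto")) {
      sprintf("auto largest-gap cut (k = %d)", k)
    } else {
      sprintf("explicit cut (k = %d)", k)
    }
  }
  main_assign <- renumber_modules(main_assign)

  # Remaining components become their own modules, ordered by smallest member.
  other <- setdiff(sort(unique(comp)), main)
  comp_first <- vapply(other, function(ci) min(nodes[comp == ci]), character(1))
  other <- other[order(comp_first, method = "radix")]
  extra_assign <- purrr::imap_dfr(other, function(ci, j) {
    tibble(node = nodes[comp == ci], module = k + as.integer(j))
  })
  assignment <- bind_rows(main_assign, extra_assign)
  assignment <- assignment[order(assignment$node, method = "radix"), ]

  new_trn_partition(
    assignment, method = "association_hclust", cut = cut_desc,
    merge_tree = h,
    component_modules = if (length(other)) k + seq_along(other) else integer()
  )
}

# k chosen at the largest gap between consecutive merge heights; the gap
# between the final merge and the maximum dissimilarity (1) represents k = 1.
largest_gap_k <- function(heights) {
  n <- length(heights) + 1L
  gaps <- c(diff(heights), 1 - heights[length(heights)])
  n - which.max(gaps)
}

#' Detect modules with the Girvan-Newman algorithm
#'
#' Community detection by iterative removal of the highest edge-betweenness
#' edge on the undirected projection of the network, the standard
#' alternative used to assess module granularity. With `cut = "auto"` the
#' partition maximizing modularity is returned; an explicit count cuts the
#' removal hierarchy at that many communities.
#'
#' @param net A non-empty [trn] object.
#' @param cut `"auto"` or an explicit module count (must be at least the
#'   number of connected components).
#' @return A `trn_partition` (method `"girvan_newman"`). The edge removal
#'   order is stored in the `removal_order` element.
#' @export
cluster_girvan_newman <- function(net, cut = "auto") {
  stopifnot(inherits(net, "trn"))
  if (n_nodes(net) == 0) {
    trn_abort("Cannot cluster an empty network.", "empty_network_error")
  }
  g <- igraph::as_undirected(igraph::simplify(as_igraph(net)), mode = "collapse")
  # Fixed vertex order for deterministic tie handling.
  g <- igraph::permute(g, match(igraph::V(g)$name, trn_sort(igraph::V(g)$name)))
  ceb <- igraph::cluster_edge_betweenness(g, directed = FALSE)
  membership <- if (identical(cut, "auto")) {
    igraph::membership(ceb)
  } else {
    n_comp <- igraph::count_components(g)
    if (cut < n_comp || cut > igraph::vcount(g)) {
      trn_abort(sprintf(
        "cut must be between the component count (%d) and the node count (%d).",
        n_comp, igraph::vcount(g)), "cut_error")
    }
    igraph::cut_at(ceb, no = cut)
  }
  assignment <- renumber_modules(
    tibble(node = igraph::V(g)$name, module = as.integer(membership)))
  removed <- igraph::as_edgelist(g)[ceb$removed.edges, , drop = FALSE]
  new_trn_partition(
    assignment, method = "girvan_newman",
    cut = if (identical(cut, "auto")) "auto (max modularity)"
          else sprintf("explicit cut (k = %d)", cut),
    extra = list(removal_order = tibble(from = removed[, 1], to = removed[, 2]))
  )
}

#' Load / save a module partition as TSV
#'
#' The partition exchange format is a two-column tab-separated table
#' (`node`, `module`), which also lets externally produced partitions (for
#' example from map-equation or natural-decomposition runs) be compared with
#' [compare_partitions()].
#'
#' @param path File path.
#' @return For `read_partition()`, a `trn_partition` with method
#'   `"external"`.
#' @export
read_partition <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = c("character", "integer"),
                          comment.char = "#")
  names(df)[1:2] <- c("node", "module")
  assignment <- renumber_modules(as_tibble(df[, 1:2]))
  new_trn_partition(assignment, method = "external", cut = "as loaded")
}

#' @rdname read_partition
#' @param partition A `trn_partition`.
#' @export
write_partition <- function(partition, path) {
  stopifnot(inherits(partition, "trn_partition"))
  utils::write.table(partition$assignment, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(partition)
}

#' Export a clustering merge tree as Newick
#'
#' Writes the average-linkage merge tree of an [cluster_modules()] partition
#' to a Newick file, with merge heights as branch lengths.
#'
#' @param partition A `trn_partition` produced by [cluster_modules()].
#' @param path Output file path.
#' @return The [ape::phylo] tree, invisibly.
#' @export
write_merge_tree <- function(partition, path) {
  stopifnot(inherits(partition, "trn_partition"))
  if (is.null(partition$merge_tree)) {
    trn_abort("This partition carries no merge tree.", "invalid_argument")
  }
  phy <- ape::as.phylo(partition$merge_tree)
  ape::write.tree(phy, file = path)
  invisible(phy)
}

#' Compare two module partitions
#'
#' Quantifies agreement between two partitions of (mostly) the same node
#' set: adjusted Rand index (ARI), normalized mutual information (NMI), the
#' pairwise module Jaccard matrix, and a set-relation label for every module
#' pair (`equal`, `subset`, `superset`, `overlap`, `disjoint`; relations are
#' stated for the module of `a` relative to the module of `b`). Nodes
#' present in only one partition are dropped with a warning.
#'
#' @param a,b `trn_partition` objects.
#' @return A `trn_partition_comparison` object; `glance()` returns the
#'   scalar indices as a one-row tibble.
#' @export
compare_partitions <- function(a, b) {
  stopifnot(inherits(a, "trn_partition"), inherits(b, "trn_partition"))
  common <- intersect(a$assignment$node, b$assignment$node)
  if (length(common) == 0) {
    trn_abort("The two partitions share no nodes.",
      "incomparable_partitions_error")
  }
  dropped <- (nrow(a$assignment) - length(common)) +
    (nrow(b$assignment) - length(common))
  if (dropped > 0) {
    trn_warn(sprintf("%d node(s) present in only one partition were dropped.",
                     dropped), "partial_overlap")
  }
  common <- trn_sort(common)
  ma <- a$assignment$module[match(common, a$assignment$node)]
  mb <- b$assignment$module[match(common, b$assignment$node)]

  ari <- adjusted_rand_index(ma, mb)
  nmi <- normalized_mutual_information(ma, mb)

  mods_a <- split(common, ma)
  mods_b <- split(common, mb)
  jac <- matrix(0, length(mods_a), length(mods_b),
                dimnames = list(names(mods_a), names(mods_b)))
  relations <- purrr::imap_dfr(mods_a, function(sa, ia) {
    purrr::imap_dfr(mods_b, function(sb, ib) {
      inter <- length(intersect(sa, sb))
      jac[ia, ib] <<- inter / length(union(sa, sb))
      rel <- if (inter == 0) "disjoint"
        else if (length(sa) == inter && length(sb) == inter) "equal"
        else if (length(sa) == inter) "subset"
        else if (length(sb) == inter) "superset"
        else "overlap"
      tibble(module_a = as.integer(ia), module_b = as.integer(ib),
             n_shared = inter, relation = rel)
    })
  })
  structure(
    list(ari = ari, nmi = nmi, jaccard = jac, relations = relations,
         n_common = length(common), n_dropped = dropped),
    class = "trn_partition_comparison"
  )
}

#' @export
print.trn_partition_comparison <- function(x, ...) {
  cat(sprintf("<trn_partition_comparison> %d common nodes: ARI %.3f, NMI %.3f\n",
              x$n_common, x$ari, x$nmi))
  invisible(x)
}

#' Chance-corrected agreement between two labelings
#'
#' `adjusted_rand_index()` is the Hubert-Arabie adjusted Rand index;
#' `normalized_mutual_information()` is mutual information normalized by the
#' mean entropy (Danon convention). Both take two equal-length membership
#' vectors and return 1 for identical partitions; a pair of degenerate
#' partitions with zero chance-corrected denominator (for example two
#' all-singleton labelings) compares as 1 when identical.
#'
#' @param x,y Membership vectors of equal length (any label type).
#' @return A number, at most 1.
#' @export
adjusted_rand_index <- function(x, y) {
  stopifnot(length(x) == length(y))
  tab <- table(x, y)
  comb2 <- function(v) sum(v * (v - 1) / 2)
  sum_ij <- comb2(as.vector(tab))
  sum_a <- comb2(rowSums(tab))
  sum_b <- comb2(colSums(tab))
  n2 <- comb2(sum(tab))
  expected <- sum_a * sum_b / n2
  denom <- (sum_a + sum_b) / 2 - expected
  if (denom == 0) return(if (sum_ij == sum_a && sum_ij == sum_b) 1 else 0)
  (sum_ij - expected) / denom
}

#' @rdname adjusted_rand_index
#' @export
normalized_mutual_information <- function(x, y) {
  stopifnot(length(x) == length(y))
  tab <- table(x, y)
  n <- sum(tab)
  pxy <- tab / n
  px <- rowSums(pxy)
  py <- colSums(pxy)
  hx <- -sum(px[px > 0] * log(px[px > 0]))
  hy <- -sum(py[py > 0] * log(py[py > 0]))
  nz <- pxy > 0
  mi <- sum(pxy[nz] * log(pxy[nz] / outer(px, py)[nz]))
  if (hx + hy == 0) return(1) # two single-cluster partitions agree trivially
  2 * mi / (hx + hy)
}

#' @export
glance.trn_partition_comparison <- function(x, ...) {
  tibble(ari = x$ari, nmi = x$nmi, n_common = x$n_common,
         n_dropped = x$n_dropped)
}
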