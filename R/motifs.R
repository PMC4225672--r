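# Shared scanner for three-node feed-forward motifs under the induced-subgraph
# (mfinder) convention: any edge beyond the motif definition disqualifies the
# triple. Self-loops are ignored. Returns counts and, optionally, instances.
motif_scan <- function(net, collect = TRUE) {
  motif_scan_pairs(net$edges$regulator, net$edges$target, collect = collect)
}

motif_scan_pairs <- function(from, to, collect = TRUE) {
  keep <- from != to
  e <- tibble(regulator = from[keep], target = to[keep])
  counts <- c(FF = 0L, CFF = 0L)
  empty <- tibble(motif_type = character(), master = character(),
                  local = character(), target = character())
  if (nrow(e) == 0) return(list(counts = counts, instances = empty))

  ids <- trn_sort(unique(c(e$regulator, e$target)))
  n <- length(ids)
  u <- match(e$regulator, ids)
  v <- match(e$target, ids)
  keys <- u + (v - 1) * n
  has <- function(a, b) (a + (b - 1) * n) %in% keys
  out <- vector("list", n)
  sp <- split(v, u)
  out[as.integer(names(sp))] <- sp

  acc <- list()
  for (idx in seq_len(nrow(e))) {
    A <- u[idx]; B <- v[idx]
    ob <- out[[B]]
    if (is.null(ob)) next
    common <- intersect(out[[A]], ob)
    common <- common[common != A & common != B]
    if (length(common) == 0) next
    mutual <- has(B, A)
    if (mutual && A > B) next # count each mutual pair once
    ok <- common[!(has(common, A) | has(common, B))]
    if (length(ok) == 0) next
    type <- if (mutual) "CFF" else "FF"
    counts[[type]] <- counts[[type]] + length(ok)
    if (collect) {
      acc[[length(acc) + 1]] <- tibble(
        motif_type = type, master = ids[A], local = ids[B], target = ids[ok])
    }
  }
  instances <- if (collect && length(acc)) bind_rows(acc) else empty
  if (collect && nrow(instances)) {
    instances <- instances[order(instances$motif_type, instances$master,
                                 instances$local, instances$target,
                                 method = "radix"), ]
  }
  list(counts = counts, instances = instances)
}

#' Enumerate feed-forward motifs
#'
#' Finds every feed-forward (FF) and complex feed-forward (CFF) three-node
#' motif in a directed regulatory network. An FF consists of a master
#' regulator A, a local regulator B, and a target C with edges `A->B`,
#' `B->C`, `A->C`; a CFF additionally has the feedback edge `B->A` between
#' the two regulators. Matching is induced-subgraph (mfinder-style): a
#' triple carrying any further edge among its three nodes (for example
#' `C->A`) matches neither class, so FF and CFF instance sets are disjoint.
#' Self-loops are ignored for motif membership. In a CFF the two regulators
#' are topologically symmetric; the byte-wise smaller identifier is reported
#' as the master.
#'
#' @param net A non-empty [trn] object.
#' @return A tibble with columns `motif_type` (`"FF"`/`"CFF"`), `master`,
#'   `local`, and `target`, one row per motif instance.
#' @examples
#' net <- trn(tibble::tibble(regulator = c("a", "b", "a"),
#'                           target = c("b", "c", "c")))
#' find_motifs(net)
#' @export
find_motifs <- function(net) {
  stopifnot(inherits(net, "trn"))
  motif_scan(net, collect = TRUE)$instances
}

#' Degree-preserving network randomization (edge switching)
#'
#' Randomizes a directed network by repeated double-edge swaps (edges
#' `u->v`, `x->y` rewired to `u->y`, `x->v`), rejecting swaps that would
#' create a self-loop or a duplicate edge, so that the number of nodes and
#' edges and every node's (in, out) degree pair are conserved exactly.
#' Existing self-loops are left in place. Degree conservation is asserted
#' after every call. Edge mode/evidence annotations are not meaningful on
#' the randomized network and are set to `"unknown"`.
#'
#' @param net A [trn] object with at least 2 edges.
#' @param n_swaps_per_edge Number of swap attempts per edge (default 100).
#' @param seed Optional integer seed; with a seed the result is
#'   reproducible.
#' @return A randomized [trn] object with identical degree sequences.
#' @export
switching_null <- function(net, n_swaps_per_edge = 100, seed = NULL) {
  stopifnot(inherits(net, "trn"), n_swaps_per_edge >= 1)
  g <- as_igraph(net)
  loop_edges <- igraph::E(g)[igraph::which_loop(g)]
  loops_from <- igraph::ends(g, loop_edges)[, 1]
  g_core <- igraph::delete_edges(g, loop_edges)
  if (igraph::ecount(g_core) < 2) {
    trn_warn("Fewer than 2 swappable edges; returning the network unchanged.",
             "unswappable")
    return(net)
  }
  niter <- n_swaps_per_edge * igraph::ecount(g_core)
  do_rewire <- function() {
    igraph::rewire(g_core, igraph::keeping_degseq(loops = FALSE, niter = niter))
  }
  r <- if (is.null(seed)) do_rewire() else withr::with_seed(seed, do_rewire())
  if (length(loops_from)) {
    r <- igraph::add_edges(r, rbind(loops_from, loops_from))
  }
  for (m in c("in", "out")) {
    stopifnot(identical(igraph::degree(g, mode = m, loops = TRUE),
                        igraph::degree(r, mode = m, loops = TRUE)))
  }
  trn_from_igraph(r, provenance = paste0(net$provenance, " [randomized]"))
}

#' Motif over-representation against the switching null model
#'
#' Counts FF and CFF motifs in the observed network and in `n_random`
#' independently seeded degree-preserving randomizations
#' ([switching_null()]), and reports the z-score and the empirical p-value
#' `p = (1 + #\{null >= observed\}) / (1 + n_random)` per motif class. A
#' class is selected as a network motif when `p < 0.01`.
#'
#' @param net A [trn] object.
#' @param n_random Number of randomized networks (default 1000; values
#'   below 100 trigger a warning because the attainable p-values become
#'   coarse).
#' @param n_swaps_per_edge Swap attempts per edge in each randomization.
#' @param seed Integer base seed; randomization `i` uses `seed + i`.
#' @return A `trn_motif_significance` tibble with columns `motif_type`,
#'   `observed`, `null_mean`, `null_sd`, `z_score`, `p_value`, `n_random`,
#'   `significant`.
#' @export
motif_significance <- function(net, n_random = 1000, n_swaps_per_edge = 100,
                               seed = 1) {
  stopifnot(inherits(net, "trn"), n_random >= 1)
  if (n_random < 100) {
    trn_warn("n_random < 100 gives coarse empirical p-values.", "few_randomizations")
  }
  obs <- motif_scan(net, collect = FALSE)$counts
  null_counts <- matrix(0L, nrow = n_random, ncol = 2,
                        dimnames = list(NULL, c("FF", "CFF")))
  # Fast path: rewire the loop-free igraph core directly; self-loops never
  # enter motif matching, so they can be left out of the null scans. Degree
  # conservation of the core is still asserted on every randomization.
  g <- as_igraph(net)
  g_core <- igraph::delete_edges(g, igraph::E(g)[igraph::which_loop(g)])
  deg_in <- igraph::degree(g_core, mode = "in")
  deg_out <- igraph::degree(g_core, mode = "out")
  if (igraph::ecount(g_core) < 2) {
    trn_warn("Fewer than 2 swappable edges; null counts equal the observed counts.",
             "unswappable")
  }
  niter <- n_swaps_per_edge * igraph::ecount(g_core)
  for (i in seq_len(n_random)) {
    r <- withr::with_seed(seed + i, igraph::rewire(
      g_core, igraph::keeping_degseq(loops = FALSE, niter = niter)))
    stopifnot(identical(igraph::degree(r, mode = "in"), deg_in),
              identical(igraph::degree(r, mode = "out"), deg_out))
    el <- igraph::as_edgelist(r, names = TRUE)
    null_counts[i, ] <- motif_scan_pairs(el[, 1], el[, 2],
                                         collect = FALSE)$counts
  }
  res <- purrr::map_dfr(c("FF", "CFF"), function(type) {
    mu <- mean(null_counts[, type])
    sdev <- stats::sd(null_counts[, type])
    p <- (1 + sum(null_counts[, type] >= obs[[type]])) / (1 + n_random)
    tibble(motif_type = type, observed = obs[[type]], null_mean = mu,
           null_sd = sdev,
           z_score = if (sdev > 0) (obs[[type]] - mu) / sdev else NA_real_,
           p_value = p, n_random = as.integer(n_random),
           significant = p < 0.01)
  })
  class(res) <- c("trn_motif_significance", class(res))
  res
}

#' Plot observed motif counts against the null expectation
#'
#' @param object A `trn_motif_significance` tibble.
#' @param ... Ignored.
#' @return A [ggplot2::ggplot] object.
#' @export
autoplot.trn_motif_significance <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$motif_type)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$observed), fill = "steelblue") +
    ggplot2::geom_pointrange(ggplot2::aes(
      y = .data$null_mean,
      ymin = .data$null_mean - .data$null_sd,
      ymax = .data$null_mean + .data$null_sd)) +
    ggplot2::labs(x = NULL, y = "motif count",
                  title = "Observed counts (bars) vs switching-null mean +/- sd")
}

#' Summarize motifs by regulator pair
#'
#' One row per `(master, local)` regulator pair with the number of distinct
#' targets they jointly regulate through FF/CFF motifs, annotated with each
#' regulator's module. Reproduces the layout of per-module motif
#' distribution tables (master regulator, local regulator, number of target
#' genes).
#'
#' @param instances Motif instances from [find_motifs()].
#' @param partition Optional `trn_partition` (or tibble `node`, `module`)
#'   giving module labels; regulators absent from it are labelled
#'   `"unassigned"`.
#' @return A tibble `master`, `master_module`, `local`, `local_module`,
#'   `n_targets`, sorted by decreasing target count.
#' @export
ff_pair_summary <- function(instances, partition = NULL) {
  labels <- module_labels(partition)
  instances %>%
    group_by(.data$master, .data$local) %>%
    summarise(n_targets = n_distinct(.data$target), .groups = "drop") %>%
    mutate(master_module = labels(.data$master),
           local_module = labels(.data$local)) %>%
    select("master", "master_module", "local", "local_module", "n_targets") %>%
    arrange(dplyr::desc(.data$n_targets), .data$master, .data$local)
}

module_labels <- function(partition) {
  if (is.null(partition)) return(function(ids) rep("unassigned", length(ids)))
  assignment <- if (inherits(partition, "trn_partition")) partition$assignment
    else as_tibble(partition)
  map <- setNames(as.character(assignment$module), assignment$node)
  function(ids) {
    out <- unname(map[ids])
    out[is.na(out)] <- "unassigned"
    out
  }
}

#' Intra- versus inter-module motif embedding
#'
#' A motif instance is *embedded* when its master and local regulators
#' belong to the same module; otherwise it mediates cross-talk between
#' modules at the level of regulatory genes (targets are typically
#' structural genes outside the regulator partition and do not enter the
#' rule). Regulators missing from the partition are labelled unassigned and
#' counted as cross-talk with a warning.
#'
#' @param instances Motif instances from [find_motifs()].
#' @param partition A `trn_partition` (or tibble `node`, `module`) over the
#'   regulators.
#' @return A tibble `motif_type`, `n_total`, `n_embedded`, `n_cross_talk`,
#'   `fraction_embedded`, with the cross-talk instances in attribute
#'   `"cross_talk"`.
#' @export
motif_embedding <- function(instances, partition) {
  labels <- module_labels(partition)
  inst <- instances %>%
    mutate(master_module = labels(.data$master),
           local_module = labels(.data$local))
  if (any(inst$master_module == "unassigned" |
          inst$local_module == "unassigned")) {
    trn_warn("Some motif regulators are not covered by the partition; counted as cross-talk.",
             "unassigned_regulators")
  }
  inst <- inst %>%
    mutate(embedded = .data$master_module == .data$local_module &
             .data$master_module != "unassigned")
  res <- inst %>%
    group_by(.data$motif_type) %>%
    summarise(n_total = n(), n_embedded = sum(.data$embedded),
              n_cross_talk = sum(!.data$embedded),
              fraction_embedded = mean(.data$embedded), .groups = "drop")
  attr(res, "cross_talk") <- inst[!inst$embedded, ]
  res
}

#' Master / local role profile of regulators
#'
#' For every regulator, counts its appearances as master (A role) and as
#' local (B role) across motif instances. The dominant role classifies the
#' regulator: predominantly-master TFs and sigma factors act as master
#' regulators of their module, predominantly-local ones as downstream
#' relays; equal counts give `"mixed"`.
#'
#' @param instances Motif instances from [find_motifs()].
#' @return A tibble `regulator`, `n_master`, `n_local`, `role`, sorted by
#'   decreasing master count.
#' @export
regulator_roles <- function(instances) {
  masters <- instances %>% count(regulator = .data$master, name = "n_master")
  locals <- instances %>% count(regulator = .data$local, name = "n_local")
  dplyr::full_join(masters, locals, by = "regulator") %>%
    mutate(across(c("n_master", "n_local"), ~ tidyr::replace_na(.x, 0L))) %>%
    mutate(role = dplyr::case_when(
      .data$n_master > .data$n_local ~ "master",
      .data$n_local > .data$n_master ~ "local",
      TRUE ~ "mixed")) %>%
    arrange(dplyr::desc(.data$n_master), .data$regulator)
}
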