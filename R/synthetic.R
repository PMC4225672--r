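#' Specification for a synthetic regulatory network
#'
#' Bundles and validates the parameters of the synthetic-network generator
#' [simulate_trn()]. The defaults emulate the statistical structure of a
#' curated bacterial TRN of the *B. subtilis* kind: 70 regulators (about a
#' fifth of them sigma factors) plus a housekeeping sigma-factor hub wired
#' to 46.5% of the network, roughly 1,500 target genes, power-law
#' out-degree with exponent 2.1, nine planted regulator modules with sparse
#' regulator-regulator wiring (a few dozen regulator-regulator edges in
#' total), planted FF/CFF motifs, and 90% strong-evidence labels.
#'
#' @param n_regulators Number of non-hub regulators.
#' @param n_targets Number of target genes in the fan-out pool.
#' @param n_modules Number of planted regulator modules.
#' @param out_exponent Target power-law exponent for regulator out-degree
#'   (fan-out sampled from a truncated discrete power law on
#'   `[1, n_targets]`).
#' @param intra_module_edge_prob,inter_module_edge_prob Probability of a
#'   directed regulator-regulator edge within / between planted modules;
#'   `inter` must be strictly smaller than `intra`.
#' @param n_planted_ff,n_planted_cff Number of FF / CFF motifs planted on
#'   regulator pairs with fresh target nodes (fresh targets guarantee the
#'   planted instance survives induced-subgraph matching).
#' @param ff_intra_fraction Probability that a planted FF's regulator pair
#'   is drawn from within one module (the default reflects the
#'   predominantly module-embedded placement of feed-forward motifs in real
#'   TRNs). Planted CFFs are always intra-module.
#' @param include_hub Add a sigA-like housekeeping hub regulator.
#' @param hub_coverage Fraction of the network's nodes the hub regulates.
#' @param prop_sigma Fraction of regulators annotated as sigma factors.
#' @param prop_strong Fraction of edges labelled with strong evidence.
#' @param seed Integer seed; generation is a pure function of the spec.
#' @return A validated `trn_spec` list.
#' @export
trn_spec <- function(n_regulators = 70, n_targets = 1500, n_modules = 9,
                     out_exponent = 2.1,
                     intra_module_edge_prob = 0.12,
                     inter_module_edge_prob = 0.005,
                     n_planted_ff = 20, n_planted_cff = 5,
                     ff_intra_fraction = 0.89,
                     include_hub = TRUE, hub_coverage = 0.465,
                     prop_sigma = 0.22, prop_strong = 0.9, seed = 1) {
  spec <- list(
    n_regulators = n_regulators, n_targets = n_targets,
    n_modules = n_modules, out_exponent = out_exponent,
    intra_module_edge_prob = intra_module_edge_prob,
    inter_module_edge_prob = inter_module_edge_prob,
    n_planted_ff = n_planted_ff, n_planted_cff = n_planted_cff,
    ff_intra_fraction = ff_intra_fraction,
    include_hub = include_hub, hub_coverage = hub_coverage,
    prop_sigma = prop_sigma, prop_strong = prop_strong, seed = seed
  )
  if (inter_module_edge_prob >= intra_module_edge_prob) {
    trn_abort("inter_module_edge_prob must be smaller than intra_module_edge_prob.",
      "spec_error")
  }
  if (n_regulators < n_modules || n_modules < 1 || out_exponent <= 1 ||
      hub_coverage < 0 || hub_coverage > 1 ||
      n_targets < 1 || prop_strong < 0 || prop_strong > 1) {
    trn_abort("Invalid synthetic-network specification.", "spec_error")
  }
  structure(spec, class = "trn_spec")
}

# Inverse-CDF sample from P(k) proportional to k^-gamma on 1..kmax.
rpowerlaw <- function(n, gamma, kmax) {
  w <- (1:kmax)^(-gamma)
  sample.int(kmax, n, replace = TRUE, prob = w / sum(w))
}

#' Generate a synthetic regulatory network with known ground truth
#'
#' Generates a directed regulator-target network according to a
#' [trn_spec()]: regulators are partitioned into planted modules and wired
#' by block-dependent edge probabilities; each regulator fans out to a
#' power-law-distributed number of targets; FF and CFF motifs are planted on
#' regulator pairs with fresh targets; optionally a housekeeping hub (id
#' `"sigA"`) is wired to the stated fraction of all nodes. Evidence labels
#' are drawn so evidence filtering is exercised end-to-end. Generation is
#' deterministic given the spec (including its seed).
#'
#' @param spec A `trn_spec`.
#' @return A list with elements `network` (a [trn]) and `truth` (list with
#'   `modules`: tibble `node`, `module`; `planted_motifs`: tibble like
#'   [find_motifs()] output; `hub_id`).
#' @examples
#' sim <- simulate_trn(trn_spec(n_regulators = 12, n_targets = 50,
#'                              n_modules = 3, seed = 7))
#' sim$network
#' @export
simulate_trn <- function(spec) {
  stopifnot(inherits(spec, "trn_spec"))
  withr::with_seed(spec$seed, simulate_trn_impl(spec))
}

simulate_trn_impl <- function(spec) {
  n_sig <- round(spec$prop_sigma * spec$n_regulators)
  regs <- c(sprintf("sig%02d", seq_len(n_sig)),
            sprintf("tf%03d", seq_len(spec$n_regulators - n_sig)))
  regs <- sample(regs) # shuffle so modules mix TFs and sigma factors
  module_of <- setNames(rep(seq_len(spec$n_modules), length.out = length(regs)),
                        regs)
  targets <- sprintf("t%04d", seq_len(spec$n_targets))

  # Regulator-regulator edges by planted-block probabilities.
  pairs <- expand.grid(from = regs, to = regs, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$from != pairs$to, ]
  p <- ifelse(module_of[pairs$from] == module_of[pairs$to],
              spec$intra_module_edge_prob, spec$inter_module_edge_prob)
  keep <- stats::runif(nrow(pairs)) < p
  rr <- tibble(regulator = pairs$from[keep], target = pairs$to[keep])

  # Power-law fan-out to the target pool.
  fan <- rpowerlaw(length(regs), spec$out_exponent, spec$n_targets)
  rt <- purrr::map2_dfr(regs, fan, function(r, k) {
    tibble(regulator = r, target = sample(targets, k))
  })

  edges <- bind_rows(rr, rt)
  edge_key <- function(e) paste(e$regulator, e$target, sep = "\r")

  # Plant motifs on regulator pairs; targets are fresh nodes so no
  # disqualifying edge can touch them.
  planted <- list()
  used_pairs <- character()
  pick_pair <- function(need_no_reverse, intra) {
    # prefer the requested placement; fall back to any free pair when the
    # preferred stratum is exhausted (small specs saturate quickly)
    for (attempt in 1:2000) {
      strict <- attempt <= 1000
      ab <- if (intra && strict) {
        mod <- sample(names(which(table(module_of) >= 2)), 1)
        sample(regs[module_of[regs] == as.integer(mod)], 2)
      } else {
        sample(regs, 2)
      }
      if (!intra && strict && module_of[ab[1]] == module_of[ab[2]]) next
      pk <- paste(sort(ab), collapse = "\r")
      rev_exists <- paste(ab[2], ab[1], sep = "\r") %in% edge_key(edges)
      if (pk %in% used_pairs) next
      if (need_no_reverse && rev_exists) next
      used_pairs <<- c(used_pairs, pk)
      return(ab)
    }
    trn_abort("Could not find a free regulator pair for motif planting.",
      "spec_error")
  }
  if (spec$n_planted_ff > 0) {
    for (i in seq_len(spec$n_planted_ff)) {
      ab <- pick_pair(need_no_reverse = TRUE,
                      intra = stats::runif(1) < spec$ff_intra_fraction)
      cfresh <- sprintf("ffT%03d", i)
      new <- tibble(regulator = c(ab[1], ab[1], ab[2]),
                    target = c(ab[2], cfresh, cfresh))
      edges <- bind_rows(edges, new)
      planted[[length(planted) + 1]] <- tibble(
        motif_type = "FF", master = ab[1], local = ab[2], target = cfresh)
    }
  }
  if (spec$n_planted_cff > 0) {
    for (i in seq_len(spec$n_planted_cff)) {
      ab <- sort(pick_pair(need_no_reverse = FALSE, intra = TRUE))
      cfresh <- sprintf("cffT%03d", i)
      new <- tibble(regulator = c(ab[1], ab[2], ab[1], ab[2]),
                    target = c(ab[2], ab[1], cfresh, cfresh))
      edges <- bind_rows(edges, new)
      planted[[length(planted) + 1]] <- tibble(
        motif_type = "CFF", master = ab[1], local = ab[2], target = cfresh)
    }
  }
  planted <- if (length(planted)) bind_rows(planted) else
    tibble(motif_type = character(), master = character(),
           local = character(), target = character())

  # Housekeeping hub wired to a stated fraction of the realized network
  # (n_targets is a pool; only sampled targets become nodes).
  hub_id <- NULL
  if (spec$include_hub) {
    hub_id <- "sigA"
    others <- unique(c(regs, edges$target))
    k_hub <- min(length(others), ceiling(spec$hub_coverage * (length(others) + 1)))
    edges <- bind_rows(edges,
                       tibble(regulator = hub_id,
                              target = sample(others, k_hub)))
  }

  edges <- distinct(edges, .data$regulator, .data$target)
  edges$regulator_class <- ifelse(grepl("^sig", edges$regulator), "sigma", "TF")
  edges$mode <- sample(c("activation", "repression"), nrow(edges),
                       replace = TRUE, prob = c(0.65, 0.35))
  edges$evidence <- ifelse(stats::runif(nrow(edges)) < spec$prop_strong,
                           "strong", "weak")

  net <- trn(edges, provenance = sprintf("synthetic (seed %d)", spec$seed))
  modules_tbl <- tibble(node = names(module_of), module = unname(module_of))
  modules_tbl <- modules_tbl[order(modules_tbl$node, method = "radix"), ]
  truth <- list(modules = modules_tbl, planted_motifs = planted,
                hub_id = hub_id)
  list(network = net, truth = truth)
}

#' Recovery report for a synthetic network
#'
#' Checks how well the analysis pipeline recovers the planted structure of a
#' [simulate_trn()] network: adjusted Rand index between a detected
#' partition and the planted modules, the fraction of planted motifs found
#' by [find_motifs()] (1 by construction on uncorrupted networks), and the
#' motif significance flags.
#'
#' @param sim A list `(network, truth)` from [simulate_trn()].
#' @param partition A `trn_partition` over the regulators.
#' @param significance Optional `trn_motif_significance` tibble.
#' @return A one-row tibble with `module_recovery_ari`,
#'   `planted_motif_recovery`, and (when supplied) `ff_significant`,
#'   `cff_significant`.
#' @export
recovery_report <- function(sim, partition, significance = NULL) {
  truth_part <- new_trn_partition(
    renumber_modules(sim$truth$modules), method = "external", cut = "planted")
  common <- intersect(partition$assignment$node, sim$truth$modules$node)
  if (length(common) == 0) {
    trn_abort("Partition and planted truth share no nodes.",
      "incomparable_partitions_error")
  }
  cmp <- withCallingHandlers(
    compare_partitions(partition, truth_part),
    trntopo_partial_overlap = function(w) invokeRestart("muffleWarning"))

  found <- find_motifs(sim$network)
  planted <- sim$truth$planted_motifs
  key <- function(df) paste(df$motif_type, df$master, df$local, df$target)
  recovery <- if (nrow(planted) == 0) NA_real_ else
    mean(key(planted) %in% key(found))

  out <- tibble(module_recovery_ari = cmp$ari,
                planted_motif_recovery = recovery)
  if (!is.null(significance)) {
    out$ff_significant <- any(significance$motif_type == "FF" &
                              significance$significant)
    out$cff_significant <- any(significance$motif_type == "CFF" &
                               significance$significant)
  }
  out
}
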