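#' @import tibble
#' @importFrom dplyr %>% mutate filter select arrange group_by summarise ungroup
#'   distinct left_join anti_join bind_rows n n_distinct row_number first rename
#'   across all_of pull count
#' @importFrom stats setNames
NULL

sigma_glyph <- "\u03c3" # curated exports sometimes write the class as the glyph

trn_mode_levels <- c("activation", "repression", "dual", "unknown")
trn_evidence_levels <- c("strong", "weak", "unknown")
trn_regulator_classes <- c("TF", "sigma")

# C-locale, byte-wise sort so node orderings never depend on the session locale.
trn_sort <- function(x) x[order(x, method = "radix")]

trn_key <- function(x) tolower(trimws(x))

# "SigA"/"SIGA" -> "sigA"; non-sigma spellings are kept as first seen.
canonical_display <- function(id, class) {
  ifelse(class == "sigma" & grepl("^sig", id, ignore.case = TRUE),
    paste0("sig", substring(id, 4)), id
  )
}

#' Build a regulatory network from an interaction table
#'
#' Constructs a validated transcriptional-regulatory-network (`trn`) object
#' from a regulator-to-target interaction table. Gene identifiers are trimmed
#' and compared case-insensitively (the first-seen spelling is preserved for
#' display; sigma-factor names are canonicalized to the `sigX` spelling).
#' Duplicate `(regulator, target)` rows are collapsed: co-occurring activation
#' and repression reconcile to `dual`, and the strongest evidence level is
#' kept. Self-loops (autoregulation) are permitted and preserved.
#'
#' @param interactions A data frame with columns `regulator` and `target`,
#'   and optionally `regulator_class` (`"TF"`, `"sigma"`, or `"unknown"`),
#'   `mode` (`"activation"`, `"repression"`, `"dual"`, `"unknown"`), and
#'   `evidence` (`"strong"`, `"weak"`, `"unknown"`). Missing annotation
#'   columns default to `"unknown"`.
#' @param isolated_nodes Optional data frame with columns `id` and `class`
#'   naming nodes that carry no interaction (kept as isolated vertices).
#' @param provenance Free-text source tag stored on the object.
#'
#' @details A regulator whose class is `"unknown"` is annotated `"sigma"` when
#'   its identifier matches the `sig*` naming convention and `"TF"` otherwise,
#'   so that every edge source ends up annotated as a TF or a sigma factor.
#'   A regulator reported as both `"TF"` and `"sigma"` across rows is a load
#'   error (`trntopo_class_conflict_error`).
#'
#' @return A `trn` object: a list with tibbles `nodes` (`id`, `class`) and
#'   `edges` (`regulator`, `target`, `mode`, `evidence`), plus `provenance`.
#' @examples
#' net <- trn(tibble::tibble(
#'   regulator = c("sigA", "ccpA"), target = c("ccpA", "ackA"),
#'   regulator_class = c("sigma", "TF")
#' ))
#' net
#' @export
trn <- function(interactions, isolated_nodes = NULL, provenance = "") {
  interactions <- as_tibble(interactions)
  if (!all(c("regulator", "target") %in% names(interactions))) {
    trn_abort("`interactions` must have columns `regulator` and `target`.",
      "invalid_interaction")
  }
  for (col in c("regulator_class", "mode", "evidence")) {
    if (!col %in% names(interactions)) interactions[[col]] <- "unknown"
  }
  ia <- interactions %>%
    mutate(across(all_of(c("regulator", "target", "regulator_class", "mode",
                           "evidence")), ~ trimws(as.character(.x))))
  if (nrow(ia) > 0 && any(is.na(ia$regulator) | is.na(ia$target) |
                          ia$regulator == "" | ia$target == "")) {
    trn_abort("regulator and target identifiers must be non-empty.",
      "invalid_interaction")
  }
  ia$regulator_class[is.na(ia$regulator_class)] <- "unknown"
  ia$mode[is.na(ia$mode) | !ia$mode %in% trn_mode_levels] <- "unknown"
  ia$evidence[is.na(ia$evidence) | !ia$evidence %in% trn_evidence_levels] <- "unknown"
  cls <- ia$regulator_class
  cls[tolower(cls) == "tf"] <- "TF"
  cls[tolower(cls) %in% c("sigma", sigma_glyph)] <- "sigma"
  cls[!cls %in% trn_regulator_classes] <- "unknown"
  ia$regulator_class <- cls

  if (nrow(ia) == 0) {
    edges <- tibble(regulator = character(), target = character(),
                    mode = character(), evidence = character())
    nodes <- tibble(id = character(), class = character())
    if (!is.null(isolated_nodes) && nrow(isolated_nodes) > 0) {
      iso <- as_tibble(isolated_nodes)
      iso$class[!iso$class %in% c(trn_regulator_classes, "target")] <- "target"
      nodes <- iso[order(iso$id, method = "radix"), c("id", "class")]
    }
    return(structure(list(nodes = nodes, edges = edges,
                          provenance = provenance), class = "trn"))
  }

  ia$reg_key <- trn_key(ia$regulator)
  ia$tgt_key <- trn_key(ia$target)

  # Resolve one class per regulator; TF vs sigma across rows is a load error.
  reg_cls <- ia %>%
    group_by(.data$reg_key) %>%
    summarise(
      classes = list(setdiff(unique(.data$regulator_class), "unknown")),
      display = first(.data$regulator), .groups = "drop"
    )
  conflict <- purrr::map_lgl(reg_cls$classes, ~ length(.x) > 1)
  if (any(conflict)) {
    trn_abort(
      paste0("Conflicting regulator class for: ",
             paste(reg_cls$display[conflict], collapse = ", ")),
      "class_conflict_error")
  }
  reg_cls$class <- purrr::map_chr(reg_cls$classes, function(x) {
    if (length(x) == 1) return(x)
    "unknown"
  })
  infer <- reg_cls$class == "unknown"
  reg_cls$class[infer] <- ifelse(
    grepl("^sig[a-z0-9]*$", reg_cls$reg_key[infer]), "sigma", "TF")
  reg_cls$display <- canonical_display(reg_cls$display, reg_cls$class)

  # One display spelling per key: regulators take their canonical display,
  # pure targets take the first-seen spelling.
  tgt_first <- ia %>%
    group_by(key = .data$tgt_key) %>%
    summarise(display = first(.data$target), .groups = "drop")
  display_map <- reg_cls %>% select(key = "reg_key", "display") %>%
    bind_rows(anti_join(tgt_first, tibble(key = reg_cls$reg_key), by = "key"))
  lookup <- setNames(display_map$display, display_map$key)

  class_map <- setNames(reg_cls$class, reg_cls$reg_key)

  edges <- ia %>%
    mutate(regulator = unname(lookup[.data$reg_key]),
           target = unname(lookup[.data$tgt_key])) %>%
    group_by(.data$regulator, .data$target) %>%
    summarise(mode = reconcile_mode(.data$mode),
              evidence = reconcile_evidence(.data$evidence), .groups = "drop")
  edges <- edges[order(edges$regulator, edges$target, method = "radix"), ]

  nodes <- tibble(id = display_map$display, key = display_map$key) %>%
    mutate(class = ifelse(.data$key %in% names(class_map),
                          unname(class_map[.data$key]), "target")) %>%
    select("id", "class")

  if (!is.null(isolated_nodes) && nrow(isolated_nodes) > 0) {
    iso <- as_tibble(isolated_nodes)
    iso$class[!iso$class %in% c(trn_regulator_classes, "target")] <- "target"
    iso$id <- canonical_display(trimws(iso$id), iso$class)
    iso <- iso[!trn_key(iso$id) %in% trn_key(nodes$id), c("id", "class")]
    nodes <- bind_rows(nodes, iso)
  }
  nodes <- nodes[order(nodes$id, method = "radix"), ]

  structure(
    list(nodes = nodes, edges = edges, provenance = provenance),
    class = "trn"
  )
}

# activation + repression (or any dual) -> dual; single known mode wins.
reconcile_mode <- function(modes) {
  m <- setdiff(unique(modes), "unknown")
  if (length(m) == 0) return("unknown")
  if ("dual" %in% m || all(c("activation", "repression") %in% m)) return("dual")
  m[[1]]
}

reconcile_evidence <- function(ev) {
  for (level in c("strong", "weak")) if (level %in% ev) return(level)
  "unknown"
}

#' @export
print.trn <- function(x, ...) {
  cls <- table(factor(x$nodes$class, levels = c("TF", "sigma", "target")))
  cat(sprintf(
    "<trn> %d nodes (%d TF, %d sigma, %d target-only), %d edges\n",
    nrow(x$nodes), cls[["TF"]], cls[["sigma"]], cls[["target"]],
    nrow(x$edges)))
  if (nzchar(x$provenance)) cat("  source:", x$provenance, "\n")
  invisible(x)
}

#' Number of nodes / edges of a regulatory network
#' @param net A `trn` object.
#' @return An integer count.
#' @export
n_nodes <- function(net) nrow(net$nodes)

#' @rdname n_nodes
#' @export
n_edges <- function(net) nrow(net$edges)

#' Regulator identifiers of a network
#' @param net A `trn` object.
#' @return Character vector of TF and sigma-factor node ids, sorted.
#' @export
regulators <- function(net) {
  trn_sort(net$nodes$id[net$nodes$class %in% trn_regulator_classes])
}

#' @export
tidy.trn <- function(x, ...) {
  cls <- setNames(x$nodes$class, x$nodes$id)
  x$edges %>%
    mutate(regulator_class = unname(cls[.data$regulator])) %>%
    select("regulator", "target", "regulator_class", "mode", "evidence")
}

#' Convert a regulatory network to an igraph object
#'
#' @param net A `trn` object.
#' @return A directed [igraph::igraph] graph with vertex attribute `class`
#'   and edge attributes `mode` and `evidence`.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "trn"))
  igraph::graph_from_data_frame(
    d = net$edges, directed = TRUE,
    vertices = as.data.frame(net$nodes)
  )
}

# Rebuild a trn from an igraph whose vertices carry the original classes.
trn_from_igraph <- function(g, provenance = "") {
  el <- igraph::as_edgelist(g, names = TRUE)
  vclass <- igraph::vertex_attr(g, "class") %||% rep("unknown", igraph::vcount(g))
  vnames <- igraph::V(g)$name
  edges <- tibble(
    regulator = el[, 1], target = el[, 2],
    regulator_class = setNames(vclass, vnames)[el[, 1]],
    mode = "unknown", evidence = "unknown"
  )
  iso <- tibble(id = vnames, class = vclass)
  iso <- iso[!iso$id %in% c(el[, 1], el[, 2]), ]
  trn(edges, isolated_nodes = iso, provenance = provenance)
}
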