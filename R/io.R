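#' Read a regulatory network from a tab-separated edge list
#'
#' Parses the TSV edge-list dialect used for curated regulator-target tables:
#' columns `regulator`, `target`, `regulator_class`, `mode`, `evidence`
#' (only the first two are required), separated by tabs. A header row is
#' auto-detected by the reserved column names; `#` starts a comment. Isolated
#' nodes written by [write_trn()] are carried on `#! node` directive lines so
#' that a write/parse round trip reproduces the network exactly. Unknown
#' columns are ignored.
#'
#' @param path Path to the edge-list file.
#' @param dialect Input dialect; only `"tsv_edgelist"` is defined.
#' @param quiet Suppress the node/edge count log message.
#' @return A [trn] object.
#' @seealso [write_trn()], [filter_evidence()], [regulator_subnetwork()]
#' @export
parse_trn <- function(path, dialect = "tsv_edgelist", quiet = FALSE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) trn_abort(paste0("File not found: ", path), "parse_error")
  lines <- readLines(path, warn = FALSE)

  iso <- list()
  data_idx <- integer()
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (grepl("^#!\\s*node\\t", ln)) {
      f <- strsplit(sub("^#!\\s*node\\t", "", ln), "\t", fixed = TRUE)[[1]]
      iso[[length(iso) + 1]] <- tibble(
        id = f[[1]], class = if (length(f) >= 2) f[[2]] else "target")
      next
    }
    if (grepl("^\\s*(#|$)", ln)) next
    data_idx <- c(data_idx, i)
  }
  iso <- if (length(iso)) bind_rows(iso) else NULL

  if (length(data_idx) == 0 && is.null(iso)) {
    trn_abort("No interactions found: the file is empty or all comments.",
      "empty_network_error")
  }

  cols <- c("regulator", "target", "regulator_class", "mode", "evidence")
  rows <- list()
  col_pos <- NULL
  for (i in data_idx) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (is.null(col_pos)) {
      low <- tolower(trimws(f))
      if (all(c("regulator", "target") %in% low)) {
        col_pos <- match(cols, low) # header row: map reserved names
        next
      }
      col_pos <- seq_along(cols) # positional columns
    }
    if (sum(!is.na(f[col_pos[1:2]])) < 2 || length(f) < 2) {
      trn_abort(sprintf("Line %d is malformed (fewer than 2 columns).", i),
        "parse_error", line = i)
    }
    vals <- purrr::map_chr(col_pos, function(j) {
      if (is.na(j) || j > length(f)) NA_character_ else f[[j]]
    })
    rows[[length(rows) + 1]] <- vals
  }

  edges <- if (length(rows)) {
    m <- do.call(rbind, rows)
    colnames(m) <- cols
    as_tibble(m)
  } else {
    tibble(regulator = character(), target = character(),
           regulator_class = character(), mode = character(),
           evidence = character())
  }
  if (nrow(edges) == 0 && is.null(iso)) {
    trn_abort("No interactions found: the file is empty or all comments.",
      "empty_network_error")
  }
  net <- trn(edges, isolated_nodes = iso, provenance = path)
  if (!quiet) {
    rlang::inform(sprintf("Parsed %s: %d nodes, %d edges.",
                          basename(path), n_nodes(net), n_edges(net)))
  }
  net
}

#' Write a regulatory network to disk
#'
#' `tsv_edgelist` writes the same dialect [parse_trn()] reads, with edges in
#' canonical (byte-wise sorted) order and isolated nodes on `#! node`
#' directive lines, so that parsing the output reproduces the network
#' exactly, byte-for-byte on re-serialization. `graphml` delegates to
#' [igraph::write_graph()] and preserves node classes and edge annotations
#' as attributes.
#'
#' @param net A [trn] object.
#' @param path Output file path.
#' @param format `"tsv_edgelist"` or `"graphml"`.
#' @return `net`, invisibly.
#' @export
write_trn <- function(net, path, format = c("tsv_edgelist", "graphml")) {
  format <- match.arg(format)
  stopifnot(inherits(net, "trn"))
  res <- tryCatch({
    if (format == "graphml") {
      igraph::write_graph(as_igraph(net), path, format = "graphml")
    } else {
      cls <- setNames(net$nodes$class, net$nodes$id)
      header <- "regulator\ttarget\tregulator_class\tmode\tevidence"
      deg_nodes <- unique(c(net$edges$regulator, net$edges$target))
      iso <- net$nodes[!net$nodes$id %in% deg_nodes, ]
      iso_lines <- if (nrow(iso)) {
        sprintf("#! node\t%s\t%s", iso$id, iso$class)
      } else character()
      e <- net$edges[order(net$edges$regulator, net$edges$target,
                           method = "radix"), ]
      edge_lines <- sprintf("%s\t%s\t%s\t%s\t%s", e$regulator, e$target,
                            unname(cls[e$regulator]), e$mode, e$evidence)
      writeLines(c(header, iso_lines, edge_lines), path)
    }
  }, error = function(e) {
    trn_abort(paste0("Failed to write ", path, ": ", conditionMessage(e)),
      "write_error")
  })
  invisible(net)
}

#' Filter interactions by evidence strength
#'
#' Keeps only edges whose evidence level is in `keep` (curated databases
#' distinguish interactions with strong experimental support from weakly
#' supported ones). Nodes left without any edge are dropped. The input
#' network is not modified.
#'
#' @param net A [trn] object.
#' @param keep Character vector of evidence levels to retain, a subset of
#'   `c("strong", "weak", "unknown")`.
#' @return A new [trn] object restricted to the kept evidence levels.
#' @export
filter_evidence <- function(net, keep = "strong") {
  stopifnot(inherits(net, "trn"))
  if (length(keep) == 0) trn_abort("`keep` must be non-empty.", "invalid_argument")
  keep <- match.arg(keep, trn_evidence_levels, several.ok = TRUE)
  edges <- net$edges[net$edges$evidence %in% keep, ]
  if (nrow(edges) == 0) {
    trn_warn("No edges left after evidence filtering; returning an empty network.",
             "empty_filter")
  }
  used <- unique(c(edges$regulator, edges$target))
  nodes <- net$nodes[net$nodes$id %in% used, ]
  structure(list(nodes = nodes, edges = edges, provenance = net$provenance),
            class = "trn")
}

#' Extract the regulator-only subnetwork
#'
#' Restricts the network to its regulators (TFs and sigma factors), keeping
#' only edges whose source and target are both regulators. This is the
#' regulator-regulator wiring on which module detection operates. Global
#' hubs such as the housekeeping sigma factor sigA can be excluded: being
#' wired to nearly every gene, they collapse all modules into one
#' mega-module.
#'
#' @param net A [trn] object.
#' @param exclude Character vector of regulator ids to drop (matched
#'   case-insensitively). Ids absent from the network raise a warning, not
#'   an error.
#' @param keep_isolated Keep regulators left without any surviving edge as
#'   isolated nodes (default), mirroring disconnected regulator groups.
#' @return A new [trn] object over the regulator set.
#' @export
regulator_subnetwork <- function(net, exclude = character(), keep_isolated = TRUE) {
  stopifnot(inherits(net, "trn"))
  regs <- net$nodes[net$nodes$class %in% trn_regulator_classes, ]
  missing <- exclude[!trn_key(exclude) %in% trn_key(net$nodes$id)]
  if (length(missing)) {
    trn_warn(paste0("Excluded ids not present in the network: ",
                    paste(missing, collapse = ", ")), "missing_exclude")
  }
  keep_ids <- regs$id[!trn_key(regs$id) %in% trn_key(exclude)]
  edges <- net$edges[net$edges$regulator %in% keep_ids &
                     net$edges$target %in% keep_ids, ]
  nodes <- regs[regs$id %in% keep_ids, ]
  if (!keep_isolated) {
    used <- unique(c(edges$regulator, edges$target))
    nodes <- nodes[nodes$id %in% used, ]
  }
  structure(list(nodes = nodes, edges = edges, provenance = net$provenance),
            class = "trn")
}
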