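#' Degree statistics of a regulatory network
#'
#' Computes the degree histogram `P(k)`, the complementary cumulative degree
#' distribution (CCDF), and the degree-dependent clustering coefficient
#' `C(k)` for one direction of a directed regulatory network. All nodes enter
#' the histogram denominator (including zero-degree nodes); a self-loop
#' contributes 1 to both the in- and the out-degree of its node. The CCDF
#' conditions on `k >= 1` (see [ccdf()]).
#'
#' @param net A [trn] object with at least one node.
#' @param direction `"out"`, `"in"`, or `"total"`.
#' @return A `trn_degree_stats` object with elements `direction`, `degrees`
#'   (named integer vector), `histogram` (tibble `degree`, `count`,
#'   `frequency`), `ccdf` (tibble `degree`, `ccdf`), `clustering_by_degree`
#'   (tibble `degree`, `mean_clustering`, on the undirected simple
#'   projection), and `mean_clustering`.
#' @examples
#' net <- trn(tibble::tibble(regulator = c("a", "a", "b"),
#'                           target = c("b", "c", "c")))
#' degree_stats(net, "out")$histogram
#' @export
degree_stats <- function(net, direction = c("out", "in", "total")) {
  stopifnot(inherits(net, "trn"))
  direction <- match.arg(direction)
  if (n_nodes(net) == 0) {
    trn_abort("Cannot compute degree statistics of an empty network.",
      "empty_network_error")
  }
  g <- as_igraph(net)
  mode <- c(out = "out", `in` = "in", total = "all")[[direction]]
  deg <- igraph::degree(g, mode = mode, loops = TRUE)

  n <- length(deg)
  hist <- tibble(degree = as.integer(names(table(deg))),
                 count = as.integer(table(deg))) %>%
    mutate(frequency = .data$count / n) %>%
    arrange(.data$degree)

  ccdf_tbl <- if (any(deg >= 1)) ccdf(as.numeric(deg)) else
    tibble(degree = numeric(), ccdf = numeric())

  cbd <- clustering_by_degree(net)

  structure(
    list(direction = direction, degrees = deg, histogram = hist,
         ccdf = ccdf_tbl, clustering_by_degree = cbd$by_degree,
         mean_clustering = cbd$mean),
    class = "trn_degree_stats"
  )
}

#' @export
print.trn_degree_stats <- function(x, ...) {
  cat(sprintf(
    "<trn_degree_stats> direction=%s, %d nodes, max degree %d, mean clustering %.3f\n",
    x$direction, length(x$degrees), max(x$degrees), x$mean_clustering))
  invisible(x)
}

#' @export
tidy.trn_degree_stats <- function(x, ...) x$histogram

# Local clustering on the undirected simple projection; nodes of projected
# degree < 2 contribute 0 to the mean.
clustering_by_degree <- function(net) {
  g <- as_igraph(net)
  gu <- igraph::as_undirected(igraph::simplify(g), mode = "collapse")
  cc <- igraph::transitivity(gu, type = "local", isolates = "zero")
  cc[is.nan(cc)] <- 0
  deg <- igraph::degree(gu)
  list(
    by_degree = tibble(degree = as.integer(deg), cc = cc) %>%
      group_by(.data$degree) %>%
      summarise(mean_clustering = mean(.data$cc), .groups = "drop"),
    mean = mean(cc)
  )
}

#' Average clustering coefficient
#'
#' Mean local clustering coefficient over all nodes, computed on the
#' undirected simple projection of the network (self-loops removed,
#' reciprocal edges merged). Nodes with projected degree below 2 contribute
#' 0, matching the convention used for hierarchical-modularity analyses of
#' regulatory networks.
#'
#' @param net A [trn] object with at least one node.
#' @return A number in `[0, 1]`.
#' @export
mean_clustering <- function(net) {
  stopifnot(inherits(net, "trn"), n_nodes(net) >= 1)
  clustering_by_degree(net)$mean
}

#' Complementary cumulative degree distribution
#'
#' For each observed degree `k >= 1`, the fraction of positive-degree nodes
#' with degree at least `k`. The CCDF is non-increasing and equals 1 at the
#' minimum observed positive degree. A power law `P(k) ~ k^-gamma` appears
#' in the CCDF as a straight log-log line of slope `-(gamma - 1)`.
#'
#' @param x A numeric vector of node degrees, or a `trn_degree_stats`
#'   object (whose stored CCDF is returned).
#' @return A tibble with columns `degree` and `ccdf`, sorted by degree.
#' @export
ccdf <- function(x) UseMethod("ccdf")

#' @export
ccdf.trn_degree_stats <- function(x) x$ccdf

#' @export
ccdf.numeric <- function(x) {
  x <- x[!is.na(x)]
  pos <- x[x >= 1]
  if (length(pos) == 0) {
    trn_abort("All degrees are zero; the CCDF is undefined.",
      "degenerate_distribution_error")
  }
  ks <- sort(unique(pos))
  tibble(degree = ks,
         ccdf = vapply(ks, function(k) sum(pos >= k), numeric(1)) / length(pos))
}

#' Least-squares tail fit of a degree CCDF
#'
#' Fits a straight line to the CCDF by ordinary least squares: on log-log
#' axes for the power-law model (`log10 F ~ log10 k`), on lin-log axes for
#' the exponential model (`log10 F ~ k`). The coefficient of determination
#' R-squared of each regression measures goodness of fit, and the two models
#' are compared with [compare_models()]. For the power-law model the implied
#' `P(k)` exponent is the CCDF slope minus one (a density `k^-gamma` has
#' CCDF slope `-(gamma - 1)`); both numbers are reported to avoid the
#' classic off-by-one ambiguity.
#'
#' @param ccdf_points A tibble as returned by [ccdf()] (columns `degree`,
#'   `ccdf`).
#' @param model `"power_law"` or `"exponential"`.
#' @param k_min Lower fit cutoff; points with `degree < k_min` are dropped.
#'   Defaults to 1 (fit over all positive degrees).
#' @return A `trn_tailfit` object; see [tidy()] and [glance()] methods.
#' @examples
#' pts <- tibble::tibble(degree = 1:50, ccdf = (1:50)^-1.11)
#' glance(fit_tail(pts, "power_law"))
#' @export
fit_tail <- function(ccdf_points, model = c("power_law", "exponential"),
                     k_min = 1) {
  model <- match.arg(model)
  pts <- as_tibble(ccdf_points)
  stopifnot(all(c("degree", "ccdf") %in% names(pts)))
  pts <- pts[pts$degree >= k_min & pts$ccdf > 0, ]
  if (n_distinct(pts$degree) < 3) {
    trn_abort("Need at least 3 distinct degree values to fit a tail model.",
      "insufficient_data_error")
  }
  x <- if (model == "power_law") log10(pts$degree) else pts$degree
  y <- log10(pts$ccdf)
  fit <- stats::lm(y ~ x)
  # summary.lm warns on numerically exact fits; those are legitimate here
  r2 <- suppressWarnings(summary(fit)$r.squared)
  slope <- unname(stats::coef(fit)[2])
  structure(
    list(model = model, slope = slope,
         intercept = unname(stats::coef(fit)[1]),
         r_squared = r2,
         implied_exponent = if (model == "power_law") slope - 1 else NA_real_,
         fit_range = c(min(pts$degree), max(pts$degree)),
         n_points = nrow(pts)),
    class = "trn_tailfit"
  )
}

#' @export
print.trn_tailfit <- function(x, ...) {
  cat(sprintf("<trn_tailfit> %s: slope %.4f, R^2 %.4f over k in [%g, %g]\n",
              x$model, x$slope, x$r_squared, x$fit_range[1], x$fit_range[2]))
  if (x$model == "power_law") {
    cat(sprintf("  implied P(k) exponent: %.4f\n", x$implied_exponent))
  }
  invisible(x)
}

#' @export
tidy.trn_tailfit <- function(x, ...) {
  tibble(term = c("intercept", "slope"),
         estimate = c(x$intercept, x$slope))
}

#' @export
glance.trn_tailfit <- function(x, ...) {
  tibble(model = x$model, slope = x$slope, intercept = x$intercept,
         r_squared = x$r_squared, implied_exponent = x$implied_exponent,
         k_min = x$fit_range[1], k_max = x$fit_range[2],
         n_points = x$n_points)
}

#' Choose between power-law and exponential tail fits
#'
#' Returns the model with the higher R-squared. Both fits must come from the
#' same CCDF point set (equal fit range and point count). Ties go to the
#' power law with a warning.
#'
#' @param pl,ex `trn_tailfit` objects for the power-law and exponential
#'   models.
#' @return `"power_law"` or `"exponential"`.
#' @export
compare_models <- function(pl, ex) {
  stopifnot(inherits(pl, "trn_tailfit"), inherits(ex, "trn_tailfit"))
  if (pl$model != "power_law" || ex$model != "exponential") {
    trn_abort("`pl` must be a power-law fit and `ex` an exponential fit.",
      "invalid_argument")
  }
  if (!identical(pl$fit_range, ex$fit_range) || pl$n_points != ex$n_points) {
    trn_abort("Fits were computed on different point sets.", "fit_range_error")
  }
  if (pl$r_squared == ex$r_squared) {
    trn_warn("Tied R-squared; preferring the power-law model.", "model_tie")
    return("power_law")
  }
  if (pl$r_squared > ex$r_squared) "power_law" else "exponential"
}

#' Plot a degree CCDF on log-log axes
#'
#' @param object A `trn_degree_stats` object.
#' @param fit Optional `trn_tailfit` to overlay as a line.
#' @param ... Ignored.
#' @return A [ggplot2::ggplot] object.
#' @export
autoplot.trn_degree_stats <- function(object, fit = NULL, ...) {
  p <- ggplot2::ggplot(object$ccdf,
                       ggplot2::aes(x = .data$degree, y = .data$ccdf)) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "degree k",
                  y = "P(K >= k)",
                  title = sprintf("%s-degree CCDF", object$direction))
  if (!is.null(fit)) {
    ks <- object$ccdf$degree
    yhat <- if (fit$model == "power_law") {
      10^(fit$intercept + fit$slope * log10(ks))
    } else {
      10^(fit$intercept + fit$slope * ks)
    }
    p <- p + ggplot2::geom_line(
      data = tibble(degree = ks, ccdf = yhat),
      ggplot2::aes(x = .data$degree, y = .data$ccdf), colour = "red")
  }
  p
}
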