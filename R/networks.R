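#' Filter a specificity matrix by occurrence across habitats
#'
#' Occurrence is defined as positive specificity in a habitat column.
#' Retains taxa occurring in at least `min_count` habitats, or at least
#' `ceiling(min_fraction * H)` habitats when a fraction is given (so a 5%
#' threshold over 318 habitats keeps taxa occurring in >= 16). A
#' threshold that removes every taxon is a warning, not an error.
#'
#' @param spec a `specificity_matrix`.
#' @param min_fraction minimum fraction of habitat columns with positive
#'   specificity (mutually exclusive with `min_count`).
#' @param min_count absolute minimum number of habitats.
#' @return the filtered `specificity_matrix`.
#' @export
filter_by_occurrence <- function(spec, min_fraction = NULL, min_count = NULL) {
  stopifnot(inherits(spec, "specificity_matrix"))
  if (is.null(min_fraction) == is.null(min_count))
    stop("give exactly one of min_fraction or min_count")
  H <- ncol(spec$delta)
  thr <- if (!is.null(min_count)) {
    if (min_count < 0 || min_count > H) stop("min_count out of range")
    min_count
  } else {
    if (min_fraction < 0 || min_fraction > 1) stop("min_fraction out of range")
    ceiling(min_fraction * H)
  }
  keep <- rowSums(spec$delta > 0) >= thr
  if (!any(keep)) warning("occurrence filter removed every taxon")
  out <- spec
  out$delta <- spec$delta[keep, , drop = FALSE]
  out$A <- spec$A[keep, , drop = FALSE]
  out$B <- spec$B[keep, , drop = FALSE]
  out$zero_total <- intersect(spec$zero_total, rownames(out$delta))
  out
}

# Spearman rho and two-sided p for one pair of vectors. The default is
# the large-sample t approximation t = rho * sqrt((n-2)/(1-rho^2)); for
# n <= 9 columns an exact p (via stats::cor.test) can be requested.
.spearman_pair <- function(x, y, method = "t") {
  n <- length(x)
  rho <- stats::cor(rank(x), rank(y))
  if (method == "exact" && n <= 9) {
    p <- suppressWarnings(
      stats::cor.test(x, y, method = "spearman", exact = TRUE)$p.value)
  } else {
    if (abs(rho) >= 1) {
      p <- 0
    } else {
      tstat <- rho * sqrt((n - 2) / (1 - rho^2))
      p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    }
  }
  c(rho = rho, p = p)
}

#' Build a specificity-correlation network
#'
#' Nodes are either taxa (`mode = "taxon"`, correlating rows of the delta
#' matrix across habitat columns) or habitats (`mode = "habitat"`,
#' correlating columns across taxa -- e.g., host classes correlated in
#' their microbial specificity profiles). For every unordered node pair a
#' Spearman correlation and two-sided p-value are computed, p-values are
#' FDR-adjusted (Benjamini-Hochberg) across all tested pairs, and edges
#' with q <= alpha are retained with their sign. Pairs involving a
#' constant vector have undefined rank correlation and are skipped (ids
#' in the `skipped` attribute).
#'
#' @param spec a (typically occurrence-filtered) `specificity_matrix`.
#' @param mode `"taxon"` or `"habitat"`.
#' @param alpha FDR level for edge retention (default 0.05).
#' @param method p-value method: `"t"` (large-sample approximation,
#'   default) or `"exact"` (exact null distribution, only for <= 9
#'   observations per vector).
#' @return object of class `ssd_network`: list with `nodes`, `edges`
#'   (data.frame u, v, rho, p, q_value, sign), `mode`, `alpha`; degree
#'   annotations are in `degree` for use by external layout tools.
#' @export
build_network <- function(spec, mode = c("taxon", "habitat"), alpha = 0.05,
                          method = c("t", "exact")) {
  stopifnot(inherits(spec, "specificity_matrix"))
  mode <- match.arg(mode)
  method <- match.arg(method)
  mat <- if (mode == "taxon") spec$delta else t(spec$delta)
  if (ncol(mat) < 3)
    stop("need >= 3 observations per node for rank correlation")
  nodes <- rownames(mat)
  const <- apply(mat, 1, function(r) length(unique(r)) == 1)
  pairs <- utils::combn(which(!const), 2)
  stats_ <- apply(pairs, 2, function(ix)
    .spearman_pair(mat[ix[1], ], mat[ix[2], ], method))
  edges <- data.frame(u = nodes[pairs[1, ]], v = nodes[pairs[2, ]],
                      rho = stats_["rho", ], p = stats_["p", ])
  edges$q_value <- fdr_adjust(edges$p)
  edges <- edges[edges$q_value <= alpha, , drop = FALSE]
  edges$sign <- ifelse(edges$rho > 0, 1L, -1L)
  rownames(edges) <- NULL
  deg <- table(factor(c(edges$u, edges$v), levels = nodes))
  skipped <- nodes[const]
  if (length(skipped))
    message("skipped constant node(s): ", paste(skipped, collapse = ", "))
  structure(list(nodes = nodes, edges = edges,
                 mode = if (mode == "taxon") "taxon_over_habitats"
                        else "habitat_over_taxa",
                 alpha = alpha,
                 degree = stats::setNames(as.integer(deg), nodes)),
            skipped = skipped, class = "ssd_network")
}

#' @export
print.ssd_network <- function(x, ...) {
  cat(sprintf("ssd_network (%s): %d nodes, %d edges (alpha = %g)\n",
              x$mode, length(x$nodes), nrow(x$edges), x$alpha))
  pr <- pn_ratio(x)
  cat("  PN ratio:", if (is.na(pr)) "undefined (no edges)" else
    if (is.infinite(pr)) "infinity (no negative edges)" else
      format(pr), "\n")
  invisible(x)
}

#' Positive-to-negative edge ratio of a network
#'
#' The ratio of positive to negative retained edges. `Inf` when the
#' network has positive edges but no negative ones, 0 when only negative
#' edges exist, and `NA` (undefined) for an edgeless network.
#'
#' @param network an `ssd_network`.
#' @return a non-negative real, `Inf`, or `NA`.
#' @export
pn_ratio <- function(network) {
  stopifnot(inherits(network, "ssd_network"))
  pos <- sum(network$edges$sign > 0)
  neg <- sum(network$edges$sign < 0)
  if (pos + neg == 0) return(NA_real_)
  if (neg == 0) return(Inf)
  pos / neg
}

#' Export a network
#'
#' `write_edge_list` writes a TSV (u, v, rho, p, q_value, sign);
#' `write_network_graphml` writes GraphML via igraph with node degree
#' annotated so external tools can render core/periphery layouts.
#'
#' @param network an `ssd_network`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(network, path) {
  stopifnot(inherits(network, "ssd_network"))
  utils::write.table(network$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_edge_list
#' @export
write_network_graphml <- function(network, path) {
  stopifnot(inherits(network, "ssd_network"))
  if (!requireNamespace("igraph", quietly = TRUE))
    stop("the 'igraph' package is required for GraphML export")
  g <- igraph::graph_from_data_frame(
    network$edges, directed = FALSE,
    vertices = data.frame(name = network$nodes,
                          degree = network$degree[network$nodes]))
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
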