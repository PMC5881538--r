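# Condition-specific co-expression networks. Edges are Pearson correlations
# between features over the samples of one condition, kept when |r| clears
# the correlation cutoff and the BH-adjusted t-distribution p-value clears
# the significance cutoff. Downstream: degree centrality, the W-core (the
# maximal subgraph in which every node keeps at least W neighbours inside
# the subgraph), and differential hub ranking by between-condition degree
# differences.

#' Build a condition-specific co-expression network
#'
#' @param norm_counts Tibble (`feature_id` + numeric sample columns) or
#'   matrix of normalized expression values (e.g. size-factor normalized,
#'   log2(x+1) counts).
#' @param samples Character vector naming the sample columns of one
#'   condition (at least 3; the t-based correlation test needs df = n - 2
#'   > 0).
#' @param condition Label stored on the network.
#' @param r_cut Absolute-correlation cutoff (default 0.9).
#' @param p_cut BH-adjusted significance cutoff (default 0.05).
#' @return A `coexp_network`: list with `condition`, `nodes` (features
#'   entering the test) and `edges` (`from`, `to`, `r`, `p_value`, `fdr`),
#'   `from < to`.
#' @export
coexp_network <- function(norm_counts, samples, condition = "condition",
                          r_cut = 0.9, p_cut = 0.05) {
  m <- if (is.matrix(norm_counts)) norm_counts else {
    counts_matrix(norm_counts)
  }
  missing <- setdiff(samples, colnames(m))
  if (length(missing) > 0) {
    abort(sprintf("samples absent from data: %s",
                  paste(missing, collapse = ", ")))
  }
  if (length(samples) < 3) {
    abort("need >= 3 samples: correlation significance is undefined at df <= 0")
  }
  sub <- m[, samples, drop = FALSE]
  sds <- apply(sub, 1, stats::sd)
  if (any(sds == 0)) {
    warn(sprintf("excluding %d zero-variance feature(s) from the network",
                 sum(sds == 0)))
    sub <- sub[sds > 0, , drop = FALSE]
  }
  nodes <- rownames(sub)
  nfeat <- nrow(sub)
  edges <- tibble(from = character(), to = character(), r = numeric(),
                  p_value = numeric(), fdr = numeric())
  if (nfeat >= 2) {
    cm <- cor(t(sub))
    iu <- which(upper.tri(cm), arr.ind = TRUE)
    r <- cm[iu]
    nn <- length(samples)
    tstat <- r * sqrt((nn - 2) / pmax(1 - r^2, 1e-12))
    p <- 2 * pt(-abs(tstat), df = nn - 2)
    p[abs(r) >= 1 - 1e-12] <- 0
    fdr <- bh_fdr(p)
    keep <- abs(r) >= r_cut & fdr <= p_cut
    edges <- tibble(
      from = nodes[iu[keep, 1]],
      to = nodes[iu[keep, 2]],
      r = r[keep], p_value = p[keep], fdr = fdr[keep]
    )
    swap <- edges$from > edges$to
    tmp <- edges$from[swap]
    edges$from[swap] <- edges$to[swap]
    edges$to[swap] <- tmp
    edges <- arrange(edges, .data$from, .data$to)
  }
  structure(
    list(condition = condition, nodes = nodes, edges = edges),
    class = "coexp_network"
  )
}

#' Construct a network from an explicit edge list
#'
#' @param edges Tibble with `from`, `to` columns (extra columns kept).
#' @param nodes Optional node universe (defaults to the endpoints).
#' @param condition Label.
#' @return A `coexp_network`.
#' @export
network_from_edges <- function(edges, nodes = NULL,
                               condition = "condition") {
  assert_tibble_cols(edges, c("from", "to"), "edges")
  edges <- edges[edges$from != edges$to, , drop = FALSE]
  if (is.null(nodes)) nodes <- sort(union(edges$from, edges$to))
  structure(list(condition = condition, nodes = nodes,
                 edges = as_tibble(edges)),
            class = "coexp_network")
}

#' Degree centrality: the number of links a node has
#'
#' @param network A `coexp_network`.
#' @return Tibble `node`, `degree` covering every node of the network
#'   (isolated nodes have degree 0).
#' @export
degree_centrality <- function(network) {
  stopifnot(inherits(network, "coexp_network"))
  deg <- table(factor(c(network$edges$from, network$edges$to),
                      levels = network$nodes))
  tibble(node = network$nodes, degree = as.integer(deg))
}

#' Extract the W-core of a network
#'
#' The maximal subgraph in which every node is connected to at least `W`
#' other nodes of the subgraph, obtained by iteratively pruning nodes of
#' degree below `W` until a fixpoint.
#'
#' @param network A `coexp_network`.
#' @param W Non-negative integer.
#' @return The `coexp_network` restricted to the W-core (possibly empty).
#' @export
w_core <- function(network, W) {
  stopifnot(inherits(network, "coexp_network"), W >= 0)
  nodes <- network$nodes
  edges <- network$edges
  repeat {
    deg <- table(factor(c(edges$from, edges$to), levels = nodes))
    drop_nodes <- nodes[deg < W]
    if (length(drop_nodes) == 0 || length(nodes) == 0) break
    nodes <- setdiff(nodes, drop_nodes)
    edges <- edges[edges$from %in% nodes & edges$to %in% nodes, ,
                   drop = FALSE]
  }
  structure(list(condition = network$condition, nodes = nodes,
                 edges = edges),
            class = "coexp_network")
}

#' Rank differential core regulators between two condition networks
#'
#' Nodes are ranked by the absolute degree difference between the two
#' networks (missing nodes count as degree 0); ties go to the larger
#' maximum degree, then to the lexicographically smaller id.
#'
#' @param network_a,network_b `coexp_network` objects.
#' @param top_k Number of nodes to return (default all).
#' @return Tibble `node`, `degree_a`, `degree_b`, `degree_diff`, ranked.
#' @export
core_regulators <- function(network_a, network_b, top_k = Inf) {
  da <- degree_centrality(network_a)
  db <- degree_centrality(network_b)
  universe <- sort(union(da$node, db$node))
  ga <- setNames(da$degree, da$node)[universe]
  gb <- setNames(db$degree, db$node)[universe]
  ga[is.na(ga)] <- 0L
  gb[is.na(gb)] <- 0L
  out <- tibble(
    node = universe,
    degree_a = as.integer(ga),
    degree_b = as.integer(gb),
    degree_diff = abs(as.integer(ga) - as.integer(gb))
  ) |>
    arrange(desc(.data$degree_diff),
            desc(pmax(.data$degree_a, .data$degree_b)),
            .data$node)
  head(out, n = if (is.finite(top_k)) top_k else nrow(out))
}

#' Normalize a count table for co-expression analysis
#'
#' Size-factor normalization followed by log2(x + 1).
#'
#' @param counts Counts tibble or matrix.
#' @param factors Optional precomputed size factors.
#' @return Matrix of normalized values (features x samples).
#' @export
normalize_log2 <- function(counts, factors = NULL) {
  m <- if (is.matrix(counts)) counts else counts_matrix(counts)
  if (is.null(factors)) factors <- size_factors(m)
  log2(sweep(m, 2, factors, "/") + 1)
}
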