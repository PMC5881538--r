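# broom-style verbs for the package's fitted objects.

#' Tidy a differential-expression result
#'
#' @param x A `circ_de` object from [run_de()].
#' @param ... Unused.
#' @return A plain tibble of per-feature results.
#' @export
tidy.circ_de <- function(x, ...) {
  as_tibble(unclass(x)[names(x)])
}

#' One-row summary of a differential-expression result
#'
#' @param x A `circ_de` object.
#' @param ... Unused.
#' @return Tibble with feature counts by status and the thresholds used.
#' @export
glance.circ_de <- function(x, ...) {
  th <- attr(x, "thresholds")
  tibble(
    n_features = nrow(x),
    n_up = sum(x$status == "up"),
    n_down = sum(x$status == "down"),
    n_unchanged = sum(x$status == "unchanged"),
    fc_up = th[["fc_up"]],
    fc_down = th[["fc_down"]],
    max_fdr = th[["max_fdr"]]
  )
}

#' Tidy a co-expression network into its edge list
#'
#' @param x A `coexp_network`.
#' @param ... Unused.
#' @return Tibble of edges.
#' @export
tidy.coexp_network <- function(x, ...) {
  x$edges
}

#' One-row summary of a co-expression network
#'
#' @param x A `coexp_network`.
#' @param ... Unused.
#' @return Tibble with node/edge counts and degree summaries.
#' @export
glance.coexp_network <- function(x, ...) {
  deg <- degree_centrality(x)
  tibble(
    condition = x$condition,
    n_nodes = length(x$nodes),
    n_edges = nrow(x$edges),
    max_degree = if (nrow(deg)) max(deg$degree) else 0L,
    mean_degree = if (nrow(deg)) mean(deg$degree) else 0
  )
}

#' @export
print.coexp_network <- function(x, ...) {
  cat(sprintf("<coexp_network '%s': %d nodes, %d edges>\n",
              x$condition, length(x$nodes), nrow(x$edges)))
  invisible(x)
}
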