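# Fisher-exact (hypergeometric) over-representation analysis against a
# user-supplied gene-set collection, with BH correction; GO-tree induction
# over a term DAG; and a pathway-relation network built from shared
# differentially expressed genes.

#' One-sided Fisher exact enrichment
#'
#' For each term with at least one background gene, the upper
#' hypergeometric tail P(X >= k) of the query/term overlap is computed,
#' followed by BH adjustment across the tested terms.
#'
#' @param query Character vector of query gene ids (must be a subset of
#'   `background`).
#' @param collection Tibble with `term_id`, `gene_id` and optionally
#'   `term_name`.
#' @param background Character vector of background gene ids.
#' @return Tibble `term_id` (+`term_name`), `k` (overlap), `K` (term size in
#'   background), `n` (query size), `N` (background size), `p_value`, `fdr`.
#' @export
fisher_enrichment <- function(query, collection, background) {
  assert_tibble_cols(collection, c("term_id", "gene_id"), "collection")
  query <- unique(query)
  background <- unique(background)
  stray <- setdiff(query, background)
  if (length(stray) > 0) {
    abort(sprintf("query genes absent from background: %s",
                  paste(stray, collapse = ", ")))
  }
  coll <- collection[collection$gene_id %in% background, , drop = FALSE]
  N <- length(background)
  n <- length(query)
  res <- coll |>
    group_by(.data$term_id) |>
    summarise(
      term_name = if ("term_name" %in% names(coll)) {
        first(.data$term_name)
      } else NA_character_,
      K = n_distinct(.data$gene_id),
      k = n_distinct(intersect(.data$gene_id, query)),
      .groups = "drop"
    )
  if (nrow(res) == 0) {
    return(tibble(term_id = character(), term_name = character(),
                  k = integer(), K = integer(), n = integer(), N = integer(),
                  p_value = numeric(), fdr = numeric()))
  }
  res <- res |>
    mutate(
      n = n, N = N,
      p_value = phyper(.data$k - 1, .data$K, N - .data$K, n,
                       lower.tail = FALSE)
    )
  res$fdr <- bh_fdr(res$p_value)
  res |>
    select(all_of(c("term_id", "term_name", "k", "K", "n", "N",
                    "p_value", "fdr"))) |>
    arrange(.data$p_value, .data$term_id)
}

# ancestors of a set of terms in a DAG given as (term_id, parent_id) edges
ancestor_closure <- function(terms, dag) {
  seen <- unique(terms)
  frontier <- seen
  while (length(frontier) > 0) {
    parents <- unique(dag$parent_id[dag$term_id %in% frontier])
    frontier <- setdiff(parents, seen)
    seen <- union(seen, frontier)
  }
  seen
}

check_acyclic <- function(dag) {
  # peel nodes without outgoing (child -> parent) edges; a cycle never peels
  nodes <- union(dag$term_id, dag$parent_id)
  edges <- dag[, c("term_id", "parent_id")]
  repeat {
    if (length(nodes) == 0) break
    leaves <- nodes[!(nodes %in% edges$term_id)]
    if (length(leaves) == 0) break
    nodes <- setdiff(nodes, leaves)
    edges <- edges[!(edges$parent_id %in% leaves), , drop = FALSE]
  }
  if (length(nodes) > 0) abort("cycle detected in term DAG")
  invisible(TRUE)
}

#' Induce a GO tree from significant terms
#'
#' Nodes are terms with `p_value < p_cut` plus all their ancestors up to the
#' root(s); edges are the DAG edges among the included nodes. When the
#' enrichment carries a `direction` column (separate up/down queries), each
#' node is annotated with the direction(s) in which it is significant.
#'
#' @param enrichment Enrichment tibble ([fisher_enrichment()]), optionally
#'   with a `direction` column.
#' @param dag Tibble of DAG edges: `term_id`, `parent_id`.
#' @param p_cut Significance cut on the raw p-value (default 0.01).
#' @return List with `nodes` (term_id, significant, direction) and `edges`
#'   tibbles.
#' @export
go_tree <- function(enrichment, dag, p_cut = 0.01) {
  assert_tibble_cols(dag, c("term_id", "parent_id"), "dag")
  if (nrow(dag) > 0) check_acyclic(dag)
  sig <- enrichment[enrichment$p_value < p_cut, , drop = FALSE]
  if (nrow(sig) == 0) {
    return(list(
      nodes = tibble(term_id = character(), significant = logical(),
                     direction = character()),
      edges = tibble(term_id = character(), parent_id = character())
    ))
  }
  nodes <- ancestor_closure(unique(sig$term_id), dag)
  dir_tab <- if ("direction" %in% names(sig)) {
    sig |>
      group_by(.data$term_id) |>
      summarise(direction = paste(sort(unique(.data$direction)),
                                  collapse = "/"),
                .groups = "drop")
  } else {
    tibble(term_id = unique(sig$term_id), direction = NA_character_)
  }
  node_tbl <- tibble(term_id = sort(nodes)) |>
    mutate(significant = .data$term_id %in% sig$term_id) |>
    left_join(dir_tab, by = "term_id")
  edge_tbl <- dag[dag$term_id %in% nodes & dag$parent_id %in% nodes, ,
                  drop = FALSE] |>
    as_tibble() |>
    distinct() |>
    arrange(.data$term_id, .data$parent_id)
  list(nodes = node_tbl, edges = edge_tbl)
}

#' Build a pathway relation network from enriched pathways
#'
#' Nodes are significantly enriched pathways, labelled up or down by the
#' majority direction of their differentially expressed genes; two pathways
#' are linked iff they share at least one DE gene, with the Jaccard index of
#' their DE-gene sets as edge weight. Core pathways are the top-degree
#' nodes.
#'
#' @param enrichment Enrichment tibble for the pathway collection.
#' @param collection Gene-set tibble (`term_id`, `gene_id`).
#' @param de_results Tibble with `feature_id` and `status` (`up`/`down`).
#' @param max_fdr Enrichment significance threshold (default 0.05, on FDR).
#' @return List with `nodes` (term_id, n_de_genes, direction, degree,
#'   is_core) and `edges` (term_a, term_b, shared, weight) tibbles.
#' @export
pathway_network <- function(enrichment, collection, de_results,
                            max_fdr = 0.05) {
  assert_tibble_cols(de_results, c("feature_id", "status"), "de_results")
  de_genes <- de_results$feature_id[de_results$status %in% c("up", "down")]
  de_dir <- setNames(de_results$status, de_results$feature_id)
  keep <- enrichment$term_id[enrichment$fdr < max_fdr]
  if (length(keep) == 0) {
    return(list(
      nodes = tibble(term_id = character(), n_de_genes = integer(),
                     direction = character(), degree = integer(),
                     is_core = logical()),
      edges = tibble(term_a = character(), term_b = character(),
                     shared = integer(), weight = numeric())
    ))
  }
  sets <- lapply(setNames(keep, keep), function(tid) {
    intersect(collection$gene_id[collection$term_id == tid], de_genes)
  })
  nodes <- tibble(
    term_id = keep,
    n_de_genes = unname(vapply(sets, length, integer(1))),
    direction = unname(vapply(sets, function(gs) {
      if (length(gs) == 0) return("none")
      nu <- sum(de_dir[gs] == "up")
      nd <- sum(de_dir[gs] == "down")
      if (nu >= nd) "up" else "down"
    }, character(1)))
  )
  edges <- list()
  if (length(keep) >= 2) {
    cmb <- utils::combn(sort(keep), 2)
    for (ci in seq_len(ncol(cmb))) {
      a <- cmb[1, ci]; b <- cmb[2, ci]
      shared <- length(intersect(sets[[a]], sets[[b]]))
      if (shared >= 1) {
        uni <- length(union(sets[[a]], sets[[b]]))
        edges[[length(edges) + 1L]] <- tibble(
          term_a = a, term_b = b, shared = shared, weight = shared / uni
        )
      }
    }
  }
  edges <- if (length(edges)) bind_rows(edges) else {
    tibble(term_a = character(), term_b = character(),
           shared = integer(), weight = numeric())
  }
  deg <- table(factor(c(edges$term_a, edges$term_b), levels = keep))
  nodes$degree <- as.integer(deg[nodes$term_id])
  nodes$is_core <- nodes$degree == max(nodes$degree) & nodes$degree > 0
  list(nodes = arrange(nodes, desc(.data$degree), .data$term_id),
       edges = edges)
}

#' Read a gene-set collection from TSV
#'
#' Expects columns `gene_id`, `term_id` and optionally `term_name`.
#'
#' @param path TSV path.
#' @return Tibble.
#' @export
read_gene_sets <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  assert_tibble_cols(tab, c("gene_id", "term_id"), path)
  tab
}
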