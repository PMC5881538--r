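# Synthetic functional annotation: random gene-to-term memberships plus a
# small rooted term DAG, enough to exercise enrichment, GO-tree induction
# and the pathway network without external databases.

#' Simulate a gene-set collection and term DAG
#'
#' Terms are arranged in a three-level rooted DAG (root, branches, leaves);
#' leaf terms receive random gene memberships.
#'
#' @param gene_ids Character vector of gene ids to annotate.
#' @param n_terms Number of leaf terms (default 10).
#' @param genes_per_term Integer range of genes per leaf term.
#' @param seed Integer seed.
#' @return List with `collection` (tibble `term_id`, `term_name`,
#'   `gene_id`) and `dag` (tibble `term_id`, `parent_id`).
#' @export
simulate_gene_sets <- function(gene_ids, n_terms = 10L,
                               genes_per_term = c(5L, 25L), seed = 1L) {
  set.seed(as.integer(seed))
  if (length(gene_ids) == 0) abort("gene_ids must be non-empty")
  leaves <- sprintf("T:%04d", seq_len(n_terms))
  branches <- sprintf("B:%02d", seq_len(max(1L, n_terms %/% 4L)))
  collection <- bind_rows(lapply(seq_len(n_terms), function(i) {
    size <- min(length(gene_ids),
                resample(genes_per_term[1]:genes_per_term[2]))
    tibble(
      term_id = leaves[i],
      term_name = sprintf("synthetic process %d", i),
      gene_id = sample(gene_ids, size)
    )
  }))
  dag <- bind_rows(
    tibble(term_id = leaves,
           parent_id = branches[(seq_len(n_terms) - 1L) %% length(branches) + 1L]),
    tibble(term_id = branches, parent_id = "ROOT")
  )
  list(collection = collection, dag = dag)
}
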