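# End-to-end orchestration: QC -> linear alignment -> backsplice detection
# -> junction quantification -> gene counting -> differential expression
# (mRNA / lncRNA / circRNA separately) -> enrichment -> co-expression
# networks. All interchange is through files under the output directory;
# the run report records counts in and out of every stage.

#' Read a genome bundle from FASTA + GTF
#'
#' @param fasta_path Genome FASTA.
#' @param gtf_path Annotation GTF (1-based inclusive; converted to the
#'   package's 0-based half-open coordinates) with `gene_id` and
#'   `transcript_biotype` attributes; exon and optional
#'   five_prime_utr/three_prime_utr features.
#' @return A `genome_bundle`.
#' @export
read_genome_bundle <- function(fasta_path, gtf_path) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  sequences <- setNames(as.character(seqs), names(seqs))

  gr <- rtracklayer::import(gtf_path)
  tab <- as_tibble(as.data.frame(gr))
  tab$chrom <- as.character(tab$seqnames)
  tab$strand <- as.character(tab$strand)
  tab$start0 <- tab$start - 1L  # GTF is 1-based inclusive
  tab$end0 <- tab$end
  if (!"transcript_biotype" %in% names(tab)) {
    tab$transcript_biotype <- "mRNA"
  }

  ex <- tab[tab$type == "exon", , drop = FALSE]
  exons <- ex |>
    group_by(.data$gene_id) |>
    arrange(.data$start0, .by_group = TRUE) |>
    mutate(
      exon_index = row_number(),
      exon_rank = if (first(.data$strand) == "+") {
        row_number()
      } else {
        rev(row_number())
      }
    ) |>
    ungroup() |>
    select(gene_id = "gene_id", chrom = "chrom", strand = "strand",
           exon_index = "exon_index", exon_rank = "exon_rank",
           start = "start0", end = "end0") |>
    arrange(.data$gene_id, .data$start)

  genes <- exons |>
    group_by(.data$gene_id) |>
    summarise(
      chrom = first(.data$chrom), strand = first(.data$strand),
      start = min(.data$start), end = max(.data$end),
      n_exons = n(), .groups = "drop"
    ) |>
    left_join(
      ex |> distinct(.data$gene_id, biotype = .data$transcript_biotype),
      by = "gene_id"
    ) |>
    select(all_of(c("gene_id", "chrom", "strand", "start", "end",
                    "biotype", "n_exons"))) |>
    arrange(.data$gene_id)

  ut <- tab[tab$type %in% c("five_prime_utr", "three_prime_utr"), ,
            drop = FALSE]
  utrs <- if (nrow(ut) > 0) {
    tibble(
      gene_id = ut$gene_id, chrom = ut$chrom, strand = ut$strand,
      type = ifelse(ut$type == "five_prime_utr", "five_utr", "three_utr"),
      start = ut$start0, end = ut$end0
    )
  } else {
    tibble(gene_id = character(), chrom = character(), strand = character(),
           type = character(), start = integer(), end = integer())
  }

  structure(
    list(sequences = sequences, genes = genes, exons = exons, utrs = utrs),
    class = "genome_bundle"
  )
}

default_pipeline_params <- function() {
  list(
    k = 15L,
    max_mismatches = 2L,
    min_segment = 18L,
    segment_mismatch_per = 25L,
    max_span = 1000000L,
    shift_window = 10L,
    min_reads = 2L,
    min_score = 10,
    min_overhang = 6L,
    quant_max_mismatches = 2L,
    fc_up = 2,
    fc_down = 0.5,
    max_fdr = 0.05,
    go_p_cut = 0.01,
    r_cut = 0.9,
    network_p_cut = 0.05,
    qc = list(adaptor = "", min_length_after_trim = 20L)
  )
}

#' Assemble and validate a pipeline configuration
#'
#' @param genome Path to the genome FASTA (or a `genome_bundle` passed via
#'   `bundle`).
#' @param gtf Path to the annotation GTF.
#' @param samples Tibble with `sample_id`, `fastq`, `condition`.
#' @param outdir Output directory (created if needed).
#' @param known_bed Optional BED of known circRNA junctions.
#' @param gene_sets Optional gene-set TSV (`gene_id`, `term_id`).
#' @param go_dag Optional term-DAG TSV (`term_id`, `parent_id`).
#' @param params Named list overriding entries of the default parameter
#'   table (alignment, detection, quantification, DE, enrichment, network
#'   settings — the defaults hold the standard operating point: min_reads 2,
#'   min_score 10, max_span 1e6, min_overhang 6, fold-change 2 / 0.5,
#'   FDR 0.05, GO p 0.01).
#' @param seed Integer seed recorded in the report (stages are themselves
#'   deterministic).
#' @param bundle Optional in-memory `genome_bundle` (skips FASTA/GTF
#'   reading; `genome`/`gtf` may then be `NULL`).
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(genome = NULL, gtf = NULL, samples, outdir,
                            known_bed = NULL, gene_sets = NULL,
                            go_dag = NULL, params = list(), seed = 1L,
                            bundle = NULL) {
  assert_tibble_cols(samples, c("sample_id", "fastq", "condition"),
                     "samples")
  if (is.null(bundle)) {
    for (p in c(genome, gtf)) {
      if (is.null(p) || !file.exists(p)) {
        abort(sprintf("required input path missing or nonexistent: %s",
                      p %||% "(genome/gtf not given)"))
      }
    }
  }
  for (p in c(samples$fastq, known_bed, gene_sets, go_dag)) {
    if (!is.null(p) && !file.exists(p)) {
      abort(sprintf("required input path missing or nonexistent: %s", p))
    }
  }
  prm <- utils::modifyList(default_pipeline_params(), params)
  structure(
    list(genome = genome, gtf = gtf, samples = samples, outdir = outdir,
         known_bed = known_bed, gene_sets = gene_sets, go_dag = go_dag,
         params = prm, seed = as.integer(seed), bundle = bundle),
    class = "pipeline_config"
  )
}

write_tsv_det <- function(x, path) {
  readr::write_tsv(x, path, progress = FALSE)
  invisible(path)
}

#' Run the full pipeline
#'
#' Executes QC, alignment, backsplice detection, junction quantification,
#' gene counting, differential expression per biotype, optional enrichment
#' and GO-tree/pathway networks, and condition co-expression networks,
#' writing all interchange tables under `config$outdir` plus a
#' machine-readable `run_report.json`. Running the same configuration twice
#' produces byte-identical outputs.
#'
#' @param config A [pipeline_config()].
#' @return The run report, invisibly (a nested list).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  prm <- config$params
  set.seed(config$seed)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  out <- function(...) file.path(config$outdir, ...)

  bundle <- config$bundle %||% read_genome_bundle(config$genome, config$gtf)

  report <- list(
    seed = config$seed,
    package_version = as.character(utils::packageVersion("circprofiler")),
    stages = list()
  )

  # --- QC + alignment per sample -----------------------------------------
  sample_ids <- config$samples$sample_id
  first_reads <- read_fastq(config$samples$fastq[1])
  read_length <- if (nrow(first_reads) > 0) {
    max(nchar(first_reads$sequence))
  } else 50L
  index <- build_kmer_index(bundle, k = prm$k, read_length = read_length)

  qc <- do.call(qc_params, prm$qc)
  alignments <- list()
  unmapped <- list()
  qc_stage <- list()
  align_stage <- list()
  for (si in seq_along(sample_ids)) {
    sid <- sample_ids[si]
    raw <- if (si == 1) first_reads else {
      read_fastq(config$samples$fastq[si])
    }
    clean <- filter_reads(raw, qc)
    qc_stage[[sid]] <- list(reads_in = nrow(raw), reads_out = nrow(clean))
    res <- align_linear(clean, index, max_mismatches = prm$max_mismatches)
    alignments[[sid]] <- res$alignments
    unmapped[[sid]] <- res$unmapped
    align_stage[[sid]] <- list(
      reads_in = nrow(clean),
      mapped = nrow(res$alignments),
      unmapped = nrow(res$unmapped)
    )
    write_fastq(res$unmapped, out(sprintf("unmapped_%s.fq", sid)))
  }
  report$stages$qc <- qc_stage
  report$stages$align <- align_stage

  all_aln <- bind_rows(alignments, .id = "sample_id")
  region <- annotate_regions(all_aln, bundle)
  write_tsv_det(region_tally(region), out("region_tally.tsv"))
  write_tsv_det(chromosome_tally(all_aln), out("chromosome_tally.tsv"))

  # --- backsplice detection on the pooled unmapped reads -----------------
  pooled_unmapped <- bind_rows(unmapped)
  det <- detect_circrnas(
    pooled_unmapped, index, bundle,
    min_segment = prm$min_segment, max_span = prm$max_span,
    mismatch_per = prm$segment_mismatch_per,
    shift_window = prm$shift_window,
    min_reads = prm$min_reads, min_score = prm$min_score
  )
  segments <- det$segments
  candidates <- det$candidates
  calls <- det$calls
  if (!is.null(config$known_bed)) {
    calls <- compare_to_known(calls, config$known_bed)
  }
  write_circ_bed(calls, out("circ_calls.bed"))
  write_tsv_det(calls, out("circ_calls.tsv"))
  report$stages$circ_detect <- list(
    unmapped_reads = nrow(pooled_unmapped),
    segments = nrow(segments),
    raw_candidates = nrow(candidates),
    calls = nrow(calls),
    known = if ("novelty" %in% names(calls)) {
      sum(calls$novelty == "known")
    } else NA,
    novel = if ("novelty" %in% names(calls)) {
      sum(calls$novelty == "novel")
    } else NA
  )

  # --- quantification ----------------------------------------------------
  circ_counts <- quantify_circrnas(
    calls, bundle, unmapped, read_length,
    min_overhang = prm$min_overhang,
    max_mismatches = prm$quant_max_mismatches
  )
  write_tsv_det(circ_counts, out("circ_counts.tsv"))
  circ_total <- tibble(
    circ_id = circ_counts$circ_id,
    junction_reads = as.integer(rowSums(as.matrix(
      circ_counts[setdiff(names(circ_counts), "circ_id")]
    )))
  )
  circ_sum <- summarize_circ(calls, circ_total)
  write_tsv_det(circ_sum$summary, out("circ_summary.tsv"))
  report$stages$circ_quant <- list(
    total_backspliced_reads = circ_sum$summary$total_backspliced_reads,
    median_length = circ_sum$summary$median_length
  )

  # --- gene counting -----------------------------------------------------
  gene_counts <- NULL
  for (sid in sample_ids) {
    ct <- count_features(alignments[[sid]], bundle)
    if (is.null(gene_counts)) {
      gene_counts <- ct |> rename(!!sid := "count")
    } else {
      gene_counts[[sid]] <- ct$count
    }
  }
  write_tsv_det(gene_counts, out("gene_counts.tsv"))
  report$stages$counting <- list(
    genes = nrow(gene_counts),
    assigned_total = sum(as.matrix(
      gene_counts[setdiff(names(gene_counts), c("feature_id", "biotype"))]
    ))
  )

  # --- differential expression per biotype -------------------------------
  design <- tibble(sample_id = config$samples$sample_id,
                   condition = config$samples$condition)
  two_cond <- length(unique(design$condition)) == 2 &&
    min(table(design$condition)) >= 2
  de_results <- list()
  if (two_cond) {
    cond_order <- sort(unique(design$condition))
    tables <- list(
      mRNA = gene_counts |> filter(.data$biotype == "mRNA"),
      lncRNA = gene_counts |> filter(.data$biotype == "lncRNA"),
      circRNA = circ_counts |>
        rename(feature_id = "circ_id") |>
        mutate(biotype = "circRNA")
    )
    for (bt in names(tables)) {
      tb <- tables[[bt]]
      usable <- nrow(tb) > 0 &&
        any(rowSums(as.matrix(tb[design$sample_id]) > 0) ==
              nrow(design))
      if (!usable) next
      de <- run_de(tb, design, condition_order = cond_order,
                   fc_up = prm$fc_up, fc_down = prm$fc_down,
                   max_fdr = prm$max_fdr)
      de_results[[bt]] <- de
      write_tsv_det(as_tibble(de), out(sprintf("de_%s.tsv", bt)))
    }
    report$stages$de <- lapply(de_results, function(d) {
      list(tested = nrow(d), up = sum(d$status == "up"),
           down = sum(d$status == "down"))
    })
  }

  # --- enrichment + term networks ----------------------------------------
  if (!is.null(config$gene_sets) && length(de_results) > 0 &&
      !is.null(de_results$mRNA)) {
    collection <- read_gene_sets(config$gene_sets)
    de_m <- de_results$mRNA
    background <- intersect(de_m$feature_id,
                            unique(collection$gene_id))
    enr_parts <- list()
    for (dir in c("up", "down")) {
      qg <- intersect(de_m$feature_id[de_m$status == dir], background)
      if (length(qg) == 0) next
      e <- fisher_enrichment(qg, collection, background)
      e$direction <- dir
      enr_parts[[dir]] <- e
    }
    if (length(enr_parts) > 0) {
      enrichment <- bind_rows(enr_parts)
      write_tsv_det(enrichment, out("enrichment.tsv"))
      report$stages$enrichment <- list(
        terms_tested = length(unique(enrichment$term_id)),
        significant = sum(enrichment$fdr < prm$max_fdr)
      )
      if (!is.null(config$go_dag)) {
        dag <- readr::read_tsv(config$go_dag, show_col_types = FALSE)
        tree <- go_tree(enrichment, dag, p_cut = prm$go_p_cut)
        write_tsv_det(tree$nodes, out("go_tree_nodes.tsv"))
        write_tsv_det(tree$edges, out("go_tree_edges.tsv"))
      }
      pw <- pathway_network(enrichment, collection,
                            de_m |> select(all_of(c("feature_id",
                                                    "status"))),
                            max_fdr = prm$max_fdr)
      write_tsv_det(pw$nodes, out("pathway_network_nodes.tsv"))
      write_tsv_det(pw$edges, out("pathway_network_edges.tsv"))
    }
  }

  # --- condition co-expression networks ----------------------------------
  if (two_cond) {
    norm <- normalize_log2(gene_counts)
    selected <- unique(unlist(lapply(de_results, function(d) {
      d$feature_id[d$status != "unchanged"]
    })))
    selected <- intersect(selected, rownames(norm))
    if (length(selected) < 5) {
      vars <- apply(norm, 1, stats::var)
      selected <- names(sort(vars, decreasing = TRUE))[
        seq_len(min(50L, nrow(norm)))
      ]
    }
    conds <- sort(unique(design$condition))
    nets <- list()
    for (cn in conds) {
      smp <- design$sample_id[design$condition == cn]
      if (length(smp) < 3) next
      net <- coexp_network(norm[selected, , drop = FALSE], smp,
                           condition = cn, r_cut = prm$r_cut,
                           p_cut = prm$network_p_cut)
      nets[[cn]] <- net
      write_tsv_det(net$edges, out(sprintf("coexp_edges_%s.tsv", cn)))
      write_tsv_det(degree_centrality(net),
                    out(sprintf("coexp_degree_%s.tsv", cn)))
    }
    if (length(nets) == 2) {
      regs <- core_regulators(nets[[1]], nets[[2]])
      write_tsv_det(regs, out("core_regulators.tsv"))
      core3 <- w_core(nets[[1]], 3L)
      report$stages$network <- list(
        nodes = length(nets[[1]]$nodes),
        edges_a = nrow(nets[[1]]$edges),
        edges_b = nrow(nets[[2]]$edges),
        w3_core_size = length(core3$nodes)
      )
    }
  }

  jsonlite::write_json(report, out("run_report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(report)
}
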