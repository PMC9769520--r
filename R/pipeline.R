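.log <- function(fmt, ...) {
  message(sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                  sprintf(fmt, ...)))
}

#' Simulate a complete Tn-Seq study to disk
#'
#' Generates genome, annotation, mutant pool and junction-read libraries
#' for a master library, a passaged reference library (neutral growth
#' through the bottleneck) and one or more selective conditions, writing
#' everything as plain text: FASTA genome, GFF3 annotation, FASTQ reads
#' per sample, TSV truth tables, YAML config and a JSON manifest with
#' checksums. All randomness derives from `config$seed`.
#'
#' @param config a [sim_config()].
#' @param out_dir output directory (created if missing).
#' @param conditions character vector of selective condition names.
#' @param frac_affected,s_magnitude passed to
#'   [simulate_fitness_effects()].
#' @param passage_generations generations of neutral growth for the
#'   reference library.
#' @return invisibly, the manifest as a list (`files`, `md5`, `samples`).
#' @export
run_simulate <- function(config, out_dir,
                         conditions = c("selective"),
                         frac_affected = 0.1, s_magnitude = 0.2,
                         passage_generations = 3L) {
  validate_sim_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  .assert(dir.exists(out_dir), paste("cannot create output dir", out_dir))

  .log("simulate: genome (%d bp, %d genes)", config$genome_length,
       config$n_genes)
  gen <- generate_genome(config)
  lib <- simulate_insertion_library(gen$genome, gen$annotation, config)
  fitness <- simulate_fitness_effects(gen$annotation, conditions,
                                      frac_affected, s_magnitude,
                                      seed = config$seed + 11L)

  write_genome_fasta(gen$genome, file.path(out_dir, "genome.fasta"))
  write_annotation_gff3(gen$annotation, file.path(out_dir, "annotation.gff3"))
  write_config_yaml(config, file.path(out_dir, "config.yaml"))
  write_table_tsv(lib$truth$true_sites,
                  file.path(out_dir, "truth_sites.tsv"),
                  comment = sprintf("# seed: %d", config$seed))
  write_table_tsv(data.frame(gene_id = lib$truth$essential_gene_ids),
                  file.path(out_dir, "truth_essential.tsv"))
  write_table_tsv(data.frame(gene_id = rownames(fitness), fitness,
                             check.names = FALSE, stringsAsFactors = FALSE),
                  file.path(out_dir, "truth_fitness.tsv"))

  neutral <- stats::setNames(numeric(0), character(0))
  passage <- simulate_selection(lib$pool, neutral, passage_generations,
                                config, seed = config$seed + 20L)
  pools <- c(list(master = lib$pool, reference = passage),
             stats::setNames(lapply(seq_along(conditions), function(j) {
               simulate_selection(passage, fitness[, j],
                                  config$generations, config,
                                  seed = config$seed + 30L + j)
             }), conditions))

  samples <- data.frame(sample = character(0), condition = character(0),
                        replicate = integer(0), fastq = character(0),
                        stringsAsFactors = FALSE)
  k <- 0L
  for (cond in names(pools)) {
    for (rep in seq_len(config$n_replicates)) {
      k <- k + 1L
      name <- sprintf("%s_rep%d", cond, rep)
      rd <- simulate_reads(pools[[cond]], gen$genome, config,
                           seed = config$seed + 100L + k)
      fq <- file.path(out_dir, paste0(name, ".fastq"))
      write_reads_fastq(rd$reads, fq)
      write_table_tsv(rd$truth, file.path(out_dir,
                                          paste0(name, ".truth.tsv")))
      samples <- rbind(samples, data.frame(sample = name, condition = cond,
                                           replicate = rep,
                                           fastq = basename(fq),
                                           stringsAsFactors = FALSE))
      .log("simulate: wrote %s (%d reads)", basename(fq), nrow(rd$reads))
    }
  }
  write_table_tsv(samples, file.path(out_dir, "sample_sheet.tsv"))

  files <- sort(list.files(out_dir, full.names = FALSE))
  manifest <- list(seed = config$seed,
                   files = files,
                   md5 = as.list(tools::md5sum(file.path(out_dir, files))),
                   samples = samples$sample)
  names(manifest$md5) <- files
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Run the full Tn-Seq analysis on a dataset directory
#'
#' Executes every analysis stage in order on a directory laid out as
#' written by [run_simulate()] (genome FASTA, GFF3 annotation, FASTQ per
#' sample, `sample_sheet.tsv`): read processing to unique sites per
#' sample, library and gap statistics, essentiality calling on the master
#' library, run-length cluster permutation on the protein-coding calls,
#' and NB-Wald enrichment/depletion of every selective condition against
#' the reference library. Any stage failure aborts with the stage name.
#'
#' @param data_dir input directory.
#' @param out_dir results directory (created if missing).
#' @param policy a [filter_policy()].
#' @param oend_marker O-end marker used for trimming; defaults to the one
#'   recorded in `config.yaml` when present.
#' @param dup_len target-site duplication length in bp.
#' @param n_perm permutations for the cluster test.
#' @param alpha_clusters family-wise level for the Holm step-down.
#' @param alpha_fdr BH false-discovery level.
#' @param essential_condition condition whose samples define essentiality
#'   (pooled); default `"master"`.
#' @param reference_condition reference for the differential contrasts;
#'   default `"reference"` (the passaged library).
#' @param circular treat the genome as circular.
#' @param seed integer seed for the permutation stage.
#' @return invisibly, a list with the main stage results (`stats`,
#'   `calls`, `clusters`, `diff`, `summary`).
#' @export
run_pipeline <- function(data_dir, out_dir,
                         policy = filter_policy(),
                         oend_marker = NULL, dup_len = 9L,
                         n_perm = 10000L, alpha_clusters = 0.05,
                         alpha_fdr = 0.1,
                         essential_condition = "master",
                         reference_condition = "reference",
                         circular = TRUE, seed = 1L) {
  stage <- function(name, expr) {
    .log("stage %s: start", name)
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  for (f in c("genome.fasta", "annotation.gff3", "sample_sheet.tsv")) {
    if (!file.exists(file.path(data_dir, f))) {
      stop(sprintf("missing input file: %s", file.path(data_dir, f)),
           call. = FALSE)
    }
  }
  genome <- read_genome_fasta(file.path(data_dir, "genome.fasta"))
  annotation <- read_annotation_gff3(file.path(data_dir, "annotation.gff3"))
  samples <- read_table_tsv(file.path(data_dir, "sample_sheet.tsv"))
  if (is.null(oend_marker)) {
    cfg_path <- file.path(data_dir, "config.yaml")
    .assert(file.exists(cfg_path),
            "oend_marker not given and no config.yaml found")
    oend_marker <- read_config_yaml(cfg_path)$oend_marker
  }

  idx <- genome_index(genome)
  site_tables <- list()
  attrition <- list()
  stage("sites", for (i in seq_len(nrow(samples))) {
    s <- samples$sample[i]
    reads <- read_reads_fastq(file.path(data_dir, samples$fastq[i]))
    rs <- reads_to_sites(reads, idx, oend_marker, dup_len = dup_len,
                         circular = circular)
    site_tables[[s]] <- rs$sites
    attrition[[s]] <- rs$attrition
    write_sites_tsv(rs$sites, file.path(out_dir, paste0(s, ".sites.tsv")),
                    comment = sprintf("# sample: %s", s))
    .log("sites: %s -> %d unique sites", s, nrow(rs$sites))
  })

  cond_of <- stats::setNames(samples$condition, samples$sample)
  pooled <- function(cond) {
    tabs <- site_tables[names(site_tables)[cond_of[names(site_tables)] == cond]]
    unique_sites(do.call(rbind, tabs))
  }

  stats_list <- stage("stats", {
    out <- list()
    for (cond in unique(samples$condition)) {
      sites <- pooled(cond)
      st <- library_stats(sites, nchar(genome), annotation)
      gp <- gap_stats(sites, nchar(genome), circular = circular)
      out[[cond]] <- list(stats = st, gaps = gp)
    }
    tab <- data.frame(
      condition = names(out),
      n_unique_sites = vapply(out, function(x) x$stats$n_unique_sites, 1),
      density_bp_per_insertion =
        vapply(out, function(x) x$stats$density_bp_per_insertion, 1),
      intragenic_fraction =
        vapply(out, function(x) x$stats$intragenic_fraction, 1),
      largest_gap = vapply(out, function(x) x$gaps$largest_gap, 1),
      pct_gaps_le_25bp =
        vapply(out, function(x) x$gaps$fraction_le_25bp, 1))
    write_table_tsv(tab, file.path(out_dir, "library_stats.tsv"))
    out
  })

  calls <- stage("essential", {
    ess_sites <- pooled(essential_condition)
    calls <- call_essentiality(ess_sites, annotation, policy)
    write_table_tsv(calls[, c("gene_id", "verdict",
                              "n_insertions_after_filter",
                              "largest_gap_fraction", "gene_type")],
                    file.path(out_dir, "essentiality_calls.tsv"))
    calls
  })

  clusters <- stage("clusters", {
    pro <- calls$gene_type == "protein"
    labels <- calls$essential[pro]
    cl <- find_clusters(labels)
    if (nrow(cl) > 0) {
      perm <- permutation_pvalues(length(labels), sum(labels),
                                  lengths = sort(unique(cl$length)),
                                  n_perm = n_perm, seed = seed)
      cl <- call_significant_clusters(cl, perm, alpha = alpha_clusters)
      write_table_tsv(as.data.frame(cl),
                      file.path(out_dir, "clusters.tsv"),
                      comment = sprintf("# n_perm: %d, seed: %d", n_perm, seed))
    }
    cl
  })

  diff <- stage("diffabund", {
    sel <- setdiff(unique(samples$condition),
                   c(essential_condition, reference_condition))
    out <- list()
    for (cond in sel) {
      use <- samples$sample[samples$condition %in%
                              c(reference_condition, cond)]
      counts <- build_count_matrix(site_tables[use], annotation,
                                   calls, policy)
      condition <- factor(cond_of[use],
                          levels = c(reference_condition, cond))
      res <- diff_abundance(counts, condition, alpha_fdr = alpha_fdr)
      write_table_tsv(as.data.frame(res),
                      file.path(out_dir, paste0("diff_", cond, ".tsv")))
      out[[cond]] <- res
      .log("diffabund: %s vs %s -> %d enriched, %d depleted", cond,
           reference_condition, sum(res$call == "enriched"),
           sum(res$call == "depleted"))
    }
    out
  })

  summary <- stage("summary", {
    ess <- summarize_calls(calls, annotation, genome)
    rep <- list(
      genome_length = nchar(genome),
      n_genes = nrow(annotation),
      libraries = lapply(stats_list, function(x) list(
        n_unique_sites = x$stats$n_unique_sites,
        density_bp_per_insertion = x$stats$density_bp_per_insertion,
        intragenic_fraction = x$stats$intragenic_fraction)),
      essential = list(total = ess$n_essential,
                       protein = ess$n_essential_protein,
                       rna = ess$n_essential_rna,
                       percent = ess$percent_essential),
      min_significant_cluster_length =
        if (nrow(clusters) > 0) attr(clusters, "min_significant_length")
        else NA,
      attrition = attrition)
    jsonlite::write_json(rep, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    rep
  })

  invisible(list(sites = site_tables, stats = stats_list, calls = calls,
                 clusters = clusters, diff = diff, summary = summary))
}
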