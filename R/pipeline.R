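# End-to-end orchestration: simulate -> call -> annotate -> phylo ->
# fluctuate, writing a reproducible report bundle. All stage randomness
# derives from one master seed through named substreams (stage_seed), so the
# same config and seed give byte-identical outputs.

#' Assemble a pipeline run configuration
#'
#' @param out_dir output directory (created if absent).
#' @param seed master seed; every stochastic stage derives its own stream
#'   from it.
#' @param genome_length,n_genes synthetic genome dimensions.
#' @param lineage a [lineage_spec()]; default is the study-shaped lineage.
#' @param pileup a [pileup_sim_params()] (the seed field is ignored; per-
#'   strain substreams are derived from the master seed).
#' @param filters a [filter_params()].
#' @param assays named list of [assay_design()]s, one per strain to assay
#'   (NULL skips the fluctuation stage).
#' @param ancestor_name strain name of the ancestor.
#' @return a `run_config` list.
#' @export
run_config <- function(out_dir, seed, genome_length = 60000L, n_genes = 60L,
                       lineage = study_lineage_spec(),
                       pileup = pileup_sim_params(),
                       filters = filter_params(),
                       assays = NULL, ancestor_name = "JA122") {
  stopifnot(inherits(lineage, "lineage_spec"),
            inherits(pileup, "pileup_sim_params"),
            inherits(filters, "filter_params"))
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 genome_length = as.integer(genome_length),
                 n_genes = as.integer(n_genes), lineage = lineage,
                 pileup = pileup, filters = filters, assays = assays,
                 ancestor_name = ancestor_name),
            class = "run_config")
}

#' Run the full pipeline on synthetic data
#'
#' Stages run in order: genome + mutation simulation, per-strain pileup
#' simulation, ancestor-versus-evolved SNP calling, annotation and spectrum
#' summary, SNP-sharing partition and parsimony phylogeny, and (when assay
#' designs are given) fluctuation-assay simulation with MSS-MLE rate
#' estimation. Every output is a plain-text file under `config$out_dir`, and
#' `summary.json` records the parameters actually used plus recall/precision
#' against the planted truth.
#'
#' @param config a [run_config()].
#' @return invisibly, the summary list.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(config$out_dir, ...)
  seed <- config$seed
  strains <- config$lineage$tips

  ## stage 1: simulate
  genome <- generate_annotated_genome(config$genome_length, config$n_genes,
                                      seed = stage_seed(seed, "genome"))
  write_genome(genome, out("genome.fa"), out("genes.gff3"))
  planted <- plant_mutations(genome, config$lineage,
                             seed = stage_seed(seed, "plant"))
  write_truth(planted$truth, out("truth.tsv"))

  pu_params <- config$pileup
  pileups <- list()
  for (s in c(config$ancestor_name, strains)) {
    p <- pu_params
    p$seed <- stage_seed(seed, paste0("pileup:", s))
    tmpl <- if (s == config$ancestor_name) genome$seq else
      planted$strain_seqs[[s]]
    pu <- simulate_pileup(genome, p, strain_seq = tmpl)
    write_pileup(pu, out(paste0(s, ".pileup")))
    pileups[[s]] <- pu
  }

  ## stage 2: call (round-trips through the pileup text files)
  anc <- read_pileup(out(paste0(config$ancestor_name, ".pileup")))
  calls_by_strain <- list()
  tallies <- list()
  for (s in strains) {
    evo <- read_pileup(out(paste0(s, ".pileup")))
    res <- call_genome(anc, evo, config$filters, strain = s)
    write_vcf(res, out(paste0(s, ".vcf")), sample_name = s)
    calls_by_strain[[s]] <- res$calls
    tallies[[s]] <- res$tally
  }
  calls <- do.call(rbind, calls_by_strain)
  rownames(calls) <- NULL
  write_tsv(calls, out("calls.tsv"))

  ## stage 3: annotate
  ann <- annotate_mutations(genome, calls)
  write_tsv(ann, out("annotated.tsv"))
  spectrum <- summarize_spectrum(ann)
  write_tsv(spectrum, out("spectrum.tsv"))
  hits <- multi_hit_report(ann)
  write_tsv(hits$genes, out("multi_hit_genes.tsv"))

  ## stage 4: phylogeny
  star_flag <- FALSE
  partition <- NULL; tree <- NULL
  if (nrow(calls) > 0) {
    pm <- presence_matrix(calls, strains = strains)
    partition <- partition_counts(pm)
    write_tsv(partition, out("partition.tsv"))
    search <- best_topology(pm)
    tree <- search$best
    star_flag <- length(search$ties) > 1
    write_clado_newick(tree, out("tree.nwk"),
                       ancestor_name = config$ancestor_name)
    writeLines(render_clado_tree(tree, config$ancestor_name),
               out("tree.txt"))
  }

  ## stage 5: fluctuation
  rates <- NULL
  if (!is.null(config$assays)) {
    rates <- data.frame(strain = character(0), m_hat = numeric(0),
                        mu_hat = numeric(0), ci_lo = numeric(0),
                        ci_hi = numeric(0), n_cultures = integer(0))
    for (s in names(config$assays)) {
      d <- config$assays[[s]]
      d$seed <- stage_seed(seed, paste0("assay:", s))
      counts <- simulate_fluctuation_assay(d)
      write_assay_counts(counts, d$Nt, out(paste0(s, "_assay.tsv")))
      est <- mss_mle(counts, Nt = d$Nt)
      rates[nrow(rates) + 1L, ] <- list(s, est$m_hat, est$mu_hat,
                                        est$ci95[1], est$ci95[2],
                                        est$n_cultures)
    }
    write_tsv(rates, out("rates.tsv"))
    if (nrow(rates) >= 2) {
      pairs <- expand.grid(a = rates$strain, b = rates$strain,
                           stringsAsFactors = FALSE)
      pairs <- pairs[pairs$a != pairs$b, , drop = FALSE]
      pairs$fold <- vapply(seq_len(nrow(pairs)), function(i) {
        mu_a <- rates$mu_hat[rates$strain == pairs$a[i]]
        mu_b <- rates$mu_hat[rates$strain == pairs$b[i]]
        if (mu_a > 0 && mu_b > 0) mu_a / mu_b else NA_real_
      }, 0)
      write_tsv(pairs, out("folds.tsv"))
    }
  }

  ## summary: recall/precision against planted truth
  truth_rows <- truth_by_strain(planted$truth)
  truth_key <- paste(truth_rows$strain, truth_rows$pos, truth_rows$alt)
  call_key <- if (nrow(calls) > 0) {
    paste(calls$strain, calls$pos, calls$alt)
  } else character(0)
  tp <- sum(call_key %in% truth_key)
  recall <- if (length(truth_key) > 0) tp / length(truth_key) else NA
  precision <- if (length(call_key) > 0) tp / length(call_key) else NA

  summary <- list(
    seed = seed,
    params = list(genome_length = config$genome_length,
                  n_genes = config$n_genes,
                  branch_counts = as.list(config$lineage$branch_counts),
                  spectrum = as.list(config$lineage$spectrum),
                  pileup = config$pileup[c("mean_depth", "error_rate",
                                           "ambiguous_rate",
                                           "deletion_rate")],
                  filters = unclass(config$filters),
                  ancestor = config$ancestor_name),
    n_truth = nrow(planted$truth),
    n_calls = nrow(calls),
    recall = recall, precision = precision,
    rejection_tallies = lapply(tallies, as.list),
    topology = if (!is.null(tree)) tree$topology else NA,
    star_tied = star_flag,
    branch_changes = if (!is.null(tree)) as.list(tree$branch_changes) else NULL,
    rates = if (!is.null(rates)) rates else NULL)
  jsonlite::write_json(summary, out("summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(summary)
}
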