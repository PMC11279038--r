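#' @name pipeline
#' @title One-command reproducible run of all stages
#' @description
#' `run_pipeline()` chains the stages (simulate, process, de, gsa) under a
#' single master seed, writes every intermediate table to the output
#' directory, echoes the effective configuration for provenance, and
#' returns a run summary with the headline tallies (miRNAs evaluated, DE
#' counts by direction, per-collection significant sets by coefficient
#' sign).
NULL

pipeline_paths <- function(outdir) {
  list(
    config = file.path(outdir, "effective_config.json"),
    counts = file.path(outdir, "counts.tsv"),
    groups = file.path(outdir, "sample_groups.tsv"),
    stats = file.path(outdir, "processing_stats.tsv"),
    counts_filtered = file.path(outdir, "counts_filtered.tsv"),
    de_table = file.path(outdir, "de_table.tsv"),
    volcano_mirna = file.path(outdir, "volcano_mirna.tsv"),
    mrna_scores = file.path(outdir, "mrna_scores.tsv"),
    gsa_table = file.path(outdir, "gsa_table.tsv"),
    volcano_gsa = file.path(outdir, "volcano_gsa.tsv"),
    summary = file.path(outdir, "run_summary.json")
  )
}

#' Run the full pipeline (or a suffix of it) on synthetic data
#'
#' Modes: `simulate` generates the dataset only; `process` additionally
#' produces the count matrix from the FASTQ files; `de` adds differential
#' expression; `gsa` and `all` add gene set analysis. Later modes expect
#' the artifacts of earlier stages in `outdir` and fail with a clear error
#' when one is missing. Reruns with an identical configuration produce
#' byte-identical tables.
#'
#' @param config A [sim_config()]; its seed drives every stage.
#' @param outdir Output directory.
#' @param mode One of `simulate`, `process`, `de`, `gsa`, `all`.
#' @param alpha,fc_threshold DE-calling thresholds.
#' @param min_total Low-count filter threshold (rows with total count
#'   > `min_total` are kept).
#' @param weighted Use voom-style precision weights in the linear model.
#' @param gsa_alpha,min_set_size,p_floor Gene-set-analysis parameters.
#' @return Invisibly, a list with the run summary and stage artifacts.
#' @export
run_pipeline <- function(config, outdir, mode = c("all", "simulate",
                                                  "process", "de", "gsa"),
                         alpha = 0.05, fc_threshold = 1.5, min_total = 4L,
                         weighted = TRUE, gsa_alpha = 0.05,
                         min_set_size = 5L, p_floor = 1e-300) {
  mode <- match.arg(mode)
  stages <- c("simulate", "process", "de", "gsa")
  active <- if (mode == "all") stages else mode
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  sp <- pipeline_paths(outdir)
  sim_dir <- file.path(outdir, "simulated")

  jsonlite::write_json(unclass(config), sp$config, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)

  sim <- NULL
  if ("simulate" %in% active) {
    message("[simulate] generating synthetic dataset (seed ", config$seed, ")")
    sim <- simulate_dataset(config, sim_dir)
  }

  if ("process" %in% active) {
    fq <- file.path(sim_dir, "fastq", paste0(sample_ids(config), ".fastq"))
    names(fq) <- sample_ids(config)
    need <- c(file.path(sim_dir, "mature_mirna.fa"),
              file.path(sim_dir, "negative_reference.fa"), fq)
    miss <- need[!file.exists(need)]
    if (length(miss)) {
      stop("missing input for stage 'process': ", paste(miss, collapse = ", "),
           " (run the simulate stage first)")
    }
    message("[process] trimming, filtering and aligning ", length(fq),
            " samples")
    pos <- read_fasta(file.path(sim_dir, "mature_mirna.fa"))
    neg <- read_fasta(file.path(sim_dir, "negative_reference.fa"))
    proc <- count_samples(fq, sample_groups(config), pos, neg,
                          adapter = config$adapter)
    write_count_matrix(proc$counts, sp$counts, sp$groups)
    write_tsv(proc$stats, sp$stats)
    filtered <- apply_min_count(proc$counts, min_total)
    write_count_matrix(filtered, sp$counts_filtered)
    message("[process] ", nrow(filtered$counts), " of ",
            nrow(proc$counts$counts), " miRNAs exceed ", min_total,
            " total reads")
  }

  if ("de" %in% active) {
    if (!file.exists(sp$counts_filtered) || !file.exists(sp$groups)) {
      stop("missing input for stage 'de': ", sp$counts_filtered,
           " (run the process stage first)")
    }
    cm <- read_count_matrix(sp$counts_filtered, sp$groups)
    message("[de] fitting moderated linear models for ", nrow(cm$counts),
            " miRNAs")
    de <- run_diffexp(cm, weighted = weighted, alpha = alpha,
                      fc_threshold = fc_threshold)
    write_tsv(de, sp$de_table)
    write_tsv(export_volcano_data(de), sp$volcano_mirna)
  }

  if ("gsa" %in% active) {
    tm_path <- file.path(sim_dir, "target_map.tsv")
    gmt_path <- file.path(sim_dir, "gene_sets.gmt")
    if (!file.exists(sp$de_table)) {
      stop("missing input for stage 'gsa': DE table ", sp$de_table,
           " (run the de stage first)")
    }
    if (!file.exists(tm_path) || !file.exists(gmt_path)) {
      stop("missing input for stage 'gsa': ", tm_path, " / ", gmt_path)
    }
    de <- read_tsv(sp$de_table)
    tm <- read_target_map(tm_path)
    sets <- read_gmt(gmt_path)
    message("[gsa] scoring ", length(unique(tm$mrna_id)),
            " mRNAs and fitting ", length(sets), " gene sets")
    ms <- data.frame(mirna_id = de$mirna_id,
                     s_mirna = mirna_score(de$p_adj, de$log2fc, p_floor))
    rs <- mrna_scores(ms, tm)
    write_tsv(rs, sp$mrna_scores)
    gsa <- gsa_collection(rs, sets, collection = "custom",
                          alpha = gsa_alpha, min_size = min_set_size)
    write_tsv(gsa, sp$gsa_table)
    write_tsv(export_volcano_data(gsa), sp$volcano_gsa)
  }

  summary <- NULL
  if (file.exists(sp$de_table)) {
    de <- read_tsv(sp$de_table)
    gsa <- if (file.exists(sp$gsa_table)) read_tsv(sp$gsa_table) else NULL
    summary <- run_summary(de, gsa)
    jsonlite::write_json(summary, sp$summary, auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
    message("[summary] ", summary$n_mirna_evaluated, " miRNAs evaluated; ",
            summary$n_de, " DE (", summary$n_de_up, " up, ",
            summary$n_de_down, " down)")
  }
  invisible(list(summary = summary, paths = sp, simulated = sim))
}

#' Tally the headline numbers of a run
#'
#' @param de_table DE table from [run_diffexp()].
#' @param gsa_table Optional GSA table from [gsa_collection()].
#' @return List: `n_mirna_evaluated`, `n_de`, `n_de_up`, `n_de_down`, and
#'   per-collection significant-set counts split by coefficient sign.
#' @export
run_summary <- function(de_table, gsa_table = NULL) {
  sig <- de_table[de_table$significant, , drop = FALSE]
  out <- list(
    n_mirna_evaluated = nrow(de_table),
    n_de = nrow(sig),
    n_de_up = sum(sig$log2fc > 0),
    n_de_down = sum(sig$log2fc < 0)
  )
  if (!is.null(gsa_table) && nrow(gsa_table)) {
    out$collections <- lapply(split(gsa_table, gsa_table$collection),
                              function(g) {
      s <- g[g$significant, , drop = FALSE]
      list(n_sets_tested = nrow(g),
           n_significant = nrow(s),
           n_positive_coef = sum(s$coefficient > 0),
           n_negative_coef = sum(s$coefficient < 0))
    })
  }
  out
}

#' Export plot-ready volcano data
#'
#' For a DE table: `id`, `log2fc`, `neg_log10_p`, `significant`. For a GSA
#' table: `set_id`, `coefficient`, `neg_log10_p_adj`, `significant`,
#' `direction`. P-values are floored so all values are finite.
#'
#' @param table A [run_diffexp()] or [gsa_collection()] table.
#' @param p_floor Floor applied before the -log10.
#' @return Plot-ready data frame.
#' @export
export_volcano_data <- function(table, p_floor = 1e-300) {
  if (all(c("mirna_id", "p_adj", "log2fc") %in% names(table))) {
    data.frame(id = table$mirna_id,
               log2fc = table$log2fc,
               neg_log10_p = -log10(pmax(table$p_adj, p_floor)),
               significant = table$significant,
               stringsAsFactors = FALSE)
  } else if (all(c("set_id", "coefficient", "p_adj") %in% names(table))) {
    data.frame(set_id = table$set_id,
               coefficient = table$coefficient,
               neg_log10_p_adj = -log10(pmax(table$p_adj, p_floor)),
               significant = table$significant,
               direction = table$direction,
               stringsAsFactors = FALSE)
  } else {
    stop("table is neither a DE table nor a GSA table")
  }
}
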