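#' Simulation configuration for the synthetic small RNA-seq study
#'
#' Bundles every parameter of the synthetic dataset: study design (group
#' sizes), miRNA universe, planted differential-expression signal,
#' negative-binomial count model, read-level artifact fractions, and the
#' miRNA-target / gene-set layer. Defaults mirror a two-group freeze-exposure
#' design with 4 control and 3 treated animals and a universe of 49 mature
#' miRNAs, of which 5 are differentially expressed (2 up, 3 down) at
#' |log2 fold change| = 2.
#'
#' @param seed Integer master seed. Every generator derives its own RNG
#'   stream from it by a fixed offset, so regenerating one artifact never
#'   perturbs another.
#' @param n_control,n_frozen Samples per group.
#' @param n_mirna Number of mature miRNAs in the positive reference.
#' @param n_de Number of planted differentially expressed miRNAs.
#' @param n_de_up How many of the planted DE miRNAs are upregulated in the
#'   frozen group; the remainder are downregulated.
#' @param de_log2fc Absolute log2 fold change of planted DE miRNAs.
#' @param nb_dispersion Negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2). Values below 1e-8 fall back to Poisson.
#' @param lib_size_mean Mean per-sample library size (miRNA-derived reads).
#' @param adapter 3' sequencing adapter appended to every synthetic read.
#' @param frac_contaminant Fraction of additional reads drawn from the
#'   negative (non-miRNA small RNA) reference.
#' @param frac_low_quality Fraction of additional reads emitted with mean
#'   Phred quality below 30.
#' @param n_mrna Size of the mRNA universe in the target map.
#' @param targets_per_mirna Distinct mRNA targets assigned to each miRNA.
#' @param n_gene_sets Number of gene sets generated.
#' @param set_size_range Integer vector of length 2: min and max set size.
#' @param n_enriched_sets Number of gene sets planted to oversample targets
#'   of DE miRNAs of one direction.
#'
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_control = 4L,
                       n_frozen = 3L,
                       n_mirna = 49L,
                       n_de = 5L,
                       n_de_up = 2L,
                       de_log2fc = 2,
                       nb_dispersion = 0.1,
                       lib_size_mean = 50000L,
                       adapter = "TGGAATTCTCGGGTGCCAAGG",
                       frac_contaminant = 0.05,
                       frac_low_quality = 0.02,
                       n_mrna = 2000L,
                       targets_per_mirna = 40L,
                       n_gene_sets = 50L,
                       set_size_range = c(15L, 50L),
                       n_enriched_sets = 4L) {
  cfg <- list(
    seed = as.integer(seed),
    n_control = as.integer(n_control),
    n_frozen = as.integer(n_frozen),
    n_mirna = as.integer(n_mirna),
    n_de = as.integer(n_de),
    n_de_up = as.integer(n_de_up),
    de_log2fc = as.numeric(de_log2fc),
    nb_dispersion = as.numeric(nb_dispersion),
    lib_size_mean = as.integer(lib_size_mean),
    adapter = toupper(as.character(adapter)),
    frac_contaminant = as.numeric(frac_contaminant),
    frac_low_quality = as.numeric(frac_low_quality),
    n_mrna = as.integer(n_mrna),
    targets_per_mirna = as.integer(targets_per_mirna),
    n_gene_sets = as.integer(n_gene_sets),
    set_size_range = as.integer(set_size_range),
    n_enriched_sets = as.integer(n_enriched_sets)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  stopifnot(
    "seed must be a finite integer" = is.finite(cfg$seed),
    "need at least one sample per group" =
      cfg$n_control >= 1L && cfg$n_frozen >= 1L,
    "n_mirna must be positive" = cfg$n_mirna >= 1L,
    "n_de cannot exceed n_mirna" = cfg$n_de <= cfg$n_mirna,
    "n_de_up cannot exceed n_de" = cfg$n_de_up <= cfg$n_de,
    "n_de and n_de_up must be non-negative" =
      cfg$n_de >= 0L && cfg$n_de_up >= 0L,
    "nb_dispersion must be non-negative" = cfg$nb_dispersion >= 0,
    "lib_size_mean must be positive" = cfg$lib_size_mean >= 1L,
    "adapter must be a non-empty ACGT string" =
      nchar(cfg$adapter) >= 3L && grepl("^[ACGT]+$", cfg$adapter),
    "frac_contaminant must lie in [0,1]" =
      cfg$frac_contaminant >= 0 && cfg$frac_contaminant <= 1,
    "frac_low_quality must lie in [0,1]" =
      cfg$frac_low_quality >= 0 && cfg$frac_low_quality <= 1,
    "targets_per_mirna cannot exceed n_mrna" =
      cfg$targets_per_mirna <= cfg$n_mrna,
    "set_size_range must be two increasing positive integers" =
      length(cfg$set_size_range) == 2L &&
        cfg$set_size_range[1] >= 1L &&
        cfg$set_size_range[1] <= cfg$set_size_range[2],
    "n_enriched_sets cannot exceed n_gene_sets" =
      cfg$n_enriched_sets <= cfg$n_gene_sets
  )
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic small RNA-seq study configuration\n")
  cat(sprintf("  seed %d | %d control vs %d frozen samples\n",
              x$seed, x$n_control, x$n_frozen))
  cat(sprintf("  %d miRNAs, %d planted DE (%d up / %d down) at |log2FC| = %g\n",
              x$n_mirna, x$n_de, x$n_de_up, x$n_de - x$n_de_up, x$de_log2fc))
  cat(sprintf("  NB dispersion %g, mean library size %d\n",
              x$nb_dispersion, x$lib_size_mean))
  cat(sprintf("  artifacts: %.1f%% contaminant, %.1f%% low-quality reads\n",
              100 * x$frac_contaminant, 100 * x$frac_low_quality))
  cat(sprintf("  %d mRNAs, %d targets/miRNA, %d gene sets (%d planted)\n",
              x$n_mrna, x$targets_per_mirna, x$n_gene_sets, x$n_enriched_sets))
  invisible(x)
}

# Derive a per-generator RNG stream from the master seed. Offsets are fixed
# per generator so each artifact is reproducible in isolation.
stream_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + offset) %% 2147483647)
}
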