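#' @name synthetic-data
#' @title Seeded synthetic small RNA-seq data with known ground truth
#' @description
#' Five generators produce a fully self-contained synthetic study:
#' mature-miRNA and negative (non-miRNA small RNA) references,
#' negative-binomial miRNA counts with a planted differential-expression
#' signal, per-sample FASTQ reads with adapter, contaminant and low-quality
#' artifacts, a miRNA-to-mRNA target map, and gene sets of which a few
#' oversample targets of the planted DE miRNAs. Each generator draws from
#' its own RNG stream derived from the master seed, so any artifact can be
#' regenerated in isolation and identical seeds give bit-identical output.
NULL

mirna_ids <- function(n) sprintf("mir-%03d", seq_len(n))
mrna_ids <- function(n) sprintf("mrna-%04d", seq_len(n))

sample_ids <- function(cfg) {
  c(sprintf("ctrl_%d", seq_len(cfg$n_control)),
    sprintf("frz_%d", seq_len(cfg$n_frozen)))
}

sample_groups <- function(cfg) {
  rep(c("control", "frozen"), c(cfg$n_control, cfg$n_frozen))
}

rand_dna <- function(n, len) {
  # one sequence per element of len (recycled against n)
  len <- rep_len(len, n)
  chars <- sample(c("A", "C", "G", "T"), sum(len), replace = TRUE)
  ends <- cumsum(len)
  starts <- ends - len + 1L
  big <- paste(chars, collapse = "")
  substring(big, starts, ends)
}

seq_windows <- function(seq, k = 20L) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  substring(seq, seq_len(n - k + 1L), k:n)
}

#' Generate positive (mature miRNA) and negative references
#'
#' Mature sequences are 20-25 nt; every 20-nt window across the positive
#' reference is unique, so each read seed maps to exactly one miRNA. The
#' negative reference emulates longer non-miRNA small RNA species (rRNA,
#' tRNA, snRNA, snoRNA, piRNA) and shares no 20-nt substring with any
#' positive sequence.
#'
#' @param config A [sim_config()].
#' @param n_negative Number of negative-reference sequences (>= 10).
#' @return List with named character vectors `positive` and `negative`.
#' @export
generate_references <- function(config, n_negative = 12L) {
  stopifnot(inherits(config, "sim_config"), n_negative >= 10L)
  if (config$n_mirna > 1e6) {
    stop("capacity error: cannot construct ", config$n_mirna,
         " mature sequences with distinct 20-nt windows")
  }
  set.seed(stream_seed(config$seed, 101L))
  k <- 20L
  seen <- new.env(hash = TRUE, parent = emptyenv())
  draw_unique <- function(len) {
    for (try in 1:200) {
      s <- rand_dna(1L, len)
      w <- seq_windows(s, k)
      if (!any(vapply(w, exists, TRUE, envir = seen))) {
        for (wi in w) assign(wi, TRUE, envir = seen)
        return(s)
      }
    }
    stop("capacity error: could not place a sequence with distinct 20-nt windows")
  }
  pos_len <- sample(20:25, config$n_mirna, replace = TRUE)
  positive <- vapply(pos_len, draw_unique, "")
  names(positive) <- mirna_ids(config$n_mirna)

  neg_classes <- c("rRNA", "tRNA", "snRNA", "snoRNA", "piRNA")
  neg_len <- sample(60:200, n_negative, replace = TRUE)
  negative <- vapply(neg_len, draw_unique, "")
  names(negative) <- sprintf("neg-%s-%02d",
                             rep_len(neg_classes, n_negative),
                             seq_len(n_negative))
  list(positive = positive, negative = negative)
}

#' Simulate a negative-binomial miRNA count matrix with planted DE
#'
#' Counts for miRNA i in sample j are drawn negative-binomial with mean
#' `libsize_j * prop_i`, multiplied by `2^(+-de_log2fc)` in the frozen group
#' for planted DE miRNAs, with variance `mu + dispersion * mu^2`
#' (Poisson when dispersion < 1e-8). Baseline proportions are log-normal;
#' library sizes vary uniformly within 20% of `lib_size_mean`.
#'
#' @param config A [sim_config()].
#' @return List with elements `counts` (a [count_matrix()]) and
#'   `ground_truth` (planted DE miRNAs with their true log2FC, the true
#'   count matrix, and the expected-count matrix `mu` the draws came from).
#' @export
simulate_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(stream_seed(config$seed, 211L))
  n_samp <- config$n_control + config$n_frozen
  ids <- mirna_ids(config$n_mirna)
  w <- exp(stats::rnorm(config$n_mirna, 0, 1))
  prop <- w / sum(w)
  libsize <- round(config$lib_size_mean * stats::runif(n_samp, 0.8, 1.2))
  mu <- outer(prop, libsize)
  de_idx <- if (config$n_de > 0L) sort(sample(config$n_mirna, config$n_de)) else integer(0)
  de_sign <- rep(c(1, -1), c(config$n_de_up, config$n_de - config$n_de_up))
  frozen_cols <- which(sample_groups(config) == "frozen")
  if (length(de_idx)) {
    mu[de_idx, frozen_cols] <- mu[de_idx, frozen_cols] *
      2^(de_sign * config$de_log2fc)
  }
  counts <- if (config$nb_dispersion < 1e-8) {
    stats::rpois(length(mu), lambda = mu)
  } else {
    stats::rnbinom(length(mu), mu = mu, size = 1 / config$nb_dispersion)
  }
  counts <- matrix(as.integer(counts), nrow = config$n_mirna,
                   dimnames = list(ids, sample_ids(config)))
  cm <- count_matrix(counts, sample_groups(config))
  de <- data.frame(
    mirna_id = ids[de_idx],
    direction = ifelse(de_sign > 0, "up", "down"),
    log2fc = de_sign * config$de_log2fc,
    stringsAsFactors = FALSE
  )[seq_along(de_idx), , drop = FALSE]
  dimnames(mu) <- dimnames(counts)
  gt <- structure(list(de_mirnas = de, enriched_sets = NULL,
                       true_counts = cm, expected_counts = mu),
                  class = "ground_truth")
  list(counts = cm, ground_truth = gt)
}

#' Synthesize per-sample FASTQ files from a count matrix
#'
#' Each counted miRNA read is laid out as mature sequence, then the 3'
#' adapter, then random filler, padded or truncated to `read_len` bases
#' (single-end small RNA library layout), with constant Phred 36 quality.
#' Additional contaminant reads are drawn from 20-30 nt windows of the
#' negative reference, and additional low-quality reads carry constant
#' Phred 20 quality so the downstream mean-Q30 filter removes them.
#'
#' @param counts A [count_matrix()] whose row names appear in
#'   `positive_reference`.
#' @param positive_reference,negative_reference Named sequence vectors from
#'   [generate_references()].
#' @param config A [sim_config()].
#' @param dir Output directory for one FASTQ file per sample.
#' @param read_len Read length in bases.
#' @return Named character vector of FASTQ paths (one per sample).
#' @export
synthesize_fastq <- function(counts, positive_reference, negative_reference,
                             config, dir, read_len = 100L) {
  stopifnot(inherits(counts, "count_matrix"))
  if (sum(counts$counts) == 0L) {
    stop("empty counts matrix: no reads to synthesize")
  }
  missing_ref <- setdiff(rownames(counts$counts), names(positive_reference))
  if (length(missing_ref)) {
    stop("counts rows absent from positive reference: ",
         paste(missing_ref, collapse = ", "))
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(stream_seed(config$seed, 307L))
  q_good <- strrep(intToUtf8(33L + 36L), read_len)
  q_low <- strrep(intToUtf8(33L + 20L), read_len)
  neg_names <- names(negative_reference)
  paths <- character(ncol(counts$counts))
  names(paths) <- colnames(counts$counts)

  finish_reads <- function(bodies) {
    # pad with random filler to read_len, truncate if longer
    need <- pmax(0L, read_len - nchar(bodies))
    filler <- rand_dna(length(bodies), pmax(need, 1L))
    substr(paste0(bodies, filler), 1L, read_len)
  }

  for (s in colnames(counts$counts)) {
    cs <- counts$counts[, s]
    n_mir <- sum(cs)
    mir_of_read <- rep(rownames(counts$counts), cs)
    good <- if (length(mir_of_read)) {
      finish_reads(paste0(positive_reference[mir_of_read], config$adapter))
    } else {
      character(0)
    }
    n_low <- round(config$frac_low_quality * n_mir)
    low <- character(0)
    if (n_low > 0L) {
      low_ids <- sample(names(positive_reference), n_low, replace = TRUE)
      low <- finish_reads(paste0(positive_reference[low_ids], config$adapter))
    }
    n_cont <- round(config$frac_contaminant * n_mir)
    cont <- character(0)
    if (n_cont > 0L) {
      src <- sample(neg_names, n_cont, replace = TRUE)
      frag_len <- sample(20:30, n_cont, replace = TRUE)
      max_start <- nchar(negative_reference[src]) - frag_len + 1L
      start <- 1L + floor(stats::runif(n_cont) * max_start)
      frag <- substring(negative_reference[src], start, start + frag_len - 1L)
      cont <- finish_reads(paste0(frag, config$adapter))
    }
    seqs <- c(good, low, cont)
    quals <- c(rep(q_good, length(good)), rep(q_low, length(low)),
               rep(q_good, length(cont)))
    ord <- sample.int(length(seqs))
    ids <- sprintf("%s_read%06d", s, seq_along(seqs))
    paths[s] <- file.path(dir, paste0(s, ".fastq"))
    write_fastq(ids, seqs[ord], quals[ord], paths[s])
  }
  paths
}

#' Generate a random miRNA-to-mRNA target map
#'
#' Every miRNA receives `targets_per_mirna` distinct mRNA targets sampled
#' uniformly from an mRNA universe of size `n_mrna`; an mRNA may be
#' targeted by several miRNAs.
#'
#' @param config A [sim_config()].
#' @return Data frame with character columns `mirna_id`, `mrna_id`.
#' @export
generate_target_map <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(stream_seed(config$seed, 401L))
  mrna <- mrna_ids(config$n_mrna)
  targets <- lapply(seq_len(config$n_mirna), function(i) {
    sample(mrna, config$targets_per_mirna)
  })
  data.frame(
    mirna_id = rep(mirna_ids(config$n_mirna),
                   each = config$targets_per_mirna),
    mrna_id = unlist(targets),
    stringsAsFactors = FALSE
  )
}

#' Generate gene sets, planting a few enriched in DE-miRNA targets
#'
#' Background sets sample uniformly from the mRNA universe. Each planted
#' set takes at least 70% of its members from the targets of planted DE
#' miRNAs of one direction. A set built from targets of upregulated miRNAs
#' is expected to yield a negative logistic-regression coefficient
#' (increased negative regulation by miRNA); targets of downregulated
#' miRNAs give the mirror expectation.
#'
#' @param config A [sim_config()].
#' @param target_map Data frame from [generate_target_map()].
#' @param ground_truth Ground truth from [simulate_counts()] (supplies the
#'   planted DE miRNAs and their directions).
#' @param planted_frac Minimum fraction of planted-set members drawn from
#'   the DE-target pool.
#' @return List with `gene_sets` (named list of member vectors, GMT-ready)
#'   and `enriched_sets` (data frame: set_id, direction, expected_sign).
#' @export
generate_gene_sets <- function(config, target_map, ground_truth,
                               planted_frac = 0.7) {
  stopifnot(inherits(config, "sim_config"), is.data.frame(target_map))
  set.seed(stream_seed(config$seed, 503L))
  mrna <- mrna_ids(config$n_mrna)
  sizes <- sample(seq(config$set_size_range[1], config$set_size_range[2]),
                  config$n_gene_sets, replace = TRUE)
  set_names <- sprintf("set-%02d", seq_len(config$n_gene_sets))
  sets <- lapply(sizes, function(sz) sample(mrna, sz))
  names(sets) <- set_names

  enriched <- data.frame(set_id = character(0), direction = character(0),
                         expected_sign = numeric(0), stringsAsFactors = FALSE)
  if (config$n_enriched_sets > 0L) {
    de <- ground_truth$de_mirnas
    if (is.null(de) || nrow(de) == 0L) {
      stop("cannot plant enriched sets: ground truth has no DE miRNAs")
    }
    pool <- list(
      up = unique(target_map$mrna_id[target_map$mirna_id %in%
                                       de$mirna_id[de$direction == "up"]]),
      down = unique(target_map$mrna_id[target_map$mirna_id %in%
                                         de$mirna_id[de$direction == "down"]])
    )
    dirs_avail <- names(pool)[vapply(pool, length, 1L) > 0L]
    if (length(dirs_avail) == 0L) {
      stop("cannot plant enriched sets: DE miRNAs have no mapped targets")
    }
    dir_cycle <- rep_len(intersect(c("up", "down"), dirs_avail),
                         config$n_enriched_sets)
    planted_idx <- sort(sample(config$n_gene_sets, config$n_enriched_sets))
    for (k in seq_len(config$n_enriched_sets)) {
      d <- dir_cycle[k]
      p <- pool[[d]]
      i <- planted_idx[k]
      n_in <- ceiling(planted_frac * sizes[i])
      if (length(p) < n_in) {
        stop("enriched-set construction failed: DE miRNA target pool (",
             length(p), " mRNAs, direction ", d,
             ") smaller than required members (", n_in, ")")
      }
      outside <- setdiff(mrna, p)
      sets[[i]] <- c(sample(p, n_in),
                     sample(outside, sizes[i] - n_in))
    }
    enriched <- data.frame(
      set_id = set_names[planted_idx],
      direction = dir_cycle,
      expected_sign = ifelse(dir_cycle == "up", -1, 1),
      stringsAsFactors = FALSE
    )
  }
  attr(sets, "description") <- ifelse(
    set_names %in% enriched$set_id, "synthetic planted set",
    "synthetic background set")
  list(gene_sets = sets, enriched_sets = enriched)
}

#' Generate and write the complete synthetic study to a directory
#'
#' Runs all five generators and writes: positive/negative FASTA references,
#' one FASTQ per sample, the true count matrix and group labels, the target
#' map, the gene sets (GMT), and a JSON ground-truth sidecar.
#'
#' @param config A [sim_config()].
#' @param outdir Output directory (created if absent).
#' @return Invisibly, a list with all in-memory artifacts and file paths.
#' @export
simulate_dataset <- function(config, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  refs <- generate_references(config)
  sim <- simulate_counts(config)
  fastq <- synthesize_fastq(sim$counts, refs$positive, refs$negative,
                            config, file.path(outdir, "fastq"))
  target_map <- generate_target_map(config)
  gs <- generate_gene_sets(config, target_map, sim$ground_truth)
  gt <- sim$ground_truth
  gt$enriched_sets <- gs$enriched_sets

  paths <- list(
    positive_fasta = file.path(outdir, "mature_mirna.fa"),
    negative_fasta = file.path(outdir, "negative_reference.fa"),
    fastq = fastq,
    true_counts = file.path(outdir, "true_counts.tsv"),
    groups = file.path(outdir, "sample_groups.tsv"),
    target_map = file.path(outdir, "target_map.tsv"),
    gmt = file.path(outdir, "gene_sets.gmt"),
    ground_truth = file.path(outdir, "ground_truth.json")
  )
  write_fasta(refs$positive, paths$positive_fasta)
  write_fasta(refs$negative, paths$negative_fasta)
  write_count_matrix(sim$counts, paths$true_counts, paths$groups)
  write_target_map(target_map, paths$target_map)
  write_gmt(gs$gene_sets, paths$gmt)
  jsonlite::write_json(
    list(seed = config$seed,
         de_mirnas = gt$de_mirnas,
         enriched_sets = gt$enriched_sets),
    paths$ground_truth, dataframe = "rows", pretty = TRUE, digits = NA
  )
  invisible(list(config = config, references = refs, counts = sim$counts,
                 ground_truth = gt, target_map = target_map,
                 gene_sets = gs$gene_sets, paths = paths))
}
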