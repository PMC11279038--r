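#' @name read-processing
#' @title From FASTQ to a miRNA count matrix
#' @description
#' The processing chain applied to every sample: 3' adapter trimming,
#' mean-quality filtering, exclusion of reads matching a negative
#' (non-miRNA small RNA) reference, perfect-match alignment of the read's
#' first 20 bases to the mature miRNA reference, and per-miRNA tallying.
#' Alignment is exact substring matching of the 20-nt seed on the forward
#' strand, with the first reference in file order winning ties; reads
#' containing N in the seed never match.
NULL

#' Trim a 3' sequencing adapter from one read
#'
#' Scans read positions left to right; at each position the leading bases
#' of the adapter are compared to the read (the overlap shrinks near the
#' read's 3' end). The read is cut at the leftmost position where the
#' overlap is at least `min_overlap` bases and the mismatch rate is at most
#' `max_error_rate`. Qualities are trimmed in lockstep. Reads without a
#' qualifying hit are returned unchanged.
#'
#' @param read List with `seq` (string) and optionally `qual`
#'   (Phred integer vector or quality string) and `id`.
#' @param adapter Adapter sequence (non-empty).
#' @param min_overlap Minimum adapter/read overlap (>= 3).
#' @param max_error_rate Maximum mismatch fraction within the overlap
#'   (0 <= rate < 0.5).
#' @return The read with `seq` (and `qual`) truncated at the adapter start.
#' @export
trim_adapter <- function(read, adapter, min_overlap = 3L,
                         max_error_rate = 0.1) {
  if (!nzchar(adapter)) stop("configuration error: empty adapter string")
  stopifnot(min_overlap >= 3L, max_error_rate >= 0, max_error_rate < 0.5)
  pos <- adapter_hit(read$seq, adapter, min_overlap, max_error_rate)
  if (is.na(pos)) return(read)
  read$seq <- substr(read$seq, 1L, pos - 1L)
  if (!is.null(read$qual)) {
    read$qual <- if (is.character(read$qual)) {
      substr(read$qual, 1L, pos - 1L)
    } else {
      read$qual[seq_len(pos - 1L)]
    }
  }
  read
}

# Leftmost qualifying adapter start position in a single sequence, NA if none.
adapter_hit <- function(seq, adapter, min_overlap, max_error_rate) {
  L <- nchar(seq)
  A <- nchar(adapter)
  if (L < min_overlap) return(NA_integer_)
  s <- strsplit(seq, "")[[1]]
  a <- strsplit(adapter, "")[[1]]
  for (p in seq_len(L - min_overlap + 1L)) {
    o <- min(A, L - p + 1L)
    mism <- sum(s[p:(p + o - 1L)] != a[seq_len(o)])
    if (mism / o <= max_error_rate) return(p)
  }
  NA_integer_
}

# Vectorized adapter trimming over many equal-importance reads; identical
# semantics to trim_adapter(), applied to character vectors. Reads are
# grouped by length so the position scan can run as column operations.
trim_adapter_batch <- function(seqs, quals, adapter, min_overlap = 3L,
                               max_error_rate = 0.1) {
  if (!nzchar(adapter)) stop("configuration error: empty adapter string")
  stopifnot(min_overlap >= 3L, max_error_rate >= 0, max_error_rate < 0.5)
  n <- length(seqs)
  cut <- rep(NA_integer_, n)
  a <- strsplit(adapter, "")[[1]]
  A <- length(a)
  for (L in unique(nchar(seqs))) {
    idx <- which(nchar(seqs) == L)
    if (L < min_overlap) next
    m <- matrix(unlist(strsplit(seqs[idx], ""), use.names = FALSE),
                nrow = length(idx), byrow = TRUE)
    active <- seq_along(idx)
    for (p in seq_len(L - min_overlap + 1L)) {
      if (!length(active)) break
      o <- min(A, L - p + 1L)
      block <- m[active, p:(p + o - 1L), drop = FALSE]
      mism <- rowSums(block != matrix(a[seq_len(o)], nrow = length(active),
                                      ncol = o, byrow = TRUE))
      hit <- mism / o <= max_error_rate
      cut[idx[active[hit]]] <- p
      active <- active[!hit]
    }
  }
  keep_to <- ifelse(is.na(cut), nchar(seqs), cut - 1L)
  list(seq = substr(seqs, 1L, keep_to),
       qual = substr(quals, 1L, keep_to),
       trimmed = !is.na(cut))
}

#' Decide whether a read passes the mean-quality filter
#'
#' A read is kept iff its mean Phred score is at least `threshold` and its
#' (post-trimming) length is at least `min_length`.
#'
#' @param read List with `seq` and `qual` (Phred integers or a Phred+33
#'   string).
#' @param threshold Minimum mean Phred score.
#' @param min_length Minimum read length.
#' @return `TRUE` (keep) or `FALSE` (discard).
#' @export
quality_filter <- function(read, threshold = 30, min_length = 16L) {
  q <- read$qual
  if (is.character(q)) q <- phred_scores(q)
  length(q) >= min_length && mean(q) >= threshold
}

#' Build an exact-substring seed index from a reference
#'
#' Indexes every `seed_len`-nt window of every reference sequence; when two
#' references share a window, the one earlier in file order keeps it, which
#' makes multi-mapping resolution deterministic.
#'
#' @param reference Named character vector of sequences, in file order.
#' @param seed_len Seed length in bases.
#' @return An object of class `seed_index`.
#' @export
build_seed_index <- function(reference, seed_len = 20L) {
  stopifnot(length(reference) >= 1L, !is.null(names(reference)),
            seed_len >= 1L)
  wins <- lapply(unname(reference), seq_windows, k = seed_len)
  keys <- unlist(wins, use.names = FALSE)
  owner <- rep(names(reference), vapply(wins, length, 1L))
  first <- !duplicated(keys)
  structure(list(keys = keys[first], owner = owner[first],
                 seed_len = seed_len, ref_ids = names(reference)),
            class = "seed_index")
}

#' Match a read's seed against a reference index
#'
#' Returns the id of the reference whose sequence contains the read's
#' first `seed_len` bases as an exact substring (forward strand), or `NA`
#' if no reference matches or the read is shorter than the seed. Ties go to
#' the reference earliest in file order.
#'
#' @param read A read list (with `seq`) or a plain sequence string.
#' @param index A `seed_index` from [build_seed_index()].
#' @return Reference id or `NA_character_`.
#' @export
matches_reference <- function(read, index) {
  seq <- if (is.list(read)) read$seq else read
  match_seeds(seq, index)
}

# Vectorized core of matches_reference.
match_seeds <- function(seqs, index) {
  stopifnot(inherits(index, "seed_index"))
  if (length(index$keys) == 0L) stop("empty reference index")
  seed <- substr(seqs, 1L, index$seed_len)
  hit <- match(seed, index$keys)
  out <- index$owner[hit]
  out[nchar(seqs) < index$seed_len] <- NA_character_
  out
}

#' Does a read match the negative (non-miRNA) reference?
#'
#' @param read A read list or sequence string.
#' @param negative_index `seed_index` built from the negative reference.
#' @return `TRUE` if the read should be removed.
#' @export
filter_negative <- function(read, negative_index) {
  !is.na(matches_reference(read, negative_index))
}

#' Process per-sample FASTQ files into a miRNA count matrix
#'
#' Runs the full chain per sample: adapter trimming, mean-quality
#' filtering, negative-reference exclusion, seed alignment to the mature
#' miRNA reference, and tallying. Every miRNA of the positive reference
#' appears as a row (zero when unobserved); per-stage read counts are
#' recorded per sample.
#'
#' @param fastq_files Named character vector of FASTQ paths; names are
#'   sample ids.
#' @param groups Group label (`control`/`frozen`) per sample, aligned with
#'   `fastq_files`.
#' @param positive_reference,negative_reference Named sequence vectors (file
#'   order preserved).
#' @param adapter Adapter sequence.
#' @param min_overlap,max_error_rate Adapter-trimming parameters.
#' @param qual_threshold,min_length Quality-filter parameters.
#' @param seed_len Alignment seed length.
#' @return List with `counts` (a [count_matrix()]) and `stats` (data frame
#'   of per-stage read counts per sample: input, post_trim, post_quality,
#'   post_negative, aligned, unaligned).
#' @export
count_samples <- function(fastq_files, groups,
                          positive_reference, negative_reference,
                          adapter, min_overlap = 3L, max_error_rate = 0.1,
                          qual_threshold = 30, min_length = 16L,
                          seed_len = 20L) {
  stopifnot(length(fastq_files) == length(groups),
            !is.null(names(fastq_files)))
  g <- factor(as.character(groups), levels = c("control", "frozen"))
  if (nlevels(droplevels(g)) < 2L) {
    stop("need at least one sample in each of the control and frozen groups")
  }
  pos_index <- build_seed_index(positive_reference, seed_len)
  neg_index <- build_seed_index(negative_reference, seed_len)
  samples <- names(fastq_files)
  counts <- matrix(0L, nrow = length(positive_reference),
                   ncol = length(samples),
                   dimnames = list(names(positive_reference), samples))
  stats <- data.frame(sample_id = samples, input = 0L, post_trim = 0L,
                      post_quality = 0L, post_negative = 0L,
                      aligned = 0L, unaligned = 0L,
                      stringsAsFactors = FALSE)

  for (k in seq_along(samples)) {
    fq <- tryCatch(read_fastq(fastq_files[[k]]), error = function(e) {
      stop("failed to parse FASTQ for sample '", samples[k], "': ",
           conditionMessage(e))
    })
    n_in <- length(fq$seq)
    stats$input[k] <- n_in
    if (n_in == 0L) {
      warning("sample '", samples[k], "' has an empty FASTQ; zero column")
      next
    }
    tr <- trim_adapter_batch(fq$seq, fq$qual, adapter, min_overlap,
                             max_error_rate)
    stats$post_trim[k] <- length(tr$seq)

    # mean quality per read; memoize on unique quality strings since
    # synthetic data uses constant qualities
    uq <- unique(tr$qual)
    mean_q <- vapply(uq, function(q) {
      if (!nzchar(q)) return(0)
      mean(utf8ToInt(q)) - 33
    }, 0)
    ok_q <- mean_q[match(tr$qual, uq)] >= qual_threshold &
      nchar(tr$seq) >= min_length
    seqs <- tr$seq[ok_q]
    stats$post_quality[k] <- length(seqs)

    neg_hit <- !is.na(match_seeds(seqs, neg_index))
    seqs <- seqs[!neg_hit]
    stats$post_negative[k] <- length(seqs)

    ref <- match_seeds(seqs, pos_index)
    stats$aligned[k] <- sum(!is.na(ref))
    stats$unaligned[k] <- sum(is.na(ref))
    if (any(!is.na(ref))) {
      tab <- table(factor(ref[!is.na(ref)],
                          levels = names(positive_reference)))
      counts[, k] <- as.integer(tab)
    }
  }
  list(counts = count_matrix(counts, g), stats = stats)
}
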