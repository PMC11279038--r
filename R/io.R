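#' Read a FASTA file into a named character vector
#'
#' Thin wrapper over [Biostrings::readDNAStringSet()] that returns plain
#' uppercase character sequences named by the first whitespace-delimited
#' token of each header, in file order.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  seqs <- toupper(as.character(x))
  names(seqs) <- sub("\\s.*$", "", names(x))
  seqs
}

#' Write a named character vector of sequences as FASTA
#'
#' @param seqs Named character vector (names become headers).
#' @param path Output path.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(!is.null(names(seqs)), all(nzchar(names(seqs))))
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path, width = 80L)
  invisible(path)
}

#' Read a FASTQ file (Phred+33)
#'
#' Returns parallel vectors of read ids, sequences and quality strings.
#' Records whose sequence and quality lengths disagree, or whose quality
#' characters fall outside the Sanger range, raise an error naming the
#' offending record.
#'
#' @param path Path to an uncompressed FASTQ file.
#' @return A list with character vectors `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L) {
    return(list(id = character(0), seq = character(0), qual = character(0)))
  }
  if (length(lines) %% 4L != 0L) {
    stop("truncated FASTQ file: ", path)
  }
  ids <- lines[seq(1L, length(lines), by = 4L)]
  seqs <- toupper(lines[seq(2L, length(lines), by = 4L)])
  quals <- lines[seq(4L, length(lines), by = 4L)]
  if (any(substr(ids, 1L, 1L) != "@")) {
    bad <- which(substr(ids, 1L, 1L) != "@")[1]
    stop("malformed FASTQ header at record ", bad, " in ", path)
  }
  ids <- sub("^@", "", sub("\\s.*$", "", ids))
  len_ok <- nchar(seqs) == nchar(quals)
  if (!all(len_ok)) {
    bad <- which(!len_ok)[1]
    stop("sequence/quality length mismatch for record '", ids[bad],
         "' in ", path)
  }
  # Sanger Phred+33: '!' (0) .. '~' (93)
  qchars <- utf8ToInt(paste(quals, collapse = ""))
  if (length(qchars) && (min(qchars) < 33L || max(qchars) > 126L)) {
    stop("quality characters outside Phred+33 range in ", path)
  }
  list(id = ids, seq = seqs, qual = quals)
}

#' Write reads as FASTQ (Phred+33)
#'
#' @param ids,seqs,quals Parallel character vectors.
#' @param path Output path.
#' @export
write_fastq <- function(ids, seqs, quals, path) {
  stopifnot(length(ids) == length(seqs), length(seqs) == length(quals),
            all(nchar(seqs) == nchar(quals)))
  out <- character(4L * length(ids))
  out[seq(1L, by = 4L, length.out = length(ids))] <- paste0("@", ids)
  out[seq(2L, by = 4L, length.out = length(ids))] <- seqs
  out[seq(3L, by = 4L, length.out = length(ids))] <- "+"
  out[seq(4L, by = 4L, length.out = length(ids))] <- quals
  writeLines(out, path)
  invisible(path)
}

#' Convert a Phred+33 quality string to integer scores
#' @param qual Quality string.
#' @return Integer vector of Phred scores.
#' @export
phred_scores <- function(qual) {
  if (!nzchar(qual)) return(integer(0))
  utf8ToInt(qual) - 33L
}

#' Read gene sets from a GMT file
#'
#' Standard tab-separated GMT: set id, description, then member gene ids.
#'
#' @param path Path to a GMT file.
#' @return Named list of character vectors of member ids; the `description`
#'   attribute carries the second column.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(fields, length, 1L) < 3L
  if (any(bad)) stop("GMT line ", which(bad)[1], " has fewer than 3 fields")
  sets <- lapply(fields, function(f) f[-(1:2)])
  names(sets) <- vapply(fields, `[[`, "", 1L)
  attr(sets, "description") <- vapply(fields, `[[`, "", 2L)
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param description Optional character vector of set descriptions.
#' @export
write_gmt <- function(sets, path, description = NULL) {
  stopifnot(!is.null(names(sets)))
  if (is.null(description)) {
    description <- attr(sets, "description")
  }
  if (is.null(description)) description <- rep("na", length(sets))
  lines <- mapply(function(id, desc, members) {
    paste(c(id, desc, members), collapse = "\t")
  }, names(sets), description, sets)
  writeLines(unname(lines), path)
  invisible(path)
}

#' Read a two-column miRNA-to-mRNA target map
#'
#' @param path Tab-separated file with columns `mirna_id`, `mrna_id`.
#' @return A data.frame with those two character columns.
#' @export
read_target_map <- function(path) {
  tm <- utils::read.delim(path, header = TRUE, colClasses = "character")
  stopifnot(all(c("mirna_id", "mrna_id") %in% names(tm)))
  tm[, c("mirna_id", "mrna_id")]
}

#' Write a target map as tab-separated text
#' @param target_map Data frame with columns `mirna_id`, `mrna_id`.
#' @param path Output path.
#' @export
write_target_map <- function(target_map, path) {
  write_tsv(target_map[, c("mirna_id", "mrna_id")], path)
}

# Deterministic TSV writer used for every exported table.
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE, ...)
}
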