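adapter <- "TGGAATTCTCGGGTGCCAAGG"

test_that("exact adapter occurrences are removed with qualities in lockstep", {
  read <- list(id = "r1", seq = paste0("ACGTACGT", adapter),
               qual = rep(36L, 8 + nchar(adapter)))
  out <- trim_adapter(read, adapter)
  expect_identical(out$seq, "ACGTACGT")
  expect_identical(out$qual, rep(36L, 8))
})

test_that("reads without an adapter hit are returned unchanged", {
  read <- list(id = "r1", seq = "ACGTACGTACGTACGTACGTACGT",
               qual = rep(36L, 24))
  expect_identical(trim_adapter(read, adapter), read)
})

test_that("a one-mismatch overlap within the error budget is trimmed", {
  set.seed(21)
  mature <- random_read(22)
  # 10-nt adapter overlap at the read end, one mismatch: 1/10 <= 0.1
  overlap <- substr(adapter, 1, 10)
  substr(overlap, 4, 4) <- setdiff(c("A", "C", "G", "T"),
                                   substr(overlap, 4, 4))[1]
  seq <- paste0(mature, overlap)
  pos <- trim_pos_brute(seq, adapter, 3L, 0.1)
  read <- trim_adapter(list(seq = seq, qual = rep(36L, nchar(seq))),
                       adapter, 3L, 0.1)
  expect_identical(nchar(read$seq) + 1L, pos)
  expect_identical(read$seq, substr(seq, 1, pos - 1L))
})

test_that("single-read and batch trimming agree with the brute-force scan", {
  set.seed(22)
  reads <- character(150)
  for (i in seq_along(reads)) {
    mature <- random_read(sample(18:30, 1))
    reads[i] <- switch(sample(3, 1),
                       paste0(mature, adapter, random_read(10)),
                       paste0(mature, substr(adapter, 1, sample(3:15, 1))),
                       mature)
  }
  quals <- strrep("E", nchar(reads))
  batch <- trim_adapter_batch(reads, quals, adapter, 3L, 0.1)
  for (i in seq_along(reads)) {
    pos <- trim_pos_brute(reads[i], adapter, 3L, 0.1)
    keep <- if (is.na(pos)) nchar(reads[i]) else pos - 1L
    expect_identical(batch$seq[i], substr(reads[i], 1, keep))
    single <- trim_adapter(list(seq = reads[i], qual = quals[i]),
                           adapter, 3L, 0.1)
    expect_identical(single$seq, batch$seq[i])
    expect_identical(single$qual, batch$qual[i])
  }
})

test_that("an empty adapter is a configuration error", {
  expect_error(trim_adapter(list(seq = "ACGT", qual = rep(36L, 4)), ""),
               "adapter")
  expect_error(trim_adapter_batch("ACGT", "EEEE", ""), "adapter")
})

test_that("the quality filter applies the mean-Q and length rules", {
  expect_true(quality_filter(list(seq = strrep("A", 20),
                                  qual = rep(36L, 20))))
  expect_false(quality_filter(list(seq = strrep("A", 20),
                                   qual = rep(20L, 20))))
  # mean 29.75 just below the threshold; length rule relaxed to isolate it
  expect_false(quality_filter(list(seq = "ACGT",
                                   qual = c(30L, 30L, 30L, 29L)),
                              threshold = 30, min_length = 1L))
  expect_true(quality_filter(list(seq = "ACGT",
                                  qual = c(30L, 30L, 30L, 30L)),
                             threshold = 30, min_length = 1L))
  # length rule: mean fine but read too short after trimming
  expect_false(quality_filter(list(seq = strrep("A", 10),
                                   qual = rep(36L, 10))))
  # quality strings are accepted too ('E' is Phred 36)
  expect_true(quality_filter(list(seq = strrep("A", 20),
                                  qual = strrep("E", 20))))
})

test_that("seed matching is exact, forward-strand, first-reference-wins", {
  set.seed(23)
  refs <- c(mirA = random_read(22), mirB = random_read(24))
  index <- build_seed_index(refs)
  expect_identical(matches_reference(refs[["mirA"]], index), "mirA")
  # any single mismatch inside the first 20 nt kills the match
  for (pos in c(1L, 7L, 20L)) {
    seq <- refs[["mirA"]]
    substr(seq, pos, pos) <- setdiff(c("A", "C", "G", "T"),
                                     substr(seq, pos, pos))[1]
    expect_true(is.na(matches_reference(seq, index)))
  }
  # mismatch after the seed is irrelevant
  seq <- refs[["mirB"]]
  substr(seq, 22, 22) <- setdiff(c("A", "C", "G", "T"),
                                 substr(seq, 22, 22))[1]
  expect_identical(matches_reference(seq, index), "mirB")
  # reads shorter than the seed never match
  expect_true(is.na(matches_reference(substr(refs[["mirA"]], 1, 19), index)))
  # N inside the seed never matches
  seqN <- refs[["mirA"]]
  substr(seqN, 5, 5) <- "N"
  expect_true(is.na(matches_reference(seqN, index)))
})

test_that("multi-mapping reads go to the first reference in file order", {
  shared <- random_read(21)
  refs <- c(first = paste0(shared, "AC"), second = paste0("T", shared))
  index <- build_seed_index(refs)
  read <- substr(shared, 1, 20)
  expect_identical(matches_reference(read, index), "first")
  expect_identical(match_brute(read, refs), "first")
})

test_that("seed matching agrees with the exhaustive substring oracle", {
  set.seed(24)
  refs <- vapply(1:8, function(i) random_read(sample(20:25, 1)), "")
  names(refs) <- paste0("mir", 1:8)
  index <- build_seed_index(refs)
  reads <- c(
    unname(refs),                                  # full-length hits
    substr(unname(refs), 2, 23),                   # offset windows
    vapply(1:20, function(i) random_read(22), "")  # mostly misses
  )
  expect_identical(
    unname(vapply(reads, matches_reference, "", index = index)),
    unname(vapply(reads, match_brute, "", reference = refs))
  )
})

test_that("negative filtering removes reads drawn from the negative reference", {
  cfg <- tiny_config(seed = 10)
  refs <- generate_references(cfg)
  neg_index <- build_seed_index(refs$negative)
  frag <- substr(refs$negative[[3]], 11, 40)
  expect_true(filter_negative(list(seq = frag), neg_index))
  expect_false(filter_negative(list(seq = refs$positive[[1]]), neg_index))
  expect_error(build_seed_index(character(0)), "reference")
})

test_that("processing artifact-free synthetic reads recovers the true counts", {
  cfg <- tiny_config(seed = 11, frac_contaminant = 0, frac_low_quality = 0)
  refs <- generate_references(cfg)
  sim <- simulate_counts(cfg)
  dir <- withr::local_tempdir()
  paths <- synthesize_fastq(sim$counts, refs$positive, refs$negative,
                            cfg, dir)
  proc <- count_samples(paths, sim$counts$groups, refs$positive,
                        refs$negative, adapter = cfg$adapter)
  expect_identical(proc$counts$counts, sim$counts$counts)
  st <- proc$stats
  expect_true(all(st$input >= st$post_trim))
  expect_true(all(st$post_trim >= st$post_quality))
  expect_true(all(st$post_quality >= st$post_negative))
  expect_identical(st$aligned + st$unaligned, st$post_negative)
})

test_that("an empty FASTQ yields a zero column with a warning", {
  cfg <- tiny_config(seed = 12, frac_contaminant = 0, frac_low_quality = 0)
  refs <- generate_references(cfg)
  sim <- simulate_counts(cfg)
  dir <- withr::local_tempdir()
  paths <- synthesize_fastq(sim$counts, refs$positive, refs$negative,
                            cfg, dir)
  writeLines(character(0), paths[["frz_1"]])
  expect_warning(
    proc <- count_samples(paths, sim$counts$groups, refs$positive,
                          refs$negative, adapter = cfg$adapter),
    "empty FASTQ"
  )
  expect_true(all(proc$counts$counts[, "frz_1"] == 0L))
})

test_that("a sample of pure contaminant reads ends with nothing aligned", {
  cfg <- tiny_config(seed = 13)
  refs <- generate_references(cfg)
  dir <- withr::local_tempdir()
  set.seed(1)
  frags <- vapply(1:30, function(i) {
    src <- refs$negative[[sample(length(refs$negative), 1)]]
    start <- sample(nchar(src) - 29L, 1)
    substr(src, start, start + 24L)
  }, "")
  seqs <- substr(paste0(frags, cfg$adapter,
                        strrep("A", 60)), 1, 100)
  for (s in c("ctrl_1", "frz_1")) {
    write_fastq(sprintf("%s_%03d", s, 1:30), seqs, strrep("E", nchar(seqs)),
                file.path(dir, paste0(s, ".fastq")))
  }
  fq <- c(ctrl_1 = file.path(dir, "ctrl_1.fastq"),
          frz_1 = file.path(dir, "frz_1.fastq"))
  proc <- count_samples(fq, c("control", "frozen"), refs$positive,
                        refs$negative, adapter = cfg$adapter)
  expect_true(all(proc$stats$post_negative == 0L))
  expect_true(all(proc$counts$counts == 0L))
})

test_that("FASTQ parse failures name the offending record", {
  dir <- withr::local_tempdir()
  bad <- file.path(dir, "bad.fastq")
  writeLines(c("@r1", "ACGT", "+", "EEE"), bad)
  expect_error(read_fastq(bad), "r1")
})

test_that("the low-count filter keeps rows with totals strictly above 4", {
  g <- c("control", "control", "frozen")
  m <- matrix(c(2L, 1L, 1L,   # 4: dropped
                2L, 2L, 1L,   # 5: kept
                0L, 0L, 0L,   # 0: dropped
                1L, 0L, 0L,   # 1: dropped
                3L, 2L, 1L),  # 6: kept
              ncol = 3, byrow = TRUE,
              dimnames = list(paste0("m", 1:5), c("c1", "c2", "f1")))
  out <- apply_min_count(count_matrix(m, g), 4L)
  expect_identical(rownames(out$counts), c("m2", "m5"))

  full <- matrix(100L, 3, 3, dimnames = list(paste0("m", 1:3),
                                             c("c1", "c2", "f1")))
  expect_identical(apply_min_count(count_matrix(full, g), 4L)$counts, full)

  low <- matrix(1L, 2, 3, dimnames = list(paste0("m", 1:2),
                                          c("c1", "c2", "f1")))
  expect_error(apply_min_count(count_matrix(low, g), 4L), "nothing to analyze")
})
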