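test_that("miRNA scores follow the signed -log10 rule", {
  expect_identical(mirna_score(0.01, -2), -2)
  expect_identical(mirna_score(1, 5), 0)
  expect_identical(mirna_score(0.5, 0), 0)
  expect_equal(mirna_score(0, 3), 300)
  expect_equal(mirna_score(0, -3), -300)
  expect_equal(mirna_score(0, 3, p_floor = 1e-10), 10)
})

test_that("mRNA scores are negated sums over targeting miRNAs", {
  ms <- data.frame(mirna_id = c("a", "b"), s_mirna = c(2, -1))
  tm <- data.frame(mirna_id = c("a", "b", "a"),
                   mrna_id = c("g1", "g1", "g2"))
  out <- mrna_scores(ms, tm)
  expect_equal(out$s_mrna[out$mrna_id == "g1"], -1)
  expect_equal(out$s_mrna[out$mrna_id == "g2"], -2)
  expect_identical(out$n_targeting[out$mrna_id == "g1"], 2L)
  expect_error(mrna_scores(ms, tm[0, ]), "empty target map")
})

test_that("an mRNA with no scored targeting miRNA scores zero", {
  ms <- data.frame(mirna_id = "a", s_mirna = 2)
  tm <- data.frame(mirna_id = c("a", "zzz"), mrna_id = c("g1", "g2"))
  out <- mrna_scores(ms, tm)
  expect_equal(out$s_mrna[out$mrna_id == "g2"], 0)
  expect_identical(out$n_targeting[out$mrna_id == "g2"], 0L)
})

test_that("unmapped miRNAs are reported and contribute nothing", {
  ms <- data.frame(mirna_id = c("a", "ghost"), s_mirna = c(2, 50))
  tm <- data.frame(mirna_id = "a", mrna_id = "g1")
  expect_message(out <- mrna_scores(ms, tm), "ghost")
  expect_equal(out$s_mrna, -2)
})

test_that("aggregation agrees with a brute-force pair-list sum", {
  set.seed(41)
  ms <- data.frame(mirna_id = paste0("mir", 1:10),
                   s_mirna = round(rnorm(10), 3))
  tm <- data.frame(mirna_id = sample(paste0("mir", 1:10), 100, replace = TRUE),
                   mrna_id = sample(paste0("g", 1:30), 100, replace = TRUE))
  tm <- unique(tm)
  out <- mrna_scores(ms, tm)
  for (g in out$mrna_id) {
    pairs <- tm$mirna_id[tm$mrna_id == g]
    brute <- -sum(ms$s_mirna[match(pairs, ms$mirna_id)])
    expect_equal(out$s_mrna[out$mrna_id == g], brute)
  }
})

test_that("score antisymmetry propagates to mRNA scores and coefficients", {
  cfg <- tiny_config(seed = 42)
  sim <- simulate_counts(cfg)
  de <- run_diffexp(apply_min_count(sim$counts, 4L))
  tm <- generate_target_map(cfg)
  ms_pos <- data.frame(mirna_id = de$mirna_id,
                       s_mirna = mirna_score(de$p_adj, de$log2fc))
  ms_neg <- data.frame(mirna_id = de$mirna_id,
                       s_mirna = mirna_score(de$p_adj, -de$log2fc))
  expect_equal(ms_neg$s_mirna, -ms_pos$s_mirna)
  rs_pos <- mrna_scores(ms_pos, tm)
  rs_neg <- mrna_scores(ms_neg, tm)
  expect_equal(rs_neg$s_mrna, -rs_pos$s_mrna)
  gs <- generate_gene_sets(cfg, tm, sim$ground_truth)
  for (set in gs$gene_sets[1:4]) {
    f_pos <- fit_logistic_gsa(rs_pos, set)
    f_neg <- fit_logistic_gsa(rs_neg, set)
    if (f_pos$status == "ok" && f_neg$status == "ok") {
      expect_equal(f_neg$coefficient, -f_pos$coefficient, tolerance = 1e-6)
    }
  }
})

test_that("splitting a miRNA score across two equal twins changes nothing", {
  ms <- data.frame(mirna_id = c("a", "b"), s_mirna = c(4, -1))
  tm <- data.frame(mirna_id = c("a", "a", "b"),
                   mrna_id = c("g1", "g2", "g1"))
  split_ms <- data.frame(mirna_id = c("a1", "a2", "b"),
                         s_mirna = c(2, 2, -1))
  split_tm <- data.frame(mirna_id = c("a1", "a1", "a2", "a2", "b"),
                         mrna_id = c("g1", "g2", "g1", "g2", "g1"))
  expect_equal(mrna_scores(ms, tm)$s_mrna,
               mrna_scores(split_ms, split_tm)$s_mrna)
})

test_that("a constant predictor is flagged degenerate, tiny sets skipped", {
  scores <- data.frame(mrna_id = paste0("g", 1:40), s_mrna = rep(1.5, 40))
  f <- fit_logistic_gsa(scores, paste0("g", 1:10))
  expect_identical(f$status, "degenerate")
  scores$s_mrna <- rnorm(40)
  expect_identical(fit_logistic_gsa(scores, paste0("g", 1:3))$status,
                   "skipped")
  expect_identical(fit_logistic_gsa(scores, paste0("g", 1:38))$status,
                   "skipped")
})

test_that("the Wald test holds its level under a null membership", {
  set.seed(43)
  n <- 2000
  scores <- data.frame(mrna_id = paste0("g", 1:n), s_mrna = rnorm(n, 0, 2))
  hits <- 0
  n_sets <- 200
  for (i in seq_len(n_sets)) {
    members <- sample(scores$mrna_id, 0.2 * n)
    f <- fit_logistic_gsa(scores, members)
    expect_identical(f$status, "ok")
    if (f$p_raw < 0.05) hits <- hits + 1
  }
  expect_gte(hits / n_sets, 0.02)
  expect_lte(hits / n_sets, 0.09)
})

test_that("the IRLS fit matches glm on random instances", {
  set.seed(44)
  for (i in 1:50) {
    n <- sample(100:300, 1)
    x <- rnorm(n, sd = runif(1, 0.5, 3))
    beta <- runif(1, -1, 1)
    y <- rbinom(n, 1, plogis(-1 + beta * x))
    if (sum(y) < 5 || sum(1 - y) < 5) next
    scores <- data.frame(mrna_id = as.character(seq_len(n)), s_mrna = x)
    f <- fit_logistic_gsa(scores, as.character(which(y == 1)))
    g <- stats::glm(y ~ x, family = stats::binomial())
    expect_identical(f$status, "ok")
    expect_equal(f$coefficient, unname(coef(g)[2]), tolerance = 1e-6)
    expect_equal(f$std_error,
                 unname(sqrt(diag(vcov(g))[2])), tolerance = 1e-3)
  }
})

test_that("sets concentrated at negative scores get negative coefficients", {
  # 30 targets of an upregulated miRNA (score +3 => target score near -3);
  # a set holding every other one of them against a spread-out background
  # whose tails straddle the cluster, so the MLE is finite
  set.seed(9)
  targets <- paste0("t", 1:30)
  background <- paste0("b", 1:170)
  scores <- data.frame(mrna_id = c(targets, background),
                       s_mrna = c(rnorm(30, -3, 0.3), rnorm(170, 0, 1.5)))
  f <- fit_logistic_gsa(scores, targets[seq(1, 30, by = 2)])
  expect_identical(f$status, "ok")
  expect_lt(f$coefficient, 0)
  expect_identical(coefficient_direction(f$coefficient),
                   "increased negative regulation")
})

test_that("collection tables are BH-adjusted, labelled and sorted", {
  set.seed(45)
  n <- 400
  scores <- data.frame(mrna_id = paste0("g", 1:n), s_mrna = rnorm(n))
  sets <- list(
    # half of the 80 lowest-scoring mRNAs: strong but not separable
    strong = sample(scores$mrna_id[order(scores$s_mrna)[1:80]], 40),
    weak = sample(scores$mrna_id, 40),
    tiny = paste0("g", 1:2)
  )
  expect_warning(tab <- gsa_collection(scores, sets), "tiny")
  expect_identical(nrow(tab), 2L)
  expect_false(is.unsorted(tab$p_adj))
  expect_identical(tab$set_id[1], "strong")
  expect_lt(tab$coefficient[tab$set_id == "strong"], 0)
  expect_equal(tab$p_adj, bh_brute(tab$p_raw), tolerance = 1e-12)
  expect_identical(tab$direction,
                   coefficient_direction(tab$coefficient))
  # a collection where every set is skipped warns twice: once for the
  # exclusions, once for having nothing to fit
  w <- capture_warnings(empty <- gsa_collection(scores,
                                                list(a = "g1", b = "g2")))
  expect_match(w, "excluded|no fit-eligible", all = TRUE)
  expect_identical(nrow(empty), 0L)
})

test_that("multi-collection analysis adjusts within each collection", {
  set.seed(46)
  n <- 300
  scores <- data.frame(mrna_id = paste0("g", 1:n), s_mrna = rnorm(n))
  mk <- function(k) lapply(seq_len(k), function(i) sample(scores$mrna_id, 30))
  cols <- list(GO_MF = setNames(mk(3), paste0("mf", 1:3)),
               KEGG = setNames(mk(2), paste0("kegg", 1:2)))
  tab <- gsa_all(scores, cols)
  expect_setequal(unique(tab$collection), c("GO_MF", "KEGG"))
  for (cn in c("GO_MF", "KEGG")) {
    sub <- tab[tab$collection == cn, ]
    expect_equal(sub$p_adj, bh_brute(sub$p_raw), tolerance = 1e-12)
  }
})
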