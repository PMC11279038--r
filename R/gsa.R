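#' @name gene-set-analysis
#' @title Score-based logistic-regression gene set analysis
#' @description
#' Each miRNA receives a signed significance score,
#' `S_miRNA = -log10(p) * signum(log2 FC)` with `p` the FDR-adjusted
#' p-value. Each mRNA receives the negated sum of the scores of the miRNAs
#' targeting it, `S_mRNA = -sum(S_miRNA_i)`, so mRNAs targeted by
#' upregulated miRNAs score negative (stronger repression). For every gene
#' set, membership of each mRNA in the universe is regressed on `S_mRNA`
#' by logistic regression; a positive slope indicates decreased negative
#' regulation by miRNA in the frozen group, a negative slope increased
#' negative regulation. P-values are Wald z tests, adjusted by
#' Benjamini-Hochberg within each collection.
NULL

#' Signed miRNA significance score
#'
#' `-log10(max(p_adj, p_floor)) * signum(log2fc)`; `signum(0) = 0`.
#'
#' @param p_adj FDR-adjusted p-value(s) in [0, 1].
#' @param log2fc Log2 fold change(s).
#' @param p_floor Lower bound applied to p before the log to keep scores
#'   finite.
#' @return Numeric score(s).
#' @export
mirna_score <- function(p_adj, log2fc, p_floor = 1e-300) {
  stopifnot(all(p_adj >= 0 & p_adj <= 1), p_floor > 0)
  -log10(pmax(p_adj, p_floor)) * sign(log2fc)
}

#' Aggregate miRNA scores into per-mRNA scores over a target map
#'
#' For every mRNA in the target-map universe,
#' `s_mrna = -sum(s_mirna)` over the scored miRNAs targeting it; mRNAs
#' targeted by no scored miRNA get score 0 with `n_targeting = 0`. Scored
#' miRNAs absent from the map contribute nothing (a message reports them).
#'
#' @param mirna_scores Data frame with `mirna_id` and `s_mirna` (e.g. built
#'   from a [run_diffexp()] table via [mirna_score()]).
#' @param target_map Data frame with `mirna_id`, `mrna_id`.
#' @return Data frame per mRNA: `mrna_id`, `s_mrna`, `n_targeting`,
#'   `contributing` (semicolon-joined miRNA ids).
#' @export
mrna_scores <- function(mirna_scores, target_map) {
  stopifnot(all(c("mirna_id", "s_mirna") %in% names(mirna_scores)),
            all(c("mirna_id", "mrna_id") %in% names(target_map)))
  if (nrow(target_map) == 0L) stop("empty target map")
  unmapped <- setdiff(mirna_scores$mirna_id, target_map$mirna_id)
  if (length(unmapped)) {
    message(length(unmapped), " scored miRNA(s) absent from the target map",
            " contribute nothing: ", paste(unmapped, collapse = ", "))
  }
  universe <- sort(unique(target_map$mrna_id))
  idx <- match(target_map$mirna_id, mirna_scores$mirna_id)
  scored <- !is.na(idx)
  pair_score <- mirna_scores$s_mirna[idx[scored]]
  pair_mrna <- factor(target_map$mrna_id[scored], levels = universe)
  s <- -as.vector(tapply(pair_score, pair_mrna, sum, default = 0))
  n <- as.vector(table(pair_mrna))
  contrib <- vapply(split(target_map$mirna_id[scored], pair_mrna),
                    paste, "", collapse = ";")
  data.frame(mrna_id = universe, s_mrna = s, n_targeting = n,
             contributing = unname(contrib), stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Logistic regression of gene-set membership on mRNA scores
#'
#' Fits `membership ~ intercept + s_mrna` by iteratively reweighted least
#' squares over the mRNA universe and reports the slope, its standard
#' error from the inverse observed information, and a two-sided Wald-z
#' p-value. Sets with fewer than `min_size` members (or non-members) in
#' the universe are skipped; a constant predictor, an absolute slope above
#' 50, or failure to converge yields a separation/degenerate flag.
#'
#' @param scores Data frame from [mrna_scores()] (universe).
#' @param members Character vector of member mRNA ids.
#' @param min_size Minimum members and non-members in the universe.
#' @param max_iter,tol IRLS iteration cap and convergence tolerance on the
#'   coefficient step.
#' @return List: `coefficient`, `std_error`, `p_raw`,
#'   `n_members_in_universe`, `status` (one of `ok`, `skipped`,
#'   `degenerate`, `separation`).
#' @export
fit_logistic_gsa <- function(scores, members, min_size = 5L,
                             max_iter = 100L, tol = 1e-8) {
  y <- as.numeric(scores$mrna_id %in% members)
  n1 <- sum(y)
  res <- list(coefficient = NA_real_, std_error = NA_real_,
              p_raw = NA_real_, n_members_in_universe = as.integer(n1),
              status = "ok")
  if (n1 < min_size || (length(y) - n1) < min_size) {
    res$status <- "skipped"
    return(res)
  }
  x <- scores$s_mrna
  if (stats::var(x) == 0) {
    res$status <- "degenerate"
    return(res)
  }
  X <- cbind(1, x)
  deviance_of <- function(beta) {
    eta <- pmin(pmax(drop(X %*% beta), -30), 30)
    -2 * sum(y * stats::plogis(eta, log.p = TRUE) +
               (1 - y) * stats::plogis(-eta, log.p = TRUE))
  }
  beta <- c(log(mean(y) / (1 - mean(y))), 0)
  dev <- deviance_of(beta)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    xtwx <- crossprod(X * w, X)
    beta_new <- tryCatch(drop(solve(xtwx, crossprod(X * w, z))),
                         error = function(e) NULL)
    if (is.null(beta_new) || any(!is.finite(beta_new))) {
      res$status <- "degenerate"
      return(res)
    }
    # step-halve until the deviance stops increasing (safeguarded IRLS)
    dev_new <- deviance_of(beta_new)
    halvings <- 0L
    while (dev_new > dev + 1e-8 && halvings < 30L) {
      beta_new <- (beta + beta_new) / 2
      dev_new <- deviance_of(beta_new)
      halvings <- halvings + 1L
    }
    step <- max(abs(beta_new - beta))
    beta <- beta_new
    dev <- dev_new
    if (abs(beta[2]) > 50) {
      res$status <- "separation"
      return(res)
    }
    if (step < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    res$status <- "separation"
    return(res)
  }
  eta <- drop(X %*% beta)
  mu <- stats::plogis(eta)
  info <- crossprod(X * (mu * (1 - mu)), X)
  vc <- tryCatch(solve(info), error = function(e) NULL)
  if (is.null(vc) || vc[2, 2] <= 0) {
    res$status <- "degenerate"
    return(res)
  }
  res$coefficient <- unname(beta[2])
  res$std_error <- sqrt(vc[2, 2])
  res$p_raw <- 2 * stats::pnorm(-abs(beta[2] / res$std_error))
  res
}

#' Direction label for a gene-set coefficient
#'
#' Positive coefficients indicate decreased negative regulation by miRNA
#' in the frozen group; negative coefficients indicate increased negative
#' regulation.
#'
#' @param coefficient Numeric coefficient(s).
#' @return Character label(s).
#' @export
coefficient_direction <- function(coefficient) {
  ifelse(coefficient > 0, "decreased negative regulation",
         ifelse(coefficient < 0, "increased negative regulation", "none"))
}

#' Gene set analysis over one collection
#'
#' Fits every set of a collection, applies Benjamini-Hochberg within the
#' collection to the fit-eligible sets, labels directions and sorts by
#' adjusted p-value. Skipped and flagged sets are excluded from the FDR
#' with a warning.
#'
#' @param scores Data frame from [mrna_scores()].
#' @param gene_sets Named list of member vectors (e.g. from [read_gmt()]).
#' @param collection Collection label (`GO_MF`, `GO_BP`, `GO_CC`, `KEGG`,
#'   or `custom`).
#' @param alpha Significance cutoff on the adjusted p-value (strict).
#' @param min_size Passed to [fit_logistic_gsa()].
#' @return Data frame per analyzed set: `collection`, `set_id`,
#'   `coefficient`, `std_error`, `p_raw`, `p_adj`,
#'   `n_members_in_universe`, `direction`, `significant`, sorted by
#'   `p_adj`.
#' @export
gsa_collection <- function(scores, gene_sets, collection = "custom",
                           alpha = 0.05, min_size = 5L) {
  stopifnot(!is.null(names(gene_sets)), length(gene_sets) >= 1L)
  fits <- lapply(gene_sets, fit_logistic_gsa, scores = scores,
                 min_size = min_size)
  status <- vapply(fits, `[[`, "", "status")
  if (any(status != "ok")) {
    bad <- status[status != "ok"]
    warning(length(bad), " set(s) excluded from FDR in collection ",
            collection, ": ",
            paste(sprintf("%s (%s)", names(bad), bad), collapse = ", "))
  }
  ok <- which(status == "ok")
  if (length(ok) == 0L) {
    warning("collection ", collection, ": no fit-eligible set")
    return(data.frame(collection = character(0), set_id = character(0),
                      coefficient = numeric(0), std_error = numeric(0),
                      p_raw = numeric(0), p_adj = numeric(0),
                      n_members_in_universe = integer(0),
                      direction = character(0), significant = logical(0),
                      stringsAsFactors = FALSE))
  }
  out <- data.frame(
    collection = collection,
    set_id = names(gene_sets)[ok],
    coefficient = vapply(fits[ok], `[[`, 0, "coefficient"),
    std_error = vapply(fits[ok], `[[`, 0, "std_error"),
    p_raw = vapply(fits[ok], `[[`, 0, "p_raw"),
    stringsAsFactors = FALSE, row.names = NULL
  )
  out$p_adj <- bh_adjust(out$p_raw)
  out$n_members_in_universe <-
    vapply(fits[ok], `[[`, 0L, "n_members_in_universe")
  out$direction <- coefficient_direction(out$coefficient)
  out$significant <- out$p_adj < alpha
  out[order(out$p_adj, out$p_raw, out$set_id), , drop = FALSE]
}

#' Gene set analysis over several collections
#'
#' Runs [gsa_collection()] per collection (FDR within each) and binds the
#' tables.
#'
#' @param scores Data frame from [mrna_scores()].
#' @param collections Named list of gene-set lists, one per collection.
#' @param ... Passed to [gsa_collection()].
#' @return Combined data frame.
#' @export
gsa_all <- function(scores, collections, ...) {
  stopifnot(!is.null(names(collections)))
  tabs <- lapply(names(collections), function(cn) {
    gsa_collection(scores, collections[[cn]], collection = cn, ...)
  })
  out <- do.call(rbind, tabs)
  rownames(out) <- NULL
  out
}
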