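#' Inference configuration
#'
#' @param alpha per-construct significance cutoff (the screen used 0.01).
#' @param min_hits minimum number of significantly depleted constructs for a
#'   gene-level essential call (the "two-hit" rule; default 2).
#' @param sidedness `two_sided` (default; direction then comes from the sign
#'   of the median fold change relative to the null), `one_sided_less`, or
#'   `one_sided_greater`.
#' @param null_class control class whose constructs form the empirical null
#'   (default `"negative"`).
#' @param p_adjust multiplicity correction applied to construct p-values
#'   before thresholding: `"none"` (default; the two-hit rule is the error
#'   control) or `"BH"`.
#' @return an `inference_config` list.
#' @export
inference_config <- function(alpha = 0.01, min_hits = 2L,
                             sidedness = c("two_sided", "one_sided_less",
                                           "one_sided_greater"),
                             null_class = "negative",
                             p_adjust = c("none", "BH")) {
  sidedness <- match.arg(sidedness)
  p_adjust <- match.arg(p_adjust)
  stopifnot(alpha > 0, alpha < 1, min_hits >= 1,
            null_class %in% control_classes)
  structure(list(alpha = alpha, min_hits = as.integer(min_hits),
                 sidedness = sidedness, null_class = null_class,
                 p_adjust = p_adjust),
            class = "inference_config")
}

#' Wilcoxon rank-sum test
#'
#' Mann-Whitney U with average ranks for ties. The p-value is exact (by
#' enumeration of the U null distribution) when `length(x) + length(y) <= 12`
#' and there are no ties, and otherwise uses the normal approximation with tie
#' and continuity corrections. Computation is delegated to
#' [stats::wilcox.test()]; the exactness policy above is fixed here so results
#' do not depend on sample-size heuristics.
#'
#' @param x,y non-empty numeric vectors.
#' @param sidedness see [inference_config()]; `one_sided_less` tests whether
#'   `x` is stochastically smaller than `y`.
#' @return list with `U` (the Mann-Whitney statistic for `x`) and `p`.
#' @export
rank_sum_test <- function(x, y, sidedness = c("two_sided", "one_sided_less",
                                              "one_sided_greater")) {
  sidedness <- match.arg(sidedness)
  if (length(x) == 0 || length(y) == 0) {
    stop("rank_sum_test requires non-empty samples", call. = FALSE)
  }
  alt <- switch(sidedness, two_sided = "two.sided",
                one_sided_less = "less", one_sided_greater = "greater")
  no_ties <- anyDuplicated(c(x, y)) == 0L
  use_exact <- (length(x) + length(y) <= 12) && no_ties
  ht <- suppressWarnings(
    wilcox.test(x, y, alternative = alt, exact = use_exact, correct = TRUE)
  )
  p <- ht$p.value
  # degenerate null variance (e.g. every pooled value identical): no evidence
  if (is.nan(p)) p <- 1
  list(U = unname(ht$statistic), p = min(max(p, 0), 1))
}

#' Per-construct depletion/enrichment tests
#'
#' Tests every construct's fold changes across biological replicates against
#' the pooled fold changes of all null-class (negative-control) constructs
#' across the same replicates. A null-class construct under test is excluded
#' from its own null sample. Direction is `depleted` if the construct's median
#' log2 fold change is below the null median, `enriched` if above, and
#' `neutral` on an exact tie (neutral never counts toward depletion hits).
#'
#' @param fc fold-change matrix from [build_fold_change_matrix()]
#'   (constructs x replicates).
#' @param manifest the pool manifest covering all rows of `fc`.
#' @param config an [inference_config()].
#' @return a data.frame (`construct_calls`) with one row per construct:
#'   `construct_id`, `gene`, `control_class`, `median_log2fc`, `U_statistic`,
#'   `p_value`, `direction`, `significant`.
#' @export
construct_tests <- function(fc, manifest, config = inference_config()) {
  stopifnot(is.matrix(fc), !is.null(rownames(fc)))
  idx <- match(rownames(fc), manifest$construct_id)
  if (anyNA(idx)) {
    stop("fold-change matrix contains constructs absent from the manifest",
         call. = FALSE)
  }
  m <- as.data.frame(manifest)[idx, , drop = FALSE]
  null_rows <- which(m$control_class == config$null_class)
  if (length(null_rows) == 0) {
    stop("no constructs of null class '", config$null_class,
         "' present; cannot form the null distribution", call. = FALSE)
  }
  if (ncol(fc) < 2) {
    warning("only one biological replicate; tests proceed with n = 1")
  }
  n <- nrow(fc)
  U <- numeric(n); p <- numeric(n); med <- numeric(n)
  direction <- character(n)
  for (i in seq_len(n)) {
    x <- fc[i, ]
    y_rows <- setdiff(null_rows, i)
    if (length(y_rows) == 0) {
      stop("construct '", m$construct_id[i], "' is the only null-class ",
           "construct; no null sample remains after excluding it", call. = FALSE)
    }
    y <- as.vector(fc[y_rows, , drop = FALSE])
    rt <- rank_sum_test(x, y, config$sidedness)
    U[i] <- rt$U; p[i] <- rt$p
    med[i] <- median(x)
    null_med <- median(y)
    direction[i] <- if (med[i] < null_med) "depleted"
                    else if (med[i] > null_med) "enriched" else "neutral"
  }
  p_adj <- if (config$p_adjust == "BH") p.adjust(p, "BH") else p
  out <- data.frame(construct_id = m$construct_id, gene = m$gene,
                    control_class = m$control_class, median_log2fc = med,
                    U_statistic = U, p_value = p, direction = direction,
                    significant = p_adj <= config$alpha,
                    stringsAsFactors = FALSE)
  attr(out, "config") <- config
  class(out) <- c("construct_calls", "data.frame")
  out
}

#' Gene-level two-hit calls
#'
#' A gene is called essential iff at least `min_hits` (default 2) of its
#' constructs are independently significantly depleted. Enriched constructs
#' are counted for reporting but never contribute to the essential call.
#'
#' @param calls output of [construct_tests()].
#' @param config an [inference_config()].
#' @return a data.frame (`gene_calls`): `gene`, `n_constructs`,
#'   `n_depleted_significant`, `n_enriched_significant`, `essential_call`.
#' @export
gene_two_hit_calls <- function(calls, config = inference_config()) {
  stopifnot(nrow(calls) >= 1)
  genes <- unique(calls$gene)
  dep <- calls$significant & calls$direction == "depleted"
  enr <- calls$significant & calls$direction == "enriched"
  out <- data.frame(
    gene = genes,
    n_constructs = vapply(genes, function(g) sum(calls$gene == g), integer(1)),
    n_depleted_significant = vapply(genes, function(g)
      sum(dep[calls$gene == g]), integer(1)),
    n_enriched_significant = vapply(genes, function(g)
      sum(enr[calls$gene == g]), integer(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  out$essential_call <- out$n_depleted_significant >= config$min_hits
  class(out) <- c("gene_calls", "data.frame")
  out
}

#' Null probability of a spurious two-hit gene call
#'
#' Under the null that construct fold changes are independent, the chance of a
#' gene acquiring two significantly depleted constructs is `alpha^2` in the
#' simple pairwise reading, or `P(X >= 2)` with `X ~ Binomial(n_constructs,
#' alpha)` when the number of constructs per gene is accounted for.
#'
#' @param alpha per-construct significance level, in (0, 1).
#' @param n_constructs constructs targeting the gene.
#' @param mode `"paper_pairwise"` (`alpha^2`; requires `n_constructs >= 2`) or
#'   `"binomial_at_least_2"` (returns 0 when `n_constructs < 2`).
#' @return a probability.
#' @export
two_hit_null_probability <- function(alpha, n_constructs,
                                     mode = c("paper_pairwise",
                                              "binomial_at_least_2")) {
  mode <- match.arg(mode)
  stopifnot(alpha >= 0, alpha < 1)
  if (mode == "paper_pairwise") {
    if (n_constructs < 2) {
      stop("pairwise mode requires at least 2 constructs per gene", call. = FALSE)
    }
    return(alpha^2)
  }
  if (n_constructs < 2) return(0)
  pbinom(1, n_constructs, alpha, lower.tail = FALSE)
}

#' Control-based error-rate estimates
#'
#' False negative rate = fraction of positive-control genes *not* called
#' essential; false positive rate = fraction of negative-control genes called
#' essential. A class with no genes yields `NA` for its rate. When construct
#' calls are supplied, the fraction of positive-class constructs that are
#' significantly enriched (a normalization artifact to monitor) is also
#' reported.
#'
#' @param gene_calls output of [gene_two_hit_calls()].
#' @param manifest the pool manifest (each gene must have one control class).
#' @param construct_calls optional output of [construct_tests()].
#' @return a `performance_report` list.
#' @export
control_performance <- function(gene_calls, manifest, construct_calls = NULL) {
  cls <- gene_classes(manifest)
  cls <- cls[gene_calls$gene]
  pos <- gene_calls[cls == "positive", , drop = FALSE]
  neg <- gene_calls[cls == "negative", , drop = FALSE]
  n_pos <- nrow(pos); n_neg <- nrow(neg)
  n_pos_called <- sum(pos$essential_call)
  n_neg_called <- sum(neg$essential_call)
  out <- list(
    n_positive = n_pos, n_positive_called = n_pos_called,
    fnr = if (n_pos > 0) (n_pos - n_pos_called) / n_pos else NA_real_,
    n_negative = n_neg, n_negative_called = n_neg_called,
    fpr = if (n_neg > 0) n_neg_called / n_neg else NA_real_
  )
  if (!is.null(construct_calls)) {
    pc <- construct_calls[construct_calls$control_class == "positive", ,
                          drop = FALSE]
    out$n_positive_constructs <- nrow(pc)
    out$n_positive_constructs_enriched <-
      sum(pc$significant & pc$direction == "enriched")
    out$positive_construct_enrichment_rate <- if (nrow(pc) > 0)
      out$n_positive_constructs_enriched / nrow(pc) else NA_real_
  }
  structure(out, class = "performance_report")
}

#' @export
print.performance_report <- function(x, ...) {
  fmt <- function(r) if (is.na(r)) "NA" else sprintf("%.1f%%", 100 * r)
  cat("Screen performance against control genes\n")
  cat(sprintf("  positives: %d/%d called essential  -> FNR %s\n",
              x$n_positive_called, x$n_positive, fmt(x$fnr)))
  cat(sprintf("  negatives: %d/%d called essential  -> FPR %s\n",
              x$n_negative_called, x$n_negative, fmt(x$fpr)))
  if (!is.null(x$n_positive_constructs)) {
    cat(sprintf("  positive-class constructs enriched: %d/%d (%s)\n",
                x$n_positive_constructs_enriched, x$n_positive_constructs,
                fmt(x$positive_construct_enrichment_rate)))
  }
  invisible(x)
}
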