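#' Minimum detectable fold change vs number of biological replicates
#'
#' For each replicate count `r` and each significance cutoff, random
#' `r`-column subsets of the fold-change matrix are drawn (all subsets are
#' enumerated when there are no more than `n_draws` of them), the construct
#' tests are rerun on each subset, and the smallest `|median log2 fold
#' change|` among significantly depleted constructs is recorded (missing when
#' nothing is significant, as happens for stringent cutoffs at very low
#' replicate counts). The median and SD of that minimum across draws trace how
#' the detectable effect size shrinks as replicates are added.
#'
#' @param fc fold-change matrix (constructs x replicates, >= 2 columns).
#' @param manifest the pool manifest.
#' @param alphas significance cutoffs to evaluate (p-values are computed once
#'   per draw and thresholded at every cutoff).
#' @param n_draws subset draws per replicate count (default 200).
#' @param seed integer seed; the curve is bit-reproducible given
#'   `(seed, n_draws)`.
#' @param config an [inference_config()] (sidedness/null class; `alpha` inside
#'   it is ignored in favor of `alphas`).
#' @return a data.frame (`replicate_curve`): `n_replicates`, `alpha`,
#'   `median_min_abs_log2fc`, `sd`, `n_informative_draws`, `n_draws`.
#' @export
replicate_subsample_curve <- function(fc, manifest,
                                      alphas = c(0.1, 0.05, 0.01),
                                      n_draws = 200, seed = NULL,
                                      config = inference_config()) {
  stopifnot(is.matrix(fc), ncol(fc) >= 2)
  if (!is.null(seed)) set.seed(seed)
  R <- ncol(fc)
  rows <- list()
  for (r in seq_len(R)) {
    n_subsets <- choose(R, r)
    subsets <- if (n_subsets <= n_draws) {
      asplit(combn(R, r), 2L)
    } else {
      replicate(n_draws, sort(sample.int(R, r)), simplify = FALSE)
    }
    mins <- matrix(NA_real_, nrow = length(subsets), ncol = length(alphas))
    for (d in seq_along(subsets)) {
      calls <- suppressWarnings(
        construct_tests(fc[, subsets[[d]], drop = FALSE], manifest, config))
      dep <- calls$direction == "depleted"
      for (a in seq_along(alphas)) {
        sel <- dep & calls$p_value <= alphas[a]
        if (any(sel)) mins[d, a] <- min(abs(calls$median_log2fc[sel]))
      }
    }
    for (a in seq_along(alphas)) {
      v <- mins[, a]
      rows[[length(rows) + 1L]] <- data.frame(
        n_replicates = r, alpha = alphas[a],
        median_min_abs_log2fc = if (all(is.na(v))) NA_real_
                                else median(v, na.rm = TRUE),
        sd = if (sum(!is.na(v)) > 1) sd(v, na.rm = TRUE) else NA_real_,
        n_informative_draws = sum(!is.na(v)),
        n_draws = length(subsets)
      )
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "seed") <- seed
  class(out) <- c("replicate_curve", "data.frame")
  out
}

#' Thin a count table to a target mean coverage
#'
#' Binomial thinning: every read is kept independently with probability
#' `p = target_mean_coverage / current_mean_coverage` (equivalent to uniform
#' read subsampling). `p = 1` returns the table unchanged; a target above the
#' current mean coverage is an error.
#'
#' @param table a [raw_count_table()].
#' @param target_mean_coverage desired mean reads per construct.
#' @param seed optional integer seed (otherwise the ambient RNG stream is
#'   used, so callers can manage reproducibility themselves).
#' @return a thinned [raw_count_table()] with totals recomputed.
#' @export
downsample_counts <- function(table, target_mean_coverage, seed = NULL) {
  stopifnot(inherits(table, "raw_counts"), target_mean_coverage >= 0)
  cur <- mean(table$counts)
  if (target_mean_coverage > cur * (1 + 1e-9)) {
    stop("target mean coverage (", target_mean_coverage,
         ") exceeds current mean coverage (", signif(cur, 6), ")", call. = FALSE)
  }
  p <- min(target_mean_coverage / cur, 1)
  if (p == 1) return(table)
  if (!is.null(seed)) set.seed(seed)
  kept <- rbinom(length(table$counts), as.integer(round(table$counts)), p)
  unm <- rbinom(1L, table$n_unmapped, p)
  multi <- rbinom(1L, table$n_multimapped, p)
  raw_count_table(table$library_id,
                  setNames(kept, names(table$counts)),
                  n_reads_total = sum(kept) + unm + multi,
                  n_unmapped = unm, n_multimapped = multi,
                  sample_id = table$sample_id, tech_rep = table$tech_rep)
}

#' Detection power vs read coverage
#'
#' For each target coverage, all post-selection (e.g. testis) technical
#' libraries are binomially thinned (`n_draws` independent thinnings), the
#' full pipeline is rerun (median aggregation, RPM + log2 fold change against
#' the *unthinned* input pool, construct tests, two-hit gene calls), and power
#' is the mean fraction of positive-control genes called essential. No
#' monotone smoothing is applied. With the target equal to the observed
#' coverage and `n_draws = 1` the result equals the plain pipeline exactly.
#'
#' @param replicate_tables nested list: one element per biological replicate,
#'   each a list of technical-replicate [raw_count_table()]s.
#' @param input_pool the input-pool table ([count_table()] or raw table).
#' @param manifest the pool manifest.
#' @param config an [inference_config()].
#' @param coverages target mean coverages (each at most the observed mean).
#' @param n_draws independent thinnings per coverage.
#' @param seed integer seed for the whole curve.
#' @param pseudocount passed to [build_fold_change_matrix()].
#' @return a data.frame (`power_curve`): `mean_coverage`, `power`, `sd`,
#'   `n_draws`, sorted by increasing coverage.
#' @export
coverage_power_curve <- function(replicate_tables, input_pool, manifest,
                                 config = inference_config(),
                                 coverages, n_draws = 20, seed = NULL,
                                 pseudocount = 0.5) {
  if (!is.null(seed)) set.seed(seed)
  coverages <- sort(coverages)
  input_agg <- if (inherits(input_pool, "count_table")) input_pool
               else aggregate_technical(input_pool)
  gcls <- gene_classes(manifest)
  pos_genes <- names(gcls)[gcls == "positive"]
  if (length(pos_genes) == 0) {
    stop("no positive-control genes in the manifest; power is undefined",
         call. = FALSE)
  }
  rows <- lapply(coverages, function(cov) {
    pw <- vapply(seq_len(n_draws), function(d) {
      samples <- lapply(replicate_tables, function(techs) {
        aggregate_technical(lapply(techs, downsample_counts,
                                   target_mean_coverage = cov))
      })
      fc <- build_fold_change_matrix(samples, input_agg, pseudocount)
      gc <- gene_two_hit_calls(construct_tests(fc, manifest, config), config)
      mean(gc$essential_call[gc$gene %in% pos_genes])
    }, numeric(1))
    data.frame(mean_coverage = cov, power = mean(pw),
               sd = if (n_draws > 1) sd(pw) else NA_real_, n_draws = n_draws)
  })
  out <- do.call(rbind, rows)
  attr(out, "seed") <- seed
  class(out) <- c("power_curve", "data.frame")
  out
}

#' Screen capacity arithmetic
#'
#' How many constructs (and genes) a pooled in vivo screen can carry, given
#' the total number of cells in the tissue, the transfection efficiency, and a
#' required minimum number of independently transfected cells per construct.
#'
#' @param n_cells_total cells available in the tissue (adult mouse testis:
#'   about 1e8).
#' @param transfection_efficiency fraction of cells receiving a construct.
#' @param min_cells_per_construct required independent cells per construct
#'   (default 100).
#' @param constructs_per_gene library design density (default 5).
#' @param library_size optional current library size L, for which the mean
#'   number of transfected cells per construct is reported.
#' @return a `capacity_estimate` list with `cells_transfected`,
#'   `mean_cells_per_construct` (when `library_size` is given),
#'   `max_constructs`, `max_genes`.
#' @export
screen_capacity <- function(n_cells_total, transfection_efficiency,
                            min_cells_per_construct = 100,
                            constructs_per_gene = 5, library_size = NULL) {
  stopifnot(n_cells_total > 0, transfection_efficiency > 0,
            transfection_efficiency <= 1, min_cells_per_construct > 0,
            constructs_per_gene > 0)
  cells <- n_cells_total * transfection_efficiency
  max_constructs <- floor(cells / min_cells_per_construct)
  structure(list(
    cells_transfected = cells,
    mean_cells_per_construct = if (!is.null(library_size))
      floor(cells / library_size) else NA_real_,
    max_constructs = max_constructs,
    max_genes = floor(max_constructs / constructs_per_gene)
  ), class = "capacity_estimate")
}

#' @export
print.capacity_estimate <- function(x, ...) {
  cat("Screen capacity:", format(x$cells_transfected, big.mark = ","),
      "transfected cells\n")
  if (!is.na(x$mean_cells_per_construct)) {
    cat("  mean cells per construct at current library size:",
        x$mean_cells_per_construct, "\n")
  }
  cat("  max constructs:", x$max_constructs, " -> max genes:", x$max_genes, "\n")
  invisible(x)
}
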