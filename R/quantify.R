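#' Aggregated count table for one biological sample
#'
#' @param sample_id biological sample identifier.
#' @param counts named non-negative numeric vector (median aggregation can
#'   yield half-integers).
#' @param n_tech_reps number of technical replicates aggregated.
#' @return a `count_table` object.
#' @export
count_table <- function(sample_id, counts, n_tech_reps = 1L) {
  stopifnot(!is.null(names(counts)), all(counts >= 0))
  structure(list(sample_id = sample_id, counts = counts,
                 n_tech_reps = as.integer(n_tech_reps)),
            class = "count_table")
}

get_counts <- function(x) {
  if (inherits(x, c("raw_counts", "count_table"))) x$counts
  else if (is.numeric(x) && !is.null(names(x))) x
  else stop("expected a count table or named numeric vector", call. = FALSE)
}

#' Collapse technical replicates by the median
#'
#' Technical sequencing replicates of the same biological sample are collapsed
#' to one table by taking, per construct, the median count across replicates
#' (for an even number of replicates, the mean of the two middle values). The
#' result is invariant to replicate order and is the identity on a single
#' table.
#'
#' @param tables list of [raw_count_table()] (or `count_table`) objects for
#'   one biological sample, all sharing the manifest construct set.
#' @param sample_id identifier for the aggregated sample; defaults to the
#'   first table's `sample_id`.
#' @return a [count_table()].
#' @export
aggregate_technical <- function(tables, sample_id = NULL) {
  if (inherits(tables, c("raw_counts", "count_table"))) tables <- list(tables)
  stopifnot(length(tables) >= 1)
  ref_names <- names(get_counts(tables[[1]]))
  mats <- lapply(tables, function(t) {
    cnt <- get_counts(t)
    if (!setequal(names(cnt), ref_names)) {
      stop("technical replicates have mismatched construct sets", call. = FALSE)
    }
    cnt[ref_names]
  })
  mat <- do.call(cbind, mats)
  med <- apply(mat, 1L, median)
  if (is.null(sample_id)) {
    sample_id <- tables[[1]]$sample_id %||% tables[[1]]$library_id %||% "sample"
  }
  count_table(sample_id, setNames(med, ref_names), n_tech_reps = length(tables))
}

#' Normalize counts to reads per million
#'
#' `rpm[c] = 1e6 * (counts[c] + pseudocount) / sum(counts + pseudocount)`.
#' The pseudocount is folded into the denominator, so the result always sums
#' to one million.
#'
#' @param table a [count_table()] (or raw table / named vector).
#' @param pseudocount non-negative real added to every construct's count;
#'   a positive value keeps downstream log fold changes finite.
#' @return an `rpm_table` with fields `sample_id`, `rpm`, `pseudocount`.
#' @export
normalize_rpm <- function(table, pseudocount = 0) {
  stopifnot(pseudocount >= 0)
  cnt <- get_counts(table)
  adj <- cnt + pseudocount
  total <- sum(adj)
  if (total <= 0) {
    stop("cannot normalize: all counts are zero and pseudocount is 0",
         call. = FALSE)
  }
  structure(list(sample_id = if (is.list(table))
                   table$sample_id %||% table$library_id else "sample",
                 rpm = 1e6 * adj / total,
                 pseudocount = pseudocount),
            class = "rpm_table")
}

#' Per-construct log2 fold change against the input pool
#'
#' `log2fc[c] = log2(rpm_sample[c] / rpm_reference[c])`, where the reference
#' is the sequenced input pool of the same pool design ("the actual injected
#' material"). Both tables should be normalized with a positive pseudocount so
#' every entry is finite.
#'
#' @param sample,reference `rpm_table` objects over the same construct set.
#' @return named numeric vector of log2 fold changes, in sample order.
#' @export
log2_fold_change <- function(sample, reference) {
  stopifnot(inherits(sample, "rpm_table"), inherits(reference, "rpm_table"))
  missing <- setdiff(names(sample$rpm), names(reference$rpm))
  if (length(missing) > 0) {
    stop("construct(s) missing in reference: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  log2(sample$rpm / reference$rpm[names(sample$rpm)])
}

#' Build a fold-change matrix across biological replicates
#'
#' Normalizes each biological sample and the input-pool reference to RPM with
#' a shared pseudocount, and returns the constructs x replicates matrix of
#' log2 fold changes relative to the reference. Samples must share the
#' reference's construct set (mixing pool designs is an error); fold-change
#' matrices from different experiments with the same pool design, each built
#' against its own sequenced input pool, can then be combined with
#' [merge_fold_change_matrices()] to gain biological replicates.
#'
#' @param samples list of [count_table()] objects (one per biological
#'   replicate), or a single table.
#' @param reference the input-pool [count_table()].
#' @param pseudocount added to all counts before RPM; default 0.5 keeps log
#'   fold changes finite with minimal bias.
#' @return numeric matrix (constructs x replicates) with attributes
#'   `reference_id` and `pseudocount`.
#' @export
build_fold_change_matrix <- function(samples, reference, pseudocount = 0.5) {
  stopifnot(pseudocount > 0)
  if (inherits(samples, c("count_table", "raw_counts"))) samples <- list(samples)
  ref_rpm <- normalize_rpm(reference, pseudocount)
  ref_names <- names(ref_rpm$rpm)
  cols <- lapply(samples, function(s) {
    cnt <- get_counts(s)
    if (!setequal(names(cnt), ref_names)) {
      stop("sample '", s$sample_id %||% "?", "' does not share the reference ",
           "construct set (mixing pool designs?)", call. = FALSE)
    }
    log2_fold_change(normalize_rpm(s, pseudocount), ref_rpm)[ref_names]
  })
  fc <- do.call(cbind, cols)
  colnames(fc) <- vapply(seq_along(samples), function(i) {
    samples[[i]]$sample_id %||% paste0("rep", i)
  }, character(1))
  rownames(fc) <- ref_names
  attr(fc, "reference_id") <- reference$sample_id %||% "input_pool"
  attr(fc, "pseudocount") <- pseudocount
  fc
}

#' @rdname build_fold_change_matrix
#' @param ... fold-change matrices over the same construct set (same pool
#'   design) to merge column-wise.
#' @export
merge_fold_change_matrices <- function(...) {
  mats <- list(...)
  stopifnot(length(mats) >= 1)
  rn <- rownames(mats[[1]])
  for (m in mats[-1]) {
    if (!identical(rownames(m), rn)) {
      stop("cannot merge fold-change matrices from different pool designs",
           call. = FALSE)
    }
  }
  out <- do.call(cbind, mats)
  attr(out, "reference_id") <- unlist(lapply(mats, attr, "reference_id"))
  attr(out, "pseudocount") <- attr(mats[[1]], "pseudocount")
  out
}
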