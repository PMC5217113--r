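#' Read / write per-library count tables
#'
#' TSV with columns `construct_id` and `count`; [write_count_table()] also
#' writes a JSON sidecar (`<path>.stats.json`) with the read-accounting
#' totals.
#'
#' @param table a [raw_count_table()] or [count_table()].
#' @param path TSV path.
#' @param sidecar write the JSON mapping-stats sidecar (raw tables only).
#' @export
write_count_table <- function(table, path, sidecar = inherits(table, "raw_counts")) {
  cnt <- get_counts(table)
  df <- data.frame(construct_id = names(cnt), count = unname(cnt))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (sidecar) {
    stats <- list(library_id = table$library_id,
                  n_reads_total = table$n_reads_total,
                  n_mapped = sum(table$counts),
                  n_unmapped = table$n_unmapped,
                  n_multimapped = table$n_multimapped)
    jsonlite::write_json(stats, paste0(path, ".stats.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_count_table
#' @param library_id id for the loaded table (default: file stem).
#' @export
read_count_table <- function(path, library_id = NULL) {
  if (!file.exists(path)) stop("count table not found: ", path, call. = FALSE)
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("construct_id", "count") %in% names(df))) {
    stop("count table ", path, " must have columns construct_id, count",
         call. = FALSE)
  }
  library_id <- library_id %||% tools::file_path_sans_ext(basename(path))
  raw_count_table(library_id, setNames(df$count, df$construct_id))
}

#' @rdname write_count_table
#' @param fc a fold-change matrix.
#' @export
write_fc_matrix <- function(fc, path) {
  df <- data.frame(construct_id = rownames(fc), fc, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_count_table
#' @export
read_fc_matrix <- function(path) {
  df <- read.delim(path, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  fc <- as.matrix(df[, -1, drop = FALSE])
  rownames(fc) <- df$construct_id
  fc
}

#' Analyze a screen held in memory
#'
#' Convenience wrapper running the quantification and inference stages on a
#' [simulate_screen()] result (or equivalently structured data): technical
#' replicates are median-collapsed, fold changes are computed against the
#' input pool, constructs are tested against the negative-control null, genes
#' are called by the two-hit rule, and control-based error rates are
#' estimated.
#'
#' @param screen a `synthetic_screen`, or a list with `replicate_counts`
#'   (list of lists of raw tables) and `input_pool_counts`.
#' @param manifest the pool manifest (defaults to the screen's own).
#' @param config an [inference_config()].
#' @param pseudocount see [build_fold_change_matrix()].
#' @return list with `fc`, `construct_calls`, `gene_calls`, `performance`.
#' @export
analyze_screen <- function(screen, manifest = NULL,
                           config = inference_config(), pseudocount = 0.5) {
  manifest <- manifest %||% screen$config$manifest
  samples <- lapply(screen$replicate_counts, aggregate_technical)
  input_agg <- aggregate_technical(screen$input_pool_counts)
  fc <- build_fold_change_matrix(samples, input_agg, pseudocount)
  calls <- construct_tests(fc, manifest, config)
  genes <- gene_two_hit_calls(calls, config)
  perf <- control_performance(genes, manifest, calls)
  list(fc = fc, construct_calls = calls, gene_calls = genes,
       performance = perf)
}

#' Run configuration for the full pipeline
#'
#' @param manifest path to the manifest TSV/CSV.
#' @param input_pool path(s) to input-pool count TSV(s) (technical replicates
#'   are median-collapsed).
#' @param counts named list: biological sample id -> character vector of
#'   technical-replicate count TSV paths. Alternatively `counts_dir`, a
#'   directory of files named `<sample>_tech<k>.tsv` (with the input pool as
#'   `input_pool*.tsv`).
#' @param outdir output directory.
#' @param pseudocount,alpha,min_hits,sidedness,null_class analysis parameters
#'   (see [build_fold_change_matrix()] and [inference_config()]).
#' @param coverages optional coverage grid: when given, a coverage power curve
#'   is computed from the raw tables.
#' @param n_draws draws for the power curve.
#' @param seed master seed.
#' @param counts_dir see `counts`.
#' @return a `run_config` list.
#' @export
run_config <- function(manifest, input_pool = NULL, counts = NULL,
                       outdir = "poolscreen_out", pseudocount = 0.5,
                       alpha = 0.01, min_hits = 2L, sidedness = "two_sided",
                       null_class = "negative", coverages = NULL,
                       n_draws = 20L, seed = 1L, counts_dir = NULL) {
  structure(list(manifest = manifest, input_pool = input_pool,
                 counts = counts, counts_dir = counts_dir, outdir = outdir,
                 pseudocount = pseudocount, alpha = alpha,
                 min_hits = min_hits, sidedness = sidedness,
                 null_class = null_class, coverages = coverages,
                 n_draws = n_draws, seed = seed),
            class = "run_config")
}

#' @rdname run_config
#' @param path JSON or YAML file with `run_config` fields.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("run config not found: ", path, call. = FALSE)
  fields <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("the 'yaml' package is required to read YAML configs", call. = FALSE)
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  do.call(run_config, fields[intersect(names(fields),
                                       names(formals(run_config)))])
}

discover_counts <- function(dir) {
  files <- list.files(dir, pattern = "_tech[0-9]+\\.tsv$", full.names = TRUE)
  input <- files[grepl("^input_pool", basename(files))]
  rep_files <- setdiff(files, input)
  keys <- sub("_tech[0-9]+\\.tsv$", "", basename(rep_files))
  counts <- split(rep_files, keys)
  if (length(input) == 0) {
    stop("no input_pool*.tsv found in ", dir, call. = FALSE)
  }
  list(input_pool = input, counts = counts)
}

#' Run the full screen analysis pipeline
#'
#' Loads the manifest and count tables, collapses technical replicates,
#' builds the fold-change matrix against the input pool, runs the construct
#' tests and two-hit gene calls, estimates control-based error rates, and
#' (optionally) computes the coverage power curve. All outputs — TSV tables,
#' a performance JSON, the serialized configuration and a markdown report —
#' are written under `config$outdir`. Rerunning with the same configuration
#' and seed reproduces the output tables byte-identically.
#'
#' @param config a [run_config()] (or path to one).
#' @return (invisibly) a list with the in-memory results.
#' @export
run_full_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(outdir, "run.log")
  logf <- function(...) {
    msg <- paste0(...)
    message("[poolscreen] ", msg)
    cat(msg, "\n", file = log_path, append = TRUE)
  }
  cat("", file = log_path)  # truncate
  logf("seed: ", config$seed)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  manifest <- stage("manifest", {
    if (!file.exists(config$manifest %||% "")) {
      stop("manifest path does not exist: ", config$manifest %||% "<missing>")
    }
    read_manifest(config$manifest)
  })
  logf("manifest: ", nrow(manifest), " constructs")

  if (!is.null(config$counts_dir)) {
    found <- stage("discover", discover_counts(config$counts_dir))
    config$input_pool <- found$input_pool
    config$counts <- found$counts
  }
  raw <- stage("load counts", lapply(config$counts, function(paths) {
    lapply(paths, read_count_table)
  }))
  input_raw <- stage("load input pool",
                     lapply(config$input_pool, read_count_table))

  icfg <- inference_config(alpha = config$alpha, min_hits = config$min_hits,
                           sidedness = config$sidedness,
                           null_class = config$null_class)
  samples <- stage("quantify", lapply(names(raw), function(s) {
    aggregate_technical(raw[[s]], sample_id = s)
  }))
  input_agg <- stage("quantify", aggregate_technical(input_raw,
                                                     sample_id = "input_pool"))
  fc <- stage("quantify",
              build_fold_change_matrix(samples, input_agg, config$pseudocount))
  write_fc_matrix(fc, file.path(outdir, "fold_changes.tsv"))
  logf("fold-change matrix: ", nrow(fc), " constructs x ", ncol(fc),
       " replicates")

  calls <- stage("test", construct_tests(fc, manifest, icfg))
  genes <- stage("test", gene_two_hit_calls(calls, icfg))
  perf <- stage("performance", control_performance(genes, manifest, calls))
  write.table(as.data.frame(calls), file.path(outdir, "construct_calls.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(as.data.frame(genes), file.path(outdir, "gene_calls.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(unclass(perf), file.path(outdir, "performance.json"),
                       auto_unbox = TRUE, digits = NA)
  logf("gene calls: ", sum(genes$essential_call), " of ", nrow(genes),
       " essential at alpha=", config$alpha)

  power <- NULL
  if (!is.null(config$coverages)) {
    power <- stage("power", coverage_power_curve(
      raw, input_agg, manifest, icfg, coverages = config$coverages,
      n_draws = config$n_draws, seed = config$seed,
      pseudocount = config$pseudocount))
    write.table(as.data.frame(power), file.path(outdir, "power_curve.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }

  jsonlite::write_json(unclass(config), file.path(outdir, "run_config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  write_report(file.path(outdir, "report.md"), manifest, calls, genes, perf,
               power, config)
  logf("done; outputs in ", normalizePath(outdir))
  invisible(list(manifest = manifest, fc = fc, construct_calls = calls,
                 gene_calls = genes, performance = perf, power = power))
}

write_report <- function(path, manifest, calls, genes, perf, power, config) {
  fmt_pct <- function(r) if (is.na(r)) "NA" else sprintf("%.1f%%", 100 * r)
  lines <- c(
    "# Pooled shRNA screen report",
    "",
    sprintf("- constructs: %d, genes: %d", nrow(manifest),
            length(unique(manifest$gene))),
    sprintf("- alpha = %g, min hits = %d, pseudocount = %g, seed = %d",
            config$alpha, config$min_hits, config$pseudocount,
            as.integer(config$seed)),
    "",
    "## Control-based error rates",
    "",
    sprintf("- false negative rate: %s (%d of %d positive-control genes missed)",
            fmt_pct(perf$fnr), perf$n_positive - perf$n_positive_called,
            perf$n_positive),
    sprintf("- false positive rate: %s (%d of %d negative-control genes called)",
            fmt_pct(perf$fpr), perf$n_negative_called, perf$n_negative),
    "",
    "## Gene calls",
    "",
    "| gene | constructs | depleted hits | enriched | essential |",
    "|------|-----------:|--------------:|---------:|-----------|",
    sprintf("| %s | %d | %d | %d | %s |", genes$gene, genes$n_constructs,
            genes$n_depleted_significant, genes$n_enriched_significant,
            ifelse(genes$essential_call, "yes", "no"))
  )
  if (!is.null(power)) {
    lines <- c(lines, "", "## Power vs coverage", "",
               "| mean coverage | power |", "|--------------:|------:|",
               sprintf("| %g | %.3f |", power$mean_coverage, power$power))
  }
  writeLines(lines, path)
  invisible(path)
}
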