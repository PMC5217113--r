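#' @rdname read_manifest
#' @export
manifest_columns <- c("construct_id", "gene", "control_class", "unique_seq")

control_classes <- c("positive", "negative", "test")

#' Construct an shRNA library manifest
#'
#' A manifest describes the designed shRNA pool: one row per construct, with
#' its target gene, control class (`positive` = gene known to be required for
#' the selected phenotype, `negative` = gene believed irrelevant, forming the
#' empirical null, `test` = gene under investigation) and the designated
#' unique half of the hairpin sequence used for exact-match read counting.
#'
#' @param constructs a data.frame (or coercible) with columns `construct_id`,
#'   `gene`, `control_class`, `unique_seq`.
#' @param name optional pool name.
#' @return a `shrna_manifest` (a validated data.frame).
#' @export
shrna_manifest <- function(constructs, name = "shRNA pool") {
  df <- as.data.frame(constructs, stringsAsFactors = FALSE)
  missing <- setdiff(manifest_columns, names(df))
  if (length(missing) > 0) {
    stop("manifest format error: missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df <- df[, manifest_columns]
  for (col in manifest_columns) df[[col]] <- as.character(df[[col]])
  df$unique_seq <- toupper(df$unique_seq)
  rownames(df) <- NULL
  validate_manifest(df)
  structure(df, class = c("shrna_manifest", "data.frame"), pool_name = name)
}

#' Validate manifest invariants
#'
#' Checks uniqueness of construct ids, the hairpin-sequence alphabet,
#' uniqueness and substring-freeness of the unique sequences, and the presence
#' of at least one negative-control construct (required to form the test
#' null). Substring collisions are a hard error because exact-substring read
#' counting would otherwise be ill-defined.
#'
#' @param m a manifest data.frame.
#' @return `TRUE`, invisibly; stops with a validation error otherwise.
#' @export
validate_manifest <- function(m) {
  if (nrow(m) == 0) stop("manifest validation error: no constructs", call. = FALSE)
  dup <- duplicated(m$construct_id) | duplicated(m$construct_id, fromLast = TRUE)
  if (any(dup)) {
    stop("manifest validation error: duplicate construct_id in rows ",
         paste(which(dup), collapse = ", "), " (",
         paste(unique(m$construct_id[dup]), collapse = ", "), ")", call. = FALSE)
  }
  bad_class <- !(m$control_class %in% control_classes)
  if (any(bad_class)) {
    stop("manifest validation error: control_class must be one of ",
         paste(control_classes, collapse = "/"), "; offending rows: ",
         paste(which(bad_class), collapse = ", "), call. = FALSE)
  }
  bad_seq <- !grepl("^[ACGT]+$", m$unique_seq)
  if (any(bad_seq)) {
    stop("manifest validation error: unique_seq must be non-empty over {A,C,G,T}; ",
         "offending rows: ", paste(which(bad_seq), collapse = ", "), call. = FALSE)
  }
  dup_seq <- duplicated(m$unique_seq) | duplicated(m$unique_seq, fromLast = TRUE)
  if (any(dup_seq)) {
    stop("manifest validation error: duplicate unique_seq in rows ",
         paste(which(dup_seq), collapse = ", "), call. = FALSE)
  }
  # substring containment between sequences of unequal length
  lens <- nchar(m$unique_seq)
  if (length(unique(lens)) > 1) {
    ord <- order(lens)
    for (i in seq_along(ord)) {
      short <- m$unique_seq[ord[i]]
      longer <- ord[-seq_len(i)][lens[ord[-seq_len(i)]] > lens[ord[i]]]
      if (length(longer) == 0) next
      hit <- longer[grepl(short, m$unique_seq[longer], fixed = TRUE)]
      if (length(hit) > 0) {
        stop("manifest validation error: unique_seq of row ", ord[i],
             " is a substring of unique_seq in row(s) ",
             paste(hit, collapse = ", "), call. = FALSE)
      }
    }
  }
  if (!any(m$control_class == "negative")) {
    stop("manifest validation error: at least one negative-control construct ",
         "is required (it forms the null distribution for the tests)", call. = FALSE)
  }
  invisible(TRUE)
}

#' Read / write a library manifest
#'
#' TSV (default) or CSV with a header row and columns `construct_id`, `gene`,
#' `control_class`, `unique_seq`; lines starting with `#` are comments.
#' `read_manifest(write_manifest(m))` is the identity.
#'
#' @param path file path; a `.csv` extension selects comma separation.
#' @param name pool name attached to the manifest.
#' @return `read_manifest`: a validated [shrna_manifest()].
#' @export
read_manifest <- function(path, name = basename(path)) {
  if (!file.exists(path)) stop("manifest file not found: ", path, call. = FALSE)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- read.delim(path, sep = sep, comment.char = "#",
                   stringsAsFactors = FALSE, colClasses = "character")
  shrna_manifest(df, name = name)
}

#' @rdname read_manifest
#' @param m a manifest.
#' @export
write_manifest <- function(m, path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  write.table(as.data.frame(m), path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Summarize a library manifest
#'
#' @param manifest an [shrna_manifest()].
#' @return a list with `n_constructs`, `n_genes`, `class_counts` (constructs
#'   per control class), `constructs_per_gene` (a table) and
#'   `mode_constructs_per_gene`.
#' @export
manifest_summary <- function(manifest) {
  per_gene <- table(manifest$gene)
  size_tab <- table(as.integer(per_gene))
  out <- list(
    n_constructs = nrow(manifest),
    n_genes = length(per_gene),
    class_counts = vapply(control_classes,
                          function(cl) sum(manifest$control_class == cl),
                          integer(1)),
    constructs_per_gene = per_gene,
    mode_constructs_per_gene = as.integer(names(size_tab)[which.max(size_tab)])
  )
  structure(out, class = "manifest_summary")
}

#' @export
print.manifest_summary <- function(x, ...) {
  cat("shRNA pool:", x$n_constructs, "constructs targeting", x$n_genes, "genes\n")
  cat("  by class:", paste(names(x$class_counts), x$class_counts,
                           sep = "=", collapse = ", "), "\n")
  cat("  constructs per gene: mode", x$mode_constructs_per_gene, "\n")
  invisible(x)
}

#' @export
print.shrna_manifest <- function(x, ...) {
  cat("<shrna_manifest>", attr(x, "pool_name") %||% "", "\n")
  print.data.frame(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("... and", nrow(x) - 6, "more constructs\n")
  invisible(x)
}

# per-gene control class; screens assign one class per gene
gene_classes <- function(manifest) {
  cls <- tapply(manifest$control_class, manifest$gene,
                function(v) unique(v), simplify = FALSE)
  mixed <- names(cls)[vapply(cls, length, integer(1)) > 1]
  if (length(mixed) > 0) {
    stop("genes with mixed control classes: ", paste(mixed, collapse = ", "),
         call. = FALSE)
  }
  vapply(cls, `[[`, character(1), 1L)
}
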