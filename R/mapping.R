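#' Describe one sequencing library
#'
#' A lightweight record tying a set of reads (a FASTA/FASTQ path, optionally
#' gzipped, a character vector of sequences, or a `DNAStringSet`) to its
#' sample of origin and technical replicate index.
#'
#' @param reads file path, character vector of sequences, or `DNAStringSet`.
#' @param library_id unique library identifier.
#' @param sample_id biological sample the library was prepared from.
#' @param tech_rep technical replicate index (>= 1).
#' @param source one of `"testis"`, `"input_pool"`, `"cell_line"`.
#' @return a `sequencing_library` object.
#' @export
sequencing_library <- function(reads, library_id, sample_id = library_id,
                               tech_rep = 1L,
                               source = c("testis", "input_pool", "cell_line")) {
  source <- match.arg(source)
  stopifnot(tech_rep >= 1)
  structure(list(reads = reads, library_id = library_id, sample_id = sample_id,
                 tech_rep = as.integer(tech_rep), source = source),
            class = "sequencing_library")
}

detect_seq_format <- function(path) {
  con <- gzfile(path, "rt")
  on.exit(close(con))
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0) return("empty")
    if (nzchar(trimws(line))) break
  }
  first <- substr(trimws(line), 1, 1)
  if (first == ">") return("fasta")
  if (first == "@") return("fastq")
  stop("cannot determine read format of ", path,
       ": first record starts with '", first, "'", call. = FALSE)
}

as_read_set <- function(x) {
  if (inherits(x, "sequencing_library")) x <- x$reads
  if (methods::is(x, "DNAStringSet")) return(x)
  if (is.character(x) && length(x) == 1 && file.exists(x)) {
    fmt <- detect_seq_format(x)
    if (fmt == "empty") return(Biostrings::DNAStringSet())
    return(tryCatch(
      Biostrings::readDNAStringSet(x, format = fmt),
      error = function(e) stop("parse error reading ", x, ": ",
                               conditionMessage(e), call. = FALSE)
    ))
  }
  if (is.character(x)) return(Biostrings::DNAStringSet(x))
  stop("unsupported read input of class ", paste(class(x), collapse = "/"),
       call. = FALSE)
}

#' Build an exact-match hairpin matcher
#'
#' Prepares the unique half-sequences of all constructs (and their reverse
#' complements, since amplicons may be sequenced in either orientation) for
#' exact substring lookup in reads. Any containment between the search
#' sequences of two different constructs — including a sequence equal to or
#' contained in another construct's reverse complement — is a validation
#' error, because it would make exact-match assignment ambiguous.
#'
#' @param manifest an [shrna_manifest()].
#' @return an opaque `shrna_matcher` used by [count_reads()].
#' @export
build_matcher <- function(manifest) {
  validate_manifest(manifest)
  pats <- manifest$unique_seq
  rcs <- revcomp_chr(pats)
  n <- length(pats)
  all_seq <- c(pats, rcs)
  owner <- rep(seq_len(n), 2L)
  for (i in seq_along(all_seq)) {
    hit <- which(grepl(all_seq[i], all_seq, fixed = TRUE) & owner != owner[i])
    if (length(hit) > 0) {
      stop("matcher validation error: search sequence of construct '",
           manifest$construct_id[owner[i]],
           "' collides (substring in either orientation) with construct(s) ",
           paste(unique(manifest$construct_id[owner[hit]]), collapse = ", "),
           call. = FALSE)
    }
  }
  structure(list(construct_id = manifest$construct_id,
                 patterns = pats, rc = rcs),
            class = "shrna_matcher")
}

#' Per-library raw count table
#'
#' @param library_id library identifier.
#' @param counts named non-negative vector, one entry per manifest construct.
#' @param n_reads_total,n_unmapped,n_multimapped read-accounting totals;
#'   `sum(counts) + n_unmapped + n_multimapped == n_reads_total` always holds.
#' @param sample_id,tech_rep optional provenance.
#' @return a `raw_counts` object.
#' @export
raw_count_table <- function(library_id, counts,
                            n_reads_total = sum(counts),
                            n_unmapped = 0L, n_multimapped = 0L,
                            sample_id = library_id, tech_rep = NA_integer_) {
  stopifnot(!is.null(names(counts)), all(counts >= 0))
  if (abs(sum(counts) + n_unmapped + n_multimapped - n_reads_total) > 1e-9) {
    stop("count conservation violated: mapped + unmapped + multimapped != total",
         call. = FALSE)
  }
  structure(list(library_id = library_id, counts = counts,
                 n_reads_total = n_reads_total, n_unmapped = n_unmapped,
                 n_multimapped = n_multimapped, sample_id = sample_id,
                 tech_rep = tech_rep),
            class = "raw_counts")
}

#' @export
print.raw_counts <- function(x, ...) {
  cat("<raw_counts>", x$library_id, "—", length(x$counts), "constructs,",
      x$n_reads_total, "reads (", sum(x$counts), "mapped,", x$n_unmapped,
      "unmapped,", x$n_multimapped, "multimapped )\n")
  invisible(x)
}

#' Count reads per construct by exact matching
#'
#' Each read is scanned for every construct's unique half-sequence, in both
#' orientations, with no mismatches allowed. A read increments exactly one
#' construct iff exactly one construct's sequence occurs in it; reads matching
#' none are tallied as unmapped, reads matching two or more constructs are
#' discarded and tallied as multimapped (a QC signal, never apportioned).
#' Counting is deterministic and invariant to read order.
#'
#' @param library a [sequencing_library()], path, character vector or
#'   `DNAStringSet`.
#' @param matcher from [build_matcher()] on the same manifest.
#' @param manifest the manifest the matcher was built from.
#' @param library_id identifier for the output table (defaults to the
#'   library's own id, or `"reads"`).
#' @return a [raw_count_table()].
#' @export
count_reads <- function(library, matcher, manifest, library_id = NULL) {
  stopifnot(inherits(matcher, "shrna_matcher"))
  if (!identical(matcher$construct_id, manifest$construct_id)) {
    stop("matcher was not built from this manifest", call. = FALSE)
  }
  if (is.null(library_id)) {
    library_id <- if (inherits(library, "sequencing_library"))
      library$library_id else "reads"
  }
  sample_id <- if (inherits(library, "sequencing_library"))
    library$sample_id else library_id
  tech_rep <- if (inherits(library, "sequencing_library"))
    library$tech_rep else NA_integer_

  reads <- as_read_set(library)
  n_reads <- length(reads)
  ids <- matcher$construct_id
  n_c <- length(ids)
  if (n_reads == 0L) {
    return(raw_count_table(library_id, setNames(integer(n_c), ids),
                           n_reads_total = 0L, sample_id = sample_id,
                           tech_rep = tech_rep))
  }
  nmatch <- integer(n_reads)
  assigned <- integer(n_reads)
  for (i in seq_len(n_c)) {
    h <- Biostrings::vcountPattern(matcher$patterns[i], reads, fixed = TRUE) > 0L
    if (matcher$rc[i] != matcher$patterns[i]) {
      h <- h | Biostrings::vcountPattern(matcher$rc[i], reads, fixed = TRUE) > 0L
    }
    idx <- which(h)
    nmatch[idx] <- nmatch[idx] + 1L
    assigned[idx] <- i
  }
  unique_hit <- nmatch == 1L
  counts <- tabulate(assigned[unique_hit], nbins = n_c)
  raw_count_table(library_id, setNames(counts, ids),
                  n_reads_total = n_reads,
                  n_unmapped = sum(nmatch == 0L),
                  n_multimapped = sum(nmatch >= 2L),
                  sample_id = sample_id, tech_rep = tech_rep)
}

#' Count paired-end mates separately and report concordance
#'
#' Mates are mapped independently and the Pearson correlation of the two
#' per-construct count vectors is reported; downstream analysis uses the R1
#' table by default. Concordance is `NA` when either count vector is constant.
#'
#' @param lib_r1,lib_r2 the two mate libraries (equal read counts required).
#' @inheritParams count_reads
#' @return list with `r1`, `r2` (both [raw_count_table()]) and `concordance`.
#' @export
count_paired <- function(lib_r1, lib_r2, matcher, manifest) {
  r1_reads <- as_read_set(lib_r1)
  r2_reads <- as_read_set(lib_r2)
  if (length(r1_reads) != length(r2_reads)) {
    stop("mate-count mismatch: R1 has ", length(r1_reads), " reads, R2 has ",
         length(r2_reads), call. = FALSE)
  }
  t1 <- count_reads(r1_reads, matcher, manifest,
                    library_id = if (inherits(lib_r1, "sequencing_library"))
                      lib_r1$library_id else "R1")
  t2 <- count_reads(r2_reads, matcher, manifest,
                    library_id = if (inherits(lib_r2, "sequencing_library"))
                      lib_r2$library_id else "R2")
  conc <- if (sd(t1$counts) > 0 && sd(t2$counts) > 0) {
    cor(t1$counts, t2$counts)
  } else NA_real_
  list(r1 = t1, r2 = t2, concordance = conc)
}
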