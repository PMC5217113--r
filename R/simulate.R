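# fixed vector backbone flanking the hairpin in simulated amplicons;
# arbitrary constant sequence, long enough for any sensible read length
sim_backbone_5p <- paste0("TTGGATCCAGTACTGCGATCGAATTCAAGCTTGCATGCCTGCAGGTCGAC",
                          "TCTAGAGGATCCCCGGGTACCGAGCTCGAATTCACTGGCCGTCGTTTTAC")
sim_backbone_3p <- paste0("CAACGTCGTGACTGGGAAAACCCTGGCGTTACCCAACTTAATCGCCTTGC",
                          "AGCACATCCCCCTTTCGCCAGCTGGCGTAATAGCGAAGAGGCCCGCACCG")

#' Random hairpin unique sequences
#'
#' Draws `n` distinct random DNA sequences suitable as the "unique half" of
#' simulated hairpins: pairwise distinct, and distinct from each other's
#' reverse complements so exact-match counting is unambiguous in either
#' orientation.
#'
#' @param n number of sequences.
#' @param length sequence length (default 21 nt).
#' @return character vector of length `n`.
#' @export
random_hairpin_seqs <- function(n, length = 21) {
  draw <- function(k) {
    apply(matrix(sample(c("A", "C", "G", "T"), k * length, replace = TRUE),
                 nrow = k), 1L, paste, collapse = "")
  }
  seqs <- character(0)
  while (base::length(seqs) < n) {
    pool <- c(seqs, draw(n - base::length(seqs)))
    pool_rc <- revcomp_chr(pool)
    keep <- rep(TRUE, base::length(pool))
    for (i in seq_along(pool)) {
      if (!keep[i]) next
      clash <- which((pool == pool[i] | pool == pool_rc[i]) &
                       seq_along(pool) > i)
      keep[clash] <- FALSE
    }
    seqs <- pool[keep]
  }
  seqs
}

#' Simulation configuration for a pooled shRNA screen
#'
#' Defaults describe a pilot-scale in vivo screen: ~1e8 cells in the adult
#' mouse testis, low transfection efficiency, nine biological replicates with
#' three technical sequencing libraries each, and a mean read coverage of
#' 3000 reads per construct.
#'
#' @param manifest an [shrna_manifest()].
#' @param n_cells_total cells in the tissue (default 1e8).
#' @param transfection_efficiency fraction of cells receiving one construct
#'   (low MOI; in vivo rates run 1-5%, default 0.02).
#' @param input_pool_weights per-construct relative abundance of the input
#'   pool (default uniform).
#' @param selection_log2 per-construct selection effect `s`: survival through
#'   selection is proportional to `2^s` (negative = depleted). Default 0.
#' @param bio_sd SD of the per-construct, per-replicate lognormal noise on the
#'   selection effect (log2 scale; default 0.3).
#' @param jackpot_shape gamma shape of the mean-1 PCR amplification multiplier
#'   applied per construct lineage in every technical library; smaller values
#'   mean stronger jackpotting (default 2).
#' @param n_bio_reps biological replicates (default 9).
#' @param n_tech_reps technical sequencing libraries per biological replicate
#'   (default 3).
#' @param mean_coverage mean sequenced reads per construct per library
#'   (default 3000).
#' @param seed master seed; everything downstream is reproducible from it.
#' @return a `sim_config` list.
#' @export
simulation_config <- function(manifest, n_cells_total = 1e8,
                              transfection_efficiency = 0.02,
                              input_pool_weights = NULL,
                              selection_log2 = NULL,
                              bio_sd = 0.3, jackpot_shape = 2,
                              n_bio_reps = 9L, n_tech_reps = 3L,
                              mean_coverage = 3000, seed = 1L) {
  n <- nrow(manifest)
  if (transfection_efficiency <= 0 || transfection_efficiency > 1) {
    stop("transfection_efficiency must be in (0, 1]", call. = FALSE)
  }
  stopifnot(bio_sd >= 0, jackpot_shape > 0, n_bio_reps >= 1, n_tech_reps >= 1,
            mean_coverage > 0, n_cells_total >= 1)
  w <- input_pool_weights %||% rep(1, n)
  stopifnot(length(w) == n, all(w >= 0), sum(w) > 0)
  s <- selection_log2 %||% setNames(rep(0, n), manifest$construct_id)
  if (is.null(names(s))) names(s) <- manifest$construct_id
  stopifnot(setequal(names(s), manifest$construct_id))
  structure(list(manifest = manifest, n_cells_total = n_cells_total,
                 transfection_efficiency = transfection_efficiency,
                 input_pool_weights = w / sum(w),
                 selection_log2 = s[manifest$construct_id],
                 bio_sd = bio_sd, jackpot_shape = jackpot_shape,
                 n_bio_reps = as.integer(n_bio_reps),
                 n_tech_reps = as.integer(n_tech_reps),
                 mean_coverage = mean_coverage, seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a pooled shRNA screen with known ground truth
#'
#' Generative model, per biological replicate: (1) the number of transfected
#' cells is Binomial(`n_cells_total`, `transfection_efficiency`); (2) each
#' transfected cell receives one construct (strict low MOI), multinomially by
#' the input-pool weights; (3) each cell survives selection independently with
#' probability `min(1, 2^(s + eps))`, `eps ~ N(0, bio_sd)` drawn per construct
#' per replicate; (4) each technical library multiplies every construct's
#' surviving lineage by a mean-1 Gamma(`jackpot_shape`) PCR amplification
#' factor and sequences `mean_coverage * n_constructs` reads multinomially in
#' proportion to the amplified mass. The input pool is sequenced directly from
#' the pool weights (abundant template, so no jackpot, no selection).
#'
#' @param config a [simulation_config()].
#' @return a `synthetic_screen`: `input_pool_counts` (a raw table),
#'   `replicate_counts` (list over biological replicates of lists over
#'   technical replicates), `truth` (per-construct `s` and per-gene essential
#'   flag: >= 2 constructs with `s < 0`), and the `config`.
#' @export
simulate_screen <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  m <- config$manifest
  n <- nrow(m)
  ids <- m$construct_id
  w <- config$input_pool_weights
  s <- config$selection_log2
  total_reads <- as.integer(round(config$mean_coverage * n))

  input_counts <- as.vector(rmultinom(1L, total_reads, w))
  input_pool <- raw_count_table("input_pool", setNames(input_counts, ids),
                                sample_id = "input_pool")

  replicate_counts <- vector("list", config$n_bio_reps)
  names(replicate_counts) <- sprintf("testis_%02d", seq_len(config$n_bio_reps))
  for (b in seq_len(config$n_bio_reps)) {
    n_trans <- rbinom(1L, config$n_cells_total, config$transfection_efficiency)
    cells <- as.vector(rmultinom(1L, n_trans, w))
    eps <- rnorm(n, 0, config$bio_sd)
    surv_p <- pmin(1, 2^(s + eps))
    surviving <- rbinom(n, cells, surv_p)
    techs <- vector("list", config$n_tech_reps)
    for (t in seq_len(config$n_tech_reps)) {
      amp <- rgamma(n, shape = config$jackpot_shape,
                    rate = config$jackpot_shape)
      mass <- surviving * amp
      reads <- if (sum(mass) > 0) {
        as.vector(rmultinom(1L, total_reads, mass))
      } else rep(0L, n)
      lib_id <- sprintf("testis_%02d_tech%d", b, t)
      techs[[t]] <- raw_count_table(lib_id, setNames(reads, ids),
                                    sample_id = sprintf("testis_%02d", b),
                                    tech_rep = t)
    }
    replicate_counts[[b]] <- techs
  }

  gene_ess <- tapply(s < 0, m$gene, sum) >= 2
  truth <- data.frame(construct_id = ids, gene = m$gene,
                      selection_log2 = unname(s),
                      gene_essential = unname(gene_ess[m$gene]),
                      stringsAsFactors = FALSE)
  structure(list(input_pool_counts = input_pool,
                 replicate_counts = replicate_counts,
                 truth = truth, config = config),
            class = "synthetic_screen")
}

#' @export
print.synthetic_screen <- function(x, ...) {
  cat("<synthetic_screen>", nrow(x$truth), "constructs,",
      length(x$replicate_counts), "biological x",
      x$config$n_tech_reps, "technical replicates, mean coverage",
      x$config$mean_coverage, "\n")
  invisible(x)
}

#' Emit simulated FASTQ reads for a screen
#'
#' Turns every counted unit of a synthetic screen into one sequencing read:
#' the construct's unique half-sequence, in a random orientation, embedded at
#' a random offset inside a fixed vector backbone, optionally with uniform
#' per-base substitution errors. Running [count_reads()] on the output (at
#' error rate 0) recovers the count tables exactly.
#'
#' @param screen a `synthetic_screen`, or a single [raw_count_table()].
#' @param manifest the manifest used in the simulation.
#' @param read_length read length; must be at least the longest unique
#'   sequence plus 4.
#' @param dir output directory for the FASTQ files.
#' @param seed optional seed.
#' @param error_rate per-base substitution probability (default 0).
#' @return named character vector of written FASTQ paths.
#' @export
simulate_reads <- function(screen, manifest, read_length = 50, dir = tempdir(),
                           seed = NULL, error_rate = 0) {
  max_len <- max(nchar(manifest$unique_seq))
  if (read_length < max_len + 4) {
    stop("read_length must be at least the longest unique_seq + 4 (",
         max_len + 4, ")", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tables <- if (inherits(screen, "raw_counts")) {
    setNames(list(screen), screen$library_id)
  } else {
    tabs <- list(input_pool = screen$input_pool_counts)
    for (techs in screen$replicate_counts) {
      for (t in techs) tabs[[t$library_id]] <- t
    }
    tabs
  }
  paths <- character(0)
  for (lib in names(tables)) {
    reads <- make_reads_for_counts(tables[[lib]]$counts, manifest,
                                   read_length, error_rate)
    path <- file.path(dir, paste0(lib, ".fastq"))
    write_fastq(reads, path, lib)
    paths[lib] <- path
  }
  paths
}

make_reads_for_counts <- function(counts, manifest, read_length, error_rate) {
  seqs <- manifest$unique_seq[match(names(counts), manifest$construct_id)]
  out <- vector("list", length(counts))
  for (i in seq_along(counts)) {
    k <- as.integer(round(counts[i]))
    if (k == 0L) next
    s <- seqs[i]
    len <- nchar(s)
    fwd <- runif(k) < 0.5
    ins <- ifelse(fwd, s, revcomp_chr(s))
    off <- sample.int(read_length - len + 1L, k, replace = TRUE) - 1L
    left <- substring(sim_backbone_5p, nchar(sim_backbone_5p) - off + 1L,
                      nchar(sim_backbone_5p))
    right <- substring(sim_backbone_3p, 1L, read_length - len - off)
    out[[i]] <- paste0(left, ins, right)
  }
  reads <- unlist(out) %||% character(0)
  if (error_rate > 0 && length(reads) > 0) {
    reads <- vapply(reads, mutate_read, character(1), rate = error_rate,
                    USE.NAMES = FALSE)
  }
  reads
}

mutate_read <- function(read, rate) {
  n_err <- rbinom(1L, nchar(read), rate)
  if (n_err == 0L) return(read)
  pos <- sample.int(nchar(read), n_err)
  chars <- strsplit(read, "", fixed = TRUE)[[1]]
  for (p in pos) {
    chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1L)
  }
  paste(chars, collapse = "")
}

write_fastq <- function(reads, path, lib_id) {
  if (length(reads) == 0) {
    file.create(path)
    return(invisible(path))
  }
  x <- Biostrings::DNAStringSet(reads)
  names(x) <- sprintf("%s_read%06d", lib_id, seq_along(reads))
  quals <- Biostrings::BStringSet(strrep("I", nchar(reads)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = quals)
  invisible(path)
}

# ---- pilot-like study design -------------------------------------------------

pilot_positive_genes <- c("BAX", "CSF", "KIT", "PIN1", "CPEB1", "GNPAT",
                          "MLH3", "SPO11", "CIB1", "MAP7", "PYGO2", "TBPL1",
                          "SH2B1", "TSN", "SIRT1", "VAMP7", "VDAC3")
pilot_negative_genes <- c("MMP3", "SYT4", "TFF3", "TNFSF4", "TYRP1",
                          "APOC4", "LCE1I", "SCRG1")

#' Pilot-pool-like manifest
#'
#' A synthetic manifest shaped like the pilot screen pool: 119 constructs with
#' a mode of five constructs per gene, targeting 17 positive-control genes
#' (83 constructs) and 8 negative-control genes (36 constructs: five
#' knockout-characterized genes with no testis phenotype plus three genes not
#' expressed in testis). Unique sequences are random 21-mers.
#'
#' @param seed seed for sequence generation.
#' @return an [shrna_manifest()].
#' @export
make_pilot_manifest <- function(seed = 1L) {
  set.seed(seed)
  four_pos <- c("MAP7", "SH2B1")          # two positive genes carry 4 constructs
  four_neg <- c("TFF3", "TNFSF4", "TYRP1", "SCRG1")
  genes <- c(pilot_positive_genes, pilot_negative_genes)
  sizes <- ifelse(genes %in% c(four_pos, four_neg), 4L, 5L)
  gene_col <- rep(genes, sizes)
  class_col <- rep(ifelse(genes %in% pilot_positive_genes,
                          "positive", "negative"), sizes)
  ids <- unlist(lapply(seq_along(genes), function(i)
    sprintf("%s_sh%d", genes[i], seq_len(sizes[i]))))
  shrna_manifest(data.frame(construct_id = ids, gene = gene_col,
                            control_class = class_col,
                            unique_seq = random_hairpin_seqs(sum(sizes)),
                            stringsAsFactors = FALSE),
                 name = "pilot-like pool")
}

#' Predicted-pool-like manifest
#'
#' A synthetic manifest shaped like the follow-up screen of predicted
#' fertility genes: 130 constructs (26 test genes, five constructs each) plus
#' 15 negative-control constructs (three knockout-negative genes and two
#' scrambled non-mammalian sequences, three constructs each), 145 in total.
#'
#' @inheritParams make_pilot_manifest
#' @export
make_predicted_manifest <- function(seed = 1L) {
  set.seed(seed)
  test_genes <- c("ALPI", "POLA1", "RFC1", "RRM1", "CRISP2", "GSTM5",
                  "HRASLS5", "KLHDC3", "LDHAL6B", "PGAM2", "PHF7", "PHKG2",
                  "RFC2", "SFI1", "SPATA4", "TAF9", "TCP1", "TCP11",
                  "ZMYND10", "4933411K16Rik", "ACTL7B", "GSG1", "MEA1",
                  "SPA17", "SPZ1", "UGT1A1")
  neg_genes <- c("MMP3", "TFF3", "TYRP1", "SCRAMBLE1", "SCRAMBLE2")
  genes <- c(rep(test_genes, each = 5L), rep(neg_genes, each = 3L))
  classes <- c(rep("test", 130L), rep("negative", 15L))
  ids <- paste0(genes, "_sh",
                c(rep(1:5, times = 26L), rep(1:3, times = 5L)))
  shrna_manifest(data.frame(construct_id = ids, gene = genes,
                            control_class = classes,
                            unique_seq = random_hairpin_seqs(145L),
                            stringsAsFactors = FALSE),
                 name = "predicted-pool-like")
}

#' Pilot-like simulation configuration
#'
#' Builds a [simulation_config()] emulating the pilot screen: the
#' [make_pilot_manifest()] pool, nine biological replicates, three technical
#' libraries each, 2% transfection efficiency, and a mean coverage of 5000
#' reads per construct (the coverage allocated per construct in the pilot
#' experiment). Each positive-gene construct is an effective knockdown with
#' probability `1 - inert_fraction`; effective constructs draw their selection
#' effect from a folded normal, `s = -|N(|effect_log2|, effect_sd)|`, so
#' knockdown strength varies continuously across constructs (as RNAi efficacy
#' does in practice) while staying negative. Inert constructs and all
#' negative-control constructs have no effect. The defaults (inert fraction
#' 0.45, mean effect -3, SD 1.25) put the per-construct significance
#' probability near 0.52 at full depth, making the expected number of
#' two-hit-detectable positive genes about 14 of 17 — a false negative rate
#' near 18%, the noneffective-RNAi failure mode of such screens.
#'
#' @param seed master seed (drives manifest sequences, efficacy assignment and
#'   the screen itself).
#' @param inert_fraction probability that a positive-gene construct fails to
#'   knock down its target (default 0.45).
#' @param effect_log2 mean selection effect of an effective construct
#'   (default -3).
#' @param effect_sd spread of effective-construct effects (default 1.25).
#' @param mean_coverage mean reads per construct per library (default 5000).
#' @param ... overrides passed to [simulation_config()].
#' @return a `sim_config` whose `selection_log2` encodes the ground truth.
#' @export
make_pilot_like_config <- function(seed = 1L, inert_fraction = 0.45,
                                   effect_log2 = -3, effect_sd = 1.25,
                                   mean_coverage = 5000, ...) {
  manifest <- make_pilot_manifest(seed)
  set.seed(seed + 1L)
  pos <- manifest$control_class == "positive"
  n_pos <- sum(pos)
  s <- setNames(rep(0, nrow(manifest)), manifest$construct_id)
  effective <- runif(n_pos) >= inert_fraction
  strength <- -abs(rnorm(n_pos, abs(effect_log2), effect_sd))
  s[pos] <- ifelse(effective, strength, 0)
  simulation_config(manifest, selection_log2 = s,
                    mean_coverage = mean_coverage, seed = seed, ...)
}
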