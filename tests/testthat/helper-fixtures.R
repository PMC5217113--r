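# small fixtures built in code; sequences are fixed literals so mapping tests
# are fully deterministic without touching the RNG

tiny_manifest <- function() {
  shrna_manifest(data.frame(
    construct_id = c("GENE1_sh1", "GENE1_sh2", "GENE2_sh1", "NEG1_sh1", "NEG1_sh2"),
    gene = c("GENE1", "GENE1", "GENE2", "NEG1", "NEG1"),
    control_class = c("test", "test", "test", "negative", "negative"),
    unique_seq = c("ACGTACGTACGTACGTACGTA",
                   "TTTTCCCCGGGGAAAATTTTC",
                   "GATTACAGATTACAGATTACA",
                   "CCCGGGTTTAAACCCGGGTTT",
                   "AGAGAGAGTCTCTCTCAGAGA"),
    stringsAsFactors = FALSE))
}

# small screen-shaped manifest with positive/negative/test classes
small_screen_manifest <- function(seed = 42, n_pos = 4, n_test = 3, n_neg = 3,
                                  per_gene = 5) {
  set.seed(seed)
  genes <- c(paste0("POS", seq_len(n_pos)), paste0("TST", seq_len(n_test)),
             paste0("NEG", seq_len(n_neg)))
  classes <- rep(c("positive", "test", "negative"), c(n_pos, n_test, n_neg))
  shrna_manifest(data.frame(
    construct_id = paste0(rep(genes, each = per_gene), "_sh",
                          seq_len(per_gene)),
    gene = rep(genes, each = per_gene),
    control_class = rep(classes, each = per_gene),
    unique_seq = random_hairpin_seqs(length(genes) * per_gene),
    stringsAsFactors = FALSE))
}

# raw count table helper over a manifest
counts_for <- function(manifest, counts, library_id = "lib", ...) {
  raw_count_table(library_id, setNames(counts, manifest$construct_id), ...)
}

# a fold-change matrix with prescribed per-construct shifts plus iid noise
toy_fc_matrix <- function(manifest, shifts, n_reps = 9, noise_sd = 0.3,
                          seed = 1) {
  set.seed(seed)
  n <- nrow(manifest)
  fc <- matrix(rep(shifts, n_reps) + rnorm(n * n_reps, 0, noise_sd),
               nrow = n, ncol = n_reps,
               dimnames = list(manifest$construct_id,
                               paste0("rep", seq_len(n_reps))))
  fc
}

# 45-construct null-calibration pool: 6 five-construct test genes plus
# 3 five-construct negative-control genes (15 null constructs)
null_calibration_manifest <- function(seed = 1) {
  set.seed(seed)
  genes <- c(paste0("TST", 1:6), paste0("NEG", 1:3))
  cls <- rep(c("test", "negative"), c(6, 3))
  shrna_manifest(data.frame(
    construct_id = paste0(rep(genes, each = 5), "_sh", 1:5),
    gene = rep(genes, each = 5),
    control_class = rep(cls, each = 5),
    unique_seq = random_hairpin_seqs(45),
    stringsAsFactors = FALSE))
}
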