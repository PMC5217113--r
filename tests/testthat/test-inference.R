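# brute-force permutation oracle: the exact distribution of the Mann-Whitney
# U statistic over all C(m+n, m) assignments of the pooled values to group x
oracle_rank_sum <- function(x, y, sidedness) {
  pooled <- c(x, y)
  m <- length(x)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  splits <- combn(length(pooled), m)
  u_all <- apply(splits, 2, function(idx) sum(r[idx]) - m * (m + 1) / 2)
  p_less <- mean(u_all <= u_obs)
  p_greater <- mean(u_all >= u_obs)
  p <- switch(sidedness,
              one_sided_less = p_less,
              one_sided_greater = p_greater,
              two_sided = min(1, 2 * min(p_less, p_greater)))
  list(U = u_obs, p = p)
}

test_that("rank-sum worked examples hold", {
  # x entirely below y: one-sided p is 1 / C(6,3) = 1/20
  rt <- rank_sum_test(c(1, 2, 3), c(4, 5, 6), "one_sided_less")
  expect_equal(rt$p, 0.05)
  expect_equal(rt$U, 0)
  # identical multisets: U = mn/2, two-sided p 1 under the tie-corrected
  # normal approximation
  rt2 <- rank_sum_test(c(1, 2, 3), c(1, 2, 3), "two_sided")
  expect_equal(rt2$U, 4.5)
  expect_equal(rt2$p, 1)
  expect_error(rank_sum_test(numeric(0), 1), "non-empty")
})

test_that("rank-sum p-values match brute-force enumeration for small samples", {
  set.seed(10)
  for (rep in 1:30) {
    m <- sample(1:5, 1); n <- sample(1:6, 1)
    vals <- sample(100, m + n)  # distinct -> no ties
    x <- vals[seq_len(m)]; y <- vals[-seq_len(m)]
    for (side in c("two_sided", "one_sided_less", "one_sided_greater")) {
      got <- rank_sum_test(x, y, side)
      want <- oracle_rank_sum(x, y, side)
      expect_equal(got$U, want$U)
      expect_equal(got$p, want$p, tolerance = 1e-12)
    }
  }
})

test_that("construct tests call extreme depletion and ignore flat screens", {
  m <- small_screen_manifest(seed = 3)
  # one positive gene's constructs pushed far below everything else
  shifts <- setNames(rep(0, nrow(m)), m$construct_id)
  shifts[m$gene == "POS1"] <- -4
  fc <- toy_fc_matrix(m, shifts, n_reps = 9, noise_sd = 0.2)
  calls <- construct_tests(fc, m, inference_config(alpha = 0.01))
  pos1 <- calls[calls$gene == "POS1", ]
  expect_true(all(pos1$p_value < 0.01))
  expect_true(all(pos1$direction == "depleted"))
  expect_true(all(pos1$significant))
  # an all-zero matrix is pure ties: p = 1, neutral, nothing significant
  fc0 <- matrix(0, nrow(m), 9,
                dimnames = list(m$construct_id, paste0("r", 1:9)))
  calls0 <- construct_tests(fc0, m, inference_config())
  expect_true(all(calls0$p_value == 1))
  expect_true(all(calls0$direction == "neutral"))
  expect_false(any(calls0$significant))
})

test_that("construct tests require a null class and warn on single replicates", {
  m <- small_screen_manifest(seed = 3)
  fc <- toy_fc_matrix(m, rep(0, nrow(m)), n_reps = 2)
  no_null <- inference_config(null_class = "positive")
  expect_silent(construct_tests(fc, m, no_null))
  m_no_neg <- m; m_no_neg$control_class[m_no_neg$control_class == "negative"] <- "test"
  expect_error(construct_tests(fc, m_no_neg, inference_config()), "null")
  expect_warning(construct_tests(fc[, 1, drop = FALSE], m, inference_config()),
                 "one biological replicate")
})

test_that("a null construct is tested against the other nulls only", {
  # 2 negative constructs: each must be tested against the one other null
  # construct, never against itself (self-inclusion would force ties)
  df <- data.frame(construct_id = c("n1", "n2"), gene = c("N1", "N2"),
                   control_class = "negative",
                   unique_seq = c("ACGTACGTACGTACGTACGTA",
                                  "TTTTCCCCGGGGAAAATTTTC"))
  m <- shrna_manifest(df)
  fc <- matrix(c(1, 2, 3, 7, 8, 9), nrow = 2, byrow = TRUE,
               dimnames = list(c("n1", "n2"), paste0("r", 1:3)))
  calls <- construct_tests(fc, m, inference_config())
  # n1 strictly below n2: exact two-sided p = 2/C(6,3) = 0.1
  expect_equal(calls$p_value, c(0.1, 0.1))
  expect_equal(calls$direction, c("depleted", "enriched"))
})

test_that("two-hit rule counts only significantly depleted constructs", {
  mk_calls <- function(gene, p, dir) {
    structure(data.frame(construct_id = paste0(gene, "_", seq_along(p)),
                         gene = gene, control_class = "test",
                         median_log2fc = ifelse(dir == "depleted", -1, 1),
                         U_statistic = 0, p_value = p, direction = dir,
                         significant = p <= 0.01, stringsAsFactors = FALSE),
              class = c("construct_calls", "data.frame"))
  }
  cfg <- inference_config(alpha = 0.01, min_hits = 2)
  hit <- mk_calls("G", c(0.001, 0.005, 0.5, 0.9, 1), rep("depleted", 5))
  expect_true(gene_two_hit_calls(hit, cfg)$essential_call)
  # 1 depleted + 2 enriched significant: enrichment never counts
  mixed <- mk_calls("G", c(0.001, 0.002, 0.003, 0.9, 1),
                    c("depleted", "enriched", "enriched", "depleted", "neutral"))
  gc <- gene_two_hit_calls(mixed, cfg)
  expect_false(gc$essential_call)
  expect_equal(gc$n_enriched_significant, 2L)
  flat <- mk_calls("G", rep(1, 5), rep("neutral", 5))
  expect_false(gene_two_hit_calls(flat, cfg)$essential_call)
})

test_that("adding a depleted hit is monotone for the essential call", {
  cfg <- inference_config(alpha = 0.01, min_hits = 2)
  base <- data.frame(construct_id = paste0("G_", 1:4), gene = "G",
                     control_class = "test", median_log2fc = -1,
                     U_statistic = 0,
                     p_value = c(0.001, 0.002, 0.5, 0.5),
                     direction = "depleted",
                     significant = c(TRUE, TRUE, FALSE, FALSE))
  more <- base
  more$p_value[3] <- 0.001; more$significant[3] <- TRUE
  expect_true(gene_two_hit_calls(base, cfg)$essential_call)
  expect_true(gene_two_hit_calls(more, cfg)$essential_call)
  expect_gte(gene_two_hit_calls(more, cfg)$n_depleted_significant,
             gene_two_hit_calls(base, cfg)$n_depleted_significant)
})

test_that("two-hit null probability modes agree with closed forms", {
  expect_identical(two_hit_null_probability(0.01, 2, "paper_pairwise"), 1e-4)
  expect_equal(two_hit_null_probability(0, 5, "binomial_at_least_2"), 0)
  expect_equal(two_hit_null_probability(0.01, 5, "binomial_at_least_2"),
               1 - 0.99^5 - 5 * 0.01 * 0.99^4, tolerance = 1e-12)
  expect_equal(two_hit_null_probability(0.01, 1, "binomial_at_least_2"), 0)
  expect_error(two_hit_null_probability(0.01, 1, "paper_pairwise"),
               "at least 2")
  # the pairwise reading understates the multi-construct tail
  expect_gt(two_hit_null_probability(0.01, 5, "binomial_at_least_2"),
            two_hit_null_probability(0.01, 5, "paper_pairwise"))
})

test_that("control-based error rates reproduce the worked arithmetic", {
  # 17 positive genes, 14 called; 8 negative genes, 1 called
  genes <- c(paste0("P", 1:17), paste0("N", 1:8))
  cls <- rep(c("positive", "negative"), c(17, 8))
  m <- shrna_manifest(data.frame(
    construct_id = paste0(genes, "_sh1"), gene = genes, control_class = cls,
    unique_seq = random_hairpin_seqs(25)))
  gc <- structure(data.frame(
    gene = genes, n_constructs = 1L,
    n_depleted_significant = c(rep(2L, 14), rep(0L, 3), 2L, rep(0L, 7)),
    n_enriched_significant = 0L,
    essential_call = c(rep(TRUE, 14), rep(FALSE, 3), TRUE, rep(FALSE, 7))),
    class = c("gene_calls", "data.frame"))
  perf <- control_performance(gc, m)
  expect_equal(perf$fnr, 3 / 17)
  expect_equal(round(100 * perf$fnr), 18)
  expect_equal(perf$fpr, 1 / 8)
  expect_equal(100 * perf$fpr, 12.5)
  # invariance to gene order
  shuffled <- gc[sample(nrow(gc)), ]
  perf2 <- control_performance(shuffled, m)
  expect_equal(perf2$fnr, perf$fnr)
  expect_equal(perf2$fpr, perf$fpr)
  # all positives called, no negatives called
  gc3 <- gc; gc3$essential_call <- cls == "positive"
  perf3 <- control_performance(gc3, m)
  expect_equal(perf3$fnr, 0)
  expect_equal(perf3$fpr, 0)
})

test_that("positive-construct enrichment rate is reported when calls given", {
  m <- shrna_manifest(data.frame(
    construct_id = c(paste0("P_sh", 1:3), "N_sh1"),
    gene = c(rep("P", 3), "N"),
    control_class = c(rep("positive", 3), "negative"),
    unique_seq = random_hairpin_seqs(4)))
  calls <- structure(data.frame(
    construct_id = m$construct_id, gene = m$gene,
    control_class = m$control_class, median_log2fc = c(1, 1, -1, 0),
    U_statistic = 0, p_value = c(0.001, 0.5, 0.001, 1),
    direction = c("enriched", "enriched", "depleted", "neutral"),
    significant = c(TRUE, FALSE, TRUE, FALSE)),
    class = c("construct_calls", "data.frame"))
  gc <- gene_two_hit_calls(calls)
  perf <- control_performance(gc, m, calls)
  expect_equal(perf$n_positive_constructs, 3L)
  expect_equal(perf$n_positive_constructs_enriched, 1L)
})
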