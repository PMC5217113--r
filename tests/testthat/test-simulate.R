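test_that("the simulator is deterministic given its seed", {
  m <- small_screen_manifest(seed = 1)
  cfg <- simulation_config(m, n_bio_reps = 3, n_tech_reps = 2,
                           mean_coverage = 200, seed = 77)
  s1 <- simulate_screen(cfg)
  s2 <- simulate_screen(cfg)
  expect_identical(s1$input_pool_counts$counts, s2$input_pool_counts$counts)
  expect_identical(
    lapply(s1$replicate_counts, function(b) lapply(b, `[[`, "counts")),
    lapply(s2$replicate_counts, function(b) lapply(b, `[[`, "counts")))
  expect_identical(s1$truth, s2$truth)
})

test_that("a neutral screen reproduces the input composition within multinomial error", {
  m <- small_screen_manifest(seed = 2)
  w <- rgamma(nrow(m), 5); w <- w / sum(w)
  # jackpot_shape very large: gamma multipliers degenerate to 1
  cfg <- simulation_config(m, input_pool_weights = w, bio_sd = 0,
                           jackpot_shape = 1e6, n_bio_reps = 2,
                           n_tech_reps = 1, mean_coverage = 5000, seed = 5)
  scr <- simulate_screen(cfg)
  total <- sum(scr$replicate_counts[[1]][[1]]$counts)
  frac <- scr$replicate_counts[[1]][[1]]$counts / total
  se <- sqrt(w * (1 - w) / total)
  expect_true(all(abs(frac - w) <= 3 * se + 1e-9))
})

test_that("a lethal construct is depleted by orders of magnitude", {
  m <- small_screen_manifest(seed = 3)
  s <- setNames(rep(0, nrow(m)), m$construct_id)
  s["POS1_sh1"] <- -10
  cfg <- simulation_config(m, selection_log2 = s, bio_sd = 0,
                           n_bio_reps = 3, n_tech_reps = 2, seed = 9)
  scr <- simulate_screen(cfg)
  for (b in scr$replicate_counts) {
    for (t in b) {
      expect_lt(t$counts[["POS1_sh1"]], 0.001 * sum(t$counts))
    }
  }
})

test_that("stronger jackpotting inflates technical-replicate variance", {
  m <- small_screen_manifest(seed = 4)
  tech_var <- function(shape, seed) {
    cfg <- simulation_config(m, jackpot_shape = shape, bio_sd = 0,
                             n_bio_reps = 1, n_tech_reps = 25,
                             mean_coverage = 2000, seed = seed)
    scr <- simulate_screen(cfg)
    counts <- sapply(scr$replicate_counts[[1]], `[[`, "counts")
    mean(apply(log2(counts + 0.5), 1, var))
  }
  v_strong <- mean(vapply(1:4, function(i) tech_var(0.5, i), numeric(1)))
  v_weak <- mean(vapply(1:4, function(i) tech_var(8, i), numeric(1)))
  expect_gt(v_strong, v_weak)
})

test_that("mean fold-change estimates track the true selection coefficients", {
  cors <- vapply(1:5, function(i) {
    cfg <- make_pilot_like_config(seed = 100 + i, effect_log2 = -2,
                                  mean_coverage = 3000)
    scr <- simulate_screen(cfg)
    res <- analyze_screen(scr)
    est <- rowMeans(res$fc)
    truth <- scr$truth$selection_log2[match(rownames(res$fc),
                                            scr$truth$construct_id)]
    cor(est, truth)
  }, numeric(1))
  expect_true(all(cors >= 0.8))
})

test_that("simulated reads round-trip through exact-match counting", {
  m <- small_screen_manifest(seed = 6, n_pos = 2, n_test = 2, n_neg = 2,
                             per_gene = 3)
  cfg <- simulation_config(m, n_bio_reps = 2, n_tech_reps = 2,
                           mean_coverage = 40, seed = 11)
  scr <- simulate_screen(cfg)
  dir <- withr::local_tempdir()
  paths <- simulate_reads(scr, m, read_length = 50, dir = dir, seed = 12)
  expect_equal(length(paths), 1 + 2 * 2)
  mt <- build_matcher(m)
  for (lib in names(paths)) {
    want <- if (lib == "input_pool") scr$input_pool_counts$counts
            else {
              b <- as.integer(sub("testis_(\\d+)_tech\\d", "\\1", lib))
              t <- as.integer(sub(".*tech(\\d)", "\\1", lib))
              scr$replicate_counts[[b]][[t]]$counts
            }
    got <- count_reads(paths[[lib]], mt, m)
    expect_equal(got$counts, want)
    expect_equal(got$n_unmapped, 0L)
  }
})

test_that("read emission validates length and handles empty tables", {
  m <- tiny_manifest()
  expect_error(simulate_reads(counts_for(m, rep(1, 5)), m, read_length = 22),
               "read_length")
  dir <- withr::local_tempdir()
  p <- simulate_reads(counts_for(m, rep(0, 5), "empty"), m, dir = dir)
  expect_true(file.exists(p[["empty"]]))
  expect_equal(file.size(p[["empty"]]), 0)
})

test_that("sequencing errors reduce recovery at roughly the per-read survival rate", {
  m <- small_screen_manifest(seed = 7, n_pos = 1, n_test = 1, n_neg = 1,
                             per_gene = 3)
  tab <- counts_for(m, rep(200, nrow(m)), "errlib")
  dir <- withr::local_tempdir()
  p <- simulate_reads(tab, m, read_length = 50, dir = dir, seed = 3,
                      error_rate = 0.01)
  got <- count_reads(p[["errlib"]], build_matcher(m), m)
  n <- sum(tab$counts)
  rate <- sum(got$counts) / n
  # a read survives iff its 21-nt unique region is error-free: (1-e)^21,
  # allow binomial noise around that expectation
  expectation <- 0.99^21
  expect_lt(abs(rate - expectation), 4 * sqrt(expectation * (1 - expectation) / n))
})

test_that("fully inert pools yield null-level gene calls", {
  cfg <- make_pilot_like_config(seed = 13, inert_fraction = 1,
                                n_bio_reps = 5, n_tech_reps = 2,
                                mean_coverage = 1000)
  expect_true(all(cfg$selection_log2 == 0))
  scr <- simulate_screen(cfg)
  res <- analyze_screen(scr)
  # 25 genes at a two-hit null rate of ~1e-3: essentially none called
  expect_lte(sum(res$gene_calls$essential_call), 1)
})

test_that("end-to-end recovery of strongly depleted genes from raw reads", {
  # genes whose every construct carries s <= -2 must be recovered through the
  # whole chain: simulate reads -> count -> quantify -> test -> two-hit
  m <- small_screen_manifest(seed = 8, n_pos = 3, n_test = 2, n_neg = 2,
                             per_gene = 3)
  s <- setNames(rep(0, nrow(m)), m$construct_id)
  s[m$control_class == "positive"] <- -2
  cfg <- simulation_config(m, selection_log2 = s, n_bio_reps = 9,
                           n_tech_reps = 2, mean_coverage = 100, seed = 21)
  scr <- simulate_screen(cfg)
  dir <- withr::local_tempdir()
  paths <- simulate_reads(scr, m, read_length = 50, dir = dir, seed = 22)
  mt <- build_matcher(m)
  rebuilt <- list(
    input_pool_counts = count_reads(paths[["input_pool"]], mt, m,
                                    library_id = "input_pool"),
    replicate_counts = lapply(1:9, function(b) {
      lapply(1:2, function(t) {
        lib <- sprintf("testis_%02d_tech%d", b, t)
        tab <- count_reads(paths[[lib]], mt, m, library_id = lib)
        tab$sample_id <- sprintf("testis_%02d", b)
        tab
      })
    })
  )
  res <- analyze_screen(rebuilt, manifest = m,
                        config = inference_config(alpha = 0.01, min_hits = 2))
  pos_genes <- unique(m$gene[m$control_class == "positive"])
  recovered <- res$gene_calls$essential_call[res$gene_calls$gene %in% pos_genes]
  expect_gte(mean(recovered), 0.8)
})
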