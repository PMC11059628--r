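test_that("mppm is the per-molecule methylated fraction of a context", {
  calls <- rbind(c(1L, 0L, 1L, 1L, 0L), c(0L, 0L, 0L, 0L, 0L))
  mc <- mc_from_matrix(calls, c(rep("CG", 4), "CHH"))
  rec <- mppm(mc, "CG")
  expect_equal(rec$mppm, c(0.75, 0))
  expect_equal(rec$n_sites, c(4L, 4L))
  # zero sites of a context: records omitted, not zero
  expect_equal(nrow(mppm(mc, "CHG")), 0L)
  # non-full-length reads are excluded
  calls2 <- rbind(c(1L, 1L, 1L, 1L, NA), c(0L, 0L, 0L, 0L, 0L))
  rec2 <- mppm(mc_from_matrix(calls2, c(rep("CG", 4), "CHH")), "CG")
  expect_equal(nrow(rec2), 1L)
})

test_that("mppm recovers the stationary probability on simulated molecules", {
  seq <- random_seq(400, gc = 0.5)
  cl <- epiallele_class("c", 1, p_meth = c(CG = 0.6, CHG = 0.2, CHH = 0.1))
  tr <- simulate_molecules(seq, list(cl), 10000, seed = 6)
  rec <- mppm(calls_from_truth(tr), "CG")
  ncg <- sum(tr$sites$context == "CG")
  se <- sqrt(0.6 * 0.4 / (10000 * ncg))
  expect_lt(abs(mean(rec$mppm) - 0.6), 4 * se)
})

test_that("pooling replicates before mppm equals concatenating per-replicate", {
  set.seed(41)
  calls <- matrix(rbinom(200, 1, 0.4), nrow = 20)
  reps <- rep(c("rep1", "rep2"), each = 10)
  mc_all <- mc_from_matrix(calls, rep("CG", 10), replicate = reps)
  pooled <- mppm(mc_all, "CG")$mppm
  split_ <- c(mppm(mc_from_matrix(calls[1:10, ], rep("CG", 10)), "CG")$mppm,
              mppm(mc_from_matrix(calls[11:20, ], rep("CG", 10)), "CG")$mppm)
  expect_equal(sort(pooled), sort(split_))
  expect_true(all(pooled >= 0 & pooled <= 1))
})

test_that("dmppm_test handles identity, degeneracy and symmetry", {
  a <- c(0.1, 0.2, 0.3, 0.4)
  expect_warning(r <- dmppm_test(a, 0.5), ">= 2")
  expect_true(is.na(r$p_value))
  same <- dmppm_test(a, a)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  const <- dmppm_test(c(0.5, 0.5), c(0.5, 0.5, 0.5))
  expect_equal(const$p_value, 1)  # all values identical
  ab <- dmppm_test(a, a + 0.05)
  ba <- dmppm_test(a + 0.05, a)
  expect_equal(ab$p_value, ba$p_value)
  expect_equal(ab$median_diff, -ba$median_diff)
})

test_that("dmppm statistic tracks the rank formula and the permutation null", {
  # extreme separation on 10 observations
  a <- rep(0, 5); b <- rep(1, 5)
  res <- dmppm_test(a, b)
  expect_equal(res$statistic, oracle_kw_h(a, b), tolerance = 1e-12)
  p_perm <- oracle_kw_perm_p(a, b)
  # chi-square approximation agrees with the exact permutation p up to
  # approximation error
  expect_lt(abs(res$p_value - p_perm), 0.05)

  set.seed(17)
  for (i in 1:10) {
    a <- round(runif(5), 2); b <- round(runif(5), 2)
    res <- dmppm_test(a, b)
    expect_equal(res$statistic, oracle_kw_h(a, b), tolerance = 1e-10)
    expect_lt(abs(res$p_value - oracle_kw_perm_p(a, b)), 0.12)
  }
})

test_that("dmppm detects a strong simulated shift with high power", {
  seq <- random_seq(300, gc = 0.5)
  hits <- 0L
  for (s in 1:20) {
    trA <- simulate_molecules(seq, list(epiallele_class("a", 1,
      p_meth = c(CG = 0.3, CHG = 0.1, CHH = 0.05))), 200, seed = 100 + s)
    trB <- simulate_molecules(seq, list(epiallele_class("b", 1,
      p_meth = c(CG = 0.6, CHG = 0.1, CHH = 0.05))), 200, seed = 900 + s)
    p <- dmppm_test(mppm(calls_from_truth(trA), "CG")$mppm,
                    mppm(calls_from_truth(trB), "CG")$mppm)$p_value
    if (p < 0.01) hits <- hits + 1L
  }
  expect_equal(hits, 20L)
})

test_that("dmppm_pairwise covers all condition pairs with optional adjustment", {
  set.seed(3)
  rec <- data.frame(
    read_id = sprintf("r%d", 1:60), target_id = "t1",
    sample = rep(c("c1", "c2", "c3"), each = 20), replicate = "rep1",
    context = "CG", n_sites = 10L, n_meth = 5L,
    mppm = c(runif(20, 0, 0.4), runif(20, 0.3, 0.7), runif(20, 0.6, 1)))
  res <- dmppm_pairwise(rec, adjust = "BH")
  expect_equal(nrow(res), 3L)
  expect_true(all(c("p_value", "p_adjusted") %in% names(res)))
  expect_true(all(res$p_value >= 0 & res$p_value <= 1))
})

test_that("site levels use informative calls only", {
  calls <- rbind(c(1L, 1L), c(0L, NA), c(NA, 0L))
  mc <- mc_from_matrix(calls, c("CG", "CG"))
  lv <- site_levels(mc, "CG")
  expect_equal(lv$level, c(0.5, 0.5))
  expect_equal(lv$n_informative, c(2L, 2L))
})

test_that("regional ANOVA matches the closed-form F test and Tukey reference", {
  set.seed(19)
  conds <- rep(c("c1", "c2", "c3", "c4"), each = 4)
  reps <- rep(paste0("rep", 1:4), times = 4)
  shift <- rep(c(0, 0.05, 0.1, 0.2), each = 4)
  # one molecule-set per replicate whose mean level is known
  n_sites <- 8L
  mats <- lapply(seq_along(conds), function(i) {
    matrix(rbinom(40 * n_sites, 1, 0.3 + shift[i]), ncol = n_sites)
  })
  calls <- do.call(rbind, mats)
  mc <- mc_from_matrix(calls, rep("CG", n_sites),
                       sample = rep(conds, each = 40),
                       replicate = rep(reps, each = 40))
  res <- region_anova(mc, "CG")
  expect_equal(nrow(res$replicate_means), 16L)
  # closed-form one-way ANOVA on the same replicate means
  orc <- oracle_anova(res$replicate_means$mean_level,
                      res$replicate_means$sample)
  expect_equal(res$anova$F, orc$F, tolerance = 1e-8)
  expect_equal(res$anova$p_value, orc$p, tolerance = 1e-8)
  expect_equal(nrow(res$tukey), choose(4, 2))
  # Tukey p from the studentized range distribution directly
  g <- split(res$replicate_means$mean_level, res$replicate_means$sample)
  mse <- mean(vapply(g, var, 0))
  q <- abs(mean(g$c4) - mean(g$c1)) / sqrt(mse / 4)
  p_ref <- ptukey(q, 4, 12, lower.tail = FALSE)
  p_got <- res$tukey$p_adj[res$tukey$comparison == "c4-c1"]
  expect_equal(p_got, p_ref, tolerance = 1e-8)
})

test_that("identical replicate means give F = 0 and Tukey p = 1", {
  # 2 conditions x 2 replicates with the same mean level everywhere
  base <- rbind(c(1L, 0L), c(0L, 1L))
  calls <- do.call(rbind, rep(list(base), 4))
  mc <- mc_from_matrix(calls, c("CG", "CG"),
                       sample = rep(c("c1", "c2"), each = 4),
                       replicate = rep(rep(c("rep1", "rep2"), each = 2), 2))
  res <- region_anova(mc, "CG")
  expect_equal(res$anova$F, 0)
  expect_equal(res$anova$p_value, 1)
  expect_true(all(res$tukey$p_adj == 1))
})

test_that("regional ANOVA requires replication", {
  calls <- matrix(rbinom(20, 1, 0.5), nrow = 10)
  mc <- mc_from_matrix(calls, c("CG", "CG"),
                       sample = rep(c("c1", "c2"), each = 5))
  expect_warning(res <- region_anova(mc, "CG"), "replicates")
  expect_null(res$anova)
})

test_that("level correlations behave on identity, anti-monotone and replicates", {
  p1 <- data.frame(offset = 1:10, level = seq(0, 1, length.out = 10))
  expect_equal(level_correlation(p1, p1), 1)
  p2 <- p1; p2$level <- 1 - p1$level
  expect_equal(level_correlation(p1, p2), -1)
  expect_true(is.na(level_correlation(p1[1:2, ], p1[1:2, ])))

  # simulated technical replicates of one scenario correlate strongly
  seq <- random_seq(500, gc = 0.5)
  cl <- epiallele_class("c", 1, p_meth = c(CG = 0.6, CHG = 0.3, CHH = 0.1),
                        persistence = c(CG = 0.5, CHG = 0.5, CHH = 0),
                        propensity_sd = 1)
  prof <- function(s) {
    tr <- simulate_molecules(seq, list(cl), 250, seed = s)
    mc <- calls_from_truth(tr)
    do.call(rbind, lapply(c("CG", "CHG", "CHH"), function(ctx)
      site_levels(mc, ctx)))
  }
  r <- level_correlation(prof(1), prof(2))
  expect_gt(r, 0.9)
})

test_that("within-molecule context statistics count strict orderings", {
  # 6 CG, 4 CHG, 5 CHH sites
  ctx <- c(rep("CG", 6), rep("CHG", 4), rep("CHH", 5))
  r1 <- c(rep(1L, 6), c(1L, 1L, 0L, 0L), c(1L, 0L, 0L, 0L, 0L))  # 1 > .5 > .2
  r2 <- c(rep(c(1L, 0L), 3), c(1L, 1L, 0L, 0L), c(1L, 0L, 0L, 0L, 0L)) # tie .5
  mc <- mc_from_matrix(rbind(r1, r2), ctx)
  st <- within_molecule_context_stats(mc)
  expect_equal(st$per_read$mppm_CG, c(1, 0.5))
  expect_equal(st$frac_cg_gt_chg, 0.5)   # tie does not count (strict)
  expect_equal(st$frac_chg_gt_chh, 1)
})

test_that("propensity coupling raises within-molecule context correlations", {
  seq <- random_seq(600, gc = 0.5)
  stat_at <- function(sd_) {
    cl <- epiallele_class("c", 1, p_meth = c(CG = 0.5, CHG = 0.2, CHH = 0.05),
                          propensity_sd = sd_)
    tr <- simulate_molecules(seq, list(cl), 5000, seed = 55)
    within_molecule_context_stats(calls_from_truth(tr))
  }
  s0 <- stat_at(0); s2 <- stat_at(2)
  expect_gt(s2$correlations["cg_chg"], s0$correlations["cg_chg"])
  expect_gt(s2$correlations["chg_chh"], s0$correlations["chg_chh"])
  expect_gt(s2$correlations["cg_chg"], 0.5)
  expect_lt(abs(s0$correlations["cg_chg"]), 0.2)
})

test_that("GC regression is exact on noiseless data and flags degeneracy", {
  gc <- seq(0.2, 0.5, length.out = 10)
  df <- data.frame(gc_content = gc, reads = 5 + 2 * log(gc))
  fit <- suppressWarnings(gc_reads_regression(df))  # exact fit warns in summary.lm
  expect_equal(fit$r_squared, 1)
  expect_equal(fit$slope, 2, tolerance = 1e-8)
  expect_equal(fit$intercept, 5, tolerance = 1e-8)

  const <- gc_reads_regression(data.frame(gc_content = gc, reads = 7))
  expect_equal(const$r_squared, 0)

  set.seed(9)
  expect_warning(
    fit2 <- gc_reads_regression(
      data.frame(gc_content = c(0, gc),
                 reads = c(1, 5 + 2 * log(gc) + rnorm(10, 0, 0.2)))),
    "non-positive")
  expect_equal(fit2$n, 10L)
})

test_that("GC regression p-values are calibrated under permutation", {
  set.seed(23)
  gc <- runif(12, 0.2, 0.5)
  reads <- rpois(12, 50)
  r2s <- replicate(400, gc_reads_regression(
    data.frame(gc_content = gc, reads = sample(reads)))$r_squared)
  # under the null, E[R^2] = 1/(n-1)
  expect_lt(abs(mean(r2s) - 1 / 11), 3 * sd(r2s) / sqrt(400))
  ps <- replicate(400, gc_reads_regression(
    data.frame(gc_content = gc, reads = sample(reads)))$p_value)
  expect_gt(mean(ps < 0.05), 0.01)
  expect_lt(mean(ps < 0.05), 0.12)
})
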