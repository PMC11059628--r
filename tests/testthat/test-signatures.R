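test_that("run-length encoding produces maximal runs with missing as a state", {
  r <- methylation_runs(c(1L, 1L, 0L, 0L, 1L))
  expect_equal(r$state, c(1L, 0L, 1L))
  expect_equal(r$start, c(0L, 2L, 4L))
  expect_equal(r$length, c(2L, 2L, 1L))

  allna <- methylation_runs(rep(NA_integer_, 4))
  expect_equal(nrow(allna), 1L)
  expect_true(is.na(allna$state))
  expect_equal(allna$length, 4L)

  expect_equal(nrow(methylation_runs(integer(0))), 0L)
})

test_that("runs agree with the brute-force scan oracle on random vectors", {
  set.seed(61)
  for (i in 1:600) {
    v <- sample(c(0L, 1L, NA), sample(1:30, 1), replace = TRUE)
    got <- methylation_runs(v)
    want <- oracle_runs(v)
    expect_equal(got$state, want$state)
    expect_equal(got$start, want$start)
    expect_equal(got$length, want$length)
    # run lengths partition the subsequence
    expect_equal(sum(got$length), length(v))
  }
})

test_that("footprint specs validate their construction and file form", {
  expect_error(footprint_spec("x", "t1", "CG", "set"), "non-empty")
  expect_error(footprint_spec("x", "t1", "CG", "run"), "min_run")
  expect_error(footprint_spec("x", "t1", "CG", "run", min_run = 2,
                              windows = c(5, 2)), "start <= end")

  f <- tempfile(fileext = ".tsv")
  writeLines(c(
    "spec_id\ttarget_id\tcontext\ttype\tstate\tsites\twindows\tmin_run",
    "open2\tt1\tCG\tset\tunmethylated\t0,1\t.\t.",
    "meth6\tt1\tCG\trun\tmethylated\t.\t.\t6"
  ), f)
  specs <- read_footprint_specs(f)
  expect_length(specs, 2L)
  expect_equal(specs[[1]]$sites, c(0L, 1L))
  expect_equal(specs[[2]]$min_run, 6L)

  # validation against a target's context subsequence
  p <- write_panel("TACGTACGTT")  # 2 CG sites
  tg <- load_targets(p$reference, p$table)
  f2 <- tempfile(fileext = ".tsv")
  writeLines(c(
    "spec_id\ttarget_id\tcontext\ttype\tstate\tsites\twindows\tmin_run",
    "bad\tt1\tCG\tset\tunmethylated\t0,5\t.\t."
  ), f2)
  expect_error(read_footprint_specs(f2, tg), "beyond")
})

test_that("set and run footprints match per their semantics", {
  ctx <- rep("CG", 8)
  mk <- function(...) {
    m <- rbind(...)
    rownames(m) <- sprintf("r%d", seq_len(nrow(m)))
    mc_from_matrix(m, ctx)
  }
  open2 <- footprint_spec("open2", "t1", "CG", "set", sites = 0:1)
  mc <- mk(c(0L, 0L, 1L, 1L, 0L, 0L, 1L, 0L),
           c(1L, 0L, 1L, 1L, 0L, 0L, 1L, 0L),
           c(0L, NA, 1L, 1L, 0L, 0L, 1L, 0L))
  expect_equal(unname(match_footprint(mc, open2)), c(TRUE, FALSE, FALSE))

  meth6 <- footprint_spec("meth6", "t1", "CG", "run",
                          state = "methylated", min_run = 6)
  mc2 <- mk(c(1L, 1L, 1L, 1L, 1L, 0L, 1L, 1L),   # max run 5
            c(0L, 1L, 1L, 1L, 1L, 1L, 1L, 0L))   # run of 6
  expect_equal(unname(match_footprint(mc2, meth6)), c(FALSE, TRUE))

  # conjunction over two flanking windows
  both <- footprint_spec("both", "t1", "CG", "run", state = "methylated",
                         min_run = 2, windows = list(c(0, 2), c(5, 7)))
  mc3 <- mk(c(1L, 1L, 0L, 0L, 0L, 1L, 1L, 0L),
            c(1L, 1L, 0L, 0L, 0L, 0L, 1L, 0L))
  expect_equal(unname(match_footprint(mc3, both)), c(TRUE, FALSE))
})

test_that("footprint matching equals the brute-force evaluator on random cases", {
  set.seed(71)
  ctx <- rep("CG", 12)
  for (i in 1:400) {
    v <- sample(c(0L, 1L, NA), 12, replace = TRUE, prob = c(0.45, 0.45, 0.1))
    m <- matrix(v, 1, dimnames = list("r", NULL))
    mc <- mc_from_matrix(m, ctx)
    spec <- if (runif(1) < 0.5) {
      footprint_spec("s", "t1", "CG", "set",
                     sites = sample(0:11, sample(1:4, 1)),
                     state = sample(c("methylated", "unmethylated"), 1))
    } else {
      w1 <- sort(sample(0:11, 2))
      footprint_spec("s", "t1", "CG", "run",
                     state = sample(c("methylated", "unmethylated"), 1),
                     min_run = sample(1:4, 1),
                     windows = if (runif(1) < 0.5) list(w1) else NULL)
    }
    expect_identical(unname(match_footprint(mc, spec)), oracle_match(v, spec),
                     info = paste(i))
  }
})

test_that("prevalence counts full-length reads and recovers mixture weights", {
  ctx <- rep("CG", 6)
  m <- rbind(matrix(1L, 100, 6), matrix(0L, 20, 6))
  rownames(m) <- sprintf("r%03d", 1:120)
  mc <- mc_from_matrix(m, ctx)
  spec <- footprint_spec("open", "t1", "CG", "set", sites = 0:1)
  res <- prevalence(mc, spec)
  expect_equal(res$n_reads, 120L)
  expect_equal(res$n_matching, 20L)
  expect_equal(res$fraction, 20 / 120)

  # none matching -> 0.0
  spec_m <- footprint_spec("m", "t1", "CG", "run", state = "methylated",
                           min_run = 7)
  expect_equal(prevalence(mc, spec_m)$fraction, 0)

  # two-class simulation: footprint class weight recovered within 99% CI
  seq <- random_seq(500, gc = 0.5)
  sites <- extract_sites(seq)
  classes <- list(
    epiallele_class("bg", 0.6, p_meth = c(CG = 0.95, CHG = 0.2, CHH = 0.05)),
    epiallele_class("fp", 0.4, p_meth = c(CG = 0.95, CHG = 0.2, CHH = 0.05),
                    footprint_mask = sites$index[sites$context == "CG"][1:2])
  )
  tr <- simulate_molecules(seq, classes, 2000, seed = 31)
  mcs <- calls_from_truth(tr)
  spec2 <- footprint_spec("open2", "t1", "CG", "set", sites = 0:1)
  est <- prevalence(mcs, spec2)$fraction
  ci <- qbinom(c(0.005, 0.995), 2000, 0.4) / 2000
  expect_gte(est, ci[1] - 0.6 * 0.05^2)  # tiny background leakage allowance
  expect_lte(est, ci[2] + 0.6 * 0.05^2)
})

test_that("complementary specs partition full-length reads", {
  set.seed(81)
  ctx <- rep("CG", 5)
  m <- matrix(rbinom(500, 1, 0.5), 100, 5)
  rownames(m) <- sprintf("r%03d", 1:100)
  mc <- mc_from_matrix(m, ctx)
  s_meth <- footprint_spec("a", "t1", "CG", "set", sites = 0,
                           state = "methylated")
  s_unmeth <- footprint_spec("b", "t1", "CG", "set", sites = 0,
                             state = "unmethylated")
  pa <- prevalence(mc, s_meth)$fraction
  pb <- prevalence(mc, s_unmeth)$fraction
  expect_equal(pa + pb, 1)
})

test_that("conditional prevalence equals direct set intersection", {
  set.seed(91)
  ctx <- rep("CG", 8)
  m <- matrix(rbinom(8 * 300, 1, 0.5), 300, 8)
  rownames(m) <- sprintf("r%03d", 1:300)
  mc <- mc_from_matrix(m, ctx)
  specA <- footprint_spec("A", "t1", "CG", "set", sites = 0:1)
  specB <- footprint_spec("B", "t1", "CG", "set", sites = 6:7)
  hitsA <- match_footprint(mc, specA)
  hitsB <- match_footprint(mc, specB)
  sub <- subset_calls(mc, hitsA)
  cond <- prevalence(sub, specB)$fraction
  expect_equal(cond, sum(hitsA & hitsB) / sum(hitsA))
})

test_that("per-replicate prevalence feeds ANOVA/Tukey across conditions", {
  set.seed(101)
  ctx <- rep("CG", 6)
  mcs <- list(
    mc_from_matrix(do.call(rbind, lapply(1:3, function(r) {
      m <- matrix(rbinom(6 * 40, 1, 0.2), 40, 6,
                  dimnames = list(sprintf("a_rep%d_r%03d", r, 1:40), NULL)); m
    })), ctx, sample = "condA",
    replicate = rep(paste0("rep", 1:3), each = 40)),
    mc_from_matrix(do.call(rbind, lapply(1:3, function(r) {
      m <- matrix(rbinom(6 * 40, 1, 0.8), 40, 6,
                  dimnames = list(sprintf("b_rep%d_r%03d", r, 1:40), NULL)); m
    })), ctx, sample = "condB",
    replicate = rep(paste0("rep", 1:3), each = 40))
  )
  mc <- combine_calls(mcs)
  spec <- footprint_spec("open2", "t1", "CG", "set", sites = 0:1)
  res <- prevalence(mc, spec, by_replicate = TRUE)
  expect_equal(nrow(res$per_replicate), 6L)
  expect_false(is.null(res$anova))
  expect_lt(res$anova$p_value, 0.01)
  expect_equal(nrow(res$tukey), 1L)
})

test_that("conditional mPPM contrasts footprint reads against all reads", {
  ctx <- c(rep("CG", 4), rep("CHH", 6))
  # footprint class: first 2 CG open and low CHH; background: high both
  set.seed(111)
  fp <- cbind(matrix(0L, 150, 2), matrix(rbinom(300, 1, 0.5), 150, 2),
              matrix(rbinom(900, 1, 0.1), 150, 6))
  bg <- cbind(matrix(1L, 150, 2), matrix(rbinom(300, 1, 0.5), 150, 2),
              matrix(rbinom(900, 1, 0.6), 150, 6))
  m <- rbind(fp, bg)
  rownames(m) <- sprintf("r%03d", 1:300)
  mc <- mc_from_matrix(m, ctx)
  spec <- footprint_spec("open2", "t1", "CG", "set", sites = 0:1)
  res <- conditional_mppm(mc, spec, "CHH")
  expect_lt(median(res$matching), median(res$all))
  expect_lt(res$test$p_value, 0.001)

  # spec matched by every read -> identical distributions, p = 1
  all_spec <- footprint_spec("any", "t1", "CG", "run", min_run = 1,
                             state = "methylated")
  mc_all <- mc_from_matrix(matrix(1L, 10, 10,
                                  dimnames = list(sprintf("r%d", 1:10), NULL)),
                           ctx)
  res2 <- conditional_mppm(mc_all, all_spec, "CHH")
  expect_equal(res2$test$p_value, 1)

  # matched by none -> NA with warning
  none <- footprint_spec("none", "t1", "CG", "set", sites = 0:1)
  expect_warning(res3 <- conditional_mppm(mc_all, none, "CHH"), "stratum")
  expect_true(!is.data.frame(res3$test) || is.na(res3$test))
})
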