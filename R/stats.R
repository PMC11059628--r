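#' Methylation proportion per molecule (mPPM)
#'
#' For every filtered, full-length read, the fraction of the target's
#' cytosine sites of one context that are methylated on that molecule.
#' Targets without sites of the requested context yield no records rather
#' than zeros.
#'
#' @param mc A `molecule_calls` object (already filtered).
#' @param context One of `"CG"`, `"CHG"`, `"CHH"`.
#' @param full_length_only Restrict to full-length reads (default TRUE, the
#'   convention for per-molecule proportions).
#' @return Data frame `read_id`, `target_id`, `sample`, `replicate`,
#'   `context`, `n_sites`, `n_meth`, `mppm`.
#' @export
mppm <- function(mc, context, full_length_only = TRUE) {
  stopifnot(context %in% c("CG", "CHG", "CHH"))
  idx <- which(mc$sites$context == context)
  empty <- data.frame(read_id = character(0), target_id = character(0),
                      sample = character(0), replicate = character(0),
                      context = character(0), n_sites = integer(0),
                      n_meth = integer(0), mppm = numeric(0),
                      stringsAsFactors = FALSE)
  if (length(idx) == 0L) return(empty)
  use <- if (full_length_only) mc$meta$full_length else rep(TRUE, nrow(mc$calls))
  if (!full_length_only) {
    # without the full-length restriction, require every site of the context
    sub <- mc$calls[, idx, drop = FALSE]
    use <- use & !apply(is.na(sub), 1L, any)
  }
  if (sum(use) == 0L) return(empty)
  sub <- mc$calls[use, idx, drop = FALSE]
  n_meth <- as.integer(rowSums(sub == 1L))
  data.frame(
    read_id = mc$meta$read_id[use],
    target_id = mc$target_id,
    sample = mc$meta$sample[use],
    replicate = mc$meta$replicate[use],
    context = context,
    n_sites = length(idx),
    n_meth = n_meth,
    mppm = n_meth / length(idx),
    stringsAsFactors = FALSE
  )
}

#' Two-group DmPPM test on molecule-level methylation proportions
#'
#' Kruskal-Wallis rank test (with tie correction) comparing the mPPM
#' distributions of two conditions, molecules pooled across replicates.
#' With two groups this is the rank-sum test up to the chi-square
#' approximation. When all pooled values are identical the statistic is 0
#' and p = 1.
#'
#' @param group_a,group_b Numeric vectors of per-molecule mPPM values.
#' @param alpha Significance level used for the `significant` flag
#'   (default 0.05).
#' @return One-row data frame `n_a`, `n_b`, `statistic` (H), `p_value`,
#'   `median_diff` (median A - median B), `significant`.
#' @export
dmppm_test <- function(group_a, group_b, alpha = 0.05) {
  group_a <- group_a[!is.na(group_a)]
  group_b <- group_b[!is.na(group_b)]
  if (length(group_a) < 2L || length(group_b) < 2L) {
    warning("dmppm_test: each group needs >= 2 values; returning NA")
    return(data.frame(n_a = length(group_a), n_b = length(group_b),
                      statistic = NA_real_, p_value = NA_real_,
                      median_diff = NA_real_, significant = NA))
  }
  pooled <- c(group_a, group_b)
  if (length(unique(pooled)) == 1L) {
    h <- 0; p <- 1
  } else {
    kt <- stats::kruskal.test(list(group_a, group_b))
    h <- unname(kt$statistic); p <- kt$p.value
  }
  data.frame(n_a = length(group_a), n_b = length(group_b),
             statistic = h, p_value = p,
             median_diff = stats::median(group_a) - stats::median(group_b),
             significant = is.finite(p) && p < alpha)
}

#' Pairwise DmPPM tests across conditions
#'
#' @param records An mPPM record data frame (one target, one context),
#'   typically from [mppm()] on pooled samples.
#' @param alpha Significance level (default 0.05).
#' @param adjust P-value adjustment method for the extra `p_adjusted` column
#'   (`"none"` to skip, default `"none"`; raw p-values are always reported).
#' @return Data frame of class `dmppm_result`, one row per condition pair:
#'   `target_id`, `context`, `sample_a`, `sample_b`, `statistic`, `p_value`,
#'   `median_diff`, `significant` (and `p_adjusted` when requested).
#' @export
dmppm_pairwise <- function(records, alpha = 0.05, adjust = "none") {
  samples <- sort(unique(records$sample))
  if (length(samples) < 2L) stop("need >= 2 conditions")
  pairs <- utils::combn(samples, 2L, simplify = FALSE)
  out <- do.call(rbind, lapply(pairs, function(pr) {
    res <- suppressWarnings(dmppm_test(records$mppm[records$sample == pr[1]],
                                       records$mppm[records$sample == pr[2]],
                                       alpha = alpha))
    cbind(data.frame(target_id = records$target_id[1],
                     context = records$context[1],
                     sample_a = pr[1], sample_b = pr[2],
                     stringsAsFactors = FALSE),
          res[, c("statistic", "p_value", "median_diff", "significant")])
  }))
  if (!identical(adjust, "none")) {
    out$p_adjusted <- stats::p.adjust(out$p_value, method = adjust)
  }
  class(out) <- c("dmppm_result", "data.frame")
  out
}

#' Per-site mean methylation levels across molecules
#'
#' For each site of a context, the mean call over molecules with an
#' informative call at that site (missing calls excluded from the
#' denominator), per condition with replicates pooled.
#'
#' @param mc A `molecule_calls` object (filtered; all reads are used, not
#'   only full-length ones).
#' @param context Context to profile.
#' @return Data frame `target_id`, `sample`, `context`, `index`, `offset`,
#'   `level`, `n_informative`.
#' @export
site_levels <- function(mc, context) {
  idx <- which(mc$sites$context == context)
  samples <- unique(mc$meta$sample)
  do.call(rbind, lapply(samples, function(s) {
    sub <- mc$calls[mc$meta$sample == s, idx, drop = FALSE]
    data.frame(
      target_id = mc$target_id, sample = s, context = context,
      index = mc$sites$index[idx], offset = mc$sites$offset[idx],
      level = colMeans(sub == 1L, na.rm = TRUE),
      n_informative = colSums(!is.na(sub)),
      stringsAsFactors = FALSE
    )
  }))
}

#' Regional mean methylation per replicate with one-way ANOVA and Tukey HSD
#'
#' For each condition x replicate, molecules are pooled and a regional mean
#' level is computed as the mean over the (sub)region's sites of the
#' per-site mean methylation. The replicate-level regional means then enter
#' a one-way ANOVA across conditions with post-hoc Tukey HSD (studentized
#' range) for all pairwise comparisons.
#'
#' @param mc A `molecule_calls` object covering >= 2 conditions with >= 2
#'   replicates each.
#' @param context Context to test.
#' @param subregion Optional integer vector of site `index` values (0-based,
#'   over the full site list) restricting the region; default all sites of
#'   the context.
#' @return List with `replicate_means` (condition, replicate, mean level),
#'   `anova` (one-row data frame `df_between`, `df_within`, `F`, `p_value`)
#'   and `tukey` (data frame `comparison`, `diff`, `lwr`, `upr`, `p_adj`),
#'   or with the tests NULL (and a warning) when replication is insufficient.
#' @export
region_anova <- function(mc, context, subregion = NULL) {
  idx <- which(mc$sites$context == context)
  if (!is.null(subregion)) idx <- idx[mc$sites$index[idx] %in% subregion]
  if (length(idx) == 0L) stop("no sites of context ", context, " in subregion")
  groups <- unique(mc$meta[, c("sample", "replicate")])
  rep_means <- do.call(rbind, lapply(seq_len(nrow(groups)), function(i) {
    sel <- mc$meta$sample == groups$sample[i] &
      mc$meta$replicate == groups$replicate[i]
    sub <- mc$calls[sel, idx, drop = FALSE]
    data.frame(sample = groups$sample[i], replicate = groups$replicate[i],
               mean_level = mean(colMeans(sub == 1L, na.rm = TRUE), na.rm = TRUE),
               stringsAsFactors = FALSE)
  }))
  nrep <- table(rep_means$sample)
  if (length(nrep) < 2L || any(nrep < 2L)) {
    warning("region_anova: need >= 2 conditions with >= 2 replicates; test skipped")
    return(list(replicate_means = rep_means, anova = NULL, tukey = NULL))
  }
  group_tests(rep_means$mean_level, rep_means$sample, rep_means)
}

# Shared one-way ANOVA + Tukey HSD on one value per condition x replicate.
group_tests <- function(values, condition, replicate_means) {
  d <- data.frame(y = values, g = factor(condition))
  if (stats::var(d$y) == 0) {
    # identical replicate means everywhere: no between-group signal
    lev <- levels(d$g)
    cmp <- utils::combn(lev, 2L, function(pr) paste(pr[2], pr[1], sep = "-"))
    return(list(
      replicate_means = replicate_means,
      anova = data.frame(df_between = length(lev) - 1L,
                         df_within = nrow(d) - length(lev),
                         F = 0, p_value = 1),
      tukey = data.frame(comparison = cmp, diff = 0, lwr = 0, upr = 0,
                         p_adj = 1, stringsAsFactors = FALSE)
    ))
  }
  fit <- stats::aov(y ~ g, data = d)
  an <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$g
  list(
    replicate_means = replicate_means,
    anova = data.frame(df_between = an$Df[1], df_within = an$Df[2],
                       F = an$`F value`[1], p_value = an$`Pr(>F)`[1]),
    tukey = data.frame(comparison = rownames(tk), diff = tk[, "diff"],
                       lwr = tk[, "lwr"], upr = tk[, "upr"],
                       p_adj = tk[, "p adj"], row.names = NULL,
                       stringsAsFactors = FALSE)
  )
}

#' Correlation between two per-site level profiles
#'
#' Used replicate-vs-replicate and against an external (e.g. WGBS-style)
#' per-site table; sites of all contexts may be pooled by the caller.
#'
#' @param profile_a,profile_b Data frames with columns `offset` and `level`
#'   (extra columns ignored); matched on `offset`.
#' @param method Correlation method (default `"pearson"`).
#' @return The correlation coefficient, or `NA` with fewer than 3 shared
#'   sites.
#' @export
level_correlation <- function(profile_a, profile_b, method = "pearson") {
  m <- merge(profile_a[, c("offset", "level")],
             profile_b[, c("offset", "level")], by = "offset")
  m <- m[stats::complete.cases(m), ]
  if (nrow(m) < 3L) return(NA_real_)
  stats::cor(m$level.x, m$level.y, method = method)
}

#' Within-molecule co-methylation across contexts
#'
#' On full-length reads covering all sites of all three contexts, emits the
#' per-read (mPPM_CG, mPPM_CHG, mPPM_CHH) triple, the fraction of reads with
#' strictly mPPM_CG > mPPM_CHG and strictly mPPM_CHG > mPPM_CHH, and the
#' pairwise correlations between context proportions across reads.
#'
#' @param mc A `molecule_calls` object.
#' @param method Correlation method (default `"pearson"`).
#' @return List with `per_read` (data frame `read_id`, `sample`,
#'   `mppm_CG`, `mppm_CHG`, `mppm_CHH`), `frac_cg_gt_chg`, `frac_chg_gt_chh`
#'   and `correlations` (named: `cg_chg`, `chg_chh`, `cg_chh`). Statistics
#'   involving a context absent from the target are `NA`.
#' @export
within_molecule_context_stats <- function(mc, method = "pearson") {
  recs <- lapply(c("CG", "CHG", "CHH"), function(ctx) mppm(mc, ctx))
  names(recs) <- c("CG", "CHG", "CHH")
  have <- vapply(recs, nrow, 1L) > 0L
  ids <- Reduce(intersect, lapply(recs[have], `[[`, "read_id"))
  per_read <- data.frame(read_id = ids, stringsAsFactors = FALSE)
  if (length(ids) > 0L)
    per_read$sample <- recs[[which(have)[1]]]$sample[
      match(ids, recs[[which(have)[1]]]$read_id)]
  for (ctx in c("CG", "CHG", "CHH")) {
    per_read[[paste0("mppm_", ctx)]] <- if (have[[ctx]])
      recs[[ctx]]$mppm[match(ids, recs[[ctx]]$read_id)] else NA_real_
  }
  safe_frac <- function(a, b) {
    if (anyNA(a) || anyNA(b) || length(a) == 0L) NA_real_ else mean(a > b)
  }
  safe_cor <- function(a, b) {
    if (anyNA(a) || anyNA(b) || length(a) < 3L) return(NA_real_)
    if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
    stats::cor(a, b, method = method)
  }
  list(
    per_read = per_read,
    frac_cg_gt_chg = safe_frac(per_read$mppm_CG, per_read$mppm_CHG),
    frac_chg_gt_chh = safe_frac(per_read$mppm_CHG, per_read$mppm_CHH),
    correlations = c(
      cg_chg = safe_cor(per_read$mppm_CG, per_read$mppm_CHG),
      chg_chh = safe_cor(per_read$mppm_CHG, per_read$mppm_CHH),
      cg_chh = safe_cor(per_read$mppm_CG, per_read$mppm_CHH)
    )
  )
}

#' Logarithmic regression of read counts on target GC content
#'
#' Fits `reads = a + b * ln(gc_content)` by least squares over targets and
#' reports the fit quality, mirroring the usual QC of capture yield against
#' target base composition. Targets with non-positive GC are excluded with a
#' warning.
#'
#' @param df Data frame with columns `gc_content` (fraction) and `reads`
#'   (pooled filtered read count per target).
#' @return List `r_squared`, `p_value` (slope test; NA when the response is
#'   constant), `intercept`, `slope`, `n`.
#' @export
gc_reads_regression <- function(df) {
  stopifnot(all(c("gc_content", "reads") %in% names(df)))
  bad <- df$gc_content <= 0
  if (any(bad)) {
    warning(sprintf("excluding %d target(s) with non-positive GC", sum(bad)))
    df <- df[!bad, ]
  }
  if (nrow(df) < 3L) stop("need >= 3 targets with positive GC")
  if (stats::var(df$reads) == 0)
    return(list(r_squared = 0, p_value = NA_real_,
                intercept = mean(df$reads), slope = 0, n = nrow(df)))
  fit <- stats::lm(reads ~ log(gc_content), data = df)
  sm <- summary(fit)
  list(r_squared = sm$r.squared,
       p_value = sm$coefficients[2, 4],
       intercept = unname(stats::coef(fit)[1]),
       slope = unname(stats::coef(fit)[2]),
       n = nrow(df))
}
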