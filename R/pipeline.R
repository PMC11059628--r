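#' Run the full targeted single-molecule methylation pipeline
#'
#' Executes every stage on a configured experiment: target loading and site
#' extraction, read assignment, per-molecule calling, the consecutive-CHH
#' filter, conversion-rate QC on the internal control, per-target mPPM and
#' pairwise DmPPM tests, per-site level profiles (with regional ANOVA for
#' configured subregions), footprint-signature prevalences and
#' single-molecule heatmaps. All tables are TSV, QC and the run manifest are
#' JSON.
#'
#' The configuration (YAML file or equivalent list) has fields:
#' * `reference`, `targets` — paths to the reference FASTA and target table
#' * `samples` — list of `{sample, replicate, reads}` entries
#' * `footprints` — optional footprint-spec TSV
#' * `subregions` — optional list of `{target_id, context, sites}` windows
#'   for regional ANOVA
#' * `heatmaps` — optional list of [heatmap_spec()] field sets
#' * `seed` — default seed for display subsampling
#'
#' @param config Path to a YAML config, or a list with the same structure.
#' @param outdir Output directory (created if needed).
#' @param seed Overrides the config seed when not NULL.
#' @return Invisibly, a list with the main in-memory results: `targets`,
#'   `qc`, per-target `calls`, `mppm`, `dmppm`, `prevalence` and the
#'   manifest.
#' @export
run_pipeline <- function(config, outdir, seed = NULL) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  for (f in c("reference", "targets", "samples"))
    if (is.null(cfg[[f]])) stop("config missing required field: ", f)
  if (is.null(seed)) seed <- if (is.null(cfg$seed)) 1L else cfg$seed
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

  targets <- load_targets(cfg$reference, cfg$targets)
  site_catalog <- do.call(rbind, lapply(seq_len(nrow(targets)), function(i)
    as.data.frame(extract_sites(targets[i, ]))))
  utils::write.table(site_catalog, file.path(outdir, "site_catalog.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  for (s in cfg$samples)
    if (!file.exists(s$reads))
      stop("sample '", s$sample, "' (", s$replicate, "): read file not found: ",
           s$reads)

  # --- assignment, calling, filtering -----------------------------------
  assignments <- list()
  calls_by_target <- stats::setNames(
    rep(list(list()), nrow(targets)), targets$target_id)
  for (s in cfg$samples) {
    reads <- read_reads(s$reads)
    asg <- assign_reads(reads, targets)
    asg$sample <- s$sample
    asg$replicate <- s$replicate
    asg$kept <- FALSE
    for (tid in unique(stats::na.omit(asg$target_id))) {
      tg <- get_target(targets, tid)
      mc <- call_molecules(reads[asg$read_id[!is.na(asg$target_id) &
                                               asg$target_id == tid]],
                           tg, sample = s$sample, replicate = s$replicate)
      mc <- filter_chh_runs(mc)
      asg$kept[asg$read_id %in% mc$meta$read_id] <- TRUE
      calls_by_target[[tid]] <- c(calls_by_target[[tid]], list(mc))
    }
    assignments[[length(assignments) + 1L]] <- asg
  }
  assignments <- do.call(rbind, assignments)
  pooled <- lapply(calls_by_target, function(xs)
    if (length(xs) > 0L) combine_calls(xs) else NULL)

  # --- QC ----------------------------------------------------------------
  ctrl_ids <- targets$target_id[targets$is_control]
  conv <- NA_real_
  if (length(ctrl_ids) > 0L && !is.null(pooled[[ctrl_ids[1]]]))
    conv <- conversion_rate(pooled[[ctrl_ids[1]]])
  qc <- coverage_summary(assignments, targets, control_rate = conv)
  utils::write.table(qc$per_target, file.path(outdir, "qc_per_target.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(per_sample = qc$per_sample, detection = qc$detection,
         conversion_rate = conv),
    file.path(outdir, "qc.json"), auto_unbox = TRUE, digits = NA, na = "null")

  # --- per-target statistics --------------------------------------------
  conditions <- unique(vapply(cfg$samples, `[[`, "", "sample"))
  mppm_all <- list(); dmppm_all <- list()
  for (tid in names(pooled)) {
    mc <- pooled[[tid]]
    if (is.null(mc)) next
    write_call_matrix(mc, file.path(outdir, paste0("calls_", tid, ".tsv")))
    for (ctx in c("CG", "CHG", "CHH")) {
      rec <- mppm(mc, ctx)
      if (nrow(rec) == 0L) next
      mppm_all[[length(mppm_all) + 1L]] <- rec
      counts <- table(rec$sample)
      if (length(conditions) >= 2L && length(counts) >= 2L && all(counts >= 2L))
        dmppm_all[[length(dmppm_all) + 1L]] <- dmppm_pairwise(rec)
    }
    for (ctx in c("CG", "CHG", "CHH")) {
      if (!any(mc$sites$context == ctx)) next
      lv <- site_levels(mc, ctx)
      utils::write.table(lv,
                         file.path(outdir, paste0("site_levels_", tid, "_", ctx, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE, append = FALSE)
    }
  }
  if (length(mppm_all) > 0L)
    utils::write.table(do.call(rbind, mppm_all),
                       file.path(outdir, "mppm.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  if (length(dmppm_all) > 0L)
    utils::write.table(do.call(rbind, dmppm_all),
                       file.path(outdir, "dmppm.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

  # --- regional ANOVA on configured subregions --------------------------
  anova_rows <- list()
  for (sr in cfg$subregions %||% list()) {
    mc <- pooled[[sr$target_id]]
    if (is.null(mc)) next
    res <- tryCatch(region_anova(mc, sr$context, unlist(sr$sites)),
                    warning = function(w) NULL)
    if (!is.null(res) && !is.null(res$anova))
      anova_rows[[length(anova_rows) + 1L]] <-
        cbind(data.frame(target_id = sr$target_id, context = sr$context),
              res$anova)
  }
  if (length(anova_rows) > 0L)
    utils::write.table(do.call(rbind, anova_rows),
                       file.path(outdir, "region_anova.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

  # --- footprint signatures ---------------------------------------------
  prev_all <- list()
  if (!is.null(cfg$footprints)) {
    specs <- read_footprint_specs(cfg$footprints, targets)
    for (sp in specs) {
      mc <- pooled[[sp$target_id]]
      if (is.null(mc)) next
      prev_all[[length(prev_all) + 1L]] <-
        suppressWarnings(prevalence(mc, sp))
    }
    if (length(prev_all) > 0L)
      utils::write.table(do.call(rbind, prev_all),
                         file.path(outdir, "footprint_prevalence.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  }

  # --- heatmaps (display only; statistics above never see subsampling) --
  for (hm in cfg$heatmaps %||% list()) {
    mc <- pooled[[hm$target_id]]
    if (is.null(mc)) next
    spec <- heatmap_spec(
      hm$target_id,
      contexts = hm$contexts %||% c("CG", "CHG", "CHH"),
      max_reads = hm$max_reads %||% 1000L,
      subsample_seed = hm$subsample_seed %||% seed,
      cluster_metric = hm$cluster_metric %||% "kendall_tau",
      cluster_context = hm$cluster_context %||% "CG",
      linkage = hm$linkage %||% "average"
    )
    for (cond in unique(mc$meta$sample)) {
      sub <- subset_calls(mc, mc$meta$sample == cond)
      f <- file.path(outdir, sprintf("heatmap_%s_%s.png", hm$target_id, cond))
      suppressWarnings(render_heatmap(sub, spec, f,
                                      target = get_target(targets, hm$target_id)))
    }
  }

  manifest <- list(
    package = "molmeth",
    version = as.character(utils::packageVersion("molmeth")),
    r_version = as.character(getRversion()),
    seed = seed,
    n_targets = nrow(targets),
    samples = lapply(cfg$samples, function(s)
      s[c("sample", "replicate", "reads")]),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(list(targets = targets, qc = qc, calls = pooled,
                 mppm = if (length(mppm_all)) do.call(rbind, mppm_all) else NULL,
                 dmppm = if (length(dmppm_all)) do.call(rbind, dmppm_all) else NULL,
                 prevalence = if (length(prev_all)) do.call(rbind, prev_all) else NULL,
                 manifest = manifest))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a bundled toy experiment for demonstrations and smoke tests
#'
#' Simulates a small two-target experiment (one analysis target, one
#' unmethylated internal control) across two conditions x two replicates,
#' writes reference, target table, reads and a pipeline config under `dir`,
#' and returns the config path. Deterministic given `seed`.
#'
#' @param dir Output directory.
#' @param seed Integer seed.
#' @param reads_per_sample Molecules per condition x replicate (default 50).
#' @return Path to the written YAML config.
#' @export
toy_experiment <- function(dir, seed = 1L, reads_per_sample = 50L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  tseq <- paste(sample(c("A", "C", "G", "T"), 600, replace = TRUE,
                       prob = c(0.3, 0.2, 0.2, 0.3)), collapse = "")
  cseq <- paste(sample(c("A", "C", "G", "T"), 558, replace = TRUE,
                       prob = c(0.3, 0.2, 0.2, 0.3)), collapse = "")
  ref <- file.path(dir, "ref.fa")
  writeLines(c(">chrT", tseq, ">chrC", cseq), ref)
  tab <- file.path(dir, "targets.tsv")
  writeLines(c(
    "target_id\tgene_id\tchrom\tstart\tend\tstrand\tis_control\telements",
    sprintf("T1\tGENE1\tchrT\t0\t600\t+\tFALSE\telement:200-230"),
    sprintf("CTRL\tCTRLGENE\tchrC\t0\t558\t+\tTRUE\t.")
  ), tab)

  targets <- load_targets(ref, tab)
  t1 <- targets[1, ]; ctrl <- targets[2, ]
  scen <- list(
    cond1 = list(epiallele_class("lo", 1, p_meth = c(CG = 0.2, CHG = 0.1, CHH = 0.03),
                                 persistence = c(CG = 0.3, CHG = 0.3, CHH = 0))),
    cond2 = list(epiallele_class("hi", 1, p_meth = c(CG = 0.6, CHG = 0.25, CHH = 0.05),
                                 persistence = c(CG = 0.3, CHG = 0.3, CHH = 0)))
  )
  ctrl_class <- list(epiallele_class("unmeth", 1, p_meth = c(CG = 0, CHG = 0, CHH = 0)))

  samples <- list()
  k <- 0L
  for (cond in names(scen)) for (rep_ in c("rep1", "rep2")) {
    k <- k + 1L
    sd1 <- seed + 13L * k
    tr1 <- simulate_molecules(t1, scen[[cond]], reads_per_sample, sd1)
    r1 <- emit_reads(tr1, t1, conversion_model(), seed = sd1 + 1L)
    trc <- simulate_molecules(ctrl, ctrl_class, reads_per_sample, sd1 + 2L)
    rc <- emit_reads(trc, ctrl, conversion_model(), seed = sd1 + 3L)
    reads <- c(r1, rc)
    names(reads) <- sprintf("%s_%s_read%04d", cond, rep_, seq_along(reads))
    path <- file.path(dir, sprintf("reads_%s_%s.fa", cond, rep_))
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(reads), path)
    samples[[k]] <- list(sample = cond, replicate = rep_, reads = path)
  }

  fps <- file.path(dir, "footprints.tsv")
  writeLines(c(
    "spec_id\ttarget_id\tcontext\ttype\tstate\tsites\twindows\tmin_run",
    "first2cg_open\tT1\tCG\tset\tunmethylated\t0,1\t.\t.",
    "run2cg_meth\tT1\tCG\trun\tmethylated\t.\t.\t2"
  ), fps)

  cfg <- list(reference = ref, targets = tab, samples = samples,
              footprints = fps,
              heatmaps = list(list(target_id = "T1", max_reads = 1000L)),
              seed = seed)
  cfg_path <- file.path(dir, "config.yaml")
  yaml::write_yaml(cfg, cfg_path)
  cfg_path
}
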