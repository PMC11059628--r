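#' Simulate a capture panel: reference, target table and internal control
#'
#' Generates a synthetic target panel emulating a multiplexed single-strand
#' capture design: `n_targets` regions of 509-704 nt whose GC content spans
#' roughly 19-52%, plus one 558 nt internal conversion-control region with
#' no methylation, all on the captured coding strand. Reference FASTA and
#' target table are written under `dir`.
#'
#' @param dir Output directory.
#' @param n_targets Number of analysis targets (default 108; the control is
#'   additional).
#' @param len_range Target length range in nt (default `c(509, 704)`).
#' @param gc_range GC-content range across targets (default `c(0.19, 0.52)`).
#' @param seed Integer seed.
#' @return List with `reference`, `table` (paths) and the loaded `targets`.
#' @export
simulate_panel <- function(dir, n_targets = 108L, len_range = c(509L, 704L),
                           gc_range = c(0.19, 0.52), seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  lens <- sample(len_range[1]:len_range[2], n_targets, replace = TRUE)
  gcs <- stats::runif(n_targets, gc_range[1], gc_range[2])
  seqs <- vapply(seq_len(n_targets), function(i) {
    p <- c(A = (1 - gcs[i]) / 2, C = gcs[i] / 2, G = gcs[i] / 2,
           T = (1 - gcs[i]) / 2)
    s <- paste(sample(names(p), lens[i], replace = TRUE, prob = p),
               collapse = "")
    # every target carries >= 2 CG sites near its 5' end, so first-k-CG
    # footprint definitions and footprint-class masks are always resolvable
    substr(s, 11, 18) <- "ACGTTACG"
    s
  }, "")
  ctrl <- paste(sample(c("A", "C", "G", "T"), 558, replace = TRUE,
                       prob = c(0.325, 0.175, 0.175, 0.325)), collapse = "")
  ids <- sprintf("TGT%03d", seq_len(n_targets))
  ref <- file.path(dir, "panel_ref.fa")
  writeLines(c(rbind(paste0(">", c(ids, "CTRL")), c(seqs, ctrl))), ref)
  tab <- file.path(dir, "panel_targets.tsv")
  rows <- sprintf("%s\tGENE%03d\t%s\t0\t%d\t+\tFALSE\t.", ids,
                  seq_len(n_targets), ids, lens)
  writeLines(c(
    "target_id\tgene_id\tchrom\tstart\tend\tstrand\tis_control\telements",
    rows,
    "CTRL\tCTRLGENE\tCTRL\t0\t558\t+\tTRUE\t."
  ), tab)
  list(reference = ref, table = tab, targets = load_targets(ref, tab))
}

#' Default epiallele mixture for one condition
#'
#' Two subpopulations per condition: a background class with moderate,
#' run-coupled methylation and within-molecule context coupling, and a
#' footprint-bearing class whose first two CG sites are protected from
#' methylation. The footprint weight and the CG stationary probability vary
#' by condition, producing between-condition DmPPM and prevalence
#' differences of the kind the molecule-level statistics are designed to
#' detect.
#'
#' @param footprint_weight Mixture weight of the footprint class.
#' @param p_cg CG stationary methylation probability of the background
#'   class.
#' @return List of two [epiallele_class()] objects.
#' @export
condition_classes <- function(footprint_weight = 0.2, p_cg = 0.5) {
  list(
    epiallele_class(
      "background", 1 - footprint_weight,
      p_meth = c(CG = p_cg, CHG = 0.2, CHH = 0.05),
      persistence = c(CG = 0.5, CHG = 0.5, CHH = 0),
      propensity_sd = 1
    ),
    epiallele_class(
      "footprint", footprint_weight,
      p_meth = c(CG = p_cg, CHG = 0.2, CHH = 0.05),
      persistence = c(CG = 0.5, CHG = 0.5, CHH = 0),
      footprint_mask = 0:1,  # replaced per target with its first 2 CG sites
      propensity_sd = 1
    )
  )
}

#' Simulate a full structured experiment
#'
#' Emulates the layout of a targeted single-molecule methylation study:
#' a panel of targets (see [simulate_panel()]), four conditions with four
#' biological replicates each, molecules drawn from epiallele subpopulations
#' with consecutive methylation runs and a footprint-bearing class, and
#' conversion of unmethylated cytosines at better than 99% efficiency. Read
#' depth per target follows a Poisson law whose mean increases with the
#' logarithm of target GC content, emulating capture-yield dependence on
#' base composition. Reads (FASTA), truth tables and a pipeline config are
#' written under `dir`.
#'
#' @param dir Output directory.
#' @param seed Integer seed.
#' @param n_targets Panel size (default 108).
#' @param conditions Condition labels (default 4 conditions).
#' @param n_replicates Replicates per condition (default 4).
#' @param mean_reads Mean reads per target per library (default 20).
#' @param footprint_weights Named per-condition footprint-class weights.
#' @param p_cg Named per-condition background CG probabilities.
#' @param model A [conversion_model()].
#' @return List with `config` (YAML path), `panel`, and `truth` (data frame
#'   of molecule-level ground truth: molecule_id, target_id, sample,
#'   replicate, class_id).
#' @export
simulate_experiment <- function(dir, seed = 1L, n_targets = 108L,
                                conditions = paste0("cond", 1:4),
                                n_replicates = 4L, mean_reads = 20,
                                footprint_weights = NULL, p_cg = NULL,
                                model = conversion_model()) {
  if (is.null(footprint_weights))
    footprint_weights <- stats::setNames(
      seq(0.1, 0.4, length.out = length(conditions)), conditions)
  if (is.null(p_cg))
    p_cg <- stats::setNames(
      seq(0.35, 0.6, length.out = length(conditions)), conditions)
  panel <- simulate_panel(dir, n_targets = n_targets, seed = seed)
  targets <- panel$targets
  analysis <- targets[!targets$is_control, ]
  ctrl <- targets[targets$is_control, ][1, ]
  ctrl_class <- list(epiallele_class("unmeth", 1,
                                     p_meth = c(CG = 0, CHG = 0, CHH = 0)))

  # depth ~ Poisson with mean increasing in ln(GC), emulating capture yield
  set.seed(seed)
  depth_mu <- pmax(1, mean_reads * (1 + 0.6 * (log(analysis$gc_content) -
                                                 mean(log(analysis$gc_content)))))

  samples <- list()
  truth_rows <- list()
  k <- 0L
  for (cond in conditions) for (r in seq_len(n_replicates)) {
    k <- k + 1L
    rep_label <- paste0("rep", r)
    lib_seed <- seed + 1000L * k
    set.seed(lib_seed)
    depths <- stats::rpois(nrow(analysis), depth_mu)
    reads <- character(0)
    for (i in seq_len(nrow(analysis))) {
      if (depths[i] == 0L) next
      tg <- analysis[i, ]
      classes <- condition_classes(footprint_weights[[cond]], p_cg[[cond]])
      cg_first2 <- which(extract_sites(tg)$context == "CG")[1:2] - 1L
      classes[[2]]$footprint_mask <- cg_first2[!is.na(cg_first2)]
      tr <- simulate_molecules(tg, classes, depths[i], lib_seed + i)
      rr <- emit_reads(tr, tg, model, seed = lib_seed + i)
      names(rr) <- sprintf("%s_%s_%s_m%04d", cond, rep_label, tg$target_id,
                           seq_along(rr))
      truth_rows[[length(truth_rows) + 1L]] <- data.frame(
        molecule_id = names(rr), target_id = tg$target_id, sample = cond,
        replicate = rep_label, class_id = tr$classes$class_id,
        stringsAsFactors = FALSE)
      reads <- c(reads, rr)
    }
    trc <- simulate_molecules(ctrl, ctrl_class, stats::rpois(1L, mean_reads),
                              lib_seed + 99991L)
    rc <- emit_reads(trc, ctrl, model, seed = lib_seed + 99992L)
    if (length(rc) > 0L)
      names(rc) <- sprintf("%s_%s_CTRL_m%04d", cond, rep_label, seq_along(rc))
    reads <- c(reads, rc)
    path <- file.path(dir, sprintf("reads_%s_%s.fa", cond, rep_label))
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(reads), path)
    samples[[k]] <- list(sample = cond, replicate = rep_label, reads = path)
  }

  cfg <- list(reference = panel$reference, targets = panel$table,
              samples = samples, seed = seed)
  cfg_path <- file.path(dir, "experiment_config.yaml")
  yaml::write_yaml(cfg, cfg_path)
  list(config = cfg_path, panel = panel,
       truth = do.call(rbind, truth_rows))
}
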