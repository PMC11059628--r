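#' Define an epiallele class for simulation
#'
#' An epiallele class describes one subpopulation of molecules at a locus:
#' its mixture weight, the per-context stationary methylation probabilities,
#' a per-context run-coupling (persistence) parameter that induces
#' consecutive methylation runs along the molecule, an optional footprint
#' mask of sites forced unmethylated, and a molecule-level propensity scale
#' that couples methylation across contexts within the same molecule.
#'
#' @param class_id Class label.
#' @param weight Mixture proportion in `[0, 1]`; weights across a scenario
#'   must sum to 1.
#' @param p_meth Named numeric vector `c(CG=, CHG=, CHH=)` of stationary
#'   methylation probabilities in `[0, 1]`.
#' @param persistence Named numeric vector `c(CG=, CHG=, CHH=)` of run
#'   coupling parameters rho in `[0, 1)`. With rho = 0 sites are independent;
#'   larger rho lengthens runs of identical state at the same stationary
#'   probability.
#' @param footprint_mask Integer vector of 0-based site indices (into the
#'   target's full site list) forced to the unmethylated state after the
#'   chain is drawn.
#' @param propensity_sd Standard deviation (logit scale) of the molecule
#'   level propensity shared across contexts; 0 disables coupling.
#' @return An object of class `epiallele_class`.
#' @export
epiallele_class <- function(class_id, weight,
                            p_meth = c(CG = 0.5, CHG = 0.2, CHH = 0.05),
                            persistence = c(CG = 0, CHG = 0, CHH = 0),
                            footprint_mask = integer(0),
                            propensity_sd = 0) {
  p_meth <- p_meth[c("CG", "CHG", "CHH")]
  persistence <- persistence[c("CG", "CHG", "CHH")]
  stopifnot(
    is.character(class_id), length(class_id) == 1L,
    weight >= 0, weight <= 1,
    !anyNA(p_meth), all(p_meth >= 0 & p_meth <= 1),
    !anyNA(persistence), all(persistence >= 0 & persistence < 1),
    propensity_sd >= 0
  )
  structure(
    list(class_id = class_id, weight = weight, p_meth = p_meth,
         persistence = persistence,
         footprint_mask = as.integer(footprint_mask),
         propensity_sd = propensity_sd),
    class = "epiallele_class"
  )
}

#' Simulate per-molecule methylation states for an epiallele mixture
#'
#' Each molecule first draws a class according to the mixture weights, then a
#' molecule-level propensity `z ~ Normal(0, propensity_sd)` shared across all
#' three contexts. Within each context, site states follow a two-state Markov
#' chain along site order with stationary probability
#' `plogis(qlogis(p_meth) + z)` and transition probabilities
#' `p(1 -> 1) = p + rho (1 - p)` and `p(0 -> 1) = p (1 - rho)`, which leave
#' the stationary probability unchanged while rho tunes run lengths. Sites in
#' the class's footprint mask are then forced unmethylated. The simulation is
#' deterministic given `seed`.
#'
#' @param target A single target row (see [load_targets()]) or a character
#'   sequence.
#' @param classes List of [epiallele_class()] objects; weights must sum to 1.
#' @param n Number of molecules (>= 0).
#' @param seed Integer RNG seed.
#' @return An object of class `epiallele_truth`: list with `states`
#'   (n x n_sites integer matrix, rownames = molecule ids), `classes`
#'   (data frame `molecule_id`, `class_id`), `sites` (the site catalog) and
#'   `target_id`.
#' @export
simulate_molecules <- function(target, classes, n, seed) {
  if (inherits(classes, "epiallele_class")) classes <- list(classes)
  stopifnot(length(classes) >= 1L,
            all(vapply(classes, inherits, TRUE, "epiallele_class")))
  if (n < 0) stop("n must be >= 0")
  w <- vapply(classes, `[[`, 0, "weight")
  if (abs(sum(w) - 1) > 1e-9) stop("class weights must sum to 1")
  sites <- extract_sites(target)
  tid <- sites$target_id[1]
  if (is.null(tid) || nrow(sites) == 0L) tid <- if (is.character(target)) "seq" else target$target_id
  nsite <- nrow(sites)

  set.seed(seed)
  class_idx <- if (n > 0)
    sample.int(length(classes), n, replace = TRUE, prob = w) else integer(0)
  z <- stats::rnorm(n, 0,
                    vapply(classes, `[[`, 0, "propensity_sd")[class_idx])

  states <- matrix(0L, nrow = n, ncol = nsite)
  for (ctx in c("CG", "CHG", "CHH")) {
    idx <- which(sites$context == ctx)
    if (length(idx) == 0L || n == 0L) next
    p0 <- vapply(classes, function(cl) cl$p_meth[[ctx]], 0)[class_idx]
    rho <- vapply(classes, function(cl) cl$persistence[[ctx]], 0)[class_idx]
    # molecule-level stationary probability on the logit scale
    p <- stats::plogis(stats::qlogis(p0) + z)
    p[p0 == 0] <- 0  # qlogis(0/1) are infinite; keep degenerate classes exact
    p[p0 == 1] <- 1
    prev <- stats::rbinom(n, 1L, p)
    states[, idx[1]] <- prev
    for (k in seq_along(idx)[-1]) {
      ptrans <- ifelse(prev == 1L, p + rho * (1 - p), p * (1 - rho))
      prev <- stats::rbinom(n, 1L, ptrans)
      states[, idx[k]] <- prev
    }
  }
  for (ci in seq_along(classes)) {
    mask <- classes[[ci]]$footprint_mask
    if (length(mask) > 0L) {
      if (any(mask < 0L | mask >= nsite))
        stop("footprint_mask index outside the target's site list")
      states[class_idx == ci, mask + 1L] <- 0L
    }
  }
  mol_ids <- sprintf("%s:mol%05d", tid, seq_len(n))
  rownames(states) <- mol_ids
  structure(
    list(states = states,
         classes = data.frame(
           molecule_id = mol_ids,
           class_id = vapply(classes, `[[`, "", "class_id")[class_idx],
           stringsAsFactors = FALSE),
         sites = sites, target_id = tid),
    class = "epiallele_truth"
  )
}

#' Define a conversion/read-out model
#'
#' Enzymatic conversion reads an unmethylated C as T with probability
#' `conv_eff` and retains a methylated C as C with probability
#' `meth_retention`; with probability `miss_rate` a site is emitted as N and
#' becomes a missing call downstream. Defaults reflect a well-behaved EM-seq
#' library: conversion above 99%, near-complete 5mC retention and a small
#' per-site dropout that leaves most ~600 nt molecules full length.
#'
#' @param conv_eff Probability an unmethylated C is read as T.
#' @param meth_retention Probability a methylated C is read as C.
#' @param miss_rate Probability a site is unreadable.
#' @return An object of class `conversion_model`.
#' @export
conversion_model <- function(conv_eff = 0.995, meth_retention = 0.995,
                             miss_rate = 5e-4) {
  stopifnot(conv_eff >= 0, conv_eff <= 1,
            meth_retention >= 0, meth_retention <= 1,
            miss_rate >= 0, miss_rate <= 1)
  structure(list(conv_eff = conv_eff, meth_retention = meth_retention,
                 miss_rate = miss_rate),
            class = "conversion_model")
}

#' Emit converted reads from simulated molecules
#'
#' Each molecule becomes one read: the target sequence with every cytosine
#' site rewritten according to its simulated state and the conversion model
#' (methylated -> C with probability `meth_retention`, else T; unmethylated
#' -> T with probability `conv_eff`, else C; with probability `miss_rate` the
#' base is N). Non-site positions are copied verbatim. Read names equal the
#' molecule ids, so truth can be joined back by id.
#'
#' @param truth An `epiallele_truth` from [simulate_molecules()].
#' @param target The same target the molecules were simulated from.
#' @param model A [conversion_model()].
#' @param seed Integer RNG seed.
#' @return A named character vector of reads (one per molecule).
#' @export
emit_reads <- function(truth, target, model = conversion_model(), seed = 1L) {
  stopifnot(inherits(truth, "epiallele_truth"),
            inherits(model, "conversion_model"))
  seq <- toupper(if (is.character(target)) target else target$sequence)
  sites <- truth$sites
  n <- nrow(truth$states)
  chars <- strsplit(seq, "")[[1]]
  set.seed(seed)
  reads <- character(n)
  off1 <- sites$offset + 1L
  for (i in seq_len(n)) {
    s <- truth$states[i, ]
    base <- ifelse(
      s == 1L,
      ifelse(stats::runif(length(s)) < model$meth_retention, "C", "T"),
      ifelse(stats::runif(length(s)) < model$conv_eff, "T", "C")
    )
    miss <- stats::runif(length(s)) < model$miss_rate
    base[miss] <- "N"
    rc <- chars
    rc[off1] <- base
    reads[i] <- paste(rc, collapse = "")
  }
  names(reads) <- rownames(truth$states)
  reads
}

#' Build molecule calls directly from simulator ground truth
#'
#' Constructs the `molecule_calls` object a perfect read-out of the
#' simulated molecules would produce (every state observed, no conversion
#' error). Convenient for exercising the statistical layers on many
#' simulated replicates without emitting and re-aligning reads; the full
#' simulate -> emit -> call path is equivalent under a noise-free
#' conversion model.
#'
#' @param truth An `epiallele_truth` from [simulate_molecules()].
#' @param sample,replicate Labels attached to the calls.
#' @return A `molecule_calls` object (all reads full length).
#' @export
calls_from_truth <- function(truth, sample = "sample", replicate = "rep1") {
  stopifnot(inherits(truth, "epiallele_truth"))
  calls <- truth$states
  mode(calls) <- "integer"
  meta <- data.frame(
    read_id = rownames(calls),
    sample = rep(sample, nrow(calls)),
    replicate = rep(replicate, nrow(calls)),
    full_length = rep(TRUE, nrow(calls)),
    stringsAsFactors = FALSE
  )
  new_molecule_calls(calls, meta, truth$sites, truth$target_id)
}

#' Write simulated reads as FASTA and truth as TSV
#'
#' @param reads Named character vector from [emit_reads()].
#' @param truth The matching `epiallele_truth`.
#' @param fasta Output FASTA path.
#' @param truth_tsv Output truth table path (molecule_id, class_id, states as
#'   a compact 0/1 string).
#' @export
write_simulated <- function(reads, truth, fasta, truth_tsv) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(reads), fasta)
  df <- truth$classes
  df$states <- apply(truth$states, 1L, paste, collapse = "")
  utils::write.table(df, truth_tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(fasta = fasta, truth = truth_tsv))
}
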