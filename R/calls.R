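#' Read converted reads from FASTA/FASTQ
#'
#' @param path Path to a FASTA or FASTQ file (extension decides the format).
#' @return Named character vector of read sequences.
#' @export
read_reads <- function(path) {
  if (!file.exists(path)) stop("read file not found: ", path)
  fmt <- if (grepl("\\.f(ast)?q(\\.gz)?$", path, ignore.case = TRUE))
    "fastq" else "fasta"
  x <- Biostrings::readDNAStringSet(path, format = fmt)
  out <- toupper(as.character(x))
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

# C/T-collapsed alphabet: conversion state cannot break matching
collapse_ct <- function(x) chartr("C", "T", x)

hamming <- function(a, b) {
  sum(charToRaw(a) != charToRaw(b))
}

#' Assign reads to capture targets by conversion-independent anchors
#'
#' Each read is compared with the 5' and 3' terminal anchors of every target
#' after collapsing C to T on both sides, so that enzymatic conversion cannot
#' break the match. A read is assigned to the target whose best anchor it
#' matches with the fewest mismatches; reads failing both anchors of every
#' target at more than `max_mismatch` mismatches are off-target.
#'
#' @param reads Named character vector of read sequences.
#' @param targets `fengc_targets` from [load_targets()].
#' @param anchor_len Anchor length in nt (default 30).
#' @param max_mismatch Maximum mismatches allowed in the better anchor
#'   (default 5).
#' @return Data frame `read_id`, `target_id` (NA when off-target),
#'   `anchor_mismatches`.
#' @export
assign_reads <- function(reads, targets, anchor_len = 30L, max_mismatch = 5L) {
  if (nrow(targets) == 0L) stop("no targets loaded")
  stopifnot(length(reads) >= 0L)
  pre <- substr(collapse_ct(targets$sequence), 1L, anchor_len)
  suf_start <- pmax(nchar(targets$sequence) - anchor_len + 1L, 1L)
  suf <- substr(collapse_ct(targets$sequence), suf_start, nchar(targets$sequence))

  n <- length(reads)
  tid <- rep(NA_character_, n)
  mm <- rep(NA_integer_, n)
  creads <- collapse_ct(reads)
  # anchors as byte matrices so each read compares against all targets at once
  full <- nchar(pre) == anchor_len & nchar(suf) == anchor_len
  pre_m <- vapply(pre, function(x)
    if (nchar(x) == anchor_len) as.integer(charToRaw(x))
    else rep(-1L, anchor_len), integer(anchor_len))
  suf_m <- vapply(suf, function(x)
    if (nchar(x) == anchor_len) as.integer(charToRaw(x))
    else rep(-1L, anchor_len), integer(anchor_len))
  for (i in seq_len(n)) {
    r <- creads[i]
    nr <- nchar(r)
    if (nr < anchor_len) next
    rp <- as.integer(charToRaw(substr(r, 1L, anchor_len)))
    rs <- as.integer(charToRaw(substr(r, nr - anchor_len + 1L, nr)))
    d <- pmin(colSums(pre_m != rp), colSums(suf_m != rs))
    d[!full] <- NA_integer_
    j <- which.min(d)
    if (length(j) == 1L && !is.na(d[j]) && d[j] <= max_mismatch) {
      tid[i] <- targets$target_id[j]
      mm[i] <- as.integer(d[j])
    }
  }
  data.frame(read_id = names(reads), target_id = tid,
             anchor_mismatches = mm, stringsAsFactors = FALSE)
}

# Conversion-aware global alignment of one read against a target sequence.
# Returns the read base over each reference position (NA over deletions).
# Fast path: equal-length reads (no indels in amplicon reads) map 1:1.
align_read_bases <- function(read, refseq) {
  if (nchar(read) == nchar(refseq))
    return(strsplit(read, "")[[1]])
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2,
                                                  baseOnly = FALSE)
  # T over reference C at full match score: conversion is not a mismatch
  mat["T", "C"] <- 1
  mat["C", "T"] <- 1
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(read), Biostrings::DNAString(refseq),
    substitutionMatrix = mat, gapOpening = 5, gapExtension = 2,
    type = "global"
  )
  p <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  out <- rep(NA_character_, nchar(refseq))
  spos <- 0L
  for (k in seq_along(s)) {
    if (s[k] != "-") {
      spos <- spos + 1L
      if (p[k] != "-") out[spos] <- p[k]
    }
  }
  out
}

#' Call per-molecule methylation states over a target's cytosine sites
#'
#' Aligns each assigned read to the target with a conversion-aware scoring
#' (T over reference C at no penalty) and converts the base over every
#' cytosine site into a ternary call: C means methylated (1), T means
#' converted unmethylated (0), anything else (A/G/N/gap/uncovered) is
#' missing. A read is full length when no call is missing. Reads with gaps
#' or unreadable bases at more than `max_gap_frac` of sites are discarded as
#' low quality.
#'
#' @param reads Named character vector of reads assigned to this target.
#' @param target Single target row.
#' @param sites Optional site catalog (computed from `target` if omitted).
#' @param sample Condition label for these reads.
#' @param replicate Replicate label.
#' @param max_gap_frac Discard reads with more than this fraction of sites
#'   missing (default 0.2).
#' @return An object of class `molecule_calls`: list with `calls` (reads x
#'   sites integer matrix, 1 methylated / 0 unmethylated / NA missing),
#'   `meta` (data frame `read_id`, `sample`, `replicate`, `full_length`),
#'   `sites` and `target_id`.
#' @export
call_molecules <- function(reads, target, sites = NULL,
                           sample = "sample", replicate = "rep1",
                           max_gap_frac = 0.2) {
  if (is.null(sites)) sites <- extract_sites(target)
  refseq <- toupper(if (is.character(target)) target else target$sequence)
  tid <- sites$target_id[1]
  n <- length(reads)
  calls <- matrix(NA_integer_, nrow = n, ncol = nrow(sites))
  off1 <- sites$offset + 1L
  for (i in seq_len(n)) {
    bases <- align_read_bases(toupper(reads[[i]]), refseq)[off1]
    v <- rep(NA_integer_, length(bases))
    v[bases == "C"] <- 1L
    v[bases == "T"] <- 0L
    calls[i, ] <- v
  }
  rownames(calls) <- names(reads)
  keep <- rowMeans(is.na(calls)) <= max_gap_frac | nrow(sites) == 0L
  if (any(!keep))
    message(sprintf("%s: discarded %d low-quality read(s) (> %.0f%% of sites missing)",
                    tid, sum(!keep), 100 * max_gap_frac))
  calls <- calls[keep, , drop = FALSE]
  meta <- data.frame(
    read_id = rownames(calls),
    sample = rep(sample, nrow(calls)),
    replicate = rep(replicate, nrow(calls)),
    full_length = !apply(is.na(calls), 1L, any),
    stringsAsFactors = FALSE
  )
  new_molecule_calls(calls, meta, sites, tid)
}

new_molecule_calls <- function(calls, meta, sites, target_id) {
  structure(list(calls = calls, meta = meta, sites = sites,
                 target_id = target_id),
            class = "molecule_calls")
}

#' @export
print.molecule_calls <- function(x, ...) {
  cat(sprintf("molecule_calls: %d read(s) x %d site(s) on %s\n",
              nrow(x$calls), ncol(x$calls), x$target_id))
  cat(sprintf("  full length: %d; samples: %s\n",
              sum(x$meta$full_length),
              paste(unique(x$meta$sample), collapse = ", ")))
  invisible(x)
}

#' Subset molecule calls by read
#'
#' @param mc A `molecule_calls` object.
#' @param which Logical/integer/character index over reads.
#' @return The subsetted `molecule_calls`.
#' @export
subset_calls <- function(mc, which) {
  if (is.character(which)) which <- match(which, mc$meta$read_id)
  new_molecule_calls(mc$calls[which, , drop = FALSE],
                     mc$meta[which, , drop = FALSE], mc$sites, mc$target_id)
}

#' Combine molecule-call sets on the same target
#'
#' @param ... `molecule_calls` objects sharing one target.
#' @return A single pooled `molecule_calls`.
#' @export
combine_calls <- function(...) {
  xs <- list(...)
  if (length(xs) == 1L && is.list(xs[[1]]) && !inherits(xs[[1]], "molecule_calls"))
    xs <- xs[[1]]
  stopifnot(length(xs) >= 1L)
  tids <- unique(vapply(xs, `[[`, "", "target_id"))
  if (length(tids) != 1L) stop("cannot combine calls across targets")
  new_molecule_calls(do.call(rbind, lapply(xs, `[[`, "calls")),
                     do.call(rbind, lapply(xs, `[[`, "meta")),
                     xs[[1]]$sites, tids)
}

# Maximum run of methylated calls over the CHH subsequence; NA breaks runs.
max_meth_run <- function(v) {
  if (length(v) == 0L) return(0L)
  r <- rle(ifelse(is.na(v), -1L, v))
  runs <- r$lengths[r$values == 1L]
  if (length(runs) == 0L) 0L else max(runs)
}

#' Filter reads with long consecutive methylated CHH runs
#'
#' Removes reads with more than `max_run` consecutively methylated CHH sites
#' (run length >= `max_run` + 1 over the CHH subsequence in site order), the
#' standard guard against enzymatic-conversion failures along a molecule.
#' Consecutive means adjacent in the CHH subsequence; a missing call breaks
#' a run, so a read is never dropped on unobserved evidence.
#'
#' @param mc A `molecule_calls` object.
#' @param max_run Longest allowed methylated CHH run (default 3).
#' @return The filtered `molecule_calls`, with attribute `n_dropped`.
#' @export
filter_chh_runs <- function(mc, max_run = 3L) {
  chh <- which(mc$sites$context == "CHH")
  keep <- vapply(seq_len(nrow(mc$calls)), function(i) {
    max_meth_run(mc$calls[i, chh]) <= max_run
  }, TRUE)
  out <- subset_calls(mc, keep)
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Estimate the C-to-T conversion rate from the internal control
#'
#' Pools every informative call (all reads, all three contexts) in the
#' control region and returns the fraction called unmethylated: on a control
#' with essentially no 5mC every cytosine should convert, so this fraction
#' estimates conversion efficiency.
#'
#' @param mc `molecule_calls` on the internal-control target.
#' @return Fraction in `[0, 1]`, or `NA` when there is no informative call.
#' @export
conversion_rate <- function(mc) {
  v <- mc$calls
  informative <- sum(!is.na(v))
  if (informative == 0L) return(NA_real_)
  sum(v == 0L, na.rm = TRUE) / informative
}

#' Summarize assay QC: on-target fractions, coverage and target detection
#'
#' @param assignments Data frame with one row per sequenced read:
#'   `read_id`, `sample`, `replicate`, `target_id` (NA when off-target) and
#'   `kept` (logical, survived filtering).
#' @param targets `fengc_targets`.
#' @param min_reads Detection threshold on pooled filtered reads
#'   (default 10). Replicates are pooled within sample before applying it.
#' @param control_rate Optional conversion rate to carry into the summary.
#' @return A list of class `qc_summary`: `per_sample` (total, on-target,
#'   fraction), `per_target` (per sample x target pre/post-filter counts and
#'   `log2_reads_p1 = log2(post-filter reads + 1)`), `detection` (per sample:
#'   percent of targets with >= 1 and >= `min_reads` pooled filtered reads,
#'   median and mean coverage) and `conversion_rate`.
#' @export
coverage_summary <- function(assignments, targets, min_reads = 10L,
                             control_rate = NA_real_) {
  a <- assignments
  stopifnot(all(c("read_id", "sample", "replicate", "target_id", "kept")
                %in% names(a)))
  samples <- unique(a$sample)
  if (length(samples) == 0L) {
    empty <- function(...) data.frame(..., stringsAsFactors = FALSE)[0, ]
    return(structure(list(
      per_sample = empty(sample = "", total_reads = 0L, on_target = 0L,
                         on_target_fraction = 0),
      per_target = empty(sample = "", target_id = "", reads_prefilter = 0L,
                         reads_postfilter = 0L, log2_reads_p1 = 0),
      detection = empty(sample = "", pct_targets_ge1 = 0,
                        pct_targets_ge_min = 0, median_coverage = 0,
                        mean_coverage = 0),
      min_reads = min_reads, conversion_rate = control_rate),
      class = "qc_summary"))
  }
  per_sample <- do.call(rbind, lapply(samples, function(s) {
    x <- a[a$sample == s, ]
    data.frame(sample = s, total_reads = nrow(x),
               on_target = sum(!is.na(x$target_id)),
               on_target_fraction =
                 if (nrow(x) == 0L) 0 else sum(!is.na(x$target_id)) / nrow(x),
               stringsAsFactors = FALSE)
  }))

  grid <- expand.grid(sample = samples, target_id = targets$target_id,
                      stringsAsFactors = FALSE)
  per_target <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    x <- a[a$sample == grid$sample[i] &
             !is.na(a$target_id) & a$target_id == grid$target_id[i], ]
    post <- sum(x$kept)
    data.frame(sample = grid$sample[i], target_id = grid$target_id[i],
               reads_prefilter = nrow(x), reads_postfilter = post,
               log2_reads_p1 = log2(post + 1), stringsAsFactors = FALSE)
  }))

  detection <- do.call(rbind, lapply(samples, function(s) {
    cnt <- per_target$reads_postfilter[per_target$sample == s]
    data.frame(sample = s,
               pct_targets_ge1 = 100 * mean(cnt >= 1L),
               pct_targets_ge_min = 100 * mean(cnt >= min_reads),
               median_coverage = stats::median(cnt),
               mean_coverage = mean(cnt),
               stringsAsFactors = FALSE)
  }))

  structure(list(per_sample = per_sample, per_target = per_target,
                 detection = detection, min_reads = min_reads,
                 conversion_rate = control_rate),
            class = "qc_summary")
}

#' @export
print.qc_summary <- function(x, ...) {
  cat("qc_summary\n")
  print(x$per_sample, row.names = FALSE)
  print(x$detection, row.names = FALSE)
  if (!is.na(x$conversion_rate))
    cat(sprintf("conversion rate (internal control): %.4f\n", x$conversion_rate))
  invisible(x)
}

#' Write the per-read call matrix as TSV
#'
#' One row per read, one column per site; values 0, 1 or `.` for missing.
#'
#' @param mc A `molecule_calls` object.
#' @param path Output path.
#' @export
write_call_matrix <- function(mc, path) {
  m <- mc$calls
  df <- as.data.frame(ifelse(is.na(m), ".", as.character(m)),
                      stringsAsFactors = FALSE)
  names(df) <- sprintf("site%03d_%s", mc$sites$index, mc$sites$context)
  df <- cbind(mc$meta[, c("read_id", "sample", "replicate", "full_length")], df)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
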