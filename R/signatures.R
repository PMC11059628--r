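#' Maximal runs over a context subsequence of one molecule
#'
#' Run-length encodes a read's calls over the sites of one context, taken in
#' site order. Missing is its own state and breaks runs of either call.
#'
#' @param calls Integer call vector (1/0/NA) over the context subsequence,
#'   or a `molecule_calls` plus `read_id`/`context` to extract one.
#' @param context,read_id When `calls` is a `molecule_calls`: which read and
#'   context to encode.
#' @return Data frame `state` (1, 0 or NA for missing), `start` (0-based
#'   index into the context subsequence) and `length`; maximal runs in
#'   order. Empty input gives zero rows.
#' @examples
#' methylation_runs(c(1L, 1L, 0L, 0L, 1L))
#' @export
methylation_runs <- function(calls, context = NULL, read_id = NULL) {
  if (inherits(calls, "molecule_calls")) {
    stopifnot(!is.null(context), !is.null(read_id))
    idx <- which(calls$sites$context == context)
    calls <- calls$calls[match(read_id, calls$meta$read_id), idx]
  }
  if (length(calls) == 0L)
    return(data.frame(state = integer(0), start = integer(0),
                      length = integer(0)))
  coded <- ifelse(is.na(calls), 2L, calls)
  r <- rle(coded)
  starts <- cumsum(c(0L, r$lengths[-length(r$lengths)]))
  state <- as.integer(r$values)
  state[state == 2L] <- NA_integer_
  data.frame(state = state, start = starts, length = r$lengths)
}

#' Define a methylation footprint / run signature
#'
#' Two signature types cover the single-molecule patterns of interest:
#' * `"set"` — an explicit ordered set of context-subsequence site indices
#'   that must all carry `state` (e.g. "the first 2 CG sites both
#'   unmethylated").
#' * `"run"` — at least `min_run` consecutive sites of `state` inside each
#'   given window of the context subsequence (e.g. "at least 6 consecutively
#'   methylated CG sites"); several windows mean the run must occur in every
#'   window (conjunction), as for signatures flanking both sides of a
#'   cis-element.
#'
#' Indices and windows are 0-based positions in the context subsequence
#' (site order), not nucleotide offsets.
#'
#' @param spec_id Signature label.
#' @param target_id Target the signature applies to.
#' @param context Context subsequence (`"CG"`, `"CHG"`, `"CHH"`).
#' @param type `"set"` or `"run"`.
#' @param sites Integer site indices (for `"set"`).
#' @param state `"unmethylated"` or `"methylated"`.
#' @param windows For `"run"`: list of `c(start, end)` windows (0-based,
#'   inclusive), or NULL for the whole subsequence.
#' @param min_run For `"run"`: minimum consecutive length.
#' @return An object of class `footprint_spec`.
#' @export
footprint_spec <- function(spec_id, target_id, context,
                           type = c("set", "run"), sites = NULL,
                           state = c("unmethylated", "methylated"),
                           windows = NULL, min_run = NULL) {
  type <- match.arg(type)
  state <- match.arg(state)
  if (type == "set") {
    if (is.null(sites) || length(sites) == 0L)
      stop("'set' spec needs non-empty site indices")
    sites <- as.integer(sites)
    if (any(sites < 0L)) stop("site indices must be >= 0")
  } else {
    if (is.null(min_run) || min_run < 1L) stop("'run' spec needs min_run >= 1")
    if (!is.null(windows)) {
      if (!is.list(windows)) windows <- list(windows)
      ok <- vapply(windows, function(w)
        length(w) == 2L && w[1] >= 0 && w[1] <= w[2], TRUE)
      if (!all(ok)) stop("each window must be c(start, end) with 0 <= start <= end")
      windows <- lapply(windows, as.integer)
    }
  }
  structure(list(spec_id = spec_id, target_id = target_id, context = context,
                 type = type, sites = sites, state = state,
                 windows = windows,
                 min_run = if (is.null(min_run)) NULL else as.integer(min_run)),
            class = "footprint_spec")
}

#' Read footprint signatures from a TSV spec file
#'
#' Columns: `spec_id`, `target_id`, `context`, `type` (`set`/`run`),
#' `state`, `sites` (comma-separated indices, `.` for run specs), `windows`
#' (`start-end` pairs separated by `;`, `.` for whole subsequence or set
#' specs) and `min_run` (`.` for set specs). Indices are validated against
#' the targets' context subsequences; out-of-range indices are fatal.
#'
#' @param path Spec file path.
#' @param targets Optional `fengc_targets` for index validation.
#' @return List of `footprint_spec` objects.
#' @export
read_footprint_specs <- function(path, targets = NULL) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  specs <- lapply(seq_len(nrow(tab)), function(i) {
    row <- tab[i, ]
    sites <- if (row$sites %in% c(".", ""))
      NULL else as.integer(strsplit(row$sites, ",")[[1]])
    windows <- if (row$windows %in% c(".", "")) NULL else
      lapply(strsplit(row$windows, ";")[[1]], function(w)
        as.integer(strsplit(w, "-")[[1]]))
    min_run <- if (row$min_run %in% c(".", ""))
      NULL else as.integer(row$min_run)
    footprint_spec(row$spec_id, row$target_id, row$context, row$type,
                   sites = sites, state = row$state, windows = windows,
                   min_run = min_run)
  })
  if (!is.null(targets)) {
    for (sp in specs) {
      tg <- get_target(targets, sp$target_id)
      nctx <- sum(extract_sites(tg)$context == sp$context)
      hi <- c(sp$sites, unlist(sp$windows))
      if (length(hi) > 0L && any(hi >= nctx))
        stop(sprintf("spec '%s': index beyond the %d %s site(s) of %s",
                     sp$spec_id, nctx, sp$context, sp$target_id))
    }
  }
  specs
}

# Does one context-subsequence call vector carry the signature?
match_one <- function(v, spec) {
  want <- if (spec$state == "methylated") 1L else 0L
  if (spec$type == "set") {
    if (any(spec$sites >= length(v))) stop("spec site index out of range")
    x <- v[spec$sites + 1L]
    return(!anyNA(x) && all(x == want))
  }
  wins <- spec$windows
  if (is.null(wins)) wins <- list(c(0L, length(v) - 1L))
  all(vapply(wins, function(w) {
    sub <- v[(w[1] + 1L):min(w[2] + 1L, length(v))]
    r <- methylation_runs(sub)
    any(!is.na(r$state) & r$state == want & r$length >= spec$min_run)
  }, TRUE))
}

#' Match a footprint signature against molecules
#'
#' A read matches when every site the spec names is observed and carries the
#' spec state ("set"), or when each window of the context subsequence holds a
#' run of the spec state of at least `min_run` consecutive sites ("run").
#' Missing calls never count toward a match.
#'
#' @param mc A `molecule_calls` object on the spec's target.
#' @param spec A [footprint_spec()].
#' @return Logical vector, one element per read (named by read id).
#' @export
match_footprint <- function(mc, spec) {
  idx <- which(mc$sites$context == spec$context)
  out <- vapply(seq_len(nrow(mc$calls)), function(i)
    match_one(mc$calls[i, idx], spec), TRUE)
  names(out) <- mc$meta$read_id
  out
}

#' Signature prevalence, optionally per replicate with cross-condition tests
#'
#' The fraction of filtered, full-length reads carrying a signature. With
#' `by_replicate = TRUE`, per-replicate fractions are computed and compared
#' across conditions by one-way ANOVA with post-hoc Tukey HSD, the
#' replicate-level layer used for signature percentages.
#'
#' @param mc A `molecule_calls` object.
#' @param spec A [footprint_spec()].
#' @param by_replicate Compute per condition x replicate and test
#'   (default FALSE: per condition, replicates pooled).
#' @return For pooled mode a data frame `spec_id`, `sample`, `n_reads`,
#'   `n_matching`, `fraction`; with `by_replicate` a list
#'   `per_replicate` (adds `replicate`), `anova`, `tukey`.
#' @export
prevalence <- function(mc, spec, by_replicate = FALSE) {
  fl <- subset_calls(mc, mc$meta$full_length)
  if (nrow(fl$calls) == 0L) {
    warning("prevalence: no full-length reads")
    return(data.frame(spec_id = spec$spec_id, sample = NA_character_,
                      n_reads = 0L, n_matching = 0L, fraction = NA_real_))
  }
  hits <- match_footprint(fl, spec)
  key <- if (by_replicate) c("sample", "replicate") else "sample"
  groups <- unique(fl$meta[, key, drop = FALSE])
  res <- do.call(rbind, lapply(seq_len(nrow(groups)), function(i) {
    sel <- rep(TRUE, nrow(fl$meta))
    for (k in key) sel <- sel & fl$meta[[k]] == groups[[k]][i]
    cbind(data.frame(spec_id = spec$spec_id, stringsAsFactors = FALSE),
          groups[i, , drop = FALSE],
          data.frame(n_reads = sum(sel), n_matching = sum(hits[sel]),
                     fraction = mean(hits[sel])))
  }))
  rownames(res) <- NULL
  if (!by_replicate) return(res)
  nrep <- table(res$sample)
  tests <- if (length(nrep) >= 2L && all(nrep >= 2L))
    group_tests(res$fraction, res$sample, res) else {
      warning("prevalence: need >= 2 conditions with >= 2 replicates for tests")
      NULL
    }
  list(per_replicate = res,
       anova = if (is.null(tests)) NULL else tests$anova,
       tukey = if (is.null(tests)) NULL else tests$tukey)
}

#' Compare mPPM between footprint-matching reads and all reads
#'
#' Computes the per-molecule methylation proportion of `context` (optionally
#' restricted to a window of that context's subsequence) in the stratum of
#' full-length reads matching `spec` and in all full-length reads, and
#' compares the two distributions with the Kruskal-Wallis DmPPM test.
#'
#' @param mc A `molecule_calls` object.
#' @param spec A [footprint_spec()] defining the stratum.
#' @param context Context whose mPPM is compared (e.g. CHG/CHH conditioned
#'   on a CG footprint).
#' @param window Optional `c(start, end)` (0-based, inclusive) restricting
#'   mPPM to part of the context subsequence (the "footprint area").
#' @return List `matching` and `all` (numeric mPPM vectors) plus `test`
#'   (the [dmppm_test()] row), or `NA` fields with a warning when a stratum
#'   has fewer than 2 reads.
#' @export
conditional_mppm <- function(mc, spec, context, window = NULL) {
  fl <- subset_calls(mc, mc$meta$full_length)
  idx <- which(fl$sites$context == context)
  if (!is.null(window)) idx <- idx[(window[1] + 1L):(window[2] + 1L)]
  if (length(idx) == 0L) stop("no sites of context ", context)
  vals <- rowMeans(fl$calls[, idx, drop = FALSE] == 1L)
  hits <- match_footprint(fl, spec)
  if (sum(hits) < 2L || length(vals) < 2L) {
    warning("conditional_mppm: a stratum has < 2 reads; returning NA")
    return(list(matching = vals[hits], all = vals, test = NA))
  }
  list(matching = vals[hits], all = vals,
       test = dmppm_test(vals[hits], vals))
}
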