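#' Load capture targets from a reference FASTA and a target table
#'
#' Reads a tab-separated target definition table and extracts the captured
#' strand sequence of every target from the reference. Coordinates in the
#' table are 0-based half-open (BED convention). When `strand` is `"-"` the
#' extracted sequence is reverse-complemented so that the stored sequence is
#' always the captured coding strand read 5' to 3'.
#'
#' The table must have a header with columns `target_id`, `gene_id`, `chrom`,
#' `start`, `end`, `strand`, `is_control` and `elements`. `elements` holds
#' cis-element annotations as `label:start-end` pairs separated by `;`,
#' in target-local 1-based inclusive nucleotide coordinates (empty or `.`
#' for none). `is_control` flags the internal conversion control region.
#'
#' @param fasta Path to the reference FASTA.
#' @param table Path to the tab-separated target table.
#' @return A data frame of class `fengc_targets` with one row per target:
#'   `target_id`, `gene_id`, `chrom`, `start`, `end`, `strand`, `sequence`
#'   (captured strand), `gc_content`, `is_control`, and a list column
#'   `elements` of per-target annotation data frames (`label`, `start`,
#'   `end`).
#' @examples
#' ref <- tempfile(fileext = ".fa")
#' writeLines(c(">chr1", "ACGTACGTAC"), ref)
#' tab <- tempfile(fileext = ".tsv")
#' writeLines(c(
#'   "target_id\tgene_id\tchrom\tstart\tend\tstrand\tis_control\telements",
#'   "t1\tg1\tchr1\t0\t8\t+\tFALSE\t."
#' ), tab)
#' load_targets(ref, tab)
#' @export
load_targets <- function(fasta, table) {
  ref <- Biostrings::readDNAStringSet(fasta)
  names(ref) <- sub("\\s.*$", "", names(ref))
  tab <- utils::read.delim(table, stringsAsFactors = FALSE,
                           colClasses = "character")
  required <- c("target_id", "gene_id", "chrom", "start", "end", "strand",
                "is_control", "elements")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols) > 0L)
    stop("target table lacks column(s): ", paste(missing_cols, collapse = ", "))
  tab$start <- as.integer(tab$start)
  tab$end <- as.integer(tab$end)

  seqs <- character(nrow(tab))
  gc <- numeric(nrow(tab))
  elements <- vector("list", nrow(tab))
  for (i in seq_len(nrow(tab))) {
    row <- tab[i, ]
    if (!row$chrom %in% names(ref))
      stop(sprintf("row %d: chromosome '%s' not present in reference", i, row$chrom))
    if (is.na(row$start) || is.na(row$end) || row$start >= row$end)
      stop(sprintf("row %d: start must be < end (0-based half-open)", i))
    chromlen <- Biostrings::width(ref[row$chrom])
    if (row$start < 0L || row$end > chromlen)
      stop(sprintf("row %d: coordinates outside '%s' (length %d)", i, row$chrom, chromlen))
    s <- Biostrings::subseq(ref[[row$chrom]], start = row$start + 1L, end = row$end)
    if (!row$strand %in% c("+", "-"))
      stop(sprintf("row %d: strand must be '+' or '-'", i))
    if (identical(row$strand, "-"))
      s <- Biostrings::reverseComplement(s)
    sc <- toupper(as.character(s))
    if (grepl("[^ACGTN]", sc))
      stop(sprintf("row %d: target sequence contains non-ACGTN characters", i))
    seqs[i] <- sc
    gc[i] <- sum(strsplit(sc, "")[[1]] %in% c("G", "C")) / nchar(sc)
    elements[[i]] <- parse_elements(row$elements, nchar(sc), i)
  }

  out <- data.frame(
    target_id = tab$target_id,
    gene_id = tab$gene_id,
    chrom = tab$chrom,
    start = tab$start,
    end = tab$end,
    strand = tab$strand,
    sequence = seqs,
    gc_content = gc,
    is_control = tolower(tab$is_control) %in% c("true", "t", "1", "yes"),
    stringsAsFactors = FALSE
  )
  out$elements <- elements
  class(out) <- c("fengc_targets", "data.frame")
  out
}

parse_elements <- function(spec, target_len, rownum) {
  empty <- data.frame(label = character(0), start = integer(0), end = integer(0),
                      stringsAsFactors = FALSE)
  if (is.na(spec) || spec %in% c("", ".")) return(empty)
  parts <- strsplit(spec, ";", fixed = TRUE)[[1]]
  m <- regmatches(parts, regexec("^([^:]+):([0-9]+)-([0-9]+)$", parts))
  bad <- vapply(m, length, 1L) != 4L
  if (any(bad))
    stop(sprintf("row %d: malformed element annotation '%s'", rownum, parts[bad][1]))
  out <- data.frame(
    label = vapply(m, `[`, "", 2L),
    start = as.integer(vapply(m, `[`, "", 3L)),
    end = as.integer(vapply(m, `[`, "", 4L)),
    stringsAsFactors = FALSE
  )
  if (any(out$start < 1L | out$end > target_len | out$start > out$end))
    stop(sprintf("row %d: element coordinates outside target (1..%d)", rownum, target_len))
  out
}

#' Retrieve one target by id
#'
#' @param targets A `fengc_targets` data frame from [load_targets()].
#' @param target_id Target identifier.
#' @return The matching single-row target.
#' @export
get_target <- function(targets, target_id) {
  i <- match(target_id, targets$target_id)
  if (is.na(i)) stop("unknown target_id: ", target_id)
  targets[i, , drop = FALSE]
}

#' Enumerate cytosine sites and their context on the captured strand
#'
#' Scans the captured-strand sequence 5' to 3' and emits every cytosine whose
#' methylation context can be resolved inside the target. Context follows the
#' plant convention: `CG` when the next base is G, `CHG` when the pattern is
#' C-H-G and `CHH` when it is C-H-H, with H one of A, C or T. A `CG` call
#' needs only one downstream base; `CHG`/`CHH` need two, so a C at the final
#' position (or second-to-last position not followed by G) is dropped. A C
#' whose context window contains N is excluded with a warning.
#'
#' @param target A single target row from [load_targets()], or a plain
#'   character sequence (then `target_id` is `"seq"`).
#' @return A data frame of class `cytosine_sites` with columns `target_id`,
#'   `index` (0-based ordinal among the target's sites, 5' to 3'), `offset`
#'   (0-based position within the target sequence) and `context`
#'   (`CG`/`CHG`/`CHH`).
#' @examples
#' extract_sites("ACGT")      # one CG site at offset 1
#' extract_sites("CAGCCGCTT") # CHG, CHG, CG, CHH
#' @export
extract_sites <- function(target) {
  if (is.character(target)) {
    seq <- toupper(target)
    tid <- "seq"
  } else {
    seq <- toupper(target$sequence)
    tid <- target$target_id
  }
  stopifnot(length(seq) == 1L, nchar(seq) >= 1L)
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars)
  cpos <- which(chars == "C")
  offsets <- integer(0)
  contexts <- character(0)
  n_dropped <- 0L
  for (i in cpos) {
    b1 <- if (i + 1L <= n) chars[i + 1L] else NA_character_
    b2 <- if (i + 2L <= n) chars[i + 2L] else NA_character_
    if (is.na(b1)) next  # 3' edge: no downstream base at all
    if (b1 == "G") {
      offsets <- c(offsets, i - 1L)
      contexts <- c(contexts, "CG")
    } else if (b1 == "N") {
      n_dropped <- n_dropped + 1L
    } else if (is.na(b2)) {
      next  # CHG/CHH need two downstream bases
    } else if (b2 == "N") {
      n_dropped <- n_dropped + 1L
    } else if (b2 == "G") {
      offsets <- c(offsets, i - 1L)
      contexts <- c(contexts, "CHG")
    } else {
      offsets <- c(offsets, i - 1L)
      contexts <- c(contexts, "CHH")
    }
  }
  if (n_dropped > 0L)
    warning(sprintf("%s: %d cytosine(s) dropped (N in context window)", tid, n_dropped))
  out <- data.frame(
    target_id = rep(tid, length(offsets)),
    index = seq_along(offsets) - 1L,
    offset = offsets,
    context = contexts,
    stringsAsFactors = FALSE
  )
  class(out) <- c("cytosine_sites", "data.frame")
  out
}

#' Write a site catalog as TSV
#'
#' @param sites A `cytosine_sites` data frame.
#' @param path Output path.
#' @export
write_site_catalog <- function(sites, path) {
  utils::write.table(as.data.frame(sites), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
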