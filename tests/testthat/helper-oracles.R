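# Independent brute-force oracles, deliberately implemented with different
# mechanics (regex / explicit scans) than the package internals.

# Context classification by regex over each C's 3-mer window.
oracle_sites <- function(seq) {
  seq <- toupper(seq)
  n <- nchar(seq)
  out <- data.frame(offset = integer(0), context = character(0))
  for (i in seq_len(n)) {
    if (substr(seq, i, i) != "C") next
    w2 <- substr(seq, i, i + 1L)
    w3 <- substr(seq, i, i + 2L)
    ctx <- if (grepl("^CG$", w2)) "CG"
    else if (grepl("^C[ACT]G$", w3)) "CHG"
    else if (grepl("^C[ACT][ACT]$", w3)) "CHH"
    else NA_character_
    if (!is.na(ctx))
      out <- rbind(out, data.frame(offset = i - 1L, context = ctx))
  }
  out
}

# Maximal runs by explicit left-to-right scan; missing is its own state.
oracle_runs <- function(v) {
  n <- length(v)
  if (n == 0L) return(data.frame(state = integer(0), start = integer(0),
                                 length = integer(0)))
  same <- function(a, b) (is.na(a) && is.na(b)) || (!is.na(a) && !is.na(b) && a == b)
  st <- integer(0); sta <- integer(0); len <- integer(0)
  cur_start <- 1L
  for (i in seq_len(n)) {
    if (i == n || !same(v[i], v[i + 1L])) {
      st <- c(st, v[cur_start]); sta <- c(sta, cur_start - 1L)
      len <- c(len, i - cur_start + 1L)
      cur_start <- i + 1L
    }
  }
  data.frame(state = st, start = sta, length = len)
}

# Longest run of `want` anywhere in v (missing breaks), by scan.
oracle_max_run <- function(v, want = 1L) {
  best <- 0L; cur <- 0L
  for (x in v) {
    if (!is.na(x) && x == want) cur <- cur + 1L else cur <- 0L
    best <- max(best, cur)
  }
  best
}

# Footprint evaluation by direct enumeration.
oracle_match <- function(v, spec) {
  want <- if (spec$state == "methylated") 1L else 0L
  if (spec$type == "set") {
    for (s in spec$sites) {
      x <- v[s + 1L]
      if (is.na(x) || x != want) return(FALSE)
    }
    return(TRUE)
  }
  wins <- spec$windows
  if (is.null(wins)) wins <- list(c(0L, length(v) - 1L))
  for (w in wins) {
    found <- FALSE
    lo <- w[1] + 1L; hi <- min(w[2] + 1L, length(v))
    for (a in lo:hi) {
      b <- a + spec$min_run - 1L
      if (b > hi) break
      seg <- v[a:b]
      if (!anyNA(seg) && all(seg == want)) { found <- TRUE; break }
    }
    if (!found) return(FALSE)
  }
  TRUE
}

# Interval coloring by per-pair if/else.
oracle_segments <- function(v) {
  n <- length(v)
  if (n < 2L) return(character(0))
  sapply(seq_len(n - 1L), function(i) {
    a <- v[i]; b <- v[i + 1L]
    if (is.na(a) || is.na(b)) "blank"
    else if (a == 1L && b == 1L) "red"
    else if (a == 0L && b == 0L) "black"
    else "gray"
  })
}

# Kruskal-Wallis H with tie correction, from the textbook formula.
oracle_kw_h <- function(a, b) {
  pooled <- c(a, b)
  N <- length(pooled)
  r <- rank(pooled)
  ra <- sum(r[seq_along(a)]); rb <- sum(r[-seq_along(a)])
  h <- 12 / (N * (N + 1)) * (ra^2 / length(a) + rb^2 / length(b)) - 3 * (N + 1)
  ties <- table(pooled)
  h / (1 - sum(ties^3 - ties) / (N^3 - N))
}

# Exact permutation p-value of the KW statistic for two small groups.
oracle_kw_perm_p <- function(a, b) {
  pooled <- c(a, b)
  n <- length(a)
  idx <- utils::combn(length(pooled), n)
  h_obs <- oracle_kw_h(a, b)
  hs <- apply(idx, 2L, function(ii) oracle_kw_h(pooled[ii], pooled[-ii]))
  mean(hs >= h_obs - 1e-12)
}

# One-way ANOVA F and p from closed-form sums of squares.
oracle_anova <- function(values, groups) {
  g <- split(values, groups)
  k <- length(g); N <- length(values)
  gm <- mean(values)
  ssb <- sum(vapply(g, function(x) length(x) * (mean(x) - gm)^2, 0))
  ssw <- sum(vapply(g, function(x) sum((x - mean(x))^2), 0))
  f <- (ssb / (k - 1)) / (ssw / (N - k))
  list(F = f, p = stats::pf(f, k - 1, N - k, lower.tail = FALSE))
}

# A random target-like sequence with a fixed base composition.
random_seq <- function(len, gc = 0.4) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# Small in-memory reference + target table written to tempfiles.
write_panel <- function(seqs, strands = NULL, is_control = NULL,
                        elements = NULL) {
  n <- length(seqs)
  if (is.null(strands)) strands <- rep("+", n)
  if (is.null(is_control)) is_control <- rep(FALSE, n)
  if (is.null(elements)) elements <- rep(".", n)
  ids <- sprintf("t%d", seq_len(n))
  ref <- tempfile(fileext = ".fa")
  writeLines(c(rbind(paste0(">chr", seq_len(n)), seqs)), ref)
  tab <- tempfile(fileext = ".tsv")
  writeLines(c(
    "target_id\tgene_id\tchrom\tstart\tend\tstrand\tis_control\telements",
    sprintf("%s\tg%d\tchr%d\t0\t%d\t%s\t%s\t%s", ids, seq_len(n), seq_len(n),
            nchar(seqs), strands, is_control, elements)
  ), tab)
  list(reference = ref, table = tab)
}

# molecule_calls built directly from a call matrix, for unit-level checks
mc_from_matrix <- function(calls, contexts, sample = "s1", replicate = "rep1") {
  n <- ncol(calls)
  sites <- data.frame(target_id = "t1", index = seq_len(n) - 1L,
                      offset = seq_len(n) * 3L, context = contexts,
                      stringsAsFactors = FALSE)
  class(sites) <- c("cytosine_sites", "data.frame")
  if (length(sample) == 1L) sample <- rep(sample, nrow(calls))
  if (length(replicate) == 1L) replicate <- rep(replicate, nrow(calls))
  if (is.null(rownames(calls)))
    rownames(calls) <- sprintf("r%03d", seq_len(nrow(calls)))
  molmeth:::new_molecule_calls(
    calls,
    data.frame(read_id = rownames(calls), sample = sample,
               replicate = replicate,
               full_length = !apply(is.na(calls), 1L, any),
               stringsAsFactors = FALSE),
    sites, "t1")
}

revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", toupper(s)), "")[[1]]),
        collapse = "")
}
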