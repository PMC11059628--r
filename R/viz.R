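#' Classify the intervals between adjacent context sites for display
#'
#' The single-molecule heatmap colors the interval between each pair of
#' adjacent sites of one context: red when both flanking calls are
#' methylated (two or more consecutively methylated cytosines), black when
#' both are unmethylated, gray for a transition, and blank when either
#' flanking call is missing.
#'
#' @param calls Integer call vector (1/0/NA) over the context subsequence.
#' @return Character vector of length `length(calls) - 1` with values
#'   `"red"`, `"black"`, `"gray"`, `"blank"`; empty when fewer than 2 sites.
#' @examples
#' segment_classes(c(1L, 1L, 0L))  # "red" "gray"
#' @export
segment_classes <- function(calls) {
  n <- length(calls)
  if (n < 2L) return(character(0))
  a <- calls[-n]
  b <- calls[-1L]
  out <- rep("blank", n - 1L)
  known <- !is.na(a) & !is.na(b)
  out[known & a == 1L & b == 1L] <- "red"
  out[known & a == 0L & b == 0L] <- "black"
  out[known & (a != b)] <- "gray"
  out
}

# Pairwise distance between binary call rows for clustering.
# kendall_tau: d = 1 - tau; a constant vector has no defined tau, so a
# constant-vs-nonconstant pair gets d = 1 and two identical constant rows 0.
read_distance <- function(mat, metric = c("kendall_tau", "euclidean")) {
  metric <- match.arg(metric)
  mat[is.na(mat)] <- 0L
  if (metric == "euclidean") return(stats::dist(mat))
  # calls are binary, where Kendall's tau-b reduces to the phi coefficient:
  # tau = (n11 n00 - n10 n01) / sqrt(n1. n0. n.1 n.0), computable in bulk
  storage.mode(mat) <- "double"
  p <- ncol(mat)
  n1 <- rowSums(mat)
  n11 <- mat %*% t(mat)
  n10 <- matrix(n1, nrow(mat), nrow(mat)) - n11
  n01 <- t(n10)
  n00 <- p - n11 - n10 - n01
  den <- sqrt(n1 * (p - n1))
  tau <- (n11 * n00 - n10 * n01) / outer(den, den)
  d <- 1 - tau
  # constant rows have no defined tau: identical constant pair -> 0, else 1
  bad <- !is.finite(d)
  if (any(bad)) {
    same <- (n11 + n00) == p  # identical rows
    d[bad] <- ifelse(same[bad], 0, 1)
  }
  stats::as.dist(d)
}

#' Deterministic hierarchical ordering of reads
#'
#' Agglomeratively clusters reads on their calls in one context and returns
#' a reproducible leaf order. Missing calls are imputed as unmethylated for
#' the distance computation only. Ties are broken by read id: rows are
#' pre-sorted lexicographically so permuting the input never changes the
#' result.
#'
#' @param mat Binary call matrix (reads x sites), rownames = read ids.
#' @param metric `"kendall_tau"` (distance `1 - tau`) or `"euclidean"`.
#' @param linkage Agglomeration method passed to [stats::hclust()]
#'   (default `"average"`).
#' @return Character vector of read ids in leaf order.
#' @export
cluster_reads <- function(mat, metric = c("kendall_tau", "euclidean"),
                          linkage = "average") {
  metric <- match.arg(metric)
  stopifnot(!is.null(rownames(mat)))
  mat <- mat[order(rownames(mat)), , drop = FALSE]
  if (nrow(mat) == 1L) return(rownames(mat))
  d <- read_distance(mat, metric)
  h <- stats::hclust(d, method = linkage)
  rownames(mat)[h$order]
}

#' Specify a single-molecule heatmap
#'
#' @param target_id Target to plot.
#' @param contexts Ordered context panels (default CG, CHG, CHH).
#' @param max_reads Cap on plotted molecules; beyond it a seeded uniform
#'   subsample of exactly `max_reads` reads is drawn (default 1000).
#' @param subsample_seed Seed for the display subsample (default 1).
#' @param cluster_metric `"kendall_tau"` or `"euclidean"`.
#' @param cluster_context Context whose calls drive the row order
#'   (default CG).
#' @param linkage Linkage method (default `"average"`).
#' @return An object of class `heatmap_spec`.
#' @export
heatmap_spec <- function(target_id, contexts = c("CG", "CHG", "CHH"),
                         max_reads = 1000L, subsample_seed = 1L,
                         cluster_metric = "kendall_tau",
                         cluster_context = "CG", linkage = "average") {
  stopifnot(max_reads >= 1L)
  structure(list(target_id = target_id, contexts = contexts,
                 max_reads = as.integer(max_reads),
                 subsample_seed = as.integer(subsample_seed),
                 cluster_metric = cluster_metric,
                 cluster_context = cluster_context, linkage = linkage),
            class = "heatmap_spec")
}

#' Render a single-molecule methylation heatmap
#'
#' Pools the replicates of one sample, subsamples to `max_reads` molecules
#' when needed (seeded, display only — statistics are never computed on the
#' subsample), orders rows by hierarchical clustering on the
#' `cluster_context` calls, and draws one panel per context with the
#' red/black/gray interval encoding, vertical white lines at site offsets
#' and cis-element windows from the target annotation. The same row is the
#' same molecule in every panel. A TSV sidecar lists plotted read ids in row
#' order.
#'
#' @param mc A `molecule_calls` object (one sample's reads; full-length
#'   reads are plotted).
#' @param spec A [heatmap_spec()].
#' @param file Output image path (`.png` or `.svg`).
#' @param target Optional target row supplying element annotations.
#' @return Invisibly, a list `read_order`, `file`, `sidecar`; `NULL` (with a
#'   warning) when there is nothing to plot.
#' @export
render_heatmap <- function(mc, spec, file, target = NULL) {
  fl <- subset_calls(mc, mc$meta$full_length)
  if (nrow(fl$calls) == 0L) {
    warning("render_heatmap: no full-length reads; nothing plotted")
    return(invisible(NULL))
  }
  ids <- fl$meta$read_id
  if (length(ids) > spec$max_reads) {
    set.seed(spec$subsample_seed)
    ids <- sort(sample(ids, spec$max_reads))
  }
  fl <- subset_calls(fl, ids)
  cidx <- which(fl$sites$context == spec$cluster_context)
  ord <- if (length(cidx) >= 1L && nrow(fl$calls) >= 2L) {
    cluster_reads(fl$calls[, cidx, drop = FALSE], spec$cluster_metric,
                  spec$linkage)
  } else fl$meta$read_id
  fl <- subset_calls(fl, ord)

  sidecar <- sub("\\.(png|svg)$", "_rows.tsv", file)
  utils::write.table(data.frame(row = seq_along(ord), read_id = ord),
                     sidecar, sep = "\t", quote = FALSE, row.names = FALSE)

  npanel <- length(spec$contexts)
  if (grepl("\\.svg$", file)) {
    grDevices::svg(file, width = 3 * npanel, height = 6)
  } else {
    grDevices::png(file, width = 300 * npanel, height = 600)
  }
  on.exit(grDevices::dev.off(), add = TRUE)
  graphics::par(mfrow = c(1, npanel), mar = c(3, 1, 2, 1))
  seqlen <- max(fl$sites$offset) + 1L
  pal <- c(red = "#C0392B", black = "#111111", gray = "#9E9E9E",
           blank = "#FFFFFF")
  for (ctx in spec$contexts) {
    idx <- which(fl$sites$context == ctx)
    graphics::plot(NA, xlim = c(0, seqlen), ylim = c(0, nrow(fl$calls)),
                   xlab = "position (nt)", ylab = "", yaxt = "n",
                   main = ctx, xaxs = "i", yaxs = "i")
    offs <- fl$sites$offset[idx]
    if (length(idx) >= 2L) {
      for (i in seq_len(nrow(fl$calls))) {
        cls <- segment_classes(fl$calls[i, idx])
        graphics::rect(offs[-length(offs)], nrow(fl$calls) - i,
                       offs[-1L], nrow(fl$calls) - i + 1L,
                       col = pal[cls], border = NA)
      }
    }
    graphics::abline(v = offs, col = "white", lwd = 0.5)
    if (!is.null(target) && nrow(target$elements[[1]]) > 0L) {
      el <- target$elements[[1]]
      graphics::rect(el$start - 1L, nrow(fl$calls) * 0.99, el$end,
                     nrow(fl$calls), col = "#27AE60", border = NA)
    }
  }
  invisible(list(read_order = ord, file = file, sidecar = sidecar))
}
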