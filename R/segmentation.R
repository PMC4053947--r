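# MDL segmentation of probe runs.
#
# A "run" is a maximal stretch of position-sorted probes whose consecutive
# gaps are all strictly below 3 kb; segmentation never crosses a run
# boundary. Within a run, a segment is scored by a two-part description
# length: the data cost is -log2 of the Gaussian likelihood at the MLE of a
# one-way model with one mean per tissue group (shared across the segment's
# probes; every probe-sample value is an observation) and pooled variance;
# the model cost is ((G + 1) / 2) * log2(n) bits for G group means plus one
# variance, n = probes * samples. Merging probes with the same group-mean
# structure saves model cost, which is the mechanism that grows segments.

DL_VAR_FLOOR <- 1e-6
DL_TIE_EPS <- 1e-9

#' Partition probes into < 3 kb-gap runs
#'
#' @param ann position-sorted annotation.
#' @param max_gap gap (bp) at which a run breaks; a gap exactly equal to
#'   `max_gap` breaks the run (strict `<` rule), default 3000.
#' @return data.frame with `run_id`, `chromosome`, `start_idx`, `end_idx`
#'   (1-based inclusive row indices into `ann`). Runs partition all probes
#'   and are maximal.
#' @export
build_runs <- function(ann, max_gap = 3000) {
  if (!is_sorted_annotation(ann))
    stop("annotation must be sorted by (chromosome, position)")
  n <- nrow(ann)
  if (n == 0)
    return(data.frame(run_id = character(), chromosome = character(),
                      start_idx = integer(), end_idx = integer()))
  new_run <- c(TRUE,
               ann$chromosome[-1] != ann$chromosome[-n] |
                 (ann$position[-1] - ann$position[-n]) >= max_gap)
  rid <- cumsum(new_run)
  starts <- which(new_run)
  ends <- c(starts[-1] - 1L, n)
  data.frame(run_id = sprintf("run%05d", seq_along(starts)),
             chromosome = ann$chromosome[starts],
             start_idx = starts, end_idx = ends)
}

# Precompute cumulative statistics for fast segment scoring.
# values: p x s complete matrix; group: character/factor of length s.
dl_prep <- function(values, group) {
  group <- as.factor(group)
  if (nlevels(group) < 2) stop("need >= 2 tissue groups")
  G <- nlevels(group)
  s <- ncol(values)
  ind <- stats::model.matrix(~ group - 1)        # s x G indicator
  gsum <- values %*% ind                         # p x G per-probe group sums
  list(G = G, s = s, sizes = colSums(ind),
       cumG = rbind(0, apply(gsum, 2, cumsum)),  # (p+1) x G
       cumQ = c(0, cumsum(rowSums(values^2))))
}

# Description length (bits) of segments [i, j] for fixed i and a vector of j.
dl_range <- function(prep, i, j) {
  p <- j - i + 1
  n <- p * prep$s
  gs <- prep$cumG[j + 1, , drop = FALSE] -
    rep(prep$cumG[i, ], each = length(j))
  dim(gs) <- c(length(j), prep$G)
  ssq <- prep$cumQ[j + 1] - prep$cumQ[i]
  rss <- ssq - rowSums(gs^2 / outer(p, prep$sizes))
  rss <- pmax(rss, 0)
  sigma2 <- pmax(rss / n, DL_VAR_FLOOR)
  data_cost <- n / 2 * log2(2 * pi * sigma2) + rss / (2 * sigma2 * log(2))
  model_cost <- (prep$G + 1) / 2 * log2(n)
  data_cost + model_cost
}

#' Description length of a probe segment under the grouped-mean model
#'
#' @param values numeric matrix, probes x samples, no missing values.
#' @param groups tissue-group label per sample (>= 2 groups).
#' @return description length in bits (`data_cost + model_cost`, attributes
#'   carry the two parts). Zero residual variance is floored at 1e-6.
#' @export
segment_dl <- function(values, groups) {
  if (!is.matrix(values)) values <- matrix(values, nrow = 1)
  if (anyNA(values)) stop("segment_dl requires complete values")
  prep <- dl_prep(values, groups)
  p <- nrow(values)
  dl <- as.numeric(dl_range(prep, 1, p))
  n <- p * prep$s
  model_cost <- (prep$G + 1) / 2 * log2(n)
  data_cost <- dl - model_cost
  attr(dl, "model_cost") <- model_cost
  attr(dl, "data_cost") <- data_cost
  dl
}

# Ordering used to break ties between partitions of equal description
# length: fewer segments first, then lexicographically earlier boundaries.
# In the DP this is realized by a suffix recursion preferring the shorter
# first segment among ties.

#' Optimal MDL partition of one run (dynamic programming)
#'
#' Minimizes the summed description length over all partitions of the run
#' into segments of at most `max_window` probes, by dynamic programming over
#' cut points (O(run length x max_window) segment evaluations). Ties (within
#' 1e-9 bits) are broken toward fewer segments, then earlier boundaries.
#'
#' @param values probes x samples matrix for the run, complete.
#' @param groups tissue-group label per sample.
#' @param max_window maximum segment length in probes (default 50).
#' @return data.frame with `start_idx`, `end_idx` (1-based within the run),
#'   `n_probes`, `dl_bits`; segments are contiguous and cover the run.
#' @export
segment_run <- function(values, groups, max_window = 50) {
  if (!is.matrix(values)) values <- matrix(values, nrow = 1)
  L <- nrow(values)
  prep <- dl_prep(values, groups)
  best_dl <- c(numeric(L), 0)   # best_dl[i] = cost of segmenting i..L
  best_ns <- c(integer(L), 0L)
  choice <- integer(L)          # end of first segment starting at i
  for (i in L:1) {
    jmax <- min(L, i + max_window - 1L)
    js <- i:jmax
    cand <- dl_range(prep, i, js) + best_dl[js + 1]
    ns <- 1L + best_ns[js + 1]
    best <- 1L
    for (k in seq_along(js)[-1]) {
      if (cand[k] < cand[best] - DL_TIE_EPS ||
          (abs(cand[k] - cand[best]) <= DL_TIE_EPS && ns[k] < ns[best])) {
        best <- k
      }
    }
    best_dl[i] <- cand[best]
    best_ns[i] <- ns[best]
    choice[i] <- js[best]
  }
  starts <- integer(0); ends <- integer(0)
  i <- 1L
  while (i <= L) {
    starts <- c(starts, i); ends <- c(ends, choice[i])
    i <- choice[i] + 1L
  }
  dl <- vapply(seq_along(starts),
               function(k) dl_range(prep, starts[k], ends[k]), 0)
  data.frame(start_idx = starts, end_idx = ends,
             n_probes = ends - starts + 1L, dl_bits = dl)
}

#' Globally optimal partition by exhaustive enumeration (test oracle)
#'
#' Enumerates all 2^(L-1) partitions of a run of L probes and returns the
#' one minimizing total description length, with the same tie-breaking as
#' [segment_run()]. Guarded to L <= 16.
#'
#' @inheritParams segment_run
#' @return as [segment_run()].
#' @export
exhaustive_segment <- function(values, groups, max_window = 50) {
  if (!is.matrix(values)) values <- matrix(values, nrow = 1)
  L <- nrow(values)
  if (L > 16) stop("exhaustive_segment limited to runs of <= 16 probes")
  prep <- dl_prep(values, groups)
  dlmat <- matrix(NA_real_, L, L)
  for (i in 1:L) {
    jmax <- min(L, i + max_window - 1L)
    dlmat[i, i:jmax] <- dl_range(prep, i, i:jmax)
  }
  best <- NULL
  for (mask in 0:(2^(max(L - 1, 0)) - 1)) {
    cuts <- which(bitwAnd(mask, 2^(0:(max(L - 2, 0)))) > 0)
    starts <- c(1L, cuts + 1L)
    ends <- c(cuts, L)
    if (any(ends - starts + 1L > max_window)) next
    dl <- sum(dlmat[cbind(starts, ends)])
    cand <- list(dl = dl, starts = starts, ends = ends)
    if (is.null(best) || dl < best$dl - DL_TIE_EPS) best <- cand
    else if (abs(dl - best$dl) <= DL_TIE_EPS) {
      if (length(starts) < length(best$starts)) best <- cand
      else if (length(starts) == length(best$starts) &&
               length(starts) > 1) {
        # earlier boundaries: lexicographically smaller cut vector
        bc <- best$ends[-length(best$ends)]
        cc <- ends[-length(ends)]
        d <- which(cc != bc)
        if (length(d) && cc[d[1]] < bc[d[1]]) best <- cand
      }
    }
  }
  data.frame(start_idx = best$starts, end_idx = best$ends,
             n_probes = best$ends - best$starts + 1L,
             dl_bits = dlmat[cbind(best$starts, best$ends)])
}

#' Segment every run of a beta matrix
#'
#' Builds < `max_gap` runs from the annotation, drops probes with any
#' missing value (count attached as attribute `n_dropped_missing`), and
#' applies [segment_run()] to each run.
#'
#' @param bm beta matrix (probes x samples), probes matching `ann` order.
#' @param ann position-sorted annotation covering `bm`'s probes.
#' @param design sample design (its `tissue_group` defines the model groups).
#' @param max_gap run-breaking gap in bp (default 3000).
#' @param max_window maximum segment length in probes (default 50).
#' @return data.frame with one row per segment: `segment_id`, `run_id`,
#'   `chromosome`, `start_idx`, `end_idx` (row indices into the complete-case
#'   matrix), `start_pos`, `end_pos`, `probe_ids` (semicolon-joined),
#'   `n_probes`, `dl_bits`. Attribute `complete_probes` holds the retained
#'   probe ids.
#' @export
segment_all <- function(bm, ann, design, max_gap = 3000, max_window = 50) {
  design <- check_design(bm, design)
  bm <- bm[, design$sample_id, drop = FALSE]
  ann <- ann[match(rownames(bm), ann$probe_id), , drop = FALSE]
  if (anyNA(ann$probe_id)) stop("annotation does not cover all probes")
  keep <- stats::complete.cases(bm)
  n_dropped <- sum(!keep)
  bm <- bm[keep, , drop = FALSE]
  ann <- ann[keep, , drop = FALSE]
  runs <- build_runs(ann, max_gap)
  out <- vector("list", nrow(runs))
  for (ri in seq_len(nrow(runs))) {
    idx <- runs$start_idx[ri]:runs$end_idx[ri]
    seg <- segment_run(bm[idx, , drop = FALSE], design$tissue_group,
                       max_window)
    seg$start_idx <- idx[seg$start_idx]
    seg$end_idx <- idx[seg$end_idx]
    seg$run_id <- runs$run_id[ri]
    out[[ri]] <- seg
  }
  segs <- do.call(rbind, out)
  segs$chromosome <- ann$chromosome[segs$start_idx]
  segs$start_pos <- ann$position[segs$start_idx]
  segs$end_pos <- ann$position[segs$end_idx]
  segs$probe_ids <- vapply(seq_len(nrow(segs)), function(k)
    paste(ann$probe_id[segs$start_idx[k]:segs$end_idx[k]], collapse = ";"),
    "")
  segs$segment_id <- sprintf("seg%06d", seq_len(nrow(segs)))
  segs <- segs[c("segment_id", "run_id", "chromosome", "start_idx",
                 "end_idx", "start_pos", "end_pos", "probe_ids",
                 "n_probes", "dl_bits")]
  attr(segs, "complete_probes") <- rownames(bm)
  attr(segs, "n_dropped_missing") <- n_dropped
  segs
}
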