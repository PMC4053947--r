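# One-vs-rest ANOVA calling of tissue-specific DMRs on MDL segments.

#' Collapse technical replicates
#'
#' Averages each replicate with its source sample so technical replicates do
#' not inflate group sizes in downstream tests.
#'
#' @param bm beta matrix.
#' @param design sample design.
#' @return list with `bm` (replicate columns merged into their source) and
#'   `design` (replicate rows removed).
#' @export
collapse_replicates <- function(bm, design) {
  design <- check_design(bm, design)
  reps <- design[!is.na(design$replicate_of), , drop = FALSE]
  for (k in seq_len(nrow(reps))) {
    src <- reps$replicate_of[k]
    bm[, src] <- rowMeans(bm[, c(src, reps$sample_id[k]), drop = FALSE],
                          na.rm = TRUE)
  }
  keep <- is.na(design$replicate_of)
  list(bm = bm[, design$sample_id[keep], drop = FALSE],
       design = design[keep, , drop = FALSE])
}

# Vectorized one-vs-rest one-way ANOVA over rows of M (regions x samples).
# Returns data.frame(p_raw, delta_beta). Zero between-group variance -> p 1.
f_one_vs_rest <- function(M, is_target) {
  n1 <- sum(is_target); n0 <- sum(!is_target); n <- n1 + n0
  if (n1 < 2 || n0 < 2) stop("each side needs >= 2 samples")
  m1 <- rowMeans(M[, is_target, drop = FALSE])
  m0 <- rowMeans(M[, !is_target, drop = FALSE])
  m <- (n1 * m1 + n0 * m0) / n
  ssb <- n1 * (m1 - m)^2 + n0 * (m0 - m)^2
  ssw <- rowSums((M[, is_target, drop = FALSE] - m1)^2) +
    rowSums((M[, !is_target, drop = FALSE] - m0)^2)
  f <- (ssb / 1) / (ssw / (n - 2))
  p <- stats::pf(f, 1, n - 2, lower.tail = FALSE)
  p[ssb <= 0] <- 1
  p[ssw <= 0 & ssb > 0] <- 0
  data.frame(p_raw = p, delta_beta = m1 - m0)
}

#' Test one segment for one-vs-rest differential methylation
#'
#' Per sample, the mean beta over the segment's probes is taken; a one-way
#' ANOVA with two groups (target tissue group vs all other samples) gives
#' the F-test p-value. `delta_beta` is target mean minus rest mean of those
#' per-sample means. Technical replicates should be collapsed beforehand
#' (see [collapse_replicates()]); [call_tdmrs()] does this automatically.
#'
#' @param bm beta matrix.
#' @param design sample design (no replicate inflation).
#' @param probe_idx row indices (or probe ids) of the segment's probes.
#' @param target_group tissue group to contrast against the rest.
#' @return list with `p_raw` and `delta_beta`.
#' @export
test_segment <- function(bm, design, probe_idx, target_group) {
  design <- check_design(bm, design)
  M <- matrix(colMeans(bm[probe_idx, design$sample_id, drop = FALSE],
                       na.rm = TRUE), nrow = 1)
  res <- f_one_vs_rest(M, design$tissue_group == target_group)
  list(p_raw = res$p_raw, delta_beta = res$delta_beta)
}

#' Call tissue-specific DMRs over all segments and tissue groups
#'
#' For each tissue group g, every segment with at least `min_probes` probes
#' is tested one-vs-rest; raw p-values are Bonferroni-adjusted within the
#' group's family (`bonferroni = "per-group"`: m = segments tested for g) or
#' over all tests (`"global"`: m = segments x groups). Calls with adjusted
#' p < `alpha` are retained; direction is `hyper` when the target group is
#' more methylated than the rest.
#'
#' @param bm beta matrix.
#' @param design sample design; technical replicates are collapsed first.
#' @param segments segment table from [segment_all()].
#' @param alpha family-wise significance level (default 0.05).
#' @param min_probes minimum probes per tested segment (default 3).
#' @param bonferroni correction family, `"per-group"` (default) or
#'   `"global"`.
#' @return data.frame of calls: segment coordinates, `target_group`,
#'   `n_probes`, `delta_beta`, `direction`, `p_raw`, `p_bonf`.
#' @export
call_tdmrs <- function(bm, design, segments, alpha = 0.05, min_probes = 3,
                       bonferroni = c("per-group", "global")) {
  bonferroni <- match.arg(bonferroni)
  cr <- collapse_replicates(bm, design)
  bm <- cr$bm; design <- cr$design
  probes <- attr(segments, "complete_probes")
  if (is.null(probes)) probes <- rownames(bm)
  segs <- segments[segments$n_probes >= min_probes, , drop = FALSE]
  if (nrow(segs) == 0) return(empty_calls())
  # per-sample segment means, all segments at once
  idx <- match(probes, rownames(bm))
  M <- matrix(NA_real_, nrow(segs), ncol(bm),
              dimnames = list(segs$segment_id, colnames(bm)))
  for (k in seq_len(nrow(segs))) {
    rows <- idx[segs$start_idx[k]:segs$end_idx[k]]
    M[k, ] <- colMeans(bm[rows, , drop = FALSE])
  }
  groups <- sort(unique(design$tissue_group))
  m_family <- if (bonferroni == "per-group") nrow(segs)
  else nrow(segs) * length(groups)
  out <- vector("list", length(groups))
  for (gi in seq_along(groups)) {
    res <- f_one_vs_rest(M, design$tissue_group == groups[gi])
    p_bonf <- pmin(1, res$p_raw * m_family)
    keep <- p_bonf < alpha
    if (!any(keep)) next
    out[[gi]] <- data.frame(
      segs[keep, c("segment_id", "chromosome", "start_idx", "end_idx",
                   "start_pos", "end_pos", "probe_ids", "n_probes")],
      target_group = groups[gi],
      delta_beta = res$delta_beta[keep],
      direction = ifelse(res$delta_beta[keep] > 0, "hyper", "hypo"),
      p_raw = res$p_raw[keep], p_bonf = p_bonf[keep],
      stringsAsFactors = FALSE)
  }
  out <- out[!vapply(out, is.null, TRUE)]
  if (!length(out)) return(empty_calls())
  calls <- do.call(rbind, out)
  rownames(calls) <- NULL
  calls
}

empty_calls <- function() {
  data.frame(segment_id = character(), chromosome = character(),
             start_idx = integer(), end_idx = integer(),
             start_pos = integer(), end_pos = integer(),
             probe_ids = character(), n_probes = integer(),
             target_group = character(), delta_beta = numeric(),
             direction = character(), p_raw = numeric(), p_bonf = numeric(),
             stringsAsFactors = FALSE)
}

#' Annotate tDMR calls with genes, location and CGI class
#'
#' A call's genes are the union of gene symbols over its probes. The
#' location class is promoter-dominant: `Promoter` if any probe has a
#' promoter-region entry (TSS1500, TSS200, UTR5, FirstExon), else `Body` if
#' any probe is genic, else `Intergenic`. The CGI class is the majority CGI
#' relation over the probes, ties resolved Island > Shore > Shelf > OpenSea.
#'
#' @param calls call table from [call_tdmrs()].
#' @param ann annotation covering every probe of every call.
#' @return calls with added `genes` (semicolon-joined), `location_class`,
#'   `cgi_class`.
#' @export
annotate_calls <- function(calls, ann) {
  if (nrow(calls) == 0) {
    calls$genes <- character(0)
    calls$location_class <- character(0)
    calls$cgi_class <- character(0)
    return(calls)
  }
  probe_lists <- strsplit(calls$probe_ids, ";", fixed = TRUE)
  aidx <- lapply(probe_lists, function(p) {
    i <- match(p, ann$probe_id)
    if (anyNA(i)) stop("missing annotation for probe ", p[which(is.na(i))[1]])
    i
  })
  calls$genes <- vapply(aidx, function(i) {
    g <- unlist(strsplit(ann$gene[i], ";", fixed = TRUE))
    paste(sort(unique(g[g != ""])), collapse = ";")
  }, "")
  calls$location_class <- vapply(aidx, function(i) {
    regs <- unlist(strsplit(ann$gene_region[i], ";", fixed = TRUE))
    if (any(regs %in% PROMOTER_REGIONS)) "Promoter"
    else if (any(ann$gene[i] != "")) "Body"
    else "Intergenic"
  }, "")
  calls$cgi_class <- vapply(aidx, function(i) {
    tab <- table(factor(ann$cgi_relation[i], levels = CGI_CLASSES))
    names(tab)[which.max(tab)]   # which.max takes the first max: priority order
  }, "")
  calls
}

#' Summarize tDMR calls (per-group counts and location/CGI cross-tab)
#'
#' @param calls annotated calls from [annotate_calls()].
#' @return list with `per_group` (tissue group, hyper blocks, hyper with
#'   gene annotation, hypo blocks, hypo with gene annotation) and
#'   `crosstab` (location_class x cgi_class counts plus percentages of total
#'   calls, half-up to one decimal).
#' @export
summarize_calls <- function(calls) {
  groups <- sort(unique(calls$target_group))
  per_group <- do.call(rbind, lapply(groups, function(g) {
    cg <- calls[calls$target_group == g, , drop = FALSE]
    data.frame(tissue_group = g,
               hyper = sum(cg$direction == "hyper"),
               hyper_gene = sum(cg$direction == "hyper" & cg$genes != ""),
               hypo = sum(cg$direction == "hypo"),
               hypo_gene = sum(cg$direction == "hypo" & cg$genes != ""),
               stringsAsFactors = FALSE)
  }))
  if (is.null(per_group))
    per_group <- data.frame(tissue_group = character(), hyper = integer(),
                            hyper_gene = integer(), hypo = integer(),
                            hypo_gene = integer())
  ct <- table(factor(calls$location_class,
                     levels = c("Promoter", "Body", "Intergenic")),
              factor(calls$cgi_class, levels = CGI_CLASSES))
  pct <- if (nrow(calls) > 0) percent_half_up(ct, nrow(calls)) else ct * 0
  list(per_group = per_group, crosstab = unclass(ct),
       crosstab_pct = unclass(pct), n_calls = nrow(calls))
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact p by hypergeometric tail summation: the sum of probabilities of all
#' tables with the observed margins whose probability does not exceed that
#' of the observed table (with a 1 + 1e-7 relative tolerance, the standard
#' guard against floating-point ties).
#'
#' @param a,b,c,d non-negative integer cell counts, row-wise.
#' @return two-sided p-value in (0, 1\]; an all-zero table gives 1.
#' @export
fisher_2x2 <- function(a, b, c, d) {
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  if (a + b + c + d == 0) return(1)
  m <- a + b          # row 1 total
  n <- c + d          # row 2 total
  k <- a + c          # column 1 total
  lo <- max(0, k - n); hi <- min(k, m)
  support <- lo:hi
  dens <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  min(1, sum(dens[dens <= p_obs * (1 + 1e-7)]))
}
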