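# Genome-wide pattern summaries: invariant classification, region/CGI
# distributions, tissue clustering, variance decomposition, and
# probe-distance correlation diagnostics.

#' Classify probes as invariantly hyper-/hypomethylated or variable
#'
#' A probe is `InvariantHyper` when every non-missing beta is strictly above
#' `hi`, `InvariantHypo` when every non-missing beta is strictly below `lo`,
#' otherwise `Variable`. Probes with all values missing are `Variable` (the
#' count is attached as attribute `n_all_missing`).
#'
#' @param bm beta matrix.
#' @param hi,lo thresholds (defaults 0.9 and 0.1, strict inequalities).
#' @return named character vector (probe -> label).
#' @export
classify_invariant <- function(bm, hi = 0.9, lo = 0.1) {
  mn <- suppressWarnings(apply(bm, 1, min, na.rm = TRUE))
  mx <- suppressWarnings(apply(bm, 1, max, na.rm = TRUE))
  all_na <- !is.finite(mn)
  lab <- rep("Variable", nrow(bm))
  lab[!all_na & mn > hi] <- "InvariantHyper"
  lab[!all_na & mx < lo] <- "InvariantHypo"
  names(lab) <- rownames(bm)
  attr(lab, "n_all_missing") <- sum(all_na)
  lab
}

# expand a probe subset into (probe index, class) pairs under a grouping
region_class_entries <- function(ann, grouping) {
  if (grouping == "gene_region") {
    regs <- strsplit(ann$gene_region, ";", fixed = TRUE)
    cls <- lapply(seq_len(nrow(ann)), function(i) {
      r <- unique(regs[[i]])
      if (ann$gene[i] == "" || !length(r) || identical(r, "")) "Intergenic"
      else r
    })
    data.frame(idx = rep(seq_len(nrow(ann)), lengths(cls)),
               class = unlist(cls), stringsAsFactors = FALSE)
  } else if (grouping == "cgi_relation") {
    data.frame(idx = seq_len(nrow(ann)), class = ann$cgi_relation,
               stringsAsFactors = FALSE)
  } else if (grouping == "cgi_by_genic") {
    genic <- ifelse(ann$gene == "", "intergenic", "intragenic")
    data.frame(idx = seq_len(nrow(ann)),
               class = paste(genic, ann$cgi_relation, sep = "."),
               stringsAsFactors = FALSE)
  } else stop("unknown grouping: ", grouping)
}

#' Distribution of probes (and their betas) over annotation classes
#'
#' Counts probes per class of the chosen grouping, with percentages (half-up,
#' one decimal) and a 10-bin beta histogram (bins \[0,0.1), ..., \[0.9,1\])
#' per class when a beta matrix is given. Under `gene_region` a probe
#' annotated to several regions contributes to each (manifest semantics);
#' percentages use the total number of (probe, class) entries so they sum to
#' 100. `cgi_by_genic` splits CGI classes by intergenic/intragenic location.
#'
#' @param ann annotation.
#' @param grouping one of `"gene_region"`, `"cgi_relation"`,
#'   `"cgi_by_genic"`.
#' @param probe_ids optional subset of probes to tabulate (e.g. the
#'   invariantly methylated ones).
#' @param bm optional beta matrix for the histograms.
#' @return list with `counts` (data.frame class/count/percent) and
#'   `histogram` (class x 10 bin counts, or NULL).
#' @export
distribution_by_region <- function(ann, grouping = "gene_region",
                                   probe_ids = NULL, bm = NULL) {
  if (!is.null(probe_ids)) {
    keep <- ann$probe_id %in% probe_ids
    ann <- ann[keep, , drop = FALSE]
  }
  ent <- region_class_entries(ann, grouping)
  tab <- table(ent$class)
  counts <- data.frame(class = names(tab), count = as.integer(tab),
                       stringsAsFactors = FALSE)
  counts$percent <- percent_half_up(counts$count, sum(counts$count))
  hist <- NULL
  if (!is.null(bm)) {
    vals <- bm[ann$probe_id[ent$idx], , drop = FALSE]
    bins <- seq(0, 1, by = 0.1)
    hist <- t(vapply(counts$class, function(cl) {
      v <- as.vector(vals[ent$class == cl, , drop = FALSE])
      v <- v[!is.na(v)]
      b <- pmin(findInterval(v, bins, rightmost.closed = TRUE), 10)
      tabulate(b, nbins = 10)
    }, integer(10)))
    colnames(hist) <- sprintf("[%.1f,%.1f%s", bins[-11], bins[-1],
                              c(rep(")", 9), "]"))
  }
  list(counts = counts, histogram = hist)
}

#' Per-tissue mean methylation profiles
#'
#' @param bm beta matrix.
#' @param design sample design.
#' @param by `"tissue"` (default) or `"tissue_group"`.
#' @return tissue x probe matrix of per-probe means over that tissue's
#'   samples (replicates included).
#' @export
tissue_mean_profiles <- function(bm, design, by = "tissue") {
  design <- check_design(bm, design)
  tissues <- sort(unique(design[[by]]))
  prof <- t(vapply(tissues, function(tt) {
    cols <- design$sample_id[design[[by]] == tt]
    rowMeans(bm[, cols, drop = FALSE], na.rm = TRUE)
  }, numeric(nrow(bm))))
  rownames(prof) <- tissues
  prof
}

#' Pairwise Pearson correlation of tissue profiles
#'
#' @param profiles tissue x probe matrix from [tissue_mean_profiles()].
#' @return symmetric correlation matrix with unit diagonal.
#' @export
tissue_correlation_matrix <- function(profiles) {
  if (ncol(profiles) < 2) stop("need >= 2 probes")
  sds <- apply(profiles, 1, stats::sd)
  if (any(sds == 0))
    stop("zero-variance profile for tissue: ",
         rownames(profiles)[which(sds == 0)[1]])
  cc <- stats::cor(t(profiles), use = "pairwise.complete.obs")
  diag(cc) <- 1
  cc
}

#' Complete-linkage clustering of tissue profiles
#'
#' Agglomerative clustering with complete linkage on `1 - PCC` distances
#' (or Euclidean). Rows are sorted lexicographically by tissue name first,
#' making the result invariant to input row order and deterministic under
#' ties.
#'
#' @param profiles tissue x probe matrix.
#' @param distance `"correlation"` (1 - Pearson, default) or `"euclidean"`.
#' @param linkage linkage method passed to [stats::hclust()].
#' @return list with `hclust` object, `newick` string, and the `merge`
#'   table.
#' @export
cluster_tissues <- function(profiles, distance = c("correlation", "euclidean"),
                            linkage = "complete") {
  distance <- match.arg(distance)
  profiles <- profiles[order(rownames(profiles)), , drop = FALSE]
  d <- if (distance == "correlation")
    stats::as.dist(1 - tissue_correlation_matrix(profiles))
  else stats::dist(profiles)
  hc <- stats::hclust(d, method = linkage)
  list(hclust = hc, newick = ape::write.tree(ape::as.phylo(hc)),
       merge = hc$merge, height = hc$height)
}

#' Per-probe variance explained by a design factor
#'
#' For each probe, the one-way R-squared `SS_between / SS_total` of the
#' chosen factor fitted alone. Probes with zero total sum of squares get
#' R-squared 0 (count attached as attribute `n_zero_ss`).
#'
#' @param bm beta matrix.
#' @param design sample design.
#' @param factor `"tissue_group"`, `"tissue"` or `"individual_id"`.
#' @return list with `r2` (per-probe vector) and `mean_r2`.
#' @export
variance_explained <- function(bm, design, factor = "tissue_group") {
  design <- check_design(bm, design)
  f <- design[[factor]]
  if (length(unique(f)) < 2) stop("factor needs >= 2 levels")
  bm <- bm[, design$sample_id, drop = FALSE]
  obs <- !is.na(bm)
  x0 <- ifelse(obs, bm, 0)
  n <- rowSums(obs)
  gm <- rowSums(x0) / n
  sst <- rowSums((x0 - gm * obs)^2 * obs)
  ssb <- 0
  for (lev in unique(f)) {
    cols <- f == lev
    nl <- rowSums(obs[, cols, drop = FALSE])
    sl <- rowSums(x0[, cols, drop = FALSE])
    ml <- ifelse(nl > 0, sl / nl, 0)
    ssb <- ssb + nl * (ml - gm)^2
  }
  r2 <- ifelse(sst > 0, ssb / sst, 0)
  r2 <- pmin(pmax(r2, 0), 1)
  names(r2) <- rownames(bm)
  out <- list(r2 = r2, mean_r2 = mean(r2))
  attr(out, "n_zero_ss") <- sum(sst == 0)
  out
}

#' Variance decomposition stratified by annotation class
#'
#' @inheritParams variance_explained
#' @param ann annotation covering the probes.
#' @param grouping grouping for [distribution_by_region()] classes.
#' @return list of per-class R-squared vectors (empty classes omitted with a
#'   warning) plus a per-class summary data.frame.
#' @export
variance_by_annotation <- function(bm, design, ann, factor = "tissue_group",
                                   grouping = "gene_region") {
  ve <- variance_explained(bm, design, factor)
  ann <- ann[match(rownames(bm), ann$probe_id), , drop = FALSE]
  ent <- region_class_entries(ann, grouping)
  classes <- sort(unique(ent$class))
  per_class <- lapply(classes, function(cl) ve$r2[ent$idx[ent$class == cl]])
  names(per_class) <- classes
  empty <- lengths(per_class) == 0
  if (any(empty)) {
    warning("empty annotation class(es): ",
            paste(classes[empty], collapse = ", "))
    per_class <- per_class[!empty]
  }
  summary <- data.frame(class = names(per_class),
                        n = lengths(per_class),
                        mean_r2 = vapply(per_class, mean, 0),
                        median_r2 = vapply(per_class, stats::median, 0))
  rownames(summary) <- NULL
  list(per_class = per_class, summary = summary)
}

#' Correlation between consecutive probes as a function of their gap
#'
#' For each pair of adjacent probes on the same chromosome, the Pearson
#' correlation of their beta vectors across samples; averaged within the
#' short-gap (< `threshold`) and long-gap (>= `threshold`) strata. Pairs
#' where either probe has zero variance are skipped and counted.
#'
#' @param bm beta matrix (rows in annotation order).
#' @param ann position-sorted annotation covering the probes.
#' @param threshold gap threshold in bp (default 3000).
#' @return list with `mean_short`, `mean_long`, and `table`
#'   (gap, pcc per pair); attribute `n_skipped` counts zero-variance pairs.
#' @export
consecutive_probe_correlation <- function(bm, ann, threshold = 3000) {
  ann <- ann[match(rownames(bm), ann$probe_id), , drop = FALSE]
  if (!is_sorted_annotation(ann))
    stop("beta matrix rows must be in (chromosome, position) order")
  n <- nrow(bm)
  same <- ann$chromosome[-1] == ann$chromosome[-n]
  i <- which(same)
  gap <- ann$position[i + 1] - ann$position[i]
  a <- bm[i, , drop = FALSE]
  b <- bm[i + 1, , drop = FALSE]
  ca <- a - rowMeans(a, na.rm = TRUE)
  cb <- b - rowMeans(b, na.rm = TRUE)
  num <- rowSums(ca * cb, na.rm = TRUE)
  den <- sqrt(rowSums(ca^2, na.rm = TRUE) * rowSums(cb^2, na.rm = TRUE))
  pcc <- ifelse(den > 0, num / den, NA_real_)
  skipped <- sum(is.na(pcc))
  tab <- data.frame(gap = gap, pcc = pcc)
  out <- list(mean_short = mean(pcc[gap < threshold], na.rm = TRUE),
              mean_long = mean(pcc[gap >= threshold], na.rm = TRUE),
              table = tab)
  attr(out, "n_skipped") <- skipped
  out
}

#' Concordance of technical replicate pairs
#'
#' @param bm beta matrix.
#' @param design sample design with `replicate_of` entries.
#' @return data.frame (sample, replicate, pcc); zero rows when no pairs are
#'   declared.
#' @export
replicate_concordance <- function(bm, design) {
  design <- check_design(bm, design)
  reps <- design[!is.na(design$replicate_of), , drop = FALSE]
  if (nrow(reps) == 0)
    return(data.frame(sample = character(), replicate = character(),
                      pcc = numeric()))
  data.frame(sample = reps$replicate_of, replicate = reps$sample_id,
             pcc = vapply(seq_len(nrow(reps)), function(k)
               stats::cor(bm[, reps$replicate_of[k]],
                          bm[, reps$sample_id[k]],
                          use = "pairwise.complete.obs"), 0))
}
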