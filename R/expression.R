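# Methylation-expression integration: gene- and tDMR-level mean methylation
# correlated against a gene x tissue expression matrix.

#' Gene-level mean methylation per tissue
#'
#' Averages tissue-mean beta values over a gene's probes, optionally
#' restricted to probes with a qualifying gene-region entry and/or CGI
#' class (e.g. `region_filter = PROMOTER_REGIONS, cgi_filter = "Island"` for
#' the promoter-CGI stratum). A gene qualifies when it has at least one
#' qualifying probe; genes with none are omitted.
#'
#' @param bm beta matrix.
#' @param ann annotation.
#' @param design sample design; tissues are taken as `tissue_group`.
#' @param region_filter optional character vector of gene-region classes; a
#'   probe qualifies for a gene if its entry for that gene is in the set.
#' @param cgi_filter optional character vector of CGI classes.
#' @return gene x tissue matrix of mean beta.
#' @export
average_beta_by_gene <- function(bm, ann, design, region_filter = NULL,
                                 cgi_filter = NULL) {
  prof <- tissue_mean_profiles(bm, design, by = "tissue_group")
  ann <- ann[match(colnames(prof), ann$probe_id), , drop = FALSE]
  if (!is.null(cgi_filter)) {
    keep <- ann$cgi_relation %in% cgi_filter
    ann <- ann[keep, , drop = FALSE]
    prof <- prof[, keep, drop = FALSE]
  }
  genes <- strsplit(ann$gene, ";", fixed = TRUE)
  regs <- strsplit(ann$gene_region, ";", fixed = TRUE)
  pidx <- rep(seq_len(nrow(ann)), lengths(genes))
  ent <- data.frame(idx = pidx, gene = unlist(genes), region = unlist(regs),
                    stringsAsFactors = FALSE)
  ent <- ent[ent$gene != "", , drop = FALSE]
  if (!is.null(region_filter))
    ent <- ent[ent$region %in% region_filter, , drop = FALSE]
  if (nrow(ent) == 0)
    return(matrix(numeric(), 0, nrow(prof),
                  dimnames = list(NULL, rownames(prof))))
  by_gene <- split(ent$idx, ent$gene)
  out <- t(vapply(by_gene, function(i)
    colMeans(t(prof)[unique(i), , drop = FALSE]), numeric(nrow(prof))))
  colnames(out) <- rownames(prof)
  out
}

#' tDMR-level mean methylation per tissue
#'
#' @param calls annotated calls from [annotate_calls()].
#' @param bm beta matrix.
#' @param design sample design.
#' @return tDMR x tissue matrix; rownames are
#'   `segment_id.target_group`.
#' @export
average_beta_by_tdmr <- function(calls, bm, design) {
  prof <- tissue_mean_profiles(bm, design, by = "tissue_group")
  out <- t(vapply(strsplit(calls$probe_ids, ";", fixed = TRUE),
                  function(p) rowMeans(prof[, p, drop = FALSE]),
                  numeric(nrow(prof))))
  rownames(out) <- paste(calls$segment_id, calls$target_group, sep = ".")
  colnames(out) <- rownames(prof)
  out
}

#' Correlate methylation with expression across shared tissues
#'
#' Duplicate expression rows per gene are collapsed by median first. For
#' every row of `meth` with a matching expression row, the Pearson
#' correlation across the shared tissues is computed; rows with fewer than
#' `min_shared` shared tissues or zero variance on either side are skipped
#' (counts attached as attributes `n_skipped_few` / `n_skipped_novar`).
#'
#' @param meth gene (or tDMR-gene) x tissue methylation matrix.
#' @param expr gene x tissue expression matrix.
#' @param min_shared minimum shared tissues (default 3).
#' @return named numeric vector of per-gene PCCs.
#' @export
correlate_methylation_expression <- function(meth, expr, min_shared = 3) {
  tissues <- intersect(colnames(meth), colnames(expr))
  if (length(tissues) == 0) stop("no shared tissues between matrices")
  if (anyDuplicated(rownames(expr))) {
    expr <- do.call(rbind, lapply(split(seq_len(nrow(expr)), rownames(expr)),
                                  function(i) apply(expr[i, , drop = FALSE],
                                                    2, stats::median)))
  }
  genes <- intersect(rownames(meth), rownames(expr))
  skipped_few <- 0L; skipped_novar <- 0L
  pccs <- numeric(0)
  for (g in genes) {
    x <- meth[g, tissues]; y <- expr[g, tissues]
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < min_shared) { skipped_few <- skipped_few + 1L; next }
    if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
      skipped_novar <- skipped_novar + 1L; next
    }
    pccs[g] <- stats::cor(x[ok], y[ok])
  }
  attr(pccs, "n_skipped_few") <- skipped_few
  attr(pccs, "n_skipped_novar") <- skipped_novar
  pccs
}

#' Classify correlation coefficients into sign / strength counts
#'
#' Negative means PCC < 0; PCC = 0 counts as positive (the dichotomy must
#' sum to the total). Strong thresholds are strict: < -`strong` and
#' > `strong`.
#'
#' @param pccs numeric vector of correlations.
#' @param strong strength threshold (default 0.5).
#' @param digits decimals for the percentages (default 1).
#' @return one-row data.frame: n_neg, n_pos, n_strong_neg, n_strong_pos,
#'   total, and the four percentages (half-up).
#' @export
classify_correlations <- function(pccs, strong = 0.5, digits = 1) {
  pccs <- pccs[!is.na(pccs)]
  total <- length(pccs)
  n_neg <- sum(pccs < 0)
  n_pos <- sum(pccs >= 0)
  n_sneg <- sum(pccs < -strong)
  n_spos <- sum(pccs > strong)
  pct <- function(x) if (total > 0) percent_half_up(x, total, digits) else 0
  data.frame(n_neg = n_neg, n_pos = n_pos, n_strong_neg = n_sneg,
             n_strong_pos = n_spos, total = total,
             pct_neg = pct(n_neg), pct_pos = pct(n_pos),
             pct_strong_neg = pct(n_sneg), pct_strong_pos = pct(n_spos))
}

#' Build the full methylation-expression correlation table
#'
#' One row per region stratum (Global, Promoter + CGI, each gene region,
#' Shores, Shelves), each counting genes by correlation sign and strength.
#'
#' @param bm beta matrix.
#' @param ann annotation.
#' @param design sample design.
#' @param expr gene x tissue expression matrix.
#' @param min_shared minimum shared tissues per correlation.
#' @param strong strength threshold.
#' @return data.frame with a `stratum` column plus the
#'   [classify_correlations()] columns.
#' @export
correlation_table <- function(bm, ann, design, expr, min_shared = 3,
                              strong = 0.5) {
  strata <- list(
    Global = list(region = NULL, cgi = NULL),
    `Promoter+CGI` = list(region = PROMOTER_REGIONS, cgi = "Island"),
    TSS1500 = list(region = "TSS1500", cgi = NULL),
    TSS200 = list(region = "TSS200", cgi = NULL),
    UTR5 = list(region = "UTR5", cgi = NULL),
    FirstExon = list(region = "FirstExon", cgi = NULL),
    Body = list(region = "Body", cgi = NULL),
    UTR3 = list(region = "UTR3", cgi = NULL),
    Shores = list(region = NULL, cgi = "Shore"),
    Shelves = list(region = NULL, cgi = "Shelf"))
  rows <- lapply(names(strata), function(nm) {
    st <- strata[[nm]]
    meth <- average_beta_by_gene(bm, ann, design, region_filter = st$region,
                                 cgi_filter = st$cgi)
    pccs <- if (nrow(meth)) correlate_methylation_expression(meth, expr,
                                                             min_shared)
    else numeric(0)
    cbind(stratum = nm, classify_correlations(pccs, strong))
  })
  do.call(rbind, rows)
}
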