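#' Pre-analysis probe filtering
#'
#' Removes SNP-overlapping probes and probes on excluded chromosomes
#' (typically chrX and chrY, to eliminate sex-specific methylation). Probe
#' order is preserved and the removal counts per criterion are attached.
#' A probe counted under `snp` is not double-counted under a chromosome.
#'
#' @param bm beta matrix.
#' @param ann annotation covering every probe of `bm`.
#' @param drop_snp drop probes with `snp_flag` TRUE.
#' @param drop_chromosomes character vector of chromosomes to drop.
#' @return filtered beta matrix with attribute `removal_report`, a named
#'   integer vector (one entry `snp` plus one per dropped chromosome).
#' @export
filter_probes <- function(bm, ann, drop_snp = TRUE,
                          drop_chromosomes = c("chrX", "chrY")) {
  idx <- match(rownames(bm), ann$probe_id)
  if (anyNA(idx))
    stop("probe lacking annotation: ", rownames(bm)[which(is.na(idx))[1]])
  a <- ann[idx, , drop = FALSE]
  report <- integer(0)
  drop <- rep(FALSE, nrow(bm))
  if (drop_snp) {
    hit <- a$snp_flag & !drop
    report["snp"] <- sum(hit)
    drop <- drop | hit
  }
  for (chr in drop_chromosomes) {
    hit <- a$chromosome == chr & !drop
    report[chr] <- sum(hit)
    drop <- drop | hit
  }
  out <- bm[!drop, , drop = FALSE]
  attr(out, "removal_report") <- report
  out
}

#' Collapse tissues into tissue groups
#'
#' Rewrites `tissue_group` in a design sheet from a tissue-to-group mapping;
#' used to merge functionally similar tissues (e.g. the two aortas) before
#' one-vs-rest testing. The mapping must cover every observed tissue.
#'
#' @param design sample design.
#' @param mapping named character vector or two-column data.frame
#'   (`tissue`, `tissue_group`).
#' @return design with updated `tissue_group`.
#' @export
merge_tissue_groups <- function(design, mapping) {
  if (is.data.frame(mapping)) {
    map <- stats::setNames(mapping$tissue_group, mapping$tissue)
  } else map <- mapping
  unmapped <- setdiff(unique(design$tissue), names(map))
  if (length(unmapped))
    stop("unmapped tissue(s): ", paste(unmapped, collapse = ", "))
  design$tissue_group <- unname(map[design$tissue])
  sample_design(design)
}
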