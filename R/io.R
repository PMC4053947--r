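#' Read a beta-value matrix from TSV
#'
#' First column `probe_id`, remaining columns one per sample. Cells must be
#' numeric in \[0,1\] or empty (missing). When an annotation is supplied the
#' probes are re-sorted to its (chromosome, position) order.
#'
#' @param path TSV file.
#' @param ann optional annotation from [read_annotation()]/[probe_annotation()].
#' @return beta matrix (see [beta_matrix()]).
#' @export
read_beta_matrix <- function(path, ann = NULL) {
  df <- utils::read.delim(path, check.names = FALSE, colClasses = "character",
                          na.strings = c("", "NA"))
  if (names(df)[1] != "probe_id") stop("first column must be 'probe_id'")
  ids <- df[[1]]
  raw <- as.matrix(df[, -1, drop = FALSE])
  vals <- suppressWarnings(matrix(as.numeric(raw), nrow = nrow(raw),
                                  dimnames = list(ids, colnames(raw))))
  bad <- which(!is.na(raw) & is.na(vals), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("malformed numeric at probe '%s', sample '%s': '%s'",
                 ids[bad[1, 1]], colnames(raw)[bad[1, 2]],
                 raw[bad[1, 1], bad[1, 2]]))
  beta_matrix(vals, ann)
}

#' Write a beta-value matrix to TSV
#' @param bm beta matrix.
#' @param path output file.
#' @export
write_beta_matrix <- function(bm, path) {
  df <- data.frame(probe_id = rownames(bm), bm, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a probe annotation CSV
#'
#' Columns: probe_id, chromosome, position, gene, gene_region, cgi_relation,
#' snp_flag. `gene` and `gene_region` may carry semicolon-joined parallel
#' lists; an empty `gene` marks an intergenic probe. Unknown region or CGI
#' tokens are rejected.
#'
#' @param path CSV file.
#' @return position-sorted annotation data.frame.
#' @export
read_annotation <- function(path) {
  df <- utils::read.csv(path, colClasses = "character", na.strings = "NA")
  df$position <- as.integer(df$position)
  df$snp_flag <- df$snp_flag %in% c("TRUE", "true", "1")
  probe_annotation(df)
}

#' Write a probe annotation CSV
#' @param ann annotation data.frame.
#' @param path output file.
#' @export
write_annotation <- function(ann, path) {
  utils::write.csv(ann, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a sample design sheet CSV
#' @param path CSV with columns sample_id, tissue, tissue_group,
#'   individual_id, replicate_of.
#' @return validated design data.frame.
#' @export
read_design <- function(path) {
  sample_design(utils::read.csv(path, colClasses = "character"))
}

#' Write a sample design sheet CSV
#' @param design design data.frame.
#' @param path output file.
#' @export
write_design <- function(design, path) {
  utils::write.csv(design, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write genomic regions as BED6
#'
#' Input coordinates are 1-based inclusive probe positions; BED output is
#' 0-based half-open, so `start = first_pos - 1`, `end = last_pos`. The score
#' column carries -log10 of the adjusted p-value capped at 1000 (0 when no
#' p-value column is present).
#'
#' @param regions data.frame with columns `chromosome`, `start_pos`,
#'   `end_pos`, optionally `name`, `p_bonf`, `strand`.
#' @param path output file.
#' @export
write_regions_bed <- function(regions, path) {
  if (nrow(regions) == 0) {
    cat("", file = path)
    return(invisible(path))
  }
  name <- if (!is.null(regions$name)) regions$name else
    sprintf("region_%04d", seq_len(nrow(regions)))
  score <- if (!is.null(regions$p_bonf))
    pmin(1000, round(-log10(pmax(regions$p_bonf, 1e-1000)), 3)) else 0
  strand <- if (!is.null(regions$strand)) regions$strand else "."
  bed <- data.frame(regions$chromosome, regions$start_pos - 1L,
                    regions$end_pos, name, score, strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read BED6 regions back as 1-based inclusive intervals
#' @param path BED file written by [write_regions_bed()].
#' @return data.frame with chromosome, start_pos, end_pos, name, score.
#' @export
read_regions_bed <- function(path) {
  if (file.size(path) == 0)
    return(data.frame(chromosome = character(), start_pos = integer(),
                      end_pos = integer(), name = character(),
                      score = numeric()))
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "start", "end", "name",
                                        "score", "strand"),
                          colClasses = c("character", "integer", "integer",
                                         "character", "numeric", "character"))
  data.frame(chromosome = df$chrom, start_pos = df$start + 1L,
             end_pos = df$end, name = df$name, score = df$score)
}

#' Write a tDMR call table to TSV
#' @param calls annotated call data.frame from [annotate_calls()].
#' @param path output file.
#' @export
write_calls <- function(calls, path) {
  utils::write.table(calls, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
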