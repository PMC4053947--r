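#' Construct and validate a probe annotation table
#'
#' The annotation is a plain `data.frame` in manifest-style form, one row per
#' probe, position-sorted by (chromosome, position):
#' \describe{
#'   \item{probe_id}{character, unique}
#'   \item{chromosome}{character, e.g. `"chr1"`}
#'   \item{position}{integer, 1-based genomic coordinate}
#'   \item{gene}{character; semicolon-joined gene symbols, `""` for intergenic}
#'   \item{gene_region}{character; semicolon-joined region classes parallel to
#'     `gene`, each one of TSS1500, TSS200, UTR5, FirstExon, Body, UTR3}
#'   \item{cgi_relation}{one of Island, Shore, Shelf, OpenSea; north/south
#'     shore and shelf variants of upstream manifests must be collapsed before
#'     entry — this package does not distinguish sides}
#'   \item{snp_flag}{logical; TRUE if the probe overlaps a known SNP}
#' }
#'
#' @param df data.frame with the columns above.
#' @return The validated, position-sorted data.frame.
#' @export
probe_annotation <- function(df) {
  need <- c("probe_id", "chromosome", "position", "gene", "gene_region",
            "cgi_relation", "snp_flag")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("annotation missing columns: ", paste(miss, collapse = ", "))
  df$probe_id <- as.character(df$probe_id)
  df$chromosome <- as.character(df$chromosome)
  df$position <- as.integer(df$position)
  df$gene <- as.character(df$gene)
  df$gene[is.na(df$gene)] <- ""
  df$gene_region <- as.character(df$gene_region)
  df$gene_region[is.na(df$gene_region)] <- ""
  df$cgi_relation <- as.character(df$cgi_relation)
  df$snp_flag <- as.logical(df$snp_flag)
  if (anyDuplicated(df$probe_id)) stop("duplicate probe_id in annotation")
  if (any(df$position < 1)) stop("annotation positions must be >= 1")
  if (anyDuplicated(df[c("chromosome", "position")]))
    stop("duplicate (chromosome, position) in annotation")
  bad_cgi <- setdiff(unique(df$cgi_relation), CGI_CLASSES)
  if (length(bad_cgi))
    stop("unknown cgi_relation token(s): ", paste(bad_cgi, collapse = ", "))
  regs <- unlist(strsplit(df$gene_region[df$gene_region != ""], ";", fixed = TRUE))
  bad_reg <- setdiff(unique(regs), GENE_REGIONS)
  if (length(bad_reg))
    stop("unknown gene_region token(s): ", paste(bad_reg, collapse = ", "))
  # gene and gene_region are parallel semicolon lists
  ng <- lengths(strsplit(df$gene, ";", fixed = TRUE))
  nr <- lengths(strsplit(df$gene_region, ";", fixed = TRUE))
  mism <- which(df$gene != "" & ng != nr)
  if (length(mism))
    stop("gene/gene_region list lengths differ for probe ",
         df$probe_id[mism[1]])
  df <- df[probe_order(df$chromosome, df$position), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Split a probe's semicolon-joined gene annotation into entries
#'
#' @param ann annotation data.frame (see [probe_annotation()]).
#' @return list (one element per probe) of data.frames with columns
#'   `gene_symbol`, `gene_region`; a zero-row data.frame marks an intergenic
#'   probe.
#' @export
gene_entries <- function(ann) {
  gs <- strsplit(ann$gene, ";", fixed = TRUE)
  rs <- strsplit(ann$gene_region, ";", fixed = TRUE)
  mapply(function(g, r) {
    if (length(g) == 0 || identical(g, ""))
      data.frame(gene_symbol = character(), gene_region = character())
    else data.frame(gene_symbol = g, gene_region = r)
  }, gs, rs, SIMPLIFY = FALSE)
}

#' Construct and validate a beta-value matrix
#'
#' @param values numeric matrix, probes x samples; rownames are probe ids,
#'   colnames sample ids. Values must be in \[0,1\] or NA.
#' @param ann optional annotation; when given, rows are reordered to the
#'   annotation's (chromosome, position) order and must match its probe set.
#' @return numeric matrix (probes x samples).
#' @export
beta_matrix <- function(values, ann = NULL) {
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values))) stop("beta matrix must have probe_id rownames")
  if (is.null(colnames(values))) stop("beta matrix must have sample_id colnames")
  bad <- which(!is.na(values) & (values < 0 | values > 1), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("beta value out of [0,1] at probe '%s', sample '%s': %g",
                 rownames(values)[bad[1, 1]], colnames(values)[bad[1, 2]],
                 values[bad[1, 1], bad[1, 2]]))
  if (!is.null(ann)) {
    missing <- setdiff(rownames(values), ann$probe_id)
    if (length(missing))
      stop("probe(s) absent from annotation: ", paste(utils::head(missing, 3), collapse = ", "))
    values <- values[ann$probe_id[ann$probe_id %in% rownames(values)], , drop = FALSE]
  }
  values
}

#' Construct and validate a sample design sheet
#'
#' @param df data.frame with columns `sample_id`, `tissue`, `tissue_group`,
#'   `individual_id`, `replicate_of` (NA for primary samples). Unbalanced
#'   designs (an individual lacking some tissues) are allowed.
#' @return validated data.frame.
#' @export
sample_design <- function(df) {
  need <- c("sample_id", "tissue", "tissue_group", "individual_id", "replicate_of")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("design missing columns: ", paste(miss, collapse = ", "))
  for (cc in need) df[[cc]] <- as.character(df[[cc]])
  df$replicate_of[df$replicate_of %in% c("", "NA")] <- NA_character_
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_id in design")
  bad <- df$replicate_of[!is.na(df$replicate_of) & !(df$replicate_of %in% df$sample_id)]
  if (length(bad)) stop("replicate_of refers to unknown sample: ", bad[1])
  # tissue_group must be a function of tissue
  tg <- unique(df[c("tissue", "tissue_group")])
  if (anyDuplicated(tg$tissue))
    stop("tissue_group is not a total mapping over tissues")
  rownames(df) <- NULL
  df
}

# Check design/matrix consistency; returns design restricted to matrix order.
check_design <- function(bm, design) {
  missing <- setdiff(design$sample_id, colnames(bm))
  if (length(missing))
    stop("design sample(s) absent from beta matrix: ",
         paste(utils::head(missing, 3), collapse = ", "))
  design
}

#' The 17-tissue somatic reference panel and its 12 functional groups
#'
#' The canonical autopsy-panel design this package emulates: 17 somatic
#' tissues collapsed into 12 tissue groups by merging functionally similar
#' pairs (the two adipose depots, the two aortas, the two arteries, bone with
#' joint cartilage, and red with yellow bone marrow).
#'
#' @return data.frame with columns `tissue`, `tissue_group` (17 rows,
#'   12 distinct groups).
#' @export
somatic_tissue_panel <- function() {
  data.frame(
    tissue = c("adipose_abdominal", "adipose_subcutaneous",
               "aorta_abdominal", "aorta_thoracic",
               "artery_coronary", "artery_splenic",
               "bone", "joint_cartilage",
               "bone_marrow_red", "bone_marrow_yellow",
               "gastric_mucosa", "lymph_node", "tonsil", "bladder",
               "gall_bladder", "medulla_oblongata", "ischiatic_nerve"),
    tissue_group = c("adipose", "adipose", "aorta", "aorta", "artery",
                     "artery", "bone_cartilage", "bone_cartilage",
                     "bone_marrow", "bone_marrow", "gastric_mucosa",
                     "lymph_node", "tonsil", "bladder", "gall_bladder",
                     "medulla_oblongata", "ischiatic_nerve"),
    stringsAsFactors = FALSE
  )
}
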