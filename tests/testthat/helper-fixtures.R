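# Small deterministic fixtures shared across test files.

tiny_annotation <- function() {
  probe_annotation(data.frame(
    probe_id = sprintf("cg%02d", 1:10),
    chromosome = c(rep("chr1", 5), rep("chrX", 2), rep("chr2", 3)),
    position = c(100L, 250L, 400L, 5000L, 5200L, 100L, 300L,
                 100L, 150L, 9000L),
    gene = c("A", "A", "A;B", "", "C", "D", "D", "E", "E", ""),
    gene_region = c("TSS200", "TSS1500", "TSS200;Body", "", "Body",
                    "Body", "UTR3", "FirstExon", "UTR5", ""),
    cgi_relation = c("Island", "Island", "Shore", "OpenSea", "OpenSea",
                     "Shelf", "OpenSea", "Island", "Island", "OpenSea"),
    snp_flag = c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE, FALSE,
                 FALSE, FALSE)))
}

tiny_betas <- function(ann = tiny_annotation(), n_samples = 4, seed = 99) {
  set.seed(seed)
  vals <- matrix(round(runif(nrow(ann) * n_samples), 4), nrow(ann),
                 dimnames = list(ann$probe_id,
                                 sprintf("s%02d", seq_len(n_samples))))
  beta_matrix(vals, ann)
}

tiny_design <- function(n_groups = 2, n_per_group = 2) {
  ids <- sprintf("s%02d", seq_len(n_groups * n_per_group))
  grp <- rep(sprintf("g%d", seq_len(n_groups)), each = n_per_group)
  sample_design(data.frame(sample_id = ids, tissue = grp,
                           tissue_group = grp,
                           individual_id = sprintf("i%d", seq_along(ids)),
                           replicate_of = NA_character_))
}

# design shaped like the reference panel: n_groups x n_ind, no replicates
grid_design <- function(n_groups = 12, n_ind = 4) {
  g <- expand.grid(group = sprintf("g%02d", seq_len(n_groups)),
                   ind = sprintf("i%d", seq_len(n_ind)),
                   stringsAsFactors = FALSE)
  sample_design(data.frame(sample_id = paste(g$group, g$ind, sep = "."),
                           tissue = g$group, tissue_group = g$group,
                           individual_id = g$ind,
                           replicate_of = NA_character_))
}

clamp_test <- function(x) pmin(pmax(x, 0), 1)

PROMOTER_REGIONS_TEST <- c("TSS1500", "TSS200", "UTR5", "FirstExon")

# manually-built segment table over a complete-case matrix: consecutive
# blocks of `len` probes (used for caller tests that do not need the MDL
# stage)
block_segments <- function(bm, ann, len = 3) {
  n <- nrow(bm) %/% len
  starts <- (seq_len(n) - 1L) * len + 1L
  ends <- starts + len - 1L
  segs <- data.frame(
    segment_id = sprintf("seg%04d", seq_len(n)), run_id = "run00001",
    chromosome = ann$chromosome[starts], start_idx = starts,
    end_idx = ends, start_pos = ann$position[starts],
    end_pos = ann$position[ends],
    probe_ids = vapply(seq_len(n), function(k)
      paste(rownames(bm)[starts[k]:ends[k]], collapse = ";"), ""),
    n_probes = len, dl_bits = NA_real_, stringsAsFactors = FALSE)
  attr(segs, "complete_probes") <- rownames(bm)
  segs
}
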