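test_that("test_segment matches the two-group closed form", {
  # 4 target samples at 0.1, 12 rest at 0.9, within-group sd 0.01
  set.seed(101)
  mu <- c(rep(0.1, 4), rep(0.9, 12))
  vals <- matrix(clamp_test(t(matrix(rep(mu, 3), 16)) + rnorm(48, 0, 0.01)),
                 3, 16)
  rownames(vals) <- paste0("p", 1:3)
  colnames(vals) <- paste0("s", 1:16)
  des <- sample_design(data.frame(
    sample_id = paste0("s", 1:16),
    tissue = c(rep("t", 4), rep(paste0("r", 1:3), each = 4)),
    tissue_group = c(rep("t", 4), rep(paste0("r", 1:3), each = 4)),
    individual_id = paste0("i", 1:16), replicate_of = NA_character_))
  res <- test_segment(vals, des, 1:3, "t")
  expect_lt(res$p_raw, 1e-10)
  expect_lt(abs(res$delta_beta - (-0.8)), 0.02)
  # oracle: F = t^2 from the per-sample segment means
  sm <- colMeans(vals)
  tt <- t.test(sm[1:4], sm[5:16], var.equal = TRUE)
  expect_equal(res$p_raw, tt$p.value, tolerance = 1e-9)

  # all values equal: zero between-group variance -> p = 1, delta 0
  flat <- matrix(0.5, 3, 16, dimnames = dimnames(vals))
  r0 <- test_segment(flat, des, 1:3, "t")
  expect_equal(r0$p_raw, 1)
  expect_equal(r0$delta_beta, 0)

  # group sizes < 2 are an error
  des1 <- des; des1$tissue_group[1] <- "solo"
  expect_error(test_segment(vals, des1, 1:3, "solo"), ">= 2")
})

test_that("call_tdmrs enforces min_probes, Bonferroni and direction", {
  cfg <- sim_config(n_probes = 400, n_chromosomes = 2, n_dmrs = 5,
                    dmr_length_probes = c(4, 10), seed = 44)
  ds <- simulate_dataset(cfg)
  segs <- segment_all(ds$betas, ds$ann, ds$design)
  calls <- call_tdmrs(ds$betas, ds$design, segs)
  expect_true(all(calls$n_probes >= 3))
  expect_true(all(calls$p_bonf < 0.05))
  expect_true(all(calls$p_bonf >= calls$p_raw))
  expect_true(all((calls$delta_beta > 0) == (calls$direction == "hyper")))
  # segments with < 3 probes are never tested
  small <- segs[segs$n_probes < 3, ]
  if (nrow(small))
    expect_false(any(calls$segment_id %in% small$segment_id))
  # global Bonferroni is at least as strict
  gcalls <- call_tdmrs(ds$betas, ds$design, segs, bonferroni = "global")
  expect_lte(nrow(gcalls), nrow(calls))
  # direction agrees with planted truth for recovered DMRs
  rec <- recovery_table(calls, ds$truth)
  expect_true(all(rec$per_dmr$detected))
})

test_that("technical replicates are collapsed before testing", {
  cfg <- sim_config(n_probes = 100, n_chromosomes = 1, n_dmrs = 0,
                    n_tissue_groups = 3, replicate_pairs = 2, seed = 45)
  ds <- simulate_dataset(cfg)
  cr <- collapse_replicates(ds$betas, ds$design)
  expect_equal(ncol(cr$bm), nrow(ds$design) - 2)
  expect_true(all(is.na(cr$design$replicate_of)))
  rep1 <- ds$design[!is.na(ds$design$replicate_of), ][1, ]
  expect_equal(cr$bm[, rep1$replicate_of],
               rowMeans(ds$betas[, c(rep1$replicate_of, rep1$sample_id)]))
})

test_that("planted one-segment DMR is called with high power", {
  # 5-probe hypo DMR, delta 0.4, 12 groups x 4 samples, kappa = 100
  called_hypo <- vapply(1:50, function(s) {
    set.seed(4000 + s)
    des <- grid_design(12, 4)
    mu <- matrix(0.5, 5, 48)
    mu[, des$tissue_group == "g01"] <- 0.1
    vals <- matrix(rbeta(5 * 48, mu * 100, (1 - mu) * 100), 5,
                   dimnames = list(paste0("p", 1:5), des$sample_id))
    ann <- probe_annotation(data.frame(
      probe_id = paste0("p", 1:5), chromosome = "chr1",
      position = seq(100L, 900L, 200L), gene = "", gene_region = "",
      cgi_relation = "OpenSea", snp_flag = FALSE))
    segs <- block_segments(vals, ann, len = 5)
    calls <- call_tdmrs(vals, des, segs)
    any(calls$target_group == "g01" & calls$direction == "hypo")
  }, TRUE)
  expect_gte(mean(called_hypo), 0.95)
})

test_that("annotate_calls applies promoter-dominant and majority-CGI rules", {
  ann <- tiny_annotation()
  base_call <- function(probes) data.frame(
    segment_id = "s1", chromosome = "chr1", start_idx = 1L, end_idx = 1L,
    start_pos = 1L, end_pos = 2L, probe_ids = paste(probes, collapse = ";"),
    n_probes = length(probes), target_group = "g", delta_beta = 0.5,
    direction = "hyper", p_raw = 1e-6, p_bonf = 1e-4,
    stringsAsFactors = FALSE)
  # probes with regions {Body, TSS200} -> Promoter; genes are the union
  a <- annotate_calls(base_call(c("cg03", "cg05")), ann)
  expect_equal(a$location_class, "Promoter")
  expect_equal(a$genes, "A;B;C")
  # only Body/UTR3 entries -> Body
  b <- annotate_calls(base_call(c("cg06", "cg07")), ann)
  expect_equal(b$location_class, "Body")
  # all intergenic -> Intergenic with empty genes
  c1 <- annotate_calls(base_call("cg04"), ann)
  expect_equal(c1$location_class, "Intergenic")
  expect_equal(c1$genes, "")
  # majority CGI: {Island, Island, Shore} -> Island
  d <- annotate_calls(base_call(c("cg01", "cg02", "cg03")), ann)
  expect_equal(d$cgi_class, "Island")
  # tie {Island, Shore} -> Island (priority order)
  e <- annotate_calls(base_call(c("cg01", "cg03")), ann)
  expect_equal(e$cgi_class, "Island")
  expect_error(annotate_calls(base_call("nope"), ann), "nope")
})

test_that("summarize_calls counts per group and cross-tabulates", {
  empty <- summarize_calls(annotate_calls(
    call_tdmrs(tiny_betas(), tiny_design(),
               block_segments(tiny_betas(), tiny_annotation())[0, ]),
    tiny_annotation()))
  expect_equal(empty$n_calls, 0)
  expect_equal(nrow(empty$per_group), 0)

  # constructed calls: 3 hyper (2 with genes) + 2 hypo (1 with gene) in g1
  calls <- data.frame(
    segment_id = paste0("s", 1:5), chromosome = "chr1",
    start_idx = 1L, end_idx = 3L, start_pos = 1L, end_pos = 9L,
    probe_ids = "x", n_probes = 3L, target_group = "g1",
    delta_beta = c(.4, .4, .4, -.4, -.4),
    direction = c("hyper", "hyper", "hyper", "hypo", "hypo"),
    p_raw = 1e-9, p_bonf = 1e-6,
    genes = c("A", "B", "", "C", ""),
    location_class = c("Promoter", "Body", "Intergenic", "Promoter", "Body"),
    cgi_class = c("Island", "OpenSea", "Shore", "Island", "Shelf"),
    stringsAsFactors = FALSE)
  s <- summarize_calls(calls)
  expect_equal(s$per_group$hyper, 3)
  expect_equal(s$per_group$hyper_gene, 2)
  expect_equal(s$per_group$hypo, 2)
  expect_equal(s$per_group$hypo_gene, 1)
  expect_equal(sum(s$crosstab), 5)
  expect_true(all(s$per_group$hyper_gene <= s$per_group$hyper))
})

test_that("fisher_2x2 matches the exact oracle and its symmetries", {
  expect_equal(fisher_2x2(1, 9, 11, 3), 0.002759456, tolerance = 1e-6)
  expect_equal(fisher_2x2(5, 5, 5, 5), 1)
  expect_equal(fisher_2x2(0, 0, 0, 0), 1)
  set.seed(55)
  for (i in 1:25) {
    tb <- sample(0:30, 4, replace = TRUE)
    if (sum(tb) == 0) next
    p <- fisher_2x2(tb[1], tb[2], tb[3], tb[4])
    expect_gt(p, 0); expect_lte(p, 1)
    # transposition invariance
    expect_equal(p, fisher_2x2(tb[1], tb[3], tb[2], tb[4]), tolerance = 1e-12)
    # independent oracle
    expect_equal(p, fisher.test(matrix(tb, 2, byrow = TRUE))$p.value,
                 tolerance = 1e-7)
  }
})
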