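test_that("classify_invariant uses strict thresholds", {
  bm <- rbind(h = c(0.95, 0.99, 0.91),
              v = c(0.95, 0.90, 0.99),   # 0.90 is not > 0.9
              l = c(0.05, 0.01, 0.099),
              v2 = c(0.05, 0.10, 0.02),  # 0.10 is not < 0.1
              m = c(0.5, 0.6, 0.4))
  colnames(bm) <- paste0("s", 1:3)
  lab <- classify_invariant(bm)
  expect_equal(unname(c(lab)), c("InvariantHyper", "Variable", "InvariantHypo",
                              "Variable", "Variable"))
  # partition property
  expect_equal(sum(table(lab)), nrow(bm))
  # all-missing probe is Variable and logged
  bm2 <- rbind(bm, allna = NA_real_)
  lab2 <- classify_invariant(bm2)
  expect_equal(unname(lab2["allna"]), "Variable")
  expect_equal(attr(lab2, "n_all_missing"), 1L)
})

test_that("labeled invariant fraction matches the generative oracle", {
  cfg <- sim_config(n_probes = 1500, n_dmrs = 0, seed = 61)
  ds <- simulate_dataset(cfg)
  # oracle: P(probe labeled hyper) = prod_s P(beta > 0.9 | mu_ps, kappa)
  k <- cfg$noise_concentration
  p_hyper <- apply(ds$mu, 1, function(m)
    prod(pbeta(0.9, m * k, (1 - m) * k, lower.tail = FALSE)))
  f_expected <- mean(p_hyper)
  lab <- classify_invariant(ds$betas)
  f_observed <- mean(lab == "InvariantHyper")
  expect_lt(abs(f_observed - f_expected), 0.02)
})

test_that("distribution_by_region counts, percentages and histograms", {
  ann <- tiny_annotation()
  d <- distribution_by_region(ann, "gene_region")
  # multi-counting: cg03 contributes to TSS200 and Body
  expect_equal(d$counts$count[d$counts$class == "TSS200"], 2)
  expect_equal(d$counts$count[d$counts$class == "Intergenic"], 2)
  expect_equal(sum(d$counts$count), 11)  # 10 probes + 1 extra entry
  expect_lt(abs(sum(d$counts$percent) - 100), 0.1 * nrow(d$counts))
  # single class -> 100.0%
  one <- distribution_by_region(ann[ann$cgi_relation == "Island", ],
                                "cgi_relation")
  expect_equal(one$counts$percent, 100.0)
  # histogram bins: values on the 0.1 boundary go to the upper bin
  bm <- matrix(c(0.05, 0.1, 0.95, 1.0), 2, 2,
               dimnames = list(c("cg01", "cg02"), c("a", "b")))
  h <- distribution_by_region(ann[1:2, ], "cgi_relation", bm = bm)
  expect_equal(sum(h$histogram), 4)
  expect_equal(unname(h$histogram["Island", 1]), 1)   # 0.05 in [0, 0.1)
  expect_equal(unname(h$histogram["Island", 2]), 1)   # 0.10 in [0.1, 0.2)
  expect_equal(unname(h$histogram["Island", 10]), 2)  # 0.95 and 1.0
  # cgi_by_genic split
  g <- distribution_by_region(ann, "cgi_by_genic")
  expect_true("intergenic.OpenSea" %in% g$counts$class)
})

test_that("tissue profiles, correlations and clustering behave", {
  ann <- tiny_annotation()
  bm <- tiny_betas(ann)
  des <- tiny_design(2, 2)
  prof <- tissue_mean_profiles(bm, des, by = "tissue_group")
  expect_equal(unname(prof["g1", ]), unname(rowMeans(bm[, 1:2])))
  # one sample per tissue: identity
  des1 <- tiny_design(4, 1)
  prof1 <- tissue_mean_profiles(bm, des1, by = "tissue_group")
  expect_equal(unname(t(prof1)), unname(bm))

  # correlation matrix properties
  p <- rbind(a = c(0.1, 0.5, 0.9), b = c(0.1, 0.5, 0.9),
             c = 1 - c(0.1, 0.5, 0.9))
  cm <- tissue_correlation_matrix(p)
  expect_equal(cm["a", "b"], 1)
  expect_equal(cm["a", "c"], -1)
  expect_true(isSymmetric(cm))
  expect_equal(unname(diag(cm)), rep(1, 3))
  pz <- rbind(a = c(0.5, 0.5), b = c(0.1, 0.9))
  expect_error(tissue_correlation_matrix(pz), "a")

  # clustering: close pair merges first; ((A,B),C) topology
  set.seed(71)
  base <- runif(60)
  p3 <- rbind(A = base + rnorm(60, 0, 0.01), B = base + rnorm(60, 0, 0.01),
              C = runif(60))
  p3 <- clamp_test(p3)
  cl <- cluster_tissues(p3)
  expect_equal(sort(cl$hclust$labels[-cl$merge[1, ]]), c("A", "B"))
  tr <- ape::read.tree(text = cl$newick)
  expect_setequal(tr$tip.label[tr$edge[tr$edge[, 1] == max(tr$edge), 2]],
                  c("A", "B"))
  # invariant to row order
  cl2 <- cluster_tissues(p3[c(3, 1, 2), ])
  expect_identical(cl$newick, cl2$newick)
  # 2 tissues: single merge at their distance
  cl3 <- cluster_tissues(p3[1:2, ])
  expect_equal(length(cl3$height), 1)
  expect_equal(cl3$height, 1 - cor(p3[1, ], p3[2, ]))
})

test_that("variance_explained decomposes and matches the null expectation", {
  des <- grid_design(3, 4)   # 3 groups x 4 individuals
  # betas fully determined by tissue -> r2_tissue = 1
  bm <- matrix(rep(c(0.1, 0.5, 0.9), 4), 5, 12, byrow = TRUE,
               dimnames = list(paste0("p", 1:5), des$sample_id))
  ve <- variance_explained(bm, des, "tissue_group")
  expect_equal(unname(ve$r2), rep(1, 5))
  # constant probe -> r2 = 0, logged
  bm0 <- bm; bm0[1, ] <- 0.5
  ve0 <- variance_explained(bm0, des, "tissue_group")
  expect_equal(unname(ve0$r2[1]), 0)
  expect_equal(attr(ve0, "n_zero_ss"), 1L)
  expect_true(all(ve0$r2 >= 0 & ve0$r2 <= 1))

  # random labels: mean R2 ~ (levels - 1)/(n - 1)
  set.seed(73)
  bmr <- matrix(rbeta(2000 * 12, 30, 30), 2000,
                dimnames = list(paste0("p", 1:2000), des$sample_id))
  shuf <- des
  shuf$tissue_group <- sample(shuf$tissue_group)
  ver <- variance_explained(bmr, shuf, "tissue_group")
  expect_lt(abs(ver$mean_r2 - 2 / 11), 0.02)

  # simulated tissue_sd >> individual_sd recovers the ordering
  ds <- simulate_dataset(sim_config(n_probes = 800, n_dmrs = 0,
                                    tissue_sd = 0.5, individual_sd = 0.1,
                                    seed = 74))
  rt <- variance_explained(ds$betas, ds$design, "tissue_group")
  ri <- variance_explained(ds$betas, ds$design, "individual_id")
  expect_gt(rt$mean_r2, ri$mean_r2)
})

test_that("variance_by_annotation stratifies and flags empty classes", {
  ds <- simulate_dataset(sim_config(n_probes = 400, n_dmrs = 0,
                                    tissue_sd = 0.3, seed = 75))
  va <- variance_by_annotation(ds$betas, ds$design, ds$ann,
                               grouping = "cgi_relation")
  expect_true(all(va$summary$class %in%
                    c("Island", "Shore", "Shelf", "OpenSea")))
  expect_equal(sum(va$summary$n), nrow(ds$betas))
  # single-class annotation equals plain variance_explained
  ann1 <- ds$ann; ann1$cgi_relation <- "Island"
  va1 <- variance_by_annotation(ds$betas, ds$design, ann1,
                                grouping = "cgi_relation")
  ve <- variance_explained(ds$betas, ds$design, "tissue_group")
  expect_equal(va1$summary$mean_r2, ve$mean_r2)
})

test_that("consecutive probe correlation separates gap strata", {
  # duplicate adjacent probes: PCC 1
  ann <- probe_annotation(data.frame(
    probe_id = c("a", "b"), chromosome = "chr1", position = c(100L, 200L),
    gene = "", gene_region = "", cgi_relation = "OpenSea",
    snp_flag = FALSE))
  v <- matrix(rep(c(0.1, 0.4, 0.8, 0.3), 2), 2, 4, byrow = TRUE,
              dimnames = list(c("a", "b"), paste0("s", 1:4)))
  cpc <- consecutive_probe_correlation(v, ann)
  expect_equal(cpc$mean_short, 1)
  # independent noise: stratum mean near 0 (1,000 pairs)
  set.seed(77)
  n <- 1001
  ann2 <- probe_annotation(data.frame(
    probe_id = sprintf("p%04d", 1:n), chromosome = "chr1",
    position = seq(100L, by = 200L, length.out = n), gene = "",
    gene_region = "", cgi_relation = "OpenSea", snp_flag = FALSE))
  v2 <- matrix(rbeta(n * 12, 5, 5), n,
               dimnames = list(ann2$probe_id, paste0("s", 1:12)))
  cpc2 <- consecutive_probe_correlation(v2, ann2)
  expect_lt(abs(cpc2$mean_short), 0.05)
  # simulator with cluster-shared latent means: short > long
  ds <- simulate_dataset(sim_config(n_probes = 2000, individual_sd = 0.25,
                                    n_dmrs = 0, seed = 78))
  cpc3 <- consecutive_probe_correlation(ds$betas, ds$ann)
  expect_gt(cpc3$mean_short, cpc3$mean_long)
})

test_that("replicate concordance is reported per declared pair", {
  ann <- tiny_annotation()
  bm <- tiny_betas(ann)
  des <- tiny_design(2, 2)
  expect_equal(nrow(replicate_concordance(bm, des)), 0)
  des$replicate_of[2] <- "s01"
  bm[, "s02"] <- bm[, "s01"]
  rc <- replicate_concordance(bm, des)
  expect_equal(rc$pcc, 1)
  # simulator at kappa = 200: PCC > 0.99
  ds <- simulate_dataset(sim_config(n_probes = 1000, replicate_pairs = 2,
                                    noise_concentration = 200, seed = 79))
  rc2 <- replicate_concordance(ds$betas, ds$design)
  expect_equal(nrow(rc2), 2)
  expect_true(all(rc2$pcc > 0.99))
})
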