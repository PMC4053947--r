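#' Simulation configuration for 450K-like methylation data
#'
#' Builds a validated configuration for the synthetic-data generator. The
#' defaults emulate the structure of a 17-tissue / 4-individual somatic
#' autopsy panel measured on a 450K-style array: probes fall in tight
#' clusters (short geometric gaps, mean 150 bp) separated by long gaps of at
#' least 3 kb; each probe carries a gene-region and CpG-island class whose
#' joint distribution mirrors the array manifest (promoter probes are
#' CGI-dense, gene-body and intergenic probes are open-sea-dense); baseline
#' methylation is bimodal (promoter islands near 0.05, gene-body open sea
#' near 0.90); tDMRs are planted as contiguous probe blocks inside clusters.
#'
#' @param n_probes total number of probes.
#' @param n_chromosomes chromosomes to spread probes over.
#' @param w_cluster probability that a consecutive gap is a short
#'   within-cluster gap; `1 - w_cluster` of gaps are long (>= 3 kb) and break
#'   the cluster.
#' @param gap_short_mean mean of the short within-cluster gap (bp).
#' @param gap_long_min,gap_long_mean minimum and mean extra spacing of
#'   between-cluster gaps (bp).
#' @param region_fractions named fractions over TSS1500, TSS200, UTR5,
#'   FirstExon, Body, UTR3, Intergenic; must sum to 1.
#' @param cgi_fractions 3 x 4 matrix of CGI-class fractions (rows promoter,
#'   body, intergenic; columns Island, Shore, Shelf, OpenSea), each row
#'   summing to 1. A single named vector is recycled to all three rows.
#' @param baseline_means 3 x 4 matrix of mean beta by (region class, CGI
#'   class); anchors: promoter-island 0.05, body-open-sea 0.90.
#' @param snp_fraction fraction of probes flagged as SNP-overlapping.
#' @param n_tissue_groups,n_individuals,replicate_pairs design shape
#'   (defaults 12 groups x 4 individuals + 2 technical replicate pairs).
#' @param noise_concentration beta-distribution concentration kappa (> 2);
#'   observed values are Beta(mu*kappa, (1-mu)*kappa).
#' @param individual_sd sd of the per-(probe, individual) logit-scale random
#'   effect.
#' @param tissue_sd sd of a per-(probe, group) logit-scale effect; default 0
#'   so that without planted tDMRs the groups differ only by noise.
#' @param n_dmrs number of planted tDMRs.
#' @param dmr_length_probes inclusive range of planted DMR lengths (probes).
#' @param dmr_delta inclusive range of the planted beta-scale effect.
#' @param dmr_direction_prob probability a planted DMR is hypomethylated in
#'   its target group (flipped when the local baseline leaves no headroom).
#' @param seed integer seed; mandatory for reproducibility.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_probes = 5000,
                       n_chromosomes = 5,
                       w_cluster = 0.9,
                       gap_short_mean = 150,
                       gap_long_min = 3000,
                       gap_long_mean = 20000,
                       region_fractions = c(TSS1500 = 0.14, TSS200 = 0.10,
                                            UTR5 = 0.12, FirstExon = 0.05,
                                            Body = 0.30, UTR3 = 0.03,
                                            Intergenic = 0.26),
                       cgi_fractions = NULL,
                       baseline_means = NULL,
                       snp_fraction = 0.01,
                       n_tissue_groups = 12,
                       n_individuals = 4,
                       replicate_pairs = 2,
                       noise_concentration = 150,
                       individual_sd = 0.1,
                       tissue_sd = 0,
                       n_dmrs = 20,
                       dmr_length_probes = c(3, 20),
                       dmr_delta = c(0.3, 0.5),
                       dmr_direction_prob = 0.5,
                       seed = 1L) {
  if (is.null(cgi_fractions)) {
    cgi_fractions <- rbind(
      promoter   = c(Island = 0.72, Shore = 0.20, Shelf = 0.02, OpenSea = 0.06),
      body       = c(Island = 0.14, Shore = 0.18, Shelf = 0.13, OpenSea = 0.55),
      intergenic = c(Island = 0.10, Shore = 0.15, Shelf = 0.15, OpenSea = 0.60))
  } else if (is.null(dim(cgi_fractions))) {
    cgi_fractions <- rbind(promoter = cgi_fractions, body = cgi_fractions,
                           intergenic = cgi_fractions)
  }
  if (is.null(baseline_means)) {
    # anchors: promoter-island 0.05, gene-body open sea 0.90; shelves sit
    # near full methylation on somatic arrays, open-sea intergenic highest
    baseline_means <- rbind(
      promoter   = c(Island = 0.05, Shore = 0.20, Shelf = 0.70, OpenSea = 0.65),
      body       = c(Island = 0.15, Shore = 0.50, Shelf = 0.90, OpenSea = 0.90),
      intergenic = c(Island = 0.10, Shore = 0.45, Shelf = 0.92, OpenSea = 0.93))
  }
  stopifnot(abs(sum(region_fractions) - 1) < 1e-8,
            all(abs(rowSums(cgi_fractions) - 1) < 1e-8),
            noise_concentration > 2,
            all(dmr_delta > 0), all(dmr_delta < 1),
            dmr_length_probes[1] >= 1,
            w_cluster >= 0, w_cluster <= 1)
  cfg <- list(n_probes = n_probes, n_chromosomes = n_chromosomes,
              w_cluster = w_cluster, gap_short_mean = gap_short_mean,
              gap_long_min = gap_long_min, gap_long_mean = gap_long_mean,
              region_fractions = region_fractions,
              cgi_fractions = cgi_fractions, baseline_means = baseline_means,
              snp_fraction = snp_fraction,
              n_tissue_groups = n_tissue_groups,
              n_individuals = n_individuals,
              replicate_pairs = replicate_pairs,
              noise_concentration = noise_concentration,
              individual_sd = individual_sd, tissue_sd = tissue_sd,
              n_dmrs = n_dmrs, dmr_length_probes = dmr_length_probes,
              dmr_delta = dmr_delta,
              dmr_direction_prob = dmr_direction_prob,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

# promoter / body / intergenic coarse class of a probe
region_class3 <- function(region) {
  ifelse(region == "Intergenic", "intergenic",
         ifelse(region %in% PROMOTER_REGIONS, "promoter", "body"))
}

#' Generate a synthetic probe annotation
#'
#' Positions are laid down chromosome by chromosome with a two-component gap
#' mixture (short within-cluster, long between-cluster); genic probes are
#' assigned a per-cluster gene symbol; a small fraction of probes receives a
#' second gene entry to exercise the semicolon-list contract.
#'
#' @param cfg a [sim_config()]. The seed used is `cfg$seed` unless the caller
#'   has already seeded the RNG and passes `seed = FALSE`.
#' @param seed set to FALSE to draw from the current RNG state.
#' @return annotation data.frame (see [probe_annotation()]).
#' @export
generate_annotation <- function(cfg, seed = TRUE) {
  if (isTRUE(seed)) set.seed(cfg$seed)
  n <- cfg$n_probes
  if (n == 0)
    return(probe_annotation(data.frame(
      probe_id = character(), chromosome = character(), position = integer(),
      gene = character(), gene_region = character(),
      cgi_relation = character(), snp_flag = logical())))
  per_chr <- diff(round(seq(0, n, length.out = cfg$n_chromosomes + 1)))
  rows <- vector("list", cfg$n_chromosomes)
  probe0 <- 0L
  for (ci in seq_len(cfg$n_chromosomes)) {
    np <- per_chr[ci]
    if (np == 0) next
    long <- stats::runif(np) > cfg$w_cluster
    gaps <- ifelse(long,
                   cfg$gap_long_min +
                     round(stats::rexp(np, 1 / cfg$gap_long_mean)),
                   1L + stats::rgeom(np, 1 / cfg$gap_short_mean))
    pos <- cumsum(c(1000L, gaps[-1]))
    cluster <- cumsum(c(TRUE, long[-1]))
    # annotation classes come in contiguous zones (CpG islands, shores and
    # gene regions are blocks of consecutive probes, not iid labels)
    zone_len <- 3L + stats::rgeom(np, 1 / 10)
    zone <- rep(seq_along(zone_len), zone_len)[seq_len(np)]
    zone <- cumsum(c(TRUE, zone[-1] != zone[-np] | cluster[-1] != cluster[-np]))
    nz <- max(zone)
    zregion <- sample(names(cfg$region_fractions), nz, replace = TRUE,
                      prob = cfg$region_fractions)
    zrc3 <- region_class3(zregion)
    zcgi <- character(nz)
    for (cls in rownames(cfg$cgi_fractions)) {
      k <- zrc3 == cls
      if (any(k))
        zcgi[k] <- sample(colnames(cfg$cgi_fractions), sum(k),
                          replace = TRUE, prob = cfg$cgi_fractions[cls, ])
    }
    region <- zregion[zone]
    cgi <- zcgi[zone]
    gene <- ifelse(region == "Intergenic", "",
                   sprintf("GENE%02d_%04d", ci, cluster))
    gene_region <- ifelse(region == "Intergenic", "", region)
    # occasional probes annotate to two overlapping genes
    two <- which(gene != "" & stats::runif(np) < 0.02)
    if (length(two)) {
      second <- sample(GENE_REGIONS, length(two), replace = TRUE)
      gene[two] <- paste0(gene[two], ";", gene[two], "B")
      gene_region[two] <- paste0(gene_region[two], ";", second)
    }
    rows[[ci]] <- data.frame(
      probe_id = sprintf("cg%07d", probe0 + seq_len(np)),
      chromosome = sprintf("chr%d", ci),
      position = as.integer(pos),
      gene = gene, gene_region = gene_region, cgi_relation = cgi,
      snp_flag = stats::runif(np) < cfg$snp_fraction,
      stringsAsFactors = FALSE)
    probe0 <- probe0 + np
  }
  probe_annotation(do.call(rbind, rows))
}

#' Generate the sample design for a simulation
#'
#' One tissue per tissue group, `n_individuals` samples per tissue, plus
#' `replicate_pairs` technical replicates of the first samples. Group names
#' come from [somatic_tissue_panel()] when 12 groups are requested.
#'
#' @param cfg a [sim_config()].
#' @return design data.frame (see [sample_design()]).
#' @export
generate_design <- function(cfg) {
  groups <- if (cfg$n_tissue_groups == 12)
    unique(somatic_tissue_panel()$tissue_group)
  else sprintf("group%02d", seq_len(cfg$n_tissue_groups))
  inds <- sprintf("I%d", seq_len(cfg$n_individuals))
  df <- expand.grid(tissue = groups, individual_id = inds,
                    stringsAsFactors = FALSE)
  df <- data.frame(sample_id = paste(df$tissue, df$individual_id, sep = "."),
                   tissue = df$tissue, tissue_group = df$tissue,
                   individual_id = df$individual_id,
                   replicate_of = NA_character_, stringsAsFactors = FALSE)
  if (cfg$replicate_pairs > 0) {
    k <- seq_len(min(cfg$replicate_pairs, nrow(df)))
    rep_rows <- df[k, , drop = FALSE]
    rep_rows$replicate_of <- rep_rows$sample_id
    rep_rows$sample_id <- paste0(rep_rows$sample_id, ".rep")
    df <- rbind(df, rep_rows)
  }
  sample_design(df)
}

#' Generate a beta-value matrix with planted tDMRs
#'
#' Each observation is drawn as Beta(mu * kappa, (1 - mu) * kappa) with
#' `mu = plogis(qlogis(baseline) + individual effect + tissue effect + DMR
#' shift)`. DMRs are planted as contiguous probe blocks inside < 3 kb-gap
#' runs only (so they are in-principle detectable), do not overlap, and shift
#' the target group's logit so the expected beta-scale effect equals the
#' drawn delta; the direction is flipped when the local baseline leaves no
#' headroom for the requested shift. Technical replicates share `mu` with
#' their source sample and differ only by measurement noise.
#'
#' @param cfg a [sim_config()].
#' @param ann annotation from [generate_annotation()].
#' @param design design from [generate_design()].
#' @param seed set to FALSE to draw from the current RNG state.
#' @return list with elements `betas` (beta matrix), `truth` (planted-DMR
#'   table: dmr_id, chromosome, start_idx, end_idx, start_pos, end_pos,
#'   n_probes, target_group, direction, delta, probe_ids), and `mu` (latent
#'   probe x sample means).
#' @export
generate_betas <- function(cfg, ann, design, seed = TRUE) {
  if (isTRUE(seed)) set.seed(cfg$seed + 1L)
  np <- nrow(ann)
  rc3 <- region_class3(primary_region(ann))
  base <- cfg$baseline_means[cbind(rc3, ann$cgi_relation)]
  primary <- design[is.na(design$replicate_of), , drop = FALSE]
  inds <- unique(primary$individual_id)
  groups <- unique(primary$tissue_group)
  eta <- matrix(stats::qlogis(clamp(base)), np, nrow(primary))
  # random effects are shared by all probes of a cluster (< 3 kb run):
  # neighbouring CpGs move together across samples, which is what gives
  # real arrays their short-gap inter-probe correlation
  runs0 <- if (np > 0) build_runs(ann) else NULL
  cl <- if (np > 0) rep(seq_len(nrow(runs0)),
                        runs0$end_idx - runs0$start_idx + 1L) else integer(0)
  ncl <- max(cl, 0L)
  ind_eff <- matrix(stats::rnorm(ncl * length(inds), 0, cfg$individual_sd),
                    ncl, length(inds), dimnames = list(NULL, inds))
  tis_eff <- if (cfg$tissue_sd > 0)
    matrix(stats::rnorm(ncl * length(groups), 0, cfg$tissue_sd),
           ncl, length(groups), dimnames = list(NULL, groups))
  else matrix(0, ncl, length(groups), dimnames = list(NULL, groups))
  eta <- eta + ind_eff[cl, primary$individual_id, drop = FALSE] +
    tis_eff[cl, primary$tissue_group, drop = FALSE]

  # ---- plant DMRs inside <3 kb runs, non-overlapping ----
  truth <- data.frame(dmr_id = character(), chromosome = character(),
                      start_idx = integer(), end_idx = integer(),
                      start_pos = integer(), end_pos = integer(),
                      n_probes = integer(), target_group = character(),
                      direction = character(), delta = numeric(),
                      probe_ids = character(), stringsAsFactors = FALSE)
  if (cfg$n_dmrs > 0 && np > 0) {
    # candidate placements are homogeneous zones (constant baseline class)
    # within a run: a planted tDMR is a coherent block, as real ones are
    zone <- cumsum(c(TRUE, rc3[-1] != rc3[-np] |
                       ann$cgi_relation[-1] != ann$cgi_relation[-np] |
                       cl[-1] != cl[-np]))
    zstart <- which(c(TRUE, zone[-1] != zone[-np]))
    zend <- c(zstart[-1] - 1L, np)
    used <- rep(FALSE, np)
    placed <- 0L
    attempts <- 0L
    while (placed < cfg$n_dmrs && attempts < cfg$n_dmrs * 100) {
      attempts <- attempts + 1L
      len <- sample(seq(cfg$dmr_length_probes[1], cfg$dmr_length_probes[2]), 1)
      ok <- which(zend - zstart + 1L >= len)
      if (!length(ok)) next
      zi <- ok[sample.int(length(ok), 1)]
      zlen <- zend[zi] - zstart[zi] + 1L
      s <- zstart[zi] + sample.int(zlen - len + 1L, 1) - 1L
      idx <- s:(s + len - 1L)
      if (any(used[idx])) next
      delta <- stats::runif(1, cfg$dmr_delta[1], cfg$dmr_delta[2])
      hypo <- stats::runif(1) < cfg$dmr_direction_prob
      mb <- mean(base[idx])
      if (hypo && mb < delta + 0.05) hypo <- FALSE
      if (!hypo && mb > 1 - delta - 0.05) hypo <- TRUE
      tgt_group <- sample(groups, 1)
      target_beta <- clamp(base[idx] + ifelse(hypo, -delta, delta), 0.01, 0.99)
      shift <- stats::qlogis(target_beta) - stats::qlogis(clamp(base[idx]))
      cols <- primary$tissue_group == tgt_group
      eta[idx, cols] <- eta[idx, cols] + shift
      used[idx] <- TRUE
      placed <- placed + 1L
      truth <- rbind(truth, data.frame(
        dmr_id = sprintf("dmr%03d", placed),
        chromosome = ann$chromosome[s],
        start_idx = s, end_idx = s + len - 1L,
        start_pos = ann$position[s], end_pos = ann$position[s + len - 1L],
        n_probes = len, target_group = tgt_group,
        direction = if (hypo) "hypo" else "hyper", delta = delta,
        probe_ids = paste(ann$probe_id[idx], collapse = ";"),
        stringsAsFactors = FALSE))
    }
  }

  mu <- stats::plogis(eta)
  colnames(mu) <- primary$sample_id
  # replicates share the latent mean of their source sample
  mu_all <- mu[, ifelse(is.na(design$replicate_of), design$sample_id,
                        design$replicate_of), drop = FALSE]
  colnames(mu_all) <- design$sample_id
  k <- cfg$noise_concentration
  vals <- matrix(stats::rbeta(length(mu_all), mu_all * k, (1 - mu_all) * k),
                 nrow = np, dimnames = list(ann$probe_id, design$sample_id))
  list(betas = beta_matrix(vals), truth = truth, mu = mu_all)
}

# first (primary) gene-region label of each probe, "Intergenic" when genic
# annotation is absent
primary_region <- function(ann) {
  first <- vapply(strsplit(ann$gene_region, ";", fixed = TRUE),
                  function(x) if (length(x)) x[1] else "", "")
  ifelse(ann$gene == "", "Intergenic", first)
}

#' Generate a full synthetic dataset
#'
#' Convenience wrapper: annotation, design, betas and truth under one seed.
#'
#' @param cfg a [sim_config()].
#' @return list with `ann`, `design`, `betas`, `truth`, `mu`, `cfg`.
#' @export
simulate_dataset <- function(cfg) {
  ann <- generate_annotation(cfg)
  design <- generate_design(cfg)
  sim <- generate_betas(cfg, ann, design)
  c(list(ann = ann, design = design, cfg = cfg), sim)
}

#' Generate expression values coupled to gene-level methylation
#'
#' For each gene the standardized (across tissues) methylation profile is
#' mixed with Gaussian noise so that the expected Pearson correlation between
#' methylation and expression equals `rho`; the result is placed on a
#' log2-expression-like scale (affine, so correlations are unchanged). Genes
#' whose methylation profile has zero variance get pure noise.
#'
#' @param gene_beta gene x tissue matrix of mean beta values.
#' @param rho target correlation in \[-1, 1\].
#' @param seed optional integer seed.
#' @return gene x tissue expression matrix.
#' @export
generate_expression <- function(gene_beta, rho, seed = NULL) {
  stopifnot(rho >= -1, rho <= 1)
  if (!is.null(seed)) set.seed(seed)
  nt <- ncol(gene_beta)
  z <- t(apply(gene_beta, 1, function(x) {
    s <- stats::sd(x)
    if (is.na(s) || s == 0) rep(0, length(x)) else (x - mean(x)) / s
  }))
  noise <- matrix(stats::rnorm(length(gene_beta)), nrow(gene_beta), nt)
  expr <- rho * z + sqrt(1 - rho^2) * noise
  expr <- 8 + 2 * expr
  dimnames(expr) <- dimnames(gene_beta)
  expr
}
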