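test_that("configuration rejects impossible generative models", {
  expect_error(sim_config(latent_loading_endoAtoh1 = -1), "non-negative")
  expect_error(sim_config(latent_noise_sd = 0), "> 0")
  expect_error(sim_config(n_genes = 100,
                          n_marker_genes_per_population = 20),
               "gene budget")
  expect_error(sim_config(continuum_populations = c("SC1", "nope")),
               "subset")
})

test_that("the same seed reproduces the dataset exactly", {
  a <- gen_umi_dataset(sim_config(seed = 11, cells_per_population = 20,
                                  n_genes = 200))
  b <- gen_umi_dataset(sim_config(seed = 11, cells_per_population = 20,
                                  n_genes = 200))
  expect_identical(a$counts, b$counts)
  expect_identical(a$cell_meta, b$cell_meta)
  c <- gen_umi_dataset(sim_config(seed = 12, cells_per_population = 20,
                                  n_genes = 200))
  expect_false(identical(a$counts, c$counts))
})

test_that("populations given zero cells are absent", {
  cfg <- sim_config(cells_per_population = c(SC1 = 10, SC2 = 0, cHC1 = 10,
                                             cHC2 = 10, cHC3 = 10, OHC = 0,
                                             IHC = 5),
                    n_genes = 200, n_marker_genes_per_population = 5)
  ds <- gen_umi_dataset(cfg)
  expect_false(any(ds$cell_meta$true_population %in% c("SC2", "OHC")))
  expect_equal(sum(ds$cell_meta$true_population == "IHC"), 5)
})

test_that("flagged special features exist exactly once", {
  ds <- gen_umi_dataset(sim_config(seed = 4, cells_per_population = 15,
                                   n_genes = 300))
  for (f in ds$special_features)
    expect_equal(sum(rownames(ds$counts) == f), 1)
})

test_that("in the noiseless limit the two Atoh1 features are collinear", {
  cfg <- sim_config(seed = 5, cells_per_population = 50, n_genes = 300,
                    latent_noise_sd = 1e-9,
                    latent_loading_endoAtoh1 = 3, latent_loading_Atoh1HA = 3)
  ds <- gen_umi_dataset(cfg)
  lat <- ds$truth$atoh1_log2mean
  cont <- !is.na(ds$cell_meta$true_latent)
  expect_gt(cor(lat[cont, 1], lat[cont, 2])^2, 0.999999)
})

test_that("marker genes have the highest generative mean in their own population", {
  ds <- gen_umi_dataset(sim_config(seed = 6, cells_per_population = 40,
                                   n_genes = 400,
                                   n_marker_genes_per_population = 10))
  pop <- ds$cell_meta$true_population
  mk <- ds$truth$marker_of
  mu <- ds$truth$expected
  ## generative mean of expected counts per population, per marker gene
  for (g in names(mk)[!is.na(mk)]) {
    own <- mean(mu[g, pop == mk[g]])
    others <- vapply(setdiff(unique(pop), mk[g]), function(p)
      mean(mu[g, pop == p]), 0)
    expect_true(all(own > others))
  }
})

test_that("the latent coordinate is monotone across the continuum order", {
  cfg <- sim_config(seed = 7, cells_per_population = 30, n_genes = 300)
  ds <- gen_umi_dataset(cfg)
  s <- ds$cell_meta$true_latent
  pop <- ds$cell_meta$true_population
  rng <- lapply(cfg$continuum_populations, function(p) range(s[pop == p]))
  for (k in seq_len(length(rng) - 1))
    expect_lt(rng[[k]][2], rng[[k + 1]][1])
  expect_true(all(is.na(s[!pop %in% cfg$continuum_populations])))
})

test_that("empirical per-gene means match the generative means (MC oracle)", {
  ## pool counts and generative expectations over 10 seeds; the pooled
  ## empirical mean must sit within 3 Monte-Carlo SEs of the pooled truth
  cfg0 <- sim_config(cells_per_population = 30, n_genes = 150,
                     n_marker_genes_per_population = 5)
  tot <- ex <- vr <- 0
  n <- 0
  for (sd_ in 1:10) {
    cfg <- sim_config(cells_per_population = 30, n_genes = 150,
                      n_marker_genes_per_population = 5, seed = sd_)
    ds <- gen_umi_dataset(cfg)
    mu <- ds$truth$expected
    theta <- ifelse(rownames(mu) %in% c("Atoh1", "Atoh1-HA", "tdTomato",
                                        cfg$latent_tf_genes),
                    cfg$special_dispersion, cfg$nb_dispersion)
    tot <- tot + rowSums(ds$counts)
    ex <- ex + rowSums(mu)
    vr <- vr + rowSums(mu + mu^2 / theta)
    n <- n + ncol(ds$counts)
  }
  z <- abs(tot / n - ex / n) / (sqrt(vr) / n)
  expect_gt(mean(z <= 3), 0.99)
  expect_true(all(z <= 5))
})

test_that("bulk replicates share their group mean and respect the noiseless limit", {
  tb <- bulk_sim_truth(n_genes = 300, n_de = 50, n_tf = 30, n_tf_de = 20,
                       seed = 2)
  bk0 <- gen_bulk_dataset(tb, seed = 2, nb_dispersion = Inf)
  si <- bk0$sample_info
  for (ct in unique(si$cell_type)) {
    s <- si$sample[si$cell_type == ct]
    expect_identical(bk0$counts[, s[1]], bk0$counts[, s[2]])
  }
  ## noiseless counts equal the rounded generative means
  rel <- 2^tb$group_log2means
  frac <- sweep(rel, 2, colSums(rel), "/")
  mu <- frac[, si$cell_type] * 1e7
  expect_equal(unname(bk0$counts), unname(round(mu)), tolerance = 0)
})

test_that("bulk generator rejects missing gene lengths", {
  tb <- bulk_sim_truth(n_genes = 50, n_de = 10, n_tf = 10, n_tf_de = 5)
  tb$gene_lengths[3] <- NA
  expect_error(gen_bulk_dataset(tb), "lengths")
})

test_that("biological duplicates are concordant at default noise", {
  rho <- vapply(1:5, function(sd_) {
    tb <- bulk_sim_truth(seed = sd_)
    bk <- gen_bulk_dataset(tb, seed = sd_)
    rc <- replicate_concordance(bk)
    min(vapply(unique(bk$sample_info$cell_type), function(ct) {
      s <- bk$sample_info$sample[bk$sample_info$cell_type == ct]
      rc[s[1], s[2]]
    }, 0))
  }, 0)
  expect_true(all(rho >= 0.85))
})

test_that("conversion count tables behave at the rate extremes", {
  z <- gen_count_table(c(ctrl = 0), n_cells = 100, n_samples = 5, seed = 1)
  expect_true(all(z$n_double_pos == 0))
  o <- gen_count_table(c(full = 1), n_cells = 100, n_samples = 5, seed = 1)
  expect_true(all(o$n_double_pos == o$n_reporter_pos))
})

test_that("pooled conversion counts sit inside the exact binomial CI", {
  tab <- gen_count_table(c(a = 0.25), n_cells = 200, n_samples = 10, seed = 9)
  ci <- stats::binom.test(sum(tab$n_double_pos),
                          sum(tab$n_reporter_pos))$conf.int
  expect_true(ci[1] <= 0.25 && 0.25 <= ci[2])
})

test_that("qPCR dilution series spacing follows the efficiency closed form", {
  tr <- qpcr_sim_truth(assays = "A1", cells_per_type = c(SC = 2, cHC = 2,
                                                         OHC = 2),
                       efficiency_range = c(0.99999, 1.0),
                       cq_noise_sd = 1e-12, seed = 1)
  sim <- gen_qpcr_plate(tr, seed = 1)
  d <- sim$dilution_series[order(sim$dilution_series$step), ]
  expect_equal(unique(round(diff(d$Ct), 4)), round(log2(3), 4))
  expect_equal(nrow(d), 15)
})

test_that("Cq increases as concentration decreases and zero expression drops out", {
  tr <- qpcr_sim_truth(seed = 3)
  sim <- gen_qpcr_plate(tr, seed = 3)
  for (a in tr$assays[1:5]) {
    d <- sim$dilution_series[sim$dilution_series$assay == a, ]
    expect_gt(cor(d$step, d$Ct, method = "spearman"), 0.99)
  }
  ## efficiency invariants
  expect_true(all(tr$efficiency > 0.7 & tr$efficiency <= 1.1))
})
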