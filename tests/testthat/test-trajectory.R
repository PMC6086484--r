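test_that("ordering-gene selection equals the brute-force filter", {
  m <- rbind(
    c(0L, 0L, 0L, 1L),            # mean 0.25, var 0.25, disp 1 -> in
    c(0L, 0L, 0L, 0L),            # mean 0 -> out (mean rule)
    c(2L, 2L, 2L, 2L),            # disp 0 -> out (dispersion rule)
    c(0L, 0L, 4L, 4L))            # mean 2, var 16/3, disp 2.67 -> in
  ds <- make_dataset(m)
  got <- select_ordering_genes(ds, min_mean = 0.1, min_dispersion = 1)
  x <- m
  mu <- rowMeans(x); v <- apply(x, 1, var)
  want <- rownames(ds$counts)[mu >= 0.1 & ifelse(mu > 0, v / mu, 0) >= 1]
  expect_equal(got, want)
  expect_equal(got, rownames(ds$counts)[c(1, 4)])
  ## detection-limit censoring: values below the limit count as zero
  m2 <- matrix(c(1L, 0L, 0L, 0L), 1)   # mean 0.25
  expect_length(select_ordering_genes(make_dataset(m2),
                                      lower_detection_limit = 2), 0)
})

test_that("a noiseless 1-D gradient yields a path whose pseudotime preserves order", {
  n <- 120
  grad <- seq(0, 6, length.out = n)
  m <- rbind(outer(c(1, 2, 4), grad) + 1, 3)
  storage.mode(m) <- "integer"
  ds <- make_dataset(m, populations = rep(c("lo", "hi"), c(10, n - 10)))
  og <- rownames(ds$counts)[1:3]
  tr <- fit_principal_tree(ds, og, n_centroids = 6, seed = 2)
  deg <- table(c(tr$edges$a, tr$edges$b))
  expect_true(all(deg <= 2))            # a path, no branch points
  pt <- assign_pseudotime(tr, labels = ds$cell_meta$true_population,
                          root_cluster = "lo")
  expect_gt(abs(cor(pt$tau, seq_len(n), method = "spearman")), 0.97)
  expect_true(all(pt$tau >= 0 & pt$tau <= 1))
  ## root cells sit near tau = 0
  expect_lt(mean(pt$tau[1:10]), 0.1)
  ## reversing the root flips the ordering
  far_node <- which.max(colSums((t(tr$centroids) -
                                   tr$centroids[pt$root_node, ])^2))
  pt2 <- assign_pseudotime(tr, root_node = far_node)
  expect_lt(cor(pt2$tau, seq_len(n), method = "spearman"), -0.97)
})

test_that("a Y-shaped layout produces exactly one branch point", {
  set.seed(3)
  arm <- function(dx, dy) cbind(seq(0, 10, length.out = 40) * dx,
                                seq(0, 10, length.out = 40) * dy)
  pts <- rbind(arm(1, 0), arm(-0.5, 1), arm(-0.5, -1))
  m <- round(rbind(60 + 3 * pts[, 1], 60 + 3 * pts[, 2], 10) +
               rnorm(3 * nrow(pts), 0, 0.1))
  storage.mode(m) <- "integer"
  ds <- make_dataset(m)
  tr <- fit_principal_tree(ds, rownames(ds$counts)[1:2], n_centroids = 7,
                           seed = 4)
  deg <- table(factor(c(tr$edges$a, tr$edges$b), levels = 1:7))
  expect_equal(sum(deg >= 3), 1)
  ## determinism under seed
  tr2 <- fit_principal_tree(ds, rownames(ds$counts)[1:2], n_centroids = 7,
                            seed = 4)
  expect_identical(tr$edges, tr2$edges)
  expect_identical(tr$cell_edge, tr2$cell_edge)
  expect_error(fit_principal_tree(ds, rownames(ds$counts)[1:2],
                                  n_centroids = 1), ">= 2")
})

test_that("pseudotime recovers the latent conversion coordinate on the preset", {
  pp <- continuum_dataset(seed = 31)
  og <- select_ordering_genes(pp)
  tr <- fit_principal_tree(pp, og, n_centroids = 10, seed = 31)
  pt <- assign_pseudotime(tr, labels = pp$cell_meta$true_population,
                          root_cluster = "SC1")
  s <- pp$cell_meta$true_latent
  expect_gte(abs(cor(pt$tau, s, method = "spearman")), 0.9)
  mt <- tapply(pt$tau, pp$cell_meta$true_population, mean)
  expect_true(all(diff(mt[c("SC1", "cHC1", "cHC2", "cHC3")]) > 0))
})

test_that("the spline LRT is calibrated under the null and powered under signal", {
  set.seed(5)
  n <- 200
  tau <- runif(n)
  null_m <- matrix(rpois(200 * n, 5), 200, n)
  ds <- make_dataset(null_m)
  res <- test_pseudotime_dependence(ds, tau)
  ## p-values approximately uniform: KS test at alpha = 0.01
  expect_gt(stats::ks.test(res$p, "punif")$p.value, 0.01)
  ## strongly monotone gene: significant after BH
  sig_m <- rbind(matrix(rpois(50 * n, 5), 50, n),
                 round(2 + 20 * tau))
  storage.mode(sig_m) <- "integer"
  res2 <- test_pseudotime_dependence(make_dataset(sig_m), tau)
  expect_lt(res2$FDR[51], 0.01)
  ## permuting tau destroys the signal
  res3 <- test_pseudotime_dependence(make_dataset(sig_m), sample(tau))
  expect_gt(res3$p[51], 0.001)
  ## FDR consistent with BH
  expect_equal(res2$FDR, p.adjust(res2$p, "BH"))
})

test_that("pseudotime profiles are brute-force bin means with interpolation", {
  set.seed(6)
  n <- 150
  tau <- runif(n)
  m <- rbind(round(1 + 9 * tau), matrix(rpois(2 * n, 4), 2, n))
  storage.mode(m) <- "integer"
  ds <- make_dataset(m)
  ## n_bins = 1 is the overall mean
  p1 <- bin_pseudotime_profiles(ds, tau, n_bins = 1)
  expect_equal(unname(p1[, 1]), rowMeans(log2(m + 1)))
  ## bin means equal direct group means on non-empty bins
  p20 <- bin_pseudotime_profiles(ds, tau, n_bins = 20)
  bin <- cut(tau, seq(0, 1, length.out = 21), include.lowest = TRUE,
             labels = FALSE)
  for (b in c(3, 11, 17)) {
    if (!any(bin == b)) next
    expect_equal(unname(p20[2, b]), mean(log2(m[2, bin == b] + 1)))
  }
  ## a linear gene gives a (weakly) monotone profile
  p100 <- bin_pseudotime_profiles(ds, tau, genes = "g01", n_bins = 100)
  expect_gt(cor(seq_len(100), p100[1, ], method = "spearman"), 0.95)
  expect_false(anyNA(p100))
  ## min-max scaling
  ps <- bin_pseudotime_profiles(ds, tau, n_bins = 10, scale = TRUE)
  expect_true(all(apply(ps, 1, max) == 1 | apply(ps, 1, function(r)
    all(r == r[1]))))
})

test_that("transgene correlation and fold change follow their definitions", {
  ## duplicated feature: R^2 = 1
  set.seed(7)
  base <- rpois(60, 8) + 1L
  m <- rbind(base, base, matrix(rpois(3 * 60, 4), 3, 60))
  rownames(m) <- c("Atoh1", "Atoh1-HA", "x1", "x2", "x3")
  ds <- make_dataset(m)
  ds$special_features <- c(atoh1_endogenous = "Atoh1", atoh1_ha = "Atoh1-HA")
  lab <- rep(c("cHC1", "cHC3"), each = 30)
  expect_equal(transgene_correlation(ds, lab)$r_squared, 1)
  ## independent features at n = 1000: R^2 below 0.01
  m2 <- rbind(rpois(1000, 20), rpois(1000, 20), rpois(1000, 3))
  rownames(m2) <- c("Atoh1", "Atoh1-HA", "x")
  ds2 <- make_dataset(m2)
  ds2$special_features <- c(atoh1_endogenous = "Atoh1", atoh1_ha = "Atoh1-HA")
  expect_lt(transgene_correlation(ds2, rep(c("cHC1", "cHC3"), 500))$r_squared,
            0.01)
  ## exact fold change from cluster means 6.58 vs 2.0
  ha <- c(rep(c(8L, 6L), c(29, 71)), rep(2L, 100))
  m3 <- rbind(rep(c(1L, 2L), 100), ha, rep(3L, 200))
  rownames(m3) <- c("Atoh1", "Atoh1-HA", "x")
  ds3 <- make_dataset(m3)
  ds3$special_features <- c(atoh1_endogenous = "Atoh1", atoh1_ha = "Atoh1-HA")
  lab3 <- rep(c("cHC3", "cHC1"), each = 100)
  expect_equal(transgene_correlation(ds3, lab3)$fold_change, 3.29)
  expect_error(transgene_correlation(ds3, rep("z", 200)), "not found")
})

test_that("transgene regime on the default continuum preset is strong", {
  pp <- continuum_dataset(seed = 32)
  tg <- transgene_correlation(pp, pp$cell_meta$true_population)
  expect_gt(tg$r_squared, 0.4)
  expect_gt(tg$fold_change, 2)
  expect_lt(tg$fold_change, 4.5)
})
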