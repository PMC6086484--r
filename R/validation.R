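#' Machine-learning validation of cluster assignments
#'
#' The cluster-validation protocol: a stratified split holds out
#' `test_fraction` of the cells of every cluster; min-max scaling (each gene
#' to `[0, 1]`) and PCA (no whitening, `n_pcs` components) are fitted on the
#' training cells only; an RBF-kernel SVM is tuned by grid search over
#' `(C, gamma)` with `cv_folds`-fold cross-validation on the training set;
#' accuracy is the trace of the confusion matrix on the held-out cells. A
#' classifier that reproduces the cluster labels from held-out expression
#' demonstrates that the clusters are separable states rather than artifacts
#' of the embedding.
#'
#' @param x genes x cells expression matrix (e.g. `log2(expected count + 1)`
#'   of the preprocessed dataset).
#' @param labels cluster label per cell; every cluster needs at least 5
#'   cells so the stratified test set is nonempty.
#' @param test_fraction held-out fraction per cluster.
#' @param n_pcs number of training-set principal components.
#' @param C_grid,gamma_grid SVM grid-search values.
#' @param cv_folds cross-validation folds.
#' @param seed integer seed (split and CV fold assignment).
#' @return list with `accuracy`, `confusion` (true x predicted), `best`
#'   (`C`, `gamma`), `test_cells`.
#' @export
train_validate_classifier <- function(x, labels, test_fraction = 0.2,
                                      n_pcs = 30,
                                      C_grid = c(0.1, 1, 10, 100),
                                      gamma_grid = 10^seq(-3, 1),
                                      cv_folds = 3, seed = 1) {
  stopifnot(ncol(x) == length(labels), test_fraction > 0, test_fraction < 1,
            length(C_grid) > 0, length(gamma_grid) > 0)
  labels <- factor(labels)
  if (any(table(labels) < 5))
    stop("every cluster needs at least 5 cells for a stratified 20% split")
  if (nlevels(labels) == 1) {
    n_test <- max(1, round(length(labels) * test_fraction))
    confusion <- table(truth = rep(levels(labels), n_test),
                       predicted = rep(levels(labels), n_test))
    return(list(accuracy = 1, confusion = confusion,
                best = list(C = C_grid[1], gamma = gamma_grid[1]),
                cv_accuracy = 1, test_cells = character()))
  }
  with_seed(derive_seed(seed, "split"), {
    test_idx <- unlist(lapply(levels(labels), function(cl) {
      i <- which(labels == cl)
      sample(i, max(1, round(length(i) * test_fraction)))
    }))
    train_idx <- setdiff(seq_along(labels), test_idx)
    if (any(table(labels[train_idx]) < cv_folds))
      stop("a cluster has fewer training cells than cv_folds")

    xtr <- t(x[, train_idx, drop = FALSE])
    xte <- t(x[, test_idx, drop = FALSE])
    ## min-max scaling fitted on training cells only
    mins <- apply(xtr, 2, min)
    spans <- apply(xtr, 2, max) - mins
    spans[spans == 0] <- 1
    str_ <- sweep(sweep(xtr, 2, mins), 2, spans, "/")
    ste_ <- sweep(sweep(xte, 2, mins), 2, spans, "/")
    ## PCA (no whitening) fitted on training cells only
    pc <- prcomp(str_, center = TRUE, scale. = FALSE)
    k <- min(n_pcs, ncol(pc$x))
    ztr <- pc$x[, seq_len(k), drop = FALSE]
    zte <- scale(ste_, center = pc$center, scale = FALSE) %*%
      pc$rotation[, seq_len(k), drop = FALSE]
    ytr <- droplevels(labels[train_idx])

    folds <- sample(rep_len(seq_len(cv_folds), nrow(ztr)))
    grid <- expand.grid(C = C_grid, gamma = gamma_grid)
    cv_acc <- vapply(seq_len(nrow(grid)), function(gi) {
      acc <- vapply(seq_len(cv_folds), function(f) {
        tr <- folds != f
        fit <- e1071::svm(ztr[tr, , drop = FALSE], ytr[tr],
                          kernel = "radial", cost = grid$C[gi],
                          gamma = grid$gamma[gi], scale = FALSE)
        mean(predict(fit, ztr[!tr, , drop = FALSE]) == ytr[!tr])
      }, 0)
      mean(acc)
    }, 0)
    best <- grid[which.max(cv_acc), ]
    fit <- e1071::svm(ztr, ytr, kernel = "radial", cost = best$C,
                      gamma = best$gamma, scale = FALSE)
    pred <- predict(fit, zte)
    truth <- factor(labels[test_idx], levels = levels(labels))
    pred <- factor(pred, levels = levels(labels))
    confusion <- table(truth = truth, predicted = pred)
    list(accuracy = sum(diag(confusion)) / sum(confusion),
         confusion = confusion,
         best = list(C = best$C, gamma = best$gamma),
         cv_accuracy = max(cv_acc),
         test_cells = colnames(x)[test_idx],
         ## fitted on training cells only; exposed so leakage is checkable
         transform = list(mins = mins, spans = spans,
                          center = pc$center,
                          rotation = pc$rotation[, seq_len(k), drop = FALSE]))
  })
}

#' Conversion rates from imaging count tables
#'
#' The conversion rate of a sample is the number of double-positive cells
#' (reporter + hair-cell marker) divided by the number of reporter-positive
#' cells, after excluding dislodged endogenous hair cells (double-positive
#' cells inside endogenous clusters) from both numerator and denominator.
#'
#' @param table `data.frame` with `sample`, `condition`, `n_reporter_pos`,
#'   `n_double_pos`, `n_excluded_dislodged`.
#' @return the table with a `rate` column, plus attributes `pooled`
#'   (per-condition pooled rates).
#' @export
conversion_rate <- function(table) {
  req <- c("sample", "condition", "n_reporter_pos", "n_double_pos",
           "n_excluded_dislodged")
  stopifnot(all(req %in% names(table)))
  with(table, {
    if (any(n_double_pos > n_reporter_pos) ||
        any(n_excluded_dislodged > n_double_pos) ||
        any(table[req[3:5]] < 0))
      stop("invalid counts: need 0 <= excluded <= double_pos <= reporter_pos")
  })
  denom <- table$n_reporter_pos - table$n_excluded_dislodged
  if (any(denom <= 0))
    stop("conversion rate undefined: no reporter-positive cells remain in ",
         paste(table$sample[denom <= 0], collapse = ", "))
  table$rate <- (table$n_double_pos - table$n_excluded_dislodged) / denom
  pooled <- vapply(split(table, table$condition), function(d)
    sum(d$n_double_pos - d$n_excluded_dislodged) /
      sum(d$n_reporter_pos - d$n_excluded_dislodged), 0)
  attr(table, "pooled") <- pooled
  table
}

#' Compare conversion rates across conditions
#'
#' Treats per-sample rates as the experimental units (matching
#' scatter-plot-of-samples quantification). `design = "t"` runs two-sided
#' Student's t-tests for all condition pairs; `design = "anova2"` runs a
#' two-way factorial ANOVA after splitting condition names of the form
#' `"A+B"`, `"A"`, `"B"`, `"ctrl"` into presence/absence of the two factors.
#'
#' @param rates a [conversion_rate()] result (needs `condition` and `rate`).
#' @param design `"t"` or `"anova2"`.
#' @param factors for `anova2`, the two factor names (e.g.
#'   `c("Atoh1", "Isl1")`).
#' @return for `"t"`: `data.frame` of pairwise tests with means +/- SEM;
#'   for `"anova2"`: the ANOVA table plus the summary per condition.
#' @export
compare_rates <- function(rates, design = c("t", "anova2"),
                          factors = c("Atoh1", "Isl1")) {
  design <- match.arg(design)
  stopifnot(all(c("condition", "rate") %in% names(rates)))
  summ <- do.call(rbind, lapply(split(rates, rates$condition), function(d)
    data.frame(condition = d$condition[1], n = nrow(d),
               mean = mean(d$rate),
               sem = sd(d$rate) / sqrt(nrow(d)),
               stringsAsFactors = FALSE)))
  rownames(summ) <- NULL
  if (design == "t") {
    conds <- unique(rates$condition)
    prs <- utils::combn(conds, 2)
    tests <- lapply(seq_len(ncol(prs)), function(k) {
      a <- prs[1, k]; b <- prs[2, k]
      tt <- t.test(rates$rate[rates$condition == a],
                   rates$rate[rates$condition == b], var.equal = TRUE)
      data.frame(group1 = a, group2 = b, t = unname(tt$statistic),
                 df = unname(tt$parameter), p = tt$p.value,
                 stringsAsFactors = FALSE)
    })
    return(list(summary = summ, tests = do.call(rbind, tests)))
  }
  has <- sapply(factors, function(f)
    grepl(tolower(f), tolower(rates$condition), fixed = TRUE))
  d <- data.frame(rate = rates$rate,
                  f1 = factor(has[, 1]), f2 = factor(has[, 2]))
  names(d)[2:3] <- factors
  fml <- stats::as.formula(paste("rate ~", factors[1], "*", factors[2]))
  fit <- aov(fml, data = d)
  list(summary = summ, anova = summary(fit)[[1]])
}
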