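#' Calibrate assays from a dilution series
#'
#' Per assay: the LOD-Ct (limit-of-detection threshold cycle) is the highest
#' Ct observed across the threefold dilution series; the standard curve is a
#' least-squares fit of Ct on log10(relative concentration), from which the
#' amplification efficiency is `10^(-1/slope) - 1`. The universal LOD-Ct is
#' the median of per-assay LOD-Cts.
#'
#' @param dilution_series `data.frame` with columns `assay`, `rel_conc`
#'   (relative concentration) and `Ct`.
#' @return class `qpcr_calibration`: `table` (per-assay `lod_ct`, `slope`,
#'   `intercept`, `efficiency`) and `universal_lod_ct`.
#' @export
calibrate_lod <- function(dilution_series) {
  stopifnot(all(c("assay", "rel_conc", "Ct") %in% names(dilution_series)))
  per <- lapply(split(dilution_series, dilution_series$assay), function(d) {
    d <- d[!is.na(d$Ct), ]
    fit <- lm(Ct ~ log10(rel_conc), data = d)
    slope <- coef(fit)[[2]]
    data.frame(assay = d$assay[1],
               lod_ct = max(d$Ct),
               slope = slope,
               intercept = coef(fit)[[1]],
               efficiency = 10^(-1 / slope) - 1,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, per)
  rownames(tab) <- tab$assay
  structure(list(table = tab,
                 universal_lod_ct = median(tab$lod_ct)),
            class = "qpcr_calibration")
}

#' @export
print.qpcr_calibration <- function(x, ...) {
  cat("qpcr_calibration:", nrow(x$table), "assays; universal LOD-Ct =",
      round(x$universal_lod_ct, 2), "\n")
  invisible(x)
}

#' Melt-curve quality control
#'
#' Removes chambers whose melt curve has more than one peak (non-specific
#' amplification); the number removed is reported via a message.
#'
#' @param plate long-format plate `data.frame` with a `melt_peaks` column.
#' @return the filtered plate, with attribute `n_removed`.
#' @export
melt_qc <- function(plate) {
  stopifnot("melt_peaks" %in% names(plate))
  bad <- plate$melt_peaks > 1
  if (any(bad)) message("melt QC removed ", sum(bad), " chamber(s)")
  out <- plate[!bad, , drop = FALSE]
  attr(out, "n_removed") <- sum(bad)
  out
}

#' Convert Cq values to expression levels
#'
#' `Log2(Ex) = LOD-Ct - Cq` per assay (or with the plate-level universal
#' LOD-Ct). Chambers with no amplification (missing Cq) are at the detection
#' floor, expression 0; values below 0 are clipped to 0.
#'
#' @param plate long-format plate (`assay`, `cell_id`, `Cq`).
#' @param calibration a [calibrate_lod()] result.
#' @param lod_mode `"per_assay"` or `"universal"`.
#' @return assays x cells matrix of `Log2(Ex)` values.
#' @export
cq_to_expression <- function(plate, calibration,
                             lod_mode = c("per_assay", "universal")) {
  lod_mode <- match.arg(lod_mode)
  assays <- sort(unique(plate$assay))
  cells <- unique(plate$cell_id)
  lod <- if (lod_mode == "universal")
    setNames(rep(calibration$universal_lod_ct, length(assays)), assays)
  else setNames(calibration$table[assays, "lod_ct"], assays)
  if (any(is.na(lod))) stop("calibration missing for some assays")
  ex <- lod[plate$assay] - plate$Cq
  ex[is.na(plate$Cq)] <- 0
  ex <- pmax(ex, 0)
  ## chambers absent from the plate (e.g. removed by melt QC) carry no
  ## measurement at all and stay NA; non-amplifying chambers are 0
  m <- matrix(NA_real_, length(assays), length(cells),
              dimnames = list(assays, cells))
  m[cbind(plate$assay, plate$cell_id)] <- ex
  m
}

#' Per-assay missingness report
#'
#' Fraction of chambers per assay with no amplification (missing Cq), which
#' flags assays with technical failures.
#'
#' @param plate long-format plate.
#' @return `data.frame` with `assay`, `n_chambers`, `n_missing`,
#'   `missing_rate`.
#' @export
assay_missingness <- function(plate) {
  sp <- split(plate, plate$assay)
  out <- do.call(rbind, lapply(sp, function(d)
    data.frame(assay = d$assay[1], n_chambers = nrow(d),
               n_missing = sum(is.na(d$Cq)),
               missing_rate = mean(is.na(d$Cq)),
               stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out
}

#' Group comparison of qPCR expression
#'
#' Per gene: one-way ANOVA across the cell-type groups; when the ANOVA p is
#' below `alpha`, all pairwise Student's t-tests with Bonferroni correction
#' over the number of pairs.
#'
#' @param expression assays x cells matrix of `Log2(Ex)` values.
#' @param cell_types group label per cell (aligned with columns).
#' @param alpha ANOVA gate for the pairwise follow-up tests.
#' @return list with `anova` (`gene`, `F`, `p`) and `pairwise` (`gene`,
#'   `group1`, `group2`, `t`, `p`, `p_bonferroni`; only genes passing the
#'   gate).
#' @export
group_compare <- function(expression, cell_types, alpha = 0.05) {
  stopifnot(ncol(expression) == length(cell_types))
  g <- factor(cell_types)
  pairs <- utils::combn(levels(g), 2)
  m <- ncol(pairs)
  an <- lapply(rownames(expression), function(gene) {
    y <- expression[gene, ]
    fit <- stats::oneway.test(y ~ g, var.equal = TRUE, subset = !is.na(y))
    data.frame(gene = gene, F = unname(fit$statistic),
               p = fit$p.value, stringsAsFactors = FALSE)
  })
  an <- do.call(rbind, an)
  pw <- list()
  for (gene in an$gene[!is.na(an$p) & an$p < alpha]) {
    y <- expression[gene, ]
    for (k in seq_len(m)) {
      a <- pairs[1, k]; b <- pairs[2, k]
      tt <- t.test(y[g == a & !is.na(y)], y[g == b & !is.na(y)],
                   var.equal = TRUE)
      pw[[length(pw) + 1]] <- data.frame(
        gene = gene, group1 = a, group2 = b,
        t = unname(tt$statistic), p = tt$p.value,
        p_bonferroni = min(1, tt$p.value * m),
        stringsAsFactors = FALSE)
    }
  }
  list(anova = an,
       pairwise = if (length(pw)) do.call(rbind, pw)
                  else data.frame(gene = character(), group1 = character(),
                                  group2 = character(), t = numeric(),
                                  p = numeric(), p_bonferroni = numeric()))
}

#' Cross-platform concordance of expression log-ratios
#'
#' For each gene shared between the qPCR expression matrix and the bulk FPKM
#' matrix, computes the log ratio of group means between two cell types on
#' each platform (difference of mean `Log2(Ex)` for qPCR; log2 ratio of mean
#' FPKM for bulk) and reports the squared Pearson correlation across genes
#' with the fitted regression line, per pair.
#'
#' @param qpcr_expression assays x cells `Log2(Ex)` matrix.
#' @param qpcr_cell_types group label per qPCR cell.
#' @param bulk_fpkm genes x samples FPKM matrix.
#' @param bulk_cell_types group label per bulk sample.
#' @param pairs list of 2-vectors `c(numerator, denominator)`; group names
#'   must exist on both platforms.
#' @return `data.frame` with `pair`, `n_genes`, `r2`, `slope`, `intercept`.
#' @export
cross_platform_concordance <- function(qpcr_expression, qpcr_cell_types,
                                       bulk_fpkm, bulk_cell_types,
                                       pairs = list(c("cHC", "SC"),
                                                    c("OHC", "cHC"))) {
  shared <- intersect(rownames(qpcr_expression), rownames(bulk_fpkm))
  if (length(shared) < 3) stop("fewer than 3 shared genes across platforms")
  qmean <- function(type) rowMeans(
    qpcr_expression[shared, qpcr_cell_types == type, drop = FALSE],
    na.rm = TRUE)
  bmean <- function(type) rowMeans(
    bulk_fpkm[shared, bulk_cell_types == type, drop = FALSE])
  out <- lapply(pairs, function(p) {
    x <- qmean(p[1]) - qmean(p[2])
    y <- log2((bmean(p[1]) + 1e-3) / (bmean(p[2]) + 1e-3))
    fit <- lm(y ~ x)
    data.frame(pair = paste(p[1], "vs", p[2]), n_genes = length(shared),
               r2 = cor(x, y)^2, slope = coef(fit)[[2]],
               intercept = coef(fit)[[1]], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
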