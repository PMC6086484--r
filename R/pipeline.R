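#' Write a UMI dataset as a Matrix Market bundle
#'
#' Writes `matrix.mtx` (1-based coordinate triplets), `genes.tsv`,
#' `barcodes.tsv` and `cell_meta.tsv` into a directory, plus a `manifest.json`
#' recording the generating configuration and seed when available.
#'
#' @param dataset a `umi_dataset`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_umi_bundle <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- Matrix::Matrix(dataset$counts, sparse = TRUE)
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  writeLines(rownames(dataset$counts), file.path(dir, "genes.tsv"))
  writeLines(colnames(dataset$counts), file.path(dir, "barcodes.tsv"))
  write.table(dataset$cell_meta, file.path(dir, "cell_meta.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- list(
    n_genes = nrow(dataset$counts), n_cells = ncol(dataset$counts),
    special_features = as.list(dataset$special_features %||% list()),
    seed = dataset$config$seed %||% NA)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Read a UMI dataset from a Matrix Market bundle
#'
#' @param dir directory written by [write_umi_bundle()].
#' @return a `umi_dataset` (without generative truth).
#' @export
read_umi_bundle <- function(dir) {
  m <- Matrix::readMM(file.path(dir, "matrix.mtx"))
  counts <- as.matrix(m)
  if (any(counts != round(counts)) || any(counts < 0))
    stop("count matrix contains non-integer or negative values")
  storage.mode(counts) <- "integer"
  rownames(counts) <- readLines(file.path(dir, "genes.tsv"))
  colnames(counts) <- readLines(file.path(dir, "barcodes.tsv"))
  meta <- read.delim(file.path(dir, "cell_meta.tsv"),
                     stringsAsFactors = FALSE)
  rownames(meta) <- meta$cell_id
  sf <- NULL
  mf <- file.path(dir, "manifest.json")
  if (file.exists(mf)) {
    man <- jsonlite::read_json(mf)
    if (length(man$special_features))
      sf <- unlist(man$special_features)
  }
  structure(list(counts = counts,
                 gene_names = rownames(counts),
                 cell_ids = colnames(counts),
                 cell_meta = meta[colnames(counts), , drop = FALSE],
                 special_features = sf,
                 truth = NULL, config = NULL),
            class = "umi_dataset")
}

#' Read or write a dense matrix as TSV
#'
#' Gene x sample table with a header row and row names in the first column;
#' round-trip lossless for integer counts.
#'
#' @param x matrix to write (for `write_matrix_tsv`).
#' @param path file path.
#' @param integer validate that values are non-negative integers on read.
#' @return the matrix (read) or the path, invisibly (write).
#' @export
write_matrix_tsv <- function(x, path) {
  df <- data.frame(gene = rownames(x) %||% seq_len(nrow(x)), x,
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path, integer = FALSE) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  if (integer) {
    if (any(m != round(m)) || any(m < 0))
      stop("validation error: expected non-negative integer counts in ", path)
    storage.mode(m) <- "integer"
  }
  m
}

#' Run the full analysis pipeline on synthetic data
#'
#' Orchestrates the stages in dependency order — simulate, preprocess,
#' cluster, trajectory + TF network, bulk differential expression, qPCR
#' quantification, classifier validation, conversion-rate statistics — and
#' writes each stage's outputs plus a manifest (seed, parameters, file
#' hashes) into `outdir`. Reruns with the same seed are bit-identical for
#' the deterministic stages.
#'
#' @param outdir output directory.
#' @param seed master seed propagated (via derived streams) to every stage.
#' @param config optional list overriding stage parameters:
#'   `sim` (arguments of [sim_config()]), `k`, `n_pcs`, `perplexity`,
#'   `n_centroids`, `root_cluster`, `n_bins`, `stages` (character subset to
#'   run).
#' @return invisible list of stage results.
#' @export
run_pipeline <- function(outdir, seed = 1, config = list()) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  stages <- config$stages %||% c("simulate", "preprocess", "cluster",
                                 "trajectory", "network", "bulk_de",
                                 "qpcr", "validate", "convert_stats")
  res <- list()
  step <- function(name, expr) {
    if (!(name %in% stages)) return(NULL)
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  res$simulate <- step("simulate", {
    cfg <- do.call(sim_config, c(config$sim %||% list(),
                                 if (is.null(config$sim$seed)) list(seed = seed)))
    ds <- gen_umi_dataset(cfg)
    write_umi_bundle(ds, file.path(outdir, "umi"))
    ds
  })
  ds <- res$simulate
  if (is.null(ds) && any(stages != "simulate")) {
    if (is.null(config$input_dir) || !dir.exists(config$input_dir))
      stop("missing input path: supply config$input_dir when the simulate ",
           "stage is disabled")
    ds <- read_umi_bundle(config$input_dir)
  }

  res$preprocess <- step("preprocess", {
    pp <- filter_cells_by_library_size(ds)
    pp <- downsample_to_reference_depth(pp, seed = derive_seed(seed, "umi"))
    hvg <- select_hvg(pp)
    list(dataset = pp, hvg = hvg)
  })

  res$cluster <- step("cluster", {
    pp <- res$preprocess$dataset
    x <- log2p1(pp$counts[res$preprocess$hvg$genes, , drop = FALSE])
    pc <- pca_embed(x, n_components = config$n_pcs %||% 30)
    emb <- tsne_embed(pc$scores,
                      perplexity = config$perplexity %||% 30, seed = seed)
    snn <- build_snn_graph(pc$scores, k = config$k %||% 20)
    cl <- cluster_modularity(snn)
    cl$embedding_2d <- emb
    cl$pc_scores <- pc$scores
    markers <- find_markers(pp, cl$labels)
    comp <- cluster_composition(cl$labels, pp$cell_meta)
    write.table(data.frame(cell_id = names(cl$labels), cluster = cl$labels,
                           emb),
                file.path(outdir, "clusters.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(markers, file.path(outdir, "markers.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    list(clusters = cl, markers = markers, composition = comp)
  })

  res$trajectory <- step("trajectory", {
    pp <- res$preprocess$dataset
    cont <- pp$cell_meta$true_population %in%
      (ds$config$continuum_populations %||%
         unique(pp$cell_meta$true_population))
    sub <- umi_subset(pp, cells = which(cont))
    og <- select_ordering_genes(sub)
    tr <- fit_principal_tree(sub, og,
                             n_centroids = config$n_centroids %||% 10,
                             seed = seed)
    pt <- assign_pseudotime(tr, labels = sub$cell_meta$true_population,
                            root_cluster = config$root_cluster %||% "SC1")
    tests <- test_pseudotime_dependence(sub, pt$tau, genes = og)
    prof <- bin_pseudotime_profiles(sub, pt$tau, genes = og,
                                    n_bins = config$n_bins %||% 100)
    write.table(data.frame(cell_id = names(pt$tau), tau = pt$tau),
                file.path(outdir, "pseudotime.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    list(tree = tr, pseudotime = pt, tests = tests, profiles = prof,
         dataset = sub)
  })

  res$network <- step("network", {
    sub <- res$trajectory$dataset
    tfs <- c(sub$special_features[["atoh1_endogenous"]],
             ds$config$latent_tf_genes %||% character())
    nodes <- filter_tf_genes(sub, tfs)
    net <- detect_communities(correlation_network(sub, nodes))
    write.table(net$edges, file.path(outdir, "tf_edges.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    net
  })

  res$bulk_de <- step("bulk_de", {
    truth <- bulk_sim_truth(seed = seed)
    bulk <- gen_bulk_dataset(truth, seed = seed)
    de <- differential_expression(bulk)
    tf_de <- subset_tf_de(de, truth$tf_genes)
    dist6 <- distance_suite(bulk, truth$tf_genes)
    write.table(tf_de, file.path(outdir, "tf_de.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    list(bulk = bulk, de = de, tf_de = tf_de, distances = dist6)
  })

  res$qpcr <- step("qpcr", {
    truth <- qpcr_sim_truth(seed = seed)
    sim <- gen_qpcr_plate(truth, seed = seed)
    cal <- calibrate_lod(sim$dilution_series)
    plate <- melt_qc(sim$plate)
    ex <- cq_to_expression(plate, cal)
    ct <- sim$plate$cell_type[match(colnames(ex), sim$plate$cell_id)]
    stats_ <- group_compare(ex, ct)
    write.table(cal$table, file.path(outdir, "qpcr_calibration.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    list(sim = sim, calibration = cal, expression = ex, stats = stats_,
         cell_types = ct)
  })

  res$validate <- step("validate", {
    pp <- res$preprocess$dataset
    labels <- res$cluster$clusters$labels
    out <- train_validate_classifier(log2p1(pp$counts), labels, seed = seed)
    jsonlite::write_json(list(accuracy = out$accuracy, best = out$best),
                         file.path(outdir, "classifier.json"),
                         auto_unbox = TRUE)
    out
  })

  res$convert_stats <- step("convert_stats", {
    tab <- gen_count_table(rates = c(Atoh1 = 0.255, `Atoh1+Isl1` = 0.439),
                           seed = seed)
    cr <- conversion_rate(tab)
    cmp <- compare_rates(cr, design = "t")
    write.table(cr, file.path(outdir, "conversion_rates.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    list(rates = cr, comparison = cmp)
  })

  files <- list.files(outdir, recursive = TRUE, full.names = TRUE)
  manifest <- list(seed = seed,
                   stages = stages,
                   config = config,
                   files = as.list(setNames(
                     unname(tools::md5sum(files)),
                     list.files(outdir, recursive = TRUE))))
  jsonlite::write_json(manifest, file.path(outdir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(res)
}
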