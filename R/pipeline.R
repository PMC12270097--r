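#' Run the full holobiont analysis from one configuration
#'
#' Orchestrates simulation (or file input), host-genetic analysis (IBS,
#' clone pruning, cluster assignment, FST, UPGMA), community processing for
#' ITS2-style and 16S-style tables, marginal PERMANOVA, the dispersion test
#' and RDA-forest importance, writing every artefact plus a JSON manifest
#' (config snapshot, seeds, thresholds, file checksums) to `out_dir`.
#'
#' The configuration is a named list (or a JSON file path) with optional
#' sections: `simulation` (arguments to [sim_config()]), `filters`
#' (arguments to [filter_config()]), `permanova` (`n_perm`), `forest`
#' (arguments to [rf_config()]), `k_clusters`, and `seed`. Alternatively an
#' `inputs` section may point at existing TSV files (`counts`, `metadata`,
#' `genotypes`). Any stage failure aborts with the stage name.
#'
#' @param config named list or path to a JSON config file.
#' @param out_dir output directory (created if needed).
#' @return invisible list with the main results (`fst`, `tree`,
#'   `permanova`, `importance`, `dispersion`, `manifest`).
#' @export
run_all <- function(config, out_dir = tempfile("holocomm_run_")) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  stopifnot(is.list(config))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed %||% 1L)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  # --- inputs -------------------------------------------------------------
  if (!is.null(config$inputs)) {
    inp <- config$inputs
    for (f in unlist(inp)) if (!file.exists(f)) stop("missing input file: ", f)
    meta <- stage("read_metadata",
                  read.table(inp$metadata, sep = "\t", header = TRUE,
                             stringsAsFactors = TRUE))
    counts <- stage("read_counts", read_asv_tsv(inp$counts, meta = meta))
    geno <- stage("read_genotypes", {
      g <- read_matrix_tsv(inp$genotypes); storage.mode(g) <- "integer"; g
    })
    truth <- NULL
  } else {
    sc <- do.call(sim_config, c(config$simulation %||% list(),
                                list(seed = seed)))
    gt <- stage("simulate_genotypes", simulate_genotypes(sc))
    meta <- stage("simulate_metadata", simulate_metadata(sc, gt$clusters))
    com <- stage("simulate_community", simulate_community(meta, sc))
    counts <- com$table
    geno <- gt$dosages
    truth <- com$truth
    # genotype rows are individuals == colonies in the simulated world
    rownames(geno) <- unique(meta$colony_id)
  }

  # --- host genetics ------------------------------------------------------
  d_ibs <- stage("ibs_distance", ibs_distance(geno))
  # the largest-gap default of prune_clones targets datasets that contain
  # clone/replicate pairs; the simulated world has none, so the pipeline
  # defaults to 0 (exact genotype duplicates only) unless configured
  pruned <- stage("prune_clones",
                  prune_clones(d_ibs,
                               clone_threshold = config$clone_threshold %||% 0))
  k <- as.integer(config$k_clusters %||% 5L)
  d_kept <- d_ibs[pruned$retained, pruned$retained]
  clusters <- stage("assign_clusters", assign_clusters(d_kept, k))
  fst <- stage("pairwise_fst",
               pairwise_fst(geno[pruned$retained, , drop = FALSE], clusters))
  tree <- stage("upgma", upgma(fst))

  # --- community processing ----------------------------------------------
  fcfg <- do.call(filter_config, config$filters %||% list())
  colony_meta <- meta[!duplicated(meta$colony_id), , drop = FALSE]
  rownames(colony_meta) <- colony_meta$colony_id
  colony_meta$cluster <- clusters[match(colony_meta$colony_id,
                                        names(clusters))]
  genotyped <- pruned$retained
  proc <- stage("process_community",
                process_community(counts, fcfg, mode = "its2",
                                  genotyped = genotyped))

  # --- statistics ---------------------------------------------------------
  n_perm <- as.integer(config$permanova$n_perm %||% 999L)
  md <- colony_meta[rownames(proc$dist), , drop = FALSE]
  perm <- stage("permanova_marginal",
                permanova_marginal(proc$dist, md,
                                   ~ cluster + site + size_class,
                                   n_perm = n_perm, seed = seed))
  disp <- stage("dispersion_test",
                dispersion_test(proc$dist, md$cluster,
                                n_perm = n_perm, seed = seed))
  rcfg <- do.call(rf_config, c(config$forest %||% list(), list(seed = seed)))
  ord <- stage("pcoa", pcoa(proc$dist))
  dc <- stage("dummy_code",
              dummy_code(md, c("cluster", "site", "size_class")))
  imp <- stage("fit_rda_forest", fit_rda_forest(ord, dc, rcfg))

  # --- outputs ------------------------------------------------------------
  paths <- c(
    metadata = file.path(out_dir, "metadata.tsv"),
    counts = file.path(out_dir, "asv_counts.tsv"),
    genotypes = file.path(out_dir, "genotypes.tsv"),
    ibs = file.path(out_dir, "ibs_distance.tsv"),
    fst = file.path(out_dir, "fst.tsv"),
    tree = file.path(out_dir, "fst_upgma.nwk"),
    dist = file.path(out_dir, "bray_curtis.tsv"),
    permanova = file.path(out_dir, "permanova.tsv"),
    importance = file.path(out_dir, "importance.tsv"),
    summary = file.path(out_dir, "summary.txt"))
  write.table(meta, paths["metadata"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write_asv_tsv(counts, paths["counts"])
  write_matrix_tsv(geno, paths["genotypes"])
  write_matrix_tsv(round(d_ibs, 10), paths["ibs"])
  write_matrix_tsv(round(fst, 10), paths["fst"])
  writeLines(tree$newick, paths["tree"])
  write_matrix_tsv(round(proc$dist, 10), paths["dist"])
  ptab <- data.frame(term = rownames(perm), round(as.data.frame(perm), 6),
                     check.names = FALSE)
  write.table(ptab, paths["permanova"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  itab <- data.frame(predictor = names(imp$importance),
                     importance = round(imp$importance, 6),
                     share_pct = imp$shares$percent)
  write.table(itab, paths["importance"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  top <- names(sort(imp$importance, decreasing = TRUE))[1]
  writeLines(c(
    sprintf("holocomm pipeline summary (seed %d)", seed),
    sprintf("colonies analysed: %d", nrow(proc$dist)),
    sprintf("top predictor by RDA-forest importance: %s (%d%%)",
            top, imp$shares$percent[top]),
    sprintf("PERMANOVA R2: %s",
            paste(sprintf("%s=%.3f", rownames(perm)[1:3], perm$R2[1:3]),
                  collapse = ", ")),
    sprintf("dispersion test (by cluster): F=%.3f p=%.4f", disp$F, disp$p)),
    paths["summary"])

  manifest <- list(
    package_version = as.character(utils::packageVersion("holocomm")),
    seed = seed,
    config = config,
    thresholds = unclass(fcfg),
    n_perm = n_perm,
    forest = unclass(rcfg),
    checksums = as.list(tools::md5sum(unname(paths))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")

  invisible(list(out_dir = out_dir, fst = fst, tree = tree, permanova = perm,
                 importance = imp, dispersion = disp, truth = truth,
                 manifest = manifest))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
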