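# Shared fixture builders and tiny independent oracles.

# labelled square matrix from a vector of coordinates (Euclidean)
euclid_dist <- function(x) {
  d <- as.matrix(stats::dist(x))
  rownames(d) <- colnames(d) <- paste0("s", seq_len(nrow(d)))
  d
}

toy_asv <- function(counts, samples = NULL, asvs = NULL, colony = NULL) {
  m <- as.matrix(counts)
  if (!is.null(samples) || is.null(rownames(m)))
    rownames(m) <- samples %||% paste0("s", seq_len(nrow(m)))
  if (!is.null(asvs) || is.null(colnames(m)))
    colnames(m) <- asvs %||% paste0("ASV", seq_len(ncol(m)))
  if (!is.null(colony)) colony <- stats::setNames(colony, rownames(m))
  asv_table(m, colony = colony)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# adjusted Rand index (closed form over the contingency table)
ari <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sij <- sum(comb2(tab))
  si <- sum(comb2(rowSums(tab)))
  sj <- sum(comb2(colSums(tab)))
  n2 <- comb2(sum(tab))
  exp_ <- si * sj / n2
  (sij - exp_) / ((si + sj) / 2 - exp_)
}

# brute-force one-way PERMANOVA from group-pairwise distances
permanova_oracle <- function(d, groups) {
  n <- nrow(d)
  ss_total <- sum(d[upper.tri(d)]^2) / n
  ss_within <- 0
  for (g in unique(groups)) {
    idx <- which(groups == g)
    if (length(idx) > 1) {
      sub <- d[idx, idx]
      ss_within <- ss_within + sum(sub[upper.tri(sub)]^2) / length(idx)
    }
  }
  ss_between <- ss_total - ss_within
  k <- length(unique(groups))
  list(ss_total = ss_total, ss_within = ss_within, ss_between = ss_between,
       F = (ss_between / (k - 1)) / (ss_within / (n - k)))
}

# default simulated world shared by several tests (cached per session)
sim_world <- local({
  cache <- new.env()
  function(seed = 1, ...) {
    key <- paste0("w", seed, "_", paste(unlist(list(...)), collapse = "_"))
    if (!is.null(cache[[key]])) return(cache[[key]])
    cfg <- sim_config(seed = seed, ...)
    gt <- simulate_genotypes(cfg)
    meta <- simulate_metadata(cfg, gt$clusters)
    com <- simulate_community(meta, cfg)
    cm <- meta[!duplicated(meta$colony_id), , drop = FALSE]
    rownames(cm) <- cm$colony_id
    cache[[key]] <- list(cfg = cfg, gt = gt, meta = meta, com = com,
                         colony_meta = cm)
    cache[[key]]
  }
})
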