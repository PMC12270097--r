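#' Simulation configuration for the synthetic holobiont world
#'
#' Builds the single configuration object consumed by the generators. The
#' defaults describe the sampling world the downstream analyses assume: five
#' host genetic clusters across four reef sites and two colony size classes,
#' with three replicate samples per large colony and one per small colony, an
#' overdispersed (Dirichlet-multinomial) ASV community carrying additive
#' cluster/site/size effects on the log scale, and a handful of
#' intragenomic-variant ASV sets whose presence is locked to a parent ASV.
#'
#' @param n_clusters number of host genetic clusters.
#' @param fst_target Balding-Nichols differentiation parameter F, in (0,1).
#' @param n_individuals number of host colonies genotyped.
#' @param n_snps number of biallelic SNPs simulated.
#' @param sites character vector of site labels.
#' @param size_classes character vector of size-class labels; the class
#'   literally named "small" yields one sample per colony, any other class
#'   three replicate samples.
#' @param cluster_site_concentration Dirichlet concentration controlling how
#'   strongly clusters associate with sites (small value = strong association,
#'   large value = sites independent of cluster).
#' @param n_asvs number of base ASVs in the community.
#' @param effect_cluster,effect_site,effect_size standard deviations of the
#'   per-ASV log-abundance effects of cluster, site and size class.
#' @param replicate_noise_sd within-colony replicate log-abundance noise sd.
#' @param library_size_log_mean,library_size_log_sd log-normal library-size
#'   parameters (natural log scale).
#' @param overdispersion Dirichlet concentration scale; smaller values give
#'   more overdispersed counts.
#' @param n_variant_sets number of intragenomic-variant ASV groups planted.
#' @param seed master integer seed; every generator derives its sub-stream
#'   from it deterministically.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_clusters = 5L,
                       fst_target = 0.25,
                       n_individuals = 60L,
                       n_snps = 1000L,
                       sites = c("NE_Pelorus", "SE_Pelorus", "Pioneer_Bay",
                                 "S_Orpheus"),
                       size_classes = c("small", "large"),
                       cluster_site_concentration = 0.5,
                       n_asvs = 80L,
                       effect_cluster = 2,
                       effect_site = 0.5,
                       effect_size = 0.2,
                       replicate_noise_sd = 0.2,
                       library_size_log_mean = log(20000),
                       library_size_log_sd = 0.4,
                       overdispersion = 200,
                       n_variant_sets = 3L,
                       seed = 1L) {
  cfg <- list(n_clusters = as.integer(n_clusters), fst_target = fst_target,
              n_individuals = as.integer(n_individuals),
              n_snps = as.integer(n_snps), sites = as.character(sites),
              size_classes = as.character(size_classes),
              cluster_site_concentration = cluster_site_concentration,
              n_asvs = as.integer(n_asvs), effect_cluster = effect_cluster,
              effect_site = effect_site, effect_size = effect_size,
              replicate_noise_sd = replicate_noise_sd,
              library_size_log_mean = library_size_log_mean,
              library_size_log_sd = library_size_log_sd,
              overdispersion = overdispersion,
              n_variant_sets = as.integer(n_variant_sets),
              seed = as.integer(seed))
  stopifnot(cfg$n_clusters >= 1, cfg$n_individuals >= 1, cfg$n_snps >= 1,
            cfg$n_asvs >= 1, cfg$n_variant_sets >= 0,
            length(cfg$sites) >= 1, length(cfg$size_classes) >= 1,
            cfg$effect_cluster >= 0, cfg$effect_site >= 0,
            cfg$effect_size >= 0, cfg$replicate_noise_sd >= 0,
            cfg$overdispersion > 0, cfg$cluster_site_concentration > 0)
  if (!is.finite(cfg$fst_target) || cfg$fst_target <= 0 || cfg$fst_target >= 1)
    stop("fst_target must lie strictly in (0, 1)")
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate host genotypes under the Balding-Nichols model
#'
#' Ancestral allele frequencies are drawn Uniform(0.1, 0.9) per SNP; each
#' cluster's frequency is Beta(p(1-F)/F, (1-p)(1-F)/F) with F =
#' `fst_target`, and dosages are Binomial(2, p_cluster). Individuals are
#' assigned to clusters as evenly as possible.
#'
#' @param config a [sim_config()].
#' @return list with `dosages` (individuals x SNPs integer matrix, rownames =
#'   individual ids), and `clusters` (named factor of true cluster labels).
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_snps < 50) stop("need n_snps >= 50")
  if (config$n_individuals < config$n_clusters)
    stop("need n_individuals >= n_clusters")
  F <- config$fst_target
  with_seed(sub_seed(config$seed, 0L), {
    p_anc <- runif(config$n_snps, 0.1, 0.9)
    shape_scale <- (1 - F) / F
    # per-cluster allele frequencies
    pc <- matrix(0, config$n_clusters, config$n_snps)
    for (k in seq_len(config$n_clusters)) {
      pc[k, ] <- rbeta(config$n_snps, p_anc * shape_scale,
                       (1 - p_anc) * shape_scale)
    }
    cl <- rep(seq_len(config$n_clusters),
              length.out = config$n_individuals)
    cl <- sort(cl)
    g <- matrix(0L, config$n_individuals, config$n_snps)
    for (i in seq_len(config$n_individuals)) {
      g[i, ] <- rbinom(config$n_snps, 2L, pc[cl[i], ])
    }
    ids <- sprintf("ind%03d", seq_len(config$n_individuals))
    rownames(g) <- ids
    colnames(g) <- sprintf("snp%05d", seq_len(config$n_snps))
    clusters <- factor(paste0("K", cl), levels = paste0("K", seq_len(config$n_clusters)))
    names(clusters) <- ids
    list(dosages = g, clusters = clusters)
  })
}

#' Simulate sampling metadata with replicate structure
#'
#' Each individual draws a site from its cluster's site distribution (a
#' Dirichlet draw with concentration `cluster_site_concentration`; small
#' concentrations confine clusters to few sites) and a size class uniformly.
#' Large colonies expand to three replicate sample rows sharing one colony
#' id; small colonies get one row.
#'
#' @param config a [sim_config()].
#' @param clusters factor/character of true cluster labels, one per
#'   individual (e.g. from [simulate_genotypes()]).
#' @return data.frame with columns sample_id, colony_id, site, size_class,
#'   cluster.
#' @export
simulate_metadata <- function(config, clusters) {
  stopifnot(inherits(config, "sim_config"))
  if (length(clusters) != config$n_individuals)
    stop("clusters must have length n_individuals")
  clusters <- as.factor(clusters)
  with_seed(sub_seed(config$seed, 1L), {
    ns <- length(config$sites)
    kl <- levels(clusters)
    # per-cluster site distribution: normalized gamma draws = Dirichlet
    site_probs <- matrix(0, length(kl), ns, dimnames = list(kl, config$sites))
    for (k in seq_along(kl)) {
      w <- rgamma(ns, shape = config$cluster_site_concentration, rate = 1)
      if (sum(w) == 0) w[which.max(runif(ns))] <- 1
      site_probs[k, ] <- w / sum(w)
    }
    n <- config$n_individuals
    site <- character(n)
    for (i in seq_len(n)) {
      site[i] <- sample(config$sites, 1L, prob = site_probs[as.character(clusters[i]), ])
    }
    size_class <- sample(config$size_classes, n, replace = TRUE)
    colony_id <- sprintf("col%03d", seq_len(n))
    n_rep <- ifelse(size_class == "small", 1L, 3L)
    idx <- rep(seq_len(n), times = n_rep)
    rep_no <- sequence(n_rep)
    data.frame(
      sample_id = sprintf("%s_r%d", colony_id[idx], rep_no),
      colony_id = colony_id[idx],
      site = factor(site[idx], levels = config$sites),
      size_class = factor(size_class[idx], levels = config$size_classes),
      cluster = factor(as.character(clusters[idx]), levels = levels(clusters)),
      stringsAsFactors = FALSE
    )
  })
}

# Dirichlet-multinomial draw: proportions prop (sum 1), concentration theta,
# library size N
rdirmult1 <- function(N, prop, theta) {
  a <- theta * prop
  g <- rgamma(length(a), shape = a, rate = 1)
  if (sum(g) == 0) g[which.max(prop)] <- 1
  p <- g / sum(g)
  as.integer(rmultinom(1L, N, p))
}

#' Simulate an ASV community with planted cluster/site/size effects
#'
#' Per-ASV baseline log-abundances are N(0,1); cluster, site and size-class
#' contributions are per-level, per-ASV N(0, effect_*) shifts; replicates add
#' N(0, replicate_noise_sd). Relative abundances are the softmax over ASVs
#' and counts are Dirichlet-multinomial with concentration `overdispersion`
#' and log-normal library sizes. Each variant set appends 2-4 "variant" ASV
#' columns locked to a parent's presence (count = ceiling(parent * U(0.2,1))),
#' mimicking intragenomic ITS2 variation.
#'
#' @param metadata data.frame from [simulate_metadata()].
#' @param config a [sim_config()].
#' @return list with `table` (an [asv_table()] at sample level) and `truth`
#'   (effect matrices, library sizes, variant-set membership).
#' @export
simulate_community <- function(metadata, config) {
  stopifnot(inherits(config, "sim_config"))
  need <- c("sample_id", "colony_id", "site", "size_class", "cluster")
  if (!all(need %in% names(metadata)))
    stop("metadata must have columns ", paste(need, collapse = ", "))
  with_seed(sub_seed(config$seed, 2L), {
    nA <- config$n_asvs
    asv_ids <- sprintf("ASV%04d", seq_len(nA))
    base <- rnorm(nA)
    lev <- function(x) levels(as.factor(x))
    eff <- function(levels_, sd_) {
      m <- matrix(rnorm(length(levels_) * nA, 0, sd_), length(levels_), nA,
                  dimnames = list(levels_, asv_ids))
      m
    }
    cl_lev <- lev(metadata$cluster); si_lev <- lev(metadata$site)
    sz_lev <- lev(metadata$size_class)
    eff_cl <- eff(cl_lev, config$effect_cluster)
    eff_si <- eff(si_lev, config$effect_site)
    eff_sz <- eff(sz_lev, config$effect_size)

    colonies <- unique(metadata$colony_id)
    colony_meta <- metadata[!duplicated(metadata$colony_id), , drop = FALSE]
    rownames(colony_meta) <- colony_meta$colony_id
    colony_log <- matrix(0, length(colonies), nA,
                         dimnames = list(colonies, asv_ids))
    for (ci in seq_along(colonies)) {
      cm <- colony_meta[colonies[ci], ]
      colony_log[ci, ] <- base +
        eff_cl[as.character(cm$cluster), ] +
        eff_si[as.character(cm$site), ] +
        eff_sz[as.character(cm$size_class), ]
    }

    ns <- nrow(metadata)
    counts <- matrix(0L, ns, nA,
                     dimnames = list(metadata$sample_id, asv_ids))
    libsize <- pmax(1L, as.integer(round(rlnorm(ns, config$library_size_log_mean,
                                                config$library_size_log_sd))))
    names(libsize) <- metadata$sample_id
    for (s in seq_len(ns)) {
      ll <- colony_log[metadata$colony_id[s], ] +
        rnorm(nA, 0, config$replicate_noise_sd)
      pr <- exp(ll - max(ll)); pr <- pr / sum(pr)
      counts[s, ] <- rdirmult1(libsize[s], pr, config$overdispersion)
    }

    # intragenomic-variant sets: extra columns slaved to a parent's presence
    variant_sets <- list()
    if (config$n_variant_sets > 0) {
      # parents chosen among prevalent ASVs so the coupling is observable
      prevalence <- colSums(counts > 0)
      parents <- order(prevalence, decreasing = TRUE)[seq_len(min(config$n_variant_sets, nA))]
      extra <- list()
      for (v in seq_along(parents)) {
        pid <- asv_ids[parents[v]]
        nv <- sample(2:4, 1L)
        vids <- sprintf("%s_var%d", pid, seq_len(nv))
        pc <- counts[, parents[v]]
        vm <- sapply(seq_len(nv), function(j)
          as.integer(ceiling(pc * runif(ns, 0.2, 1))))
        colnames(vm) <- vids
        extra[[v]] <- vm
        variant_sets[[pid]] <- c(pid, vids)
      }
      counts <- cbind(counts, do.call(cbind, extra))
    }

    tab <- asv_table(counts, colony = setNames(metadata$colony_id,
                                               metadata$sample_id))
    list(table = tab,
         truth = list(baseline = base, effect_cluster = eff_cl,
                      effect_site = eff_si, effect_size = eff_sz,
                      library_sizes = libsize, variant_sets = variant_sets,
                      base_asvs = asv_ids))
  })
}

#' Simulate a BLAST tabular fixture for consensus-taxonomy testing
#'
#' Emits outfmt-6 style hit rows for one query: a fraction of hits point to
#' strain labels of the true subtype (random lowercase strain suffixes, e.g.
#' "C15au"), the rest to a decoy subtype. E-values are log-uniform below
#' 1e-110 and identities Uniform(96, 100); whether any given hit is a decoy
#' is an independent Bernoulli(noise_fraction) draw.
#'
#' @param true_subtype subtype label, e.g. "C15".
#' @param n_hits number of hit rows.
#' @param noise_fraction probability a hit belongs to the decoy subtype.
#' @param seed integer seed.
#' @param decoy_subtype decoy label (default "C3").
#' @param query_id query sequence id.
#' @return data.frame in outfmt-6 column order (qseqid, sseqid, pident,
#'   length, mismatch, gapopen, qstart, qend, sstart, send, evalue, bitscore).
#' @export
simulate_blast_hits <- function(true_subtype, n_hits, noise_fraction = 0,
                                seed = 1L, decoy_subtype = "C3",
                                query_id = "ASV0001") {
  stopifnot(n_hits >= 1, noise_fraction >= 0, noise_fraction <= 1)
  with_seed(sub_seed(seed, 3L), {
    is_decoy <- runif(n_hits) < noise_fraction
    suffixes <- replicate(n_hits, paste(sample(letters, 2L, replace = TRUE),
                                        collapse = ""))
    sseqid <- paste0(ifelse(is_decoy, decoy_subtype, true_subtype), suffixes)
    evalue <- 10^runif(n_hits, -180, -110)
    pident <- runif(n_hits, 96, 100)
    bitscore <- round(-log10(evalue) * 1.8 + runif(n_hits, 0, 5), 1)
    len <- 260L
    data.frame(qseqid = query_id, sseqid = sseqid, pident = round(pident, 3),
               length = len, mismatch = as.integer(round((100 - pident) / 100 * len)),
               gapopen = 0L, qstart = 1L, qend = len, sstart = 1L, send = len,
               evalue = evalue, bitscore = bitscore,
               stringsAsFactors = FALSE)
  })
}
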