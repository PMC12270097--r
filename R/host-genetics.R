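#' Identity-by-state distance between individuals
#'
#' Analytic expectation of the single-allele-resampling mismatch
#' probability: at a site with dosages g_i, g_j, writing p = g_i/2 and
#' q = g_j/2, the site distance is p(1-q) + (1-p)q; the pairwise distance is
#' the mean over sites non-missing in both individuals (pairwise deletion).
#'
#' @param g individuals x SNPs dosage matrix valued 0/1/2 with NA allowed;
#'   rownames are individual ids.
#' @return labelled square distance matrix.
#' @export
ibs_distance <- function(g) {
  g <- as.matrix(g)
  if (nrow(g) < 2) stop("need >= 2 individuals")
  ok <- g %in% c(0, 1, 2) | is.na(g)
  if (!all(ok)) stop("dosages must be 0, 1, 2 or NA")
  if (is.null(rownames(g))) rownames(g) <- paste0("ind", seq_len(nrow(g)))
  p <- g / 2
  m <- !is.na(p)                      # typed mask
  p0 <- p; p0[!m] <- 0
  storage.mode(m) <- "double"
  n_shared <- m %*% t(m)              # jointly typed sites per pair
  sp <- p0 %*% t(m)                   # sum of p over shared sites
  sq <- m %*% t(p0)                   # sum of q over shared sites
  spq <- p0 %*% t(p0)                 # sum of p*q
  off <- n_shared == 0; diag(off) <- FALSE
  if (any(off)) {
    bad <- which(off, arr.ind = TRUE)[1, ]
    stop("no jointly typed sites for pair ", rownames(g)[bad[1]], " / ",
         rownames(g)[bad[2]])
  }
  d <- (sp + sq - 2 * spq) / n_shared
  dimnames(d) <- list(rownames(g), rownames(g))
  validate_dist(d)
}

#' Collapse clones and replicates to one individual per genotype
#'
#' Cuts an average-linkage hierarchical tree on the distance matrix at
#' `clone_threshold`; within each resulting clone group the sample with the
#' highest genotyping call rate is retained (ties broken towards the
#' lexicographically smallest id). The default threshold is the midpoint of
#' the largest gap in the sorted vector of pairwise distances.
#'
#' @param d labelled square distance matrix.
#' @param clone_threshold height at which to cut the tree; `NULL` for the
#'   largest-gap default.
#' @param quality named per-sample call rates; defaults to 1 for all.
#' @return list with `retained` (character vector), `groups` (named group id
#'   per sample) and `threshold` used.
#' @export
prune_clones <- function(d, clone_threshold = NULL, quality = NULL) {
  d <- validate_dist(d)
  if (nrow(d) == 0) stop("empty distance matrix")
  labs <- rownames(d)
  if (is.null(quality)) quality <- setNames(rep(1, length(labs)), labs)
  if (is.null(clone_threshold)) {
    v <- sort(d[upper.tri(d)])
    if (length(v) < 2) clone_threshold <- 0
    else {
      gaps <- diff(v)
      i <- which.max(gaps)
      clone_threshold <- (v[i] + v[i + 1]) / 2
    }
  }
  if (clone_threshold < 0) stop("clone_threshold must be >= 0")
  if (nrow(d) == 1) {
    groups <- setNames(1L, labs)
  } else {
    hc <- hclust(stats::as.dist(d), method = "average")
    groups <- cutree(hc, h = clone_threshold)
  }
  retained <- vapply(split(labs, groups), function(g) {
    q <- quality[g]
    best <- g[q == max(q)]
    sort(best)[1]
  }, character(1))
  list(retained = unname(sort(retained)), groups = groups,
       threshold = clone_threshold)
}

#' Assign individuals to k genetic clusters
#'
#' Average-linkage hierarchical clustering of the distance matrix cut into
#' `k` groups; group labels are renumbered by order of first appearance so
#' the assignment is deterministic.
#'
#' @param d labelled square distance matrix.
#' @param k number of clusters, 1 <= k <= n.
#' @return named integer factor of cluster labels K1..Kk.
#' @export
assign_clusters <- function(d, k) {
  d <- validate_dist(d)
  n <- nrow(d)
  if (k < 1 || k > n) stop("k must lie in [1, n]")
  if (k == n) {
    lab <- seq_len(n)
  } else if (k == 1) {
    lab <- rep(1L, n)
  } else {
    hc <- hclust(stats::as.dist(d), method = "average")
    lab <- cutree(hc, k = k)
  }
  relabel <- match(lab, unique(lab))  # renumber by first appearance
  out <- factor(paste0("K", relabel), levels = paste0("K", seq_len(max(relabel))))
  names(out) <- rownames(d)
  out
}

#' Weir-Cockerham pairwise FST between clusters
#'
#' Per-SNP variance components a (between populations), b (between
#' individuals within populations) and c (within individuals) of the
#' two-population Weir-Cockerham (1984) estimator, combined across loci as a
#' ratio of sums ("weighted" estimate): FST = sum(a) / sum(a + b + c).
#' Loci monomorphic across a pair are skipped; small negative totals are
#' clamped to zero and flagged in the `clamped` attribute.
#'
#' @param g individuals x SNPs dosage matrix (0/1/2, NA allowed).
#' @param labels cluster labels, one per individual (>= 2 individuals each).
#' @return labelled square FST matrix with attribute `clamped` (logical
#'   matrix marking pairs whose raw estimate was negative).
#' @export
pairwise_fst <- function(g, labels) {
  g <- as.matrix(g)
  labels <- as.factor(labels)
  if (length(labels) != nrow(g)) stop("labels must match rows of g")
  sizes <- table(labels)
  if (any(sizes < 2))
    stop("every cluster needs >= 2 individuals; too small: ",
         paste(names(sizes)[sizes < 2], collapse = ", "))
  kl <- levels(labels)
  K <- length(kl)
  fst <- matrix(0, K, K, dimnames = list(kl, kl))
  clamped <- matrix(FALSE, K, K, dimnames = list(kl, kl))
  for (i in seq_len(K)) for (j in seq_len(i - 1L)) {
    est <- wc_fst_pair(g[labels == kl[i], , drop = FALSE],
                       g[labels == kl[j], , drop = FALSE])
    fst[i, j] <- fst[j, i] <- est$fst
    clamped[i, j] <- clamped[j, i] <- est$clamped
  }
  attr(fst, "clamped") <- clamped
  fst
}

# Weir-Cockerham (1984) components for two populations, all loci vectorised.
wc_fst_pair <- function(g1, g2) {
  n1 <- colSums(!is.na(g1)); n2 <- colSums(!is.na(g2))
  p1 <- colMeans(g1, na.rm = TRUE) / 2
  p2 <- colMeans(g2, na.rm = TRUE) / 2
  h1 <- colMeans(g1 == 1, na.rm = TRUE)
  h2 <- colMeans(g2 == 1, na.rm = TRUE)
  use <- n1 > 0 & n2 > 0
  pbar_all <- (n1 * p1 + n2 * p2) / (n1 + n2)
  poly <- use & pbar_all > 0 & pbar_all < 1 & (n1 + n2) > 2
  if (!any(poly)) return(list(fst = 0, clamped = FALSE))
  n1 <- n1[poly]; n2 <- n2[poly]; p1 <- p1[poly]; p2 <- p2[poly]
  h1 <- h1[poly]; h2 <- h2[poly]
  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2
  num <- sum(a); den <- sum(a + b + cc)
  if (den == 0) return(list(fst = 0, clamped = FALSE))
  fst <- num / den
  clamped <- fst < 0
  list(fst = max(0, min(1, fst)), clamped = clamped)
}

#' UPGMA tree from a distance matrix
#'
#' Standard unweighted pair-group method with arithmetic mean: repeatedly
#' merge the closest pair of clusters at height equal to their mean
#' inter-cluster distance; after merging i and j (i first in the active
#' list), distances to the merged cluster are size-weighted averages. Branch
#' length to a child = merge height / 2 - child height. The result is
#' ultrametric by construction.
#'
#' @param m labelled square distance (or FST) matrix, >= 2 labels.
#' @return object of class `upgma_tree`: list with `merge` (hclust-style),
#'   `heights` (merge heights), `labels` and `newick`.
#' @export
upgma <- function(m) {
  m <- validate_dist(m)
  n <- nrow(m)
  if (n < 2) stop("need >= 2 labels")
  labs <- rownames(m)
  active <- as.list(seq_len(n))            # active cluster -> member leaf idx
  node_str <- as.list(labs)                # newick fragment per active cluster
  node_h <- rep(0, n)                      # height of each active cluster
  neg <- -seq_len(n)                       # hclust-style node codes
  d <- m
  merge <- matrix(0L, n - 1L, 2L)
  heights <- numeric(n - 1L)
  for (step in seq_len(n - 1L)) {
    nn <- nrow(d)
    dd <- d; dd[lower.tri(dd, diag = TRUE)] <- Inf
    ij <- which(dd == min(dd), arr.ind = TRUE)
    ij <- ij[order(ij[, 1], ij[, 2]), , drop = FALSE][1, ]  # deterministic ties
    i <- ij[1]; j <- ij[2]
    h <- d[i, j]
    bi <- h / 2 - node_h[i]
    bj <- h / 2 - node_h[j]
    merge[step, ] <- c(neg[i], neg[j])
    heights[step] <- h
    new_str <- sprintf("(%s:%.10g,%s:%.10g)", node_str[[i]], bi,
                       node_str[[j]], bj)
    si <- length(active[[i]]); sj <- length(active[[j]])
    # merged cluster takes position i; position j is removed
    pos <- setdiff(seq_len(nn), j)
    others <- setdiff(seq_len(nn), c(i, j))
    newd_all <- rep(0, nn)
    if (length(others))
      newd_all[others] <- (si * d[i, others] + sj * d[j, others]) / (si + sj)
    d2 <- d[pos, pos, drop = FALSE]
    ii <- match(i, pos)
    d2[ii, ] <- newd_all[pos]
    d2[, ii] <- newd_all[pos]
    d2[ii, ii] <- 0
    rn <- rownames(d)[pos]; rn[ii] <- sprintf("node%d", step)
    dimnames(d2) <- list(rn, rn)
    d <- d2
    active[[i]] <- c(active[[i]], active[[j]]); active <- active[pos]
    node_str[[i]] <- new_str; node_str <- node_str[pos]
    node_h[i] <- h / 2; node_h <- node_h[pos]
    neg[i] <- step; neg <- neg[pos]
  }
  structure(list(merge = merge, heights = heights, labels = labs,
                 newick = paste0(node_str[[1]], ";")),
            class = "upgma_tree")
}

#' @export
print.upgma_tree <- function(x, ...) {
  cat("UPGMA tree over", length(x$labels), "leaves\n", x$newick, "\n")
  invisible(x)
}

#' Cophenetic (tree) distances of an UPGMA tree
#'
#' @param tree an `upgma_tree`.
#' @return labelled matrix of 2 x merge-height distances between leaves.
#' @export
upgma_cophenetic <- function(tree) {
  n <- length(tree$labels)
  members <- lapply(seq_len(n), identity)
  coph <- matrix(0, n, n, dimnames = list(tree$labels, tree$labels))
  for (s in seq_len(n - 1L)) {
    get_m <- function(code) if (code < 0) -code else members[[n + code]]
    a <- get_m(tree$merge[s, 1]); b <- get_m(tree$merge[s, 2])
    coph[a, b] <- tree$heights[s]
    coph[b, a] <- tree$heights[s]
    members[[n + s]] <- c(a, b)
  }
  coph
}
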