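#' Principal coordinates analysis (classical metric scaling)
#'
#' Gower double-centering of the squared distance matrix, B = -1/2 J D^2 J
#' with J = I - 11'/n, followed by an eigendecomposition. Axes with
#' eigenvalue > 1e-10 are kept and scaled by the square root of their
#' eigenvalue; negative eigenvalues are reported, not corrected.
#'
#' @param d labelled square distance matrix.
#' @return list of class `pcoa_result`: `coordinates` (n x m), `eigenvalues`
#'   (all, descending) and `rel_eig` (positive-eigenvalue variance shares).
#' @export
pcoa <- function(d) {
  d <- validate_dist(d)
  n <- nrow(d)
  if (n < 2) stop("need >= 2 points")
  B <- gower_center(d)
  eg <- eigen(B, symmetric = TRUE)
  vals <- eg$values
  keep <- vals > 1e-10
  coords <- eg$vectors[, keep, drop = FALSE] %*%
    diag(sqrt(vals[keep]), sum(keep))
  rownames(coords) <- rownames(d)
  colnames(coords) <- paste0("PCo", seq_len(ncol(coords)))
  structure(list(coordinates = coords, eigenvalues = vals,
                 rel_eig = vals[keep] / sum(vals[keep])),
            class = "pcoa_result")
}

# -1/2 J D^2 J
gower_center <- function(d) {
  a <- -0.5 * d^2
  rm_ <- rowMeans(a); gm <- mean(a)
  sweep(sweep(a, 1, rm_), 2, rm_) + gm
}

#' Marginal-term PERMANOVA on a distance matrix
#'
#' Permutational multivariate ANOVA with marginal (type-III-like) sums of
#' squares: with G the Gower-centered matrix and H the hat matrix of the
#' full design, each term's SS is trace(GH_full) - trace(GH_without-term),
#' its df the rank drop, and its pseudo-F uses the full-model residual.
#' p-values come from free permutation of the sample labels (joint
#' row/column permutation of the distance matrix), recomputing every term
#' per permutation; the comparison is F_perm >= F_obs with the +1
#' convention. Factors use treatment coding; interaction columns are
#' products of main-effect columns (standard `model.matrix` behaviour).
#' Confounded terms (zero rank drop) are reported with df 0 and NA F/p.
#'
#' @param d labelled square distance matrix.
#' @param metadata data.frame, rows matching `rownames(d)` (reordered by
#'   label when rownames are present).
#' @param formula right-hand-side model formula, e.g.
#'   `~ cluster + site + size_class` or with interactions `site * size_class`.
#' @param n_perm number of permutations (>= 99), or `"exhaustive"` to
#'   enumerate all n! label permutations (n <= 8).
#' @param seed permutation RNG seed.
#' @return data.frame of class `permanova_table` with per-term Df, SumOfSqs,
#'   R2, F and `Pr(>F)` plus Residual and Total rows; attributes `n_perm`,
#'   `seed`, `clamped`.
#' @export
permanova_marginal <- function(d, metadata, formula, n_perm = 999, seed = 1L) {
  d <- validate_dist(d)
  n <- nrow(d)
  exhaustive <- identical(n_perm, "exhaustive")
  if (!exhaustive && n_perm < 99) stop("n_perm must be >= 99 (or \"exhaustive\")")
  if (!is.null(rownames(metadata)) &&
      all(rownames(d) %in% rownames(metadata))) {
    metadata <- metadata[rownames(d), , drop = FALSE]
  } else if (nrow(metadata) != n) {
    stop("metadata rows must match the distance matrix labels")
  }
  tt <- terms(formula)
  labels_t <- attr(tt, "term.labels")
  if (length(labels_t) == 0) stop("formula has no terms")
  for (v in all.vars(formula)) {
    if (is.factor(metadata[[v]]) || is.character(metadata[[v]])) {
      f <- droplevels(as.factor(metadata[[v]]))
      if (nlevels(f) < 2) stop("term '", v, "' has a single level")
      metadata[[v]] <- f
    }
  }
  X <- model.matrix(formula, data = metadata)
  assign_ <- attr(X, "assign")
  G <- gower_center(d)
  ss_total <- sum(diag(G))

  hat_of <- function(cols) {
    Xs <- X[, cols, drop = FALSE]
    if (ncol(Xs) == 0) return(matrix(0, n, n))
    s <- svd(Xs)
    pos <- s$d > max(dim(Xs)) * .Machine$double.eps * max(s$d, 1)
    U <- s$u[, pos, drop = FALSE]
    U %*% t(U)
  }
  H_full <- hat_of(seq_len(ncol(X)))
  rank_full <- qr_rank(X)
  H_red <- lapply(seq_along(labels_t), function(ti)
    hat_of(which(assign_ != ti)))
  rank_red <- vapply(seq_along(labels_t), function(ti)
    qr_rank(X[, assign_ != ti, drop = FALSE]), integer(1))
  df_t <- rank_full - rank_red
  df_res <- n - rank_full

  stat_for <- function(p) {
    Gp <- G[p, p]
    ss_model <- sum(Gp * H_full)          # trace(Gp H), H symmetric
    ss_res <- ss_total - ss_model
    ss_t <- vapply(H_red, function(h) ss_model - sum(Gp * h), numeric(1))
    Fv <- ifelse(df_t > 0, (ss_t / df_t) / (ss_res / df_res), NA_real_)
    list(ss_t = ss_t, ss_res = ss_res, F = Fv)
  }
  obs <- stat_for(seq_len(n))

  if (exhaustive) {
    P <- all_perms(n)
    count <- rep(0, length(labels_t)); tot <- nrow(P)
    for (r in seq_len(nrow(P))) {
      Fp <- stat_for(P[r, ])$F
      count <- count + as.numeric(!is.na(Fp) & Fp >= obs$F - 1e-12)
    }
    pval <- count / tot
    n_perm_used <- tot
  } else {
    count <- rep(0, length(labels_t))
    with_seed(sub_seed(seed, 4L), {
      for (b in seq_len(n_perm)) {
        Fp <- stat_for(sample.int(n))$F
        count <- count + as.numeric(!is.na(Fp) & Fp >= obs$F - 1e-12)
      }
    })
    pval <- (1 + count) / (1 + n_perm)
    n_perm_used <- n_perm
  }
  pval[df_t == 0] <- NA_real_

  clamped <- any(obs$ss_t < 0)
  ss_rep <- pmax(obs$ss_t, 0)
  out <- data.frame(
    Df = c(df_t, df_res, n - 1L),
    SumOfSqs = c(ss_rep, obs$ss_res, ss_total),
    R2 = c(ss_rep / ss_total, obs$ss_res / ss_total, 1),
    F = c(obs$F, NA, NA),
    `Pr(>F)` = c(pval, NA, NA),
    row.names = c(labels_t, "Residual", "Total"),
    check.names = FALSE)
  attr(out, "n_perm") <- n_perm_used
  attr(out, "seed") <- seed
  attr(out, "clamped") <- clamped
  class(out) <- c("permanova_table", "data.frame")
  out
}

#' Group-dispersion permutation test (betadisper-style)
#'
#' Embeds the distance matrix by [pcoa()] (positive axes only), computes
#' each sample's Euclidean distance to its group centroid in that space, and
#' tests homogeneity of these dispersions with a one-way F statistic whose
#' null distribution comes from permuting group labels.
#'
#' @param d labelled square distance matrix.
#' @param groups group labels, >= 2 groups with >= 2 members.
#' @param n_perm number of permutations.
#' @param seed permutation RNG seed.
#' @return list of class `dispersion_result`: `group_means`, `distances`,
#'   `F`, `p`, `n_perm`.
#' @export
dispersion_test <- function(d, groups, n_perm = 999, seed = 1L) {
  d <- validate_dist(d)
  groups <- droplevels(as.factor(groups))
  if (length(groups) != nrow(d)) stop("groups must match the matrix")
  sizes <- table(groups)
  if (sum(sizes >= 2) < 2)
    stop("need >= 2 groups with >= 2 members")
  co <- pcoa(d)$coordinates
  dist_to_centroid <- function(g) {
    out <- numeric(length(g))
    for (lev in levels(g)) {
      idx <- which(g == lev)
      cen <- colMeans(co[idx, , drop = FALSE])
      out[idx] <- sqrt(rowSums((co[idx, , drop = FALSE] -
                                  rep(cen, each = length(idx)))^2))
    }
    out
  }
  oneway_F <- function(z, g) {
    gm <- mean(z)
    mg <- tapply(z, g, mean); ng <- tapply(z, g, length)
    ssb <- sum(ng * (mg - gm)^2)
    ssw <- sum((z - mg[g])^2)
    dfb <- nlevels(g) - 1L; dfw <- length(z) - nlevels(g)
    if (ssw == 0) return(if (ssb == 0) 0 else Inf)
    (ssb / dfb) / (ssw / dfw)
  }
  z_obs <- dist_to_centroid(groups)
  F_obs <- oneway_F(z_obs, groups)
  count <- 0L
  with_seed(sub_seed(seed, 6L), {
    for (b in seq_len(n_perm)) {
      gp <- groups[sample.int(length(groups))]
      Fp <- oneway_F(dist_to_centroid(gp), gp)
      if (Fp >= F_obs - 1e-12) count <- count + 1L
    }
  })
  structure(list(group_means = tapply(z_obs, groups, mean),
                 distances = setNames(z_obs, rownames(d)),
                 F = F_obs, p = (1 + count) / (1 + n_perm),
                 n_perm = n_perm),
            class = "dispersion_result")
}

#' @export
print.permanova_table <- function(x, ...) {
  cat("Marginal-term PERMANOVA (", attr(x, "n_perm"), " permutations)\n",
      sep = "")
  print.data.frame(round(as.data.frame(x), 4))
  invisible(x)
}

#' @export
print.dispersion_result <- function(x, ...) {
  cat("Group dispersion test: F =", round(x$F, 3), ", p =", x$p, "\n")
  print(round(x$group_means, 4))
  invisible(x)
}
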