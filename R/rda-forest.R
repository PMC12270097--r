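#' One-hot (full dummy) coding of categorical predictors
#'
#' Each categorical predictor expands to one 0/1 column per level, with no
#' reference level dropped; quantitative predictors pass through as single
#' columns. The level-to-parent map is recorded for later aggregation.
#'
#' @param metadata data.frame of predictors (rows = samples).
#' @param predictors character vector of column names to use.
#' @return list with `x` (numeric matrix) and `parent` (named character
#'   vector: column -> parent predictor).
#' @export
dummy_code <- function(metadata, predictors) {
  stopifnot(all(predictors %in% names(metadata)))
  cols <- list(); parent <- character(0)
  for (v in predictors) {
    val <- metadata[[v]]
    if (is.numeric(val)) {
      if (var(val) == 0) stop("constant predictor: ", v)
      cols[[v]] <- matrix(val, ncol = 1, dimnames = list(NULL, v))
      parent[v] <- v
    } else {
      f <- droplevels(as.factor(val))
      if (nlevels(f) < 2) stop("constant predictor: ", v)
      m <- sapply(levels(f), function(l) as.numeric(f == l))
      colnames(m) <- paste0(v, ".", levels(f))
      cols[[v]] <- m
      parent[colnames(m)] <- v
    }
  }
  x <- do.call(cbind, cols)
  rownames(x) <- rownames(metadata)
  list(x = x, parent = parent)
}

#' Maximum conditional-permutation level
#'
#' floor(log2(n * 0.368 / 2)), the depth bound used when permutation
#' importance is stratified by correlated predictors (0.368 is the expected
#' OOB fraction of a bootstrap sample).
#'
#' @param n_individuals sample size; must satisfy n * 0.368 / 2 > 1.
#' @return integer level.
#' @export
compute_max_level <- function(n_individuals) {
  arg <- n_individuals * 0.368 / 2
  if (arg <= 1) stop("n_individuals too small: log2 argument <= 1")
  as.integer(floor(log2(arg)))
}

#' Configuration for the RDA-forest importance analysis
#'
#' @param n_axes number of leading PCoA axes used as responses (default 15).
#' @param n_trees bootstrapped trees per forest (default 1500).
#' @param max_level conditional-permutation depth bound; `NULL` = derive via
#'   [compute_max_level()] from the sample size.
#' @param seed forest RNG seed.
#' @param conditional_importance stratify OOB permutations within partitions
#'   of correlated predictors (experimental; default off = standard Breiman
#'   permutation importance).
#' @param mtry predictors tried per split; default max(1, floor(p/3)).
#' @param min_node minimal node size eligible for splitting (default 5).
#' @return list of class `rf_config`.
#' @export
rf_config <- function(n_axes = 15L, n_trees = 1500L, max_level = NULL,
                      seed = 1L, conditional_importance = FALSE,
                      mtry = NULL, min_node = 5L) {
  stopifnot(n_axes >= 1, n_trees >= 1)
  structure(list(n_axes = as.integer(n_axes), n_trees = as.integer(n_trees),
                 max_level = max_level, seed = as.integer(seed),
                 conditional_importance = isTRUE(conditional_importance),
                 mtry = mtry, min_node = as.integer(min_node)),
            class = "rf_config")
}

#' Random-forest variable importance for ordination axes
#'
#' For each retained PCoA axis (up to `n_axes`), a regression random forest
#' predicts the axis scores from all predictor columns; the axis's
#' contribution is weighted by its floored out-of-bag R-squared times its
#' eigenvalue share among the axes used. Per-column OOB permutation
#' importances (negatives floored at 0) are normalised to sum 1 within an
#' axis and combined across axes with those weights. Total model importance
#' is the sum over columns.
#'
#' @param p a `pcoa_result` from [pcoa()].
#' @param x a predictor matrix from [dummy_code()] (the list, or a bare
#'   matrix plus `parent`).
#' @param cfg an [rf_config()].
#' @return list of class `importance_report`: `column_importance`,
#'   `importance` (per parent), `shares`, `axis_r2`, `axis_weights`,
#'   `total`, `parent`, `config`.
#' @export
fit_rda_forest <- function(p, x, cfg = rf_config()) {
  stopifnot(inherits(p, "pcoa_result"))
  if (is.list(x) && !is.null(x$x)) { parent <- x$parent; x <- x$x }
  else stop("x must be the list returned by dummy_code()")
  co <- p$coordinates
  if (!is.null(rownames(x)) && !is.null(rownames(co))) {
    if (!setequal(rownames(x), rownames(co)))
      stop("sample labels of predictors and coordinates differ")
    x <- x[rownames(co), , drop = FALSE]
  } else if (nrow(x) != nrow(co)) {
    stop("predictor rows must match coordinate rows")
  }
  m <- min(cfg$n_axes, ncol(co))
  if (m < 1) stop("no positive PCoA axes available")
  eig <- p$eigenvalues[seq_len(m)]
  eig_w <- eig / sum(eig)
  n <- nrow(x); pcols <- ncol(x)
  mtry <- if (is.null(cfg$mtry)) max(1L, floor(pcols / 3)) else as.integer(cfg$mtry)

  strata <- matrix(0L, 0, 0)
  if (cfg$conditional_importance) {
    max_level <- if (is.null(cfg$max_level)) compute_max_level(n) else cfg$max_level
    strata <- conditional_strata(x, max_level)
  }

  imp_cols <- matrix(0, pcols, m, dimnames = list(colnames(x), NULL))
  axis_r2 <- numeric(m)
  for (k in seq_len(m)) {
    y <- co[, k]
    fit <- .rf_regression(x, y, cfg$n_trees, mtry, cfg$min_node,
                          sub_seed(cfg$seed, 5L + k), strata)
    ok <- !is.na(fit$oob_pred)
    mse <- mean((y[ok] - fit$oob_pred[ok])^2)
    r2 <- 1 - mse / mean((y - mean(y))^2)
    axis_r2[k] <- max(0, r2)
    ii <- pmax(fit$importance, 0)
    if (sum(ii) > 0) ii <- ii / sum(ii)
    imp_cols[, k] <- ii
  }
  w <- axis_r2 * eig_w
  col_imp <- as.vector(imp_cols %*% w)
  names(col_imp) <- colnames(x)
  rep_ <- structure(list(column_importance = col_imp,
                         importance = NULL, shares = NULL,
                         axis_r2 = axis_r2, axis_weights = w,
                         total = sum(col_imp), parent = parent,
                         config = cfg),
                    class = "importance_report")
  rep_ <- aggregate_importance(rep_)
  rep_
}

# Stratum ids per predictor for conditional permutation: samples are
# partitioned by the joint levels of up to `max_level` other predictors with
# |cor| > 0.5 to the permuted one (extendedForest-style, simplified to a
# direct partition of the predictor values).
conditional_strata <- function(x, max_level) {
  p <- ncol(x); n <- nrow(x)
  cm <- suppressWarnings(cor(x))
  cm[!is.finite(cm)] <- 0
  out <- matrix(0L, n, p)
  for (f in seq_len(p)) {
    related <- setdiff(order(-abs(cm[, f])), f)
    related <- related[abs(cm[related, f]) > 0.5]
    related <- utils::head(related, max_level)
    if (!length(related)) next
    key <- apply(x[, related, drop = FALSE], 1, paste, collapse = "|")
    out[, f] <- as.integer(factor(key)) - 1L
  }
  out
}

#' Sum dummy-column importances to parent predictors
#'
#' @param report an `importance_report` with `column_importance` and
#'   `parent` populated.
#' @param parent optional replacement column -> parent map.
#' @return the report with `importance` (per parent) and `shares` filled in;
#'   total importance is unchanged by aggregation.
#' @export
aggregate_importance <- function(report, parent = NULL) {
  stopifnot(inherits(report, "importance_report"))
  if (is.null(parent)) parent <- report$parent
  ci <- report$column_importance
  unmapped <- setdiff(names(ci), names(parent))
  if (length(unmapped))
    stop("columns without a parent mapping: ", paste(unmapped, collapse = ", "))
  fac <- factor(parent[names(ci)], levels = unique(parent))
  agg <- tapply(ci, fac, sum)
  report$importance <- setNames(as.numeric(agg), names(agg))
  report$shares <- if (sum(report$importance) > 0)
    relative_importance(report$importance) else NULL
  report
}

#' Relative importance shares
#'
#' share_v = I_v / total; reported both as fractions and rounded integer
#' percentages.
#'
#' @param importances named nonnegative importances per predictor.
#' @param total denominator; defaults to `sum(importances)`.
#' @return list with `fraction` and `percent` (named vectors).
#' @export
relative_importance <- function(importances, total = sum(importances)) {
  if (any(importances < 0)) stop("importances must be >= 0")
  if (total <= 0) stop("total importance must be > 0")
  fr <- importances / total
  list(fraction = fr, percent = round(100 * fr))
}

#' @export
print.importance_report <- function(x, ...) {
  cat("RDA-forest importance (", length(x$axis_r2), " axes, total = ",
      format(x$total, digits = 3), ")\n", sep = "")
  df <- data.frame(importance = round(x$importance, 4),
                   share = paste0(x$shares$percent, "%"))
  print(df)
  invisible(x)
}
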