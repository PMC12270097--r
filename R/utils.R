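#' @useDynLib holocomm, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats cor cutree dist hclust model.matrix pf rbeta rbinom
#'   rgamma rlnorm rmultinom rnorm runif setNames terms var
#' @importFrom utils read.table write.table
NULL

#' Evaluate an expression under a fixed RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded draws inside package
#' functions never disturb the caller's RNG stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a documented sub-stream seed from a master seed. Offsets used:
# genotypes 0, metadata 1, community 2, blast 3, permanova 4, forest 5,
# dispersion 6. Kept below 2^31.
sub_seed <- function(seed, offset) {
  as.integer((as.double(seed) * 101L + offset) %% .Machine$integer.max)
}

#' Validate a labelled distance matrix
#'
#' Checks that `d` is square, numeric, symmetric (within `tol`), has a zero
#' diagonal and nonnegative entries, and carries row/column labels.
#'
#' @param d square numeric matrix.
#' @param tol symmetry tolerance.
#' @return `d`, with diagonal forced to exactly zero.
#' @export
validate_dist <- function(d, tol = 1e-12) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (!is.matrix(d) || !is.numeric(d) || nrow(d) != ncol(d))
    stop("distance matrix must be a square numeric matrix")
  if (is.null(rownames(d))) {
    rownames(d) <- colnames(d) <- paste0("s", seq_len(nrow(d)))
  }
  if (is.null(colnames(d))) colnames(d) <- rownames(d)
  if (!identical(rownames(d), colnames(d)))
    stop("row and column labels of a distance matrix must agree")
  if (max(abs(d - t(d))) > tol)
    stop("distance matrix is not symmetric within tolerance ", tol)
  if (any(d < -tol)) stop("distance matrix has negative entries")
  d <- (d + t(d)) / 2
  d[d < 0] <- 0
  diag(d) <- 0
  d
}

#' Read / write a labelled square matrix as TSV
#'
#' Plain-text interchange used across the pipeline: tab-separated, header row,
#' first column holds the row labels.
#'
#' @param path file path.
#' @param m labelled matrix.
#' @name matrix_io
#' @export
read_matrix_tsv <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                   row.names = 1, comment.char = "")
  as.matrix(df)
}

#' @rdname matrix_io
#' @export
write_matrix_tsv <- function(m, path) {
  df <- data.frame(id = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# rank of a design matrix via QR, shared by the PERMANOVA code
qr_rank <- function(x) {
  if (ncol(x) == 0L) return(0L)
  qr(x)$rank
}

# all permutations of 1..n (n small); used for exhaustive PERMANOVA p-values
all_perms <- function(n) {
  if (n > 8L) stop("exhaustive permutations only supported for n <= 8")
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1L)
  out <- matrix(0L, nrow = factorial(n), ncol = n)
  r <- 0L
  for (pos in seq_len(n)) {
    blk <- cbind(sub[, seq_len(pos - 1L), drop = FALSE], n,
                 sub[, seq(pos, n - 1L)[seq_len(n - pos)], drop = FALSE])
    out[r + seq_len(nrow(sub)), ] <- blk
    r <- r + nrow(sub)
  }
  storage.mode(out) <- "integer"
  out
}
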