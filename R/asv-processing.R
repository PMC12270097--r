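#' ASV count table
#'
#' Thin container for a samples x ASVs nonnegative integer count matrix plus
#' the sample-to-colony map used when collapsing replicate samples.
#'
#' @param counts integer matrix, rows samples (or colonies), columns ASVs;
#'   must carry row and column names.
#' @param colony named character vector mapping sample id to colony id; when
#'   `NULL` every row is its own colony (already colony-level).
#' @return object of class `asv_table` with elements `counts` and `colony`.
#' @export
asv_table <- function(counts, colony = NULL) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (is.null(rownames(counts)) && nrow(counts) > 0 ||
      is.null(colnames(counts)) && ncol(counts) > 0)
    stop("counts must have row (sample) and column (ASV) names")
  if (is.null(rownames(counts))) rownames(counts) <- character(0)
  if (is.null(colnames(counts))) colnames(counts) <- character(0)
  if (anyDuplicated(rownames(counts)) || anyDuplicated(colnames(counts)))
    stop("duplicate sample or ASV ids")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be nonnegative integers")
  storage.mode(counts) <- "integer"
  if (is.null(colony)) colony <- setNames(rownames(counts), rownames(counts))
  missing <- setdiff(rownames(counts), names(colony))
  if (length(missing))
    stop("samples without a colony mapping: ", paste(missing, collapse = ", "))
  structure(list(counts = counts,
                 colony = colony[rownames(counts)]),
            class = "asv_table")
}

#' @export
print.asv_table <- function(x, ...) {
  cat(sprintf("asv_table: %d samples x %d ASVs (%d colonies), %s reads\n",
              nrow(x$counts), ncol(x$counts), length(unique(x$colony)),
              format(sum(as.double(x$counts)), big.mark = ",")))
  invisible(x)
}

#' Filtering thresholds for ASV community processing
#'
#' Defaults follow the retention rules used for both amplicon communities:
#' an ASV is kept if present in at least `min_colonies_per_asv` colonies
#' (inclusive) and has strictly more than `min_reads_per_asv` total reads; a
#' colony is kept if it has strictly more than `min_reads_per_colony` total
#' reads and strictly more than `min_nonzero_asvs_per_colony` nonzero ASVs.
#' Presence means count > 0. ASVs with presence/absence correlation strictly
#' above `correlation_threshold` are merged into one group.
#'
#' @param min_colonies_per_asv inclusive colony-prevalence floor (default 3).
#' @param min_reads_per_asv strict total-read floor per ASV (default 100).
#' @param min_reads_per_colony strict total-read floor per colony (default 1000).
#' @param min_nonzero_asvs_per_colony strict richness floor (default 3).
#' @param correlation_threshold strict presence-correlation threshold (default 0.8).
#' @return list of class `filter_config`.
#' @export
filter_config <- function(min_colonies_per_asv = 3,
                          min_reads_per_asv = 100,
                          min_reads_per_colony = 1000,
                          min_nonzero_asvs_per_colony = 3,
                          correlation_threshold = 0.8) {
  cfg <- list(min_colonies_per_asv = min_colonies_per_asv,
              min_reads_per_asv = min_reads_per_asv,
              min_reads_per_colony = min_reads_per_colony,
              min_nonzero_asvs_per_colony = min_nonzero_asvs_per_colony,
              correlation_threshold = correlation_threshold)
  if (any(unlist(cfg) < 0)) stop("all thresholds must be >= 0")
  class(cfg) <- "filter_config"
  cfg
}

#' Sum replicate samples into colony-level counts
#'
#' @param t an [asv_table()] at sample level.
#' @return an [asv_table()] whose rows are colonies (ordered by first
#'   appearance); total reads are conserved.
#' @export
aggregate_replicates <- function(t) {
  stopifnot(inherits(t, "asv_table"))
  cols <- unique(t$colony)
  out <- rowsum(t$counts, group = factor(t$colony, levels = cols))
  storage.mode(out) <- "integer"
  asv_table(out)
}

#' Group ASVs with correlated presence/absence patterns
#'
#' Computes the phi coefficient (Pearson correlation of 0/1 presence
#' vectors) between all ASV pairs and merges ASVs connected by correlations
#' strictly above the threshold into one group (connected components, so
#' grouping is transitive). Zero-variance presence vectors (all-present or
#' all-absent ASVs) are merged only with identical vectors, never through a
#' correlation edge. Grouped counts are the per-sample sums over members and
#' the group id is the lexicographically smallest member id.
#'
#' @param t an [asv_table()].
#' @param cfg a [filter_config()].
#' @return list with `groups` (data.frame asv_id, group_id), `members`
#'   (named list group id -> member ids) and `table` (grouped [asv_table()]).
#' @export
group_correlated_asvs <- function(t, cfg = filter_config()) {
  stopifnot(inherits(t, "asv_table"))
  if (nrow(t$counts) < 2) stop("need >= 2 samples to correlate presences")
  pres <- t$counts > 0
  storage.mode(pres) <- "double"
  p <- ncol(pres)
  vars <- apply(pres, 2, var)
  const <- vars == 0
  parent <- seq_len(p)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  union_ <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj)
    invisible(NULL)
  }
  if (any(!const)) {
    idx <- which(!const)
    if (length(idx) >= 2) {
      cm <- suppressWarnings(cor(pres[, idx, drop = FALSE]))
      for (a in seq_along(idx)) for (b in seq_len(a - 1L)) {
        if (isTRUE(cm[a, b] > cfg$correlation_threshold)) union_(idx[a], idx[b])
      }
    }
  }
  # constant-presence ASVs: group with exact duplicates only
  if (any(const)) {
    cidx <- which(const)
    key <- apply(pres[, cidx, drop = FALSE], 2, paste, collapse = "")
    for (k in unique(key)) {
      same <- cidx[key == k]
      if (length(same) > 1) for (j in same[-1]) union_(same[1], j)
    }
  }
  roots <- vapply(seq_len(p), find, integer(1))
  ids <- colnames(t$counts)
  members <- split(ids, roots)
  group_id <- vapply(members, function(m) min(m), character(1))
  names(members) <- group_id
  members <- members[order(names(members))]
  asv2group <- setNames(rep(names(members), lengths(members)),
                        unlist(members, use.names = FALSE))
  grouped <- rowsum(t(t$counts), group = factor(asv2group[ids],
                                                levels = names(members)))
  grouped <- t(grouped)
  storage.mode(grouped) <- "integer"
  list(groups = data.frame(asv_id = ids, group_id = unname(asv2group[ids]),
                           stringsAsFactors = FALSE),
       members = members,
       table = asv_table(grouped, colony = t$colony))
}

#' Retain ASVs by colony prevalence and total reads
#'
#' Keeps an ASV iff it is present (count > 0) in at least
#' `min_colonies_per_asv` rows (inclusive) and its total reads strictly
#' exceed `min_reads_per_asv`.
#'
#' @param t a colony-level [asv_table()].
#' @param cfg a [filter_config()].
#' @return filtered [asv_table()].
#' @export
filter_asvs <- function(t, cfg = filter_config()) {
  stopifnot(inherits(t, "asv_table"))
  prevalence <- colSums(t$counts > 0)
  reads <- colSums(t$counts)
  keep <- prevalence >= cfg$min_colonies_per_asv & reads > cfg$min_reads_per_asv
  asv_table(t$counts[, keep, drop = FALSE], colony = t$colony)
}

#' Retain colonies by total reads and richness
#'
#' Keeps a row iff its total reads strictly exceed `min_reads_per_colony`
#' and its number of nonzero ASVs strictly exceeds
#' `min_nonzero_asvs_per_colony`.
#'
#' @param t an [asv_table()].
#' @param cfg a [filter_config()].
#' @return filtered [asv_table()].
#' @export
filter_colonies <- function(t, cfg = filter_config()) {
  stopifnot(inherits(t, "asv_table"))
  reads <- rowSums(t$counts)
  rich <- rowSums(t$counts > 0)
  keep <- reads > cfg$min_reads_per_colony &
    rich > cfg$min_nonzero_asvs_per_colony
  if (!any(keep))
    stop("all colonies removed by the colony filters; review ",
         "min_reads_per_colony / min_nonzero_asvs_per_colony")
  asv_table(t$counts[keep, , drop = FALSE], colony = t$colony[keep])
}

#' Restrict a community table to genotyped colonies
#'
#' Inner join on colony id against the set of colonies with host genetic
#' data; colonies without genotypes are dropped (reported via a message).
#'
#' @param t an [asv_table()] (colony-level).
#' @param genotyped character vector of genotyped colony ids.
#' @return restricted [asv_table()].
#' @export
join_with_genotyped <- function(t, genotyped) {
  stopifnot(inherits(t, "asv_table"))
  keep <- rownames(t$counts) %in% genotyped
  if (!any(keep))
    stop("no overlap between community colonies and genotyped colonies")
  dropped <- rownames(t$counts)[!keep]
  if (length(dropped))
    message("dropping ", length(dropped), " colonies without genotypes: ",
            paste(utils::head(dropped, 5), collapse = ", "),
            if (length(dropped) > 5) ", ..." else "")
  asv_table(t$counts[keep, , drop = FALSE], colony = t$colony[keep])
}

#' Hellinger standardisation
#'
#' value = sqrt(count / row total); every row then has unit sum of squares.
#'
#' @param t an [asv_table()] or nonnegative matrix.
#' @return numeric matrix of Hellinger-standardised abundances.
#' @export
hellinger <- function(t) {
  m <- if (inherits(t, "asv_table")) t$counts else as.matrix(t)
  tot <- rowSums(m)
  if (any(tot == 0)) stop("zero-sum rows cannot be Hellinger standardised: ",
                          paste(rownames(m)[tot == 0], collapse = ", "))
  sqrt(m / tot)
}

#' Bray-Curtis dissimilarity
#'
#' d(x, y) = sum|x_i - y_i| / sum(x_i + y_i), computed between all row
#' pairs of a nonnegative abundance matrix.
#'
#' @param m nonnegative matrix, rows = colonies/samples.
#' @return labelled square distance matrix in \[0, 1\].
#' @export
bray_curtis <- function(m) {
  m <- as.matrix(m)
  if (any(m < 0)) stop("Bray-Curtis requires nonnegative abundances")
  tot <- rowSums(m)
  n <- nrow(m)
  # sum|x-y| = rowtot_x + rowtot_y - 2*sum(pmin); pmin sum via loop over pairs
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n)) {
    xi <- m[i, ]
    for (j in seq_len(i - 1L)) {
      denom <- tot[i] + tot[j]
      if (denom == 0) stop("both rows all-zero: ", rownames(m)[i], ", ",
                           rownames(m)[j])
      d[i, j] <- d[j, i] <- 1 - 2 * sum(pmin(xi, m[j, ])) / denom
    }
  }
  validate_dist(d)
}

#' Run the fixed community-processing pipeline
#'
#' Order (logged): ASV grouping (ITS2 mode only) -> replicate aggregation ->
#' ASV filters -> colony filters -> restriction to genotyped colonies ->
#' Hellinger -> Bray-Curtis.
#'
#' @param t sample-level [asv_table()].
#' @param cfg a [filter_config()].
#' @param mode `"its2"` (with ASV grouping) or `"16s"` (without).
#' @param genotyped optional character vector of genotyped colony ids.
#' @return list with the intermediate tables, the Hellinger matrix and the
#'   Bray-Curtis distance matrix.
#' @export
process_community <- function(t, cfg = filter_config(),
                              mode = c("its2", "16s"), genotyped = NULL) {
  mode <- match.arg(mode)
  steps <- character(0)
  grouping <- NULL
  if (mode == "its2") {
    grouping <- group_correlated_asvs(t, cfg)
    t <- grouping$table
    steps <- c(steps, "group_correlated_asvs")
  }
  t <- aggregate_replicates(t); steps <- c(steps, "aggregate_replicates")
  t <- filter_asvs(t, cfg); steps <- c(steps, "filter_asvs")
  t <- filter_colonies(t, cfg); steps <- c(steps, "filter_colonies")
  if (!is.null(genotyped)) {
    t <- join_with_genotyped(t, genotyped)
    steps <- c(steps, "join_with_genotyped")
  }
  h <- hellinger(t); steps <- c(steps, "hellinger")
  d <- bray_curtis(h); steps <- c(steps, "bray_curtis")
  list(table = t, grouping = grouping, hellinger = h, dist = d, steps = steps)
}

#' Read / write an ASV count table as TSV
#'
#' @param path file path; tab-separated, header row, first column sample id.
#' @param meta optional metadata data.frame with sample_id and colony_id used
#'   to attach the colony map.
#' @name asv_io
#' @export
read_asv_tsv <- function(path, meta = NULL) {
  m <- read_matrix_tsv(path)
  storage.mode(m) <- "integer"
  colony <- NULL
  if (!is.null(meta)) colony <- setNames(meta$colony_id, meta$sample_id)
  asv_table(m, colony = colony)
}

#' @rdname asv_io
#' @param t an [asv_table()].
#' @export
write_asv_tsv <- function(t, path) {
  write_matrix_tsv(t$counts, path)
}
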