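#' Strip strain suffixes from a Symbiodiniaceae subtype label
#'
#' The subtype is the longest prefix of the form one clade letter followed by
#' digits (e.g. "C15au" -> "C15", "D4c" -> "D4"); trailing lowercase strain
#' letters and anything after them are dropped. Labels not matching the
#' pattern are returned unchanged with attribute `unparsed = TRUE` marked in
#' the result vector's `unparsed` attribute, and a warning.
#'
#' @param strain_label character vector of strain labels.
#' @return character vector of subtype labels with logical attribute
#'   `unparsed`.
#' @export
extract_subtype <- function(strain_label) {
  if (any(!nzchar(strain_label))) stop("empty strain label")
  m <- regmatches(strain_label, regexpr("^[A-I][0-9]+", strain_label))
  hit <- grepl("^[A-I][0-9]+", strain_label)
  out <- strain_label
  out[hit] <- m
  if (any(!hit))
    warning("labels without a clade-letter+digits prefix returned unchanged: ",
            paste(unique(strain_label[!hit]), collapse = ", "))
  attr(out, "unparsed") <- !hit
  out
}

#' Read BLAST tabular output (outfmt 6)
#'
#' Standard 12-column tab-separated format: qseqid, sseqid, pident, length,
#' mismatch, gapopen, qstart, qend, sstart, send, evalue, bitscore.
#'
#' @param path file path.
#' @return data.frame of hits.
#' @export
read_blast_outfmt6 <- function(path) {
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  df <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE,
                   comment.char = "", quote = "")
  if (ncol(df) < 12)
    stop("expected >= 12 outfmt-6 columns, found ", ncol(df))
  bad <- which(!is.finite(suppressWarnings(as.numeric(df[[11]]))) |
                 !is.finite(suppressWarnings(as.numeric(df[[12]]))))
  if (length(bad))
    stop("malformed hit rows (non-numeric evalue/bitscore) at lines: ",
         paste(utils::head(bad, 10), collapse = ", "))
  names(df)[1:12] <- cols
  df
}

#' Consensus subtype assignment from BLAST hits
#'
#' Per query: rank hits by bitscore descending (ties: lower e-value, then
#' subject id), keep the best `max_hits`; retain hits with e-value <
#' `evalue_max` and percent identity > `min_identity`; map subjects to
#' subtypes via [extract_subtype()]. If the modal subtype's share among
#' retained hits exceeds `consensus_min` (strictly, by default; inclusive
#' when `strict = FALSE`) the query is assigned that subtype, otherwise it is
#' left unassigned. No retained hits gives an unassigned call with consensus
#' 0.
#'
#' @param hits data.frame of BLAST hits (one or many queries) with columns
#'   qseqid, sseqid, pident, evalue, bitscore.
#' @param max_hits best hits considered per query (default 30).
#' @param evalue_max strict e-value ceiling (default 1e-100).
#' @param min_identity strict percent-identity floor (default 95).
#' @param consensus_min consensus threshold (default 0.90).
#' @param strict compare consensus with `>` (default) or `>=`.
#' @return data.frame with columns query, subtype (NA when unassigned),
#'   consensus, n_retained.
#' @export
assign_consensus <- function(hits, max_hits = 30, evalue_max = 1e-100,
                             min_identity = 95, consensus_min = 0.90,
                             strict = TRUE) {
  stopifnot(max_hits >= 1, evalue_max > 0, consensus_min >= 0)
  need <- c("qseqid", "sseqid", "pident", "evalue", "bitscore")
  if (!all(need %in% names(hits)))
    stop("hits must have columns ", paste(need, collapse = ", "))
  out <- lapply(split(hits, hits$qseqid), function(h) {
    ord <- order(-h$bitscore, h$evalue, h$sseqid)
    h <- h[ord, , drop = FALSE][seq_len(min(max_hits, nrow(h))), , drop = FALSE]
    keep <- h$evalue < evalue_max & h$pident > min_identity
    h <- h[keep, , drop = FALSE]
    if (nrow(h) == 0)
      return(data.frame(query = NA_character_, subtype = NA_character_,
                        consensus = 0, n_retained = 0L,
                        stringsAsFactors = FALSE))
    subs <- suppressWarnings(extract_subtype(h$sseqid))
    tab <- sort(table(subs), decreasing = TRUE)
    # deterministic mode: highest count, then lexicographic
    top_n <- max(tab)
    modal <- sort(names(tab)[tab == top_n])[1]
    cons <- top_n / nrow(h)
    ok <- if (strict) cons > consensus_min else cons >= consensus_min
    data.frame(query = NA_character_,
               subtype = if (ok) modal else NA_character_,
               consensus = cons, n_retained = nrow(h),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  res$query <- names(out)
  rownames(res) <- NULL
  res[, c("query", "subtype", "consensus", "n_retained")]
}
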