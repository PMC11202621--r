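#' Assign candidate sites to genes by genomic span
#'
#' A site is assigned to every gene whose span [start, end] contains its
#' position (1-based inclusive); overlap resolution uses
#' \code{GenomicRanges::findOverlaps}. Sites outside all gene spans are
#' tallied as intergenic.
#'
#' @param candidates \code{CandidateSet} or variant table.
#' @param genes Gene-model table.
#' @return \code{data.frame} with one row per (gene, site) pair: columns
#'   \code{gene_id}, \code{symbol}, \code{chrom}, \code{pos}, \code{ref},
#'   \code{alt}. Attribute \code{n_intergenic} counts unassigned sites.
#' @export
assign_to_genes <- function(candidates, genes) {
  sites <- if (inherits(candidates, "CandidateSet")) candidates$sites else candidates
  empty <- data.frame(gene_id = character(0), symbol = character(0),
                      chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      stringsAsFactors = FALSE)
  if (nrow(sites) == 0) {
    attr(empty, "n_intergenic") <- 0L
    return(empty)
  }
  site_gr <- GenomicRanges::GRanges(sites$chrom,
                                    IRanges::IRanges(sites$pos, sites$pos))
  gene_gr <- GenomicRanges::GRanges(genes$chrom,
                                    IRanges::IRanges(genes$start, genes$end))
  hits <- GenomicRanges::findOverlaps(site_gr, gene_gr, ignore.strand = TRUE)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  out <- data.frame(gene_id = genes$gene_id[si],
                    symbol = genes$symbol[si],
                    chrom = sites$chrom[qi],
                    pos = sites$pos[qi],
                    ref = sites$ref[qi],
                    alt = sites$alt[qi],
                    stringsAsFactors = FALSE)
  attr(out, "n_intergenic") <- nrow(sites) - length(unique(qi))
  out
}

#' Per-gene mutation rates
#'
#' For every gene with at least \code{min_count} assigned mutations,
#' computes \code{frequency = count / length}, where length is the gene's
#' genomic span in bp. Records are sorted by frequency descending, ties
#' broken by symbol.
#'
#' @param assignment Output of \code{\link{assign_to_genes}}.
#' @param genes Gene-model table (provides lengths).
#' @param min_count Minimum mutation count to report a gene (default 2).
#' @return \code{data.frame}(gene_id, symbol, chrom, length, count,
#'   frequency).
#' @export
mutation_rates <- function(assignment, genes, min_count = 2L) {
  if (min_count < 0) {
    stop("min_count must be non-negative")
  }
  if (any(genes$length <= 0)) {
    stop("gene with non-positive length")
  }
  counts <- table(assignment$gene_id)
  count <- as.integer(counts[genes$gene_id])
  count[is.na(count)] <- 0L
  out <- data.frame(gene_id = genes$gene_id,
                    symbol = genes$symbol,
                    chrom = genes$chrom,
                    length = genes$length,
                    count = count,
                    stringsAsFactors = FALSE)
  out <- out[out$count >= min_count, , drop = FALSE]
  out$frequency <- out$count / out$length
  out <- out[order(-out$frequency, out$symbol), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Top-n mutation-rate records
#'
#' @param records Sorted output of \code{\link{mutation_rates}}.
#' @param n Number of records to keep; more than available returns all.
#' @return The first \code{n} records.
#' @export
top_n_rates <- function(records, n) {
  if (n < 0) {
    stop("n must be non-negative")
  }
  utils::head(records, n)
}

#' Format a mutation rate like a published table entry
#'
#' Three significant figures in scientific notation, e.g. \code{"3.23e-03"}.
#'
#' @param x Numeric rates.
#' @return Character vector.
#' @export
format_rate <- function(x) {
  sprintf("%.2e", signif(x, 3))
}

#' Write a mutation-rate table as TSV
#'
#' Columns Gene, Chr, Length, Count, Frequency, with the frequency
#' formatted to 3 significant figures.
#'
#' @param records Output of \code{\link{mutation_rates}}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_rate_table <- function(records, path) {
  utils::write.table(
    data.frame(Gene = records$symbol, Chr = records$chrom,
               Length = records$length, Count = records$count,
               Frequency = format_rate(records$frequency)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
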