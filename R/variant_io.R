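#' Read a VCF into a variant table
#'
#' Reads a VCF 4.x file (via \pkg{vcfR}) and returns one row per biallelic
#' variant. Multi-allelic records are split into one row per alternate
#' allele; symbolic (\code{<DEL>}-style) and star alleles are skipped and
#' tallied in the \code{"n_skipped"} attribute. Per-sample genotypes are
#' classified relative to each split alternate allele: a genotype carrying
#' the allele once is \code{het}, twice is \code{hom_alt}, zero times is
#' \code{hom_ref}; any missing allele makes the observation \code{missing}.
#'
#' @param path Path to an uncompressed or gzipped VCF file.
#' @param sample_names Samples to extract. \code{NULL} takes every sample in
#'   the header; naming a sample absent from the header is an error.
#' @return A \code{data.frame} with columns \code{chrom}, \code{pos},
#'   \code{ref}, \code{alt}, \code{ann} (the SnpEff ANN INFO string or
#'   \code{NA}), and per-sample columns \code{gt_<sample>} and
#'   \code{dp_<sample>}. Attributes: \code{samples}, \code{n_skipped}.
#' @export
read_vcf <- function(path, sample_names = NULL) {
  if (!file.exists(path)) {
    stop("VCF file not found: ", path)
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  have_gt <- ncol(v@gt) > 1
  avail <- if (have_gt) colnames(v@gt)[-1] else character(0)
  if (is.null(sample_names)) {
    sample_names <- avail
  }
  missing_s <- setdiff(sample_names, avail)
  if (length(missing_s) > 0) {
    stop("sample(s) not present in VCF header: ", paste(missing_s, collapse = ", "))
  }
  if (nrow(fix) == 0) {
    return(empty_variants(sample_names))
  }

  gt_raw <- if (have_gt) vcfR::extract.gt(v, element = "GT") else NULL
  dp_raw <- if (have_gt) {
    suppressWarnings(vcfR::extract.gt(v, element = "DP", as.numeric = TRUE))
  } else NULL
  ann_raw <- vcfR::extract.info(v, element = "ANN")

  alts_list <- strsplit(fix$ALT, ",", fixed = TRUE)
  n_alt <- lengths(alts_list)
  idx <- rep.int(seq_len(nrow(fix)), n_alt)
  k <- sequence(n_alt)
  ref <- toupper(fix$REF)[idx]
  alt <- toupper(unlist(alts_list))

  keep <- grepl("^[ACGT]+$", alt) & grepl("^[ACGT]+$", ref) & alt != ref
  n_skipped <- sum(!keep)
  idx <- idx[keep]; k <- k[keep]; ref <- ref[keep]; alt <- alt[keep]
  if (length(idx) == 0) {
    out <- empty_variants(sample_names)
    attr(out, "n_skipped") <- n_skipped
    return(out)
  }

  out <- data.frame(
    chrom = fix$CHROM[idx],
    pos = as.integer(fix$POS[idx]),
    ref = ref,
    alt = alt,
    ann = if (is.null(ann_raw)) NA_character_ else ann_raw[idx],
    stringsAsFactors = FALSE
  )
  for (s in sample_names) {
    gt_strs <- if (have_gt) gt_raw[idx, s] else rep(NA_character_, length(idx))
    out[[paste0("gt_", s)]] <- classify_gt_vec(gt_strs, k)
    dp <- if (have_gt) dp_raw[idx, s] else rep(NA_real_, length(idx))
    out[[paste0("dp_", s)]] <- as.integer(round(dp))
  }
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "samples") <- sample_names
  attr(out, "n_skipped") <- n_skipped
  out
}

empty_variants <- function(sample_names) {
  out <- data.frame(chrom = character(0), pos = integer(0), ref = character(0),
                    alt = character(0), ann = character(0),
                    stringsAsFactors = FALSE)
  for (s in sample_names) {
    out[[paste0("gt_", s)]] <- character(0)
    out[[paste0("dp_", s)]] <- integer(0)
  }
  attr(out, "samples") <- sample_names
  attr(out, "n_skipped") <- 0L
  out
}

# Classify a raw GT string ("0/1", "1|2", "./.") relative to split alt index k.
classify_gt <- function(gt_str, k) {
  if (is.na(gt_str) || gt_str == ".") {
    return("missing")
  }
  alleles <- strsplit(gt_str, "[/|]")[[1]]
  if (any(alleles == ".")) {
    return("missing")
  }
  n_k <- sum(alleles == as.character(k))
  if (n_k >= 2) "hom_alt" else if (n_k == 1) "het" else "hom_ref"
}

classify_gt_vec <- function(gt_strs, k) {
  mapply(classify_gt, gt_strs, k, USE.NAMES = FALSE)
}

#' Unique site key (chrom:pos:ref:alt)
#' @param variants Variant table.
#' @return Character vector of keys.
#' @export
variant_key <- function(variants) {
  paste(variants$chrom, variants$pos, variants$ref, variants$alt, sep = ":")
}

#' Write a variant table as a minimal VCF
#'
#' Emits an uncompressed VCF 4.2 file with GT and DP FORMAT fields and an
#' ANN INFO field where present. Genotype classes are rendered as
#' \code{0/0}, \code{0/1}, \code{1/1} and \code{./.}.
#'
#' @param variants Variant table as returned by \code{\link{read_vcf}}.
#' @param path Output path.
#' @param sample_names Samples to emit; default every sample in the table.
#' @return \code{path}, invisibly.
#' @export
write_vcf <- function(variants, path, sample_names = NULL) {
  if (is.null(sample_names)) {
    sample_names <- attr(variants, "samples")
  }
  if (is.null(sample_names)) {
    sample_names <- sub("^gt_", "", grep("^gt_", names(variants), value = TRUE))
  }
  gt_code <- c(hom_ref = "0/0", het = "0/1", hom_alt = "1/1", missing = "./.")
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=ANN,Number=.,Type=String,Description=\"Functional annotations\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO", "FORMAT",
            sample_names), collapse = "\t")
  )
  ord <- order(variants$chrom, variants$pos)
  v <- variants[ord, , drop = FALSE]
  lines <- character(nrow(v))
  for (i in seq_len(nrow(v))) {
    info <- if (!is.null(v$ann) && !is.na(v$ann[i]) && nzchar(v$ann[i])) {
      paste0("ANN=", v$ann[i])
    } else "."
    cells <- vapply(sample_names, function(s) {
      gt <- gt_code[[v[[paste0("gt_", s)]][i]]]
      dp <- v[[paste0("dp_", s)]][i]
      paste0(gt, ":", if (is.na(dp)) "." else dp)
    }, character(1))
    lines[i] <- paste(c(v$chrom[i], v$pos[i], ".", v$ref[i], v$alt[i], ".",
                        "PASS", info, "GT:DP", cells), collapse = "\t")
  }
  writeLines(c(header, lines), path)
  invisible(path)
}

#' Read a reference genome from FASTA
#'
#' @param path FASTA path (an accompanying \code{.fai} index is not required).
#' @return An object of class \code{ReferenceGenome}: list with \code{seq}
#'   (named uppercase character vector, one element per chromosome) and
#'   \code{lengths}.
#' @export
read_reference <- function(path) {
  if (!file.exists(path)) {
    stop("FASTA file not found: ", path)
  }
  ss <- Biostrings::readDNAStringSet(path)
  # drop description after first whitespace, matching samtools naming
  names(ss) <- sub("\\s.*$", "", names(ss))
  seqs <- toupper(as.character(ss))
  structure(list(seq = seqs, lengths = nchar(seqs)), class = "ReferenceGenome")
}

#' Query a reference genome substring
#'
#' Coordinates are 1-based inclusive.
#'
#' @param genome \code{ReferenceGenome}.
#' @param chrom Chromosome name.
#' @param start,end 1-based inclusive range.
#' @return Uppercase substring.
#' @export
ref_query <- function(genome, chrom, start, end) {
  if (!chrom %in% names(genome$seq)) {
    stop("chromosome not in reference: ", chrom)
  }
  if (start < 1 || end > genome$lengths[[chrom]] || start > end) {
    stop("query out of range: ", chrom, ":", start, "-", end)
  }
  substring(genome$seq[[chrom]], start, end)
}

#' Write a reference genome as FASTA
#' @param genome \code{ReferenceGenome}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_reference <- function(genome, path) {
  ss <- Biostrings::DNAStringSet(genome$seq)
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}

#' Read gene models from GFF3 or GTF
#'
#' One record per \code{gene} feature. Gene length is the genomic span
#' (\code{end - start + 1}). CDS segments are linked to their gene through
#' the transcript layer and only the longest transcript's CDS (by summed
#' CDS width) is kept.
#'
#' @param path GFF3 or GTF path.
#' @param dialect \code{"auto"} (by extension), \code{"gff3"} or \code{"gtf"}.
#' @return \code{data.frame} with columns \code{gene_id}, \code{symbol},
#'   \code{chrom}, \code{start}, \code{end}, \code{strand}, \code{length}
#'   and a list-column \code{cds} of two-column (start, end) matrices.
#' @export
read_gene_models <- function(path, dialect = c("auto", "gff3", "gtf")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.gtf(\\.gz)?$", path, ignore.case = TRUE)) "gtf" else "gff3"
  }
  gr <- rtracklayer::import(path, format = if (dialect == "gtf") "gtf" else "gff3")
  md <- as.data.frame(gr, stringsAsFactors = FALSE)
  types <- tolower(as.character(md$type))

  genes <- md[types == "gene", , drop = FALSE]
  if (nrow(genes) == 0) {
    stop("no gene features found in ", path)
  }
  if (any(genes$end < genes$start)) {
    stop("gene feature with end < start in ", path)
  }
  gene_id <- get_attr(genes, c("gene_id", "ID", "Name"))
  symbol <- get_attr(genes, c("gene_name", "Name", "gene_id", "ID"))
  symbol[is.na(symbol)] <- gene_id[is.na(symbol)]

  out <- data.frame(
    gene_id = gene_id,
    symbol = symbol,
    chrom = as.character(genes$seqnames),
    start = genes$start,
    end = genes$end,
    strand = as.character(genes$strand),
    length = genes$end - genes$start + 1L,
    stringsAsFactors = FALSE
  )

  # attach CDS via the transcript layer; keep the longest transcript per gene
  cds <- md[types == "cds", , drop = FALSE]
  out$cds <- replicate(nrow(out), matrix(integer(0), ncol = 2), simplify = FALSE)
  if (nrow(cds) > 0) {
    if (dialect == "gtf") {
      cds_tx <- get_attr(cds, c("transcript_id"))
      cds_gene <- get_attr(cds, c("gene_id"))
    } else {
      cds_tx <- get_attr(cds, c("Parent", "transcript_id"))
      cds_tx <- vapply(cds_tx, function(x) paste(unlist(x), collapse = ","), character(1))
      tx <- md[types %in% c("mrna", "transcript"), , drop = FALSE]
      tx_id <- get_attr(tx, c("ID", "transcript_id"))
      tx_gene <- get_attr(tx, c("Parent", "gene_id"))
      tx_gene <- vapply(tx_gene, function(x) paste(unlist(x), collapse = ","), character(1))
      cds_gene <- tx_gene[match(cds_tx, tx_id)]
    }
    widths <- cds$end - cds$start + 1L
    for (g in unique(cds_gene[!is.na(cds_gene)])) {
      sel <- which(cds_gene == g)
      tx_of <- cds_tx[sel]
      tx_len <- tapply(widths[sel], tx_of, sum)
      best <- names(tx_len)[which.max(tx_len)]
      seg <- sel[tx_of == best]
      seg <- seg[order(cds$start[seg])]
      gi <- which(out$gene_id == g)
      if (length(gi) == 1) {
        out$cds[[gi]] <- cbind(start = cds$start[seg], end = cds$end[seg])
      }
    }
  }
  rownames(out) <- NULL
  out
}

get_attr <- function(df, candidates) {
  for (nm in candidates) {
    if (nm %in% names(df)) {
      x <- df[[nm]]
      if (is.list(x)) {
        return(vapply(x, function(e) {
          e <- unlist(e)
          if (length(e) == 0) NA_character_ else as.character(e[1])
        }, character(1)))
      }
      return(as.character(x))
    }
  }
  rep(NA_character_, nrow(df))
}

#' Write gene models as GFF3
#'
#' Emits gene, mRNA and CDS features so that
#' \code{\link{read_gene_models}} round-trips the table.
#'
#' @param genes Gene-model table from \code{\link{read_gene_models}} or
#'   \code{\link{simulate_gene_models}}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_gff3 <- function(genes, path) {
  lines <- "##gff-version 3"
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    lines <- c(lines, paste(g$chrom, "somaclone", "gene", g$start, g$end, ".",
                            g$strand, ".",
                            paste0("ID=", g$gene_id, ";Name=", g$symbol),
                            sep = "\t"))
    segs <- genes$cds[[i]]
    if (nrow(segs) > 0) {
      tx_id <- paste0(g$gene_id, ".t1")
      lines <- c(lines, paste(g$chrom, "somaclone", "mRNA", g$start, g$end, ".",
                              g$strand, ".",
                              paste0("ID=", tx_id, ";Parent=", g$gene_id),
                              sep = "\t"))
      for (j in seq_len(nrow(segs))) {
        lines <- c(lines, paste(g$chrom, "somaclone", "CDS", segs[j, 1], segs[j, 2],
                                ".", g$strand, "0",
                                paste0("ID=", tx_id, ".cds;Parent=", tx_id),
                                sep = "\t"))
      }
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a COSMIC-style 96-channel signature matrix
#'
#' The file must be a TSV with one channel-label column (\code{"A[C>A]A"}
#' style) and one column per signature. Channels are re-ordered into the
#' canonical order of \code{\link{sbs_channels}}; each signature column is
#' renormalized to sum to 1 when its sum is within 1e-3 of 1, otherwise the
#' file is rejected.
#'
#' @param path TSV path.
#' @return Object of class \code{ReferenceSignatureSet}: a 96-row numeric
#'   matrix (rownames = channel labels, one column per signature).
#' @export
read_signature_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  is_chan <- vapply(df, function(col) {
    is.character(col) && all(grepl("^[ACGT]\\[[CT]>[ACGT]\\][ACGT]$", col))
  }, logical(1))
  if (!any(is_chan)) {
    stop("no channel-label column found in ", path)
  }
  chan_col <- names(df)[which(is_chan)[1]]
  channels <- df[[chan_col]]
  if (length(channels) != 96 || anyDuplicated(channels)) {
    stop("signature matrix must have exactly the 96 distinct channels (found ",
         length(channels), " rows)")
  }
  canon <- sbs_channels()
  if (!setequal(channels, canon)) {
    stop("channel labels do not match the 96 canonical SBS channels")
  }
  mat <- as.matrix(df[, setdiff(names(df), chan_col), drop = FALSE])
  storage.mode(mat) <- "double"
  if (any(mat < 0)) {
    stop("negative proportion in signature matrix")
  }
  mat <- mat[match(canon, channels), , drop = FALSE]
  rownames(mat) <- canon
  sums <- colSums(mat)
  if (any(abs(sums - 1) > 1e-3)) {
    stop("signature column(s) do not sum to 1 (tolerance 1e-3): ",
         paste(colnames(mat)[abs(sums - 1) > 1e-3], collapse = ", "))
  }
  mat <- sweep(mat, 2, sums, "/")
  structure(mat, class = c("ReferenceSignatureSet", "matrix"))
}

#' Write a signature matrix as TSV
#' @param signatures 96-row matrix with channel rownames.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_signature_matrix <- function(signatures, path) {
  df <- data.frame(Type = rownames(signatures), as.data.frame(unclass(signatures)),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a plain gene list (one symbol per line)
#' @param path File path.
#' @return Character vector of unique, whitespace-trimmed symbols.
#' @export
read_gene_list <- function(path) {
  x <- trimws(readLines(path))
  unique(x[nzchar(x)])
}

#' Read a gene-set collection (2-column TSV: set_name, gene_symbol)
#' @param path File path.
#' @return \code{data.frame} with columns \code{set_name}, \code{gene_symbol}.
#' @export
read_gene_sets <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (ncol(df) < 2) {
    stop("gene-set collection must have two columns (set_name, gene_symbol)")
  }
  names(df)[1:2] <- c("set_name", "gene_symbol")
  df$gene_symbol <- trimws(df$gene_symbol)
  df[, 1:2]
}

#' Read a population allele-frequency panel
#'
#' Accepts either a TSV with columns \code{chrom}, \code{pos}, \code{ref},
#' \code{alt}, \code{af}, \code{missing_rate}, or a VCF with per-sample
#' genotypes, from which the alternate-allele frequency and per-site
#' genotype missing rate are computed.
#'
#' @param path File path.
#' @param n_samples Panel size; required metadata for a TSV panel, computed
#'   from the header for a VCF panel.
#' @return Object of class \code{PopulationPanel}: \code{data.frame} with
#'   columns \code{key}, \code{af}, \code{missing_rate}; attribute
#'   \code{n_samples}.
#' @export
read_population_panel <- function(path, n_samples = NA_integer_) {
  first <- readLines(path, n = 1)
  if (grepl("^##fileformat=VCF", first)) {
    v <- read_vcf(path)
    samples <- attr(v, "samples")
    gt_cols <- paste0("gt_", samples)
    gts <- as.matrix(v[, gt_cols, drop = FALSE])
    n_missing <- rowSums(gts == "missing")
    n_called <- length(samples) - n_missing
    alt_count <- rowSums(gts == "het") + 2 * rowSums(gts == "hom_alt")
    af <- ifelse(n_called > 0, alt_count / (2 * n_called), NA_real_)
    panel <- data.frame(key = variant_key(v), af = af,
                        missing_rate = n_missing / length(samples),
                        stringsAsFactors = FALSE)
    n_samples <- length(samples)
  } else {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("chrom", "pos", "ref", "alt", "af", "missing_rate")
    if (!all(need %in% names(df))) {
      stop("panel TSV must have columns: ", paste(need, collapse = ", "))
    }
    panel <- data.frame(
      key = paste(df$chrom, df$pos, df$ref, df$alt, sep = ":"),
      af = df$af, missing_rate = df$missing_rate, stringsAsFactors = FALSE
    )
  }
  if (any(panel$af < 0 | panel$af > 1, na.rm = TRUE) ||
      any(panel$missing_rate < 0 | panel$missing_rate > 1, na.rm = TRUE)) {
    stop("panel frequencies and missing rates must lie in [0, 1]")
  }
  attr(panel, "n_samples") <- n_samples
  class(panel) <- c("PopulationPanel", "data.frame")
  panel
}
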