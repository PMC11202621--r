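#' SBS channel of a single-base substitution
#'
#' Returns the 96-channel trinucleotide-context label of an SNV,
#' pyrimidine-normalized: when the reference base is a purine (A/G) the
#' context and both alleles are reverse-complemented so that the mutated
#' base is C or T.
#'
#' @param chrom,pos,ref,alt The SNV.
#' @param reference \code{ReferenceGenome}.
#' @return The channel label, or \code{NA} when the site cannot be
#'   classified (position at a chromosome edge, or N in the trinucleotide
#'   context).
#' @export
sbs_channel <- function(chrom, pos, ref, alt, reference) {
  stopifnot(nchar(ref) == 1, nchar(alt) == 1)
  len <- reference$lengths[[chrom]]
  if (is.null(len)) {
    stop("chromosome not in reference: ", chrom)
  }
  genome_base <- ref_query(reference, chrom, pos, pos)
  if (genome_base != ref) {
    stop("ref allele ", ref, " disagrees with reference base ", genome_base,
         " at ", chrom, ":", pos)
  }
  if (pos - 1 < 1 || pos + 1 > len) {
    return(NA_character_)
  }
  ctx <- ref_query(reference, chrom, pos - 1, pos + 1)
  if (grepl("N", ctx, fixed = TRUE)) {
    return(NA_character_)
  }
  r <- ref; a <- alt
  if (r %in% c("A", "G")) {
    ctx <- revcomp(ctx)
    r <- comp_base(r)
    a <- comp_base(a)
  }
  paste0(substring(ctx, 1, 1), "[", r, ">", a, "]", substring(ctx, 3, 3))
}

#' Build the 96-channel substitution spectrum of a set of SNVs
#'
#' Non-SNV rows (multi-base ref or alt) are ignored per the SNV-only
#' contract. SNVs that cannot be classified (chromosome edge or N context)
#' are tallied in \code{dropped}.
#'
#' @param sites Variant table (or \code{CandidateSet}).
#' @param reference \code{ReferenceGenome}.
#' @return Object of class \code{Spectrum96}: list with \code{counts}
#'   (named integer vector over the canonical 96 channels), \code{dropped}
#'   and \code{total}.
#' @export
build_spectrum <- function(sites, reference) {
  if (inherits(sites, "CandidateSet")) {
    sites <- sites$sites
  }
  snv <- sites[nchar(sites$ref) == 1 & nchar(sites$alt) == 1, , drop = FALSE]
  counts <- stats::setNames(integer(96), sbs_channels())
  dropped <- 0L
  for (i in seq_len(nrow(snv))) {
    ch <- sbs_channel(snv$chrom[i], snv$pos[i], snv$ref[i], snv$alt[i], reference)
    if (is.na(ch)) {
      dropped <- dropped + 1L
    } else {
      counts[ch] <- counts[ch] + 1L
    }
  }
  structure(list(counts = counts, dropped = dropped,
                 total = sum(counts)), class = "Spectrum96")
}

#' @export
print.Spectrum96 <- function(x, ...) {
  cat("Spectrum96:", x$total, "classified SNVs,", x$dropped, "dropped\n")
  six <- collapse_to_six_safe(x)
  if (!is.null(six)) {
    cat("6-class proportions:\n")
    print(round(six, 4))
  }
  invisible(x)
}

collapse_to_six_safe <- function(spectrum) {
  if (spectrum$total == 0) NULL else collapse_to_six(spectrum)
}

#' Spectrum proportions
#' @param spectrum \code{Spectrum96}.
#' @return Named numeric vector of 96 proportions summing to 1.
#' @export
spectrum_proportions <- function(spectrum) {
  if (spectrum$total == 0) {
    stop("cannot normalize an empty spectrum")
  }
  spectrum$counts / spectrum$total
}

#' Collapse a 96-channel spectrum to the six substitution classes
#'
#' @param spectrum \code{Spectrum96} with \code{total > 0}.
#' @return Named numeric vector of proportions over C>A, C>G, C>T, T>A,
#'   T>C, T>G, summing to 1.
#' @export
collapse_to_six <- function(spectrum) {
  p <- spectrum_proportions(spectrum)
  cls <- substring(names(p), 3, 5)
  out <- tapply(p, cls, sum)
  classes <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  stats::setNames(as.numeric(out[classes]), classes)
}

#' Cosine similarity between a spectrum and a reference signature
#'
#' @param spectrum \code{Spectrum96}, or a numeric 96-vector of
#'   counts/proportions.
#' @param signature Numeric 96-vector (a column of a
#'   \code{ReferenceSignatureSet}).
#' @return Cosine of the angle between the two vectors, in [0, 1] for
#'   non-negative inputs.
#' @export
cosine_similarity <- function(spectrum, signature) {
  x <- if (inherits(spectrum, "Spectrum96")) as.numeric(spectrum$counts) else
    as.numeric(spectrum)
  y <- as.numeric(signature)
  stopifnot(length(x) == length(y))
  nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0) {
    stop("cosine similarity undefined for a zero-norm vector")
  }
  sum(x * y) / (nx * ny)
}

#' Spectral flatness
#'
#' Shannon entropy of the channel proportions divided by \code{log(96)}:
#' 1 for a perfectly uniform spectrum, 0 when all mass sits in one channel.
#'
#' @param spectrum \code{Spectrum96} with \code{total > 0}.
#' @return Value in [0, 1].
#' @export
flatness <- function(spectrum) {
  p <- spectrum_proportions(spectrum)
  p <- p[p > 0]
  -sum(p * log(p)) / log(96)
}

#' Rank reference signatures by similarity to a spectrum
#'
#' @param spectrum \code{Spectrum96}.
#' @param signatures \code{ReferenceSignatureSet}.
#' @return \code{data.frame}(signature, similarity) sorted by descending
#'   similarity, ties broken by signature name.
#' @export
best_match <- function(spectrum, signatures) {
  if (ncol(signatures) == 0) {
    stop("empty signature set")
  }
  sims <- vapply(colnames(signatures), function(nm) {
    cosine_similarity(spectrum, signatures[, nm])
  }, numeric(1))
  out <- data.frame(signature = names(sims), similarity = unname(sims),
                    stringsAsFactors = FALSE)
  out[order(-out$similarity, out$signature), , drop = FALSE]
}

#' Built-in reference signatures
#'
#' Two pedagogical signatures shipped with the package: \code{"flat"}, the
#' uniform clock-like profile (all 96 channels equal, the shape of the
#' aging-associated SBS5 signature), and \code{"uv_ct"}, a UV-like
#' C>T-dominant profile of the kind seen in transmissible canine tumors and
#' human melanoma. UV photoproducts form at dipyrimidines, so \code{uv_ct}
#' concentrates 90\% of its mass on the eight C>T channels with a
#' pyrimidine 5' flank and spreads the remainder uniformly.
#'
#' @return \code{ReferenceSignatureSet} with columns \code{flat} and
#'   \code{uv_ct}.
#' @export
builtin_signatures <- function() {
  channels <- sbs_channels()
  flat <- rep(1 / 96, 96)
  hot <- substring(channels, 3, 5) == "C>T" &
    substring(channels, 1, 1) %in% c("C", "T")
  uv <- ifelse(hot, 0.9 / 8, 0.1 / 88)
  mat <- cbind(flat = flat, uv_ct = uv)
  rownames(mat) <- channels
  structure(mat, class = c("ReferenceSignatureSet", "matrix"))
}

#' Write spectrum outputs as TSV
#'
#' @param spectrum \code{Spectrum96}.
#' @param signatures Optional \code{ReferenceSignatureSet} for a
#'   similarity table.
#' @param out_dir Output directory.
#' @return Named list of written paths, invisibly.
#' @export
write_spectrum <- function(spectrum, out_dir, signatures = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(spectrum96 = file.path(out_dir, "spectrum_96.tsv"),
                spectrum6 = file.path(out_dir, "spectrum_6class.tsv"))
  prop <- if (spectrum$total > 0) spectrum$counts / spectrum$total else
    rep(NA_real_, 96)
  utils::write.table(
    data.frame(channel = names(spectrum$counts), count = as.integer(spectrum$counts),
               proportion = prop),
    paths$spectrum96, sep = "\t", quote = FALSE, row.names = FALSE)
  if (spectrum$total > 0) {
    six <- collapse_to_six(spectrum)
    utils::write.table(data.frame(class = names(six), proportion = as.numeric(six)),
                       paths$spectrum6, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(signatures) && spectrum$total > 0) {
    paths$similarity <- file.path(out_dir, "signature_similarity.tsv")
    utils::write.table(best_match(spectrum, signatures), paths$similarity,
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(paths)
}
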