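EFFECT_IMPACT <- c(
  intergenic = "MODIFIER",
  intronic = "MODIFIER",
  synonymous = "LOW",
  missense = "MODERATE",
  stop_gained = "HIGH",
  stop_lost = "HIGH",
  start_lost = "HIGH",
  splice_region = "HIGH",
  other = "MODIFIER"
)

IMPACT_RANK <- c(MODIFIER = 0L, LOW = 1L, MODERATE = 2L, HIGH = 3L)

# SnpEff sequence-ontology term -> internal effect class
ANN_EFFECT_MAP <- c(
  intergenic_region = "intergenic",
  intergenic_variant = "intergenic",
  intron_variant = "intronic",
  synonymous_variant = "synonymous",
  missense_variant = "missense",
  stop_gained = "stop_gained",
  stop_lost = "stop_lost",
  start_lost = "start_lost",
  splice_region_variant = "splice_region",
  splice_donor_variant = "splice_region",
  splice_acceptor_variant = "splice_region"
)

#' Parse a SnpEff ANN INFO string
#'
#' The ANN field is a comma-separated list of pipe-delimited entries
#' (\code{Allele|Annotation|Impact|Gene_Name|Gene_ID|Feature_Type|Feature_ID|...},
#' SnpEff 4.3 dialect). Unknown effect terms map to \code{other}/MODIFIER
#' with a warning.
#'
#' @param ann The ANN string (without the leading \code{ANN=}), or a variant
#'   table row's \code{ann} value. \code{NA}/empty gives an empty result.
#' @return \code{data.frame} with columns \code{effect}, \code{impact},
#'   \code{gene_id}, \code{transcript_id}; zero rows when no ANN present.
#' @export
parse_ann_field <- function(ann) {
  empty <- data.frame(effect = character(0), impact = character(0),
                      gene_id = character(0), transcript_id = character(0),
                      stringsAsFactors = FALSE)
  if (length(ann) == 0 || is.na(ann) || !nzchar(ann)) {
    return(empty)
  }
  entries <- strsplit(ann, ",", fixed = TRUE)[[1]]
  rows <- lapply(entries, function(e) {
    f <- strsplit(e, "|", fixed = TRUE)[[1]]
    term <- if (length(f) >= 2) f[2] else ""
    # SnpEff may join several terms with '&'; take the highest-ranked one
    terms <- strsplit(term, "&", fixed = TRUE)[[1]]
    effs <- ANN_EFFECT_MAP[terms]
    if (all(is.na(effs))) {
      warning("unknown effect term(s) mapped to 'other': ", term, call. = FALSE)
      eff <- "other"
    } else {
      effs <- effs[!is.na(effs)]
      eff <- effs[which.max(IMPACT_RANK[EFFECT_IMPACT[effs]])]
    }
    imp <- if (length(f) >= 3 && f[3] %in% names(IMPACT_RANK)) f[3] else
      EFFECT_IMPACT[[eff]]
    data.frame(effect = unname(eff), impact = imp,
               gene_id = if (length(f) >= 5 && nzchar(f[5])) f[5] else
                 if (length(f) >= 4) f[4] else NA_character_,
               transcript_id = if (length(f) >= 7 && nzchar(f[7])) f[7] else NA_character_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Classify the coding effect of an SNV against gene models
#'
#' Internal coding-effect classifier used when no ANN annotation is present.
#' A position outside every gene span is intergenic; inside a span but
#' outside the CDS is intronic (or splice_region within 2 bp of a CDS
#' boundary); inside the CDS the affected codon is translated on the coding
#' strand before and after the substitution (standard nuclear genetic code)
#' and classified as synonymous, missense, stop_gained, stop_lost or
#' start_lost.
#'
#' @param chrom,pos,ref,alt The SNV (single-base ref and alt).
#' @param genes Gene-model table (see \code{\link{read_gene_models}}).
#' @param reference \code{ReferenceGenome}.
#' @return \code{data.frame}(effect, impact, gene_id, transcript_id), one
#'   row per overlapping gene (a single intergenic row if none overlap).
#' @export
classify_effect <- function(chrom, pos, ref, alt, genes, reference) {
  stopifnot(nchar(ref) == 1, nchar(alt) == 1)
  genome_base <- ref_query(reference, chrom, pos, pos)
  if (genome_base != ref) {
    stop("ref allele ", ref, " disagrees with reference base ", genome_base,
         " at ", chrom, ":", pos)
  }
  hit <- which(genes$chrom == chrom & genes$start <= pos & genes$end >= pos)
  if (length(hit) == 0) {
    return(data.frame(effect = "intergenic", impact = "MODIFIER",
                      gene_id = NA_character_, transcript_id = NA_character_,
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(hit, function(gi) {
    g <- genes[gi, ]
    segs <- genes$cds[[gi]]
    eff <- classify_within_gene(pos, ref, alt, g, segs, reference)
    data.frame(effect = eff, impact = EFFECT_IMPACT[[eff]],
               gene_id = g$gene_id, transcript_id = NA_character_,
               stringsAsFactors = FALSE)
  }))
}

classify_within_gene <- function(pos, ref, alt, gene, segs, reference) {
  if (nrow(segs) == 0) {
    return("intronic")
  }
  in_cds <- any(segs[, 1] <= pos & segs[, 2] >= pos)
  if (!in_cds) {
    near <- any(abs(pos - segs[, 1]) <= 2 | abs(pos - segs[, 2]) <= 2)
    return(if (near) "splice_region" else "intronic")
  }
  # coding coordinate: concatenate CDS segments in transcription order
  seg_order <- order(segs[, 1])
  if (gene$strand == "-") seg_order <- rev(seg_order)
  coding_pos <- 0L
  for (si in seg_order) {
    s <- segs[si, 1]; e <- segs[si, 2]
    if (pos >= s && pos <= e) {
      coding_pos <- coding_pos + if (gene$strand == "-") e - pos + 1L else pos - s + 1L
      break
    }
    coding_pos <- coding_pos + (e - s + 1L)
  }
  codon_index <- (coding_pos - 1L) %/% 3L
  pos_in_codon <- (coding_pos - 1L) %% 3L + 1L

  cds_seq <- paste(vapply(seg_order, function(si) {
    s <- ref_query(reference, gene$chrom, segs[si, 1], segs[si, 2])
    if (gene$strand == "-") revcomp(s) else s
  }, character(1)), collapse = "")
  codon <- substring(cds_seq, codon_index * 3L + 1L, codon_index * 3L + 3L)
  if (nchar(codon) < 3) {
    return("other")  # trailing partial codon
  }
  ref_c <- if (gene$strand == "-") comp_base(ref) else ref
  alt_c <- if (gene$strand == "-") comp_base(alt) else alt
  if (substring(codon, pos_in_codon, pos_in_codon) != ref_c) {
    stop("CDS sequence inconsistent with ref allele at ", gene$chrom, ":", pos)
  }
  new_codon <- codon
  substring(new_codon, pos_in_codon, pos_in_codon) <- alt_c

  aa_ref <- translate_codon(codon)
  aa_alt <- translate_codon(new_codon)
  if (codon_index == 0L && aa_ref == "M" && aa_alt != "M") {
    "start_lost"
  } else if (aa_ref != "*" && aa_alt == "*") {
    "stop_gained"
  } else if (aa_ref == "*" && aa_alt != "*") {
    "stop_lost"
  } else if (aa_ref == aa_alt) {
    "synonymous"
  } else {
    "missense"
  }
}

translate_codon <- function(codon) {
  unname(Biostrings::GENETIC_CODE[codon])
}

#' Annotate a candidate set with effect and impact
#'
#' Uses the ANN field when a site carries one, otherwise the internal
#' classifier. Each site receives its maximum-impact annotation across
#' transcripts/genes (\code{effect}, \code{impact}, \code{gene} columns).
#' Non-SNV sites without ANN are classed \code{other}/MODIFIER.
#'
#' @param candidates \code{CandidateSet} or a variant table.
#' @param genes Gene-model table.
#' @param reference \code{ReferenceGenome}.
#' @return The input with \code{effect}, \code{impact} and \code{gene}
#'   columns added to its sites.
#' @export
annotate_effects <- function(candidates, genes, reference) {
  sites <- if (inherits(candidates, "CandidateSet")) candidates$sites else candidates
  n <- nrow(sites)
  eff <- character(n); imp <- character(n); gene <- character(n)
  for (i in seq_len(n)) {
    ann <- if (!is.null(sites$ann)) sites$ann[i] else NA_character_
    tab <- if (!is.na(ann) && nzchar(ann)) {
      parse_ann_field(ann)
    } else if (nchar(sites$ref[i]) == 1 && nchar(sites$alt[i]) == 1) {
      classify_effect(sites$chrom[i], sites$pos[i], sites$ref[i], sites$alt[i],
                      genes, reference)
    } else {
      data.frame(effect = "other", impact = "MODIFIER", gene_id = NA_character_,
                 stringsAsFactors = FALSE)
    }
    best <- which.max(IMPACT_RANK[tab$impact])
    eff[i] <- tab$effect[best]
    imp[i] <- tab$impact[best]
    gene[i] <- tab$gene_id[best]
  }
  sites$effect <- eff
  sites$impact <- imp
  sites$gene <- gene
  if (inherits(candidates, "CandidateSet")) {
    candidates$sites <- sites
    candidates
  } else {
    sites
  }
}

#' Select moderate- or high-impact candidates
#'
#' Retains sites whose (maximum) impact is MODERATE or HIGH.
#'
#' @param candidates \code{CandidateSet} or variant table previously run
#'   through \code{\link{annotate_effects}}.
#' @return Same type as the input, restricted to the selected sites.
#' @export
select_moderate_high <- function(candidates) {
  sites <- if (inherits(candidates, "CandidateSet")) candidates$sites else candidates
  if (is.null(sites$impact)) {
    stop("candidates must be annotated with annotate_effects() first")
  }
  keep <- sites$impact %in% c("MODERATE", "HIGH")
  sites <- sites[keep, , drop = FALSE]
  rownames(sites) <- NULL
  if (inherits(candidates, "CandidateSet")) {
    candidates$sites <- sites
    candidates$stage_counts["moderate_high"] <- nrow(sites)
    candidates
  } else {
    sites
  }
}
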