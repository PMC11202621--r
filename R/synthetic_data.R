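#' Simulation configuration
#'
#' Defaults describe a desk-scale emulation of a donor/two-clone SCNT
#' study: a 1 Mb four-chromosome genome, 200 non-overlapping genes, a
#' shared germline heterozygous background, somatic SNVs planted under a
#' chosen 96-channel signature (300 shared between clones, 200/150
#' clone-private, 40 shared-but-low-depth decoys), Poisson read depths
#' truncated to guarantee pass/fail against the depth filter, a
#' 196-sample population panel, and gene lists with a controlled
#' enrichment odds ratio.
#'
#' @param seed Master seed; every downstream draw derives from it.
#' @param n_chrom,chrom_length Genome shape.
#' @param n_genes Number of genes to place.
#' @param gene_length_range Min/max gene span (bp).
#' @param frac_minus_strand Fraction of genes on the minus strand.
#' @param donor,clones Sample names.
#' @param n_germline_het Heterozygous sites shared by donor and clones.
#' @param n_somatic_shared Somatic SNVs planted het in every clone,
#'   hom-ref in the donor, at passing depth.
#' @param n_somatic_private Per-clone private somatic SNVs (recycled over
#'   clones).
#' @param n_somatic_lowdepth Somatic SNVs shared by the clones but planted
#'   at failing depth.
#' @param depth_mean,lowdepth_mean Poisson depth means for passing and
#'   failing sites.
#' @param depth_pass_floor,lowdepth_ceiling Truncation bounds keeping
#'   passing sites at or above, and failing sites below, the depth filter.
#' @param signature \code{"flat"}, \code{"uv_ct"}, or a numeric 96-vector
#'   of channel probabilities.
#' @param aging_list_size Size of the simulated aging gene list.
#' @param aging_enrichment_odds Sampling odds favouring mutation-bearing
#'   genes in the aging list (1 = null).
#' @param n_null_sets,set_size_range Null gene-set collection shape.
#' @param enriched_set_size,enriched_set_odds One planted enriched set.
#' @param panel_n_samples Population panel size.
#' @param n_panel_rare_colliders Somatic sites planted into the panel at
#'   frequencies below 0.01.
#' @param n_panel_missing_colliders Somatic sites planted into the panel
#'   with a genotype missing rate above the 10\% threshold.
#' @return List of class \code{SimulationConfig}.
#' @export
simulation_config <- function(seed = 1L,
                              n_chrom = 4L, chrom_length = 250000L,
                              n_genes = 200L,
                              gene_length_range = c(800L, 4000L),
                              frac_minus_strand = 0.5,
                              donor = "Donor", clones = c("NT2", "NT4"),
                              n_germline_het = 2000L,
                              n_somatic_shared = 300L,
                              n_somatic_private = c(200L, 150L),
                              n_somatic_lowdepth = 40L,
                              depth_mean = 80, lowdepth_mean = 25,
                              depth_pass_floor = 51L, lowdepth_ceiling = 50L,
                              signature = "flat",
                              aging_list_size = 50L,
                              aging_enrichment_odds = 2,
                              n_null_sets = 50L, set_size_range = c(10L, 30L),
                              enriched_set_size = 25L, enriched_set_odds = 8,
                              panel_n_samples = 196L,
                              n_panel_rare_colliders = 5L,
                              n_panel_missing_colliders = 3L) {
  cfg <- list(seed = as.integer(seed), n_chrom = as.integer(n_chrom),
              chrom_length = as.integer(chrom_length),
              n_genes = as.integer(n_genes),
              gene_length_range = as.integer(gene_length_range),
              frac_minus_strand = frac_minus_strand,
              donor = donor, clones = clones,
              n_germline_het = as.integer(n_germline_het),
              n_somatic_shared = as.integer(n_somatic_shared),
              n_somatic_private = as.integer(rep_len(n_somatic_private,
                                                     length(clones))),
              n_somatic_lowdepth = as.integer(n_somatic_lowdepth),
              depth_mean = depth_mean, lowdepth_mean = lowdepth_mean,
              depth_pass_floor = as.integer(depth_pass_floor),
              lowdepth_ceiling = as.integer(lowdepth_ceiling),
              signature = signature,
              aging_list_size = as.integer(aging_list_size),
              aging_enrichment_odds = aging_enrichment_odds,
              n_null_sets = as.integer(n_null_sets),
              set_size_range = as.integer(set_size_range),
              enriched_set_size = as.integer(enriched_set_size),
              enriched_set_odds = enriched_set_odds,
              panel_n_samples = as.integer(panel_n_samples),
              n_panel_rare_colliders = as.integer(n_panel_rare_colliders),
              n_panel_missing_colliders = as.integer(n_panel_missing_colliders))
  stopifnot(cfg$n_chrom >= 1, cfg$chrom_length >= 100,
            cfg$n_genes >= 0, length(cfg$clones) >= 1,
            cfg$n_germline_het >= 0, cfg$n_somatic_shared >= 0,
            all(cfg$n_somatic_private >= 0), cfg$n_somatic_lowdepth >= 0,
            cfg$lowdepth_ceiling < cfg$depth_pass_floor,
            cfg$aging_list_size <= cfg$n_genes)
  structure(cfg, class = "SimulationConfig")
}

resolve_signature <- function(signature) {
  if (is.character(signature) && length(signature) == 1) {
    sigs <- builtin_signatures()
    if (!signature %in% colnames(sigs)) {
      stop("unknown built-in signature: ", signature)
    }
    return(stats::setNames(sigs[, signature], rownames(sigs)))
  }
  sig <- as.numeric(signature)
  if (length(sig) != 96 || any(sig < 0) || sum(sig) <= 0) {
    stop("signature must be a non-negative 96-vector")
  }
  stats::setNames(sig / sum(sig), sbs_channels())
}

#' Simulate a reference genome
#'
#' I.i.d. uniform A/C/G/T per chromosome, deterministic under the seed.
#'
#' @param config \code{\link{simulation_config}}.
#' @return \code{ReferenceGenome}.
#' @export
simulate_reference <- function(config) {
  set.seed(config$seed)
  bases <- c("A", "C", "G", "T")
  seqs <- vapply(seq_len(config$n_chrom), function(i) {
    paste(sample(bases, config$chrom_length, replace = TRUE), collapse = "")
  }, character(1))
  names(seqs) <- paste0("chr", seq_len(config$n_chrom))
  structure(list(seq = seqs, lengths = nchar(seqs)), class = "ReferenceGenome")
}

#' Simulate non-overlapping gene models
#'
#' Genes are placed by rejection with 100 bp spacing; each gene has a
#' single CDS covering the central 60\% of its span (trimmed to a codon
#' multiple), on a randomly chosen strand.
#'
#' @param config \code{\link{simulation_config}}.
#' @param reference \code{ReferenceGenome} from \code{\link{simulate_reference}}.
#' @return Gene-model table in the shape of \code{\link{read_gene_models}}.
#' @export
simulate_gene_models <- function(config, reference) {
  set.seed(config$seed + 1L)
  chroms <- names(reference$seq)
  per_chrom <- table(factor(rep_len(chroms, config$n_genes), levels = chroms))
  rows <- list()
  gi <- 0L
  for (ch in chroms) {
    placed <- matrix(integer(0), ncol = 2)
    n_here <- per_chrom[[ch]]
    attempts <- 0L
    while (nrow(placed) < n_here) {
      attempts <- attempts + 1L
      if (attempts > 1e6) {
        stop("cannot place ", n_here, " genes on ", ch,
             " within the attempt budget")
      }
      len <- sample(config$gene_length_range[1]:config$gene_length_range[2], 1)
      start <- sample.int(reference$lengths[[ch]] - len - 1L, 1) + 1L
      end <- start + len - 1L
      if (nrow(placed) == 0 ||
          all(end + 100L < placed[, 1] | start - 100L > placed[, 2])) {
        placed <- rbind(placed, c(start, end))
      }
    }
    placed <- placed[order(placed[, 1]), , drop = FALSE]
    for (j in seq_len(nrow(placed))) {
      gi <- gi + 1L
      start <- placed[j, 1]; end <- placed[j, 2]
      len <- end - start + 1L
      cds_start <- start + as.integer(floor(0.2 * len))
      cds_width <- as.integer(floor(0.6 * len))
      cds_width <- cds_width - cds_width %% 3L
      rows[[gi]] <- data.frame(
        gene_id = sprintf("G%04d", gi),
        symbol = sprintf("GENE%04d", gi),
        chrom = ch, start = start, end = end,
        strand = if (stats::runif(1) < config$frac_minus_strand) "-" else "+",
        length = len, stringsAsFactors = FALSE)
      rows[[gi]]$cds <- list(cbind(start = cds_start,
                                   end = cds_start + cds_width - 1L))
    }
  }
  if (gi == 0L) {
    out <- data.frame(gene_id = character(0), symbol = character(0),
                      chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      length = integer(0), stringsAsFactors = FALSE)
    out$cds <- list()
    return(out)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Integer-coded trinucleotide index of a genome: for every internal
# position, code = 16*b(-1) + 4*b(0) + b(+1) with A,C,G,T -> 0..3.
# Returns, per code 0..63, pre-shuffled (chrom, pos) stacks.
build_context_index <- function(reference) {
  base_code <- integer(128)
  base_code[utf8ToInt("A") + 1L] <- 0L
  base_code[utf8ToInt("C") + 1L] <- 1L
  base_code[utf8ToInt("G") + 1L] <- 2L
  base_code[utf8ToInt("T") + 1L] <- 3L
  stacks <- vector("list", 64)
  for (ci in seq_along(reference$seq)) {
    v <- base_code[utf8ToInt(reference$seq[[ci]]) + 1L]
    L <- length(v)
    pos <- 2:(L - 1L)
    code <- v[pos - 1L] * 16L + v[pos] * 4L + v[pos + 1L]
    grp <- split(pos, code)
    for (nm in names(grp)) {
      k <- as.integer(nm) + 1L
      p <- sample(grp[[nm]])  # pre-shuffle for uniform draws
      stacks[[k]] <- rbind(stacks[[k]], cbind(chrom = ci, pos = p))
    }
  }
  list(stacks = stacks, ptr = rep(1L, 64))
}

trinuc_code <- function(trinuc) {
  m <- match(strsplit(trinuc, NULL)[[1]], c("A", "C", "G", "T")) - 1L
  m[1] * 16L + m[2] * 4L + m[3]
}

#' Plant germline and somatic variants
#'
#' Builds the donor/clone variant table: germline heterozygous sites shared
#' by all samples; shared somatic SNVs heterozygous in every clone and
#' homozygous reference in the donor at passing depth; clone-private
#' somatic SNVs; and shared low-depth decoys. Each somatic site's
#' substitution and trinucleotide context are drawn from the configured
#' 96-channel signature and matched against the genome (on either strand)
#' through a pre-built context index.
#'
#' @param config \code{\link{simulation_config}}.
#' @param reference \code{ReferenceGenome}.
#' @param genes Gene-model table (for manifest gene assignment).
#' @return List with \code{variants} (multi-sample variant table) and
#'   \code{manifest} (\code{data.frame} of planted sites with class,
#'   channel and gene; attributes \code{planted_signature} and
#'   \code{expected_final_count}).
#' @export
plant_somatic_mutations <- function(config, reference, genes) {
  set.seed(config$seed + 2L)
  sig <- resolve_signature(config$signature)
  idx <- build_context_index(reference)
  chrom_names <- names(reference$seq)
  samples <- c(config$donor, config$clones)

  classes <- c(rep("shared", config$n_somatic_shared),
               unlist(lapply(seq_along(config$clones), function(i) {
                 rep(paste0("private:", config$clones[i]),
                     config$n_somatic_private[i])
               })),
               rep("lowdepth", config$n_somatic_lowdepth))
  n_somatic <- length(classes)
  channels <- if (n_somatic > 0) {
    sample(names(sig), n_somatic, replace = TRUE, prob = sig)
  } else character(0)

  som_chrom <- character(n_somatic)
  som_pos <- integer(n_somatic)
  som_ref <- character(n_somatic)
  som_alt <- character(n_somatic)
  for (i in seq_len(n_somatic)) {
    pc <- parse_channel(channels[i])
    fwd <- paste0(pc$five, pc$ref, pc$three)
    c1 <- trinuc_code(fwd) + 1L
    c2 <- trinuc_code(revcomp(fwd)) + 1L
    r1 <- if (is.null(idx$stacks[[c1]])) 0L else nrow(idx$stacks[[c1]]) - idx$ptr[c1] + 1L
    r2 <- if (is.null(idx$stacks[[c2]])) 0L else nrow(idx$stacks[[c2]]) - idx$ptr[c2] + 1L
    if (r1 + r2 <= 0) {
      stop("insufficient genome space for context of channel ", channels[i])
    }
    use1 <- stats::runif(1) < r1 / (r1 + r2)
    cc <- if (use1) c1 else c2
    entry <- idx$stacks[[cc]][idx$ptr[cc], ]
    idx$ptr[cc] <- idx$ptr[cc] + 1L
    som_chrom[i] <- chrom_names[entry[["chrom"]]]
    som_pos[i] <- entry[["pos"]]
    som_ref[i] <- if (use1) pc$ref else comp_base(pc$ref)
    som_alt[i] <- if (use1) pc$alt else comp_base(pc$alt)
  }

  # germline heterozygous background on untouched positions
  used <- paste(som_chrom, som_pos)
  g_chrom <- character(0); g_pos <- integer(0)
  while (length(g_pos) < config$n_germline_het) {
    need <- config$n_germline_het - length(g_pos)
    ch <- sample(chrom_names, need, replace = TRUE)
    p <- vapply(ch, function(cc) {
      sample(2:(reference$lengths[[cc]] - 1L), 1)
    }, integer(1))
    key <- paste(ch, p)
    ok <- !(key %in% used) & !duplicated(key)
    used <- c(used, key[ok])
    g_chrom <- c(g_chrom, ch[ok])
    g_pos <- c(g_pos, p[ok])
  }
  bases <- c("A", "C", "G", "T")
  g_ref <- vapply(seq_along(g_pos), function(i) {
    ref_query(reference, g_chrom[i], g_pos[i], g_pos[i])
  }, character(1))
  g_alt <- vapply(g_ref, function(r) sample(setdiff(bases, r), 1), character(1))

  all_chrom <- c(som_chrom, g_chrom)
  all_pos <- c(som_pos, g_pos)
  all_ref <- c(som_ref, g_ref)
  all_alt <- c(som_alt, g_alt)
  all_class <- c(classes, rep("germline", length(g_pos)))
  n <- length(all_pos)

  rpois_floor <- function(n, mean, floor_) pmax(floor_, stats::rpois(n, mean))
  rpois_ceil <- function(n, mean, ceil_) pmin(ceil_, stats::rpois(n, mean))

  variants <- data.frame(chrom = all_chrom, pos = all_pos, ref = all_ref,
                         alt = all_alt, ann = NA_character_,
                         stringsAsFactors = FALSE)
  donor_gt <- ifelse(all_class == "germline", "het", "hom_ref")
  variants[[paste0("gt_", config$donor)]] <- donor_gt
  variants[[paste0("dp_", config$donor)]] <-
    as.integer(stats::rpois(n, config$depth_mean))
  for (cl in config$clones) {
    gt <- ifelse(all_class %in% c("germline", "shared", "lowdepth") |
                   all_class == paste0("private:", cl), "het", "hom_ref")
    low <- all_class == "lowdepth"
    dp <- integer(n)
    dp[!low] <- rpois_floor(sum(!low), config$depth_mean, config$depth_pass_floor)
    dp[low] <- rpois_ceil(sum(low), config$lowdepth_mean, config$lowdepth_ceiling)
    variants[[paste0("gt_", cl)]] <- gt
    variants[[paste0("dp_", cl)]] <- dp
  }
  ord <- order(variants$chrom, variants$pos)
  variants <- variants[ord, , drop = FALSE]
  rownames(variants) <- NULL
  attr(variants, "samples") <- samples

  gene_of <- function(chrom, pos) {
    hit <- which(genes$chrom == chrom & genes$start <= pos & genes$end >= pos)
    if (length(hit) == 0) NA_character_ else genes$gene_id[hit[1]]
  }
  manifest <- data.frame(
    class = all_class[ord], chrom = all_chrom[ord], pos = all_pos[ord],
    ref = all_ref[ord], alt = all_alt[ord],
    channel = c(channels, rep(NA_character_, length(g_pos)))[ord],
    stringsAsFactors = FALSE)
  manifest$gene_id <- mapply(gene_of, manifest$chrom, manifest$pos,
                             USE.NAMES = FALSE)
  attr(manifest, "planted_signature") <- sig
  attr(manifest, "expected_final_count") <- config$n_somatic_shared
  list(variants = variants, manifest = manifest)
}

#' Simulate a population allele-frequency panel
#'
#' The panel contains most germline sites at common frequencies, none of
#' the planted somatic sites (so their downstream frequency is 0), except
#' for a configured handful of colliders: somatic sites present at
#' frequencies below 0.01, and somatic sites whose genotype missing rate
#' exceeds the 10\% threshold (exercising the undefined-frequency rule).
#'
#' @param config \code{\link{simulation_config}}.
#' @param plant Output of \code{\link{plant_somatic_mutations}}.
#' @return \code{PopulationPanel} with extra columns \code{chrom},
#'   \code{pos}, \code{ref}, \code{alt} retained for writing.
#' @export
simulate_panel <- function(config, plant) {
  set.seed(config$seed + 3L)
  man <- plant$manifest
  germ <- man[man$class == "germline", , drop = FALSE]
  keep <- stats::runif(nrow(germ)) < 0.9
  germ <- germ[keep, , drop = FALSE]
  rows <- data.frame(chrom = germ$chrom, pos = germ$pos, ref = germ$ref,
                     alt = germ$alt,
                     af = round(stats::rbeta(nrow(germ), 2, 2), 4),
                     missing_rate = round(stats::runif(nrow(germ), 0, 0.05), 4),
                     stringsAsFactors = FALSE)
  shared <- man[man$class == "shared", , drop = FALSE]
  n_rare <- min(config$n_panel_rare_colliders, nrow(shared))
  n_miss <- min(config$n_panel_missing_colliders, max(0, nrow(shared) - n_rare))
  if (n_rare + n_miss > 0) {
    pick <- sample(nrow(shared), n_rare + n_miss)
    rare <- shared[pick[seq_len(n_rare)], , drop = FALSE]
    miss <- shared[pick[n_rare + seq_len(n_miss)], , drop = FALSE]
    if (n_rare > 0) {
      rows <- rbind(rows, data.frame(
        chrom = rare$chrom, pos = rare$pos, ref = rare$ref, alt = rare$alt,
        af = round(stats::runif(n_rare, 1e-4, 0.009), 4),
        missing_rate = round(stats::runif(n_rare, 0, 0.05), 4),
        stringsAsFactors = FALSE))
    }
    if (n_miss > 0) {
      rows <- rbind(rows, data.frame(
        chrom = miss$chrom, pos = miss$pos, ref = miss$ref, alt = miss$alt,
        af = round(stats::runif(n_miss, 0.05, 0.5), 4),
        missing_rate = round(stats::runif(n_miss, 0.15, 0.3), 4),
        stringsAsFactors = FALSE))
    }
  }
  rows <- rows[order(rows$chrom, rows$pos), , drop = FALSE]
  rownames(rows) <- NULL
  rows$key <- paste(rows$chrom, rows$pos, rows$ref, rows$alt, sep = ":")
  attr(rows, "n_samples") <- config$panel_n_samples
  class(rows) <- c("PopulationPanel", "data.frame")
  rows
}

#' Write a population panel as TSV
#' @param panel \code{PopulationPanel} with positional columns.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_population_panel <- function(panel, path) {
  utils::write.table(panel[, c("chrom", "pos", "ref", "alt", "af", "missing_rate")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Simulate an aging gene list and a gene-set collection
#'
#' The aging list is sampled so that mutation-bearing genes enter it at
#' \code{aging_enrichment_odds}-fold weight (1 = independent of mutation
#' status). The collection holds one enriched set sampled at
#' \code{enriched_set_odds}-fold weight toward mutation-bearing genes plus
#' \code{n_null_sets} sets drawn uniformly.
#'
#' @param config \code{\link{simulation_config}}.
#' @param genes Gene-model table.
#' @param mutated_gene_ids Gene ids bearing candidate somatic mutations
#'   (e.g. manifest genes of shared planted sites).
#' @return List: \code{aging_genes} (symbols), \code{sets}
#'   (\code{data.frame} set_name/gene_symbol), \code{background} (all
#'   symbols), \code{enriched_set} (name of the planted enriched set).
#' @export
simulate_gene_sets <- function(config, genes, mutated_gene_ids) {
  set.seed(config$seed + 4L)
  if (nrow(genes) == 0) {
    return(list(aging_genes = character(0),
                sets = data.frame(set_name = character(0),
                                  gene_symbol = character(0),
                                  stringsAsFactors = FALSE),
                background = character(0), enriched_set = NA_character_))
  }
  if (nrow(genes) < config$aging_list_size) {
    stop("aging_list_size exceeds number of genes")
  }
  mutated <- genes$gene_id %in% mutated_gene_ids
  w_aging <- ifelse(mutated, config$aging_enrichment_odds, 1)
  aging_idx <- sample(nrow(genes), config$aging_list_size, prob = w_aging)
  aging_genes <- sort(genes$symbol[aging_idx])

  w_enr <- ifelse(mutated, config$enriched_set_odds, 1)
  enr_size <- min(config$enriched_set_size, nrow(genes))
  enr_idx <- sample(nrow(genes), enr_size, prob = w_enr)
  sets <- data.frame(set_name = "SET_ENRICHED",
                     gene_symbol = sort(genes$symbol[enr_idx]),
                     stringsAsFactors = FALSE)
  for (i in seq_len(config$n_null_sets)) {
    sz <- sample(config$set_size_range[1]:config$set_size_range[2], 1)
    sz <- min(sz, nrow(genes))
    sets <- rbind(sets, data.frame(
      set_name = sprintf("NULL_%03d", i),
      gene_symbol = sort(genes$symbol[sample(nrow(genes), sz)]),
      stringsAsFactors = FALSE))
  }
  list(aging_genes = aging_genes, sets = sets,
       background = genes$symbol, enriched_set = "SET_ENRICHED")
}

#' Run the full simulation and optionally write every pipeline input
#'
#' Orchestrates \code{\link{simulate_reference}},
#' \code{\link{simulate_gene_models}},
#' \code{\link{plant_somatic_mutations}}, \code{\link{simulate_panel}} and
#' \code{\link{simulate_gene_sets}}. With \code{out_dir} set, emits
#' FASTA, GFF3, a multi-sample VCF, the panel TSV, the built-in signature
#' TSV, gene list/set files and the ground-truth manifest TSV — one master
#' seed reproduces every file byte-for-byte.
#'
#' @param config \code{\link{simulation_config}}.
#' @param out_dir Optional output directory.
#' @return List: \code{config}, \code{reference}, \code{genes},
#'   \code{variants}, \code{manifest}, \code{panel}, \code{gene_sets},
#'   and \code{paths} (when written).
#' @export
simulate_all <- function(config = simulation_config(), out_dir = NULL) {
  reference <- simulate_reference(config)
  genes <- simulate_gene_models(config, reference)
  plant <- plant_somatic_mutations(config, reference, genes)
  panel <- simulate_panel(config, plant)
  shared_genes <- unique(stats::na.omit(
    plant$manifest$gene_id[plant$manifest$class == "shared"]))
  gene_sets <- simulate_gene_sets(config, genes, shared_genes)

  out <- list(config = config, reference = reference, genes = genes,
              variants = plant$variants, manifest = plant$manifest,
              panel = panel, gene_sets = gene_sets)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    paths <- list(
      reference = file.path(out_dir, "reference.fa"),
      genes = file.path(out_dir, "genes.gff3"),
      variants = file.path(out_dir, "variants.vcf"),
      panel = file.path(out_dir, "panel.tsv"),
      signatures = file.path(out_dir, "signatures.tsv"),
      aging_genes = file.path(out_dir, "aging_genes.txt"),
      gene_sets = file.path(out_dir, "gene_sets.tsv"),
      background = file.path(out_dir, "background_genes.txt"),
      manifest = file.path(out_dir, "manifest.tsv")
    )
    write_reference(reference, paths$reference)
    write_gff3(genes, paths$genes)
    write_vcf(plant$variants, paths$variants)
    write_population_panel(panel, paths$panel)
    write_signature_matrix(builtin_signatures(), paths$signatures)
    writeLines(gene_sets$aging_genes, paths$aging_genes)
    utils::write.table(gene_sets$sets, paths$gene_sets, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    writeLines(gene_sets$background, paths$background)
    utils::write.table(plant$manifest, paths$manifest, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    out$paths <- paths
  }
  out
}
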