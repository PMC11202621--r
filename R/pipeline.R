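#' Pipeline configuration
#'
#' Bundles inputs and thresholds for a full run. Either \code{simulate}
#' (a \code{\link{simulation_config}}) or the file paths must be given.
#' Defaults are the published analysis settings: depth filter at DP > 50,
#' two clones required, rare-frequency threshold 0.01, panel missing-rate
#' threshold 0.10, per-gene minimum count 2, top 20 rate records,
#' enrichment alpha 0.01 with minimum overlap 2.
#'
#' @param simulate Optional \code{SimulationConfig}; when set, all inputs
#'   are simulated.
#' @param donor_vcf,clone_vcfs,reference_fasta,genes_path,panel_path,
#'   signatures_path,aging_genes_path,gene_sets_path,background_path
#'   Input paths for a file-based run (\code{clone_vcfs} is a named
#'   character vector \code{c(NT2 = "...")} or \code{NULL} when the donor
#'   VCF is multi-sample).
#' @param donor,clones Sample names.
#' @param filter \code{\link{filter_config}}.
#' @param rate_min_count,rate_top_n Per-gene rate settings.
#' @param enrich_alpha,enrich_min_overlap Over-representation settings.
#' @param out_dir Output directory.
#' @return List of class \code{PipelineConfig}.
#' @export
pipeline_config <- function(simulate = NULL,
                            donor_vcf = NULL, clone_vcfs = NULL,
                            reference_fasta = NULL, genes_path = NULL,
                            panel_path = NULL, signatures_path = NULL,
                            aging_genes_path = NULL, gene_sets_path = NULL,
                            background_path = NULL,
                            donor = "Donor", clones = c("NT2", "NT4"),
                            filter = filter_config(),
                            rate_min_count = 2L, rate_top_n = 20L,
                            enrich_alpha = 0.01, enrich_min_overlap = 2L,
                            out_dir = tempfile("somaclone_run")) {
  structure(list(simulate = simulate, donor_vcf = donor_vcf,
                 clone_vcfs = clone_vcfs, reference_fasta = reference_fasta,
                 genes_path = genes_path, panel_path = panel_path,
                 signatures_path = signatures_path,
                 aging_genes_path = aging_genes_path,
                 gene_sets_path = gene_sets_path,
                 background_path = background_path,
                 donor = donor, clones = clones, filter = filter,
                 rate_min_count = as.integer(rate_min_count),
                 rate_top_n = as.integer(rate_top_n),
                 enrich_alpha = enrich_alpha,
                 enrich_min_overlap = as.integer(enrich_min_overlap),
                 out_dir = out_dir),
            class = "PipelineConfig")
}

#' Run the full analysis pipeline
#'
#' Executes simulate (optional) -> filter cascade -> effect annotation ->
#' 96-channel spectrum -> per-gene rates -> aging-list and gene-set
#' enrichment, writing every stage's table under \code{config$out_dir} and
#' returning a run report.
#'
#' @param config \code{\link{pipeline_config}}.
#' @return List of class \code{RunReport}: \code{stage_counts},
#'   \code{final_count}, \code{n_moderate_high}, \code{n_rare_moderate_high},
#'   \code{spectrum} (totals, 6-class proportions, flatness, best match),
#'   \code{rates} (top records), \code{aging} (table, percent, test),
#'   \code{enrichment} (set table), and \code{manifest_expected} when
#'   simulated.
#' @export
run_all <- function(config = pipeline_config(simulate = simulation_config())) {
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  if (!is.null(config$simulate)) {
    sim <- simulate_all(config$simulate, out_dir = file.path(out_dir, "inputs"))
    reference <- sim$reference
    genes <- sim$genes
    variants <- sim$variants
    panel <- sim$panel
    signatures <- builtin_signatures()
    aging_genes <- sim$gene_sets$aging_genes
    gene_sets <- sim$gene_sets$sets
    background <- sim$gene_sets$background
    donor <- config$simulate$donor
    clones <- config$simulate$clones
    manifest_expected <- attr(sim$manifest, "expected_final_count")
  } else {
    reference <- read_reference(config$reference_fasta)
    genes <- read_gene_models(config$genes_path)
    donor <- config$donor
    clones <- config$clones
    variants <- if (is.null(config$clone_vcfs)) {
      read_vcf(config$donor_vcf)
    } else {
      stats::setNames(lapply(config$clone_vcfs, read_vcf), names(config$clone_vcfs))
    }
    panel <- if (is.null(config$panel_path)) NULL else
      read_population_panel(config$panel_path)
    signatures <- if (is.null(config$signatures_path)) builtin_signatures() else
      read_signature_matrix(config$signatures_path)
    aging_genes <- if (is.null(config$aging_genes_path)) NULL else
      read_gene_list(config$aging_genes_path)
    gene_sets <- if (is.null(config$gene_sets_path)) NULL else
      read_gene_sets(config$gene_sets_path)
    background <- if (is.null(config$background_path)) genes$symbol else
      read_gene_list(config$background_path)
    manifest_expected <- NULL
  }

  candidates <- run_filter_cascade(variants, donor, clones, panel, config$filter)
  write_candidate_set(candidates, out_dir)

  candidates <- annotate_effects(candidates, genes, reference)
  mh <- select_moderate_high(candidates)
  n_rare_mh <- if (!is.null(mh$sites$rare)) sum(mh$sites$rare, na.rm = TRUE) else NA
  utils::write.table(
    candidates$sites[, intersect(c("chrom", "pos", "ref", "alt", "gene",
                                   "effect", "impact", "population_af"),
                                 names(candidates$sites))],
    file.path(out_dir, "effects.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)

  spectrum <- build_spectrum(candidates, reference)
  write_spectrum(spectrum, out_dir, signatures)
  spectrum_summary <- list(
    total = spectrum$total, dropped = spectrum$dropped,
    six_class = if (spectrum$total > 0) collapse_to_six(spectrum) else NULL,
    flatness = if (spectrum$total > 0) flatness(spectrum) else NA_real_,
    best_match = if (spectrum$total > 0) best_match(spectrum, signatures) else NULL)

  assignment <- assign_to_genes(candidates, genes)
  rates <- mutation_rates(assignment, genes, config$rate_min_count)
  top <- top_n_rates(rates, config$rate_top_n)
  write_rate_table(top, file.path(out_dir, "mutation_rates_top.tsv"))
  write_rate_table(rates, file.path(out_dir, "mutation_rates_all.tsv"))

  mutated_symbols <- unique(assignment$symbol)
  aging <- if (!is.null(aging_genes)) {
    aging_enrichment(mutated_symbols, aging_genes, background)
  } else NULL
  enrichment <- if (!is.null(gene_sets)) {
    enrich_gene_sets(mutated_symbols, gene_sets, background,
                     alpha = config$enrich_alpha,
                     min_overlap = config$enrich_min_overlap)
  } else NULL
  if (!is.null(enrichment)) {
    utils::write.table(enrichment, file.path(out_dir, "enrichment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  report <- structure(list(
    stage_counts = candidates$stage_counts,
    final_count = unname(candidates$stage_counts["annotated"]),
    n_genes_mutated = length(mutated_symbols),
    n_intergenic = attr(assignment, "n_intergenic"),
    n_moderate_high = nrow(mh$sites),
    n_rare_moderate_high = n_rare_mh,
    spectrum = spectrum_summary,
    rates = top,
    aging = aging,
    enrichment = enrichment,
    manifest_expected = manifest_expected,
    out_dir = out_dir), class = "RunReport")
  writeLines(utils::capture.output(print(report)),
             file.path(out_dir, "run_report.txt"))
  report
}

#' @export
print.RunReport <- function(x, ...) {
  cat("somaclone run report\n")
  cat("====================\n")
  cat("stage counts:\n")
  for (nm in names(x$stage_counts)) {
    cat(sprintf("  %-24s %d\n", nm, x$stage_counts[[nm]]))
  }
  cat("final candidate somatic mutations:", x$final_count, "\n")
  if (!is.null(x$manifest_expected)) {
    cat("manifest expected final count:    ", x$manifest_expected, "\n")
  }
  cat("mutation-bearing genes:", x$n_genes_mutated,
      "(intergenic sites:", x$n_intergenic, ")\n")
  cat("moderate/high-impact candidates:", x$n_moderate_high,
      "| of which rare:", x$n_rare_moderate_high, "\n")
  if (!is.null(x$spectrum$six_class)) {
    cat("spectrum: n =", x$spectrum$total,
        sprintf("flatness = %.3f", x$spectrum$flatness), "\n")
    cat("  6-class:", paste(sprintf("%s %.3f", names(x$spectrum$six_class),
                                    x$spectrum$six_class), collapse = ", "), "\n")
    cat("  best signature match:", x$spectrum$best_match$signature[1],
        sprintf("(cosine %.3f)", x$spectrum$best_match$similarity[1]), "\n")
  }
  if (!is.null(x$aging)) {
    cat(sprintf("aging-list overlap: %.1f%% of mutated genes; ",
                x$aging$overlap_percent))
    print(x$aging$test)
  }
  if (!is.null(x$enrichment)) {
    nsig <- sum(x$enrichment$significant)
    cat("gene sets significant:", nsig, "of", nrow(x$enrichment),
        "| top set:", x$enrichment$set_name[1], "\n")
  }
  invisible(x)
}
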