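#' Filter configuration for the somatic-mutation cascade
#'
#' @param min_depth Minimum clone read depth to keep a site. The default 51
#'   removes every site with DP of 50 or less.
#' @param min_shared_clones Minimum number of clones a candidate must be
#'   found in (default 2).
#' @param rare_af_max Population allele-frequency threshold below which a
#'   candidate is flagged rare (default 0.01).
#' @param panel_missing_max Maximum tolerated panel genotype missing rate;
#'   sites exceeding it get an undefined population frequency (default 0.10).
#' @return List of class \code{FilterConfig}.
#' @export
filter_config <- function(min_depth = 51L, min_shared_clones = 2L,
                          rare_af_max = 0.01, panel_missing_max = 0.10) {
  stopifnot(min_depth >= 0, min_shared_clones >= 1,
            rare_af_max >= 0, rare_af_max <= 1,
            panel_missing_max >= 0, panel_missing_max <= 1)
  structure(list(min_depth = as.integer(min_depth),
                 min_shared_clones = as.integer(min_shared_clones),
                 rare_af_max = rare_af_max,
                 panel_missing_max = panel_missing_max),
            class = "FilterConfig")
}

#' Clone-specific heterozygous sites
#'
#' A site is clone-specific when the clone sample is heterozygous and the
#' donor sample is homozygous reference. Sites where the donor is
#' heterozygous (inherited variation), homozygous alternate, or missing are
#' excluded.
#'
#' @param variants Variant table with genotype columns for both samples.
#' @param donor_name,clone_name Sample names; must differ.
#' @return Subset of \code{variants}.
#' @export
clone_specific_hets <- function(variants, donor_name, clone_name) {
  if (identical(donor_name, clone_name)) {
    stop("donor and clone sample names must differ")
  }
  gd <- variants[[paste0("gt_", donor_name)]]
  gc_ <- variants[[paste0("gt_", clone_name)]]
  if (is.null(gd) || is.null(gc_)) {
    stop("variant table lacks genotype columns for ", donor_name, " and/or ", clone_name)
  }
  out <- variants[gc_ == "het" & gd == "hom_ref", , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read-depth filter
#'
#' Keeps sites whose read depth in the clone sample is at least
#' \code{config$min_depth}; missing DP removes the site.
#'
#' @param sites Variant table.
#' @param clone_name Clone sample whose DP is thresholded.
#' @param config \code{\link{filter_config}}.
#' @return Subset of \code{sites}.
#' @export
depth_filter <- function(sites, clone_name, config = filter_config()) {
  dp <- sites[[paste0("dp_", clone_name)]]
  if (is.null(dp)) {
    stop("variant table lacks depth column for ", clone_name)
  }
  out <- sites[!is.na(dp) & dp >= config$min_depth, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Intersect per-clone candidate sets
#'
#' Keeps sites (matched on chrom, pos, ref, alt) present in at least
#' \code{config$min_shared_clones} of the per-clone sets. The returned
#' table carries a \code{clone_specific_in} provenance column listing the
#' clones whose sets contained each site, and \code{shared = TRUE}.
#'
#' @param clone_sets Named list of variant tables, one per clone.
#' @param config \code{\link{filter_config}}.
#' @return Variant table of shared sites, ordered by (chrom, pos).
#' @export
intersect_clones <- function(clone_sets, config = filter_config()) {
  if (length(clone_sets) < config$min_shared_clones) {
    stop("need at least ", config$min_shared_clones, " clone sets, got ",
         length(clone_sets))
  }
  if (is.null(names(clone_sets)) || any(!nzchar(names(clone_sets)))) {
    stop("clone_sets must be a named list")
  }
  keys_by_clone <- lapply(clone_sets, variant_key)
  all_keys <- unique(unlist(keys_by_clone))
  in_clone <- vapply(keys_by_clone, function(k) all_keys %in% k,
                     logical(length(all_keys)))
  if (length(all_keys) == 1) in_clone <- matrix(in_clone, nrow = 1)
  n_in <- rowSums(in_clone)
  shared_keys <- all_keys[n_in >= config$min_shared_clones]

  # take each shared site's row from the first set containing it
  pieces <- list()
  taken <- character(0)
  for (nm in names(clone_sets)) {
    cs <- clone_sets[[nm]]
    k <- variant_key(cs)
    sel <- k %in% shared_keys & !(k %in% taken)
    if (any(sel)) {
      pieces[[nm]] <- cs[sel, , drop = FALSE]
      taken <- c(taken, k[sel])
    }
  }
  out <- if (length(pieces) > 0) rbind_fill(pieces) else
    clone_sets[[1]][0, , drop = FALSE]
  key <- variant_key(out)
  membership <- vapply(key, function(kk) {
    paste(names(clone_sets)[vapply(keys_by_clone, function(x) kk %in% x, logical(1))],
          collapse = ",")
  }, character(1))
  out$clone_specific_in <- unname(membership)
  out$shared <- rep(TRUE, nrow(out))
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# rbind data.frames whose column sets may differ (paired-VCF mode); absent
# columns are filled with NA
rbind_fill <- function(dfs) {
  all_cols <- unique(unlist(lapply(dfs, names)))
  do.call(rbind, lapply(dfs, function(d) {
    for (nm in setdiff(all_cols, names(d))) d[[nm]] <- NA
    d[, all_cols, drop = FALSE]
  }))
}

#' Annotate candidates with population allele frequency
#'
#' Adds \code{population_af} and \code{rare} columns; no site is removed.
#' A site absent from the panel gets frequency 0 (and is rare). A site whose
#' panel genotype missing rate exceeds \code{config$panel_missing_max} gets
#' an undefined (\code{NA}) frequency and rarity.
#'
#' @param sites Variant table.
#' @param panel \code{PopulationPanel} from \code{\link{read_population_panel}}.
#' @param config \code{\link{filter_config}}.
#' @return \code{sites} with the two added columns; same row set and order.
#' @export
annotate_population_frequency <- function(sites, panel, config = filter_config()) {
  key <- variant_key(sites)
  m <- match(key, panel$key)
  af <- ifelse(is.na(m), 0, panel$af[m])
  missing_rate <- ifelse(is.na(m), 0, panel$missing_rate[m])
  bad <- missing_rate > config$panel_missing_max
  af[bad] <- NA_real_
  sites$population_af <- af
  sites$rare <- ifelse(is.na(af), NA, af < config$rare_af_max)
  sites
}

#' Run the full candidate somatic-mutation cascade
#'
#' Composition of the four stages: per-clone clone-specific heterozygous
#' site selection, per-clone depth filtering, cross-clone intersection, and
#' population allele-frequency annotation. Stage survivor counts are
#' recorded for every stage.
#'
#' @param variants Either a single multi-sample variant table containing the
#'   donor and all clones, or a named list of per-clone tables (each
#'   containing the donor and that clone).
#' @param donor Donor sample name.
#' @param clones Character vector of clone sample names (at least 2 by
#'   default configuration).
#' @param panel Optional \code{PopulationPanel}; \code{NULL} skips
#'   annotation.
#' @param config \code{\link{filter_config}}.
#' @return Object of class \code{CandidateSet}: list with \code{sites} (the
#'   final annotated table), \code{stage_counts} (named integer vector) and
#'   \code{config}.
#' @export
run_filter_cascade <- function(variants, donor, clones, panel = NULL,
                               config = filter_config()) {
  if (length(clones) < config$min_shared_clones) {
    stop("need at least ", config$min_shared_clones, " clones")
  }
  per_clone_input <- if (is.data.frame(variants)) {
    stats::setNames(rep(list(variants), length(clones)), clones)
  } else {
    if (!all(clones %in% names(variants))) {
      stop("per-clone variant list must be named by clone")
    }
    variants[clones]
  }

  stage_counts <- integer(0)
  filtered <- list()
  for (cl in clones) {
    spec <- clone_specific_hets(per_clone_input[[cl]], donor, cl)
    stage_counts[paste0("clone_specific_", cl)] <- nrow(spec)
    deep <- depth_filter(spec, cl, config)
    stage_counts[paste0("depth_pass_", cl)] <- nrow(deep)
    deep$depth_pass <- rep(TRUE, nrow(deep))
    filtered[[cl]] <- deep
  }
  shared <- intersect_clones(filtered, config)
  stage_counts["shared"] <- nrow(shared)
  if (!is.null(panel)) {
    shared <- annotate_population_frequency(shared, panel, config)
  }
  stage_counts["annotated"] <- nrow(shared)

  structure(list(sites = shared, stage_counts = stage_counts, config = config),
            class = "CandidateSet")
}

#' @export
print.CandidateSet <- function(x, ...) {
  cat("CandidateSet:", nrow(x$sites), "candidate somatic mutations\n")
  cat("stage counts:\n")
  for (nm in names(x$stage_counts)) {
    cat(sprintf("  %-24s %d\n", nm, x$stage_counts[[nm]]))
  }
  invisible(x)
}

#' Write cascade outputs as TSV / VCF
#'
#' @param candidates \code{CandidateSet}.
#' @param out_dir Output directory (created if needed).
#' @return Named list of the written paths, invisibly.
#' @export
write_candidate_set <- function(candidates, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    vcf = file.path(out_dir, "candidates.vcf"),
    stage_counts = file.path(out_dir, "stage_counts.tsv"),
    provenance = file.path(out_dir, "candidate_provenance.tsv")
  )
  write_vcf(candidates$sites, paths$vcf)
  utils::write.table(
    data.frame(stage = names(candidates$stage_counts),
               surviving = as.integer(candidates$stage_counts)),
    paths$stage_counts, sep = "\t", quote = FALSE, row.names = FALSE)
  prov_cols <- intersect(c("chrom", "pos", "ref", "alt", "clone_specific_in",
                           "depth_pass", "shared", "population_af", "rare"),
                         names(candidates$sites))
  utils::write.table(candidates$sites[, prov_cols, drop = FALSE],
                     paths$provenance, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}
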