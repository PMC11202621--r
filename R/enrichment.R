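#' Build a 2x2 contingency table from overlap margins
#'
#' Rows: gene-list membership (in / not in); columns: mutation-bearing
#' status (bearing / not). Cells are a = overlap, b = query minus overlap,
#' c = set minus overlap, d = the remainder of the background.
#'
#' @param n_total Background size (e.g. all annotated genes).
#' @param n_set Gene-set (e.g. aging-list) size within the background.
#' @param n_query Query size (e.g. mutation-bearing genes).
#' @param n_overlap Overlap between set and query.
#' @return 2x2 integer matrix \code{rbind(c(a, c), c(b, d))} arranged so
#'   that rows are query membership and columns set membership; cell [1,1]
#'   is the overlap.
#' @export
build_contingency <- function(n_total, n_set, n_query, n_overlap) {
  a <- n_overlap
  b <- n_query - n_overlap
  c_ <- n_set - n_overlap
  d <- n_total - n_set - n_query + n_overlap
  if (any(c(a, b, c_, d) < 0)) {
    stop("inconsistent margins: negative cell in contingency table")
  }
  matrix(as.integer(c(a, b, c_, d)), nrow = 2, byrow = TRUE,
         dimnames = list(query = c("in_query", "not_query"),
                         set = c("in_set", "not_set")))
}

#' Chi-squared test of independence with Yates continuity correction
#'
#' For a 2x2 table, the statistic is
#' \deqn{\sum (|O - E| - \min(0.5, |O - E|))^2 / E}
#' over the four cells, with expected counts from the margin products. The
#' correction is clamped at \eqn{|O - E|} so it never over-corrects. One
#' degree of freedom; the p-value is the upper tail of the chi-squared
#' distribution.
#'
#' @param tab 2x2 matrix of non-negative counts.
#' @return List of class \code{EnrichmentStat}: \code{statistic}, \code{df},
#'   \code{p_value}.
#' @export
chisq_yates <- function(tab) {
  stopifnot(is.matrix(tab), all(dim(tab) == c(2, 2)), all(tab >= 0))
  n <- sum(tab)
  rs <- rowSums(tab); cs <- colSums(tab)
  if (any(rs == 0) || any(cs == 0)) {
    stop("degenerate table: zero margin")
  }
  E <- outer(rs, cs) / n
  dev <- abs(tab - E)
  stat <- sum((dev - pmin(0.5, dev))^2 / E)
  structure(list(statistic = stat, df = 1L,
                 p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE)),
            class = "EnrichmentStat")
}

#' @export
print.EnrichmentStat <- function(x, ...) {
  cat(sprintf("chi-squared = %.3f, df = %d, p-value = %.3g\n",
              x$statistic, x$df, x$p_value))
  invisible(x)
}

#' Hypergeometric over-representation p-value
#'
#' Upper-tail probability P(X >= n_overlap) for X ~
#' Hypergeometric(background = n_total, set = n_set, draws = n_query),
#' accumulated in log space for numerical stability.
#'
#' @inheritParams build_contingency
#' @return p-value in (0, 1].
#' @export
hypergeom_overrep <- function(n_total, n_set, n_query, n_overlap) {
  if (n_overlap > min(n_set, n_query) || n_set > n_total || n_query > n_total ||
      any(c(n_total, n_set, n_query, n_overlap) < 0)) {
    stop("infeasible hypergeometric counts")
  }
  if (n_overlap == 0) {
    return(1)
  }
  k <- n_overlap:min(n_set, n_query)
  lp <- stats::dhyper(k, m = n_set, n = n_total - n_set, k = n_query, log = TRUE)
  lp <- lp[is.finite(lp)]
  if (length(lp) == 0) {
    return(0)
  }
  mx <- max(lp)
  min(1, exp(mx) * sum(exp(lp - mx)))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Standard step-up adjustment (via \code{stats::p.adjust}), returned in the
#' input order and clipped at 1.
#'
#' @param p_values Numeric vector in [0, 1].
#' @return Adjusted p-values.
#' @export
bh_adjust <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Gene-set over-representation analysis
#'
#' Hypergeometric upper-tail test of each set against the query, over a
#' common background, with Benjamini-Hochberg correction across all tested
#' sets. Gene identity is by case-insensitive, whitespace-trimmed symbol;
#' sets are intersected with the background (and deduplicated) before
#' testing. A set is significant when its adjusted p-value is below
#' \code{alpha} and it overlaps the query in at least \code{min_overlap}
#' genes.
#'
#' @param query Character vector of query gene symbols (must lie in the
#'   background).
#' @param sets \code{data.frame}(set_name, gene_symbol) as returned by
#'   \code{\link{read_gene_sets}}.
#' @param background Character vector of background gene symbols.
#' @param alpha Adjusted-p significance threshold (default 0.01).
#' @param min_overlap Minimum overlap for significance (default 2).
#' @return \code{data.frame}(set_name, n_set, n_overlap, p_value,
#'   adjusted_p, significant), sorted by adjusted p ascending, ties by
#'   set name.
#' @export
enrich_gene_sets <- function(query, sets, background, alpha = 0.01,
                             min_overlap = 2L) {
  norm <- function(x) toupper(trimws(x))
  background <- unique(norm(background))
  if (length(background) == 0) {
    stop("empty background")
  }
  query <- unique(norm(query))
  outside <- setdiff(query, background)
  if (length(outside) > 0) {
    warning(length(outside), " query gene(s) not in background were dropped",
            call. = FALSE)
    query <- intersect(query, background)
  }
  sets$gene_symbol <- norm(sets$gene_symbol)
  n_total <- length(background)
  n_query <- length(query)
  set_names <- sort(unique(sets$set_name))
  rows <- lapply(set_names, function(nm) {
    members <- intersect(unique(sets$gene_symbol[sets$set_name == nm]), background)
    ov <- length(intersect(members, query))
    data.frame(set_name = nm, n_set = length(members), n_overlap = ov,
               p_value = hypergeom_overrep(n_total, length(members), n_query, ov),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$adjusted_p <- bh_adjust(out$p_value)
  out$significant <- out$adjusted_p < alpha & out$n_overlap >= min_overlap
  out <- out[order(out$adjusted_p, out$set_name), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Aging-list enrichment of mutation-bearing genes
#'
#' Convenience wrapper reproducing the aging-gene association analysis:
#' builds the 2x2 table of list membership versus mutation-bearing status
#' over a gene background and applies the Yates-corrected chi-squared test.
#'
#' @param mutated_genes Symbols of mutation-bearing genes.
#' @param aging_genes Symbols of the aging-associated gene list.
#' @param background All annotated gene symbols.
#' @return List with \code{table} (the 2x2 matrix), \code{overlap_percent}
#'   (share of mutated genes on the list, in percent) and \code{test}
#'   (\code{EnrichmentStat}).
#' @export
aging_enrichment <- function(mutated_genes, aging_genes, background) {
  norm <- function(x) unique(toupper(trimws(x)))
  background <- norm(background)
  mutated <- intersect(norm(mutated_genes), background)
  aging <- intersect(norm(aging_genes), background)
  ov <- length(intersect(mutated, aging))
  tab <- build_contingency(length(background), length(aging), length(mutated), ov)
  list(table = tab,
       overlap_percent = 100 * ov / length(mutated),
       test = chisq_yates(tab))
}
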