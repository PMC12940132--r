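#' Presence calls from coverage breadth
#'
#' `call_gene_presence()` flags a gene present when the covered fraction of
#' its length reaches `gene_cutoff`; `call_bgc_presence()` flags a BGC
#' present when the fraction of its genes called present reaches
#' `bgc_cutoff`. Both comparisons are inclusive (`>=`): the cutoffs read as
#' minimum requirements. Defaults (0.3, 0.5) are the operating point
#' selected by mock-community optimization (see [evaluate_cutoffs()]).
#'
#' @param covered_fraction Numeric vector in \[0, 1\].
#' @param gene_cutoff Minimum covered fraction for a gene call.
#' @return Logical vector.
#' @export
#' @examples
#' call_gene_presence(c(0.30, 0.299, 1)) # TRUE FALSE TRUE
call_gene_presence <- function(covered_fraction, gene_cutoff = 0.3) {
  stopifnot(all(is.finite(covered_fraction)),
            all(covered_fraction >= 0), all(covered_fraction <= 1))
  covered_fraction >= gene_cutoff
}

#' @rdname call_gene_presence
#' @param gene_flags Logical vector of per-gene presence calls (>= 1 gene).
#' @param bgc_cutoff Minimum fraction of present genes for a BGC call.
#' @export
call_bgc_presence <- function(gene_flags, bgc_cutoff = 0.5) {
  if (length(gene_flags) < 1) {
    abort("a BGC needs at least one gene", class = "bgctempo_validation_error")
  }
  mean(gene_flags) >= bgc_cutoff
}

#' RPKM abundance
#'
#' Reads per kilobase per million mapped reads:
#' `read_count / ((length_bp / 1000) * (total_mapped_reads / 1e6))`.
#' The denominator uses reads mapped to the catalog in the same sample.
#'
#' @param read_count Mapped reads on the feature (vectorized).
#' @param length_bp Feature length in nucleotides (> 0).
#' @param total_mapped_reads Total mapped reads in the sample (> 0; zero is
#'   an error, never a silent NaN).
#' @return Numeric RPKM values.
#' @export
#' @examples
#' rpkm(10, 1000, 1e6) # 10
rpkm <- function(read_count, length_bp, total_mapped_reads) {
  if (any(length_bp <= 0)) {
    abort("length_bp must be > 0", class = "bgctempo_validation_error")
  }
  if (any(total_mapped_reads <= 0)) {
    abort("total_mapped_reads must be > 0", class = "bgctempo_validation_error")
  }
  read_count / ((length_bp / 1000) * (total_mapped_reads / 1e6))
}

# shared scaffolding: per-(gene, sample) covered-fraction and read-count
# matrices in catalog gene order, absent pairs filled with 0
coverage_matrices <- function(coverage, catalog, samples = NULL) {
  coverage <- validate_coverage(coverage)
  genes <- catalog_genes(catalog)
  stray <- setdiff(coverage$gene_id, genes$gene_id)
  if (length(stray) > 0) {
    abort(paste0("coverage refers to genes absent from the catalog: ",
                 paste(utils::head(stray, 5), collapse = ", ")),
          class = "bgctempo_validation_error")
  }
  if (anyDuplicated(genes$gene_id)) {
    abort("gene ids must be unique across the catalog for coverage mapping",
          class = "bgctempo_validation_error")
  }
  if (is.null(samples)) samples <- sort(unique(coverage$sample_id))
  gi <- match(coverage$gene_id, genes$gene_id)
  si <- match(coverage$sample_id, samples)
  keep <- !is.na(si)
  frac <- matrix(0, nrow(genes), length(samples),
                 dimnames = list(genes$gene_id, samples))
  reads <- frac
  frac[cbind(gi[keep], si[keep])] <- coverage$covered_fraction[keep]
  reads[cbind(gi[keep], si[keep])] <- coverage$read_count[keep]
  list(genes = genes, samples = samples, frac = frac, reads = reads)
}

#' Build a BGC presence table from coverage
#'
#' Applies the two-stage call of [call_gene_presence()] and
#' [call_bgc_presence()] across every (BGC, sample) pair. (sample, gene)
#' pairs absent from the coverage table count as fraction 0.
#'
#' @param coverage Coverage tibble as from [read_coverage_table()].
#' @param catalog A `bgc_catalog`.
#' @param gene_cutoff,bgc_cutoff Detection cutoffs (inclusive).
#' @param samples Optional character vector fixing the sample set and order
#'   (samples with no coverage rows become all-absent columns).
#' @return A `bgc_presence` tibble: `bgc_id`, `sample_id`, `gene_fraction`
#'   (fraction of genes called present), `present`; the cutoffs used are
#'   recorded in attributes `gene_cutoff` and `bgc_cutoff`.
#' @export
presence_from_coverage <- function(coverage, catalog, gene_cutoff = 0.3,
                                   bgc_cutoff = 0.5, samples = NULL) {
  cm <- coverage_matrices(coverage, catalog, samples)
  gene_on <- cm$frac >= gene_cutoff
  bgc_of_gene <- factor(cm$genes$bgc_id, levels = catalog$bgc_id)
  n_genes <- as.vector(table(bgc_of_gene))
  frac_on <- rowsum(gene_on + 0, bgc_of_gene) / n_genes
  out <- tibble(
    bgc_id = rep(rownames(frac_on), times = ncol(frac_on)),
    sample_id = rep(colnames(frac_on), each = nrow(frac_on)),
    gene_fraction = as.vector(frac_on),
    present = as.vector(frac_on >= bgc_cutoff)
  )
  attr(out, "gene_cutoff") <- gene_cutoff
  attr(out, "bgc_cutoff") <- bgc_cutoff
  class(out) <- c("bgc_presence", class(out))
  out
}

#' RPKM abundance table from coverage
#'
#' Sums mapped reads over each BGC's genes and converts to RPKM against the
#' BGC length and the sample's total catalog-mapped reads. Optionally masks
#' abundance to 0 where the presence call is absent (off by default; the
#' unmasked table is always recoverable by rerunning without the mask).
#'
#' @inheritParams presence_from_coverage
#' @param mask_to_presence If `TRUE`, abundance is zeroed where `presence`
#'   says absent.
#' @param presence A `bgc_presence` table; required when masking.
#' @return Tibble `bgc_id`, `sample_id`, `reads`, `total_mapped_reads`,
#'   `rpkm`.
#' @export
abundance_from_coverage <- function(coverage, catalog, samples = NULL,
                                    mask_to_presence = FALSE, presence = NULL) {
  cm <- coverage_matrices(coverage, catalog, samples)
  bgc_of_gene <- factor(cm$genes$bgc_id, levels = catalog$bgc_id)
  bgc_reads <- rowsum(cm$reads, bgc_of_gene)
  totals <- colSums(cm$reads)
  if (any(totals <= 0)) {
    abort(paste0("sample(s) with zero mapped reads: ",
                 paste(utils::head(cm$samples[totals <= 0], 5), collapse = ", ")),
          class = "bgctempo_validation_error")
  }
  lens <- catalog$length_bp[match(rownames(bgc_reads), catalog$bgc_id)]
  out <- tibble(
    bgc_id = rep(rownames(bgc_reads), times = ncol(bgc_reads)),
    sample_id = rep(cm$samples, each = nrow(bgc_reads)),
    reads = as.vector(bgc_reads),
    total_mapped_reads = rep(unname(totals), each = nrow(bgc_reads))
  )
  out$rpkm <- rpkm(out$reads, rep(lens, times = ncol(bgc_reads)),
                   out$total_mapped_reads)
  if (mask_to_presence) {
    if (is.null(presence)) {
      abort("mask_to_presence = TRUE needs a presence table",
            class = "bgctempo_validation_error")
    }
    out <- out %>%
      dplyr::left_join(
        dplyr::select(as_tibble(presence), "bgc_id", "sample_id", "present"),
        by = c("bgc_id", "sample_id")
      ) %>%
      dplyr::mutate(rpkm = ifelse(is.na(.data$present) | !.data$present,
                                  0, .data$rpkm)) %>%
      dplyr::select(-"present")
  }
  out
}

#' Widen a presence table to a logical matrix
#'
#' @param presence A `bgc_presence` tibble (or any tibble with `bgc_id`,
#'   `sample_id` and a logical `present` column).
#' @return Logical matrix, BGC rows by sample columns.
#' @export
presence_matrix <- function(presence) {
  long_to_matrix(presence, "present")
}

#' Widen an abundance table to an RPKM matrix
#'
#' @param abundance Tibble with `bgc_id`, `sample_id`, `rpkm`.
#' @return Numeric matrix, BGC rows by sample columns.
#' @export
abundance_matrix <- function(abundance) {
  long_to_matrix(abundance, "rpkm")
}

long_to_matrix <- function(tbl, value_col) {
  tbl <- as_tibble(tbl)
  rows <- unique(tbl$bgc_id)
  cols <- unique(tbl$sample_id)
  mat <- matrix(if (is.logical(tbl[[value_col]])) NA else NA_real_,
                length(rows), length(cols), dimnames = list(rows, cols))
  mat[cbind(match(tbl$bgc_id, rows), match(tbl$sample_id, cols))] <- tbl[[value_col]]
  if (anyNA(mat)) {
    abort("long table does not cover the full BGC-by-sample grid",
          class = "bgctempo_validation_error")
  }
  mat
}

#' Grid-search detection cutoffs against ground truth
#'
#' Mock-community optimization of the two detection cutoffs: for every
#' (gene_cutoff, bgc_cutoff) grid point the presence calls over all
#' (sample, BGC) pairs are scored against the ground-truth presence matrix
#' as TP/FP/FN/TN with recall, precision and F1. The selected pair
#' maximizes F1; ties break to higher precision, then lower gene cutoff,
#' then lower BGC cutoff. The whole grid is returned so any other selection
#' rule can be applied downstream.
#'
#' @inheritParams presence_from_coverage
#' @param truth Logical matrix (BGC by sample) of true presence, or a
#'   tibble with `bgc_id`, `sample_id`, `present`. Ids must match the
#'   catalog and coverage samples.
#' @param gene_grid,bgc_grid Cutoff grids (default 0.1..0.9 by 0.1).
#' @return A `cutoff_grid` tibble with one row per grid point:
#'   `gene_cutoff`, `bgc_cutoff`, `tp`, `fp`, `fn`, `tn`, `recall`,
#'   `precision`, `f1` (undefined ratios are `NA`); the winning pair is in
#'   attribute `selected` and via [glance()].
#' @export
evaluate_cutoffs <- function(coverage, catalog, truth,
                             gene_grid = seq(0.1, 0.9, by = 0.1),
                             bgc_grid = seq(0.1, 0.9, by = 0.1)) {
  if (!is.matrix(truth)) truth <- presence_matrix(truth)
  if (!setequal(rownames(truth), catalog$bgc_id)) {
    abort("truth rows do not match catalog BGC ids",
          class = "bgctempo_validation_error")
  }
  cm <- coverage_matrices(coverage, catalog, samples = colnames(truth))
  truth <- truth[catalog$bgc_id, cm$samples, drop = FALSE]
  bgc_of_gene <- factor(cm$genes$bgc_id, levels = catalog$bgc_id)
  n_genes <- as.vector(table(bgc_of_gene))

  grid <- tidyr::expand_grid(gene_cutoff = gene_grid, bgc_cutoff = bgc_grid)
  res <- purrr::pmap_dfr(grid, function(gene_cutoff, bgc_cutoff) {
    frac_on <- rowsum((cm$frac >= gene_cutoff) + 0, bgc_of_gene) / n_genes
    calls <- frac_on >= bgc_cutoff
    tp <- sum(calls & truth); fp <- sum(calls & !truth)
    fn <- sum(!calls & truth); tn <- sum(!calls & !truth)
    tibble(gene_cutoff, bgc_cutoff, tp, fp, fn, tn,
           recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
           precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_)
  })
  res$f1 <- dplyr::if_else(
    !is.na(res$recall) & !is.na(res$precision) & (res$recall + res$precision) > 0,
    2 * res$recall * res$precision / (res$recall + res$precision),
    NA_real_
  )
  ord <- order(-ifelse(is.na(res$f1), -Inf, res$f1),
               -ifelse(is.na(res$precision), -Inf, res$precision),
               res$gene_cutoff, res$bgc_cutoff)
  sel <- res[ord[1], ]
  attr(res, "selected") <- list(gene_cutoff = sel$gene_cutoff,
                                bgc_cutoff = sel$bgc_cutoff, f1 = sel$f1,
                                recall = sel$recall, precision = sel$precision)
  class(res) <- c("cutoff_grid", class(res))
  res
}

#' @export
tidy.cutoff_grid <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "cutoff_grid")
  attr(out, "selected") <- NULL
  out
}

#' @export
glance.cutoff_grid <- function(x, ...) {
  sel <- attr(x, "selected")
  tibble(gene_cutoff = sel$gene_cutoff, bgc_cutoff = sel$bgc_cutoff,
         f1 = sel$f1, recall = sel$recall, precision = sel$precision,
         n_grid = nrow(x))
}
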