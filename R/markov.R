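#' Count presence/absence transitions for one BGC
#'
#' Tallies consecutive-visit state transitions (0 = absent, 1 = present)
#' pooled across subjects. Only pairs of consecutively indexed visits
#' (v, v+1) that are both observed contribute; gaps are skipped, never
#' imputed, and subjects with a single visit contribute nothing.
#'
#' @param presence A `bgc_presence` tibble (or tibble with `bgc_id`,
#'   `sample_id`, `present`).
#' @param meta Sample metadata with `sample_id`, `subject_id`, `visit`.
#' @param bgc_id The BGC to count.
#' @return Named list `n00`, `n01`, `n10`, `n11` (first index = earlier
#'   state).
#' @export
count_transitions <- function(presence, meta, bgc_id) {
  fit <- fit_markov(dplyr::filter(as_tibble(presence), .data$bgc_id == !!bgc_id),
                    meta)
  est <- tidy(fit)
  if (nrow(est) != 1) {
    abort(paste0("no presence rows for ", bgc_id), class = "bgctempo_validation_error")
  }
  as.list(est[, c("n00", "n01", "n10", "n11")])
}

#' Estimate two-state Markov transition probabilities from counts
#'
#' Maximum-likelihood row-normalized transition frequencies. The inflow
#' probability (absence to presence) is `n01 / (n00 + n01)`; the outflow
#' probability (presence to absence) is `n10 / (n10 + n11)`. An empty
#' from-state row yields `NA` — no pseudocount smoothing is applied, so a
#' BGC never observed absent has an undefined inflow.
#'
#' @param counts Named list or vector with `n00`, `n01`, `n10`, `n11`.
#' @param threshold Classification threshold on both probabilities.
#' @return Named list `p_inflow`, `p_outflow`, `log10_ratio`,
#'   `classification`.
#' @export
#' @examples
#' estimate_markov(list(n00 = 0, n01 = 2, n10 = 2, n11 = 2))
estimate_markov <- function(counts, threshold = 0.3) {
  n00 <- counts[["n00"]]; n01 <- counts[["n01"]]
  n10 <- counts[["n10"]]; n11 <- counts[["n11"]]
  stopifnot(all(c(n00, n01, n10, n11) >= 0))
  p_in <- if (n00 + n01 > 0) n01 / (n00 + n01) else NA_real_
  p_out <- if (n10 + n11 > 0) n10 / (n10 + n11) else NA_real_
  list(
    p_inflow = p_in,
    p_outflow = p_out,
    log10_ratio = markov_log_ratio(p_in, p_out),
    classification = classify_markov(p_in, p_out, threshold)
  )
}

markov_log_ratio <- function(p_in, p_out) {
  out <- log10(p_in / p_out)
  out[is.nan(out)] <- NA_real_ # 0/0
  out
}

#' Classify a BGC as persistent or transient
#'
#' Persistent: inflow above the threshold and outflow below it — once
#' present the cluster stays, and when lost it tends to reappear.
#' Transient: the mirror image. Both inequalities are strict, so a
#' probability exactly at the threshold is `unclassified`; any `NA`
#' probability makes the classification `NA`.
#'
#' @param p_inflow,p_outflow Transition probabilities (vectorized).
#' @param threshold Decision threshold (default 0.3).
#' @return Character vector: `"persistent"`, `"transient"`,
#'   `"unclassified"`, or `NA`.
#' @export
classify_markov <- function(p_inflow, p_outflow, threshold = 0.3) {
  dplyr::case_when(
    is.na(p_inflow) | is.na(p_outflow) ~ NA_character_,
    p_inflow > threshold & p_outflow < threshold ~ "persistent",
    p_inflow < threshold & p_outflow > threshold ~ "transient",
    TRUE ~ "unclassified"
  )
}

#' Fit per-BGC two-state Markov turnover models over a cohort
#'
#' For every BGC, pools consecutive-visit transitions across all subjects
#' into one chain (per-subject fits are unsupported by 3 transitions per
#' subject), estimates inflow/outflow by maximum likelihood and classifies
#' the cluster as persistent or transient.
#'
#' @inheritParams count_transitions
#' @param threshold Classification threshold (default 0.3).
#' @return Object of class `markov_fit`. [tidy()] gives one row per BGC:
#'   `bgc_id`, `n00`..`n11`, `p_inflow`, `p_outflow`, `log10_ratio`,
#'   `prevalence`, `classification`; [glance()] gives cohort-level counts.
#' @export
fit_markov <- function(presence, meta, threshold = 0.3) {
  presence <- as_tibble(presence)
  meta <- validate_metadata(meta)
  missing <- setdiff(unique(presence$sample_id), meta$sample_id)
  if (length(missing) > 0) {
    abort(paste0("presence samples missing from metadata: ",
                 paste(utils::head(missing, 5), collapse = ", ")),
          class = "bgctempo_validation_error")
  }
  pm <- presence_matrix(presence)
  meta <- meta[match(colnames(pm), meta$sample_id), ]

  # consecutive observed visit pairs within each subject
  pairs <- meta %>%
    dplyr::select("sample_id", "subject_id", "visit") %>%
    dplyr::inner_join(
      meta %>% dplyr::select(sample_to = "sample_id", "subject_id",
                             visit_to = "visit"),
      by = "subject_id", relationship = "many-to-many"
    ) %>%
    dplyr::filter(.data$visit_to == .data$visit + 1L)

  if (nrow(pairs) > 0) {
    from <- pm[, pairs$sample_id, drop = FALSE]
    to <- pm[, pairs$sample_to, drop = FALSE]
    n11 <- rowSums(from & to); n10 <- rowSums(from & !to)
    n01 <- rowSums(!from & to); n00 <- rowSums(!from & !to)
  } else {
    n11 <- n10 <- n01 <- n00 <- stats::setNames(rep(0, nrow(pm)), rownames(pm))
  }
  p_in <- ifelse(n00 + n01 > 0, n01 / (n00 + n01), NA_real_)
  p_out <- ifelse(n10 + n11 > 0, n10 / (n10 + n11), NA_real_)

  est <- tibble(
    bgc_id = rownames(pm),
    n00 = as.integer(n00), n01 = as.integer(n01),
    n10 = as.integer(n10), n11 = as.integer(n11),
    p_inflow = unname(p_in), p_outflow = unname(p_out),
    log10_ratio = markov_log_ratio(unname(p_in), unname(p_out)),
    prevalence = unname(prevalence_vector(pm, meta)),
    classification = classify_markov(unname(p_in), unname(p_out), threshold)
  )
  structure(list(estimates = est, threshold = threshold,
                 n_subjects = dplyr::n_distinct(meta$subject_id),
                 n_pairs = nrow(pairs)),
            class = "markov_fit")
}

#' @export
print.markov_fit <- function(x, ...) {
  cls <- table(factor(x$estimates$classification,
                      levels = c("persistent", "transient", "unclassified")),
               useNA = "ifany")
  cat("Two-state Markov turnover fit\n")
  cat("  BGCs: ", nrow(x$estimates), "; subjects: ", x$n_subjects,
      "; transition pairs: ", x$n_pairs, "\n", sep = "")
  cat("  persistent: ", cls[["persistent"]],
      "  transient: ", cls[["transient"]],
      "  unclassified: ", cls[["unclassified"]],
      "  (threshold ", x$threshold, ", strict)\n", sep = "")
  invisible(x)
}

#' @export
tidy.markov_fit <- function(x, ...) x$estimates

#' @export
glance.markov_fit <- function(x, ...) {
  est <- x$estimates
  tibble(
    n_bgcs = nrow(est),
    n_subjects = x$n_subjects,
    n_transition_pairs = x$n_pairs,
    n_persistent = sum(est$classification == "persistent", na.rm = TRUE),
    n_transient = sum(est$classification == "transient", na.rm = TRUE),
    n_unclassified = sum(est$classification == "unclassified", na.rm = TRUE),
    n_na = sum(is.na(est$classification)),
    threshold = x$threshold
  )
}

prevalence_vector <- function(pm, meta) {
  subj <- factor(meta$subject_id[match(colnames(pm), meta$sample_id)])
  any_by_subject <- t(rowsum(t(pm + 0), subj) > 0) # bgc x subject
  rowSums(any_by_subject) / nlevels(subj)
}

#' One-year prevalence of BGCs across subjects
#'
#' Fraction of subjects in which the BGC was detected in at least one
#' visit.
#'
#' @inheritParams count_transitions
#' @param bgc_id Optional single BGC id; default all.
#' @return Tibble `bgc_id`, `prevalence`, or a single numeric when
#'   `bgc_id` is given.
#' @export
prevalence <- function(presence, meta, bgc_id = NULL) {
  meta <- validate_metadata(meta)
  pm <- presence_matrix(presence)
  prev <- prevalence_vector(pm, meta)
  if (!is.null(bgc_id)) {
    if (!bgc_id %in% names(prev)) {
      abort(paste0("unknown bgc_id: ", bgc_id), class = "bgctempo_validation_error")
    }
    return(unname(prev[bgc_id]))
  }
  tibble(bgc_id = names(prev), prevalence = unname(prev))
}

#' Fraction of BGCs shared between consecutive visits
#'
#' For each subject and each consecutive observed visit pair, the overlap
#' between the BGC sets present at the two visits. The default measure is
#' the Jaccard fraction `|A ∩ B| / |A ∪ B|`; `method = "retention"` gives
#' the forward retention `|A ∩ B| / |A|`. `NA` when the denominator set is
#' empty.
#'
#' @inheritParams count_transitions
#' @param method `"jaccard"` (default) or `"retention"`.
#' @param subject Optional subject id filter.
#' @param visit_pair Optional length-2 integer vector `c(v, v + 1)` filter.
#' @return Tibble `subject_id`, `visit_from`, `visit_to`,
#'   `shared_fraction`.
#' @export
consecutive_shared_fraction <- function(presence, meta,
                                        method = c("jaccard", "retention"),
                                        subject = NULL, visit_pair = NULL) {
  method <- match.arg(method)
  meta <- validate_metadata(meta)
  pm <- presence_matrix(presence)
  meta <- meta[match(colnames(pm), meta$sample_id), ]
  pairs <- meta %>%
    dplyr::select("sample_id", "subject_id", "visit") %>%
    dplyr::inner_join(
      meta %>% dplyr::select(sample_to = "sample_id", "subject_id",
                             visit_to = "visit"),
      by = "subject_id", relationship = "many-to-many"
    ) %>%
    dplyr::filter(.data$visit_to == .data$visit + 1L)
  if (!is.null(subject)) pairs <- dplyr::filter(pairs, .data$subject_id %in% subject)
  if (!is.null(visit_pair)) {
    pairs <- dplyr::filter(pairs, .data$visit == visit_pair[1],
                           .data$visit_to == visit_pair[2])
  }
  a <- pm[, pairs$sample_id, drop = FALSE]
  b <- pm[, pairs$sample_to, drop = FALSE]
  inter <- colSums(a & b)
  denom <- if (method == "jaccard") colSums(a | b) else colSums(a)
  tibble(
    subject_id = pairs$subject_id,
    visit_from = pairs$visit,
    visit_to = pairs$visit_to,
    shared_fraction = unname(ifelse(denom > 0, inter / denom, NA_real_))
  )
}

#' Spearman correlation between BGC and host-species abundance
#'
#' Rank correlation (average ranks on ties) between a BGC's abundance
#' profile and the abundance profile of its assigned metagenomic species
#' pan-genome (MSP) across the same samples. A constant profile on either
#' side gives `NA`.
#'
#' @param bgc_abundance_row,msp_abundance_row Numeric vectors over the same
#'   samples.
#' @return Spearman's rho, or `NA`.
#' @export
abundance_msp_correlation <- function(bgc_abundance_row, msp_abundance_row) {
  stopifnot(length(bgc_abundance_row) == length(msp_abundance_row))
  if (length(unique(bgc_abundance_row)) < 2 ||
      length(unique(msp_abundance_row)) < 2) {
    return(NA_real_)
  }
  stats::cor(bgc_abundance_row, msp_abundance_row, method = "spearman")
}
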