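#' Assemble FMT triads from presence calls and metadata
#'
#' An FMT triad couples one donor sample, one pre-FMT recipient sample and
#' one designated post-FMT recipient sample. Cohorts with several post-FMT
#' timepoints must designate one per triad in the metadata — the package
#' never picks one heuristically. The BGC set of each role is read from the
#' presence table, so triads inherit the detection cutoffs used upstream.
#'
#' @param presence A `bgc_presence` tibble.
#' @param meta Sample metadata with `triad_id`, `triad_role` (donor, pre,
#'   post), `cohort`, `response` filled on triad samples.
#' @return A `fmt_triads` tibble: `triad_id`, `cohort`, `response`, and
#'   list-columns `donor_set`, `pre_set`, `post_set` of present BGC ids.
#'   Detection cutoffs from the presence table are carried in attributes.
#' @export
build_triads <- function(presence, meta) {
  meta <- validate_metadata(meta)
  tm <- dplyr::filter(meta, !is.na(.data$triad_id))
  if (nrow(tm) == 0) {
    abort("metadata contains no triad samples", class = "bgctempo_validation_error")
  }
  if (anyDuplicated(tm[, c("triad_id", "triad_role")])) {
    abort("a triad has more than one sample for the same role; designate one",
          class = "bgctempo_validation_error")
  }
  counts <- tm %>% dplyr::count(.data$triad_id)
  incomplete <- counts$triad_id[counts$n != 3]
  if (length(incomplete) > 0) {
    abort(paste0("incomplete triads (need donor, pre, post): ",
                 paste(utils::head(incomplete, 5), collapse = ", ")),
          class = "bgctempo_validation_error")
  }
  pm <- presence_matrix(presence)
  missing <- setdiff(tm$sample_id, colnames(pm))
  if (length(missing) > 0) {
    abort(paste0("triad samples absent from presence table: ",
                 paste(utils::head(missing, 5), collapse = ", ")),
          class = "bgctempo_validation_error")
  }
  set_of <- function(s) rownames(pm)[pm[, s]]
  out <- tm %>%
    dplyr::select("triad_id", "triad_role", "sample_id", "cohort", "response") %>%
    tidyr::pivot_wider(id_cols = c("triad_id", "cohort", "response"),
                       names_from = "triad_role", values_from = "sample_id") %>%
    dplyr::mutate(
      response = dplyr::coalesce(.data$response, "unknown"),
      donor_set = purrr::map(.data$donor, set_of),
      pre_set = purrr::map(.data$pre, set_of),
      post_set = purrr::map(.data$post, set_of)
    ) %>%
    dplyr::select("triad_id", "cohort", "response",
                  "donor_set", "pre_set", "post_set")
  attr(out, "gene_cutoff") <- attr(presence, "gene_cutoff")
  attr(out, "bgc_cutoff") <- attr(presence, "bgc_cutoff")
  class(out) <- c("fmt_triads", class(out))
  out
}

restrict_sets <- function(donor, pre, post, restrict_to) {
  if (!is.null(restrict_to)) {
    donor <- intersect(donor, restrict_to)
    pre <- intersect(pre, restrict_to)
    post <- intersect(post, restrict_to)
  }
  list(donor = donor, pre = pre, post = post)
}

#' Colonization rate of one FMT triad
#'
#' Fraction of the donor's BGCs that were absent from the recipient before
#' FMT and present after: `|donor ∩ post \ pre| / |donor \ pre|`. `NA`
#' when no donor BGC was absent pre-FMT (empty denominator). With
#' `restrict_to`, all three sets are first intersected with the given BGC
#' universe (used to stratify by persistent/transient class).
#'
#' @param triad One row of a `fmt_triads` table (or a list with
#'   `donor_set`, `pre_set`, `post_set`).
#' @param restrict_to Optional character vector of BGC ids.
#' @return A rate in \[0, 1\] or `NA`.
#' @export
#' @examples
#' triad_colonization_rate(list(donor_set = list(c("A", "B", "C", "D")),
#'                              pre_set = list("B"),
#'                              post_set = list(c("A", "C")))) # 2/3
triad_colonization_rate <- function(triad, restrict_to = NULL) {
  s <- restrict_sets(triad$donor_set[[1]], triad$pre_set[[1]],
                     triad$post_set[[1]], restrict_to)
  eligible <- setdiff(s$donor, s$pre)
  if (length(eligible) == 0) {
    return(NA_real_)
  }
  length(intersect(eligible, s$post)) / length(eligible)
}

#' Shared fractions of a triad's post-FMT BGCs
#'
#' Of the BGCs present in the post-FMT sample, the fraction also present in
#' the donor and the fraction also present in the pre-FMT recipient.
#' `NA` pair when the (restricted) post set is empty.
#'
#' @inheritParams triad_colonization_rate
#' @return Named list `frac_post_in_donor`, `frac_post_in_pre`.
#' @export
shared_fractions <- function(triad, restrict_to = NULL) {
  s <- restrict_sets(triad$donor_set[[1]], triad$pre_set[[1]],
                     triad$post_set[[1]], restrict_to)
  if (length(s$post) == 0) {
    return(list(frac_post_in_donor = NA_real_, frac_post_in_pre = NA_real_))
  }
  list(
    frac_post_in_donor = length(intersect(s$post, s$donor)) / length(s$post),
    frac_post_in_pre = length(intersect(s$post, s$pre)) / length(s$post)
  )
}

#' Per-BGC colonization rate across triads
#'
#' For each BGC, the number of triads where it was present in the donor and
#' the post-FMT sample but absent pre-FMT, divided by the number of triads
#' where it was present in the donor and absent pre-FMT. `NA` with no
#' eligible triad.
#'
#' @param triads An `fmt_triads` table.
#' @param bgc_id Optional single id; default all BGCs seen in any donor.
#' @return Tibble `bgc_id`, `n_eligible`, `n_colonized`, `rate`, or a
#'   single numeric when `bgc_id` is given.
#' @export
bgc_colonization_rate <- function(triads, bgc_id = NULL) {
  universe <- sort(unique(unlist(triads$donor_set)))
  per_triad <- purrr::pmap(
    list(triads$donor_set, triads$pre_set, triads$post_set),
    function(d, p, q) {
      eligible <- setdiff(d, p)
      list(eligible = eligible, colonized = intersect(eligible, q))
    }
  )
  n_eligible <- table(factor(unlist(purrr::map(per_triad, "eligible")),
                             levels = universe))
  n_colonized <- table(factor(unlist(purrr::map(per_triad, "colonized")),
                              levels = universe))
  out <- tibble(
    bgc_id = universe,
    n_eligible = as.integer(n_eligible),
    n_colonized = as.integer(n_colonized),
    rate = ifelse(n_eligible > 0, as.integer(n_colonized) / as.integer(n_eligible),
                  NA_real_)
  )
  if (!is.null(bgc_id)) {
    row <- out$rate[out$bgc_id == bgc_id]
    return(if (length(row) == 0) NA_real_ else row)
  }
  out
}

#' Triad-level colonization statistics, stratified by BGC class
#'
#' Computes each triad's colonization rate and shared fractions within each
#' BGC class of `class_map` (typically persistent vs transient from
#' [fit_markov()]).
#'
#' @param triads An `fmt_triads` table.
#' @param class_map Tibble `bgc_id`, `classification`; `NA` classifications
#'   are dropped. `NULL` computes unstratified rates (class `"all"`).
#' @return Tibble `triad_id`, `cohort`, `response`, `classification`,
#'   `rate`, `frac_post_in_donor`, `frac_post_in_pre`.
#' @export
fmt_colonization <- function(triads, class_map = NULL) {
  classes <- if (is.null(class_map)) {
    list(all = NULL)
  } else {
    cm <- dplyr::filter(as_tibble(class_map), !is.na(.data$classification))
    split(cm$bgc_id, cm$classification)
  }
  purrr::imap_dfr(classes, function(ids, cls) {
    purrr::map_dfr(seq_len(nrow(triads)), function(i) {
      triad <- triads[i, ]
      sf <- shared_fractions(triad, restrict_to = ids)
      tibble(
        triad_id = triad$triad_id, cohort = triad$cohort,
        response = triad$response, classification = cls,
        rate = triad_colonization_rate(triad, restrict_to = ids),
        frac_post_in_donor = sf$frac_post_in_donor,
        frac_post_in_pre = sf$frac_post_in_pre
      )
    })
  })
}

#' Mean and SD of triad colonization rates per group
#'
#' Groups triad-level rates by BGC class and cohort (and clinical response
#' when `by_response`), reporting the mean, SD, group size and how many
#' triads were excluded for an undefined (`NA`) rate. The SD of a
#' single-triad group is `NA`.
#'
#' @param triads An `fmt_triads` table.
#' @param class_map Tibble `bgc_id`, `classification` (or `NULL`).
#' @param by_response Also stratify by clinical response.
#' @return Tibble with grouping columns plus `n`, `n_excluded`,
#'   `mean_rate`, `sd_rate`.
#' @export
group_summary <- function(triads, class_map = NULL, by_response = FALSE) {
  rates <- fmt_colonization(triads, class_map)
  keys <- c("classification", "cohort", if (by_response) "response")
  rates %>%
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) %>%
    dplyr::summarise(
      n = sum(!is.na(.data$rate)),
      n_excluded = sum(is.na(.data$rate)),
      mean_rate = mean(.data$rate, na.rm = TRUE),
      sd_rate = stats::sd(.data$rate[!is.na(.data$rate)]),
      .groups = "drop"
    ) %>%
    dplyr::mutate(mean_rate = ifelse(is.nan(.data$mean_rate), NA_real_,
                                     .data$mean_rate))
}

#' Count BGCs detected anywhere in a triad collection
#'
#' How many of `bgc_set` appear in at least one donor, pre- or post-FMT
#' sample of any triad.
#'
#' @param triads An `fmt_triads` table.
#' @param bgc_set Character vector of BGC ids.
#' @return Integer count.
#' @export
detected_in_any <- function(triads, bgc_set) {
  if (nrow(triads) == 0) {
    return(0L)
  }
  seen <- unique(unlist(c(triads$donor_set, triads$pre_set, triads$post_set)))
  length(intersect(bgc_set, seen))
}
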