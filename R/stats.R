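#' One-tailed hypergeometric enrichment / depletion test
#'
#' Exact tail probabilities for drawing `k` annotated members in a group of
#' size `n` from a background of `N` BGCs of which `K` are annotated:
#' enrichment p = P\[X >= k\], depletion p = P\[X <= k\], X ~
#' Hypergeometric(N, K, n). Directional one-tailed tests are the default
#' (matching how enrichment and depletion are conventionally reported);
#' `direction = "two_sided"` doubles the smaller tail, capped at 1.
#'
#' @param N Background size.
#' @param K Annotated in the background.
#' @param n Group size.
#' @param k Annotated in the group.
#' @param direction `"enrichment"`, `"depletion"`, or `"two_sided"`.
#' @return One-row tibble: `N`, `K`, `n`, `k`, `fold`, `direction`,
#'   `p_value`.
#' @export
#' @examples
#' hypergeom_test(10, 5, 4, 4) # p = choose(5,4)/choose(10,4)
hypergeom_test <- function(N, K, n, k,
                           direction = c("enrichment", "depletion", "two_sided")) {
  direction <- match.arg(direction)
  if (!(K >= 0 && K <= N && n >= 0 && n <= N && k >= 0 && k <= min(n, K))) {
    abort("need 0 <= K <= N, 0 <= n <= N, 0 <= k <= min(n, K)",
          class = "bgctempo_validation_error")
  }
  p_enrich <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  p_deplete <- stats::phyper(k, K, N - K, n)
  p <- switch(direction,
    enrichment = p_enrich,
    depletion = p_deplete,
    two_sided = min(1, 2 * min(p_enrich, p_deplete))
  )
  tibble(N = N, K = K, n = n, k = k,
         fold = fold_enrichment(N, K, n, k,
                                direction = if (direction == "depletion")
                                  "depletion" else "enrichment"),
         direction = direction, p_value = p)
}

#' Fold enrichment / depletion
#'
#' The ratio of the observed annotation rate in the group to the background
#' rate, `(k/n) / (K/N)`. For `direction = "depletion"` the reciprocal
#' (expected over observed) is returned, so printed folds are >= 1 in the
#' reported direction ("2-fold depletion" means half the expected rate).
#'
#' @inheritParams hypergeom_test
#' @return A fold ratio (may be `Inf` when the observed side is 0, `NA`
#'   when `K = 0` or `n = 0`).
#' @export
fold_enrichment <- function(N, K, n, k, direction = c("enrichment", "depletion")) {
  direction <- match.arg(direction)
  if (K <= 0 || n <= 0) {
    return(NA_real_)
  }
  raw <- (k / n) / (K / N)
  if (direction == "depletion") 1 / raw else raw
}

#' Mann-Whitney U test
#'
#' Rank-sum comparison of two samples with average ranks on ties. For small
#' samples (both sizes <= 20) the p-value is exact, computed from the full
#' permutation distribution of U over all group relabelings (a
#' subset-sum dynamic program over the tied rank vector, identical to
#' explicit enumeration); larger samples use the normal approximation with
#' the tie-corrected variance.
#'
#' @param x,y Numeric samples.
#' @param alternative `"two_sided"` (default), `"greater"` (x tends
#'   larger), or `"less"`.
#' @return List with `U` (statistic of the first sample), `p_value`, and
#'   `method` (`"exact"` or `"normal"`).
#' @export
#' @examples
#' mann_whitney_u(c(4, 5, 6), c(1, 2, 3))$p_value # 0.1
mann_whitney_u <- function(x, y, alternative = c("two_sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n <- length(x); m <- length(y)
  if (n < 1 || m < 1) {
    abort("both samples must be non-empty", class = "bgctempo_validation_error")
  }
  r <- rank(c(x, y)) # average ranks on ties
  u <- sum(r[seq_len(n)]) - n * (n + 1) / 2

  if (n <= 20 && m <= 20) {
    dist <- u_permutation_distribution(r, n)
    probs <- dist$count / sum(dist$count)
    uvals <- dist$u
    eps <- 1e-9
    p <- switch(alternative,
      greater = sum(probs[uvals >= u - eps]),
      less = sum(probs[uvals <= u + eps]),
      two_sided = {
        center <- n * m / 2
        sum(probs[abs(uvals - center) >= abs(u - center) - eps])
      }
    )
    return(list(U = u, p_value = min(1, p), method = "exact"))
  }

  nt <- n + m
  ties <- table(r)
  mu <- n * m / 2
  sigma2 <- n * m / 12 * ((nt + 1) - sum(ties^3 - ties) / (nt * (nt - 1)))
  z <- (u - mu) / sqrt(sigma2)
  p <- switch(alternative,
    greater = stats::pnorm(z, lower.tail = FALSE),
    less = stats::pnorm(z),
    two_sided = 2 * stats::pnorm(-abs(z))
  )
  list(U = u, p_value = min(1, p), method = "normal")
}

# exact permutation distribution of the rank sum of a size-n subset of the
# pooled (possibly tied, half-integer) rank vector; returns U values
u_permutation_distribution <- function(r, n) {
  r2 <- as.integer(round(2 * r)) # ranks doubled -> integers
  total <- sum(r2)
  # count[s+1, j+1] = number of j-subsets with doubled-rank sum s
  counts <- matrix(0, nrow = total + 1, ncol = n + 1)
  counts[1, 1] <- 1
  for (v in r2) {
    jmax <- n
    for (j in jmax:1) {
      nz <- which(counts[, j] > 0)
      if (length(nz) > 0) {
        counts[nz + v, j + 1] <- counts[nz + v, j + 1] + counts[nz, j]
      }
    }
  }
  s <- which(counts[, n + 1] > 0) - 1
  list(u = s / 2 - n * (n + 1) / 2, count = counts[s + 1, n + 1])
}

#' Pearson chi-square test on a contingency table
#'
#' Pearson's statistic without continuity correction by default (set
#' `correct = TRUE` for the Yates correction on 2x2 tables), with
#' df = (r - 1)(c - 1). Delegates to `stats::chisq.test`.
#'
#' @param table A matrix of counts (e.g. 2x2).
#' @param correct Apply the Yates continuity correction.
#' @return List with `statistic`, `df`, `p_value`.
#' @export
#' @examples
#' chi_square(matrix(c(10, 0, 0, 10), 2))$statistic # 20
chi_square <- function(table, correct = FALSE) {
  table <- as.matrix(table)
  ht <- suppressWarnings(stats::chisq.test(table, correct = correct))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value)
}

#' Annotation enrichment of BGC groups
#'
#' For each BGC group (typically persistent and transient) and each feature
#' class (ARG, VF, MGE), tests whether BGCs carrying at least one feature
#' of that class are over- or under-represented in the group relative to
#' the whole classified background, by one-tailed hypergeometric test in
#' the observed direction. Raw p-values are reported by default;
#' `adjust = "BH"` adds a Benjamini-Hochberg column.
#'
#' @param class_map Tibble `bgc_id`, `classification`; rows with `NA`
#'   classification are dropped. The background N is all remaining BGCs.
#' @param annotations Annotation tibble (`bgc_id`, `feature_class`,
#'   `feature_label`).
#' @param groups Which classifications to test (default persistent and
#'   transient).
#' @param feature_classes Which feature classes to test.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return Tibble `group`, `feature_class`, `N`, `K`, `n`, `k`, `fold`,
#'   `direction`, `p_value` (and `p_adjusted` when requested).
#' @export
enrich_features <- function(class_map, annotations,
                            groups = c("persistent", "transient"),
                            feature_classes = c("ARG", "VF", "MGE"),
                            adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  cm <- dplyr::filter(as_tibble(class_map), !is.na(.data$classification))
  universe <- unique(cm$bgc_id)
  N <- length(universe)
  ann <- dplyr::filter(as_tibble(annotations), .data$bgc_id %in% universe)
  out <- purrr::map_dfr(groups, function(g) {
    members <- cm$bgc_id[cm$classification == g]
    purrr::map_dfr(feature_classes, function(fc) {
      carriers <- unique(ann$bgc_id[ann$feature_class == fc])
      K <- length(carriers)
      n <- length(members)
      k <- length(intersect(members, carriers))
      raw_fold <- if (K > 0 && n > 0) (k / n) / (K / N) else NA_real_
      dir <- if (!is.na(raw_fold) && raw_fold < 1) "depletion" else "enrichment"
      ht <- hypergeom_test(N, K, n, k, direction = dir)
      tibble(group = g, feature_class = fc, N = N, K = K, n = n, k = k,
             fold = ht$fold, direction = dir, p_value = ht$p_value)
    })
  })
  if (adjust == "BH") {
    out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
  }
  out
}
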