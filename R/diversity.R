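#' Alpha diversity: Shannon index and richness
#'
#' `shannon()` computes H = -sum p_i log(p_i) over the positive entries of
#' an abundance vector after normalization to relative abundances; the log
#' base defaults to 2 (bits). `richness()` counts present features.
#' Both delegate to vegan, the reference implementation for community
#' diversity in R.
#'
#' @param x Non-negative abundance vector (`shannon`) or logical presence
#'   vector (`richness`).
#' @param base Logarithm base for `shannon` (default 2).
#' @return `shannon()` a double; `richness()` an integer.
#' @export
#' @examples
#' shannon(rep(1, 4)) # 2 bits
shannon <- function(x, base = 2) {
  stopifnot(all(x >= 0))
  if (sum(x) == 0) {
    return(NA_real_)
  }
  unname(vegan::diversity(x, index = "shannon", base = base))
}

#' @rdname shannon
#' @export
richness <- function(x) {
  stopifnot(is.logical(x) || all(x %in% c(0, 1)))
  as.integer(sum(x))
}

#' Bray-Curtis and Jaccard distances between two samples
#'
#' `bray_curtis()` on abundance vectors: `sum |x - y| / sum (x + y)`;
#' `jaccard_distance()` on presence vectors: `1 - |A ∩ B| / |A ∪ B|`.
#' Both live in \[0, 1\], are symmetric, and are 0 on identical inputs;
#' computed by `vegan::vegdist`. A pair with empty total support gives
#' `NA`.
#'
#' @param x,y Non-negative abundance vectors of equal length.
#' @return A distance in \[0, 1\] or `NA`.
#' @export
#' @examples
#' bray_curtis(c(1, 1), c(1, 3)) # 1/3
bray_curtis <- function(x, y) {
  stopifnot(length(x) == length(y), all(x >= 0), all(y >= 0))
  if (sum(x) + sum(y) == 0) {
    return(NA_real_)
  }
  as.numeric(vegan::vegdist(rbind(x, y), method = "bray"))
}

#' @rdname bray_curtis
#' @param a,b Logical presence vectors of equal length.
#' @export
jaccard_distance <- function(a, b) {
  stopifnot(length(a) == length(b))
  a <- as.logical(a); b <- as.logical(b)
  if (!any(a) && !any(b)) {
    return(NA_real_)
  }
  as.numeric(vegan::vegdist(rbind(a, b), method = "jaccard", binary = TRUE))
}

#' Per-sample alpha-diversity table
#'
#' Shannon index from the RPKM abundance table and richness from the
#' presence table, one row per sample.
#'
#' @param abundance Tibble `bgc_id`, `sample_id`, `rpkm` (from
#'   [abundance_from_coverage()]).
#' @param presence A `bgc_presence` tibble over the same samples.
#' @param base Shannon log base (default 2, recorded in the output).
#' @return Tibble `sample_id`, `shannon`, `richness`, `shannon_base`.
#' @export
alpha_diversity <- function(abundance, presence, base = 2) {
  am <- abundance_matrix(abundance)
  pm <- presence_matrix(presence)
  if (!setequal(colnames(am), colnames(pm))) {
    abort("abundance and presence cover different samples",
          class = "bgctempo_validation_error")
  }
  pm <- pm[, colnames(am), drop = FALSE]
  tibble(
    sample_id = colnames(am),
    shannon = vapply(colnames(am), function(s) shannon(am[, s], base = base),
                     double(1)),
    richness = vapply(colnames(am), function(s) richness(pm[, s]), integer(1)),
    shannon_base = base
  )
}

#' Pairwise beta-diversity table
#'
#' Bray-Curtis distances on RPKM abundance (`method = "bray"`) or Jaccard
#' distances on presence (`method = "jaccard"`), for every unordered sample
#' pair.
#'
#' @param x Abundance tibble (`bray`) or presence tibble (`jaccard`).
#' @param method `"bray"` or `"jaccard"`.
#' @return Tibble `sample_a`, `sample_b`, `distance`.
#' @export
beta_diversity <- function(x, method = c("bray", "jaccard")) {
  method <- match.arg(method)
  mat <- if (method == "bray") abundance_matrix(x) else presence_matrix(x)
  d <- if (method == "bray") {
    vegan::vegdist(t(mat), method = "bray")
  } else {
    vegan::vegdist(t(mat + 0), method = "jaccard", binary = TRUE)
  }
  dm <- as.matrix(d)
  idx <- which(upper.tri(dm), arr.ind = TRUE)
  tibble(
    sample_a = rownames(dm)[idx[, 1]],
    sample_b = colnames(dm)[idx[, 2]],
    distance = dm[idx]
  )
}
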