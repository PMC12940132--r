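#' MinHash sketch of a nucleotide sequence
#'
#' Bottom-s MinHash over canonical k-mers (the lexicographically smaller of a
#' k-mer and its reverse complement), the sketch representation behind
#' Mash-style distance estimation. The hash is a fixed, published 64-bit
#' mixing function (SplitMix64, truncated to its top 53 bits so values are
#' exact R numerics), identical across runs and platforms. k-mers containing
#' non-ACGT characters are skipped.
#'
#' @param sequence A single nucleotide string (ACGT, case-insensitive).
#' @param k K-mer size, 1--31 (default 21).
#' @param sketch_size Maximum number of hashes retained (default 1000).
#' @param seq_id Optional identifier carried on the sketch.
#' @return An object of class `minhash_sketch`: list with `seq_id`, `k`,
#'   `sketch_size`, `hash_version`, and `hashes` (strictly increasing
#'   numeric vector, length `<= sketch_size`).
#' @export
#' @examples
#' s <- make_sketch("ACGTACGTACGTACGTACGTACGTA", k = 21)
#' length(s$hashes)
make_sketch <- function(sequence, k = 21L, sketch_size = 1000L, seq_id = NULL) {
  stopifnot(is.character(sequence), length(sequence) == 1)
  if (nchar(sequence) < k) {
    abort(paste0("sequence shorter than k = ", k), class = "bgctempo_validation_error")
  }
  hashes <- cpp_sketch(sequence, as.integer(k), as.integer(sketch_size))
  structure(
    list(seq_id = seq_id, k = as.integer(k), sketch_size = as.integer(sketch_size),
         hash_version = "splitmix64/1", hashes = hashes),
    class = "minhash_sketch"
  )
}

#' Sketch every sequence of a catalog
#'
#' @param catalog A `bgc_catalog` with a `sequence` column, or any tibble
#'   with `bgc_id` and `sequence`.
#' @inheritParams make_sketch
#' @return Named list of `minhash_sketch` objects, one per BGC.
#' @export
sketch_catalog <- function(catalog, k = 21L, sketch_size = 1000L) {
  if (any(is.na(catalog$sequence))) {
    abort("catalog has BGCs without sequences; cannot sketch",
          class = "bgctempo_validation_error")
  }
  sk <- purrr::map2(catalog$sequence, catalog$bgc_id,
                    ~ make_sketch(.x, k = k, sketch_size = sketch_size, seq_id = .y))
  stats::setNames(sk, catalog$bgc_id)
}

#' Mash distance between two sketches
#'
#' Estimates k-mer-set dissimilarity from two MinHash sketches: the Jaccard
#' index j is estimated on the merged bottom sketch, and converted to a
#' distance d = -(1/k) ln(2j / (1 + j)), capped at 1; j = 0 gives d = 1.
#' Symmetric, with d(a, a) = 0.
#'
#' @param a,b `minhash_sketch` objects with equal `k`.
#' @return Distance in \[0, 1\].
#' @export
mash_distance <- function(a, b) {
  stopifnot(inherits(a, "minhash_sketch"), inherits(b, "minhash_sketch"))
  if (a$k != b$k) {
    abort("sketches have different k", class = "bgctempo_validation_error")
  }
  s <- min(a$sketch_size, b$sketch_size)
  merged <- sort(unique(c(a$hashes, b$hashes)))
  bottom <- merged[seq_len(min(s, length(merged)))]
  shared <- sum(bottom %in% a$hashes & bottom %in% b$hashes)
  j <- shared / length(bottom)
  if (j <= 0) {
    return(1)
  }
  min(1, -(1 / a$k) * log(2 * j / (1 + j)))
}

#' Build a sequence-similarity network from sketches
#'
#' Nodes are sequences; an undirected edge connects two sequences whose
#' MinHash similarity (1 - mash distance) is strictly above `sim_cutoff`
#' (0.95 by default).
#'
#' @param sketches Named list of `minhash_sketch` objects.
#' @param sim_cutoff Similarity threshold; edges require similarity
#'   `> sim_cutoff` (strict).
#' @return Object of class `similarity_network`: list with `nodes`
#'   (character vector) and `edges` (tibble `id_a`, `id_b`, `similarity`,
#'   `id_a < id_b`, no self edges, no duplicates).
#' @export
build_network <- function(sketches, sim_cutoff = 0.95) {
  ids <- names(sketches)
  if (is.null(ids) || any(ids == "")) {
    ids <- vapply(sketches, function(s) s$seq_id %||% "", character(1))
  }
  if (anyDuplicated(ids) || any(ids == "")) {
    abort("sketches must carry unique non-empty ids",
          class = "bgctempo_validation_error")
  }
  n <- length(sketches)
  pairs <- if (n >= 2) utils::combn(n, 2) else matrix(integer(0), nrow = 2)
  edges <- purrr::map_dfr(seq_len(ncol(pairs)), function(p) {
    i <- pairs[1, p]; j <- pairs[2, p]
    sim <- 1 - mash_distance(sketches[[i]], sketches[[j]])
    if (sim > sim_cutoff) {
      tibble(id_a = min(ids[i], ids[j]), id_b = max(ids[i], ids[j]),
             similarity = sim)
    } else {
      NULL
    }
  })
  if (nrow(edges) == 0) {
    edges <- tibble(id_a = character(), id_b = character(), similarity = double())
  }
  structure(list(nodes = ids, edges = edges), class = "similarity_network")
}

#' Markov clustering (MCL) of a similarity network
#'
#' Standard MCL: the weighted adjacency matrix gains self-loops (weight 1),
#' is column-normalized into a stochastic flow matrix, then alternates
#' expansion (matrix power) and inflation (elementwise power followed by
#' column renormalization) with pruning of small entries until the flow
#' stabilizes. Clusters are read from the attractor structure of the limit
#' matrix; every node lands in exactly one cluster (a node attracted by two
#' attractor systems is assigned to the smaller cluster id).
#'
#' @param network A `similarity_network`.
#' @param inflation Inflation exponent (default 2.0, the mcl default).
#' @param expansion Expansion power (integer >= 2).
#' @param max_iter Iteration cap.
#' @param tol Convergence tolerance on the max absolute change.
#' @param prune Entries below this are zeroed each iteration.
#' @return Tibble `cluster` (integer, numbered by smallest member position),
#'   `seq_id`; every network node appears exactly once.
#' @export
mcl_cluster <- function(network, inflation = 2.0, expansion = 2L,
                        max_iter = 100L, tol = 1e-6, prune = 1e-5) {
  stopifnot(inherits(network, "similarity_network"))
  ids <- network$nodes
  n <- length(ids)
  if (n == 0) {
    abort("empty network", class = "bgctempo_validation_error")
  }
  M <- matrix(0, n, n, dimnames = list(ids, ids))
  e <- network$edges
  if (nrow(e) > 0) {
    ia <- match(e$id_a, ids); ib <- match(e$id_b, ids)
    if (any(is.na(ia)) || any(is.na(ib))) {
      abort("edge refers to unknown node", class = "bgctempo_validation_error")
    }
    M[cbind(ia, ib)] <- e$similarity
    M[cbind(ib, ia)] <- e$similarity
  }
  if (!isSymmetric(unname(M))) {
    abort("non-symmetric adjacency", class = "bgctempo_validation_error")
  }
  diag(M) <- 1
  M <- normalize_cols(M)
  for (it in seq_len(max_iter)) {
    prev <- M
    for (p in seq_len(expansion - 1L)) M <- M %*% prev  # prev^expansion
    M <- M ^ inflation
    M[M < prune] <- 0
    M <- normalize_cols(M)
    if (max(abs(M - prev)) < tol) break
  }
  clusters_from_limit(M, ids)
}

normalize_cols <- function(M) {
  cs <- colSums(M)
  zero <- cs == 0
  if (any(zero)) {
    # a fully pruned column recovers as a self-loop
    M[cbind(which(zero), which(zero))] <- 1
    cs[zero] <- 1
  }
  sweep(M, 2, cs, "/")
}

# read clusters from the converged flow matrix: attractors carry positive
# diagonal mass; attractors sharing flow form one attractor system; a
# cluster is the system plus all columns it attracts
clusters_from_limit <- function(M, ids, eps = 1e-9) {
  n <- length(ids)
  attract <- which(diag(M) > eps)
  if (length(attract) == 0) attract <- seq_len(n) # degenerate; each node its own
  # union attractor systems: i ~ j if either row places mass on the other
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  unite <- function(x, y) { rx <- find(x); ry <- find(y); if (rx != ry) parent[max(rx, ry)] <<- min(rx, ry) }
  for (i in attract) {
    for (j in attract) {
      if (i < j && (M[i, j] > eps || M[j, i] > eps)) unite(i, j)
    }
  }
  # assign every column to the attractor row with mass on it; overlaps go to
  # the smallest cluster id (== smallest system root by construction)
  assignment <- integer(n)
  for (jcol in seq_len(n)) {
    rows <- attract[M[attract, jcol] > eps]
    if (length(rows) == 0) {
      assignment[jcol] <- find(jcol)
    } else {
      assignment[jcol] <- min(vapply(rows, find, integer(1)))
    }
  }
  roots <- sort(unique(assignment))
  tibble(
    cluster = match(assignment, roots),
    seq_id = ids
  ) %>% dplyr::arrange(.data$cluster, .data$seq_id)
}

#' Choose one representative sequence per cluster
#'
#' The longest member of each cluster is the representative; length ties
#' break to the lexicographically smallest id.
#'
#' @param partition Tibble with `cluster` and `seq_id` (from
#'   [mcl_cluster()]).
#' @param lengths Named numeric vector of sequence lengths covering every
#'   `seq_id`.
#' @return Tibble `cluster`, `representative`.
#' @export
pick_representatives <- function(partition, lengths) {
  missing <- setdiff(partition$seq_id, names(lengths))
  if (length(missing) > 0) {
    abort(paste0("no length for: ", paste(utils::head(missing, 5), collapse = ", ")),
          class = "bgctempo_validation_error")
  }
  partition %>%
    dplyr::mutate(length_bp = unname(lengths[.data$seq_id])) %>%
    dplyr::group_by(.data$cluster) %>%
    dplyr::arrange(dplyr::desc(.data$length_bp), .data$seq_id, .by_group = TRUE) %>%
    dplyr::summarise(representative = dplyr::first(.data$seq_id), .groups = "drop")
}

#' Dereplicate a BGC catalog
#'
#' Full dereplication stage: sketch every sequence, connect pairs with
#' MinHash similarity above the cutoff, cluster the network with MCL and
#' keep the longest sequence of each cluster as its representative.
#'
#' @param catalog A `bgc_catalog` with sequences.
#' @param sim_cutoff Similarity threshold for network edges (default 0.95).
#' @param k,sketch_size Sketching parameters.
#' @param inflation MCL inflation.
#' @return Tibble `cluster`, `member_id`, `length_bp`, `is_representative`;
#'   the similarity network is attached as attribute `"network"`.
#' @export
dereplicate_catalog <- function(catalog, sim_cutoff = 0.95, k = 21L,
                                sketch_size = 1000L, inflation = 2.0) {
  sketches <- sketch_catalog(catalog, k = k, sketch_size = sketch_size)
  net <- build_network(sketches, sim_cutoff = sim_cutoff)
  part <- mcl_cluster(net, inflation = inflation)
  lens <- stats::setNames(as.numeric(catalog$length_bp), catalog$bgc_id)
  reps <- pick_representatives(part, lens)
  out <- part %>%
    dplyr::left_join(reps, by = "cluster") %>%
    dplyr::mutate(
      length_bp = unname(lens[.data$seq_id]),
      is_representative = .data$seq_id == .data$representative
    ) %>%
    dplyr::select("cluster", member_id = "seq_id", "length_bp",
                  "is_representative")
  attr(out, "network") <- net
  out
}

`%||%` <- function(x, y) if (is.null(x)) y else x
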