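test_that("sketches are canonical, deterministic and bounded", {
  set.seed(21)
  s <- rand_dna(500)
  expect_identical(make_sketch(s)$hashes, make_sketch(revcomp(s))$hashes)
  expect_identical(make_sketch(s)$hashes, make_sketch(s)$hashes)
  expect_true(all(diff(make_sketch(s)$hashes) > 0)) # strictly increasing

  short <- rand_dna(25)
  sk <- make_sketch(short, k = 21)
  expect_lte(length(sk$hashes), 5) # at most 5 distinct 21-mers in 25 nt
  expect_error(make_sketch(rand_dna(10), k = 21), "shorter",
               class = "bgctempo_validation_error")

  # N-containing k-mers are skipped, not hashed
  with_n <- paste0(substr(s, 1, 100), "N", substr(s, 101, 500))
  expect_lt(length(make_sketch(with_n, sketch_size = 1e6)$hashes),
            length(make_sketch(s, sketch_size = 1e6)$hashes) + 21)
})

test_that("mash distance is a symmetric premetric with the documented caps", {
  set.seed(22)
  a <- make_sketch(rand_dna(2000))
  b <- make_sketch(rand_dna(2000))
  expect_equal(mash_distance(a, a), 0)
  expect_equal(mash_distance(a, b), mash_distance(b, a))
  expect_equal(mash_distance(a, b), 1) # random 2 kb sequences share ~no k-mers
  expect_error(mash_distance(a, make_sketch(rand_dna(100), k = 15)),
               "different k", class = "bgctempo_validation_error")
})

test_that("sketch distance agrees with the exact k-mer Jaccard oracle", {
  set.seed(23)
  base <- rand_dna(10000)
  variant <- mutate_sequence(base, rate = 0.02)
  k <- 21; s <- 1000

  # brute-force oracle: exact Jaccard on the full canonical k-mer sets
  ka <- canonical_kmers(base, k)
  kb <- canonical_kmers(variant, k)
  j_exact <- length(intersect(ka, kb)) / length(union(ka, kb))
  d_exact <- -(1 / k) * log(2 * j_exact / (1 + j_exact))

  d_sketch <- mash_distance(make_sketch(base, k, s), make_sketch(variant, k, s))
  # sampling error of j on a size-s sketch, pushed through the distance map
  se_j <- sqrt(j_exact * (1 - j_exact) / s)
  d_lo <- -(1 / k) * log(2 * (j_exact + 3 * se_j) / (1 + j_exact + 3 * se_j))
  d_hi <- -(1 / k) * log(2 * (j_exact - 3 * se_j) / (1 + j_exact - 3 * se_j))
  expect_gte(d_sketch, d_lo)
  expect_lte(d_sketch, d_hi)
})

test_that("similarity network applies the strict cutoff", {
  set.seed(24)
  s1 <- rand_dna(3000)
  sketches <- list(a = make_sketch(s1, seq_id = "a"),
                   b = make_sketch(s1, seq_id = "b"),
                   c = make_sketch(rand_dna(3000), seq_id = "c"))
  net <- build_network(sketches, sim_cutoff = 0.95)
  expect_equal(nrow(net$edges), 1) # only the identical pair
  expect_setequal(c(net$edges$id_a, net$edges$id_b), c("a", "b"))

  # cutoff 0: complete graph minus pairs at distance 1
  net0 <- build_network(sketches, sim_cutoff = 0)
  expect_equal(nrow(net0$edges), 1) # random pairs have d = 1, similarity 0
})

test_that("MCL recovers components, singletons and cliques", {
  # two disjoint triangles -> exactly their components
  tri <- structure(list(
    nodes = letters[1:6],
    edges = tibble::tibble(id_a = c("a", "a", "b", "d", "d", "e"),
                           id_b = c("b", "c", "c", "e", "f", "f"),
                           similarity = 1)
  ), class = "similarity_network")
  part <- mcl_cluster(tri)
  expect_equal(max(part$cluster), 2)
  expect_equal(sort(part$seq_id[part$cluster == part$cluster[part$seq_id == "a"]]),
               c("a", "b", "c"))

  # singleton node is its own cluster
  single <- structure(list(nodes = "z",
                           edges = tibble::tibble(id_a = character(),
                                                  id_b = character(),
                                                  similarity = double())),
                      class = "similarity_network")
  expect_equal(mcl_cluster(single)$cluster, 1L)

  # a 5-clique collapses to one cluster (flow concentrates on one attractor)
  cl5 <- t(utils::combn(letters[1:5], 2))
  clique <- structure(list(
    nodes = letters[1:5],
    edges = tibble::tibble(id_a = cl5[, 1], id_b = cl5[, 2], similarity = 1)
  ), class = "similarity_network")
  p5 <- mcl_cluster(clique)
  expect_equal(max(p5$cluster), 1)
  expect_equal(nrow(p5), 5)

  expect_error(mcl_cluster(structure(list(nodes = character(),
                                          edges = tibble::tibble()),
                                     class = "similarity_network")),
               "empty", class = "bgctempo_validation_error")
})

test_that("MCL partition is invariant to node relabeling", {
  set.seed(25)
  # random graph of two planted groups
  edges <- dplyr::bind_rows(
    tibble::tibble(id_a = "n1", id_b = c("n2", "n3", "n4"), similarity = 1),
    tibble::tibble(id_a = "n2", id_b = c("n3", "n4"), similarity = 1),
    tibble::tibble(id_a = "n5", id_b = c("n6", "n7"), similarity = 1),
    tibble::tibble(id_a = "n6", id_b = "n7", similarity = 1)
  )
  net <- structure(list(nodes = sprintf("n%d", 1:7), edges = edges),
                   class = "similarity_network")
  part <- mcl_cluster(net)

  relabel <- stats::setNames(sprintf("m%d", 7:1), sprintf("n%d", 1:7))
  net2 <- structure(list(
    nodes = unname(relabel[net$nodes]),
    edges = tibble::tibble(
      id_a = pmin(relabel[edges$id_a], relabel[edges$id_b]),
      id_b = pmax(relabel[edges$id_a], relabel[edges$id_b]),
      similarity = 1)
  ), class = "similarity_network")
  part2 <- mcl_cluster(net2)

  # same partition up to label permutation
  f1 <- split(part$seq_id, part$cluster)
  f2 <- split(names(relabel)[match(part2$seq_id, relabel)], part2$cluster)
  expect_setequal(unname(lapply(f1, sort)), unname(lapply(f2, sort)))
  # covers all nodes exactly once
  expect_setequal(part2$seq_id, net2$nodes)
  expect_equal(anyDuplicated(part2$seq_id), 0)
})

test_that("representative picking takes the longest member, ties lexicographic", {
  part <- tibble::tibble(cluster = c(1, 1, 2, 2, 3),
                         seq_id = c("A", "B", "C", "D", "E"))
  lens <- c(A = 900, B = 1200, C = 1000, D = 1000, E = 50)
  reps <- pick_representatives(part, lens)
  expect_equal(reps$representative, c("B", "C", "E"))
  expect_error(pick_representatives(part, lens[-1]), "no length",
               class = "bgctempo_validation_error")
})

test_that("planted near-identical copies collapse to their originals", {
  set.seed(26)
  m <- 6; copies <- 3
  seqs <- character(0); ids <- character(0)
  for (i in seq_len(m)) {
    base <- rand_dna(5000)
    for (j in seq_len(copies)) {
      s <- if (j == 1) base else
        mutate_sequence(substr(base, 1, 5000 - (j - 1) * 40), rate = 0.01)
      seqs <- c(seqs, s)
      ids <- c(ids, sprintf("s%d_c%d", i, j))
    }
  }
  catalog <- build_catalog(
    tibble::tibble(bgc_id = ids, length_bp = nchar(seqs), sequence = seqs),
    tibble::tibble(bgc_id = ids, gene_id = paste0(ids, "_g1"),
                   start = 1L, end = nchar(seqs))
  )
  out <- dereplicate_catalog(catalog)
  expect_equal(dplyr::n_distinct(out$cluster), m)
  reps <- out$member_id[out$is_representative]
  expect_setequal(reps, sprintf("s%d_c1", seq_len(m))) # longest copy of each
})
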