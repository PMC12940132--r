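test_that("gene and BGC presence calls use inclusive cutoffs", {
  expect_equal(call_gene_presence(c(0.30, 0.299, 1.0), gene_cutoff = 0.3),
               c(TRUE, FALSE, TRUE))
  expect_true(call_bgc_presence(c(TRUE, TRUE, FALSE, FALSE), bgc_cutoff = 0.5))
  expect_false(call_bgc_presence(c(TRUE, FALSE, FALSE, FALSE), bgc_cutoff = 0.5))
  expect_false(call_bgc_presence(rep(FALSE, 4), bgc_cutoff = 0.1))
  expect_error(call_bgc_presence(logical(0)), "at least one gene",
               class = "bgctempo_validation_error")
})

test_that("rpkm follows the formula and rejects a zero denominator", {
  expect_equal(rpkm(10, 1000, 1e6), 10)
  expect_equal(rpkm(0, 500, 1e6), 0)
  expect_equal(rpkm(7, 1234, 2e6), rpkm(7, 1234, 1e6) / 2) # proportionality
  expect_error(rpkm(1, 1000, 0), "total_mapped_reads",
               class = "bgctempo_validation_error")
  expect_error(rpkm(1, 0, 1e6), "length_bp",
               class = "bgctempo_validation_error")
})

test_that("presence_from_coverage composes the two calls over the matrix", {
  catalog <- tiny_catalog() # bgcA: 2 genes, bgcB: 4 genes
  cov <- tibble::tibble(
    sample_id = c("s1", "s1", "s1", "s2"),
    gene_id = c("a1", "a2", "b1", "b2"),
    covered_fraction = c(0.9, 0.1, 0.95, 0.5),
    read_count = c(10, 1, 20, 5)
  )
  pres <- presence_from_coverage(cov, catalog, gene_cutoff = 0.3,
                                 bgc_cutoff = 0.5)
  pm <- presence_matrix(pres)
  expect_true(pm["bgcA", "s1"])   # 1/2 genes >= 0.5 fraction
  expect_false(pm["bgcB", "s1"])  # 1/4 genes
  expect_false(pm["bgcA", "s2"])  # absent pairs count as fraction 0
  expect_false(pm["bgcB", "s2"])  # 1/4 genes
  expect_equal(attr(pres, "gene_cutoff"), 0.3)
  expect_equal(attr(pres, "bgc_cutoff"), 0.5)

  # unknown gene ids are a loud error, never dropped
  bad <- dplyr::bind_rows(cov, tibble::tibble(
    sample_id = "s1", gene_id = "ghost", covered_fraction = 1, read_count = 1))
  expect_error(presence_from_coverage(bad, catalog), "absent from the catalog",
               class = "bgctempo_validation_error")
})

test_that("presence is monotone in both cutoffs", {
  set.seed(31)
  catalog <- gen_catalog(n_bgcs = 8, seed = 31)
  genes <- catalog_genes(catalog)
  cov <- tidyr::expand_grid(sample_id = sprintf("s%d", 1:6),
                            gene_id = genes$gene_id) |>
    dplyr::mutate(covered_fraction = stats::runif(dplyr::n()),
                  read_count = stats::rpois(dplyr::n(), 5))
  grid <- seq(0, 1, by = 0.25)
  previous <- NULL
  for (g in grid) {
    for (b in grid) {
      n_present <- sum(presence_from_coverage(cov, catalog, g, b)$present)
      if (g == 0 && b == 0) {
        expect_equal(n_present, 8 * 6) # everything present at (0, 0)
      }
    }
  }
  # raising one cutoff while fixing the other never adds a present call
  for (fixed_b in c(0.3, 0.6)) {
    sets <- lapply(grid, function(g) {
      p <- presence_from_coverage(cov, catalog, g, fixed_b)
      paste(p$bgc_id, p$sample_id)[p$present]
    })
    for (i in seq_len(length(sets) - 1)) {
      expect_true(all(sets[[i + 1]] %in% sets[[i]]))
    }
  }
  for (fixed_g in c(0.3, 0.6)) {
    sets <- lapply(grid, function(b) {
      p <- presence_from_coverage(cov, catalog, fixed_g, b)
      paste(p$bgc_id, p$sample_id)[p$present]
    })
    for (i in seq_len(length(sets) - 1)) {
      expect_true(all(sets[[i + 1]] %in% sets[[i]]))
    }
  }
})

test_that("abundance table computes RPKM against per-sample mapped totals", {
  catalog <- tiny_catalog()
  cov <- tibble::tibble(
    sample_id = "s1",
    gene_id = c("a1", "a2", "b1"),
    covered_fraction = c(1, 1, 1),
    read_count = c(600, 400, 1000)
  )
  ab <- abundance_from_coverage(cov, catalog)
  # total mapped = 2000; bgcA: 1000 reads over 1000 bp
  expect_equal(ab$rpkm[ab$bgc_id == "bgcA"],
               1000 / ((1000 / 1000) * (2000 / 1e6)))
  expect_equal(ab$rpkm[ab$bgc_id == "bgcB"],
               1000 / ((2000 / 1000) * (2000 / 1e6)))
  # zero reads give zero RPKM
  expect_true(all(ab$rpkm[ab$reads == 0] == 0))
})

test_that("cutoff grid matches a pairwise brute-force recount", {
  set.seed(32)
  catalog <- gen_catalog(n_bgcs = 12, genome_ids = sprintf("g%03d", 1:12),
                         seed = 32)
  comm <- gen_mock_community(n_genomes = 12, n_samples = 10, seed = 33)
  gc <- gen_coverage(comm, catalog, depth_factor = 50, seed = 34)
  gene_grid <- c(0.2, 0.5, 0.8)
  bgc_grid <- c(0.25, 0.5, 0.75)
  grid <- evaluate_cutoffs(gc$coverage, catalog, gc$truth,
                           gene_grid = gene_grid, bgc_grid = bgc_grid)

  # independent oracle: per (sample, BGC) pair, recompute the call from the
  # raw coverage rows and recount the confusion matrix
  genes <- catalog_genes(catalog)
  truth_m <- presence_matrix(gc$truth)
  cov_key <- paste(gc$coverage$sample_id, gc$coverage$gene_id)
  frac_of <- stats::setNames(gc$coverage$covered_fraction, cov_key)
  for (r in seq_len(nrow(grid))) {
    g <- grid$gene_cutoff[r]; b <- grid$bgc_cutoff[r]
    tp <- fp <- fn <- tn <- 0
    for (s in colnames(truth_m)) {
      for (bgc in rownames(truth_m)) {
        gids <- genes$gene_id[genes$bgc_id == bgc]
        fr <- frac_of[paste(s, gids)]
        fr[is.na(fr)] <- 0
        call <- mean(fr >= g) >= b
        tru <- truth_m[bgc, s]
        if (call && tru) tp <- tp + 1
        if (call && !tru) fp <- fp + 1
        if (!call && tru) fn <- fn + 1
        if (!call && !tru) tn <- tn + 1
      }
    }
    expect_equal(c(grid$tp[r], grid$fp[r], grid$fn[r], grid$tn[r]),
                 c(tp, fp, fn, tn))
    expect_equal(grid$recall[r], if (tp + fn > 0) tp / (tp + fn) else NA_real_)
    expect_equal(grid$precision[r], if (tp + fp > 0) tp / (tp + fp) else NA_real_)
  }
  # counts always partition the full pair universe
  expect_true(all(grid$tp + grid$fp + grid$fn + grid$tn == 12 * 10))
})

test_that("cutoff selection maximizes F1 with the documented tie-breaks", {
  set.seed(35)
  catalog <- gen_catalog(n_bgcs = 10, genome_ids = sprintf("g%03d", 1:10),
                         seed = 35)
  comm <- gen_mock_community(n_genomes = 10, n_samples = 8, seed = 36)
  gc <- gen_coverage(comm, catalog, depth_factor = 50, seed = 37)
  grid <- evaluate_cutoffs(gc$coverage, catalog, gc$truth)
  sel <- glance(grid)
  best_f1 <- max(grid$f1, na.rm = TRUE)
  expect_equal(sel$f1, best_f1)
  cands <- grid[which(grid$f1 == best_f1), ]
  cands <- cands[order(-cands$precision, cands$gene_cutoff, cands$bgc_cutoff), ]
  expect_equal(sel$gene_cutoff, cands$gene_cutoff[1])
  expect_equal(sel$bgc_cutoff, cands$bgc_cutoff[1])

  # a perfect grid point reports recall = precision = 1
  pres <- presence_from_coverage(gc$coverage, catalog, sel$gene_cutoff,
                                 sel$bgc_cutoff)
  if (identical(presence_matrix(pres)[rownames(presence_matrix(gc$truth)),
                                      colnames(presence_matrix(gc$truth))],
                presence_matrix(gc$truth))) {
    expect_equal(sel$recall, 1)
    expect_equal(sel$precision, 1)
  }

  # all-absent calls: precision undefined, reported NA
  empty_cov <- dplyr::mutate(gc$coverage, covered_fraction = 0, read_count = 0L)
  grid0 <- evaluate_cutoffs(empty_cov, catalog, gc$truth,
                            gene_grid = 0.5, bgc_grid = 0.5)
  expect_equal(grid0$recall, 0)
  expect_true(is.na(grid0$precision))
})
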