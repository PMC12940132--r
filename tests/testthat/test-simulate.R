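test_that("mock community follows the planted presence and abundance model", {
  # degenerate p: everything present
  all_in <- gen_mock_community(n_genomes = 10, n_samples = 5, p_present = 1,
                               seed = 1)
  expect_true(all(all_in$present))

  cm <- gen_mock_community(n_genomes = 100, n_samples = 1000, seed = 2)
  per_sample <- tapply(cm$present, cm$sample_id, sum)
  # mean present per sample: 100 * 0.7 = 70, SE of the grand mean =
  # sqrt(100 * 0.7 * 0.3 / 1000)
  expect_lt(abs(mean(per_sample) - 70), 3 * sqrt(100 * 0.7 * 0.3 / 1000))

  # abundance zero iff absent; per-sample sums 1
  expect_true(all((cm$rel_abundance == 0) == (!cm$present)))
  sums <- tapply(cm$rel_abundance, cm$sample_id, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
})

test_that("generators are deterministic for a fixed seed", {
  expect_identical(gen_mock_community(20, 10, seed = 5),
                   gen_mock_community(20, 10, seed = 5))
  expect_identical(gen_catalog(5, seed = 5)$sequence,
                   gen_catalog(5, seed = 5)$sequence)
  a <- gen_markov_cohort(10, n_subjects = 5, seed = 5)
  b <- gen_markov_cohort(10, n_subjects = 5, seed = 5)
  expect_identical(a$presence, b$presence)
  expect_identical(a$truth, b$truth)
})

test_that("coverage generator maps depth to breadth via 1 - exp(-c)", {
  catalog <- gen_catalog(n_bgcs = 1, genome_ids = "g1", seed = 1)

  # single genome at relative abundance 1, depth ln 2, no noise:
  # covered fraction is exactly 0.5
  comm <- tibble::tibble(sample_id = "s1", genome_id = "g1",
                         present = TRUE, rel_abundance = 1)
  gc <- gen_coverage(comm, catalog, depth_factor = log(2), noise_sd = 0,
                     seed = 2)
  expect_true(all(abs(gc$coverage$covered_fraction - 0.5) < 1e-12))
  expect_true(all(gc$truth$present))

  # absent genome, no noise: fraction and counts are exactly zero
  comm0 <- tibble::tibble(sample_id = "s1", genome_id = "g1",
                          present = FALSE, rel_abundance = 0)
  gc0 <- gen_coverage(comm0, catalog, depth_factor = 50, noise_sd = 0,
                      seed = 3)
  expect_true(all(gc0$coverage$covered_fraction == 0))
  expect_true(all(gc0$coverage$read_count == 0))
  expect_false(any(gc0$truth$present))

  # saturation: large depth drives breadth to 1
  gcb <- gen_coverage(comm, catalog, depth_factor = 100, noise_sd = 0,
                      seed = 4)
  expect_true(all(gcb$coverage$covered_fraction > 0.999999))
})

test_that("markov cohort generator honors the chain and its stationary start", {
  # p_in = 1, p_out = 0: stationary pi = 1, so all-present throughout
  mk <- gen_markov_cohort(3, n_subjects = 10, n_visits = 4,
                          param_sampler = function(n)
                            tibble::tibble(p_in = rep(1, n), p_out = rep(0, n)),
                          seed = 6)
  expect_true(all(mk$presence$present))

  # truth labels follow the strict 0.3 thresholds
  mk2 <- gen_markov_cohort(2, n_subjects = 2,
                           param_sampler = function(n)
                             tibble::tibble(p_in = c(0.6, 0.1),
                                            p_out = c(0.1, 0.6)),
                           seed = 7)
  expect_equal(mk2$truth$true_class, c("persistent", "transient"))

  expect_error(
    gen_markov_cohort(1, n_subjects = 2,
                      param_sampler = function(n)
                        tibble::tibble(p_in = 0, p_out = 0), seed = 1),
    "stationary", class = "bgctempo_validation_error"
  )
})

test_that("long single chains reach their stationary presence fraction", {
  # property: empirical fraction within 3 sd of pi, with the effective
  # sample size corrected for chain autocorrelation rho = 1 - p_in - p_out
  cases <- list(c(0.5, 0.5), c(0.2, 0.4), c(0.7, 0.1), c(0.1, 0.8))
  for (i in seq_along(cases)) {
    p_in <- cases[[i]][1]; p_out <- cases[[i]][2]
    pi_stat <- p_in / (p_in + p_out)
    n <- 5000
    x <- simulate_chain(p_in, p_out, n, seed = 100 + i)
    rho <- 1 - p_in - p_out
    t_eff <- n * (1 - rho) / (1 + rho)
    expect_lt(abs(mean(x) - pi_stat),
              3 * sqrt(pi_stat * (1 - pi_stat) / t_eff))
  }
})

test_that("fmt triad generator plants engraftment probabilities", {
  ids <- sprintf("b%03d", 1:100)
  # degenerate engraftment: probability 1 puts every donor-only BGC in post
  ft1 <- gen_fmt_triads(ids, n_triads = 5, donor_richness = 40,
                        pre_richness = 30,
                        engraft_prob_by_class = c(persistent = 1, transient = 1),
                        retention_prob = 0, seed = 8)
  rates1 <- vapply(seq_len(5),
                   function(i) triad_colonization_rate(ft1$triads[i, ]),
                   double(1))
  expect_true(all(rates1 == 1))

  ft0 <- gen_fmt_triads(ids, n_triads = 5, donor_richness = 40,
                        pre_richness = 30,
                        engraft_prob_by_class = c(persistent = 0, transient = 0),
                        retention_prob = 0, seed = 9)
  rates0 <- vapply(seq_len(5),
                   function(i) triad_colonization_rate(ft0$triads[i, ]),
                   double(1))
  expect_true(all(rates0 == 0))

  # truth records every donor-only opportunity
  ft <- gen_fmt_triads(ids, n_triads = 4, donor_richness = 30,
                       pre_richness = 20, seed = 10)
  for (i in 1:4) {
    opp <- setdiff(ft$triads$donor_set[[i]], ft$triads$pre_set[[i]])
    expect_setequal(ft$truth$bgc_id[ft$truth$triad_id == ft$triads$triad_id[i]],
                    opp)
  }
})

test_that("annotation generator plants the requested fold enrichment", {
  ids <- sprintf("b%04d", 1:1000)
  group <- ids[1:500]
  expect_equal(nrow(gen_annotations(ids, group, planted_fold = 1,
                                    base_rate = 0, seed = 11)), 0)

  ann <- gen_annotations(ids, group, planted_fold = 2, base_rate = 0.2,
                         seed = 12)
  in_rate <- mean(group %in% ann$bgc_id)
  out_rate <- mean(setdiff(ids, group) %in% ann$bgc_id)
  fold <- in_rate / out_rate
  # binomial error on both rates, 3 SE propagated on the ratio
  se <- fold * sqrt(0.4 * 0.6 / (500 * 0.4^2) + 0.2 * 0.8 / (500 * 0.2^2))
  expect_lt(abs(fold - 2), 3 * se)
})

test_that("gen_study produces a coherent, self-consistent dataset", {
  study <- gen_study(n_bgcs = 20, n_subjects = 6, n_visits = 3, n_triads = 3,
                     seed = 13)
  expect_s3_class(study$catalog, "bgc_catalog")
  expect_silent(bgctempo:::validate_metadata(study$meta))
  expect_silent(bgctempo:::validate_coverage(study$coverage))
  # coverage covers every metadata sample
  expect_setequal(unique(study$coverage$sample_id), study$meta$sample_id)
  # truth presence covers the same grid
  expect_setequal(unique(study$truth$presence$sample_id), study$meta$sample_id)
  # determinism
  study2 <- gen_study(n_bgcs = 20, n_subjects = 6, n_visits = 3, n_triads = 3,
                      seed = 13)
  expect_identical(study$coverage, study2$coverage)
})
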