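## Synthetic-data generators: every pipeline input with planted ground truth.
## Each generator takes a `seed` and is byte-reproducible for a fixed seed;
## RNG kind is pinned so results do not drift across R versions.

set_sim_seed <- function(seed) {
  if (!is.null(seed)) {
    set.seed(as.integer(seed), kind = "Mersenne-Twister",
             normal.kind = "Inversion", sample.kind = "Rejection")
  }
}

#' Simulate an in silico mock community
#'
#' Presence of each genome in each sample is an independent Bernoulli draw
#' with probability `p_present` (default 0.7); relative abundances of the
#' present genomes are log-normal (`mu` = 0, `sigma` = 1 by default) and
#' renormalized to sum to 1 per sample. Defaults reproduce the
#' 100-genome / 100-sample benchmark community used to calibrate the
#' detection cutoffs.
#'
#' @param n_genomes,n_samples Community dimensions (>= 1).
#' @param p_present Bernoulli presence probability in (0, 1\].
#' @param lognorm_mu,lognorm_sigma Log-normal parameters (sigma > 0).
#' @param seed RNG seed.
#' @return Tibble `sample_id`, `genome_id`, `present`, `rel_abundance`
#'   (0 exactly when absent; per-sample sum 1 when any genome is present).
#' @export
gen_mock_community <- function(n_genomes = 100, n_samples = 100,
                               p_present = 0.7, lognorm_mu = 0,
                               lognorm_sigma = 1, seed = NULL) {
  if (n_genomes < 1 || n_samples < 1) {
    abort("n_genomes and n_samples must be >= 1", class = "bgctempo_validation_error")
  }
  if (p_present <= 0 || p_present > 1 || lognorm_sigma <= 0) {
    abort("need 0 < p_present <= 1 and sigma > 0", class = "bgctempo_validation_error")
  }
  set_sim_seed(seed)
  genome_id <- sprintf("g%03d", seq_len(n_genomes))
  out <- tidyr::expand_grid(
    sample_id = sprintf("mock%03d", seq_len(n_samples)),
    genome_id = genome_id
  )
  out$present <- stats::runif(nrow(out)) < p_present
  ab <- numeric(nrow(out))
  ab[out$present] <- stats::rlnorm(sum(out$present), lognorm_mu, lognorm_sigma)
  out$rel_abundance <- ab
  out %>%
    dplyr::group_by(.data$sample_id) %>%
    dplyr::mutate(rel_abundance = if (sum(.data$rel_abundance) > 0) {
      .data$rel_abundance / sum(.data$rel_abundance)
    } else {
      .data$rel_abundance
    }) %>%
    dplyr::ungroup()
}

#' Generate a random BGC catalog with genome assignments
#'
#' Random nucleotide sequences partitioned into ordered gene intervals,
#' standing in for a real assembled catalog in tests and simulations. Each
#' BGC is assigned to one genome (round-robin over `genome_ids`), the link
#' used by [gen_coverage()] to couple BGC detectability to community
#' structure.
#'
#' @param n_bgcs Number of clusters.
#' @param genome_ids Genomes to assign BGCs to (default one per BGC).
#' @param genes_range Inclusive range of genes per BGC.
#' @param gene_length_range Inclusive range of gene lengths (bp).
#' @param seed RNG seed.
#' @return A `bgc_catalog` tibble with an extra `genome_id` column.
#' @export
gen_catalog <- function(n_bgcs = 100, genome_ids = NULL,
                        genes_range = c(3L, 8L),
                        gene_length_range = c(500L, 2000L), seed = NULL) {
  set_sim_seed(seed)
  if (is.null(genome_ids)) genome_ids <- sprintf("g%03d", seq_len(n_bgcs))
  ids <- sprintf("bgc%04d", seq_len(n_bgcs))
  genes <- purrr::map_dfr(seq_len(n_bgcs), function(i) {
    id <- ids[i]
    ng <- sample(genes_range[1]:genes_range[2], 1)
    lens <- sample(gene_length_range[1]:gene_length_range[2], ng, replace = TRUE)
    gaps <- sample(0:50, ng, replace = TRUE)
    start <- cumsum(gaps + dplyr::lag(lens, default = 0L)) + 1L
    tibble(bgc_id = id,
           gene_id = sprintf("%s_gene%02d", id, seq_len(ng)),
           start = start, end = start + lens - 1L)
  })
  lengths <- genes %>%
    dplyr::group_by(.data$bgc_id) %>%
    dplyr::summarise(length_bp = max(.data$end), .groups = "drop")
  seqs <- vapply(lengths$length_bp, random_sequence, character(1))
  catalog <- build_catalog(
    tibble(bgc_id = lengths$bgc_id, length_bp = lengths$length_bp,
           sequence = seqs),
    genes
  )
  catalog$genome_id <- rep_len(genome_ids, n_bgcs)
  catalog
}

random_sequence <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

#' Mutate sequences to make near-identical catalog copies
#'
#' Applies random substitutions at a given per-base rate; used to plant
#' redundant copies for dereplication benchmarks.
#'
#' @param sequence Nucleotide string.
#' @param rate Per-base substitution probability.
#' @return Mutated string.
#' @export
mutate_sequence <- function(sequence, rate = 0.01) {
  bases <- strsplit(sequence, "")[[1]]
  hit <- which(stats::runif(length(bases)) < rate)
  for (i in hit) {
    bases[i] <- sample(setdiff(c("A", "C", "G", "T"), bases[i]), 1)
  }
  paste(bases, collapse = "")
}

#' Simulate per-gene coverage from a mock community
#'
#' Maps community structure to the coverage summaries the pipeline
#' consumes, replacing read simulation with the Lander-Waterman
#' depth-to-breadth relation: a gene of a BGC whose genome has relative
#' abundance a gets expected per-base depth `c = depth_factor * a`,
#' covered fraction `clamp(1 - exp(-c) + Normal(0, noise_sd), 0, 1)` and
#' read count `Poisson(c * gene_length / read_length)` (read length fixed
#' at 150 nt). Ground truth marks a BGC present exactly when its genome is
#' present.
#'
#' @param community Output of [gen_mock_community()].
#' @param catalog A `bgc_catalog` with a `genome_id` column (see
#'   [gen_catalog()]).
#' @param depth_factor Sequencing depth scalar (> 0); at the default 50 a
#'   genome at 1% relative abundance gets breadth ~0.39, so detection is
#'   good but imperfect — the regime cutoff optimization is meant for.
#' @param noise_sd Gaussian noise on covered fraction.
#' @param read_length Read length for the count model.
#' @param seed RNG seed.
#' @return List: `coverage` (tibble `sample_id`, `gene_id`,
#'   `covered_fraction`, `read_count`), `truth` (tibble `bgc_id`,
#'   `sample_id`, `present`).
#' @export
gen_coverage <- function(community, catalog, depth_factor = 50,
                         noise_sd = 0.05, read_length = 150, seed = NULL) {
  if (depth_factor <= 0) {
    abort("depth_factor must be > 0", class = "bgctempo_validation_error")
  }
  if (!"genome_id" %in% names(catalog)) {
    abort("catalog needs a genome_id column (see gen_catalog)",
          class = "bgctempo_validation_error")
  }
  set_sim_seed(seed)
  genes <- catalog_genes(catalog) %>%
    dplyr::left_join(
      dplyr::select(as_tibble(catalog), "bgc_id", "genome_id"),
      by = "bgc_id"
    )
  grid <- tidyr::expand_grid(
    sample_id = unique(community$sample_id),
    genes
  ) %>%
    dplyr::left_join(
      dplyr::select(community, "sample_id", "genome_id", "rel_abundance"),
      by = c("sample_id", "genome_id")
    ) %>%
    dplyr::mutate(rel_abundance = dplyr::coalesce(.data$rel_abundance, 0))
  c_depth <- depth_factor * grid$rel_abundance
  frac <- pmin(pmax(1 - exp(-c_depth) +
                      stats::rnorm(nrow(grid), 0, noise_sd), 0), 1)
  count <- stats::rpois(nrow(grid), c_depth * grid$gene_length / read_length)
  coverage <- tibble(
    sample_id = grid$sample_id, gene_id = grid$gene_id,
    covered_fraction = frac, read_count = count
  )
  truth <- tidyr::expand_grid(
    sample_id = unique(community$sample_id),
    bgc_id = catalog$bgc_id
  ) %>%
    dplyr::left_join(
      dplyr::select(as_tibble(catalog), "bgc_id", "genome_id"),
      by = "bgc_id"
    ) %>%
    dplyr::left_join(
      dplyr::select(community, "sample_id", "genome_id", "present"),
      by = c("sample_id", "genome_id")
    ) %>%
    dplyr::mutate(present = dplyr::coalesce(.data$present, FALSE)) %>%
    dplyr::select("bgc_id", "sample_id", "present")
  list(coverage = coverage, truth = truth)
}

#' Simulate a longitudinal cohort of per-BGC Markov chains
#'
#' Each BGC follows an independent two-state chain within every subject:
#' the visit-1 state is drawn from the chain's stationary distribution
#' `pi = p_in / (p_in + p_out)` (so the short cohort is a steady-state
#' sample), and later visits follow the transition probabilities. Ground
#' truth records the sampled parameters and the class the thresholds imply.
#'
#' @param n_bgcs Number of BGCs.
#' @param n_subjects,n_visits Cohort design (defaults 86 subjects, 4
#'   visits).
#' @param param_sampler Function `n -> tibble(p_in, p_out)` in (0, 1)^2;
#'   default uniform on (0.05, 0.95)^2.
#' @param threshold Classification threshold for the truth labels.
#' @param seed RNG seed.
#' @return List: `presence` (a `bgc_presence` tibble), `meta` (sample
#'   metadata), `truth` (tibble `bgc_id`, `p_inflow_true`,
#'   `p_outflow_true`, `true_class`).
#' @export
gen_markov_cohort <- function(n_bgcs, n_subjects = 86, n_visits = 4,
                              param_sampler = NULL, threshold = 0.3,
                              seed = NULL) {
  set_sim_seed(seed)
  if (is.null(param_sampler)) {
    param_sampler <- function(n) {
      tibble(p_in = stats::runif(n, 0.05, 0.95),
             p_out = stats::runif(n, 0.05, 0.95))
    }
  }
  par <- param_sampler(n_bgcs)
  if (any(par$p_in + par$p_out <= 0)) {
    abort("p_in = p_out = 0: stationary distribution undefined",
          class = "bgctempo_validation_error")
  }
  bgc_id <- sprintf("bgc%04d", seq_len(n_bgcs))
  subject_id <- sprintf("S%03d", seq_len(n_subjects))
  pi_stat <- par$p_in / (par$p_in + par$p_out)

  # state[bgc, subject] per visit; vectorized over the whole grid
  states <- vector("list", n_visits)
  states[[1]] <- matrix(stats::runif(n_bgcs * n_subjects) < pi_stat,
                        n_bgcs, n_subjects)
  for (v in seq_len(n_visits - 1)) {
    prev <- states[[v]]
    u <- matrix(stats::runif(n_bgcs * n_subjects), n_bgcs, n_subjects)
    states[[v + 1]] <- ifelse(prev, u >= par$p_out, u < par$p_in)
  }

  meta <- tidyr::expand_grid(subject_id = subject_id,
                             visit = seq_len(n_visits)) %>%
    dplyr::mutate(sample_id = sprintf("%s_V%d", .data$subject_id, .data$visit),
                  cohort = "sim") %>%
    dplyr::select("sample_id", "subject_id", "visit", "cohort")

  presence <- purrr::map_dfr(seq_len(n_visits), function(v) {
    tibble(
      bgc_id = rep(bgc_id, times = n_subjects),
      sample_id = rep(sprintf("%s_V%d", subject_id, v), each = n_bgcs),
      present = as.vector(states[[v]])
    )
  })
  class(presence) <- c("bgc_presence", class(presence))

  truth <- tibble(
    bgc_id = bgc_id,
    p_inflow_true = par$p_in,
    p_outflow_true = par$p_out,
    true_class = classify_markov(par$p_in, par$p_out, threshold)
  )
  list(presence = presence, meta = meta, truth = truth)
}

#' Simulate a single long two-state chain
#'
#' One chain of presence/absence states, initialized from the stationary
#' distribution unless `init` is given. Used to check that empirical
#' presence fractions converge to `p_in / (p_in + p_out)`.
#'
#' @param p_in,p_out Transition probabilities with `p_in + p_out > 0`.
#' @param n_steps Chain length.
#' @param init Optional initial state (logical).
#' @param seed RNG seed.
#' @return Logical vector of length `n_steps`.
#' @export
simulate_chain <- function(p_in, p_out, n_steps, init = NULL, seed = NULL) {
  if (p_in + p_out <= 0) {
    abort("p_in + p_out must be > 0", class = "bgctempo_validation_error")
  }
  set_sim_seed(seed)
  pi_stat <- p_in / (p_in + p_out)
  x <- logical(n_steps)
  x[1] <- if (is.null(init)) stats::runif(1) < pi_stat else isTRUE(init)
  u <- stats::runif(n_steps)
  for (t in seq_len(n_steps - 1)) {
    x[t + 1] <- if (x[t]) u[t] >= p_out else u[t] < p_in
  }
  x
}

#' Simulate FMT triads with planted engraftment probabilities
#'
#' Donor and pre-FMT BGC sets are sampled independently from the catalog;
#' every donor-only BGC engrafts into the post-FMT set with the probability
#' of its class, and each pre-FMT BGC is retained with `retention_prob`.
#' Every engraftment opportunity and outcome is recorded as ground truth.
#' Triads get alternating responder / non_responder labels so
#' response-stratified summaries are exercisable; the labels carry no
#' planted effect.
#'
#' @param bgc_ids Catalog BGC ids (the sampling universe).
#' @param n_triads Number of triads.
#' @param donor_richness,pre_richness BGCs per donor / pre-FMT sample.
#' @param engraft_prob_by_class Named probabilities, e.g.
#'   `c(persistent = 0.8, transient = 0.2)`.
#' @param retention_prob Probability a pre-FMT BGC stays post-FMT.
#' @param class_map Optional tibble `bgc_id`, `classification`; default
#'   assigns classes round-robin over the names of
#'   `engraft_prob_by_class`.
#' @param seed RNG seed.
#' @return List: `triads` (an `fmt_triads` tibble), `class_map`, `truth`
#'   (tibble `triad_id`, `bgc_id`, `classification`, `engrafted`, one row
#'   per donor-only opportunity).
#' @export
gen_fmt_triads <- function(bgc_ids, n_triads, donor_richness, pre_richness,
                           engraft_prob_by_class = c(persistent = 0.8,
                                                     transient = 0.2),
                           retention_prob = 0.8, class_map = NULL,
                           seed = NULL) {
  set_sim_seed(seed)
  if (is.null(class_map)) {
    class_map <- tibble(
      bgc_id = bgc_ids,
      classification = rep_len(names(engraft_prob_by_class), length(bgc_ids))
    )
  }
  cls_of <- stats::setNames(class_map$classification, class_map$bgc_id)
  rows <- purrr::map(seq_len(n_triads), function(i) {
    donor <- sort(sample(bgc_ids, min(donor_richness, length(bgc_ids))))
    pre <- sort(sample(bgc_ids, min(pre_richness, length(bgc_ids))))
    opportunity <- setdiff(donor, pre)
    p <- unname(engraft_prob_by_class[cls_of[opportunity]])
    engrafted <- stats::runif(length(opportunity)) < p
    retained <- pre[stats::runif(length(pre)) < retention_prob]
    post <- sort(unique(c(opportunity[engrafted], retained)))
    list(
      triad = tibble(
        triad_id = sprintf("triad%03d", i), cohort = "sim",
        response = c("responder", "non_responder")[(i %% 2) + 1],
        donor_set = list(donor), pre_set = list(pre), post_set = list(post)
      ),
      truth = tibble(
        triad_id = sprintf("triad%03d", i), bgc_id = opportunity,
        classification = unname(cls_of[opportunity]), engrafted = engrafted
      )
    )
  })
  triads <- purrr::map_dfr(rows, "triad")
  class(triads) <- c("fmt_triads", class(triads))
  list(triads = triads, class_map = class_map,
       truth = purrr::map_dfr(rows, "truth"))
}

#' Simulate an annotation table with planted fold enrichment
#'
#' Background BGCs carry the feature with probability `base_rate`; BGCs in
#' the target group with probability `min(1, planted_fold * base_rate)`.
#'
#' @param bgc_ids All BGC ids (the background universe).
#' @param group_ids BGC ids of the target group (subset of `bgc_ids`).
#' @param planted_fold True fold enrichment of the group.
#' @param base_rate Background annotation rate.
#' @param feature_class One of `"ARG"`, `"VF"`, `"MGE"`.
#' @param seed RNG seed.
#' @return Annotation tibble (`bgc_id`, `feature_class`, `feature_label`);
#'   only annotated BGCs appear, so `base_rate = 0` with fold 1 gives an
#'   empty table. The planted parameters are attached as attribute
#'   `"truth"`.
#' @export
gen_annotations <- function(bgc_ids, group_ids, planted_fold = 1,
                            base_rate = 0.2, feature_class = "ARG",
                            seed = NULL) {
  set_sim_seed(seed)
  rate <- ifelse(bgc_ids %in% group_ids,
                 min(1, planted_fold * base_rate), base_rate)
  hit <- stats::runif(length(bgc_ids)) < rate
  out <- tibble(
    bgc_id = bgc_ids[hit],
    feature_class = feature_class,
    feature_label = paste0(tolower(feature_class), "_feature")
  )
  attr(out, "truth") <- list(planted_fold = planted_fold,
                             base_rate = base_rate,
                             group_ids = group_ids)
  out
}

#' Simulate a complete study: cohort, FMT triads, coverage, annotations
#'
#' One call generates every input of the full pipeline with consistent
#' ground truth: a random catalog (one genome per BGC), a longitudinal
#' cohort whose per-sample BGC presence follows per-BGC Markov chains,
#' FMT triads with class-dependent planted engraftment, per-gene coverage
#' derived from per-sample communities (present BGCs get log-normal
#' abundance), and an annotation table with a planted enrichment in the
#' truly persistent group.
#'
#' @param n_bgcs,n_subjects,n_visits Cohort design.
#' @param n_triads FMT triads to simulate.
#' @param depth_factor Sequencing depth scalar passed to [gen_coverage()];
#'   the default 200 makes presence calls track the planted states
#'   closely while leaving realistic detection noise.
#' @param engraft_prob_by_class,retention_prob See [gen_fmt_triads()].
#' @param planted_fold,base_rate See [gen_annotations()]; the target group
#'   is the truly persistent BGCs.
#' @param seed RNG seed (single integer driving the whole dataset).
#' @return List: `catalog`, `coverage`, `meta` (cohort + triad samples),
#'   `annotations`, and `truth` (list with `markov`, `presence`,
#'   `engraftment`, `class_map`).
#' @export
gen_study <- function(n_bgcs = 60, n_subjects = 20, n_visits = 4,
                      n_triads = 8, depth_factor = 200,
                      engraft_prob_by_class = c(persistent = 0.8,
                                                transient = 0.2),
                      retention_prob = 0.8, planted_fold = 2,
                      base_rate = 0.2, seed = NULL) {
  set_sim_seed(seed)
  catalog <- gen_catalog(n_bgcs = n_bgcs, seed = NULL)
  cohort <- gen_markov_cohort(n_bgcs, n_subjects = n_subjects,
                              n_visits = n_visits, seed = NULL)
  # rename cohort BGC ids to the catalog's (same sprintf scheme, same count)
  stopifnot(identical(sort(unique(cohort$presence$bgc_id)), sort(catalog$bgc_id)))

  genome_of <- stats::setNames(catalog$genome_id, catalog$bgc_id)
  community_from_presence <- function(presence_tbl) {
    presence_tbl %>%
      dplyr::mutate(genome_id = unname(genome_of[.data$bgc_id])) %>%
      dplyr::group_by(.data$sample_id) %>%
      dplyr::mutate(rel_abundance = {
        ab <- ifelse(.data$present, stats::rlnorm(dplyr::n(), 0, 1), 0)
        if (sum(ab) > 0) ab / sum(ab) else ab
      }) %>%
      dplyr::ungroup() %>%
      dplyr::select("sample_id", "genome_id", "present", "rel_abundance")
  }
  cohort_comm <- community_from_presence(cohort$presence)

  fmt <- gen_fmt_triads(catalog$bgc_id, n_triads = n_triads,
                        donor_richness = max(5, round(n_bgcs * 0.5)),
                        pre_richness = max(5, round(n_bgcs * 0.35)),
                        engraft_prob_by_class = engraft_prob_by_class,
                        retention_prob = retention_prob,
                        class_map = dplyr::select(
                          cohort$truth, "bgc_id", classification = "true_class"),
                        seed = NULL)
  triad_presence <- purrr::pmap_dfr(
    list(fmt$triads$triad_id, fmt$triads$donor_set, fmt$triads$pre_set,
         fmt$triads$post_set),
    function(tid, d, p, q) {
      purrr::map2_dfr(
        c("donor", "pre", "post"), list(d, p, q),
        function(role, set) {
          tibble(bgc_id = catalog$bgc_id,
                 sample_id = paste0(tid, "_", role),
                 present = catalog$bgc_id %in% set)
        }
      )
    }
  )
  triad_comm <- community_from_presence(triad_presence)

  coverage <- gen_coverage(dplyr::bind_rows(cohort_comm, triad_comm),
                           catalog, depth_factor = depth_factor,
                           seed = NULL)

  triad_meta <- fmt$triads %>%
    dplyr::select("triad_id", "cohort", "response") %>%
    tidyr::expand_grid(triad_role = c("donor", "pre", "post")) %>%
    dplyr::mutate(
      sample_id = paste0(.data$triad_id, "_", .data$triad_role),
      subject_id = paste0(.data$triad_id, "_",
                          ifelse(.data$triad_role == "donor", "donor", "recipient")),
      visit = ifelse(.data$triad_role == "post", 2L, 1L),
      cohort = "fmt"
    ) %>%
    dplyr::select("sample_id", "subject_id", "visit", "cohort",
                  "triad_id", "triad_role", "response")
  meta <- dplyr::bind_rows(
    cohort$meta %>% dplyr::mutate(triad_id = NA_character_,
                                  triad_role = NA_character_,
                                  response = NA_character_),
    triad_meta
  )

  class_map <- dplyr::select(cohort$truth, "bgc_id", classification = "true_class")
  annotations <- gen_annotations(
    catalog$bgc_id,
    class_map$bgc_id[class_map$classification %in% "persistent"],
    planted_fold = planted_fold, base_rate = base_rate, seed = NULL
  )

  list(
    catalog = catalog, coverage = coverage$coverage, meta = meta,
    annotations = annotations,
    truth = list(markov = cohort$truth,
                 presence = dplyr::bind_rows(
                   dplyr::mutate(cohort$presence, bgc_id = .data$bgc_id,
                                 .keep = "all"),
                   triad_presence),
                 engraftment = fmt$truth, class_map = class_map)
  )
}
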