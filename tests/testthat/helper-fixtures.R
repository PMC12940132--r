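# fixtures are built in code; nothing is read from disk except what a test
# writes into its own tempdir

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# canonical k-mer set of a sequence, as strings (brute-force oracle)
canonical_kmers <- function(s, k) {
  n <- nchar(s)
  kmers <- substring(s, 1:(n - k + 1), k:n)
  rcs <- vapply(kmers, revcomp, character(1), USE.NAMES = FALSE)
  unique(pmin(kmers, rcs))
}

tiny_catalog <- function() {
  build_catalog(
    tibble::tibble(
      bgc_id = c("bgcA", "bgcB"),
      length_bp = c(1000L, 2000L)
    ),
    tibble::tibble(
      bgc_id = c("bgcA", "bgcA", "bgcB", "bgcB", "bgcB", "bgcB"),
      gene_id = c("a1", "a2", "b1", "b2", "b3", "b4"),
      start = c(1L, 501L, 1L, 501L, 1001L, 1501L),
      end = c(400L, 1000L, 500L, 1000L, 1500L, 2000L)
    )
  )
}

write_fasta <- function(ids, seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- ids
  Biostrings::writeXStringSet(x, path)
  path
}

# long presence tibble from a named-by-sample list of logical vectors
presence_tbl <- function(mat) {
  out <- tibble::tibble(
    bgc_id = rep(rownames(mat), times = ncol(mat)),
    sample_id = rep(colnames(mat), each = nrow(mat)),
    present = as.vector(mat)
  )
  class(out) <- c("bgc_presence", class(out))
  out
}

# metadata for a complete subjects x visits design
grid_meta <- function(n_subjects, n_visits, prefix = "S") {
  tidyr::expand_grid(
    subject_id = sprintf("%s%02d", prefix, seq_len(n_subjects)),
    visit = seq_len(n_visits)
  ) |>
    dplyr::mutate(sample_id = sprintf("%s_V%d", subject_id, visit),
                  cohort = "test") |>
    dplyr::select(sample_id, subject_id, visit, cohort)
}

# one-row triad in the fmt_triads layout
one_triad <- function(donor, pre, post, id = "t1", response = "unknown") {
  out <- tibble::tibble(
    triad_id = id, cohort = "test", response = response,
    donor_set = list(donor), pre_set = list(pre), post_set = list(post)
  )
  class(out) <- c("fmt_triads", class(out))
  out
}
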