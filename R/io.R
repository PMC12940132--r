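#' Read a BGC catalog from FASTA plus a gene-model table
#'
#' A catalog couples each biosynthetic gene cluster (BGC) nucleotide sequence
#' with its ordered gene intervals. Gene coordinates are 1-based inclusive on
#' the BGC sequence (GFF convention); strand is ignored throughout the
#' package because presence calling and RPKM are strand-agnostic.
#'
#' @param fasta_path Path to the catalog FASTA (one record per BGC).
#' @param gene_table_path Path to a TSV with header
#'   `bgc_id, gene_id, start, end` (extra columns `product_type`, `taxonomy`
#'   on any row of a BGC are carried through). `#`-prefixed lines are skipped.
#' @return A tibble of class `bgc_catalog` with one row per BGC: `bgc_id`,
#'   `length_bp`, `genes` (list-column of tibbles `gene_id`, `start`, `end`,
#'   sorted by `start`), `product_type`, `taxonomy`, `sequence`.
#' @export
read_catalog <- function(fasta_path, gene_table_path) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  if (length(seqs) == 0) {
    abort("empty FASTA: no catalog records", class = "bgctempo_validation_error")
  }
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids)) {
    abort("duplicate FASTA ids in catalog", class = "bgctempo_validation_error")
  }
  genes <- read_tsv_strict(
    gene_table_path,
    required = c("bgc_id", "gene_id", "start", "end"),
    col_types = readr::cols(
      bgc_id = readr::col_character(), gene_id = readr::col_character(),
      start = readr::col_double(), end = readr::col_double(),
      .default = readr::col_character()
    )
  )
  genes$start <- validate_whole(genes$start, "start")
  genes$end <- validate_whole(genes$end, "end")

  build_catalog(
    tibble(
      bgc_id = ids,
      length_bp = as.integer(Biostrings::width(seqs)),
      sequence = unname(as.character(seqs))
    ),
    genes
  )
}

#' Assemble a BGC catalog from in-memory tables
#'
#' Builder behind [read_catalog()], exposed so synthetic catalogs can be
#' constructed without touching disk. Validates every catalog invariant:
#' at least one gene per BGC, unique gene ids within a BGC, and
#' `1 <= start <= end <= length_bp`.
#'
#' @param bgcs Tibble with `bgc_id`, `length_bp` and optionally `sequence`,
#'   `product_type`, `taxonomy`.
#' @param genes Tibble with `bgc_id`, `gene_id`, `start`, `end`.
#' @return A `bgc_catalog` tibble (see [read_catalog()]).
#' @export
build_catalog <- function(bgcs, genes) {
  bgcs <- as_tibble(bgcs)
  genes <- as_tibble(genes)
  for (col in c("product_type", "taxonomy")) {
    if (!col %in% names(bgcs)) {
      bgcs[[col]] <- if (col %in% names(genes)) {
        genes[[col]][match(bgcs$bgc_id, genes$bgc_id)]
      } else {
        NA_character_
      }
    }
  }
  if (!"sequence" %in% names(bgcs)) bgcs$sequence <- NA_character_
  if (any(bgcs$length_bp < 1)) {
    abort("length_bp must be >= 1 for every BGC", class = "bgctempo_validation_error")
  }
  stray <- setdiff(genes$bgc_id, bgcs$bgc_id)
  if (length(stray) > 0) {
    abort(paste0("gene table refers to unknown BGC ids: ",
                 paste(utils::head(stray, 5), collapse = ", ")),
          class = "bgctempo_validation_error")
  }
  nested <- genes %>%
    dplyr::select("bgc_id", "gene_id", "start", "end") %>%
    dplyr::arrange(.data$bgc_id, .data$start, .data$gene_id) %>%
    tidyr::nest(genes = c("gene_id", "start", "end"))
  out <- bgcs %>%
    dplyr::select("bgc_id", "length_bp", "product_type", "taxonomy", "sequence") %>%
    dplyr::left_join(nested, by = "bgc_id")

  for (i in seq_len(nrow(out))) {
    g <- out$genes[[i]]
    id <- out$bgc_id[i]
    if (is.null(g) || nrow(g) == 0) {
      abort(paste0("no genes for ", id), class = "bgctempo_validation_error")
    }
    if (anyDuplicated(g$gene_id)) {
      abort(paste0("duplicate gene ids within ", id), class = "bgctempo_validation_error")
    }
    if (any(g$start < 1) || any(g$end < g$start) || any(g$end > out$length_bp[i])) {
      abort(paste0("gene coordinates out of bounds on ", id,
                   " (need 1 <= start <= end <= ", out$length_bp[i], ")"),
            class = "bgctempo_validation_error")
    }
  }
  class(out) <- c("bgc_catalog", class(out))
  out
}

#' Flatten a catalog's gene models into one long tibble
#'
#' @param catalog A `bgc_catalog` from [read_catalog()] or [build_catalog()].
#' @return Tibble with `bgc_id`, `gene_id`, `start`, `end`, `gene_length`.
#' @export
catalog_genes <- function(catalog) {
  catalog %>%
    dplyr::select("bgc_id", "genes") %>%
    tidyr::unnest("genes") %>%
    dplyr::mutate(gene_length = .data$end - .data$start + 1L)
}

#' Read a per-sample, per-gene coverage table
#'
#' The bridge from read alignment to presence and abundance: one row per
#' observed (sample, gene) pair with the breadth of coverage (fraction of
#' gene positions covered by at least one best-hit alignment) and the
#' mapped-read count. Pairs absent from the table mean fraction 0 and
#' count 0; they are not materialized here.
#'
#' @param path TSV with header `sample_id, gene_id, covered_fraction,
#'   read_count`; `#` comment lines skipped.
#' @return A tibble with those four columns, validated: fractions inside
#'   \[0, 1\] (out-of-range is an error, never clamped), non-negative
#'   integer counts, no duplicate (sample, gene) rows.
#' @export
read_coverage_table <- function(path) {
  cov <- read_tsv_strict(
    path,
    required = c("sample_id", "gene_id", "covered_fraction", "read_count"),
    col_types = readr::cols(
      sample_id = readr::col_character(), gene_id = readr::col_character(),
      covered_fraction = readr::col_double(), read_count = readr::col_double()
    )
  )
  validate_coverage(cov)
}

validate_coverage <- function(cov) {
  cov <- as_tibble(cov)
  need <- c("sample_id", "gene_id", "covered_fraction", "read_count")
  missing <- setdiff(need, names(cov))
  if (length(missing) > 0) {
    abort(paste0("coverage table lacks columns: ", paste(missing, collapse = ", ")),
          class = "bgctempo_validation_error")
  }
  if (any(!is.finite(cov$covered_fraction)) ||
      any(cov$covered_fraction < 0) || any(cov$covered_fraction > 1)) {
    abort("covered_fraction outside [0, 1]", class = "bgctempo_validation_error")
  }
  cov$read_count <- validate_whole(cov$read_count, "read_count")
  if (any(cov$read_count < 0)) {
    abort("negative read_count", class = "bgctempo_validation_error")
  }
  if (anyDuplicated(cov[, c("sample_id", "gene_id")])) {
    abort("duplicate (sample_id, gene_id) rows in coverage table",
          class = "bgctempo_validation_error")
  }
  cov[, need]
}

#' Read sample metadata
#'
#' @param path TSV with header `sample_id, subject_id, visit, cohort` and
#'   optional `triad_id, triad_role, response` columns.
#' @return Validated tibble; `(subject_id, visit)` must be unique within a
#'   cohort, `triad_role` (donor/pre/post) must be set exactly when
#'   `triad_id` is.
#' @export
read_sample_metadata <- function(path) {
  meta <- read_tsv_strict(
    path,
    required = c("sample_id", "subject_id", "visit", "cohort"),
    col_types = readr::cols(
      visit = readr::col_double(), .default = readr::col_character()
    )
  )
  validate_metadata(meta)
}

validate_metadata <- function(meta) {
  meta <- as_tibble(meta)
  need <- c("sample_id", "subject_id", "visit", "cohort")
  missing <- setdiff(need, names(meta))
  if (length(missing) > 0) {
    abort(paste0("metadata lacks columns: ", paste(missing, collapse = ", ")),
          class = "bgctempo_validation_error")
  }
  meta$visit <- validate_whole(meta$visit, "visit")
  if (any(meta$visit < 1)) {
    abort("visit indices must be >= 1", class = "bgctempo_validation_error")
  }
  if (anyDuplicated(meta$sample_id)) {
    abort("duplicate sample_id in metadata", class = "bgctempo_validation_error")
  }
  if (anyDuplicated(meta[, c("cohort", "subject_id", "visit")])) {
    abort("duplicate (subject_id, visit) within a cohort",
          class = "bgctempo_validation_error")
  }
  for (col in c("triad_id", "triad_role", "response")) {
    if (!col %in% names(meta)) meta[[col]] <- NA_character_
  }
  if (any(is.na(meta$triad_id) != is.na(meta$triad_role))) {
    abort("triad_role must be set exactly when triad_id is set",
          class = "bgctempo_validation_error")
  }
  bad_role <- !is.na(meta$triad_role) & !meta$triad_role %in% c("donor", "pre", "post")
  if (any(bad_role)) {
    abort("triad_role must be one of donor, pre, post",
          class = "bgctempo_validation_error")
  }
  bad_resp <- !is.na(meta$response) &
    !meta$response %in% c("responder", "non_responder", "unknown")
  if (any(bad_resp)) {
    abort("response must be responder, non_responder or unknown",
          class = "bgctempo_validation_error")
  }
  meta
}

#' Read a BGC annotation table
#'
#' Plain-table consumption of upstream functional annotation: antibiotic
#' resistance genes (ARG), virulence factors (VF) and mobile genetic
#' elements (MGE). A BGC may carry zero or many features.
#'
#' @param path TSV with header `bgc_id, feature_class, feature_label`.
#' @param catalog Optional `bgc_catalog`; when given, annotation `bgc_id`s
#'   must refer to catalog entries.
#' @return Validated tibble with the three columns.
#' @export
read_annotations <- function(path, catalog = NULL) {
  ann <- read_tsv_strict(
    path,
    required = c("bgc_id", "feature_class", "feature_label"),
    col_types = readr::cols(.default = readr::col_character())
  )
  bad <- !ann$feature_class %in% c("ARG", "VF", "MGE")
  if (any(bad)) {
    abort(paste0("unknown feature_class: ",
                 paste(unique(ann$feature_class[bad]), collapse = ", ")),
          class = "bgctempo_validation_error")
  }
  if (!is.null(catalog)) {
    stray <- setdiff(ann$bgc_id, catalog$bgc_id)
    if (length(stray) > 0) {
      abort(paste0("annotation refers to unknown BGC ids: ",
                   paste(utils::head(stray, 5), collapse = ", ")),
            class = "bgctempo_validation_error")
    }
  }
  ann
}

#' Write / read a BGC-by-sample matrix as TSV
#'
#' Matrices (boolean presence or float abundance) are serialized with BGC
#' rows and sample columns, header `bgc_id` then sample ids. Floats are
#' written with 12 significant digits so `read_matrix(write_matrix(M)) == M`
#' holds to at least 10 digits; logical matrices round-trip exactly.
#'
#' @param mat A logical or numeric matrix with row and column names.
#' @param path Output TSV path.
#' @return `write_matrix()` returns `path` invisibly; `read_matrix()`
#'   returns the matrix (logical if every cell is TRUE/FALSE, else numeric).
#' @export
write_matrix <- function(mat, path) {
  if (is.null(rownames(mat)) || is.null(colnames(mat))) {
    abort("matrix must have row and column names", class = "bgctempo_validation_error")
  }
  cells <- if (is.logical(mat)) {
    ifelse(mat, "TRUE", "FALSE")
  } else {
    sprintf("%.12g", mat)
  }
  cells <- matrix(cells, nrow = nrow(mat))
  lines <- c(
    paste(c("bgc_id", colnames(mat)), collapse = "\t"),
    vapply(seq_len(nrow(mat)),
           function(i) paste(c(rownames(mat)[i], cells[i, ]), collapse = "\t"),
           character(1))
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  if (length(lines) < 1) {
    abort("empty matrix file", class = "bgctempo_validation_error")
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  widths <- lengths(fields)
  if (length(unique(widths)) != 1) {
    abort("ragged rows in matrix file", class = "bgctempo_validation_error")
  }
  header <- fields[[1]]
  ncol_mat <- length(header) - 1L
  body <- fields[-1]
  rn <- vapply(body, `[[`, character(1), 1L)
  cells <- vapply(body, function(f) f[-1], character(ncol_mat))
  cells <- matrix(cells, nrow = ncol_mat)  # vapply returns column-per-row
  cells <- t(cells)
  if (ncol_mat == 1) cells <- matrix(cells, ncol = 1)
  if (all(cells %in% c("TRUE", "FALSE"))) {
    mat <- matrix(cells == "TRUE", nrow = length(rn))
  } else {
    vals <- suppressWarnings(as.numeric(cells))
    if (any(is.na(vals) & !cells %in% c("NA", "NaN"))) {
      abort("non-numeric cells in matrix file", class = "bgctempo_validation_error")
    }
    mat <- matrix(vals, nrow = length(rn))
  }
  dimnames(mat) <- list(rn, header[-1])
  mat
}

#' Write a catalog to FASTA plus a gene-model table
#'
#' Inverse of [read_catalog()]: sequences to FASTA, gene models to a TSV
#' with header `bgc_id, gene_id, start, end` (plus `product_type`,
#' `taxonomy` when present on the catalog).
#'
#' @param catalog A `bgc_catalog` with sequences.
#' @param fasta_path,gene_table_path Output paths.
#' @return `fasta_path` invisibly.
#' @export
write_catalog <- function(catalog, fasta_path, gene_table_path) {
  if (any(is.na(catalog$sequence))) {
    abort("catalog has BGCs without sequences", class = "bgctempo_validation_error")
  }
  seqs <- Biostrings::DNAStringSet(catalog$sequence)
  names(seqs) <- catalog$bgc_id
  Biostrings::writeXStringSet(seqs, fasta_path)
  genes <- catalog_genes(catalog) %>%
    dplyr::select("bgc_id", "gene_id", "start", "end")
  extra <- as_tibble(catalog)[, intersect(c("bgc_id", "product_type", "taxonomy"),
                                          names(catalog))]
  if (ncol(extra) > 1 && !all(is.na(extra$product_type %||% NA))) {
    genes <- dplyr::left_join(genes, extra, by = "bgc_id")
  }
  readr::write_tsv(genes, gene_table_path, progress = FALSE)
  invisible(fasta_path)
}

# strict TSV reader: mandatory header, '#' comments skipped, required columns
read_tsv_strict <- function(path, required, col_types) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "bgctempo_io_error")
  }
  tbl <- readr::read_tsv(path, comment = "#", col_types = col_types,
                         progress = FALSE)
  missing <- setdiff(required, names(tbl))
  if (length(missing) > 0) {
    abort(paste0(basename(path), " lacks required columns: ",
                 paste(missing, collapse = ", ")),
          class = "bgctempo_validation_error")
  }
  probs <- readr::problems(tbl)
  if (nrow(probs) > 0) {
    abort(paste0("malformed rows in ", basename(path), " (first at line ",
                 probs$row[1], ")"),
          class = "bgctempo_validation_error")
  }
  tbl
}

# integers stored as doubles in TSV: require them whole, return integer
validate_whole <- function(x, what) {
  if (any(!is.finite(x)) || any(x != floor(x))) {
    abort(paste0(what, " must be a whole number"), class = "bgctempo_validation_error")
  }
  as.integer(x)
}
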