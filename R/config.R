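#' Default pipeline configuration
#'
#' All tunable thresholds used across the pipeline, in one list. The values
#' are the operating points of the published workflow this package
#' re-implements as defaults: a gene is called present when at least 30% of
#' its length is covered, a BGC when at least 50% of its genes are present,
#' the persistent/transient split uses 0.3 on both Markov transition
#' probabilities, and dereplication connects sequences with MinHash
#' similarity strictly above 0.95 (k = 21, sketch size 1000) before MCL
#' clustering at inflation 2.0.
#'
#' @return A named list with elements `gene_cov`, `bgc_cov`,
#'   `markov_threshold`, `mash_sim`, `kmer`, `sketch`, `inflation`.
#' @export
#' @examples
#' default_config()$gene_cov
default_config <- function() {
  list(
    gene_cov = 0.3,
    bgc_cov = 0.5,
    markov_threshold = 0.3,
    mash_sim = 0.95,
    kmer = 21L,
    sketch = 1000L,
    inflation = 2.0
  )
}

#' Read a pipeline configuration file
#'
#' Reads a YAML (or JSON, which YAML subsumes) configuration file and merges
#' it over [default_config()]: keys absent from the file keep their default,
#' unknown keys are rejected loudly.
#'
#' @param path Path to a YAML config file, or `NULL` for pure defaults.
#' @return A config list as in [default_config()].
#' @export
read_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) {
    return(cfg)
  }
  if (!file.exists(path)) {
    abort(paste0("config file not found: ", path), class = "bgctempo_io_error")
  }
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown) > 0) {
    abort(paste0("unknown config keys: ", paste(unknown, collapse = ", ")),
          class = "bgctempo_validation_error")
  }
  for (k in names(user)) {
    val <- user[[k]]
    if (!is.numeric(val) || length(val) != 1 || is.na(val)) {
      abort(paste0("config key '", k, "' must be a single number"),
            class = "bgctempo_validation_error")
    }
    cfg[[k]] <- if (k %in% c("kmer", "sketch")) as.integer(val) else as.numeric(val)
  }
  cfg
}
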