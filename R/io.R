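#' NRXN3 individual genotyping counts
#'
#' The packaged genotype count table for the two Neurexin 3 SNPs
#' (rs11845632 and rs2196447) individually genotyped in the test cohort
#' (175 cases / 244 controls) and the replication cohort (234 / 271).
#' Genotype classes are labelled by the A/G alleles of both SNPs; `n_AA`
#' counts A-homozygotes.
#'
#' @return A tibble: `snp_id`, `cohort`, `group`, `n_AA`, `n_AG`, `n_GG`,
#'   `allele_ref`, `allele_alt`.
#' @examples
#' nrxn3_counts()
#' @export
nrxn3_counts <- function() {
  read_genotype_counts(
    system.file("extdata", "nrxn3_genotype_counts.tsv", package = "poolgwas",
                mustWork = TRUE)
  )
}

count_col_types <- function() {
  readr::cols(
    snp_id = readr::col_character(),
    cohort = readr::col_character(),
    group = readr::col_character(),
    n_AA = readr::col_integer(),
    n_AG = readr::col_integer(),
    n_GG = readr::col_integer(),
    .default = readr::col_character()
  )
}

#' Read and write the package's TSV contracts
#'
#' All stage inputs and outputs are UTF-8 tab-separated tables with a
#' mandatory header row; `#`-prefixed lines are treated as comments (the
#' pipeline writes its config hash and seed there).
#'
#' @param path File path.
#' @return A tibble.
#' @export
read_genotype_counts <- function(path) {
  out <- readr::read_tsv(path, col_types = count_col_types(), comment = "#")
  check_columns(out, c("snp_id", "cohort", "group", "n_AA", "n_AG", "n_GG"),
                "genotype count file")
  if (any(out[c("n_AA", "n_AG", "n_GG")] < 0)) {
    abort("genotype counts must be non-negative")
  }
  out
}

#' @rdname read_genotype_counts
#' @export
read_intensities <- function(path) {
  out <- readr::read_tsv(
    path, comment = "#",
    col_types = readr::cols(
      channel_A = readr::col_double(), channel_B = readr::col_double(),
      .default = readr::col_character()
    )
  )
  check_columns(out, c("snp_id", "channel_A", "channel_B"), "intensity file")
  if ("replicate" %in% names(out)) out$replicate <- as.integer(out$replicate)
  out
}

#' @rdname read_genotype_counts
#' @param data Table to write.
#' @param comments Character vector of comment lines to place above the
#'   header (written with a leading `"# "`).
#' @export
write_stage_tsv <- function(data, path, comments = character()) {
  data <- tibble::as_tibble(data)
  data <- data[!vapply(data, is.list, logical(1))]
  lines <- if (length(comments) > 0) paste0("# ", comments) else character()
  readr::write_lines(lines, path)
  readr::write_tsv(data, path, append = length(lines) > 0, col_names = TRUE)
  invisible(path)
}
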