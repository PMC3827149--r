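#' Configure an end-to-end pipeline run
#'
#' Collects every stage input and threshold of the two-stage workflow:
#' synthetic-study generation (optional), pooled-array calibration, the
#' gender-stratified pooled screen, candidate selection, and the
#' individual-genotyping stage.
#'
#' @param sim A [sim_config()] for the synthetic study, or `NULL` to skip
#'   the pooled stages (then `counts` must be supplied).
#' @param counts Genotype count table (tibble) or path to a count TSV for
#'   the individual stage; `NULL` (default) derives candidate counts from
#'   the simulated genotypes.
#' @param replicate_sd_max Replicate-SD QC threshold, frequency units.
#' @param fdr_q Per-gender FDR level.
#' @param or_min,p_max Candidate screen thresholds.
#' @param top_n Candidates carried to the individual stage.
#' @param effective_n_mode Effective sample size behind the pooled test:
#'   `"chromosomes"` or `"individuals"`.
#' @param out_dir Directory for stage output TSVs, or `NULL` to keep
#'   results in memory only.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(sim = sim_config(),
                            counts = NULL,
                            replicate_sd_max = 0.05,
                            fdr_q = 0.05,
                            or_min = 1.4,
                            p_max = 0.05,
                            top_n = 48,
                            effective_n_mode = c("chromosomes", "individuals"),
                            out_dir = NULL) {
  if (is.null(sim) && is.null(counts)) {
    abort("either `sim` or `counts` must be supplied")
  }
  if (!is.null(sim)) stopifnot(inherits(sim, "sim_config"))
  structure(
    list(
      sim = sim,
      counts = counts,
      replicate_sd_max = check_number(replicate_sd_max, "replicate_sd_max",
                                      min = 0, max = 1, strict_min = TRUE),
      fdr_q = check_number(fdr_q, "fdr_q", min = 0, max = 1, strict_min = TRUE),
      or_min = check_number(or_min, "or_min", min = 1),
      p_max = check_number(p_max, "p_max", min = 0, max = 1, strict_min = TRUE),
      top_n = check_count(top_n, "top_n"),
      effective_n_mode = match.arg(effective_n_mode),
      out_dir = out_dir
    ),
    class = "pipeline_config"
  )
}

run_stage <- function(stage, code) {
  tryCatch(
    force(code),
    error = function(e) {
      abort(paste0("stage '", stage, "' failed: ", conditionMessage(e)))
    }
  )
}

#' Per-SNP genotype counts from simulated individuals
#'
#' Tabulates simulated genotypes into the count-table contract of the
#' individual-association stage.
#'
#' @param genotypes A [simulate_genotypes()] tibble.
#' @param snp_ids SNPs to tabulate (default: all).
#' @param cohort Cohort label to attach (default `"test"`).
#' @return A tibble: `snp_id`, `cohort`, `group`, `n_AA`, `n_AG`, `n_GG`.
#' @export
genotype_counts <- function(genotypes, snp_ids = NULL, cohort = "test") {
  check_columns(genotypes, c("group", "snp_id", "dosage"), "`genotypes`")
  if (!is.null(snp_ids)) {
    genotypes <- genotypes[genotypes$snp_id %in% snp_ids, , drop = FALSE]
  }
  genotypes |>
    dplyr::group_by(.data$snp_id, .data$group) |>
    dplyr::summarise(
      n_AA = sum(.data$dosage == 2L),
      n_AG = sum(.data$dosage == 1L),
      n_GG = sum(.data$dosage == 0L),
      .groups = "drop"
    ) |>
    dplyr::mutate(cohort = cohort) |>
    dplyr::select("snp_id", "cohort", "group", "n_AA", "n_AG", "n_GG")
}

#' Run the two-stage pooled-GWAS pipeline
#'
#' Executes, in order: synthetic-study simulation (if configured),
#' calibration-reference estimation, pooled RAF estimation with replicate
#' QC, the gender-stratified pooled association screen, candidate
#' selection, and the individual-genotyping association battery. Any stage
#' failure aborts with the stage name. The returned manifest (seed, config
#' hash, thresholds, per-filter record counts) is identical across runs
#' with an identical config, and output tables are byte-identical.
#'
#' @param config A [pipeline_config()].
#' @return A `pool_pipeline` list: `config`, `manifest`, and the stage
#'   results (`reference`, `raf`, `association`, `candidates`,
#'   `individual`, `truth`, `params`).
#' @examples
#' cfg <- pipeline_config(sim = sim_config(n_snps = 50, n_effect_snps = 5))
#' run <- run_pipeline(cfg)
#' run$manifest$funnel
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  config_hash <- rlang::hash(config[setdiff(names(config), "out_dir")])
  seed <- if (!is.null(config$sim)) config$sim$seed else NA_integer_
  out <- list(config = config)
  funnel <- c()

  if (!is.null(config$sim)) {
    study <- run_stage("synthetic_data", simulate_pool_study(config$sim))
    out$reference <- run_stage(
      "pool_calibration",
      calibration_reference(study$calibration)
    )
    out$raf <- run_stage(
      "pool_calibration",
      estimate_raf(study$pools, out$reference,
                   replicate_sd_max = config$replicate_sd_max)
    )
    out$association <- run_stage(
      "pooled_association",
      pooled_association(out$raf, study$design, fdr_q = config$fdr_q,
                         effective_n_mode = config$effective_n_mode)
    )
    out$candidates <- run_stage(
      "pooled_association",
      top_candidates(out$association, or_min = config$or_min,
                     p_max = config$p_max, top_n = config$top_n)
    )
    out$truth <- study$truth
    out$params <- study$params
    out$genotypes <- study$genotypes
    funnel <- c(
      attr(out$association, "funnel"),
      attr(out$candidates, "funnel")[-1],
      n_fdr_significant = sum(out$association$fdr_significant)
    )
  }

  counts <- config$counts
  if (is.null(counts) && !is.null(config$sim)) {
    counts <- genotype_counts(out$genotypes, out$candidates$snp_id, "test")
    indiv_cohort <- "test"
  } else {
    indiv_cohort <- "combined"
  }
  if (is.character(counts)) {
    if (!file.exists(counts)) {
      abort(paste0(
        "stage 'individual_association' failed: input path '", counts,
        "' not found"
      ))
    }
    counts <- run_stage("individual_association", read_genotype_counts(counts))
  }
  if (!is.null(counts) && nrow(counts) > 0) {
    out$individual <- run_stage(
      "individual_association",
      snp_association(counts, cohort = indiv_cohort)
    )
    funnel <- c(funnel, n_individually_genotyped = nrow(out$individual$results))
  }

  out$manifest <- list(
    package_version = as.character(packageVersion("poolgwas")),
    seed = seed,
    config_hash = config_hash,
    thresholds = list(
      replicate_sd_max = config$replicate_sd_max, fdr_q = config$fdr_q,
      or_min = config$or_min, p_max = config$p_max, top_n = config$top_n,
      effective_n_mode = config$effective_n_mode
    ),
    funnel = funnel
  )
  out <- structure(out, class = "pool_pipeline")

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    comments <- c(
      paste0("config_hash=", config_hash),
      paste0("seed=", seed)
    )
    tables <- list(
      raf = out$raf, association = out$association,
      candidates = out$candidates,
      individual = if (!is.null(out$individual)) out$individual$results
    )
    for (name in names(tables)) {
      if (!is.null(tables[[name]])) {
        write_stage_tsv(
          tables[[name]], file.path(config$out_dir, paste0(name, ".tsv")),
          comments = comments
        )
      }
    }
    manifest_path <- file.path(config$out_dir, "manifest.txt")
    readr::write_lines(
      c(
        paste0("package_version=", out$manifest$package_version),
        paste0("seed=", seed),
        paste0("config_hash=", config_hash),
        paste0(names(unlist(out$manifest$thresholds)), "=",
               unlist(out$manifest$thresholds)),
        paste0("funnel.", names(funnel), "=", funnel)
      ),
      manifest_path
    )
  }
  out
}

#' @export
print.pool_pipeline <- function(x, ...) {
  cat("<pool_pipeline>\n")
  cat("  config hash:", x$manifest$config_hash, " seed:", x$manifest$seed, "\n")
  if (length(x$manifest$funnel) > 0) {
    cat("  funnel:\n")
    f <- x$manifest$funnel
    for (i in seq_along(f)) {
      cat(sprintf("    %-22s %d\n", names(f)[i], f[i]))
    }
  }
  if (!is.null(x$individual)) {
    cat("  individual stage:\n")
    print(x$individual)
  }
  invisible(x)
}
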