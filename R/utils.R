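# Internal helpers shared across stages.

# Derive a reproducible per-stage seed from the root seed so that stages can
# be re-run in isolation and adding draws to one stage never perturbs another.
# Kept below 2^31 - 1 (R integers are 32-bit).
stage_seed <- function(seed, stage) {
  offsets <- c(
    params = 11L, genotypes = 23L, individual_intensities = 37L,
    pools = 51L, replication = 67L
  )
  if (!stage %in% names(offsets)) {
    abort(paste0("unknown RNG stage '", stage, "'"))
  }
  (as.integer(seed) %% 1000000L) * 2011L + offsets[[stage]]
}

with_stage_seed <- function(seed, stage, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(stage_seed(seed, stage))
  force(code)
}

# Multiplicative lognormal noise with unit mean and coefficient of variation
# `cv`; returns 1s when cv = 0 so the noise-free path is exact.
rnoise <- function(n, cv) {
  if (cv == 0) {
    return(rep(1, n))
  }
  sdlog <- sqrt(log1p(cv^2))
  rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

check_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x < min || x != round(x)) {
    abort(paste0("`", name, "` must be a single integer >= ", min))
  }
  as.integer(x)
}

check_number <- function(x, name, min = -Inf, max = Inf, strict_min = FALSE) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x)) {
    abort(paste0("`", name, "` must be a single number"))
  }
  lo_ok <- if (strict_min) x > min else x >= min
  if (!lo_ok || x > max) {
    abort(paste0(
      "`", name, "` must be in ", if (strict_min) "(" else "[", min, ", ", max, "]"
    ))
  }
  as.numeric(x)
}

check_columns <- function(data, cols, what) {
  missing <- setdiff(cols, names(data))
  if (length(missing) > 0) {
    abort(paste0(
      what, " is missing required column(s): ", paste(missing, collapse = ", ")
    ))
  }
  invisible(data)
}
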