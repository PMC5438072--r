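`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible sub-stream seed from a global seed
#'
#' Every source of randomness in the package draws from a named sub-stream of
#' a single global seed, so that e.g. the genotype draw of a cohort can be
#' reproduced without replaying the lifespan draw. Streams are separated by a
#' fixed large multiplier modulo 2^31 - 1, keeping the result a valid R
#' integer seed.
#'
#' @param seed integer global seed.
#' @param stream one of `"genotypes"`, `"covariates"`, `"ages"`,
#'   `"lifespans"`, `"contamination"`, `"misc"`, or an integer offset.
#' @return An integer seed for [set.seed()].
#' @export
stream_seed <- function(seed, stream = "misc") {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  offsets <- c(genotypes = 11, covariates = 17, ages = 23, lifespans = 37,
               contamination = 53, misc = 71)
  k <- if (is.character(stream)) {
    if (!stream %in% names(offsets)) stop("unknown random stream: ", stream)
    offsets[[stream]]
  } else as.numeric(stream)
  as.integer((abs(as.numeric(seed)) + 1000003 * k) %% 2147483647)
}

# first non-covariate columns of a phenotype table, in canonical order
.pheno_required_cols <- c("subject_id", "parent", "entry", "observed_age",
                          "event", "adopted")

.check_pheno_schema <- function(pheno) {
  miss <- setdiff(.pheno_required_cols, names(pheno))
  if (length(miss) > 0)
    stop("phenotype table is missing column(s): ", paste(miss, collapse = ", "))
  invisible(grep("^covariate_", names(pheno), value = TRUE))
}
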