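#' Random Mutation Capture experiment record
#'
#' One subject's RMC run: a set of PCR wells, each loaded with a known number
#' of target bases (4 bases of the TCGA TaqI recognition site per template
#' copy), and the list of sequence-confirmed mutant molecules.  The assay
#' detects single mutant mtDNA molecules as templates that escape TaqI
#' digestion and amplify.
#'
#' @param subject_id Identifier.
#' @param wells `data.frame` with columns `well_id`, `target_bases` (> 0).
#' @param mutants `data.frame` with columns `well_id`, `position`, `ref`,
#'   `alt`, `site_offset` (1..4, position within the TCGA site); may be empty.
#' @param age_years Optional subject age carried along for cohort analyses.
#' @return Object of class `"rmc_experiment"`.
#' @export
rmc_experiment <- function(subject_id, wells, mutants = NULL,
                           age_years = NA_real_) {
  stopifnot(is.data.frame(wells), all(c("well_id", "target_bases") %in% names(wells)))
  if (any(wells$target_bases <= 0)) stop("target_bases must be > 0")
  if (is.null(mutants))
    mutants <- data.frame(well_id = character(), position = integer(),
                          ref = character(), alt = character(),
                          site_offset = integer(), stringsAsFactors = FALSE)
  if (nrow(mutants)) {
    if (!all(mutants$well_id %in% wells$well_id))
      stop("mutant rows reference unknown wells")
    if (!all(mutants$site_offset %in% 1:4))
      stop("site_offset must be in 1..4")
  }
  out <- list(subject_id = subject_id, age_years = age_years,
              wells = wells, mutants = mutants)
  class(out) <- "rmc_experiment"
  out
}

#' @export
print.rmc_experiment <- function(x, ...) {
  cat(sprintf("RMC experiment '%s': %d wells, %s target bases, %d confirmed mutant(s)\n",
              x$subject_id, nrow(x$wells),
              format(sum(x$wells$target_bases), big.mark = ",",
                     scientific = FALSE),
              nrow(x$mutants)))
  invisible(x)
}

#' Total bases screened in an RMC experiment
#' @param experiment An [rmc_experiment()].
#' @return Numeric scalar.
#' @export
bases_screened <- function(experiment) {
  stopifnot(inherits(experiment, "rmc_experiment"))
  sum(as.numeric(experiment$wells$target_bases))
}

#' Low-level mutation frequency from RMC counts
#'
#' The mutation load is the number of confirmed mutant molecules divided by
#' the total number of base pairs screened, `f = m / b`, with an exact
#' Poisson (Garwood) 95% confidence interval on `m` scaled by `1/b`:
#' lower `qchisq(0.025, 2m) / 2 / b` (0 when `m = 0`), upper
#' `qchisq(0.975, 2(m + 1)) / 2 / b`.
#'
#' @param m Number of confirmed mutants (>= 0), or an [rmc_experiment()]
#'   (in which case `b` is taken from its wells).
#' @param b Total base pairs screened (> 0).
#' @param conf_level Confidence level (default 0.95).
#' @return Object of class `"rmc_freq"`: list with `m`, `b`, `frequency`,
#'   `ci_low`, `ci_high`, `conf_level`.
#' @examples
#' rmc_frequency(803, 2e8)       # ~4.0e-6 per bp
#' rmc_frequency(5, 20 * 10000)  # 2.5e-5 per bp
#' @export
rmc_frequency <- function(m, b = NULL, conf_level = 0.95) {
  if (inherits(m, "rmc_experiment")) {
    b <- bases_screened(m)
    m <- nrow(m$mutants)
  }
  if (is.null(b) || b <= 0) stop("b (bases screened) must be > 0")
  if (m < 0 || m != round(m)) stop("m must be a non-negative integer")
  alpha <- 1 - conf_level
  lo <- if (m == 0) 0 else qchisq(alpha / 2, 2 * m) / 2
  hi <- qchisq(1 - alpha / 2, 2 * (m + 1)) / 2
  out <- list(m = as.integer(m), b = b, frequency = m / b,
              ci_low = lo / b, ci_high = hi / b, conf_level = conf_level)
  class(out) <- "rmc_freq"
  out
}

#' @export
print.rmc_freq <- function(x, ...) {
  cat(sprintf(paste0("RMC mutation frequency: %d mutants / %s bp = %.3g per bp\n",
                     "  exact Poisson %d%% CI: [%.3g, %.3g]\n"),
              x$m, format(x$b, big.mark = ",", scientific = FALSE),
              x$frequency, round(100 * x$conf_level), x$ci_low, x$ci_high))
  invisible(x)
}

#' Simulate a Random Mutation Capture experiment
#'
#' Each well receives `copies_per_well` template copies, i.e.
#' `4 * copies_per_well` target bases (the four bases of the TCGA site; 2,500
#' copies give the assay's standard 10,000 target bases per well).  The
#' number of mutant molecules per well is Poisson with mean
#' `true_freq * target_bases`; mutant identities (site offset and
#' substitution) are drawn from the spectrum.
#'
#' @param true_freq True mutation frequency per base pair (>= 0).
#' @param n_wells Number of wells.
#' @param copies_per_well Template copies per well (>= 1).
#' @param spectrum A [spectrum_config()].
#' @param subject_id Identifier for the returned experiment.
#' @param site_start Reference position of the first TCGA site base
#'   (default 6562, the TaqI site inside MT-CO1).
#' @param seed Optional integer seed.
#' @return An [rmc_experiment()].
#' @examples
#' ex <- simulate_rmc_experiment(4e-6, n_wells = 20, seed = 1)
#' rmc_frequency(ex)
#' @export
simulate_rmc_experiment <- function(true_freq, n_wells,
                                    copies_per_well = 2500,
                                    spectrum = spectrum_config(),
                                    subject_id = "sim",
                                    site_start = 6562L,
                                    seed = NULL) {
  if (true_freq < 0) stop("true_freq must be >= 0")
  if (copies_per_well < 1) stop("copies_per_well must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  target_bases <- 4 * copies_per_well
  wells <- data.frame(well_id = sprintf("W%04d", seq_len(n_wells)),
                      target_bases = rep(target_bases, n_wells),
                      stringsAsFactors = FALSE)
  n_mut <- rpois(n_wells, true_freq * target_bases)
  total <- sum(n_mut)
  mutants <- if (total > 0) {
    ids <- .draw_site_mutations(total, spectrum)
    data.frame(well_id = rep(wells$well_id, n_mut),
               position = site_start + ids$site_offset - 1L,
               ref = ids$ref, alt = ids$alt,
               site_offset = ids$site_offset, stringsAsFactors = FALSE)
  } else NULL
  ex <- rmc_experiment(subject_id, wells, mutants)
  ex$positive_wells <- wells$well_id[n_mut > 0]
  ex
}

#' Observed-vs-expected validation of the RMC assay
#'
#' For a dilution/mixing series of wild-type and mutant clones, compares the
#' observed mutant fractions with the expected ones row by row and reports the
#' maximum absolute deviation and a pass flag.
#'
#' @param expected,observed Equal-length numeric vectors of fractions in
#'   `[0, 1]`.
#' @param tolerance Maximum absolute deviation accepted (default 0.05).
#' @return Object of class `"mixing_validation"`: `data.frame` of rows plus
#'   `max_abs_deviation` and `pass` attributes.
#' @examples
#' mixing_validation(c(0, 0.5, 1), c(0, 0.48, 1))
#' @export
mixing_validation <- function(expected, observed, tolerance = 0.05) {
  if (length(expected) != length(observed))
    stop("expected and observed must have equal length")
  if (any(expected < 0 | expected > 1 | observed < 0 | observed > 1))
    stop("fractions must lie in [0, 1]")
  dev <- abs(observed - expected)
  out <- data.frame(expected = expected, observed = observed,
                    abs_deviation = dev)
  attr(out, "max_abs_deviation") <- if (length(dev)) max(dev) else 0
  attr(out, "pass") <- all(dev <= tolerance)
  attr(out, "tolerance") <- tolerance
  class(out) <- c("mixing_validation", "data.frame")
  out
}

#' @export
print.mixing_validation <- function(x, ...) {
  cat(sprintf("RMC mixing validation: max |obs - exp| = %.3f (%s at tolerance %.2f)\n",
              attr(x, "max_abs_deviation"),
              if (attr(x, "pass")) "PASS" else "FAIL", attr(x, "tolerance")))
  print.data.frame(x, ...)
  invisible(x)
}
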