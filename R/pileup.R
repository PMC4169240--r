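#' Pileup simulation parameters
#'
#' Error and depth model for Ion-Torrent-style amplicon sequencing of the
#' whole mitochondrial genome.  Per-site read depth is Poisson around the mean
#' coverage; each read reports the true allele of its template molecule and is
#' then corrupted to one of the three alternative bases with total probability
#' `error_rate`, split evenly (the platform's published aggregate
#' base-substitution error rate for mtDNA is 0.12%, the default).  Strand is
#' assigned independently per read.
#'
#' @param coverage_per_site Mean read depth (>= 1).
#' @param error_rate Total per-base substitution error probability
#'   (in `[0, 0.01]`).
#' @param strand_balance Expected forward-strand fraction.
#' @param quality_mean,quality_sd Gaussian model of the per-site mean
#'   Phred-like quality score.
#' @param seed Optional integer seed.
#' @return Object of class `"pileup_params"`.
#' @export
pileup_params <- function(coverage_per_site = 2000,
                          error_rate = 0.0012,
                          strand_balance = 0.5,
                          quality_mean = 30, quality_sd = 2,
                          seed = NULL) {
  if (coverage_per_site < 1) stop("coverage_per_site must be >= 1")
  if (error_rate < 0 || error_rate > 0.01)
    stop("error_rate must be in [0, 0.01]")
  if (strand_balance <= 0 || strand_balance >= 1)
    stop("strand_balance must be in (0, 1)")
  out <- list(coverage = coverage_per_site, error_rate = error_rate,
              strand_balance = strand_balance,
              quality_mean = quality_mean, quality_sd = quality_sd,
              seed = if (!is.null(seed)) as.integer(seed) else NULL)
  class(out) <- "pileup_params"
  out
}

# empty per-site count table for a reference
.empty_counts <- function(ref_chars) {
  n <- length(ref_chars)
  m <- matrix(0L, nrow = n, ncol = 8L,
              dimnames = list(NULL, c("A_fwd", "A_rev", "C_fwd", "C_rev",
                                      "G_fwd", "G_rev", "T_fwd", "T_rev")))
  list(position = seq_len(n), ref = ref_chars, counts = m)
}

#' Simulate a whole-genome pileup count table
#'
#' For each of the 16,569 reference positions, draws a Poisson read depth,
#' assigns each read a true allele (reference, or a variant allele with its
#' heteroplasmy), corrupts reads to each of the three alternative bases with
#' probability `error_rate/3`, splits every allele's reads over strands, and
#' reports per-allele forward/reverse counts with a per-site mean quality.
#'
#' @param variants Variant `data.frame` with columns `position`, `ref`, `alt`,
#'   `heteroplasmy` (fractions in `[0, 1]`); may be empty.  Rows with
#'   multi-base alleles (indels) are ignored with a warning: the platform
#'   model covers substitutions only.
#' @param params A [pileup_params()].
#' @param reference Reference sequence string (default bundled synthetic).
#' @param seed Optional integer seed (overrides `params$seed`).
#' @return A `data.frame` of per-site counts: `position`, `ref`, `A_fwd`,
#'   `A_rev`, `C_fwd`, `C_rev`, `G_fwd`, `G_rev`, `T_fwd`, `T_rev`,
#'   `mean_quality`.
#' @examples
#' ref <- synthetic_rcrs()
#' v <- data.frame(position = 100, ref = ref_base(ref, 100),
#'                 alt = setdiff(c("A", "C", "G", "T"), ref_base(ref, 100))[1],
#'                 heteroplasmy = 0.5)
#' pl <- simulate_pileup(v, pileup_params(coverage_per_site = 100,
#'                                        error_rate = 0), ref, seed = 1)
#' @export
simulate_pileup <- function(variants = NULL,
                            params = pileup_params(),
                            reference = synthetic_rcrs(),
                            seed = NULL) {
  stopifnot(inherits(params, "pileup_params"))
  seed <- if (!is.null(seed)) seed else params$seed
  if (!is.null(seed)) set.seed(seed)
  reference <- .index_reference(reference)
  ref_chars <- attr(reference, "chars")
  n <- length(ref_chars)
  if (is.null(variants))
    variants <- data.frame(position = integer(), ref = character(),
                           alt = character(), heteroplasmy = numeric())
  if (nrow(variants)) {
    bad <- nchar(as.character(variants$ref)) != 1L |
      nchar(as.character(variants$alt)) != 1L |
      !(toupper(as.character(variants$alt)) %in% .mt_bases)
    bad[is.na(bad)] <- TRUE
    if (any(bad)) {
      warning(sum(bad), " non-substitution variant row(s) ignored")
      variants <- variants[!bad, , drop = FALSE]
    }
    if (any(variants$heteroplasmy < 0 | variants$heteroplasmy > 1))
      stop("heteroplasmy must lie in [0, 1]")
    vref <- ref_chars[variants$position]
    if (any(toupper(as.character(variants$ref)) != vref))
      stop("variant ref allele does not match the reference sequence")
  }

  depth <- rpois(n, params$coverage)
  # true allele counts: start with everything on the reference allele
  true_counts <- matrix(0L, nrow = n, ncol = 4L,
                        dimnames = list(NULL, .mt_bases))
  ref_col <- match(ref_chars, .mt_bases)
  true_counts[cbind(seq_len(n), ref_col)] <- depth
  if (nrow(variants)) {
    for (pos in unique(variants$position)) {
      rows <- variants[variants$position == pos, , drop = FALSE]
      p <- c(rows$heteroplasmy, 1 - sum(rows$heteroplasmy))
      if (p[length(p)] < 0) stop("heteroplasmies at position ", pos,
                                 " sum to more than 1")
      alloc <- as.integer(rmultinom(1L, depth[pos], p))
      true_counts[pos, ] <- 0L
      for (i in seq_len(nrow(rows))) {
        j <- match(toupper(rows$alt[i]), .mt_bases)
        true_counts[pos, j] <- true_counts[pos, j] + alloc[i]
      }
      true_counts[pos, ref_col[pos]] <-
        true_counts[pos, ref_col[pos]] + alloc[length(alloc)]
    }
  }

  # sequencing error: each read flips to one of the 3 other bases w.p. e/3.
  observed <- true_counts
  e <- params$error_rate
  if (e > 0) {
    for (b in seq_len(4L)) {
      src <- true_counts[, b]
      nerr <- rbinom(n, src, e)
      e1 <- rbinom(n, nerr, 1 / 3)
      e2 <- rbinom(n, nerr - e1, 1 / 2)
      e3 <- nerr - e1 - e2
      dest <- setdiff(seq_len(4L), b)
      observed[, b] <- observed[, b] - nerr
      observed[, dest[1]] <- observed[, dest[1]] + e1
      observed[, dest[2]] <- observed[, dest[2]] + e2
      observed[, dest[3]] <- observed[, dest[3]] + e3
    }
  }

  # strand split per allele
  out <- matrix(0L, nrow = n, ncol = 8L)
  colnames(out) <- c("A_fwd", "A_rev", "C_fwd", "C_rev",
                     "G_fwd", "G_rev", "T_fwd", "T_rev")
  for (b in seq_len(4L)) {
    fwd <- rbinom(n, observed[, b], params$strand_balance)
    out[, 2L * b - 1L] <- fwd
    out[, 2L * b] <- observed[, b] - fwd
  }
  data.frame(position = seq_len(n), ref = ref_chars, out,
             mean_quality = round(rnorm(n, params$quality_mean,
                                        params$quality_sd), 1),
             stringsAsFactors = FALSE)
}

#' Simulate the mutation-free clonal plasmid control
#'
#' A pileup from a clonal plasmid template carrying the whole mitochondrial
#' genome: every observed non-reference read is pure platform error, which is
#' what the noise-floor calibration ([calibrate_noise()]) measures.
#' Identical to [simulate_pileup()] with an empty variant list.
#'
#' @inheritParams simulate_pileup
#' @return Per-site count `data.frame` as in [simulate_pileup()].
#' @export
simulate_plasmid_control <- function(params = pileup_params(),
                                     reference = synthetic_rcrs(),
                                     seed = NULL) {
  simulate_pileup(NULL, params, reference, seed = seed)
}
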