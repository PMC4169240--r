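#' Quality-control filter configuration
#'
#' The complete threshold set of the heteroplasmy-calling cascade, with the
#' study defaults: call-level quality score above 20; variant present on both
#' strands at comparable frequencies (at most a 3-fold difference between the
#' strand-specific variant fractions); at least 3 variant reads and at least
#' 600 total reads at the site; positions 750 and 3902-3908 blacklisted
#' unconditionally (recurrent platform artefacts); substitutions only; and a
#' final heteroplasmy threshold of strictly more than 0.8%, set one safety
#' step above the 0.65% noise ceiling observed on a clonal plasmid control
#' (see [calibrate_noise()]).
#'
#' @param min_quality Minimum mean quality (strict `>`).
#' @param max_strand_fold Maximum fold difference between strand-specific
#'   variant fractions (>= 1).
#' @param min_alt_reads Minimum combined-strand variant reads.
#' @param min_coverage Minimum combined-strand total reads at the site.
#' @param het_threshold Heteroplasmy calling threshold (strict `>`, in (0,1)).
#' @param blacklist Integer vector of excluded positions.
#' @param substitutions_only Reject indel records.
#' @return Object of class `"filter_config"`.
#' @export
filter_config <- function(min_quality = 20,
                          max_strand_fold = 3,
                          min_alt_reads = 3,
                          min_coverage = 600,
                          het_threshold = 0.008,
                          blacklist = c(750L, 3902:3908),
                          substitutions_only = TRUE) {
  if (min_quality < 0 || min_alt_reads < 0 || min_coverage < 0)
    stop("thresholds must be >= 0")
  if (max_strand_fold < 1) stop("max_strand_fold must be >= 1")
  if (het_threshold <= 0 || het_threshold >= 1)
    stop("het_threshold must be in (0, 1)")
  out <- list(min_quality = min_quality, max_strand_fold = max_strand_fold,
              min_alt_reads = min_alt_reads, min_coverage = min_coverage,
              het_threshold = het_threshold,
              blacklist = as.integer(blacklist),
              substitutions_only = isTRUE(substitutions_only))
  class(out) <- "filter_config"
  out
}

#' @export
print.filter_config <- function(x, ...) {
  cat(sprintf(paste0("heteroplasmy filter cascade: quality > %g, strand fold <= %g,\n",
                     "  alt reads >= %g, coverage >= %g, heteroplasmy > %.2f%%, ",
                     "%d blacklisted position(s)%s\n"),
              x$min_quality, x$max_strand_fold, x$min_alt_reads,
              x$min_coverage, 100 * x$het_threshold, length(x$blacklist),
              if (x$substitutions_only) ", substitutions only" else ""))
  invisible(x)
}

#' Candidate variant calls from a pileup count table
#'
#' Emits one candidate call per (position, alternative allele) with at least
#' one supporting read.  Heteroplasmy is computed on combined strands:
#' `h = (fwd_alt + rev_alt) / (fwd_total + rev_total)`, the denominator being
#' the full site depth.  Zero-depth sites are skipped (and counted in the
#' `n_skipped` attribute).
#'
#' @param pileup Per-site count `data.frame` as produced by
#'   [simulate_pileup()] / [read_pileup()].
#' @return `data.frame` of calls: `position`, `ref`, `alt`, `fwd_alt`,
#'   `rev_alt`, `fwd_total`, `rev_total`, `heteroplasmy`, `mean_quality`.
#' @export
call_sites <- function(pileup) {
  need <- c("position", "ref", "A_fwd", "A_rev", "C_fwd", "C_rev",
            "G_fwd", "G_rev", "T_fwd", "T_rev", "mean_quality")
  miss <- setdiff(need, names(pileup))
  if (length(miss)) stop("pileup missing columns: ", paste(miss, collapse = ", "))
  fwd <- as.matrix(pileup[, c("A_fwd", "C_fwd", "G_fwd", "T_fwd")])
  rev <- as.matrix(pileup[, c("A_rev", "C_rev", "G_rev", "T_rev")])
  if (any(fwd < 0) || any(rev < 0)) stop("read counts must be >= 0")
  fwd_total <- rowSums(fwd)
  rev_total <- rowSums(rev)
  depth <- fwd_total + rev_total
  zero <- depth == 0
  calls <- vector("list", 4L)
  for (b in seq_len(4L)) {
    alt_base <- .mt_bases[b]
    altn <- fwd[, b] + rev[, b]
    keep <- !zero & altn >= 1L & pileup$ref != alt_base
    if (!any(keep)) next
    calls[[b]] <- data.frame(
      position = pileup$position[keep],
      ref = pileup$ref[keep],
      alt = alt_base,
      fwd_alt = fwd[keep, b], rev_alt = rev[keep, b],
      fwd_total = fwd_total[keep], rev_total = rev_total[keep],
      heteroplasmy = (fwd[keep, b] + rev[keep, b]) / depth[keep],
      mean_quality = pileup$mean_quality[keep],
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, calls)
  if (is.null(out))
    out <- data.frame(position = integer(), ref = character(),
                      alt = character(), fwd_alt = integer(),
                      rev_alt = integer(), fwd_total = integer(),
                      rev_total = integer(), heteroplasmy = numeric(),
                      mean_quality = numeric(), stringsAsFactors = FALSE)
  out <- out[order(out$position, out$alt), , drop = FALSE]
  rownames(out) <- NULL
  if (any(zero)) {
    message(sum(zero), " zero-depth site(s) skipped")
    attr(out, "n_skipped") <- sum(zero)
  }
  out
}

#' Strand concordance of a variant
#'
#' A variant is strand-concordant when it is seen on both strands and the
#' strand-specific variant fractions `p_f = fwd_alt/fwd_total`,
#' `p_r = rev_alt/rev_total` differ by at most `max_fold`.  A strand with no
#' variant read -- or no reads at all -- fails.
#'
#' @param fwd_alt,fwd_total,rev_alt,rev_total Integer vectors (recycled).
#' @param max_fold Maximum allowed fold difference (default 3).
#' @return Logical vector.
#' @examples
#' strand_concordant(10, 1000, 12, 1000)        # TRUE
#' strand_concordant(0, 1000, 9, 1000)          # FALSE: one strand only
#' strand_concordant(10, 1000, 35, 1000)        # FALSE: 3.5-fold
#' @export
strand_concordant <- function(fwd_alt, fwd_total, rev_alt, rev_total,
                              max_fold = 3) {
  n <- max(length(fwd_alt), length(fwd_total), length(rev_alt),
           length(rev_total))
  fwd_alt <- rep_len(fwd_alt, n); fwd_total <- rep_len(fwd_total, n)
  rev_alt <- rep_len(rev_alt, n); rev_total <- rep_len(rev_total, n)
  ok <- fwd_total > 0 & rev_total > 0 & fwd_alt >= 1 & rev_alt >= 1
  pf <- ifelse(fwd_total > 0, fwd_alt / fwd_total, 0)
  pr <- ifelse(rev_total > 0, rev_alt / rev_total, 0)
  fold <- pmax(pf / pr, pr / pf)
  ok & fold <= max_fold
}

# reason matrix (TRUE = fails that reason) for a call table under a config;
# optionally with the heteroplasmy threshold disabled (for calibration)
.filter_reasons_matrix <- function(calls, config, skip_threshold = FALSE) {
  n <- nrow(calls)
  is_sub <- nchar(calls$ref) == 1L & nchar(calls$alt) == 1L &
    toupper(calls$ref) %in% .mt_bases & toupper(calls$alt) %in% .mt_bases
  m <- cbind(
    quality   = !(calls$mean_quality > config$min_quality),
    strand    = !strand_concordant(calls$fwd_alt, calls$fwd_total,
                                   calls$rev_alt, calls$rev_total,
                                   config$max_strand_fold),
    min_reads = (calls$fwd_alt + calls$rev_alt) < config$min_alt_reads,
    coverage  = (calls$fwd_total + calls$rev_total) < config$min_coverage,
    blacklist = calls$position %in% config$blacklist,
    threshold = if (skip_threshold) rep(FALSE, n)
                else !(calls$heteroplasmy > config$het_threshold),
    indel     = config$substitutions_only & !is_sub)
  m
}

#' Apply the QC filter cascade to candidate calls
#'
#' A call passes iff its mean quality exceeds `min_quality`, it is
#' strand-concordant, it has at least `min_alt_reads` variant reads and
#' `min_coverage` total reads, its position is not blacklisted, it is a
#' substitution, and its heteroplasmy strictly exceeds `het_threshold`.
#' Rejected calls carry *every* failed reason, drawn from the fixed
#' enumeration quality / strand / min_reads / coverage / blacklist /
#' threshold / indel.
#'
#' @param calls Call `data.frame` from [call_sites()].
#' @param config A [filter_config()].
#' @return List with elements `passed` and `rejected` (the latter with a
#'   `reasons` character column, comma-separated), plus a `counts` element
#'   tallying failures per reason.
#' @export
apply_filters <- function(calls, config = filter_config()) {
  stopifnot(inherits(config, "filter_config"))
  if (nrow(calls) == 0L) {
    return(list(passed = calls,
                rejected = cbind(calls, data.frame(reasons = character())),
                counts = setNames(integer(length(.mt_filter_reasons)),
                                  .mt_filter_reasons)))
  }
  m <- .filter_reasons_matrix(calls, config)
  fails <- rowSums(m) > 0
  reasons <- apply(m, 1L, function(r)
    paste(.mt_filter_reasons[r], collapse = ","))
  rejected <- calls[fails, , drop = FALSE]
  rejected$reasons <- reasons[fails]
  passed <- calls[!fails, , drop = FALSE]
  rownames(passed) <- rownames(rejected) <- NULL
  stopifnot(nrow(passed) + nrow(rejected) == nrow(calls),
            all(nchar(rejected$reasons) > 0L))
  list(passed = passed, rejected = rejected,
       counts = setNames(as.integer(colSums(m)), colnames(m)))
}

#' Calibrate the heteroplasmy threshold from a clonal control
#'
#' Runs the control calls through the whole cascade *except* the heteroplasmy
#' threshold; any surviving variant fraction is pure platform noise.  The
#' derived threshold is the maximum surviving fraction rounded up to the next
#' 0.1 percentage point plus one further 0.1-point safety step, capped by
#' `override` when given.  A control with a 0.65% noise ceiling therefore
#' yields the 0.8% threshold.
#'
#' @param control_calls Calls from [call_sites()] on a clonal (mutation-free)
#'   control pileup; may have zero rows, but not be `NULL`.
#' @param config A [filter_config()] (its `het_threshold` is ignored).
#' @param override Optional user threshold; the derived threshold is
#'   `min(derived, override)`.
#' @return Object of class `"noise_calibration"`: list with
#'   `max_control_fraction`, `derived_threshold`, `n_surviving`.
#' @examples
#' # a clean control with no surviving calls floors at one safety step:
#' calib <- calibrate_noise(call_sites(simulate_plasmid_control(
#'   pileup_params(coverage_per_site = 50, error_rate = 0), seed = 1)))
#' @export
calibrate_noise <- function(control_calls, config = filter_config(),
                            override = NULL) {
  if (is.null(control_calls) || !is.data.frame(control_calls))
    stop("calibration impossible: no control calls supplied")
  res <- apply_filters_no_threshold(control_calls, config)
  max_frac <- if (nrow(res$passed)) max(res$passed$heteroplasmy) else 0
  step <- 0.001  # 0.1 percentage point
  derived <- ceiling(max_frac / step - 1e-9) * step + step
  if (!is.null(override)) derived <- min(derived, override)
  if (derived < max_frac) stop("override threshold lies below the noise ceiling")
  out <- list(max_control_fraction = max_frac,
              derived_threshold = derived,
              n_surviving = nrow(res$passed))
  class(out) <- "noise_calibration"
  out
}

#' @rdname calibrate_noise
#' @param calls Calls to filter with the heteroplasmy threshold disabled.
#' @export
apply_filters_no_threshold <- function(calls, config = filter_config()) {
  stopifnot(inherits(config, "filter_config"))
  if (nrow(calls) == 0L)
    return(list(passed = calls,
                rejected = cbind(calls, data.frame(reasons = character()))))
  m <- .filter_reasons_matrix(calls, config, skip_threshold = TRUE)
  fails <- rowSums(m) > 0
  reasons <- apply(m, 1L, function(r)
    paste(.mt_filter_reasons[r], collapse = ","))
  rejected <- calls[fails, , drop = FALSE]
  rejected$reasons <- reasons[fails]
  list(passed = calls[!fails, , drop = FALSE], rejected = rejected)
}

#' @export
print.noise_calibration <- function(x, ...) {
  cat(sprintf(paste0("noise calibration: max control fraction %.3f%% over %d ",
                     "surviving call(s)\n  derived heteroplasmy threshold: > %.2f%%\n"),
              100 * x$max_control_fraction, x$n_surviving,
              100 * x$derived_threshold))
  invisible(x)
}

#' Minimum number of fully clonal crypts detectable at tissue level
#'
#' With `n_crypts` equally weighted crypts per biopsy, a mutation homoplasmic
#' in `k` crypts reaches tissue heteroplasmy `k / n_crypts`; the detection
#' limit is the smallest `k` strictly exceeding the calling threshold.  At
#' the 0.8% threshold and ~200 crypts per biopsy this is 2 crypts.
#'
#' @param het_threshold Calling threshold (in (0, 1)).
#' @param n_crypts Crypts per biopsy (>= 1).
#' @return Integer, the smallest `k` with `k / n_crypts > het_threshold`.
#' @examples
#' detection_limit(0.008, 200)   # 2
#' detection_limit(0.008, 1000)  # 9
#' @export
detection_limit <- function(het_threshold, n_crypts) {
  if (het_threshold <= 0 || het_threshold >= 1)
    stop("het_threshold must be in (0, 1)")
  if (n_crypts < 1) stop("n_crypts must be >= 1")
  # small epsilon guards against binary representation of thresholds like 0.008
  as.integer(floor(het_threshold * n_crypts + 1e-9) + 1L)
}
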