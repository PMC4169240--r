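#' Substitution spectrum configuration
#'
#' Holds the empirical mtDNA point-mutation spectrum used by every simulator
#' in the package: the three substitution-class weights (G>A/C>T transitions,
#' T>C/A>G transitions, all eight transversions pooled) and the positional
#' weights of the four bases of the TCGA TaqI recognition site interrogated by
#' the random-mutation-capture assay.  Defaults are the empirical values for
#' ageing human colonic epithelium: 60% G>A/C>T, 24% T>C/A>G, 16%
#' transversions, and 63% of restriction-site changes at the third site base.
#'
#' @param weight_GA_CT Fraction of mutations that are G>A or C>T transitions.
#' @param weight_TC_AG Fraction that are T>C or A>G transitions.
#' @param weight_transversion Fraction that are transversions.
#' @param site_position_weights Length-4 numeric, weight of each base of the
#'   TCGA site (must sum to 1).
#' @return An object of class `"spectrum_config"`.
#' @examples
#' spectrum_config()
#' @export
spectrum_config <- function(weight_GA_CT = 0.60,
                            weight_TC_AG = 0.24,
                            weight_transversion = 0.16,
                            site_position_weights = c(0.123, 0.123, 0.630, 0.124)) {
  w <- c(GA_CT = weight_GA_CT, TC_AG = weight_TC_AG,
         transversion = weight_transversion)
  if (any(w < 0) || any(site_position_weights < 0))
    stop("spectrum weights must be non-negative")
  if (abs(sum(w) - 1) > 1e-12)
    stop("class weights must sum to 1 (got ", sum(w), ")")
  if (length(site_position_weights) != 4L)
    stop("site_position_weights must have length 4")
  if (abs(sum(site_position_weights) - 1) > 1e-12)
    stop("site position weights must sum to 1 (got ",
         sum(site_position_weights), ")")
  out <- list(class_weights = w,
              site_position_weights = site_position_weights)
  class(out) <- "spectrum_config"
  out
}

#' @export
print.spectrum_config <- function(x, ...) {
  cat("mtDNA substitution spectrum\n")
  cat(sprintf("  G>A/C>T: %.1f%%  T>C/A>G: %.1f%%  transversion: %.1f%%\n",
              100 * x$class_weights[1], 100 * x$class_weights[2],
              100 * x$class_weights[3]))
  cat(sprintf("  TCGA site position weights: %s\n",
              paste(sprintf("%.1f%%", 100 * x$site_position_weights),
                    collapse = " / ")))
  invisible(x)
}

.transition_partner <- c(A = "G", G = "A", C = "T", T = "C")

#' Classify a base substitution
#'
#' Maps a substitution to one of the three spectrum classes: `GA_CT`
#' (G>A or C>T transitions), `TC_AG` (T>C or A>G transitions), or
#' `transversion` (the remaining eight changes).  The classification is
#' strand-symmetric: a substitution and its reverse complement fall in the
#' same class.
#'
#' @param ref,alt Character vectors of single bases (A/C/G/T); recycled.
#' @return Character vector in `c("GA_CT", "TC_AG", "transversion")`.
#' @examples
#' classify_substitution("G", "A")
#' classify_substitution(c("T", "A"), c("C", "T"))
#' @export
classify_substitution <- function(ref, alt) {
  n <- max(length(ref), length(alt))
  ref <- toupper(rep_len(ref, n)); alt <- toupper(rep_len(alt, n))
  if (!all(ref %in% .mt_bases) || !all(alt %in% .mt_bases))
    stop("ref and alt must be single bases in A/C/G/T")
  if (any(ref == alt)) stop("ref and alt must differ")
  is_ts <- unname(.transition_partner[ref] == alt)
  unname(ifelse(!is_ts, "transversion",
                ifelse(ref %in% c("G", "C"), "GA_CT", "TC_AG")))
}

# Draw n substitutions at the TCGA recognition site, consistent with BOTH the
# configured class weights and the configured site-position weights.  The site
# reads T-C-G-A, so the reference base is fixed by the offset; transitions at
# offsets 2/3 are the GA_CT class and at offsets 1/4 the TC_AG class.  We draw
# the offset from the positional weights, then a transition with the
# offset-group's conditional probability  P(ts | offset in {2,3}) =
# w_GA_CT / (w2 + w3)  (resp. w_TC_AG / (w1 + w4)), else a transversion
# (uniform over the two possibilities).  Both configured marginals are then
# matched exactly in expectation.
.draw_site_mutations <- function(n, spectrum = spectrum_config()) {
  stopifnot(inherits(spectrum, "spectrum_config"))
  w <- spectrum$class_weights
  pw <- spectrum$site_position_weights
  site_ref <- c("T", "C", "G", "A")
  mass_gc <- pw[2] + pw[3]
  mass_ta <- pw[1] + pw[4]
  p_ts_gc <- if (mass_gc > 0) w[["GA_CT"]] / mass_gc else 0
  p_ts_ta <- if (mass_ta > 0) w[["TC_AG"]] / mass_ta else 0
  if (p_ts_gc > 1 + 1e-9 || p_ts_ta > 1 + 1e-9)
    stop("class and site-position weights are incompatible: required ",
         "conditional transition probability exceeds 1")
  if (n == 0L)
    return(data.frame(site_offset = integer(), ref = character(),
                      alt = character(), stringsAsFactors = FALSE))
  offset <- sample.int(4L, n, replace = TRUE, prob = pw)
  ref <- site_ref[offset]
  p_ts <- ifelse(offset %in% c(2L, 3L), min(p_ts_gc, 1), min(p_ts_ta, 1))
  is_ts <- runif(n) < p_ts
  alt <- character(n)
  alt[is_ts] <- .transition_partner[ref[is_ts]]
  if (any(!is_ts)) {
    tv <- lapply(ref[!is_ts], function(b) {
      others <- setdiff(.mt_bases, c(b, .transition_partner[[b]]))
      others[sample.int(2L, 1L)]
    })
    alt[!is_ts] <- unlist(tv)
  }
  data.frame(site_offset = offset, ref = ref, alt = alt,
             stringsAsFactors = FALSE)
}

# Draw n genome-wide substitutions against a reference: class from the
# spectrum, ref base uniform within the class pair, position uniform among
# reference positions carrying that base.  Optionally rejection-sample on the
# annotated consequence so the caller can control the pathogenic
# (non-synonymous) fraction; `target` is NULL (no constraint), "pathogenic"
# (non-synonymous coding) or "benign" (synonymous, RNA or non-coding).
.draw_genome_mutations <- function(n, spectrum, reference, genemap,
                                   target = NULL, max_tries = 200L) {
  if (n == 0L)
    return(data.frame(position = integer(), ref = character(),
                      alt = character(), pathogenic = logical(),
                      stringsAsFactors = FALSE))
  base_idx <- attr(reference, "base_index")
  if (is.null(base_idx)) {
    chars <- strsplit(as.character(reference), "")[[1L]]
    base_idx <- lapply(setNames(.mt_bases, .mt_bases), function(b) which(chars == b))
  }
  one <- function(tgt) {
    for (i in seq_len(max_tries)) {
      cls <- sample(names(spectrum$class_weights), 1L,
                    prob = spectrum$class_weights)
      refb <- switch(cls,
                     GA_CT = sample(c("G", "C"), 1L),
                     TC_AG = sample(c("T", "A"), 1L),
                     transversion = sample(.mt_bases, 1L))
      altb <- if (cls == "transversion") {
        sample(setdiff(.mt_bases, c(refb, .transition_partner[[refb]])), 1L)
      } else .transition_partner[[refb]]
      pos <- base_idx[[refb]][sample.int(length(base_idx[[refb]]), 1L)]
      ann <- annotate(pos, refb, altb, genemap = genemap,
                      reference = reference)
      patho <- identical(ann$consequence, "non-synonymous")
      if (is.null(tgt) ||
          (tgt == "pathogenic" && patho) ||
          (tgt == "benign" && !patho))
        return(list(position = pos, ref = refb, alt = altb, pathogenic = patho))
    }
    stop("could not draw a '", tgt, "' mutation in ", max_tries, " tries")
  }
  rows <- lapply(rep_len(list(target), n), function(t) one(t[[1]]))
  data.frame(position = vapply(rows, `[[`, 0L, "position"),
             ref = vapply(rows, `[[`, "", "ref"),
             alt = vapply(rows, `[[`, "", "alt"),
             pathogenic = vapply(rows, `[[`, TRUE, "pathogenic"),
             stringsAsFactors = FALSE)
}

#' Tally the substitution spectrum of confirmed mutants
#'
#' Computes the class proportions (G>A/C>T, T>C/A>G, transversion) and, when
#' site offsets are available, the positional proportions across the four
#' bases of the TCGA recognition site.  Indel records (multi-base or empty
#' alleles) are counted in a separate `indel` class and excluded from the
#' three-class substitution tally.
#'
#' @param x Either a `data.frame` of mutant records with columns `ref`, `alt`
#'   and optionally `site_offset`, or a list of [rmc_experiment()] objects
#'   whose confirmed mutants are pooled.
#' @return An object of class `"spectrum_tally"`: list with `n`, `class_prop`,
#'   `offset_prop` (or `NULL`), `n_indel` and `empty` flag.
#' @examples
#' spectrum_tally(data.frame(ref = c("G", "T"), alt = c("A", "C"),
#'                           site_offset = c(3, 1)))
#' @export
spectrum_tally <- function(x) {
  if (is.list(x) && !is.data.frame(x))
    x <- do.call(rbind, lapply(x, function(e) e$mutants))
  stopifnot(is.data.frame(x))
  if (is.null(x$ref) || is.null(x$alt))
    stop("mutant records need 'ref' and 'alt' columns")
  is_indel <- nchar(x$ref) != 1L | nchar(x$alt) != 1L |
    !(toupper(x$ref) %in% .mt_bases) | !(toupper(x$alt) %in% .mt_bases)
  subs <- x[!is_indel, , drop = FALSE]
  n <- nrow(subs)
  if (n == 0L) {
    out <- list(n = 0L, n_indel = sum(is_indel), class_prop = NULL,
                offset_prop = NULL, empty = TRUE)
    class(out) <- "spectrum_tally"
    return(out)
  }
  cls <- factor(classify_substitution(subs$ref, subs$alt),
                levels = c("GA_CT", "TC_AG", "transversion"))
  class_prop <- as.numeric(table(cls)) / n
  names(class_prop) <- levels(cls)
  stopifnot(abs(sum(class_prop) - 1) < 1e-12)
  offset_prop <- NULL
  if (!is.null(subs$site_offset) && all(!is.na(subs$site_offset))) {
    off <- as.integer(subs$site_offset)
    if (any(off < 1L | off > 4L)) stop("site_offset must be in 1..4")
    offset_prop <- as.numeric(table(factor(off, levels = 1:4))) / n
    names(offset_prop) <- paste0("offset", 1:4)
    stopifnot(abs(sum(offset_prop) - 1) < 1e-12)
  }
  out <- list(n = n, n_indel = sum(is_indel), class_prop = class_prop,
              offset_prop = offset_prop, empty = FALSE)
  class(out) <- "spectrum_tally"
  out
}

#' @export
print.spectrum_tally <- function(x, ...) {
  if (x$empty) {
    cat("spectrum tally: no substitution records",
        if (x$n_indel) sprintf(" (%d indels)", x$n_indel), "\n", sep = "")
    return(invisible(x))
  }
  cat(sprintf("spectrum tally of %d substitutions", x$n))
  if (x$n_indel) cat(sprintf(" (+%d indels, tallied separately)", x$n_indel))
  cat("\n")
  cat(sprintf("  G>A/C>T %.1f%% | T>C/A>G %.1f%% | transversion %.1f%%\n",
              100 * x$class_prop[1], 100 * x$class_prop[2],
              100 * x$class_prop[3]))
  if (!is.null(x$offset_prop))
    cat(sprintf("  TCGA site offsets 1-4: %s\n",
                paste(sprintf("%.1f%%", 100 * x$offset_prop), collapse = " / ")))
  invisible(x)
}
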