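#' Cohort simulation configuration
#'
#' Study-design parameters for [simulate_cohort()]: cohort size, age range,
#' crypts per biopsy, clonal-patch structure, and the germline / buccal
#' variant models.  A colonoscopic biopsy contains roughly 200 crypts, and
#' these are not all independent lineages: expanded mutations can span small
#' clusters of clonally related crypts, which is what makes a single expansion
#' visible above a tissue-level calling threshold.  Patch sizes are drawn as
#' `1 + Geometric(patch_geom_prob)` (mean 2 at the default); crypts within a
#' patch share one simulated lineage.
#'
#' Germline / early-embryonic variants are injected into both tissues of a
#' subject (about one per subject, 95% of them benign -- synonymous, RNA or
#' non-coding -- reflecting purifying selection in the germline).  The buccal
#' tissue is modelled as a variant table: the shared germline variants plus
#' rare independent low-level somatic variants.
#'
#' @param n_subjects Number of subjects (>= 0).
#' @param age_range Inclusive integer age range to draw subject ages from.
#' @param n_crypts Crypts per colonic biopsy (> 0).
#' @param patch_geom_prob Success probability of the geometric patch-size law;
#'   1 gives fully independent crypts.
#' @param germline_mean Poisson mean of germline variants per subject.
#' @param germline_nonsyn_fraction Fraction of germline variants that are
#'   non-synonymous (default 0.05).
#' @param germline_het_range Range the (log-uniform) germline heteroplasmy is
#'   drawn from.
#' @param buccal_somatic_mean Poisson mean of buccal-only somatic variants.
#' @param buccal_het_range Heteroplasmy range of buccal somatic variants.
#' @return Object of class `"cohort_config"`.
#' @export
cohort_config <- function(n_subjects = 16L,
                          age_range = c(17L, 78L),
                          n_crypts = 200L,
                          patch_geom_prob = 0.5,
                          germline_mean = 1,
                          germline_nonsyn_fraction = 0.05,
                          germline_het_range = c(0.01, 0.05),
                          buccal_somatic_mean = 0.5,
                          buccal_het_range = c(0.008, 0.03)) {
  if (n_subjects < 0) stop("n_subjects must be >= 0")
  if (n_crypts < 1) stop("n_crypts must be > 0")
  if (patch_geom_prob <= 0 || patch_geom_prob > 1)
    stop("patch_geom_prob must be in (0, 1]")
  if (germline_nonsyn_fraction < 0 || germline_nonsyn_fraction > 1)
    stop("germline_nonsyn_fraction must be in [0, 1]")
  if (length(age_range) != 2L || age_range[1] > age_range[2])
    stop("age_range must be c(lo, hi) with lo <= hi")
  out <- list(n_subjects = as.integer(n_subjects),
              age_range = as.integer(age_range),
              n_crypts = as.integer(n_crypts),
              patch_geom_prob = patch_geom_prob,
              germline_mean = germline_mean,
              germline_nonsyn_fraction = germline_nonsyn_fraction,
              germline_het_range = germline_het_range,
              buccal_somatic_mean = buccal_somatic_mean,
              buccal_het_range = buccal_het_range)
  class(out) <- "cohort_config"
  out
}

.draw_het <- function(n, range) {
  exp(runif(n, log(range[1]), log(range[2])))
}

# variant table row template (TSV interchange schema)
.variant_df <- function(position = integer(), ref = character(),
                        alt = character(), heteroplasmy = numeric(),
                        origin = character(), pathogenic = logical()) {
  data.frame(position = as.integer(position), ref = ref, alt = alt,
             heteroplasmy = heteroplasmy, origin = origin,
             pathogenic = pathogenic, stringsAsFactors = FALSE)
}

#' Simulate one subject (two tissues)
#'
#' Draws germline variants shared by colon and buccal tissue, simulates the
#' colonic crypt population (clonal patches of drifted crypt lineages) and the
#' buccal somatic variant list.  Usually called through [simulate_cohort()].
#'
#' @param subject_id Identifier.
#' @param age_years Subject age.
#' @param config A [cohort_config()].
#' @param params A [drift_params()].
#' @param reference,genemap Reference sequence and gene map.
#' @return Object of class `"sim_subject"` with elements `subject_id`,
#'   `age_years`, `n_crypts`, `crypts` (list of [crypt_state()]), `germline`
#'   and `buccal_somatic` variant tables.
#' @export
simulate_subject <- function(subject_id, age_years,
                             config = cohort_config(),
                             params = drift_params(),
                             reference = synthetic_rcrs(),
                             genemap = read_genemap()) {
  reference <- .index_reference(reference)
  n_g <- rpois(1L, config$germline_mean)
  germline <- if (n_g > 0L) {
    tgt <- ifelse(runif(n_g) < config$germline_nonsyn_fraction,
                  "pathogenic", "benign")
    g <- do.call(rbind, lapply(tgt, function(t)
      .draw_genome_mutations(1L, params$spectrum, reference, genemap,
                             target = t)))
    g$het_colon <- .draw_het(n_g, config$germline_het_range)
    g$het_buccal <- pmin(1, g$het_colon * exp(runif(n_g, -0.3, 0.3)))
    g
  } else {
    cbind(.variant_df()[, c("position", "ref", "alt", "pathogenic")],
          data.frame(het_colon = numeric(), het_buccal = numeric()))
  }

  # clonal patches: one drifted lineage per patch, replicated patch-size times
  crypts <- list(); i <- 0L
  while (length(crypts) < config$n_crypts) {
    i <- i + 1L
    size <- 1L + rgeom(1L, config$patch_geom_prob)
    size <- min(size, config$n_crypts - length(crypts))
    lineage <- simulate_crypt(age_years, params,
                              crypt_id = sprintf("%s_lineage%d", subject_id, i),
                              reference = reference, genemap = genemap)
    for (j in seq_len(size)) {
      cs <- lineage
      cs$crypt_id <- sprintf("%s_crypt%d", subject_id, length(crypts) + 1L)
      crypts[[length(crypts) + 1L]] <- cs
    }
  }

  n_b <- rpois(1L, config$buccal_somatic_mean)
  buccal <- if (n_b > 0L) {
    b <- .draw_genome_mutations(n_b, params$spectrum, reference, genemap)
    b$heteroplasmy <- .draw_het(n_b, config$buccal_het_range)
    b$origin <- "somatic"
    b[, c("position", "ref", "alt", "heteroplasmy", "origin", "pathogenic")]
  } else .variant_df()

  out <- list(subject_id = subject_id, age_years = age_years,
              n_crypts = config$n_crypts, crypts = crypts,
              germline = germline, buccal_somatic = buccal)
  class(out) <- "sim_subject"
  out
}

#' @export
print.sim_subject <- function(x, ...) {
  cat(sprintf("simulated subject '%s': age %d y, %d crypts, %d germline variant(s)\n",
              x$subject_id, as.integer(x$age_years), x$n_crypts,
              nrow(x$germline)))
  invisible(x)
}

#' Simulate a two-tissue cohort
#'
#' Each subject receives an age drawn uniformly from the configured range,
#' germline variants injected into both tissues, an independently drifted
#' colonic crypt population and a buccal variant list.  With a fixed seed the
#' cohort is bit-identical across runs.
#'
#' @param config A [cohort_config()].
#' @param params A [drift_params()].
#' @param seed Integer seed (optional; falls back to `params$seed`).
#' @param ages Optional explicit integer vector of subject ages (length
#'   `n_subjects`), overriding the uniform draw.
#' @param reference,genemap Reference sequence and gene map.
#' @return Object of class `"sim_cohort"`: list of [simulate_subject()]
#'   results.
#' @examples
#' coh <- simulate_cohort(cohort_config(n_subjects = 2, n_crypts = 5),
#'                        drift_params(copies_per_crypt = 50,
#'                                     events_per_year = 500), seed = 1)
#' variant_table(coh)
#' @export
simulate_cohort <- function(config = cohort_config(),
                            params = drift_params(),
                            seed = NULL, ages = NULL,
                            reference = synthetic_rcrs(),
                            genemap = read_genemap()) {
  stopifnot(inherits(config, "cohort_config"), inherits(params, "drift_params"))
  seed <- if (!is.null(seed)) seed else params$seed
  if (!is.null(seed)) set.seed(seed)
  reference <- .index_reference(reference)
  if (config$n_subjects == 0L) {
    out <- list(); class(out) <- "sim_cohort"; return(out)
  }
  if (is.null(ages))
    ages <- sample(seq(config$age_range[1], config$age_range[2]),
                   config$n_subjects, replace = TRUE)
  if (length(ages) != config$n_subjects)
    stop("ages must have length n_subjects")
  out <- lapply(seq_len(config$n_subjects), function(i)
    simulate_subject(sprintf("S%03d", i), ages[i], config, params,
                     reference = reference, genemap = genemap))
  class(out) <- "sim_cohort"
  out
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf("simulated cohort of %d subject(s)", length(x)))
  if (length(x))
    cat(sprintf(", ages %d-%d", min(vapply(x, `[[`, 0, "age_years")),
                max(vapply(x, `[[`, 0, "age_years"))))
  cat("\n")
  invisible(x)
}

#' Aggregate a subject's crypts to tissue-level variants
#'
#' The tissue-level heteroplasmy of each crypt-borne mutation is the mean over
#' all crypts of its within-crypt fraction `copies / N`, all crypts weighted
#' equally; mutations aggregating to 0 are dropped.  One homoplasmic crypt
#' among 200 therefore contributes tissue heteroplasmy 1/200 = 0.5%.
#'
#' @param subject A [simulate_subject()] result.
#' @return Variant `data.frame` (columns `position`, `ref`, `alt`,
#'   `heteroplasmy`, `origin = "somatic"`, `pathogenic`).
#' @export
aggregate_biopsy <- function(subject) {
  stopifnot(inherits(subject, "sim_subject"))
  if (length(subject$crypts) < 1L) stop("subject has no crypts")
  tabs <- lapply(subject$crypts, function(cs) {
    m <- cs$mutations
    if (!nrow(m)) return(NULL)
    m$h <- m$copies / cs$N
    m
  })
  tabs <- do.call(rbind, tabs)
  if (is.null(tabs) || !nrow(tabs)) return(.variant_df())
  key <- paste(tabs$position, tabs$ref, tabs$alt, sep = ":")
  h <- tapply(tabs$h, key, sum) / length(subject$crypts)
  first <- tabs[!duplicated(key), , drop = FALSE]
  first <- first[match(names(h), paste(first$position, first$ref, first$alt,
                                       sep = ":")), , drop = FALSE]
  out <- .variant_df(first$position, first$ref, first$alt, as.numeric(h),
                     "somatic", first$pathogenic)
  out <- out[out$heteroplasmy > 0, , drop = FALSE]
  out[order(out$position), , drop = FALSE]
}

#' Tissue-level variant lists of a simulated subject
#'
#' `colon_variants()` is the crypt aggregate plus the germline rows at their
#' colonic heteroplasmy; `buccal_variants()` is the germline rows at their
#' buccal heteroplasmy plus the buccal-only somatic variants.
#'
#' @param subject A [simulate_subject()] result.
#' @return Variant `data.frame` as in [aggregate_biopsy()], with `origin`
#'   ground truth (`"germline"` / `"somatic"`).
#' @export
colon_variants <- function(subject) {
  g <- subject$germline
  gd <- .variant_df(g$position, g$ref, g$alt, g$het_colon,
                    rep("germline", nrow(g)), g$pathogenic)
  out <- rbind(gd, aggregate_biopsy(subject))
  out[order(out$position), , drop = FALSE]
}

#' @rdname colon_variants
#' @export
buccal_variants <- function(subject) {
  g <- subject$germline
  gd <- .variant_df(g$position, g$ref, g$alt, g$het_buccal,
                    rep("germline", nrow(g)), g$pathogenic)
  out <- rbind(gd, subject$buccal_somatic)
  out[order(out$position), , drop = FALSE]
}

#' Combined variant table of a cohort
#'
#' Stacks every subject's two tissue variant lists into the package's TSV
#' interchange schema: `subject_id`, `age_years`, `tissue`, `position`,
#' `ref`, `alt`, `heteroplasmy`, `origin`.
#'
#' @param cohort A [simulate_cohort()] result.
#' @return `data.frame` in the interchange schema.
#' @export
variant_table <- function(cohort) {
  stopifnot(inherits(cohort, "sim_cohort"))
  rows <- lapply(cohort, function(s) {
    cv <- colon_variants(s); bv <- buccal_variants(s)
    rbind(
      if (nrow(cv)) cbind(data.frame(subject_id = s$subject_id,
                                     age_years = s$age_years,
                                     tissue = "colon",
                                     stringsAsFactors = FALSE),
                          cv[, c("position", "ref", "alt", "heteroplasmy",
                                 "origin")]),
      if (nrow(bv)) cbind(data.frame(subject_id = s$subject_id,
                                     age_years = s$age_years,
                                     tissue = "buccal",
                                     stringsAsFactors = FALSE),
                          bv[, c("position", "ref", "alt", "heteroplasmy",
                                 "origin")]))
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(subject_id = character(), age_years = numeric(),
                      tissue = character(), position = integer(),
                      ref = character(), alt = character(),
                      heteroplasmy = numeric(), origin = character(),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Fraction of COX-deficient crypts in a subject
#'
#' @param subject A [simulate_subject()] result.
#' @param biochem_threshold Passed to [mark_cox_deficient()].
#' @return Fraction in `[0, 1]`.
#' @export
cox_deficient_fraction <- function(subject, biochem_threshold = 0.85) {
  stopifnot(inherits(subject, "sim_subject"))
  mean(vapply(subject$crypts, mark_cox_deficient, TRUE,
              biochem_threshold = biochem_threshold))
}
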