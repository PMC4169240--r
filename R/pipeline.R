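#' End-to-end pipeline configuration
#'
#' Bundles every stage's parameters for [run_pipeline()], mirroring the study
#' design: an RMC arm (low-level mutation frequency across the age range) and
#' an NGS arm (whole-mtDNA sequencing of the youngest and oldest subjects,
#' paired colon/buccal tissues, plasmid-calibrated filtering, partitioning,
#' annotation and the group contrasts).
#'
#' @param seed Integer seed; mandatory, drives every stage.
#' @param n_young,n_old NGS group sizes (default 8 and 8).
#' @param young_age_range,old_age_range Inclusive age ranges of the two NGS
#'   groups.
#' @param cohort A [cohort_config()] template (its `n_subjects` and
#'   `age_range` are overridden per group).
#' @param drift A [drift_params()].
#' @param pileup A [pileup_params()].
#' @param filter A [filter_config()]; its `het_threshold` acts as the
#'   override cap on the control-derived threshold.
#' @param mb_per_subject Megabases sequenced per subject for per-Mb
#'   frequencies (study average: 35).
#' @param n_rmc_subjects Subjects in the RMC arm (ages drawn over the full
#'   range).
#' @param rmc_true_freq True low-level mutation frequency per bp in the RMC
#'   arm.
#' @param rmc_wells Wells per RMC subject (2,500 copies, 10,000 target bases
#'   each).
#' @param out_dir Optional directory; when given, per-stage TSV outputs are
#'   written there.
#' @return Object of class `"pipeline_config"`.
#' @export
pipeline_config <- function(seed,
                            n_young = 8L, n_old = 8L,
                            young_age_range = c(17L, 25L),
                            old_age_range = c(71L, 78L),
                            cohort = cohort_config(),
                            drift = drift_params(),
                            pileup = pileup_params(),
                            filter = filter_config(),
                            mb_per_subject = 35,
                            n_rmc_subjects = 40L,
                            rmc_true_freq = 4e-6,
                            rmc_wells = 100L,
                            out_dir = NULL) {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory")
  stopifnot(inherits(cohort, "cohort_config"), inherits(drift, "drift_params"),
            inherits(pileup, "pileup_params"), inherits(filter, "filter_config"))
  out <- list(seed = as.integer(seed), n_young = as.integer(n_young),
              n_old = as.integer(n_old),
              young_age_range = young_age_range,
              old_age_range = old_age_range,
              cohort = cohort, drift = drift, pileup = pileup,
              filter = filter, mb_per_subject = mb_per_subject,
              n_rmc_subjects = as.integer(n_rmc_subjects),
              rmc_true_freq = rmc_true_freq, rmc_wells = as.integer(rmc_wells),
              out_dir = out_dir)
  class(out) <- "pipeline_config"
  out
}

# call + filter one tissue's pileup, back to a variant data.frame
.call_tissue <- function(variants, config, reference, threshold_cfg) {
  pl <- simulate_pileup(variants, config$pileup, reference)
  calls <- suppressMessages(call_sites(pl))
  res <- apply_filters(calls, threshold_cfg)
  list(variants = data.frame(position = res$passed$position,
                             ref = res$passed$ref, alt = res$passed$alt,
                             heteroplasmy = res$passed$heteroplasmy,
                             stringsAsFactors = FALSE),
       counts = res$counts, n_calls = nrow(calls))
}

#' Run the full simulated study
#'
#' Deterministic given the seed.  Stages: (1) RMC arm -- per-subject
#' random-mutation-capture experiments, frequency estimates, age correlation
#' and decade-binned ANOVA; (2) plasmid control -- noise calibration of the
#' heteroplasmy threshold; (3) NGS arm -- young and old cohorts simulated
#' down to crypt level, per-tissue pileups, the filter cascade, tissue
#' partitioning, annotation; (4) contrasts -- old-vs-young total and somatic
#' mutation frequencies, the purifying-selection Fisher test, the COX
#' deficiency age correlation, recurrence screen and spectrum tally.
#'
#' @param config A [pipeline_config()].
#' @return Object of class `"mt_pipeline"`; see the elements `rmc`,
#'   `calibration`, `subjects`, `stats` and `filter_log`.
#' @examples
#' \donttest{
#' res <- run_pipeline(pipeline_config(seed = 1, n_young = 2, n_old = 2,
#'                                     cohort = cohort_config(n_crypts = 20),
#'                                     n_rmc_subjects = 6))
#' }
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  set.seed(config$seed)
  reference <- .index_reference(synthetic_rcrs())
  genemap <- read_genemap()
  stage <- "rmc"
  out <- try({
    ## --- RMC arm -----------------------------------------------------------
    rmc <- NULL
    if (config$n_rmc_subjects > 0L) {
      ages <- sample(17:77, config$n_rmc_subjects, replace = TRUE)
      exps <- lapply(seq_len(config$n_rmc_subjects), function(i) {
        ex <- simulate_rmc_experiment(config$rmc_true_freq, config$rmc_wells,
                                      spectrum = config$drift$spectrum,
                                      subject_id = sprintf("R%03d", i))
        ex$age_years <- ages[i]
        ex
      })
      freqs <- vapply(exps, function(e) rmc_frequency(e)$frequency, 0)
      rmc_cor <- pearson(ages, freqs)
      bins <- bin_by_decade(ages, freqs)
      bins_ok <- sum(vapply(bins, length, 0L) >= 2L) >= 2L
      rmc_anova <- if (bins_ok)
        one_way_anova(bins[vapply(bins, length, 0L) >= 2L]) else NULL
      rmc <- list(experiments = exps, frequencies = freqs, ages = ages,
                  age_correlation = rmc_cor, decade_anova = rmc_anova,
                  spectrum = spectrum_tally(exps))
    }

    ## --- noise calibration -------------------------------------------------
    stage <- "calibration"
    # the control-derived threshold is reported as QC evidence; calling uses
    # the configured (conservative) threshold, which must not undercut it
    control <- simulate_plasmid_control(config$pileup, reference)
    calib <- calibrate_noise(suppressMessages(call_sites(control)),
                             config$filter)
    if (config$filter$het_threshold < calib$max_control_fraction)
      stop("configured het_threshold lies below the control noise ceiling")
    threshold_cfg <- config$filter

    ## --- NGS arm -----------------------------------------------------------
    stage <- "ngs"
    young_cfg <- config$cohort
    young_cfg$n_subjects <- config$n_young
    young_cfg$age_range <- as.integer(config$young_age_range)
    old_cfg <- config$cohort
    old_cfg$n_subjects <- config$n_old
    old_cfg$age_range <- as.integer(config$old_age_range)
    young <- simulate_cohort(young_cfg, config$drift, reference = reference,
                             genemap = genemap)
    old <- simulate_cohort(old_cfg, config$drift, reference = reference,
                           genemap = genemap)
    for (i in seq_along(old)) old[[i]]$subject_id <- sprintf("O%03d", i)
    cohort <- c(young, old)
    class(cohort) <- "sim_cohort"
    group <- rep(c("young", "old"), c(length(young), length(old)))

    filter_counts <- setNames(integer(length(.mt_filter_reasons)),
                              .mt_filter_reasons)
    subjects <- vector("list", length(cohort))
    for (i in seq_along(cohort)) {
      s <- cohort[[i]]
      col <- .call_tissue(colon_variants(s), config, reference, threshold_cfg)
      buc <- .call_tissue(buccal_variants(s), config, reference, threshold_cfg)
      filter_counts <- filter_counts + col$counts + buc$counts
      part <- partition_tissues(col$variants, buc$variants)
      n_total <- nrow(col$variants)
      n_germ <- nrow(part$germline)
      subjects[[i]] <- list(
        subject_id = s$subject_id, age_years = s$age_years, group = group[i],
        colon = col$variants, buccal = buc$variants, partition = part,
        total_freq = n_total / config$mb_per_subject,
        somatic_freq = somatic_frequency(n_total, n_germ,
                                         config$mb_per_subject),
        germline_freq = n_germ / config$mb_per_subject,
        cox_fraction = cox_deficient_fraction(s))
    }

    ## --- contrasts ---------------------------------------------------------
    stage <- "stats"
    gv <- function(field) vapply(subjects, `[[`, 0, field)
    is_old <- group == "old"
    # degenerate groups (e.g. all-zero frequencies in a tiny cohort) yield
    # no comparison rather than aborting the run
    safe_cmp <- function(a, b) tryCatch(group_comparison(a, b),
                                        error = function(e) NULL)
    total_cmp <- safe_cmp(gv("total_freq")[is_old],
                          gv("total_freq")[!is_old])
    somatic_cmp <- safe_cmp(gv("somatic_freq")[is_old],
                            gv("somatic_freq")[!is_old])
    germline_cmp <- safe_cmp(gv("germline_freq")[is_old],
                             gv("germline_freq")[!is_old])

    germ_all <- do.call(rbind, lapply(subjects, function(x) x$partition$germline))
    som_all <- do.call(rbind, lapply(subjects, function(x)
      x$partition$colon_somatic))
    sel <- NULL
    if (!is.null(germ_all) && !is.null(som_all) &&
        nrow(germ_all) && nrow(som_all)) {
      ga <- annotate_variants(germ_all, genemap, reference)
      sa <- annotate_variants(som_all, genemap, reference)
      gc <- ga[ga$region_class == "protein", , drop = FALSE]
      sc <- sa[sa$region_class == "protein", , drop = FALSE]
      sel <- selection_test(
        c(sum(gc$consequence == "synonymous" | gc$known_polymorphism),
          sum(gc$consequence == "non-synonymous" & !gc$known_polymorphism)),
        c(sum(sc$consequence == "synonymous" | sc$known_polymorphism),
          sum(sc$consequence == "non-synonymous" & !sc$known_polymorphism)))
    }

    ages_ngs <- gv("age_years")
    cox_cor <- if (var(gv("cox_fraction")) > 0)
      pearson(ages_ngs, gv("cox_fraction")) else NULL

    colon_tab <- do.call(rbind, lapply(subjects, function(x)
      if (nrow(x$colon)) cbind(data.frame(subject_id = x$subject_id,
                                          stringsAsFactors = FALSE), x$colon)))
    recur <- if (!is.null(colon_tab) && length(unique(colon_tab$subject_id)) >= 2L)
      recurrent_across_subjects(colon_tab, genemap = genemap) else NULL
    spec_tally <- if (!is.null(colon_tab) && nrow(colon_tab))
      spectrum_tally(colon_tab) else NULL

    res <- list(config = config, rmc = rmc, calibration = calib,
                subjects = subjects,
                truth = cohort,
                stats = list(total = total_cmp, somatic = somatic_cmp,
                             germline = germline_cmp,
                             selection = sel, cox_age_correlation = cox_cor,
                             recurrence = recur, spectrum = spec_tally),
                filter_log = filter_counts)
    class(res) <- "mt_pipeline"
    res
  }, silent = TRUE)
  if (inherits(out, "try-error"))
    stop("pipeline failed at stage '", stage, "': ",
         attr(out, "condition")$message)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    tabs <- lapply(out$subjects, function(x) {
      rbind(
        if (nrow(x$colon)) cbind(data.frame(subject_id = x$subject_id,
                                            age_years = x$age_years,
                                            tissue = "colon"), x$colon),
        if (nrow(x$buccal)) cbind(data.frame(subject_id = x$subject_id,
                                             age_years = x$age_years,
                                             tissue = "buccal"), x$buccal))
    })
    tab <- do.call(rbind, tabs)
    if (!is.null(tab)) {
      tab$origin <- NA_character_
      write_variant_table(tab, file.path(config$out_dir,
                                         "called_variants.tsv"))
    }
    if (!is.null(out$rmc))
      write_rmc_table(out$rmc$experiments,
                      file.path(config$out_dir, "rmc_wells.tsv"))
  }
  out
}

#' @export
print.mt_pipeline <- function(x, ...) {
  cat("simulated mtDNA ageing study\n")
  cat(sprintf(paste0("  seed %d | %d young + %d old NGS subjects | ",
                     "threshold > %.2f%% (control noise max %.2f%%)\n"),
              x$config$seed, x$config$n_young, x$config$n_old,
              100 * x$config$filter$het_threshold,
              100 * x$calibration$max_control_fraction))
  if (!is.null(x$rmc)) {
    cat(sprintf("  RMC: %d subjects, frequency x age r = %.3f (p = %.3g)",
                length(x$rmc$frequencies), x$rmc$age_correlation$r,
                x$rmc$age_correlation$p.value))
    if (!is.null(x$rmc$decade_anova))
      cat(sprintf("; decade ANOVA p = %.3g", x$rmc$decade_anova$p.value))
    cat("\n")
  }
  cat("  NGS old vs young per-Mb frequency:\n")
  for (nm in c("total", "somatic", "germline")) {
    cat(sprintf("    %-9s", paste0(nm, ":")))
    if (is.null(x$stats[[nm]])) cat("(degenerate groups, no test)\n")
    else print(x$stats[[nm]])
  }
  if (!is.null(x$stats$selection)) {
    cat(sprintf("  purifying-selection Fisher p = %.4g\n",
                x$stats$selection$p.value))
  }
  if (!is.null(x$stats$cox_age_correlation))
    cat(sprintf("  %% COX-deficient crypts x age: r = %.3f (p = %.3g)\n",
                x$stats$cox_age_correlation$r,
                x$stats$cox_age_correlation$p.value))
  cat("  filter failures: ",
      paste(sprintf("%s=%d", names(x$filter_log), x$filter_log),
            collapse = " "), "\n")
  invisible(x)
}
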