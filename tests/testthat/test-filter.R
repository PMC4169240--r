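test_that("candidate calls report combined-strand heteroplasmy", {
  pp <- pileup_params(coverage_per_site = 1000, error_rate = 0)
  pl <- simulate_pileup(NULL, pp, ref_fix, seed = 51)
  expect_identical(nrow(call_sites(pl)), 0L)  # no alt reads, no calls

  pos <- 777L
  rb <- ref_base(ref_fix, pos)
  alt <- setdiff(c("A", "C", "G", "T"), rb)[1]
  row <- pl[pl$position == pos, ]
  row[[paste0(alt, "_fwd")]] <- 5L
  row[[paste0(alt, "_rev")]] <- 5L
  row[[paste0(rb, "_fwd")]] <- 495L
  row[[paste0(rb, "_rev")]] <- 495L
  calls <- call_sites(row)
  expect_identical(nrow(calls), 1L)
  expect_equal(calls$heteroplasmy, 0.01)
})

test_that("a planted variant is called once at its heteroplasmy", {
  pos <- 3000L
  rb <- ref_base(ref_fix, pos)
  alt <- setdiff(c("A", "C", "G", "T"), rb)[1]
  v <- data.frame(position = pos, ref = rb, alt = alt, heteroplasmy = 0.05)
  pp <- pileup_params(coverage_per_site = 2000, error_rate = 0)
  calls <- call_sites(simulate_pileup(v, pp, ref_fix, seed = 52))
  expect_identical(nrow(calls), 1L)
  expect_identical(calls$position, pos)
  expect_identical(calls$alt, alt)
  expect_lt(abs(calls$heteroplasmy - 0.05), 3 * sqrt(0.05 * 0.95 / 2000))
})

test_that("strand concordance uses fractions with a fold cap", {
  expect_true(strand_concordant(10, 1000, 10, 1000, 3))
  expect_false(strand_concordant(0, 1000, 9, 1000, 3))
  expect_false(strand_concordant(10, 1000, 35, 1000, 3))   # 3.5-fold
  expect_true(strand_concordant(10, 1000, 30, 1000, 3))    # exactly 3-fold
  expect_false(strand_concordant(5, 0, 5, 100, 3))         # dead strand
})

test_that("the cascade rejects with every applicable reason", {
  cfg <- filter_config()
  ok <- clean_call()
  expect_identical(nrow(apply_filters(ok, cfg)$rejected), 0L)

  black <- clean_call(750L)
  res <- apply_filters(black, cfg)
  expect_identical(res$rejected$reasons, "blacklist")
  expect_identical(apply_filters(clean_call(3905L), cfg)$rejected$reasons,
                   "blacklist")

  # boundary: h exactly at the threshold fails (strict >)
  border <- clean_call(h = 0.008)
  expect_match(apply_filters(border, cfg)$rejected$reasons, "threshold")
  above <- clean_call(h = 0.0085)
  expect_identical(nrow(apply_filters(above, cfg)$rejected), 0L)

  # a maximally bad call accumulates all reasons at once
  bad <- data.frame(position = 750L, ref = "AC", alt = "A", fwd_alt = 2L,
                    rev_alt = 0L, fwd_total = 100L, rev_total = 100L,
                    heteroplasmy = 0.002, mean_quality = 10,
                    stringsAsFactors = FALSE)
  reasons <- strsplit(apply_filters(bad, cfg)$rejected$reasons, ",")[[1]]
  expect_setequal(reasons, c("quality", "strand", "min_reads", "coverage",
                             "blacklist", "threshold", "indel"))
})

test_that("passed and rejected partition the input and filtering is idempotent", {
  set.seed(53)
  n <- 200L
  pos <- sample(16569L, n)
  rb <- ref_base(ref_fix, pos)
  calls <- data.frame(
    position = pos, ref = rb,
    alt = vapply(rb, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1), ""),
    fwd_alt = rpois(n, 4), rev_alt = rpois(n, 4),
    fwd_total = rpois(n, 500), rev_total = rpois(n, 500),
    mean_quality = rnorm(n, 22, 4), stringsAsFactors = FALSE)
  calls$heteroplasmy <- (calls$fwd_alt + calls$rev_alt) /
    pmax(1, calls$fwd_total + calls$rev_total)
  cfg <- filter_config()
  res <- apply_filters(calls, cfg)
  expect_identical(nrow(res$passed) + nrow(res$rejected), n)
  expect_true(all(nchar(res$rejected$reasons) > 0))
  again <- apply_filters(res$passed, cfg)
  expect_identical(again$passed, res$passed)
  expect_identical(nrow(again$rejected), 0L)
})

test_that("tightening any single threshold never grows the passed set", {
  set.seed(54)
  n <- 300L
  pos <- sample(16569L, n)
  rb <- ref_base(ref_fix, pos)
  calls <- data.frame(
    position = pos, ref = rb,
    alt = vapply(rb, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1), ""),
    fwd_alt = rpois(n, 5), rev_alt = rpois(n, 5),
    fwd_total = rpois(n, 700), rev_total = rpois(n, 700),
    mean_quality = rnorm(n, 25, 5), stringsAsFactors = FALSE)
  calls$heteroplasmy <- (calls$fwd_alt + calls$rev_alt) /
    pmax(1, calls$fwd_total + calls$rev_total)
  base_cfg <- filter_config(min_quality = 20, max_strand_fold = 4,
                            min_alt_reads = 2, min_coverage = 500,
                            het_threshold = 0.004)
  base_keys <- with(apply_filters(calls, base_cfg)$passed,
                    paste(position, alt))
  tighter <- list(
    filter_config(min_quality = 26, max_strand_fold = 4, min_alt_reads = 2,
                  min_coverage = 500, het_threshold = 0.004),
    filter_config(min_quality = 20, max_strand_fold = 2, min_alt_reads = 2,
                  min_coverage = 500, het_threshold = 0.004),
    filter_config(min_quality = 20, max_strand_fold = 4, min_alt_reads = 6,
                  min_coverage = 500, het_threshold = 0.004),
    filter_config(min_quality = 20, max_strand_fold = 4, min_alt_reads = 2,
                  min_coverage = 900, het_threshold = 0.004),
    filter_config(min_quality = 20, max_strand_fold = 4, min_alt_reads = 2,
                  min_coverage = 500, het_threshold = 0.009))
  for (cfg in tighter) {
    keys <- with(apply_filters(calls, cfg)$passed, paste(position, alt))
    expect_true(all(keys %in% base_keys))
  }
})

test_that("noise calibration reconstructs the conservative threshold", {
  # floor case: nothing survives the cascade
  clean <- clean_call()[0, ]
  cal0 <- calibrate_noise(clean)
  expect_equal(cal0$max_control_fraction, 0)
  expect_equal(cal0$derived_threshold, 0.001)

  # a 0.65% noise ceiling yields the adopted 0.8% threshold
  noisy <- clean_call(h = 0.0065)
  cal <- calibrate_noise(noisy)
  expect_equal(cal$max_control_fraction, 0.0065)
  expect_equal(cal$derived_threshold, 0.008)
  expect_gte(cal$derived_threshold, cal$max_control_fraction)

  # the override can only pin the threshold downwards, never below the noise
  expect_equal(calibrate_noise(noisy, override = 0.008)$derived_threshold,
               0.008)
  expect_error(calibrate_noise(noisy, override = 0.005), "below the noise")
  expect_error(calibrate_noise(NULL), "calibration impossible")
})

test_that("pure sequencing error never survives the full cascade", {
  pp <- pileup_params()  # 2000x, 0.12% error
  for (seed in 61:65) {
    ctrl <- simulate_plasmid_control(pp, ref_fix, seed = seed)
    res <- apply_filters(call_sites(ctrl), filter_config())
    expect_identical(nrow(res$passed), 0L)
  }
})

test_that("a 2% variant on balanced strands is always recovered", {
  pos <- 8000L
  rb <- ref_base(ref_fix, pos)
  alt <- setdiff(c("A", "C", "G", "T"), rb)[1]
  v <- data.frame(position = pos, ref = rb, alt = alt, heteroplasmy = 0.02)
  pp <- pileup_params()
  for (seed in 71:75) {
    pl <- simulate_pileup(v, pp, ref_fix, seed = seed)
    passed <- apply_filters(call_sites(pl), filter_config())$passed
    expect_true(any(passed$position == pos & passed$alt == alt))
  }
})

test_that("the detection limit counts whole clonal crypts", {
  expect_identical(detection_limit(0.008, 200), 2L)
  expect_identical(detection_limit(0.5, 2), 2L)
  expect_identical(detection_limit(0.008, 1000), 9L)
  expect_error(detection_limit(0, 200), "\\(0, 1\\)")
})
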