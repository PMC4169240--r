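test_that("an empty cohort and deterministic replay behave as configured", {
  empty <- simulate_cohort(cohort_config(n_subjects = 0), fast_drift())
  expect_length(empty, 0L)

  cfg <- cohort_config(n_subjects = 3, n_crypts = 10, germline_mean = 2)
  a <- simulate_cohort(cfg, fast_drift(), seed = 21,
                       reference = ref_fix, genemap = gm_fix)
  b <- simulate_cohort(cfg, fast_drift(), seed = 21,
                       reference = ref_fix, genemap = gm_fix)
  expect_identical(variant_table(a), variant_table(b))
})

test_that("germline variants appear in both tissues at positive heteroplasmy", {
  cfg <- cohort_config(n_subjects = 6, n_crypts = 2, germline_mean = 3)
  coh <- simulate_cohort(cfg, fast_drift(), seed = 22,
                         reference = ref_fix, genemap = gm_fix)
  tab <- variant_table(coh)
  germ <- tab[tab$origin == "germline", ]
  key <- paste(germ$subject_id, germ$position, germ$ref, germ$alt)
  for (k in unique(key)) {
    rows <- germ[key == k, ]
    expect_setequal(rows$tissue, c("colon", "buccal"))
    expect_true(all(rows$heteroplasmy > 0))
  }
})

test_that("germline synonymous/non-synonymous ratio matches the configured fraction", {
  cfg <- cohort_config(n_subjects = 200, n_crypts = 1, germline_mean = 1.5,
                       germline_nonsyn_fraction = 0.05)
  p <- drift_params(copies_per_crypt = 10, events_per_year = 0)
  coh <- simulate_cohort(cfg, p, seed = 23,
                         reference = ref_fix, genemap = gm_fix)
  germ <- do.call(rbind, lapply(coh, `[[`, "germline"))
  n <- nrow(germ)
  expect_gt(n, 100)
  phat <- mean(germ$pathogenic)
  expect_lt(abs(phat - 0.05), qnorm(0.975) * sqrt(0.05 * 0.95 / n) + 1e-9)
})

test_that("biopsy aggregation averages crypts with equal weight", {
  N <- 100L
  pos <- 500L
  mut <- data.frame(position = pos, ref = ref_base(ref_fix, pos), alt = "A",
                    pathogenic = FALSE, copies = N)
  if (mut$ref == "A") mut$alt <- "G"
  homo <- crypt_state("h", N, mut)
  wt <- crypt_state("w", N)

  one_in_200 <- manual_subject(c(list(homo), rep(list(wt), 199)))
  agg <- aggregate_biopsy(one_in_200)
  expect_equal(agg$heteroplasmy, 0.005)

  # two homoplasmic crypts among 200 cross the 0.8% detection threshold
  two_in_200 <- manual_subject(c(list(homo, homo), rep(list(wt), 198)))
  agg2 <- aggregate_biopsy(two_in_200)
  expect_equal(agg2$heteroplasmy, 0.01)
  expect_gt(agg2$heteroplasmy, filter_config()$het_threshold)
  expect_identical(detection_limit(0.008, 200), 2L)

  all_wt <- manual_subject(rep(list(wt), 200))
  expect_identical(nrow(aggregate_biopsy(all_wt)), 0L)
})

test_that("tissue variant lists combine germline and tissue-private variants", {
  N <- 100L
  pos <- 900L
  rb <- ref_base(ref_fix, pos)
  alt <- setdiff(c("A", "C", "G", "T"), rb)[1]
  cry <- crypt_state("c", N, data.frame(position = pos, ref = rb, alt = alt,
                                        pathogenic = FALSE, copies = 50L))
  germ <- data.frame(position = 42L, ref = ref_base(ref_fix, 42),
                     alt = setdiff(c("A", "C", "G", "T"),
                                   ref_base(ref_fix, 42))[1],
                     pathogenic = FALSE, het_colon = 0.02, het_buccal = 0.015)
  s <- manual_subject(list(cry), germline = germ)
  cv <- colon_variants(s)
  expect_setequal(cv$origin, c("germline", "somatic"))
  expect_equal(cv$heteroplasmy[cv$origin == "germline"], 0.02)
  expect_equal(cv$heteroplasmy[cv$origin == "somatic"], 0.5)
  bv <- buccal_variants(s)
  expect_identical(bv$origin, "germline")
  expect_equal(bv$heteroplasmy, 0.015)
})

test_that("clonal patches replicate whole lineages", {
  cfg <- cohort_config(n_subjects = 1, n_crypts = 50, patch_geom_prob = 0.2,
                       germline_mean = 0, buccal_somatic_mean = 0)
  p <- drift_params(copies_per_crypt = 50, events_per_year = 20000,
                    mut_rate_per_copy_per_event = 5e-4)
  coh <- simulate_cohort(cfg, p, seed = 24, ages = 60,
                         reference = ref_fix, genemap = gm_fix)
  s <- coh[[1]]
  expect_length(s$crypts, 50L)
  # crypts from one patch share identical mutation tables
  muts <- lapply(s$crypts, function(cs) cs$mutations[order(cs$mutations$position), ])
  sig <- vapply(muts, function(m) paste(m$position, m$copies, collapse = ";"), "")
  expect_lt(length(unique(sig[sig != ""])), sum(sig != "") + 1)
})
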