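test_that("fixed and lost mutations are absorbing states", {
  p <- drift_params(copies_per_crypt = 100, mut_rate_per_copy_per_event = 0)
  fixed <- crypt_state("c1", 100, data.frame(
    position = 10L, ref = ref_base(ref_fix, 10), alt = "A",
    pathogenic = FALSE, copies = 100L))
  set.seed(1)
  s <- fixed
  for (i in 1:50) s <- step_moran(s, p, ref_fix, gm_fix)
  expect_identical(s$mutations$copies, 100L)

  # a pruned (count-0) mutation never reappears at zero mutation rate
  lost <- crypt_state("c2", 100, data.frame(
    position = 10L, ref = ref_base(ref_fix, 10), alt = "A",
    pathogenic = FALSE, copies = 0L))
  expect_identical(nrow(lost$mutations), 0L)
  s <- lost
  for (i in 1:50) s <- step_moran(s, p, ref_fix, gm_fix)
  expect_identical(nrow(s$mutations), 0L)
})

test_that("copy counts always stay within 0..N", {
  set.seed(2)
  k <- mtclone:::moran_locus_cpp(rep(25L, 500), 50L, 5000)
  expect_true(all(k >= 0L & k <= 50L))
  expect_error(crypt_state("x", 10, data.frame(
    position = 1L, ref = "A", alt = "G", pathogenic = FALSE, copies = 11L)),
    "exceed N")
})

test_that("neutral drift is a martingale in heteroplasmy", {
  set.seed(3)
  n_rep <- 10000L
  for (steps in c(200, 1000)) {
    k <- mtclone:::moran_locus_cpp(rep(50L, n_rep), 100L, steps)
    h <- k / 100
    se <- sd(h) / sqrt(n_rep)
    expect_lt(abs(mean(h) - 0.5), 3 * se)
  }
})

test_that("fixation probability equals the initial heteroplasmy", {
  set.seed(4)
  n_rep <- 10000L
  for (h0 in c(0.1, 0.5)) {
    k0 <- as.integer(h0 * 50)
    k <- mtclone:::moran_locus_cpp(rep(k0, n_rep), 50L, 1e7)
    expect_true(all(k %in% c(0L, 50L)))  # absorbed by this horizon
    fixed <- mean(k == 50L)
    expect_lt(abs(fixed - h0), 3 * sqrt(h0 * (1 - h0) / n_rep))
  }
})

test_that("crypts start mutation-free and stay so without mutation input", {
  p0 <- drift_params(copies_per_crypt = 100, events_per_year = 1000,
                     mut_rate_per_copy_per_event = 0)
  expect_identical(nrow(simulate_crypt(0, p0, seed = 1)$mutations), 0L)
  expect_identical(nrow(simulate_crypt(50, p0, seed = 1)$mutations), 0L)
})

test_that("identical seeds give bit-identical crypts", {
  p <- drift_params(copies_per_crypt = 100, events_per_year = 5000,
                    mut_rate_per_copy_per_event = 1e-3)
  a <- simulate_crypt(40, p, seed = 99, reference = ref_fix, genemap = gm_fix)
  b <- simulate_crypt(40, p, seed = 99, reference = ref_fix, genemap = gm_fix)
  expect_identical(a$mutations, b$mutations)
})

test_that("high-heteroplasmy clonal expansions become more common with age", {
  set.seed(5)
  p <- drift_params()
  frac_high <- vapply(c(20, 40, 60, 80), function(age) {
    hits <- vapply(seq_len(1000), function(i) {
      counts <- mtclone:::moran_crypt_cpp(p$events_per_year * age, p$N,
                                          p$mut_rate)$counts
      any(counts / p$N > 0.85)
    }, TRUE)
    mean(hits)
  }, 0)
  expect_true(all(diff(frac_high) >= 0))
  expect_gt(frac_high[4], frac_high[1])
})

test_that("COX deficiency requires an expanded pathogenic mutation", {
  patho_fixed <- crypt_state("c", 100, data.frame(
    position = 10L, ref = ref_base(ref_fix, 10), alt = "A",
    pathogenic = TRUE, copies = 100L))
  expect_true(mark_cox_deficient(patho_fixed, 0.85))
  syn_fixed <- crypt_state("c", 100, data.frame(
    position = 10L, ref = ref_base(ref_fix, 10), alt = "A",
    pathogenic = FALSE, copies = 100L))
  expect_false(mark_cox_deficient(syn_fixed, 0.85))
  patho_low <- crypt_state("c", 100, data.frame(
    position = 10L, ref = ref_base(ref_fix, 10), alt = "A",
    pathogenic = TRUE, copies = 50L))
  expect_false(mark_cox_deficient(patho_low, 0.85))
  expect_error(mark_cox_deficient(patho_fixed, 0), "in \\(0, 1\\]")
})

test_that("step_moran injects new mutations at one copy", {
  p <- drift_params(copies_per_crypt = 100, mut_rate_per_copy_per_event = 1)
  set.seed(6)
  s <- step_moran(crypt_state("c", 100), p, ref_fix, gm_fix)
  expect_identical(nrow(s$mutations), 1L)
  expect_identical(s$mutations$copies, 1L)
  expect_identical(s$mutations$ref, ref_base(ref_fix, s$mutations$position))
})
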