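test_that("annotation locates genes and validates the reference allele", {
  rb <- ref_base(ref_fix, 6563)
  alt <- setdiff(c("A", "C", "G", "T"), rb)[1]
  a <- annotate(6563, rb, alt, gm_fix, ref_fix)
  expect_identical(a$gene, "MT-CO1")  # the TaqI site lies inside MT-CO1
  expect_identical(a$region_class, "protein")
  expect_true(a$consequence %in% c("synonymous", "non-synonymous"))

  expect_error(annotate(6563, setdiff(c("A", "C", "G", "T"), rb)[2], rb,
                        gm_fix, ref_fix), "does not match")

  # control region -> noncoding; rRNA -> rna
  rb400 <- ref_base(ref_fix, 400)
  a400 <- annotate(400, rb400, setdiff(c("A", "C", "G", "T"), rb400)[1],
                   gm_fix, ref_fix)
  expect_identical(a400$consequence, "noncoding")
  rb1000 <- ref_base(ref_fix, 1000)
  a1000 <- annotate(1000, rb1000, setdiff(c("A", "C", "G", "T"), rb1000)[1],
                    gm_fix, ref_fix)
  expect_identical(a1000$region_class, "rRNA")
  expect_identical(a1000$consequence, "rna")
})

test_that("consequences agree with a whole-gene translation oracle", {
  set.seed(81)
  prot <- gm_fix[gm_fix$type == "protein", ]
  checked <- 0L
  while (checked < 100L) {
    g <- prot[sample.int(nrow(prot), 1L), ]
    pos <- sample(g$start:g$end, 1L)
    rb <- ref_base(ref_fix, pos)
    alt <- sample(setdiff(c("A", "C", "G", "T"), rb), 1L)
    a <- annotate(pos, rb, alt, gm_fix, ref_fix)
    if (a$gene != g$name) next  # overlapping gene precedence: skip ambiguity
    expect_identical(a$consequence, oracle_consequence(g$name, pos, alt),
                     info = sprintf("m.%d%s>%s in %s", pos, rb, alt, g$name))
    checked <- checked + 1L
  }
})

test_that("light-strand and incomplete-stop codons are annotated coherently", {
  # MT-ND6 is encoded on the light strand
  nd6 <- gm_fix[gm_fix$name == "MT-ND6", ]
  set.seed(82)
  for (i in 1:20) {
    pos <- sample(nd6$start:nd6$end, 1L)
    rb <- ref_base(ref_fix, pos)
    alt <- sample(setdiff(c("A", "C", "G", "T"), rb), 1L)
    a <- annotate(pos, rb, alt, gm_fix, ref_fix)
    expect_identical(a$gene, "MT-ND6")
    expect_identical(a$consequence, oracle_consequence("MT-ND6", pos, alt))
  }
  # the last base of MT-ND4 sits in an incomplete (polyadenylated) stop codon
  nd4 <- gm_fix[gm_fix$name == "MT-ND4", ]
  rb <- ref_base(ref_fix, nd4$end)
  alt <- setdiff(c("A", "C", "G", "T"), rb)[1]
  a <- annotate(nd4$end, rb, alt, gm_fix, ref_fix)
  expect_identical(a$region_class, "protein")
  expect_identical(a$consequence, oracle_consequence("MT-ND4", nd4$end, alt))
})

test_that("known polymorphisms are flagged from a supplied list", {
  rb <- ref_base(ref_fix, 263)
  alt <- setdiff(c("A", "C", "G", "T"), rb)[1]
  poly <- data.frame(position = 263L, ref = rb, alt = alt)
  a <- annotate(263, rb, alt, gm_fix, ref_fix, polymorphisms = poly)
  expect_true(a$known_polymorphism)
  b <- annotate(263, rb, setdiff(c("A", "C", "G", "T"), c(rb, alt))[1],
                gm_fix, ref_fix, polymorphisms = poly)
  expect_false(b$known_polymorphism)
  expect_s3_class(read_polymorphisms(), "data.frame")
})

test_that("tissue partitioning is a disjoint cover keyed on the mutation", {
  colon <- data.frame(position = c(73L, 152L), ref = c("A", "T"),
                      alt = c("G", "C"), heteroplasmy = c(0.02, 0.01))
  buccal <- data.frame(position = 73L, ref = "A", alt = "G",
                       heteroplasmy = 0.015)
  p <- partition_tissues(colon, buccal)
  expect_identical(p$germline$position, 73L)
  expect_identical(p$colon_somatic$position, 152L)
  expect_identical(nrow(p$buccal_somatic), 0L)
  expect_equal(p$germline$het_buccal, 0.015)

  disjoint <- partition_tissues(colon,
                                data.frame(position = 999L, ref = "A",
                                           alt = "C", heteroplasmy = 0.01))
  expect_identical(nrow(disjoint$germline), 0L)

  expect_error(partition_tissues(rbind(colon, colon[1, ]), buccal),
               "duplicate")
})

test_that("simulated ground-truth germline variants are recovered exactly", {
  cfg <- cohort_config(n_subjects = 8, n_crypts = 5, germline_mean = 2,
                       buccal_somatic_mean = 1)
  coh <- simulate_cohort(cfg, fast_drift(), seed = 83,
                         reference = ref_fix, genemap = gm_fix)
  for (s in coh) {
    cv <- colon_variants(s); bv <- buccal_variants(s)
    p <- partition_tissues(cv, bv)
    truth_key <- paste(s$germline$position, s$germline$ref, s$germline$alt)
    found_key <- paste(p$germline$position, p$germline$ref, p$germline$alt)
    somatic_truth <- cv$origin[match(paste(p$colon_somatic$position,
                                           p$colon_somatic$ref,
                                           p$colon_somatic$alt),
                                     paste(cv$position, cv$ref, cv$alt))]
    # sensitivity 1 (both tissues carry every injected variant) and
    # specificity 1 (nothing somatic is called germline), barring the
    # vanishing chance of an identical somatic mutation in both tissues
    expect_setequal(found_key, truth_key)
    expect_true(all(somatic_truth == "somatic"))
  }
})

test_that("somatic frequency subtracts the germline count per megabase", {
  expect_equal(somatic_frequency(5, 2, 35), 3 / 35)
  expect_equal(somatic_frequency(0, 0, 35), 0)
  expect_error(somatic_frequency(5, 2, 0), "> 0")
  expect_error(somatic_frequency(2, 5, 35), "exceed")
})

test_that("recurrence and contamination screening over a cohort table", {
  tab <- data.frame(
    subject_id = c("a", "b", "c", "a"),
    position = c(100L, 100L, 555L, 777L),
    ref = c("A", "A", "C", "G"), alt = c("G", "G", "T", "A"))
  rep1 <- recurrent_across_subjects(tab)
  expect_identical(rep1$recurrent$position, 100L)
  expect_identical(rep1$recurrent$n_subjects, 2L)
  expect_identical(nrow(rep1$flagged_pairs), 0L)

  none <- recurrent_across_subjects(tab[3:4, ])
  expect_identical(nrow(none$recurrent), 0L)

  shared5 <- do.call(rbind, lapply(1:5, function(i)
    data.frame(subject_id = c("x", "y"), position = 1000L + i,
               ref = "A", alt = "G")))
  shared5$ref <- ref_base(ref_fix, shared5$position)
  shared5$alt <- vapply(shared5$ref, function(b)
    setdiff(c("A", "C", "G", "T"), b)[1], "")
  rep2 <- recurrent_across_subjects(shared5)
  expect_identical(nrow(rep2$flagged_pairs), 1L)
  expect_identical(rep2$flagged_pairs$n_shared, 5L)
})

test_that("the Fisher selection test matches enumeration and closed forms", {
  expect_equal(selection_test(c(5, 5), c(5, 5))$p.value, 1)
  expect_lt(selection_test(c(0, 16), c(16, 0))$p.value, 1e-6)
  expect_warning(p0 <- selection_test(c(0, 0), c(3, 0))$p.value, "margin")
  expect_equal(p0, 1)

  # equality with the independent implementation on the worked table
  t1 <- selection_test(c(1, 15), c(10, 10))
  expect_equal(t1$p.value,
               fisher.test(matrix(c(1, 15, 10, 10), 2, byrow = TRUE))$p.value,
               tolerance = 1e-12)
  expect_lt(t1$direction, 0)  # non-synonymous enriched in the germline set here

  set.seed(84)
  for (i in 1:200) {
    tot <- sample(4:40, 1)
    cnt <- as.vector(rmultinom(1, tot, runif(4, 0.05, 1)))
    mine <- suppressWarnings(selection_test(cnt[1:2], cnt[3:4])$p.value)
    ref_p <- fisher.test(matrix(cnt, 2, byrow = TRUE))$p.value
    expect_equal(mine, ref_p, tolerance = 1e-10,
                 info = paste(cnt, collapse = ","))
  }
})
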