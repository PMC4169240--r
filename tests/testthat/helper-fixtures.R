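# shared fixtures, built in code at test time

ref_fix <- mtclone:::.index_reference(synthetic_rcrs())
gm_fix <- read_genemap()

# one perfectly clean candidate call that passes the default cascade
clean_call <- function(position = 100L, h = 0.05, depth = 2000L,
                       quality = 30) {
  alt_n <- round(h * depth)
  rb <- ref_base(ref_fix, position)
  data.frame(position = position, ref = rb,
             alt = setdiff(c("A", "C", "G", "T"), rb)[1L],
             fwd_alt = ceiling(alt_n / 2), rev_alt = floor(alt_n / 2),
             fwd_total = depth / 2, rev_total = depth / 2,
             heteroplasmy = alt_n / depth, mean_quality = quality,
             stringsAsFactors = FALSE)
}

# hand-built subject with explicit crypt states (bypasses the drift engine)
manual_subject <- function(crypts, germline = NULL, subject_id = "T01",
                           age_years = 50) {
  if (is.null(germline))
    germline <- data.frame(position = integer(), ref = character(),
                           alt = character(), pathogenic = logical(),
                           het_colon = numeric(), het_buccal = numeric(),
                           stringsAsFactors = FALSE)
  s <- list(subject_id = subject_id, age_years = age_years,
            n_crypts = length(crypts), crypts = crypts,
            germline = germline,
            buccal_somatic = data.frame(position = integer(),
                                        ref = character(), alt = character(),
                                        heteroplasmy = numeric(),
                                        origin = character(),
                                        pathogenic = logical(),
                                        stringsAsFactors = FALSE))
  class(s) <- "sim_subject"
  s
}

# small drift parameter set for fast cohort tests
fast_drift <- function(...) {
  drift_params(copies_per_crypt = 50, events_per_year = 200,
               mut_rate_per_copy_per_event = 1e-4, ...)
}

# brute-force consequence oracle: translate the whole mutated gene and diff
# the peptide (Biostrings path, independent of the per-codon lookup)
oracle_consequence <- function(gene_name, position, alt,
                               genemap = gm_fix, reference = ref_fix) {
  g <- genemap[genemap$name == gene_name, ]
  chars <- attr(reference, "chars")
  seq <- chars[g$start:g$end]
  mut <- seq
  mut[position - g$start + 1L] <- alt
  if (g$strand == "-") {
    rc <- function(v) rev(c(A = "T", C = "G", G = "C", T = "A")[v])
    seq <- rc(seq); mut <- rc(mut)
  }
  pad <- (3L - length(seq) %% 3L) %% 3L
  seq <- c(seq, rep("A", pad)); mut <- c(mut, rep("A", pad))
  tr <- function(v) as.character(Biostrings::translate(
    Biostrings::DNAString(paste(v, collapse = "")),
    genetic.code = Biostrings::getGeneticCode("2"),
    if.fuzzy.codon = "solve"))
  if (tr(seq) == tr(mut)) "synonymous" else "non-synonymous"
}
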