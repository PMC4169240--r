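#' Annotate a mitochondrial substitution
#'
#' Locates a substitution on the gene map and, for protein-coding genes,
#' translates the affected codon under the vertebrate mitochondrial genetic
#' code to assign a synonymous / non-synonymous consequence (stop gain and
#' stop loss count as non-synonymous).  Light-strand genes (MT-ND6) are
#' handled on their coding strand; codons running past a gene end (incomplete
#' stop codons) are completed with adenines, as by polyadenylation.  When a
#' position lies in several overlapping features, protein-coding genes take
#' precedence and ties break on feature start.
#'
#' @param position 1-based rCRS position.
#' @param ref,alt Single bases; `ref` must match the reference sequence.
#' @param genemap Gene map from [read_genemap()].
#' @param reference Reference string from [load_reference()] /
#'   [synthetic_rcrs()].
#' @param polymorphisms Optional `data.frame` of known polymorphic variants
#'   (columns `position`, `ref`, `alt`) to set the `known_polymorphism` flag;
#'   e.g. from [read_polymorphisms()].
#' @return List of class `"mt_annotation"`: `region_class` (protein / tRNA /
#'   rRNA / noncoding), `gene`, `codon_change` (e.g. `"GCA>GTA"` or `NA`),
#'   `consequence` (synonymous / non-synonymous / rna / noncoding),
#'   `known_polymorphism`.
#' @examples
#' ref <- synthetic_rcrs()
#' annotate(6563, ref_base(ref, 6563),
#'          setdiff(c("A", "C", "G", "T"), ref_base(ref, 6563))[1],
#'          reference = ref)$gene  # "MT-CO1"
#' @export
annotate <- function(position, ref, alt, genemap = read_genemap(),
                     reference = synthetic_rcrs(), polymorphisms = NULL) {
  position <- as.integer(position)
  ref <- toupper(ref); alt <- toupper(alt)
  if (!ref %in% .mt_bases || !alt %in% .mt_bases || ref == alt)
    stop("ref and alt must be distinct single bases")
  chars <- attr(reference, "chars")
  true_ref <- if (!is.null(chars)) chars[position]
              else substring(reference, position, position)
  if (true_ref != ref)
    stop("ref allele '", ref, "' does not match reference base '",
         true_ref, "' at position ", position)

  hit <- genemap[genemap$start <= position & genemap$end >= position, ,
                 drop = FALSE]
  known <- !is.null(polymorphisms) && nrow(polymorphisms) > 0 &&
    any(polymorphisms$position == position &
        toupper(polymorphisms$ref) == ref &
        toupper(polymorphisms$alt) == alt)

  res <- function(region, gene, codon_change, consequence) {
    out <- list(region_class = region, gene = gene,
                codon_change = codon_change, consequence = consequence,
                known_polymorphism = known, position = position,
                ref = ref, alt = alt)
    class(out) <- "mt_annotation"
    out
  }

  if (nrow(hit) == 0L || all(hit$type == "noncoding"))
    return(res("noncoding",
               if (nrow(hit)) hit$name[1L] else NA_character_,
               NA_character_, "noncoding"))
  prot <- hit[hit$type == "protein", , drop = FALSE]
  if (nrow(prot) == 0L) {
    g <- hit[order(hit$start), ][1L, ]
    return(res(ifelse(g$type == "tRNA", "tRNA", "rRNA"), g$name,
               NA_character_, "rna"))
  }
  g <- prot[order(prot$start), ][1L, ]
  cod <- .codon_at(g, position, reference)
  codon_ref <- cod$codon
  codon_alt <- codon_ref
  alt_coding <- if (g$strand == "+") alt else .revcomp_base(alt)
  substr(codon_alt, cod$within, cod$within) <- alt_coding
  aa_ref <- .mt_translate_codon(codon_ref)
  aa_alt <- .mt_translate_codon(codon_alt)
  res("protein", g$name, paste0(codon_ref, ">", codon_alt),
      if (aa_ref == aa_alt) "synonymous" else "non-synonymous")
}

#' @export
print.mt_annotation <- function(x, ...) {
  cat(sprintf("m.%d%s>%s: %s%s, %s%s%s\n", x$position, x$ref, x$alt,
              x$region_class,
              if (!is.na(x$gene)) paste0(" (", x$gene, ")") else "",
              x$consequence,
              if (!is.na(x$codon_change)) paste0(", codon ", x$codon_change) else "",
              if (x$known_polymorphism) ", known polymorphism" else ""))
  invisible(x)
}

.revcomp_base <- function(b) c(A = "T", C = "G", G = "C", T = "A")[[b]]

# genetic code: vertebrate mitochondrial (NCBI table 2), via Biostrings
.mt_code_env <- new.env(parent = emptyenv())
.mt_genetic_code <- function() {
  if (is.null(.mt_code_env$code))
    .mt_code_env$code <- Biostrings::getGeneticCode("2")
  .mt_code_env$code
}

.mt_translate_codon <- function(codon) {
  aa <- .mt_genetic_code()[[codon]]
  if (is.null(aa)) stop("untranslatable codon: ", codon)
  aa
}

# Reference codon containing `position` in protein gene `g` (one gene-map
# row).  Returns the codon read on the coding strand and the 1..3 offset of
# the queried base within it; bases beyond the gene end (incomplete stop
# codon) are filled with "A".
.codon_at <- function(g, position, reference) {
  chars <- attr(reference, "chars")
  getb <- function(p) {
    inside <- p >= 1L & p <= .mt_genome_length
    b <- rep("A", length(p))
    if (!is.null(chars)) b[inside] <- chars[p[inside]]
    else b[inside] <- substring(reference, p[inside], p[inside])
    b
  }
  if (g$strand == "+") {
    cds_pos <- position - g$start + 1L
    codon_i <- (cds_pos - 1L) %/% 3L
    within <- (cds_pos - 1L) %% 3L + 1L
    gpos <- g$start + codon_i * 3L + 0:2
    gpos[gpos > g$end] <- .Machine$integer.max  # off-gene -> "A" pad
    codon <- paste(getb(gpos), collapse = "")
  } else {
    cds_pos <- g$end - position + 1L
    codon_i <- (cds_pos - 1L) %/% 3L
    within <- (cds_pos - 1L) %% 3L + 1L
    gpos <- g$end - (codon_i * 3L + 0:2)
    gpos[gpos < g$start] <- .Machine$integer.max
    codon <- paste(vapply(getb(gpos), .revcomp_base, ""), collapse = "")
  }
  list(codon = codon, within = within)
}

#' Annotate a variant table
#'
#' Vectorised wrapper around [annotate()]: appends `region_class`, `gene`,
#' `consequence` and `known_polymorphism` columns to a variant `data.frame`.
#'
#' @param variants `data.frame` with `position`, `ref`, `alt` columns.
#' @inheritParams annotate
#' @return The input with annotation columns appended.
#' @export
annotate_variants <- function(variants, genemap = read_genemap(),
                              reference = synthetic_rcrs(),
                              polymorphisms = NULL) {
  reference <- .index_reference(reference)
  ann <- lapply(seq_len(nrow(variants)), function(i)
    annotate(variants$position[i], variants$ref[i], variants$alt[i],
             genemap, reference, polymorphisms))
  variants$region_class <- vapply(ann, `[[`, "", "region_class")
  variants$gene <- vapply(ann, `[[`, "", "gene")
  variants$consequence <- vapply(ann, `[[`, "", "consequence")
  variants$known_polymorphism <- vapply(ann, `[[`, TRUE, "known_polymorphism")
  variants
}

#' Read a known-polymorphism list
#'
#' Loads a TSV of previously reported polymorphic variants (columns
#' `position`, `ref`, `alt`) used only to set the `known_polymorphism` flag.
#' The bundled `known_polymorphisms_example.tsv` is a tiny synthetic
#' illustration; supply a curated list for real analyses.
#'
#' @param path TSV path; default the bundled example list.
#' @return `data.frame` with columns `position`, `ref`, `alt`.
#' @export
read_polymorphisms <- function(path = system.file(
  "extdata", "known_polymorphisms_example.tsv", package = "mtclone")) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("position", "ref", "alt")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("polymorphism list missing columns: ",
                         paste(miss, collapse = ", "))
  df$position <- as.integer(df$position)
  df
}

#' Partition a subject's variants into germline and somatic sets
#'
#' Variants observed in both tissues of a subject (matched on position, ref
#' and alt, regardless of heteroplasmy) are classed germline / early
#' embryological -- they must predate the divergence of the two tissue
#' lineages in embryogenesis; variants private to one tissue are somatic to
#' it.  The three sets are pairwise disjoint and jointly cover each tissue's
#' list.
#'
#' @param colon,buccal Variant `data.frame`s of one subject (columns
#'   `position`, `ref`, `alt`, ...).  Duplicate (position, ref, alt) keys
#'   within one tissue are an error.
#' @return Object of class `"tissue_partition"`: list with `germline`
#'   (colon rows, plus `het_buccal`), `colon_somatic`, `buccal_somatic`.
#' @examples
#' colon <- data.frame(position = c(73, 152), ref = c("A", "T"),
#'                     alt = c("G", "C"), heteroplasmy = c(0.02, 0.01))
#' buccal <- data.frame(position = 73, ref = "A", alt = "G",
#'                      heteroplasmy = 0.015)
#' partition_tissues(colon, buccal)
#' @export
partition_tissues <- function(colon, buccal) {
  key <- function(df) paste(df$position, toupper(df$ref), toupper(df$alt),
                            sep = ":")
  kc <- key(colon); kb <- key(buccal)
  if (anyDuplicated(kc)) stop("duplicate variant keys in colon list")
  if (anyDuplicated(kb)) stop("duplicate variant keys in buccal list")
  shared <- intersect(kc, kb)
  germline <- colon[kc %in% shared, , drop = FALSE]
  if (nrow(germline) && !is.null(buccal$heteroplasmy))
    germline$het_buccal <-
      buccal$heteroplasmy[match(key(germline), kb)]
  colon_somatic <- colon[!(kc %in% shared), , drop = FALSE]
  buccal_somatic <- buccal[!(kb %in% shared), , drop = FALSE]
  stopifnot(nrow(germline) + nrow(colon_somatic) == nrow(colon),
            nrow(germline) + nrow(buccal_somatic) == nrow(buccal),
            !any(key(colon_somatic) %in% key(buccal_somatic)))
  out <- list(germline = germline, colon_somatic = colon_somatic,
              buccal_somatic = buccal_somatic)
  class(out) <- "tissue_partition"
  out
}

#' @export
print.tissue_partition <- function(x, ...) {
  cat(sprintf(paste0("tissue partition: %d germline/early-embryonic, ",
                     "%d colon-somatic, %d buccal-somatic variant(s)\n"),
              nrow(x$germline), nrow(x$colon_somatic), nrow(x$buccal_somatic)))
  invisible(x)
}

#' Somatic mutation frequency of a subject
#'
#' Subtracts the germline / early-embryonic variants from the subject's total
#' variant count and scales by the megabases sequenced:
#' `(total - germline) / mb_sequenced`.
#'
#' @param total_count Total variants detected in the tissue.
#' @param germline_count Of these, the number shared with the other tissue.
#' @param mb_sequenced Megabases sequenced for the subject (> 0); the study
#'   average is 35 Mb per subject.
#' @return Somatic mutations per Mb.
#' @examples
#' somatic_frequency(5, 2, 35)  # 3/35
#' @export
somatic_frequency <- function(total_count, germline_count, mb_sequenced = 35) {
  if (mb_sequenced <= 0) stop("mb_sequenced must be > 0")
  if (germline_count > total_count)
    stop("germline_count cannot exceed total_count")
  (total_count - germline_count) / mb_sequenced
}

#' Recurrent variants across subjects and contamination screen
#'
#' Reports variants (position, ref, alt) observed in at least `min_subjects`
#' distinct subjects of a cohort variant table, with a gene-map region
#' breakdown, and flags subject pairs sharing at least `contamination_k`
#' variants -- multiple shared markers in one pair suggest a haplogroup-like
#' (contamination) pattern rather than independent recurrence.
#'
#' @param variants Cohort variant table (columns `subject_id`, `position`,
#'   `ref`, `alt`; extra columns ignored).  Use one tissue at a time.
#' @param min_subjects Minimum number of distinct subjects (default 2).
#' @param contamination_k Shared-variant count that flags a pair (default 3).
#' @param genemap Gene map for the region breakdown.
#' @return Object of class `"recurrence_report"`: list with `recurrent`
#'   (`data.frame`: key columns, `n_subjects`, `subjects`, `region_class`)
#'   and `flagged_pairs` (`data.frame`: `subject_a`, `subject_b`,
#'   `n_shared`).
#' @export
recurrent_across_subjects <- function(variants, min_subjects = 2L,
                                      contamination_k = 3L,
                                      genemap = read_genemap()) {
  if (length(unique(variants$subject_id)) < 2L)
    stop("need a cohort table with >= 2 subjects")
  key <- paste(variants$position, toupper(variants$ref),
               toupper(variants$alt), sep = ":")
  by_key <- split(variants$subject_id, key)
  subs <- lapply(by_key, unique)
  n_sub <- vapply(subs, length, 0L)
  rec_keys <- names(subs)[n_sub >= min_subjects]
  region_of <- function(pos) {
    hit <- genemap[genemap$start <= pos & genemap$end >= pos, , drop = FALSE]
    if (nrow(hit) == 0L) return("noncoding")
    if (any(hit$type == "protein")) return("protein")
    hit$type[order(hit$start)][1L]
  }
  recurrent <- if (length(rec_keys)) {
    parts <- strsplit(rec_keys, ":", fixed = TRUE)
    data.frame(position = as.integer(vapply(parts, `[`, "", 1L)),
               ref = vapply(parts, `[`, "", 2L),
               alt = vapply(parts, `[`, "", 3L),
               n_subjects = n_sub[rec_keys],
               subjects = vapply(subs[rec_keys], paste, "", collapse = ","),
               region_class = vapply(as.integer(vapply(parts, `[`, "", 1L)),
                                     region_of, ""),
               stringsAsFactors = FALSE, row.names = NULL)
  } else {
    data.frame(position = integer(), ref = character(), alt = character(),
               n_subjects = integer(), subjects = character(),
               region_class = character(), stringsAsFactors = FALSE)
  }
  # pairwise shared-variant counts over recurrent keys
  pair_counts <- list()
  for (k in rec_keys) {
    ss <- sort(subs[[k]])
    if (length(ss) < 2L) next
    prs <- utils::combn(ss, 2L)
    for (j in seq_len(ncol(prs))) {
      id <- paste(prs[1L, j], prs[2L, j], sep = "|")
      pair_counts[[id]] <- (pair_counts[[id]] %||% 0L) + 1L
    }
  }
  flagged <- names(pair_counts)[unlist(pair_counts) >= contamination_k]
  flagged_pairs <- if (length(flagged)) {
    parts <- strsplit(flagged, "|", fixed = TRUE)
    data.frame(subject_a = vapply(parts, `[`, "", 1L),
               subject_b = vapply(parts, `[`, "", 2L),
               n_shared = unlist(pair_counts[flagged], use.names = FALSE),
               stringsAsFactors = FALSE)
  } else {
    data.frame(subject_a = character(), subject_b = character(),
               n_shared = integer(), stringsAsFactors = FALSE)
  }
  out <- list(recurrent = recurrent, flagged_pairs = flagged_pairs,
              min_subjects = min_subjects, contamination_k = contamination_k)
  class(out) <- "recurrence_report"
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.recurrence_report <- function(x, ...) {
  cat(sprintf("recurrence report: %d variant(s) in >= %d subjects; %d flagged pair(s)\n",
              nrow(x$recurrent), x$min_subjects, nrow(x$flagged_pairs)))
  if (nrow(x$recurrent)) print.data.frame(x$recurrent)
  if (nrow(x$flagged_pairs)) {
    cat("possible contamination (>= ", x$contamination_k, " shared variants):\n",
        sep = "")
    print.data.frame(x$flagged_pairs)
  }
  invisible(x)
}

#' Purifying-selection contrast (Fisher's exact test)
#'
#' Two-sided Fisher's exact test on the 2x2 table of benign (synonymous or
#' polymorphic) versus non-synonymous counts in the germline/early-embryonic
#' and somatic variant sets.  The p value is computed from the hypergeometric
#' distribution with fixed margins, summing the probabilities of all tables
#' no more probable than the observed one.  A depleted non-synonymous class
#' among germline variants relative to somatic ones indicates purifying
#' selection in the germline.
#'
#' @param germline Length-2 integer vector `c(syn_or_poly, nonsyn)` for the
#'   germline set.
#' @param somatic Same for the somatic set.
#' @return Object of class `"selection_test"`: list with `p.value`, `table`,
#'   `direction` (sign of the somatic non-synonymous enrichment).
#' @examples
#' selection_test(c(15, 1), c(20, 15))
#' @export
selection_test <- function(germline, somatic) {
  stopifnot(length(germline) == 2L, length(somatic) == 2L)
  counts <- c(germline, somatic)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  tab <- matrix(as.integer(counts), nrow = 2L, byrow = TRUE,
                dimnames = list(set = c("germline", "somatic"),
                                class = c("syn_or_poly", "nonsyn")))
  m <- sum(tab[, 1L]); n <- sum(tab[, 2L]); k <- sum(tab[1L, ])
  if (m + n == 0L || k == 0L || k == m + n || m == 0L || n == 0L) {
    if (sum(tab) > 0L && (m == 0L || n == 0L || k == 0L || k == m + n))
      warning("a table margin is zero; p = 1")
    p <- 1
  } else {
    x <- tab[1L, 1L]
    support <- max(0L, k - n):min(k, m)
    probs <- dhyper(support, m, n, k)
    p_obs <- dhyper(x, m, n, k)
    p <- min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
  }
  prop_ns <- tab[, 2L] / pmax(1L, rowSums(tab))
  out <- list(p.value = p, table = tab,
              direction = sign(prop_ns[["somatic"]] - prop_ns[["germline"]]))
  class(out) <- "selection_test"
  out
}

#' @export
print.selection_test <- function(x, ...) {
  cat("purifying-selection contrast (two-sided Fisher's exact test)\n")
  print(x$table)
  dir <- if (x$direction > 0) "non-synonymous enriched in somatic set"
         else if (x$direction < 0) "non-synonymous enriched in germline set"
         else "no directional difference"
  cat(sprintf("  p = %.4g (%s)\n", x$p.value, dir))
  invisible(x)
}
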