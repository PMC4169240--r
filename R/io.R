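#' Read and write tissue variant tables
#'
#' The package's TSV interchange schema for tissue-level variants:
#' `subject_id`, `age_years`, `tissue` (colon/buccal), `position`, `ref`,
#' `alt`, `heteroplasmy` (fraction in `[0, 1]`), `origin`
#' (germline/somatic ground truth; optional on read).  Writing then reading a
#' table yields identical records.
#'
#' @param path File path.
#' @param variants Variant `data.frame` in the schema (e.g. from
#'   [variant_table()]).
#' @return `read_variant_table()` returns the `data.frame`;
#'   `write_variant_table()` returns `path` invisibly.
#' @export
read_variant_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE,
                   colClasses = c(subject_id = "character"))
  mandatory <- c("subject_id", "age_years", "tissue", "position", "ref",
                 "alt", "heteroplasmy")
  miss <- setdiff(mandatory, names(df))
  if (length(miss))
    stop("variant table missing mandatory columns: ",
         paste(miss, collapse = ", "))
  extra <- setdiff(names(df), c(mandatory, "origin"))
  if (length(extra))
    warning("unknown columns ignored: ", paste(extra, collapse = ", "))
  if (nrow(df) && any(df$heteroplasmy < 0 | df$heteroplasmy > 1))
    stop("heteroplasmy outside [0, 1]")
  if (nrow(df) && any(!df$tissue %in% c("colon", "buccal")))
    stop("tissue must be 'colon' or 'buccal'")
  df$position <- as.integer(df$position)
  df
}

#' @rdname read_variant_table
#' @export
write_variant_table <- function(variants, path) {
  mandatory <- c("subject_id", "age_years", "tissue", "position", "ref",
                 "alt", "heteroplasmy")
  miss <- setdiff(mandatory, names(variants))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  cols <- c(mandatory, intersect("origin", names(variants)))
  write.table(variants[, cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read and write pileup count tables
#'
#' TSV schema: `position`, `ref`, `A_fwd`, `A_rev`, `C_fwd`, `C_rev`,
#' `G_fwd`, `G_rev`, `T_fwd`, `T_rev`, `mean_quality`.
#'
#' @param path File path.
#' @param pileup Pileup `data.frame` (e.g. from [simulate_pileup()]).
#' @return `read_pileup()` returns the `data.frame`; `write_pileup()`
#'   returns `path` invisibly.
#' @export
read_pileup <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("position", "ref", "A_fwd", "A_rev", "C_fwd", "C_rev",
            "G_fwd", "G_rev", "T_fwd", "T_rev", "mean_quality")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("pileup missing mandatory columns: ", paste(miss, collapse = ", "))
  counts <- df[, need[3:10]]
  if (nrow(df) && any(counts < 0)) stop("negative read counts")
  df$position <- as.integer(df$position)
  df
}

#' @rdname read_pileup
#' @export
write_pileup <- function(pileup, path) {
  need <- c("position", "ref", "A_fwd", "A_rev", "C_fwd", "C_rev",
            "G_fwd", "G_rev", "T_fwd", "T_rev", "mean_quality")
  miss <- setdiff(need, names(pileup))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  write.table(pileup[, need], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read and write RMC well records
#'
#' TSV schema mirroring per-well random-mutation-capture raw data:
#' `subject_id`, `age_years`, `well_id`, `target_bases`, `position`, `ref`,
#' `alt` -- one row per confirmed mutant; wells without mutants appear once
#' with empty allele fields.  `read_rmc_table()` reconstructs one
#' [rmc_experiment()] per subject (site offsets are recovered from the
#' position relative to `site_start`).
#'
#' @param path File path.
#' @param experiments A single [rmc_experiment()] or list of them.
#' @param site_start First position of the TCGA site (default 6562).
#' @return `read_rmc_table()` returns a named list of [rmc_experiment()];
#'   `write_rmc_table()` returns `path` invisibly.
#' @export
read_rmc_table <- function(path, site_start = 6562L) {
  df <- read.delim(path, stringsAsFactors = FALSE,
                   colClasses = c(subject_id = "character",
                                  well_id = "character",
                                  ref = "character", alt = "character"))
  need <- c("subject_id", "age_years", "well_id", "target_bases",
            "position", "ref", "alt")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("RMC table missing mandatory columns: ", paste(miss, collapse = ", "))
  lapply(split(df, df$subject_id), function(d) {
    wells <- unique(d[, c("well_id", "target_bases")])
    has_mut <- !is.na(d$ref) & d$ref != "" & !is.na(d$alt) & d$alt != ""
    mut <- d[has_mut, , drop = FALSE]
    mutants <- if (nrow(mut))
      data.frame(well_id = mut$well_id,
                 position = as.integer(mut$position),
                 ref = mut$ref, alt = mut$alt,
                 site_offset = as.integer(mut$position) - site_start + 1L,
                 stringsAsFactors = FALSE)
    else NULL
    rmc_experiment(d$subject_id[1L], wells, mutants,
                   age_years = d$age_years[1L])
  })
}

#' @rdname read_rmc_table
#' @export
write_rmc_table <- function(experiments, path) {
  if (inherits(experiments, "rmc_experiment"))
    experiments <- list(experiments)
  rows <- lapply(experiments, function(ex) {
    base <- data.frame(subject_id = ex$subject_id, age_years = ex$age_years,
                       ex$wells, stringsAsFactors = FALSE)
    m <- ex$mutants
    if (nrow(m)) {
      mut_rows <- merge(base, m, by = "well_id", sort = FALSE)
      empty <- base[!(base$well_id %in% m$well_id), , drop = FALSE]
      if (nrow(empty)) {
        empty$position <- NA_integer_; empty$ref <- ""; empty$alt <- ""
        mut_rows <- rbind(mut_rows[, c("subject_id", "age_years", "well_id",
                                       "target_bases", "position", "ref",
                                       "alt")],
                          empty[, c("subject_id", "age_years", "well_id",
                                    "target_bases", "position", "ref", "alt")])
      } else {
        mut_rows <- mut_rows[, c("subject_id", "age_years", "well_id",
                                 "target_bases", "position", "ref", "alt")]
      }
      mut_rows
    } else {
      base$position <- NA_integer_; base$ref <- ""; base$alt <- ""
      base[, c("subject_id", "age_years", "well_id", "target_bases",
               "position", "ref", "alt")]
    }
  })
  out <- do.call(rbind, rows)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export variant calls as VCF v4.2
#'
#' Writes a minimal well-formed VCF: one record per call, heteroplasmy in the
#' `AF` INFO field, supporting read counts in `DP`/`AD`, and the filter
#' cascade outcome in FILTER (`PASS`, or the semicolon-joined failure
#' reasons).
#'
#' @param filtered Result of [apply_filters()], or a call `data.frame` (then
#'   all records are written as PASS).
#' @param path Output path.
#' @param sample_id Sample name recorded in the header.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(filtered, path, sample_id = "sample") {
  if (is.data.frame(filtered))
    filtered <- list(passed = filtered,
                     rejected = cbind(filtered[0, , drop = FALSE],
                                      data.frame(reasons = character())))
  p <- filtered$passed; r <- filtered$rejected
  p$FILTER <- rep("PASS", nrow(p))
  r$FILTER <- gsub(",", ";", r$reasons)
  cols <- c("position", "ref", "alt", "fwd_alt", "rev_alt", "fwd_total",
            "rev_total", "heteroplasmy", "mean_quality", "FILTER")
  all <- rbind(p[, cols], r[, cols])
  all <- all[order(all$position, all$alt), , drop = FALSE]
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chrM,length=16569>",
    "##INFO=<ID=AF,Number=A,Type=Float,Description=\"Heteroplasmy fraction\">",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Total read depth\">",
    "##INFO=<ID=AD,Number=1,Type=Integer,Description=\"Variant read depth\">",
    paste0("##FILTER=<ID=", .mt_filter_reasons, ",Description=\"Failed ",
           .mt_filter_reasons, " filter\">"),
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          sep = "\t"))
  body <- if (nrow(all)) {
    sprintf("chrM\t%d\t.\t%s\t%s\t%.1f\t%s\tAF=%.6f;DP=%d;AD=%d",
            all$position, all$ref, all$alt, all$mean_quality, all$FILTER,
            all$heteroplasmy, all$fwd_total + all$rev_total,
            all$fwd_alt + all$rev_alt)
  } else character()
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write a reference sequence as FASTA
#'
#' @param reference Reference string (e.g. from [synthetic_rcrs()]).
#' @param path Output path.
#' @param name Record name.
#' @return `path`, invisibly.
#' @export
write_reference_fasta <- function(reference, path,
                                  name = attr(reference, "name") %||% "chrM") {
  seq <- as.character(reference)
  lines <- substring(seq, seq(1, nchar(seq), 70),
                     pmin(seq(70, nchar(seq) + 69, 70), nchar(seq)))
  writeLines(c(paste0(">", name), lines), path)
  invisible(path)
}
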