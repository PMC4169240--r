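#' Load a mitochondrial reference sequence
#'
#' Reads a single-record FASTA containing a full human mitochondrial genome
#' (rCRS coordinate frame, 16,569 bp) and returns it as an uppercase
#' character string addressed 1-based, as in the rCRS convention.
#'
#' @param path Path to a FASTA file with exactly one record.
#' @return A length-one character vector of 16,569 uppercase bases, with the
#'   record name attached as the `"name"` attribute.
#' @examples
#' ref <- load_reference(system.file("extdata", "synthetic_rCRS.fasta",
#'                                   package = "mtclone"))
#' nchar(ref)
#' @export
load_reference <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) != 1L)
    stop("expected a single-record FASTA, found ", length(set), " records")
  seq <- toupper(as.character(set[[1L]]))
  if (nchar(seq) != .mt_genome_length)
    stop("reference length is ", nchar(seq), " bp; expected the 16,569 bp ",
         "mitochondrial reference (rCRS, NC_012920.1)")
  if (grepl("[^ACGT]", seq))
    stop("reference contains non-ACGT characters")
  attr(seq, "name") <- names(set)[1L]
  seq
}

#' Reference base at given positions
#'
#' @param reference Reference string from [load_reference()] or
#'   [synthetic_rcrs()].
#' @param position Integer vector of 1-based positions.
#' @return Character vector of bases.
#' @export
ref_base <- function(reference, position) {
  position <- as.integer(position)
  if (any(position < 1L | position > nchar(reference)))
    stop("position outside 1..", nchar(reference))
  out <- substring(reference, position, position)
  attributes(out) <- NULL
  out
}

#' Deterministic synthetic mitochondrial reference
#'
#' Generates a synthetic 16,569-bp stand-in for the human mitochondrial
#' reference: random bases from a fixed internal seed, with a TCGA TaqI
#' recognition site placed at positions 6562-6565 (inside the MT-CO1 gene,
#' where the random-mutation-capture assay interrogates it).  The sequence is
#' *not* the rCRS -- it only shares its length, coordinate frame and gene map
#' -- and exists so that simulation, annotation and the test-suite run without
#' any download.  Supply the real NC_012920.1 FASTA via [load_reference()] for
#' real data.
#'
#' @return Uppercase character string of length 16,569.
#' @export
synthetic_rcrs <- function() {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(16569L)
  b <- sample(.mt_bases, .mt_genome_length, replace = TRUE)
  b[6562:6565] <- c("T", "C", "G", "A")
  seq <- paste(b, collapse = "")
  attr(seq, "name") <- "synthetic_rCRS"
  seq
}

# Attach cached per-base position indices and a character-vector view to a
# reference string so repeated spectrum draws / annotations avoid re-splitting
# the 16.6 kb sequence.
.index_reference <- function(reference) {
  if (!is.null(attr(reference, "base_index"))) return(reference)
  chars <- strsplit(as.character(reference), "")[[1L]]
  attr(reference, "chars") <- chars
  attr(reference, "base_index") <-
    lapply(setNames(.mt_bases, .mt_bases), function(b) which(chars == b))
  reference
}

# Standard rCRS gene coordinates (1-based inclusive).  These are the public
# annotation facts of NC_012920.1; light-strand features carry strand "-".
# The control region wraps the origin and is represented as two rows.
.genemap_table <- function() {
  txt <- c(
    "MT-CR-1|16024|16569|+|noncoding",
    "MT-CR-2|1|576|+|noncoding",
    "MT-TF|577|647|+|tRNA",
    "MT-RNR1|648|1601|+|rRNA",
    "MT-TV|1602|1670|+|tRNA",
    "MT-RNR2|1671|3229|+|rRNA",
    "MT-TL1|3230|3304|+|tRNA",
    "MT-ND1|3307|4262|+|protein",
    "MT-TI|4263|4331|+|tRNA",
    "MT-TQ|4329|4400|-|tRNA",
    "MT-TM|4402|4469|+|tRNA",
    "MT-ND2|4470|5511|+|protein",
    "MT-TW|5512|5579|+|tRNA",
    "MT-TA|5587|5655|-|tRNA",
    "MT-TN|5657|5729|-|tRNA",
    "MT-TC|5761|5826|-|tRNA",
    "MT-TY|5826|5891|-|tRNA",
    "MT-CO1|5904|7445|+|protein",
    "MT-TS1|7446|7514|-|tRNA",
    "MT-TD|7518|7585|+|tRNA",
    "MT-CO2|7586|8269|+|protein",
    "MT-TK|8295|8364|+|tRNA",
    "MT-ATP8|8366|8572|+|protein",
    "MT-ATP6|8527|9207|+|protein",
    "MT-CO3|9207|9990|+|protein",
    "MT-TG|9991|10058|+|tRNA",
    "MT-ND3|10059|10404|+|protein",
    "MT-TR|10405|10469|+|tRNA",
    "MT-ND4L|10470|10766|+|protein",
    "MT-ND4|10760|12137|+|protein",
    "MT-TH|12138|12206|+|tRNA",
    "MT-TS2|12207|12265|+|tRNA",
    "MT-TL2|12266|12336|+|tRNA",
    "MT-ND5|12337|14148|+|protein",
    "MT-ND6|14149|14673|-|protein",
    "MT-TE|14674|14742|-|tRNA",
    "MT-CYB|14747|15887|+|protein",
    "MT-TT|15888|15953|+|tRNA",
    "MT-TP|15956|16023|-|tRNA")
  f <- strsplit(txt, "|", fixed = TRUE)
  data.frame(name   = vapply(f, `[`, "", 1L),
             start  = as.integer(vapply(f, `[`, "", 2L)),
             end    = as.integer(vapply(f, `[`, "", 3L)),
             strand = vapply(f, `[`, "", 4L),
             type   = vapply(f, `[`, "", 5L),
             stringsAsFactors = FALSE)
}

#' Mitochondrial gene map
#'
#' The standard rCRS feature table: 13 protein-coding genes, 22 tRNAs,
#' 2 rRNAs and the control region (split into two rows because it wraps the
#' origin), with 1-based inclusive coordinates and strand.  Used for region
#' classification and protein-coding consequence annotation.
#'
#' @param path Optional path to a BED-like TSV (columns `name`, `start`,
#'   `end`, `strand`, `type`) to load instead of the built-in map.
#' @return A `data.frame` with columns `name`, `start`, `end`, `strand`
#'   (`"+"`/`"-"`), `type` (`protein`, `tRNA`, `rRNA`, `noncoding`).
#' @export
read_genemap <- function(path = NULL) {
  gm <- if (is.null(path)) .genemap_table()
        else read.delim(path, stringsAsFactors = FALSE)
  required <- c("name", "start", "end", "strand", "type")
  miss <- setdiff(required, names(gm))
  if (length(miss)) stop("gene map missing columns: ", paste(miss, collapse = ", "))
  gm$start <- as.integer(gm$start); gm$end <- as.integer(gm$end)
  if (any(gm$start < 1L | gm$end > .mt_genome_length | gm$start > gm$end))
    stop("gene map features must lie within 1..", .mt_genome_length)
  if (!all(gm$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  if (!all(gm$type %in% c("protein", "tRNA", "rRNA", "noncoding")))
    stop("feature type must be protein/tRNA/rRNA/noncoding")
  gm
}
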