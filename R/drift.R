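#' Parameters of the neutral drift model of crypt mtDNA turnover
#'
#' The clonal-expansion engine is a neutral Moran process on the effective
#' mtDNA population of one crypt stem-cell niche: per replacement event one
#' copy (drawn uniformly, with replacement) is duplicated -- possibly
#' acquiring a new point mutation -- and one copy is destroyed, so the
#' population size `N` is conserved exactly.  Concurrently segregating
#' mutations are tracked as independent loci.
#'
#' Defaults are chosen so that, as observed in ageing human colonic
#' epithelium, clonal expansion of a new mutation to high heteroplasmy takes
#' of the order of 25 years (conditional fixation time of a neutral Moran
#' mutant, roughly `N^2` events) and a few percent of crypts carry an
#' expanded pathogenic mutation by age 70 while almost none do before age
#' 20.  See the package vignette for the calibration argument.
#'
#' @param copies_per_crypt Effective number of mtDNA copies in the stem-cell
#'   niche (`N`, >= 2).
#' @param events_per_year Moran replacement events per year.
#' @param mut_rate_per_copy_per_event Probability that the replicated copy
#'   acquires a new point mutation at one event.
#' @param pathogenic_fraction Probability that a new mutation is
#'   non-synonymous (potentially pathogenic); the remainder are synonymous,
#'   RNA or non-coding changes.
#' @param spectrum A [spectrum_config()].
#' @param seed Optional integer seed used by [simulate_crypt()] and
#'   [simulate_cohort()]; identical seeds give bit-identical output.
#' @return An object of class `"drift_params"`.
#' @export
drift_params <- function(copies_per_crypt = 500L,
                         events_per_year = 10000L,
                         mut_rate_per_copy_per_event = 1e-4,
                         pathogenic_fraction = 0.5,
                         spectrum = spectrum_config(),
                         seed = NULL) {
  N <- as.integer(copies_per_crypt)
  if (is.na(N) || N < 2L) stop("copies_per_crypt must be an integer >= 2")
  if (events_per_year < 0) stop("events_per_year must be >= 0")
  for (r in c(mut_rate_per_copy_per_event, pathogenic_fraction))
    if (r < 0 || r > 1) stop("rates must lie in [0, 1]")
  stopifnot(inherits(spectrum, "spectrum_config"))
  out <- list(N = N,
              events_per_year = as.integer(events_per_year),
              mut_rate = mut_rate_per_copy_per_event,
              pathogenic_fraction = pathogenic_fraction,
              spectrum = spectrum,
              seed = if (!is.null(seed)) as.integer(seed) else NULL)
  class(out) <- "drift_params"
  out
}

#' @export
print.drift_params <- function(x, ...) {
  cat(sprintf(paste0("neutral Moran drift parameters: N = %d copies, ",
                     "%d events/year,\n  mutation rate %.2g per replicated ",
                     "copy per event, pathogenic fraction %.2f\n"),
              x$N, x$events_per_year, x$mut_rate, x$pathogenic_fraction))
  invisible(x)
}

#' Construct a crypt state
#'
#' One crypt's mtDNA population: `N` copies and, for every segregating or
#' fixed mutation, the number of copies carrying it.  Mutations whose count
#' drops to 0 are pruned.
#'
#' @param crypt_id Identifier.
#' @param N Copy number of the niche.
#' @param mutations `data.frame` with columns `position`, `ref`, `alt`,
#'   `pathogenic` (logical) and `copies` (1..N).
#' @param age_years Age the state has been evolved to.
#' @return Object of class `"crypt_state"`.
#' @export
crypt_state <- function(crypt_id = "crypt1", N = 500L,
                        mutations = NULL, age_years = 0) {
  if (is.null(mutations))
    mutations <- data.frame(position = integer(), ref = character(),
                            alt = character(), pathogenic = logical(),
                            copies = integer(), stringsAsFactors = FALSE)
  stopifnot(is.data.frame(mutations))
  mutations$copies <- as.integer(mutations$copies)
  mutations <- mutations[mutations$copies > 0L, , drop = FALSE]
  if (nrow(mutations) && any(mutations$copies > N))
    stop("copy counts cannot exceed N")
  out <- list(crypt_id = crypt_id, N = as.integer(N),
              mutations = mutations, age_years = age_years)
  class(out) <- "crypt_state"
  out
}

#' @export
print.crypt_state <- function(x, ...) {
  cat(sprintf("crypt '%s': N = %d copies, age %.1f y, %d mutation(s)\n",
              x$crypt_id, x$N, x$age_years, nrow(x$mutations)))
  if (nrow(x$mutations)) {
    m <- x$mutations
    cat(sprintf("  m.%d%s>%s  h = %.3f%s\n", m$position, m$ref, m$alt,
                m$copies / x$N, ifelse(m$pathogenic, "  [pathogenic]", "")))
  }
  invisible(x)
}

#' Heteroplasmy of each mutation in a crypt
#' @param state A [crypt_state()].
#' @return Named numeric vector `copies / N`.
#' @export
heteroplasmy <- function(state) {
  stopifnot(inherits(state, "crypt_state"))
  h <- state$mutations$copies / state$N
  names(h) <- sprintf("m.%d%s>%s", state$mutations$position,
                      state$mutations$ref, state$mutations$alt)
  h
}

#' Advance a crypt by one Moran replacement event
#'
#' One copy chosen uniformly (with replacement) is duplicated and one is
#' destroyed; the duplicated copy acquires a new mutation with probability
#' `mut_rate_per_copy_per_event`.  Each tracked mutation's count performs the
#' exact single-locus Moran transition (+1 with probability `p(1-p)`, -1 with
#' probability `p(1-p)`, `p = copies/N`); counts 0 and `N` are absorbing and
#' total copy number is exactly `N` throughout.  New-mutation identities are
#' drawn from the spectrum against the supplied reference.
#'
#' @param state A [crypt_state()].
#' @param params A [drift_params()].
#' @param reference,genemap Reference sequence and gene map used to assign
#'   identities to new mutations (defaults: bundled synthetic reference).
#' @return The updated `crypt_state`.
#' @export
step_moran <- function(state, params, reference = synthetic_rcrs(),
                       genemap = read_genemap()) {
  stopifnot(inherits(state, "crypt_state"), inherits(params, "drift_params"))
  if (state$N != params$N)
    stop("state and params disagree on N")
  m <- state$mutations
  if (nrow(m))
    m$copies <- moran_locus_cpp(m$copies, params$N, 1)
  if (runif(1L) < params$mut_rate) {
    tgt <- if (runif(1L) < params$pathogenic_fraction) "pathogenic" else "benign"
    new <- .draw_genome_mutations(1L, params$spectrum, reference, genemap,
                                  target = tgt)
    new$copies <- 1L
    m <- rbind(m, new[, c("position", "ref", "alt", "pathogenic", "copies")])
  }
  crypt_state(state$crypt_id, state$N, m, state$age_years)
}

#' Simulate a crypt's mtDNA population to a given age
#'
#' Runs `events_per_year * age_years` Moran replacement events from a
#' mutation-free niche.  New mutations enter at the configured per-event rate
#' and drift as independent neutral loci (the event-skipping engine simulates
#' the embedded jump chain of the same process); mutations surviving at the
#' horizon are returned with their copy counts and spectrum-drawn identities.
#'
#' @inheritParams step_moran
#' @param age_years Subject age (>= 0).
#' @param crypt_id Identifier for the returned state.
#' @param seed Optional integer seed (overrides `params$seed`).
#' @return A [crypt_state()].
#' @examples
#' p <- drift_params(copies_per_crypt = 100, events_per_year = 2000,
#'                   mut_rate_per_copy_per_event = 1e-3)
#' simulate_crypt(60, p, seed = 1)
#' @export
simulate_crypt <- function(age_years, params, crypt_id = "crypt1",
                           seed = NULL, reference = synthetic_rcrs(),
                           genemap = read_genemap()) {
  stopifnot(inherits(params, "drift_params"))
  if (age_years < 0) stop("age_years must be >= 0")
  seed <- if (!is.null(seed)) seed else params$seed
  if (!is.null(seed)) set.seed(seed)
  n_events <- as.numeric(params$events_per_year) * age_years
  res <- moran_crypt_cpp(n_events, params$N, params$mut_rate)
  counts <- res$counts
  if (length(counts) == 0L)
    return(crypt_state(crypt_id, params$N, NULL, age_years))
  n_path <- rbinom(1L, length(counts), params$pathogenic_fraction)
  tgt <- sample(c(rep("pathogenic", n_path),
                  rep("benign", length(counts) - n_path)))
  muts <- do.call(rbind, lapply(tgt, function(t)
    .draw_genome_mutations(1L, params$spectrum, reference, genemap, target = t)))
  muts$copies <- counts
  # infinite-sites: re-draw on the (vanishingly rare) identity collision
  key <- paste(muts$position, muts$ref, muts$alt)
  while (anyDuplicated(key)) {
    i <- which(duplicated(key))[1L]
    redraw <- .draw_genome_mutations(1L, params$spectrum, reference, genemap,
                                     target = tgt[i])
    muts[i, c("position", "ref", "alt", "pathogenic")] <- redraw
    key <- paste(muts$position, muts$ref, muts$alt)
  }
  crypt_state(crypt_id, params$N, muts, age_years)
}

#' Is a crypt biochemically deficient?
#'
#' A crypt is scored deficient in cytochrome c oxidase when any pathogenic
#' (non-synonymous) mutation has clonally expanded to at least the
#' biochemical-threshold heteroplasmy.  This is the crypt-level counterpart
#' of the histological rule scoring a crypt deficient when most of its cells
#' have lost COX activity; the simulator has no per-cell resolution, so the
#' threshold is applied to the niche heteroplasmy directly.
#'
#' @param crypt A [crypt_state()].
#' @param biochem_threshold Heteroplasmy above which a pathogenic mutation
#'   causes biochemical deficiency (in (0, 1]; default 0.85).
#' @return Logical scalar.
#' @export
mark_cox_deficient <- function(crypt, biochem_threshold = 0.85) {
  stopifnot(inherits(crypt, "crypt_state"))
  if (biochem_threshold <= 0 || biochem_threshold > 1)
    stop("biochem_threshold must be in (0, 1]")
  m <- crypt$mutations
  any(m$pathogenic & m$copies / crypt$N >= biochem_threshold)
}
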