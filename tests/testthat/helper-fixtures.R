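# Shared fixtures and independent oracles for the test suite.

## references are expensive enough to build once per insertion coordinate
.ref_cache <- new.env(parent = emptyenv())
ref_for <- function(insertion, seed = 7L) {
  key <- paste0("i", insertion, "_s", seed)
  if (is.null(.ref_cache[[key]]))
    .ref_cache[[key]] <- build_reference(
      genome_config(insertion_pos = insertion, seed = seed))
  .ref_cache[[key]]
}

## parameters that force a single repair pathway (refusion included),
## leaving everything else at defaults
params_forcing <- function(pathway) {
  pp <- lapply(sim_params()$pathway_propensities, function(w) {
    w[] <- 0
    w[pathway] <- 1
    w
  })
  sim_params(pathway_propensities = pp)
}

## genotype + classify a list of colony fates
classify_fates <- function(fates, ref, panel = primer_panel()) {
  pats <- do.call(rbind, lapply(seq_along(fates), function(i) {
    genotype_colony(fates[[i]]$final_karyotype, ref, panel,
                    colony_id = paste0("c", i))
  }))
  classify_cohort(pats)
}

## ---- independent oracles ---------------------------------------------------

## breakpoint-placement count by exhaustive enumeration of equal-size
## deletions reproducing the derivative
brute_placements <- function(ref_allele, derived_allele) {
  k <- nchar(ref_allele) - nchar(derived_allele)
  n <- 0L
  for (d in seq_len(nchar(ref_allele) - k + 1L)) {
    cand <- paste0(substr(ref_allele, 1L, d - 1L),
                   substr(ref_allele, d + k, nchar(ref_allele)))
    if (cand == derived_allele) n <- n + 1L
  }
  n
}

## leftmost valid deletion start by the same enumeration
brute_leftmost <- function(ref_allele, derived_allele) {
  k <- nchar(ref_allele) - nchar(derived_allele)
  for (d in seq_len(nchar(ref_allele) - k + 1L)) {
    cand <- paste0(substr(ref_allele, 1L, d - 1L),
                   substr(ref_allele, d + k, nchar(ref_allele)))
    if (cand == derived_allele) return(d)
  }
  NA_integer_
}

## exhaustive in-silico PCR: slide both primers (and their reverse
## complements) over every position by direct substring comparison, then
## pair convergent sites -- independent of the package's matcher
brute_pcr <- function(template, fwd, rev, max_amplicon = 6000L) {
  L <- nchar(template)
  sites <- function(p) {
    n <- nchar(p)
    if (n > L) return(integer(0))
    starts <- seq_len(L - n + 1L)
    starts[substring(template, starts, starts + n - 1L) == p]
  }
  out <- NULL
  for (orient in 1:2) {
    f <- if (orient == 1L) fwd else rev
    r <- if (orient == 1L) rev else fwd
    for (fs in sites(f)) {
      for (rs in sites(revcomp(r))) {
        end <- rs + nchar(r) - 1L
        len <- end - fs + 1L
        if (fs < rs && len <= max_amplicon)
          out <- rbind(out, data.frame(start = fs, end = end, length = len))
      }
    }
  }
  if (is.null(out))
    return(data.frame(start = integer(), end = integer(),
                      length = integer()))
  out <- unique(out[order(out$start, out$length), , drop = FALSE])
  rownames(out) <- NULL
  out
}
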