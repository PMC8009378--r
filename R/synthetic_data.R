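# Synthetic fixtures: random backgrounds, colony-PCR cohort tables matching
# the published repair-class compositions, and junction sequence pairs with
# planted ground truth.

#' Random DNA sequence with a given GC content
#'
#' Bases are drawn i.i.d.; G and C each get `gc_content/2` probability.
#' Deterministic for a fixed seed.
#'
#' @param length number of bases (>= 1).
#' @param gc_content GC fraction in `[0, 1]` (default 0.38).
#' @param seed optional integer seed; if NULL the current RNG state is used.
#' @return DNA string of the requested length.
#' @export
random_sequence <- function(length, gc_content = 0.38, seed = NULL) {
  if (length < 1L) stop("length must be >= 1", call. = FALSE)
  if (gc_content < 0 || gc_content > 1)
    stop("gc_content must be in [0, 1]", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  probs <- c(A = (1 - gc_content) / 2, C = gc_content / 2,
             G = gc_content / 2, T = (1 - gc_content) / 2)
  paste(sample(names(probs), length, replace = TRUE, prob = probs),
        collapse = "")
}

## ---- junction fixtures -----------------------------------------------------

#' Specification for simulated deletion-junction fixtures
#'
#' Defaults mirror the envelope of the sequenced GALCEN3 deletion products:
#' deletions of 278-585 bp with 1-9 bp of junction microhomology, and an
#' occasional short insertion at the junction.
#'
#' @param n number of junctions.
#' @param del_range integer deletion-size range in bp (default c(278, 585)).
#' @param mh_range integer microhomology range in bp (default c(1, 9)).
#' @param p_insertion probability that a junction carries inserted novel
#'   bases instead of microhomology (default 0.1).
#' @param ins_len_range insertion length range (default c(1, 3)).
#' @param mh_zero_inflation extra probability mass on zero microhomology
#'   (default 0; junctions without identifiable homology do occur).
#' @param seed integer seed.
#' @return an object of class `bfb_junction_spec`.
#' @export
junction_spec <- function(n = 100L, del_range = c(278L, 585L),
                          mh_range = c(1L, 9L), p_insertion = 0.1,
                          ins_len_range = c(1L, 3L),
                          mh_zero_inflation = 0, seed = 1L) {
  stopifnot(length(del_range) == 2L, del_range[1L] <= del_range[2L],
            length(mh_range) == 2L, mh_range[1L] <= mh_range[2L],
            mh_range[1L] >= 0L,
            p_insertion >= 0, p_insertion <= 1,
            mh_zero_inflation >= 0, mh_zero_inflation <= 1,
            del_range[1L] > mh_range[2L] + 2L)
  structure(list(n = as.integer(n), del_range = as.integer(del_range),
                 mh_range = as.integer(mh_range),
                 p_insertion = p_insertion,
                 ins_len_range = as.integer(ins_len_range),
                 mh_zero_inflation = mh_zero_inflation,
                 seed = as.integer(seed)),
            class = "bfb_junction_spec")
}

## force maximal-microhomology planting: after copying the mh seed across the
## junction, single bases inside the deleted interval are set so the shared
## flank cannot extend in either direction; recovery is then exact.
plant_junction <- function(ref_allele, del_size, mh, insertion = "") {
  L <- nchar(ref_allele)
  need <- del_size + mh + 2L
  if (L < need + 2L)
    stop("ref_allele too short for requested deletion", call. = FALSE)
  d <- draw_int(2L, L - del_size - mh - 1L)
  e <- d + del_size - 1L
  r <- ref_allele
  if (nzchar(insertion)) {
    ni <- nchar(insertion)
    ## junction insertions suppress microhomology bookkeeping; pin both ends
    ## of the insert so prefix/suffix scans stop at the true breakpoints
    if (ni == 1L) {
      substr(insertion, 1L, 1L) <-
        other_base(c(substr(r, d, d), substr(r, e, e)))
    } else {
      substr(insertion, 1L, 1L) <- other_base(substr(r, d, d))
      substr(insertion, ni, ni) <- other_base(substr(r, e, e))
    }
    derived <- paste0(substr(r, 1L, d - 1L), insertion,
                      substr(r, e + 1L, L))
    truth <- list(del_start = d, del_end = e, del_size = del_size,
                  mh_total = 0L, insertion = insertion)
    return(list(ref = r, derived = derived, truth = truth))
  }
  if (mh > 0L)
    substr(r, e + 1L, e + mh) <- substr(r, d, d + mh - 1L)
  ## block extension: right of the seed ...
  substr(r, d + mh, d + mh) <-
    other_base(substr(r, e + mh + 1L, e + mh + 1L))
  ## ... and left of the junction (position e is inside the deletion)
  substr(r, e, e) <- other_base(substr(r, d - 1L, d - 1L))
  derived <- paste0(substr(r, 1L, d - 1L), substr(r, e + 1L, L))
  truth <- list(del_start = d, del_end = e, del_size = del_size,
                mh_total = mh, insertion = "")
  list(ref = r, derived = derived, truth = truth)
}

#' Simulate one derivative allele with a planted deletion junction
#'
#' Plants a deletion whose flanks realize exactly the drawn microhomology
#' (copying the mh bases across the junction before deleting, then pinning
#' the flanking bases so the planted mh is maximal), or optionally a junction
#' with inserted novel bases. The (locally modified) reference allele is
#' returned with the derivative so downstream recovery is well defined.
#'
#' @param ref_allele reference allele DNA string.
#' @param spec a [junction_spec()].
#' @return list with `ref`, `derived`, and `truth`
#'   (del_start, del_end, del_size, mh_total, insertion).
#' @export
random_junction <- function(ref_allele, spec = junction_spec()) {
  del_size <- draw_int(spec$del_range[1L], spec$del_range[2L])
  ins <- ""
  mh <- 0L
  if (runif(1) < spec$p_insertion) {
    ni <- draw_int(spec$ins_len_range[1L], spec$ins_len_range[2L])
    ins <- random_sequence(ni, 0.5)
  } else if (spec$mh_zero_inflation > 0 && runif(1) < spec$mh_zero_inflation) {
    mh <- 0L
  } else {
    mh <- draw_int(spec$mh_range[1L], spec$mh_range[2L])
  }
  plant_junction(ref_allele, del_size, mh, ins)
}

#' Generate a cohort of junction fixtures
#'
#' @param spec a [junction_spec()]; `spec$seed` fixes the whole fixture set.
#' @param ref_allele optional shared reference allele; by default a fresh
#'   random allele long enough for the largest deletion is drawn per junction.
#' @return list of [random_junction()] results, length `spec$n`.
#' @export
random_junctions <- function(spec = junction_spec(), ref_allele = NULL) {
  set.seed(spec$seed)
  lapply(seq_len(spec$n), function(i) {
    ra <- ref_allele %||%
      random_sequence(spec$del_range[2L] + 200L, 0.38)
    random_junction(ra, spec)
  })
}

## ---- colony-PCR cohort fixtures -------------------------------------------

## canonical presence/absence pattern for each repair class, in the TSV
## schema used throughout (one row per colony)
canonical_pattern <- function(class, galcen_len = 932L, ecen_len = 900L,
                              rearr_len = 1162L, recip_len = 640L,
                              reduced_len = 532L) {
  ab <- function(state, len = NA_integer_) list(state = state, len = len)
  row <- switch(
    class,
    HR = list(eCEN3 = ab("absent"), GALCEN3 = ab("absent"),
              rearr = ab("present", rearr_len),
              recip = ab("present", recip_len)),
    SSA = list(eCEN3 = ab("absent"), GALCEN3 = ab("absent"),
               rearr = ab("present", rearr_len), recip = ab("absent")),
    EJ = list(eCEN3 = ab("wildtype_size", ecen_len),
              GALCEN3 = ab("reduced_size", reduced_len),
              rearr = ab("absent"), recip = ab("absent")),
    SSA_plus_EJ = list(eCEN3 = ab("wildtype_size", ecen_len),
                       GALCEN3 = ab("absent"), rearr = ab("absent"),
                       recip = ab("present", recip_len)),
    unrearranged = list(eCEN3 = ab("wildtype_size", ecen_len),
                        GALCEN3 = ab("wildtype_size", galcen_len),
                        rearr = ab("absent"), recip = ab("absent")),
    aneuploid = list(eCEN3 = ab("wildtype_size", ecen_len),
                     GALCEN3 = ab("wildtype_size", galcen_len),
                     rearr = ab("present", rearr_len), recip = ab("absent")),
    stop("no canonical PCR pattern for class ", class, call. = FALSE)
  )
  data.frame(
    eCEN3_state = row$eCEN3$state, eCEN3_len = row$eCEN3$len,
    GALCEN3_state = row$GALCEN3$state, GALCEN3_len = row$GALCEN3$len,
    rearr_state = row$rearr$state, rearr_len = row$rearr$len,
    recip_state = row$recip$state, recip_len = row$recip$len,
    stringsAsFactors = FALSE
  )
}

#' Cohort specification: repair-class composition of a colony panel
#'
#' @param label cohort label, e.g. "57.7kb-WT".
#' @param composition named integer vector, class -> colony count.
#' @param approximate flag marking compositions published only approximately
#'   (excluded from exact checks).
#' @return an object of class `bfb_cohort_spec`.
#' @export
cohort_spec <- function(label, composition, approximate = FALSE) {
  stopifnot(is.numeric(composition), length(composition) > 0L,
            !is.null(names(composition)), all(composition >= 0))
  structure(list(label = label,
                 composition = setNames(as.integer(composition),
                                        names(composition)),
                 n_colonies = sum(as.integer(composition)),
                 approximate = isTRUE(approximate)),
            class = "bfb_cohort_spec")
}

#' Packaged cohort specifications for the published colony panels
#'
#' Reads the packaged composition table (integer counts out of 30 colonies
#' per strain). The 57.7 kb wild-type panel is printed exactly
#' (40% EJ / 33% HR / 20% SSA+EJ / 7% unrearranged, i.e. 12/10/6/2 of 30);
#' the remaining panels are stated only approximately in the source and are
#' flagged `approximate`.
#'
#' @param label optional panel label (e.g. "57.7kb-WT"); if NULL, all specs.
#' @return a `bfb_cohort_spec`, or a named list of them.
#' @export
packaged_cohorts <- function(label = NULL) {
  path <- system.file("extdata", "fig_cohort_compositions.tsv",
                      package = "bfbsim", mustWork = TRUE)
  tab <- read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  specs <- lapply(split(tab, tab$label), function(d) {
    cohort_spec(d$label[1L], setNames(d$count, d$class),
                approximate = any(d$approximate))
  })
  if (is.null(label)) return(specs)
  if (!label %in% names(specs))
    stop("unknown packaged cohort: ", label, call. = FALSE)
  specs[[label]]
}

#' Emit a colony-PCR pattern table for a cohort specification
#'
#' Produces exactly the specified count of each class's canonical pattern,
#' in the standard cohort TSV schema.
#'
#' @param spec a [cohort_spec()] (or packaged label via [packaged_cohorts()]).
#' @return data frame with colony_id and the four assay state/length columns.
#' @export
fig4_cohort <- function(spec) {
  stopifnot(inherits(spec, "bfb_cohort_spec"))
  rows <- lapply(names(spec$composition), function(cl) {
    k <- spec$composition[[cl]]
    if (k == 0L) return(NULL)
    do.call(rbind, replicate(k, canonical_pattern(cl), simplify = FALSE))
  })
  out <- do.call(rbind, rows)
  if (is.null(out) || nrow(out) != spec$n_colonies)
    stop("composition/count mismatch in cohort spec", call. = FALSE)
  cbind(colony_id = sprintf("%s_c%03d", spec$label, seq_len(nrow(out))),
        out, stringsAsFactors = FALSE)
}
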