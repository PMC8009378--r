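# Junction analysis: locate the deletion in a sequenced derivative allele
# relative to its reference allele, decompose the junction into
# microhomology / inserted bases, and label the likely joining mechanism.
#
# Breakpoint placement is ambiguous whenever the junction carries
# microhomology: a junction with mh_total bases of flanking homology has
# mh_total + 1 equivalent placements. The reported interval is the leftmost
# (VCF-style left alignment).

#' Locate a deletion (and any junction insertion) in a derivative allele
#'
#' Compares the derivative against the reference allele by longest common
#' prefix/suffix. If prefix + suffix reconstruct the derivative the junction
#' is a pure deletion, reported at its leftmost equivalent placement;
#' otherwise the unexplained middle of the derivative is reported as
#' inserted bases and the deletion spans the unexplained middle of the
#' reference.
#'
#' @param ref_allele reference allele DNA string.
#' @param derived_allele derivative allele DNA string (shorter than the
#'   reference).
#' @param max_insertion junctions needing more than this many inserted bases
#'   are rejected as unalignable by this procedure (default 50).
#' @return list with del_start, del_end (1-based inclusive, leftmost),
#'   del_size, inserted_bases.
#' @export
find_deletion <- function(ref_allele, derived_allele, max_insertion = 50L) {
  nr <- nchar(ref_allele)
  nd <- nchar(derived_allele)
  if (nr == 0L || nd == 0L) stop("empty input", call. = FALSE)
  if (nd >= nr)
    stop("derived allele is not shorter than the reference", call. = FALSE)
  p <- common_prefix_len(ref_allele, derived_allele)
  s <- common_suffix_len(ref_allele, derived_allele)
  s <- min(s, nd)
  p <- min(p, nd - s)   # cap the prefix: maximal suffix gives the leftmost placement
  size <- nr - nd
  if (p + s == nd) {
    d <- nr - size - s + 1L
    return(list(del_start = d, del_end = d + size - 1L, del_size = size,
                inserted_bases = ""))
  }
  ins <- substr(derived_allele, p + 1L, nd - s)
  if (nchar(ins) > max_insertion)
    stop("junction needs ", nchar(ins), " inserted bases; local realignment ",
         "beyond this procedure's scope", call. = FALSE)
  list(del_start = p + 1L, del_end = nr - s,
       del_size = (nr - s) - p, inserted_bases = ins)
}

#' Microhomology decomposition of a deletion interval
#'
#' For the deletion `ref[d..e]`: `mh_right` is the longest common prefix of
#' the deleted sequence and the sequence following it; `mh_left` the longest
#' common suffix of the sequence preceding the deletion and the deleted
#' sequence. The junction has `mh_total + 1` equivalent breakpoint
#' placements.
#'
#' @param ref_allele reference allele DNA string.
#' @param del_start,del_end deletion interval, 1-based inclusive.
#' @return list with mh_left, mh_right, mh_total, placements.
#' @export
microhomology <- function(ref_allele, del_start, del_end) {
  n <- nchar(ref_allele)
  d <- as.integer(del_start); e <- as.integer(del_end)
  if (d < 1L || e > n || d > e)
    stop("deletion interval outside the reference", call. = FALSE)
  mh_right <- if (e >= n) 0L else
    common_prefix_len(substr(ref_allele, d, n), substr(ref_allele, e + 1L, n))
  mh_left <- if (d <= 1L) 0L else
    common_suffix_len(substr(ref_allele, 1L, d - 1L),
                      substr(ref_allele, 1L, e))
  list(mh_left = mh_left, mh_right = mh_right,
       mh_total = mh_left + mh_right,
       placements = mh_left + mh_right + 1L)
}

#' Full junction call for a reference/derivative allele pair
#'
#' @inheritParams find_deletion
#' @param threshold_mmej microhomology length at or above which the junction
#'   is labelled MMEJ (default 5).
#' @return an object of class `bfb_junction_call`: deletion interval and
#'   size, inserted bases, mh decomposition, placements, mechanism label.
#' @export
call_junction <- function(ref_allele, derived_allele, threshold_mmej = 5L,
                          max_insertion = 50L) {
  del <- find_deletion(ref_allele, derived_allele, max_insertion)
  mh <- if (nzchar(del$inserted_bases))
    list(mh_left = 0L, mh_right = 0L, mh_total = 0L, placements = 1L)
  else
    microhomology(ref_allele, del$del_start, del$del_end)
  call <- c(del, mh)
  call$mechanism <- label_mechanism(call, threshold_mmej)
  class(call) <- "bfb_junction_call"
  call
}

#' Label the likely joining mechanism of a junction
#'
#' Junctions with long microhomology look microhomology-mediated (MMEJ);
#' blunt joins without inserted bases look non-homologous (NHEJ); the 2-4 bp
#' middle ground is left ambiguous. The observed 1-9 bp range does not
#' dichotomize cleanly, so the threshold is a configurable convention.
#'
#' @param call a junction call (needs mh_total and inserted_bases).
#' @param threshold_mmej mh length at or above which MMEJ is called
#'   (default 5).
#' @return "MMEJ", "NHEJ" or "ambiguous".
#' @export
label_mechanism <- function(call, threshold_mmej = 5L) {
  if (call$mh_total >= threshold_mmej) return("MMEJ")
  if (call$mh_total <= 1L && !nzchar(call$inserted_bases)) return("NHEJ")
  "ambiguous"
}

#' Aggregate statistics over a cohort of junction calls
#'
#' @param calls list of `bfb_junction_call` (or compatible lists).
#' @param core_interval optional c(start, end) of the centromere core in the
#'   reference allele frame; when given, every deletion is audited for
#'   complete core removal. A junction passes if any of its equivalent
#'   breakpoint placements (the reported leftmost interval shifted right by
#'   up to mh_total) covers the core.
#' @return list with n, deletion size min/max/median, microhomology length
#'   histogram (table), fraction of junctions with insertions, and (when
#'   audited) `core_removed_all` plus the indices of violating calls.
#' @export
junction_cohort_stats <- function(calls, core_interval = NULL) {
  if (length(calls) == 0L) stop("empty junction cohort", call. = FALSE)
  sizes <- vapply(calls, function(x) as.integer(x$del_size), integer(1))
  mh <- vapply(calls, function(x) as.integer(x$mh_total), integer(1))
  ins <- vapply(calls, function(x) nzchar(x$inserted_bases), logical(1))
  out <- list(n = length(calls),
              del_min = min(sizes), del_max = max(sizes),
              del_median = median(sizes),
              mh_hist = table(mh),
              frac_insertion = mean(ins))
  if (!is.null(core_interval)) {
    covered <- vapply(calls, function(x) {
      k_lo <- max(0L, core_interval[2L] - x$del_end)
      k_hi <- min(x$mh_total, core_interval[1L] - x$del_start)
      k_lo <= k_hi
    }, logical(1))
    out$core_removed_all <- all(covered)
    out$core_violations <- which(!covered)
  }
  out
}
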