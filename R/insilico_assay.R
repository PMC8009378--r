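# In-silico PCR genotyping and the repair-class decision key.
#
# Four diagnostic assays on colony DNA:
#   eCEN3         eC1 + eC2   (intact endogenous centromere)
#   GALCEN3       GC1 + GC2   (intact conditional centromere; 932 bp wild type)
#   rearrangement GC1 + eC2   (hybrid GALCEN3/eCEN3 centromere)
#   reciprocal    eC1 + GC2   (hybrid eCEN3/GALCEN3 centromere)
# Each colony's pattern of present / wild-type-size / reduced-size products
# maps deterministically onto a repair class.

REPAIR_CLASSES <- c("HR", "SSA", "EJ", "unrearranged", "aneuploid",
                    "SSA_plus_EJ", "unclassified")

#' Diagnostic primer panel
#'
#' @param primers named character vector with GC1, GC2, eC1, eC2 (defaults
#'   are the published assay primers).
#' @param max_amplicon longest detectable product in bp (default 6000).
#' @param reduced_margin a parental product shorter than
#'   `expected - reduced_margin` counts as reduced/deleted (default 50).
#' @return an object of class `bfb_primer_panel` with the four assay pairs.
#' @export
primer_panel <- function(primers = DEFAULT_PRIMERS, max_amplicon = 6000L,
                         reduced_margin = 50L) {
  stopifnot(all(c("GC1", "GC2", "eC1", "eC2") %in% names(primers)),
            all(nzchar(primers)))
  structure(list(
    primers = primers,
    assays = list(
      eCEN3 = c("eC1", "eC2"),
      GALCEN3 = c("GC1", "GC2"),
      rearr = c("GC1", "eC2"),
      recip = c("eC1", "GC2")
    ),
    max_amplicon = as.integer(max_amplicon),
    reduced_margin = as.integer(reduced_margin)
  ), class = "bfb_primer_panel")
}

#' Predict PCR products from a template by exact primer matching
#'
#' Scans for the forward primer and the reverse complement of the reverse
#' primer (and the swapped orientation) and reports every convergent pair
#' within `max_amplicon`. Circular templates are scanned across the origin.
#'
#' @param template DNA string.
#' @param fwd,rev primer sequences (>= 15 nt).
#' @param max_amplicon longest reported product in bp.
#' @param circular treat the template as circular.
#' @return data frame with columns start, end, length (template coordinates;
#'   for circular templates `end` may exceed the template length, meaning
#'   the product wraps the origin). Zero rows if no product.
#' @export
insilico_pcr <- function(template, fwd, rev, max_amplicon = 6000L,
                         circular = FALSE) {
  if (nchar(fwd) < 15L || nchar(rev) < 15L)
    stop("primers must be at least 15 nt", call. = FALSE)
  L <- nchar(template)
  subject <- if (circular) paste0(template, template) else template
  pairs <- function(p_fwd, p_rev) {
    fs <- find_all(p_fwd, subject)                 # forward primer, plus strand
    rs <- find_all(revcomp(p_rev), subject)        # reverse primer, minus strand
    if (!length(fs) || !length(rs)) return(NULL)
    grid <- expand.grid(f = fs, r = rs)
    grid$end <- grid$r + nchar(p_rev) - 1L
    grid$len <- grid$end - grid$f + 1L
    keep <- grid$f < grid$r & grid$len <= max_amplicon
    if (circular) keep <- keep & grid$f <= L & grid$len <= L
    grid[keep, , drop = FALSE]
  }
  hits <- rbind(pairs(fwd, rev), pairs(rev, fwd))
  if (is.null(hits) || nrow(hits) == 0L)
    return(data.frame(start = integer(), end = integer(),
                      length = integer()))
  out <- data.frame(start = as.integer(hits$f), end = as.integer(hits$end),
                    length = as.integer(hits$len))
  out <- unique(out[order(out$start, out$length), , drop = FALSE])
  rownames(out) <- NULL
  out
}

## one assay over all chromosomes of a colony (products pooled across
## chromosomes, as for DNA prepped from a single colony)
assay_products <- function(kt, ref, panel, assay) {
  pr <- panel$assays[[assay]]
  fwd <- panel$primers[[pr[1L]]]
  rev <- panel$primers[[pr[2L]]]
  lens <- integer(0)
  for (chrom in kt$chromosomes) {
    tmpl <- realize_sequence(chrom, ref)
    hits <- insilico_pcr(tmpl, fwd, rev, panel$max_amplicon,
                         circular = chrom$topology == "circular")
    lens <- c(lens, hits$length)
  }
  sort(unique(lens))
}

#' Genotype a colony: run the four diagnostic assays on its karyotype
#'
#' Parental assays score `wildtype_size` when a product of (about) the
#' expected length is seen, `reduced_size` when only shorter products are
#' seen, and `absent` otherwise; hybrid assays score `present`/`absent`.
#'
#' @param kt a `bfb_karyotype`.
#' @param ref a `bfb_reference`.
#' @param panel a [primer_panel()].
#' @param colony_id identifier carried into the output row.
#' @return one-row data frame in the standard cohort schema (colony_id,
#'   then state and length for eCEN3, GALCEN3, rearr, recip).
#' @export
genotype_colony <- function(kt, ref, panel = primer_panel(),
                            colony_id = "colony1") {
  expected <- c(eCEN3 = ref$config$ecen_amplicon_len,
                GALCEN3 = ref$config$galcen_amplicon_len)
  res <- list()
  for (assay in names(panel$assays)) {
    lens <- assay_products(kt, ref, panel, assay)
    if (assay %in% names(expected)) {
      exp_len <- expected[[assay]]
      if (any(lens >= exp_len - panel$reduced_margin)) {
        st <- "wildtype_size"; ln <- max(lens)
      } else if (length(lens)) {
        st <- "reduced_size"; ln <- max(lens)
      } else {
        st <- "absent"; ln <- NA_integer_
      }
    } else {
      if (length(lens)) {
        st <- "present"; ln <- min(lens)
      } else {
        st <- "absent"; ln <- NA_integer_
      }
    }
    res[[paste0(assay, "_state")]] <- st
    res[[paste0(assay, "_len")]] <- as.integer(ln)
  }
  cbind(data.frame(colony_id = colony_id, stringsAsFactors = FALSE),
        as.data.frame(res, stringsAsFactors = FALSE))
}

#' Classify a colony PCR pattern into a repair class
#'
#' Deterministic decision list (a parental centromere counts as present only
#' at wild-type size; reduced or absent means deleted):
#' \enumerate{
#'   \item HR: rearrangement and reciprocal products, neither parental.
#'   \item aneuploid: rearrangement product plus at least one parental.
#'   \item SSA: rearrangement only.
#'   \item SSA+EJ: reciprocal product plus eCEN3, no rearrangement, no
#'     GALCEN3.
#'   \item unrearranged: both parentals, no hybrid products.
#'   \item EJ: exactly one parental, no hybrids.
#'   \item otherwise unclassified.
#' }
#'
#' @param pattern one-row data frame in the cohort schema (as produced by
#'   [genotype_colony()] or [fig4_cohort()]).
#' @return a repair class string.
#' @export
classify_pattern <- function(pattern) {
  gal <- identical(pattern$GALCEN3_state, "wildtype_size")
  ecen <- identical(pattern$eCEN3_state, "wildtype_size")
  ## deleted-but-detectable parentals still rule out "intact"
  gal_any <- pattern$GALCEN3_state %in% c("wildtype_size", "reduced_size")
  ecen_any <- pattern$eCEN3_state %in% c("wildtype_size", "reduced_size")
  rearr <- !identical(pattern$rearr_state, "absent")
  recip <- !identical(pattern$recip_state, "absent")
  if (rearr && recip && !gal && !ecen) return("HR")
  if (rearr && (gal || ecen)) return("aneuploid")
  if (rearr && !recip && !gal && !ecen) return("SSA")
  if (recip && ecen && !rearr && !gal) return("SSA_plus_EJ")
  if (gal && ecen && !rearr && !recip) return("unrearranged")
  if (!rearr && !recip && xor(gal, ecen) && (gal_any || ecen_any))
    return("EJ")
  "unclassified"
}

#' Classify every colony in a cohort table
#' @param patterns cohort data frame (one row per colony).
#' @return the input with a `class` column appended.
#' @export
classify_cohort <- function(patterns) {
  patterns$class <- vapply(seq_len(nrow(patterns)), function(i) {
    classify_pattern(patterns[i, , drop = FALSE])
  }, character(1))
  patterns
}

#' Repair-class distribution of a cohort
#'
#' @param classes character vector of repair classes, or a cohort data frame
#'   with a `class` column.
#' @return data frame with class, count and percent (one decimal; percents
#'   sum to 100 within rounding).
#' @export
summarize_cohort <- function(classes) {
  if (is.data.frame(classes)) classes <- classes$class
  if (length(classes) == 0L) stop("empty cohort", call. = FALSE)
  tab <- table(factor(classes, levels = REPAIR_CLASSES))
  tab <- tab[tab > 0L]
  data.frame(class = names(tab), count = as.integer(tab),
             percent = round(100 * as.integer(tab) / sum(tab), 1L),
             stringsAsFactors = FALSE)
}

## ---- circular-derivative contiguity mapping --------------------------------

#' Tile a circular derivative with overlapping in-silico amplicons
#'
#' Emulates contiguity mapping of a candidate circular chromosome with
#' nested primer pairs: tiling primers are taken from the realized circle
#' sequence every `tile_len - overlap` bp, each pair is amplified in silico
#' on the circular template, and the union of amplicons is checked to cover
#' the full circumference.
#'
#' @param kt a `bfb_karyotype`.
#' @param ref a `bfb_reference`.
#' @param tile_len amplicon tile length in bp (default 2000).
#' @param overlap overlap between adjacent tiles in bp (default 500).
#' @param primer_len tiling primer length (default 20).
#' @param ablate optional integer vector of tile indices whose forward
#'   priming site is treated as absent (for gap detection checks).
#' @return data frame, one row per tile per circular chromosome: circle
#'   index, tile index, start, product length (NA if no product), plus
#'   attribute `full_coverage` (logical per circle, as a named vector).
#'   Zero rows if the karyotype has no circular chromosome.
#' @export
circle_contiguity <- function(kt, ref, tile_len = 2000L, overlap = 500L,
                              primer_len = 20L, ablate = integer(0)) {
  circles <- which(vapply(kt$chromosomes,
                          function(ch) ch$topology == "circular", logical(1)))
  out <- NULL
  coverage <- logical(0)
  for (ci in seq_along(circles)) {
    chrom <- kt$chromosomes[[circles[ci]]]
    s <- realize_sequence(chrom, ref)
    L <- nchar(s)
    step <- tile_len - overlap
    starts <- seq.int(1L, L, by = step)
    s2 <- paste0(s, s)
    covered <- logical(L)
    rows <- lapply(seq_along(starts), function(ti) {
      o <- starts[ti]
      fwd <- substr(s2, o, o + primer_len - 1L)
      rev <- revcomp(substr(s2, o + tile_len - primer_len,
                            o + tile_len - 1L))
      if (ti %in% ablate)
        return(data.frame(circle = ci, tile = ti, start = o,
                          product_len = NA_integer_))
      hits <- insilico_pcr(s, fwd, rev, max_amplicon = tile_len + primer_len,
                           circular = TRUE)
      if (nrow(hits)) {
        idx <- ((hits$start[1L] - 1L):(hits$end[1L] - 1L)) %% L + 1L
        covered[idx] <<- TRUE
      }
      data.frame(circle = ci, tile = ti, start = o,
                 product_len = if (nrow(hits)) hits$length[1L]
                               else NA_integer_)
    })
    out <- rbind(out, do.call(rbind, rows))
    coverage <- c(coverage, setNames(all(covered), paste0("circle", ci)))
  }
  if (is.null(out))
    out <- data.frame(circle = integer(), tile = integer(),
                      start = integer(), product_len = integer())
  attr(out, "full_coverage") <- coverage
  out
}
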