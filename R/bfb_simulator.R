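# BFB simulator: division cycles of cells carrying an activated dicentric.
#
# Model summary (founder-lineage approximation):
#  * each division, every dicentric chromosome breaks with probability
#    p_break (~50% chance the two non-sister kinetochores on one strand
#    orient to opposite poles and the anaphase bridge is severed);
#  * the break position follows a mixture: half the probability mass falls
#    within 10 kb of either centromere, the rest is uniform over the
#    inter-centromeric span;
#  * the break resolves by one of four routes, drawn proportionally to
#    distance-class propensities times genotype modifiers:
#      SSA       linear monocentric deletion chromosome (anneals the two
#                336 bp homology blocks, losing the intervening DNA)
#      RCO       composite reciprocal-crossover outcome: linear monocentric
#                deletion chromosome plus a circular monocentric derivative
#                carrying the full inter-centromeric segment
#      EJ        two cuts flanking one centromere core remove it entirely
#                (278-585 bp deletion, 1-9 bp junction microhomology);
#                GALCEN3 is deleted with probability 0.7
#      refusion  the ends rejoin, regenerating the dicentric (BFB continues)
#  * the colony's fate is that of a single founder lineage, matching the
#    single-colony PCR readout.

PATHWAYS <- c("SSA", "RCO", "EJ", "refusion")
DISTANCE_LABELS <- c("6.5", "9.8", "12.3", "18.2", "46.3", "57.7")

default_propensities <- function() {
  ## calibration knobs, not predictions: chosen so wild-type cohorts
  ## reproduce the observed regime at each distance (SSA-dominant at 6.5 kb,
  ## EJ-dominant at 9.8-18.2 kb, crossover-dominant at 46.3 kb, mixed with
  ## frequent refusion at 57.7 kb)
  list(
    `6.5`  = c(SSA = 0.70, RCO = 0.05, EJ = 0.10, refusion = 0.15),
    `9.8`  = c(SSA = 0.02, RCO = 0.03, EJ = 0.85, refusion = 0.10),
    `12.3` = c(SSA = 0.02, RCO = 0.03, EJ = 0.85, refusion = 0.10),
    `18.2` = c(SSA = 0.02, RCO = 0.03, EJ = 0.85, refusion = 0.10),
    `46.3` = c(SSA = 0.12, RCO = 0.55, EJ = 0.08, refusion = 0.25),
    `57.7` = c(SSA = 0.15, RCO = 0.30, EJ = 0.05, refusion = 0.50)
  )
}

#' Simulation parameters for the BFB cycle
#'
#' @param p_break probability a dicentric breaks at each division
#'   (default 0.5).
#' @param break_locality_weight probability mass placed within
#'   `locality_window` of either centromere (default 0.5).
#' @param locality_window size of the pericentric break window in bp
#'   (default 10000).
#' @param pathway_propensities named list (distance label ->
#'   c(SSA, RCO, EJ, refusion) weights); see `default_propensities`.
#' @param ej_galcen_bias probability an end-joining event deletes GALCEN3
#'   rather than eCEN3 (default 0.7).
#' @param ej_del_range end-joining deletion size range in bp
#'   (default c(278, 585)); the minimum must exceed the centromere core plus
#'   a small flank so the whole core is always removed.
#' @param ej_mh_range junction microhomology range in bp (default c(1, 9)).
#' @param p_nondisjunction probability per division that one chromosome is
#'   duplicated in the followed daughter (default 0.01).
#' @param max_cycles divisions before an unresolved lineage is scored dead
#'   (default 20).
#' @return an object of class `bfb_params`.
#' @export
sim_params <- function(p_break = 0.5,
                       break_locality_weight = 0.5,
                       locality_window = 10000L,
                       pathway_propensities = default_propensities(),
                       ej_galcen_bias = 0.7,
                       ej_del_range = c(278L, 585L),
                       ej_mh_range = c(1L, 9L),
                       p_nondisjunction = 0.01,
                       max_cycles = 20L) {
  probs <- c(p_break, break_locality_weight, ej_galcen_bias,
             p_nondisjunction)
  if (any(probs < 0 | probs > 1))
    stop("probabilities must be in [0, 1]", call. = FALSE)
  stopifnot(ej_del_range[1L] <= ej_del_range[2L],
            ej_mh_range[1L] >= 0L, ej_mh_range[1L] <= ej_mh_range[2L],
            max_cycles >= 1L)
  for (w in pathway_propensities) {
    if (any(w < 0) || !all(PATHWAYS %in% names(w)))
      stop("each propensity entry needs non-negative SSA/RCO/EJ/refusion ",
           "weights", call. = FALSE)
  }
  structure(list(p_break = p_break,
                 break_locality_weight = break_locality_weight,
                 locality_window = as.integer(locality_window),
                 pathway_propensities = pathway_propensities,
                 ej_galcen_bias = ej_galcen_bias,
                 ej_del_range = as.integer(ej_del_range),
                 ej_mh_range = as.integer(ej_mh_range),
                 p_nondisjunction = p_nondisjunction,
                 max_cycles = as.integer(max_cycles)),
            class = "bfb_params")
}

#' Genotype presets modifying repair-pathway propensities
#'
#' Modifiers multiply the SSA/RCO/EJ propensities (refusion is unaffected).
#' `rad52` removes both homology pathways, `lif1` removes end-joining, and
#' `mrc1` is a phenomenological stand-in that penalizes homology pathways
#' only when the centromeres are more than 20 kb apart (its mechanism is not
#' modeled).
#'
#' @param name one of "WT", "rad52", "lif1", "mrc1", "custom".
#' @param modifiers named multiplicative factors on c(SSA, RCO, EJ), applied
#'   at all distances (used with name = "custom").
#' @param far_modifiers factors applied instead when the centromere
#'   separation exceeds `far_threshold_kb`.
#' @param far_threshold_kb distance threshold in kb (default 20).
#' @return an object of class `bfb_genotype`.
#' @export
genotype <- function(name = c("WT", "rad52", "lif1", "mrc1", "custom"),
                     modifiers = c(SSA = 1, RCO = 1, EJ = 1),
                     far_modifiers = NULL,
                     far_threshold_kb = 20) {
  name <- match.arg(name)
  preset <- switch(name,
    WT = list(near = c(SSA = 1, RCO = 1, EJ = 1), far = NULL),
    rad52 = list(near = c(SSA = 0, RCO = 0, EJ = 1), far = NULL),
    lif1 = list(near = c(SSA = 1, RCO = 1, EJ = 0), far = NULL),
    mrc1 = list(near = c(SSA = 1, RCO = 1, EJ = 1),
                far = c(SSA = 0.1, RCO = 0.1, EJ = 1)),
    custom = list(near = modifiers, far = far_modifiers)
  )
  stopifnot(all(c("SSA", "RCO", "EJ") %in% names(preset$near)),
            all(preset$near >= 0))
  structure(list(name = name, modifiers = preset$near,
                 far_modifiers = preset$far,
                 far_threshold_kb = far_threshold_kb),
            class = "bfb_genotype")
}

genotype_modifiers <- function(gt, distance_kb) {
  if (!is.null(gt$far_modifiers) && distance_kb > gt$far_threshold_kb)
    gt$far_modifiers
  else gt$modifiers
}

## nearest configured distance label for a reference
distance_label <- function(ref) {
  d <- cen_cen_distance(ref)
  DISTANCE_LABELS[which.min(abs(as.numeric(DISTANCE_LABELS) - d))]
}

## engineered-frame coordinates the simulator works with
ref_geometry <- function(ref) {
  cores <- ref$features[ref$features$kind == "centromere_core", ]
  cores <- cores[order(cores$start), ]
  blocks <- ref$features[ref$features$kind == "homology_block", ]
  blocks <- blocks[order(blocks$start), ]
  sites <- ref$features[ref$features$kind == "primer_site", ]
  list(
    gal_core = c(cores$start[1L], cores$end[1L]),
    ecen_core = c(cores$start[2L], cores$end[2L]),
    gal_block = c(blocks$start[1L], blocks$end[1L]),
    ecen_block = c(blocks$start[2L], blocks$end[2L]),
    gc1 = unlist(sites[sites$name == "GC1", c("start", "end")]),
    gc2 = unlist(sites[sites$name == "GC2", c("start", "end")]),
    ec1 = unlist(sites[sites$name == "eC1", c("start", "end")]),
    ec2 = unlist(sites[sites$name == "eC2", c("start", "end")]),
    total_len = ref$length
  )
}

#' Sample a bridge-break position between the two centromeres
#'
#' Draws from a two-component mixture over the inter-centromeric interval:
#' with probability `break_locality_weight`, uniform over the union of the
#' `locality_window` regions flanking each centromere core (clipped to the
#' span); otherwise uniform over the whole span. When the span is shorter
#' than twice the window the locality component degenerates to uniform.
#'
#' @param ref a `bfb_reference`.
#' @param params a [sim_params()].
#' @return an integer coordinate strictly between the two centromere cores.
#' @export
sample_break_position <- function(ref, params = sim_params()) {
  g <- ref_geometry(ref)
  lo <- g$gal_core[2L] + 1L
  hi <- g$ecen_core[1L] - 1L
  if (hi - lo + 1L <= 2L)
    stop("inter-centromeric span too short to break", call. = FALSE)
  w <- params$locality_window
  if (runif(1) < params$break_locality_weight) {
    left <- c(lo, min(lo + w - 1L, hi))
    right <- c(max(hi - w + 1L, lo), hi)
    if (right[1L] <= left[2L]) {           # windows cover the whole span
      return(sample.int(hi - lo + 1L, 1L) + lo - 1L)
    }
    nl <- left[2L] - left[1L] + 1L
    nr <- right[2L] - right[1L] + 1L
    u <- sample.int(nl + nr, 1L)
    if (u <= nl) left[1L] + u - 1L else right[1L] + (u - nl) - 1L
  } else {
    sample.int(hi - lo + 1L, 1L) + lo - 1L
  }
}

## ---- repair ---------------------------------------------------------------

new_event <- function(pathway, break_pos = NA_integer_, deleted = NULL,
                      deleted_centromere = "none", mh_len = NA_integer_,
                      del_size = NA_integer_, products = list(),
                      cycle = NA_integer_) {
  structure(list(pathway = pathway, break_pos = break_pos,
                 deleted_interval = deleted,
                 deleted_centromere = deleted_centromere,
                 mh_len = mh_len, del_size = del_size,
                 products = products, cycle_index = cycle),
            class = "bfb_repair_event")
}

ssa_linear_product <- function(g) {
  ## anneal the two homology blocks; one merged block remains
  chromosome(data.frame(start = c(1L, g$ecen_block[2L] + 1L),
                        end = c(g$gal_block[2L], g$total_len)))
}

rco_circle_product <- function(g) {
  ## reciprocal product: everything between the exchange points, circularized
  chromosome(data.frame(start = g$gal_block[2L] + 1L,
                        end = g$ecen_block[2L]),
             topology = "circular")
}

ej_products <- function(ref, g, params) {
  s <- draw_int(params$ej_del_range[1L], params$ej_del_range[2L])
  mh <- if (params$ej_mh_range[2L] == 0L) 0L else
    draw_int(params$ej_mh_range[1L], params$ej_mh_range[2L])
  del_gal <- runif(1) < params$ej_galcen_bias
  core <- if (del_gal) g$gal_core else g$ecen_core
  ## two-cut abscission: the deletion covers the whole core; placements are
  ## restricted to keep both primer sites of the diagnostic amplicon intact,
  ## so the deleted product is still detected as a reduced-size band
  if (del_gal) {
    r_lo <- max(core[2L], g$gc1[2L] + s)
    r_hi <- g$gc2[1L] - 1L
  } else {
    r_lo <- max(core[2L], g$ec1[2L] + s)
    r_hi <- g$ec2[1L] - 1L
  }
  r_hi <- min(r_hi, core[1L] + s - 1L)
  if (r_lo > r_hi)
    stop("end-joining deletion cannot cover the core within the amplicon; ",
         "check ej_del_range against the reference layout", call. = FALSE)
  r <- draw_int(r_lo, r_hi)
  d <- r - s + 1L
  chrom <- chromosome(data.frame(start = c(1L, r + 1L),
                                 end = c(d - 1L, g$total_len)))
  list(chrom = chrom, del = c(d, r), size = s, mh = mh,
       centromere = if (del_gal) "GALCEN3" else "eCEN3")
}

#' Resolve one dicentric break into a repair event
#'
#' Draws the pathway proportionally to the distance-class propensities times
#' the genotype modifiers, then constructs the product chromosome(s). If all
#' propensities are zero the event is `unrepaired` with no products.
#'
#' @param ref a `bfb_reference`.
#' @param params a [sim_params()].
#' @param gt a [genotype()].
#' @param break_pos break coordinate (default: freshly sampled).
#' @param cycle division index recorded on the event.
#' @return a `bfb_repair_event` with elements pathway, break_pos,
#'   deleted_interval, deleted_centromere, mh_len, del_size, products,
#'   cycle_index.
#' @export
repair_break <- function(ref, params = sim_params(), gt = genotype("WT"),
                         break_pos = NULL, cycle = NA_integer_) {
  g <- ref_geometry(ref)
  if (is.null(break_pos)) break_pos <- sample_break_position(ref, params)
  lab <- distance_label(ref)
  w <- params$pathway_propensities[[lab]][PATHWAYS]
  mods <- genotype_modifiers(gt, cen_cen_distance(ref))
  w[c("SSA", "RCO", "EJ")] <- w[c("SSA", "RCO", "EJ")] *
    mods[c("SSA", "RCO", "EJ")]
  if (sum(w) <= 0)
    return(new_event("unrepaired", break_pos, cycle = cycle))
  path <- sample(PATHWAYS, 1L, prob = w)
  switch(path,
    SSA = {
      lin <- ssa_linear_product(g)
      new_event("SSA", break_pos,
                deleted = c(g$gal_block[2L] + 1L, g$ecen_block[2L]),
                products = list(lin), cycle = cycle)
    },
    RCO = {
      ## composite event: linear deletion chromosome + circular reciprocal
      ## product (the extra circularization exchange is not modeled
      ## separately)
      new_event("RCO", break_pos,
                products = list(ssa_linear_product(g), rco_circle_product(g)),
                cycle = cycle)
    },
    EJ = {
      ej <- ej_products(ref, g, params)
      new_event("EJ", break_pos, deleted = ej$del,
                deleted_centromere = ej$centromere, mh_len = ej$mh,
                del_size = ej$size, products = list(ej$chrom), cycle = cycle)
    },
    refusion = {
      new_event("refusion", break_pos,
                products = list(chromosome(data.frame(start = 1L,
                                                      end = g$total_len))),
                cycle = cycle)
    })
}

#' One division of a karyotype carrying zero or more dicentrics
#'
#' Each dicentric chromosome breaks with probability `p_break` and is
#' replaced by the products of [repair_break()]; monocentric chromosomes
#' segregate intact. With probability `p_nondisjunction` one chromosome is
#' additionally duplicated in the followed daughter.
#'
#' @param kt a `bfb_karyotype`.
#' @param ref a `bfb_reference`.
#' @param params a [sim_params()].
#' @param gt a [genotype()].
#' @param cycle division index recorded on events.
#' @return list with `karyotype` (the followed daughter) and `events`
#'   (list of `bfb_repair_event`, possibly empty).
#' @export
attempt_division <- function(kt, ref, params = sim_params(),
                             gt = genotype("WT"), cycle = NA_integer_) {
  out <- list()
  events <- list()
  for (chrom in kt$chromosomes) {
    if (centromere_count(chrom, ref) >= 2L && runif(1) < params$p_break) {
      ev <- repair_break(ref, params, gt, cycle = cycle)
      events[[length(events) + 1L]] <- ev
      out <- c(out, ev$products)
    } else {
      out <- c(out, list(chrom))
    }
  }
  if (length(out) && runif(1) < params$p_nondisjunction) {
    i <- sample.int(length(out), 1L)
    out <- c(out, out[i])
  }
  list(karyotype = karyotype(out), events = events)
}

## ---- viability ------------------------------------------------------------

#' Audit a karyotype for viability and fitness flags
#'
#' A karyotype is inviable if any essential gene is absent from every
#' chromosome or any chromosome lacks a centromere core. Loss of the
#' fitness gene PGS1 (adjacent to eCEN3, lost in the 6.5 kb SSA product)
#' flags `slow_growth`.
#'
#' @param kt a `bfb_karyotype`.
#' @param ref a `bfb_reference`.
#' @return list with `viable`, `death_cause`
#'   ("essential_gene_loss", "acentric_chromosome" or "none") and
#'   `fitness_flags` (character vector, e.g. "slow_growth").
#' @export
audit_viability <- function(kt, ref) {
  genes <- ref$features[ref$features$kind == "gene", ]
  flags <- character(0)
  cause <- "none"
  viable <- TRUE
  if (any(vapply(kt$chromosomes, function(ch) centromere_count(ch, ref) == 0L,
                 logical(1)))) {
    viable <- FALSE
    cause <- "acentric_chromosome"
  }
  for (i in seq_len(nrow(genes))) {
    present <- any(vapply(kt$chromosomes, interval_present, logical(1),
                          genes$start[i], genes$end[i]))
    if (!present) {
      if (identical(genes$essentiality[i], "essential")) {
        viable <- FALSE
        cause <- "essential_gene_loss"
      } else if (identical(genes$essentiality[i], "fitness")) {
        flags <- union(flags, "slow_growth")
      }
    }
  }
  list(viable = viable, death_cause = cause, fitness_flags = flags)
}

has_dicentric <- function(kt, ref) {
  any(vapply(kt$chromosomes, function(ch) centromere_count(ch, ref) >= 2L,
             logical(1)))
}

## ---- colony simulation ----------------------------------------------------

#' Simulate one colony founder lineage to its fate
#'
#' Iterates [attempt_division()] until every chromosome is stably
#' monocentric, the lineage dies (essential gene loss or an unrepaired
#' break), or `max_cycles` divisions pass. A lineage that reaches
#' `max_cycles` still dicentric after one or more breakage/refusion rounds
#' is scored dead (it never resolved); one whose dicentric simply never
#' broke survives as an unrearranged colony.
#'
#' @param ref a `bfb_reference`.
#' @param params a [sim_params()].
#' @param gt a [genotype()].
#' @param seed optional integer seed for this colony.
#' @return an object of class `bfb_colony_fate`: list with `viable`,
#'   `death_cause`, `fitness_flags`, `final_karyotype`, `event_log`,
#'   `n_cycles`.
#' @export
run_colony <- function(ref, params = sim_params(), gt = genotype("WT"),
                       seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  kt <- founder_karyotype(ref)
  log <- list()
  cause <- "none"
  viable <- TRUE
  cycles_used <- 0L
  n_breaks <- 0L
  for (cycle in seq_len(params$max_cycles)) {
    if (!has_dicentric(kt, ref)) break
    step <- attempt_division(kt, ref, params, gt, cycle = cycle)
    kt <- step$karyotype
    log <- c(log, step$events)
    n_breaks <- n_breaks + length(step$events)
    cycles_used <- cycle
    if (any(vapply(step$events, function(e) e$pathway == "unrepaired",
                   logical(1)))) {
      viable <- FALSE
      cause <- "unrepaired_after_max_cycles"
      break
    }
    aud <- audit_viability(kt, ref)
    if (!aud$viable) {
      viable <- FALSE
      cause <- aud$death_cause
      break
    }
  }
  if (viable && has_dicentric(kt, ref) && n_breaks > 0L) {
    viable <- FALSE
    cause <- "unrepaired_after_max_cycles"
  }
  aud <- audit_viability(kt, ref)
  structure(list(viable = viable, death_cause = cause,
                 fitness_flags = aud$fitness_flags,
                 final_karyotype = kt, event_log = log,
                 n_cycles = cycles_used),
            class = "bfb_colony_fate")
}

#' Simulate a plating of independent colonies
#'
#' Colonies are mutually independent: each gets its own RNG substream
#' derived from `(seed, colony index)`, so a cohort is reproducible and
#' order-independent.
#'
#' @param ref a `bfb_reference`.
#' @param params a [sim_params()].
#' @param gt a [genotype()].
#' @param n_colonies number of colonies (>= 1).
#' @param seed integer master seed.
#' @return list of `bfb_colony_fate`, length `n_colonies`.
#' @export
simulate_plating <- function(ref, params = sim_params(), gt = genotype("WT"),
                             n_colonies = 100L, seed = 1L) {
  stopifnot(n_colonies >= 1L)
  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max, n_colonies)
  lapply(seq_len(n_colonies), function(i) {
    run_colony(ref, params, gt, seed = sub_seeds[i])
  })
}

#' Pool repair events from simulated colonies
#' @param fates list of `bfb_colony_fate` (from [simulate_plating()]).
#' @return data frame, one row per repair event: pathway, break_pos,
#'   deleted_centromere, mh_len, del_size, cycle_index.
#' @export
pool_events <- function(fates) {
  evs <- unlist(lapply(fates, `[[`, "event_log"), recursive = FALSE)
  if (length(evs) == 0L)
    return(data.frame(pathway = character(), break_pos = integer(),
                      deleted_centromere = character(), mh_len = integer(),
                      del_size = integer(), cycle_index = integer(),
                      stringsAsFactors = FALSE))
  data.frame(
    pathway = vapply(evs, `[[`, character(1), "pathway"),
    break_pos = vapply(evs, function(e) as.integer(e$break_pos), integer(1)),
    deleted_centromere = vapply(evs, `[[`, character(1),
                                "deleted_centromere"),
    mh_len = vapply(evs, function(e) as.integer(e$mh_len), integer(1)),
    del_size = vapply(evs, function(e) as.integer(e$del_size), integer(1)),
    cycle_index = vapply(evs, function(e) as.integer(e$cycle_index),
                         integer(1)),
    stringsAsFactors = FALSE
  )
}
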