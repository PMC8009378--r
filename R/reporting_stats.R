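# Viability statistics and report rendering. Purely deterministic
# aggregation: no randomness enters this module.

#' Percent viability from a plating pair
#'
#' Viability of a dicentric strain is the colony count on glucose (dicentric
#' active) divided by the count on galactose (dicentric inactive), as a
#' percentage. Values above 100 are possible with plating noise and are
#' reported as-is.
#'
#' @param n_glucose colonies on glucose (YPD); vectorized.
#' @param n_galactose colonies on galactose (YPG); must be positive.
#' @return percent viability (numeric).
#' @export
viability <- function(n_glucose, n_galactose) {
  if (any(n_galactose <= 0))
    stop("galactose colony count must be positive", call. = FALSE)
  if (any(n_glucose < 0)) stop("counts must be non-negative", call. = FALSE)
  100 * n_glucose / n_galactose
}

#' Two-sample t test on viability percentages
#'
#' Student's (pooled-variance) test by default, matching the published
#' comparisons of each mutant against its distance-matched wild type;
#' Welch's test is available. Two-sided.
#'
#' @param group_a,group_b numeric vectors of replicate viabilities
#'   (>= 2 each).
#' @param variant "student" (pooled variance, default) or "welch".
#' @param alpha significance level for the `significant` flag (default 0.05;
#'   no multiple-testing correction is applied).
#' @return list with statistic, df, p_value, significant, variant.
#' @export
viability_t_test <- function(group_a, group_b,
                             variant = c("student", "welch"),
                             alpha = 0.05) {
  variant <- match.arg(variant)
  if (length(group_a) < 2L || length(group_b) < 2L)
    stop("each group needs at least 2 replicates", call. = FALSE)
  va <- stats::var(group_a); vb <- stats::var(group_b)
  if (va == 0 && vb == 0) {
    ## degenerate: no within-group variance
    if (mean(group_a) == mean(group_b))
      return(list(statistic = 0, df = length(group_a) + length(group_b) - 2L,
                  p_value = 1, significant = FALSE, variant = variant))
    return(list(statistic = Inf,
                df = length(group_a) + length(group_b) - 2L,
                p_value = 0, significant = TRUE, variant = variant))
  }
  tt <- t.test(group_a, group_b, var.equal = variant == "student")
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, significant = tt$p.value < alpha,
       variant = variant)
}

#' Summarize plating results into a viability table
#'
#' @param plating data frame with columns strain, genotype, distance_kb,
#'   replicate, n_ypd, n_ypg.
#' @return data frame with per-replicate percent viability plus per-strain
#'   mean and SEM.
#' @export
viability_table <- function(plating) {
  need <- c("strain", "genotype", "distance_kb", "replicate", "n_ypd",
            "n_ypg")
  if (!all(need %in% names(plating)))
    stop("plating table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  plating$viability_pct <- viability(plating$n_ypd, plating$n_ypg)
  agg <- do.call(rbind, lapply(split(plating, plating$strain), function(d) {
    data.frame(strain = d$strain[1L], genotype = d$genotype[1L],
               distance_kb = d$distance_kb[1L], n_replicates = nrow(d),
               mean_viability_pct = mean(d$viability_pct),
               sem_viability_pct = stats::sd(d$viability_pct) /
                 sqrt(nrow(d)),
               stringsAsFactors = FALSE)
  }))
  rownames(agg) <- NULL
  list(replicates = plating, strains = agg)
}

#' Render a machine-readable report of a simulated or assayed experiment
#'
#' Writes one JSON summary (class distribution, junction statistics,
#' viability table, seeds/configuration echo) plus human-readable TSVs.
#' Re-running on identical inputs yields byte-identical files.
#'
#' @param out_dir output directory (created if needed).
#' @param classes cohort data frame with colony_id and class columns.
#' @param junction_stats optional output of [junction_cohort_stats()].
#' @param viability_tab optional output of [viability_table()].
#' @param meta optional named list echoed into the JSON (seeds, config).
#' @return path to the JSON summary, invisibly.
#' @export
render_report <- function(out_dir, classes, junction_stats = NULL,
                          viability_tab = NULL, meta = list()) {
  if (!"class" %in% names(classes) || !"colony_id" %in% names(classes))
    stop("classes must carry colony_id and class columns", call. = FALSE)
  if (anyDuplicated(classes$colony_id))
    stop("duplicated colony ids: ",
         paste(unique(classes$colony_id[duplicated(classes$colony_id)]),
               collapse = ", "), call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  dist <- summarize_cohort(classes$class)
  write.table(classes, file.path(out_dir, "classes.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(dist, file.path(out_dir, "class_distribution.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  summary <- list(
    n_colonies = nrow(classes),
    class_distribution = setNames(as.list(dist$percent), dist$class),
    class_counts = setNames(as.list(dist$count), dist$class)
  )
  if (!is.null(junction_stats)) {
    summary$junctions <- list(
      n = junction_stats$n,
      del_min = junction_stats$del_min,
      del_max = junction_stats$del_max,
      del_median = junction_stats$del_median,
      mh_hist = as.list(setNames(as.integer(junction_stats$mh_hist),
                                 names(junction_stats$mh_hist))),
      frac_insertion = junction_stats$frac_insertion
    )
  }
  if (!is.null(viability_tab)) {
    write.table(viability_tab$strains,
                file.path(out_dir, "viability.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    summary$viability <- setNames(
      as.list(viability_tab$strains$mean_viability_pct),
      viability_tab$strains$strain)
  }
  if (length(meta)) summary$meta <- meta
  json_path <- file.path(out_dir, "summary.json")
  jsonlite::write_json(summary, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(json_path)
}
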