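test_that("break positions follow the pericentric mixture", {
  ref <- ref_for(68000L)
  g <- bfbsim:::ref_geometry(ref)
  set.seed(21)
  pos <- replicate(10000L, sample_break_position(ref))
  lo <- g$gal_core[2L]
  hi <- g$ecen_core[1L]
  expect_true(all(pos > lo & pos < hi))
  ## closed-form mixture mass within 10 kb of either centromere
  D <- hi - lo
  expected <- 0.5 + 0.5 * 20000 / D
  expect_lt(abs(mean(pos <= lo + 10000L | pos >= hi - 10000L) - expected),
            0.02)
})

test_that("locality weight zero degenerates to uniform on the span", {
  ref <- ref_for(68000L)
  g <- bfbsim:::ref_geometry(ref)
  set.seed(22)
  p0 <- sim_params(break_locality_weight = 0)
  pos <- replicate(4000L, sample_break_position(ref, p0))
  ks <- suppressWarnings(
    stats::ks.test(pos, "punif", g$gal_core[2L] + 1L, g$ecen_core[1L] - 1L))
  expect_gt(ks$p.value, 0.01)
})

test_that("short spans are fully covered by the locality windows", {
  ref <- ref_for(107830L)      # 6.5 kb: span < 2 windows, clipping rule
  g <- bfbsim:::ref_geometry(ref)
  set.seed(23)
  pos <- replicate(4000L, sample_break_position(ref))
  ks <- suppressWarnings(
    stats::ks.test(pos, "punif", g$gal_core[2L] + 1L, g$ecen_core[1L] - 1L))
  expect_gt(ks$p.value, 0.01)
})

test_that("divisions without breakage leave the karyotype intact", {
  ref <- ref_for(104458L)
  kt <- founder_karyotype(ref)
  set.seed(1)
  st <- attempt_division(kt, ref, sim_params(p_break = 0,
                                             p_nondisjunction = 0))
  expect_identical(st$karyotype, kt)
  expect_length(st$events, 0L)
})

test_that("monocentric chromosomes never break even at p_break = 1", {
  ref <- ref_for(104458L)
  set.seed(2)
  ev <- repair_break(ref, params_forcing("SSA"))
  mono <- karyotype(ev$products)
  st <- attempt_division(mono, ref, sim_params(p_break = 1,
                                               p_nondisjunction = 0))
  expect_length(st$events, 0L)
  expect_identical(st$karyotype, mono)
})

test_that("sequence is conserved or lost exactly as each pathway dictates", {
  ref <- ref_for(68000L)
  set.seed(3)
  blocks <- ref$features[ref$features$kind == "homology_block", ]
  block_sep <- blocks$end[2L] - blocks$end[1L]      # SSA loses exactly this

  ssa <- repair_break(ref, params_forcing("SSA"))
  expect_identical(ref$length - chromosome_length(ssa$products[[1L]]),
                   block_sep)

  rco <- repair_break(ref, params_forcing("RCO"))
  total <- sum(vapply(rco$products, chromosome_length, integer(1)))
  expect_identical(total, ref$length)

  ej <- repair_break(ref, params_forcing("EJ"))
  expect_identical(ref$length - chromosome_length(ej$products[[1L]]),
                   ej$del_size)

  ref2 <- repair_break(ref, params_forcing("refusion"))
  expect_identical(chromosome_length(ref2$products[[1L]]), ref$length)
})

test_that("end-joining always removes one whole centromere core", {
  ref <- ref_for(101976L)
  cores <- ref$features[ref$features$kind == "centromere_core", ]
  set.seed(4)
  for (i in 1:200) {
    ev <- repair_break(ref, params_forcing("EJ"))
    expect_identical(ev$pathway, "EJ")
    expect_true(ev$del_size >= 278L && ev$del_size <= 585L)
    expect_true(ev$mh_len >= 1L && ev$mh_len <= 9L)
    core <- cores[cores$name == ev$deleted_centromere, ]
    expect_true(ev$deleted_interval[1L] <= core$start &&
                  ev$deleted_interval[2L] >= core$end)
    expect_identical(centromere_count(ev$products[[1L]], ref), 1L)
  }
})

test_that("pathway products carry exactly one centromere", {
  ref <- ref_for(68000L)
  set.seed(5)
  for (path in c("SSA", "RCO", "EJ")) {
    ev <- repair_break(ref, params_forcing(path))
    for (pr in ev$products)
      expect_identical(centromere_count(pr, ref), 1L)
  }
})

test_that("genotype modifiers restrict the accessible pathways", {
  ref <- ref_for(101976L)
  set.seed(6)
  rad <- replicate(150L, repair_break(ref, gt = genotype("rad52"))$pathway)
  expect_true(all(rad %in% c("EJ", "refusion")))
  lif <- replicate(150L, repair_break(ref, gt = genotype("lif1"))$pathway)
  expect_true(all(lif %in% c("SSA", "RCO", "refusion")))
  dead <- genotype("custom", modifiers = c(SSA = 0, RCO = 0, EJ = 0))
  p_norefusion <- sim_params(pathway_propensities = lapply(
    sim_params()$pathway_propensities,
    function(w) { w["refusion"] <- 0; w }))
  ev <- repair_break(ref, p_norefusion, dead)
  expect_identical(ev$pathway, "unrepaired")
})

test_that("viability audit tracks essential genes and fitness flags", {
  ## intact reference: viable, no flags
  ref65 <- ref_for(107830L)
  aud <- audit_viability(founder_karyotype(ref65), ref65)
  expect_true(aud$viable)
  expect_length(aud$fitness_flags, 0L)

  ## 6.5 kb SSA derivative: viable but slow growing (PGS1 lost)
  set.seed(7)
  ssa65 <- repair_break(ref65, params_forcing("SSA"))
  aud65 <- audit_viability(karyotype(ssa65$products), ref65)
  expect_true(aud65$viable)
  expect_true("slow_growth" %in% aud65$fitness_flags)

  ## 57.7 kb SSA linear derivative alone loses RRP7 and NFS1: dead
  ref57 <- ref_for(56740L)
  ssa57 <- repair_break(ref57, params_forcing("SSA"))
  aud57 <- audit_viability(karyotype(ssa57$products), ref57)
  expect_false(aud57$viable)
  expect_identical(aud57$death_cause, "essential_gene_loss")

  ## ... but the crossover's circle rescues both essentials
  rco57 <- repair_break(ref57, params_forcing("RCO"))
  expect_true(audit_viability(karyotype(rco57$products), ref57)$viable)
})

test_that("colony lineages are reproducible per seed", {
  ref <- ref_for(101976L)
  a <- run_colony(ref, seed = 31L)
  b <- run_colony(ref, seed = 31L)
  expect_identical(pool_events(list(a)), pool_events(list(b)))
  expect_identical(a$viable, b$viable)
  cohort1 <- pool_events(simulate_plating(ref, n_colonies = 20L, seed = 8L))
  cohort2 <- pool_events(simulate_plating(ref, n_colonies = 20L, seed = 8L))
  expect_identical(cohort1, cohort2)
})

test_that("breakage-free platings leave every colony unrearranged", {
  ref <- ref_for(101976L)
  fates <- simulate_plating(ref, sim_params(p_break = 0,
                                            p_nondisjunction = 0),
                            n_colonies = 5L, seed = 9L)
  expect_true(all(vapply(fates, `[[`, logical(1), "viable")))
  cls <- classify_fates(fates, ref)
  expect_true(all(cls$class == "unrearranged"))
})

test_that("homology-deficient viability declines with centromere distance", {
  ## qualitative trend only: the mutant magnitudes are experimental
  ## outcomes, not simulator predictions
  ref12 <- ref_for(101976L)
  ref57 <- ref_for(56740L)
  v12 <- mean(vapply(simulate_plating(ref12, gt = genotype("rad52"),
                                      n_colonies = 100L, seed = 10L),
                     `[[`, logical(1), "viable"))
  v57 <- mean(vapply(simulate_plating(ref57, gt = genotype("rad52"),
                                      n_colonies = 100L, seed = 10L),
                     `[[`, logical(1), "viable"))
  expect_lt(v57, v12)
})
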