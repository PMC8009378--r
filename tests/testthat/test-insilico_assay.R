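test_that("diagnostic amplicons on the unrearranged reference", {
  ref <- ref_for(107830L)
  p <- primer_panel()
  gal <- insilico_pcr(ref$sequence, p$primers[["GC1"]], p$primers[["GC2"]])
  expect_identical(nrow(gal), 1L)
  expect_identical(gal$length, 932L)
  ecen <- insilico_pcr(ref$sequence, p$primers[["eC1"]], p$primers[["eC2"]])
  expect_identical(ecen$length, 900L)
  ## hybrid pair on the unrearranged template: sites too far apart
  rearr <- insilico_pcr(ref$sequence, p$primers[["GC1"]], p$primers[["eC2"]])
  expect_identical(nrow(rearr), 0L)
  ## template without sites
  expect_identical(nrow(insilico_pcr(random_sequence(2000L, 0.5, seed = 1),
                                     p$primers[["GC1"]],
                                     p$primers[["GC2"]])), 0L)
  expect_error(insilico_pcr("ACGT", "ACGTACGTACGTACG", "ACG"), "15 nt")
})

test_that("swapped primer orientation is detected", {
  set.seed(12)
  tmpl <- random_sequence(500L, 0.5)
  fwd <- substr(tmpl, 51L, 70L)
  rev <- revcomp(substr(tmpl, 381L, 400L))
  a <- insilico_pcr(tmpl, fwd, rev, max_amplicon = 1000L)
  b <- insilico_pcr(tmpl, rev, fwd, max_amplicon = 1000L)  # swapped
  expect_identical(a$length, 350L)
  expect_identical(b$length, 350L)
})

test_that("circular templates amplify across the origin", {
  set.seed(13)
  tmpl <- random_sequence(400L, 0.5)
  fwd <- substr(tmpl, 361L, 380L)            # near the end
  rev <- revcomp(substr(tmpl, 21L, 40L))     # near the start
  lin <- insilico_pcr(tmpl, fwd, rev, max_amplicon = 1000L)
  expect_identical(nrow(lin), 0L)
  circ <- insilico_pcr(tmpl, fwd, rev, max_amplicon = 1000L, circular = TRUE)
  expect_identical(circ$length, 80L)          # 40 to end + 40 wrapped
})

test_that("matcher agrees with the exhaustive scan oracle", {
  set.seed(14)
  for (i in 1:25) {
    tmpl <- random_sequence(800L, 0.5)
    f_at <- sample(600L, 1L)
    r_at <- sample(600L, 1L)
    fwd <- substr(tmpl, f_at, f_at + 17L)
    rev <- revcomp(substr(tmpl, r_at, r_at + 17L))
    got <- insilico_pcr(tmpl, fwd, rev, max_amplicon = 700L)
    want <- brute_pcr(tmpl, fwd, rev, max_amplicon = 700L)
    expect_identical(got, want)
  }
})

test_that("colony genotyping matches the derivative structures", {
  ref <- ref_for(101976L)
  panel <- primer_panel()
  set.seed(15)

  ej <- repair_break(ref, params_forcing("EJ"))
  while (ej$deleted_centromere != "GALCEN3")
    ej <- repair_break(ref, params_forcing("EJ"))
  pat <- genotype_colony(karyotype(ej$products), ref, panel)
  expect_identical(pat$GALCEN3_state, "reduced_size")
  expect_identical(pat$GALCEN3_len, 932L - ej$del_size)
  expect_identical(pat$eCEN3_state, "wildtype_size")
  expect_identical(pat$rearr_state, "absent")
  expect_identical(pat$recip_state, "absent")

  rco <- repair_break(ref, params_forcing("RCO"))
  pat <- genotype_colony(karyotype(rco$products), ref, panel)
  expect_identical(pat$rearr_state, "present")
  expect_identical(pat$recip_state, "present")
  expect_identical(pat$GALCEN3_state, "absent")
  expect_identical(pat$eCEN3_state, "absent")

  pat <- genotype_colony(founder_karyotype(ref), ref, panel)
  expect_identical(pat$GALCEN3_state, "wildtype_size")
  expect_identical(pat$eCEN3_state, "wildtype_size")
  expect_identical(pat$rearr_state, "absent")
})

test_that("decision key reproduces the published class definitions", {
  mk <- function(ecen, gal, rearr, recip) {
    data.frame(eCEN3_state = ecen, GALCEN3_state = gal,
               rearr_state = rearr, recip_state = recip,
               stringsAsFactors = FALSE)
  }
  W <- "wildtype_size"; A <- "absent"; P <- "present"; R <- "reduced_size"
  ## the six key-listed patterns
  expect_identical(classify_pattern(mk(A, A, P, P)), "HR")
  expect_identical(classify_pattern(mk(A, A, P, A)), "SSA")
  expect_identical(classify_pattern(mk(W, W, A, A)), "unrearranged")
  expect_identical(classify_pattern(mk(W, R, A, A)), "EJ")
  expect_identical(classify_pattern(mk(R, W, A, A)), "EJ")
  expect_identical(classify_pattern(mk(W, A, P, A)), "aneuploid")
  expect_identical(classify_pattern(mk(A, W, P, A)), "aneuploid")
  expect_identical(classify_pattern(mk(W, A, A, P)), "SSA_plus_EJ")
  ## patterns the key does not define
  expect_identical(classify_pattern(mk(A, W, A, P)), "unclassified")
  expect_identical(classify_pattern(mk(A, A, A, A)), "unclassified")
  ## precedence: rearrangement + parental is aneuploid even with reciprocal
  expect_identical(classify_pattern(mk(W, A, P, P)), "aneuploid")
})

test_that("every simulated pathway classifies to its matching class", {
  ## full pipeline consistency: simulator product -> PCR -> decision key
  ref <- ref_for(101976L)
  panel <- primer_panel()
  set.seed(16)
  expect_class <- function(pathway, class) {
    ev <- repair_break(ref, params_forcing(pathway))
    pat <- genotype_colony(karyotype(ev$products), ref, panel)
    expect_identical(classify_pattern(pat), class)
  }
  expect_class("SSA", "SSA")
  expect_class("RCO", "HR")
  expect_class("EJ", "EJ")
  expect_class("refusion", "unrearranged")
  ## nondisjunction then two different repairs -> aneuploid-type pattern
  ej <- repair_break(ref, params_forcing("EJ"))
  ssa <- repair_break(ref, params_forcing("SSA"))
  kt <- karyotype(c(ej$products, ssa$products))
  pat <- genotype_colony(kt, ref, panel)
  expect_identical(classify_pattern(pat), "aneuploid")
})

test_that("cohort summaries are normalized percentages", {
  expect_error(summarize_cohort(character(0)), "empty")
  s <- summarize_cohort(rep("SSA", 30L))
  expect_identical(s$percent, 100)
  s2 <- summarize_cohort(c(rep("EJ", 12L), rep("HR", 10L),
                           rep("SSA_plus_EJ", 6L), rep("unrearranged", 2L)))
  expect_lt(abs(sum(s2$percent) - 100), 0.1 + 1e-9)
  expect_identical(s2$count[s2$class == "EJ"], 12L)
})

test_that("circle contiguity mapping covers the full circumference", {
  ref <- ref_for(68000L)
  set.seed(17)
  rco <- repair_break(ref, params_forcing("RCO"))
  kt <- karyotype(rco$products)
  cov <- circle_contiguity(kt, ref)
  expect_true(all(attr(cov, "full_coverage")))
  expect_true(all(!is.na(cov$product_len)))
  ## ablating one tile's priming site leaves a reported gap
  gap <- circle_contiguity(kt, ref, ablate = 2L)
  expect_false(any(attr(gap, "full_coverage")))
  expect_true(is.na(gap$product_len[gap$tile == 2L]))
  ## linear-only karyotype: empty report
  empty <- circle_contiguity(founder_karyotype(ref), ref)
  expect_identical(nrow(empty), 0L)
})
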