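test_that("centromere separation reproduces the printed kb strain labels", {
  cases <- list(c(104458L, 9.8), c(101976L, 12.3), c(68000L, 46.3),
                c(107830L, 6.5), c(114300L - 1000L, 1.0))
  for (cs in cases) {
    ref <- build_reference(genome_config(insertion_pos = cs[1L], seed = 3))
    expect_identical(cen_cen_distance(ref), cs[2L])
  }
})

test_that("degenerate or invalid configurations are rejected", {
  expect_error(genome_config(insertion_pos = 114300L), "upstream")
  expect_error(genome_config(insertion_pos = 114000L), "1 kb")
  expect_error(genome_config(insertion_pos = 107830L,
                             ssa_homology_len = 100L), "core")
  expect_error(genome_config(insertion_pos = 107830L, gc_content = 1.4),
               "gc_content")
  bad_genes <- data.frame(name = "X", start = 114250L, end = 114400L,
                          essentiality = "essential")
  expect_error(genome_config(gene_annotations = bad_genes), "core")
})

test_that("monocentric input is rejected by cen_cen_distance", {
  ref <- ref_for(107830L)
  mono <- ref
  mono$features <- mono$features[mono$features$name != "GALCEN3", ]
  expect_error(cen_cen_distance(mono), "dicentric")
})

test_that("built reference satisfies its structural invariants", {
  for (ins in c(107830L, 68000L, 56740L)) {
    ref <- ref_for(ins)
    expect_true(validate_reference(ref))
    expect_identical(ref$length,
                     ref$config$chrom_len + ref$config$galcen_amplicon_len)
    cores <- ref$features[ref$features$kind == "centromere_core", ]
    expect_identical(nrow(cores), 2L)
    expect_true(all(cores$end - cores$start + 1L ==
                      ref$config$cen_core_len))
  }
})

test_that("reference construction is hash-stable for a fixed seed", {
  a <- build_reference(genome_config(insertion_pos = 104458L, seed = 11))
  b <- build_reference(genome_config(insertion_pos = 104458L, seed = 11))
  expect_identical(a$sequence, b$sequence)
  expect_identical(a$features, b$features)
  c <- build_reference(genome_config(insertion_pos = 104458L, seed = 12))
  expect_false(identical(a$sequence, c$sequence))
})

test_that("cassette shares exactly the designed homology with eCEN3 region", {
  ref <- ref_for(107830L)
  cass <- cassette_sequence(ref)
  region <- ecen_region_sequence(ref)
  expect_identical(longest_shared_substring(cass, region), 336L)
  ## ablating the homology block drops the shared substring far below 336
  blk <- ref$features[ref$features$name == "GALCEN3_homology", ]
  iv <- cassette_interval(ref)
  cass_broken <- cass
  substr(cass_broken, blk$start - iv[1L] + 1L, blk$end - iv[1L] + 1L) <-
    random_sequence(336L, 0.38, seed = 99)
  expect_lt(longest_shared_substring(cass_broken, region), 336L)
})

test_that("longest_shared_substring handles identity and disjoint inputs", {
  x <- random_sequence(50L, 0.5, seed = 1)
  expect_identical(longest_shared_substring(x, x), 50L)
  expect_identical(longest_shared_substring("AAAA", "CCCC"), 0L)
  expect_error(longest_shared_substring("", "ACGT"), "non-empty")
})

test_that("each diagnostic primer occurs exactly once, convergently", {
  ref <- ref_for(104458L)
  seqs <- ref$sequence
  for (nm in c("GC1", "eC1")) {
    expect_length(bfbsim:::find_all(ref$primers[[nm]], seqs), 1L)
    expect_length(bfbsim:::find_all(revcomp(ref$primers[[nm]]), seqs), 0L)
  }
  for (nm in c("GC2", "eC2")) {     # reverse primers planted as rc
    expect_length(bfbsim:::find_all(revcomp(ref$primers[[nm]]), seqs), 1L)
    expect_length(bfbsim:::find_all(ref$primers[[nm]], seqs), 0L)
  }
})

test_that("realize_sequence concatenates oriented segments", {
  ref <- ref_for(107830L)
  full <- chromosome(data.frame(start = 1L, end = ref$length))
  expect_identical(realize_sequence(full, ref), ref$sequence)
  revseg <- chromosome(data.frame(start = 101L, end = 160L, strand = "-"))
  expect_identical(realize_sequence(revseg, ref),
                   revcomp(substr(ref$sequence, 101L, 160L)))
  dangling <- chromosome(data.frame(start = 1L, end = ref$length + 5L))
  expect_error(realize_sequence(dangling, ref), "dangling")
})

test_that("reciprocal-crossover circle length matches the separation", {
  ref <- ref_for(68000L)
  set.seed(4)
  ev <- repair_break(ref, params_forcing("RCO"))
  circle <- ev$products[[2L]]
  expect_identical(circle$topology, "circular")
  expect_lt(abs(chromosome_length(circle) - 46300L), 336L + 1L)
})

test_that("FASTA and BED round-trip with the coordinate conventions", {
  ref <- ref_for(104458L)
  fa <- withr::local_tempfile(fileext = ".fa")
  write_fasta(c(chr = ref$sequence), fa)
  expect_identical(unname(read_fasta(fa)[[1L]]), ref$sequence)

  bed <- withr::local_tempfile(fileext = ".bed")
  write_features_bed(ref, bed)
  ## BED on disk is 0-based half-open: Ty2-1 (84811, 90769) -> (84810, 90769)
  raw <- read.table(bed, sep = "\t", stringsAsFactors = FALSE)
  ty <- raw[grepl("Ty2-1", raw$V4), ]
  expect_identical(ty$V2, 84810L)
  expect_identical(ty$V3, 90769L)
  back <- read_features_bed(bed)
  expect_setequal(back$start, ref$features$start)
  expect_setequal(back$end, ref$features$end)

  empty <- withr::local_tempfile(fileext = ".bed")
  write_features_bed(ref$features[0L, ], empty)
  expect_identical(nrow(read_features_bed(empty)), 0L)
})

test_that("Ty2-1 element is annotated at its printed span", {
  ref <- ref_for(68000L)
  expect_identical(feature_length(ref, "Ty2-1"), 90769L - 84811L + 1L)
})
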