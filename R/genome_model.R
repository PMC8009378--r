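# Genome model: synthetic engineered chromosome III with a conditional
# GALCEN3 cassette inserted upstream of the endogenous centromere eCEN3.
#
# Coordinate conventions:
#  * config coordinates ("parental frame") are 1-based inclusive positions on
#    the unmodified chromosome, as printed for the strain constructions
#    (eCEN3 at 114,300; insertions at 107,830 / 104,458 / 101,976 / 96,020 /
#    68,000 / 56,740).
#  * the built reference lives in the "engineered frame": the cassette is
#    inserted after `insertion_pos`, so every parental coordinate greater than
#    `insertion_pos` is shifted right by the cassette length.
#  * BED export converts to 0-based half-open.

## printed diagnostic primers (Methods): GALCEN3 assay = GC1+GC2,
## eCEN3 assay = eC1+eC2, rearrangement = GC1+eC2, reciprocal = eC1+GC2
DEFAULT_PRIMERS <- c(
  GC1 = "TCGACTACGCGATCATGGCG",
  GC2 = "CACGATGCGTCCGGCGTAGA",
  eC1 = "TCAATAGCTTGCAGCGTAGCTAA",
  eC2 = "GGGTGGGAAACTGAAGAAATC"
)

## fixed layout margins inside the cassette / around eCEN3 (bp)
GALCEN_RIGHT_MARGIN <- 50L   # spacer between homology block end and GC2 site
ECEN_DOWNSTREAM_END <- 300L  # eC2 site ends this far 3' of the eCEN3 core end

default_gene_annotations <- function() {
  ## exact gene coordinates are not modeled; each gene sits at the midpoint of
  ## the interval that brackets it between printed insertion sites, length
  ## 1.5 kb. Only interval membership matters for the viability audit.
  data.frame(
    name = c("RRP7", "NFS1", "PGS1"),
    start = c(61620L, 81260L, 110315L),
    end = c(63119L, 82759L, 111814L),
    essentiality = c("essential", "essential", "fitness"),
    stringsAsFactors = FALSE
  )
}

#' Configuration for a synthetic dicentric chromosome III reference
#'
#' Captures the engineered-strain geometry: the endogenous centromere eCEN3 at
#' 114,300, a conditional GALCEN3 cassette inserted at one of the six printed
#' coordinates, the 336 bp of sequence shared between the two centromere
#' regions (which contains the 125 bp centromere core), and the diagnostic
#' amplicon sizes.
#'
#' @param insertion_pos 1-based parental coordinate after which the GALCEN3
#'   cassette is inserted. One of 107830, 104458, 101976, 96020, 68000, 56740
#'   (6.5 / 9.8 / 12.3 / 18.2 / 46.3 / 57.7 kb from eCEN3). Other values are
#'   accepted if they keep at least 1 kb to eCEN3.
#' @param ecen3_pos parental coordinate of the 3' end of the eCEN3 core
#'   (default 114300).
#' @param cen_core_len length of the functional centromere core in bp
#'   (default 125).
#' @param ssa_homology_len length of the sequence block shared verbatim
#'   between the cassette and the eCEN3 region (default 336); must contain
#'   the core.
#' @param galcen_amplicon_len GC1-GC2 amplicon (= cassette) length in bp
#'   (default 932).
#' @param ecen_amplicon_len eC1-eC2 amplicon length in bp (default 900; the
#'   assay defines the primer scheme but not this size, so it is
#'   configurable).
#' @param ty2_span parental interval of the TCLWTy2-1 element
#'   (default c(84811, 90769)).
#' @param chrom_len parental chromosome length in bp (default 316620).
#' @param gc_content GC fraction of the random background sequence
#'   (default 0.38, yeast-like).
#' @param gene_annotations data frame with columns name, start, end,
#'   essentiality (one of "essential", "fitness", "neutral"), parental frame.
#' @param seed integer seed making the built sequence reproducible.
#' @return an object of class `bfb_config`.
#' @export
genome_config <- function(insertion_pos = 107830L,
                          ecen3_pos = 114300L,
                          cen_core_len = 125L,
                          ssa_homology_len = 336L,
                          galcen_amplicon_len = 932L,
                          ecen_amplicon_len = 900L,
                          ty2_span = c(84811L, 90769L),
                          chrom_len = 316620L,
                          gc_content = 0.38,
                          gene_annotations = default_gene_annotations(),
                          seed = 1L) {
  cfg <- list(
    insertion_pos = as.integer(insertion_pos),
    ecen3_pos = as.integer(ecen3_pos),
    cen_core_len = as.integer(cen_core_len),
    ssa_homology_len = as.integer(ssa_homology_len),
    galcen_amplicon_len = as.integer(galcen_amplicon_len),
    ecen_amplicon_len = as.integer(ecen_amplicon_len),
    ty2_span = as.integer(ty2_span),
    chrom_len = as.integer(chrom_len),
    gc_content = as.numeric(gc_content),
    gene_annotations = gene_annotations,
    seed = as.integer(seed)
  )
  class(cfg) <- "bfb_config"
  validate_genome_config(cfg)
  cfg
}

validate_genome_config <- function(cfg) {
  with(cfg, {
    if (is.na(insertion_pos) || insertion_pos < 1L)
      stop("insertion_pos must be a positive coordinate", call. = FALSE)
    if (insertion_pos >= ecen3_pos)
      stop("configuration error: insertion_pos must lie upstream of ecen3_pos",
           call. = FALSE)
    if (ecen3_pos - insertion_pos < 1000L)
      stop("configuration error: cassette insertion within 1 kb of eCEN3 ",
           "collides with the eCEN3 diagnostic region", call. = FALSE)
    if (ssa_homology_len < cen_core_len)
      stop("ssa_homology_len must contain the centromere core ",
           "(>= cen_core_len)", call. = FALSE)
    p <- DEFAULT_PRIMERS
    min_cassette <- nchar(p["GC1"]) + nchar(p["GC2"]) + ssa_homology_len +
      GALCEN_RIGHT_MARGIN + 101L
    if (galcen_amplicon_len < min_cassette)
      stop("galcen_amplicon_len too small for the cassette layout (needs >= ",
           min_cassette, " bp)", call. = FALSE)
    if (ecen_amplicon_len < ssa_homology_len + ECEN_DOWNSTREAM_END +
        nchar(p["eC1"]) + 23L)
      stop("ecen_amplicon_len too small to bracket the homology block",
           call. = FALSE)
    if (ecen3_pos + ECEN_DOWNSTREAM_END > chrom_len ||
        ecen3_pos - ecen_amplicon_len < 1L)
      stop("eCEN3 diagnostic region outside [1, chrom_len]", call. = FALSE)
    if (ty2_span[1L] > ty2_span[2L] || ty2_span[2L] > chrom_len)
      stop("ty2_span invalid", call. = FALSE)
    if (gc_content < 0 || gc_content > 1) stop("gc_content must be in [0,1]",
                                               call. = FALSE)
    ga <- gene_annotations
    if (nrow(ga)) {
      if (any(ga$start > ga$end) || any(ga$start < 1L) ||
          any(ga$end > chrom_len))
        stop("gene annotations outside [1, chrom_len]", call. = FALSE)
      core <- c(ecen3_pos - cen_core_len + 1L, ecen3_pos)
      if (any(ga$start <= core[2L] & ga$end >= core[1L]))
        stop("gene annotations overlap the eCEN3 core", call. = FALSE)
      if (!all(ga$essentiality %in% c("essential", "fitness", "neutral")))
        stop("essentiality must be essential/fitness/neutral", call. = FALSE)
    }
  })
  invisible(cfg)
}

## engineered-frame shift: parental coordinates past the insertion point move
## right by the cassette length
shift_coord <- function(x, cfg) {
  ifelse(x > cfg$insertion_pos, x + cfg$galcen_amplicon_len, x)
}

#' Build a synthetic engineered dicentric reference
#'
#' Generates a random background chromosome, plants the eC1/eC2 priming sites
#' around eCEN3, and inserts the GALCEN3 cassette
#' (GC1 - GAL1 promoter - homology block - spacer - GC2) after
#' `insertion_pos`. The homology block is copied verbatim from the eCEN3
#' region so the cassette and the eCEN3 region share exactly
#' `ssa_homology_len` bp; the bases flanking both copies are forced to
#' mismatch so the shared substring cannot extend.
#'
#' @param config a [genome_config()] object.
#' @return an object of class `bfb_reference` with elements `sequence`
#'   (character), `features` (data frame: name, start, end, kind, strand,
#'   essentiality), `primers` (named character), `config`, and `length`.
#' @export
build_reference <- function(config = genome_config()) {
  validate_genome_config(config)
  cfg <- config
  p <- DEFAULT_PRIMERS
  I <- cfg$insertion_pos
  E <- cfg$ecen3_pos
  G <- cfg$galcen_amplicon_len
  H <- cfg$ssa_homology_len
  K <- cfg$cen_core_len
  A <- cfg$ecen_amplicon_len

  set.seed(cfg$seed)
  bg <- random_sequence(cfg$chrom_len, cfg$gc_content)

  ## eCEN3-side sites in the parental frame
  ec2_end <- E + ECEN_DOWNSTREAM_END
  ec2_start <- ec2_end - nchar(p["eC2"]) + 1L
  ec1_start <- ec2_end - A + 1L
  ec1_end <- ec1_start + nchar(p["eC1"]) - 1L
  block_par <- c(E - H + 1L, E)
  if (ec1_end >= block_par[1L])
    stop("configuration error: eC1 priming site collides with the homology ",
         "block; increase ecen_amplicon_len", call. = FALSE)
  substr(bg, ec1_start, ec1_end) <- as.character(p["eC1"])
  substr(bg, ec2_start, ec2_end) <- revcomp(as.character(p["eC2"]))

  ## cassette layout (offsets within the G bp cassette)
  gc1_len <- nchar(p["GC1"]); gc2_len <- nchar(p["GC2"])
  cblock_end <- G - gc2_len - GALCEN_RIGHT_MARGIN
  cblock_start <- cblock_end - H + 1L
  promoter <- random_sequence(cblock_start - 1L - gc1_len, cfg$gc_content)
  spacer <- random_sequence(GALCEN_RIGHT_MARGIN, cfg$gc_content)
  block_seq <- substr(bg, block_par[1L], block_par[2L])
  ## forbid accidental extension of the shared block on either side
  substr(promoter, nchar(promoter), nchar(promoter)) <-
    other_base(substr(bg, block_par[1L] - 1L, block_par[1L] - 1L))
  substr(spacer, 1L, 1L) <- other_base(substr(bg, E + 1L, E + 1L))
  cassette <- paste0(as.character(p["GC1"]), promoter, block_seq, spacer,
                     revcomp(as.character(p["GC2"])))
  stopifnot(nchar(cassette) == G)

  sequence <- paste0(substr(bg, 1L, I), cassette,
                     substr(bg, I + 1L, cfg$chrom_len))

  sh <- function(x) shift_coord(x, cfg)
  feat <- function(name, start, end, kind, strand = "*",
                   essentiality = NA_character_) {
    data.frame(name = name, start = as.integer(start), end = as.integer(end),
               kind = kind, strand = strand, essentiality = essentiality,
               stringsAsFactors = FALSE)
  }
  ga <- cfg$gene_annotations
  features <- rbind(
    feat("GC1", I + 1L, I + gc1_len, "primer_site", "+"),
    feat("GAL1pr", I + gc1_len + 1L, I + cblock_start - 1L, "gal_promoter"),
    feat("GALCEN3_homology", I + cblock_start, I + cblock_end,
         "homology_block"),
    feat("GALCEN3", I + cblock_end - K + 1L, I + cblock_end,
         "centromere_core"),
    feat("GC2", I + G - gc2_len + 1L, I + G, "primer_site", "-"),
    feat("eC1", sh(ec1_start), sh(ec1_end), "primer_site", "+"),
    feat("eCEN3_homology", sh(block_par[1L]), sh(block_par[2L]),
         "homology_block"),
    feat("eCEN3", sh(E - K + 1L), sh(E), "centromere_core"),
    feat("eC2", sh(ec2_start), sh(ec2_end), "primer_site", "-"),
    feat("Ty2-1", sh(cfg$ty2_span[1L]), sh(cfg$ty2_span[2L]), "ty_element")
  )
  if (nrow(ga)) {
    features <- rbind(features, feat(ga$name, sh(ga$start), sh(ga$end),
                                     "gene", "*", ga$essentiality))
  }
  features <- features[order(features$start), ]
  rownames(features) <- NULL

  ref <- list(sequence = sequence, features = features, primers = p,
              config = cfg, length = nchar(sequence))
  class(ref) <- "bfb_reference"
  ref
}

#' @export
print.bfb_reference <- function(x, ...) {
  cat(sprintf(
    "<bfb_reference> %d bp engineered chromosome III\n", x$length))
  cat(sprintf("  GALCEN3 cassette after %d; eCEN3 at %d (parental frame)\n",
              x$config$insertion_pos, x$config$ecen3_pos))
  cat(sprintf("  centromere separation: %.1f kb; %d features\n",
              cen_cen_distance(x), nrow(x$features)))
  invisible(x)
}

ref_feature <- function(ref, name) {
  f <- ref$features[ref$features$name == name, , drop = FALSE]
  if (nrow(f) == 0L) stop("no feature named ", name, call. = FALSE)
  f
}

#' Length of a named feature in bp
#' @param ref a `bfb_reference`.
#' @param name feature name (e.g. "Ty2-1").
#' @return integer length in bp.
#' @export
feature_length <- function(ref, name) {
  f <- ref_feature(ref, name)
  as.integer(f$end - f$start + 1L)
}

#' Engineered-frame interval of the GALCEN3 cassette
#' @param ref a `bfb_reference`.
#' @return integer vector c(start, end).
#' @export
cassette_interval <- function(ref) {
  I <- ref$config$insertion_pos
  c(I + 1L, I + ref$config$galcen_amplicon_len)
}

#' Cassette subsequence of the reference
#' @param ref a `bfb_reference`.
#' @return DNA string of the cassette.
#' @export
cassette_sequence <- function(ref) {
  iv <- cassette_interval(ref)
  substr(ref$sequence, iv[1L], iv[2L])
}

#' eCEN3-region subsequence of the reference
#'
#' The eCEN3 homology block plus `flank` bp on either side (engineered frame),
#' the region against which the cassette shares its homology block.
#'
#' @param ref a `bfb_reference`.
#' @param flank flank size in bp (default 300).
#' @return DNA string.
#' @export
ecen_region_sequence <- function(ref, flank = 300L) {
  b <- ref_feature(ref, "eCEN3_homology")
  substr(ref$sequence, max(1L, b$start - flank),
         min(ref$length, b$end + flank))
}

#' Distance between the two centromeres in kilobases
#'
#' Computed from the parental-frame coordinates as
#' `|ecen3_pos - insertion_pos| / 1000`, rounded half-up to one decimal --
#' the convention behind the printed 6.5/9.8/12.3/46.3 kb strain labels
#' (the printed 18.2 and 57.7 labels deviate from this rounding by 0.1).
#'
#' @param ref a `bfb_reference`.
#' @return numeric distance in kb (one decimal).
#' @export
cen_cen_distance <- function(ref) {
  ncore <- sum(ref$features$kind == "centromere_core")
  if (ncore < 2L)
    stop("reference is not dicentric: fewer than two centromere cores",
         call. = FALSE)
  round_half_up(abs(ref$config$ecen3_pos - ref$config$insertion_pos) / 1000,
                1L)
}

#' Longest exact substring shared by two DNA strings
#'
#' Forward-strand exact matching only. Used to verify that the cassette and
#' the eCEN3 region share exactly the designed homology block.
#'
#' @param a,b non-empty DNA strings.
#' @return integer length in bp of the longest common substring.
#' @export
longest_shared_substring <- function(a, b) {
  if (!nzchar(a) || !nzchar(b)) stop("inputs must be non-empty", call. = FALSE)
  na <- nchar(a); nb <- nchar(b)
  has_common <- function(L) {
    if (L == 0L) return(TRUE)
    if (L > na || L > nb) return(FALSE)
    sa <- unique(substring(a, seq_len(na - L + 1L), L:na))
    sb <- substring(b, seq_len(nb - L + 1L), L:nb)
    any(sb %in% sa)
  }
  lo <- 0L; hi <- min(na, nb)
  while (lo < hi) {
    mid <- as.integer(ceiling((lo + hi) / 2))
    if (has_common(mid)) lo <- mid else hi <- mid - 1L
  }
  lo
}

#' Check structural invariants of a built reference
#'
#' Asserts that each diagnostic primer occurs exactly once (as given or as
#' reverse complement), that exactly two centromere cores are annotated, and
#' that the cassette carries a copy of the eCEN3 homology block.
#'
#' @param ref a `bfb_reference`.
#' @return TRUE invisibly; errors describe the violated invariant.
#' @export
validate_reference <- function(ref) {
  for (nm in names(ref$primers)) {
    n <- length(find_all(ref$primers[[nm]], ref$sequence)) +
      length(find_all(revcomp(ref$primers[[nm]]), ref$sequence))
    if (n != 1L)
      stop("primer ", nm, " occurs ", n, " times (expected exactly 1)",
           call. = FALSE)
  }
  if (sum(ref$features$kind == "centromere_core") != 2L)
    stop("expected exactly two centromere cores", call. = FALSE)
  blocks <- ref$features[ref$features$kind == "homology_block", ]
  s1 <- substr(ref$sequence, blocks$start[1L], blocks$end[1L])
  s2 <- substr(ref$sequence, blocks$start[2L], blocks$end[2L])
  if (!identical(s1, s2))
    stop("homology blocks are not identical", call. = FALSE)
  invisible(TRUE)
}

## ---- segments, chromosomes, karyotypes ------------------------------------

#' Chromosome as an ordered list of reference segments
#'
#' A derivative chromosome is a list of oriented intervals of the engineered
#' reference. Circular chromosomes are stored with the segment of lowest
#' source coordinate first (the declared rotation), and have no free ends.
#'
#' @param segments data frame with columns start, end and optionally strand
#'   ("+" or "-", default "+"), engineered-frame 1-based inclusive.
#' @param topology "linear" or "circular".
#' @return an object of class `bfb_chromosome`.
#' @export
chromosome <- function(segments, topology = c("linear", "circular")) {
  topology <- match.arg(topology)
  segments <- as.data.frame(segments)
  if (is.null(segments$strand)) segments$strand <- "+"
  stopifnot(all(segments$start <= segments$end),
            all(segments$strand %in% c("+", "-")))
  segments$start <- as.integer(segments$start)
  segments$end <- as.integer(segments$end)
  if (topology == "circular" && nrow(segments) > 1L) {
    i <- which.min(segments$start)
    if (i > 1L)
      segments <- segments[c(i:nrow(segments), 1L:(i - 1L)), , drop = FALSE]
  }
  rownames(segments) <- NULL
  structure(list(segments = segments, topology = topology),
            class = "bfb_chromosome")
}

#' Karyotype: the set of chromosomes carried by a cell or colony
#' @param chromosomes list of [chromosome()] objects.
#' @return an object of class `bfb_karyotype`.
#' @export
karyotype <- function(chromosomes) {
  stopifnot(all(vapply(chromosomes, inherits, logical(1), "bfb_chromosome")))
  structure(list(chromosomes = chromosomes), class = "bfb_karyotype")
}

#' The intact engineered dicentric as a one-chromosome karyotype
#' @param ref a `bfb_reference`.
#' @return a `bfb_karyotype` holding the full-length dicentric chromosome.
#' @export
founder_karyotype <- function(ref) {
  karyotype(list(chromosome(data.frame(start = 1L, end = ref$length))))
}

#' Realize the DNA sequence of a derivative chromosome
#'
#' Concatenates the oriented segment sequences. For circular chromosomes the
#' returned string starts at the declared rotation (lowest source coordinate
#' first).
#'
#' @param chrom a `bfb_chromosome`.
#' @param ref a `bfb_reference`.
#' @return DNA string.
#' @export
realize_sequence <- function(chrom, ref) {
  seg <- chrom$segments
  if (any(seg$end > ref$length) || any(seg$start < 1L))
    stop("dangling segment reference: segment outside the reference",
         call. = FALSE)
  parts <- substring(ref$sequence, seg$start, seg$end)
  rev_idx <- which(seg$strand == "-")
  for (i in rev_idx) parts[i] <- revcomp(parts[i])
  paste(parts, collapse = "")
}

#' Total length of a derivative chromosome in bp
#' @param chrom a `bfb_chromosome`.
#' @return integer bp.
#' @export
chromosome_length <- function(chrom) {
  sum(chrom$segments$end - chrom$segments$start + 1L)
}

## number of centromere cores fully contained in the chromosome's segments
centromere_count <- function(chrom, ref) {
  cores <- ref$features[ref$features$kind == "centromere_core", ]
  n <- 0L
  for (i in seq_len(nrow(cores))) {
    hit <- any(chrom$segments$start <= cores$start[i] &
                 chrom$segments$end >= cores$end[i])
    n <- n + as.integer(hit)
  }
  n
}

## TRUE if the interval [start, end] is fully contained in one segment
interval_present <- function(chrom, start, end) {
  any(chrom$segments$start <= start & chrom$segments$end >= end)
}

## ---- FASTA / BED I/O -------------------------------------------------------

#' Write sequences to a FASTA file
#' @param seqs named character vector of DNA strings.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, filepath = path)
  invisible(path)
}

#' Read a FASTA file as a named character vector
#' @param path FASTA file path.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' Export reference features as BED
#'
#' Internal 1-based inclusive intervals are converted to BED's 0-based
#' half-open convention; the BED name field is `name|kind`.
#'
#' @param ref a `bfb_reference` (or a feature data frame).
#' @param path output BED path.
#' @param seqname chromosome name used in the BED file.
#' @return the path, invisibly.
#' @export
write_features_bed <- function(ref, path, seqname = "chrIII_dicentric") {
  features <- if (inherits(ref, "bfb_reference")) ref$features else ref
  if (nrow(features) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  gr <- GenomicRanges::GRanges(
    seqnames = seqname,
    ranges = IRanges::IRanges(start = features$start, end = features$end),
    strand = ifelse(features$strand %in% c("+", "-"), features$strand, "*")
  )
  S4Vectors::mcols(gr)$name <- paste(features$name, features$kind, sep = "|")
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Import features from a BED file written by [write_features_bed()]
#' @param path BED path.
#' @return data frame with columns name, start, end, kind, strand
#'   (1-based inclusive).
#' @export
read_features_bed <- function(path) {
  if (file.size(path) == 0L)
    return(data.frame(name = character(), start = integer(),
                      end = integer(), kind = character(),
                      strand = character(), stringsAsFactors = FALSE))
  gr <- rtracklayer::import(path, format = "BED")
  nm <- as.character(S4Vectors::mcols(gr)$name)
  parts <- strsplit(nm, "|", fixed = TRUE)
  data.frame(
    name = vapply(parts, `[`, character(1), 1L),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    kind = vapply(parts, function(x) if (length(x) > 1L) x[2L] else NA_character_,
                  character(1)),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  )
}
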