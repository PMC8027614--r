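# Shared fixtures, all generated in code at test time.

tiny_genome <- function(lengths = c(chrI = 12000, chrII = 8000), seed = 42) {
  simulateGenome(lengths, at_fraction = 0.6, seed = seed)
}

# One alignment-record row in the internal data.frame representation.
aln_row <- function(read_id, contig, pos, cigar, seq,
                    strand = "+", mapq = 60L, supplementary = FALSE) {
  data.frame(read_id = read_id, contig = contig, pos = pos, strand = strand,
             cigar = cigar, mapq = mapq, seq = seq,
             supplementary = supplementary,
             ref_end = pos + svharvest:::cigarRefWidth(cigar),
             stringsAsFactors = FALSE)
}

# A small GFF3 gene-model fixture on chrI of tiny_genome():
#   geneA (1001..3000, 1-based): exon 1001..1600 with CDS 1101..1500
#     (so UTR-free exon parts at 1001..1100 and 1501..1600), exon
#     2401..3000 with CDS 2401..2800 and three_prime_UTR 2801..3000;
#     intron 1601..2400.
#   geneB (4001..5000): single exon = gene, CDS 4001..5000.
#   pseudoC (6001..6500): pseudogene.
write_tiny_gff <- function(path) {
  lines <- c(
    "##gff-version 3",
    "chrI\ttest\tgene\t1001\t3000\t.\t+\t.\tID=geneA",
    "chrI\ttest\tmRNA\t1001\t3000\t.\t+\t.\tID=tA;Parent=geneA",
    "chrI\ttest\texon\t1001\t1600\t.\t+\t.\tID=eA1;Parent=tA",
    "chrI\ttest\tCDS\t1101\t1500\t.\t+\t0\tID=cA1;Parent=tA",
    "chrI\ttest\texon\t2401\t3000\t.\t+\t.\tID=eA2;Parent=tA",
    "chrI\ttest\tCDS\t2401\t2800\t.\t+\t0\tID=cA2;Parent=tA",
    "chrI\ttest\tthree_prime_UTR\t2801\t3000\t.\t+\t.\tID=uA;Parent=tA",
    "chrI\ttest\tgene\t4001\t5000\t.\t-\t.\tID=geneB",
    "chrI\ttest\tmRNA\t4001\t5000\t.\t-\t.\tID=tB;Parent=geneB",
    "chrI\ttest\texon\t4001\t5000\t.\t-\t.\tID=eB1;Parent=tB",
    "chrI\ttest\tCDS\t4001\t5000\t.\t-\t0\tID=cB1;Parent=tB",
    "chrI\ttest\tpseudogene\t6001\t6500\t.\t+\t.\tID=pseudoC"
  )
  writeLines(lines, path)
  path
}

write_tiny_bed <- function(path) {
  lines <- c(
    "chrI\t7000\t7200\tenh1\tenhancer",
    "chrI\t7300\t7400\tprom1\tpromoter",
    "chrI\t7500\t7550\ttss1\tTSS",
    "chrII\t1000\t1100\ttf1\tTF_binding_site",
    "chrII\t2000\t2050\tsl1\tsplice_leader"
  )
  writeLines(lines, path)
  path
}

tiny_feature_db <- function() {
  gff <- tempfile(fileext = ".gff3")
  bed <- tempfile(fileext = ".bed")
  write_tiny_gff(gff)
  write_tiny_bed(bed)
  readFeatureDB(gff, bed)
}

# Brute-force full-scan realignment oracle: all positions, both strands,
# full-length mismatch count; best = minimal mismatches, unique or bust.
brute_force_realign <- function(clip, genome, min_identity = 0.95) {
  L <- nchar(clip)
  best_mm <- Inf
  hits <- list()
  for (str in c("+", "-")) {
    pat <- if (str == "+") clip else
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(clip)))
    pv <- strsplit(pat, "")[[1]]
    for (ctg in names(genome)) {
      s <- as.character(genome[[ctg]])
      n <- nchar(s)
      if (n < L) next
      for (st in 0:(n - L)) {
        wv <- strsplit(substr(s, st + 1, st + L), "")[[1]]
        mm <- sum(wv != pv)
        if (mm <= floor(L * (1 - min_identity))) {
          if (mm < best_mm) {
            best_mm <- mm
            hits <- list(list(contig = ctg, start = st, strand = str, mm = mm))
          } else if (mm == best_mm) {
            hits[[length(hits) + 1]] <- list(contig = ctg, start = st,
                                             strand = str, mm = mm)
          }
        }
      }
    }
  }
  list(hits = hits, best_mm = best_mm)
}
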