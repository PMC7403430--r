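# Shared fixtures, built in code.

# 2-exon plus-strand toy: exon 100-199, exon 300-499, CDS 312-450.
toyPlusModel <- function() {
  transcriptModel("TOYT1", "TOYG1", "TOY1", "10", "+",
                  exonStarts = c(100L, 300L), exonEnds = c(199L, 499L),
                  cdsStartGenomic = 312L, cdsEndGenomic = 450L)
}

# Same intervals on the minus strand (transcription order reversed).
toyMinusModel <- function() {
  transcriptModel("TOYT2", "TOYG2", "TOY2", "11", "-",
                  exonStarts = c(300L, 100L), exonEnds = c(499L, 199L),
                  cdsStartGenomic = 420L, cdsEndGenomic = 150L)
}

# Random multi-exon model for property tests; returns the model.
randomModel <- function(nExons = sample(1:5, 1), strand = sample(c("+", "-"), 1)) {
  widths <- sample(20:200, nExons, replace = TRUE)
  gaps <- if (nExons > 1) sample(50:500, nExons - 1, replace = TRUE) else integer(0)
  at <- sample(1000:10000, 1)
  starts <- integer(nExons); ends <- integer(nExons)
  for (i in seq_len(nExons)) {
    if (strand == "+") {
      starts[i] <- at; ends[i] <- at + widths[i] - 1L
      at <- ends[i] + 1L + if (i < nExons) gaps[i] else 0L
    } else {
      ends[i] <- at + 20000L; starts[i] <- ends[i] - widths[i] + 1L
      at <- starts[i] - 20001L - if (i < nExons) gaps[i] else 0L
    }
  }
  transcriptModel(paste0("RT", sample(1e6, 1)), "RG", "RND", "1", strand,
                  starts, ends)
}

# Candidate row in the layout readFusionCandidates() produces.
candidateRow <- function(leftGene, leftChrom, leftPos, leftStrand,
                         rightGene, rightChrom, rightPos, rightStrand,
                         sample = "S1", name = paste0(leftGene, "--", rightGene)) {
  data.frame(fusion_name = name, left_gene = leftGene, right_gene = rightGene,
             junction_reads = 10L, spanning_frags = 5L, sample_id = sample,
             left_chrom = leftChrom, left_pos = leftPos,
             left_strand = leftStrand, right_chrom = rightChrom,
             right_pos = rightPos, right_strand = rightStrand,
             stringsAsFactors = FALSE)
}

mgmtDomains <- function() fusionscapeResource("mgmt_domains.tsv")
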