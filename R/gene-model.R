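## Gene-model construction, GTF I/O and spliced-coordinate queries.
## Coordinates are GTF convention throughout: 1-based, inclusive.

#' Construct a TranscriptModel
#'
#' @param transcriptId,geneId,geneName,biotype character scalars.
#' @param chrom chromosome name; a leading "chr" prefix is stripped.
#' @param strand "+" or "-".
#' @param exonStarts,exonEnds integer vectors of exon boundaries in
#'   transcription order (decreasing genomic coordinate on the minus strand).
#' @param cdsStartGenomic,cdsEndGenomic genomic coordinate of the first/last
#'   CDS base in transcription order, or `NA` for a non-coding transcript.
#' @return a [TranscriptModel-class] object.
#' @examples
#' tm <- transcriptModel("T1", "G1", "TOY", "10", "+",
#'                       exonStarts = c(100, 300), exonEnds = c(199, 499),
#'                       cdsStartGenomic = 312, cdsEndGenomic = 450)
#' mrnaLength(tm)
#' @export
transcriptModel <- function(transcriptId, geneId, geneName, chrom, strand,
                            exonStarts, exonEnds,
                            cdsStartGenomic = NA_integer_,
                            cdsEndGenomic = NA_integer_,
                            biotype = "protein_coding") {
  stopifnot(length(exonStarts) == length(exonEnds))
  new("TranscriptModel",
      transcriptId = as.character(transcriptId),
      geneId = as.character(geneId),
      geneName = as.character(geneName),
      chrom = normalizeChrom(chrom),
      strand = as.character(strand),
      exons = IRanges::IRanges(start = as.integer(exonStarts),
                               end = as.integer(exonEnds)),
      cdsStartGenomic = as.integer(cdsStartGenomic),
      cdsEndGenomic = as.integer(cdsEndGenomic),
      biotype = as.character(biotype))
}

#' Normalise a chromosome name
#'
#' Both "10" and "chr10" are accepted across the package; internally names
#' are stored un-prefixed.
#' @param x character vector of chromosome names.
#' @return character vector without "chr" prefixes.
#' @export
normalizeChrom <- function(x) sub("^chr", "", as.character(x))

#' Accessors for TranscriptModel
#'
#' `mrnaLength()` is the spliced length (sum of exon widths); `isCoding()`
#' tests for an annotated CDS; `txStrand()` returns "+" or "-".
#'
#' @param x a [TranscriptModel-class].
#' @return the corresponding slot value (scalar, or an `IRanges` for
#'   `exons()`; an integer for `mrnaLength()`).
#' @name TranscriptModel-accessors
NULL

#' @rdname TranscriptModel-accessors
#' @export
setMethod("transcriptId", "TranscriptModel", function(x) x@transcriptId)
#' @rdname TranscriptModel-accessors
#' @export
setMethod("geneName", "TranscriptModel", function(x) x@geneName)
#' @rdname TranscriptModel-accessors
#' @export
setMethod("geneId", "TranscriptModel", function(x) x@geneId)
#' @rdname TranscriptModel-accessors
#' @export
setMethod("chrom", "TranscriptModel", function(x) x@chrom)
#' @rdname TranscriptModel-accessors
#' @export
setMethod("txStrand", "TranscriptModel", function(x) x@strand)
#' @rdname TranscriptModel-accessors
#' @export
setMethod("exons", "TranscriptModel", function(x) x@exons)
#' @rdname TranscriptModel-accessors
#' @export
setMethod("mrnaLength", "TranscriptModel",
          function(x) sum(IRanges::width(x@exons)))
#' @rdname TranscriptModel-accessors
#' @export
setMethod("isCoding", "TranscriptModel", function(x) !is.na(x@cdsStartGenomic))
#' @rdname TranscriptModel-accessors
#' @export
setMethod("cdsStartGenomic", "TranscriptModel", function(x) x@cdsStartGenomic)
#' @rdname TranscriptModel-accessors
#' @export
setMethod("cdsEndGenomic", "TranscriptModel", function(x) x@cdsEndGenomic)

#' Read Ensembl-dialect GTF gene models
#'
#' Parses exon and CDS features into one [TranscriptModel-class] per
#' `transcript_id`. Exons are ordered in transcription order (reverse genomic
#' order on the minus strand); feature types other than exon/CDS are ignored.
#' A light structural pre-check reports the line number of any non-comment
#' line that does not have the nine tab-separated GTF fields; heavy lifting
#' is delegated to [rtracklayer::import()].
#'
#' @param path path to a GTF file (Ensembl attribute dialect: `gene_id`,
#'   `gene_name`, `transcript_id`, `gene_biotype`).
#' @return a named list of [TranscriptModel-class] objects, one per
#'   transcript id.
#' @examples
#' gtf <- system.file("extdata", "toy_models.gtf", package = "fusionscape")
#' models <- readGtf(gtf)
#' models[[1]]
#' @export
readGtf <- function(path) {
  if (!file.exists(path)) stop("GTF file not found: ", path)
  lines <- readLines(path)
  body <- !startsWith(lines, "#") & nzchar(lines)
  nf <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  if (any(nf != 9L)) {
    bad <- which(body)[which(nf != 9L)[1L]]
    stop("malformed GTF line ", bad, ": expected 9 tab-separated fields, found ",
         nf[which(nf != 9L)[1L]])
  }
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type %in% c("exon", "CDS")]
  if (length(gr) == 0L) return(list())
  md <- S4Vectors::mcols(gr)
  txs <- unique(md$transcript_id)
  models <- lapply(txs, function(tx) {
    sel <- md$transcript_id == tx
    sub <- gr[sel]
    ex <- sub[sub$type == "exon"]
    cds <- sub[sub$type == "CDS"]
    if (length(ex) == 0L)
      stop("transcript ", tx, " has CDS features but no exons")
    strand <- as.character(GenomicRanges::strand(ex))[1L]
    if (!strand %in% c("+", "-"))
      stop("transcript ", tx, " has no stranded exons")
    o <- order(GenomicRanges::start(ex),
               decreasing = identical(strand, "-"))
    ex <- ex[o]
    if (length(cds) > 0L) {
      cs <- if (strand == "+") min(GenomicRanges::start(cds)) else max(GenomicRanges::end(cds))
      ce <- if (strand == "+") max(GenomicRanges::end(cds)) else min(GenomicRanges::start(cds))
    } else {
      cs <- ce <- NA_integer_
    }
    bt <- md$gene_biotype[sel][1L]
    transcriptModel(
      transcriptId = tx,
      geneId = md$gene_id[sel][1L],
      geneName = if (!is.null(md$gene_name)) md$gene_name[sel][1L] else md$gene_id[sel][1L],
      chrom = as.character(GenomicRanges::seqnames(ex))[1L],
      strand = strand,
      exonStarts = GenomicRanges::start(ex),
      exonEnds = GenomicRanges::end(ex),
      cdsStartGenomic = cs, cdsEndGenomic = ce,
      biotype = if (is.null(bt) || is.na(bt)) "protein_coding" else bt)
  })
  names(models) <- txs
  models
}

#' Write TranscriptModels as Ensembl-dialect GTF
#'
#' Emits exon features for every model and CDS features for coding models,
#' via [rtracklayer::export()]. Round-trips through [readGtf()].
#'
#' @param models a list of [TranscriptModel-class] objects.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeGtf <- function(models, path) {
  grs <- lapply(models, function(m) {
    ex <- exons(m)
    ranges <- data.frame(start = IRanges::start(ex), end = IRanges::end(ex),
                         type = "exon")
    if (isCoding(m)) {
      cds <- cdsRangesGenomic(m)
      ranges <- rbind(ranges,
                      data.frame(start = IRanges::start(cds),
                                 end = IRanges::end(cds), type = "CDS"))
    }
    gr <- GenomicRanges::GRanges(
      seqnames = chrom(m),
      ranges = IRanges::IRanges(ranges$start, ranges$end),
      strand = txStrand(m))
    gr$source <- "fusionscape"
    gr$type <- ranges$type
    gr$gene_id <- geneId(m)
    gr$gene_name <- geneName(m)
    gr$transcript_id <- transcriptId(m)
    gr$gene_biotype <- m@biotype
    gr
  })
  all <- suppressWarnings(do.call(c, unname(grs)))
  ## rtracklayer warns about absent CDS phase; phase is irrelevant to the
  ## exon/CDS queries this package performs
  suppressWarnings(rtracklayer::export(all, path, format = "gtf"))
  invisible(path)
}

## Genomic intervals covered by the CDS, in genomic order.
cdsRangesGenomic <- function(model) {
  stopifnot(isCoding(model))
  lo <- min(model@cdsStartGenomic, model@cdsEndGenomic)
  hi <- max(model@cdsStartGenomic, model@cdsEndGenomic)
  ex <- model@exons
  keep <- IRanges::end(ex) >= lo & IRanges::start(ex) <= hi
  trimmed <- IRanges::restrict(ex[keep], start = lo, end = hi)
  trimmed[order(IRanges::start(trimmed))]
}

#' Map a genomic position to a spliced mRNA offset
#'
#' Returns the 1-based position of `genomicPos` in the spliced transcript,
#' counting from the transcript 5' end (strand-aware).
#'
#' @param model a [TranscriptModel-class].
#' @param genomicPos integer genomic coordinate (1-based).
#' @return integer mRNA offset in `1..mrnaLength(model)`.
#' @examples
#' tm <- transcriptModel("T1", "G1", "TOY", "10", "+",
#'                       c(100, 300), c(199, 499), 312L, 450L)
#' genomicToMrna(tm, 300)  # 101: all 100 exon-1 bases precede it
#' @export
genomicToMrna <- function(model, genomicPos) {
  genomicPos <- as.integer(genomicPos)
  ex <- model@exons
  idx <- which(genomicPos >= IRanges::start(ex) & genomicPos <= IRanges::end(ex))
  if (length(idx) == 0L)
    stop("position ", genomicPos, " is not exonic in transcript ",
         model@transcriptId)
  idx <- idx[1L]
  before <- if (idx > 1L) sum(IRanges::width(ex[seq_len(idx - 1L)])) else 0L
  within <- if (identical(model@strand, "+"))
    genomicPos - IRanges::start(ex)[idx] + 1L
  else
    IRanges::end(ex)[idx] - genomicPos + 1L
  as.integer(before + within)
}

#' Map a spliced mRNA offset back to a genomic position
#'
#' Inverse of [genomicToMrna()].
#'
#' @param model a [TranscriptModel-class].
#' @param offset 1-based position in the spliced mRNA.
#' @return integer genomic coordinate.
#' @export
mrnaToGenomic <- function(model, offset) {
  offset <- as.integer(offset)
  if (offset < 1L || offset > mrnaLength(model))
    stop("mRNA offset ", offset, " outside 1..", mrnaLength(model))
  w <- IRanges::width(model@exons)
  ends <- cumsum(w)
  idx <- which(offset <= ends)[1L]
  within <- offset - (if (idx > 1L) ends[idx - 1L] else 0L)
  if (identical(model@strand, "+"))
    IRanges::start(model@exons)[idx] + within - 1L
  else
    IRanges::end(model@exons)[idx] - within + 1L
}

#' Signed distance from a breakpoint to the start codon
#'
#' Computed in spliced mRNA coordinates as
#' `offset(CDS start) - offset(breakpoint)`: positive values mean the
#' breakpoint lies that many nucleotides upstream of the ATG (e.g. +12 for a
#' junction at the start of an exon whose first coding base is 12 nt further
#' downstream), negative values mean the breakpoint falls inside the CDS.
#'
#' @param model a coding [TranscriptModel-class].
#' @param genomicBreakpoint exonic genomic coordinate of the breakpoint.
#' @return signed integer distance in nucleotides.
#' @export
distanceToStartCodon <- function(model, genomicBreakpoint) {
  if (!isCoding(model))
    stop("transcript ", model@transcriptId, " is non-coding: no start codon")
  genomicToMrna(model, model@cdsStartGenomic) -
    genomicToMrna(model, genomicBreakpoint)
}

#' Classify a genomic position against exon boundaries
#'
#' In transcription order, the last base of an exon is its splice-donor
#' boundary and the first base its splice-acceptor boundary. Fusion
#' breakpoints reported by callers sit on these bases.
#'
#' @param model a [TranscriptModel-class].
#' @param genomicPos integer genomic coordinate.
#' @return one of `"donor_boundary"`, `"acceptor_boundary"`, `"internal"`,
#'   `"not_exonic"`. A single-base exon reports `"donor_boundary"`.
#' @export
exonBoundaryClass <- function(model, genomicPos) {
  genomicPos <- as.integer(genomicPos)
  ex <- model@exons
  hit <- genomicPos >= IRanges::start(ex) & genomicPos <= IRanges::end(ex)
  if (!any(hit)) return("not_exonic")
  plus <- identical(model@strand, "+")
  first <- if (plus) IRanges::start(ex) else IRanges::end(ex)   # acceptor side
  last <- if (plus) IRanges::end(ex) else IRanges::start(ex)    # donor side
  if (genomicPos %in% last[hit]) "donor_boundary"
  else if (genomicPos %in% first[hit]) "acceptor_boundary"
  else "internal"
}

#' Select one representative transcript per gene
#'
#' For annotation a single isoform per gene is used: the transcript with the
#' longest CDS, ties broken by lexicographic transcript id; non-coding
#' transcripts rank below all coding ones (by mRNA length among themselves).
#'
#' @param models a list of [TranscriptModel-class] objects.
#' @return a named list with one model per gene name.
#' @export
selectRepresentativeTranscript <- function(models) {
  if (length(models) == 0L) return(list())
  genes <- vapply(models, geneName, character(1))
  out <- lapply(split(models, genes), function(ms) {
    cdsLen <- vapply(ms, function(m) {
      if (!isCoding(m)) return(-1L)
      abs(genomicToMrna(m, m@cdsEndGenomic) - genomicToMrna(m, m@cdsStartGenomic)) + 1L
    }, integer(1))
    key <- order(-cdsLen, vapply(ms, transcriptId, character(1)))
    ms[[key[1L]]]
  })
  out
}
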