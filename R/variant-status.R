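## IDH hotspot status from RNA-seq pileup base counts, plus ingestion of
## upstream 1p/19q and hypermutation calls.

#' Packaged IDH hotspot definitions (GRCh37)
#'
#' One row per hotspot codon with its canonical genomic position and
#' reference base: IDH1 R132 and IDH2 R172.
#' @return data.frame with columns `gene`, `codon`, `chrom`, `pos`, `ref`,
#'   `alt`.
#' @export
idhHotspots <- function() {
  utils::read.delim(fusionscapeResource("idh_hotspots_grch37.tsv"),
                    stringsAsFactors = FALSE, colClasses = c(
                      gene = "character", codon = "character",
                      chrom = "character", pos = "integer",
                      ref = "character", alt = "character"))
}

#' Read a pileup base-count table
#'
#' Reads pre-tallied per-site base counts (sample, chrom, pos, ref and the
#' four nucleotide columns), as distilled from `samtools mpileup` output.
#' Depth is recomputed as the sum of the four counts.
#'
#' @param path TSV with header columns `sample_id`, `chrom`, `pos`, `ref`,
#'   `A`, `C`, `G`, `T`.
#' @return data.frame of sites with a recomputed `depth` column.
#' @export
readPileup <- function(path) {
  if (!file.exists(path)) stop("pileup file not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("sample_id", "chrom", "pos", "ref", "A", "C", "G", "T")
  missing <- setdiff(need, colnames(tab))
  if (length(missing))
    stop("pileup table lacks required column(s): ",
         paste(missing, collapse = ", "))
  counts <- as.matrix(tab[, c("A", "C", "G", "T")])
  if (nrow(tab) && (anyNA(counts) || any(counts < 0)))
    stop("negative or missing base count in pileup table")
  tab$chrom <- normalizeChrom(tab$chrom)
  tab$depth <- if (nrow(tab)) as.integer(rowSums(counts)) else integer(0)
  tab
}

#' Call hotspot mutation status from one pileup site
#'
#' Availability rule: a site covered by fewer than `minDepth` reads is not
#' callable and gets status `NA` regardless of allele content. Otherwise the
#' site is `mutant` when the non-reference reads reach both `minAltReads`
#' and `minVaf`, else `wildtype`.
#'
#' @param site one row of a [readPileup()] table (data.frame or list with
#'   `chrom`, `pos`, `ref` and base counts `A`,`C`,`G`,`T`).
#' @param hotspotDef one row of [idhHotspots()] (must match the site
#'   position).
#' @param minDepth minimum reads covering the position for a call
#'   (default 5).
#' @param minAltReads,minVaf mutant-call thresholds on non-reference read
#'   count and fraction (defaults 2 and 0.1).
#' @return a data.frame row: `sample_id`, `gene`, `codon`, `status`
#'   (`"mutant"`, `"wildtype"` or `NA`), `depth`, `variant_fraction`
#'   (NA when not callable).
#' @export
callHotspot <- function(site, hotspotDef, minDepth = 5L, minAltReads = 2L,
                        minVaf = 0.1) {
  if (normalizeChrom(site$chrom) != normalizeChrom(hotspotDef$chrom) ||
      as.integer(site$pos) != as.integer(hotspotDef$pos))
    stop("pileup site ", site$chrom, ":", site$pos,
         " does not match hotspot ", hotspotDef$gene, " ", hotspotDef$codon,
         " at ", hotspotDef$chrom, ":", hotspotDef$pos)
  counts <- c(A = as.integer(site$A), C = as.integer(site$C),
              G = as.integer(site$G), T = as.integer(site$T))
  depth <- sum(counts)
  ref <- toupper(as.character(site$ref))
  alt <- depth - counts[[ref]]
  if (depth < minDepth) {
    status <- NA_character_; vaf <- NA_real_
  } else {
    vaf <- alt / depth
    status <- if (alt >= minAltReads && vaf >= minVaf) "mutant" else "wildtype"
  }
  data.frame(sample_id = as.character(site$sample_id),
             gene = hotspotDef$gene, codon = hotspotDef$codon,
             status = status, depth = depth, variant_fraction = vaf,
             stringsAsFactors = FALSE)
}

#' Call hotspot status across a pileup table
#'
#' Applies [callHotspot()] to every site matching a packaged (or supplied)
#' hotspot definition; sites at other positions are ignored.
#'
#' @param pileup data.frame from [readPileup()].
#' @param hotspots hotspot definition table (default [idhHotspots()]).
#' @inheritParams callHotspot
#' @return data.frame of per-sample calls (one row per sample x hotspot seen).
#' @export
callHotspots <- function(pileup, hotspots = idhHotspots(), minDepth = 5L,
                         minAltReads = 2L, minVaf = 0.1) {
  rows <- list()
  for (h in seq_len(nrow(hotspots))) {
    def <- hotspots[h, ]
    sel <- which(pileup$chrom == normalizeChrom(def$chrom) &
                   pileup$pos == def$pos)
    if (!length(sel)) next
    counts <- as.matrix(pileup[sel, c("A", "C", "G", "T")])
    depth <- as.integer(rowSums(counts))
    refIdx <- match(toupper(pileup$ref[sel]), c("A", "C", "G", "T"))
    alt <- depth - counts[cbind(seq_along(sel), refIdx)]
    callable <- depth >= minDepth
    vaf <- ifelse(callable, alt / pmax(depth, 1L), NA_real_)
    status <- ifelse(!callable, NA_character_,
                     ifelse(alt >= minAltReads & vaf >= minVaf,
                            "mutant", "wildtype"))
    rows[[length(rows) + 1L]] <- data.frame(
      sample_id = as.character(pileup$sample_id[sel]),
      gene = def$gene, codon = def$codon, status = status,
      depth = depth, variant_fraction = vaf, stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(sample_id = character(0), gene = character(0),
                      codon = character(0), status = character(0),
                      depth = integer(0), variant_fraction = numeric(0)))
  do.call(rbind, rows)
}

#' Summarise IDH status per patient
#'
#' A patient is IDH-mutant if any hotspot call is mutant, wildtype if all
#' callable hotspots are wildtype, and NA when no hotspot was callable.
#'
#' @param calls data.frame from [callHotspots()].
#' @return data.frame with `patient_id` and `idh_status`.
#' @export
summarizeIdhStatus <- function(calls) {
  sp <- split(calls$status, calls$sample_id)
  status <- vapply(sp, function(s) {
    if (any(!is.na(s) & s == "mutant")) "mutant"
    else if (any(!is.na(s) & s == "wildtype")) "wildtype"
    else NA_character_
  }, character(1))
  data.frame(patient_id = names(sp), idh_status = unname(status),
             stringsAsFactors = FALSE)
}

#' Ingest upstream 1p/19q and hypermutation calls
#'
#' Copy-number (1p/19q co-deletion) and hypermutation are produced by
#' dedicated upstream tools; this only validates and attaches their calls.
#'
#' @param table data.frame or CSV path with columns `patient_id` and one or
#'   both of `codel_1p19q`, `hypermutation`; statuses in `yes`/`no`/`NA`.
#' @param cohortIds optional character vector of known patient ids; rows for
#'   unknown patients are skipped with a warning.
#' @return validated data.frame keyed by `patient_id`.
#' @export
ingestUpstreamCalls <- function(table, cohortIds = NULL) {
  if (is.character(table)) table <- utils::read.csv(table, stringsAsFactors = FALSE)
  if (!"patient_id" %in% colnames(table))
    stop("upstream calls need a patient_id column")
  statusCols <- intersect(c("codel_1p19q", "hypermutation"), colnames(table))
  if (!length(statusCols))
    stop("upstream calls need a codel_1p19q and/or hypermutation column")
  for (col in statusCols) {
    v <- as.character(table[[col]])
    bad <- !(is.na(v) | v %in% c("yes", "no", "NA"))
    if (any(bad))
      stop("invalid ", col, " status token: '", v[which(bad)[1L]],
           "' (expected yes/no/NA)")
    v[v == "NA"] <- NA_character_
    table[[col]] <- v
  }
  if (!is.null(cohortIds)) {
    known <- table$patient_id %in% cohortIds
    if (any(!known)) {
      warning("skipping ", sum(!known),
              " upstream call row(s) for unknown patient(s): ",
              paste(unique(table$patient_id[!known]), collapse = ", "))
      table <- table[known, , drop = FALSE]
    }
  }
  table
}
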