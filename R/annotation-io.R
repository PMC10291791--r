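#' @importFrom data.table data.table setkey setorder rbindlist as.data.table :=
#' @importFrom rtracklayer import
#' @importFrom GenomeInfoDb seqlevels seqnames
NULL

# strip a leading "chr" so VCF and annotation dialects match deterministically
normalizeChrom <- function(x) sub("^chr", "", as.character(x))

#' Derive intron intervals from the exons of one transcript
#'
#' Introns are the gaps between consecutive genomic exons:
#' `[exon_i.end + 1, exon_(i+1).start - 1]`. A single-exon transcript yields
#' no introns; directly adjacent exons (gap of width 0) yield no intron and
#' a warning, since a zero-width interval cannot hold a variant.
#'
#' @param starts,ends integer vectors of 1-based inclusive exon coordinates,
#'   sorted by start, non-overlapping.
#' @param transcript_id identifier used in error messages.
#' @return data.frame with columns `start`, `end` (possibly 0 rows).
#' @examples
#' deriveIntrons(c(1001, 1501), c(1100, 1600))  # one intron [1101, 1500]
#' @export
deriveIntrons <- function(starts, ends, transcript_id = "<transcript>") {
  stopifnot(length(starts) == length(ends))
  if (length(starts) <= 1L)
    return(data.frame(start = integer(), end = integer()))
  o <- order(starts)
  starts <- starts[o]; ends <- ends[o]
  if (any(starts[-1] <= ends[-length(ends)]))
    stop("overlapping exons in transcript ", transcript_id)
  istart <- ends[-length(ends)] + 1L
  iend <- starts[-1] - 1L
  if (any(iend < istart))
    warning("adjacent exons (zero-length gap) in transcript ", transcript_id,
            "; no intron emitted for that junction")
  keep <- iend >= istart
  data.frame(start = as.integer(istart[keep]), end = as.integer(iend[keep]))
}

# exon table (chrom,start,end,strand,transcript_id,gene_id) -> GenomeAnnotation
.buildAnnotation <- function(ex, windowWidth) {
  stopifnot(nrow(ex) > 0)
  dt <- as.data.table(ex)
  dt[, chrom := normalizeChrom(chrom)]
  setorder(dt, transcript_id, start)
  # overlap check per transcript
  bad <- dt[, .(bad = .N > 1L && any(start[-1] <= end[-.N])), by = transcript_id]
  if (any(bad$bad))
    stop("overlapping exons in transcript ",
         paste(bad$transcript_id[bad$bad], collapse = ", "))
  dt[, genomic_idx := seq_len(.N), by = transcript_id]
  dt[, n_ex := .N, by = transcript_id]
  dt[, exon_rank := ifelse(strand == "-", n_ex - genomic_idx + 1L, genomic_idx)]

  intr <- dt[n_ex > 1L, {
    res <- deriveIntrons(start, end, transcript_id = .BY$transcript_id)
    if (nrow(res))
      cbind(res, chrom = chrom[1], strand = strand[1], gene_id = gene_id[1])
    else NULL
  }, by = transcript_id]

  exons <- GRanges(dt$chrom, IRanges(dt$start, dt$end), strand = dt$strand,
                   transcript_id = dt$transcript_id, gene_id = dt$gene_id,
                   exon_rank = as.integer(dt$exon_rank))
  if (!is.null(intr) && nrow(intr)) {
    setorder(intr, transcript_id, start)
    intr[, genomic_idx := seq_len(.N), by = transcript_id]
    intr[, n_in := .N, by = transcript_id]
    intr[, intron_rank := ifelse(strand == "-", n_in - genomic_idx + 1L,
                                 genomic_idx)]
    introns <- GRanges(intr$chrom, IRanges(intr$start, intr$end),
                       strand = intr$strand,
                       transcript_id = intr$transcript_id,
                       gene_id = intr$gene_id,
                       intron_rank = as.integer(intr$intron_rank))
  } else {
    introns <- GRanges(transcript_id = character(), gene_id = character(),
                       intron_rank = integer())
  }
  new("GenomeAnnotation", exons = exons, introns = introns,
      windowWidth = as.integer(windowWidth))
}

# cheap line-shape validation so parse failures can name a line number
.checkFieldCounts <- function(path, n_fields, format) {
  lines <- readLines(path, warn = FALSE)
  body <- !grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))
  counts <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  if (any(counts < n_fields)) {
    lineno <- which(body)[which(counts < n_fields)[1]]
    stop("unparseable ", format, " line ", lineno, " in ", path,
         ": expected at least ", n_fields, " tab-separated fields")
  }
  invisible(sum(body))
}

#' Load a gene annotation and derive introns and flanking windows
#'
#' Reads transcript exon structures from GFF3, GTF or BED12 (format guessed
#' from the file extension unless given), converts BED 0-based half-open
#' coordinates to the package's 1-based inclusive convention, and derives
#' the intron intervals between consecutive exons. Chromosome names are
#' normalised by stripping any `chr` prefix.
#'
#' @param path annotation file.
#' @param format one of `"auto"`, `"gff3"`, `"gtf"`, `"bed12"`.
#' @param windowWidth flanking window half-width W in bp (default 200).
#' @return a [GenomeAnnotation-class] object.
#' @export
loadAnnotation <- function(path, format = c("auto", "gff3", "gtf", "bed12"),
                           windowWidth = 200L) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("annotation file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
    format <- switch(ext,
      gff = , gff3 = "gff3", gtf = "gtf", bed = "bed12",
      stop("cannot guess annotation format from extension '", ext, "'"))
  }
  ex <- switch(format,
    gff3 = .readExonsGff3(path),
    gtf = .readExonsGtf(path),
    bed12 = .readExonsBed12(path))
  if (nrow(ex) == 0L) stop("no transcripts in annotation file ", path)
  .buildAnnotation(ex, windowWidth)
}

.readExonsGff3 <- function(path) {
  if (.checkFieldCounts(path, 9L, "GFF3") == 0L) return(data.frame())
  gr <- rtracklayer::import(path, format = "gff3")
  feats <- as.character(gr$type)
  # transcript -> gene from the mRNA/transcript level, if present
  txrow <- feats %in% c("mRNA", "transcript")
  tx2gene <- character()
  if (any(txrow)) {
    par <- vapply(gr$Parent[txrow],
                  function(p) if (length(p)) p[[1]] else NA_character_,
                  character(1))
    tx2gene <- structure(par, names = as.character(gr$ID[txrow]))
  }
  ex <- gr[feats == "exon"]
  if (!length(ex)) return(data.frame())
  tx <- vapply(ex$Parent, function(p) if (length(p)) p[[1]] else NA_character_,
               character(1))
  if (anyNA(tx)) stop("exon feature without Parent transcript in ", path)
  gene <- tx2gene[tx]
  gene[is.na(gene)] <- tx[is.na(gene)]
  data.frame(chrom = as.character(seqnames(ex)),
             start = start(ex), end = end(ex),
             strand = as.character(strand(ex)),
             transcript_id = tx, gene_id = unname(gene))
}

.readExonsGtf <- function(path) {
  if (.checkFieldCounts(path, 9L, "GTF") == 0L) return(data.frame())
  gr <- rtracklayer::import(path, format = "gtf")
  ex <- gr[as.character(gr$type) == "exon"]
  if (!length(ex)) return(data.frame())
  gene <- if ("gene_id" %in% colnames(mcols(ex))) ex$gene_id else ex$transcript_id
  gene[is.na(gene)] <- ex$transcript_id[is.na(gene)]
  data.frame(chrom = as.character(seqnames(ex)),
             start = start(ex), end = end(ex),
             strand = as.character(strand(ex)),
             transcript_id = ex$transcript_id, gene_id = gene)
}

.readExonsBed12 <- function(path) {
  if (.checkFieldCounts(path, 12L, "BED12") == 0L) return(data.frame())
  gr <- rtracklayer::import(path, format = "bed")
  if (!length(gr)) return(data.frame())
  if (is.null(gr$blocks))
    stop("BED input lacks the 12-column block structure: ", path)
  res <- lapply(seq_along(gr), function(i) {
    bl <- gr$blocks[[i]]
    # rtracklayer blocks are 1-based relative to the (already converted)
    # 1-based feature start
    data.frame(chrom = as.character(seqnames(gr))[i],
               start = start(gr)[i] + start(bl) - 1L,
               end = start(gr)[i] + end(bl) - 1L,
               strand = as.character(strand(gr))[i],
               transcript_id = gr$name[i], gene_id = gr$name[i])
  })
  do.call(rbind, res)
}

#' Write the derived intron table as TSV
#'
#' Emits one row per intron: chrom, start, end, strand, transcript_id,
#' intron_rank (1-based in transcript orientation). Intended for debugging
#' and for downstream inspection of the derived gene geometry.
#'
#' @param ann a [GenomeAnnotation-class].
#' @param path output file.
#' @export
writeIntronTable <- function(ann, path) {
  gi <- introns(ann)
  df <- data.frame(chrom = as.character(seqnames(gi)),
                   start = start(gi), end = end(gi),
                   strand = as.character(strand(gi)),
                   transcript_id = mcols(gi)$transcript_id,
                   intron_rank = mcols(gi)$intron_rank)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export the annotation as BED12
#'
#' One line per transcript with exons as blocks; coordinates are converted
#' back to BED's 0-based half-open convention. Round-tripping through
#' [loadAnnotation()] preserves exon coordinates exactly.
#'
#' @param ann a [GenomeAnnotation-class].
#' @param path output file.
#' @export
exportBed12 <- function(ann, path) {
  ex <- exons(ann)
  dt <- data.table(chrom = as.character(seqnames(ex)),
                   start = start(ex), end = end(ex),
                   strand = as.character(strand(ex)),
                   transcript_id = mcols(ex)$transcript_id)
  setorder(dt, transcript_id, start)
  lines <- dt[, {
    chromStart <- start[1] - 1L
    chromEnd <- end[.N]
    sizes <- end - start + 1L
    offs <- start - start[1]
    sprintf("%s\t%d\t%d\t%s\t0\t%s\t%d\t%d\t0\t%d\t%s\t%s",
            chrom[1], chromStart, chromEnd, .BY$transcript_id, strand[1],
            chromStart, chromEnd, .N,
            paste0(paste(sizes, collapse = ","), ","),
            paste0(paste(offs, collapse = ","), ","))
  }, by = transcript_id]$V1
  writeLines(lines, path)
  invisible(path)
}
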