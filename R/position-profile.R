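#' Assign genomic positions to region classes and splice-site offsets
#'
#' Classifies each (chrom, pos) against the annotation:
#' \itemize{
#'   \item \strong{exonic} if the position lies in any exon of any
#'     transcript (exonic precedence over intronic);
#'   \item otherwise \strong{intronic_flanking} with a side (donor = moving
#'     3' from an exon end into the intron in transcript orientation,
#'     acceptor = moving 5' from an exon start) and offset bucket
#'     `d` = distance to that splice site, when `d <= W` for some
#'     transcript;
#'   \item otherwise \strong{deep_intronic} if inside any intron;
#'   \item otherwise \strong{intergenic}.
#' }
#' Inside an intron each base belongs to its nearer boundary only (never
#' double-counted); a donor/acceptor distance tie resolves to donor. Among
#' multiple transcripts the assignment with minimal `d` wins, remaining
#' ties resolve to the lexicographically smallest transcript id.
#' A chromosome absent from the annotation yields intergenic with one
#' warning per chromosome.
#'
#' @param chrom,pos vectors of chromosome names and 1-based positions.
#' @param ann a [GenomeAnnotation-class].
#' @return data.frame with columns `region`, `d` (NA unless flanking),
#'   `side` (NA unless flanking), `transcript_id`, `gene_id`.
#' @examples
#' ann <- .buildAnnotation(data.frame(
#'   chrom = "1", start = c(1001, 1501), end = c(1100, 1600),
#'   strand = "+", transcript_id = "TX1", gene_id = "G1"), 200)
#' classifyPosition("1", 1109, ann)  # donor, d = 9
#' @export
classifyPosition <- function(chrom, pos, ann) {
  if (length(chrom) == 1L && length(pos) > 1L)
    chrom <- rep(chrom, length(pos))
  stopifnot(length(chrom) == length(pos))
  n <- length(pos)
  if (any(pos < 1L, na.rm = TRUE)) stop("positions must be >= 1")
  chrom <- normalizeChrom(chrom)
  out <- data.frame(region = rep("intergenic", n),
                    d = rep(NA_integer_, n),
                    side = rep(NA_character_, n),
                    transcript_id = rep(NA_character_, n),
                    gene_id = rep(NA_character_, n),
                    stringsAsFactors = FALSE)
  if (n == 0L) return(out)

  ex <- exons(ann); gi <- introns(ann)
  known_chroms <- unique(c(as.character(seqnames(ex)),
                           as.character(seqnames(gi))))
  unknown <- setdiff(unique(chrom), known_chroms)
  if (length(unknown))
    warning("chromosome(s) absent from annotation, classified intergenic: ",
            paste(unknown, collapse = ", "))
  idx <- which(chrom %in% known_chroms)
  if (!length(idx)) return(out)

  v <- GRanges(chrom[idx], IRanges(pos[idx], pos[idx]))
  GenomeInfoDb::seqlevels(v) <-
    unique(c(GenomeInfoDb::seqlevels(v), known_chroms))

  # exonic precedence; resolve to lexicographically smallest transcript
  eh <- findOverlaps(v, ex, ignore.strand = TRUE)
  if (length(eh)) {
    ed <- data.table(q = queryHits(eh),
                     tx = mcols(ex)$transcript_id[subjectHits(eh)],
                     gene = mcols(ex)$gene_id[subjectHits(eh)])
    setorder(ed, q, tx)
    ed <- ed[!duplicated(q)]
    out$region[idx[ed$q]] <- "exonic"
    out$transcript_id[idx[ed$q]] <- ed$tx
    out$gene_id[idx[ed$q]] <- ed$gene
  }

  todo <- which(out$region[idx] == "intergenic")
  if (length(todo) && length(gi)) {
    vsub <- v[todo]
    ih <- findOverlaps(vsub, gi, ignore.strand = TRUE)
    if (length(ih)) {
      s <- start(gi)[subjectHits(ih)]
      e <- end(gi)[subjectHits(ih)]
      str <- as.character(strand(gi))[subjectHits(ih)]
      p <- pos[idx][todo][queryHits(ih)]
      d_donor <- ifelse(str == "-", e - p + 1L, p - s + 1L)
      len <- e - s + 1L
      d_acc <- len - d_donor + 1L
      hd <- data.table(
        q = todo[queryHits(ih)],
        d = as.integer(pmin(d_donor, d_acc)),
        side = ifelse(d_donor <= d_acc, "donor", "acceptor"),
        tx = mcols(gi)$transcript_id[subjectHits(ih)],
        gene = mcols(gi)$gene_id[subjectHits(ih)])
      W <- windowWidth(ann)
      fl <- hd[d <= W]
      if (nrow(fl)) {
        setorder(fl, q, d, tx)
        fl <- fl[!duplicated(q)]
        out$region[idx[fl$q]] <- "intronic_flanking"
        out$d[idx[fl$q]] <- fl$d
        out$side[idx[fl$q]] <- fl$side
        out$transcript_id[idx[fl$q]] <- fl$tx
        out$gene_id[idx[fl$q]] <- fl$gene
      }
      dp <- hd[!q %in% fl$q]
      if (nrow(dp)) {
        setorder(dp, q, d, tx)
        dp <- dp[!duplicated(q)]
        out$region[idx[dp$q]] <- "deep_intronic"
        out$transcript_id[idx[dp$q]] <- dp$tx
        out$gene_id[idx[dp$q]] <- dp$gene
      }
    }
  }
  out
}

#' Build the per-position profile of unique variants
#'
#' Tallies unique variants per flanking offset bucket d in 1..W: raw count,
#' pass count (aggregated pass status), false count, the false proportion
#' FP = false/raw (NA where no variants), mean depth (mean over the
#' per-variant mean DP), and the deleterious count from
#' [deleteriousFilter()]. Totals over the exonic / intronic / flanking /
#' deep-intronic partitions, with distinct-gene counts, are recorded in the
#' `totals` slot.
#'
#' @param uvs a [UniqueVariantSet-class].
#' @param ann a [GenomeAnnotation-class].
#' @param delThresholds,delScores,dpsiAbsolute forwarded to
#'   [deleteriousFilter()].
#' @return a [PositionProfile-class].
#' @export
buildProfile <- function(uvs, ann, delThresholds = deleteriousThresholds(),
                         delScores = "present", dpsiAbsolute = FALSE) {
  W <- windowWidth(ann)
  if (W <= 0L) stop("window width W must be positive")
  uv <- uniqueVariants(uvs)
  asn <- classifyPosition(uv$chrom, uv$pos, ann)
  del <- deleteriousFilter(uvs, thresholds = delThresholds,
                           scores = delScores, dpsiAbsolute = dpsiAbsolute)

  tab <- data.frame(d = seq_len(W), raw_count = 0L, pass_count = 0L,
                    false_count = 0L, fp = NA_real_, mean_depth = NA_real_,
                    deleterious_count = 0L)
  fl <- asn$region == "intronic_flanking"
  if (any(fl)) {
    dt <- data.table(d = asn$d[fl], pass = uv$any_pass[fl],
                     dp = uv$mean_dp[fl], del = del[fl])
    agg <- dt[, .(raw = .N, pass = sum(pass), del = sum(del & pass),
                  dep = if (all(is.na(dp))) NA_real_ else mean(dp, na.rm = TRUE)),
              by = d]
    i <- match(agg$d, tab$d)
    tab$raw_count[i] <- agg$raw
    tab$pass_count[i] <- agg$pass
    tab$false_count[i] <- agg$raw - agg$pass
    tab$fp[i] <- (agg$raw - agg$pass) / agg$raw
    tab$mean_depth[i] <- agg$dep
    tab$deleterious_count[i] <- agg$del
  }

  part <- function(sel) {
    genes <- function(keep) length(unique(asn$gene_id[sel & keep]))
    list(raw = sum(sel), pass = sum(uv$any_pass[sel]),
         deleterious = sum(del[sel] & uv$any_pass[sel]),
         genes_raw = genes(TRUE), genes_pass = genes(uv$any_pass),
         genes_deleterious = genes(del & uv$any_pass))
  }
  totals <- list(
    all = part(rep(TRUE, nrow(uv))),
    exonic = part(asn$region == "exonic"),
    intronic = part(asn$region %in% c("intronic_flanking", "deep_intronic")),
    intronic_flanking = part(fl),
    deep_intronic = part(asn$region == "deep_intronic"),
    intergenic = part(asn$region == "intergenic")
  )
  new("PositionProfile", table = tab, totals = totals,
      windowWidth = as.integer(W))
}

#' Count distinct genes contributing variants to a partition
#'
#' @param uvs a [UniqueVariantSet-class].
#' @param ann a [GenomeAnnotation-class].
#' @param partition one of `"all"`, `"exonic"`, `"intronic"`,
#'   `"intronic_flanking"`, `"deep_intronic"`.
#' @param which count genes over `"raw"`, `"pass"` or `"deleterious"`
#'   variants.
#' @param ... forwarded to [deleteriousFilter()] when
#'   `which = "deleterious"`.
#' @return integer count of distinct gene identifiers.
#' @export
geneCounts <- function(uvs, ann,
                       partition = c("all", "exonic", "intronic",
                                     "intronic_flanking", "deep_intronic"),
                       which = c("raw", "pass", "deleterious"), ...) {
  partition <- match.arg(partition)
  which <- match.arg(which)
  uv <- uniqueVariants(uvs)
  if (nrow(uv) == 0L) return(0L)
  asn <- classifyPosition(uv$chrom, uv$pos, ann)
  sel <- switch(partition,
    all = asn$region != "intergenic",
    exonic = asn$region == "exonic",
    intronic = asn$region %in% c("intronic_flanking", "deep_intronic"),
    intronic_flanking = asn$region == "intronic_flanking",
    deep_intronic = asn$region == "deep_intronic")
  keep <- switch(which,
    raw = rep(TRUE, nrow(uv)),
    pass = uv$any_pass,
    deleterious = deleteriousFilter(uvs, ...) & uv$any_pass)
  length(unique(asn$gene_id[sel & keep & !is.na(asn$gene_id)]))
}

#' Write the four per-position profile tables as TSV
#'
#' Emits the table structures of the study's supplementary profiles:
#' `raw_counts.tsv` (position, raw_count), `fp_profile.tsv` (position,
#' raw_count, pass_count, false_count, fp, mean_depth), `pass_counts.tsv`
#' (position, pass_count) and `deleterious_counts.tsv` (position,
#' deleterious_count), plus `totals.tsv` with the partition totals.
#'
#' @param profile a [PositionProfile-class].
#' @param dir output directory (created if needed).
#' @return invisibly, the written file paths.
#' @export
writeProfileTables <- function(profile, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tb <- profileTable(profile)
  w <- function(df, name) {
    path <- file.path(dir, name)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    path
  }
  paths <- c(
    w(data.frame(position = tb$d, raw_count = tb$raw_count), "raw_counts.tsv"),
    w(data.frame(position = tb$d, raw_count = tb$raw_count,
                 pass_count = tb$pass_count, false_count = tb$false_count,
                 fp = tb$fp, mean_depth = tb$mean_depth), "fp_profile.tsv"),
    w(data.frame(position = tb$d, pass_count = tb$pass_count),
      "pass_counts.tsv"),
    w(data.frame(position = tb$d, deleterious_count = tb$deleterious_count),
      "deleterious_counts.tsv")
  )
  tot <- profileTotals(profile)
  totdf <- do.call(rbind, lapply(names(tot), function(p)
    data.frame(partition = p, as.data.frame(tot[[p]]))))
  paths <- c(paths, w(totdf, "totals.tsv"))
  invisible(paths)
}

#' Plot a per-position profile
#'
#' Simple base-graphics line plot of one profile column against position.
#'
#' @param profile a [PositionProfile-class].
#' @param what column to plot.
#' @param ... forwarded to [graphics::plot()].
#' @export
plotProfile <- function(profile, what = c("raw_count", "pass_count", "fp",
                                          "mean_depth", "deleterious_count"),
                        ...) {
  what <- match.arg(what)
  tb <- profileTable(profile)
  graphics::plot(tb$d, tb[[what]], type = "l", xlab = "intronic offset d",
                 ylab = what, ...)
  invisible(NULL)
}
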