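suppressPackageStartupMessages(library(GenomicRanges))

# small annotations built in code, shared across test files

# one +strand transcript, exons [1001,1100] and [1501,1600]
toyAnnotation <- function(W = 200L, strand = "+") {
  ex <- data.frame(chrom = "1", start = c(1001L, 1501L),
                   end = c(1100L, 1600L), strand = strand,
                   transcript_id = "TX1", gene_id = "G1")
  IntronProfiler:::.buildAnnotation(ex, W)
}

# two genes, one multi-transcript with disagreeing exon boundaries
multiTxAnnotation <- function(W = 50L) {
  ex <- rbind(
    data.frame(chrom = "1", start = c(1000L, 2000L, 3000L),
               end = c(1199L, 2199L, 3199L), strand = "+",
               transcript_id = "TXA1", gene_id = "GA"),
    data.frame(chrom = "1", start = c(1000L, 1600L),
               end = c(1199L, 1799L), strand = "+",
               transcript_id = "TXA2", gene_id = "GA"),
    data.frame(chrom = "2", start = c(500L, 901L),
               end = c(700L, 1100L), strand = "-",
               transcript_id = "TXB1", gene_id = "GB"))
  IntronProfiler:::.buildAnnotation(ex, W)
}

# random multi-transcript annotation for oracle-equivalence sweeps;
# includes short introns (< 2W) so nearer-boundary assignment is exercised
randomAnnotation <- function(n_tx = 25L, W = 60L) {
  rows <- lapply(seq_len(n_tx), function(i) {
    chrom <- as.character(sample(1:3, 1))
    nex <- sample(2:5, 1)
    el <- sample(30:120, nex, replace = TRUE)
    il <- sample(15:260, nex - 1, replace = TRUE)
    start0 <- sample(1000:50000, 1)
    starts <- integer(nex); ends <- integer(nex); p <- start0
    for (k in seq_len(nex)) {
      starts[k] <- p; ends[k] <- p + el[k] - 1L
      p <- ends[k] + (if (k < nex) il[k] else 0L) + 1L
    }
    data.frame(chrom = chrom, start = starts, end = ends,
               strand = sample(c("+", "-"), 1),
               transcript_id = sprintf("RT%03d", i),
               gene_id = sprintf("RG%03d", (i - 1L) %/% 3L + 1L))
  })
  IntronProfiler:::.buildAnnotation(do.call(rbind, rows), W)
}

# Independent brute-force position classifier: scans every exon and every
# intron boundary of every transcript, computes all donor/acceptor
# distances explicitly, and applies the precedence rules written out
# independently of the package implementation.
oracleClassify <- function(chrom, pos, ann) {
  ex <- as.data.frame(exons(ann))
  W <- windowWidth(ann)
  n <- length(pos)
  region <- character(n); dd <- rep(NA_integer_, n)
  side <- rep(NA_character_, n); tx <- rep(NA_character_, n)
  for (v in seq_len(n)) {
    p <- pos[v]; ch <- sub("^chr", "", chrom[v])
    sub <- ex[ex$seqnames == ch, , drop = FALSE]
    if (nrow(sub) == 0L) { region[v] <- "intergenic"; next }
    hit_ex <- sub[p >= sub$start & p <= sub$end, , drop = FALSE]
    if (nrow(hit_ex)) {
      region[v] <- "exonic"
      tx[v] <- sort(hit_ex$transcript_id)[1]
      next
    }
    # candidate assignments over every transcript's introns
    cand <- list()
    in_intron <- FALSE
    for (t in unique(sub$transcript_id)) {
      te <- sub[sub$transcript_id == t, , drop = FALSE]
      te <- te[order(te$start), , drop = FALSE]
      if (nrow(te) < 2L) next
      str <- te$strand[1]
      for (k in seq_len(nrow(te) - 1L)) {
        is <- te$end[k] + 1L; ie <- te$start[k + 1L] - 1L
        if (ie < is || p < is || p > ie) next
        in_intron <- TRUE
        dist_left <- p - is + 1L
        dist_right <- ie - p + 1L
        if (str == "+") { d_don <- dist_left; d_acc <- dist_right }
        else { d_don <- dist_right; d_acc <- dist_left }
        if (d_don <= d_acc) { dmin <- d_don; sd <- "donor" }
        else { dmin <- d_acc; sd <- "acceptor" }
        if (dmin <= W)
          cand[[length(cand) + 1L]] <- list(d = dmin, side = sd, tx = t)
      }
    }
    if (length(cand)) {
      ds <- vapply(cand, `[[`, numeric(1), "d")
      txs <- vapply(cand, `[[`, character(1), "tx")
      best <- order(ds, txs)[1]
      region[v] <- "intronic_flanking"
      dd[v] <- as.integer(cand[[best]]$d)
      side[v] <- cand[[best]]$side
      tx[v] <- cand[[best]]$tx
    } else if (in_intron) {
      region[v] <- "deep_intronic"
    } else {
      region[v] <- "intergenic"
    }
  }
  data.frame(region = region, d = dd, side = side, transcript_id = tx,
             stringsAsFactors = FALSE)
}
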