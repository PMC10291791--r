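#' Construct a synthetic-cohort configuration
#'
#' The defaults encode the positional structure the generator emulates, at
#' a desk scale of 20 samples and 50 multi-exon genes:
#' \itemize{
#'   \item variant intensity lambda(d) per flanking base: elevated at d = 1,
#'     global minimum within 150 bp at d = 2, linear rise to a sharp peak at
#'     d = 9, a drop at d = 10, a gentle linear decay out to d = 149 and a
#'     steeper decay to d = 200;
#'   \item mean sequencing depth decaying with distance from the exon,
#'     half-life parameterisation with its midpoint near d = 50 and a floor
#'     in the deep flank;
#'   \item QC-failure probability logistic in depth, producing an S-shaped
#'     false-proportion curve inverse to the depth profile;
#'   \item deleterious-annotation enrichment spike at d = 5.
#' }
#' Contrasts are deliberately sharper than a full-scale patient cohort so
#' the designed structure is recoverable from a 20-sample simulation; see
#' the package vignette.
#'
#' @param seed RNG seed (integer).
#' @param nSamples cohort size.
#' @param nGenes number of genes.
#' @param exonsPerGene,exonLengthRange,intronLengthRange inclusive integer
#'   ranges; the default minimum intron length 2W + 1 guarantees both
#'   flanking windows fit without overlap.
#' @param windowWidth flanking half-width W.
#' @param lambda1,lambda2,lambdaPrePeak,peakPos,lambdaPeak,lambdaPostPeak,farPos,lambdaFar,lambdaEnd
#'   piecewise intensity parameters (per-base, per cohort).
#' @param depthPlateau,depthFloor,depthHalfLife depth model (reads; bp).
#' @param qcFailBase,qcFailMidpoint,qcFailSlope QC-failure logistic in
#'   depth: `base + (1 - base) * plogis((midpoint - DP) / slope)`.
#' @param carrierProb probability each additional sample carries a variant.
#' @param delBase,delSpikePos,delSpikeProb deleterious-annotation
#'   probability for pass flanking variants, with the spike position.
#' @param exonicLambda,exonicDepth exonic variant intensity and depth.
#' @param deepLambda intensity beyond the flanking window.
#' @param indelFraction fraction of variants generated as indels.
#' @return a [SyntheticConfig-class].
#' @export
syntheticConfig <- function(seed = 20230626L,
                            nSamples = 20L, nGenes = 50L,
                            exonsPerGene = c(4L, 7L),
                            exonLengthRange = c(120L, 180L),
                            intronLengthRange = c(420L, 900L),
                            windowWidth = 200L,
                            lambda1 = 0.25, lambda2 = 0.012,
                            lambdaPrePeak = 0.55, peakPos = 9L,
                            lambdaPeak = 0.80, lambdaPostPeak = 0.60,
                            farPos = 149L, lambdaFar = 0.50,
                            lambdaEnd = 0.12,
                            depthPlateau = 130, depthFloor = 18,
                            depthHalfLife = 55,
                            qcFailBase = 0.08, qcFailMidpoint = 55,
                            qcFailSlope = 16,
                            carrierProb = 0.06,
                            delBase = 0.008, delSpikePos = 5L,
                            delSpikeProb = 0.15,
                            exonicLambda = 0.25, exonicDepth = 150,
                            deepLambda = 0.02,
                            indelFraction = 0.10) {
  new("SyntheticConfig",
      seed = as.integer(seed), nSamples = as.integer(nSamples),
      nGenes = as.integer(nGenes),
      exonsPerGene = as.integer(exonsPerGene),
      exonLengthRange = as.integer(exonLengthRange),
      intronLengthRange = as.integer(intronLengthRange),
      windowWidth = as.integer(windowWidth),
      lambda1 = lambda1, lambda2 = lambda2,
      lambdaPrePeak = lambdaPrePeak, peakPos = as.integer(peakPos),
      lambdaPeak = lambdaPeak, lambdaPostPeak = lambdaPostPeak,
      farPos = as.integer(farPos), lambdaFar = lambdaFar,
      lambdaEnd = lambdaEnd,
      depthPlateau = depthPlateau, depthFloor = depthFloor,
      depthHalfLife = depthHalfLife,
      qcFailBase = qcFailBase, qcFailMidpoint = qcFailMidpoint,
      qcFailSlope = qcFailSlope,
      carrierProb = carrierProb,
      delBase = delBase, delSpikePos = as.integer(delSpikePos),
      delSpikeProb = delSpikeProb,
      exonicLambda = exonicLambda, exonicDepth = exonicDepth,
      deepLambda = deepLambda, indelFraction = indelFraction)
}

#' Designed per-base variant intensity lambda(d)
#' @param cfg a [SyntheticConfig-class].
#' @return numeric vector over d = 1..W.
#' @export
designedLambda <- function(cfg) {
  W <- cfg@windowWidth
  d <- seq_len(W)
  pk <- cfg@peakPos; fp <- cfg@farPos
  lam <- numeric(W)
  lam[1] <- cfg@lambda1
  if (W >= 2) lam[2] <- cfg@lambda2
  rise <- d > 2 & d < pk
  lam[rise] <- cfg@lambda2 +
    (d[rise] - 2) / (pk - 1 - 2) * (cfg@lambdaPrePeak - cfg@lambda2)
  if (W >= pk) lam[pk] <- cfg@lambdaPeak
  mid <- d > pk & d <= fp
  lam[mid] <- cfg@lambdaPostPeak +
    (d[mid] - (pk + 1)) / (fp - (pk + 1)) * (cfg@lambdaFar - cfg@lambdaPostPeak)
  tail <- d > fp
  lam[tail] <- cfg@lambdaFar +
    (d[tail] - fp) / (W - fp) * (cfg@lambdaEnd - cfg@lambdaFar)
  lam
}

#' Designed mean sequencing depth at flanking offset d
#' @param cfg a [SyntheticConfig-class].
#' @param d offset(s).
#' @export
designedDepth <- function(cfg, d) {
  cfg@depthFloor + (cfg@depthPlateau - cfg@depthFloor) * 2^(-d / cfg@depthHalfLife)
}

#' QC-failure probability as a logistic function of depth
#' @param cfg a [SyntheticConfig-class].
#' @param dp read depth(s).
#' @export
qcFailProb <- function(cfg, dp) {
  cfg@qcFailBase + (1 - cfg@qcFailBase) *
    stats::plogis((cfg@qcFailMidpoint - dp) / cfg@qcFailSlope)
}

#' Designed false proportion at flanking offset d
#' @param cfg a [SyntheticConfig-class].
#' @param d offset(s); default the full window.
#' @export
designedFp <- function(cfg, d = seq_len(cfg@windowWidth)) {
  qcFailProb(cfg, designedDepth(cfg, d))
}

.delProb <- function(cfg, d) {
  ifelse(d == cfg@delSpikePos, cfg@delSpikeProb, cfg@delBase)
}

# available flanking bases per bucket d, honouring nearer-boundary
# assignment in short introns (no base is double-counted)
.flankBases <- function(ann) {
  W <- windowWidth(ann)
  L <- width(introns(ann))
  if (!length(L)) return(rep(0L, W))
  ndon <- pmin(W, (L + 1L) %/% 2L)
  nacc <- pmin(W, L %/% 2L)
  vapply(seq_len(W), function(d) sum(ndon >= d) + sum(nacc >= d), integer(1))
}

#' Designed per-bucket truth table for a synthetic cohort
#'
#' The acceptance surface for parameter recovery: for each flanking offset
#' d, the number of available bases, the designed intensity and its
#' expected raw unique-variant count, the designed depth, the expected
#' false proportion, the expected pass count, and the deleterious
#' probability with its expected count.
#'
#' @param cfg a [SyntheticConfig-class].
#' @param ann the [GenomeAnnotation-class] from [generateAnnotation()].
#' @return data.frame, one row per d in 1..W.
#' @export
truthTable <- function(cfg, ann) {
  W <- cfg@windowWidth
  d <- seq_len(W)
  nb <- .flankBases(ann)
  lam <- designedLambda(cfg)
  dep <- designedDepth(cfg, d)
  fp <- qcFailProb(cfg, dep)
  pdel <- .delProb(cfg, d)
  data.frame(d = d, n_bases = nb, lambda = lam,
             expected_raw = lam * nb,
             depth = dep, expected_fp = fp,
             expected_pass = lam * nb * (1 - fp),
             del_prob = pdel,
             expected_deleterious = lam * nb * (1 - fp) * pdel)
}

#' Generate a synthetic gene annotation
#'
#' Lays out `nGenes` multi-exon transcripts (one transcript per gene,
#' alternating strands, several chromosomes) with exon and intron lengths
#' drawn from the configured ranges, writes the annotation as GFF3 when
#' `path` is given, and returns the in-memory [GenomeAnnotation-class].
#' Deterministic under `cfg@seed` (byte-identical files across runs).
#'
#' @param cfg a [SyntheticConfig-class].
#' @param path optional GFF3 output file.
#' @return a [GenomeAnnotation-class].
#' @export
generateAnnotation <- function(cfg, path = NULL) {
  validObject(cfg)
  set.seed(cfg@seed)
  nchrom <- max(1L, min(4L, cfg@nGenes %/% 10L))
  cursor <- rep(10000L, nchrom)
  rows <- vector("list", cfg@nGenes)
  draw_range <- function(rng, n) {
    v <- seq(rng[1], rng[2])
    v[sample.int(length(v), n, replace = TRUE)]
  }
  for (g in seq_len(cfg@nGenes)) {
    chrom <- ((g - 1L) %% nchrom) + 1L
    nex <- draw_range(cfg@exonsPerGene, 1L)
    el <- draw_range(cfg@exonLengthRange, nex)
    il <- if (nex > 1L) draw_range(cfg@intronLengthRange, nex - 1L)
          else integer()
    starts <- integer(nex); ends <- integer(nex)
    p <- cursor[chrom]
    for (i in seq_len(nex)) {
      starts[i] <- p
      ends[i] <- p + el[i] - 1L
      p <- ends[i] + (if (i < nex) il[i] else 0L) + 1L
    }
    cursor[chrom] <- ends[nex] + 5000L
    rows[[g]] <- data.frame(
      chrom = as.character(chrom), start = starts, end = ends,
      strand = if (g %% 2L == 0L) "-" else "+",
      transcript_id = sprintf("TX%04d", g),
      gene_id = sprintf("GENE%04d", g))
  }
  ex <- do.call(rbind, rows)
  ann <- .buildAnnotation(ex, cfg@windowWidth)
  if (!is.null(path)) .writeGff3(ann, path)
  ann
}

.writeGff3 <- function(ann, path) {
  ex <- exons(ann)
  dt <- data.table(chrom = as.character(seqnames(ex)),
                   start = start(ex), end = end(ex),
                   strand = as.character(strand(ex)),
                   tx = mcols(ex)$transcript_id,
                   gene = mcols(ex)$gene_id)
  setorder(dt, chrom, start, tx)
  lines <- c("##gff-version 3")
  for (txid in unique(dt$tx)) {
    sub <- dt[tx == txid]
    g <- sub$gene[1]
    lines <- c(lines,
      sprintf("%s\tsynthetic\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
              sub$chrom[1], min(sub$start), max(sub$end), sub$strand[1], g),
      sprintf("%s\tsynthetic\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
              sub$chrom[1], min(sub$start), max(sub$end), sub$strand[1],
              txid, g),
      sprintf("%s\tsynthetic\texon\t%d\t%d\t.\t%s\t.\tID=%s.e%d;Parent=%s",
              sub$chrom, sub$start, sub$end, sub$strand,
              txid, seq_len(nrow(sub)), txid))
  }
  writeLines(lines, path)
  invisible(path)
}

.BASES <- c("A", "C", "G", "T")

# draw ref/alt alleles; indels get a one-base insertion or deletion
.drawAlleles <- function(n, indelFraction) {
  ref <- sample(.BASES, n, replace = TRUE)
  shift <- sample(1:3, n, replace = TRUE)
  alt <- .BASES[(match(ref, .BASES) - 1L + shift) %% 4L + 1L]
  is_indel <- stats::runif(n) < indelFraction
  if (any(is_indel)) {
    extra <- sample(.BASES, sum(is_indel), replace = TRUE)
    ins <- stats::runif(sum(is_indel)) < 0.5
    idx <- which(is_indel)
    alt[idx[ins]] <- paste0(ref[idx[ins]], extra[ins])
    ref[idx[!ins]] <- paste0(ref[idx[!ins]], extra[!ins])
    # deletions: alt reverts to the anchor base
    alt[idx[!ins]] <- substr(ref[idx[!ins]], 1L, 1L)
  }
  list(ref = ref, alt = alt)
}

# per-variant annotation scores; `damaging` variants are drawn inside the
# deleterious cascade's acceptance region, others are guaranteed outside it
.drawScores <- function(damaging) {
  n <- length(damaging)
  af <- rep(NA_real_, n); clin <- rep(NA_character_, n)
  cadd <- rep(NA_real_, n); dpsi <- rep(NA_real_, n); dbsc <- rep(NA_real_, n)
  dmg <- which(damaging)
  if (length(dmg)) {
    nd <- length(dmg)
    af[dmg] <- stats::runif(nd, 0, 0.04)
    clin[dmg] <- sample(c(NA, "Uncertain_significance", "Likely_pathogenic",
                          "Pathogenic"), nd, replace = TRUE,
                        prob = c(0.5, 0.3, 0.15, 0.05))
    has_cadd <- stats::runif(nd) < 0.95
    has_dpsi <- stats::runif(nd) < 0.80
    has_dbsc <- stats::runif(nd) < 0.60
    none <- !(has_cadd | has_dpsi | has_dbsc)
    has_cadd[none] <- TRUE
    cadd[dmg[has_cadd]] <- stats::runif(sum(has_cadd), 10.5, 35)
    dpsi[dmg[has_dpsi]] <- stats::runif(sum(has_dpsi), 2, 4)
    dbsc[dmg[has_dbsc]] <- stats::runif(sum(has_dbsc), 0.65, 1)
  }
  ben <- which(!damaging)
  if (length(ben)) {
    nb <- length(ben)
    mode <- sample(c("score", "freq", "clinsig", "noscore"), nb,
                   replace = TRUE, prob = c(0.70, 0.15, 0.10, 0.05))
    af[ben] <- ifelse(mode == "freq", stats::runif(nb, 0.06, 0.5),
                      stats::runif(nb, 0, 0.04))
    sc <- mode %in% c("score", "freq", "clinsig")
    cadd[ben[sc & mode == "score"]] <-
      stats::runif(sum(sc & mode == "score"), 0, 9.9)
    cadd[ben[sc & mode != "score"]] <-
      stats::runif(sum(sc & mode != "score"), 0, 9.5)
    hd <- sc & stats::runif(nb) < 0.4
    dpsi[ben[hd]] <- stats::runif(sum(hd), -1, 1.8)
    clin[ben[mode == "clinsig"]] <-
      sample(c("Benign", "Likely_benign", "Benign/Likely_benign"),
             sum(mode == "clinsig"), replace = TRUE)
  }
  list(af_popmax = af, clinsig = clin, cadd = cadd, dpsi_zscore = dpsi,
       dbscsnv = dbsc)
}

#' Generate a synthetic multi-sample variant cohort
#'
#' Draws unique variants per flanking bucket d as Poisson counts with the
#' designed intensity lambda(d), plus exonic and deep-intronic variants;
#' assigns each unique variant to a random subset of samples; decides
#' pass/false at the variant level from the depth-driven QC-failure
#' logistic (false variants are given genuinely failing metrics, pass
#' variants nominal ones); draws annotation scores with the deleterious
#' spike at the configured position; and writes one VCF 4.2 per sample
#' plus the designed per-bucket truth table. Deterministic under
#' `cfg@seed`.
#'
#' @param cfg a [SyntheticConfig-class].
#' @param ann annotation from [generateAnnotation()].
#' @param dir output directory for the VCFs and `truth.tsv`.
#' @return invisibly, a list with `vcfs` (paths), `samples`, `truth`
#'   (designed per-bucket table) and `variants` (the realised per-variant
#'   generation record).
#' @export
generateCohort <- function(cfg, ann, dir) {
  validObject(cfg)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(cfg@seed + 1L)
  W <- cfg@windowWidth
  gi <- introns(ann)
  idf <- data.frame(chrom = as.character(seqnames(gi)),
                    s = start(gi), e = end(gi),
                    strand = as.character(strand(gi)),
                    L = width(gi))

  uv <- list()
  if (nrow(idf)) {
    lam <- designedLambda(cfg)
    ndon <- pmin(W, (idf$L + 1L) %/% 2L)
    nacc <- pmin(W, idf$L %/% 2L)
    for (d in seq_len(W)) {
      don_ok <- which(ndon >= d); acc_ok <- which(nacc >= d)
      cand_chrom <- c(idf$chrom[don_ok], idf$chrom[acc_ok])
      cand_pos <- c(
        ifelse(idf$strand[don_ok] == "-", idf$e[don_ok] - d + 1L,
               idf$s[don_ok] + d - 1L),
        ifelse(idf$strand[acc_ok] == "-", idf$s[acc_ok] + d - 1L,
               idf$e[acc_ok] - d + 1L))
      navail <- length(cand_pos)
      if (!navail) next
      cnt <- min(stats::rpois(1L, lam[d] * navail), navail)
      if (!cnt) next
      pick <- sample.int(navail, cnt)
      uv[[length(uv) + 1L]] <- data.frame(
        chrom = cand_chrom[pick], pos = cand_pos[pick],
        region = "intronic_flanking", d = d)
    }
  }

  ex <- exons(ann)
  if (length(ex)) {
    exlen <- width(ex)
    total <- sum(exlen)
    cnt <- min(stats::rpois(1L, cfg@exonicLambda * total), total)
    if (cnt) {
      off <- sort(sample.int(total, cnt))
      cum <- cumsum(exlen)
      exi <- findInterval(off - 1L, cum) + 1L
      within <- off - c(0L, cum)[exi] - 1L
      uv[[length(uv) + 1L]] <- data.frame(
        chrom = as.character(seqnames(ex))[exi],
        pos = start(ex)[exi] + within,
        region = "exonic", d = NA_integer_)
    }
  }

  deep <- idf[idf$L >= 2L * W + 1L, ]
  if (nrow(deep)) {
    blen <- deep$e - deep$s + 1L - 2L * W
    total <- sum(blen)
    cnt <- min(stats::rpois(1L, cfg@deepLambda * total), total)
    if (cnt) {
      off <- sort(sample.int(total, cnt))
      cum <- cumsum(blen)
      ii <- findInterval(off - 1L, cum) + 1L
      within <- off - c(0L, cum)[ii] - 1L
      uv[[length(uv) + 1L]] <- data.frame(
        chrom = deep$chrom[ii], pos = deep$s[ii] + W + within,
        region = "deep_intronic", d = NA_integer_)
    }
  }

  uvdf <- if (length(uv)) do.call(rbind, uv) else
    data.frame(chrom = character(), pos = integer(), region = character(),
               d = integer())
  n <- nrow(uvdf)
  samples <- sprintf("sample%02d", seq_len(cfg@nSamples))

  if (n) {
    al <- .drawAlleles(n, cfg@indelFraction)
    uvdf$ref <- al$ref; uvdf$alt <- al$alt
    mu <- ifelse(uvdf$region == "exonic", cfg@exonicDepth,
          ifelse(uvdf$region == "deep_intronic", cfg@depthFloor,
                 designedDepth(cfg, uvdf$d)))
    uvdf$mu_depth <- mu
    uvdf$is_false <- stats::runif(n) < qcFailProb(cfg, mu)
    uvdf$damaging <- uvdf$region == "intronic_flanking" & !uvdf$is_false &
      stats::runif(n) < .delProb(cfg, ifelse(is.na(uvdf$d), 0L, uvdf$d))
    sc <- .drawScores(uvdf$damaging)
    uvdf <- cbind(uvdf, as.data.frame(sc, stringsAsFactors = FALSE))
    ncar <- 1L + stats::rbinom(n, cfg@nSamples - 1L, cfg@carrierProb)
    carriers <- lapply(ncar, function(k) sort(sample.int(cfg@nSamples, k)))
    uvdf$n_carriers <- ncar

    # expand to per-observation records
    vi <- rep(seq_len(n), ncar)
    obs <- uvdf[vi, c("chrom", "pos", "ref", "alt", "region", "d",
                      "is_false", "af_popmax", "clinsig", "cadd",
                      "dpsi_zscore", "dbscsnv")]
    obs$sample <- samples[unlist(carriers)]
    m <- nrow(obs)
    dp <- pmax(1L, as.integer(round(stats::rnorm(m, uvdf$mu_depth[vi],
                                                 0.12 * uvdf$mu_depth[vi]))))
    QD <- stats::runif(m, 10, 35)
    FS <- stats::runif(m, 0, 40)
    MQ <- stats::runif(m, 50, 60)
    MQRS <- pmax(-4, pmin(4, stats::rnorm(m)))
    RPRS <- pmax(-4, pmin(4, stats::rnorm(m)))
    MQRS[stats::runif(m) < 0.10] <- NA  # hom-alt sites lack rank sums
    RPRS[stats::runif(m) < 0.10] <- NA
    dv <- integer(m)
    fls <- obs$is_false
    dp[!fls] <- pmax(dp[!fls], 20L)
    dv[!fls] <- pmin(dp[!fls], pmax(8L, stats::rbinom(sum(!fls), dp[!fls], 0.45)))
    if (any(fls)) {
      fi <- which(fls)
      lowdp <- dp[fi] < 20L
      dv[fi[lowdp]] <- pmin(dp[fi[lowdp]],
                            stats::rbinom(sum(lowdp), dp[fi[lowdp]], 0.45))
      hi <- fi[!lowdp]
      if (length(hi)) {
        lowdv <- stats::runif(length(hi)) < 0.7
        dv[hi[lowdv]] <- sample(0:7, sum(lowdv), replace = TRUE)
        qdbad <- hi[!lowdv]
        QD[qdbad] <- stats::runif(length(qdbad), 0, 1.9)
        dv[qdbad] <- pmin(dp[qdbad],
                          pmax(8L, stats::rbinom(length(qdbad), dp[qdbad], 0.45)))
      }
    }
    obs$DP <- dp; obs$DV <- dv; obs$QD <- QD; obs$FS <- FS; obs$MQ <- MQ
    obs$MQRankSum <- MQRS; obs$ReadPosRankSum <- RPRS
  } else {
    obs <- data.frame()
  }

  contigs <- .contigTable(ann)
  vcfs <- file.path(dir, paste0(samples, ".vcf"))
  for (si in seq_along(samples)) {
    sub <- if (nrow(obs)) obs[obs$sample == samples[si], , drop = FALSE]
           else obs
    .writeSyntheticVcf(sub, vcfs[si], samples[si], contigs)
  }

  truth <- truthTable(cfg, ann)
  utils::write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(list(vcfs = vcfs, samples = samples, truth = truth,
                 variants = uvdf))
}

.contigTable <- function(ann) {
  ex <- exons(ann)
  dt <- data.table(chrom = as.character(seqnames(ex)), end = end(ex))
  agg <- dt[, .(len = max(end) + 10000L), by = chrom]
  setorder(agg, chrom)
  agg
}

.fmtNum <- function(x, digits = 3) {
  ifelse(is.na(x), NA_character_,
         formatC(x, digits = digits, format = "g"))
}

.writeSyntheticVcf <- function(obs, path, sample_id, contigs) {
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", contigs$chrom, contigs$len),
    "##INFO=<ID=QD,Number=1,Type=Float,Description=\"Quality by depth\">",
    "##INFO=<ID=FS,Number=1,Type=Float,Description=\"Fisher strand bias (phred)\">",
    "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"RMS mapping quality\">",
    "##INFO=<ID=MQRankSum,Number=1,Type=Float,Description=\"Mapping quality rank sum z\">",
    "##INFO=<ID=ReadPosRankSum,Number=1,Type=Float,Description=\"Read position rank sum z\">",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Read depth at site\">",
    "##INFO=<ID=AF_POPMAX,Number=1,Type=Float,Description=\"Population max allele frequency\">",
    "##INFO=<ID=CLNSIG,Number=.,Type=String,Description=\"Clinical significance\">",
    "##INFO=<ID=CADD,Number=1,Type=Float,Description=\"CADD phred score\">",
    "##INFO=<ID=DPSI_Z,Number=1,Type=Float,Description=\"SPIDEX dpsi z-score\">",
    "##INFO=<ID=DBSCSNV,Number=1,Type=Float,Description=\"dbscSNV ensemble score (max)\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths (ref,alt)\">",
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
           sample_id)
  )
  if (!nrow(obs)) {
    writeLines(header, path)
    return(invisible(path))
  }
  o <- order(obs$chrom, obs$pos, obs$ref, obs$alt)
  obs <- obs[o, , drop = FALSE]
  kv <- function(key, val) ifelse(is.na(val), NA_character_,
                                  paste0(key, "=", val))
  parts <- cbind(
    kv("QD", .fmtNum(obs$QD)), kv("FS", .fmtNum(obs$FS)),
    kv("MQ", .fmtNum(obs$MQ)), kv("MQRankSum", .fmtNum(obs$MQRankSum)),
    kv("ReadPosRankSum", .fmtNum(obs$ReadPosRankSum)),
    kv("DP", obs$DP), kv("AF_POPMAX", .fmtNum(obs$af_popmax, 4)),
    kv("CLNSIG", obs$clinsig), kv("CADD", .fmtNum(obs$cadd)),
    kv("DPSI_Z", .fmtNum(obs$dpsi_zscore)),
    kv("DBSCSNV", .fmtNum(obs$dbscsnv, 4)))
  info <- apply(parts, 1L, function(row)
    paste(row[!is.na(row)], collapse = ";"))
  info[!nzchar(info)] <- "."
  fmt <- sprintf("0/1:%d,%d", obs$DP - obs$DV, obs$DV)
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\t.\t%s\tGT:AD\t%s",
                  obs$chrom, obs$pos, obs$ref, obs$alt, info, fmt)
  writeLines(c(header, body), path)
  invisible(path)
}
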