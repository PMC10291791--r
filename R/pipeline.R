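#' Assemble an effective run configuration
#'
#' Collects every tunable of the pipeline with its documented default —
#' thresholds default to the hard-filter and deleterious-cascade values the
#' pipeline is built around — and records, per entry, whether it is a
#' default or a user override, so the run log is a complete record of the
#' effective parameters.
#'
#' @param ... overrides for any of: `window_width`, `hard_filter`,
#'   `deleterious`, `field_map`, `pass_policy`, `score_policy`,
#'   `dpsi_absolute`, `qc_missing`, `alpha`, `seed`.
#' @return a named list with a `source` attribute.
#' @export
runConfig <- function(...) {
  defaults <- list(
    window_width = 200L,
    hard_filter = hardFilterThresholds(),
    deleterious = deleteriousThresholds(),
    field_map = defaultFieldMap(),
    pass_policy = "any_pass",
    score_policy = "present",
    dpsi_absolute = FALSE,
    qc_missing = "pass",
    alpha = 0.05,
    seed = 1L
  )
  reference_default <- c("window_width", "hard_filter", "deleterious")
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, over)
  src <- ifelse(names(cfg) %in% names(over), "user-override",
                ifelse(names(cfg) %in% reference_default, "reference-default",
                       "package-default"))
  names(src) <- names(cfg)
  attr(cfg, "source") <- src
  cfg
}

#' Load a run configuration from a YAML file
#'
#' File values override the built-in defaults; `...` overrides (e.g. from
#' command-line flags) win over the file.
#'
#' @param path YAML file, or NULL for defaults only.
#' @param ... explicit overrides, as in [runConfig()].
#' @export
loadRunConfig <- function(path = NULL, ...) {
  file_over <- if (!is.null(path)) yaml::read_yaml(path) else list()
  over <- utils::modifyList(file_over, list(...))
  do.call(runConfig, over)
}

.flatten <- function(x, prefix = "") {
  out <- character()
  for (nm in names(x)) {
    key <- if (nzchar(prefix)) paste0(prefix, ".", nm) else nm
    v <- x[[nm]]
    if (is.list(v)) out <- c(out, .flatten(v, key))
    else out <- c(out, paste0(key, " = ", paste(v, collapse = ",")))
  }
  out
}

.writeRunLog <- function(path, config, stages) {
  src <- attr(config, "source")
  lines <- c("# effective configuration")
  for (nm in names(config)) {
    lines <- c(lines, paste0("config ", .flatten(config[nm]),
                             " [", src[nm], "]"))
  }
  lines <- c(lines, "# stages")
  lines <- c(lines, vapply(stages, identity, character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Simulate a synthetic dataset directory
#'
#' Writes the GFF3 annotation, one VCF per sample and the per-bucket truth
#' table under `outdir`. Deterministic under the configuration seed.
#'
#' @param cfg a [SyntheticConfig-class] (see [syntheticConfig()]).
#' @param outdir output directory.
#' @return invisibly, a list of paths plus the generated objects.
#' @export
cmdSimulate <- function(cfg, outdir) {
  validObject(cfg)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  gff <- file.path(outdir, "annotation.gff3")
  ann <- generateAnnotation(cfg, path = gff)
  res <- generateCohort(cfg, ann, outdir)
  invisible(c(list(annotation = gff, ann = ann), res))
}

#' Run the profiling stage: VCFs to per-position tables
#'
#' Reads the cohort, applies the hard filter, deduplicates across samples,
#' builds the per-position profile, and writes the four profile tables,
#' the partition totals and a run log listing every effective threshold
#' with its source and per-stage record counts.
#'
#' @param vcfs VCF paths (one per sample).
#' @param annotation a [GenomeAnnotation-class] or an annotation file path.
#' @param config from [runConfig()].
#' @param outdir output directory.
#' @return invisibly, a list with the profile, variant sets, annotation
#'   and written file paths.
#' @export
cmdProfile <- function(vcfs, annotation, config = runConfig(), outdir) {
  if (length(vcfs) < 1L) stop("need at least one VCF")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  ann <- if (is(annotation, "GenomeAnnotation")) annotation
         else loadAnnotation(annotation, windowWidth = config$window_width)
  stages <- character()
  log1 <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    message(line)
    stages <<- c(stages, line)
  }
  vs <- readVcfCohort(vcfs, fieldMap = config$field_map)
  log1("stage=read_vcf n_files=%d n_records=%d", length(vcfs),
       nrow(variantRecords(vs)))
  if (nrow(variantRecords(vs)) == 0L)
    warning("no variant records in input; emitting all-zero tables")
  uvs <- dedupUnique(vs, policy = config$pass_policy,
                     thresholds = config$hard_filter,
                     missing = config$qc_missing)
  uv <- uniqueVariants(uvs)
  log1("stage=dedup n_unique=%d n_pass=%d n_false=%d", nrow(uv),
       sum(uv$any_pass), sum(!uv$any_pass))
  profile <- buildProfile(uvs, ann, delThresholds = config$deleterious,
                          delScores = config$score_policy,
                          dpsiAbsolute = config$dpsi_absolute)
  tot <- profileTotals(profile)
  log1("stage=profile flanking_raw=%d flanking_pass=%d flanking_deleterious=%d",
       tot$intronic_flanking$raw, tot$intronic_flanking$pass,
       tot$intronic_flanking$deleterious)
  log1("stage=partitions exonic_raw=%d intronic_raw=%d intergenic_raw=%d",
       tot$exonic$raw, tot$intronic$raw, tot$intergenic$raw)
  files <- writeProfileTables(profile, outdir)
  log <- .writeRunLog(file.path(outdir, "run_log.txt"), config, stages)
  invisible(list(profile = profile, vs = vs, uvs = uvs, ann = ann,
                 files = c(files, log)))
}

#' Run the statistics stage: positional tests and the flanking-vs-exonic
#' comparison
#'
#' Computes pairwise paired t-test matrices on per-sample raw, pass and
#' deleterious counts, the pairwise Fisher's exact matrix on per-position
#' FP, and the flanking-versus-exonic FP comparison (paired t plus pooled
#' Fisher), and writes the five artifacts as long-format TSVs with
#' significance masks at `config$alpha` and 0.01.
#'
#' @param profiled output of [cmdProfile()].
#' @param config from [runConfig()].
#' @param outdir output directory.
#' @param buckets bucket subset for the pairwise matrices (default all).
#' @return invisibly, the computed objects and file paths.
#' @export
cmdStats <- function(profiled, config = runConfig(), outdir, buckets = NULL) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  vs <- profiled$vs; uvs <- profiled$uvs
  ann <- profiled$ann; profile <- profiled$profile
  alpha <- c(config$alpha, 0.01)
  multi <- length(sampleIds(vs)) >= 2L

  m_raw <- sampleCountMatrix(vs, ann, "raw", config$hard_filter,
                             config$qc_missing)
  m_pass <- sampleCountMatrix(vs, ann, "pass", config$hard_filter,
                              config$qc_missing)
  m_del <- .deleteriousCountMatrix(vs, uvs, ann, config)

  out <- list()
  paths <- character()
  wp <- function(pm, name) {
    p <- writePairwiseTable(pm, file.path(outdir, name), alpha)
    paths <<- c(paths, p)
  }
  if (multi) {
    out$raw_ttest <- pairwiseMatrix(m_raw, "t_test", buckets)
    out$pass_ttest <- pairwiseMatrix(m_pass, "t_test", buckets)
    out$deleterious_ttest <- pairwiseMatrix(m_del, "t_test", buckets)
    wp(out$raw_ttest, "pairwise_raw_ttest.tsv")
    wp(out$pass_ttest, "pairwise_pass_ttest.tsv")
    wp(out$deleterious_ttest, "pairwise_deleterious_ttest.tsv")
  } else {
    warning("single-sample cohort: t-test matrices reported as missing")
  }
  out$fp_fisher <- pairwiseMatrix(profile, "fisher_exact", buckets)
  wp(out$fp_fisher, "pairwise_fp_fisher.tsv")

  fl <- perSampleFp(vs, ann, "intronic_flanking", config$hard_filter,
                    config$qc_missing)
  exn <- perSampleFp(vs, ann, "exonic", config$hard_filter,
                     config$qc_missing)
  fve <- if (multi)
    flankingVsExonicFpTest(fl$fp, exn$fp, fl$pooled, exn$pooled)
  else list(p_t = NA_real_,
            p_fisher = stats::fisher.test(rbind(fl$pooled, exn$pooled))$p.value,
            delta_fp = mean(fl$fp, na.rm = TRUE) - mean(exn$fp, na.rm = TRUE))
  fve_path <- file.path(outdir, "flanking_vs_exonic_fp.tsv")
  utils::write.table(
    data.frame(comparison = "flanking_vs_exonic_fp", p_t = fve$p_t,
               p_fisher = fve$p_fisher, delta_fp = fve$delta_fp),
    fve_path, sep = "\t", quote = FALSE, row.names = FALSE)
  out$flanking_vs_exonic <- fve
  invisible(c(out, list(files = c(paths, fve_path))))
}

# per-sample counts of records whose unique variant passes the
# deleterious cascade
.deleteriousCountMatrix <- function(vs, uvs, ann, config) {
  df <- variantRecords(vs)
  samples <- sampleIds(vs)
  W <- windowWidth(ann)
  m <- matrix(0L, nrow = length(samples), ncol = W,
              dimnames = list(samples, as.character(seq_len(W))))
  uv <- uniqueVariants(uvs)
  if (!nrow(df) || !nrow(uv)) return(m)
  del <- deleteriousFilter(uvs, thresholds = config$deleterious,
                           scores = config$score_policy,
                           dpsiAbsolute = config$dpsi_absolute)
  key <- function(x) paste(x$chrom, x$pos, x$ref, x$alt, sep = ":")
  delkeys <- key(uv)[del]
  keep <- key(df) %in% delkeys
  if (!any(keep)) return(m)
  asn <- classifyPosition(df$chrom[keep], df$pos[keep], ann)
  fl <- asn$region == "intronic_flanking"
  if (!any(fl)) return(m)
  tt <- table(factor(df$sample_id[keep][fl], levels = samples),
              factor(asn$d[fl], levels = seq_len(W)))
  m[] <- as.integer(tt)
  m
}

#' Run simulate + profile + stats as one report
#'
#' @param cfg a [SyntheticConfig-class].
#' @param outdir output directory (`data/`, `profile/`, `stats/` inside).
#' @param config pipeline configuration from [runConfig()].
#' @param buckets forwarded to [cmdStats()].
#' @return invisibly, the combined result list.
#' @export
cmdReport <- function(cfg, outdir, config = runConfig(), buckets = NULL) {
  sim <- cmdSimulate(cfg, file.path(outdir, "data"))
  prof <- cmdProfile(sim$vcfs, sim$ann, config, file.path(outdir, "profile"))
  st <- cmdStats(prof, config, file.path(outdir, "stats"), buckets)
  invisible(list(sim = sim, profile = prof, stats = st))
}
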