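# File-based pipeline driver: each stage reads and writes plain-text
# artifacts (bins BED, triplet matrices, bedGraph score tracks, TSV results)
# with no hidden state between stages, so runs are resumable and
# reproducible; every output carries the package version and a config hash.

#' Read a key=value run configuration file
#'
#' One `key = value` pair per line; `#` comments and blank lines are ignored.
#'
#' @param path configuration file.
#' @return named list of character values.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_config("config file not found: ", path)
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  kv <- regmatches(lines, regexec("^([^=]+)=(.*)$", lines))
  bad <- vapply(kv, length, 0L) != 3L
  if (any(bad)) stop_config("malformed config line: ", lines[bad][1L])
  stats::setNames(lapply(kv, function(x) trimws(x[3L])),
                  vapply(kv, function(x) trimws(x[2L]), ""))
}

config_hash <- function(cfg) {
  # hash the analysis parameters only: file locations (and the output
  # directory) may differ between reruns of the same analysis
  paths <- c("outdir", "bins", "design", "gc_fasta", "gc_bedgraph", "genes",
             "genes_bedgraph", "interactions")
  cfg <- cfg[setdiff(names(cfg), paths)]
  s <- paste(sort(paste0(names(cfg), "=",
                         vapply(cfg, function(x) paste(x, collapse = ","), ""))),
             collapse = ";")
  h <- 17
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

output_header <- function(cfg)
  sprintf(" hicomp v%s config_hash=%s",
          as.character(utils::packageVersion("hicomp")), config_hash(cfg))

write_tsv_artifact <- function(df, path, cfg) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", output_header(cfg)), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

cfg_num <- function(cfg, key, default) {
  if (is.null(cfg[[key]])) default else as.numeric(cfg[[key]])
}
cfg_chr <- function(cfg, key, default = NULL) cfg[[key]] %||% default
cfg_flag <- function(cfg, key, default = FALSE) {
  v <- cfg[[key]]
  if (is.null(v)) default else tolower(v) %in% c("1", "true", "yes", "on")
}

cfg_md_config <- function(cfg) {
  md_config(df = if (!is.null(cfg$df)) as.integer(cfg$df) else NULL,
            outlier_quantile = cfg_num(cfg, "outlier_quantile", 0.90),
            fdr_threshold = cfg_num(cfg, "fdr_threshold", 0.10),
            weighting = cfg_chr(cfg, "weighting", "distant"),
            seed = as.integer(cfg_num(cfg, "seed", 1)),
            ihw_nbins = as.integer(cfg_num(cfg, "ihw_nbins", 5)),
            ihw_nfolds = as.integer(cfg_num(cfg, "ihw_nfolds", 5)))
}

read_design <- function(cfg) {
  path <- cfg$design %||% stop_config("config needs `design`")
  if (!file.exists(path)) stop_config("design file not found: ", path)
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  if (!all(c("file", "sample", "replicate") %in% names(d)))
    stop_format("design needs columns file, sample, replicate")
  abs <- file.exists(d$file)
  d$file[!abs] <- file.path(dirname(path), d$file[!abs])
  d
}

design_covariates <- function(cfg, bins) {
  gc <- if (!is.null(cfg$gc_bedgraph)) read_scores_bedgraph(cfg$gc_bedgraph, bins)
        else if (!is.null(cfg$gc_fasta)) gc_track(cfg$gc_fasta, bins)
        else stop_config("config needs gc_fasta or gc_bedgraph")
  genes <- if (!is.null(cfg$genes_bedgraph))
             read_scores_bedgraph(cfg$genes_bedgraph, bins)
           else if (!is.null(cfg$genes)) gene_density_track(cfg$genes, bins)
           else stop_config("config needs genes or genes_bedgraph")
  list(gc = gc, genes = genes)
}

score_column_path <- function(outdir, sample, replicate)
  file.path(outdir, sprintf("%s_%s.pc.bedgraph", sample, replicate))

write_runlog <- function(cfg, stage, extra = list()) {
  log <- c(list(stage = stage,
                version = as.character(utils::packageVersion("hicomp")),
                config_hash = config_hash(cfg),
                parameters = cfg), extra)
  jsonlite::write_json(log, file.path(cfg$outdir, paste0("runlog_", stage, ".json")),
                       auto_unbox = TRUE, pretty = TRUE)
}

stage_simulate <- function(cfg) {
  spec <- simulation_spec(
    n_bins = cfg_num(cfg, "sim_n_bins", 2000),
    resolution = cfg_num(cfg, "sim_resolution", 1e5),
    decay_exponent = cfg_num(cfg, "sim_decay_exponent", 1),
    affinity = cfg_num(cfg, "sim_affinity", 1),
    depth = cfg_num(cfg, "sim_depth", 5e6),
    n_conditions = cfg_num(cfg, "sim_n_conditions", 2),
    n_replicates = cfg_num(cfg, "sim_n_replicates", 2),
    flip_fraction = cfg_num(cfg, "sim_flip_fraction", 0),
    shift_fraction = cfg_num(cfg, "sim_shift_fraction", 0),
    shift_factor = cfg_num(cfg, "sim_shift_factor", 0.5),
    seed = as.integer(cfg_num(cfg, "seed", 1)))
  sim <- simulate_experiment(spec, cfg$outdir)
  write_runlog(cfg, "simulate")
  sim$files
}

stage_scores <- function(cfg) {
  bins <- read_bins(cfg$bins %||% stop_config("config needs `bins`"))
  design <- read_design(cfg)
  missing <- design$file[!file.exists(design$file)]
  if (length(missing)) stop_config("input file not found: ", missing[1L])
  cov <- design_covariates(cfg, bins)
  k <- as.integer(cfg_num(cfg, "k", 2))
  mcf <- cfg_num(cfg, "min_coverage_frac", 0.01)
  audits <- NULL
  for (i in seq_len(nrow(design))) {
    score <- rep(NA_real_, nrow(bins))
    for (ch in unique(bins$chrom)) {
      rows <- which(bins$chrom == ch)
      map <- read_contact_matrix(design$file[i], bins, chrom = ch,
                                 sample = design$sample[i],
                                 replicate = design$replicate[i])
      cs <- compartment_scores(map, cov$gc[rows], cov$genes[rows], k = k,
                               min_coverage_frac = mcf)
      score[rows] <- cs$score
      if (!is.null(cs$correlations))
        audits <- rbind(audits, data.frame(
          sample = design$sample[i], replicate = design$replicate[i],
          chrom = ch, pc = rownames(cs$correlations),
          selected = seq_len(nrow(cs$correlations)) == cs$component,
          cor_gc = cs$correlations[, "gc"],
          cor_gene_density = cs$correlations[, "gene_density"],
          row.names = NULL))
    }
    write_scores_bedgraph(bins, score,
                          score_column_path(cfg$outdir, design$sample[i],
                                            design$replicate[i]),
                          header = output_header(cfg))
  }
  write_tsv_artifact(audits, file.path(cfg$outdir, "pc_covariate_audit.tsv"), cfg)
  write_runlog(cfg, "scores")
  invisible(NULL)
}

load_score_columns <- function(cfg) {
  bins <- read_bins(cfg$bins %||% stop_config("config needs `bins`"))
  design <- read_design(cfg)
  paths <- if (cfg_flag(cfg, "precomputed")) design$file
           else score_column_path(cfg$outdir, design$sample, design$replicate)
  missing <- paths[!file.exists(paths)]
  if (length(missing)) stop_config("score track not found: ", missing[1L])
  load_precomputed_scores(paths, bins, design$sample, design$replicate)
}

stage_normalize <- function(cfg) {
  sm <- load_score_columns(cfg)
  qn <- quantile_normalize(sm)
  for (j in seq_along(qn$sample))
    write_scores_bedgraph(qn$bins, qn$scores[, j],
                          file.path(cfg$outdir,
                                    sprintf("%s_%s.qn.bedgraph", qn$sample[j],
                                            qn$replicate[j])),
                          header = output_header(cfg))
  avg <- average_replicates(qn)
  for (j in seq_along(avg$sample))
    write_scores_bedgraph(avg$bins, avg$scores[, j],
                          file.path(cfg$outdir,
                                    sprintf("%s.avg.bedgraph", avg$sample[j])),
                          header = output_header(cfg))
  write_runlog(cfg, "normalize")
  invisible(NULL)
}

stage_diff <- function(cfg) {
  sm <- load_score_columns(cfg)
  fit <- diff_compartments(sm, cfg_md_config(cfg))
  write_tsv_artifact(fit$results, file.path(cfg$outdir, "differential.tsv"), cfg)
  sig <- significant_bins(fit)
  write_tsv_artifact(sig[, c("chrom", "start", "end", "padj", "label")],
                     file.path(cfg$outdir, "differential_significant.bed"), cfg)
  write_runlog(cfg, "diff",
               list(n_tested = nrow(fit$results), n_significant = nrow(sig)))
  fit
}

stage_interactions <- function(cfg) {
  if (is.null(cfg$interactions)) stop_config("config needs `interactions`")
  bins <- read_bins(cfg$bins)
  design <- read_design(cfg)
  paths <- strsplit(cfg$interactions, ",")[[1L]]
  records <- read_interactions(paths, bins)
  sig_path <- file.path(cfg$outdir, "differential_significant.bed")
  if (!file.exists(sig_path))
    stop_config("run the diff stage first: missing ", sig_path)
  sig <- utils::read.table(sig_path, header = TRUE, sep = "\t",
                           comment.char = "#", stringsAsFactors = FALSE)
  out <- NULL
  mdcfg <- cfg_md_config(cfg)
  for (ch in unique(records$chrom)) {
    maps <- lapply(seq_len(nrow(design)), function(i)
      read_contact_matrix(design$file[i], bins, chrom = ch,
                          sample = design$sample[i],
                          replicate = design$replicate[i]))
    di <- diff_interactions(maps, records[records$chrom == ch, , drop = FALSE],
                            sig[sig$chrom == ch, , drop = FALSE], bins, mdcfg)
    out <- rbind(out, di)
  }
  write_tsv_artifact(out, file.path(cfg$outdir, "interactions_diff.tsv"), cfg)
  write_runlog(cfg, "interactions", list(n_tested = nrow(out)))
  out
}

#' Run a pipeline stage
#'
#' Orchestrates the package as file-based stages: `simulate` writes a
#' synthetic dataset; `scores` computes per-replicate compartment-score
#' bedGraphs from contact matrices; `normalize` writes quantile-normalized
#' and replicate-averaged tracks; `diff` fits the differential-compartment
#' model and writes the result TSV plus a BED of significant bins;
#' `interactions` tests differential interactions; `all` chains the stages.
#' Inputs are validated before any computation starts.
#'
#' @param subcommand one of `"simulate"`, `"scores"`, `"normalize"`,
#'   `"diff"`, `"interactions"`, `"all"`.
#' @param config named list of configuration values or the path of a
#'   `key = value` file (see [read_run_config()]). Common keys: `outdir`,
#'   `bins`, `design`, `gc_fasta`/`gc_bedgraph`, `genes`/`genes_bedgraph`,
#'   `seed`, `fdr_threshold`, `weighting`, `k`, `precomputed`,
#'   `interactions`, and `sim_*` generator settings.
#' @return the main artifact of the final stage (invisibly for file-only
#'   stages); a `compartment_diff` fit for `diff`/`all`.
#' @export
run <- function(subcommand = c("simulate", "scores", "normalize", "diff",
                               "interactions", "all"),
                config = list()) {
  subcommand <- match.arg(subcommand)
  cfg <- if (is.character(config)) read_run_config(config) else config
  if (is.null(cfg$outdir)) stop_config("config needs `outdir`")
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  for (key in c("bins", "design", "gc_fasta", "gc_bedgraph", "genes",
                "genes_bedgraph"))
    if (!is.null(cfg[[key]]) && !file.exists(cfg[[key]]))
      stop_config("configured file not found: ", key, " = ", cfg[[key]])
  switch(subcommand,
    simulate = invisible(stage_simulate(cfg)),
    scores = invisible(stage_scores(cfg)),
    normalize = invisible(stage_normalize(cfg)),
    diff = stage_diff(cfg),
    interactions = stage_interactions(cfg),
    all = {
      if (cfg_flag(cfg, "simulate") || !is.null(cfg$sim_flip_fraction) ||
          is.null(cfg$design)) {
        files <- stage_simulate(cfg)
        cfg$bins <- cfg$bins %||% files$bins
        cfg$design <- cfg$design %||% files$design
        cfg$gc_bedgraph <- cfg$gc_bedgraph %||% files$gc
        cfg$genes_bedgraph <- cfg$genes_bedgraph %||% files$genes
      }
      if (!cfg_flag(cfg, "precomputed")) stage_scores(cfg)
      stage_normalize(cfg)
      fit <- stage_diff(cfg)
      if (!is.null(cfg$interactions)) stage_interactions(cfg)
      fit
    })
}

#' Annotate significant bins with overlapping genes
#'
#' For every significant bin, lists the comma-joined names of the genes whose
#' bodies overlap it by at least 1 bp (`"."` when none).
#'
#' @param significant data frame with `chrom`, `start`, `end`, or the path of
#'   a BED/TSV file of significant bins.
#' @param genes gene annotation (BED or GTF/GFF path).
#' @param path optional output TSV.
#' @return data frame `chrom`, `start`, `end`, `genes`.
#' @export
annotate_genes <- function(significant, genes, path = NULL) {
  if (is.character(significant))
    significant <- utils::read.table(significant, header = TRUE, sep = "\t",
                                     comment.char = "#",
                                     stringsAsFactors = FALSE)
  gr <- read_gene_ranges(genes)
  labels <- gene_labels(gr)
  target <- GenomicRanges::GRanges(
    significant$chrom,
    IRanges::IRanges(start = significant$start + 1L, end = significant$end))
  hits <- GenomicRanges::findOverlaps(target, gr, minoverlap = 1L)
  joined <- rep(".", length(target))
  if (length(hits)) {
    agg <- tapply(labels[S4Vectors::subjectHits(hits)],
                  S4Vectors::queryHits(hits),
                  function(x) paste(unique(x), collapse = ","))
    joined[as.integer(names(agg))] <- agg
  }
  out <- data.frame(chrom = significant$chrom, start = significant$start,
                    end = significant$end, genes = joined,
                    stringsAsFactors = FALSE)
  if (!is.null(path))
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  out
}
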