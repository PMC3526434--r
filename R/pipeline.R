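#' Default run configuration
#'
#' @param genotypes path to a genotype TSV, or a [genotype_matrix()].
#' @param map path to a chromosome-map TSV, or a [chromosome_map()].
#' @param reference optional path to a reference-partition TSV
#'   (sample_id, label), or a named vector.
#' @param subset optional path to a sample-subset file (one id per
#'   line), or a character vector of ids.
#' @param method `"ensemble"` or `"solo"`.
#' @param chromosomes `"all"`, a chromosome id vector (solo method), or
#'   an integer n meaning the n longest chromosomes.
#' @param n_iterations ensemble iterations N (default 25).
#' @param grain_size,peak_distance,threshold detector parameters, see
#'   [dsr_params()].
#' @param k number of clusters (default 10).
#' @param alpha2 precision/recall weight for the F-index.
#' @param seed master seed; per-iteration seeds are derived by a
#'   counter scheme so changing N never reshuffles earlier iterations.
#' @param out_dir output directory for run artifacts.
#' @return a `run_config` list.
#' @export
run_config <- function(genotypes, map, reference = NULL, subset = NULL,
                       method = c("ensemble", "solo"), chromosomes = "all",
                       n_iterations = 25L, grain_size = 1L,
                       peak_distance = 2L, threshold = 5L, k = 10L,
                       alpha2 = 1.0, seed = 1L, out_dir = tempfile("run")) {
  method <- match.arg(method)
  if (method == "ensemble" && n_iterations < 1L)
    stop("ensemble method requires N >= 1", call. = FALSE)
  if (method == "solo" && is.null(chromosomes))
    stop("solo method requires a chromosome selection", call. = FALSE)
  structure(list(genotypes = genotypes, map = map, reference = reference,
                 subset = subset, method = method, chromosomes = chromosomes,
                 n_iterations = as.integer(n_iterations),
                 grain_size = as.integer(grain_size),
                 peak_distance = as.integer(peak_distance),
                 threshold = as.integer(threshold), k = as.integer(k),
                 alpha2 = alpha2, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "run_config")
}

#' Read a YAML run configuration
#' @param path path to a YAML file with [run_config()] fields.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(run_config, y)
}

iteration_seed <- function(master, i) {
  as.integer((as.numeric(master) + 7919 * i) %% .Machine$integer.max)
}

#' Run the full classification pipeline
#'
#' Imputes the panel, stages chromosomes (N randomized ensemble layouts
#' or solo per-chromosome), runs recombination detection, subARG
#' construction, age estimation and pairwise distances per staged
#' input, consolidates the distance matrices, and summarizes the result
#' as a neighbor-joining tree, a k-cluster partition and a 2-d MDS
#' embedding. If a reference partition is supplied, the labeled
#' contingency table and precision/recall/F metrics are written too.
#' Re-running with the same config reproduces all artifacts
#' bit-identically.
#'
#' @param cfg a [run_config()].
#' @return the output directory path, invisibly; artifacts include
#'   `consolidated.phy`, `tree.nwk`, `partition.tsv`, `mds.tsv`,
#'   `metrics.json` (with a reference), `convergence.json` and
#'   `manifest.json`.
#' @export
run_pipeline <- function(cfg) {
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  g <- if (is.character(cfg$genotypes)) read_genotypes(cfg$genotypes)
       else cfg$genotypes
  map <- if (is.character(cfg$map)) read_chromosome_map(cfg$map) else cfg$map
  ref <- cfg$reference
  if (is.character(ref) && length(ref) == 1L) ref <- read_partition(ref)
  if (!is.null(cfg$subset)) {
    ids <- if (is.character(cfg$subset) && length(cfg$subset) == 1L &&
               file.exists(cfg$subset)) readLines(cfg$subset) else cfg$subset
    g <- subset_samples(g, ids)
    if (!is.null(ref)) ref <- ref[ids]
  }
  stage_wrap <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", stage, conditionMessage(e)), call. = FALSE))
  }
  params <- dsr_params(cfg$grain_size, cfg$peak_distance, cfg$threshold)
  g_imp <- stage_wrap("impute", impute_missing(g, map, seed = cfg$seed))
  summ <- summarize_panel(g_imp, map)
  jsonlite::write_json(list(n_samples = nrow(g_imp), n_loci = ncol(g_imp),
                            distinct_alleles = unname(summ$distinct_alleles),
                            loci_per_chromosome =
                              as.list(summ$loci_per_chromosome),
                            missing_fraction_input = mean(g == MISSING)),
                       file.path(cfg$out_dir, "panel_summary.json"),
                       auto_unbox = TRUE, digits = NA)

  one_distance <- function(staged) {
    r <- stage_wrap("detect", detect_recombinations(staged, params))
    a <- stage_wrap("build", build_subarg(staged, r))
    a <- stage_wrap("ages", estimate_ages(a))
    stage_wrap("distances", pairwise_distances(a))
  }
  seeds <- integer(0L)
  if (cfg$method == "ensemble") {
    ds <- lapply(seq_len(cfg$n_iterations), function(i) {
      si <- iteration_seed(cfg$seed, i)
      seeds[i] <<- si
      layout <- build_ensemble(map, seed = si)
      one_distance(stage_ensemble(g_imp, layout))
    })
  } else {
    chroms <- cfg$chromosomes
    if (is.numeric(chroms)) chroms <- longest_chromosomes(map, chroms)
    staged <- stage_solo(g_imp, map, chroms)
    ds <- lapply(staged, one_distance)
  }
  cons <- stage_wrap("consolidate", average_distances(ds))
  write_dist_phylip(cons$mean, file.path(cfg$out_dir, "consolidated.phy"))
  if (length(ds) >= 2L) {
    curve <- convergence_curve(ds)
    jsonlite::write_json(curve, file.path(cfg$out_dir, "convergence.json"),
                         digits = NA)
  }
  tr <- stage_wrap("tree", nnj_tree(cons$mean))
  ape::write.tree(tr, file.path(cfg$out_dir, "tree.nwk"))
  part <- stage_wrap("partition", cut_to_k(tr, cons$mean, cfg$k))
  write_partition(part, file.path(cfg$out_dir, "partition.tsv"))
  emb <- stage_wrap("mds", mds_embed(cons$mean, 2L))
  utils::write.table(data.frame(sample_id = rownames(emb$points),
                                mds1 = emb$points[, 1L],
                                mds2 = emb$points[, 2L]),
                     file.path(cfg$out_dir, "mds.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(ref)) {
    tab <- stage_wrap("evaluate", contingency(ref, part))
    labeled <- if (nrow(tab) == ncol(tab)) assign_labels(tab) else tab
    fx <- f_index(labeled, cfg$alpha2)
    write_contingency(labeled, file.path(cfg$out_dir, "contingency.csv"))
    per_cluster <- if (nrow(labeled) == ncol(labeled)) {
      list(labels = rownames(labeled),
           precision = diag(fx$precision),
           recall = diag(fx$recall))
    } else NULL
    jsonlite::write_json(list(F = fx$F, alpha2 = cfg$alpha2,
                              n = fx$n, k = cfg$k,
                              per_cluster = per_cluster),
                         file.path(cfg$out_dir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  files <- sort(setdiff(list.files(cfg$out_dir), "manifest.json"))
  manifest <- list(
    package_version = as.character(utils::packageVersion("argstr")),
    method = cfg$method, n_iterations = cfg$n_iterations,
    k = cfg$k, alpha2 = cfg$alpha2, seed = cfg$seed,
    iteration_seeds = seeds,
    params = list(grain_size = cfg$grain_size,
                  peak_distance = cfg$peak_distance,
                  threshold = cfg$threshold),
    files = as.list(stats::setNames(
      unname(tools::md5sum(file.path(cfg$out_dir, files))), files)))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(cfg$out_dir)
}

#' Human-readable summary of a completed run
#'
#' @param run_dir a [run_pipeline()] output directory.
#' @return the markdown summary, invisibly; also written to
#'   `report.md` in the run directory.
#' @export
report_run <- function(run_dir) {
  need <- function(f) {
    p <- file.path(run_dir, f)
    if (!file.exists(p)) stop(sprintf("missing artifact: %s", f),
                              call. = FALSE)
    p
  }
  manifest <- jsonlite::read_json(need("manifest.json"),
                                  simplifyVector = TRUE)
  panel <- jsonlite::read_json(need("panel_summary.json"),
                               simplifyVector = TRUE)
  need("consolidated.phy")
  tr <- ape::read.tree(need("tree.nwk"))
  part <- read_partition(need("partition.tsv"))
  lines <- c(
    "# Classification run summary", "",
    sprintf("- method: %s (N = %d iterations), k = %d clusters",
            manifest$method, manifest$n_iterations, manifest$k),
    sprintf("- seed: %d", manifest$seed),
    sprintf("- panel: %d samples x %d loci; %.2f%% missing on input",
            panel$n_samples, panel$n_loci,
            100 * panel$missing_fraction_input),
    sprintf("- distinct alleles per locus: %d-%d",
            min(panel$distinct_alleles), max(panel$distinct_alleles)),
    sprintf("- tree: %d leaves, %d internal edges",
            length(tr$tip.label), length(tree_internal_edges(tr))),
    sprintf("- partition: %d clusters, sizes %s",
            length(unique(part)),
            paste(sort(table(part), decreasing = TRUE), collapse = ", ")))
  conv_path <- file.path(run_dir, "convergence.json")
  if (file.exists(conv_path)) {
    curve <- jsonlite::read_json(conv_path, simplifyVector = TRUE)
    lines <- c(lines, sprintf(
      "- consolidation change at N = %d: %.4g (vs %.4g at N = 2)",
      max(curve$n), curve$change[which.max(curve$n)], curve$change[1L]))
  }
  metrics_path <- file.path(run_dir, "metrics.json")
  if (file.exists(metrics_path)) {
    mx <- jsonlite::read_json(metrics_path, simplifyVector = TRUE)
    lines <- c(lines, "", "## Agreement with the reference", "",
               sprintf("- overall F-index (alpha^2 = %g): %.4f",
                       mx$alpha2, mx$F))
    if (!is.null(mx$per_cluster)) {
      lines <- c(lines, "", "| cluster | precision | recall |",
                 "|---|---|---|",
                 sprintf("| %s | %.2f | %.2f |", mx$per_cluster$labels,
                         round_half_up(mx$per_cluster$precision),
                         round_half_up(mx$per_cluster$recall)))
    }
  }
  text <- paste(lines, collapse = "\n")
  writeLines(text, file.path(run_dir, "report.md"))
  invisible(text)
}
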