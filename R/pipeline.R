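#' Validate a pipeline run configuration
#'
#' The configuration (a list, or the path of a YAML file) names the input
#' files and thresholds of a full scoring run. Required: \code{matrix},
#' \code{design}. Optional: \code{annotation} (needed when consensus is
#' enabled), \code{tf_list} and \code{categories} (GMT paths), stage
#' toggles \code{quantile} (default TRUE), \code{combat} (FALSE,
#' "nonparametric" or "parametric"), \code{consensus} (auto: on when an
#' annotation is given), \code{tfnet} (on when a TF list is given), and
#' thresholds \code{fc} (1.5), \code{q} (0.05), \code{baseline} (6),
#' \code{min_count} (tied to the class presets, default 3),
#' \code{edge_quantile} (0.001), \code{mi_k} (9), \code{seed} (1).
#'
#' @param config List or YAML path.
#' @return Normalized config list with defaults filled in.
#' @export
validate_run_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a list or a YAML file path")
  defaults <- list(quantile = TRUE, combat = FALSE, fc = 1.5, q = 0.05,
                   baseline = 6, min_count = 3, edge_quantile = 0.001,
                   mi_k = 9, seed = 1,
                   consensus = NULL, tfnet = NULL)
  for (nm in names(defaults)) {
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  }
  for (nm in c("matrix", "design")) {
    if (is.null(config[[nm]])) stop("config must name a '", nm, "' file")
  }
  if (is.null(config$consensus)) config$consensus <- !is.null(config$annotation)
  if (is.null(config$tfnet)) config$tfnet <- !is.null(config$tf_list)
  if (isTRUE(config$consensus) && is.null(config$annotation)) {
    stop("consensus stage enabled but no annotation file configured")
  }
  if (isTRUE(config$tfnet) && is.null(config$tf_list)) {
    stop("tfnet stage enabled but no tf_list GMT configured")
  }
  for (f in c("matrix", "design", "annotation", "tf_list", "categories")) {
    if (!is.null(config[[f]]) && !file.exists(config[[f]])) {
      stop("configured ", f, " file does not exist: ", config[[f]])
    }
  }
  if (config$fc < 1 || config$q <= 0 || config$q > 1 ||
      config$edge_quantile <= 0 || config$edge_quantile > 1 || config$mi_k < 1) {
    stop("threshold out of range in config")
  }
  config
}

#' Run the full scoring pipeline
#'
#' Executes preprocess (quantile normalization, optional batch correction),
#' differential expression (developmental contrast plus one toxicant
#' contrast per compound/concentration), index computation, and, when
#' configured, gene-level consensus and the TF co-expression network.
#' Per-stage outputs are written as TSV/JSON under \code{out_dir} together
#' with a machine-readable manifest (inputs with md5 hashes, thresholds,
#' seed, stage list). A rerun with the same config reproduces all outputs.
#'
#' @param config Run configuration (list or YAML path); see
#'   \code{\link{validate_run_config}}.
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config, out_dir) {
  config <- validate_run_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)

  fail <- function(stage, e) {
    writeLines(paste0("FAILED at stage: ", stage, "\n", conditionMessage(e)),
               file.path(out_dir, "FAILED"))
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  }

  m <- tryCatch({
    mat <- read_expression_matrix(config$matrix)
    design <- read_sample_design(config$design)
    validate_sample_design(design, mat)
    if (isTRUE(config$quantile)) mat <- quantile_normalize(mat)
    if (!isFALSE(config$combat)) {
      mode <- if (isTRUE(config$combat)) "nonparametric" else config$combat
      mat <- combat_correct(mat, design, mode = mode)
    }
    list(mat = mat, design = design)
  }, error = function(e) fail("preprocess", e))
  mat <- m$mat; design <- m$design
  write_expression_matrix(mat, file.path(out_dir, "normalized_matrix.tsv"))

  dge <- tryCatch({
    day0 <- design$sample_id[design$role == "day0_control"]
    diffc <- design$sample_id[design$role == "diff_control"]
    d_deg <- differential_expression(mat, day0, diffc,
                                     fc_threshold = config$fc,
                                     q_threshold = config$q)
    treated <- design[design$role == "treated", , drop = FALSE]
    contrasts <- unique(treated[, c("compound", "concentration")])
    t_degs <- list()
    for (i in seq_len(nrow(contrasts))) {
      sel <- treated$compound == contrasts$compound[i] &
        treated$concentration == contrasts$concentration[i]
      key <- paste0(contrasts$compound[i], "@", contrasts$concentration[i])
      t_degs[[key]] <- differential_expression(
        mat, diffc, treated$sample_id[sel],
        fc_threshold = config$fc, q_threshold = config$q)
    }
    list(d_deg = d_deg, t_degs = t_degs)
  }, error = function(e) fail("dge", e))
  write_report(dge$d_deg, file.path(out_dir, "deg_developmental.tsv"), "tsv")

  idx <- tryCatch({
    d <- call_regulons(dge$d_deg, label = "D-genes")
    rows <- lapply(names(dge$t_degs), function(key) {
      t <- call_regulons(dge$t_degs[[key]], label = paste("T-genes", key))
      r <- developmental_indices(d, t, N = nrow(mat))
      data.frame(contrast = key, D = r$D, T = r$T, O = r$O, N = r$N,
                 Dp = r$Dp, Di = r$Di, o_over_t = r$o_over_t,
                 fisher_p = r$fisher_p,
                 antagonistic_fraction = r$antagonistic_fraction,
                 stringsAsFactors = FALSE)
    })
    list(d = d, table = do.call(rbind, rows))
  }, error = function(e) fail("indices", e))
  write_report(idx$table, file.path(out_dir, "indices.tsv"), "tsv")

  results <- list(matrix = mat, design = design, dge = dge, indices = idx$table)

  if (isTRUE(config$consensus)) {
    cons <- tryCatch({
      ann <- read_probe_annotation(config$annotation)
      per_compound <- lapply(dge$t_degs, collapse_to_genes, annotation = ann)
      consensus_genes(per_compound,
                      min_count = min(config$min_count, length(per_compound)))
    }, error = function(e) fail("consensus", e))
    write_report(cons, file.path(out_dir, "consensus.tsv"), "tsv")
    results$consensus <- cons
  }

  if (isTRUE(config$tfnet)) {
    net <- tryCatch({
      tfs <- read_gmt(config$tf_list, namespace = "symbol")
      ann <- read_probe_annotation(config$annotation)
      # collapse probes to genes and average expression per TF symbol
      sym_mat <- collapse_matrix_to_genes(mat, ann, unique(unlist(tfs)))
      mi <- knn_mutual_information(sym_mat, k = config$mi_k)
      sc <- clr_scores(mi)
      nw <- build_network(sc, tfs, edge_quantile = config$edge_quantile)
      comm <- detect_communities(nw)
      list(network = nw, communities = comm)
    }, error = function(e) fail("tfnet", e))
    write_report(net$network$edges, file.path(out_dir, "tf_edges.tsv"), "tsv")
    results$tfnet <- net
  }

  manifest <- list(
    package = "stoptox",
    version = as.character(utils::packageVersion("stoptox")),
    seed = config$seed,
    thresholds = config[c("fc", "q", "baseline", "min_count",
                          "edge_quantile", "mi_k")],
    stages = c("preprocess", "dge", "indices",
               if (isTRUE(config$consensus)) "consensus",
               if (isTRUE(config$tfnet)) "tfnet"),
    inputs = lapply(
      Filter(Negate(is.null),
             config[c("matrix", "design", "annotation", "tf_list", "categories")]),
      function(p) list(path = p, md5 = unname(tools::md5sum(p)))))
  write_report(manifest, file.path(out_dir, "manifest.json"), "json")
  results$manifest <- manifest
  invisible(results)
}

#' Average probe rows into gene-symbol rows
#'
#' @param matrix Probe-level expression matrix.
#' @param annotation Probe-to-symbol table.
#' @param symbols Optional subset of symbols to keep.
#' @return Gene x sample matrix (mean over the probes mapping to a symbol).
#' @export
collapse_matrix_to_genes <- function(matrix, annotation, symbols = NULL) {
  ann <- annotation[annotation$probe_id %in% rownames(matrix), , drop = FALSE]
  if (!is.null(symbols)) ann <- ann[ann$symbol %in% symbols, , drop = FALSE]
  if (!nrow(ann)) stop("annotation covers no probe of the matrix")
  sub <- matrix[ann$probe_id, , drop = FALSE]
  out <- rowsum(sub, group = ann$symbol) /
    as.vector(table(ann$symbol)[sort(unique(ann$symbol))])
  out[sort(unique(ann$symbol)), , drop = FALSE]
}
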