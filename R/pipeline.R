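#' Assemble a run configuration
#'
#' A configuration names either on-disk inputs (`activity_file`,
#' `connectome_file`, `annotation_file`, delimited text) or a `synthetic`
#' block of generator parameters — never both. Convention switches and
#' seeds are recorded in the output manifest so every run is reproducible.
#'
#' @param activity_file,connectome_file,annotation_file Paths to
#'   delimited-text inputs (activity: nodes x time; connectome: square
#'   weight matrix; annotations: TSV).
#' @param synthetic Named list of generator parameters: `n_nodes`,
#'   `n_time`, `density`, `length_scale`, `alpha`, `baseline`,
#'   `timescale`, `n_networks`, `seed`.
#' @param n_perm Number of spin permutations for group-level tests.
#' @param out_dir Output directory (created); `NULL` keeps results in
#'   memory only.
#' @return List of class `"run_config"`.
#' @export
run_config <- function(activity_file = NULL, connectome_file = NULL,
                       annotation_file = NULL, synthetic = NULL,
                       n_perm = 1000, out_dir = NULL) {
  has_files <- !is.null(activity_file)
  if (has_files == !is.null(synthetic))
    stop2("supply exactly one of input files or a synthetic block")
  if (has_files && (is.null(connectome_file) || is.null(annotation_file)))
    stop2("file-based config needs activity, connectome and annotation paths")
  structure(list(activity_file = activity_file,
                 connectome_file = connectome_file,
                 annotation_file = annotation_file,
                 synthetic = synthetic, n_perm = n_perm,
                 out_dir = out_dir,
                 conventions = list(zscore_divisor = "T (population sd)",
                                    temporal_sd_divisor = "n-1 (sample sd)",
                                    percentile = "linear interpolation (type 7)",
                                    spin_tails = "two")),
            class = "run_config")
}

load_subject_inputs <- function(config, subject_id) {
  if (!is.null(config$synthetic)) {
    p <- config$synthetic
    # per-subject seed offset keeps subjects independent but reproducible
    seed_s <- p$seed + subject_id
    geometry <- gen_geometry(p$n_nodes, seed = p$seed)
    sc <- gen_connectome(geometry, p$density, p$length_scale, seed = seed_s)
    act <- gen_activity(sc, geometry, p$n_time, p$alpha, p$baseline,
                        p$timescale, seed = seed_s + 10000L)
    annotation <- gen_annotations(geometry, p$n_networks, seed = p$seed)
    list(activity = act$activity, sc = sc, geometry = geometry,
         annotation = annotation, ground_truth = act$ground_truth,
         seed = seed_s)
  } else {
    activity <- read_matrix_file(config$activity_file)
    sc <- read_matrix_file(config$connectome_file)
    annotation <- utils::read.delim(config$annotation_file)
    geometry <- annotation[, intersect(c("node_id", "hemisphere", "x", "y",
                                         "z", "sx", "sy", "sz"),
                                       names(annotation))]
    list(activity = activity, sc = sc, geometry = geometry,
         annotation = annotation, ground_truth = NULL, seed = NA)
  }
}

#' Run the full coupling analysis for one subject
#'
#' Pre-flight validates all inputs, then executes the per-subject chain:
#' z-score activity, build the co-fluctuation tensor, build structural
#' predictors, fit dynamic and static coupling, and compute temporal
#' summary statistics. When the configuration has an output directory,
#' all artifacts are written as delimited text plus a JSON manifest.
#'
#' @param config A `run_config`.
#' @param subject_id Integer subject identifier (also offsets synthetic
#'   seeds so subjects differ).
#' @return List of class `"subject_result"`: `coupling` (node x time
#'   adjusted R2), `static`, `cv`, `dvs` (dynamic-vs-static data frame),
#'   `fc`, `sc`, `predictors`, `geometry`, `annotation`, `ground_truth`,
#'   `n_degenerate`, `subject_id`.
#' @export
run_subject <- function(config, subject_id = 1L) {
  if (!inherits(config, "run_config")) stop2("config must be a run_config")
  inp <- load_subject_inputs(config, subject_id)
  # pre-flight: fail before any computation or output
  check_activity(inp$activity)
  check_connectome(inp$sc)
  if (nrow(inp$activity) != nrow(inp$sc) ||
      nrow(inp$sc) != nrow(inp$annotation))
    stop2("activity (", nrow(inp$activity), "), connectome (",
          nrow(inp$sc), ") and annotations (", nrow(inp$annotation),
          ") disagree on node count")
  if (!is_connected_graph(inp$sc))
    stop2("structural connectome is not connected")

  z <- zscore_activity(inp$activity)
  ets <- edge_time_series(z)
  fc <- static_fc(inp$activity)
  predictors <- build_predictors(inp$geometry, inp$sc)
  coupling <- dynamic_coupling(predictors, ets)
  static <- static_coupling(predictors, fc)
  cv <- coefficient_of_variation(coupling)
  dvs <- dynamic_vs_static(coupling, static)

  res <- structure(list(coupling = coupling, static = static, cv = cv,
                        dvs = dvs, fc = fc, sc = inp$sc,
                        predictors = predictors, geometry = inp$geometry,
                        annotation = inp$annotation,
                        ground_truth = inp$ground_truth,
                        n_degenerate = attr(coupling, "n_degenerate"),
                        subject_id = subject_id, seed = inp$seed),
                   class = "subject_result")
  if (!is.null(config$out_dir)) write_subject_result(res, config)
  res
}

#' Aggregate subject results into group-level maps and statistics
#'
#' Averages coupling and cv maps across subjects (the group cv map is the
#' mean of per-subject cv maps, not the cv of pooled series), computes
#' inter-node coupling similarity, annotation-scheme summaries of the
#' group cv map, a spin test of the cv map against the gradient, and
#' robust correlations of the cv map with network-embedding metrics
#' (structural degree and strength, mean connection distance, functional
#' strength, betweenness on -log lengths, weighted clustering).
#'
#' @param config A `run_config`.
#' @param subjects List of `subject_result` objects (aligned node sets).
#' @return List of class `"group_result"`.
#' @export
run_group <- function(config, subjects) {
  if (!length(subjects)) stop2("need at least one completed subject")
  nn <- vapply(subjects, function(s) nrow(s$coupling), integer(1))
  if (length(unique(nn)) != 1)
    stop2("subjects have inconsistent node sets: ",
          paste(unique(nn), collapse = ", "))
  mean_coupling <- Reduce(`+`, lapply(subjects, function(s) {
    m <- s$coupling; m[is.na(m)] <- 0; m
  })) / length(subjects)
  cv_map <- rowMeans(do.call(cbind, lapply(subjects, `[[`, "cv")),
                     na.rm = TRUE)
  mean_static <- rowMeans(do.call(cbind, lapply(subjects, `[[`, "static")))
  similarity <- coupling_similarity(lapply(subjects, `[[`, "coupling"))
  ref <- subjects[[1]]
  summaries <- list(
    network = annotate_summary(cv_map, ref$annotation, "network"),
    class = annotate_summary(cv_map, ref$annotation, "class"),
    gradient_bins = annotate_summary(cv_map, ref$annotation, "gradient_bins",
                                     n_bins = min(10, length(cv_map) %/% 2))
  )
  spins <- generate_spins(ref$geometry, config$n_perm,
                          seed = spin_seed(config))
  spin_gradient <- spin_pvalue(cv_map, ref$annotation$gradient, spins)
  metrics <- embedding_metrics(ref$sc, ref$predictors$dist, ref$fc)
  robust <- lapply(metrics, function(m)
    list(biweight = biweight_midcorrelation(cv_map, m)$estimate,
         pbend = percentage_bend_correlation(cv_map, m)$estimate,
         pearson = stats::cor(cv_map, m)))
  contrast_sc <- group_similarity_contrast(similarity, ref$sc)
  contrast_net <- group_similarity_contrast(similarity,
                                            ref$annotation$network)
  structure(list(mean_coupling = mean_coupling, cv_map = cv_map,
                 mean_static = mean_static, similarity = similarity,
                 summaries = summaries, spin_gradient = spin_gradient,
                 robust = robust, contrast_connected = contrast_sc,
                 contrast_network = contrast_net,
                 n_subjects = length(subjects)),
            class = "group_result")
}

spin_seed <- function(config) {
  if (!is.null(config$synthetic)) config$synthetic$seed + 777L else 777L
}

# Node-level embedding metrics used to contextualize the cv map.
embedding_metrics <- function(sc, dist, fc) {
  sc_norm <- minmax_normalize(sc)
  lengths <- weight_to_length(sc_norm)
  adj <- !is.na(lengths) & row(lengths) != col(lengths)
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           diag = FALSE)
  el <- igraph::as_edgelist(g, names = FALSE)
  gw <- igraph::graph_from_adjacency_matrix(sc_norm, mode = "undirected",
                                            weighted = TRUE, diag = FALSE)
  list(
    degree = rowSums(sc > 0),
    strength = rowSums(sc),
    mean_edge_length = connectivity_distance(sc, dist),
    functional_strength = rowSums(fc) - diag(fc),
    # zero-length edges (unit weight) floored so Dijkstra weights stay > 0
    betweenness = igraph::betweenness(g, weights = pmax(lengths[el], 1e-6)),
    clustering = replace_na(igraph::transitivity(gw, type = "weighted"), 0)
  )
}

replace_na <- function(x, value) { x[is.na(x)] <- value; x }

#' @export
print.subject_result <- function(x, ...) {
  cat("Subject", x$subject_id, "coupling:", nrow(x$coupling), "nodes x",
      ncol(x$coupling), "frames;", x$n_degenerate, "degenerate frames\n")
  cat("  mean dynamic R2:", format(mean(x$coupling, na.rm = TRUE),
                                   digits = 4),
      " mean static R2:", format(mean(x$static), digits = 4), "\n")
  invisible(x)
}

#' @export
print.group_result <- function(x, ...) {
  cat("Group result over", x$n_subjects, "subjects;",
      length(x$cv_map), "nodes\n")
  cat("  mean cv(R2):", format(mean(x$cv_map), digits = 4),
      " spin p (cv vs gradient):", format(x$spin_gradient$p, digits = 4),
      "\n")
  invisible(x)
}

# ---- delimited-text I/O -------------------------------------------------

#' Read a delimited numeric matrix
#'
#' Whitespace- or tab-delimited text, one matrix row per line, optional
#' header row.
#' @param path File path.
#' @param header Logical; whether the first line names columns.
#' @return Numeric matrix.
#' @export
read_matrix_file <- function(path, header = FALSE) {
  m <- as.matrix(utils::read.table(path, header = header))
  dimnames(m) <- NULL
  m
}

#' Write a numeric matrix as tab-delimited text
#' @param m Matrix. @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_matrix_file <- function(m, path) {
  utils::write.table(m, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

write_subject_result <- function(res, config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stem <- file.path(config$out_dir, sprintf("subject-%03d", res$subject_id))
  write_matrix_file(res$coupling, paste0(stem, "_coupling.tsv"))
  per_node <- data.frame(node_id = seq_along(res$static),
                         static = res$static, cv = res$cv,
                         prob_greater = res$dvs$prob_greater,
                         bias = res$dvs$bias, variance = res$dvs$variance)
  utils::write.table(per_node, paste0(stem, "_node_stats.tsv"), sep = "\t",
                     row.names = FALSE)
  manifest <- list(subject_id = res$subject_id, seed = res$seed,
                   n_nodes = nrow(res$coupling),
                   n_time = ncol(res$coupling),
                   n_degenerate = res$n_degenerate,
                   conventions = config$conventions,
                   synthetic = config$synthetic,
                   package_version = as.character(
                     utils::packageVersion("dynsfc")))
  jsonlite::write_json(manifest, paste0(stem, "_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(stem)
}
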