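# End-to-end pipeline: obtain a network (file or generator), run the
# permutation tests and the envelope, lay the network out, and write a
# reproducible set of outputs.

#' Pipeline configuration
#'
#' Exactly one of `input` (a `.net` or delimited edge-list path) or
#' `generator` (a [generator_config()], or a list of its arguments) must be
#' given.
#'
#' @param input optional path to a network file.
#' @param generator optional generator configuration.
#' @param out_dir output directory (created if needed).
#' @param tests character subset of `c("degree_distribution",
#'   "disease_down", "concordance", "curve_envelope")`.
#' @param n_replicates replicates B for every null ensemble (default 1000).
#' @param level envelope confidence level (default 0.999).
#' @param min_genes_per_degree curve filter (default 3).
#' @param threshold mostly-down threshold (default 0.5).
#' @param layout_dims 2, 3, or both (default `c(2, 3)`).
#' @param layout_iterations FR iterations (default 500).
#' @param seed root seed; child streams are derived per stage so adding a
#'   stage does not perturb the others.
#' @param plot if `TRUE`, also write a curve-vs-envelope plot (PDF).
#' @return A list of class `run_config`.
#' @export
run_config <- function(input = NULL, generator = NULL, out_dir,
                       tests = c("degree_distribution", "disease_down",
                                 "concordance", "curve_envelope"),
                       n_replicates = 1000, level = 0.999,
                       min_genes_per_degree = 3, threshold = 0.5,
                       layout_dims = c(2, 3), layout_iterations = 500,
                       seed = 1L, plot = FALSE) {
  if (is.null(input) == is.null(generator))
    stop("exactly one of `input` or `generator` must be given", call. = FALSE)
  if (!is.null(generator) && !inherits(generator, "generator_config"))
    generator <- do.call(generator_config, generator)
  tests <- match.arg(tests, several.ok = TRUE)
  stopifnot(all(layout_dims %in% c(2, 3)), n_replicates >= 1)
  structure(list(input = input, generator = generator, out_dir = out_dir,
                 tests = tests, n_replicates = n_replicates, level = level,
                 min_genes_per_degree = min_genes_per_degree,
                 threshold = threshold, layout_dims = layout_dims,
                 layout_iterations = layout_iterations,
                 seed = as.integer(seed), plot = isTRUE(plot)),
            class = "run_config")
}

# Fixed per-stage child-stream offsets (documented: adding a stage must not
# perturb existing ones, so each stage owns a disjoint replicate range).
PIPELINE_STREAMS <- c(degree_distribution = 1e6, disease_down = 2e6,
                      concordance = 3e6, curve_envelope = 4e6,
                      layout2 = 5e6, layout3 = 6e6)

#' Run the full analysis pipeline
#'
#' Reads or generates the network, runs the requested permutation tests and
#' the curve envelope, computes the FR layouts, and writes: the network
#' (`network.net` + `.clu`, `edge_list.csv`), a results table
#' (`results.csv`), a JSON report (`report.json`: statistics, p-values,
#' envelope, discordant genes, config echo, seed, package version), layout
#' exports (`layout_2d.net` / `layout_3d.net` and csv), and optionally a
#' curve plot. A second run with the same config reproduces all non-image
#' outputs byte-identically.
#'
#' @param cfg a [run_config()].
#' @return The report, invisibly (a list).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  net <- if (!is.null(cfg$input)) {
    if (!file.exists(cfg$input))
      stop("input file not found: ", cfg$input, call. = FALSE)
    if (grepl("\\.net$", cfg$input, ignore.case = TRUE))
      read_pajek(cfg$input)
    else read_edge_list(cfg$input)
  } else generate_network(cfg$generator)

  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- cfg$seed
  report <- list(
    package = "dgnet", version = as.character(packageVersion("dgnet")),
    seed = seed,
    config = cfg[setdiff(names(cfg), c("generator", "out_dir"))],
    generator = if (!is.null(cfg$generator)) unclass(cfg$generator),
    network = list(n_diseases = length(net$diseases),
                   n_genes = length(net$genes), n_edges = n_edges(net)),
    tests = list(), errors = list())

  run_one <- function(name, fn) {
    tryCatch(fn(), error = function(e) {
      message("test '", name, "' failed: ", conditionMessage(e))
      report$errors[[name]] <<- conditionMessage(e)
      NULL
    })
  }

  rows <- list()
  if ("degree_distribution" %in% cfg$tests) {
    t <- run_one("degree_distribution", function()
      degree_distribution_test(net, cfg$n_replicates,
                               seed = child_seed(seed, PIPELINE_STREAMS[["degree_distribution"]])))
    if (!is.null(t)) {
      report$tests$degree_distribution <-
        list(statistic = unname(t$statistic), p_value = t$p.value)
      rows$degree_distribution <-
        data.frame(test = "degree_distribution", statistic = unname(t$statistic),
                   p_value = t$p.value)
    }
  }
  if ("disease_down" %in% cfg$tests) {
    t <- run_one("disease_down", function()
      suppressMessages(disease_down_test(net, cfg$n_replicates,
                                         threshold = cfg$threshold,
                                         seed = child_seed(seed, PIPELINE_STREAMS[["disease_down"]]))))
    if (!is.null(t)) {
      report$tests$disease_down <-
        list(statistic = unname(t$statistic), p_value = t$p.value,
             threshold = cfg$threshold)
      rows$disease_down <-
        data.frame(test = "disease_down", statistic = unname(t$statistic),
                   p_value = t$p.value)
    }
  }
  if ("concordance" %in% cfg$tests) {
    t <- run_one("concordance", function()
      concordance_test(net, cfg$n_replicates,
                       seed = child_seed(seed, PIPELINE_STREAMS[["concordance"]])))
    if (!is.null(t)) {
      report$tests$concordance <-
        list(statistic = unname(t$statistic), p_value = t$p.value)
      rows$concordance <-
        data.frame(test = "concordance", statistic = unname(t$statistic),
                   p_value = t$p.value)
    }
  }
  env <- NULL
  if ("curve_envelope" %in% cfg$tests) {
    env <- run_one("curve_envelope", function()
      withCallingHandlers(
        curve_envelope(net, cfg$n_replicates, cfg$level,
                       cfg$min_genes_per_degree,
                       seed = child_seed(seed, PIPELINE_STREAMS[["curve_envelope"]])),
        dgnet_envelope_B = function(w) invokeRestart("muffleWarning")))
    if (!is.null(env)) {
      report$tests$curve_envelope <- list(
        level = env$level, scheme = env$scheme,
        envelope = env$envelope,
        excluded = env$curve$excluded)
      write.table(env$envelope, file.path(cfg$out_dir, "curve_envelope.csv"),
                  sep = ",", row.names = FALSE, quote = FALSE)
    }
  }
  disc <- discordant_high_degree_genes(net)
  report$discordant_high_degree_genes <- disc

  # outputs
  write_pajek(net, file.path(cfg$out_dir, "network.net"))
  write_edge_list(net, file.path(cfg$out_dir, "edge_list.csv"))
  if (length(rows) > 0)
    write.table(do.call(rbind, rows), file.path(cfg$out_dir, "results.csv"),
                sep = ",", row.names = FALSE, quote = FALSE)

  for (d in cfg$layout_dims) {
    lay <- fr_layout(net, dims = d, iterations = cfg$layout_iterations,
                     seed = child_seed(seed, PIPELINE_STREAMS[[paste0("layout", d)]]))
    export_layout(net, lay, file.path(cfg$out_dir, sprintf("layout_%dd.net", d)),
                  "pajek_net")
    export_layout(net, lay, file.path(cfg$out_dir, sprintf("layout_%dd.csv", d)),
                  "csv")
  }

  if (cfg$plot && !is.null(env)) {
    grDevices::pdf(file.path(cfg$out_dir, "curve_envelope.pdf"), 6, 5)
    plot(env)
    grDevices::dev.off()
  }

  jsonlite::write_json(report, file.path(cfg$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null", force = TRUE)
  invisible(report)
}
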