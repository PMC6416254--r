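#' Run the full morphotype-delineation pipeline
#'
#' Orchestrates every stage in order: load (or synthesize) the measurement
#' table, prune collinear variables, build the dendrogram, report
#' diagnostics for the candidate group counts, cut at the chosen `k`, check
#' and refine the grouping by CVA reclassification, summarise the groups,
#' match them to the reference morphotypes, and attach the squamation map.
#' All randomness (synthetic data only) flows from the single `seed`; the
#' analysis stages themselves are deterministic, so identical configs give
#' identical reports.
#'
#' @param config a list (or path to a YAML file) with elements:
#'   \describe{
#'     \item{input}{CSV path of a measurement table, or `NULL` to use the
#'       default synthetic spec.}
#'     \item{schema}{optional column mapping for [read_measurement_table()].}
#'     \item{threshold}{correlation cutoff for variable pruning (default 0.90).}
#'     \item{priority}{variable preference order for pruning.}
#'     \item{ks}{candidate group counts to diagnose (default `c(7, 8, 9)`).}
#'     \item{k}{the chosen group count (required; default 8).}
#'     \item{max_rounds}{CVA refinement rounds (default 1).}
#'     \item{ridge}{ridge coefficient for the CVA fit (default 0).}
#'     \item{label_noise}{synthetic-only label noise fraction (default 0).}
#'     \item{seed}{seed for synthetic generation (default 1).}
#'   }
#' @return object of class `pipeline_result` with elements `config`,
#'   `table`, `selection`, `dendrogram`, `k_diagnostics`, `partition`,
#'   `refinement` (classification history and accuracies), `summary`,
#'   `matching`, `squamation`, `timings`.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- list(input = NULL, schema = NULL, threshold = 0.90,
                   priority = c("L6", "L5", "L1", "L3", "L4", "L2", "L7", "L8"),
                   ks = c(7, 8, 9), k = 8, max_rounds = 1, ridge = 0,
                   label_noise = 0, seed = 1)
  config <- utils::modifyList(defaults, config)
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e) {
      stop_scalemorph("stage", "stage '%s' failed: %s", name,
                      conditionMessage(e))
    })
    list(value = out, elapsed = proc.time()[["elapsed"]] - t0)
  }
  timings <- list()

  s <- stage("load", {
    if (!is.null(config$input)) {
      list(table = read_measurement_table(config$input, config$schema),
           truth = NULL)
    } else {
      spec <- default_reference_spec(label_noise = config$label_noise)
      gen <- generate_measurements(spec, seed = config$seed)
      list(table = gen$table, truth = gen)
    }
  })
  timings$load <- s$elapsed
  tab <- s$value$table; truth <- s$value$truth

  s <- stage("select_variables",
             select_variables(tab, threshold = config$threshold,
                              priority = config$priority))
  timings$select_variables <- s$elapsed
  selection <- s$value
  vars <- selection$kept

  s <- stage("cluster", agglomerate(tab, vars))
  timings$cluster <- s$elapsed
  dend <- s$value

  s <- stage("compare_k", {
    ks <- unique(c(config$ks, config$k))
    parts <- lapply(ks, function(k) cut_k(dend, k))
    names(parts) <- as.character(ks)
    X <- as.matrix(tab$data[vars])
    dEuc <- stats::dist(X)
    diag_df <- do.call(rbind, lapply(seq_along(ks), function(ii) {
      p <- parts[[ii]]
      sil <- if (p$k > 1 && p$k < nrow(X))
        mean(cluster::silhouette(p$labels, dEuc)[, "sil_width"]) else NA_real_
      data.frame(k = ks[ii],
                 sizes = paste(sort(tabulate(p$labels, p$k),
                                    decreasing = TRUE), collapse = "/"),
                 mean_silhouette = sil)
    }))
    list(diagnostics = diag_df, partitions = parts)
  })
  timings$compare_k <- s$elapsed
  kdiag <- s$value
  part <- kdiag$partitions[[as.character(config$k)]]

  s <- stage("cva_refine",
             refine_labels(tab, part, max_rounds = config$max_rounds,
                           variables = vars, ridge = config$ridge))
  timings$cva_refine <- s$elapsed
  refinement <- s$value

  s <- stage("summarize", summarize_groups(tab, refinement$partition))
  timings$summarize <- s$elapsed
  summary <- s$value

  s <- stage("match", match_to_reference(summary))
  timings$match <- s$elapsed
  matching <- s$value

  structure(list(
    config = config,
    table = tab,
    truth = if (!is.null(truth))
      list(labels = truth$labels, morphotypes = truth$morphotypes),
    selection = selection,
    dendrogram = dend,
    k_diagnostics = kdiag$diagnostics,
    partition = part,
    refinement = list(
      accuracy = refinement$accuracy,
      moves = refinement$moves,
      final_k = refinement$partition$k,
      partition = refinement$partition,
      history = lapply(refinement$history, function(h)
        list(accuracy = h$accuracy,
             confusion = as.data.frame.matrix(h$confusion)))),
    summary = summary,
    matching = matching,
    squamation = squamation_map(),
    timings = timings), class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  cat(sprintf("  %d scales; kept variables: %s\n", n_scales(x$table),
              paste(x$selection$kept, collapse = ", ")))
  cat(sprintf("  k = %d; group sizes %s\n", x$partition$k,
              paste(sort(tabulate(x$partition$labels, x$partition$k),
                         decreasing = TRUE), collapse = "/")))
  cat(sprintf("  CVA accuracy per round: %s\n",
              paste(sprintf("%.4f", x$refinement$accuracy), collapse = " -> ")))
  cat(sprintf("  assignment cost to reference morphotypes: %.3f\n",
              x$matching$total_cost))
  invisible(x)
}
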