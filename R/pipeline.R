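#' Run the whole systems-pharmacology pipeline
#'
#' Orchestrates the stages in analysis order — ADME screen, compound-target
#' network construction, degree summary and target-provenance
#' classification, contribution scores, over-representation analysis
#' (when an annotation file is configured), and organ assignment (when an
#' expression matrix is configured) — and returns one self-contained,
#' machine-readable report. Re-running with identical inputs and config
#' reproduces identical numeric content.
#'
#' @param config a named list, or the path of a YAML file holding one.
#'   Recognized keys (defaults in parentheses):
#'   \describe{
#'     \item{edges}{path to the compound-target edge TSV — required;}
#'     \item{ingredients, targets}{paths of the ingredient and disease-target
#'       tables; the packaged table transcriptions are used when omitted;}
#'     \item{gmt, expression}{optional annotation (GMT) and gene-by-organ
#'       expression (TSV) inputs; their stages are skipped when absent;}
#'     \item{whitelist}{rescue whitelist ids; `"auto"` (default) uses
#'       [default_whitelist()] on the ingredient table;}
#'     \item{ob_min (30), dl_min (0.10)}{ADME screen thresholds;}
#'     \item{alpha (0.05)}{significance cut-off for enrichment and the
#'       target-pathway network;}
#'     \item{coverage (0.90)}{contribution-score coverage level;}
#'     \item{convention ("as_printed_guarded")}{affinity-index convention;}
#'     \item{enrich_method ("holm")}{multiple-testing correction;}
#'     \item{out_dir}{optional directory for report.json and stage tables.}
#'   }
#' @return the run report (list), invisibly when `out_dir` is set.
#' @export
run_all <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a list or a YAML file path")
  defaults <- list(ingredients = NULL, targets = NULL, edges = NULL,
                   gmt = NULL, expression = NULL, whitelist = "auto",
                   ob_min = 30, dl_min = 0.10, alpha = 0.05,
                   coverage = 0.90, convention = "as_printed_guarded",
                   enrich_method = "holm", out_dir = NULL)
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  cfg <- utils::modifyList(defaults, config)
  if (is.null(cfg$edges)) stop("config must name an 'edges' file")
  paths <- Filter(Negate(is.null),
                  cfg[c("ingredients", "targets", "edges", "gmt",
                        "expression")])
  missing <- paths[!vapply(paths, file.exists, logical(1))]
  if (length(missing) > 0) {
    stop("input file(s) not found: ",
         paste(unlist(missing), collapse = ", "))
  }

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  ingredients <- stage("ingredients", {
    if (is.null(cfg$ingredients)) load_table1_fixture()
    else read_ingredient_table(cfg$ingredients)
  })
  targets <- stage("targets", {
    if (is.null(cfg$targets)) load_table2_fixture()
    else read.delim(cfg$targets, stringsAsFactors = FALSE)
  })
  edges <- stage("edges", read_edge_list(cfg$edges))

  whitelist <- if (identical(cfg$whitelist, "auto")) {
    default_whitelist(ingredients, cfg$ob_min, cfg$dl_min)
  } else {
    as.character(cfg$whitelist)
  }
  scr <- stage("screen",
               screen(ingredients, cfg$ob_min, cfg$dl_min, whitelist))
  message("screen: ", length(scr$passed), " passed / ",
          length(scr$supplemented), " supplemented / ",
          length(scr$rejected), " rejected")

  active <- c(scr$passed, scr$supplemented)
  net <- stage("network", {
    build_ct_network(edges[edges$compound %in% active, , drop = FALSE],
                     ingredients, targets$gene)
  })
  summ <- degree_summary(net)
  cls <- classify_target_sources(net)
  message("network: ", summ$n_compounds, " compounds, ", summ$n_targets,
          " targets, ", summ$n_edges, " edges; ",
          sprintf("%.1f%% shared targets", cls$fraction_shared))

  cs <- stage("contribution",
              contribution_scores(net, convention = cfg$convention,
                                  coverage = cfg$coverage))
  message("contribution: top ", cs$coverage_n, " compounds cover ",
          sprintf("%.2f%%", cs$coverage_percent))

  enr <- NULL
  tp <- NULL
  if (!is.null(cfg$gmt)) {
    ann <- stage("enrichment", read_gmt(cfg$gmt))
    enr <- stage("enrichment",
                 suppressMessages(enrich(net$targets, ann,
                                         method = cfg$enrich_method,
                                         alpha = cfg$alpha)))
    tp <- build_tp_network(enr, alpha = cfg$alpha)
    message("enrichment: ", sum(enr$significant), " significant term(s)")
  }

  organs <- NULL
  cto <- NULL
  if (!is.null(cfg$expression)) {
    mat <- stage("organs", read_expression_matrix(cfg$expression))
    organs <- stage("organs",
                    suppressMessages(assign_organs(mat, net$targets)))
    cto <- stage("organs", build_cto_network(net, organs))
    message("organs: ", length(unique(organs$organ)), " organ(s) used")
  }

  report <- list(
    config = cfg[c("ob_min", "dl_min", "alpha", "coverage", "convention",
                   "enrich_method")],
    screen = list(n_passed = length(scr$passed),
                  n_supplemented = length(scr$supplemented),
                  n_rejected = length(scr$rejected),
                  passed = scr$passed, supplemented = scr$supplemented),
    network = list(n_compounds = summ$n_compounds,
                   n_targets = summ$n_targets, n_edges = summ$n_edges,
                   mean_targets_per_compound = summ$mean_targets_per_compound,
                   mean_compounds_per_target = summ$mean_compounds_per_target,
                   fraction_shared_targets = cls$fraction_shared,
                   target_labels = setNames(cls$labels$label,
                                            cls$labels$target)),
    contribution = list(scores = cs$scores, coverage_n = cs$coverage_n,
                        coverage_percent = cs$coverage_percent,
                        herb_subtotals = as.list(cs$herb_subtotals)),
    enrichment = if (!is.null(enr)) {
      list(table = enr, n_significant = sum(enr$significant),
           pathway_degrees = as.list(tp$degree_pathway))
    },
    organs = if (!is.null(organs)) {
      list(assignments = organs,
           distribution = as.list(cto$degree_organ))
    },
    provenance = list(
      package_version = as.character(utils::packageVersion("herbsynergy")),
      input_md5 = as.list(tools::md5sum(unlist(paths))),
      timestamp = format(Sys.time(), tz = "UTC")))

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(report, file.path(cfg$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    write.table(cs$scores, file.path(cfg$out_dir, "contribution_scores.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(enr)) {
      write.table(enr, file.path(cfg$out_dir, "enrichment.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    return(invisible(report))
  }
  report
}
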