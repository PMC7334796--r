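#' Build the compound-target bipartite network
#'
#' Restricts a compound-target edge list to a disease target set, drops
#' compounds left without any disease-relevant edge (inactive ingredients),
#' and computes per-node degrees. Compounds shared by both herbs appear as a
#' single node carrying the `SHARED` label.
#'
#' @param edges data.frame with columns compound, target (see
#'   [make_edge_list()]).
#' @param ingredients ingredient data.frame (id, herb, ...) or a named
#'   character vector mapping compound id to herb label.
#' @param disease_targets character vector of disease gene symbols.
#' @return a `ct_network` list: `edges` (filtered edge data.frame),
#'   `compounds` (data.frame id, herb), `targets` (character), and named
#'   integer degree vectors `degree_compound`, `degree_target`.
#' @export
build_ct_network <- function(edges, ingredients, disease_targets) {
  if (length(disease_targets) == 0) stop("disease target set is empty")
  herb_map <- if (is.data.frame(ingredients)) {
    setNames(.normalize_herb(ingredients$herb),
             normalize_compound_id(ingredients$id))
  } else {
    setNames(.normalize_herb(ingredients),
             normalize_compound_id(names(ingredients)))
  }
  edges <- make_edge_list(edges$compound, edges$target)
  unlabeled <- setdiff(unique(edges$compound), names(herb_map))
  if (length(unlabeled) > 0) {
    stop("compound(s) without a herb label: ",
         paste(unlabeled, collapse = ", "))
  }
  disease_targets <- toupper(disease_targets)
  keep <- edges$target %in% disease_targets
  edges <- edges[keep, , drop = FALSE]
  if (nrow(edges) == 0) {
    stop("empty network: no edge hits the disease target set")
  }
  # compounds with degree 0 after restriction simply do not appear
  compounds <- sort(unique(edges$compound))
  targets <- sort(unique(edges$target))
  rownames(edges) <- NULL
  structure(
    list(edges = edges,
         compounds = data.frame(id = compounds,
                                herb = unname(herb_map[compounds]),
                                stringsAsFactors = FALSE),
         targets = targets,
         degree_compound = vapply(split(edges$target, factor(edges$compound, compounds)),
                                  length, integer(1)),
         degree_target = vapply(split(edges$compound, factor(edges$target, targets)),
                                length, integer(1))),
    class = "ct_network")
}

#' @export
print.ct_network <- function(x, ...) {
  cat("compound-target network: ", nrow(x$compounds), " compounds, ",
      length(x$targets), " targets, ", nrow(x$edges), " edges\n", sep = "")
  invisible(x)
}

#' Summarize network degrees
#'
#' Reports node and edge counts, the two mean-degree ratios, and the top-k
#' nodes by degree on each side. `mean_targets_per_compound` is
#' edges/compounds and `mean_compounds_per_target` is edges/targets; both are
#' returned raw and rounded half-up to one decimal for display. Degree ties
#' in the top-k lists are broken by lexicographic node id.
#'
#' @param net a `ct_network`.
#' @param k how many top nodes per side to list.
#' @return a `degree_summary` list.
#' @export
degree_summary <- function(net, k = 10) {
  stopifnot(inherits(net, "ct_network"))
  n_edges <- nrow(net$edges)
  n_compounds <- nrow(net$compounds)
  n_targets <- length(net$targets)
  top_of <- function(deg) {
    ord <- order(-deg, names(deg))
    head(deg[ord], k)
  }
  structure(
    list(n_compounds = n_compounds, n_targets = n_targets, n_edges = n_edges,
         mean_targets_per_compound = n_edges / n_compounds,
         mean_compounds_per_target = n_edges / n_targets,
         mean_targets_per_compound_rounded =
           round_half_up(n_edges / n_compounds, 1),
         mean_compounds_per_target_rounded =
           round_half_up(n_edges / n_targets, 1),
         top_compounds = top_of(net$degree_compound),
         top_targets = top_of(net$degree_target)),
    class = "degree_summary")
}

#' @export
print.degree_summary <- function(x, ...) {
  cat(x$n_edges, " edges between ", x$n_compounds, " compounds and ",
      x$n_targets, " targets\n",
      "mean targets per compound: ", x$mean_targets_per_compound_rounded,
      "; mean compounds per target: ", x$mean_compounds_per_target_rounded,
      "\n", sep = "")
  invisible(x)
}

#' Classify targets as shared or herb-unique
#'
#' A target is `SHARED` (synergistically regulated) when it is reached by at
#' least one ATR-side and at least one CR-side compound; a compound labeled
#' `SHARED` counts for both sides. Otherwise the target is `ATR_ONLY` or
#' `CR_ONLY` (complementary regulation).
#'
#' @param net a `ct_network` whose compounds all carry herb labels.
#' @return a `target_sources` list: `labels` (data.frame target, label) and
#'   `fraction_shared` (percent of targets labeled SHARED).
#' @export
classify_target_sources <- function(net) {
  stopifnot(inherits(net, "ct_network"))
  herb <- setNames(net$compounds$herb, net$compounds$id)
  if (any(is.na(herb))) {
    stop("compound(s) without a herb label: ",
         paste(names(herb)[is.na(herb)], collapse = ", "))
  }
  label_one <- function(genes_compounds) {
    h <- herb[genes_compounds]
    atr <- any(h %in% c("ATR", "SHARED"))
    cr <- any(h %in% c("CR", "SHARED"))
    if (atr && cr) "SHARED" else if (atr) "ATR_ONLY" else "CR_ONLY"
  }
  by_target <- split(net$edges$compound, factor(net$edges$target, net$targets))
  labels <- vapply(by_target, label_one, character(1))
  structure(
    list(labels = data.frame(target = net$targets, label = unname(labels),
                             stringsAsFactors = FALSE),
         fraction_shared = 100 * sum(labels == "SHARED") / length(labels)),
    class = "target_sources")
}

#' @export
print.target_sources <- function(x, ...) {
  tab <- table(x$labels$label)
  cat("target provenance: ", paste(names(tab), tab, sep = "=", collapse = ", "),
      sprintf(" (%.1f%% shared)\n", x$fraction_shared), sep = "")
  invisible(x)
}

#' Build the target-pathway bipartite network
#'
#' Keeps enrichment terms with adjusted p below `alpha` (strict `<`) and
#' links each kept term to its member target genes. The degree of a pathway
#' node is therefore the number of selected targets it annotates.
#'
#' @param enrichment data.frame as returned by [enrich()] (columns term,
#'   p_adj, genes with comma-separated members).
#' @param alpha significance cut-off on adjusted p; default 0.05.
#' @return a `tp_network` list: `edges` (data.frame term, target),
#'   `degree_pathway`, `degree_target`.
#' @export
build_tp_network <- function(enrichment, alpha = 0.05) {
  keep <- enrichment[enrichment$p_adj < alpha, , drop = FALSE]
  if (nrow(keep) == 0) {
    edges <- data.frame(term = character(), target = character(),
                        stringsAsFactors = FALSE)
  } else {
    members <- strsplit(keep$genes, ",", fixed = TRUE)
    edges <- data.frame(term = rep(keep$term, lengths(members)),
                        target = unlist(members), stringsAsFactors = FALSE)
  }
  structure(
    list(edges = edges,
         degree_pathway = sort(table(edges$term), decreasing = TRUE),
         degree_target = sort(table(edges$target), decreasing = TRUE)),
    class = "tp_network")
}

#' Build the compound-target-organ tripartite network
#'
#' Extends a compound-target network by linking every target to the single
#' organ of its maximal expression. Each target node gets exactly one organ
#' edge; compound-target edges are kept as they are.
#'
#' @param net a `ct_network`.
#' @param organs organ assignments: a data.frame with columns gene, organ
#'   (as from [assign_organs()]) or a named character vector gene -> organ.
#' @return a `cto_network` list: `ct_edges`, `to_edges` (data.frame target,
#'   organ), `degree_organ`.
#' @export
build_cto_network <- function(net, organs) {
  stopifnot(inherits(net, "ct_network"))
  if (is.data.frame(organs)) organs <- setNames(organs$organ, organs$gene)
  names(organs) <- toupper(names(organs))
  missing <- setdiff(net$targets, names(organs))
  if (length(missing) > 0) {
    stop("no organ assignment for target(s): ",
         paste(missing, collapse = ", "))
  }
  to_edges <- data.frame(target = net$targets,
                         organ = unname(organs[net$targets]),
                         stringsAsFactors = FALSE)
  structure(
    list(ct_edges = net$edges, to_edges = to_edges,
         degree_organ = sort(table(to_edges$organ), decreasing = TRUE)),
    class = "cto_network")
}
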