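#' Assign a gene to the organ of its maximum expression
#'
#' Places a gene in the organ where its expression is highest. When the
#' matrix carries several rows (probes) for the gene they are first
#' aggregated per organ, by mean (default) or max. Ties at the maximum are
#' broken by the lexicographically smallest organ name and flagged.
#'
#' @param mat numeric gene-by-organ matrix (rownames are gene symbols;
#'   duplicates allowed).
#' @param gene gene symbol.
#' @param aggregate probe aggregation: `"mean"` (default) or `"max"`.
#' @return one-row data.frame: gene, organ, value, tie.
#' @export
assign_organ <- function(mat, gene, aggregate = c("mean", "max")) {
  aggregate <- match.arg(aggregate)
  gene <- toupper(gene)
  rows <- which(rownames(mat) == gene)
  if (length(rows) == 0) stop("gene not in expression matrix: ", gene)
  sub <- mat[rows, , drop = FALSE]
  agg_fun <- if (aggregate == "mean") {
    function(v) mean(v, na.rm = TRUE)
  } else {
    function(v) if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE)
  }
  profile <- apply(sub, 2, agg_fun)
  profile[is.nan(profile)] <- NA_real_
  if (all(is.na(profile))) stop("all expression values missing for ", gene)
  m <- max(profile, na.rm = TRUE)
  at_max <- sort(names(profile)[!is.na(profile) & profile == m])
  data.frame(gene = gene, organ = at_max[1], value = m,
             tie = length(at_max) > 1, stringsAsFactors = FALSE)
}

#' Assign several genes to their maximal-expression organs
#'
#' @param mat numeric gene-by-organ matrix.
#' @param genes gene symbols; those absent from the matrix are dropped with
#'   a message.
#' @inheritParams assign_organ
#' @return data.frame with one row per assigned gene (gene, organ, value,
#'   tie).
#' @export
assign_organs <- function(mat, genes, aggregate = c("mean", "max")) {
  aggregate <- match.arg(aggregate)
  genes <- toupper(unique(genes))
  missing <- setdiff(genes, rownames(mat))
  if (length(missing) > 0) {
    message("no expression row for ", length(missing), " gene(s): ",
            paste(missing, collapse = ", "))
    genes <- setdiff(genes, missing)
  }
  out <- do.call(rbind, lapply(genes, assign_organ, mat = mat,
                               aggregate = aggregate))
  if (is.null(out)) {
    out <- data.frame(gene = character(), organ = character(),
                      value = numeric(), tie = logical())
  }
  rownames(out) <- NULL
  out
}

#' Organ distribution of a target set
#'
#' Counts how many of the given genes land in each organ under the
#' maximal-expression rule, ranked by count (descending) with ties broken
#' by organ name.
#'
#' @inheritParams assign_organs
#' @return data.frame with columns organ, count, in rank order.
#' @export
organ_distribution <- function(mat, genes, aggregate = c("mean", "max")) {
  asg <- assign_organs(mat, genes, aggregate = aggregate)
  if (nrow(asg) == 0) {
    return(data.frame(organ = character(), count = integer()))
  }
  tab <- table(asg$organ)
  out <- data.frame(organ = names(tab), count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$organ), , drop = FALSE]
  rownames(out) <- NULL
  out
}
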