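#' Edge-share weight of each compound
#'
#' The weight of compound i is its degree divided by the total number of
#' edges in the network, so the weights sum to one.
#'
#' @param net a `ct_network`.
#' @return named numeric vector, one weight per compound.
#' @export
omega <- function(net) {
  stopifnot(inherits(net, "ct_network"))
  n_edges <- nrow(net$edges)
  if (n_edges == 0) stop("empty network")
  net$degree_compound / n_edges
}

#' Affinity index of a compound
#'
#' Combines the edge-share weight with the per-herb degree contrast:
#' \deqn{A_i = \omega_i + \frac{C_{Ai} + C_{Bi}}{C_{Ai} - C_{Bi}}}
#' where \eqn{C_{Ai}} is the compound's degree in the CR-restricted network
#' and \eqn{C_{Bi}} its degree in the ATR-restricted network. Under the
#' default `"as_printed_guarded"` convention the denominator is
#' \eqn{\max(|C_{Ai} - C_{Bi}|, 1)} carrying the sign of the difference
#' (+1 when the degrees are equal), so the ratio is +1 for CR-only
#' compounds, -1 for ATR-only compounds, and the formula never divides by
#' zero for shared compounds with balanced degrees.
#' `"as_printed_strict"` instead raises an error when the degrees are equal,
#' for auditing the unguarded formula.
#'
#' @param omega_i edge-share weight(s) of the compound(s).
#' @param c_a degree(s) in the CR-restricted network.
#' @param c_b degree(s) in the ATR-restricted network.
#' @param convention `"as_printed_guarded"` (default) or
#'   `"as_printed_strict"`.
#' @return numeric affinity value(s), possibly negative; downstream scoring
#'   uses the absolute value.
#' @export
#' @examples
#' affinity_index(0.75, 3, 0)   # CR-only: 1.75
#' affinity_index(0.5, 2, 2)    # shared, balanced: 4.5 under the guard
affinity_index <- function(omega_i, c_a, c_b,
                           convention = c("as_printed_guarded",
                                          "as_printed_strict")) {
  convention <- match.arg(convention)
  if (any(c_a < 0) || any(c_b < 0)) stop("per-herb degrees must be >= 0")
  if (any(c_a + c_b == 0)) stop("compound with zero degree in both herb networks")
  d <- c_a - c_b
  if (convention == "as_printed_strict" && any(d == 0)) {
    stop("zero denominator: C_A equals C_B for ",
         sum(d == 0), " compound(s) under as_printed_strict")
  }
  denom <- ifelse(d == 0, 1, sign(d) * pmax(abs(d), 1))
  omega_i + (c_a + c_b) / denom
}

#' Restrict a compound-target network to one herb
#'
#' Keeps the compounds labeled with the given herb plus the `SHARED`
#' compounds (which belong to both herbs), along with all their edges;
#' targets no longer reached are dropped.
#'
#' @param net a `ct_network`.
#' @param herb `"ATR"` or `"CR"`.
#' @return a `ct_network` restricted to that herb's side.
#' @export
herb_restriction <- function(net, herb = c("ATR", "CR")) {
  herb <- match.arg(herb)
  keep_ids <- net$compounds$id[net$compounds$herb %in% c(herb, "SHARED")]
  if (length(keep_ids) == 0) stop("no compounds on the ", herb, " side")
  herb_map <- setNames(net$compounds$herb, net$compounds$id)
  edges <- net$edges[net$edges$compound %in% keep_ids, , drop = FALSE]
  build_ct_network(edges, herb_map[keep_ids], unique(edges$target))
}

#' Degree-based contribution scores of the formula's ingredients
#'
#' Scores every compound's share of the formula's network action:
#' \deqn{CS_i = C_i \times |A_i| \times \sum_{j \in N(i)} P_j}
#' where \eqn{C_i} and \eqn{P_j} are compound and target degrees in the
#' combined network, \eqn{N(i)} the targets adjacent to compound i, and
#' \eqn{A_i} the [affinity_index()] computed from the per-herb restricted
#' degrees. Scores are reported as percent of the total, sorted descending
#' (ties by id) with a cumulative percent, the minimal set of top compounds
#' reaching the requested coverage, and per-herb subtotals (`SHARED`
#' compounds split between the herbs by `shared_split`).
#'
#' @param net the combined `ct_network`.
#' @param atr_net,cr_net the per-herb restrictions; computed with
#'   [herb_restriction()] when `NULL`.
#' @param convention affinity-denominator convention, see
#'   [affinity_index()].
#' @param coverage cumulative-percent level defining the "top contributors"
#'   prefix; default 0.90.
#' @param shared_split fraction of a SHARED compound's percent credited to
#'   ATR (the rest goes to CR); default 0.5.
#' @return a `contribution_result`: `scores` data.frame (id, herb, c, c_a,
#'   c_b, omega, a, cs, cs_percent, cumulative_percent), `coverage_n`,
#'   `coverage_ids`, `coverage_percent`, `herb_subtotals`.
#' @export
contribution_scores <- function(net, atr_net = NULL, cr_net = NULL,
                                convention = c("as_printed_guarded",
                                               "as_printed_strict"),
                                coverage = 0.90, shared_split = 0.5) {
  stopifnot(inherits(net, "ct_network"))
  convention <- match.arg(convention)
  has_atr <- any(net$compounds$herb %in% c("ATR", "SHARED"))
  has_cr <- any(net$compounds$herb %in% c("CR", "SHARED"))
  if (is.null(atr_net) && has_atr) atr_net <- herb_restriction(net, "ATR")
  if (is.null(cr_net) && has_cr) cr_net <- herb_restriction(net, "CR")
  ids <- net$compounds$id
  deg <- net$degree_compound[ids]
  w <- omega(net)[ids]
  deg_in <- function(sub, id) {
    if (is.null(sub) || !id %in% names(sub$degree_compound)) 0L
    else sub$degree_compound[[id]]
  }
  c_a <- vapply(ids, deg_in, integer(1), sub = cr_net)   # CR-side degree
  c_b <- vapply(ids, deg_in, integer(1), sub = atr_net)  # ATR-side degree
  a <- affinity_index(w, c_a, c_b, convention)
  neighbor_p <- vapply(ids, function(id) {
    sum(net$degree_target[net$edges$target[net$edges$compound == id]])
  }, numeric(1))
  cs <- deg * abs(a) * neighbor_p
  total <- sum(cs)
  if (total == 0) {
    stop("all contribution scores are zero: percentages undefined")
  }
  res <- data.frame(id = ids,
                    herb = net$compounds$herb,
                    c = unname(deg), c_a = unname(c_a), c_b = unname(c_b),
                    omega = unname(w), a = unname(a), cs = unname(cs),
                    cs_percent = 100 * unname(cs) / total,
                    stringsAsFactors = FALSE)
  res <- res[order(-res$cs_percent, res$id), , drop = FALSE]
  res$cumulative_percent <- cumsum(res$cs_percent)
  rownames(res) <- NULL
  n_cov <- which(res$cumulative_percent >= 100 * coverage)[1]
  if (is.na(n_cov)) n_cov <- nrow(res)  # numerical slack at coverage = 1
  split_w <- ifelse(res$herb == "ATR", 1,
                    ifelse(res$herb == "CR", 0, shared_split))
  subtotals <- c(ATR = sum(res$cs_percent * split_w),
                 CR = sum(res$cs_percent * (1 - split_w)))
  structure(
    list(scores = res,
         coverage_n = n_cov,
         coverage_ids = res$id[seq_len(n_cov)],
         coverage_percent = res$cumulative_percent[n_cov],
         herb_subtotals = subtotals,
         convention = convention),
    class = "contribution_result")
}

#' @export
print.contribution_result <- function(x, ...) {
  cat("contribution scores for ", nrow(x$scores), " compounds; top ",
      x$coverage_n, " cover ", sprintf("%.2f", x$coverage_percent),
      "% of the total (ATR ", sprintf("%.2f", x$herb_subtotals[["ATR"]]),
      "%, CR ", sprintf("%.2f", x$herb_subtotals[["CR"]]), "%)\n", sep = "")
  invisible(x)
}
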