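#' Tanimoto drug-likeness score
#'
#' Drug-likeness of a compound is scored as the Tanimoto coefficient between
#' its molecular-descriptor vector and the average descriptor vector of the
#' DrugBank reference set:
#' \deqn{T(A, B) = \frac{A \cdot B}{|A|^2 + |B|^2 - A \cdot B}}
#' For non-negative descriptor vectors the score lies in (0, 1], with 1 for
#' identical vectors and 0 for orthogonal ones.
#'
#' @param a numeric descriptor vector of the compound.
#' @param b reference descriptor vector (same length).
#' @return scalar Tanimoto score.
#' @export
#' @examples
#' tanimoto_dl(c(1, 1, 0), c(1, 0, 1))  # 1/3
tanimoto_dl <- function(a, b) {
  a <- as.numeric(a)
  b <- as.numeric(b)
  if (length(a) != length(b)) {
    stop("descriptor vectors differ in length (", length(a), " vs ",
         length(b), ")")
  }
  if (!all(is.finite(a)) || !all(is.finite(b))) {
    stop("descriptor vectors must be finite")
  }
  ab <- sum(a * b)
  denom <- sum(a^2) + sum(b^2) - ab
  if (denom == 0) stop("Tanimoto score undefined: both vectors are zero")
  ab / denom
}

#' Screen ingredients by oral bioavailability and drug-likeness
#'
#' Applies the two ADME gates with inclusive thresholds — OB >= `ob_min`
#' (percent) and DL >= `dl_min` — and partitions the input into
#' \describe{
#'   \item{passed}{ids meeting both thresholds;}
#'   \item{supplemented}{ids failing a threshold but rescued by the
#'     bioactivity whitelist (ids on the whitelist that also pass are counted
#'     as passed);}
#'   \item{rejected}{everything else.}
#' }
#'
#' @param ingredients ingredient data.frame (id, ob, dl, ...).
#' @param ob_min minimum oral bioavailability, percent; default 30.
#' @param dl_min minimum drug-likeness; default 0.10.
#' @param whitelist character vector of compound ids to rescue; ids absent
#'   from the input raise a warning, not an error.
#' @return a `screen_result` list with elements `passed`, `supplemented`,
#'   `rejected` (character id vectors) and `thresholds`.
#' @export
screen <- function(ingredients, ob_min = 30, dl_min = 0.10,
                   whitelist = character()) {
  if (any(is.na(ingredients$ob)) || any(is.na(ingredients$dl))) {
    stop("screen() requires ob and dl for every ingredient")
  }
  whitelist <- normalize_compound_id(whitelist)
  unknown <- setdiff(whitelist, ingredients$id)
  if (length(unknown) > 0) {
    warning("whitelist id(s) absent from input: ",
            paste(unknown, collapse = ", "))
  }
  ok <- ingredients$ob >= ob_min & ingredients$dl >= dl_min
  passed <- ingredients$id[ok]
  supplemented <- setdiff(intersect(whitelist, ingredients$id), passed)
  rejected <- setdiff(ingredients$id, c(passed, supplemented))
  structure(
    list(passed = passed, supplemented = supplemented, rejected = rejected,
         thresholds = c(ob_min = ob_min, dl_min = dl_min)),
    class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  cat("ADME screen (OB >= ", x$thresholds[["ob_min"]], "%, DL >= ",
      x$thresholds[["dl_min"]], "): ", length(x$passed), " passed, ",
      length(x$supplemented), " supplemented, ", length(x$rejected),
      " rejected\n", sep = "")
  invisible(x)
}

#' Default rescue whitelist for the packaged ingredient table
#'
#' The published ingredient table includes compounds that fail the strict
#' OB/DL thresholds but were retained for their reported bioactivity
#' (e.g. beta-asarone, syringin, HMF, apigenin). The exact rescue list is not
#' printed, so this default is a reconstruction: it is exactly the set of
#' packaged table ids that fail the strict thresholds, which by construction
#' makes the screen of the packaged table keep all 68 ingredients.
#'
#' @param ingredients ingredient table; defaults to [load_table1_fixture()].
#' @param ob_min,dl_min the strict thresholds.
#' @return character vector of compound ids.
#' @export
default_whitelist <- function(ingredients = load_table1_fixture(),
                              ob_min = 30, dl_min = 0.10) {
  ingredients$id[ingredients$ob < ob_min | ingredients$dl < dl_min]
}

# Welch/Student two-sample t with explicit guards for zero-variance groups:
# identical constant groups give t = 0, p = 1; constant groups with
# different means give t = Inf (p = 0) rather than an error.
.two_sample_t <- function(x, y, var_equal = FALSE) {
  nx <- length(x); ny <- length(y)
  vx <- stats::var(x); vy <- stats::var(y)
  if (vx == 0 && vy == 0) {
    if (mean(x) == mean(y)) return(c(t = 0, p = 1))
    return(c(t = Inf, p = 0))
  }
  ht <- stats::t.test(x, y, var.equal = var_equal)
  c(t = unname(ht$statistic), p = ht$p.value)
}

#' Compare physicochemical properties between the two herbs
#'
#' For each requested property, computes the per-herb means over non-missing
#' values and a two-sided two-sample t-test (Welch by default; set
#' `var_equal = TRUE` for the pooled-variance Student test). Ingredients
#' labeled `SHARED` are counted in both herb groups. Properties with fewer
#' than two non-missing values in either group are skipped with a message.
#'
#' @param ingredients ingredient data.frame with a `herb` column.
#' @param properties character vector of property column names; default the
#'   six standard descriptors.
#' @param var_equal logical; `FALSE` (Welch) by default.
#' @return data.frame with columns property, mean_ATR, mean_CR, n_ATR, n_CR,
#'   t, p — one row per retained property.
#' @export
compare_herb_properties <- function(ingredients,
                                    properties = c("mw", "alogp", "nhdon",
                                                   "nhacc", "ob", "dl"),
                                    var_equal = FALSE) {
  herb <- .normalize_herb(ingredients$herb)
  out <- lapply(properties, function(prop) {
    if (!prop %in% names(ingredients)) {
      message("property ", prop, " not in table; skipped")
      return(NULL)
    }
    v <- ingredients[[prop]]
    x <- v[herb %in% c("ATR", "SHARED")]
    y <- v[herb %in% c("CR", "SHARED")]
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    if (length(x) < 2 || length(y) < 2) {
      message("property ", prop, ": fewer than 2 values in a herb group; skipped")
      return(NULL)
    }
    tt <- .two_sample_t(x, y, var_equal = var_equal)
    data.frame(property = prop, mean_ATR = mean(x), mean_CR = mean(y),
               n_ATR = length(x), n_CR = length(y),
               t = tt[["t"]], p = tt[["p"]], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(property = character(), mean_ATR = numeric(),
                      mean_CR = numeric(), n_ATR = integer(),
                      n_CR = integer(), t = numeric(), p = numeric())
  }
  rownames(out) <- NULL
  out
}
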