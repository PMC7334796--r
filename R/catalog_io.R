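#' Normalize compound identifiers to the canonical herb prefixes
#'
#' The two herbs appear under two naming conventions: `ATR`/`CR` and the
#' pinyin-derived aliases `SCP` (Shi Chang Pu = ATR) and `DS` (Dang Shen = CR).
#' Identifiers are upper-cased and aliases rewritten to the canonical prefix,
#' so `"scp93"` and `"ATR93"` refer to the same compound.
#'
#' @param ids character vector of compound identifiers.
#' @return character vector of canonical identifiers.
#' @export
#' @examples
#' normalize_compound_id(c("SCP93", "DS77", "atr3"))
normalize_compound_id <- function(ids) {
  ids <- toupper(trimws(as.character(ids)))
  ids <- sub("^SCP", "ATR", ids)
  ids <- sub("^DS", "CR", ids)
  ids
}

.normalize_herb <- function(herb) {
  herb <- toupper(trimws(as.character(herb)))
  herb[herb == "SCP"] <- "ATR"
  herb[herb == "DS"] <- "CR"
  bad <- !herb %in% c("ATR", "CR", "SHARED")
  if (any(bad)) {
    stop("unknown herb label(s): ", paste(unique(herb[bad]), collapse = ", "))
  }
  herb
}

#' Read an ingredient property table
#'
#' Reads a delimited table of herb ingredients with their ADME properties.
#' Required columns: `id`, `name`, `herb`, `ob`, `dl`. Optional numeric
#' columns (`mw`, `alogp`, `nhdon`, `nhacc`) are kept when present; empty
#' numeric cells become `NA`, never zero. Compound ids are normalized via
#' [normalize_compound_id()].
#'
#' @param path path to a TSV/CSV file with a header row.
#' @param sep field delimiter; default `"\t"`, use `","` for CSV.
#' @return a `data.frame` with columns id, name, herb, mw, alogp, nhdon,
#'   nhacc, ob, dl (one row per ingredient).
#' @export
read_ingredient_table <- function(path, sep = "\t") {
  df <- read.delim(path, sep = sep, stringsAsFactors = FALSE,
                   check.names = FALSE, na.strings = c("NA", ""))
  names(df) <- tolower(names(df))
  required <- c("id", "name", "herb", "ob", "dl")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("ingredient table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  df$id <- normalize_compound_id(df$id)
  if (anyDuplicated(df$id)) {
    stop("duplicate ingredient id(s): ",
         paste(unique(df$id[duplicated(df$id)]), collapse = ", "))
  }
  df$herb <- .normalize_herb(df$herb)
  for (col in c("mw", "alogp", "nhdon", "nhacc", "ob", "dl")) {
    df[[col]] <- if (col %in% names(df)) {
      suppressWarnings(as.numeric(df[[col]]))
    } else {
      rep(NA_real_, nrow(df))
    }
  }
  bad_ob <- which(!is.na(df$ob) & (df$ob < 0 | df$ob > 100))
  if (length(bad_ob) > 0) {
    stop("ob outside [0, 100] in row(s): ", paste(bad_ob, collapse = ", "),
         " (id ", paste(df$id[bad_ob], collapse = ", "), ")")
  }
  bad_dl <- which(!is.na(df$dl) & (df$dl < 0 | df$dl > 1))
  if (length(bad_dl) > 0) {
    stop("dl outside [0, 1] in row(s): ", paste(bad_dl, collapse = ", "),
         " (id ", paste(df$id[bad_dl], collapse = ", "), ")")
  }
  df[c("id", "name", "herb", "mw", "alogp", "nhdon", "nhacc", "ob", "dl")]
}

#' Write an ingredient table
#'
#' @param ingredients data.frame as returned by [read_ingredient_table()].
#' @param path output path.
#' @param sep field delimiter.
#' @return `path`, invisibly.
#' @export
write_ingredient_table <- function(ingredients, path, sep = "\t") {
  write.table(ingredients, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Load the packaged active-ingredient table
#'
#' Returns the packaged transcription of the published table of 68 active
#' ingredients of Acori Tatarinowii Rhizoma (ATR, 32 rows) and Codonopsis
#' Radix (CR, 36 rows) with their oral bioavailability (OB, percent) and
#' drug-likeness (DL) values. The hydroxymethylfurfural (CR75) and apigenin
#' (CR77) entries are labeled `SHARED` because both herbs contain them.
#' The table carries only OB and DL; the other property columns are `NA`.
#'
#' @return a `data.frame` of 68 ingredients.
#' @export
#' @examples
#' ing <- load_table1_fixture()
#' nrow(ing)  # 68
load_table1_fixture <- function() {
  path <- system.file("extdata", "table1_ingredients.tsv",
                      package = "herbsynergy", mustWork = TRUE)
  read_ingredient_table(path)
}

#' Load the packaged disease-target table
#'
#' Returns the packaged transcription of the published table of 62
#' Alzheimer's-disease-related target proteins (HGNC gene symbol, protein
#' name, UniProt accession), in printed order.
#'
#' @return a `data.frame` with columns gene, name, uniprot.
#' @export
load_table2_fixture <- function() {
  path <- system.file("extdata", "table2_targets.tsv",
                      package = "herbsynergy", mustWork = TRUE)
  df <- read.delim(path, stringsAsFactors = FALSE)
  df$gene <- toupper(df$gene)
  uniprot_re <- paste0("^([OPQ][0-9][A-Z0-9]{3}[0-9]|",
                       "[A-NR-Z][0-9]([A-Z][A-Z0-9]{2}[0-9]){1,2})$")
  bad <- !grepl(uniprot_re, df$uniprot)
  if (any(bad)) {
    stop("malformed UniProt accession(s): ",
         paste(df$uniprot[bad], collapse = ", "))
  }
  if (anyDuplicated(df$gene)) stop("duplicate gene symbol in target table")
  df
}

#' Look up a target by gene symbol
#'
#' @param targets target table as from [load_table2_fixture()].
#' @param gene gene symbol (case-insensitive).
#' @return one-row data.frame.
#' @export
lookup_target <- function(targets, gene) {
  hit <- targets[targets$gene == toupper(gene), , drop = FALSE]
  if (nrow(hit) == 0) stop("target gene not found: ", gene)
  hit
}

#' Read a compound-target edge list
#'
#' Expects a delimited file with a header and columns `compound` and
#' `target`. Compound ids are normalized, gene symbols upper-cased, and
#' duplicate pairs dropped with a message stating how many were removed.
#'
#' @param path input path.
#' @param sep field delimiter.
#' @return a `data.frame` with columns compound, target.
#' @export
read_edge_list <- function(path, sep = "\t") {
  df <- read.delim(path, sep = sep, stringsAsFactors = FALSE)
  names(df) <- tolower(names(df))
  if (!all(c("compound", "target") %in% names(df))) {
    stop("edge list is missing required column(s): ",
         paste(setdiff(c("compound", "target"), names(df)), collapse = ", "))
  }
  make_edge_list(df$compound, df$target)
}

#' Build a validated edge list from paired vectors
#'
#' @param compound,target equal-length character vectors.
#' @return a `data.frame` with columns compound, target, duplicates removed.
#' @export
make_edge_list <- function(compound, target) {
  df <- data.frame(compound = normalize_compound_id(compound),
                   target = toupper(trimws(as.character(target))),
                   stringsAsFactors = FALSE)
  dup <- duplicated(df)
  if (any(dup)) {
    message("dropped ", sum(dup), " duplicate edge(s)")
    df <- df[!dup, , drop = FALSE]
  }
  rownames(df) <- NULL
  df
}

#' @rdname read_edge_list
#' @param edges edge-list data.frame.
#' @export
write_edge_list <- function(edges, path, sep = "\t") {
  write.table(edges[c("compound", "target")], path, sep = sep,
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' Standard GMT: one tab-separated line per term — term id, description,
#' then the member genes. Lines with fewer than three fields are a format
#' error reported with the offending line number.
#'
#' @param path GMT file path.
#' @return named list of character gene vectors; term descriptions are kept
#'   in the `"description"` attribute (named character vector).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3)) {
    stop("malformed GMT line (fewer than 3 fields) at line ",
         which(nf < 3)[1])
  }
  terms <- vapply(fields, `[[`, character(1), 1)
  desc <- vapply(fields, `[[`, character(1), 2)
  sets <- lapply(fields, function(f) toupper(unique(f[-(1:2)])))
  names(sets) <- terms
  names(desc) <- terms
  attr(sets, "description") <- desc
  sets
}

#' Write gene sets in GMT format
#'
#' @param sets named list of character gene vectors; an optional
#'   `"description"` attribute supplies the second column (defaults to the
#'   term id).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  desc <- attr(sets, "description")
  if (is.null(desc)) desc <- setNames(names(sets), names(sets))
  lines <- vapply(names(sets), function(tm) {
    paste(c(tm, desc[[tm]], sets[[tm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a gene-by-organ expression matrix
#'
#' First column is the gene symbol; remaining columns are organs. Duplicate
#' gene rows (multiple probes) are allowed and aggregated downstream by
#' [assign_organ()].
#'
#' @param path TSV path.
#' @return numeric matrix with gene rownames and organ colnames.
#' @export
read_expression_matrix <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(df) < 2) stop("expression matrix needs a gene column and >=1 organ column")
  genes <- toupper(df[[1]])
  mat <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- genes
  mat
}

#' @rdname read_expression_matrix
#' @param mat numeric gene-by-organ matrix.
#' @export
write_expression_matrix <- function(mat, path) {
  df <- data.frame(gene = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a compound-target network
#'
#' Writes a [build_ct_network()] result as a plain edge TSV, Cytoscape SIF
#' (`node <tab> interaction <tab> node`), or GraphML.
#'
#' @param net a `ct_network` object.
#' @param path output path.
#' @param format one of `"tsv"`, `"sif"`, `"graphml"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, format = c("tsv", "sif", "graphml")) {
  format <- match.arg(format)
  stopifnot(inherits(net, "ct_network"))
  edges <- net$edges
  if (format == "tsv") {
    write_edge_list(edges, path)
  } else if (format == "sif") {
    writeLines(paste(edges$compound, "binds", edges$target, sep = "\t"), path)
  } else {
    g <- igraph::graph_from_data_frame(
      edges,
      vertices = data.frame(
        name = c(net$compounds$id, net$targets),
        type = c(rep("compound", nrow(net$compounds)),
                 rep("target", length(net$targets))),
        herb = c(net$compounds$herb, rep(NA_character_, length(net$targets))),
        stringsAsFactors = FALSE),
      directed = FALSE)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}
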