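#' Ordered entity universe
#'
#' An `entity_index` is the ordered set of identifiers of one entity kind
#' (disease, protein or drug). Identifiers are opaque, case-sensitive,
#' non-empty strings; the ordering is deterministic -- lexicographic
#' (C-locale radix order) unless `sort_ids = FALSE`, in which case the
#' supplied order is kept.
#'
#' @param ids character vector of identifiers (duplicates are collapsed).
#' @param kind one of `"disease"`, `"protein"`, `"drug"`.
#' @param sort_ids sort identifiers lexicographically (default) or keep the
#'   supplied order.
#' @return an object of class `entity_index` with elements `kind` and `ids`.
#' @export
entity_index <- function(ids, kind = c("disease", "protein", "drug"),
                         sort_ids = TRUE) {
  kind <- match.arg(kind)
  ids <- as.character(ids)
  if (anyNA(ids) || !all(nzchar(ids))) {
    stop("entity ids must be non-empty strings", call. = FALSE)
  }
  ids <- unique(ids)
  if (sort_ids) ids <- sort(ids, method = "radix")
  structure(list(kind = kind, ids = ids), class = "entity_index")
}

#' @export
length.entity_index <- function(x) length(x$ids)

#' @export
print.entity_index <- function(x, ...) {
  cat(sprintf("<entity_index> %s: %d ids\n", x$kind, length(x$ids)))
  invisible(x)
}

#' Position of identifiers in an entity index
#'
#' @param index an [entity_index()].
#' @param ids character vector of identifiers.
#' @return 0-based integer positions (the index is a bijection onto
#'   `0..length(index)-1`).
#' @export
entity_position <- function(index, ids) {
  pos <- match(ids, index$ids)
  if (anyNA(pos)) {
    stop("unknown ", index$kind, " id(s): ",
         paste(ids[is.na(pos)], collapse = ", "), call. = FALSE)
  }
  pos - 1L
}

#' Binary association table between two entity universes
#'
#' Represents a deduplicated set of (row-id, col-id) links -- e.g. diseases
#' x proteins -- equivalently a binary matrix whose (i, k) entry is the
#' k-th component of entity i's association profile. Membership is binary;
#' there are no weights.
#'
#' @param pairs two-column character matrix or data.frame of
#'   (row-id, col-id) links; duplicate rows collapse to one pair.
#' @param row_kind,col_kind entity kinds of the rows and columns.
#' @param row_ids,col_ids optional explicit universes (must cover the ids in
#'   `pairs`); by default the universes are the distinct ids observed,
#'   ordered lexicographically.
#' @return an object of class `association_table` with elements `row_index`,
#'   `col_index` (both [entity_index()]) and `matrix` (sparse binary
#'   `Matrix::dgCMatrix` with dimnames).
#' @export
association_table <- function(pairs, row_kind, col_kind,
                              row_ids = NULL, col_ids = NULL) {
  if (is.matrix(pairs)) pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  if (length(pairs) == 0L || nrow(as.data.frame(pairs)) == 0L) {
    pairs <- data.frame(row = character(), col = character(),
                        stringsAsFactors = FALSE)
  }
  stopifnot(ncol(pairs) >= 2L)
  rows <- as.character(pairs[[1L]])
  cols <- as.character(pairs[[2L]])
  keep <- !duplicated(paste(rows, cols, sep = "\r"))
  rows <- rows[keep]
  cols <- cols[keep]

  row_index <- if (is.null(row_ids)) entity_index(rows, row_kind)
               else entity_index(row_ids, row_kind)
  col_index <- if (is.null(col_ids)) entity_index(cols, col_kind)
               else entity_index(col_ids, col_kind)
  i <- match(rows, row_index$ids)
  j <- match(cols, col_index$ids)
  if (anyNA(i) || anyNA(j)) {
    stop("pairs reference ids absent from the supplied universes",
         call. = FALSE)
  }
  m <- Matrix::sparseMatrix(
    i = i, j = j, x = 1,
    dims = c(length(row_index), length(col_index)),
    dimnames = list(row_index$ids, col_index$ids)
  )
  structure(list(row_index = row_index, col_index = col_index, matrix = m),
            class = "association_table")
}

#' @export
print.association_table <- function(x, ...) {
  cat(sprintf("<association_table> %d %ss x %d %ss, %d pairs\n",
              length(x$row_index), x$row_index$kind,
              length(x$col_index), x$col_index$kind, n_pairs(x)))
  invisible(x)
}

#' @export
dim.association_table <- function(x) dim(x$matrix)

#' Number of association pairs in a table
#' @param table an [association_table()].
#' @return integer count of (row, col) pairs.
#' @export
n_pairs <- function(table) as.integer(Matrix::nnzero(table$matrix))

#' Extract the pair set of an association table
#'
#' @param table an [association_table()].
#' @return data.frame with character columns `row` and `col`, sorted by
#'   (row, col) for determinism.
#' @export
association_pairs <- function(table) {
  idx <- Matrix::which(table$matrix != 0, arr.ind = TRUE)
  out <- data.frame(row = table$row_index$ids[idx[, 1L]],
                    col = table$col_index$ids[idx[, 2L]],
                    stringsAsFactors = FALSE)
  out[order(out$row, out$col, method = "radix"), , drop = FALSE] ->
    out
  rownames(out) <- NULL
  out
}

#' Read an association table from a two-column TSV edge list
#'
#' The file is tab-separated with exactly two non-empty fields per data
#' row. Lines starting with `#` (comments or a header) and blank lines are
#' skipped. Duplicate rows collapse to one pair.
#'
#' @param path path to the file.
#' @param row_kind,col_kind entity kinds of the two columns.
#' @param comment_char prefix marking comment/header lines (default `"#"`).
#' @return an [association_table()].
#' @export
read_association_table <- function(path, row_kind, col_kind,
                                   comment_char = "#") {
  if (!file.exists(path)) {
    stop("input file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  is_data <- nzchar(trimws(lines)) &
    !startsWith(trimws(lines), comment_char)
  data_lines <- lines[is_data]
  line_no <- which(is_data)
  if (length(data_lines) == 0L) {
    return(association_table(NULL, row_kind, col_kind))
  }
  fields <- strsplit(data_lines, "\t", fixed = TRUE)
  fields <- lapply(fields, function(f) {
    f <- trimws(f)
    f[nzchar(f)]
  })
  bad <- which(vapply(fields, length, integer(1)) != 2L)
  if (length(bad) > 0L) {
    stop(sprintf(
      "malformed row at line %d of %s: expected 2 non-empty tab-separated fields",
      line_no[bad[1L]], path), call. = FALSE)
  }
  pairs <- data.frame(
    row = vapply(fields, `[`, character(1), 1L),
    col = vapply(fields, `[`, character(1), 2L),
    stringsAsFactors = FALSE
  )
  association_table(pairs, row_kind, col_kind)
}

#' Write an association table as a two-column TSV edge list
#'
#' Writes one `# row_kind<TAB>col_kind` header comment followed by the
#' sorted pair list; [read_association_table()] round-trips the pair set.
#'
#' @param table an [association_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_association_table <- function(table, path) {
  p <- association_pairs(table)
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("# %s\t%s", table$row_index$kind, table$col_index$kind),
             con)
  if (nrow(p) > 0L) writeLines(paste(p$row, p$col, sep = "\t"), con)
  invisible(path)
}

#' Derive disease-drug associations through shared target proteins
#'
#' A disease and a drug are linked when they share at least one protein:
#' the result is the boolean product of the disease-protein and
#' drug-protein binary matrices over their common protein universe. This
#' is how new disease-drug associations are computed for the drug-based
#' disease network when direct curation is sparse.
#'
#' @param disease_protein disease x protein [association_table()].
#' @param drug_protein drug x protein [association_table()].
#' @return disease x drug [association_table()] whose row universe is the
#'   diseases of `disease_protein` and column universe the drugs of
#'   `drug_protein`.
#' @export
derive_disease_drug_via_protein <- function(disease_protein, drug_protein) {
  stopifnot(inherits(disease_protein, "association_table"),
            inherits(drug_protein, "association_table"))
  if (disease_protein$col_index$kind != "protein" ||
      drug_protein$col_index$kind != "protein") {
    stop("both tables must have protein columns", call. = FALSE)
  }
  common <- intersect(disease_protein$col_index$ids, drug_protein$col_index$ids)
  dis_ids <- disease_protein$row_index$ids
  drug_ids <- drug_protein$row_index$ids
  if (length(common) == 0L) {
    warning("no proteins shared between the two tables; derived table is empty")
    return(association_table(NULL, "disease", "drug",
                             row_ids = dis_ids, col_ids = drug_ids))
  }
  prod <- Matrix::tcrossprod(disease_protein$matrix[, common, drop = FALSE],
                             drug_protein$matrix[, common, drop = FALSE])
  idx <- Matrix::which(prod != 0, arr.ind = TRUE)
  pairs <- data.frame(row = dis_ids[idx[, 1L]], col = drug_ids[idx[, 2L]],
                      stringsAsFactors = FALSE)
  association_table(pairs, "disease", "drug",
                    row_ids = dis_ids, col_ids = drug_ids)
}

#' Merge two association tables of identical kinds (pair-set union)
#'
#' Used to combine directly curated disease-drug pairs with the
#' protein-derived ones.
#'
#' @param a,b [association_table()] objects over the same entity kinds.
#' @return an [association_table()] holding the union of both pair sets,
#'   over the union of both universes.
#' @export
merge_association_tables <- function(a, b) {
  if (a$row_index$kind != b$row_index$kind ||
      a$col_index$kind != b$col_index$kind) {
    stop("tables to merge must have matching entity kinds", call. = FALSE)
  }
  pairs <- rbind(association_pairs(a), association_pairs(b))
  association_table(pairs, a$row_index$kind, a$col_index$kind,
                    row_ids = union(a$row_index$ids, b$row_index$ids),
                    col_ids = union(a$col_index$ids, b$col_index$ids))
}

#' Restrict two disease tables to diseases covered by both
#'
#' Keeps exactly the diseases having at least one protein association and
#' at least one drug association, so that both returned tables share one
#' identical disease universe. Column entities left without any association
#' are pruned. Idempotent.
#'
#' @param disease_protein disease x protein [association_table()].
#' @param disease_drug disease x drug [association_table()].
#' @return list with elements `disease_protein` and `disease_drug`, both
#'   with the same disease `row_index`.
#' @export
restrict_to_common_diseases <- function(disease_protein, disease_drug) {
  stopifnot(disease_protein$row_index$kind == "disease",
            disease_drug$row_index$kind == "disease")
  with_p <- disease_protein$row_index$ids[
    Matrix::rowSums(disease_protein$matrix) > 0]
  with_d <- disease_drug$row_index$ids[
    Matrix::rowSums(disease_drug$matrix) > 0]
  common <- sort(intersect(with_p, with_d), method = "radix")
  if (length(common) == 0L) {
    stop("no disease has both protein and drug associations; ",
         "the pipeline cannot proceed", call. = FALSE)
  }
  prune <- function(table) {
    m <- table$matrix[common, , drop = FALSE]
    keep_col <- Matrix::colSums(m) > 0
    m <- m[, keep_col, drop = FALSE]
    idx <- Matrix::which(m != 0, arr.ind = TRUE)
    pairs <- data.frame(row = rownames(m)[idx[, 1L]],
                        col = colnames(m)[idx[, 2L]],
                        stringsAsFactors = FALSE)
    association_table(pairs, "disease", table$col_index$kind,
                      row_ids = common, col_ids = colnames(m))
  }
  list(disease_protein = prune(disease_protein),
       disease_drug = prune(disease_drug))
}

#' Write a JSON manifest of entity and pair counts
#'
#' @param tables named list of [association_table()] objects.
#' @param path output path for the JSON manifest.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(tables, path) {
  manifest <- lapply(tables, function(t) {
    list(rows = length(t$row_index), row_kind = t$row_index$kind,
         cols = length(t$col_index), col_kind = t$col_index$kind,
         pairs = n_pairs(t))
  })
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
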