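#' Tanimoto similarity of two binary profiles
#'
#' `sum(u*v) / (sum(u) + sum(v) - sum(u*v))` -- the size of the
#' intersection over the size of the union of the two supports. Defined as
#' 0 when both vectors are all-zero (no shared evidence).
#'
#' @param u,v binary (0/1) vectors of equal length.
#' @return similarity in `[0, 1]`, symmetric in its arguments.
#' @export
tanimoto_similarity <- function(u, v) {
  if (length(u) != length(v)) {
    stop("vectors must have equal length", call. = FALSE)
  }
  if (!all(u %in% c(0, 1)) || !all(v %in% c(0, 1))) {
    stop("vectors must be binary (0/1)", call. = FALSE)
  }
  inter <- sum(u * v)
  uni <- sum(u) + sum(v) - inter
  if (uni == 0) return(0)
  inter / uni
}

#' Construct a disease network object from a weight matrix
#'
#' Low-level constructor, mainly useful for tests and for feeding
#' externally computed similarity matrices into the prioritisation and SSL
#' stages. [build_disease_network()] is the standard route from association
#' tables.
#'
#' @param weights symmetric numeric matrix with entries in `[0, 1]`;
#'   rownames (or `ids`) give the disease identifiers.
#' @param ids disease identifiers; defaults to `rownames(weights)`.
#' @param source one of `"protein"`, `"drug"` -- which kind of profile the
#'   weights were computed from.
#' @return an object of class `disease_network` with elements `diseases`
#'   ([entity_index()]), `weights` (dense matrix, diagonal as supplied) and
#'   `source`.
#' @export
disease_network <- function(weights, ids = rownames(weights),
                            source = c("protein", "drug")) {
  source <- match.arg(source)
  weights <- as.matrix(weights)
  if (is.null(ids)) stop("disease ids are required", call. = FALSE)
  stopifnot(nrow(weights) == ncol(weights), length(ids) == nrow(weights))
  if (max(abs(weights - t(weights))) > 1e-12) {
    stop("weight matrix must be symmetric", call. = FALSE)
  }
  if (min(weights) < 0 || max(weights) > 1) {
    stop("weights must lie in [0, 1]", call. = FALSE)
  }
  dimnames(weights) <- list(ids, ids)
  structure(list(diseases = entity_index(ids, "disease", sort_ids = FALSE),
                 weights = weights, source = source),
            class = "disease_network")
}

#' Build a disease network from binary association profiles
#'
#' Every off-diagonal weight is the Tanimoto similarity of the two
#' diseases' binary profile rows; the weight grows with the number of
#' shared proteins (or drugs), holding profile sizes fixed. The diagonal is
#' set to `self_weight` (0 by default: a disease's own-row mass would
#' otherwise dominate the exponential row normalisation used downstream).
#'
#' @param table disease-row [association_table()] (protein or drug columns).
#' @param self_weight diagonal value, default 0.
#' @return a [disease_network()] whose `source` is the column kind of
#'   `table`.
#' @export
build_disease_network <- function(table, self_weight = 0) {
  stopifnot(inherits(table, "association_table"),
            table$row_index$kind == "disease")
  n <- length(table$row_index)
  if (n < 2L) {
    stop("at least two diseases are required to build a network",
         call. = FALSE)
  }
  m <- table$matrix
  inter <- as.matrix(Matrix::tcrossprod(m))
  sizes <- Matrix::rowSums(m)
  uni <- outer(sizes, sizes, "+") - inter
  w <- matrix(0, n, n)
  pos <- uni > 0
  w[pos] <- inter[pos] / uni[pos]
  diag(w) <- self_weight
  disease_network(w, ids = table$row_index$ids,
                  source = table$col_index$kind)
}

#' @export
print.disease_network <- function(x, ...) {
  n <- length(x$diseases)
  off <- x$weights
  diag(off) <- 0
  cat(sprintf("<disease_network> %s-based, %d diseases, %d weighted edges\n",
              x$source, n, sum(off[upper.tri(off)] > 0)))
  invisible(x)
}

#' Export a disease network as a weighted edge-list TSV
#'
#' Writes the nonzero upper-triangle edges as
#' `disease_i<TAB>disease_j<TAB>weight`, weights at 10 significant digits.
#'
#' @param network a [disease_network()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_disease_network <- function(network, path) {
  w <- network$weights
  ids <- network$diseases$ids
  ut <- upper.tri(w)
  keep <- ut & w > 0
  idx <- which(keep, arr.ind = TRUE)
  ord <- order(idx[, 1L], idx[, 2L])
  idx <- idx[ord, , drop = FALSE]
  lines <- sprintf("%s\t%s\t%s", ids[idx[, 1L]], ids[idx[, 2L]],
                   formatC(w[keep][ord], digits = 10, format = "g"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("# disease_i\tdisease_j\tweight", con)
  if (length(lines) > 0L) writeLines(lines, con)
  invisible(path)
}
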