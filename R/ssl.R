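#' Reusable solver for graph-based semi-supervised learning
#'
#' The SSL scores solve `(I + mu * L) f = y`, where `L` is the graph
#' Laplacian of the disease network and `y` a one-hot label vector --
#' equivalently, f minimises `sum((f - y)^2) + mu * t(f) %*% L %*% f`.
#' `I + mu*L` is symmetric positive definite, so one Cholesky factorisation
#' is computed here and reused across any number of label vectors (only `y`
#' changes between candidate diseases); results are identical to
#' independent solves.
#'
#' @param network a [disease_network()] (PrDN for the repositioning
#'   pipeline).
#' @param mu regularisation strength, `> 0`; larger values diffuse the
#'   label further along strong edges.
#' @param laplacian `"combinatorial"` (`D - W`, default) or `"normalized"`
#'   (`I - D^{-1/2} W D^{-1/2}`, isolated nodes contributing zero rows).
#' @return an object of class `ssl_solver` with a `solve(y)` function
#'   accepting a vector or a matrix of label columns.
#' @export
ssl_solver <- function(network, mu = 1,
                       laplacian = c("combinatorial", "normalized")) {
  stopifnot(inherits(network, "disease_network"))
  laplacian <- match.arg(laplacian)
  if (!is.numeric(mu) || length(mu) != 1L || mu <= 0) {
    stop("mu must be a positive scalar", call. = FALSE)
  }
  w <- network$weights
  diag(w) <- 0
  deg <- rowSums(w)
  n <- nrow(w)
  if (laplacian == "combinatorial") {
    lap <- -w
    diag(lap) <- deg
  } else {
    dinv <- ifelse(deg > 0, 1 / sqrt(deg), 0)
    lap <- -(dinv %o% dinv) * w
    diag(lap) <- as.numeric(deg > 0)
  }
  a <- diag(n) + mu * lap
  r <- chol(a)
  solve_fun <- function(y) {
    backsolve(r, backsolve(r, y, transpose = TRUE))
  }
  structure(list(solve = solve_fun, diseases = network$diseases, mu = mu,
                 laplacian = laplacian),
            class = "ssl_solver")
}

#' Wrap precomputed SSL scores
#'
#' Constructor for an `ssl_scores` object from an externally supplied named
#' score vector -- e.g. the worked toy where the five unlabeled diseases
#' score (0.6, 0.2, 0.9, 0.3, 0.1).
#'
#' @param f named numeric vector of scores for all diseases, each in
#'   `[0, 1]`; if the labeled disease is absent from `f` it is added with
#'   score 1.
#' @param labeled_disease id of the label-1 disease.
#' @param mu regularisation strength the scores were computed with
#'   (metadata only here).
#' @return an object of class `ssl_scores`.
#' @export
ssl_scores <- function(f, labeled_disease, mu = 1) {
  if (is.null(names(f)) || !all(nzchar(names(f)))) {
    stop("scores must be a named vector", call. = FALSE)
  }
  if (!labeled_disease %in% names(f)) {
    f <- c(stats::setNames(1, labeled_disease), f)
  }
  if (min(f) < -1e-10 || max(f) > 1 + 1e-10) {
    stop("f-scores must lie in [0, 1]", call. = FALSE)
  }
  structure(list(diseases = entity_index(names(f), "disease",
                                         sort_ids = FALSE),
                 labeled_disease = labeled_disease,
                 f = f, mu = mu),
            class = "ssl_scores")
}

#' Graph-SSL scores of all diseases against one labeled disease
#'
#' The candidate disease is labeled 1, all others 0, and the smoothed
#' scores `f = (I + mu*L)^{-1} y` are returned for every disease. Scores
#' lie in `[0, 1]` (since `(I + mu*L) 1 = 1` for the combinatorial
#' Laplacian), the labeled disease attains the maximum, stronger
#' connections to the labeled disease yield higher scores, and diseases in
#' components disconnected from the label score exactly 0.
#'
#' @param network a [disease_network()].
#' @param labeled_disease disease id to label 1.
#' @param mu regularisation strength, `> 0` (default 1).
#' @param solver optional [ssl_solver()] built on `network` with the same
#'   `mu`, to reuse its factorisation across candidates.
#' @param laplacian passed to [ssl_solver()] when none is supplied.
#' @return an [ssl_scores()] object.
#' @export
ssl_f_scores <- function(network, labeled_disease, mu = 1, solver = NULL,
                         laplacian = c("combinatorial", "normalized")) {
  if (is.null(solver)) {
    solver <- ssl_solver(network, mu = mu, laplacian = match.arg(laplacian))
  }
  ids <- solver$diseases$ids
  if (!labeled_disease %in% ids) {
    stop("labeled disease not in the network: ", labeled_disease,
         call. = FALSE)
  }
  y <- as.numeric(ids == labeled_disease)
  f <- as.vector(solver$solve(y))
  names(f) <- ids
  ssl_scores(f, labeled_disease, mu = solver$mu)
}

#' @export
print.ssl_scores <- function(x, ...) {
  cat(sprintf("<ssl_scores> labeled %s (mu = %g), %d diseases\n",
              x$labeled_disease, x$mu, length(x$f)))
  invisible(x)
}

#' Select similar diseases (top delta percent by SSL score)
#'
#' Takes the top `ceiling(delta/100 * (N - 1))` *unlabeled* diseases by
#' descending score; the labeled disease itself is excluded and ties break
#' by ascending disease id.
#'
#' @param scores an [ssl_scores()] object.
#' @param delta percentage in `(0, 100]`.
#' @return character vector of similar disease ids in descending score
#'   order.
#' @export
select_similar_diseases <- function(scores, delta) {
  stopifnot(inherits(scores, "ssl_scores"))
  if (!is.numeric(delta) || length(delta) != 1L || delta <= 0 || delta > 100) {
    stop("delta must be a percentage in (0, 100]", call. = FALSE)
  }
  f <- scores$f
  unlabeled <- setdiff(names(f), scores$labeled_disease)
  n_sel <- ceiling(delta / 100 * length(unlabeled))
  ord <- order(-f[unlabeled], unlabeled, method = "radix")
  unlabeled[ord][seq_len(n_sel)]
}
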