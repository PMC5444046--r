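#' Probability profile constructor
#'
#' Low-level constructor wrapping a row-stochastic matrix: row i is disease
#' i's probability distribution over its comparison set (all other diseases
#' under the default exclude-self convention). Mainly useful for tests and
#' for feeding externally computed distributions into
#' [kl_divergence_per_disease()].
#'
#' @param probs numeric matrix, rows summing to 1 over the comparison set;
#'   with `include_self = FALSE` the diagonal must be 0 and all off-diagonal
#'   entries strictly positive.
#' @param ids disease identifiers; defaults to `rownames(probs)`.
#' @param include_self whether the comparison set includes the disease
#'   itself.
#' @return an object of class `probability_profile`.
#' @export
probability_profile <- function(probs, ids = rownames(probs),
                                include_self = FALSE) {
  probs <- as.matrix(probs)
  if (is.null(ids)) stop("disease ids are required", call. = FALSE)
  stopifnot(nrow(probs) == ncol(probs), length(ids) == nrow(probs))
  if (!include_self && any(diag(probs) != 0)) {
    stop("diagonal must be zero under the exclude-self convention",
         call. = FALSE)
  }
  off <- probs
  if (!include_self) diag(off) <- NA
  if (any(off[!is.na(off)] <= 0)) {
    stop("comparison-set probabilities must be strictly positive",
         call. = FALSE)
  }
  if (max(abs(rowSums(probs) - 1)) > 1e-9) {
    stop("every row must sum to 1 (within 1e-9)", call. = FALSE)
  }
  dimnames(probs) <- list(ids, ids)
  structure(list(diseases = entity_index(ids, "disease", sort_ids = FALSE),
                 probs = probs, include_self = include_self),
            class = "probability_profile")
}

#' Convert a disease network to per-disease probability distributions
#'
#' Each weight row is passed through an exponential transform and
#' normalised: `p_ij = exp(w_ij) / sum_k exp(w_ik)` over disease i's
#' comparison set. The exponential maps absent edges (weight 0) to
#' `exp(0) = 1`, so every probability is strictly positive -- this is what
#' makes the KL divergence well defined on sparse networks and must not be
#' replaced by plain weight normalisation. An isolated disease (all weights
#' 0) yields the uniform distribution.
#'
#' @param network a [disease_network()].
#' @param include_self include the disease itself in its comparison set
#'   (default `FALSE`: distributions are over the other diseases).
#' @return a [probability_profile()].
#' @export
to_probability_profile <- function(network, include_self = FALSE) {
  stopifnot(inherits(network, "disease_network"))
  w <- network$weights
  if (any(!is.finite(w)) || min(w) < 0 || max(w) > 1) {
    stop("network weights must be finite and in [0, 1]", call. = FALSE)
  }
  e <- exp(w)
  if (!include_self) diag(e) <- 0
  p <- e / rowSums(e)
  probability_profile(p, ids = network$diseases$ids,
                      include_self = include_self)
}

#' Per-disease Kullback-Leibler divergence ranking
#'
#' For each disease i, `KL_i = sum_j p_ij * ln(p_ij / q_ij)` over the
#' comparison set, where `p` comes from the protein-based network (PrDN)
#' and `q` from the drug-based network (DrDN) -- the divergence of the
#' molecular-similarity neighbourhood from the treatment neighbourhood, in
#' nats. The direction matters: KL is not symmetric, and the repositioning
#' rationale fixes P = PrDN, Q = DrDN. `KL_i >= 0`, with equality iff the
#' two rows are identical. Ties in the ranking break by ascending disease
#' id.
#'
#' @param p [probability_profile()] from the protein-based network.
#' @param q [probability_profile()] from the drug-based network.
#' @return an object of class `kl_ranking`: a data.frame with columns
#'   `disease`, `kl`, `rank` (1 = largest divergence), `tier`
#'   (`NA` until [assign_tiers()]) and `is_candidate` (`FALSE` until
#'   selection), sorted by rank.
#' @export
kl_divergence_per_disease <- function(p, q) {
  stopifnot(inherits(p, "probability_profile"),
            inherits(q, "probability_profile"))
  if (!identical(p$diseases$ids, q$diseases$ids)) {
    stop("profiles are not aligned: disease indexes differ", call. = FALSE)
  }
  if (!identical(p$include_self, q$include_self)) {
    stop("profiles use different comparison-set conventions", call. = FALSE)
  }
  pp <- p$probs
  qq <- q$probs
  s <- pp * log(pp / qq)
  s[pp == 0] <- 0  # excluded self entries: 0 * log(0/0) contributes nothing
  kl <- rowSums(s)
  ids <- p$diseases$ids
  ord <- order(-kl, ids, method = "radix")
  rank <- integer(length(kl))
  rank[ord] <- seq_along(kl)
  out <- data.frame(disease = ids, kl = kl, rank = rank,
                    tier = NA_integer_, is_candidate = FALSE,
                    stringsAsFactors = FALSE)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("kl_ranking", "data.frame"))
}

#' Assign KL-rank tiers
#'
#' Partitions the ranking into `n_tiers` contiguous rank blocks of sizes
#' differing by at most one (the first `N %% n_tiers` tiers take the extra
#' member); tier 1 holds the largest divergences.
#'
#' @param ranking a [kl_divergence_per_disease()] result.
#' @param n_tiers number of tiers (default 5, i.e. 20\% blocks).
#' @return the ranking with its `tier` column filled.
#' @export
assign_tiers <- function(ranking, n_tiers = 5L) {
  stopifnot(inherits(ranking, "kl_ranking"))
  n <- nrow(ranking)
  if (n_tiers < 1L || n_tiers > n) {
    stop("n_tiers must be between 1 and the number of diseases",
         call. = FALSE)
  }
  base <- n %/% n_tiers
  extra <- n %% n_tiers
  sizes <- base + as.integer(seq_len(n_tiers) <= extra)
  tier_by_rank <- rep(seq_len(n_tiers), times = sizes)
  ranking$tier <- tier_by_rank[ranking$rank]
  ranking
}

#' Select candidate diseases (top sigma percent by KL divergence)
#'
#' @param ranking a [kl_divergence_per_disease()] result.
#' @param sigma percentage in `(0, 100]`; `ceiling(sigma/100 * N)` diseases
#'   are selected.
#' @return character vector of candidate disease ids in descending KL order
#'   (ties by ascending id).
#' @export
select_candidates <- function(ranking, sigma) {
  stopifnot(inherits(ranking, "kl_ranking"))
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0 || sigma > 100) {
    stop("sigma must be a percentage in (0, 100]", call. = FALSE)
  }
  n_sel <- ceiling(sigma / 100 * nrow(ranking))
  ranking$disease[ranking$rank <= n_sel][
    order(ranking$rank[ranking$rank <= n_sel])]
}
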