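#' Candidate drugs for a candidate disease
#'
#' The candidate drug set is the union of the drug profiles of the similar
#' diseases: every drug used by any similar disease is proposed for the
#' candidate.
#'
#' @param candidate candidate disease id (must not appear among `similar`).
#' @param similar character vector of similar disease ids.
#' @param disease_drug disease x drug [association_table()].
#' @return sorted character vector of drug ids (empty if `similar` is
#'   empty).
#' @export
candidate_drugs <- function(candidate, similar, disease_drug) {
  stopifnot(inherits(disease_drug, "association_table"))
  if (candidate %in% similar) {
    stop("candidate disease must not appear among its similar diseases",
         call. = FALSE)
  }
  if (length(similar) == 0L) return(character())
  missing <- setdiff(similar, disease_drug$row_index$ids)
  if (length(missing) > 0L) {
    stop("similar disease(s) absent from the disease-drug table: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  m <- disease_drug$matrix[similar, , drop = FALSE]
  sort(colnames(m)[Matrix::colSums(m) > 0], method = "radix")
}

#' Run the full network-mirroring repositioning pipeline
#'
#' Four stages, fully deterministic given inputs and parameters:
#' (1) restrict both tables to diseases with at least one protein and one
#' drug and build PrDN / DrDN by Tanimoto similarity; (2) rank diseases by
#' the per-disease KL divergence of their PrDN neighbour distribution from
#' their DrDN one and keep the top `sigma` percent as candidates;
#' (3) for each candidate, score all other diseases on PrDN by graph-SSL
#' (one shared factorisation) and keep the top `delta` percent as similar
#' diseases; (4) propose the union of the similar diseases' drugs for the
#' candidate. Drugs already associated with the candidate are kept and
#' flagged `known_covered` rather than dropped; the remainder are
#' `novel_drugs`.
#'
#' @param disease_protein disease x protein [association_table()].
#' @param disease_drug disease x drug [association_table()].
#' @param sigma candidate-disease percentage in `(0, 100]` (default 20).
#' @param delta similar-disease percentage in `(0, 100]` (default 20).
#' @param mu SSL regularisation strength (default 1).
#' @param n_tiers number of KL-rank tiers recorded on the ranking
#'   (default 5).
#' @return an object of class `network_mirroring`: list with `ranking`
#'   (tiered [kl_divergence_per_disease()] result with `is_candidate`
#'   filled), `results` (one `repositioning_result` per candidate, in KL
#'   rank order), `networks` (`prdn`, `drdn`) and `params`. Each
#'   `repositioning_result` carries `candidate_disease`, `kl`, `rank`,
#'   `f` (full named score vector), `similar_diseases` (named f-scores,
#'   selection order), `candidate_drugs`, `novel_drugs`, `known_covered`.
#' @export
run_network_mirroring <- function(disease_protein, disease_drug,
                                  sigma = 20, delta = 20, mu = 1,
                                  n_tiers = 5L) {
  restricted <- restrict_to_common_diseases(disease_protein, disease_drug)
  prdn <- build_disease_network(restricted$disease_protein)
  drdn <- build_disease_network(restricted$disease_drug)
  ranking <- kl_divergence_per_disease(to_probability_profile(prdn),
                                       to_probability_profile(drdn))
  ranking <- assign_tiers(ranking, n_tiers)
  cands <- select_candidates(ranking, sigma)
  ranking$is_candidate <- ranking$disease %in% cands

  solver <- ssl_solver(prdn, mu = mu)
  dd <- restricted$disease_drug
  results <- lapply(cands, function(d) {
    scores <- ssl_f_scores(prdn, d, solver = solver)
    similar <- select_similar_diseases(scores, delta)
    drugs <- candidate_drugs(d, similar, dd)
    known <- colnames(dd$matrix)[dd$matrix[d, ] > 0]
    structure(list(
      candidate_disease = d,
      kl = ranking$kl[ranking$disease == d],
      rank = ranking$rank[ranking$disease == d],
      f = scores$f,
      similar_diseases = scores$f[similar],
      candidate_drugs = drugs,
      novel_drugs = setdiff(drugs, known),
      known_covered = intersect(drugs, known)
    ), class = "repositioning_result")
  })
  structure(list(ranking = ranking, results = results,
                 networks = list(prdn = prdn, drdn = drdn),
                 params = list(sigma = sigma, delta = delta, mu = mu,
                               n_tiers = n_tiers)),
            class = "network_mirroring")
}

#' @export
print.network_mirroring <- function(x, ...) {
  cat(sprintf(
    "<network_mirroring> %d diseases, %d candidates (sigma = %g, delta = %g, mu = %g)\n",
    nrow(x$ranking), length(x$results), x$params$sigma, x$params$delta,
    x$params$mu))
  invisible(x)
}

#' @export
print.repositioning_result <- function(x, ...) {
  cat(sprintf(
    "<repositioning_result> %s (KL = %.4g, rank %d): %d similar disease(s), %d candidate drug(s) (%d novel)\n",
    x$candidate_disease, x$kl, x$rank, length(x$similar_diseases),
    length(x$candidate_drugs), length(x$novel_drugs)))
  invisible(x)
}

#' Write a KL ranking as TSV
#'
#' Columns: `disease_id`, `kl`, `rank`, `tier`, `is_candidate`.
#'
#' @param ranking a `kl_ranking`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ranking <- function(ranking, path) {
  out <- data.frame(disease_id = ranking$disease,
                    kl = formatC(ranking$kl, digits = 10, format = "g"),
                    rank = ranking$rank, tier = ranking$tier,
                    is_candidate = ranking$is_candidate)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write per-candidate SSL f-scores as TSV
#'
#' Columns: `candidate_id`, `disease_id`, `f`, `selected`.
#'
#' @param run a [run_network_mirroring()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fscores <- function(run, path) {
  rows <- lapply(run$results, function(res) {
    others <- setdiff(names(res$f), res$candidate_disease)
    data.frame(candidate_id = res$candidate_disease,
               disease_id = others,
               f = formatC(res$f[others], digits = 10, format = "g"),
               selected = others %in% names(res$similar_diseases))
  })
  out <- do.call(rbind, rows)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write repositioning results as JSON
#'
#' One record per candidate disease: its KL score and rank, the similar
#' diseases with their f-scores, and the candidate / novel / known-covered
#' drug sets.
#'
#' @param run a [run_network_mirroring()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_repositioning_json <- function(run, path) {
  records <- lapply(run$results, function(res) {
    list(candidate_disease = res$candidate_disease,
         kl = res$kl,
         rank = res$rank,
         similar_diseases = lapply(seq_along(res$similar_diseases),
                                   function(i) list(
                                     disease = names(res$similar_diseases)[i],
                                     f = unname(res$similar_diseases[i]))),
         candidate_drugs = as.list(res$candidate_drugs),
         novel_drugs = as.list(res$novel_drugs),
         known_covered = as.list(res$known_covered))
  })
  jsonlite::write_json(list(params = run$params, results = records), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
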