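#' Precision, recall and F-measure from confusion counts
#'
#' `precision = tp/(tp+fp)`, `recall = tp/(tp+fn)`,
#' `f = 2*p*r/(p+r)` -- with the convention that any zero-denominator
#' quantity is 0.
#'
#' @param tp,fp,fn nonnegative counts (vectorised).
#' @param quiet suppress the zero-denominator warning (used by the
#'   cross-validation loops).
#' @return data.frame with columns `precision`, `recall`, `f_measure`.
#' @export
f_measure <- function(tp, fp, fn, quiet = FALSE) {
  stopifnot(all(tp >= 0), all(fp >= 0), all(fn >= 0))
  precision <- ifelse(tp + fp > 0, tp / (tp + fp), 0)
  recall <- ifelse(tp + fn > 0, tp / (tp + fn), 0)
  f <- ifelse(precision + recall > 0,
              2 * precision * recall / (precision + recall), 0)
  if (!quiet && any(tp + fp == 0 | tp + fn == 0 | precision + recall == 0)) {
    warning("zero-denominator case(s): metric set to 0 by convention")
  }
  data.frame(precision = precision, recall = recall, f_measure = f)
}

#' Tiered repeated k-fold cross-validation of drug repositioning
#'
#' The validation design for the pipeline. The disease-drug association *pairs*
#' are partitioned into `k` near-equal folds by a seeded shuffle, `repeats`
#' times. Tier membership and the SSL similar-disease sets depend only on
#' the full data (the KL ranking is computed once on the complete networks;
#' PrDN never changes), so per fold only the drug profiles `Drug(.)` are
#' rebuilt from the training pairs: each disease's prediction is the union
#' of its similar diseases' *training* drugs.
#'
#' Per candidate disease the prediction universe is the full drug index:
#' TP = predicted drugs that are known associations of the disease
#' (training or held-out -- covering an existing drug counts as success,
#' mirroring the dementia-style accounting); FN = held-out drugs not
#' predicted; FP = predicted drugs never associated with the disease;
#' TN = the remainder. Metrics are macro-averaged over the diseases of a
#' tier, then averaged over folds and repeats (`average = "micro"` instead
#' pools counts within a tier before computing metrics). Predictions are
#' evaluated for *every* disease so each tier is measured; `sigma` is
#' recorded with the run and flags the candidates on the returned ranking.
#'
#' @param disease_protein disease x protein [association_table()].
#' @param disease_drug disease x drug [association_table()].
#' @param k number of folds (default 10).
#' @param repeats number of repetitions (default 10).
#' @param sigma candidate percentage recorded with the run (default 20).
#' @param delta similar-disease percentage (default 20).
#' @param mu SSL regularisation strength (default 1).
#' @param seed RNG seed for the fold shuffles.
#' @param n_tiers number of KL tiers (default 5).
#' @param average `"macro"` (per-disease metrics averaged; default) or
#'   `"micro"` (counts pooled within tier).
#' @return an object of class `evaluation_report`: list with `per_tier`
#'   (tier, precision, recall, f_measure, n_diseases), `overall` (same
#'   metrics over all diseases -- the greedy-reference aggregate),
#'   `folds` (per repeat x fold x tier metric rows), `ranking`, `params`
#'   and `n_dropped_disease_folds` (disease-fold combinations whose
#'   training drug profile was empty).
#' @export
cross_validate <- function(disease_protein, disease_drug, k = 10L,
                           repeats = 10L, sigma = 20, delta = 20, mu = 1,
                           seed = 1L, n_tiers = 5L,
                           average = c("macro", "micro")) {
  average <- match.arg(average)
  if (k < 2L) stop("k must be at least 2", call. = FALSE)
  restricted <- restrict_to_common_diseases(disease_protein, disease_drug)
  prdn <- build_disease_network(restricted$disease_protein)
  drdn <- build_disease_network(restricted$disease_drug)
  ranking <- assign_tiers(
    kl_divergence_per_disease(to_probability_profile(prdn),
                              to_probability_profile(drdn)), n_tiers)
  ranking$is_candidate <- ranking$disease %in% select_candidates(ranking, sigma)

  ids <- prdn$diseases$ids
  n <- length(ids)
  drug_ids <- restricted$disease_drug$col_index$ids
  n_drugs <- length(drug_ids)
  tier_of <- ranking$tier[match(ids, ranking$disease)]

  # SSL similar sets depend only on PrDN: one factorisation, all labels.
  solver <- ssl_solver(prdn, mu = mu)
  fmat <- solver$solve(diag(n))  # column j = scores when disease j is labeled
  n_sim <- ceiling(delta / 100 * (n - 1L))
  similar_idx <- lapply(seq_len(n), function(j) {
    others <- setdiff(seq_len(n), j)
    ord <- order(-fmat[others, j], ids[others], method = "radix")
    others[ord][seq_len(n_sim)]
  })

  pr <- association_pairs(restricted$disease_drug)
  pair_i <- match(pr$row, ids)
  pair_j <- match(pr$col, drug_ids)
  np <- length(pair_i)
  if (np < k) stop("fewer association pairs than folds", call. = FALSE)
  known <- lapply(seq_len(n), function(i) pair_j[pair_i == i])

  fold_rows <- list()
  n_dropped <- 0L
  with_seed(seed, {
    for (r in seq_len(repeats)) {
      fold_of <- sample(rep_len(seq_len(k), np))
      for (f in seq_len(k)) {
        train <- fold_of != f
        train_drugs <- lapply(seq_len(n), function(i) {
          pair_j[train & pair_i == i]
        })
        n_dropped <- n_dropped +
          sum(vapply(train_drugs, length, integer(1)) == 0L)
        tp <- fp <- fn <- integer(n)
        for (i in seq_len(n)) {
          pred <- unique(unlist(train_drugs[similar_idx[[i]]],
                                use.names = FALSE))
          held <- pair_j[!train & pair_i == i]
          tp[i] <- sum(pred %in% known[[i]])
          fp[i] <- length(pred) - tp[i]
          fn[i] <- sum(!held %in% pred)
        }
        tn <- n_drugs - tp - fp - fn
        for (t in seq_len(n_tiers)) {
          in_t <- tier_of == t
          if (average == "macro") {
            m <- f_measure(tp[in_t], fp[in_t], fn[in_t], quiet = TRUE)
            row <- colMeans(m)
          } else {
            row <- unlist(f_measure(sum(tp[in_t]), sum(fp[in_t]),
                                    sum(fn[in_t]), quiet = TRUE))
          }
          fold_rows[[length(fold_rows) + 1L]] <- data.frame(
            repeat_ = r, fold = f, tier = t,
            precision = row[["precision"]], recall = row[["recall"]],
            f_measure = row[["f_measure"]],
            tp = sum(tp[in_t]), fp = sum(fp[in_t]), fn = sum(fn[in_t]),
            tn = sum(tn[in_t]), n_diseases = sum(in_t))
        }
        ov <- if (average == "macro") {
          colMeans(f_measure(tp, fp, fn, quiet = TRUE))
        } else {
          unlist(f_measure(sum(tp), sum(fp), sum(fn), quiet = TRUE))
        }
        fold_rows[[length(fold_rows) + 1L]] <- data.frame(
          repeat_ = r, fold = f, tier = NA_integer_,
          precision = ov[["precision"]], recall = ov[["recall"]],
          f_measure = ov[["f_measure"]],
          tp = sum(tp), fp = sum(fp), fn = sum(fn), tn = sum(tn),
          n_diseases = n)
      }
    }
  })
  folds <- do.call(rbind, fold_rows)

  agg <- function(sub) {
    data.frame(precision = mean(sub$precision), recall = mean(sub$recall),
               f_measure = mean(sub$f_measure),
               n_diseases = sub$n_diseases[1L])
  }
  per_tier <- do.call(rbind, lapply(seq_len(n_tiers), function(t) {
    cbind(tier = t, agg(folds[!is.na(folds$tier) & folds$tier == t, ]))
  }))
  overall <- agg(folds[is.na(folds$tier), ])
  structure(list(per_tier = per_tier, overall = overall, folds = folds,
                 ranking = ranking,
                 params = list(sigma = sigma, delta = delta, mu = mu,
                               k = k, repeats = repeats, seed = seed,
                               n_tiers = n_tiers, average = average),
                 n_dropped_disease_folds = n_dropped),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> %dx%d-fold CV (%s average)\n",
              x$params$repeats, x$params$k, x$params$average))
  print(x$per_tier, row.names = FALSE)
  cat(sprintf("overall (greedy reference): F = %.4f\n",
              x$overall$f_measure))
  invisible(x)
}

#' Greedy whole-disease-set reference experiment
#'
#' Identical cross-validation protocol, but every disease is treated as a
#' candidate (no KL prioritisation, i.e. sigma = 100): the returned metrics
#' are the macro aggregate over all diseases.
#'
#' @inheritParams cross_validate
#' @return data.frame with `precision`, `recall`, `f_measure` and
#'   `n_diseases`; the full [cross_validate()] report is attached as
#'   attribute `"report"`.
#' @export
greedy_reference <- function(disease_protein, disease_drug, delta = 20,
                             mu = 1, k = 10L, repeats = 10L, seed = 1L,
                             average = c("macro", "micro")) {
  report <- cross_validate(disease_protein, disease_drug, k = k,
                           repeats = repeats, sigma = 100, delta = delta,
                           mu = mu, seed = seed,
                           average = match.arg(average))
  out <- report$overall
  attr(out, "report") <- report
  out
}

#' Write a per-tier evaluation TSV
#'
#' @param report an [cross_validate()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_evaluation_tsv <- function(report, path) {
  utils::write.table(report$per_tier, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write an evaluation report as JSON
#'
#' @param report an [cross_validate()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_evaluation_json <- function(report, path) {
  jsonlite::write_json(
    list(params = report$params, per_tier = report$per_tier,
         overall = report$overall,
         n_dropped_disease_folds = report$n_dropped_disease_folds),
    path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}
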