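#' Specification for a synthetic tripartite association instance
#'
#' Describes a disease-protein-drug association universe with modular
#' structure and a planted repositioning signal. Diseases are grouped into
#' modules sharing a protein block; drugs target proteins of one block; the
#' baseline disease-drug table is protein-consistent (a disease can be
#' treated by a drug sharing one of its proteins), thinned to a realistic
#' treatment density. Per-disease *module coherence* -- the fraction of a
#' disease's protein picks that fall inside its own module block -- varies
#' across diseases, emulating heterogeneous molecular characterisation:
#' coherent diseases have informative protein neighbourhoods, incoherent
#' ones noisy ones. Planted diseases are fully coherent but have part of
#' their drug profile decoupled from their protein profile -- the
#' repositioning signal.
#'
#' @param n_diseases,n_proteins,n_drugs universe sizes (defaults
#'   200 / 1000 / 100, a desk-scale rendering of the tripartite structure).
#' @param protein_density per-block association probability in `(0, 1)`: a
#'   fully coherent disease links to each protein of its module block with
#'   this probability (default 0.6).
#' @param drug_density treatment coverage in `(0, 1)`: each disease keeps
#'   its protein-consistent drugs with a probability scaled so the expected
#'   treatment count is `drug_density` times the module drug-pool size
#'   (default 0.8 -- observed treatments closely track the
#'   protein-consistent associations); at least one drug per disease is
#'   always kept.
#' @param n_modules number of disease modules / protein blocks (default 10).
#' @param n_planted number of planted diseases (default 20).
#' @param decouple_mode `"permute_neighbors"` (replacement drugs all come
#'   from one donor module, so the planted disease's drug-network
#'   neighbours move to that module by construction) or `"resample"`
#'   (replacement drugs drawn uniformly from the non-consistent drugs).
#' @param decouple_frac fraction of a planted disease's observed drugs that
#'   are removed (default 0.55); half the removed count is replaced by
#'   decoupled drugs, leaving the disease under-treated relative to its
#'   protein profile and pointing elsewhere.
#' @param coherence_range lower and upper bound of the per-disease module
#'   coherence, drawn uniformly for non-planted diseases (default
#'   `c(0.05, 1)`); planted diseases are drawn from the top band of the
#'   range.
#' @param targets_per_drug proteins targeted by each drug, sampled from its
#'   module block (default 8).
#' @param seed RNG seed; all randomness of [generate_tripartite()] flows
#'   from it.
#' @return an object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_diseases = 200L, n_proteins = 1000L,
                           n_drugs = 100L, protein_density = 0.6,
                           drug_density = 0.8, n_modules = 10L,
                           n_planted = 20L,
                           decouple_mode = c("permute_neighbors", "resample"),
                           decouple_frac = 0.55,
                           coherence_range = c(0.05, 1),
                           targets_per_drug = 8L, seed = 1L) {
  decouple_mode <- match.arg(decouple_mode)
  stopifnot(n_diseases >= 2L, n_proteins >= n_modules, n_drugs >= n_modules,
            n_modules >= 2L, n_planted >= 0L, n_planted <= n_diseases,
            protein_density > 0, protein_density < 1,
            drug_density > 0, drug_density < 1,
            decouple_frac > 0, decouple_frac <= 1,
            length(coherence_range) == 2L,
            coherence_range[1] > 0, coherence_range[2] <= 1,
            coherence_range[1] <= coherence_range[2],
            targets_per_drug >= 1L)
  structure(list(n_diseases = as.integer(n_diseases),
                 n_proteins = as.integer(n_proteins),
                 n_drugs = as.integer(n_drugs),
                 protein_density = protein_density,
                 drug_density = drug_density,
                 n_modules = as.integer(n_modules),
                 n_planted = as.integer(n_planted),
                 decouple_mode = decouple_mode,
                 decouple_frac = decouple_frac,
                 coherence_range = coherence_range,
                 targets_per_drug = as.integer(targets_per_drug),
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# sample() without the scalar-x surprise
sample_ids <- function(x, size) x[sample.int(length(x), size)]

#' Generate a synthetic tripartite association instance
#'
#' Produces disease-protein, disease-drug and drug-protein association
#' tables according to a [synthetic_spec()], plus the ground truth of the
#' planted signal. Deterministic given the spec (including its seed); the
#' caller's RNG state is untouched. Every disease ends up with at least one
#' protein and one drug, matching the restriction applied to real data.
#'
#' @param spec a [synthetic_spec()].
#' @return list with elements `disease_protein`, `disease_drug`,
#'   `drug_protein` ([association_table()] objects over the full
#'   universes), `truth` (list: `planted_diseases`, `withheld_true_pairs` --
#'   the protein-consistent observed pairs removed from planted diseases,
#'   disjoint from the returned disease-drug pairs -- and `module_of`,
#'   `donor_module`, `coherence` diagnostics) and `spec`.
#' @export
generate_tripartite <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, {
    nd <- spec$n_diseases
    np <- spec$n_proteins
    nr <- spec$n_drugs
    nm <- spec$n_modules
    dis_ids <- sprintf("D%04d", seq_len(nd))
    prot_ids <- sprintf("P%05d", seq_len(np))
    drug_ids <- sprintf("R%04d", seq_len(nr))
    module_of_disease <- sort(rep_len(seq_len(nm), nd))
    block_of_protein <- sort(rep_len(seq_len(nm), np))
    module_of_drug <- sort(rep_len(seq_len(nm), nr))

    planted <- sort(sample_ids(dis_ids, spec$n_planted))
    is_planted <- dis_ids %in% planted
    coherence <- runif(nd, spec$coherence_range[1], spec$coherence_range[2])
    # planted diseases are molecularly well characterised (upper band of the
    # coherence range) without being uniformly the strongest PrDN hubs
    band <- spec$coherence_range[2] -
      c(0.15, 0) * diff(spec$coherence_range)
    coherence[is_planted] <- runif(sum(is_planted), band[1], band[2])

    # disease-protein rows: in-block Bernoulli picks scaled by coherence,
    # plus background picks elsewhere keeping the expected row size constant
    dp_pairs_i <- integer(0)
    dp_pairs_j <- integer(0)
    for (i in seq_len(nd)) {
      block <- which(block_of_protein == module_of_disease[i])
      bg_pool <- which(block_of_protein != module_of_disease[i])
      row <- integer(0)
      for (attempt in seq_len(100L)) {
        in_block <- block[runif(length(block)) <
                            spec$protein_density * coherence[i]]
        n_bg <- rbinom(1L, length(block),
                       spec$protein_density * (1 - coherence[i]))
        bg <- sample_ids(bg_pool, min(n_bg, length(bg_pool)))
        row <- c(in_block, bg)
        if (length(row) > 0L) break
      }
      if (length(row) == 0L) {
        stop("could not generate a non-empty protein profile; ",
             "protein_density too low", call. = FALSE)
      }
      dp_pairs_i <- c(dp_pairs_i, rep(i, length(row)))
      dp_pairs_j <- c(dp_pairs_j, row)
    }

    # drug-protein rows: each drug targets proteins of one block
    rp_pairs_i <- integer(0)
    rp_pairs_j <- integer(0)
    for (r in seq_len(nr)) {
      block <- which(block_of_protein == module_of_drug[r])
      targets <- sample_ids(block, min(spec$targets_per_drug, length(block)))
      rp_pairs_i <- c(rp_pairs_i, rep(r, length(targets)))
      rp_pairs_j <- c(rp_pairs_j, targets)
    }

    dp_m <- Matrix::sparseMatrix(i = dp_pairs_i, j = dp_pairs_j, x = 1,
                                 dims = c(nd, np))
    rp_m <- Matrix::sparseMatrix(i = rp_pairs_i, j = rp_pairs_j, x = 1,
                                 dims = c(nr, np))
    consistent <- Matrix::tcrossprod(dp_m, rp_m) > 0  # disease x drug

    # observed disease-drug rows: thinned protein-consistent treatments.
    # The keep probability is scaled so the expected treatment count is
    # drug_density * (module drug-pool size) regardless of how broad the
    # consistent pool is -- treatment-list length does not grow with
    # annotation breadth.
    target_n <- spec$drug_density * nr / nm
    dd_rows <- vector("list", nd)
    for (i in seq_len(nd)) {
      pool <- which(consistent[i, ])
      if (length(pool) == 0L) {
        dd_rows[[i]] <- sample_ids(seq_len(nr), 1L)
        next
      }
      keep <- pool[runif(length(pool)) < min(1, target_n / length(pool))]
      if (length(keep) == 0L) keep <- sample_ids(pool, 1L)
      dd_rows[[i]] <- keep
    }

    # planted signal: replace a fraction of each planted disease's drugs
    # with decoupled ones (from a single donor module, or at random)
    donor_module <- stats::setNames(rep(NA_integer_, length(planted)), planted)
    withheld <- data.frame(disease = character(), drug = character(),
                           stringsAsFactors = FALSE)
    for (d in planted) {
      i <- match(d, dis_ids)
      cur <- dd_rows[[i]]
      n_rm <- ceiling(spec$decouple_frac * length(cur))
      removed <- sample_ids(cur, n_rm)
      # replace only part of what was removed: the planted disease ends up
      # under-treated relative to its protein profile AND pointing elsewhere
      n_repl <- ceiling(n_rm / 2)
      pool <- which(consistent[i, ])
      excluded <- union(pool, cur)
      if (spec$decouple_mode == "permute_neighbors") {
        donor <- sample_ids(setdiff(seq_len(nm), module_of_disease[i]), 1L)
        donor_module[d] <- donor
        repl_pool <- setdiff(which(module_of_drug == donor), excluded)
        if (length(repl_pool) < n_repl) {
          repl_pool <- union(repl_pool,
                             setdiff(seq_len(nr), excluded))
        }
      } else {
        repl_pool <- setdiff(seq_len(nr), excluded)
      }
      repl <- sample_ids(repl_pool, min(n_repl, length(repl_pool)))
      dd_rows[[i]] <- sort(union(setdiff(cur, removed), repl))
      withheld <- rbind(withheld,
                        data.frame(disease = d, drug = drug_ids[sort(removed)],
                                   stringsAsFactors = FALSE))
    }

    dd_pairs <- data.frame(
      row = rep(dis_ids, vapply(dd_rows, length, integer(1))),
      col = drug_ids[unlist(dd_rows, use.names = FALSE)],
      stringsAsFactors = FALSE)
    dp_pairs <- data.frame(row = dis_ids[dp_pairs_i],
                           col = prot_ids[dp_pairs_j],
                           stringsAsFactors = FALSE)
    rp_pairs <- data.frame(row = drug_ids[rp_pairs_i],
                           col = prot_ids[rp_pairs_j],
                           stringsAsFactors = FALSE)

    list(
      disease_protein = association_table(dp_pairs, "disease", "protein",
                                          row_ids = dis_ids,
                                          col_ids = prot_ids),
      disease_drug = association_table(dd_pairs, "disease", "drug",
                                       row_ids = dis_ids,
                                       col_ids = drug_ids),
      drug_protein = association_table(rp_pairs, "drug", "protein",
                                       row_ids = drug_ids,
                                       col_ids = prot_ids),
      truth = list(planted_diseases = planted,
                   withheld_true_pairs = withheld,
                   module_of = stats::setNames(module_of_disease, dis_ids),
                   donor_module = donor_module,
                   coherence = stats::setNames(coherence, dis_ids)),
      spec = spec
    )
  })
}

#' Fraction of planted diseases recovered among the KL candidates
#'
#' Runs the prioritisation stage (networks, probability profiles, KL
#' ranking, top-sigma-percent selection) on a generated instance and
#' returns `|planted diseases among candidates| / |planted diseases|`.
#'
#' @param tables a [generate_tripartite()] result (or any list with
#'   `disease_protein` and `disease_drug` tables).
#' @param truth ground truth list with `planted_diseases`; defaults to
#'   `tables$truth`.
#' @param sigma candidate percentage (default 20).
#' @return fraction in `[0, 1]`; vacuously 1 (with a warning) when no
#'   disease was planted.
#' @export
planted_recovery_rate <- function(tables, truth = tables$truth, sigma = 20) {
  planted <- truth$planted_diseases
  if (length(planted) == 0L) {
    warning("no planted diseases: recovery is vacuously 1")
    return(1)
  }
  restricted <- restrict_to_common_diseases(tables$disease_protein,
                                            tables$disease_drug)
  prdn <- build_disease_network(restricted$disease_protein)
  drdn <- build_disease_network(restricted$disease_drug)
  ranking <- kl_divergence_per_disease(to_probability_profile(prdn),
                                       to_probability_profile(drdn))
  cands <- select_candidates(ranking, sigma)
  mean(planted %in% cands)
}
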