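# six-disease toy mirroring the schematic worked example: D_A shares
# proteins with D_B and D_D but drugs with D_C and D_E, so its neighbourhood
# diverges between the two networks; every other disease's neighbourhoods
# agree. D_D is D_A's strongest protein-side neighbour and carries Dr4.
toy_tables <- function() {
  dp <- association_table(data.frame(
    row = c("D_A", "D_A", "D_A", "D_B", "D_D", "D_D",
            "D_C", "D_E", "D_F", "D_F"),
    col = c("p1", "p2", "p6", "p1", "p2", "p6",
            "p3", "p4", "p3", "p4")), "disease", "protein")
  dd <- association_table(data.frame(
    row = c("D_A", "D_C", "D_C", "D_E", "D_E", "D_B",
            "D_D", "D_D", "D_F"),
    col = c("r1", "r1", "r5", "r1", "r6", "r2",
            "r4", "r7", "r7")), "disease", "drug")
  list(dp = dp, dd = dd)
}

test_that("candidate drugs are the union of similar diseases' drugs", {
  dd <- association_table(data.frame(
    row = c("X", "X", "Y", "Y", "D_D"),
    col = c("a", "b", "b", "c", "Dr_4")), "disease", "drug")
  expect_equal(candidate_drugs("Z", c("X", "Y"), dd), c("a", "b", "c"))
  expect_equal(candidate_drugs("D_A", "D_D", dd), "Dr_4")
  expect_equal(candidate_drugs("Z", character(), dd), character())
  expect_error(candidate_drugs("X", c("X", "Y"), dd), "must not appear")
  expect_error(candidate_drugs("Z", "missing", dd), "absent")
})

test_that("the six-disease toy repositions D_D's drugs onto D_A", {
  tt <- toy_tables()
  run <- run_network_mirroring(tt$dp, tt$dd, sigma = 16, delta = 20, mu = 1)
  expect_length(run$results, 1L)
  res <- run$results[[1L]]
  expect_equal(res$candidate_disease, "D_A")
  expect_equal(names(res$similar_diseases), "D_D")
  expect_setequal(res$candidate_drugs, c("r4", "r7"))
  expect_setequal(res$novel_drugs, c("r4", "r7"))  # D_A only has r1
  expect_equal(res$known_covered, character())
})

test_that("sigma = delta = 100 proposes every other disease's drugs", {
  tt <- toy_tables()
  run <- run_network_mirroring(tt$dp, tt$dd, sigma = 100, delta = 100)
  expect_length(run$results, 6L)
  pairs <- association_pairs(tt$dd)
  for (res in run$results) {
    want <- sort(unique(pairs$col[pairs$row != res$candidate_disease]))
    expect_setequal(res$candidate_drugs, want)
    expect_true(all(res$novel_drugs %in% res$candidate_drugs))
    expect_setequal(union(res$novel_drugs, res$known_covered),
                    res$candidate_drugs)
    expect_length(intersect(res$novel_drugs, res$known_covered), 0L)
  }
})

test_that("candidate drug sets are nested as delta grows", {
  set.seed(5)
  g <- generate_tripartite(synthetic_spec(n_diseases = 40, n_proteins = 200,
                                          n_drugs = 40, n_modules = 4,
                                          n_planted = 4, seed = 2))
  prev <- NULL
  for (delta in c(5, 15, 40, 80)) {
    run <- run_network_mirroring(g$disease_protein, g$disease_drug,
                                 sigma = 10, delta = delta)
    drugs <- run$results[[1L]]$candidate_drugs
    if (!is.null(prev)) expect_true(all(prev %in% drugs))
    prev <- drugs
  }
})

test_that("the pipeline equals its four stages composed by hand", {
  g <- generate_tripartite(synthetic_spec(n_diseases = 30, n_proteins = 150,
                                          n_drugs = 30, n_modules = 3,
                                          n_planted = 3, seed = 4))
  run <- run_network_mirroring(g$disease_protein, g$disease_drug,
                               sigma = 20, delta = 10, mu = 1)

  r <- restrict_to_common_diseases(g$disease_protein, g$disease_drug)
  prdn <- build_disease_network(r$disease_protein)
  drdn <- build_disease_network(r$disease_drug)
  rk <- assign_tiers(kl_divergence_per_disease(to_probability_profile(prdn),
                                               to_probability_profile(drdn)),
                     5)
  cands <- select_candidates(rk, 20)
  expect_equal(vapply(run$results, `[[`, "", "candidate_disease"), cands)
  for (res in run$results) {
    scores <- ssl_f_scores(prdn, res$candidate_disease, mu = 1)
    similar <- select_similar_diseases(scores, 10)
    expect_equal(names(res$similar_diseases), similar)
    expect_equal(res$candidate_drugs,
                 candidate_drugs(res$candidate_disease, similar,
                                 r$disease_drug))
  }
})

test_that("two identical runs write byte-identical outputs", {
  g <- generate_tripartite(synthetic_spec(n_diseases = 30, n_proteins = 150,
                                          n_drugs = 30, n_modules = 3,
                                          n_planted = 3, seed = 6))
  out <- replicate(2, {
    run <- run_network_mirroring(g$disease_protein, g$disease_drug,
                                 sigma = 20, delta = 10)
    paths <- c(tempfile(fileext = ".tsv"), tempfile(fileext = ".tsv"),
               tempfile(fileext = ".json"))
    write_ranking(run$ranking, paths[1])
    write_fscores(run, paths[2])
    write_repositioning_json(run, paths[3])
    paths
  })
  on.exit(unlink(c(out)), add = TRUE)
  for (k in 1:3) {
    expect_identical(readBin(out[k, 1], "raw", file.size(out[k, 1])),
                     readBin(out[k, 2], "raw", file.size(out[k, 2])))
  }
})
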