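test_that("exponential row normalisation produces valid distributions", {
  # isolated disease: uniform over the 4 others
  w <- matrix(0, 5, 5)
  net <- disease_network(w, ids = letters[1:5], source = "protein")
  p <- to_probability_profile(net)
  expect_equal(unname(p$probs["a", letters[2:5]]), rep(0.25, 4))

  # weights (1,0,1,0,0) over five others: connected entries e/(2e+3)
  w6 <- matrix(0, 6, 6)
  w6[1, 2] <- w6[2, 1] <- 1
  w6[1, 4] <- w6[4, 1] <- 1
  net6 <- disease_network(w6, ids = letters[1:6], source = "protein")
  p6 <- to_probability_profile(net6)$probs
  z <- 2 * exp(1) + 3
  expect_equal(unname(p6[1, 2:6]),
               c(exp(1), 1, exp(1), 1, 1) / z, tolerance = 1e-12)
  expect_equal(exp(1) / z, 0.3222, tolerance = 1e-4)
  expect_equal(1 / z, 0.1185, tolerance = 1e-3)

  # every row sums to 1 and off-diagonal entries are strictly positive
  set.seed(31)
  for (rep in 1:10) {
    wr <- random_weights(7)
    pr <- to_probability_profile(disease_network(wr, ids = letters[1:7],
                                                 source = "drug"))$probs
    expect_equal(unname(rowSums(pr)), rep(1, 7), tolerance = 1e-9)
    off <- pr[upper.tri(pr) | lower.tri(pr)]
    expect_true(all(off > 0))
  }
})

test_that("per-disease KL divergence matches direct summation", {
  # identical rows diverge by zero
  pm <- matrix(0, 3, 3)
  pm[1, 2:3] <- c(0.5, 0.5); pm[2, c(1, 3)] <- c(0.4, 0.6)
  pm[3, 1:2] <- c(0.7, 0.3)
  p <- probability_profile(pm, ids = c("a", "b", "c"))
  expect_equal(kl_divergence_per_disease(p, p)$kl, rep(0, 3))

  # p = (.5,.5) vs q = (.25,.75): 0.5 ln 2 + 0.5 ln(2/3)
  qm <- pm
  qm[1, 2:3] <- c(0.25, 0.75)
  q <- probability_profile(qm, ids = c("a", "b", "c"))
  rk <- kl_divergence_per_disease(p, q)
  expect_equal(rk$kl[rk$disease == "a"],
               0.5 * log(2) + 0.5 * log(2 / 3), tolerance = 1e-12)
  expect_equal(rk$kl[rk$disease == "a"], 0.14384, tolerance = 1e-5)
})

test_that("composed pipeline equals one-shot brute force on raw weights", {
  set.seed(57)
  for (rep in 1:5) {
    w_pr <- random_weights(9)
    w_dr <- random_weights(9)
    ids <- sprintf("d%02d", 1:9)
    rk <- kl_divergence_per_disease(
      to_probability_profile(disease_network(w_pr, ids, source = "protein")),
      to_probability_profile(disease_network(w_dr, ids, source = "drug")))
    want <- oracle_kl_from_weights(w_pr, w_dr)
    expect_lt(max(abs(rk$kl[match(ids, rk$disease)] - want)), 1e-12)
  }
})

test_that("KL is nonnegative, zero iff rows equal, and asymmetric", {
  set.seed(97)
  n_zero_checked <- 0
  for (rep in 1:200) {
    w_pr <- random_weights(6)
    w_dr <- random_weights(6)
    if (rep %% 2 == 0) {
      # force some identical rows so the zero case is exercised
      w_dr[1, ] <- w_pr[1, ]
      w_dr[, 1] <- w_pr[, 1]
    }
    ids <- letters[1:6]
    p <- to_probability_profile(disease_network(w_pr, ids, source = "protein"))
    q <- to_probability_profile(disease_network(w_dr, ids, source = "drug"))
    kl_pq <- kl_divergence_per_disease(p, q)
    expect_true(all(kl_pq$kl >= -1e-15))
    same <- sapply(seq_along(ids), function(i) {
      isTRUE(all.equal(p$probs[i, ], q$probs[i, ], tolerance = 1e-15))
    })
    kl_i <- kl_pq$kl[match(ids, kl_pq$disease)]
    expect_true(all(kl_i[same] < 1e-12))
    expect_true(all(kl_i[!same] > 1e-12))
    n_zero_checked <- n_zero_checked + sum(same)
    # direction matters on asymmetric inputs
    kl_qp <- kl_divergence_per_disease(q, p)
    if (any(!same)) {
      expect_false(isTRUE(all.equal(sort(kl_pq$kl), sort(kl_qp$kl))))
    }
  }
  expect_gt(n_zero_checked, 0)
})

test_that("matching a disease's drug neighbourhood to its protein one zeroes its KL", {
  set.seed(13)
  w_pr <- random_weights(8)
  w_dr <- random_weights(8)
  ids <- letters[1:8]
  # give disease 3 the same drug neighbourhood as its protein one; its q row
  # depends only on its own weight row, so its KL must vanish
  w_dr[3, ] <- w_pr[3, ]
  w_dr[, 3] <- w_pr[, 3]
  rk <- kl_divergence_per_disease(
    to_probability_profile(disease_network(w_pr, ids, source = "protein")),
    to_probability_profile(disease_network(w_dr, ids, source = "drug")))
  expect_lt(rk$kl[rk$disease == "c"], 1e-12)
})

test_that("a permuted drug neighbourhood makes a disease the unique top candidate", {
  set.seed(71)
  for (rep in 1:5) {
    n <- 12
    w_pr <- random_weights(n, density = 0.7)
    ids <- sprintf("d%02d", 1:n)
    w_dr <- w_pr
    # permute disease 1's connections to the others, symmetrically
    perm <- 1 + sample(n - 1)
    w_dr[1, 2:n] <- w_pr[1, perm]
    w_dr[2:n, 1] <- w_dr[1, 2:n]
    if (isTRUE(all.equal(w_dr[1, ], w_pr[1, ]))) next
    rk <- kl_divergence_per_disease(
      to_probability_profile(disease_network(w_pr, ids, source = "protein")),
      to_probability_profile(disease_network(w_dr, ids, source = "drug")))
    expect_equal(select_candidates(rk, sigma = 100 / n)[1], "d01")
    expect_equal(rk$disease[rk$rank == 1], "d01")
  }
})

test_that("candidate selection takes ceiling(sigma% of N) top-KL diseases", {
  kl <- c(0.2, 0.05, 0.0, 0.01, 0.03, 0.0)
  ids <- sprintf("d%d", 1:6)
  # build a ranking through the public api: profiles that reproduce these KLs
  # are unnecessary -- construct the ranking from a synthetic object instead
  rk <- structure(
    data.frame(disease = ids, kl = kl,
               rank = c(1L, 2L, 5L, 4L, 3L, 6L),
               tier = NA_integer_, is_candidate = FALSE),
    class = c("kl_ranking", "data.frame"))
  expect_equal(select_candidates(rk, 20), c("d1", "d2"))
  expect_equal(select_candidates(rk, 100),
               c("d1", "d2", "d5", "d4", "d3", "d6"))
  expect_error(select_candidates(rk, 0), "percentage")
  expect_error(select_candidates(rk, 101), "percentage")

  # ties broken by ascending id via the public route
  pm <- matrix(1 / 3, 4, 4); diag(pm) <- 0
  p <- probability_profile(pm, ids = c("b", "a", "d", "c"))
  rk2 <- kl_divergence_per_disease(p, p)  # all KL equal (zero)
  expect_equal(rk2$disease, c("a", "b", "c", "d"))
  expect_equal(rk2$rank, 1:4)
})

test_that("tier assignment balances block sizes with the top tiers larger", {
  mk <- function(n) {
    structure(data.frame(disease = sprintf("d%02d", 1:n), kl = 0,
                         rank = 1:n, tier = NA_integer_,
                         is_candidate = FALSE),
              class = c("kl_ranking", "data.frame"))
  }
  t10 <- assign_tiers(mk(10), 5)
  expect_equal(as.integer(table(t10$tier)), rep(2L, 5))
  t7 <- assign_tiers(mk(7), 5)
  expect_equal(as.integer(table(t7$tier)), c(2L, 2L, 1L, 1L, 1L))
  expect_equal(t7$tier[t7$rank == 1], 1L)
  expect_error(assign_tiers(mk(3), 5), "between 1 and")
})
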