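make_cohort_from_scores <- function(scores_by_item, maxes) {
  # scores_by_item: list of [n x m] matrices, one per item
  n <- nrow(scores_by_item[[1]]); m <- ncol(scores_by_item[[1]])
  items <- data.frame(item = paste0("IT", seq_along(maxes)),
                      max_score = as.integer(maxes))
  arr <- array(0L, dim = c(n, length(maxes), m),
               dimnames = list(sprintf("P%02d", seq_len(n)), items$item,
                               as.character(seq_len(m) - 1L)))
  for (j in seq_along(maxes)) arr[, j, ] <- scores_by_item[[j]]
  cohort_tensor(arr, items)
}

test_that("binarization thresholds at a strict fraction of the item maximum", {
  co <- make_cohort_from_scores(
    list(matrix(c(0:5, 0, 0), 4, 2, byrow = TRUE)), maxes = 5)
  prof <- binarize(co, 0.5)
  # max 5, kappa 0.5 -> cutoff 2.5: scores 0..2 -> 0, 3..5 -> 1
  expect_equal(as.vector(prof[1, 1, ]), c(0, 0))   # scores 0, 1
  expect_equal(as.vector(prof[2, 1, ]), c(0, 1))   # scores 2, 3
  expect_equal(as.vector(prof[3, 1, ]), c(1, 1))   # scores 4, 5

  # a score exactly at max * kappa maps to 0 (max 4, kappa 0.5, score 2)
  co4 <- make_cohort_from_scores(list(matrix(c(2, 3, 2, 1), 2, 2)), maxes = 4)
  prof4 <- binarize(co4, 0.5)
  expect_equal(as.vector(prof4[, 1, ]), c(0, 1, 0, 0))

  # kappa near 0 marks every positive score; zero scores stay zero
  tiny <- binarize(co4, 1e-9)
  expect_equal(as.vector(tiny[, 1, ]), c(1, 1, 1, 1))
  zeroes <- make_cohort_from_scores(list(matrix(0, 2, 2)), maxes = 4)
  expect_true(all(binarize(zeroes, 1e-9) == 0))

  expect_error(binarize(co4, 0), "kappa")
  expect_error(binarize(co4, 1.5), "kappa")
})

test_that("median-mode binarization cuts at the item's population level", {
  sc <- matrix(c(0, 1, 2, 3, 4, 0, 1, 2), 4, 2)
  co <- make_cohort_from_scores(list(sc), maxes = 4)
  prof <- binarize(co, mode = "median")
  expect_equal(as.vector(prof[, 1, ]), as.integer(sc > median(sc)))
})

test_that("agreement counts match the brute-force oracle", {
  set.seed(41)
  for (i in 1:50) {
    arr <- random_profiles(2, 15, 5)
    net <- patient_similarity(arr, zero_diagonal = FALSE)
    expect_equal(net$matrix[1, 2],
                 oracle_agreement(arr[1, , ], arr[2, , ]))
    w <- matrix(runif(75), 15, 5)
    netw <- patient_similarity(arr, weights = w, zero_diagonal = FALSE)
    expect_equal(netw$matrix[1, 2],
                 oracle_agreement(arr[1, , ], arr[2, , ], w),
                 tolerance = 1e-12)
  }
})

test_that("agreement networks are symmetric, bounded and integral", {
  set.seed(42)
  for (i in 1:20) {
    n <- sample(3:8, 1); v <- sample(2:6, 1); m <- sample(2:4, 1)
    arr <- random_profiles(n, v, m)
    net <- patient_similarity(arr)
    p <- net$matrix
    expect_identical(p, t(p))
    expect_true(all(p >= 0 & p <= v * m))
    expect_true(all(p == round(p)))   # uniform unit weights -> counts
    expect_true(all(diag(p) == 0))
  }
  ident <- array(rep(c(1L, 0L), each = 4), dim = c(2, 2, 2))
  expect_equal(patient_similarity(ident, zero_diagonal = FALSE)$matrix[1, 2], 4)
  comp <- ident; comp[2, , ] <- 1L - comp[1, , ]
  expect_equal(patient_similarity(comp)$matrix[1, 2], 0)
  expect_error(patient_similarity(list(matrix(0, 2, 2), matrix(0, 3, 2))),
               "shape mismatch")
})

test_that("modularity agrees with closed forms and the double-sum oracle", {
  clique <- function(n) { m <- matrix(1, n, n); diag(m) <- 0; m }
  two <- as.matrix(Matrix::bdiag(clique(6), clique(6)))
  expect_equal(newman_girvan_modularity(two, rep(1, 12)), 0, tolerance = 1e-12)
  expect_equal(newman_girvan_modularity(two, rep(1:2, each = 6)), 0.5,
               tolerance = 1e-12)
  set.seed(7)
  for (i in 1:100) {
    p <- matrix(runif(144), 12, 12); p <- p + t(p); diag(p) <- 0
    labs <- sample(1:3, 12, replace = TRUE)
    q <- newman_girvan_modularity(p, labs)
    expect_equal(q, oracle_modularity(p, labs), tolerance = 1e-10)
    # independent library cross-check
    g <- igraph::graph_from_adjacency_matrix(p, mode = "undirected",
                                             weighted = TRUE, diag = FALSE)
    expect_equal(q, igraph::modularity(g, labs, weights = igraph::E(g)$weight),
                 tolerance = 1e-10)
  }
  expect_error(newman_girvan_modularity(matrix(0, 3, 3), rep(1, 3)),
               "empty network")
})

test_that("Louvain recovers unambiguous structure deterministically", {
  clique <- function(n) { m <- matrix(1, n, n); diag(m) <- 0; m }
  two <- as.matrix(Matrix::bdiag(clique(10), clique(10)))
  rownames(two) <- colnames(two) <- sprintf("P%02d", 1:20)
  part <- louvain_cluster(two, seed = 3)
  expect_equal(part$n_communities, 2L)
  expect_equal(unname(part$labels), rep(1:2, each = 10))
  expect_equal(part$modularity, 0.5, tolerance = 1e-12)
  part2 <- louvain_cluster(two, seed = 3)
  expect_identical(part$labels, part2$labels)
  # uniform network: no structure, collapses to one community
  unif <- matrix(5, 8, 8); diag(unif) <- 0
  pu <- louvain_cluster(unif, seed = 1)
  expect_equal(pu$n_communities, 1L)
  expect_error(louvain_cluster(matrix(0, 4, 4)), "degenerate network")
})

test_that("returned partitions never score below the trivial partition", {
  set.seed(13)
  for (i in 1:5) {
    arr <- random_profiles(20, 6, 3)
    net <- patient_similarity(arr)
    part <- louvain_cluster(net, seed = i, n_restarts = 5)
    expect_gte(part$modularity, 0)
  }
})

test_that("subtype profiles are member means with reportability flags", {
  set.seed(17)
  arr <- random_profiles(12, 5, 4)
  net <- patient_similarity(arr)
  part <- louvain_cluster(net, seed = 2)
  part <- subtype_profiles(arr, part, min_report_size = 3)
  ids <- dimnames(arr)[[1]]
  for (l in seq_len(part$n_communities)) {
    members <- part$communities[[l]]
    mats <- lapply(match(members, ids), function(i) arr[i, , ])
    expect_equal(unname(part$subtype_profiles[[l]]),
                 oracle_profile_mean(mats), tolerance = 1e-12)
    expect_true(all(part$subtype_profiles[[l]] >= 0 &
                      part$subtype_profiles[[l]] <= 1))
    expect_equal(part$reportable[l], part$sizes[l] >= 3)
  }
  # singleton community: profile equals that patient's trajectory profile
  single <- part
  single$communities <- list(ids[1])
  single$sizes <- 1L; single$n_communities <- 1L
  single$labels <- setNames(1L, ids[1])
  single <- subtype_profiles(arr, single, min_report_size = 10)
  expect_equal(unname(single$subtype_profiles[[1]]), arr[1, , ] * 1.0)
  expect_false(single$reportable[1])
  # complementary pair averages to one half everywhere
  pair <- array(0L, dim = c(2, 3, 2))
  pair[1, , ] <- 1L
  ppart <- structure(list(labels = c(`1` = 1L, `2` = 1L),
                          communities = list(c("1", "2")), sizes = 2L,
                          n_communities = 1L, modularity = 0,
                          reportable = NULL, subtype_profiles = NULL,
                          min_report_size = NULL),
                     class = "subtype_partition")
  dimnames(pair)[[1]] <- c("1", "2")
  ppart <- subtype_profiles(pair, ppart, 1)
  expect_true(all(ppart$subtype_profiles[[1]] == 0.5))
})

test_that("TPC recovers planted archetypes on the default cohort", {
  gen <- generate_cohort(sim_config())
  part <- run_tpc(gen$cohort, kappa = 0.5, seed = 1, n_restarts = 20,
                  verbose = FALSE)
  expect_equal(sum(part$reportable), 3L)
  ari <- mclust::adjustedRandIndex(part$labels,
                                   gen$archetype[names(part$labels)])
  expect_gte(ari, 0.9)
})

test_that("TPC boundary behavior: duplicates collapse, kappa = 1 errors", {
  items <- data.frame(item = c("A", "B"), max_score = c(2L, 4L))
  arr <- array(rep(c(2L, 4L, 0L, 1L), each = 6), dim = c(6, 2, 2),
               dimnames = list(sprintf("P%d", 1:6), items$item, c("0", "1")))
  co <- cohort_tensor(arr, items)
  part <- run_tpc(co, verbose = FALSE)
  expect_equal(part$n_communities, 1L)
  expect_error(run_tpc(co, kappa = 1.0, verbose = FALSE),
               "degenerate network")
})

test_that("relabeling patients permutes subtype assignments identically", {
  set.seed(31)
  gen <- generate_cohort(sim_config(n_patients = 60, seed = 8))
  part <- run_tpc(gen$cohort, seed = 4, verbose = FALSE)
  # bijective renaming that lands the patients in a different stored order
  new_ids <- setNames(sample(sprintf("Q%02d", 1:60)), gen$cohort$patients)
  arr <- gen$cohort$scores
  dimnames(arr)[[1]] <- unname(new_ids[dimnames(arr)[[1]]])
  arm2 <- setNames(gen$cohort$arm, unname(new_ids[names(gen$cohort$arm)]))
  co2 <- cohort_tensor(arr, gen$cohort$items, arm = arm2)
  part2 <- run_tpc(co2, seed = 4, verbose = FALSE)
  expect_identical(unname(part2$labels[unname(new_ids[names(part$labels)])]),
                   unname(part$labels))
})
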