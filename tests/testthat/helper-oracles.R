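# Independent brute-force oracles and fixture builders used across tests.
# Every oracle is a plain double loop over the defining formula, kept free
# of any package internals.

# agreement count between two binary profile matrices, optional weights
oracle_agreement <- function(ti, tj, w = NULL) {
  if (is.null(w)) w <- matrix(1, nrow(ti), ncol(ti))
  s <- 0
  for (v in seq_len(nrow(ti)))
    for (t in seq_len(ncol(ti)))
      if (ti[v, t] == tj[v, t]) s <- s + w[v, t]
  s
}

# Newman-Girvan modularity by the literal double sum
oracle_modularity <- function(p, labels) {
  twom <- sum(p)
  deg <- rowSums(p)
  q <- 0
  for (i in seq_len(nrow(p)))
    for (j in seq_len(ncol(p)))
      if (labels[i] == labels[j])
        q <- q + p[i, j] - deg[i] * deg[j] / twom
  q / twom
}

# outer product of a binary vector with itself, by explicit loops
oracle_outer <- function(v) {
  g <- matrix(0, length(v), length(v))
  for (a in seq_along(v))
    for (b in seq_along(v))
      g[a, b] <- v[a] * v[b]
  g
}

# element-wise mean of a list of matrices, by accumulation
oracle_profile_mean <- function(mats) {
  acc <- mats[[1]] * 0
  for (m in mats) acc <- acc + m
  acc / length(mats)
}

# all set partitions of 1..n as label vectors (restricted growth strings)
all_set_partitions <- function(n) {
  out <- list()
  recurse <- function(labels, used) {
    k <- length(labels)
    if (k == n) {
      out[[length(out) + 1L]] <<- labels
      return(invisible())
    }
    for (l in seq_len(used + 1L))
      recurse(c(labels, l), max(used, l))
  }
  recurse(integer(0), 0L)
  out
}

# small random catalog + complete cohort for round-trip property tests
random_tiny_cohort <- function(with_arm = FALSE) {
  v <- sample(1:4, 1)
  m <- sample(2:4, 1)
  n <- sample(2:5, 1)
  items <- data.frame(item = paste0("IT", seq_len(v)),
                      display_name = paste0("Item ", seq_len(v)),
                      max_score = sample(1:5, v, replace = TRUE))
  arr <- array(0L, dim = c(n, v, m),
               dimnames = list(sprintf("P%02d", seq_len(n)), items$item,
                               as.character(seq_len(m) - 1L)))
  for (j in seq_len(v))
    arr[, j, ] <- sample(0:items$max_score[j], n * m, replace = TRUE)
  arm <- if (with_arm)
    setNames(sample(c("treated", "placebo"), n, replace = TRUE),
             dimnames(arr)[[1]])
  cohort_tensor(arr, items, arm = arm)
}

# random binary trajectory profiles as an [n, v, m] array
random_profiles <- function(n, v = 15, m = 5, p = 0.4) {
  arr <- array(rbinom(n * v * m, 1, p), dim = c(n, v, m),
               dimnames = list(sprintf("P%02d", seq_len(n)), NULL, NULL))
  arr
}

# separable two-class graph fixture: classes live on disjoint item blocks
separable_graph_fixture <- function(n_per_class = 30, v = 15, seed = 1) {
  set.seed(seed)
  mk <- function(block) {
    vec <- integer(v)
    vec[sample(block, sample(2:length(block), 1))] <- 1L
    outer(vec, vec)
  }
  graphs <- c(replicate(n_per_class, mk(1:5), simplify = FALSE),
              replicate(n_per_class, mk(8:12), simplify = FALSE))
  list(graphs = graphs,
       labels = rep(c("blockA", "blockB"), each = n_per_class))
}

# cohort whose two archetypes share identical templates at t = 0, 1 and
# diverge from t = 2 on (class B switches symptom blocks)
late_separation_cohort <- function(n_patients = 200, seed = 11) {
  catalog <- nihss_catalog()
  mk <- function(name, late_block) {
    sev <- matrix(0.03, 15, 5,
                  dimnames = list(catalog$item, as.character(0:4)))
    sev[1:4, 1:2] <- 0.9
    sev[late_block, 3:5] <- 0.9
    archetype_template(name, sev, 0.5)
  }
  cfg <- sim_config(n_patients = n_patients,
                    templates = list(mk("stayA", 1:4), mk("switchB", 5:8)),
                    treatment_fraction = 0, treatment_recovery_boost = 0,
                    noise_sd = 0.05, seed = seed)
  generate_cohort(cfg)
}
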