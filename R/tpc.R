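#' Binarize a cohort into trajectory profiles
#'
#' Builds each patient's trajectory profile `T^i`: a binary item-by-time
#' matrix marking the symptoms the patient *severely* expresses at each
#' visit. Under the default `"fraction"` mode an entry is 1 iff the score
#' strictly exceeds `kappa * max_score(item)` (a score exactly at the
#' threshold maps to 0). For an item scored 0-5 with `kappa = 0.5` the
#' threshold is 2.5, so scores 0-2 map to 0 and 3-5 map to 1. Under
#' `"median"` mode the cutoff is instead the item's population median
#' (pooled over patients and visits): severity means scoring above the
#' cohort's typical level for that item.
#'
#' @param cohort a [cohort_tensor()].
#' @param kappa threshold fraction in `(0, 1]` (`"fraction"` mode only).
#' @param mode `"fraction"` (threshold at `kappa * max_score`) or
#'   `"median"` (threshold at the per-item population median).
#' @return A binary array `[patient, item, timepoint]` of class
#'   `trajectory_profiles`, with attributes `kappa` and `mode`.
#' @export
binarize <- function(cohort, kappa = 0.5, mode = c("fraction", "median")) {
  stopifnot(inherits(cohort, "cohort_tensor"))
  mode <- match.arg(mode)
  x <- cohort$scores
  if (mode == "fraction") {
    if (!is.numeric(kappa) || length(kappa) != 1L || kappa <= 0 || kappa > 1)
      stop("kappa must be a single value in (0, 1]")
    thr <- cohort$items$max_score * kappa
  } else {
    thr <- apply(x, 2, stats::median)
  }
  prof <- array(0L, dim = dim(x), dimnames = dimnames(x))
  for (j in seq_len(dim(x)[2]))
    prof[, j, ] <- (x[, j, ] > thr[j]) + 0L
  structure(prof, class = "trajectory_profiles",
            kappa = if (mode == "fraction") kappa else NA_real_, mode = mode)
}

# accept a trajectory_profiles array or a list of [item, timepoint]
# matrices; return [patient, item, timepoint] array
as_profile_array <- function(profiles) {
  if (is.array(profiles) && length(dim(profiles)) == 3L) return(profiles)
  if (!is.list(profiles) || !length(profiles))
    stop("profiles must be a trajectory_profiles array or a list of matrices")
  dims <- vapply(profiles, dim, integer(2))
  if (any(dims != dims[, 1]))
    stop("profile shape mismatch: all profiles must share one item x timepoint shape")
  arr <- array(0L, dim = c(length(profiles), dims[1, 1], dims[2, 1]))
  for (i in seq_along(profiles)) arr[i, , ] <- profiles[[i]]
  ids <- names(profiles)
  dimnames(arr) <- list(if (is.null(ids)) as.character(seq_along(profiles))
                        else ids, NULL, NULL)
  arr
}

#' Patient-patient agreement network
#'
#' Edge weight `P[i, j]` counts the profile positions at which patients `i`
#' and `j` agree (both 0 or both 1), optionally weighted per position:
#' `P_ij = sum_vt w_vt * (T^i_vt == T^j_vt)`. With uniform unit weights the
#' raw diagonal is `V * M`; self-similarities are zeroed by default before
#' community detection since they carry no inter-patient information.
#'
#' @param profiles a `trajectory_profiles` array or list of binary
#'   `[item, timepoint]` matrices sharing one shape.
#' @param weights optional nonnegative `[item, timepoint]` weight matrix;
#'   `NULL` means uniform unit weights.
#' @param zero_diagonal zero out `P[i, i]` (default `TRUE`).
#' @return An object of class `patient_network`: list with the symmetric
#'   `matrix`, the `weights` used, `total_weight` (`sum w_vt`) and
#'   `diagonal_zeroed`.
#' @export
patient_similarity <- function(profiles, weights = NULL,
                               zero_diagonal = TRUE) {
  arr <- as_profile_array(profiles)
  n <- dim(arr)[1]
  vm <- dim(arr)[2] * dim(arr)[3]
  b <- matrix(as.numeric(arr), nrow = n)  # columns run over (item, time)
  if (is.null(weights)) {
    w <- rep(1, vm)
  } else {
    if (length(weights) != vm)
      stop("weights must match the item x timepoint shape")
    w <- as.numeric(weights)
    if (any(w < 0)) stop("weights must be nonnegative")
  }
  bw <- sweep(b, 2, w, `*`)
  cw <- sweep(1 - b, 2, w, `*`)
  p <- bw %*% t(b) + cw %*% t(1 - b)
  p <- (p + t(p)) / 2
  if (zero_diagonal) diag(p) <- 0
  dimnames(p) <- list(dimnames(arr)[[1]], dimnames(arr)[[1]])
  structure(list(matrix = p, weights = weights, total_weight = sum(w),
                 diagonal_zeroed = zero_diagonal),
            class = "patient_network")
}

#' @export
print.patient_network <- function(x, ...) {
  cat("patient_network:", nrow(x$matrix), "patients, total position weight",
      x$total_weight, if (x$diagonal_zeroed) "(self-similarities zeroed)",
      "\n")
  invisible(x)
}

as_network_matrix <- function(network) {
  p <- if (inherits(network, "patient_network")) network$matrix else
    as.matrix(network)
  if (nrow(p) != ncol(p) || nrow(p) == 0) stop("network matrix must be square and non-empty")
  if (max(abs(p - t(p))) > 1e-8) stop("network matrix must be symmetric")
  if (any(p < 0)) stop("network weights must be nonnegative")
  p
}

#' Newman-Girvan modularity of a partition
#'
#' `Q = (1/2m) * sum_ij (P_ij - k_i k_j / 2m) * delta(c_i, c_j)` with
#' weighted degrees `k_i = sum_j P_ij` and total weight `2m = sum_ij P_ij`.
#' The all-in-one partition always scores 0; two equal disconnected cliques
#' split apart score 0.5.
#'
#' @param network a [patient_similarity()] result or symmetric nonnegative
#'   matrix.
#' @param labels community label per node (any atomic type).
#' @return Modularity `Q` in `[-1, 1]`.
#' @export
newman_girvan_modularity <- function(network, labels) {
  p <- as_network_matrix(network)
  if (length(labels) != nrow(p))
    stop("labels must assign a community to every node")
  twom <- sum(p)
  if (twom <= 0) stop("empty network: total weight must be positive")
  deg <- rowSums(p)
  q <- 0
  for (l in unique(labels)) {
    idx <- which(labels == l)
    q <- q + sum(p[idx, idx]) - sum(deg[idx])^2 / twom
  }
  q / twom
}

# canonical labels: 1..L by decreasing size, ties by smallest member index
relabel_partition <- function(membership) {
  sizes <- table(membership)
  firsts <- vapply(names(sizes), function(l) min(which(membership == l)), 0)
  ord <- names(sizes)[order(-as.integer(sizes), firsts)]
  as.integer(match(as.character(membership), ord))
}

#' Louvain community detection on a patient network
#'
#' Maximizes Newman-Girvan modularity with the Louvain method over
#' `n_restarts` seeded runs, keeping the best-modularity labeling. The
#' number of communities is an output of the optimization, never an input.
#' Labels are canonical: community 1 is the largest (ties broken by the
#' smallest member index). A network whose off-diagonal weights are all
#' equal has no community structure and collapses to a single community; an
#' all-zero network is an error.
#'
#' @param network a [patient_similarity()] result or symmetric nonnegative
#'   matrix.
#' @param seed master seed; restart `r` runs under `seed + r - 1`.
#' @param n_restarts number of Louvain restarts (default 20).
#' @return An object of class `subtype_partition` with `labels` (named
#'   integer vector), `communities` (list of member-id vectors),
#'   `modularity`, `sizes` and `n_communities`.
#' @export
louvain_cluster <- function(network, seed = 1, n_restarts = 20) {
  p <- as_network_matrix(network)
  diag(p) <- 0  # self-similarities carry no inter-patient information
  ids <- rownames(p)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(p)))
  offd <- p[upper.tri(p)]
  if (all(offd == 0))
    stop("degenerate network: all pairwise similarities are zero")
  if (max(offd) - min(offd) < 1e-12) {
    memb <- rep(1L, nrow(p))
  } else {
    g <- igraph::graph_from_adjacency_matrix(p, mode = "undirected",
                                             weighted = TRUE, diag = FALSE)
    best <- NULL
    best_q <- -Inf
    for (r in seq_len(n_restarts)) {
      set.seed(seed + r - 1L)
      cl <- igraph::cluster_louvain(g)
      mb <- as.integer(igraph::membership(cl))
      q <- newman_girvan_modularity(p, mb)
      if (q > best_q + 1e-12) { best <- mb; best_q <- q }
    }
    memb <- best
  }
  memb <- relabel_partition(memb)
  comms <- split(ids, memb)
  structure(list(
    labels = stats::setNames(memb, ids),
    communities = comms,
    modularity = newman_girvan_modularity(p, memb),
    sizes = as.integer(lengths(comms)),
    n_communities = length(comms),
    subtype_profiles = NULL, reportable = NULL, min_report_size = NULL,
    diagonal_zeroed = TRUE
  ), class = "subtype_partition")
}

#' @export
print.subtype_partition <- function(x, ...) {
  cat("subtype_partition:", x$n_communities, "communities, modularity",
      format(x$modularity, digits = 4), "\n")
  cat("  sizes:", paste(x$sizes, collapse = ", "), "\n")
  if (!is.null(x$reportable))
    cat("  reportable (>=", x$min_report_size, "patients):",
        sum(x$reportable), "\n")
  invisible(x)
}

#' Aggregate subtype profiles
#'
#' The subtype profile `S^l` is the element-wise mean of its members'
#' trajectory profiles: entry `[v, t]` is the fraction of subtype members
#' severely affected by symptom `v` at visit `t` (the "affected fraction").
#' Communities smaller than `min_report_size` keep their labels but are
#' flagged non-reportable.
#'
#' @param profiles trajectory profiles matching the partition's patients.
#' @param partition a `subtype_partition` from [louvain_cluster()].
#' @param min_report_size smallest community size shown in reports
#'   (default 10).
#' @return The partition, augmented with `subtype_profiles` (list of
#'   `[item, timepoint]` matrices in `[0, 1]`) and `reportable` flags.
#' @export
subtype_profiles <- function(profiles, partition, min_report_size = 10) {
  stopifnot(inherits(partition, "subtype_partition"))
  arr <- as_profile_array(profiles)
  ids <- dimnames(arr)[[1]]
  if (!all(names(partition$labels) %in% ids))
    stop("partition refers to patients absent from the profiles")
  prof <- lapply(partition$communities, function(members) {
    idx <- match(members, ids)
    if (!length(idx)) stop("empty community in partition")
    s <- apply(arr[idx, , , drop = FALSE], c(2, 3), mean)
    dimnames(s) <- dimnames(arr)[2:3]
    s
  })
  partition$subtype_profiles <- prof
  partition$min_report_size <- min_report_size
  partition$reportable <- partition$sizes >= min_report_size
  partition
}

#' Run trajectory profile clustering end to end
#'
#' Composes [binarize()], [patient_similarity()], [louvain_cluster()] and
#' [subtype_profiles()]: patients are clustered into recovery subtypes with
#' high intra-subtype trajectory similarity, with the number of subtypes
#' chosen by modularity maximization.
#'
#' @inheritParams binarize
#' @inheritParams patient_similarity
#' @inheritParams louvain_cluster
#' @inheritParams subtype_profiles
#' @param threshold_mode passed to [binarize()] as `mode`.
#' @param verbose log threshold, community count, modularity and sizes.
#' @return A `subtype_partition` with subtype profiles attached, plus
#'   attributes `kappa` and `threshold_mode`.
#' @export
run_tpc <- function(cohort, kappa = 0.5, weights = NULL, seed = 1,
                    n_restarts = 20, min_report_size = 10,
                    threshold_mode = c("fraction", "median"),
                    verbose = TRUE) {
  threshold_mode <- match.arg(threshold_mode)
  prof <- binarize(cohort, kappa, mode = threshold_mode)
  if (all(prof == 0L))
    stop("degenerate network: binarization produced all-zero profiles ",
         "(threshold too high); no severe symptom expression to cluster")
  net <- patient_similarity(prof, weights = weights)
  part <- louvain_cluster(net, seed = seed, n_restarts = n_restarts)
  part <- subtype_profiles(prof, part, min_report_size = min_report_size)
  attr(part, "kappa") <- attr(prof, "kappa")
  attr(part, "threshold_mode") <- threshold_mode
  if (verbose)
    message("TPC: kappa=", attr(prof, "kappa"), " mode=", threshold_mode,
            " -> L=", part$n_communities,
            " communities (modularity=", format(part$modularity, digits = 4),
            "; sizes: ", paste(part$sizes, collapse = ", "), ")")
  part
}
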