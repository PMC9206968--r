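#' Per-patient symptom-symptom graphs at one visit
#'
#' Projects each patient's binary symptom vector at one timepoint onto
#' symptom space: `G_it = v v^T` where `v` is the patient's binarized
#' item vector at visit `t`. The result is a rank-at-most-one symmetric
#' 0/1 adjacency over the items; diagonal entry `(v, v)` is 1 iff symptom
#' `v` is severely expressed.
#'
#' @param profiles a `trajectory_profiles` array from [binarize()].
#' @param timepoint visit rank in `0..M-1`.
#' @return A named list (one per patient) of `V x V` binary matrices.
#' @export
build_symptom_graphs <- function(profiles, timepoint) {
  arr <- as_profile_array(profiles)
  m <- dim(arr)[3]
  if (!is.numeric(timepoint) || length(timepoint) != 1L ||
      timepoint < 0 || timepoint > m - 1)
    stop("timepoint must lie in 0..", m - 1)
  t1 <- as.integer(timepoint) + 1L
  ids <- dimnames(arr)[[1]]
  out <- lapply(seq_len(dim(arr)[1]), function(i) {
    v <- arr[i, , t1]
    g <- outer(v, v)
    storage.mode(g) <- "double"
    g
  })
  stats::setNames(out, ids)
}

# symmetric degree normalization with self-connections: D^-1/2 (G+I) D^-1/2
normalize_adjacency <- function(g) {
  a <- g + diag(nrow(g))
  d <- rowSums(a)
  a / sqrt(outer(d, d))
}

node_features <- function(g, features) {
  switch(features,
         onehot = diag(nrow(g)),
         degree = matrix(rowSums(g), ncol = 1),
         stop("unknown feature mode: ", features))
}

# Stack a graph set for full-batch propagation: block-diagonal normalized
# adjacency (sparse), pre-propagated features AF = Ahat %*% F, and the
# graph index of each node row.
gcn_batch <- function(graphs, features = "onehot") {
  ahat <- lapply(graphs, normalize_adjacency)
  af <- if (features == "onehot") {
    do.call(rbind, ahat)  # Ahat %*% I
  } else {
    do.call(rbind, Map(function(a, g) a %*% node_features(g, features),
                       ahat, graphs))
  }
  v <- nrow(graphs[[1]])
  list(bigA = Matrix::bdiag(ahat), AF = af,
       gidx = rep(seq_along(graphs), each = v), n = length(graphs), v = v,
       fdim = ncol(af))
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# forward pass on a stacked batch; returns intermediates for backprop
gcn_batch_forward <- function(w0, w1, batch) {
  z1 <- as.matrix(batch$AF %*% w0)
  h1 <- pmax(z1, 0)
  ah1 <- as.matrix(batch$bigA %*% h1)
  z2 <- ah1 %*% w1
  h2 <- pmax(z2, 0)
  r <- rowsum(h2, batch$gidx) / batch$v   # mean readout over nodes
  list(z1 = z1, h1 = h1, ah1 = ah1, z2 = z2, h2 = h2, r = r,
       prob = softmax_rows(r))
}

# mean cross-entropy loss and analytic gradients wrt W0, W1
gcn_loss_grad <- function(w0, w1, batch, y) {
  fw <- gcn_batch_forward(w0, w1, batch)
  n <- batch$n
  loss <- -mean(log(pmax(fw$prob[cbind(seq_len(n), y)], 1e-300)))
  dy <- fw$prob
  dy[cbind(seq_len(n), y)] <- dy[cbind(seq_len(n), y)] - 1
  dr <- dy / n
  dh2 <- dr[batch$gidx, , drop = FALSE] / batch$v
  dz2 <- dh2 * (fw$z2 > 0)
  dw1 <- crossprod(fw$ah1, dz2)
  dh1 <- as.matrix(batch$bigA %*% (dz2 %*% t(w1)))
  dz1 <- dh1 * (fw$z1 > 0)
  dw0 <- as.matrix(crossprod(batch$AF, dz1))
  list(loss = loss, dw0 = dw0, dw1 = dw1, prob = fw$prob)
}

glorot_init <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -lim, lim), nin, nout)
}

# stratified train/test split: within each class, shuffled assignment with
# at least one test case (and at least one training case) per class
stratified_split <- function(y, split_fraction) {
  train <- logical(length(y))
  for (cl in levels(y)) {
    idx <- which(y == cl)
    idx <- idx[sample.int(length(idx))]
    n_test <- max(1L, round((1 - split_fraction) * length(idx)))
    n_train <- length(idx) - n_test
    if (n_train < 1L)
      stop("split leaves no training example for class '", cl, "'")
    train[idx[seq_len(n_train)]] <- TRUE
  }
  train
}

#' Train a per-timepoint subtype classifier
#'
#' Fits a two-layer graph convolutional network on symptom-symptom graphs:
#' `H1 = ReLU(Ahat F W0)`, `H2 = ReLU(Ahat H1 W1)`, graph representation =
#' node-wise mean of `H2` (one output neuron per subtype), class
#' probabilities by softmax. `Ahat` is the symmetrically degree-normalized
#' adjacency with self-connections. Training minimizes mean cross-entropy
#' with full-batch ADAM on a seeded stratified 70/30 split and reports
#' held-out accuracy.
#'
#' @param graphs list of `V x V` binary adjacencies from
#'   [build_symptom_graphs()].
#' @param labels subtype label per graph (coerced to factor); at least two
#'   classes must be present.
#' @param split_fraction fraction of graphs used for training (default
#'   0.7).
#' @param epochs number of full-batch training epochs (default 100).
#' @param seed RNG seed controlling the split and the weight
#'   initialization.
#' @param hidden_units width of the hidden layer (default 64).
#' @param learning_rate ADAM step size (default 0.01; beta1 = 0.9,
#'   beta2 = 0.999, eps = 1e-8).
#' @param features node feature mode: `"onehot"` (identity features, one
#'   per item) or `"degree"`.
#' @return An object of class `gcn_fit`: list with `model` (weights and
#'   metadata), `accuracy` (held-out), `n_train`, `n_test` and `loss`
#'   (per-epoch training loss).
#' @export
train_timepoint_classifier <- function(graphs, labels, split_fraction = 0.7,
                                       epochs = 100, seed = 1,
                                       hidden_units = 64,
                                       learning_rate = 0.01,
                                       features = c("onehot", "degree")) {
  features <- match.arg(features)
  y <- factor(labels)
  if (nlevels(y) < 2L)
    stop("classification requires at least two subtype classes")
  if (length(graphs) != length(y))
    stop("one label per graph required")
  set.seed(seed)
  train <- stratified_split(y, split_fraction)
  if (!any(!train)) stop("empty test split")
  btr <- gcn_batch(graphs[train], features)
  bte <- gcn_batch(graphs[!train], features)
  ytr <- as.integer(y[train])
  yte <- as.integer(y[!train])
  k <- nlevels(y)
  w0 <- glorot_init(btr$fdim, hidden_units)
  w1 <- glorot_init(hidden_units, k)
  m0 <- v0 <- w0 * 0; m1 <- v1 <- w1 * 0
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  loss <- numeric(epochs)
  for (step in seq_len(epochs)) {
    g <- gcn_loss_grad(w0, w1, btr, ytr)
    loss[step] <- g$loss
    m0 <- b1 * m0 + (1 - b1) * g$dw0; v0 <- b2 * v0 + (1 - b2) * g$dw0^2
    m1 <- b1 * m1 + (1 - b1) * g$dw1; v1 <- b2 * v1 + (1 - b2) * g$dw1^2
    c1 <- 1 - b1^step; c2 <- 1 - b2^step
    w0 <- w0 - learning_rate * (m0 / c1) / (sqrt(v0 / c2) + eps)
    w1 <- w1 - learning_rate * (m1 / c1) / (sqrt(v1 / c2) + eps)
  }
  pte <- gcn_batch_forward(w0, w1, bte)$prob
  acc <- mean(max.col(pte, ties.method = "first") == yte)
  structure(list(
    model = list(w0 = w0, w1 = w1, hidden_units = hidden_units,
                 classes = levels(y), features = features),
    accuracy = acc, n_train = sum(train), n_test = sum(!train),
    loss = loss
  ), class = "gcn_fit")
}

#' Forward pass of the graph convolutional classifier on one graph
#'
#' @param model the `model` element of a [train_timepoint_classifier()]
#'   fit (or any list with `w0`, `w1`, `features`).
#' @param graph a `V x V` binary symmetric adjacency.
#' @param features optional override: a feature-mode string, or an explicit
#'   `V x d` node-feature matrix (e.g. to carry features through a node
#'   relabeling).
#' @return A probability vector over subtypes (sums to 1), named by class.
#' @export
gcn_forward <- function(model, graph, features = NULL) {
  if (!is.null(model$model)) model <- model$model
  g <- as.matrix(graph)
  a <- normalize_adjacency(g)
  f <- if (is.matrix(features)) features else
    node_features(g, if (is.null(features)) model$features else features)
  if (ncol(f) != nrow(model$w0))
    stop("feature dimension mismatch: model expects ", nrow(model$w0),
         ", features provide ", ncol(f))
  h1 <- pmax(a %*% f %*% model$w0, 0)
  h2 <- pmax(a %*% h1 %*% model$w1, 0)
  p <- drop(softmax_rows(matrix(colMeans(h2), nrow = 1)))
  stats::setNames(p, model$classes)
}

#' When do recovery subtypes become identifiable?
#'
#' For each visit, trains a fresh per-timepoint classifier on single-visit
#' symptom-symptom graphs, labeled by the full-trajectory subtypes, and
#' records held-out accuracy -- overall and per treatment arm. Patients in
#' non-reportable communities are excluded. Each (timepoint, slice) cell is
#' replicated over `replicates` seeds; the curve reports mean accuracy and
#' its standard error. Rising accuracy across visits means the subtypes
#' are determined by late-visit symptom configurations; accuracy near
#' chance at a visit means subtype membership is not yet expressed there.
#'
#' @param cohort a [cohort_tensor()] (arm labels required for arm slices).
#' @param partition a `subtype_partition` from [run_tpc()].
#' @param slices cohort slices to evaluate: subset of
#'   `c("all", "treated", "placebo")`. Arm slices are dropped with a
#'   message when the cohort has no arm labels.
#' @param replicates seeded training replicates per cell (default 10).
#' @param seed master seed; replicate `r` of timepoint `t` derives its own
#'   seed from it.
#' @inheritParams train_timepoint_classifier
#' @return A data frame of class `stratification_curve` with columns
#'   `timepoint`, `cohort`, `mean_accuracy`, `stderr`, `n_train`,
#'   `n_test`.
#' @export
stratification_analysis <- function(cohort, partition,
                                    slices = c("all", "treated", "placebo"),
                                    replicates = 10, seed = 1, epochs = 100,
                                    hidden_units = 64, learning_rate = 0.01,
                                    split_fraction = 0.7,
                                    features = c("onehot", "degree")) {
  stopifnot(inherits(cohort, "cohort_tensor"),
            inherits(partition, "subtype_partition"))
  features <- match.arg(features)
  slices <- match.arg(slices, several.ok = TRUE)
  if (is.null(cohort$arm) && any(slices != "all")) {
    message("no arm labels in cohort; dropping arm-specific slices")
    slices <- "all"
  }
  kappa <- attr(partition, "kappa")
  mode <- attr(partition, "threshold_mode")
  if (is.null(mode)) mode <- "fraction"
  if (is.null(kappa) || is.na(kappa)) kappa <- 0.5
  prof <- binarize(cohort, kappa, mode = mode)
  labels <- partition$labels[cohort$patients]
  keep <- !is.na(labels)
  if (!is.null(partition$reportable))
    keep <- keep & partition$reportable[labels]
  ids <- cohort$patients[keep]
  labels <- factor(labels[keep])
  rows <- list()
  for (tp in cohort$timepoints) {
    graphs_all <- build_symptom_graphs(prof, tp)[ids]
    for (sl in slices) {
      in_slice <- switch(sl, all = rep(TRUE, length(ids)),
                         treated = cohort$arm[ids] == "treated",
                         placebo = cohort$arm[ids] == "placebo")
      accs <- numeric(replicates)
      ntr <- nte <- NA_integer_
      for (r in seq_len(replicates)) {
        fit <- train_timepoint_classifier(
          graphs_all[in_slice], droplevels(labels[in_slice]),
          split_fraction = split_fraction, epochs = epochs,
          seed = seed + 1000L * tp + r, hidden_units = hidden_units,
          learning_rate = learning_rate, features = features)
        accs[r] <- fit$accuracy
        ntr <- fit$n_train; nte <- fit$n_test
      }
      rows[[length(rows) + 1L]] <- data.frame(
        timepoint = tp, cohort = sl, mean_accuracy = mean(accs),
        stderr = stats::sd(accs) / sqrt(replicates),
        n_train = ntr, n_test = nte, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("stratification_curve", class(out))
  out
}
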