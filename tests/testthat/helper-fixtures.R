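# small parcellation: 12 subregions in 3 bilateral regions of 4
toy_parc <- function(n_nodes = 12, n_regions = 3) {
  synthetic_parcellation(n_nodes, n_regions)
}

# random symmetric adjacency with zero diagonal and labelled nodes
rand_adj <- function(n, seed = 1) {
  set.seed(seed)
  W <- matrix(stats::runif(n * n), n)
  W <- (W + t(W)) / 2
  diag(W) <- 0
  lbl <- sprintf("n%02d", seq_len(n))
  dimnames(W) <- list(lbl, lbl)
  W
}

# cohort of random networks: first n_sd subjects SD, rest HC
rand_networks <- function(n_subj, n_nodes, seed = 1) {
  nets <- lapply(seq_len(n_subj), function(s) rand_adj(n_nodes, seed + s))
  names(nets) <- sprintf("sub-%03d", seq_len(n_subj))
  nets
}

# networks where edge (1,2) separates the groups by a wide margin and the
# remaining edges are identically distributed noise
separated_networks <- function(w_sd, w_hc, n_nodes = 3, seed = 1) {
  set.seed(seed)
  build_one <- function(w, id) {
    W <- matrix(stats::runif(n_nodes^2, 0.4, 0.6), n_nodes)
    W <- (W + t(W)) / 2
    diag(W) <- 0
    W[1, 2] <- W[2, 1] <- w
    lbl <- sprintf("n%02d", seq_len(n_nodes))
    dimnames(W) <- list(lbl, lbl)
    W
  }
  nets <- c(lapply(w_sd, build_one), lapply(w_hc, build_one))
  names(nets) <- sprintf("sub-%03d", seq_along(nets))
  list(networks = nets,
       groups = c(rep("SD", length(w_sd)), rep("HC", length(w_hc))))
}

# complete off-diagonal mask
complete_mask <- function(n, labels = sprintf("n%02d", seq_len(n))) {
  m <- matrix(TRUE, n, n, dimnames = list(labels, labels))
  diag(m) <- FALSE
  m
}

# small grid so model fits stay fast in tests
tiny_svm_config <- function(seed = 1) {
  svm_config(C_grid = 2^c(-1, 3, 7), gamma_grid = 2^c(-9, -5, -1),
             inner_folds = 3, seed = seed)
}

region_nodes_for_test <- function(parc, region) {
  parc$subregion_index[parc$merged_region == region]
}

# brute-force step-up BH definition, independent of the implementation
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (k in seq_len(m)) {
    q[o[k]] <- min(vapply(k:m, function(jj) min(1, m * p[o[jj]] / jj),
                          numeric(1)))
  }
  q
}

# pairwise-comparison AUC oracle: half credit for ties
pairwise_auc <- function(scores, labels, positive = "SD") {
  pos <- scores[labels == positive]
  neg <- scores[labels != positive]
  tot <- 0
  for (a in pos) for (b in neg) {
    tot <- tot + (a > b) + 0.5 * (a == b)
  }
  tot / (length(pos) * length(neg))
}
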