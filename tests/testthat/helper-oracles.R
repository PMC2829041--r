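# Shared helpers and independent oracles for the test suite.

# Independent connected-component oracle: label 4-connected components of a
# logical matrix via igraph, without touching the package's flood fill.
igraph_label <- function(active) {
  ny <- nrow(active); nt <- ncol(active)
  idx <- which(active)
  labels <- matrix(0L, ny, nt)
  if (!length(idx)) return(labels)
  id_of <- integer(ny * nt)
  id_of[idx] <- seq_along(idx)
  edges <- integer(0)
  for (cell in idx) {
    i <- ((cell - 1L) %% ny) + 1L
    j <- ((cell - 1L) %/% ny) + 1L
    if (i < ny && active[cell + 1L]) edges <- c(edges, id_of[cell], id_of[cell + 1L])
    if (j < nt && active[cell + ny]) edges <- c(edges, id_of[cell], id_of[cell + ny])
  }
  g <- igraph::make_graph(edges = edges, n = length(idx), directed = FALSE)
  labels[idx] <- as.integer(igraph::components(g)$membership)
  labels
}

# Map component labelings to a canonical form (components numbered by first
# cell in column-major order) so two labelings can be compared directly.
canonical_labels <- function(lab) {
  out <- matrix(0L, nrow(lab), ncol(lab))
  ids <- unique(lab[lab > 0][order(which(lab > 0))])
  for (k in seq_along(ids)) out[lab == ids[k]] <- k
  out
}

# Event-accepted canonical labeling from an oracle component labeling plus
# the two-threshold rule (component must contain a cell >= high).
oracle_events <- function(v, mask, low, high) {
  comp <- igraph_label((v >= low) & !mask)
  keep <- integer(0)
  for (k in seq_len(max(comp, 0)))
    if (any(v[comp == k] >= high)) keep <- c(keep, k)
  out <- matrix(0L, nrow(comp), ncol(comp))
  for (k in keep) out[comp == k] <- k
  canonical_labels(out)
}

# Parameter set whose only active channels are myosin recruitment/decay at
# frozen S (birth-death toy embedded in the production engine).
birth_death_params <- function() {
  base_case_params(k_ecm = 0, k_d_n = 0, k_a_s = 0, k_d_s = 0,
                   k_a_x = 0, k_d_x = 0, k_a_r = 0, k_d_r = 0,
                   k_a_p = 0, k_d_p = 0, p0 = 0)
}

# Uniformly sample a valid random discrete state (respecting P <= X <= N).
random_state <- function(max_n = 40) {
  N <- sample.int(max_n, 1)
  X <- sample.int(N + 1L, 1) - 1L
  P <- sample.int(X + 1L, 1) - 1L
  discrete_state(N = N, S = sample.int(20, 1), M = sample.int(60, 1),
                 X = X, R = sample.int(80, 1), P = P)
}
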