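#' @title Nodal and global graph measures on binary brain networks
#'
#' @description Measures follow the binary-graph conventions of the GRETNA /
#'   Brain Connectivity Toolbox school: clustering as realized neighbour
#'   edges over possible ones, path length as mean hop count over reachable
#'   pairs, efficiencies as means of inverse distances (1/Inf = 0),
#'   betweenness unnormalized, assortativity as the Pearson correlation of
#'   end-point degrees, hierarchy as the exponent beta of C(k) ~ k^-beta,
#'   and synchronization as the Laplacian eigenratio lambda2 / lambda_max.
#'   Small-world coefficients gamma, lambda and sigma = gamma/lambda
#'   normalize Cp and Lp by the means of a degree-preserving rewired null
#'   ensemble (default 100 networks).
#' @name graph-measures
NULL

as_adjacency <- function(net) {
  if (inherits(net, "binary_network")) net <- net$adjacency
  A <- as.matrix(net)
  if (nrow(A) != ncol(A)) stop("adjacency must be square")
  A
}

as_igraph <- function(net) {
  igraph::graph_from_adjacency_matrix(as_adjacency(net), mode = "undirected",
                                      diag = FALSE)
}

#' Degree centrality (row sums of the adjacency)
#' @param net binary network or adjacency matrix
#' @return integer vector of node degrees
#' @export
degree_centrality <- function(net) {
  as.integer(rowSums(as_adjacency(net)))
}

#' Clustering coefficient per node and its network mean Cp
#'
#' Realized edges among a node's neighbours over the possible
#' k(k-1)/2; nodes of degree < 2 have coefficient 0. Cp is the unweighted
#' mean over all nodes.
#'
#' @param net binary network or adjacency matrix
#' @return list: `nodal` (vector), `Cp` (scalar)
#' @export
clustering_coefficient <- function(net) {
  g <- as_igraph(net)
  ci <- igraph::transitivity(g, type = "local", isolates = "zero")
  ci[is.nan(ci)] <- 0
  list(nodal = ci, Cp = mean(ci))
}

#' All-pairs shortest-path hop distances
#' @param net binary network or adjacency matrix
#' @return n x n matrix of hop counts; unreachable pairs are `Inf`
#' @export
shortest_path_lengths <- function(net) {
  igraph::distances(as_igraph(net), algorithm = "unweighted")
}

#' Characteristic path length (mean over reachable pairs)
#'
#' Mean of finite off-diagonal distances only; at sparse densities the
#' binary network is often disconnected, so unreachable pairs are excluded
#' and their count is attached as `attr(, "excluded_pairs")` (unordered
#' pairs).
#'
#' @param distances matrix from [shortest_path_lengths()]
#' @return scalar Lp with attribute `excluded_pairs`
#' @export
characteristic_path_length <- function(distances) {
  d <- distances[upper.tri(distances)]
  fin <- is.finite(d)
  if (!any(fin)) stop("no reachable pairs; path length undefined")
  structure(mean(d[fin]), excluded_pairs = sum(!fin))
}

#' Nodal path length: mean hop distance from each node to reachable others
#' @param distances matrix from [shortest_path_lengths()]
#' @return per-node vector (NA for isolated nodes)
#' @export
nodal_path_length <- function(distances) {
  diag(distances) <- NA
  apply(distances, 1, function(r) {
    r <- r[is.finite(r)]
    if (length(r) == 0) NA_real_ else mean(r)
  })
}

#' Shortest-path betweenness centrality
#'
#' Unnormalized by default (the scale on which hub thresholds are set);
#' `normalized = TRUE` divides by (n-1)(n-2)/2.
#'
#' @param net binary network or adjacency matrix
#' @param normalized divide by the number of pairs excluding the node
#' @return per-node vector
#' @export
betweenness_centrality <- function(net, normalized = FALSE) {
  g <- as_igraph(net)
  b <- igraph::betweenness(g, directed = FALSE, normalized = FALSE)
  if (normalized) {
    n <- igraph::vcount(g)
    b <- b / ((n - 1) * (n - 2) / 2)
  }
  unname(b)
}

inv_dist <- function(distances) {
  iv <- 1 / distances
  iv[!is.finite(iv)] <- 0       # unreachable and the diagonal contribute 0
  diag(iv) <- 0
  iv
}

#' Global efficiency: mean inverse distance over all pairs
#' @param distances matrix from [shortest_path_lengths()]
#' @return scalar in [0, 1]
#' @export
global_efficiency <- function(distances) {
  n <- nrow(distances)
  if (n < 2) return(0)
  sum(inv_dist(distances)) / (n * (n - 1))
}

#' Nodal efficiency: mean inverse distance from one node to all others
#' @param distances matrix from [shortest_path_lengths()]
#' @return per-node vector in [0, 1]
#' @export
nodal_efficiency <- function(distances) {
  n <- nrow(distances)
  rowSums(inv_dist(distances)) / (n - 1)
}

#' Local efficiency: efficiency of each node's neighbour subgraph
#'
#' Per node, the global efficiency of the subgraph induced by its
#' neighbours (0 when degree < 2); the network value is the mean over nodes.
#'
#' @param net binary network or adjacency matrix
#' @return list: `nodal` (vector), `network` (scalar)
#' @export
local_efficiency <- function(net) {
  A <- as_adjacency(net)
  n <- nrow(A)
  nodal <- vapply(seq_len(n), function(i) {
    nb <- which(A[i, ] == 1)
    if (length(nb) < 2) return(0)
    sub <- A[nb, nb, drop = FALSE]
    global_efficiency(shortest_path_lengths(sub))
  }, 0)
  list(nodal = nodal, network = mean(nodal))
}

#' Degree assortativity (Newman)
#'
#' Pearson correlation of the degrees at the two ends of every edge, both
#' orientations counted. Undefined (returned as NA) when all degrees are
#' equal.
#'
#' @param net binary network or adjacency matrix
#' @return scalar in [-1, 1] or NA
#' @export
assortativity_degree <- function(net) {
  A <- as_adjacency(net)
  if (sum(A) / 2 < 2) stop("need at least 2 edges")
  r <- suppressWarnings(igraph::assortativity_degree(as_igraph(net)))
  if (is.nan(r)) NA_real_ else r
}

#' Hierarchy exponent beta of C(k) ~ k^-beta
#'
#' Least-squares slope of log clustering on log degree over nodes with
#' degree >= 2 and positive clustering; beta is the negated slope. NA when
#' fewer than two distinct degrees qualify.
#'
#' @param net binary network or adjacency matrix
#' @return scalar beta or NA
#' @export
hierarchy <- function(net) {
  k <- degree_centrality(net)
  ci <- clustering_coefficient(net)$nodal
  ok <- k >= 2 & ci > 0
  if (sum(ok) < 2 || length(unique(k[ok])) < 2) return(NA_real_)
  fit <- stats::lm.fit(cbind(1, log(k[ok])), log(ci[ok]))
  -unname(fit$coefficients[2])
}

#' Synchronization: Laplacian eigenratio lambda2 / lambda_max
#'
#' Ratio of the second-smallest to the largest eigenvalue of the graph
#' Laplacian L = D - A; 0 for a disconnected network (lambda2 = 0).
#'
#' @param net binary network or adjacency matrix
#' @return scalar in [0, 1]
#' @export
synchronization <- function(net) {
  A <- as_adjacency(net)
  L <- diag(rowSums(A)) - A
  ev <- sort(eigen(L, symmetric = TRUE, only.values = TRUE)$values)
  if (ev[length(ev)] <= .Machine$double.eps) return(0)
  l2 <- ev[2]
  if (l2 < 1e-10) return(0)
  l2 / ev[length(ev)]
}

#' Degree-preserving rewiring (Markov chain of double-edge swaps)
#'
#' Repeatedly picks two disjoint edges (a,b), (c,d) and replaces them with
#' (a,d), (c,b) when no self-loop or multi-edge would result. Node count,
#' edge count and the full degree sequence are invariant.
#'
#' @param net binary network or adjacency matrix
#' @param n_swaps number of swap trials (default 10 x edge count)
#' @param seed integer seed
#' @return rewired adjacency matrix
#' @export
rewire_degree_preserving <- function(net, n_swaps = NULL, seed = 1L) {
  g <- as_igraph(net)
  if (is.null(n_swaps)) n_swaps <- 10L * igraph::ecount(g)
  if (n_swaps == 0) return(as_adjacency(net))
  with_seed(seed, {
    gr <- igraph::rewire(g, igraph::keeping_degseq(niter = n_swaps))
    A <- as.matrix(igraph::as_adjacency_matrix(gr, sparse = FALSE))
    dimnames(A) <- NULL
    A
  })
}

largest_component <- function(A) {
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected",
                                           diag = FALSE)
  comp <- igraph::components(g)
  keep <- which(comp$membership == which.max(comp$csize))
  A[keep, keep, drop = FALSE]
}

#' Small-world coefficients against a rewired null ensemble
#'
#' gamma = Cp / mean C(rand), lambda = Lp / mean L(rand), sigma =
#' gamma / lambda, with C(rand) and L(rand) averaged over `n_random`
#' degree-preserving rewired networks. Computed on the largest connected
#' component when the input is disconnected (coverage returned).
#'
#' @param net binary network or adjacency matrix
#' @param n_random null-ensemble size (default 100)
#' @param seed integer seed for the ensemble
#' @param n_swaps swap trials per null (default 10 x edge count)
#' @return list: `gamma`, `lambda`, `sigma`, `Cp`, `Lp`, `C_rand`, `L_rand`,
#'   `component_coverage` (fraction of nodes in the component used)
#' @export
small_world_coefficients <- function(net, n_random = 100L, seed = 1L,
                                     n_swaps = NULL) {
  A <- as_adjacency(net)
  Ac <- largest_component(A)
  coverage <- nrow(Ac) / nrow(A)
  Cp <- clustering_coefficient(Ac)$Cp
  Lp <- as.numeric(characteristic_path_length(shortest_path_lengths(Ac)))
  Cr <- Lr <- numeric(n_random)
  for (r in seq_len(n_random)) {
    An <- rewire_degree_preserving(Ac, n_swaps = n_swaps,
                                   seed = derive_seed(seed, r))
    Cr[r] <- clustering_coefficient(An)$Cp
    Lr[r] <- as.numeric(characteristic_path_length(shortest_path_lengths(An)))
  }
  C_rand <- mean(Cr)
  L_rand <- mean(Lr)
  if (C_rand == 0) stop("null ensemble has zero mean clustering")
  gamma <- Cp / C_rand
  lambda <- Lp / L_rand
  list(gamma = gamma, lambda = lambda, sigma = gamma / lambda,
       Cp = Cp, Lp = Lp, C_rand = C_rand, L_rand = L_rand,
       component_coverage = coverage)
}

#' Average a per-density series over the sparsity sweep
#'
#' Trapezoidal integral over density divided by the density range: a
#' threshold-free summary on the same scale as the metric itself (a
#' constant series averages to itself).
#'
#' @param values numeric series, one value per density
#' @param sweep the densities
#' @return scalar
#' @export
auc_over_sparsity <- function(values, sweep) {
  if (length(values) != length(sweep)) stop("series and sweep lengths differ")
  if (any(!is.finite(values))) stop("non-finite values in series")
  if (length(sweep) == 1) return(values)
  dx <- diff(sweep)
  auc <- sum(dx * (utils::head(values, -1) + utils::tail(values, -1)) / 2)
  auc / (sweep[length(sweep)] - sweep[1])
}

globals_for <- function(A, n_random, seed, include_smallworld) {
  D <- shortest_path_lengths(A)
  cc <- clustering_coefficient(A)
  le <- local_efficiency(A)
  out <- c(Cp = cc$Cp,
           Lp = as.numeric(characteristic_path_length(D)),
           global_efficiency = global_efficiency(D),
           local_efficiency = le$network,
           assortativity = assortativity_degree(A),
           hierarchy = hierarchy(A),
           synchronization = synchronization(A))
  if (include_smallworld) {
    sw <- small_world_coefficients(A, n_random = n_random, seed = seed)
    out <- c(out, gamma = sw$gamma, lambda = sw$lambda, sigma = sw$sigma)
  }
  out
}

nodal_metric_names <- c("degree", "betweenness", "clustering",
                        "nodal_path_length", "nodal_efficiency",
                        "nodal_local_efficiency")

nodals_for <- function(A) {
  D <- shortest_path_lengths(A)
  rbind(degree = degree_centrality(A),
        betweenness = betweenness_centrality(A),
        clustering = clustering_coefficient(A)$nodal,
        nodal_path_length = nodal_path_length(D),
        nodal_efficiency = nodal_efficiency(D),
        nodal_local_efficiency = local_efficiency(A)$nodal)
}

#' Compute every nodal and global measure across a subject's density sweep
#'
#' @param networks list of `binary_network` from [sweep_networks()]
#' @param sweep densities matching `networks`
#' @param n_random null-ensemble size for gamma/lambda/sigma
#' @param seed integer seed (null ensembles are derived per density)
#' @param include_smallworld compute the rewired-null normalized
#'   coefficients (set FALSE for reduced, null-free metric sets)
#' @param subject_id optional identifier carried into the result
#' @return list of class `metric_table`: `global` (density x metric
#'   data.frame), `nodal` (array density x metric x node), `auc_global`
#'   (named vector), `auc_nodal` (metric x node matrix), `sweep`,
#'   `subject_id`
#' @export
compute_metric_table <- function(networks, sweep = density_sweep(),
                                 n_random = 100L, seed = 1L,
                                 include_smallworld = TRUE,
                                 subject_id = NA_character_) {
  if (length(networks) != length(sweep)) stop("networks and sweep differ")
  n <- nrow(as_adjacency(networks[[1]]))
  gnames <- c("Cp", "Lp", "global_efficiency", "local_efficiency",
              "assortativity", "hierarchy", "synchronization")
  if (include_smallworld) gnames <- c(gnames, "gamma", "lambda", "sigma")
  G <- matrix(NA_real_, length(sweep), length(gnames),
              dimnames = list(NULL, gnames))
  N <- array(NA_real_, c(length(sweep), length(nodal_metric_names), n),
             dimnames = list(NULL, nodal_metric_names, NULL))
  for (i in seq_along(sweep)) {
    A <- as_adjacency(networks[[i]])
    G[i, ] <- globals_for(A, n_random, derive_seed(seed, i),
                          include_smallworld)
    N[i, , ] <- nodals_for(A)
  }
  auc_global <- vapply(gnames, function(m) {
    v <- G[, m]
    if (any(!is.finite(v))) return(NA_real_)
    auc_over_sparsity(v, sweep)
  }, 0)
  auc_nodal <- matrix(NA_real_, length(nodal_metric_names), n,
                      dimnames = list(nodal_metric_names, NULL))
  for (m in nodal_metric_names) {
    for (j in seq_len(n)) {
      v <- N[, m, j]
      auc_nodal[m, j] <- if (any(!is.finite(v))) NA_real_ else
        auc_over_sparsity(v, sweep)
    }
  }
  structure(list(global = as.data.frame(cbind(density = sweep, G)),
                 nodal = N, auc_global = auc_global, auc_nodal = auc_nodal,
                 sweep = sweep, subject_id = subject_id),
            class = "metric_table")
}
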