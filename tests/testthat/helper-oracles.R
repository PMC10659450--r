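# Independent oracles: igraph for acyclicity / graph structure, exhaustive
# depth-first search for longest paths. These never call the package's own
# Kahn/DP kernels.

h_debruijn_igraph <- function(space) {
  from <- rep(0:(space$n_kmers - 1L), each = space$sigma)
  to <- as.vector(vapply(0:(space$n_kmers - 1L),
                         function(u) kmer_successors(u, space),
                         integer(space$sigma)))
  igraph::graph_from_edgelist(cbind(from, to) + 1L, directed = TRUE)
}

h_oracle_is_decycling <- function(members, space) {
  g <- h_debruijn_igraph(space)
  igraph::is_dag(igraph::delete_vertices(g, members + 1L))
}

# longest path in vertex counts by exhaustive DFS over all simple paths
h_oracle_rpl_vertices <- function(members, space) {
  rem <- setdiff(0:(space$n_kmers - 1L), members)
  adj <- lapply(rem, function(u) intersect(kmer_successors(u, space), rem))
  names(adj) <- as.character(rem)
  best <- 0L
  dfs <- function(u, depth) {
    if (depth > best) best <<- depth
    for (v in adj[[as.character(u)]]) dfs(v, depth + 1L)
  }
  for (u in rem) dfs(u, 1L)
  best
}

# a decycling set built from an MDS plus a few random extra k-mers
# (supersets of decycling sets are decycling)
h_random_decycling_set <- function(space, n_extra = 3L) {
  M <- random_mds_walk(mykkeltveit_set(space), n_moves = 5L)
  extra <- sample(0:(space$n_kmers - 1L), n_extra)
  kmer_set(union(M$members, extra), space)
}

# the F-move graph over an explicit list of kmer_sets, as an igraph;
# nodes indexed by position in `sets`
h_fmove_igraph <- function(sets) {
  keys <- vapply(sets, format, "")
  edges <- integer(0)
  for (i in seq_along(sets)) {
    for (f in valid_f_moves(sets[[i]])) {
      j <- match(format(apply_f_move(sets[[i]], f)), keys)
      if (!is.na(j)) edges <- c(edges, i, j)
    }
  }
  igraph::graph_from_edgelist(matrix(edges, ncol = 2, byrow = TRUE),
                              directed = TRUE)
}

h_all_mds <- local({
  cache <- list()
  function(k) {
    key <- as.character(k)
    if (is.null(cache[[key]]))
      cache[[key]] <<- brute_force_mds(kmer_space(2, k))
    cache[[key]]
  }
})
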