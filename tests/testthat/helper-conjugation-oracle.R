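# independent all-pairs BFS (plain queue, no igraph) over a conjugated system
bfs_diameter <- function(mol, atoms) {
  adj <- lapply(seq_len(nrow(mol$atoms)), function(a) integer())
  for (r in seq_len(nrow(mol$bonds))) {
    i <- mol$bonds$i[r]; j <- mol$bonds$j[r]
    if (i %in% atoms && j %in% atoms) {
      adj[[i]] <- c(adj[[i]], j)
      adj[[j]] <- c(adj[[j]], i)
    }
  }
  best <- 0
  for (s in atoms) {
    dist <- rep(NA_integer_, nrow(mol$atoms))
    dist[s] <- 0L
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (w in adj[[v]]) {
        if (is.na(dist[w])) {
          dist[w] <- dist[v] + 1L
          queue <- c(queue, w)
        }
      }
    }
    best <- max(best, max(dist[atoms], na.rm = TRUE))
  }
  best
}

oracle_L <- function(mol) {
  systems <- perceive_conjugated_systems(mol)
  if (!length(systems)) return(0L)
  max(vapply(systems, function(s) bfs_diameter(mol, s$atom_indices), 0))
}

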