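# shared fixtures: all graphs are built in code at test time

# connected Erdos-Renyi draw (resampled until connected)
random_connected_graph <- function(n, p = 0.25, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  repeat {
    ig <- igraph::sample_gnp(n, p)
    if (igraph::is_connected(ig) && igraph::ecount(ig) > 0) {
      igraph::V(ig)$name <- as.character(seq_len(n))
      return(dd_graph(ig))
    }
  }
}

# star on n nodes, hub first
star_graph <- function(n) {
  ig <- igraph::make_star(n, mode = "undirected", center = 1)
  igraph::V(ig)$name <- as.character(seq_len(n))
  dd_graph(ig)
}

two_node_graph <- function(w = 1) {
  dd_graph(data.frame(from = "a", to = "b", weight = w))
}

write_edgelist_file <- function(lines) {
  path <- withr::local_tempfile(fileext = ".txt",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
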