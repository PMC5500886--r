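# Shared fixtures: small databases and trees built in code.

toy_db_rows <- function() {
  data.frame(
    study_id = c("s1", "s1", "s2", "s2", "s3"),
    host_species = c("aphid", "aphid", "weevil", "tubeworm", "tubeworm"),
    symbiont_species = c("Buchnera", "Buchnera", "Nardonella", "Endoriftia",
                         "Endoriftia"),
    fitness_with = c(10, 20, 8, 5, 12),
    fitness_without = c(4.8, 10, 2, 4, 12),
    measure_type = c("fecundity", "fecundity", "size_mass", "survival",
                     "resistance"),
    sample_size = c(10L, 20L, 5L, 8L, 12L),
    transmission = c("vertical", "vertical", "vertical", "horizontal",
                     "horizontal"),
    func = c("nutritional", "nutritional", "nutritional", "nutritional",
             "nutritional"),
    localization = c("intracellular", "intracellular", "intracellular",
                     "extracellular", "extracellular"),
    obligacy = c("obligate", "obligate", "obligate", "facultative",
                 "facultative"),
    genome_size = c(4.0, 6.0, NA, 3.4, 3.4),
    age = c(150, 150, NA, NA, NA),
    stringsAsFactors = FALSE
  )
}

write_toy_db <- function(rows = toy_db_rows()) {
  path <- tempfile(fileext = ".csv")
  write.csv(rows, path, row.names = FALSE, na = "")
  path
}

# Independent Grafen oracle: node heights ((d-1)/(n-1))^rho computed by a
# plain recursion over the edge table, then shared root-to-MRCA depths by
# enumeration over tip pairs.
grafen_vcv_oracle <- function(tree, rho = 1) {
  ntip <- length(tree$tip.label)
  n_nodes <- ntip + tree$Nnode
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  n_desc <- integer(n_nodes)
  count_desc <- function(node) {
    if (node <= ntip) return(1L)
    s <- sum(vapply(kids[[as.character(node)]], count_desc, 1L))
    n_desc[node] <<- s
    s
  }
  count_desc(ntip + 1L)
  height <- ifelse(seq_len(n_nodes) <= ntip, 0,
                   ((n_desc - 1) / (ntip - 1))^rho)
  parent <- integer(n_nodes)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  ancestors <- function(tip) {
    path <- tip
    while (path[length(path)] != ntip + 1L)
      path <- c(path, parent[path[length(path)]])
    path
  }
  A <- matrix(0, ntip, ntip, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(ntip)) for (j in seq_len(ntip)) {
    # MRCA = shared ancestor closest to the tips (minimum Grafen height);
    # shared root-to-MRCA path length = root height (1) - MRCA height
    shared <- intersect(ancestors(i), ancestors(j))
    A[i, j] <- 1 - min(height[shared])
  }
  A
}
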