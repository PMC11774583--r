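# Independent oracles and small fixture builders shared across tests.

# Patristic distance by explicit root-path walk: climb parent pointers from
# each tip, then subtract twice the shared prefix (LCA depth). Independent of
# the cophenetic-based implementation path.
oracle_patristic <- function(tree) {
  ntip <- length(tree$tip.label)
  parent <- integer(ntip + tree$Nnode)
  elen <- numeric(ntip + tree$Nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  elen[tree$edge[, 2]] <- tree$edge.length
  root <- ntip + 1L
  path_to_root <- function(v) {
    nodes <- v
    while (v != root) {
      v <- parent[v]
      nodes <- c(nodes, v)
    }
    nodes
  }
  depth <- function(v) {
    d <- 0
    while (v != root) {
      d <- d + elen[v]
      v <- parent[v]
    }
    d
  }
  m <- matrix(0, ntip, ntip, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(ntip - 1)) {
    pi_ <- path_to_root(i)
    for (j in (i + 1):ntip) {
      pj <- path_to_root(j)
      lca <- intersect(pi_, pj)[1]
      d <- depth(i) + depth(j) - 2 * depth(lca)
      m[i, j] <- d
      m[j, i] <- d
    }
  }
  m
}

# Step-up Benjamini-Hochberg from first principles.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# Step-down Holm from first principles.
oracle_holm <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- (m - seq_len(m) + 1) * p[o]
  adj <- cummax(adj)
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# Random labeled symmetric distance matrix with zero diagonal.
random_dist_matrix <- function(n, labels = paste0("L", seq_len(n))) {
  m <- matrix(stats::runif(n * n), n, n)
  m <- (m + t(m)) / 2
  diag(m) <- 0
  dimnames(m) <- list(labels, labels)
  m
}

# Random tree with strictly positive branch lengths and unique labels.
random_tree <- function(n, prefix = "t") {
  tr <- ape::rtree(n, br = function(k) stats::runif(k, 0.1, 1))
  tr$tip.label <- paste0(prefix, seq_len(n))
  tr
}

tree_from_text <- function(txt) codivscan:::parse_newick_text(txt)

# Tiny fully consistent toy dataset: 2 host taxa x 2 sites x 2 strains each.
toy_dataset <- function() {
  tree <- tree_from_text(
    "((a1:0.1,a2:0.1):1,(b1:0.1,b2:0.1):1);")
  host_tree <- tree_from_text("(HA:1,HB:1);")
  metadata <- data.frame(
    tip_id = c("a1", "a2", "b1", "b2"),
    host_taxon_id = c("HA", "HA", "HB", "HB"),
    host_genus = c("GenA", "GenA", "GenB", "GenB"),
    site_id = c("X", "Y", "X", "Y"),
    phylum = "P1", genus = "g1",
    stringsAsFactors = FALSE
  )
  sites <- data.frame(site_id = c("X", "Y"),
                      latitude = c(0, 1), longitude = c(0, 1),
                      stringsAsFactors = FALSE)
  list(tree = tree, metadata = metadata, sites = sites, host_tree = host_tree)
}
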