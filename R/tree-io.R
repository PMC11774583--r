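#' Read a rooted, branch-length-bearing phylogeny from a Newick file
#'
#' Thin validating wrapper around [ape::read.tree()]. The returned tree is an
#' ape \code{phylo} object with unique tip labels and a branch length on every
#' edge; these are the invariants the downstream clade scan relies on (a
#' silently missing length would corrupt the distal-tenth criterion).
#'
#' @param path Path to a Newick file. Quoted labels, internal-node support
#'   labels and square-bracket comments are tolerated.
#' @param assume_zero_lengths If \code{TRUE}, edges without a stated branch
#'   length are assigned length 0 instead of raising an error.
#' @return An object of class \code{phylo}.
#' @export
read_newick <- function(path, assume_zero_lengths = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  tree <- parse_newick_text(txt, source = path,
                            assume_zero_lengths = assume_zero_lengths)
  tree
}

# Shared parser used by read_newick() and the synthetic generator.
parse_newick_text <- function(txt, source = "<text>",
                              assume_zero_lengths = FALSE) {
  # cheap structural pre-check so malformed input reports a position
  stripped <- gsub("\\[[^]]*\\]", "", txt)  # drop bracket comments
  depth <- 0L
  chars <- strsplit(stripped, "")[[1]]
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L) {
        stop("malformed Newick in ", source,
             ": unbalanced ')' at character ", i, call. = FALSE)
      }
    }
  }
  if (depth != 0L) {
    stop("malformed Newick in ", source, ": ", depth,
         " unclosed '(' at end of input", call. = FALSE)
  }
  tree <- tryCatch(
    ape::read.tree(text = stripped),
    error = function(e) NULL, warning = function(w) NULL
  )
  if (is.null(tree) || !inherits(tree, "phylo")) {
    stop("malformed Newick in ", source, ": ape parser failed", call. = FALSE)
  }
  if (anyDuplicated(tree$tip.label)) {
    dups <- unique(tree$tip.label[duplicated(tree$tip.label)])
    stop("duplicate tip labels in ", source, ": ",
         paste(dups, collapse = ", "), call. = FALSE)
  }
  if (is.null(tree$edge.length)) {
    if (assume_zero_lengths) {
      tree$edge.length <- rep(0, nrow(tree$edge))
    } else {
      stop("tree in ", source, " has no branch lengths ",
           "(use assume_zero_lengths = TRUE to map them to 0)",
           call. = FALSE)
    }
  }
  if (anyNA(tree$edge.length)) {
    if (assume_zero_lengths) {
      tree$edge.length[is.na(tree$edge.length)] <- 0
    } else {
      stop("tree in ", source, " has edges with missing branch lengths",
           call. = FALSE)
    }
  }
  if (any(tree$edge.length < 0)) {
    stop("tree in ", source, " has negative branch lengths", call. = FALSE)
  }
  tree
}

#' Write a phylogeny to a Newick file
#'
#' @param tree A \code{phylo} object.
#' @param path Output file path.
#' @param digits Significant digits for branch lengths (default 10, enough for
#'   lossless round-tripping of the package's own outputs).
#' @return \code{path}, invisibly.
#' @export
write_newick <- function(tree, path, digits = 10) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree, file = path, digits = digits)
  invisible(path)
}

#' Patristic (tip-to-tip path-length) distance matrix
#'
#' Entry (i, j) is the sum of branch lengths along the unique path between
#' tips i and j.
#'
#' @param tree A \code{phylo} object with branch lengths.
#' @param tips Optional character vector restricting the matrix to a subset of
#'   tip labels (order preserved). Default: all tips, in tree order.
#' @return A labeled symmetric numeric matrix with zero diagonal.
#' @export
patristic_distances <- function(tree, tips = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) stop("tree has no branch lengths", call. = FALSE)
  d <- ape::cophenetic.phylo(tree)
  if (!is.null(tips)) {
    missing <- setdiff(tips, rownames(d))
    if (length(missing)) {
      stop("unknown tip label(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    d <- d[tips, tips, drop = FALSE]
  }
  assert_distance_matrix(d, "patristic matrix")
  d
}

#' Cross-check a strain tree, its tip metadata, the site table and host tree
#'
#' Produces a report of referential-integrity problems rather than raising on
#' the first one: bacterial tips without a metadata row, metadata rows whose
#' tip is absent from the tree, and metadata referencing unknown host taxa or
#' sites. A dataset is valid iff all lists are empty.
#'
#' @param tree Strain phylogeny (\code{phylo}).
#' @param metadata Tip metadata data frame with columns \code{tip_id},
#'   \code{host_taxon_id}, \code{host_genus}, \code{site_id}, \code{phylum},
#'   \code{genus}.
#' @param sites Site table with columns \code{site_id}, \code{latitude},
#'   \code{longitude}.
#' @param host_tree Host phylogeny whose tips are host taxon identifiers.
#' @return An object of class \code{codiv_validation}: a list with logical
#'   \code{valid} and character vectors \code{tips_missing_metadata},
#'   \code{metadata_missing_tips}, \code{unknown_host_taxa},
#'   \code{unknown_sites}, \code{duplicate_tip_ids}.
#' @export
validate_dataset <- function(tree, metadata, sites, host_tree) {
  stopifnot(inherits(tree, "phylo"), inherits(host_tree, "phylo"))
  req <- c("tip_id", "host_taxon_id", "host_genus", "site_id")
  miss_cols <- setdiff(req, names(metadata))
  if (length(miss_cols)) {
    stop("metadata lacks column(s): ", paste(miss_cols, collapse = ", "),
         call. = FALSE)
  }
  if (!all(c("site_id", "latitude", "longitude") %in% names(sites))) {
    stop("site table must have columns site_id, latitude, longitude",
         call. = FALSE)
  }
  res <- list(
    tips_missing_metadata = setdiff(tree$tip.label, metadata$tip_id),
    metadata_missing_tips = setdiff(metadata$tip_id, tree$tip.label),
    unknown_host_taxa = sort(unique(
      metadata$host_taxon_id[!metadata$host_taxon_id %in% host_tree$tip.label])),
    unknown_sites = sort(unique(
      metadata$site_id[!metadata$site_id %in% sites$site_id])),
    duplicate_tip_ids = unique(metadata$tip_id[duplicated(metadata$tip_id)])
  )
  res$valid <- all(lengths(res) == 0)
  class(res) <- "codiv_validation"
  res
}

#' @export
print.codiv_validation <- function(x, ...) {
  cat("Dataset validation:", if (x$valid) "VALID" else "INVALID", "\n")
  for (nm in setdiff(names(x), "valid")) {
    if (length(x[[nm]])) {
      cat("  ", nm, " (", length(x[[nm]]), "): ",
          paste(utils::head(x[[nm]], 5), collapse = ", "),
          if (length(x[[nm]]) > 5) ", ..." else "", "\n", sep = "")
    }
  }
  invisible(x)
}

#' Total branch length of a tree
#'
#' @param tree A \code{phylo} object with branch lengths.
#' @return Sum of all edge lengths.
#' @export
total_branch_length <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  sum(tree$edge.length)
}

# Per-node clade statistics in one postorder pass.
#
# For every node (tips and internals) of `phy` computes: the set of descendant
# tip labels, the number of tips, the maximum tip-to-tip path length within
# the clade ("diameter"), the maximal root-to-tip depth ("height"), and the
# sum of branch lengths of edges strictly inside the clade. Handles
# multifurcations. Returns a list of per-node vectors indexed by ape node
# number, plus the tree-wide maximum tip-to-tip distance.
clade_table <- function(phy) {
  stopifnot(inherits(phy, "phylo"))
  ntip <- length(phy$tip.label)
  ntot <- ntip + phy$Nnode
  po <- ape::reorder.phylo(phy, "postorder")
  E <- po$edge
  L <- po$edge.length
  height <- numeric(ntot)
  diam <- numeric(ntot)
  subtree_bl <- numeric(ntot)
  n_tips <- integer(ntot)
  n_tips[seq_len(ntip)] <- 1L
  tipsets <- vector("list", ntot)
  tipsets[seq_len(ntip)] <- as.list(phy$tip.label)
  child_heights <- vector("list", ntot)
  for (k in seq_len(nrow(E))) {
    p <- E[k, 1]; ch <- E[k, 2]; w <- L[k]
    n_tips[p] <- n_tips[p] + n_tips[ch]
    subtree_bl[p] <- subtree_bl[p] + subtree_bl[ch] + w
    tipsets[[p]] <- c(tipsets[[p]], tipsets[[ch]])
    hc <- height[ch] + w
    child_heights[[p]] <- c(child_heights[[p]], hc)
    height[p] <- max(height[p], hc)
  }
  # diameter at each node = max over its subtree of the local two-deepest
  # child-height sum; compute the local part, then propagate maxima rootward
  # in a second postorder pass
  internal <- (ntip + 1L):ntot
  for (v in internal) {
    hs <- child_heights[[v]]
    if (length(hs) >= 2) {
      hs <- sort(hs, decreasing = TRUE)
      diam[v] <- max(diam[v], hs[1] + hs[2])
    }
  }
  for (k in seq_len(nrow(E))) {
    p <- E[k, 1]; ch <- E[k, 2]
    diam[p] <- max(diam[p], diam[ch])
  }
  # edge subtending each node (NA for the root)
  stem_len <- rep(NA_real_, ntot)
  stem_len[phy$edge[, 2]] <- phy$edge.length
  list(
    n_tips = n_tips,
    diameter = diam,
    height = height,
    subtree_branch_length = subtree_bl,
    stem_length = stem_len,
    tipsets = tipsets,
    tree_diameter = max(diam),
    root = ntip + 1L,
    ntip = ntip
  )
}
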