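#' Parse a Newick tree string
#'
#' Parses a rooted Newick string into an \code{ape} \code{phylo} object and
#' validates the contract the downstream relatedness-matrix code relies on:
#' unique tip labels, non-negative branch lengths, and no mixture of present
#' and absent branch lengths.
#'
#' @param text A Newick string terminated by ';'. Quoted labels and polytomies
#'   are supported.
#' @return An \code{ape::phylo} object.
#' @export
parse_newick <- function(text) {
  text <- trimws(text)
  if (!nzchar(text) || !grepl(";\\s*$", text))
    stop("newick parse error: string must be terminated by ';'")
  n_open <- lengths(regmatches(text, gregexpr("(", text, fixed = TRUE)))
  n_close <- lengths(regmatches(text, gregexpr(")", text, fixed = TRUE)))
  if (n_open != n_close)
    stop("newick parse error: unbalanced parentheses (", n_open, " '(' vs ",
         n_close, "')')")
  tree <- tryCatch(ape::read.tree(text = text),
                   error = function(e) stop("newick parse error: ", conditionMessage(e)),
                   warning = function(w) stop("newick parse error: ", conditionMessage(w)))
  if (is.null(tree)) stop("newick parse error: could not parse tree")
  validate_phylogeny(tree)
  tree
}

#' Read a Newick tree from a file
#'
#' @param path Path to a file containing one Newick tree.
#' @return An \code{ape::phylo} object.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  parse_newick(paste(readLines(path, warn = FALSE), collapse = ""))
}

validate_phylogeny <- function(tree) {
  if (anyDuplicated(tree$tip.label))
    stop("newick parse error: duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]), collapse = ", "))
  if (!is.null(tree$edge.length)) {
    if (any(is.na(tree$edge.length)))
      stop("mixed tree rejected: some but not all branch lengths present")
    if (any(tree$edge.length < 0))
      stop("newick parse error: negative branch length (edge ",
           which(tree$edge.length < 0)[1], ")")
  }
  invisible(tree)
}

has_branch_lengths <- function(tree) !is.null(tree$edge.length)

#' Prune a phylogeny to a set of taxa
#'
#' Returns the induced subtree on \code{keep}: degree-2 internal nodes are
#' collapsed with their branch lengths summed, so root-to-tip distances of the
#' kept taxa are preserved.
#'
#' @param tree An \code{ape::phylo} object.
#' @param keep Character vector of tip labels to retain (>= 2).
#' @return The pruned \code{phylo} object.
#' @export
prune_to_taxa <- function(tree, keep) {
  keep <- unique(trimws(keep))
  missing <- setdiff(keep, tree$tip.label)
  if (length(missing) > 0)
    stop("taxa not in tree: ", paste(missing, collapse = ", "))
  if (length(keep) < 2)
    stop("cannot prune to fewer than 2 taxa")
  if (setequal(keep, tree$tip.label)) return(tree)
  depth_of <- function(tr, tip) {
    d <- ape::node.depth.edgelength(tr)
    d[match(tip, tr$tip.label)]
  }
  ref <- keep[1]
  d0 <- if (has_branch_lengths(tree)) depth_of(tree, ref) else NULL
  out <- ape::keep.tip(tree, keep)
  if (!is.null(d0)) {
    # when the kept taxa form a subclade the old root-to-MRCA stem would be
    # lost; keep it as a root edge so root-to-tip distances are preserved
    stem <- d0 - depth_of(out, ref)
    if (stem > 1e-12) out$root.edge <- (out$root.edge %||% 0) + stem
  }
  out
}

#' Assign Grafen branch lengths to a lengthless tree
#'
#' Gives each internal node the height \eqn{((d-1)/(n-1))^\rho}, where \eqn{d}
#' is its number of descendant tips and \eqn{n} the total number of tips; tips
#' get height 0 and each edge length is the parent height minus the child
#' height. The result is ultrametric with depth 1. This is the standard
#' convention for turning a topology-only tree (for example a taxonomy-derived
#' supertree) into one usable for a relatedness matrix.
#'
#' @param tree An \code{ape::phylo} object without branch lengths.
#' @param rho Positive exponent controlling how node heights are compressed
#'   toward the root (1 = linear in relative clade size).
#' @param overwrite Set TRUE to replace branch lengths a tree already has.
#' @return Ultrametric \code{phylo} with depth 1.
#' @export
assign_branch_lengths_grafen <- function(tree, rho = 1, overwrite = FALSE) {
  stopifnot(rho > 0)
  if (has_branch_lengths(tree) && !overwrite)
    stop("tree already has branch lengths; pass overwrite = TRUE to replace them")
  ape::compute.brlen(tree, method = "Grafen", power = rho)
}

#' Phylogenetic relatedness (variance-covariance) matrix
#'
#' Builds the matrix \eqn{A} whose entry \eqn{A_{ij}} is the shared
#' root-to-MRCA path length of taxa i and j (and \eqn{A_{ii}} the root-to-tip
#' distance): the expected trait covariance structure under Brownian
#' evolution on the tree.
#'
#' @param tree Rooted \code{ape::phylo} with branch lengths (use
#'   \code{assign_branch_lengths_grafen()} first if it has none).
#' @return A symmetric positive semi-definite matrix with taxon names as
#'   dimnames (the taxon-order contract: joins are by name, not position).
#' @export
build_relatedness <- function(tree) {
  if (!has_branch_lengths(tree))
    stop("tree has no branch lengths; assign them first ",
         "(see assign_branch_lengths_grafen)")
  validate_phylogeny(tree)
  A <- ape::vcv(tree)
  # vcv() measures from the tree's root node; a retained stem (root edge)
  # is shared ancestry of all tips and adds to every entry
  if (!is.null(tree$root.edge) && tree$root.edge > 0)
    A <- A + tree$root.edge
  A[A < 0 & A > -1e-12] <- 0  # clip numerical negatives
  A
}

#' Scale a relatedness matrix to unit mean diagonal
#'
#' Divides A by the mean of its diagonal so that variance components estimated
#' against differently scaled trees are comparable (ultrametric trees end up
#' with unit depth). Idempotent.
#'
#' @param A Relatedness matrix.
#' @return The rescaled matrix.
#' @export
scale_relatedness <- function(A) {
  d <- mean(diag(A))
  if (d <= 0) stop("cannot scale: mean diagonal is not positive")
  A / d
}

# Inverse of a relatedness matrix, optionally jittering the diagonal to
# guarantee strict positive-definiteness (zero-length internal branches can
# make A singular).
invert_relatedness <- function(A, jitter = 0) {
  if (jitter > 0) diag(A) <- diag(A) + jitter
  ch <- tryCatch(chol(A), error = function(e)
    stop("relatedness matrix is not positive definite; ",
         "consider the jitter option (", conditionMessage(e), ")"))
  Ainv <- chol2inv(ch)
  dimnames(Ainv) <- dimnames(A)
  Ainv
}
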