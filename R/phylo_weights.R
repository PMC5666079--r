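#' Unit branching weights
#'
#' The standard analysis sets every species' branching weight to 1.0, so
#' that the weighted regression reduces to ordinary OLS on the AAVs.
#'
#' @param species Character vector of species ids (may be empty).
#' @return `data.frame(species, w)` with attribute `scheme = "unit"`.
#' @export
unit_weights <- function(species) {
  structure(
    data.frame(species = as.character(species),
               w = rep(1, length(species)),
               stringsAsFactors = FALSE),
    scheme = "unit", tree_source = "none"
  )
}

#' Branching weights derived from a phylogenetic tree
#'
#' Two pluggable schemes, both normalized so the mean weight is 1 (so the
#' weight choice cannot rescale the fitted response):
#' \describe{
#'   \item{root-to-tip}{`W_i` proportional to the inverse root-to-leaf
#'     path length. Unrooted trees are midpoint-rooted first. On an
#'     ultrametric tree all weights are 1.}
#'   \item{clade-scale}{one user-supplied multiplier per named clade,
#'     then normalized to mean 1.}
#' }
#' These derivations are approximations for synthetic and exploratory
#' studies; when a study supplies its own per-species weights, read those
#' instead.
#'
#' @param tree An `ape::phylo` object or a Newick file path. Branch
#'   lengths required, non-negative.
#' @param scheme `"root-to-tip"` (default) or `"clade-scale"`.
#' @param species Species to weight; default all tips.
#' @param clade_members Named list (clade -> character vector of species)
#'   for `"clade-scale"`; must cover every requested species exactly once.
#' @param clade_multipliers Named numeric, one multiplier per clade.
#' @return `data.frame(species, w)` with attributes `scheme`,
#'   `tree_source`.
#' @export
weights_from_tree <- function(tree, scheme = c("root-to-tip", "clade-scale"),
                              species = NULL, clade_members = NULL,
                              clade_multipliers = NULL) {
  scheme <- match.arg(scheme)
  if (is.character(tree) && length(tree) == 1L) {
    tree <- ape::read.tree(tree)
  }
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (any(tree$edge.length < 0)) stop("tree has negative branch lengths")
  if (is.null(species)) species <- tree$tip.label
  missing_sp <- setdiff(species, tree$tip.label)
  if (length(missing_sp)) {
    stop("species not found as tree leaves: ",
         paste(missing_sp, collapse = ", "))
  }
  if (scheme == "root-to-tip") {
    if (!ape::is.rooted(tree)) tree <- phangorn::midpoint(tree)
    depths <- ape::node.depth.edgelength(tree)[seq_along(tree$tip.label)]
    d <- depths[match(species, tree$tip.label)]
    if (any(d <= 0)) {
      stop("zero-length root-to-leaf path for: ",
           paste(species[d <= 0], collapse = ", "))
    }
    w <- 1 / d
  } else {
    if (is.null(clade_members) || is.null(clade_multipliers)) {
      stop("clade-scale scheme needs clade_members and clade_multipliers")
    }
    miss_mult <- setdiff(names(clade_members), names(clade_multipliers))
    if (length(miss_mult)) {
      stop("no multiplier for clade(s): ", paste(miss_mult, collapse = ", "))
    }
    assign_tab <- unlist(lapply(names(clade_members), function(cl) {
      stats::setNames(rep(cl, length(clade_members[[cl]])),
                      clade_members[[cl]])
    }))
    uncovered <- setdiff(species, names(assign_tab))
    if (length(uncovered)) {
      stop("species not covered by any clade: ",
           paste(uncovered, collapse = ", "))
    }
    if (anyDuplicated(names(assign_tab))) {
      dups <- unique(names(assign_tab)[duplicated(names(assign_tab))])
      stop("species assigned to more than one clade: ",
           paste(dups, collapse = ", "))
    }
    w <- unname(clade_multipliers[assign_tab[species]])
    if (any(!is.finite(w)) || any(w <= 0)) {
      stop("clade multipliers must be positive")
    }
  }
  w <- w / mean(w)
  structure(
    data.frame(species = species, w = w, stringsAsFactors = FALSE),
    scheme = scheme, tree_source = "supplied"
  )
}

#' Read / write per-species weights as CSV
#'
#' @param path CSV with columns `species`, `w` (positive).
#' @export
read_weights <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("species", "w") %in% names(x))) {
    stop("weight table needs columns 'species' and 'w'")
  }
  if (any(!is.finite(x$w)) || any(x$w <= 0)) stop("weights must be positive")
  x
}

#' Neighbor-joining tree from aligned protein sequences
#'
#' A convenience distance-based tree builder: pairwise p-distances on the
#' aligned, concatenated amino-acid sequences with a Poisson correction
#' `d = -ln(1 - p)`, followed by neighbor joining. Deterministic given
#' the input order; negative NJ branch lengths are clamped to zero. This
#' is a quick approximation, not a substitute for model-based phylogenetic
#' inference.
#'
#' Positions where either sequence carries a gap or `X` are ignored for
#' that pair.
#'
#' @param sequences Named character vector of equal-length aligned
#'   amino-acid sequences, at least 4 taxa.
#' @return An unrooted `ape::phylo` tree.
#' @export
build_nj_tree <- function(sequences) {
  if (is.null(names(sequences)) || anyDuplicated(names(sequences))) {
    stop("sequences must carry unique names")
  }
  n <- length(sequences)
  if (n < 4L) stop("neighbor joining needs at least 4 taxa, got ", n)
  lens <- nchar(sequences)
  if (length(unique(lens)) != 1L) {
    stop("sequences are not aligned (lengths ",
         paste(sort(unique(lens)), collapse = ", "), ")")
  }
  mat <- do.call(rbind, strsplit(toupper(sequences), ""))
  ok <- !(mat %in% c("X", "-", ".", "*"))
  dim(ok) <- dim(mat)
  D <- matrix(0, n, n, dimnames = list(names(sequences), names(sequences)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      use <- ok[i, ] & ok[j, ]
      if (!any(use)) stop("no comparable sites between ",
                          names(sequences)[i], " and ", names(sequences)[j])
      p <- mean(mat[i, use] != mat[j, use])
      if (p >= 1) {
        stop("saturated distance (p = 1) between ", names(sequences)[i],
             " and ", names(sequences)[j])
      }
      D[i, j] <- D[j, i] <- -log(1 - p)
    }
  }
  tree <- ape::nj(stats::as.dist(D))
  tree$edge.length[tree$edge.length < 0] <- 0
  tree
}
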