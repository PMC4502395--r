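#' Write a phylogenetic tree as newick
#'
#' Serialises an [ape::phylo] tree with branch lengths to 6 decimals and any
#' bootstrap supports (`node.label`) as internal node labels, the convention
#' most tree viewers expect.  Reading the file back reproduces the topology,
#' lengths and supports.
#'
#' @param tree an `ape::phylo` object, branch lengths >= 0, optional integer
#'   `node.label` supports.
#' @param path output path.
#' @return `path`, invisibly.
#' @examples
#' tr <- ape::read.tree(text = "(A:1,B:2,C:3);")
#' f <- tempfile(fileext = ".nwk")
#' writeNewick(tr, f)
#' readLines(f)
#' @export
writeNewick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  if (!is.null(tree$edge.length) && any(tree$edge.length < -1e-12))
    stop("newick write error: negative branch length")
  ntip <- length(tree$tip.label)
  kids <- split(tree$edge[, 2L], tree$edge[, 1L])
  elen <- stats::setNames(tree$edge.length, tree$edge[, 2L])
  lab <- function(node) {
    if (node <= ntip) return(tree$tip.label[node])
    if (is.null(tree$node.label)) return("")
    l <- tree$node.label[node - ntip]
    if (is.na(l) || l == "" || is.null(l)) "" else as.character(l)
  }
  rec <- function(node) {
    inner <- if (node > ntip)
      paste0("(", paste(vapply(kids[[as.character(node)]], rec, character(1)),
                        collapse = ","), ")")
    else ""
    br <- if (!is.null(tree$edge.length) && as.character(node) %in% names(elen))
      sprintf(":%.6f", elen[[as.character(node)]]) else ""
    paste0(inner, lab(node), br)
  }
  root <- setdiff(tree$edge[, 1L], tree$edge[, 2L])[1L]
  writeLines(paste0(rec(root), ";"), path)
  invisible(path)
}

#' Read a newick tree
#'
#' Thin wrapper over [ape::read.tree()]; internal node labels are kept as
#' `node.label` (bootstrap supports, when present).
#'
#' @param path newick file path.
#' @return an `ape::phylo` object.
#' @export
readNewick <- function(path) {
  tr <- ape::read.tree(path)
  if (is.null(tr)) stop("newick format error: could not parse ", path)
  tr
}

#' Unrooted bipartitions of a tree
#'
#' Each internal edge induces a split of the leaf set; splits are returned
#' in canonical form (the side not containing the alphabetically first
#' leaf), as sorted comma-joined label strings.  Used for bootstrap support
#' counting and round-trip topology checks.
#'
#' @param tree an `ape::phylo` object.
#' @return character vector of canonical splits (may be empty for stars).
#' @export
bipartitions <- function(tree) {
  ntip <- length(tree$tip.label)
  ref <- sort(tree$tip.label)[1L]
  kids <- split(tree$edge[, 2L], tree$edge[, 1L])
  below <- vector("list", ntip + tree$Nnode)
  fill <- function(node) {
    if (node <= ntip) {
      below[[node]] <<- tree$tip.label[node]
    } else {
      for (k in kids[[as.character(node)]]) fill(k)
      below[[node]] <<- unlist(lapply(kids[[as.character(node)]],
                                      function(k) below[[k]]))
    }
  }
  root <- setdiff(tree$edge[, 1L], tree$edge[, 2L])[1L]
  fill(root)
  internal <- tree$edge[, 2L][tree$edge[, 2L] > ntip]
  splits <- vapply(internal, function(node) {
    side <- below[[node]]
    if (ref %in% side) side <- setdiff(tree$tip.label, side)
    if (length(side) < 2L || length(side) > ntip - 2L) return(NA_character_)
    paste(sort(side), collapse = ",")
  }, character(1))
  unique(splits[!is.na(splits)])
}
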