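#' p-distance matrix from a protein alignment
#'
#' Proportion of mismatching residues among compared sites.  With
#' `deletion = "pairwise"` each pair compares the sites ungapped in both
#' rows; with `"complete"` columns gapped in any row are dropped first.  A
#' pair with zero comparable sites is an error naming the pair.
#'
#' @param alignment named character vector of equal-length aligned rows
#'   (`-` gaps).
#' @param deletion `"pairwise"` (default) or `"complete"`.
#' @return symmetric distance matrix with zero diagonal.
#' @examples
#' pDistance(c(a = "AAAA", b = "AAAT"))["a", "b"]  # 0.25
#' @export
pDistance <- function(alignment, deletion = c("pairwise", "complete")) {
  deletion <- match.arg(deletion)
  m <- do.call(rbind, strsplit(toupper(as.character(alignment)), ""))
  rownames(m) <- names(alignment)
  if (deletion == "complete") {
    keep <- colSums(m == "-") == 0L
    m <- m[, keep, drop = FALSE]
  }
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j) {
      ok <- m[i, ] != "-" & m[j, ] != "-"
      if (!any(ok))
        stop("distance input error: zero comparable sites for pair ",
             rownames(m)[i], " / ", rownames(m)[j])
      d[i, j] <- d[j, i] <- mean(m[i, ok] != m[j, ok])
    }
  }
  d
}

#' Neighbour-joining tree (Saitou-Nei)
#'
#' Standard NJ: at each step the pair minimising
#' `Q(i,j) = (n-2) d(i,j) - r_i - r_j` is joined; ties go to the
#' lexicographically smallest name pair (internal nodes are named by their
#' smallest leaf).  Branch lengths follow the usual formulas; a negative
#' length is clamped to 0 with the deficit moved to its sister branch so
#' the pair's summed length is preserved.  The result is unrooted (root
#' trifurcation).
#'
#' @param d symmetric distance matrix with named rows/columns (>= 3 taxa).
#' @return an `ape::phylo` tree.
#' @export
njTree <- function(d) {
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-8)))
    stop("NJ input error: distance matrix must be symmetric")
  n0 <- nrow(d)
  if (n0 < 3L) stop("NJ input error: need >= 3 taxa")
  labels <- rownames(d)
  # node: newick fragment + representative (smallest leaf) name
  frag <- labels
  rep_ <- labels
  D <- d
  fmt <- function(x) sprintf("%.10g", max(x, 0))
  while (nrow(D) > 3L) {
    n <- nrow(D)
    r <- rowSums(D)
    Q <- (n - 2) * D - outer(r, r, `+`)
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q <= qmin + 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1L] < cand[, 2L], , drop = FALSE]
    key <- apply(cand, 1L, function(ij) {
      p <- sort(c(rep_[ij[1L]], rep_[ij[2L]]))
      paste(p, collapse = "\r")
    })
    pick <- cand[order(key)[1L], ]
    i <- pick[[1L]]; j <- pick[[2L]]
    li <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2))
    lj <- D[i, j] - li
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    newFrag <- sprintf("(%s:%s,%s:%s)", frag[i], fmt(li), frag[j], fmt(lj))
    newRep <- min(rep_[i], rep_[j])
    dNew <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(n), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], dNew[keep]),
               c(dNew[keep], 0))
    frag <- c(frag[keep], newFrag)
    rep_ <- c(rep_[keep], newRep)
    rownames(D) <- colnames(D) <- rep_
  }
  la <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  lb <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  lc <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  nwk <- sprintf("(%s:%s,%s:%s,%s:%s);",
                 frag[1], fmt(la), frag[2], fmt(lb), frag[3], fmt(lc))
  ape::read.tree(text = nwk)
}

# canonical split below each internal node of a (rooted or trifurcating)
# tree; names are node numbers
nodeSplits <- function(tree) {
  ntip <- length(tree$tip.label)
  ref <- sort(tree$tip.label)[1L]
  kids <- split(tree$edge[, 2L], tree$edge[, 1L])
  below <- vector("list", ntip + tree$Nnode)
  root <- setdiff(tree$edge[, 1L], tree$edge[, 2L])[1L]
  fill <- function(node) {
    if (node <= ntip) { below[[node]] <<- tree$tip.label[node]; return() }
    for (k in kids[[as.character(node)]]) fill(k)
    below[[node]] <<- unlist(lapply(kids[[as.character(node)]],
                                    function(k) below[[k]]))
  }
  fill(root)
  nodes <- (ntip + 1L):(ntip + tree$Nnode)
  splits <- vapply(nodes, function(node) {
    side <- below[[node]]
    if (ref %in% side) side <- setdiff(tree$tip.label, side)
    if (length(side) < 2L || length(side) > ntip - 2L) return(NA_character_)
    paste(sort(side), collapse = ",")
  }, character(1))
  stats::setNames(splits, nodes)
}

#' Bootstrap supports for an NJ tree of a protein alignment
#'
#' Builds the full-data NJ tree from p-distances, then resamples alignment
#' columns with replacement `replicates` times, rebuilds the tree, and
#' reports for each internal bipartition of the full-data tree the
#' percentage of replicates containing it, stored as integer `node.label`s.
#'
#' @param alignment named character vector of aligned rows (>= 4).
#' @param replicates bootstrap replicates (default 1000); 0 returns the
#'   tree without supports.
#' @param seed RNG seed.
#' @param deletion passed to [pDistance()].
#' @return an `ape::phylo` tree with `node.label` supports (except
#'   `replicates = 0`).
#' @export
bootstrapSupports <- function(alignment, replicates = 1000L, seed = 1L,
                              deletion = "pairwise") {
  alignment <- alignment[sort(names(alignment))]  # input-order invariance
  main <- njTree(pDistance(alignment, deletion))
  if (replicates == 0L) return(main)
  if (length(alignment) < 4L)
    stop("bootstrap input error: need >= 4 sequences")
  chars <- do.call(rbind, strsplit(toupper(as.character(alignment)), ""))
  rownames(chars) <- names(alignment)
  L <- ncol(chars)
  splits <- nodeSplits(main)
  counts <- stats::setNames(numeric(length(splits)), splits)
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  for (b in seq_len(replicates)) {
    cols <- sample.int(L, L, replace = TRUE)
    rep_aln <- apply(chars[, cols, drop = FALSE], 1L, paste, collapse = "")
    tr <- tryCatch(njTree(pDistance(rep_aln, deletion)),
                   error = function(e) NULL)
    if (is.null(tr)) next
    bp <- bipartitions(tr)
    hit <- names(counts)[!is.na(names(counts)) & names(counts) %in% bp]
    counts[hit] <- counts[hit] + 1
  }
  support <- round(100 * counts / replicates)
  main$node.label <- ifelse(is.na(splits), "",
                            as.character(as.integer(support[splits])))
  main
}

subfamilyLabels <- function(n) {
  single <- LETTERS
  if (n <= 26L) return(single[seq_len(n)])
  double <- as.vector(t(outer(LETTERS, LETTERS, paste0)))
  c(single, double)[seq_len(n)]
}

#' Assign subfamily labels by anchored clades and a depth cut
#'
#' The tree is midpoint-rooted.  Each anchor leaf (a known regulator with a
#' pre-assigned subfamily) propagates its label to the maximal clade
#' containing it in which every internal node's bootstrap support is at
#' least `minSupport`.  Remaining leaves are partitioned by cutting the
#' rooted tree at branch-length depth `maxDepthFraction` x tree height;
#' each subtree hanging below the cut is one subfamily, labelled `A`, `B`,
#' ... in leaf order.
#'
#' @param tree an `ape::phylo`, optionally with `node.label` supports.
#' @param anchors named character vector: leaf name -> subfamily label
#'   (optional).
#' @param minSupport minimum support for anchored-clade expansion
#'   (default 50).
#' @param maxDepthFraction depth-cut fraction of tree height (default 0.5).
#' @return named character vector: leaf name -> subfamily label.
#' @export
assignSubfamilies <- function(tree, anchors = NULL, minSupport = 50,
                              maxDepthFraction = 0.5) {
  if (!is.null(anchors) && !all(names(anchors) %in% tree$tip.label))
    stop("subfamily input error: anchor(s) not in tree: ",
         paste(setdiff(names(anchors), tree$tip.label), collapse = ", "))
  rooted <- if (ape::is.rooted(tree)) tree else phangorn::midpoint(tree)
  ntip <- length(rooted$tip.label)
  root <- setdiff(rooted$edge[, 1L], rooted$edge[, 2L])[1L]
  parent <- integer(ntip + rooted$Nnode)
  depth <- numeric(ntip + rooted$Nnode)
  for (k in seq_len(nrow(rooted$edge))) {
    parent[rooted$edge[k, 2L]] <- rooted$edge[k, 1L]
    depth[rooted$edge[k, 2L]] <- rooted$edge[k, 1L]  # placeholder
  }
  # depths by preorder walk
  ord <- rev(ape::postorder(rooted))
  depth[] <- 0
  for (k in ord) {
    child <- rooted$edge[k, 2L]
    depth[child] <- depth[rooted$edge[k, 1L]] +
      if (is.null(rooted$edge.length)) 1 else rooted$edge.length[k]
  }
  height <- max(depth[seq_len(ntip)])
  cutDepth <- maxDepthFraction * height
  kids <- split(rooted$edge[, 2L], rooted$edge[, 1L])
  leavesBelow <- function(node) {
    if (node <= ntip) return(rooted$tip.label[node])
    unlist(lapply(kids[[as.character(node)]], leavesBelow))
  }
  supportOf <- function(node) {
    if (is.null(rooted$node.label)) return(Inf)
    s <- suppressWarnings(as.numeric(rooted$node.label[node - ntip]))
    if (is.na(s)) Inf else s
  }
  labels <- stats::setNames(rep(NA_character_, ntip), rooted$tip.label)
  # anchored clades first
  if (!is.null(anchors)) {
    anchorClade <- lapply(names(anchors), function(a) {
      node <- match(a, rooted$tip.label)
      while (parent[node] != 0L && parent[node] != root &&
             supportOf(parent[node]) >= minSupport)
        node <- parent[node]
      leavesBelow(node)
    })
    names(anchorClade) <- names(anchors)
    for (i in seq_along(anchorClade)) for (j in seq_along(anchorClade)) {
      if (i < j && anchors[i] != anchors[j] &&
          length(intersect(anchorClade[[i]], anchorClade[[j]])))
        stop("subfamily conflict error: anchors ", names(anchors)[i],
             " and ", names(anchors)[j],
             " with different labels share a clade")
    }
    for (a in names(anchorClade))
      labels[anchorClade[[a]]] <- anchors[[a]]
  }
  # depth-cut partition for the rest
  groupOf <- stats::setNames(integer(ntip), rooted$tip.label)
  for (t in seq_len(ntip)) {
    path <- t
    node <- t
    while (parent[node] != 0L) { node <- parent[node]; path <- c(path, node) }
    path <- rev(path)                      # root ... tip
    hit <- path[which(depth[path] >= cutDepth)[1L]]
    groupOf[t] <- if (is.na(hit)) t else hit
  }
  unlabeled <- is.na(labels)
  grp <- groupOf[rooted$tip.label[unlabeled]]
  uniq <- unique(grp)                      # leaf order
  lab <- subfamilyLabels(length(uniq))
  used <- unique(stats::na.omit(labels))
  lab <- setdiff(c(lab, subfamilyLabels(length(uniq) + length(used))),
                 used)[seq_along(uniq)]
  labels[unlabeled] <- lab[match(grp, uniq)]
  labels
}
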