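# ---------------------------------------------------------------------------
# Phylogeny: rooted, strictly bifurcating tree with branch lengths indexed
# by child node.  Node labels follow the array convention used throughout:
# tips 1..N (order of first appearance), internal nodes N+1..2N-2, root
# 2N-1.  Branch i (i = 1..2N-2) is the branch above node i.
# ---------------------------------------------------------------------------

new_phylogeny <- function(n_tips, parent, children, brlen, taxon_names) {
  structure(list(n_tips = as.integer(n_tips),
                 n_nodes = 2L * as.integer(n_tips) - 1L,
                 parent = as.integer(parent),
                 children = children,           # (2N-1) x 2 int, NA for tips
                 brlen = as.numeric(brlen),     # length 2N-1, NA at root
                 taxon_names = taxon_names),
            class = "phylogeny")
}

#' @export
print.phylogeny <- function(x, ...) {
  cat("phylogeny:", x$n_tips, "tips,", x$n_nodes - x$n_tips,
      "internal nodes (root =", x$n_nodes, ")\n")
  invisible(x)
}

root_node <- function(tree) tree$n_nodes
is_tip <- function(tree, i) i <= tree$n_tips

validate_phylogeny <- function(tree) {
  N <- tree$n_tips
  M <- tree$n_nodes
  stopifnot(N >= 2, M == 2L * N - 1L,
            length(tree$parent) == M, length(tree$brlen) == M,
            length(tree$taxon_names) == N,
            !anyDuplicated(tree$taxon_names))
  stopifnot(tree$parent[M] == 0L, all(tree$parent[-M] >= 1L))
  for (k in (N + 1L):M) {
    ch <- tree$children[k, ]
    stopifnot(!any(is.na(ch)), length(unique(ch)) == 2L,
              all(tree$parent[ch] == k))
  }
  b <- tree$brlen[-M]
  stopifnot(all(is.finite(b)), all(b >= 0))
  # connectivity: every node reaches the root
  for (i in seq_len(M - 1L)) {
    j <- i; steps <- 0L
    while (j != M) {
      j <- tree$parent[j]; steps <- steps + 1L
      stopifnot(steps <= M)
    }
  }
  invisible(TRUE)
}

#' Parse a Newick tree
#'
#' Reads a rooted, strictly bifurcating Newick string with branch lengths
#' on every non-root node.  Quoted labels and bracketed comments are
#' tolerated; internal-node labels are ignored.  Taxon order is the order
#' of first appearance in the string.
#'
#' @param text Newick string (or a file path via `file`).
#' @param file Optional path to a file containing the tree.
#' @return A `phylogeny` object.
#' @examples
#' tr <- parse_newick("((A:0.1,B:0.2):0.05,C:0.3);")
#' tr$n_tips
#' @export
parse_newick <- function(text = NULL, file = NULL) {
  if (is.null(text)) {
    if (is.null(file)) pg_stop("parse_error", "parse-error: no input")
    if (!file.exists(file))
      pg_stop("input_error", "file-not-found: ", file)
    text <- paste(readLines(file, warn = FALSE), collapse = "")
  }
  text <- gsub("\\[[^]]*\\]", "", text)   # strip bracketed comments
  ph <- tryCatch(ape::read.tree(text = text),
                 error = function(e) NULL, warning = function(w) NULL)
  if (is.null(ph))
    pg_stop("parse_error", "parse-error: malformed Newick")
  from_ape_phylo(ph)
}

#' Convert an ape "phylo" object to a phylogeny
#'
#' @param ph An [ape::read.tree()]-style `phylo` object; must be rooted and
#'   strictly bifurcating with branch lengths on all edges.
#' @return A `phylogeny` object.
#' @export
from_ape_phylo <- function(ph) {
  N <- length(ph$tip.label)
  if (N < 2) pg_stop("parse_error", "parse-error: need at least 2 taxa")
  if (anyDuplicated(ph$tip.label))
    pg_stop("parse_error", "parse-error: duplicate taxon name '",
            ph$tip.label[duplicated(ph$tip.label)][1], "'")
  if (is.null(ph$edge.length) || anyNA(ph$edge.length))
    pg_stop("parse_error", "parse-error: missing branch length")
  nkids <- tabulate(ph$edge[, 1], nbins = N + ph$Nnode)
  bad <- which(nkids > 2)
  if (length(bad))
    pg_stop("unsupported_topology",
            "unsupported-topology: polytomy at internal node ", bad[1])
  if (any(nkids[(N + 1):(N + ph$Nnode)] == 1))
    pg_stop("unsupported_topology",
            "unsupported-topology: single-child internal node")
  if (ph$Nnode != N - 1)
    pg_stop("unsupported_topology",
            "unsupported-topology: tree is not rooted-bifurcating")
  M <- 2L * N - 1L
  ape_root <- N + 1L
  # relabel: tips unchanged; ape root -> 2N-1; other internals fill N+1..2N-2
  map <- integer(M)
  map[seq_len(N)] <- seq_len(N)
  others <- setdiff((N + 1L):M, ape_root)
  map[others] <- if (N > 2) (N + 1L):(2L * N - 2L) else integer(0)
  map[ape_root] <- M
  parent <- integer(M); brlen <- rep(NA_real_, M)
  children <- matrix(NA_integer_, M, 2)
  for (e in seq_len(nrow(ph$edge))) {
    p <- map[ph$edge[e, 1]]; c <- map[ph$edge[e, 2]]
    parent[c] <- p
    brlen[c] <- ph$edge.length[e]
    slot <- if (is.na(children[p, 1])) 1L else 2L
    children[p, slot] <- c
  }
  tree <- new_phylogeny(N, parent, children, brlen, ph$tip.label)
  validate_phylogeny(tree)
  tree
}

#' Convert a phylogeny to an ape "phylo" object
#'
#' @param tree A `phylogeny`.
#' @return An ape `phylo` object with the same topology, branch lengths
#'   and tip order.
#' @export
as_ape_phylo <- function(tree) {
  ape::read.tree(text = write_newick(tree))
}

#' Write a phylogeny as Newick
#'
#' Branch lengths are written at full double precision so that
#' parse -> write -> parse round-trips exactly.
#'
#' @param tree A `phylogeny`.
#' @return A single Newick string terminated by ";".
#' @export
write_newick <- function(tree) {
  fmt <- function(i) {
    if (is_tip(tree, i)) {
      lab <- tree$taxon_names[i]
    } else {
      ch <- tree$children[i, ]
      lab <- paste0("(", fmt(ch[1]), ",", fmt(ch[2]), ")")
    }
    if (i == root_node(tree)) paste0(lab, ";")
    else paste0(lab, ":", sprintf("%.17g", tree$brlen[i]))
  }
  fmt(root_node(tree))
}

# ---------------------------------------------------------------------------
# Traversal schedules
# ---------------------------------------------------------------------------

#' Post- and pre-order traversal schedules
#'
#' The post-order schedule lists one `(parent, child1, child2)` triple per
#' internal node with children strictly before parents (the pruning
#' order); the pre-order schedule lists one `(node, parent, sibling)`
#' triple per non-root node -- tips included -- with parents strictly
#' before children.
#'
#' @param tree A `phylogeny`.
#' @return List with integer matrices `postorder` ((N-1) x 3, columns
#'   parent/child1/child2) and `preorder` ((2N-2) x 3, columns
#'   node/parent/sibling).
#' @export
traversal_schedule <- function(tree) {
  M <- root_node(tree)
  post <- matrix(0L, tree$n_tips - 1L, 3,
                 dimnames = list(NULL, c("parent", "child1", "child2")))
  pre <- matrix(0L, 2L * tree$n_tips - 2L, 3,
                dimnames = list(NULL, c("node", "parent", "sibling")))
  pi_ <- 0L
  rec <- function(k) {
    if (is_tip(tree, k)) return(invisible(NULL))
    ch <- tree$children[k, ]
    rec(ch[1]); rec(ch[2])
    pi_ <<- pi_ + 1L
    post[pi_, ] <<- c(k, ch[1], ch[2])
  }
  rec(M)
  qi <- 0L
  queue <- c(M)
  while (length(queue)) {
    k <- queue[1]; queue <- queue[-1]
    if (is_tip(tree, k)) next
    ch <- tree$children[k, ]
    for (s in 1:2) {
      qi <- qi + 1L
      pre[qi, ] <- c(ch[s], k, ch[3 - s])
    }
    queue <- c(queue, ch)
  }
  list(postorder = post, preorder = pre)
}

# ---------------------------------------------------------------------------
# Rerooting: place the root anywhere on the unrooted topology
# ---------------------------------------------------------------------------

#' Reroot a phylogeny along a branch
#'
#' Places a new root on the branch above node `new_root_branch`, at
#' fraction `split` of that branch's length measured from the child end,
#' after suppressing the old (degree-2) root.  All pairwise tip path
#' lengths are preserved; under a reversible model with stationary root
#' prior the likelihood is invariant (pulley principle).
#'
#' @param tree A `phylogeny`.
#' @param new_root_branch Branch id = child-node id, in 1..(2N-2).
#' @param split Fraction in `[0, 1]` of the branch length kept on the
#'   child side of the new root.
#' @return A new `phylogeny` on the same unrooted topology; tip ids and
#'   names are unchanged.
#' @export
reroot <- function(tree, new_root_branch, split = 0.5) {
  N <- tree$n_tips; M <- tree$n_nodes
  if (!is.numeric(new_root_branch) || new_root_branch < 1 ||
      new_root_branch > M - 1)
    pg_stop("invalid_parameter", "invalid-parameter: branch id out of range")
  if (split < 0 || split > 1)
    pg_stop("invalid_parameter", "invalid-parameter: split must be in [0,1]")
  v <- as.integer(new_root_branch)
  oldroot <- M
  rc <- tree$children[oldroot, ]

  # undirected edge list of the unrooted topology (old root suppressed)
  ef <- integer(0); et <- integer(0); el <- numeric(0)
  for (i in seq_len(M - 1L)) {
    if (tree$parent[i] == oldroot) next
    ef <- c(ef, i); et <- c(et, tree$parent[i]); el <- c(el, tree$brlen[i])
  }
  ef <- c(ef, rc[1]); et <- c(et, rc[2])
  el <- c(el, tree$brlen[rc[1]] + tree$brlen[rc[2]])

  # locate the attachment edge and split position (measured from v)
  b <- tree$brlen[v]
  if (tree$parent[v] == oldroot) {
    sib <- if (rc[1] == v) rc[2] else rc[1]
    eidx <- which((ef == v & et == sib) | (ef == sib & et == v))
  } else {
    eidx <- which((ef == v & et == tree$parent[v]) |
                  (ef == tree$parent[v] & et == v))
  }
  pos <- split * b
  a <- ef[eidx]; z <- et[eidx]; len <- el[eidx]
  if (a != v) { tmp <- a; a <- z; z <- tmp }   # ensure a == v
  ef <- ef[-eidx]; et <- et[-eidx]; el <- el[-eidx]
  newroot <- M + 1L                             # temporary id
  ef <- c(ef, a, newroot); et <- c(et, newroot, z)
  el <- c(el, pos, len - pos)

  # orient away from the new root
  adj <- vector("list", M + 1L)
  for (e in seq_along(ef)) {
    adj[[ef[e]]] <- rbind(adj[[ef[e]]], c(et[e], el[e]))
    adj[[et[e]]] <- rbind(adj[[et[e]]], c(ef[e], el[e]))
  }
  parent0 <- integer(M + 1L); blen0 <- rep(NA_real_, M + 1L)
  seen <- logical(M + 1L)
  order0 <- integer(0)
  stack <- newroot; seen[newroot] <- TRUE
  while (length(stack)) {
    k <- stack[length(stack)]; stack <- stack[-length(stack)]
    order0 <- c(order0, k)
    nb <- adj[[k]]
    if (is.null(nb)) next
    for (e in seq_len(nrow(nb))) {
      j <- nb[e, 1]
      if (seen[j]) next
      seen[j] <- TRUE
      parent0[j] <- k; blen0[j] <- nb[e, 2]
      stack <- c(stack, j)
    }
  }

  # relabel internals: tips keep 1..N, internal non-root N+1..2N-2, root 2N-1
  internals <- setdiff(order0[order0 > N], newroot)
  map <- integer(M + 1L)
  map[seq_len(N)] <- seq_len(N)
  map[internals] <- if (length(internals)) (N + 1L):(2L * N - 2L) else integer(0)
  map[newroot] <- M
  parent <- integer(M); brlen <- rep(NA_real_, M)
  children <- matrix(NA_integer_, M, 2)
  for (j in seq_len(M + 1L)) {
    if (j == newroot || !seen[j]) next
    cj <- map[j]; pj <- map[parent0[j]]
    parent[cj] <- pj; brlen[cj] <- blen0[j]
    slot <- if (is.na(children[pj, 1])) 1L else 2L
    children[pj, slot] <- cj
  }
  out <- new_phylogeny(N, parent, children, brlen, tree$taxon_names)
  validate_phylogeny(out)
  out
}

#' Pairwise tip path-length matrix
#'
#' @param tree A `phylogeny`.
#' @return N x N symmetric matrix of tip-to-tip path lengths (taxon names
#'   as dimnames).
#' @export
tip_distances <- function(tree) {
  d <- stats::cophenetic(as_ape_phylo(tree))
  d[tree$taxon_names, tree$taxon_names]
}
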