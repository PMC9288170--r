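# Gene-tree screening for the two-population model: classify rooted
# trees as reciprocally monophyletic / paraphyletic / polyphyletic with
# respect to the barrier, and select the sample subset (clade minus at
# most a few migrant tips) that fits the model.

# tip labels descending from each node, for a rooted ape::phylo
.tipDescendants <- function(tree) {
  nt <- length(tree$tip.label)
  nn <- nt + tree$Nnode
  desc <- vector("list", nn)
  for (i in seq_len(nt)) desc[[i]] <- tree$tip.label[i]
  # accumulate bottom-up over edges in postorder
  for (e in ape::postorder(tree)) {
    p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    desc[[p]] <- c(desc[[p]], desc[[ch]])
  }
  desc
}

.childrenOf <- function(tree, node) tree$edge[tree$edge[, 1] == node, 2]

# Is `tips` a clade under some resolution of soft polytomies?  True iff
# every child subtree of the MRCA is entirely inside or entirely outside
# the set (a resolution can then group the inside children).
.isSoftClade <- function(tree, tips, desc = NULL) {
  if (length(tips) <= 1L) return(TRUE)
  if (length(tips) == length(tree$tip.label)) return(TRUE)
  if (is.null(desc)) desc <- .tipDescendants(tree)
  mrca <- ape::getMRCA(tree, tips)
  for (ch in .childrenOf(tree, mrca)) {
    d <- desc[[ch]]
    inn <- sum(d %in% tips)
    if (inn != 0L && inn != length(d)) return(FALSE)
  }
  TRUE
}

.sideVector <- function(tree, sides) {
  if (is.null(names(sides))) stop("'sides' must be named by tip label")
  s <- sides[tree$tip.label]
  if (anyNA(s)) stop("tips without a side assignment: ",
                     paste(tree$tip.label[is.na(s)], collapse = ", "))
  s <- toupper(as.character(s))
  if (!all(s %in% c("E", "W"))) stop("sides must be 'E' or 'W'")
  s
}

#' Classify a labelled gene tree against the barrier
#'
#' A rooted tree whose tips are labelled east/west is reciprocally
#' monophyletic if both side sets are clades, paraphyletic if exactly one
#' is, and polyphyletic otherwise.  Multifurcations are treated as soft
#' polytomies: a side set counts as a clade if some resolution makes it
#' one.  The classification depends on the root position.
#'
#' @param tree a rooted \link[ape]{phylo}.
#' @param sides named character vector, tip label to \code{"E"}/\code{"W"};
#'   both sides must be represented.
#' @return one of \code{"reciprocal_monophyly"}, \code{"paraphyly"},
#'   \code{"polyphyly"}.
#' @examples
#' tr <- ape::read.tree(text = "((E1,E2),(W1,W2));")
#' classifyTopology(tr, c(E1="E", E2="E", W1="W", W2="W"))
#' @export
classifyTopology <- function(tree, sides) {
  stopifnot(inherits(tree, "phylo"))
  s <- .sideVector(tree, sides)
  if (!all(c("E", "W") %in% s))
    stop("both sides must have at least one tip")
  desc <- .tipDescendants(tree)
  eC <- .isSoftClade(tree, tree$tip.label[s == "E"], desc)
  wC <- .isSoftClade(tree, tree$tip.label[s == "W"], desc)
  if (eC && wC) "reciprocal_monophyly"
  else if (eC || wC) "paraphyly"
  else "polyphyly"
}

# induced subtree on a tip subset; handles 1-2 tips without ape errors
.inducedClassify <- function(tree, keep, sides) {
  sk <- sides[keep]
  if (!all(c("E", "W") %in% sk)) return(NA_character_)
  if (length(keep) == 2L) return("reciprocal_monophyly")
  sub <- ape::keep.tip(tree, keep)
  classifyTopology(sub, sides[keep])
}

#' Select the sample subset fitting the two-population model
#'
#' Searches the internal nodes whose subtree contains both sides for
#' candidates that become reciprocally monophyletic after removing at
#' most \code{maxRemovals} tips (e.g. one or two migrant samples nested
#' in the opposite clade).  Among the candidates the choice maximises the
#' number of retained tips, then the fewest removals, then the smallest
#' sum of priority ranks over retained tips (rank 1 = geographically
#' closest to the barrier), then node order for determinism.
#'
#' @param tree a rooted \link[ape]{phylo}.
#' @param sides named tip-to-side vector as in
#'   \code{\link{classifyTopology}}.
#' @param priority optional named numeric vector of per-tip ranks (lower
#'   is preferred); unnamed tips get the median rank.
#' @param maxRemovals maximum tips to remove (default 2).
#' @return list with \code{tips} (retained labels), \code{removed},
#'   \code{node} (chosen subtree root, ape node id) and
#'   \code{classification} of the retained set.
#' @export
selectTwoPopulationSubset <- function(tree, sides, priority = NULL,
                                      maxRemovals = 2L) {
  stopifnot(inherits(tree, "phylo"))
  s <- .sideVector(tree, sides)
  names(s) <- tree$tip.label
  nt <- length(tree$tip.label)
  prio <- setNames(rep(0, nt), tree$tip.label)
  if (!is.null(priority)) {
    common <- intersect(names(priority), tree$tip.label)
    prio[common] <- priority[common]
  }
  desc <- .tipDescendants(tree)
  nodes <- (nt + 1L):(nt + tree$Nnode)
  nodes <- nodes[vapply(nodes, function(v)
    all(c("E", "W") %in% s[desc[[v]]]), logical(1))]

  best <- NULL
  score <- function(kept, removed, node, setIdx)
    c(-length(kept), length(removed), sum(prio[kept]), node, setIdx)
  for (v in nodes) {
    tips <- desc[[v]]
    for (r in 0:min(maxRemovals, length(tips) - 2L)) {
      sets <- if (r == 0L) list(character(0))
              else apply(combn(tips, r), 2L, identity, simplify = FALSE)
      for (k in seq_along(sets)) {
        rem <- sets[[k]]
        keep <- setdiff(tips, rem)
        cls <- .inducedClassify(tree, keep, s)
        if (identical(cls, "reciprocal_monophyly")) {
          sc <- score(keep, rem, v, k)
          if (is.null(best) || .lexLess(sc, best$score)) {
            best <- list(tips = keep, removed = rem, node = v,
                         classification = cls, score = sc)
          }
        }
      }
    }
  }
  if (is.null(best))
    stop("no valid two-population subset within ", maxRemovals,
         " removals; the tree may be deeply polyphyletic")
  best$score <- NULL
  best
}

# lexicographic comparison of numeric score vectors
.lexLess <- function(a, b) {
  for (i in seq_along(a)) {
    if (a[i] < b[i]) return(TRUE)
    if (a[i] > b[i]) return(FALSE)
  }
  FALSE
}

#' Read side and priority maps from TSV
#'
#' Expects columns \code{sample}, \code{side} and optionally
#' \code{priority}.
#'
#' @param path TSV file path.
#' @return list with named vectors \code{sides} and (optionally)
#'   \code{priority}.
#' @export
readSideMap <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample", "side") %in% names(tab)))
    stop("side map needs 'sample' and 'side' columns")
  out <- list(sides = setNames(toupper(tab$side), tab$sample))
  if ("priority" %in% names(tab))
    out$priority <- setNames(as.numeric(tab$priority), tab$sample)
  out
}
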