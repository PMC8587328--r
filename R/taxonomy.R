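#' Build a taxonomy tree for a categorical quasi-identifier attribute
#'
#' A taxonomy tree describes the generalization hierarchy of a categorical
#' attribute.  The single root is conventionally labelled `"ANY"`; leaves are
#' the raw values observed in the data.  Generalizing a value means replacing
#' it by one of its ancestors.
#'
#' @param parent named character vector mapping each non-root label to its
#'   parent label (an edge list `child -> parent`).
#' @param root root label, default `"ANY"`.
#' @return An object of class `taxonomy` with components `labels`, `parent`
#'   (integer parent ids, 0 for the root), `depth`, `height` (maximum leaf
#'   depth), `node_height` (height measured from the leaf level: leaves at
#'   maximal depth have height 0, the root has height `height`), `anc`
#'   (ancestor-at-depth lookup matrix) and `leaves_under` (leaf labels below
#'   each node).
#' @examples
#' tx <- taxonomy(c(Male = "ANY", Female = "ANY"))
#' tx$height  # 1
#' @export
taxonomy <- function(parent, root = "ANY") {
  children <- names(parent)
  if (is.null(children) || any(children == ""))
    stop("'parent' must be a named character vector child -> parent")
  labels <- unique(c(root, as.character(parent), children))
  if (anyDuplicated(children)) stop("a node may have only one parent")
  if (root %in% children) stop("root must not have a parent")
  missing_par <- setdiff(setdiff(as.character(parent), children), root)
  if (length(missing_par))
    stop("parent label(s) without a path to root: ",
         paste(missing_par, collapse = ", "))
  id <- seq_along(labels)
  names(id) <- labels
  parent_id <- integer(length(labels))          # 0 for root
  parent_id[id[children]] <- id[as.character(parent)]

  # depth by walking to root; also detects cycles
  depth <- integer(length(labels))
  for (i in seq_along(labels)) {
    d <- 0L; j <- i
    while (parent_id[j] != 0L) {
      j <- parent_id[j]; d <- d + 1L
      if (d > length(labels)) stop("taxonomy contains a cycle")
    }
    depth[i] <- d
  }
  height <- max(depth)
  if (height < 1L) stop("taxonomy must have at least one level below the root")

  # anc[i, d+1] = id of the ancestor of node i at depth d (0 if depth[i] < d)
  anc <- matrix(0L, nrow = length(labels), ncol = height + 1L)
  for (i in seq_along(labels)) {
    j <- i
    anc[i, depth[i] + 1L] <- j
    while (parent_id[j] != 0L) {
      j <- parent_id[j]
      anc[i, depth[j] + 1L] <- j
    }
  }
  is_leaf <- !(id %in% parent_id)
  leaves_under <- lapply(seq_along(labels), function(i) {
    below <- which(anc[, depth[i] + 1L] == i & is_leaf)
    labels[below]
  })
  structure(
    list(labels = labels, id = id, parent = parent_id, depth = depth,
         height = height, node_height = pmax(height - depth, 0L),
         anc = anc, is_leaf = is_leaf, leaves_under = leaves_under,
         root = root),
    class = "taxonomy")
}

#' @export
print.taxonomy <- function(x, ...) {
  cat("Taxonomy tree: ", length(x$labels), " nodes, height ", x$height,
      ", root '", x$root, "'\n", sep = "")
  invisible(x)
}

#' Read / write a taxonomy edge list
#'
#' Taxonomy files are two-column tab-separated edge lists (`parent<TAB>child`,
#' no header); the root is the one parent that never appears as a child and is
#' conventionally labelled `ANY`.
#'
#' @param path file path.
#' @return `read_taxonomy()` returns a [taxonomy] object.
#' @export
read_taxonomy <- function(path) {
  edges <- utils::read.table(path, sep = "\t", header = FALSE,
                             col.names = c("parent", "child"),
                             colClasses = "character", quote = "",
                             comment.char = "")
  roots <- setdiff(edges$parent, edges$child)
  if (length(roots) != 1L)
    stop("taxonomy file must have exactly one root; found: ",
         paste(roots, collapse = ", "))
  parent <- stats::setNames(edges$parent, edges$child)
  taxonomy(parent, root = roots)
}

#' @rdname read_taxonomy
#' @param tx a [taxonomy] object.
#' @export
write_taxonomy <- function(tx, path) {
  stopifnot(inherits(tx, "taxonomy"))
  child <- which(tx$parent != 0L)
  utils::write.table(
    data.frame(parent = tx$labels[tx$parent[child]], child = tx$labels[child]),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# node ids for labels, with validation
tax_id <- function(tx, labels) {
  i <- tx$id[labels]
  if (anyNA(i))
    stop("label(s) not in taxonomy: ",
         paste(unique(labels[is.na(i)]), collapse = ", "))
  unname(i)
}

# is node a (weak) ancestor of each node in b?  vectorized over b
tax_is_ancestor <- function(tx, a, b) {
  da <- tx$depth[a]
  tx$depth[b] >= da & tx$anc[b, da + 1L] == a
}

# lowest common ancestor of node a and each node in b; vectorized over b.
# Ancestor paths agree at depth d only if they agree at all shallower depths,
# so the LCA depth is the number of depths >= 1 at which the paths coincide.
tax_lca <- function(tx, a, b) {
  if (length(b) == 0L) return(integer(0))
  dmax <- min(tx$depth[a], max(tx$depth[b]))
  lca_depth <- integer(length(b))
  if (dmax >= 1L) for (d in seq_len(dmax)) {
    eq <- tx$anc[b, d + 1L] == tx$anc[a, d + 1L] & tx$anc[b, d + 1L] != 0L
    lca_depth <- lca_depth + (eq & lca_depth == (d - 1L))
  }
  tx$anc[a, ][lca_depth + 1L]
}

#' Toy age taxonomy used in examples and tests
#'
#' A small two-level age-group hierarchy (`ANY` over `Nonadult`/`Adult`, each
#' over a few leaf groups), in the spirit of the MeSH age groups commonly used
#' to categorize the FAERS `Age` field.  It is a synthetic stand-in, not the
#' actual MeSH tree.
#'
#' @return A [taxonomy] object of height 2.
#' @export
toy_age_taxonomy <- function() {
  taxonomy(c(
    Nonadult = "ANY", Adult = "ANY",
    Newborn = "Nonadult", Infant = "Nonadult", Preschool = "Nonadult",
    Child = "Nonadult", Adolescent = "Nonadult",
    YoungAdult = "Adult", MiddleAged = "Adult", Aged = "Adult"))
}

#' @rdname toy_age_taxonomy
#' @export
sex_taxonomy <- function() {
  taxonomy(c(Male = "ANY", Female = "ANY"))
}
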