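#' Build a germline-rooted clonal lineage tree
#'
#' Reconstructs a lineage tree over the unique member sequences of one clone,
#' rooted at the germline V sequence, minimizing the total number of
#' mutations along edges. Each sequence is represented by its mutation set
#' versus the germline. Sequences are attached greedily in order of
#' increasing mutation count to the deepest existing node whose mutation set
#' they contain; when a new sequence shares with a sibling a common mutation
#' subset strictly larger than their parent's, an inferred intermediate node
#' carrying the shared mutations is created. The procedure is deterministic:
#' ties are broken by larger node multiplicity, then lexicographic sequence
#' order. Back-mutations are never inferred.
#'
#' On perfect-phylogeny input (every mutation arising once, no reversions)
#' the total tree weight equals the size of the union of the observed
#' mutation sets, which is the minimum possible.
#'
#' @param v_seqs character vector of aligned member V sequences (duplicates
#'   allowed; they only increase node multiplicity).
#' @param ref a [germline_reference()].
#' @param clone_id optional identifier stored on the tree.
#' @return object of class `lineage_tree`: list with `nodes` (tibble
#'   `label, type, multiplicity, n_mut, sequence`; `type` is `germline`,
#'   `observed` or `inferred`) and `edges` (tibble `parent, child, weight`).
#' @export
build_lineage_tree <- function(v_seqs, ref, clone_id = NA) {
  stopifnot(inherits(ref, "germline_reference"))
  v_seqs <- unlist(v_seqs)
  L <- nchar(ref$sequence)
  if (any(nchar(v_seqs) != L)) abort("sequences must share the germline length")
  gc <- s2c(ref$sequence)

  mutset_of <- function(seq) {
    vc <- s2c(seq)
    d <- which(vc != gc & vc %in% DNA_BASES)
    if (length(d) == 0L) character() else paste0(d, ":", vc[d])
  }
  seq_of_mutset <- function(ms) {
    vc <- gc
    if (length(ms)) {
      parts <- strsplit(ms, ":", fixed = TRUE)
      for (p in parts) vc[as.integer(p[1])] <- p[2]
    }
    c2s(vc)
  }

  tab <- table(v_seqs)
  uniq <- names(tab)
  sets <- lapply(uniq, mutset_of)
  ord <- order(lengths(sets), uniq)

  nodes <- list(list(label = "germline", type = "germline",
                     multiplicity = 0L, set = character(),
                     sequence = ref$sequence, parent = NA_integer_))
  n_inferred <- 0L

  find_node <- function(set) {
    for (i in seq_along(nodes)) {
      if (setequal(nodes[[i]]$set, set)) return(i)
    }
    NA_integer_
  }

  for (oi in ord) {
    s <- sets[[oi]]
    mult <- as.integer(tab[[uniq[oi]]])

    existing <- find_node(s)
    if (!is.na(existing)) {
      nodes[[existing]]$multiplicity <- nodes[[existing]]$multiplicity + mult
      if (nodes[[existing]]$type == "inferred") {
        nodes[[existing]]$type <- "observed"
        nodes[[existing]]$label <- uniq[oi]
      }
      next
    }

    # deepest node whose mutation set is contained in s;
    # ties: larger multiplicity, then lexicographic sequence order
    cand <- which(vapply(nodes, function(n) all(n$set %in% s), TRUE))
    sizes <- vapply(nodes[cand], function(n) length(n$set), 1L)
    mults <- vapply(nodes[cand], function(n) n$multiplicity, 1L)
    seqs <- vapply(nodes[cand], function(n) n$sequence, "")
    pick <- order(-sizes, -mults, seqs)[1]
    parent <- cand[pick]

    # look for a sibling sharing a larger common prefix than the parent set
    children <- which(vapply(nodes, function(n)
      identical(n$parent, parent), TRUE))
    best_sib <- NA_integer_; best_I <- character()
    for (ch in children) {
      I <- intersect(nodes[[ch]]$set, s)
      better <- length(I) > length(best_I) ||
        (length(I) == length(best_I) && !is.na(best_sib) &&
           nodes[[ch]]$multiplicity > nodes[[best_sib]]$multiplicity)
      if (length(I) > length(nodes[[parent]]$set) && better) {
        best_sib <- ch; best_I <- I
      }
    }
    if (!is.na(best_sib) && length(best_I) < length(nodes[[best_sib]]$set)) {
      n_inferred <- n_inferred + 1L
      nodes[[length(nodes) + 1L]] <- list(
        label = sprintf("inferred_%d", n_inferred), type = "inferred",
        multiplicity = 0L, set = best_I,
        sequence = seq_of_mutset(best_I), parent = parent)
      inode <- length(nodes)
      nodes[[best_sib]]$parent <- inode
      parent <- inode
    }

    nodes[[length(nodes) + 1L]] <- list(
      label = uniq[oi], type = "observed", multiplicity = mult, set = s,
      sequence = uniq[oi], parent = parent)
  }

  node_tbl <- bind_rows(lapply(nodes, function(n) tibble(
    label = n$label, type = n$type, multiplicity = n$multiplicity,
    n_mut = length(n$set), sequence = n$sequence)))
  # readable labels for observed nodes
  obs <- which(node_tbl$type == "observed")
  node_tbl$label[obs] <- sprintf("seq%d", seq_along(obs))
  edges <- bind_rows(lapply(seq_along(nodes)[-1], function(i) tibble(
    parent = node_tbl$label[nodes[[i]]$parent],
    child = node_tbl$label[i],
    weight = length(nodes[[i]]$set) - length(nodes[[nodes[[i]]$parent]]$set))))
  structure(list(nodes = node_tbl, edges = edges, clone_id = clone_id),
            class = "lineage_tree")
}

#' @export
print.lineage_tree <- function(x, ...) {
  cat(sprintf("<lineage_tree> %d nodes (%d inferred), total weight %d\n",
              nrow(x$nodes), sum(x$nodes$type == "inferred"),
              total_tree_weight(x)))
  invisible(x)
}

#' Total mutation weight of a lineage tree
#'
#' @param tree a `lineage_tree`.
#' @return sum of edge weights (total mutations along all edges).
#' @export
total_tree_weight <- function(tree) {
  stopifnot(inherits(tree, "lineage_tree"))
  sum(tree$edges$weight)
}

#' Serialize a lineage tree to Newick
#'
#' Branch lengths are the edge mutation counts; inferred nodes keep their
#' `inferred_k` labels. The output round-trips through standard Newick
#' parsers.
#'
#' @param tree a `lineage_tree`.
#' @param path optional file to write to.
#' @return the Newick string, invisibly when `path` is given.
#' @export
write_newick <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "lineage_tree"))
  children_of <- split(seq_len(nrow(tree$edges)), tree$edges$parent)
  labels <- tree$nodes$label
  recurse <- function(label) {
    kid_rows <- children_of[[label]]
    if (is.null(kid_rows)) return(label)
    inner <- vapply(kid_rows, function(r) {
      paste0(recurse(tree$edges$child[r]), ":", tree$edges$weight[r])
    }, "")
    paste0("(", paste(inner, collapse = ","), ")", label)
  }
  nwk <- paste0(recurse("germline"), ";")
  if (!is.null(path)) {
    writeLines(nwk, path)
    return(invisible(nwk))
  }
  nwk
}

#' Build lineage trees for all clones in a clone set
#'
#' @param clones a `clone_set` from [group_clones()].
#' @param ref a [germline_reference()].
#' @param min_size smallest clone size to build a tree for (default 1).
#' @return named list of `lineage_tree` objects, keyed by clone id.
#' @export
build_clone_trees <- function(clones, ref, min_size = 1L) {
  keep <- clones[clones$size >= min_size, ]
  trees <- lapply(seq_len(nrow(keep)), function(i) {
    build_lineage_tree(keep$v_seqs[[i]], ref, clone_id = keep$clone_id[i])
  })
  names(trees) <- paste0("clone", keep$clone_id, recycle0 = TRUE)
  trees
}

#' Edge list of one or more lineage trees
#'
#' @param trees a `lineage_tree` or list of them.
#' @return tibble `clone_id, parent, child, weight, multiplicity, inferred`.
#' @export
tree_edge_table <- function(trees) {
  if (inherits(trees, "lineage_tree")) trees <- list(trees)
  bind_rows(lapply(trees, function(tr) {
    info <- tr$nodes[match(tr$edges$child, tr$nodes$label), ]
    tibble(clone_id = tr$clone_id, parent = tr$edges$parent,
           child = tr$edges$child, weight = tr$edges$weight,
           multiplicity = info$multiplicity,
           inferred = info$type == "inferred")
  }))
}
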