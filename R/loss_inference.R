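#' Map gene losses onto a rooted tree under Dollo parsimony
#'
#' Under Dollo parsimony a gene is gained at most once (on the root
#' edge), so along any root-to-tip path states may only flip
#' present -> absent. The minimal reconstruction labels a node present
#' exactly when its subtree contains at least one tip known to carry the
#' gene; every edge from a present parent to an absent child whose
#' subtree contains at least one known-absent tip is an independent loss
#' event. This minimal labeling is unique, so repeated runs are
#' identical.
#'
#' Unknown tip states are unconstrained: they are assigned whatever
#' state minimizes losses (in practice, the parent's state) and are
#' flagged in the result.
#'
#' @param tree Rooted \code{phylo} tree (polytomies allowed; a loss on a
#'   polytomy edge counts once).
#' @param states Character matrix from \code{\link{read_state_matrix}}
#'   (taxa x genes), or a named character vector of states for one gene.
#'   Entries: present/absent/unknown.
#' @param gene Column of \code{states} to map (ignored when
#'   \code{states} is a vector).
#' @param assume_ancestral_present When every tip lacks the gene, count
#'   one loss on the root edge (default TRUE, reflecting an ancestor
#'   that carried a complete complex); with FALSE such a gene is simply
#'   reconstructed as ancestrally absent with zero losses.
#' @return A list of class \code{loss_map}: \code{gene},
#'   \code{ancestral_state} (named vector over all nodes, tips first in
#'   \code{tree$tip.label} order then internal nodes in ape numbering),
#'   \code{loss_edges} (data frame: parent, child, child_label),
#'   \code{n_independent_losses}, \code{unknown_tips}.
#' @export
dollo_loss_map <- function(tree, states, gene = NULL,
                           assume_ancestral_present = TRUE) {
  check_rooted(tree)
  if (is.matrix(states)) {
    if (is.null(gene)) stop("gene must be named when states is a matrix")
    if (!gene %in% colnames(states)) stop("gene not in state matrix: ", gene)
    tipstate <- states[, gene]
  } else {
    tipstate <- states
    if (is.null(gene)) gene <- "gene"
  }
  missing <- setdiff(tree$tip.label, names(tipstate))
  if (length(missing) > 0L) {
    stop("tip(s) missing from state matrix: ", paste(missing, collapse = ", "))
  }
  tipstate <- tipstate[tree$tip.label]
  stopifnot(all(tipstate %in% c("present", "absent", "unknown")))

  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  nno <- ntip + nnode
  node_label <- c(tree$tip.label, paste0("node", seq_len(nnode) + ntip))

  if (ntip == 1L) {
    st <- tipstate[[1]]
    if (st == "present") {
      return(new_loss_map(gene, stats::setNames("present", node_label[1]),
                          empty_loss_edges(), tipstate))
    }
    if (assume_ancestral_present && st == "absent") {
      le <- data.frame(parent = NA_integer_, child = 1L, child_label = node_label[1])
      return(new_loss_map(gene, stats::setNames("absent", node_label[1]), le, tipstate))
    }
    return(new_loss_map(gene, stats::setNames(if (st == "absent") "absent" else "present",
                                              node_label[1]),
                        empty_loss_edges(), tipstate))
  }

  edge <- tree$edge
  # postorder accumulation of present/absent tip counts below each node
  po <- ape::reorder.phylo(tree, "postorder")$edge
  present_below <- integer(nno)
  absent_below <- integer(nno)
  present_below[seq_len(ntip)] <- as.integer(tipstate == "present")
  absent_below[seq_len(ntip)] <- as.integer(tipstate == "absent")
  for (i in seq_len(nrow(po))) {
    p <- po[i, 1]; ch <- po[i, 2]
    present_below[p] <- present_below[p] + present_below[ch]
    absent_below[p] <- absent_below[p] + absent_below[ch]
  }
  root <- setdiff(edge[, 1], edge[, 2])

  any_present <- present_below[root] > 0L
  loss <- edge[present_below[edge[, 1]] > 0L & present_below[edge[, 2]] == 0L &
               absent_below[edge[, 2]] > 0L, , drop = FALSE]

  state <- character(nno)
  if (any_present) {
    # preorder walk: present where the subtree holds a present tip;
    # otherwise inherit absent below a loss edge, or the parent's state
    # for unknown-only subtrees
    pre <- po[rev(seq_len(nrow(po))), , drop = FALSE]
    state[root] <- "present"
    for (i in seq_len(nrow(pre))) {
      p <- pre[i, 1]; ch <- pre[i, 2]
      state[ch] <- if (present_below[ch] > 0L) {
        "present"
      } else if (absent_below[ch] > 0L) {
        "absent"
      } else {
        state[p]   # unknown-only subtree: follow parent, no event
      }
    }
    le <- data.frame(parent = loss[, 1], child = loss[, 2],
                     child_label = node_label[loss[, 2]])
    le <- le[order(le$child), , drop = FALSE]
    rownames(le) <- NULL
  } else if (assume_ancestral_present && any(tipstate == "absent")) {
    state[] <- "absent"
    le <- data.frame(parent = NA_integer_, child = root,
                     child_label = "root")
  } else {
    state[] <- if (any(tipstate == "absent")) "absent" else "present"
    le <- empty_loss_edges()
  }
  names(state) <- node_label
  new_loss_map(gene, state, le, tipstate)
}

#' @noRd
empty_loss_edges <- function() {
  data.frame(parent = integer(), child = integer(), child_label = character())
}

#' @noRd
new_loss_map <- function(gene, state, loss_edges, tipstate) {
  structure(list(gene = gene,
                 ancestral_state = state,
                 loss_edges = loss_edges,
                 n_independent_losses = nrow(loss_edges),
                 unknown_tips = names(tipstate)[tipstate == "unknown"]),
            class = "loss_map")
}

#' Independent-loss summary over all genes of a state matrix
#'
#' @param tree Rooted \code{phylo}.
#' @param states Character matrix (taxa x genes).
#' @param assume_ancestral_present See \code{\link{dollo_loss_map}}.
#' @return Data frame: gene, n_independent_losses, loss_edges (child
#'   labels, comma-separated), n_unknown_tips.
#' @export
loss_summary <- function(tree, states, assume_ancestral_present = TRUE) {
  out <- lapply(colnames(states), function(g) {
    lm <- dollo_loss_map(tree, states, g, assume_ancestral_present)
    data.frame(gene = g,
               n_independent_losses = lm$n_independent_losses,
               loss_edges = paste(lm$loss_edges$child_label, collapse = ","),
               n_unknown_tips = length(lm$unknown_tips))
  })
  do.call(rbind, out)
}

#' Export a loss map as an annotated Newick string
#'
#' Internal nodes that head a loss edge carry a \code{[&loss=<gene>]}
#' comment tag, readable by tree viewers that understand NHX-style
#' comments.
#'
#' @param tree Rooted \code{phylo}.
#' @param loss_map A \code{loss_map} from \code{\link{dollo_loss_map}}.
#' @return A single Newick string.
#' @export
loss_map_newick <- function(tree, loss_map) {
  lab <- character(tree$Nnode)
  ntip <- length(tree$tip.label)
  tr <- tree
  flagged <- loss_map$loss_edges$child
  flagged <- flagged[!is.na(flagged)]
  for (ch in flagged) {
    if (ch > ntip) lab[ch - ntip] <- paste0("[&loss=", loss_map$gene, "]")
  }
  tr$node.label <- lab
  tips_flagged <- flagged[flagged <= ntip]
  if (length(tips_flagged) > 0L) {
    tr$tip.label[tips_flagged] <- paste0(tr$tip.label[tips_flagged],
                                         "[&loss=", loss_map$gene, "]")
  }
  ape::write.tree(tr)
}
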