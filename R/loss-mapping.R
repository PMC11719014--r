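#' Place gene-loss events on a species tree by Dollo parsimony
#'
#' Under Dollo parsimony the gene is present at the root (a single gain) and
#' can only be lost, never regained. This function finds the minimal set of
#' branches such that every pseudogenized tip descends from exactly one loss
#' and no intact tip descends from any; indeterminate tips are free
#' variables that may sit inside or outside a loss clade. Among equally
#' minimal placements the default tie-break puts each loss on the deepest
#' branch consistent with the constraints (the maximally early loss, i.e.
#' the largest clade containing no intact tip); `tie_break = "shallow"`
#' instead uses the most recent common ancestor of the pseudogenized tips
#' of each loss clade, for sensitivity analysis.
#'
#' @param tree A rooted `phylo` tree whose tip labels match the status
#'   taxa exactly.
#' @param statuses A tibble with columns `taxon` and `call` (typically from
#'   [screen_alignment()]); every tree tip must have a status and every
#'   status must name a tree tip.
#' @param tie_break `"deep"` (default) or `"shallow"`.
#' @return A tibble of class `pseudoscan_losses`, one row per loss event,
#'   sorted by clade size descending: `node` (internal node or tip number of
#'   the clade the loss branch subtends), `clade_tips` (list column of tip
#'   labels), `n_tips` and `n_pseudogenized`. The tree is attached as an
#'   attribute for [narrate_losses()].
#' @export
dollo_losses <- function(tree, statuses, tie_break = c("deep", "shallow")) {
  tie_break <- match.arg(tie_break)
  stopifnot(inherits(tree, "phylo"))
  tips <- tree$tip.label
  extra <- setdiff(statuses$taxon, tips)
  if (length(extra)) {
    abort(paste0("unknown tip: '", extra[1], "' not in tree"))
  }
  missing <- setdiff(tips, statuses$taxon)
  if (length(missing)) {
    abort(paste0("missing status: tip '", missing[1], "'"))
  }
  call_of <- stats::setNames(statuses$call, statuses$taxon)[tips]

  n_tip <- length(tips)
  n_node <- n_tip + tree$Nnode
  desc <- descendant_tips(tree)
  n_pseudo <- vapply(desc, function(d) sum(call_of[d] == "pseudogenized"),
                     integer(1))
  has_intact <- vapply(desc, function(d) any(call_of[d] == "intact"),
                       logical(1))
  candidate <- n_pseudo > 0L & !has_intact

  parent <- integer(n_node)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  root <- n_tip + 1L
  parent_candidate <- rep(FALSE, n_node)
  has_parent <- parent > 0L
  parent_candidate[has_parent] <- candidate[parent[has_parent]]
  maximal <- which(candidate & !parent_candidate)

  events <- purrr::map(maximal, function(v) {
    node <- v
    if (tie_break == "shallow") {
      ptips <- desc[[v]][call_of[desc[[v]]] == "pseudogenized"]
      node <- if (length(ptips) == 1L) ptips else
        ape::getMRCA(tree, tips[ptips])
    }
    tibble(
      node = as.integer(node),
      clade_tips = list(tips[desc[[node]]]),
      n_tips = length(desc[[node]]),
      n_pseudogenized = sum(call_of[desc[[node]]] == "pseudogenized")
    )
  })
  out <- bind_rows(events)
  if (nrow(out) == 0) {
    out <- tibble(node = integer(0), clade_tips = list(),
                  n_tips = integer(0), n_pseudogenized = integer(0))
  } else {
    out <- arrange(out, dplyr::desc(.data$n_tips))
  }
  class(out) <- c("pseudoscan_losses", class(out))
  attr(out, "tree") <- tree
  out
}

# tip indices under every node (tips included, indexed by node id)
descendant_tips <- function(tree) {
  n_tip <- length(tree$tip.label)
  out <- vector("list", n_tip + tree$Nnode)
  for (i in seq_len(n_tip)) out[[i]] <- i
  eo <- ape::reorder.phylo(tree, "postorder")$edge
  for (k in seq_len(nrow(eo))) {
    out[[eo[k, 1]]] <- c(out[[eo[k, 1]]], out[[eo[k, 2]]])
  }
  out
}

#' Phrase loss events relative to the lineages that diverged before them
#'
#' Produces the narrative form used in comparative gene-loss studies: a loss
#' on an internal branch is phrased "loss after the divergence of X", where
#' X is the sister lineage (or lineages, at a polytomy) splitting off
#' immediately before the loss branch; a loss on a terminal branch is
#' phrased "loss on terminal branch of <tip>".
#'
#' @param tree The species tree (defaults to the one attached to `events`).
#' @param events Result of [dollo_losses()].
#' @return A tibble with columns `node`, `clade`, `sister` and `narrative`;
#'   when `events` is empty, a single row with narrative "no loss events".
#' @export
narrate_losses <- function(events, tree = attr(events, "tree")) {
  if (nrow(events) == 0) {
    return(tibble(node = NA_integer_, clade = "", sister = "",
                  narrative = "no loss events"))
  }
  stopifnot(inherits(tree, "phylo"))
  tips <- tree$tip.label
  n_tip <- length(tips)
  desc <- descendant_tips(tree)
  root <- n_tip + 1L
  label_clade <- function(node) {
    tl <- tips[desc[[node]]]
    if (length(tl) == 1L) tl else paste0("(", paste(tl, collapse = ", "), ")")
  }
  rows <- purrr::map(seq_len(nrow(events)), function(i) {
    v <- events$node[i]
    clade <- paste(tips[desc[[v]]], collapse = ", ")
    if (v <= n_tip) {
      return(tibble(node = v, clade = clade, sister = "",
                    narrative = paste0("loss on terminal branch of ",
                                       tips[v])))
    }
    if (v == root) {
      return(tibble(node = v, clade = clade, sister = "",
                    narrative = "loss at the root: all sampled taxa affected"))
    }
    parent <- tree$edge[tree$edge[, 2] == v, 1]
    sibs <- setdiff(tree$edge[tree$edge[, 1] == parent, 2], v)
    sister <- paste(vapply(sibs, label_clade, character(1)), collapse = ", ")
    tibble(node = v, clade = clade, sister = sister,
           narrative = paste0("loss after the divergence of ", sister))
  })
  bind_rows(rows)
}
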