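# Tree utilities shared by the Dollo placement and the sequence simulator.
# A branch is identified by the set of tips it subtends, written as the
# sorted tip names joined with "+"; the stem above the root (subtending all
# tips) is a valid branch so that a gain predating the root is expressible.

.as_phylo <- function(tree) {
  if (inherits(tree, "phylo")) return(tree)
  if (is.character(tree) && length(tree) == 1) {
    phy <- tryCatch(ape::read.tree(text = tree), error = function(e) NULL,
                    warning = function(w) NULL)
    if (is.null(phy)) stop("malformed Newick string")
    return(phy)
  }
  stop("tree must be a phylo object or a Newick string")
}

# list mapping node number -> integer vector of descendant tip indices
.node_tipsets <- function(phy) {
  n <- ape::Ntip(phy)
  sets <- vector("list", n + phy$Nnode)
  for (i in seq_len(n)) sets[[i]] <- i
  eo <- ape::reorder.phylo(phy, "postorder")$edge
  for (k in seq_len(nrow(eo)))
    sets[[eo[k, 1]]] <- c(sets[[eo[k, 1]]], sets[[eo[k, 2]]])
  sets
}

.branch_label <- function(phy, tipset)
  paste(sort(phy$tip.label[tipset]), collapse = "+")

#' Branch labels of a rooted tree
#'
#' Every branch is named by the sorted "+"-joined tip labels it subtends;
#' the root stem (all tips) is included so a gain older than the root can
#' be specified.
#'
#' @param tree A rooted `phylo` object or Newick string.
#' @return Character vector of branch labels (one per non-root node plus
#'   the root stem).
#' @examples
#' branch_labels("(urocyon,(vulpes,(lycaon,(latrans,familiaris))));")
#' @export
branch_labels <- function(tree) {
  phy <- .as_phylo(tree)
  if (!ape::is.rooted(phy)) stop("tree must be rooted")
  sets <- .node_tipsets(phy)
  root <- ape::Ntip(phy) + 1L
  nodes <- setdiff(seq_along(sets), root)
  c(vapply(nodes, function(v) .branch_label(phy, sets[[v]]), character(1)),
    .branch_label(phy, sets[[root]]))
}

#' Dollo-parsimony placement of retrocopy gains on a species tree
#'
#' Places presence/absence of a retrocopy on a fixed rooted species tree
#' under the Dollo constraint: the homologous copy is gained exactly once,
#' and may be lost any number of times.  The placement minimizes total
#' events (the single gain plus losses); ties among equally parsimonious
#' gain positions are broken toward the root (a gain is slid rootward over
#' purely unconstrained sister clades).
#'
#' Tip states:
#' * `present` / `absent` - constrain the shared copy;
#' * `unknown` - contributes no constraint;
#' * `present_independent` - the tip carries its own, independently gained
#'   homolog: it receives a mandatory gain on its terminal branch and is
#'   excluded from the shared copy's objective.
#'
#' @param tree Rooted `phylo` or Newick string.
#' @param profile Named character vector tip name -> state.
#' @param allow_loss If `FALSE`, a profile that cannot be explained by a
#'   single gain without losses is an error.
#' @return Object of class `event_placement`: list with `gains` and
#'   `losses` (branch labels, see [branch_labels()]), `independent_gains`,
#'   `n_events`, and the `tree`.
#' @examples
#' tr <- "(urocyon,(vulpes,(lycaon,(latrans,familiaris))));"
#' dollo_place(tr, c(urocyon = "present", vulpes = "present",
#'                   lycaon = "present", latrans = "present",
#'                   familiaris = "present"))
#' @export
dollo_place <- function(tree, profile, allow_loss = TRUE) {
  phy <- .as_phylo(tree)
  if (!ape::is.rooted(phy)) stop("tree must be rooted")
  tips <- phy$tip.label
  if (anyDuplicated(tips)) stop("tip names must be unique")
  bad <- setdiff(names(profile), tips)
  if (length(bad))
    stop("profile names absent from the tree: ", paste(bad, collapse = ", "))
  missing_tips <- setdiff(tips, names(profile))
  if (length(missing_tips))
    stop("profile must cover all tips; missing: ",
         paste(missing_tips, collapse = ", "))
  states <- c("present", "absent", "unknown", "present_independent")
  if (!all(profile %in% states))
    stop("states must be one of: ", paste(states, collapse = ", "))

  n <- ape::Ntip(phy)
  root <- n + 1L
  sets <- .node_tipsets(phy)
  parent <- integer(n + phy$Nnode)
  parent[phy$edge[, 2]] <- phy$edge[, 1]
  children <- split(phy$edge[, 2], phy$edge[, 1])

  P <- which(tips %in% names(profile)[profile == "present"])
  A <- which(tips %in% names(profile)[profile == "absent"])
  indep <- names(profile)[profile == "present_independent"]
  independent_gains <- vapply(match(indep, tips),
                              function(i) .branch_label(phy, i), character(1))

  gains <- character(0)
  losses <- character(0)
  if (length(P)) {
    g <- if (length(P) == 1) P else ape::getMRCA(phy, P)
    # slide the gain rootward while every sister clade is unconstrained
    repeat {
      if (g == root) break
      pa <- parent[g]
      sibs <- setdiff(children[[as.character(pa)]], g)
      sib_tips <- unlist(sets[sibs])
      if (any(sib_tips %in% c(P, A))) break
      g <- pa
    }
    gains <- .branch_label(phy, sets[[g]])
    # minimal losses: maximal subtrees below the gain holding absent but no
    # present tips (purely unconstrained subtrees need no event)
    find_losses <- function(v) {
      for (ch in children[[as.character(v)]]) {
        S <- sets[[ch]]
        if (any(S %in% P)) {
          if (ch > n) find_losses(ch)
        } else if (any(S %in% A)) {
          losses <<- c(losses, .branch_label(phy, S))
        }
      }
    }
    if (g > n) find_losses(g)
    if (!allow_loss && length(losses))
      stop("profile requires ", length(losses),
           " loss(es); rerun with allow_loss = TRUE")
  }

  structure(list(gains = gains, losses = losses,
                 independent_gains = independent_gains,
                 n_events = length(gains) + length(losses) +
                   length(independent_gains),
                 tree = phy),
            class = "event_placement")
}

#' @export
print.event_placement <- function(x, ...) {
  cat(sprintf("<event_placement> %d event(s)\n", x$n_events))
  if (length(x$gains)) cat("  gain:", x$gains, "\n")
  for (l in x$losses) cat("  loss:", l, "\n")
  for (g in x$independent_gains) cat("  independent gain:", g, "\n")
  invisible(x)
}

#' Compare an inferred event placement with a simulated truth
#'
#' @param placement,truth `event_placement` objects on the same tree.
#' @return List with `gains_match` (shared-copy gain branches identical as
#'   sets, independent gains included), `event_diff`
#'   (`placement$n_events - truth$n_events`) and `exact` (gains match and
#'   zero event difference and identical loss sets).
#' @export
reconcile_with_truth <- function(placement, truth) {
  stopifnot(inherits(placement, "event_placement"),
            inherits(truth, "event_placement"))
  same_tree <- isTRUE(ape::all.equal.phylo(placement$tree, truth$tree,
                                           use.edge.length = FALSE))
  if (!same_tree) stop("placements are on different trees")
  gains_match <- setequal(c(placement$gains, placement$independent_gains),
                          c(truth$gains, truth$independent_gains))
  event_diff <- placement$n_events - truth$n_events
  list(gains_match = gains_match, event_diff = event_diff,
       exact = gains_match && event_diff == 0 &&
         setequal(placement$losses, truth$losses))
}
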