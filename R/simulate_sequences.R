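#' Configuration for the retrocopy sequence simulator
#'
#' Emulates the creation of a retrocopy: a parent gene sequence, a copy
#' diverged from it at a stated per-site substitution rate on a chosen
#' branch of a species tree, inheritance (with optional further per-branch
#' mutation) down all descendant lineages, and absence elsewhere.
#'
#' @param parent_length Parent sequence length in bp.
#' @param divergence_rate Per-site substitution probability applied at the
#'   retrotransposition event (e.g. 0.02 gives ~98% parent-copy identity).
#' @param indel_rate Per-site probability of a 1-bp insertion or deletion
#'   at the retrotransposition event.
#' @param tree Rooted species tree (Newick string or `phylo`).
#' @param gain_branch Branch carrying the gain, as a [branch_labels()]
#'   label, or `NULL` for no event.
#' @param branch_rate Per-site substitution probability applied on each
#'   branch below the gain (default 0: descendants inherit the copy
#'   unchanged).
#' @param seed Integer seed.
#' @return A `seq_sim_config` list.
#' @export
seq_sim_config <- function(parent_length = 1000, divergence_rate = 0.02,
                           indel_rate = 0, tree, gain_branch = NULL,
                           branch_rate = 0, seed = 1) {
  phy <- .as_phylo(tree)
  if (!ape::is.rooted(phy)) stop("tree must be rooted")
  rates <- c(divergence_rate, indel_rate, branch_rate)
  if (any(rates < 0) || any(rates >= 1)) stop("rates must be in [0, 1)")
  if (!is.null(gain_branch) && !(gain_branch %in% branch_labels(phy)))
    stop("gain_branch is not a branch of the tree; see branch_labels()")
  structure(list(parent_length = as.integer(parent_length),
                 divergence_rate = divergence_rate, indel_rate = indel_rate,
                 tree = phy, gain_branch = gain_branch,
                 branch_rate = branch_rate, seed = as.integer(seed)),
            class = "seq_sim_config")
}

# substitute each site with probability `rate`, uniformly to one of the
# other three bases
.mutate_seq <- function(chars, rate) {
  if (rate <= 0) return(chars)
  hit <- which(runif(length(chars)) < rate)
  bases <- c("A", "C", "G", "T")
  for (i in hit) chars[i] <- sample(setdiff(bases, chars[i]), 1)
  chars
}

.apply_indels <- function(chars, rate) {
  if (rate <= 0) return(chars)
  hit <- which(runif(length(chars)) < rate)
  if (!length(hit)) return(chars)
  out <- as.list(chars)
  bases <- c("A", "C", "G", "T")
  for (i in hit) {
    if (runif(1) < 0.5) out[[i]] <- character(0)                 # deletion
    else out[[i]] <- c(chars[i], sample(bases, 1))               # insertion
  }
  unlist(out)
}

#' Simulate a parent gene and its retrocopies across a species tree
#'
#' Draws a uniform-composition random DNA parent sequence, creates the
#' retrocopy on `gain_branch` by applying `divergence_rate` substitutions
#' (and `indel_rate` 1-bp indels), then passes it down every descendant
#' branch with `branch_rate` further substitutions per branch.  Species
#' descending from the gain branch carry a copy; all others do not.
#'
#' @param cfg A [seq_sim_config()].
#' @return List with `parent` (character DNA string), `copies` (named
#'   character vector, one element per species carrying the copy) and
#'   `truth` (an `event_placement` with the gain branch, for
#'   [reconcile_with_truth()]).
#' @examples
#' tr <- "(urocyon,(vulpes,(lycaon,(latrans,familiaris))));"
#' cfg <- seq_sim_config(parent_length = 500, divergence_rate = 0.02,
#'                       tree = tr, gain_branch = "familiaris+latrans",
#'                       seed = 3)
#' sim <- simulate_retrocopy_sequences(cfg)
#' names(sim$copies)
#' @export
simulate_retrocopy_sequences <- function(cfg) {
  stopifnot(inherits(cfg, "seq_sim_config"))
  phy <- cfg$tree
  n <- ape::Ntip(phy)
  root <- n + 1L
  sets <- .node_tipsets(phy)
  children <- split(phy$edge[, 2], phy$edge[, 1])

  withr::with_seed(cfg$seed, {
    parent <- sample(c("A", "C", "G", "T"), cfg$parent_length, replace = TRUE)
    copies <- character(0)
    if (!is.null(cfg$gain_branch)) {
      labels_all <- vapply(seq_along(sets),
                           function(v) .branch_label(phy, sets[[v]]),
                           character(1))
      g <- which(labels_all == cfg$gain_branch)[1]
      copy0 <- .apply_indels(.mutate_seq(parent, cfg$divergence_rate),
                             cfg$indel_rate)
      seqs <- vector("list", length(sets))
      seqs[[g]] <- copy0
      descend <- function(v) {
        for (ch in if (v > n) children[[as.character(v)]] else integer(0)) {
          seqs[[ch]] <<- .mutate_seq(seqs[[v]], cfg$branch_rate)
          descend(ch)
        }
      }
      descend(g)
      carrier_tips <- sets[[g]]
      copies <- vapply(carrier_tips,
                       function(t) paste(seqs[[t]], collapse = ""),
                       character(1))
      names(copies) <- phy$tip.label[carrier_tips]
    }
    truth <- structure(list(
      gains = if (is.null(cfg$gain_branch)) character(0) else cfg$gain_branch,
      losses = character(0), independent_gains = character(0),
      n_events = as.integer(!is.null(cfg$gain_branch)), tree = phy),
      class = "event_placement")
    list(parent = paste(parent, collapse = ""), copies = copies,
         truth = truth)
  })
}
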