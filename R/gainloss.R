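## Gain/loss inference of piC expression on a dated phylogeny by Wagner
## parsimony (binary characters, both gains and losses allowed).

#' Wagner parsimony reconstruction of presence/absence characters
#'
#' Minimum-cost ancestral-state reconstruction of binary
#' expressed/not-expressed characters on a rooted tree, by bottom-up cost
#' propagation (Sankoff) and top-down state choice. A state change 0 -> 1
#' on a branch costs `gain_cost`, 1 -> 0 costs `loss_cost` (default 1:1,
#' plain Wagner parsimony; asymmetric costs are supported). Cost ties at
#' the root are broken toward absence — consistent with small ancestral
#' piC repertoires — and ties below the root toward the parent state (no
#' event); both choices attain the minimum cost.
#'
#' @param tree Rooted [ape::phylo] with branch lengths (MY).
#' @param presence Loci-by-taxa binary matrix (rownames = loci), or a
#'   tibble with a `locus` column and one 0/1 column per taxon. Taxa must
#'   match the tree's tip labels exactly (any order).
#' @param gain_cost,loss_cost Event costs.
#' @param tie_break Root-state tie break, `"absent"` (default) or
#'   `"present"`.
#' @return A `wagner_fit`: per-branch event counts (`$events`), chosen
#'   node states (`$states`, nodes x loci), `$total_cost`, `$n_char`.
#'   Methods: [tidy()], [glance()], [branch_rates()], [autoplot()].
#' @export
wagner_parsimony <- function(tree, presence, gain_cost = 1, loss_cost = 1,
                             tie_break = c("absent", "present")) {
  tie_break <- match.arg(tie_break)
  if (!ape::is.rooted(tree)) abort("tree must be rooted")
  mat <- presence_as_matrix(presence)
  if (!setequal(colnames(mat), tree$tip.label)) {
    abort("presence matrix taxa do not match tree tip labels")
  }
  mat <- mat[, tree$tip.label, drop = FALSE]
  if (!all(mat %in% c(0, 1))) abort("presence states must be 0/1")

  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  nchar_ <- nrow(mat)
  INF <- .Machine$double.xmax / 4

  ## bottom-up: cost0/cost1 [node, character]
  cost0 <- matrix(0, nnode, nchar_)
  cost1 <- matrix(0, nnode, nchar_)
  cost0[seq_len(ntip), ] <- t(ifelse(mat == 0, 0, INF))
  cost1[seq_len(ntip), ] <- t(ifelse(mat == 1, 0, INF))
  po <- ape::reorder.phylo(tree, "postorder")
  for (e in seq_len(nrow(po$edge))) {
    par <- po$edge[e, 1]; chi <- po$edge[e, 2]
    cost0[par, ] <- cost0[par, ] + pmin(cost0[chi, ], gain_cost + cost1[chi, ])
    cost1[par, ] <- cost1[par, ] + pmin(loss_cost + cost0[chi, ], cost1[chi, ])
  }
  root <- ntip + 1L
  root_state <- if (tie_break == "absent") {
    as.integer(cost1[root, ] < cost0[root, ])
  } else {
    as.integer(cost1[root, ] <= cost0[root, ])
  }
  total_cost <- sum(pmin(cost0[root, ], cost1[root, ]))

  ## top-down choice, preorder = reversed postorder edges
  states <- matrix(NA_integer_, nnode, nchar_)
  states[root, ] <- root_state
  for (e in rev(seq_len(nrow(po$edge)))) {
    par <- po$edge[e, 1]; chi <- po$edge[e, 2]
    s <- states[par, ]
    c_to0 <- ifelse(s == 1, loss_cost, 0) + cost0[chi, ]
    c_to1 <- ifelse(s == 0, gain_cost, 0) + cost1[chi, ]
    pick <- integer(nchar_)
    pick[c_to0 < c_to1] <- 0L
    pick[c_to1 < c_to0] <- 1L
    tie <- c_to0 == c_to1
    pick[tie] <- s[tie]  # no event on ties below the root
    states[chi, ] <- pick
  }
  edge_states_par <- states[tree$edge[, 1], , drop = FALSE]
  edge_states_chi <- states[tree$edge[, 2], , drop = FALSE]
  gains <- rowSums(edge_states_par == 0 & edge_states_chi == 1)
  losses <- rowSums(edge_states_par == 1 & edge_states_chi == 0)
  node_lab <- c(tree$tip.label, paste0("node_", seq_len(tree$Nnode) + ntip))
  events <- tibble(
    edge = seq_len(nrow(tree$edge)),
    parent = tree$edge[, 1], child = tree$edge[, 2],
    child_label = node_lab[tree$edge[, 2]],
    branch_my = tree$edge.length,
    gains = as.integer(gains), losses = as.integer(losses))
  rownames(states) <- node_lab
  colnames(states) <- rownames(mat)
  stopifnot(isTRUE(all.equal(
    total_cost, sum(gains) * gain_cost + sum(losses) * loss_cost)))
  structure(list(tree = tree, events = events, states = states,
                 total_cost = total_cost, n_char = nchar_,
                 gain_cost = gain_cost, loss_cost = loss_cost,
                 root_states = root_state, tie_break = tie_break),
            class = "wagner_fit")
}

presence_as_matrix <- function(presence) {
  if (is.matrix(presence)) {
    if (is.null(rownames(presence))) {
      rownames(presence) <- paste0("locus_", seq_len(nrow(presence)))
    }
    return(presence)
  }
  df <- as_tibble(presence)
  if (!"locus" %in% names(df)) abort("presence tibble needs a 'locus' column")
  m <- as.matrix(df[setdiff(names(df), "locus")])
  rownames(m) <- df$locus
  m
}

#' @export
print.wagner_fit <- function(x, ...) {
  cat(sprintf("Wagner parsimony fit: %d characters, total cost %g (%d gains, %d losses)\n",
              x$n_char, x$total_cost, sum(x$events$gains), sum(x$events$losses)))
  print(x$events)
  invisible(x)
}

#' Per-branch gain/loss rates
#'
#' Converts per-branch event counts into rates per million years, both raw
#' (events/MY) and per character (events/MY/locus), using the tree's dated
#' branch lengths. Zero-length branches yield `NA` rates and are flagged.
#'
#' @param fit A `wagner_fit` from [wagner_parsimony()].
#' @return Tibble: branch identity, `gains`, `losses`, `branch_my`,
#'   `gain_rate`, `loss_rate`, `gain_rate_per_char`, `loss_rate_per_char`,
#'   `zero_length`.
#' @export
branch_rates <- function(fit) {
  ev <- fit$events
  zero <- ev$branch_my <= 0
  if (any(zero)) warn("zero-length branch(es): rates undefined there")
  len <- ifelse(zero, NA_real_, ev$branch_my)
  ev |>
    dplyr::mutate(gain_rate = .data$gains / len,
                  loss_rate = .data$losses / len,
                  gain_rate_per_char = .data$gain_rate / fit$n_char,
                  loss_rate_per_char = .data$loss_rate / fit$n_char,
                  zero_length = zero)
}

#' @method tidy wagner_fit
#' @export
tidy.wagner_fit <- function(x, ...) branch_rates(x)

#' @method glance wagner_fit
#' @export
glance.wagner_fit <- function(x, ...) {
  tibble(n_char = x$n_char, total_cost = x$total_cost,
         total_gains = sum(x$events$gains),
         total_losses = sum(x$events$losses),
         gain_cost = x$gain_cost, loss_cost = x$loss_cost,
         tree_my = sum(x$tree$edge.length))
}
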