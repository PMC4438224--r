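# shared fixtures: tiny hand-built trees and the packaged configuration

builtin_config <- function() builtin_paper_parameters()

# symmetric two-leaf chance tree
coin_tree <- function(p = 0.5, cost_heads = 0, cost_tails = 0) {
  decision_tree(chance_node("flip", list(
    tree_edge(terminal_node("heads", cost_pair(cost_heads, 0)), p),
    tree_edge(terminal_node("tails", cost_pair(cost_tails, 0)), 1 - p))))
}

# depth-2 binary tree with all probabilities 0.5 and leaf mother-costs 0..3
depth2_tree <- function() {
  leaf <- function(id, cost) terminal_node(id, cost_pair(cost, 0))
  lower <- function(stub, c1, c2) {
    chance_node(paste0("n_", stub), list(
      tree_edge(leaf(paste0(stub, "_a"), c1), 0.5),
      tree_edge(leaf(paste0(stub, "_b"), c2), 0.5)))
  }
  decision_tree(chance_node("root", list(
    tree_edge(lower("L", 0, 1), 0.5),
    tree_edge(lower("R", 2, 3), 0.5))))
}

# independent oracle for OR -> probability: explicit odds arithmetic
odds_oracle <- function(b, or) {
  odds <- b / (1 - b)
  new_odds <- odds * or
  new_odds / (1 + new_odds)
}

# expected cost by weighting enumerated paths (oracle for rollback)
path_sum <- function(tree, ...) {
  paths <- enumerate_paths(tree, ...)
  cost_pair(sum(paths$probability * paths$mother_cost),
            sum(paths$probability * paths$child_cost))
}

# scale every cost (edge and payoff) in a tree by k
scale_tree_costs <- function(tree, k) {
  scale_node <- function(node) {
    if (!is.null(node$payoff)) {
      node$payoff <- cp_scale(node$payoff, k)
    }
    node$children <- lapply(node$children, function(e) {
      e$cost <- cp_scale(e$cost, k)
      e$node <- scale_node(e$node)
      e
    })
    node
  }
  tree$root <- scale_node(tree$root)
  tree
}

# random valid transition matrix via Dirichlet-style row normalization
random_markov <- function(n_states, seed) {
  with_seed_local(seed, {
    m <- matrix(stats::runif(n_states^2), n_states)
    m <- m / rowSums(m)
    markov_model(paste0("s", seq_len(n_states)), m,
                 cycle_cost = stats::runif(n_states, 0, 1000))
  })
}

with_seed_local <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}
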