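#' @title Decision-tree engine
#' @description Generic rooted decision trees made of decision, chance and
#'   terminal nodes, with branch probabilities and mother/child costs on
#'   edges, expected-value rollback, and an exhaustive path-enumeration
#'   oracle. Trees are immutable nested lists, so they are acyclic by
#'   construction.
#' @name tree_engine
NULL

MAX_ENUM_PATHS <- 1e6
PROB_TOL <- 1e-9

#' Construct a terminal node
#'
#' @param id unique node identifier within the tree.
#' @param payoff a [cost_pair()] collected when a cohort reaches this leaf.
#' @param label human-readable label (defaults to `id`).
#' @return a `tree_node` of kind `"terminal"`.
#' @export
terminal_node <- function(id, payoff = cost_pair(), label = id) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  structure(list(id = id, kind = "terminal", label = label,
                 children = list(), payoff = payoff),
            class = "tree_node")
}

#' Construct a chance node
#'
#' Branch probabilities must sum to 1; at most one child edge may carry
#' the sentinel probability `"complement"`, which is resolved to one minus
#' the sum of its siblings when the tree is assembled. This mirrors how
#' clinical tables usually print event probabilities only, leaving the
#' no-event branch implicit.
#'
#' @param id unique node identifier.
#' @param children list of [tree_edge()] objects (at least one).
#' @param label human-readable label.
#' @return a `tree_node` of kind `"chance"`.
#' @export
chance_node <- function(id, children, label = id) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id), is.list(children))
  structure(list(id = id, kind = "chance", label = label,
                 children = children, payoff = NULL),
            class = "tree_node")
}

#' Construct a decision node
#'
#' Decision-node children carry no probabilities; evaluation requires an
#' explicit arm selection (the engine never auto-optimizes, because the
#' underlying comparisons are descriptive).
#'
#' @inheritParams chance_node
#' @return a `tree_node` of kind `"decision"`.
#' @export
decision_node <- function(id, children, label = id) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id), is.list(children))
  structure(list(id = id, kind = "decision", label = label,
                 children = children, payoff = NULL),
            class = "tree_node")
}

#' Construct a tree edge
#'
#' @param node child `tree_node`.
#' @param probability branch probability in `[0, 1]` for chance-node
#'   children, the string `"complement"` for the implicit residual branch,
#'   or `NULL` for decision-node children.
#' @param cost [cost_pair()] accrued when the cohort traverses this edge
#'   (in addition to any terminal payoff downstream).
#' @return a `tree_edge` object.
#' @export
tree_edge <- function(node, probability = NULL, cost = cost_pair()) {
  stopifnot(inherits(node, "tree_node"), is_cost_pair(cost))
  if (!is.null(probability) && !identical(probability, "complement")) {
    stopifnot(is.numeric(probability), length(probability) == 1L)
  }
  structure(list(probability = probability, cost = cost, node = node),
            class = "tree_edge")
}

#' Assemble a decision tree
#'
#' Resolves any `"complement"` branch probabilities, then wraps the root
#' node with an arm name. Complement resolution is purely syntactic; the
#' result is checked later by [validate_tree()].
#'
#' @param root the root `tree_node`.
#' @param arm_name free-text name of the modeled arm.
#' @return an object of class `decision_tree`.
#' @export
decision_tree <- function(root, arm_name = "") {
  stopifnot(inherits(root, "tree_node"))
  structure(list(root = resolve_complements(root), arm_name = arm_name),
            class = "decision_tree")
}

# replace at most one "complement" probability per chance node with
# 1 - sum(siblings); recursive over the whole tree
resolve_complements <- function(node) {
  if (length(node$children) == 0L) return(node)
  node$children <- lapply(node$children, function(e) {
    e$node <- resolve_complements(e$node)
    e
  })
  if (node$kind == "chance") {
    is_comp <- vapply(node$children,
                      function(e) identical(e$probability, "complement"),
                      logical(1))
    if (sum(is_comp) > 1L) {
      stop(sprintf("node '%s': more than one 'complement' branch", node$id),
           call. = FALSE)
    }
    if (any(is_comp)) {
      others <- vapply(node$children[!is_comp], function(e) {
        if (!is.numeric(e$probability)) {
          stop(sprintf("node '%s': sibling of a 'complement' branch lacks a numeric probability",
                       node$id), call. = FALSE)
        }
        e$probability
      }, numeric(1))
      node$children[[which(is_comp)]]$probability <- 1 - sum(others)
    }
  }
  node
}

#' Validate a decision tree
#'
#' Collects every invariant violation rather than stopping at the first:
#' duplicated node ids, terminal nodes with children or without payoffs,
#' decision/chance nodes without children, chance branch probabilities
#' that are missing, negative, above one, or do not sum to 1 (tolerance
#' 1e-9), probabilities attached to decision-node children, and negative
#' or non-finite costs. Structural malformations (an element that is not a
#' node/edge) raise an error naming the offending node.
#'
#' @param tree a `decision_tree`.
#' @return an object of class `validation_report`: a character vector of
#'   violation messages, empty iff the tree is valid.
#' @export
#' @examples
#' good <- decision_tree(chance_node("c", list(
#'   tree_edge(terminal_node("a"), 0.5),
#'   tree_edge(terminal_node("b"), 0.5))))
#' validate_tree(good)          # no violations
validate_tree <- function(tree) {
  stopifnot(inherits(tree, "decision_tree"))
  violations <- character(0)
  seen_ids <- character(0)
  note <- function(msg) violations[[length(violations) + 1L]] <<- msg

  walk <- function(node) {
    if (!inherits(node, "tree_node")) {
      stop("malformed tree: child element is not a tree_node", call. = FALSE)
    }
    if (node$id %in% seen_ids) {
      note(sprintf("node '%s': duplicated node_id", node$id))
    }
    seen_ids <<- c(seen_ids, node$id)

    if (node$kind == "terminal") {
      if (length(node$children) > 0L) {
        note(sprintf("node '%s': terminal node has children", node$id))
      }
      if (is.null(node$payoff)) {
        note(sprintf("node '%s': terminal node lacks a payoff", node$id))
      } else {
        check_cost(node$payoff, node$id, "payoff")
      }
      return(invisible(NULL))
    }

    if (length(node$children) == 0L) {
      note(sprintf("node '%s': %s node has no children (leaf must be terminal)",
                   node$id, node$kind))
      return(invisible(NULL))
    }

    probs <- numeric(0)
    for (e in node$children) {
      if (!inherits(e, "tree_edge")) {
        stop(sprintf("malformed tree at node '%s': child is not a tree_edge",
                     node$id), call. = FALSE)
      }
      if (node$kind == "chance") {
        if (!is.numeric(e$probability)) {
          note(sprintf("node '%s': chance branch to '%s' lacks a numeric probability",
                       node$id, e$node$id))
        } else {
          p <- e$probability
          if (!is.finite(p) || p < 0) {
            note(sprintf("node '%s': negative or non-finite branch probability %g",
                         node$id, p))
          } else if (p > 1) {
            note(sprintf("node '%s': branch probability %g exceeds 1", node$id, p))
          }
          probs <- c(probs, p)
        }
      } else {  # decision
        if (!is.null(e$probability)) {
          note(sprintf("node '%s': decision branch to '%s' carries a probability",
                       node$id, e$node$id))
        }
      }
      check_cost(e$cost, node$id, "edge cost")
      walk(e$node)
    }
    if (node$kind == "chance" && length(probs) == length(node$children)) {
      s <- sum(probs)
      if (abs(s - 1) > PROB_TOL) {
        note(sprintf("node '%s': probabilities sum to %g != 1", node$id, s))
      }
    }
    invisible(NULL)
  }

  check_cost <- function(cp, id, what) {
    if (!is_cost_pair(cp)) {
      stop(sprintf("malformed tree at node '%s': %s is not a cost_pair", id, what),
           call. = FALSE)
    }
    if (!is.finite(cp$mother) || !is.finite(cp$child)) {
      note(sprintf("node '%s': non-finite %s", id, what))
    } else if (cp$mother < 0 || cp$child < 0) {
      note(sprintf("node '%s': negative %s (%g, %g)", id, what,
                   cp$mother, cp$child))
    }
  }

  walk(tree$root)
  structure(violations, class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  if (length(x) == 0L) {
    cat("<validation_report> tree is valid (no violations)\n")
  } else {
    cat(sprintf("<validation_report> %d violation(s):\n", length(x)))
    cat(paste0("  - ", unclass(x), collapse = "\n"), "\n")
  }
  invisible(x)
}

#' Is a validation report clean?
#' @param report a `validation_report`.
#' @return `TRUE` iff no violations were recorded.
#' @export
is_valid <- function(report) length(report) == 0L

# resolve a decision at `node` from the `decisions` mapping (id -> child
# index or child node id); errors if absent
select_arm <- function(node, decisions) {
  sel <- decisions[[node$id]]
  if (is.null(sel)) {
    stop(sprintf("decision node '%s' requires an explicit arm selection (pass `decisions`)",
                 node$id), call. = FALSE)
  }
  if (is.character(sel)) {
    ids <- vapply(node$children, function(e) e$node$id, character(1))
    idx <- match(sel, ids)
    if (is.na(idx)) {
      stop(sprintf("decision node '%s': no child with id '%s'", node$id, sel),
           call. = FALSE)
    }
  } else {
    idx <- as.integer(sel)
    if (idx < 1L || idx > length(node$children)) {
      stop(sprintf("decision node '%s': arm index %d out of range", node$id, idx),
           call. = FALSE)
    }
  }
  idx
}

#' Expected cost of a decision tree by rollback
#'
#' Computes the probability-weighted sum of costs over all root-to-leaf
#' paths by recursive rollback: a terminal returns its payoff, a chance
#' node returns the probability-weighted sum of (edge cost + child value),
#' and a decision node returns the value of the explicitly selected arm.
#'
#' @param tree a `decision_tree`.
#' @param decisions named list mapping decision-node ids to the selected
#'   child (index or child node id); required iff the tree contains
#'   decision nodes.
#' @param validate if `TRUE` (default), refuse trees that fail
#'   [validate_tree()].
#' @return a [cost_pair()] of expected mother and child costs.
#' @export
#' @examples
#' t1 <- decision_tree(terminal_node("only", cost_pair(7790, 0)))
#' expected_value(t1)  # (7790, 0)
expected_value <- function(tree, decisions = NULL, validate = TRUE) {
  stopifnot(inherits(tree, "decision_tree"))
  if (validate) {
    rep <- validate_tree(tree)
    if (!is_valid(rep)) {
      stop(paste0("tree failed validation:\n",
                  paste0("  - ", unclass(rep), collapse = "\n")),
           call. = FALSE)
    }
  }
  roll <- function(node) {
    if (node$kind == "terminal") return(node$payoff)
    if (node$kind == "decision") {
      e <- node$children[[select_arm(node, decisions)]]
      return(cp_add(e$cost, roll(e$node)))
    }
    # chance node
    acc <- cost_pair(0, 0)
    for (e in node$children) {
      acc <- cp_add(acc, cp_scale(cp_add(e$cost, roll(e$node)), e$probability))
    }
    acc
  }
  roll(tree$root)
}

# number of root-to-leaf paths under a decision selection; stops counting
# once `cap` is exceeded so oversized trees are refused without a full walk
count_paths <- function(node, decisions, cap = Inf) {
  if (node$kind == "terminal") return(1)
  if (node$kind == "decision") {
    return(count_paths(node$children[[select_arm(node, decisions)]]$node,
                       decisions, cap))
  }
  total <- 0
  for (e in node$children) {
    total <- total + count_paths(e$node, decisions, cap - total)
    if (total > cap) return(total)
  }
  total
}

#' Enumerate all root-to-leaf paths
#'
#' Exhaustive enumeration of the tree's paths with their joint
#' probabilities and accumulated costs. This is the independent oracle for
#' [expected_value()]: summing `probability * cost` over the returned rows
#' reproduces the rollback value. Refuses trees with more than one million
#' paths.
#'
#' @inheritParams expected_value
#' @return a `data.frame` with one row per path and columns `path`
#'   (node labels joined by `" > "`), `probability`, `mother_cost`,
#'   `child_cost`.
#' @export
enumerate_paths <- function(tree, decisions = NULL, validate = TRUE) {
  stopifnot(inherits(tree, "decision_tree"))
  if (validate) {
    rep <- validate_tree(tree)
    if (!is_valid(rep)) {
      stop(paste0("tree failed validation:\n",
                  paste0("  - ", unclass(rep), collapse = "\n")),
           call. = FALSE)
    }
  }
  n <- count_paths(tree$root, decisions, cap = MAX_ENUM_PATHS)
  if (n > MAX_ENUM_PATHS) {
    stop(sprintf("tree has more than %g root-to-leaf paths; enumeration refused",
                 MAX_ENUM_PATHS), call. = FALSE)
  }
  rows <- vector("list", n)
  k <- 0L
  walk <- function(node, labels, prob, mother, child) {
    labels <- c(labels, node$label)
    if (node$kind == "terminal") {
      k <<- k + 1L
      rows[[k]] <<- list(path = paste(labels, collapse = " > "),
                         probability = prob,
                         mother_cost = mother + node$payoff$mother,
                         child_cost = child + node$payoff$child)
      return(invisible(NULL))
    }
    if (node$kind == "decision") {
      e <- node$children[[select_arm(node, decisions)]]
      walk(e$node, labels, prob,
           mother + e$cost$mother, child + e$cost$child)
      return(invisible(NULL))
    }
    for (e in node$children) {
      walk(e$node, labels, prob * e$probability,
           mother + e$cost$mother, child + e$cost$child)
    }
    invisible(NULL)
  }
  walk(tree$root, character(0), 1, 0, 0)
  data.frame(path = vapply(rows, `[[`, character(1), "path"),
             probability = vapply(rows, `[[`, numeric(1), "probability"),
             mother_cost = vapply(rows, `[[`, numeric(1), "mother_cost"),
             child_cost = vapply(rows, `[[`, numeric(1), "child_cost"),
             stringsAsFactors = FALSE)
}

#' Generate a random valid chance tree
#'
#' Deterministic fixture generator used for oracle testing: given a seed it
#' produces a tree of chance and terminal nodes whose branch probabilities
#' are drawn uniformly and normalized to sum to one, and whose edge costs
#' and terminal payoffs are drawn non-negative. The caller's RNG state is
#' left untouched. Decision nodes are never generated, so every generated
#' tree is evaluable without an arm selection.
#'
#' @param seed integer seed; the same seed always yields the same tree.
#' @param max_depth maximum depth of chance nodes (>= 1).
#' @param max_branching maximum children per chance node (>= 2).
#' @return a valid `decision_tree`.
#' @export
random_tree <- function(seed, max_depth = 3, max_branching = 3) {
  stopifnot(max_depth >= 1, max_branching >= 2)
  with_private_seed(seed, {
    counter <- 0L
    next_id <- function(prefix) {
      counter <<- counter + 1L
      sprintf("%s%d", prefix, counter)
    }
    build <- function(depth) {
      if (depth > max_depth || (depth > 1 && stats::runif(1) < 0.3)) {
        return(terminal_node(next_id("t"),
                             cost_pair(stats::runif(1, 0, 1000),
                                       stats::runif(1, 0, 1000))))
      }
      k <- sample(2:max_branching, 1L)
      raw <- stats::runif(k)
      probs <- raw / sum(raw)
      children <- lapply(seq_len(k), function(i) {
        tree_edge(build(depth + 1L), probs[[i]],
                  cost_pair(stats::runif(1, 0, 500), stats::runif(1, 0, 500)))
      })
      chance_node(next_id("c"), children)
    }
    decision_tree(build(1L), arm_name = sprintf("random_seed_%d", seed))
  })
}

TREE_SCHEMA_VERSION <- 1L

node_to_list <- function(node) {
  out <- list(id = node$id, kind = node$kind, label = node$label)
  if (node$kind == "terminal") {
    out$payoff <- list(mother = node$payoff$mother, child = node$payoff$child)
  } else {
    out$children <- lapply(node$children, function(e) {
      list(p = if (is.null(e$probability)) NULL else e$probability,
           cost_mother = e$cost$mother,
           cost_child = e$cost$child,
           node = node_to_list(e$node))
    })
  }
  out
}

node_from_list <- function(x) {
  if (is.null(x$kind)) stop("tree document: node without 'kind'", call. = FALSE)
  id <- x$id %||% stop("tree document: node without 'id'", call. = FALSE)
  label <- x$label %||% id
  if (x$kind == "terminal") {
    pay <- x$payoff %||% list(mother = 0, child = 0)
    return(terminal_node(id, cost_pair(pay$mother %||% 0, pay$child %||% 0),
                         label = label))
  }
  children <- lapply(x$children, function(c) {
    tree_edge(node_from_list(c$node),
              probability = c$p,
              cost = cost_pair(c$cost_mother %||% 0, c$cost_child %||% 0))
  })
  if (x$kind == "chance") chance_node(id, children, label = label)
  else if (x$kind == "decision") decision_node(id, children, label = label)
  else stop(sprintf("tree document: unknown node kind '%s'", x$kind),
            call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Serialize a decision tree to a structured-text file
#'
#' The on-disk schema (version 1) is a nested document: each node object
#' carries `id`, `kind`, `label`, and either `payoff`
#' (`{mother, child}`) for terminals or `children`, a list of
#' `{p, cost_mother, cost_child, node}` objects where `p` may be the
#' string `"complement"` for the implicit residual branch. Format is
#' chosen by file extension: `.json` or `.yaml`/`.yml`.
#'
#' @param tree a `decision_tree`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_tree <- function(tree, path) {
  stopifnot(inherits(tree, "decision_tree"))
  doc <- list(schema_version = TREE_SCHEMA_VERSION,
              arm_name = tree$arm_name,
              root = node_to_list(tree$root))
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(doc, path, precision = 15L)
  } else {
    stop(sprintf("unsupported tree file extension '%s' (use json or yaml)", ext),
         call. = FALSE)
  }
  invisible(path)
}

#' Read a decision tree from a structured-text file
#'
#' @param path file written by [write_tree()] or hand-authored in the same
#'   schema.
#' @return a `decision_tree` (with `"complement"` branches resolved).
#' @export
read_tree <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("tree file not found: %s", path), call. = FALSE)
  }
  ext <- tolower(tools::file_ext(path))
  doc <- if (ext == "json") {
    jsonlite::read_json(path)
  } else if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else {
    stop(sprintf("unsupported tree file extension '%s' (use json or yaml)", ext),
         call. = FALSE)
  }
  sv <- doc$schema_version %||% NA
  if (!identical(as.integer(sv), TREE_SCHEMA_VERSION)) {
    stop(sprintf("unsupported tree schema_version '%s' (expected %d)",
                 sv, TREE_SCHEMA_VERSION), call. = FALSE)
  }
  decision_tree(node_from_list(doc$root), arm_name = doc$arm_name %||% "")
}

#' @export
print.decision_tree <- function(x, ...) {
  n_nodes <- local({
    count <- function(node) 1L + sum(vapply(node$children, function(e)
      count(e$node), integer(1)))
    count(x$root)
  })
  cat(sprintf("<decision_tree> arm: '%s', %d nodes\n", x$arm_name, n_nodes))
  invisible(x)
}
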