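# Independent brute-force oracle for SNAP grouping: repeatedly split
# groups that violate the pairwise-edge condition (some members of group A
# have an edge of a given kind/direction into group B, others do not),
# starting from the attribute-based partition. This is the group-pair
# formulation; the implementation under test refines per-node neighborhood
# signatures instead.
snap_bruteforce <- function(g, group_attributes = character(),
                            use_parameters = FALSE) {
  n <- igraph::vcount(g)
  key <- provtrace:::node_group_key(g, group_attributes, use_parameters)
  groups <- split(seq_len(n), match(key, unique(key)))
  el <- igraph::as_data_frame(g, what = "edges")
  vn <- igraph::V(g)$name
  from_i <- match(el$from, vn)
  to_i <- match(el$to, vn)
  kind <- ifelse(el$membership, "member", "flow")

  has_edge_to <- function(i, target_group, k, direction) {
    if (direction == "out") {
      any(from_i == i & kind == k & to_i %in% target_group)
    } else {
      any(to_i == i & kind == k & from_i %in% target_group)
    }
  }

  repeat {
    changed <- FALSE
    for (a in seq_along(groups)) {
      A <- groups[[a]]
      if (length(A) < 2L) next
      for (b in seq_along(groups)) {
        B <- groups[[b]]
        for (k in unique(kind)) {
          for (dir in c("out", "in")) {
            flags <- vapply(A, has_edge_to, logical(1),
                            target_group = B, k = k, direction = dir)
            if (any(flags) && !all(flags)) {
              groups[[a]] <- A[flags]
              groups[[length(groups) + 1L]] <- A[!flags]
              changed <- TRUE
              break
            }
          }
          if (changed) break
        }
        if (changed) break
      }
      if (changed) break
    }
    if (!changed) break
  }
  # canonical representation: sorted member-name sets
  unname(sort(vapply(groups, function(idx) {
    paste(sort(vn[idx], method = "radix"), collapse = ";")
  }, character(1)), method = "radix"))
}

# Random toy property graph with the node attributes the aggregator keys on.
random_toy_graph <- function(n, seed) {
  set.seed(seed)
  labels <- sample(c("stepA", "stepB", "data"), n, replace = TRUE)
  vdf <- data.frame(
    name = paste0("n", seq_len(n)),
    type = ifelse(labels == "data", "object", "function"),
    label = labels,
    Python_name = paste0("toy.", labels),
    param_key = sample(c("", "k=1", "k=2"), n, replace = TRUE),
    grp_attr = sample(c("red", "blue"), n, replace = TRUE),
    `Time Interval` = "<[1,1]>",
    stringsAsFactors = FALSE, check.names = FALSE)
  m <- max(1L, round(n * 1.3))
  edf <- unique(data.frame(
    from = paste0("n", sample(n, m, replace = TRUE)),
    to = paste0("n", sample(n, m, replace = TRUE)),
    membership = sample(c(TRUE, FALSE), m, replace = TRUE, prob = c(.2, .8)),
    label = "",
    stringsAsFactors = FALSE))
  edf <- edf[edf$from != edf$to, , drop = FALSE]
  igraph::graph_from_data_frame(edf, directed = TRUE, vertices = vdf)
}

aggregate_members <- function(ag) {
  sort(igraph::V(ag)$members, method = "radix")
}
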