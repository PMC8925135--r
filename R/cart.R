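# Class-weighted CART over binary recurrence indicators.
#
# Greedy recursive binary partitioning minimizing weighted Gini impurity.
# The three operating points (high sensitivity, high overall accuracy, high
# PPV) come from one mechanism: a weight w on recurrent-class observations
# applied both in the Gini proportions and in leaf majority voting. Boolean
# features admit no score threshold to shift, so asymmetric observation
# weights are the natural way to trade sensitivity against PPV.

#' Tree induction configuration and operating-point presets
#'
#' @param max_depth maximum tree depth (root split = depth 1).
#' @param min_leaf minimum (unweighted) observations in each child of a
#'   split.
#' @param fn_cost_weight weight `w > 0` on recurrent-class observations;
#'   `w > 1` penalizes missed recurrences (raising sensitivity), `w < 1`
#'   penalizes false flags (raising PPV).
#' @param operating_points named `w` presets; defaults
#'   `high_sensitivity = 4`, `high_accuracy = 1`, `high_ppv = 0.5`.
#' @return a `tree_config` list.
#' @export
tree_config <- function(max_depth = 5, min_leaf = 10, fn_cost_weight = 1,
                        operating_points = c(high_sensitivity = 4,
                                             high_accuracy = 1,
                                             high_ppv = 0.5)) {
  stopifnot(max_depth >= 1, min_leaf >= 1, fn_cost_weight > 0,
            all(operating_points > 0))
  structure(list(max_depth = as.integer(max_depth),
                 min_leaf = as.integer(min_leaf),
                 fn_cost_weight = fn_cost_weight,
                 operating_points = operating_points),
            class = "tree_config")
}

#' Gini impurity of weighted two-class counts
#'
#' `1 - sum(p_k^2)` with `p_k` the weighted class proportions; 0 for a pure
#' node, 0.5 at a balanced binary node.
#'
#' @param weighted_counts numeric vector of per-class weighted counts
#'   (two classes here, but any length works).
#' @return impurity in `[0, 0.5]` for two classes.
#' @export
gini_impurity <- function(weighted_counts) {
  if (any(weighted_counts < 0)) stop("counts must be non-negative", call. = FALSE)
  tot <- sum(weighted_counts)
  if (tot <= 0) stop("gini_impurity undefined for zero total count", call. = FALSE)
  p <- weighted_counts / tot
  1 - sum(p^2)
}

#' Gini gain of splitting on one boolean column
#'
#' Parent impurity minus the weighted average of child impurities, all in
#' the given observation weights. Zero for a constant column; never
#' negative.
#'
#' @param column logical split feature.
#' @param labels logical outcome (`TRUE` = recurrent).
#' @param weights per-observation weights.
#' @return the impurity decrease.
#' @export
split_gain <- function(column, labels, weights = rep(1, length(labels))) {
  if (length(column) != length(labels) || length(labels) != length(weights))
    stop("column, labels and weights must have equal length", call. = FALSE)
  wc <- function(idx) c(sum(weights[idx & labels]), sum(weights[idx & !labels]))
  all_idx <- rep(TRUE, length(labels))
  tot <- sum(weights)
  w_yes <- sum(weights[column]); w_no <- tot - w_yes
  if (w_yes == 0 || w_no == 0) return(0)
  gain <- gini_impurity(wc(all_idx)) -
    (w_yes / tot) * gini_impurity(wc(column)) -
    (w_no / tot) * gini_impurity(wc(!column))
  max(gain, 0)
}

leaf_node <- function(labels, weights) {
  w_rec <- sum(weights[labels]); w_non <- sum(weights[!labels])
  # exact tie goes to recurrent (favors sensitivity)
  list(leaf = TRUE, label = if (w_rec >= w_non) "recurrent" else "non_recurrent",
       n = length(labels), n_recurrent = sum(labels))
}

grow_node <- function(m, labels, weights, depth, cfg, used) {
  w_rec <- sum(weights[labels]); w_non <- sum(weights[!labels])
  if (depth > cfg$max_depth || w_rec == 0 || w_non == 0)
    return(leaf_node(labels, weights))
  candidates <- setdiff(colnames(m), used)
  best <- NULL; best_gain <- 0
  for (cn in candidates) {       # column order breaks exact gain ties
    col <- m[, cn]
    if (sum(col) < cfg$min_leaf || sum(!col) < cfg$min_leaf) next
    g <- split_gain(col, labels, weights)
    if (g > best_gain + 1e-12) { best_gain <- g; best <- cn }
  }
  if (is.null(best)) return(leaf_node(labels, weights))
  col <- m[, best]
  list(leaf = FALSE, indicator = best,
       yes = grow_node(m[col, , drop = FALSE], labels[col], weights[col],
                       depth + 1L, cfg, c(used, best)),
       no = grow_node(m[!col, , drop = FALSE], labels[!col], weights[!col],
                      depth + 1L, cfg, c(used, best)))
}

#' Fit a Gini decision tree over the indicator matrix
#'
#' Greedy recursive partitioning: each node splits on the indicator with
#' maximal [split_gain()] (ties and near-ties resolved toward the earlier
#' column in the documented indicator order), stopping at `max_depth`, at a
#' weighted-pure node, when no admissible split improves impurity, or when
#' a split would leave a child below `min_leaf` observations. Leaves take
#' the weighted-majority label, with exact ties labelled recurrent. Each
#' root-to-leaf path tests an indicator at most once.
#'
#' @param indicator_matrix logical matrix (patients x indicators) from
#'   [build_indicator_matrix()].
#' @param labels logical vector, `TRUE` for gold-recurrent patients.
#' @param config a [tree_config()]; `fn_cost_weight` sets the operating
#'   point.
#' @return a `recurrence_tree`.
#' @export
fit_tree <- function(indicator_matrix, labels, config = tree_config()) {
  if (is.null(dim(indicator_matrix)) || nrow(indicator_matrix) == 0)
    stop("indicator_matrix must have at least one row", call. = FALSE)
  stopifnot(is.logical(indicator_matrix), nrow(indicator_matrix) == length(labels))
  weights <- ifelse(labels, config$fn_cost_weight, 1)
  root <- grow_node(indicator_matrix, labels, weights, 1L, config, character())
  structure(list(root = root, config = config,
                 indicators = colnames(indicator_matrix)),
            class = "recurrence_tree")
}

#' Predict one patient's recurrence status from a fitted tree
#'
#' Follows the path given by the patient's indicator presence/absence.
#' When the leaf is recurrent, the triggering indicator — the one the
#' patient "met" — is the last indicator on the path answered present;
#' non-recurrent leaves carry no trigger.
#'
#' @param object a `recurrence_tree`.
#' @param indicator_vector named logical vector (or an `indicator_vector`
#'   from [extract_indicators()]) covering every indicator the tree tests.
#' @param ... unused.
#' @return `list(label, triggering_indicator)` with
#'   `triggering_indicator = NA` for non-recurrent calls.
#' @export
predict.recurrence_tree <- function(object, indicator_vector, ...) {
  present <- as_presence(indicator_vector)
  tested <- collect_indicators(object$root)
  absent <- tested[!tested %in% names(present) | is.na(present[tested])]
  if (length(absent))
    stop(sprintf("indicator_vector is missing tested indicator '%s'",
                 absent[1]), call. = FALSE)
  node <- object$root
  last_met <- NA_character_
  while (!node$leaf) {
    if (present[[node$indicator]]) {
      last_met <- node$indicator
      node <- node$yes
    } else {
      node <- node$no
    }
  }
  if (node$label == "recurrent")
    list(label = "recurrent", triggering_indicator = last_met)
  else list(label = "non_recurrent", triggering_indicator = NA_character_)
}

as_presence <- function(x) {
  if (inherits(x, "indicator_vector")) {
    fields <- setdiff(names(x), c("patient_id", "landmark_date"))
    vapply(x[fields], function(e) e$present, logical(1))
  } else if (is.logical(x) && !is.null(names(x))) x
  else stop("indicator_vector must be a named logical vector or indicator_vector",
            call. = FALSE)
}

#' Fit the three operating-point trees
#'
#' One tree per preset weight in `config$operating_points`
#' (high-sensitivity, high-accuracy, high-PPV by default).
#'
#' @inheritParams fit_tree
#' @return named list of `recurrence_tree`s keyed by operating point.
#' @export
fit_operating_points <- function(indicator_matrix, labels,
                                 config = tree_config()) {
  out <- lapply(config$operating_points, function(w) {
    cfg <- config; cfg$fn_cost_weight <- w
    fit_tree(indicator_matrix, labels, cfg)
  })
  names(out) <- names(config$operating_points)
  out
}

# ---- text serialization -------------------------------------------------

format_node <- function(node, indent) {
  pad <- strrep("  ", indent)
  if (node$leaf) return(sprintf("%s[%s]", pad, node$label))
  c(sprintf("%s%s?", pad, node$indicator),
    sprintf("%syes:", strrep("  ", indent + 1)),
    format_node(node$yes, indent + 2),
    sprintf("%sno:", strrep("  ", indent + 1)),
    format_node(node$no, indent + 2))
}

#' @export
print.recurrence_tree <- function(x, ...) {
  cat(format_node(x$root, 0), sep = "\n")
  invisible(x)
}

#' Write a fitted tree to an indented text file
#' @param tree a `recurrence_tree`.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_tree <- function(tree, path) {
  writeLines(format_node(tree$root, 0), path)
  invisible(path)
}

parse_node <- function(lines, pos) {
  line <- trimws(lines[pos])
  if (grepl("^\\[", line)) {
    label <- sub("^\\[(.*)\\]$", "\\1", line)
    if (!label %in% c("recurrent", "non_recurrent"))
      stop(sprintf("bad leaf label '%s' at line %d", label, pos), call. = FALSE)
    return(list(node = list(leaf = TRUE, label = label), pos = pos + 1L))
  }
  if (!grepl("\\?$", line))
    stop(sprintf("expected 'indicator?' or '[label]' at line %d", pos), call. = FALSE)
  ind <- sub("\\?$", "", line)
  if (trimws(lines[pos + 1L]) != "yes:")
    stop(sprintf("expected 'yes:' at line %d", pos + 1L), call. = FALSE)
  yes <- parse_node(lines, pos + 2L)
  if (trimws(lines[yes$pos]) != "no:")
    stop(sprintf("expected 'no:' at line %d", yes$pos), call. = FALSE)
  no <- parse_node(lines, yes$pos + 1L)
  list(node = list(leaf = FALSE, indicator = ind, yes = yes$node, no = no$node),
       pos = no$pos)
}

collect_indicators <- function(node) {
  if (node$leaf) return(character())
  unique(c(node$indicator, collect_indicators(node$yes),
           collect_indicators(node$no)))
}

#' Read a tree from its text serialization
#' @param path file written by [write_tree()].
#' @return a `recurrence_tree`.
#' @export
read_tree <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parsed <- parse_node(lines, 1L)
  if (parsed$pos != length(lines) + 1L)
    stop("trailing content after tree definition", call. = FALSE)
  structure(list(root = parsed$node, config = NULL,
                 indicators = collect_indicators(parsed$node)),
            class = "recurrence_tree")
}
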