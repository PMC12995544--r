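#' Within-pair outcome differences for exactly matched pairs
#'
#' For every pair exactly matched on all potential effect modifiers, computes
#' the treated-minus-control outcome difference `Y_i` and its absolute value.
#' Inexactly matched pairs are excluded and counted (they can be recovered by
#' [rematch_inexact()] after the tree selects a smaller covariate set).
#'
#' @param sample A pair-matched `matched_sample`.
#' @param table The underlying `obs_table`.
#' @param pem_keys Covariate names treated as potential effect modifiers.
#' @return Data frame with columns `set`, `y`, `absy` and one column per
#'   modifier (the pair's shared value); attribute `n_excluded`.
#' @export
pair_differences <- function(sample, table, pem_keys) {
  sets <- ms_sets(sample)
  if (any(vapply(sets, function(s) length(s$controls), numeric(1)) != 1))
    stop("pair_differences requires a pair matching")
  stopifnot(all(pem_keys %in% names(table$x)))
  tu <- vapply(sets, function(s) s$treated, numeric(1))
  cu <- vapply(sets, function(s) s$controls, numeric(1))
  exact <- rep(TRUE, length(sets))
  for (key in pem_keys) {
    v <- as.character(table$x[[key]])
    exact <- exact & v[tu] == v[cu]
  }
  if (!any(exact))
    stop("no pairs exactly matched on the potential effect modifiers")
  rows <- which(exact)
  y <- table$y[tu[rows]] - table$y[cu[rows]]
  out <- data.frame(set = rows, y = y, absy = abs(y))
  for (key in pem_keys)
    out[[key]] <- table$x[[key]][tu[rows]]
  attr(out, "n_excluded") <- sum(!exact)
  out
}

#' Fit a regression tree to absolute pair differences
#'
#' Least-squares recursive partitioning of `|Y_i|` on the potential effect
#' modifiers, with cost-complexity pruning (no cross-validation, so the fit is
#' deterministic for fixed inputs). Because the tree sees only the absolute
#' differences, subsequent subgroup inference on the signed differences
#' remains valid.
#'
#' @param records Output of [pair_differences()].
#' @param minsplit,minbucket,cp,maxdepth Tree controls (conventional
#'   recursive-partitioning defaults).
#' @return An `hte_tree`: the fitted `rpart` object plus `vars` (distinct
#'   splitting covariates), `split_points` (variable, threshold), `n_leaves`,
#'   and `leaves` (node numbers).
#' @export
fit_tree <- function(records, minsplit = 20, minbucket = 7, cp = 0.01,
                     maxdepth = 30) {
  pem <- setdiff(names(records), c("set", "y", "absy"))
  dat <- records[, c("absy", pem), drop = FALSE]
  fit <- rpart::rpart(absy ~ ., data = dat, method = "anova",
                      control = rpart::rpart.control(
                        minsplit = minsplit, minbucket = minbucket, cp = cp,
                        maxdepth = maxdepth, xval = 0))
  frame <- fit$frame
  is_leaf <- frame$var == "<leaf>"
  vars <- unique(as.character(frame$var[!is_leaf]))
  sp <- NULL
  if (length(vars) > 0) {
    prim <- primary_splits(fit)
    sp <- unique(data.frame(var = prim$var,
                            point = ifelse(prim$ncat %in% c(-1, 1),
                                           prim$index, NA)))
  }
  structure(list(fit = fit, vars = vars, split_points = sp,
                 n_leaves = sum(is_leaf),
                 leaves = as.integer(rownames(frame))[is_leaf],
                 pem = pem),
            class = "hte_tree")
}

#' @export
print.hte_tree <- function(x, ...) {
  cat("hte_tree:", x$n_leaves, "leaves; splitting on",
      if (length(x$vars)) paste(x$vars, collapse = ", ") else "(nothing)",
      "\n")
  invisible(x)
}

# Extract the primary split of each non-leaf node of an rpart fit, in frame
# order: node number, variable, ncat, index (threshold or csplit row).
primary_splits <- function(fit) {
  frame <- fit$frame
  nonleaf <- which(frame$var != "<leaf>")
  if (length(nonleaf) == 0)
    return(data.frame(node = integer(0), var = character(0),
                      ncat = numeric(0), index = numeric(0)))
  ptr <- 1L
  out <- vector("list", length(nonleaf))
  k <- 0L
  for (r in seq_len(nrow(frame))) {
    if (frame$var[r] == "<leaf>") next
    k <- k + 1L
    out[[k]] <- data.frame(node = as.integer(rownames(frame))[r],
                           var = as.character(frame$var[r]),
                           ncat = fit$splits[ptr, "ncat"],
                           index = fit$splits[ptr, "index"])
    ptr <- ptr + 1L + frame$ncompete[r] + frame$nsurrogate[r]
  }
  do.call(rbind, out)
}

#' Route observations through a fitted tree
#'
#' @param tree An `hte_tree`.
#' @param newdata Data frame containing the tree's modifier columns.
#' @return Integer vector of leaf node numbers.
#' @export
route_tree <- function(tree, newdata) {
  frame <- tree$fit$frame
  nodes <- as.integer(rownames(frame))
  prim <- primary_splits(tree$fit)
  csplit <- tree$fit$csplit
  xlev <- attr(tree$fit, "xlevels")
  vapply(seq_len(nrow(newdata)), function(r) {
    node <- 1L
    repeat {
      fr <- match(node, nodes)
      if (frame$var[fr] == "<leaf>") return(node)
      sp <- prim[prim$node == node, ]
      x <- newdata[[sp$var]][r]
      if (is.na(x) || (!is.null(xlev[[sp$var]]) &&
                       !as.character(x) %in% xlev[[sp$var]]))
        stop("cannot route row ", r, ": unseen or missing value for '",
             sp$var, "'")
      go_left <- if (sp$ncat == -1) {
        as.numeric(x) < sp$index
      } else if (sp$ncat == 1) {
        as.numeric(x) >= sp$index
      } else {
        lev <- match(as.character(x), xlev[[sp$var]])
        csplit[sp$index, lev] == 1L
      }
      node <- if (go_left) 2L * node else 2L * node + 1L
    }
  }, integer(1))
}

new_partition <- function(group, labels) {
  stopifnot(all(group >= 1), all(group <= length(labels)))
  sizes <- tabulate(group, nbins = length(labels))
  if (any(sizes == 0)) stop("empty subgroup in partition")
  structure(list(group = group, labels = labels, G = length(labels),
                 sizes = sizes),
            class = "subgroup_partition")
}

#' @export
print.subgroup_partition <- function(x, ...) {
  cat("subgroup_partition: G =", x$G, "groups;",
      paste0(x$labels, " (", x$sizes, ")", collapse = ", "), "\n")
  invisible(x)
}

#' Partition matched sets by the leaves of a fitted tree
#'
#' Each matched set is routed through the tree using its (shared) modifier
#' values; the leaves define mutually exclusive, exhaustive subgroups.
#'
#' @param sample A `matched_sample`.
#' @param table The underlying `obs_table`.
#' @param tree An `hte_tree`.
#' @return A `subgroup_partition` (group per set, leaf labels).
#' @export
partition_from_tree <- function(sample, table, tree) {
  sets <- ms_sets(sample)
  tu <- vapply(sets, function(s) s$treated, numeric(1))
  newdata <- table$x[tu, tree$pem, drop = FALSE]
  leaf <- tryCatch(route_tree(tree, newdata), error = function(e)
    stop("failed to route matched sets through the tree: ",
         conditionMessage(e)))
  labels <- paste0("leaf", tree$leaves)
  new_partition(match(leaf, tree$leaves), labels)
}

#' Partition matched sets by combinations of binary modifiers
#'
#' One group per observed combination of the binary modifiers (so `G <= 2^L`;
#' absent combinations are noted). With no modifiers there is a single group.
#'
#' @param sample A `matched_sample`.
#' @param table The underlying `obs_table`.
#' @param modifier_keys Covariate names, each binary per set.
#' @return A `subgroup_partition`.
#' @export
partition_from_modifiers <- function(sample, table, modifier_keys) {
  sets <- ms_sets(sample)
  I <- length(sets)
  if (length(modifier_keys) == 0)
    return(new_partition(rep(1L, I), "all"))
  vals <- lapply(modifier_keys, function(key) {
    v <- as.character(table$x[[key]])
    if (length(unique(v)) > 2)
      stop("modifier '", key, "' is not binary; dichotomize it first")
    tu <- vapply(sets, function(s) s$treated, numeric(1))
    v[tu]
  })
  combo <- do.call(paste, c(Map(function(k, v) paste0(k, "=", v),
                                modifier_keys, vals), sep = ","))
  labels <- sort(unique(combo))
  if (length(labels) < 2^length(modifier_keys))
    message("only ", length(labels), " of ", 2^length(modifier_keys),
            " modifier combinations are present")
  new_partition(match(combo, labels), labels)
}

#' Serialize a fitted tree to a JSON string
#'
#' @param tree An `hte_tree`.
#' @return A JSON string describing splits, leaves and per-leaf means.
#' @export
tree_to_json <- function(tree) {
  frame <- tree$fit$frame
  is_leaf <- frame$var == "<leaf>"
  jsonlite::toJSON(list(
    splits = if (length(tree$vars)) primary_splits(tree$fit) else list(),
    leaves = data.frame(node = as.integer(rownames(frame))[is_leaf],
                        n = frame$n[is_leaf],
                        mean_absy = frame$yval[is_leaf])),
    auto_unbox = TRUE, digits = NA)
}
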