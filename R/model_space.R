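# Enumeration of binary directed-graph model specifications and the
# plausibility rules that prune them to a biologically credible set.

#' Enumerate every binary model specification for n nodes
#'
#' All 2^(n^2) binary n x n adjacency matrices, in lexicographic order of
#' the flattened (column-major) adjacency. Entry [i, j] = 1 means the
#' directed influence of node j on node i is present.
#'
#' @param n number of nodes (1..5; the count grows as 2^(n^2)).
#' @param labels optional node labels; laterality is parsed from a leading
#'   "l"/"r" prefix or a "left_"/"right_" prefix (anything else: midline).
#' @return object of class \code{model_space}: list with \code{n_nodes},
#'   \code{labels}, \code{models} (list of binary matrices).
#' @export
enumerate_full <- function(n, labels = NULL) {
  stopifnot(n >= 1, n <= 5)
  if (is.null(labels)) labels <- paste0("node", seq_len(n))
  stopifnot(length(labels) == n)
  n2 <- n * n
  count <- 2^n2
  bits <- as.matrix(expand.grid(rep(list(0:1), n2), KEEP.OUT.ATTRS = FALSE))
  # expand.grid varies the first factor fastest; reorder to lexicographic
  # order of the flattened adjacency (last entry fastest)
  ord <- do.call(order, as.data.frame(bits))
  bits <- bits[ord, , drop = FALSE]
  models <- lapply(seq_len(count), function(k) {
    matrix(as.integer(bits[k, ]), n, n)
  })
  structure(list(n_nodes = n, labels = labels, models = models),
            class = "model_space")
}

#' @export
print.model_space <- function(x, ...) {
  cat(sprintf("<model_space> %d models over %d nodes (%s)\n",
              length(x$models), x$n_nodes, paste(x$labels, collapse = ", ")))
  invisible(x)
}

#' Plausibility rules for pruning a model space
#'
#' @param require_self every node must carry its self-connection
#'   (diagonal all 1).
#' @param require_connected no node may be isolated, i.e. without any
#'   off-diagonal link in either direction ("completely disconnected from
#'   every other network"). Stronger graph-theoretic readings are available
#'   via \code{connectivity}.
#' @param connectivity one of "isolated_node" (default), "weak", "strong":
#'   how \code{require_connected} is interpreted (weak/strong connectivity
#'   of the off-diagonal digraph).
#' @param sagittal_symmetry adjacency must be invariant under swapping every
#'   left node with its right homologue.
#' @param bilateral_homotopic_only list of node-label pairs whose mutual
#'   links must be bidirectional or absent (no unilateral connection).
#' @param required_links list of unordered label pairs that must have at
#'   least one directed edge between them.
#' @param forbidden_links list of unordered label pairs that may have no
#'   direct edge in either direction.
#' @return object of class \code{plausibility_rules}.
#' @export
plausibility_rules <- function(require_self = TRUE, require_connected = TRUE,
                               connectivity = c("isolated_node", "weak", "strong"),
                               sagittal_symmetry = FALSE,
                               bilateral_homotopic_only = list(),
                               required_links = list(),
                               forbidden_links = list()) {
  structure(list(require_self = require_self,
                 require_connected = require_connected,
                 connectivity = match.arg(connectivity),
                 sagittal_symmetry = sagittal_symmetry,
                 bilateral_homotopic_only = bilateral_homotopic_only,
                 required_links = required_links,
                 forbidden_links = forbidden_links),
            class = "plausibility_rules")
}

# left<->right homologue permutation from labels; nodes pair if their names
# match after swapping a leading l/r (or left_/right_) prefix.
laterality_map <- function(labels) {
  strip <- function(x) sub("^(left_|right_|l(?=[A-Z])|r(?=[A-Z]))", "", x, perl = TRUE)
  side <- ifelse(grepl("^(left_|l(?=[A-Z]))", labels, perl = TRUE), "L",
                 ifelse(grepl("^(right_|r(?=[A-Z]))", labels, perl = TRUE), "R", "M"))
  base <- strip(labels)
  perm <- seq_along(labels)
  for (k in seq_along(labels)) {
    if (side[k] == "M") next
    mate <- which(base == base[k] & side == setdiff(c("L", "R"), side[k]))
    if (length(mate) == 1) perm[k] <- mate
  }
  perm
}

label_pair_index <- function(pair, labels) {
  idx <- match(pair, labels)
  if (anyNA(idx)) stop("unknown node label in rule: ", paste(pair, collapse = ", "))
  idx
}

rule_satisfied <- function(adj, rules, labels, perm) {
  n <- nrow(adj)
  off <- adj
  diag(off) <- 0
  if (rules$require_self && any(diag(adj) == 0)) return(FALSE)
  if (rules$require_connected && n > 1) {
    ok <- switch(rules$connectivity,
      isolated_node = all(rowSums(off) + colSums(off) > 0),
      weak = {
        U <- (off + t(off)) > 0
        reach <- reachable_from(U, 1)
        all(reach)
      },
      strong = {
        fwd <- reachable_from(off > 0, 1)
        bwd <- reachable_from(t(off) > 0, 1)
        all(fwd) && all(bwd)
      })
    if (!ok) return(FALSE)
  }
  if (rules$sagittal_symmetry) {
    if (!identical(adj[perm, perm, drop = FALSE], adj)) return(FALSE)
  }
  for (pair in rules$bilateral_homotopic_only) {
    ij <- label_pair_index(pair, labels)
    if (adj[ij[1], ij[2]] != adj[ij[2], ij[1]]) return(FALSE)
  }
  for (pair in rules$required_links) {
    ij <- label_pair_index(pair, labels)
    if (adj[ij[1], ij[2]] == 0 && adj[ij[2], ij[1]] == 0) return(FALSE)
  }
  for (pair in rules$forbidden_links) {
    ij <- label_pair_index(pair, labels)
    if (adj[ij[1], ij[2]] != 0 || adj[ij[2], ij[1]] != 0) return(FALSE)
  }
  TRUE
}

reachable_from <- function(adj_logical, start) {
  n <- nrow(adj_logical)
  reach <- rep(FALSE, n)
  frontier <- start
  reach[start] <- TRUE
  while (length(frontier)) {
    nxt <- which(apply(adj_logical[frontier, , drop = FALSE], 2, any))
    nxt <- nxt[!reach[nxt]]
    reach[nxt] <- TRUE
    frontier <- nxt
  }
  reach
}

#' Prune a model space by plausibility rules
#'
#' Keeps exactly the members satisfying every enabled rule; the output
#' preserves the deterministic lexicographic order of [enumerate_full()].
#' Filtering is idempotent.
#'
#' @param space a [enumerate_full()] result.
#' @param rules a [plausibility_rules()] object.
#' @return a pruned \code{model_space}; a warning (and an empty space) if
#'   nothing survives.
#' @export
apply_rules <- function(space, rules) {
  stopifnot(inherits(space, "model_space"), inherits(rules, "plausibility_rules"))
  perm <- laterality_map(space$labels)
  keep <- vapply(space$models, rule_satisfied, logical(1),
                 rules = rules, labels = space$labels, perm = perm)
  if (!any(keep)) warning("no model satisfies the rules; returning an empty space")
  structure(list(n_nodes = space$n_nodes, labels = space$labels,
                 models = space$models[keep]),
            class = "model_space")
}

#' Translate a model specification into a prior specification
#'
#' Couplings absent from the adjacency are switched off (zero mean, zero
#' variance: they are simply not free parameters); all present parameters
#' inherit the supplied defaults.
#'
#' @param model binary adjacency matrix (a member of a \code{model_space}).
#' @param defaults a [default_priors()] object built on the full adjacency
#'   (or NULL to use package defaults).
#' @param overrides passed through to [default_priors()].
#' @return a \code{prior_spec} whose adjacency is \code{model}.
#' @export
to_prior <- function(model, defaults = NULL, overrides = NULL) {
  model <- as.matrix(model)
  n <- nrow(model)
  adj <- model
  diag(adj) <- 1   # self-connections always present
  pr <- default_priors(n, adj, overrides)
  if (!is.null(defaults)) {
    stopifnot(inherits(defaults, "prior_spec"))
    common <- intersect(names(pr$mean), names(defaults$mean))
    pr$mean[common] <- defaults$mean[common]
    pr$var[common] <- defaults$var[common]
  }
  pr
}

#' Serialize / deserialize a model space as JSON
#'
#' Models are stored as lists of 0/1 rows with the node labels.
#'
#' @param space a \code{model_space}.
#' @param path file path.
#' @return \code{write_model_space} returns \code{path} invisibly;
#'   \code{read_model_space} returns the reconstructed \code{model_space}.
#' @export
write_model_space <- function(space, path) {
  jsonlite::write_json(
    list(labels = space$labels,
         models = lapply(space$models, function(m) unname(apply(m, 1, as.integer, simplify = FALSE)))),
    path, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_model_space
#' @export
read_model_space <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  labels <- unlist(x$labels)
  models <- lapply(x$models, function(m) {
    do.call(rbind, lapply(m, function(r) as.integer(unlist(r))))
  })
  structure(list(n_nodes = length(labels), labels = labels, models = models),
            class = "model_space")
}

#' Deterministic reduced subset of a model space
#'
#' Picks \code{n} members at evenly spaced positions of the (lexicographic)
#' space, always including any \code{include} indices — a fast stand-in for
#' the full space in simulation studies.
#'
#' @param space a \code{model_space}.
#' @param n subset size.
#' @param include indices (into \code{space$models}) that must be present.
#' @return a \code{model_space} of \code{n} models, original order.
#' @export
reduced_space <- function(space, n = 8, include = integer(0)) {
  stopifnot(inherits(space, "model_space"), n >= 1, n <= length(space$models))
  stopifnot(all(include >= 1), all(include <= length(space$models)))
  pick <- unique(c(include, round(seq(1, length(space$models), length.out = n))))
  pick <- sort(pick)[seq_len(min(n, length(pick)))]
  structure(list(n_nodes = space$n_nodes, labels = space$labels,
                 models = space$models[pick]),
            class = "model_space")
}
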