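#' Directed acyclic path diagrams for piecewise SEM
#'
#' A `path_dag` holds the causal structure of the multilevel path model:
#' directed edges among the variables, the random-intercept specification
#' of each endogenous node, deterministic companion nodes (the quadratic
#' tailwind term, which is a function of tailwind and never generates
#' independence claims of its own), and optional extra fixed-effect terms
#' (interactions) attached to a node's component model without being DAG
#' edges.
#'
#' @param edges Two-column data.frame (`from`, `to`) of directed edges.
#' @param endogenous Nodes that always carry a component model, even when
#'   parentless (an intercept-only regression still contributes variance
#'   parameters to K, mirroring the bookkeeping of published selection
#'   tables).
#' @param random Named list mapping endogenous nodes to character vectors
#'   of random-intercept grouping factors, or a single character vector
#'   applied to all endogenous nodes.
#' @param deterministic Named character vector: deterministic node ->
#'   source node (default `c(tailwind_sq = "tailwind")`). Deterministic
#'   nodes may only appear as predictors.
#' @param extra_terms Named list of extra fixed-effect term strings per
#'   endogenous node (e.g. `"tailwind:crosswind"`).
#' @param nodes Additional nodes that belong to the modelled system even
#'   when currently edgeless. Exogenous variables must stay listed here:
#'   if a variable silently left the system when its last edge was
#'   eliminated, its independence claims would vanish with it and
#'   Fisher's C could no longer veto the removal.
#' @return An object of class `path_dag`.
#' @export
path_dag <- function(edges, endogenous = character(0),
                     random = c("nest_id", "individual_id"),
                     deterministic = c(tailwind_sq = "tailwind"),
                     extra_terms = list(), nodes = character(0)) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  names(edges) <- c("from", "to")
  nodes <- unique(c(edges$from, edges$to, endogenous, names(deterministic),
                    unname(deterministic), nodes))
  endo <- unique(c(endogenous,
                   setdiff(unique(edges$to), names(deterministic))))
  if (!is.list(random))
    random <- setNames(rep(list(random), length(endo)), endo)
  ord <- .topo_order(nodes, edges)   # errors on cycles
  dag <- structure(list(nodes = nodes, edges = edges, endogenous = endo,
                        random = random, deterministic = deterministic,
                        extra_terms = extra_terms, order = ord),
                   class = "path_dag")
  det_as_target <- intersect(unique(edges$to), names(deterministic))
  if (length(det_as_target) &&
      !all(edges$from[edges$to %in% det_as_target] %in% deterministic[det_as_target]))
    stop("deterministic nodes cannot be regression targets", call. = FALSE)
  dag
}

.topo_order <- function(nodes, edges) {
  # Kahn's algorithm; depth ranks double as the causal order for claims
  remaining <- nodes
  ed <- edges
  depth <- setNames(rep(NA_real_, length(nodes)), nodes)
  d <- 0
  while (length(remaining)) {
    roots <- remaining[!remaining %in% ed$to]
    if (!length(roots)) stop("path diagram contains a cycle", call. = FALSE)
    depth[roots] <- d
    remaining <- setdiff(remaining, roots)
    ed <- ed[!ed$from %in% roots, , drop = FALSE]
    d <- d + 1
  }
  depth
}

.parents <- function(dag, node)
  dag$edges$from[dag$edges$to == node]

.adjacent <- function(dag, a, b)
  any((dag$edges$from == a & dag$edges$to == b) |
        (dag$edges$from == b & dag$edges$to == a))

#' Remove an edge from a path diagram
#'
#' Removing the tailwind edge into a node also removes that node's
#' quadratic tailwind edge (the quadratic enters only alongside the linear
#' term).
#'
#' @param dag A [path_dag()].
#' @param from,to Edge to remove.
#' @return The reduced `path_dag`.
#' @export
drop_edge <- function(dag, from, to) {
  keep <- !(dag$edges$from == from & dag$edges$to == to)
  if (all(keep)) stop("no such edge: ", from, " -> ", to, call. = FALSE)
  ed <- dag$edges[keep, , drop = FALSE]
  det_children <- names(dag$deterministic)[dag$deterministic == from]
  if (length(det_children))
    ed <- ed[!(ed$from %in% det_children & ed$to == to), , drop = FALSE]
  path_dag(ed, endogenous = dag$endogenous, random = dag$random,
           deterministic = dag$deterministic,
           extra_terms = dag$extra_terms, nodes = dag$nodes)
}

#' The d-separation basis set of a path diagram
#'
#' Enumerates the conditional-independence claims implied by the missing
#' edges: one claim per non-adjacent pair of non-deterministic nodes, with
#' pairs of exogenous nodes excluded (their association is left free).
#' The claim regresses the causally later node Y on the union of both
#' nodes' parents plus X; pairs in the same causal layer take the
#' later-declared node as Y. Each claim is testable as the coefficient of
#' X in the mixed model `Y ~ parents + X`.
#'
#' @param dag A [path_dag()].
#' @return data.frame with columns `x`, `y`, `conditioning`
#'   (comma-separated), one row per claim; zero rows for a saturated DAG.
#' @export
basis_set <- function(dag) {
  testable <- setdiff(dag$nodes, names(dag$deterministic))
  exo <- setdiff(testable, dag$endogenous)
  claims <- list()
  if (length(testable) >= 2) {
    prs <- utils::combn(testable, 2, simplify = FALSE)
    for (pr in prs) {
      a <- pr[1]; b <- pr[2]
      if (all(pr %in% exo)) next
      if (.adjacent(dag, a, b)) next
      # Y: causally later node; ties broken by declaration order
      if (dag$order[a] == dag$order[b]) {
        y <- pr[which.max(match(pr, dag$nodes))]
      } else {
        y <- if (dag$order[a] > dag$order[b]) a else b
      }
      if (!(y %in% dag$endogenous)) y <- setdiff(pr, y)
      if (!(y %in% dag$endogenous)) next
      x <- setdiff(pr, y)
      cond <- setdiff(union(.parents(dag, y), .parents(dag, x)), c(x, y))
      claims[[length(claims) + 1]] <-
        data.frame(x = x, y = y,
                   conditioning = paste(cond, collapse = ","),
                   stringsAsFactors = FALSE)
    }
  }
  if (!length(claims))
    return(data.frame(x = character(0), y = character(0),
                      conditioning = character(0), stringsAsFactors = FALSE))
  do.call(rbind, claims)
}

#' Full path diagram for the flight-performance analysis
#'
#' Age and flight stage point at the tailwind and crosswind components;
#' age, stage, tailwind, its quadratic companion, and crosswind point at
#' the response. The tailwind-by-crosswind and tailwind-by-stage
#' interactions ride on the response's component model as extra fixed
#' terms. Every endogenous node carries nest and individual random
#' intercepts.
#'
#' @param response `"flight_duration"` or `"log_groundspeed"` (any column
#'   name in the analysis table).
#' @param interactions Include the two interaction terms (default TRUE).
#' @return A [path_dag()].
#' @export
full_flight_dag <- function(response = "flight_duration",
                            interactions = TRUE) {
  ed <- rbind(
    data.frame(from = c("age", "stage"), to = "tailwind"),
    data.frame(from = c("age", "stage"), to = "crosswind"),
    data.frame(from = c("age", "stage", "tailwind", "tailwind_sq",
                        "crosswind"), to = response))
  extra <- if (interactions)
    setNames(list(c("tailwind:crosswind", "tailwind:stage")), response)
  else list()
  path_dag(ed, endogenous = c("tailwind", "crosswind", response),
           extra_terms = extra, nodes = c("age", "stage"))
}

#' @export
print.path_dag <- function(x, ...) {
  cat("path_dag:", nrow(x$edges), "edges among",
      length(x$nodes), "nodes\n")
  for (nd in x$endogenous) {
    pa <- .parents(x, nd)
    cat(" ", nd, "~", if (length(pa)) paste(pa, collapse = " + ") else "1",
        "\n")
  }
  invisible(x)
}
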