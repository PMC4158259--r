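# Matching a query image (reference or moving) to its most suitable graph
# node: random start, subgraph rejection below dif_h < 0.2, and a greedy
# walk guided by the stored affine "direction" vectors.

# register query features against node `i`; NULL when registration fails
query_node_registration <- function(qf, g, i, ratio = 0.8, inlier_tol = 3,
                                    ransac_iter = 2000L, seed = 1L,
                                    min_overlap = 0.25, query_image = NULL) {
  nf <- g$features[[i]]
  if (n_features(qf) == 0L || n_features(nf) == 0L) return(NULL)
  m <- match_features(qf, nf, ratio = ratio)
  if (nrow(m) < 3L) return(NULL)
  fit <- tryCatch(
    estimate_affine(m, qf, nf, inlier_tol = inlier_tol,
                    max_iter = ransac_iter, seed = child_seed(seed, i)),
    gg_error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  sc <- tryCatch(
    ncc_score(query_image, g$frames[[i]]$image, fit$transform,
              min_overlap = min_overlap),
    gg_error = function(e) NULL)
  if (is.null(sc)) return(NULL)
  list(transform = fit$transform, dif_h = sc$dif_h)
}

#' Direction-guided neighbour selection
#'
#' The stored edge transforms around the current node act as an "affine
#' matrix vector": each neighbour `n_k` holds `H_{n_k -> current}`, its
#' pose relative to the current node.  The neighbour whose stored pose is
#' closest (Frobenius norm of the 3x3 difference) to the query's estimated
#' pose `H_{query -> current}` has the most consistent movement and is the
#' next candidate in the walk.
#'
#' @param query_transform [affine_transform()] mapping query coordinates
#'   into the current node's frame.
#' @param current_node Index of the current node in `g`.
#' @param g An `image_graph`.
#' @param exclude Indices never to return (already-visited nodes).
#' @return The chosen neighbour's index, or `NA_integer_` when the node
#'   has no (eligible) neighbours.  Ties resolve to the lower index.
#' @export
direction_step <- function(query_transform, current_node, g,
                           exclude = integer(0)) {
  r <- direction_rank(query_transform, current_node, g, exclude)
  if (length(r) == 0L) return(NA_integer_)
  r[1]
}

# all eligible neighbours ordered by pose consistency (ties: lower index)
direction_rank <- function(query_transform, current_node, g,
                           exclude = integer(0)) {
  nb <- setdiff(graph_neighbors(g, current_node), exclude)
  if (length(nb) == 0L) return(integer(0))
  qm <- unclass(affine_transform(unclass(query_transform)))
  d <- vapply(nb, function(k) {
    hk <- graph_transform(g, k, current_node)   # H_{n_k -> current}
    sqrt(sum((unclass(hk) - qm)^2))
  }, numeric(1))
  nb[order(d, nb)]
}

#' Match a query image to its most suitable graph node
#'
#' Starts at a seeded random node of a seeded random anatomic subgraph and
#' registers the query against it (features, RANSAC affine, NCC).  If the
#' node scores `dif_h < reject_dif` the whole subgraph is abandoned and the
#' next unvisited subgraph is tried (deterministic round-robin from the
#' seeded start); otherwise the walk greedily follows
#' [direction_step()] neighbours while `dif_h` improves, stopping early
#' once `dif_h >= accept_dif`.  Registration failures count as rejections.
#'
#' @param query 2-D numeric intensity matrix.
#' @param g An `image_graph`.
#' @param reject_dif Abandon a subgraph when the current node's
#'   `dif_h` falls below this (default 0.2).
#' @param accept_dif Stop searching once `dif_h` reaches this (default 0.8).
#' @param seed RNG seed governing the starting subgraph/node.
#' @param max_visits Hard cap on registered nodes (default 50).
#' @param max_features,ratio,inlier_tol,ransac_iter,min_overlap
#'   Registration parameters.
#' @return A `node_match`: list with `node` (index), `node_id`,
#'   `transform` (query -> node coordinates), `dif_h`, `visited`
#'   (node ids in visit order) and `truncated`.  Signals a
#'   `gg_no_match` error when every subgraph rejects the query.
#' @export
match_query <- function(query, g, reject_dif = 0.2, accept_dif = 0.8,
                        seed = 1L, max_visits = 50L, max_features = 200L,
                        ratio = 0.8, inlier_tol = 3, ransac_iter = 2000L,
                        min_overlap = 0.25) {
  assert_image(query, "query")
  n <- length(g$frame_ids)
  if (n == 0L) gg_stop("graph is empty", "gg_invalid_input")
  qf <- extract_features(query, max_features = max_features)

  sites <- unique(g$site_labels)
  start_site <- with_seed(seed, sample.int(length(sites), 1L))
  site_order <- sites[((start_site - 1L + seq_along(sites) - 1L) %% length(sites)) + 1L]

  best <- NULL
  visited <- integer(0)
  truncated <- FALSE
  reg_cache <- new.env(parent = emptyenv())
  register <- function(i) {
    key <- as.character(i)
    if (is.null(reg_cache[[key]])) {
      r <- query_node_registration(qf, g, i, ratio = ratio,
                                   inlier_tol = inlier_tol,
                                   ransac_iter = ransac_iter, seed = seed,
                                   min_overlap = min_overlap,
                                   query_image = query)
      reg_cache[[key]] <- if (is.null(r)) list(transform = NULL, dif_h = -Inf) else r
    }
    reg_cache[[key]]
  }
  note_best <- function(i, reg) {
    if (reg$dif_h >= reject_dif &&
        (is.null(best) || reg$dif_h > best$dif_h)) {
      best <<- list(node = i, transform = reg$transform, dif_h = reg$dif_h)
    }
  }

  for (site in site_order) {
    members <- which(g$site_labels == site)
    start <- members[with_seed(child_seed(seed, match(site, sites)),
                               sample.int(length(members), 1L))]
    if (length(visited) >= max_visits) { truncated <- TRUE; break }
    cur <- start
    visited <- c(visited, cur)
    reg <- register(cur)
    if (reg$dif_h < reject_dif) next      # abandon this subgraph
    note_best(cur, reg)
    while (reg$dif_h < accept_dif) {
      # try neighbours in pose-consistency order until one improves dif_h
      cand <- direction_rank(reg$transform, cur, g, exclude = visited)
      moved <- FALSE
      for (nxt in cand) {
        if (length(visited) >= max_visits) { truncated <- TRUE; break }
        visited <- c(visited, nxt)
        nreg <- register(nxt)
        note_best(nxt, nreg)
        if (nreg$dif_h > reg$dif_h) {
          cur <- nxt
          reg <- nreg
          moved <- TRUE
          break
        }
      }
      if (!moved || truncated) break      # no improving neighbour
    }
    break                                 # subgraph accepted: stop here
  }

  if (is.null(best) || best$dif_h < reject_dif) {
    gg_stop("query cannot be grouped to any subgraph (all nodes rejected)",
            "gg_no_match")
  }
  structure(
    list(node = best$node,
         node_id = g$frame_ids[best$node],
         transform = best$transform,
         dif_h = best$dif_h,
         visited = g$frame_ids[visited],
         truncated = truncated),
    class = "node_match")
}

#' @export
print.node_match <- function(x, ...) {
  cat(sprintf("<node_match> node %s, dif_h = %.3f, %d nodes visited%s\n",
              x$node_id, x$dif_h, length(x$visited),
              if (x$truncated) " (truncated)" else ""))
  invisible(x)
}
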