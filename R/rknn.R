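#' Euclidean distance between two backlink vectors
#'
#' \eqn{D = \sqrt{\sum_k (a_k - b_k)^2}} over a shared referrer axis.
#' Coordinates that are zero in both vectors contribute nothing, so padding
#' the axis with referrers unseen by either pharmacy leaves the distance
#' unchanged.
#'
#' @param a,b named integer vectors as returned by [backlink_vector()],
#'   on the same axis (same names, same order).
#' @return Non-negative numeric distance.
#' @export
euclidean_distance <- function(a, b) {
  if (length(a) != length(b) || !identical(names(a), names(b))) {
    stop("backlink vectors must share the same referrer axis")
  }
  sqrt(sum((as.numeric(a) - as.numeric(b))^2))
}

#' Fit the referral-based K-nearest-neighbour model (RKNN)
#'
#' The feature space is the raw backlink count vector of each training
#' pharmacy over the axis of all referrers with at least one edge to a
#' training pharmacy (no scaling by default; `log1p` optionally compresses
#' heavy-tailed counts). Training pharmacies with no edges contribute
#' all-zero vectors and are retained.
#'
#' @param graph a [referral_graph].
#' @param labels a [label_set] of training pharmacies.
#' @param k number of neighbours, \eqn{1 \le K \le} number of training
#'   pharmacies.
#' @param log1p if `TRUE`, distances are computed on `log(1 + l_ij)`.
#' @return An object of class `rknn_model`: list with `axis`, `vectors`
#'   (training matrix, pharmacies x axis), `labels` (named status vector),
#'   `k`, `log1p`.
#' @export
fit_rknn <- function(graph, labels, k, log1p = FALSE) {
  stopifnot(inherits(graph, "referral_graph"), inherits(labels, "label_set"))
  train <- names(labels$status)
  if (!length(train)) stop("no training pharmacies")
  k <- as.integer(k)
  if (k < 1L || k > length(train)) {
    stop(sprintf("k must be in 1..%d", length(train)))
  }
  e <- graph$edges
  axis <- sort(unique(e$referrer[e$pharmacy %in% train]))
  m <- .backlink_matrix(graph, train, axis)
  structure(list(axis = axis, vectors = m, labels = labels$status,
                 k = k, log1p = isTRUE(log1p)),
            class = "rknn_model")
}

#' @export
print.rknn_model <- function(x, ...) {
  cat(sprintf("<rknn_model> K = %d, %d training pharmacies, %d-referrer axis\n",
              x$k, nrow(x$vectors), length(x$axis)))
  invisible(x)
}

# Squared distances from query rows to training rows. Counts are integers,
# so the expansion |q|^2 + |t|^2 - 2 q.t is exact in doubles and ties are
# broken identically to a coordinate-wise computation.
.cross_dist2 <- function(q, tr) {
  d2 <- outer(rowSums(q^2), rowSums(tr^2), `+`) - 2 * tcrossprod(q, tr)
  pmax(d2, 0)
}

# Neighbour labels for each query, ordered by ascending distance with ties
# broken by ascending training pharmacy identifier.
.neighbor_order <- function(model, graph, pharmacies) {
  q <- .backlink_matrix(graph, pharmacies, model$axis)
  tr <- model$vectors
  if (model$log1p) { q <- log1p(q); tr <- log1p(tr) }
  d2 <- .cross_dist2(q, tr)
  ids <- rownames(tr)
  lapply(seq_along(pharmacies), function(i) {
    o <- order(d2[i, ], ids)
    list(pharmacy = ids[o], dist = sqrt(d2[i, o]))
  })
}

#' Classify a pharmacy with a fitted RKNN model
#'
#' A query with no referral edges at all is `unknown`. Otherwise its
#' backlink vector is projected onto the model axis (query referrers unseen
#' in training are dropped, which provably never changes the neighbour
#' ranking), training pharmacies are ranked by ascending distance (ties by
#' ascending identifier), and among the K nearest the legitimate fraction
#' \eqn{R_x = K_s / K} decides: legitimate iff \eqn{R_x > 0.5}, so an even
#' split is called illicit (safety-first).
#'
#' @param graph a [referral_graph] containing the query pharmacy's edges.
#' @param pharmacy a single pharmacy identifier.
#' @param model a fitted [fit_rknn()] model.
#' @return List with `status` and `neighbors` (data frame of the K nearest:
#'   `pharmacy`, `distance`, `status`), plus `k_s`, `k_r`, `r_x`; neighbour
#'   fields are `NULL`/`NA` when `unknown`.
#' @export
classify_rknn <- function(graph, pharmacy, model) {
  stopifnot(inherits(model, "rknn_model"), length(pharmacy) == 1L)
  if (total_backlinks(graph, pharmacy) == 0L) {
    return(list(status = "unknown", neighbors = NULL,
                k_s = NA_integer_, k_r = NA_integer_, r_x = NA_real_))
  }
  nb <- .neighbor_order(model, graph, pharmacy)[[1L]]
  top <- seq_len(model$k)
  st <- unname(model$labels[nb$pharmacy[top]])
  k_s <- sum(st == "legitimate")
  r_x <- k_s / model$k
  list(status = if (r_x > 0.5) "legitimate" else "illicit",
       neighbors = data.frame(pharmacy = nb$pharmacy[top],
                              distance = nb$dist[top],
                              status = st, stringsAsFactors = FALSE),
       k_s = k_s, k_r = model$k - k_s, r_x = r_x)
}

#' Predict status for many pharmacies with RKNN
#'
#' @param object a fitted `rknn_model`.
#' @param graph a [referral_graph] with the query pharmacies' edges.
#' @param pharmacies character vector of query identifiers.
#' @param ... unused.
#' @return Data frame with columns `pharmacy`, `status`, `r_x` (legitimate
#'   fraction among the K nearest, `NA` for `unknown`).
#' @export
predict.rknn_model <- function(object, graph, pharmacies, ...) {
  stopifnot(inherits(graph, "referral_graph"))
  pharmacies <- as.character(pharmacies)
  has_edges <- pharmacies %in% .pharmacies_with_edges(graph)
  n <- length(pharmacies)
  out <- data.frame(pharmacy = pharmacies, status = rep("unknown", n),
                    r_x = rep(NA_real_, n), stringsAsFactors = FALSE)
  if (any(has_edges)) {
    nbs <- .neighbor_order(object, graph, pharmacies[has_edges])
    r_x <- vapply(nbs, function(nb) {
      mean(unname(object$labels[nb$pharmacy[seq_len(object$k)]]) == "legitimate")
    }, 0)
    out$status[has_edges] <- ifelse(r_x > 0.5, "legitimate", "illicit")
    out$r_x[has_edges] <- r_x
  }
  out
}

#' Serialize an RKNN model to versioned JSON
#'
#' The training matrix is stored sparsely as an edge list.
#'
#' @param model an `rknn_model`.
#' @param path output file path.
#' @export
write_rknn_model <- function(model, path) {
  stopifnot(inherits(model, "rknn_model"))
  nz <- which(model$vectors > 0, arr.ind = TRUE)
  edges <- data.frame(
    pharmacy = rownames(model$vectors)[nz[, 1L]],
    referrer = colnames(model$vectors)[nz[, 2L]],
    backlinks = as.integer(model$vectors[nz]),
    stringsAsFactors = FALSE
  )
  edges <- edges[order(edges$pharmacy, edges$referrer), , drop = FALSE]
  obj <- list(
    format = "pharmref-rknn", version = 1L,
    k = model$k, log1p = model$log1p, axis = model$axis,
    labels = as.list(model$labels), edges = edges
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a serialized RKNN model
#'
#' @param path file written by [write_rknn_model()].
#' @return An `rknn_model`.
#' @export
read_rknn_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "pharmref-rknn")) stop("not an RKNN model file")
  st <- unlist(obj$labels)
  labels <- label_set(names(st), unname(st))
  e <- obj$edges
  g <- referral_graph(
    data.frame(pharmacy = as.character(e$pharmacy),
               referrer = as.character(e$referrer),
               backlinks = as.integer(e$backlinks), stringsAsFactors = FALSE),
    pharmacies = names(labels$status), referrers = as.character(obj$axis)
  )
  m <- fit_rknn(g, labels, k = as.integer(obj$k), log1p = isTRUE(obj$log1p))
  # preserve the stored axis exactly (it may include edge-free referrers)
  if (!identical(m$axis, sort(as.character(obj$axis)))) {
    m$axis <- sort(as.character(obj$axis))
    m$vectors <- .backlink_matrix(g, names(labels$status), m$axis)
  }
  m
}
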