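#' Fit referrer quality scores
#'
#' For every referring web site \eqn{j} with at least one backlink to a
#' labeled pharmacy, the quality is
#' \deqn{M_j = (n_{s,j} - n_{r,j}) / n_j}
#' where \eqn{n_{s,j}}, \eqn{n_{r,j}} and \eqn{n_j} count the *distinct*
#' legitimate, illicit and all labeled pharmacies \eqn{j} refers to
#' (backlink multiplicity does not enter). So \eqn{M_j \in [-1, 1]}, with
#' \eqn{M_j = 1} iff \eqn{j} refers only to legitimate pharmacies and
#' \eqn{M_j = -1} iff only to illicit ones. Referrers linking solely to
#' unlabeled pharmacies carry no evidence and are omitted.
#'
#' @param graph a [referral_graph].
#' @param labels a [label_set] of training pharmacies.
#' @return An object of class `referrer_quality`: data frame with columns
#'   `referrer`, `m`, `n_s`, `n_r`, `n`, sorted by referrer.
#' @export
fit_referrer_quality <- function(graph, labels) {
  stopifnot(inherits(graph, "referral_graph"), inherits(labels, "label_set"))
  e <- graph$edges
  e <- e[e$pharmacy %in% names(labels$status), , drop = FALSE]
  if (!nrow(e)) stop("empty training signal: no labeled pharmacy has backlinks")
  illicit <- unname(labels$status[e$pharmacy]) == "illicit"
  # distinct pharmacies per referrer; each (pharmacy, referrer) pair occurs
  # once in the aggregated edge table, so counting rows counts pharmacies
  n_r <- tapply(illicit, e$referrer, sum)
  n   <- tapply(illicit, e$referrer, length)
  ref <- sort(names(n))
  n_r <- as.integer(n_r[ref]); n <- as.integer(n[ref])
  n_s <- n - n_r
  q <- data.frame(referrer = ref, m = (n_s - n_r) / n,
                  n_s = n_s, n_r = n_r, n = n, stringsAsFactors = FALSE)
  rownames(q) <- NULL
  structure(q, class = c("referrer_quality", "data.frame"))
}

#' Reliability score of a pharmacy
#'
#' The backlink-weighted mean quality of a pharmacy's referrers:
#' \deqn{R_i = \frac{\sum_{j \in \mathrm{known}} l_{ij} M_j}
#'                  {\sum_{j \in \mathrm{known}} l_{ij}}}
#' where "known" are the pharmacy's referrers present in `qualities`. Higher
#' scores mean more likely legitimate. If the pharmacy has backlinks but
#' none from a known referrer, the score is indeterminate and set to 0. A
#' pharmacy with no backlinks at all has no referral data and raises an
#' error (classification maps that case to status `unknown`).
#'
#' @param graph a [referral_graph].
#' @param pharmacy a single pharmacy identifier.
#' @param qualities a [fit_referrer_quality()] result.
#' @return List with `score` (\eqn{R_i \in [-1,1]}), `total_links`
#'   (\eqn{L_i}, backlinks from known referrers), and `indeterminate`.
#' @export
reliability_score <- function(graph, pharmacy, qualities) {
  stopifnot(inherits(qualities, "referrer_quality"), length(pharmacy) == 1L)
  if (total_backlinks(graph, pharmacy) == 0L) {
    stop(sprintf("no referral data for pharmacy '%s'", pharmacy))
  }
  e <- graph$edges
  e <- e[e$pharmacy == pharmacy, , drop = FALSE]
  idx <- match(e$referrer, qualities$referrer)
  known <- !is.na(idx)
  if (!any(known)) {
    return(list(score = 0, total_links = 0L, indeterminate = TRUE))
  }
  l <- e$backlinks[known]
  m <- qualities$m[idx[known]]
  list(score = sum(l * m) / sum(l), total_links = as.integer(sum(l)),
       indeterminate = FALSE)
}

# Vectorized reliability scores for a set of pharmacies that all have >= 1
# edge. Returns data frame pharmacy/score/total_links/indeterminate.
.reliability_scores <- function(graph, pharmacies, qualities) {
  e <- graph$edges
  e <- e[e$pharmacy %in% pharmacies, , drop = FALSE]
  idx <- match(e$referrer, qualities$referrer)
  known <- !is.na(idx)
  ek <- e[known, , drop = FALSE]
  wsum <- lsum <- stats::setNames(numeric(length(pharmacies)), pharmacies)
  if (nrow(ek)) {
    w <- tapply(ek$backlinks * qualities$m[idx[known]], ek$pharmacy, sum)
    l <- tapply(ek$backlinks, ek$pharmacy, sum)
    wsum[names(w)] <- w
    lsum[names(l)] <- l
  }
  ind <- lsum == 0
  data.frame(pharmacy = pharmacies,
             score = ifelse(ind, 0, wsum / ifelse(ind, 1, lsum)),
             total_links = as.integer(lsum),
             indeterminate = unname(ind),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Select the RRPM decision threshold
#'
#' Under the rule "illicit iff \eqn{R_i < T}", two strategies:
#' \describe{
#'   \item{`conservative`}{\eqn{T} = the maximum training reliability score
#'     over illicit pharmacies. Sensitivity-first: a pharmacy predicted
#'     legitimate is then highly unlikely to be illicit, at the cost of
#'     specificity.}
#'   \item{`accuracy_max`}{\eqn{T} scanned over the unique training scores
#'     and their midpoints, maximizing training accuracy; ties broken
#'     toward the larger \eqn{T} (the more sensitive rule).}
#' }
#'
#' @param training_scores named numeric vector of reliability scores
#'   \eqn{R_i}, names are pharmacy identifiers.
#' @param labels a [label_set] covering those pharmacies.
#' @param strategy `"conservative"` or `"accuracy_max"`.
#' @return The threshold \eqn{T}, a number in \eqn{[-1, 1]}.
#' @export
select_threshold <- function(training_scores, labels,
                             strategy = c("conservative", "accuracy_max")) {
  strategy <- match.arg(strategy)
  stopifnot(length(training_scores) > 0, inherits(labels, "label_set"))
  st <- labels$status[names(training_scores)]
  if (any(is.na(st))) stop("training scores include unlabeled pharmacies")
  illicit <- unname(st) == "illicit"
  if (strategy == "conservative") {
    if (!any(illicit)) stop("conservative threshold needs >= 1 illicit training pharmacy")
    return(max(training_scores[illicit]))
  }
  if (!any(illicit) || all(illicit)) {
    stop("accuracy_max threshold needs both classes in training")
  }
  v <- sort(unique(training_scores))
  cand <- sort(unique(c(v, if (length(v) > 1L) (v[-1L] + v[-length(v)]) / 2)))
  acc <- vapply(cand, function(t) {
    pred_illicit <- training_scores < t
    mean(pred_illicit == illicit)
  }, 0)
  best <- acc >= max(acc) - 1e-15
  max(cand[best])
}

#' Fit the referral rating prediction model (RRPM)
#'
#' Fits referrer qualities on the labeled training pharmacies, computes each
#' training pharmacy's reliability score, and selects the decision
#' threshold. Training pharmacies without any backlinks are excluded from
#' scoring (they carry no referral signal).
#'
#' @inheritParams fit_referrer_quality
#' @param strategy threshold strategy, see [select_threshold()].
#' @return An object of class `rrpm_model`: list with `qualities`
#'   ([fit_referrer_quality()] output), `threshold`, `strategy`, and
#'   `training_scores` (named numeric vector, retained for audit).
#' @export
fit_rrpm <- function(graph, labels, strategy = c("conservative", "accuracy_max")) {
  strategy <- match.arg(strategy)
  q <- fit_referrer_quality(graph, labels)
  train <- intersect(names(labels$status), .pharmacies_with_edges(graph))
  sc <- .reliability_scores(graph, train, q)
  scores <- stats::setNames(sc$score, sc$pharmacy)
  structure(list(qualities = q,
                 threshold = select_threshold(scores, labels, strategy),
                 strategy = strategy,
                 training_scores = scores),
            class = "rrpm_model")
}

#' @export
print.rrpm_model <- function(x, ...) {
  cat(sprintf("<rrpm_model> %d referrer qualities, threshold T = %.4f (%s)\n",
              nrow(x$qualities), x$threshold, x$strategy))
  invisible(x)
}

#' Classify a pharmacy with a fitted RRPM model
#'
#' A pharmacy with no referral edges at all is `unknown` (the model
#' abstains). Otherwise illicit iff \eqn{R_i < T}; the boundary
#' \eqn{R_i = T} is legitimate, per the strict inequality of the decision
#' rule. An indeterminate score (edges only to referrers unseen in
#' training) enters the rule as \eqn{R_i = 0}.
#'
#' @param graph a [referral_graph] containing the query pharmacy's edges.
#' @param pharmacy a single pharmacy identifier.
#' @param model a fitted [fit_rrpm()] model.
#' @return List with `status` (`"legitimate"`, `"illicit"` or `"unknown"`)
#'   and `reliability` (the [reliability_score()] result, or `NULL` when
#'   `unknown`).
#' @export
classify_rrpm <- function(graph, pharmacy, model) {
  stopifnot(inherits(model, "rrpm_model"))
  if (total_backlinks(graph, pharmacy) == 0L) {
    return(list(status = "unknown", reliability = NULL))
  }
  r <- reliability_score(graph, pharmacy, model$qualities)
  list(status = if (r$score < model$threshold) "illicit" else "legitimate",
       reliability = r)
}

#' Predict status for many pharmacies with RRPM
#'
#' @param object a fitted `rrpm_model`.
#' @param graph a [referral_graph] with the query pharmacies' edges.
#' @param pharmacies character vector of query identifiers.
#' @param ... unused.
#' @return Data frame with columns `pharmacy`, `status`, `score`,
#'   `total_links`, `indeterminate`; score columns are `NA` for `unknown`.
#' @export
predict.rrpm_model <- function(object, graph, pharmacies, ...) {
  stopifnot(inherits(graph, "referral_graph"))
  pharmacies <- as.character(pharmacies)
  has_edges <- pharmacies %in% .pharmacies_with_edges(graph)
  n <- length(pharmacies)
  out <- data.frame(pharmacy = pharmacies, status = rep("unknown", n),
                    score = rep(NA_real_, n),
                    total_links = rep(NA_integer_, n),
                    indeterminate = rep(NA, n), stringsAsFactors = FALSE)
  if (any(has_edges)) {
    sc <- .reliability_scores(graph, pharmacies[has_edges], object$qualities)
    out$status[has_edges] <- ifelse(sc$score < object$threshold,
                                    "illicit", "legitimate")
    out$score[has_edges] <- sc$score
    out$total_links[has_edges] <- sc$total_links
    out$indeterminate[has_edges] <- sc$indeterminate
  }
  out
}

#' Serialize an RRPM model to versioned JSON
#'
#' @param model an `rrpm_model`.
#' @param path output file path.
#' @export
write_rrpm_model <- function(model, path) {
  stopifnot(inherits(model, "rrpm_model"))
  obj <- list(
    format = "pharmref-rrpm", version = 1L,
    strategy = model$strategy, threshold = model$threshold,
    qualities = as.data.frame(model$qualities),
    training_scores = as.list(model$training_scores)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a serialized RRPM model
#'
#' @param path file written by [write_rrpm_model()].
#' @return An `rrpm_model`.
#' @export
read_rrpm_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "pharmref-rrpm")) stop("not an RRPM model file")
  q <- obj$qualities
  q <- data.frame(referrer = as.character(q$referrer), m = as.numeric(q$m),
                  n_s = as.integer(q$n_s), n_r = as.integer(q$n_r),
                  n = as.integer(q$n), stringsAsFactors = FALSE)
  structure(list(qualities = structure(q, class = c("referrer_quality", "data.frame")),
                 threshold = as.numeric(obj$threshold),
                 strategy = obj$strategy,
                 training_scores = unlist(obj$training_scores)),
            class = "rrpm_model")
}
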