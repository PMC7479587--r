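#' Configuration for the synthetic referral-ecosystem generator
#'
#' The generator emulates the structure the classifiers exploit: two
#' pharmacy classes under heavy imbalance, "good" referrers that mostly
#' link to legitimate pharmacies and cluster into groups sharing target
#' pools, and "bad" referrers that scatter their links across the illicit
#' class. Defaults mirror a screening study at the scale of 50 legitimate
#' and 713 illicit pharmacies.
#'
#' @param n_legit,n_illicit pharmacy counts per class (defaults 50 / 713).
#' @param n_good_ref,n_bad_ref referrer counts (defaults 150 / 600: bad
#'   referral sites outnumber good ones in illicit-pharmacy ecosystems).
#' @param purity_good probability a good referrer's link targets a
#'   legitimate pharmacy (default 0.95).
#' @param purity_bad probability a bad referrer's link targets an illicit
#'   pharmacy (default 0.95).
#' @param links_per_referrer mean out-degree per referrer; drawn as
#'   1 + Poisson(mean - 1) so every referrer has at least one link
#'   (default 8).
#' @param multiplicity_mean mean backlink count per realized
#'   (pharmacy, referrer) pair; drawn geometrically on 1, 2, ...
#'   (default 3).
#' @param cluster_good if `TRUE` (default), good referrers are split into
#'   `n_clusters` groups, each drawing its legitimate targets from a shared
#'   pool of pharmacies — good referral sites referring to each other's
#'   pharmacies.
#' @param n_clusters number of good-referrer groups (default 5).
#' @param seed integer seed; generation is fully reproducible from it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_legit = 50L, n_illicit = 713L,
                       n_good_ref = 150L, n_bad_ref = 600L,
                       purity_good = 0.95, purity_bad = 0.95,
                       links_per_referrer = 8, multiplicity_mean = 3,
                       cluster_good = TRUE, n_clusters = 5L, seed = 1L) {
  cfg <- list(n_legit = as.integer(n_legit), n_illicit = as.integer(n_illicit),
              n_good_ref = as.integer(n_good_ref), n_bad_ref = as.integer(n_bad_ref),
              purity_good = purity_good, purity_bad = purity_bad,
              links_per_referrer = links_per_referrer,
              multiplicity_mean = multiplicity_mean,
              cluster_good = isTRUE(cluster_good),
              n_clusters = as.integer(n_clusters), seed = as.integer(seed))
  if (any(unlist(cfg[1:4]) < 0L)) stop("counts must be non-negative")
  if (purity_good < 0 || purity_good > 1 || purity_bad < 0 || purity_bad > 1) {
    stop("purities must be probabilities in [0, 1]")
  }
  if (links_per_referrer <= 0 || multiplicity_mean <= 0) {
    stop("links_per_referrer and multiplicity_mean must be positive")
  }
  if ((cfg$n_good_ref + cfg$n_bad_ref) > 0L && (cfg$n_legit + cfg$n_illicit) == 0L) {
    stop("referrers need at least one pharmacy to link to")
  }
  structure(cfg, class = "sim_config")
}

#' Small preset configuration for fast tests
#'
#' Same mechanism as [sim_config()] at one-fortieth the scale.
#'
#' @param ... overrides passed to [sim_config()].
#' @export
sim_config_tiny <- function(...) {
  defaults <- list(n_legit = 6L, n_illicit = 14L, n_good_ref = 8L,
                   n_bad_ref = 16L, links_per_referrer = 5,
                   n_clusters = 2L)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

# out-degree >= 1 with the configured mean
.rdegree <- function(n, mean) 1L + stats::rpois(n, max(mean - 1, 0))

# backlink multiplicity on {1, 2, ...} with the configured mean
.rmultiplicity <- function(n, mean) {
  if (mean <= 1) return(rep(1L, n))
  1L + stats::rgeom(n, prob = 1 / mean)
}

# draw one referrer's targets: n_links class-conditional picks of distinct
# pharmacies (out-degree counts distinct referred pharmacies; repeat links
# to one pharmacy are the multiplicity, not extra targets)
.draw_targets <- function(n_links, primary_pool, other_pool, purity) {
  to_primary <- stats::runif(n_links) < purity
  pick <- function(pool, k) {
    if (k == 0L || !length(pool)) return(character())
    pool[sample.int(length(pool), min(k, length(pool)))]
  }
  c(pick(primary_pool, sum(to_primary)), pick(other_pool, sum(!to_primary)))
}

#' Generate a synthetic labeled referral graph
#'
#' Each good referrer draws an out-degree and sends each link to a
#' legitimate pharmacy with probability `purity_good` (within its cluster
#' pool when `cluster_good`), otherwise to a uniform illicit pharmacy; bad
#' referrers mirror this toward the illicit class but always scatter
#' uniformly. Each realized (pharmacy, referrer) pair receives a geometric
#' backlink multiplicity; repeated draws of the same pair are summed.
#'
#' @param config a [sim_config()].
#' @return List with `graph` (a [referral_graph]; pharmacies with no drawn
#'   links are still declared) and `labels` (a [label_set]).
#' @export
generate_graph <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  legit <- sprintf("L%03d", seq_len(config$n_legit))
  illicit <- sprintf("I%03d", seq_len(config$n_illicit))
  good <- sprintf("g%03d", seq_len(config$n_good_ref))
  bad <- sprintf("b%03d", seq_len(config$n_bad_ref))
  labels <- label_set(c(legit, illicit),
                      rep(c("legitimate", "illicit"),
                          c(length(legit), length(illicit))))

  edges <- withr::with_seed(config$seed, {
    pools <- if (config$cluster_good && length(good) && length(legit)) {
      k <- max(1L, min(config$n_clusters, length(legit)))
      membership <- rep_len(seq_len(k), length(legit))
      cluster_of <- sample.int(k, length(good), replace = TRUE)
      lapply(cluster_of, function(cl) legit[membership == cl])
    } else {
      rep(list(legit), length(good))
    }
    deg_good <- .rdegree(length(good), config$links_per_referrer)
    deg_bad <- .rdegree(length(bad), config$links_per_referrer)
    # backlink multiplicity is a property of the referring site (its page
    # count and link template), drawn once per referrer and shared by all
    # its targets; the per-pair marginal stays geometric with the given mean
    mult_good <- .rmultiplicity(length(good), config$multiplicity_mean)
    mult_bad <- .rmultiplicity(length(bad), config$multiplicity_mean)
    rows <- vector("list", length(good) + length(bad))
    for (g in seq_along(good)) {
      tg <- .draw_targets(deg_good[g], pools[[g]], illicit, config$purity_good)
      if (length(tg)) rows[[g]] <- data.frame(pharmacy = tg, referrer = good[g],
                                              backlinks = mult_good[g],
                                              stringsAsFactors = FALSE)
    }
    for (b in seq_along(bad)) {
      tg <- .draw_targets(deg_bad[b], illicit, legit, config$purity_bad)
      if (length(tg)) rows[[length(good) + b]] <-
          data.frame(pharmacy = tg, referrer = bad[b], backlinks = mult_bad[b],
                     stringsAsFactors = FALSE)
    }
    e <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
    if (is.null(e)) {
      data.frame(pharmacy = character(), referrer = character(),
                 backlinks = integer(), stringsAsFactors = FALSE)
    } else e
  })
  graph <- referral_graph(edges, pharmacies = c(legit, illicit),
                          referrers = c(good, bad))
  list(graph = graph, labels = labels)
}

#' Generate unlabeled query pharmacies against an existing graph
#'
#' Emits `n_queries` new pharmacies with known ground truth, extending the
#' graph: a fraction with no referral edges at all (which the classifiers
#' must call `unknown`), a fraction linked only to brand-new referrers
#' never seen in training (which makes RRPM's reliability indeterminate),
#' and the rest wired to the existing referrers by the same
#' class-conditional mechanism as [generate_graph()].
#'
#' @param config the [sim_config()] used for the training graph.
#' @param graph the [referral_graph] returned by [generate_graph()].
#' @param n_queries number of query pharmacies.
#' @param frac_no_referral fraction with zero edges.
#' @param frac_unseen_referrers fraction linked only to novel referrers;
#'   `frac_no_referral + frac_unseen_referrers` must be at most 1.
#' @param seed integer seed (default: `config$seed + 1`).
#' @return List with `graph` (the input graph extended with the query
#'   pharmacies and their edges) and `truth` (a [label_set] with the
#'   queries' true statuses).
#' @export
generate_query_set <- function(config, graph, n_queries = 50L,
                               frac_no_referral = 0.1,
                               frac_unseen_referrers = 0.1,
                               seed = config$seed + 1L) {
  stopifnot(inherits(config, "sim_config"), inherits(graph, "referral_graph"))
  if (frac_no_referral < 0 || frac_unseen_referrers < 0 ||
      frac_no_referral + frac_unseen_referrers > 1) {
    stop("fractions must be in [0, 1] and sum to at most 1")
  }
  n_queries <- as.integer(n_queries)
  ids <- sprintf("Q%03d", seq_len(n_queries))
  good <- grep("^g", graph$referrers, value = TRUE)
  bad <- grep("^b", graph$referrers, value = TRUE)

  res <- withr::with_seed(as.integer(seed), {
    truth_status <- sample(c("legitimate", "illicit"), n_queries,
                           replace = TRUE,
                           prob = c(config$n_legit, config$n_illicit) /
                             max(config$n_legit + config$n_illicit, 1L))
    n_none <- round(frac_no_referral * n_queries)
    n_novel <- round(frac_unseen_referrers * n_queries)
    kind <- rep_len("linked", n_queries)
    if (n_none) kind[seq_len(n_none)] <- "none"
    if (n_novel) kind[n_none + seq_len(n_novel)] <- "novel"
    rows <- list()
    novel_i <- 0L
    for (qi in seq_len(n_queries)) {
      if (kind[qi] == "none") next
      deg <- .rdegree(1L, config$links_per_referrer)
      if (kind[qi] == "novel") {
        novel_refs <- sprintf("nov%04d", novel_i + seq_len(deg))
        novel_i <- novel_i + deg
        rows[[length(rows) + 1L]] <- data.frame(
          pharmacy = ids[qi], referrer = novel_refs,
          stringsAsFactors = FALSE)
      } else {
        # in-links mirror the generator: a legitimate query is mostly
        # referred by good referrers, an illicit one by bad referrers
        primary <- if (truth_status[qi] == "legitimate") good else bad
        other <- if (truth_status[qi] == "legitimate") bad else good
        purity <- if (truth_status[qi] == "legitimate") config$purity_good else config$purity_bad
        refs <- .draw_targets(deg, primary, other, purity)
        if (length(refs)) rows[[length(rows) + 1L]] <- data.frame(
          pharmacy = ids[qi], referrer = refs, stringsAsFactors = FALSE)
      }
    }
    e <- if (length(rows)) do.call(rbind, rows) else
      data.frame(pharmacy = character(), referrer = character(),
                 stringsAsFactors = FALSE)
    e$backlinks <- if (nrow(e)) .rmultiplicity(nrow(e), config$multiplicity_mean) else integer()
    list(edges = e, truth = truth_status)
  })

  extended <- referral_graph(rbind(graph$edges, res$edges),
                             pharmacies = c(graph$pharmacies, ids),
                             referrers = unique(c(graph$referrers,
                                                  res$edges$referrer)))
  list(graph = extended, truth = label_set(ids, res$truth))
}
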