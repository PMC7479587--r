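# Shared fixtures and independent brute-force oracles.

# The worked snapshot of a backlink matrix: rows are pharmacies, columns
# referrers, entries l_ij.
snapshot_graph <- function() {
  referral_graph(data.frame(
    pharmacy  = c("p1", "p1", "p1", "p2", "p2"),
    referrer  = c("r1", "r3", "r9", "r1", "r2"),
    backlinks = c(5L, 3L, 16L, 9L, 3L)
  ))
}

# Random sparse bipartite graph + labels; independent of the simgen module.
random_graph <- function(n_pharm, n_ref, density = 0.2, max_count = 5L,
                         seed = 1L, p_illicit = 0.5) {
  withr::with_seed(seed, {
    ph <- sprintf("p%03d", seq_len(n_pharm))
    rf <- sprintf("r%03d", seq_len(n_ref))
    pairs <- expand.grid(pharmacy = ph, referrer = rf,
                         stringsAsFactors = FALSE)
    keep <- runif(nrow(pairs)) < density
    edges <- pairs[keep, , drop = FALSE]
    edges$backlinks <- sample.int(max_count, nrow(edges), replace = TRUE)
    status <- ifelse(runif(n_pharm) < p_illicit, "illicit", "legitimate")
    # guarantee both classes
    status[1L] <- "illicit"
    status[n_pharm] <- "legitimate"
    list(graph = referral_graph(edges, pharmacies = ph, referrers = rf),
         labels = label_set(ph, status))
  })
}

# Dense double-loop reliability scores: the oracle for the sparse
# implementation. Loops over every (pharmacy, referrer) cell explicitly.
oracle_rrpm_scores <- function(graph, labels) {
  ph_lab <- names(labels$status)
  refs <- graph$referrers
  l <- function(i, j) {
    e <- graph$edges
    hit <- e$pharmacy == i & e$referrer == j
    if (any(hit)) e$backlinks[hit] else 0L
  }
  m <- numeric(0)
  for (j in refs) {
    n_s <- n_r <- 0L
    for (i in ph_lab) {
      if (l(i, j) > 0L) {
        if (labels$status[[i]] == "illicit") n_r <- n_r + 1L else n_s <- n_s + 1L
      }
    }
    if (n_s + n_r > 0L) m[j] <- (n_s - n_r) / (n_s + n_r)
  }
  scores <- numeric(0)
  for (i in graph$pharmacies) {
    num <- den <- 0
    for (j in names(m)) {
      num <- num + l(i, j) * m[[j]]
      den <- den + l(i, j)
    }
    if (sum(graph$edges$backlinks[graph$edges$pharmacy == i]) > 0L) {
      scores[i] <- if (den > 0) num / den else 0
    }
  }
  list(m = m, scores = scores)
}

# Brute-force KNN oracle: all-pairs euclidean_distance and a plain sort.
# Returns the training statuses in neighbour order (ties by identifier);
# the K-neighbour prediction is then the strict-majority rule on the first
# K entries.
oracle_knn_rank <- function(graph, train_labels, query) {
  train <- names(train_labels$status)
  axis <- sort(unique(graph$edges$referrer[graph$edges$pharmacy %in% train]))
  qv <- backlink_vector(graph, query, axis)
  d <- vapply(train, function(i)
    euclidean_distance(qv, backlink_vector(graph, i, axis)), 0)
  o <- order(d, train)
  unname(train_labels$status[train[o]])
}

oracle_knn_predict <- function(graph, train_labels, k, query) {
  st <- oracle_knn_rank(graph, train_labels, query)[seq_len(k)]
  if (mean(st == "legitimate") > 0.5) "legitimate" else "illicit"
}

# Textbook Cohen's kappa from the four cells of a 2x2 table
# (rows predicted, cols actual).
oracle_kappa <- function(tp, fn, fp, tn) {
  n <- tp + fn + fp + tn
  p_o <- (tp + tn) / n
  p_yes <- ((tp + fn) / n) * ((tp + fp) / n)
  p_no <- ((fp + tn) / n) * ((fn + tn) / n)
  p_e <- p_yes + p_no
  if (p_e == 1) return(if (p_o == 1) 1 else 0)
  (p_o - p_e) / (1 - p_e)
}
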