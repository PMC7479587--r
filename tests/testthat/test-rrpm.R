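test_that("referrer quality hits its endpoints and counts distinct pharmacies", {
  g <- referral_graph(data.frame(
    pharmacy  = c("i1", "i2", "l1", "l2", "l3", "l4", "l1", "l2", "l3", "i3"),
    referrer  = c("jb", "jb", "jg", "jg", "jg", "jg", "jm", "jm", "jm", "jm"),
    backlinks = c(2L, 7L, 1L, 1L, 3L, 9L, 2L, 2L, 2L, 6L)
  ))
  lab <- label_set(c("i1", "i2", "i3", "l1", "l2", "l3", "l4"),
                   c("illicit", "illicit", "illicit",
                     "legitimate", "legitimate", "legitimate", "legitimate"))
  q <- fit_referrer_quality(g, lab)
  m <- setNames(q$m, q$referrer)
  expect_equal(m[["jb"]], -1)            # refers only to illicit pharmacies
  expect_equal(m[["jg"]], 1)             # refers only to legitimate pharmacies
  expect_equal(m[["jm"]], (3 - 1) / 4)   # 3 legitimate, 1 illicit
  expect_equal(q$n[q$referrer == "jm"], 4L)
  # multiplicity must not affect quality: scale every count by 7
  g7 <- referral_graph(within(g$edges, backlinks <- backlinks * 7L))
  q7 <- fit_referrer_quality(g7, lab)
  expect_equal(q7$m, q$m)
})

test_that("quality fitting omits uninformative referrers and flags empty signal", {
  g <- referral_graph(data.frame(pharmacy = c("lab1", "unl1"),
                                 referrer = c("j1", "j2"),
                                 backlinks = c(1L, 5L)))
  lab <- label_set("lab1", "illicit")
  q <- fit_referrer_quality(g, lab)
  expect_equal(q$referrer, "j1")   # j2 links only to an unlabeled pharmacy
  expect_error(fit_referrer_quality(g, label_set("other", "illicit")),
               "empty training signal")
})

test_that("reliability score is the backlink-weighted mean of known qualities", {
  quality <- function(refs, ms) {
    structure(data.frame(referrer = refs, m = ms, n_s = 1L, n_r = 1L, n = 2L,
                         stringsAsFactors = FALSE),
              class = c("referrer_quality", "data.frame"))
  }
  g <- referral_graph(data.frame(pharmacy = c("x", "x", "y", "y", "z"),
                                 referrer = c("j1", "j2", "j1", "j2", "jnew"),
                                 backlinks = c(2L, 2L, 3L, 1L, 4L)))
  allgood <- reliability_score(g, "x", quality(c("j1", "j2"), c(1, 1)))
  expect_equal(allgood$score, 1)
  balanced <- reliability_score(g, "x", quality(c("j1", "j2"), c(1, -1)))
  expect_equal(balanced$score, 0)
  mixed <- reliability_score(g, "y", quality(c("j1", "j2"), c(0.5, -1)))
  expect_equal(mixed$score, (3 * 0.5 - 1) / 4)   # 0.125
  expect_equal(mixed$total_links, 4L)
  unseen <- reliability_score(g, "z", quality(c("j1", "j2"), c(1, -1)))
  expect_true(unseen$indeterminate)
  expect_equal(unseen$score, 0)
  expect_error(reliability_score(g, "ghost", quality("j1", 1)),
               "no referral data")
})

test_that("threshold selection implements both strategies", {
  scores <- c(i1 = -0.8, i2 = -0.2, i3 = 0.1, l1 = 0.6, l2 = 0.9)
  lab <- label_set(names(scores),
                   c("illicit", "illicit", "illicit", "legitimate", "legitimate"))
  expect_equal(select_threshold(scores, lab, "conservative"), 0.1)
  degenerate <- c(a = -1, b = -1)
  dlab <- label_set(c("a", "b"), c("illicit", "illicit"))
  expect_equal(select_threshold(degenerate, dlab, "conservative"), -1)
  expect_error(select_threshold(c(l1 = 0.5),
                                label_set("l1", "legitimate"), "conservative"),
               "illicit")
  # perfectly separated: accuracy_max reaches training accuracy 1
  t_acc <- select_threshold(scores, lab, "accuracy_max")
  expect_equal(mean((scores < t_acc) == c(TRUE, TRUE, TRUE, FALSE, FALSE)), 1)
  expect_true(t_acc > 0.1 && t_acc <= 0.6)
  # exhaustive-scan cross-check on a random score set
  rs <- withr::with_seed(5, round(runif(20, -1, 1), 2))
  names(rs) <- sprintf("p%02d", 1:20)
  rl <- label_set(names(rs), rep(c("illicit", "legitimate"), 10))
  t2 <- select_threshold(rs, rl, "accuracy_max")
  grid <- sort(unique(c(rs, seq(-1, 1, by = 0.001))))
  acc <- vapply(grid, function(t)
    mean((rs < t) == (unname(rl$status[names(rs)]) == "illicit")), 0)
  expect_equal(mean((rs < t2) == (unname(rl$status[names(rs)]) == "illicit")),
               max(acc))
})

test_that("RRPM classification honours boundary, indeterminate and unknown rules", {
  g <- referral_graph(data.frame(
    pharmacy  = c("i1", "i2", "l1", "l2", "q_at", "q_new"),
    referrer  = c("jb", "jb", "jg", "jg", "jmix", "brand_new"),
    backlinks = c(3L, 2L, 4L, 1L, 2L, 9L)),
    pharmacies = "q_none")
  g <- referral_graph(rbind(g$edges,
                            data.frame(pharmacy = c("i1", "l1"),
                                       referrer = c("jmix", "jmix"),
                                       backlinks = c(1L, 1L))),
                      pharmacies = g$pharmacies)
  lab <- label_set(c("i1", "i2", "l1", "l2"),
                   c("illicit", "illicit", "legitimate", "legitimate"))
  model <- fit_rrpm(g, lab, "conservative")
  # conservative T is the max illicit training score
  ill_scores <- model$training_scores[c("i1", "i2")]
  expect_equal(model$threshold, max(ill_scores))
  # boundary case: the illicit training pharmacy at R = T is legitimate
  at <- names(which.max(ill_scores))
  expect_equal(classify_rrpm(g, at, model)$status, "legitimate")
  # strictly below T is illicit
  below <- names(which.min(ill_scores))
  expect_equal(classify_rrpm(g, below, model)$status, "illicit")
  # no referral data at all: unknown
  expect_equal(classify_rrpm(g, "q_none", model)$status, "unknown")
  expect_equal(predict(model, g, "q_none")$status, "unknown")
  # only unseen referrers: indeterminate score 0, decided by 0 < T
  res <- classify_rrpm(g, "q_new", model)
  expect_true(res$reliability$indeterminate)
  if (model$threshold > 0) expect_equal(res$status, "illicit")
})

test_that("indeterminate zero score classifies illicit under a positive threshold", {
  quality <- structure(data.frame(referrer = "j1", m = 1, n_s = 1L, n_r = 0L,
                                  n = 1L, stringsAsFactors = FALSE),
                       class = c("referrer_quality", "data.frame"))
  model <- structure(list(qualities = quality, threshold = 0.1,
                          strategy = "conservative",
                          training_scores = c(tr = 1)),
                     class = "rrpm_model")
  g <- referral_graph(data.frame(pharmacy = "q", referrer = "unseen",
                                 backlinks = 1L))
  expect_equal(classify_rrpm(g, "q", model)$status, "illicit")
})

test_that("scores stay bounded and respond monotonically to pure backlinks", {
  for (seed in 1:5) {
    rg <- random_graph(25, 15, density = 0.25, seed = seed)
    q <- fit_referrer_quality(rg$graph, rg$labels)
    expect_true(all(q$m >= -1 & q$m <= 1))
    expect_true(all(q$n_s + q$n_r == q$n))
    sc <- predict(fit_rrpm(rg$graph, rg$labels), rg$graph, rg$graph$pharmacies)
    det <- sc$score[!is.na(sc$score) & !sc$indeterminate]
    expect_true(all(abs(det) <= 1 + 1e-12))
  }
  # adding a backlink from a quality-1 referrer never decreases R_i,
  # from a quality -1 referrer never increases it
  rg <- random_graph(20, 12, density = 0.3, seed = 11)
  # plant one referrer of each pure type so both endpoints exist
  g <- referral_graph(rbind(rg$graph$edges, data.frame(
    pharmacy = c(rg$labels$safe[1], rg$labels$rogue[1]),
    referrer = c("pure_good", "pure_bad"), backlinks = c(1L, 1L))))
  q <- fit_referrer_quality(g, rg$labels)
  expect_equal(q$m[q$referrer == "pure_good"], 1)
  expect_equal(q$m[q$referrer == "pure_bad"], -1)
  target <- g$pharmacies[1]
  base <- reliability_score(g, target, q)$score
  bump <- function(ref) {
    g2 <- referral_graph(rbind(g$edges,
                               data.frame(pharmacy = target, referrer = ref,
                                          backlinks = 1L)))
    reliability_score(g2, target, q)$score
  }
  expect_gte(bump("pure_good"), base)
  expect_lte(bump("pure_bad"), base)
})

test_that("uniform multiplicity scaling changes neither qualities nor scores", {
  rg <- random_graph(30, 20, density = 0.2, seed = 3)
  q1 <- fit_referrer_quality(rg$graph, rg$labels)
  s1 <- predict(fit_rrpm(rg$graph, rg$labels), rg$graph, rg$graph$pharmacies)
  g5 <- referral_graph(within(rg$graph$edges, backlinks <- backlinks * 5L),
                       pharmacies = rg$graph$pharmacies,
                       referrers = rg$graph$referrers)
  q5 <- fit_referrer_quality(g5, rg$labels)
  s5 <- predict(fit_rrpm(g5, rg$labels), g5, g5$pharmacies)
  expect_equal(q5$m, q1$m)
  expect_equal(s5$score, s1$score)
})

test_that("sparse reliability scores match the dense double-loop oracle", {
  for (seed in c(2, 9, 23)) {
    rg <- random_graph(20, 12, density = 0.25, seed = seed)
    oracle <- oracle_rrpm_scores(rg$graph, rg$labels)
    q <- fit_referrer_quality(rg$graph, rg$labels)
    expect_equal(setNames(q$m, q$referrer), oracle$m[q$referrer],
                 tolerance = 1e-12)
    model <- fit_rrpm(rg$graph, rg$labels)
    pred <- predict(model, rg$graph, names(oracle$scores))
    expect_equal(setNames(pred$score, pred$pharmacy), oracle$scores,
                 tolerance = 1e-12)
  }
})

test_that("conservative training threshold flags every strictly sub-maximal illicit score", {
  rg <- random_graph(40, 25, density = 0.2, seed = 17)
  model <- fit_rrpm(rg$graph, rg$labels, "conservative")
  pred <- predict(model, rg$graph, names(model$training_scores))
  ill <- pred[unname(rg$labels$status[pred$pharmacy]) == "illicit", ]
  strictly_below <- ill$score < max(model$training_scores[
    intersect(rg$labels$rogue, names(model$training_scores))])
  expect_true(all(ill$status[strictly_below] == "illicit"))
})

test_that("RRPM models round-trip through serialization", {
  rg <- random_graph(15, 10, seed = 4)
  model <- fit_rrpm(rg$graph, rg$labels, "accuracy_max")
  f <- withr::local_tempfile(fileext = ".json")
  write_rrpm_model(model, f)
  back <- read_rrpm_model(f)
  expect_equal(back$threshold, model$threshold)
  expect_equal(back$strategy, model$strategy)
  expect_equal(as.data.frame(back$qualities), as.data.frame(model$qualities))
  p1 <- predict(model, rg$graph, rg$graph$pharmacies)
  p2 <- predict(back, rg$graph, rg$graph$pharmacies)
  expect_equal(p2, p1)
})
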