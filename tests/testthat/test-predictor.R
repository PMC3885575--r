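# Separable toy fixture: one informative attribute ("pos10_blosum62",
# positives shifted up), the rest i.i.d. noise.
toy_training <- function(n = 40, n_noise = 4, shift = 8, seed = 1) {
  set.seed(seed)
  labels <- rep(c(TRUE, FALSE), each = n / 2)
  sites <- list(asr = 10L, lbr = integer(), csr = integer())
  schema <- attribute_schema(sites, has_esst = FALSE)
  vals <- tibble::tibble(query_id = sprintf("q%02d", seq_len(n)))
  for (nm in schema$name) {
    vals[[nm]] <- if (nm == "pos10_blosum62")
      rnorm(n) + ifelse(labels, shift, 0) else rnorm(n)
  }
  list(attrs = vals, labels = labels, schema = schema)
}

test_that("forest training honours the stated hyper-parameters and separates", {
  toy <- toy_training()
  fit <- train_forest(toy$attrs, toy$labels, toy$schema, seed = 2)
  expect_equal(fit$ntree, 500L)
  expect_equal(fit$mtry, floor(sqrt(nrow(toy$schema))))
  expect_equal(fit$oob_error, 0)  # margin forces separability at n >= 40

  # determinism: same data + seed -> identical predictions on held-out data
  fit2 <- train_forest(toy$attrs, toy$labels, toy$schema, seed = 2)
  held <- toy_training(n = 20, seed = 99)$attrs
  expect_equal(predict(fit, held), predict(fit2, held))
  expect_equal(fit$importance, fit2$importance)

  expect_error(train_forest(toy$attrs, rep(TRUE, 40), toy$schema),
               "single-class")
})

test_that("prediction is a majority vote with schema checking", {
  toy <- toy_training()
  fit <- train_forest(toy$attrs, toy$labels, toy$schema, seed = 2)
  pred <- predict(fit, toy$attrs)
  expect_equal(pred$predicted, toy$labels)      # training-set recall on
  expect_true(all(pred$vote_fraction >= 0 & pred$vote_fraction <= 1))
  expect_equal(pred$predicted, pred$vote_fraction > 0.5)
  # permuting attribute columns leaves predictions unchanged
  shuffled <- toy$attrs[, c(1, sample(2:ncol(toy$attrs)))]
  expect_equal(predict(fit, shuffled), pred)
  expect_error(predict(fit, toy$attrs[, 1:3]), "schema")
})

test_that("the simple baseline tree finds the optimal 1-D threshold", {
  set.seed(8)
  scores <- c(rnorm(10, 150, 5), rnorm(10, 30, 5))
  labels <- rep(c(TRUE, FALSE), each = 10)
  fit <- train_simple(scores, labels)
  expect_equal(length(fit$thresholds), 1L)
  expect_gt(fit$thresholds, max(scores[!labels]))
  expect_lt(fit$thresholds, min(scores[labels]))
  expect_equal(predict(fit, scores)$predicted, labels)

  # brute-force information-gain check: the threshold separates exactly
  # like the best midpoint cut
  ent <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  info_gain <- function(cut) {
    left <- labels[scores < cut]; right <- labels[scores >= cut]
    h <- function(l) if (length(l) == 0) 0 else
      ent(table(l) / length(l)) * length(l) / length(labels)
    ent(table(labels) / length(labels)) - h(left) - h(right)
  }
  mids <- (head(sort(scores), -1) + tail(sort(scores), -1)) / 2
  best <- mids[which.max(vapply(mids, info_gain, numeric(1)))]
  expect_equal(scores < fit$thresholds, scores < best)

  # constant scores: majority-class stump
  stump <- train_simple(rep(5, 10), rep(c(TRUE, FALSE), each = 5))
  expect_equal(length(stump$thresholds), 0L)
})

test_that("importance ranking selects the 3*floor(sqrt(n)) prefix", {
  toy <- toy_training()
  fit <- train_forest(toy$attrs, toy$labels, toy$schema, seed = 3)
  rk <- rank_importance(fit)
  n <- nrow(toy$schema)
  expect_equal(sum(rk$highly_contributing), min(3 * floor(sqrt(n)), n))
  expect_equal(rk$rank, seq_len(n))
  expect_equal(rk$name[1], "pos10_blosum62")  # planted informative attr

  # cap at n when 3*floor(sqrt(n)) exceeds it
  sites <- list(asr = 10L, lbr = integer(), csr = integer())
  sch <- attribute_schema(sites)[1:4, ]
  toy4 <- toy$attrs[, c("query_id", sch$name)]
  fit4 <- train_forest(toy4, toy$labels, sch, seed = 3)
  expect_equal(sum(rank_importance(fit4)$highly_contributing), 4L)
})

test_that("the informative attribute outranks noise across seeded runs", {
  wins <- 0L
  for (s in 1:20) {
    toy <- toy_training(n = 30, shift = 8, seed = s)
    fit <- train_forest(toy$attrs, toy$labels, toy$schema, ntree = 150L,
                        seed = s)
    rk <- rank_importance(fit)
    if (rk$name[1] == "pos10_blosum62") wins <- wins + 1L
  }
  expect_gte(wins, 20L * 0.99)
})

test_that("rf-SDR extraction walks the prefix, skips globals, dedups", {
  sites <- list(asr = c(12L, 40L), lbr = integer(), csr = integer())
  schema <- attribute_schema(sites)
  ranking <- tibble::tibble(
    name = c("full_pssm", "pos40_pssm", "pos40_blosum62", "blast",
             "pos12_pssm", "full_blosum62", "pos12_blosum62"),
    importance = 7:1,
    schema_index = match(name, schema$name),
    rank = 1:7,
    highly_contributing = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE)
  )
  attr(ranking, "schema") <- schema
  sdrs <- extract_rf_sdrs(ranking)
  expect_equal(sdrs$position, c(12L, 40L))
  expect_equal(sdrs$best_rank[sdrs$position == 40L], 2L)
  expect_equal(sdrs$matrices[sdrs$position == 40L], "blosum62,pssm")
  expect_equal(sdrs$matrices[sdrs$position == 12L], "pssm")
  # positions never come from blast/full-length attributes
  expect_true(all(sdrs$position %in% c(sites$asr, sites$lbr, sites$csr)))

  ranking$highly_contributing <- ranking$name %in% c("full_pssm", "blast")
  expect_equal(nrow(extract_rf_sdrs(ranking)), 0L)
})

test_that("tidy and glance expose the fitted forest in broom style", {
  ms <- small_model_set()
  fit <- ms$enzymes[[1]]$forest
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_true(all(c("name", "importance", "rank") %in% names(td)))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1L)
  expect_equal(gl$ntree, fit$ntree)
  expect_equal(gl$n_attributes, nrow(fit$schema))
})
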