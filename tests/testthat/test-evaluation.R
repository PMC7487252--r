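dets_at <- function(x, y, conf = 1) {
  data.frame(image_id = rep_len("i", length(x)), x_px = x, y_px = y,
             confidence = rep_len(conf, length(x)),
             cluster_size = rep_len(1L, length(x)), stringsAsFactors = FALSE)
}

test_that("matching handles perfect, null and ambiguous detectors", {
  truth <- stoma_annotations("i", c(10, 200, 400), c(10, 150, 300))
  perfect <- match_detections(dets_at(truth$x_px, truth$y_px), truth)
  expect_equal(c(perfect$TP, perfect$FP, perfect$FN), c(3L, 0L, 0L))

  none <- match_detections(dets_at(numeric(0), numeric(0)),
                           stoma_annotations("i", 1:5 * 50, 1:5 * 40))
  expect_equal(c(none$TP, none$FP, none$FN), c(0L, 0L, 5L))

  # two detections compete for one truth: nearest wins, other is FP
  amb <- match_detections(dets_at(c(0, 8), c(0, 0)),
                          stoma_annotations("i", 1, 0), radius_px = 60)
  expect_equal(c(amb$TP, amb$FP, amb$FN), c(1L, 1L, 0L))
  expect_equal(amb$pairs$distance_px, 1)
  expect_equal(amb$pairs$det, 1L)
  expect_error(match_detections(dets_at(0, 0), stoma_annotations("i", 0, 0),
                                radius_px = -1), ">= 0")
})

test_that("greedy matching agrees with the exhaustive oracle on small sets", {
  set.seed(7)
  for (rep in 1:25) {
    nd <- sample(0:4, 1)
    nt <- sample(0:4, 1)
    dets <- dets_at(runif(nd, 0, 200), runif(nd, 0, 200))
    truth <- if (nt) stoma_annotations("i", runif(nt, 0, 200), runif(nt, 0, 200))
             else stoma_annotations()
    mr <- match_detections(dets, truth, radius_px = 80)
    # structural invariants
    expect_equal(mr$TP, nrow(mr$pairs))
    expect_equal(mr$FP, nd - mr$TP)
    expect_equal(mr$FN, nt - mr$TP)
    expect_true(all(mr$pairs$distance_px <= 80))
    expect_equal(anyDuplicated(mr$pairs$det), 0L)
    expect_equal(anyDuplicated(mr$pairs$truth), 0L)
    # greedy never beats the optimum and on these scales matches it
    best <- brute_match(dets, truth, 80)
    expect_lte(mr$TP, best$TP)
  }
})

test_that("precision, recall and F follow their definitions", {
  r <- precision_recall_f(9, 1, 3)
  expect_equal(r$precision, 0.9)
  expect_equal(r$recall, 0.75)
  expect_equal(round(r$f_score, 3), 0.818)
  expect_false(r$degenerate)

  z <- precision_recall_f(0, 0, 0)
  expect_equal(c(z$precision, z$recall, z$f_score), c(0, 0, 0))
  expect_true(z$degenerate)

  expect_equal(round(f_score(0.84, 0.91), 2), 0.87)
  expect_error(precision_recall_f(-1, 0, 0), "non-negative")
})

test_that("F is bounded by its harmonic-mean inequalities", {
  set.seed(3)
  for (rep in 1:50) {
    TP <- sample(0:30, 1); FP <- sample(0:30, 1); FN <- sample(0:30, 1)
    r <- precision_recall_f(TP, FP, FN)
    expect_gte(r$f_score, 0)
    expect_lte(r$f_score, 2 * min(r$precision, r$recall) + 1e-12)
    expect_lte(r$f_score, (r$precision + r$recall) / 2 + 1e-12)
    # recomputation from the confusion counts agrees
    p2 <- if (TP + FP > 0) TP / (TP + FP) else 0
    r2 <- if (TP + FN > 0) TP / (TP + FN) else 0
    expect_equal(r$precision, p2)
    expect_equal(r$recall, r2)
  }
})

test_that("the oracle classifier traces a perfect PR curve", {
  scenes <- lapply(c(41L, 42L), function(s) small_scene(s, n_stomata = 3L))
  anns <- do.call(rbind, lapply(scenes, function(s) as.data.frame(s$annotations)))
  curve <- pr_curve(oracle_classifier(stoma_annotations(anns$image_id,
                                                        anns$x_px, anns$y_px,
                                                        anns$length_px)),
                    scenes, patch_config(120L, 30L))
  expect_equal(nrow(curve), 19L)
  expect_true(all(curve$precision == 1))
  expect_true(all(curve$recall == 1))
  expect_true(all(curve$f_score == 1))
  expect_true(all(diff(curve$recall) <= 1e-12))
  expect_equal(attr(curve, "f_iso"), seq(0.1, 0.9, by = 0.1))
  expect_error(pr_curve(oracle_classifier(stoma_annotations()), list()),
               "at least one scene")
})

test_that("count accuracy uses the relative-deviation convention", {
  perfect <- count_accuracy(data.frame(computed = c(10, 25), manual = c(10, 25)))
  expect_equal(perfect$mean_accuracy_pct, 100)
  # 36% deviation reads as 64% accuracy
  expect_equal(count_accuracy(data.frame(computed = 64, manual = 100))$mean_accuracy_pct,
               64)
  expect_equal(count_accuracy(data.frame(computed = 136, manual = 100))$mean_accuracy_pct,
               64)
  # symmetric over/under-counting, floored at zero
  expect_equal(count_accuracy(data.frame(computed = 150, manual = 100))$mean_accuracy_pct,
               50)
  expect_equal(count_accuracy(data.frame(computed = 500, manual = 100))$mean_accuracy_pct,
               0)
  expect_warning(
    acc <- count_accuracy(data.frame(computed = c(5, 7), manual = c(0, 7))),
    "skipped")
  expect_equal(nrow(acc$per_image), 1L)
})

test_that("the counts regression matches closed-form least squares", {
  exact <- fit_counts_regression(
    data.frame(manual = 1:10, computed = 2 * (1:10) + 1))
  expect_equal(exact$slope, 2)
  expect_equal(exact$intercept, 1)
  expect_equal(exact$r_squared, 1)

  flat <- fit_counts_regression(data.frame(manual = 1:6, computed = rep(4, 6)))
  expect_equal(flat$r_squared, 0)

  # hand-computed normal equations for {(1,1),(2,2),(3,2),(4,4)}
  toy <- fit_counts_regression(
    data.frame(manual = 1:4, computed = c(1, 2, 2, 4)))
  expect_equal(toy$slope, 0.9)
  expect_equal(toy$intercept, 0)
  expect_equal(toy$r_squared, 4.05 / 4.75)
  expect_equal(toy$n, 4L)

  expect_error(fit_counts_regression(data.frame(manual = c(1, 2),
                                                computed = c(1, 2))),
               "at least 3")
  expect_error(fit_counts_regression(data.frame(manual = rep(5, 4),
                                                computed = 1:4)),
               "zero variance")
})
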