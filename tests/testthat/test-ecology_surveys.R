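make_points <- function(labels, statuses, station = "E5", phase = "pre") {
  n <- length(labels)
  data.frame(station = station, phase = phase,
             photo_id = ((seq_len(n) - 1) %/% 5) + 1,
             point_index = ((seq_len(n) - 1) %% 5) + 1,
             label = labels, status = statuses)
}

test_that("survey design arithmetic multiplies out transects, photos and points", {
  expect_equal(survey_design(5, 50, 1, 5),
               list(photos_per_station = 250, points_per_station = 1250))
  expect_equal(survey_design(1, 1, 1, 1),
               list(photos_per_station = 1, points_per_station = 1))
  expect_equal(survey_design(2, 10, 2, 3),
               list(photos_per_station = 10, points_per_station = 30))
  expect_error(survey_design(5, 50, 3, 5), "divisible")
  expect_error(survey_design(0, 50, 1, 5), "positive")
})

test_that("cover tabulation yields fractions that sum to one and live cover", {
  pts <- make_points(c(rep("Porites", 275), rep("sand", 600), rep("algae", 375)),
                     c(rep("pigmented", 275), rep("not_coral", 975)))
  cov <- tabulate_cover(pts)
  expect_equal(sum(cov$fraction), 1, tolerance = 1e-12)
  expect_equal(unname(live_coral_cover(cov)), 0.22)
  expect_equal(cov$fraction[cov$category == "Porites"], 275 / 1250)
  # single-label table
  one <- tabulate_cover(make_points(rep("rubble", 10), rep("not_coral", 10)))
  expect_equal(one$fraction, 1)
  expect_error(tabulate_cover(pts[0, ]), "empty")
})

test_that("cover is permutation-invariant and pooling weights by points", {
  pts1 <- make_points(c(rep("Porites", 30), rep("sand", 70)),
                      c(rep("pigmented", 30), rep("not_coral", 70)), station = "E2")
  pts2 <- make_points(c(rep("Porites", 10), rep("sand", 40)),
                      c(rep("pigmented", 10), rep("not_coral", 40)), station = "E3")
  pts <- rbind(pts1, pts2)
  set.seed(4)
  shuffled <- pts[sample(nrow(pts)), ]
  expect_equal(tabulate_cover(shuffled)$fraction, tabulate_cover(pts)$fraction)
  per <- tabulate_cover(pts, "station")
  pooled <- tabulate_cover(pts, "all")
  lc <- attr(per, "live_cover")
  expect_equal(sum(lc$live_cover * lc$n_points) / sum(lc$n_points),
               unname(live_coral_cover(pooled)))
})

test_that("genus status fractions partition coral points three ways", {
  pts <- make_points(
    c(rep("Acropora", 100), rep("Porites", 50), rep("sand", 50)),
    c(rep("recently_dead", 56), rep("pigmented", 30), rep("bleached", 14),
      rep("pigmented", 50), rep("not_coral", 50)))
  g <- genus_status_fractions(pts)
  acro <- g[g$genus == "Acropora", ]
  expect_equal(acro$recently_dead, 0.56)
  expect_equal(acro$pigmented + acro$bleached + acro$recently_dead, 1)
  expect_equal(g[g$genus == "Porites", "pigmented"], 1)
  expect_equal(g[g$genus == "Porites", c("bleached", "recently_dead")],
               data.frame(bleached = 0, recently_dead = 0, row.names = 2L))
  # sampled fractions converge to the generator's probabilities
  pts2 <- generate_survey_points(
    c(Porites = 1), list(Porites = c(0.5, 0.3, 0.2)),
    n_photos = 2000, points_per_photo = 5, seed = 31)
  g2 <- genus_status_fractions(pts2)
  expect_lt(abs(g2$pigmented - 0.5), 0.02)
  expect_lt(abs(g2$bleached - 0.3), 0.02)
  expect_lt(abs(g2$recently_dead - 0.2), 0.02)
})

test_that("survey comparison reports changes and flags halving", {
  pre <- tabulate_cover(make_points(
    c(rep("Porites", 22), rep("sand", 78)),
    c(rep("pigmented", 22), rep("not_coral", 78))))
  post <- tabulate_cover(make_points(
    c(rep("Porites", 22), rep("sand", 78)),
    c(rep("pigmented", 11), rep("bleached", 5), rep("recently_dead", 6),
      rep("not_coral", 78))))
  cmp <- compare_surveys(pre, pre)
  expect_true(all(cmp$change == 0))
  expect_false(any(cmp$halved))
  # 0.10 -> 0.06 is a 40% relative drop, not halving
  a <- tabulate_cover(make_points(c(rep("x", 10), rep("y", 90)),
                                  rep("not_coral", 100)))
  b <- tabulate_cover(make_points(c(rep("x", 6), rep("y", 94)),
                                  rep("not_coral", 100)))
  cmp2 <- compare_surveys(a, b)
  expect_equal(cmp2$rel_change_pct[cmp2$category == "x"], -40)
  expect_false(cmp2$halved[cmp2$category == "x"])
  # mismatched category universes are listed
  expect_error(compare_surveys(pre, a), "differ")
})

test_that("live coral cover halving is flagged from status fractions", {
  # live cover 22% pre vs 11% post, via the status-based live-cover summary
  pre <- tabulate_cover(make_points(
    c(rep("Porites", 275), rep("sand", 975)),
    c(rep("pigmented", 275), rep("not_coral", 975))))
  post <- tabulate_cover(make_points(
    c(rep("Porites", 275), rep("sand", 975)),
    c(rep("pigmented", 137), rep("bleached", 60), rep("recently_dead", 78),
      rep("not_coral", 975))))
  lc_pre <- unname(live_coral_cover(pre))
  lc_post <- unname(live_coral_cover(post))
  expect_equal(lc_pre, 0.22)
  expect_equal(lc_post, 137 / 1250, tolerance = 1e-12)
  expect_lte(lc_post, 0.5 * lc_pre)
})
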