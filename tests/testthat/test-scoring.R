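test_that("the undisplaced case scores the full 18 displacement points", {
  s <- score_displacement(0, 0, 0)
  expect_equal(unlist(s[c("collapse_pts", "broadening_pts", "angulation_pts")]),
               c(collapse_pts = 6L, broadening_pts = 6L, angulation_pts = 6L))
  expect_equal(s$displacement_total, 18L)
  expect_equal(as.character(s$displacement_grade), "excellent")
})

test_that("single measurements map to their printed table bands", {
  expect_equal(score_displacement(8, 0, 0)$collapse_pts, 2L)   # 6-10 mm band
  s <- score_displacement(8, 12, 5)
  expect_equal(s$collapse_pts, 2L)
  expect_equal(s$broadening_pts, 0L)
  expect_equal(s$angulation_pts, 4L)
  expect_equal(s$displacement_total, 6L)
  expect_equal(as.character(s$displacement_grade), "common")
})

test_that("damage-area and comminution points follow the printed table", {
  expect_equal(score_surface("intercondylar", 0),
               list(damage_pts = 6L, comminution_pts = 6L))
  expect_equal(score_surface(character(0), 0),
               list(damage_pts = 6L, comminution_pts = 6L))
  expect_equal(score_surface(c("anterolateral", "posteromedial"), 2),
               list(damage_pts = 4L, comminution_pts = 2L))
  all4 <- c("anterolateral", "anteromedial", "posterolateral", "posteromedial")
  expect_equal(score_surface(all4, 5),
               list(damage_pts = 0L, comminution_pts = 0L))
  # intercondylar involvement on top of articular damage never lowers points
  expect_equal(score_surface(c("intercondylar", "anterolateral"), 1)$damage_pts, 4L)
})

test_that("total scores and grades combine per the printed boundaries", {
  best <- imaging_score(0, 0, 0, "intercondylar", 0)
  expect_equal(best$total, 30L)
  expect_equal(as.character(best$total_grade), "excellent")

  s8 <- imaging_score(8, 12, 5,
                      c("anterolateral", "anteromedial", "posterolateral"), 3)
  expect_equal(s8$total, 6L + 2L + 0L)
  expect_equal(as.character(s8$total_grade), "bad")

  # the good/common boundary lies between totals 20 and 19; every category
  # scores an even number of points, so 20 vs 18 brackets it in practice
  s_g <- imaging_score(0, 0, 5, "anterolateral", 3)    # 16 + 4 + 0 = 20
  expect_equal(s_g$total, 20L)
  expect_equal(as.character(s_g$total_grade), "good")
  s_c <- imaging_score(0, 0, 12, "anterolateral", 3)   # 14 + 4 + 0 = 18
  expect_equal(s_c$total, 18L)
  expect_equal(as.character(s_c$total_grade), "common")
})

test_that("every integer measurement maps to the transcribed table bands", {
  for (mm in 0:25) {
    expect_equal(score_displacement(mm, 0, 0)$collapse_pts,
                 oracle_table_points("collapse", mm))
    expect_equal(score_displacement(0, mm, 0)$broadening_pts,
                 oracle_table_points("broadening", mm))
  }
  for (deg in 0:30)
    expect_equal(score_displacement(0, 0, deg)$angulation_pts,
                 oracle_table_points("angulation", deg))
  # fractional boundary values around every band edge
  for (x in c(0.5, 4.5, 5, 5.5, 6, 9.5, 10, 10.5, 19.5, 20, 20.5)) {
    expect_equal(score_displacement(x, 0, 0)$collapse_pts,
                 oracle_table_points("collapse", x))
    expect_equal(score_displacement(0, x, 0)$broadening_pts,
                 oracle_table_points("broadening", x))
    expect_equal(score_displacement(0, 0, x)$angulation_pts,
                 oracle_table_points("angulation", x))
  }
})

test_that("displacement grades follow the printed score ranges exhaustively", {
  vals <- c(0, 3, 5.5, 8, 12, 15, 25)   # spans all point bands per category
  for (cm in vals) for (bm in vals) for (ad in vals) {
    s <- score_displacement(cm, bm, ad)
    expect_equal(s$displacement_total,
                 oracle_table_points("collapse", cm) +
                 oracle_table_points("broadening", bm) +
                 oracle_table_points("angulation", ad))
    expect_equal(as.character(s$displacement_grade),
                 oracle_displacement_grade(s$displacement_total))
  }
})

test_that("score extrema and grade monotonicity hold over the input domain", {
  vals <- c(0, 3, 5.5, 8, 12, 25)
  arts <- list(character(0), "anterolateral",
               c("anterolateral", "anteromedial"),
               c("anterolateral", "anteromedial", "posterolateral"),
               c("anterolateral", "anteromedial", "posterolateral",
                 "posteromedial"))
  totals <- c(); grades <- c()
  for (cm in vals) for (ad in c(0, 25)) for (a in seq_along(arts)) {
    frag <- if (length(arts[[a]])) 2L else 0L
    s <- imaging_score(cm, 0, ad, arts[[a]], frag)
    totals <- c(totals, s$total)
    grades <- c(grades, as.character(s$total_grade))
    expect_equal(s$total,
                 s$displacement_total + s$damage_pts + s$comminution_pts)
    expect_equal(as.character(s$total_grade), oracle_total_grade(s$total))
  }
  expect_equal(max(totals), 30L)
  expect_lte(max(totals), 30L)
  expect_gte(min(totals), 0L)
  # grade is monotone non-decreasing in the total
  ord <- order(totals)
  g <- factor(grades[ord], levels = c("bad", "common", "good", "excellent"),
              ordered = TRUE)
  expect_true(all(diff(as.integer(g)) >= 0 | diff(totals[ord]) == 0))
})

test_that("invalid measurements and inconsistent damage records are rejected", {
  expect_error(score_displacement(-1, 0, 0), "finite and >= 0")
  expect_error(score_surface("tibial_shaft", 1), "unknown region")
  expect_error(score_surface("anterolateral", 0), "inconsistent")
  expect_error(score_surface("intercondylar", -1), "non-negative")
})

test_that("plateau division partitions the foreground into the five regions", {
  mask <- matrix(TRUE, 60, 100)
  lab <- divide_plateau(mask, eminence_halfwidth_frac = 0.1)
  expect_true(all(lab[mask] > 0L))             # every foreground pixel labeled
  expect_true(all(lab[!mask] == 0L))
  # centroid column 50.5, half-width 10: central band = columns 41..60
  expect_true(all(lab[, 41:60] == 1L))
  expect_true(all(lab[, c(1:40, 61:100)] != 1L))
  counts <- tabulate(lab[lab > 0], nbins = 5)
  expect_equal(counts[1], 60L * 20L)
  # the four articular quadrants of a symmetric rectangle are equal-sized
  expect_true(all(counts[2:5] == 40L * 30L))
  expect_equal(sum(counts), sum(mask))
})

test_that("plateau division works on non-rectangular masks and rejects bad input", {
  ph <- generate_plateau(phantom_spec(width = 80, height = 60, rng_seed = 2))
  lab <- divide_plateau(ph$truth_mask)
  expect_equal(sum(lab > 0), sum(ph$truth_mask))
  expect_equal(sort(unique(as.vector(lab[ph$truth_mask]))), 1:5)
  expect_error(divide_plateau(matrix(FALSE, 4, 4)), "empty")
  expect_error(divide_plateau(matrix(TRUE, 4, 4), 0.6), "halfwidth_frac")
})

test_that("damaged regions are counted by overlap with the region map", {
  mask <- matrix(TRUE, 60, 100)
  lab <- divide_plateau(mask, eminence_halfwidth_frac = 0.1)
  central <- matrix(FALSE, 60, 100); central[10:50, 50] <- TRUE
  expect_equal(count_damaged_regions(lab, central), "intercondylar")

  diagonal <- matrix(FALSE, 60, 100)
  for (k in 0:19) diagonal[cbind(5 + k, 5 + k)] <- TRUE      # anterolateral
  for (k in 0:19) diagonal[cbind(36 + k, 76 + k)] <- TRUE    # posteromedial
  expect_equal(count_damaged_regions(lab, diagonal, min_overlap_px = 1),
               c("anterolateral", "posteromedial"))

  expect_equal(count_damaged_regions(lab, matrix(FALSE, 60, 100)), character(0))
  expect_error(count_damaged_regions(lab, matrix(FALSE, 2, 2)), "mismatch")
  # a higher overlap requirement can drop a barely-touched region
  one_px <- matrix(FALSE, 60, 100); one_px[5, 5] <- TRUE
  expect_equal(count_damaged_regions(lab, one_px, min_overlap_px = 2),
               character(0))
})
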