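delay_df <- function(early, late, mean_s, sd_s = 1, n = 5) {
  data.frame(early = early, late = late, mean_s = mean_s, sd_s = sd_s, n = n)
}

test_that("fluorophore tags are stripped from either end", {
  expect_equal(strip_fluorophore_tags(
    c("EGFP-Emp46", "Mnn9-mCherry", "Grh1-2xEGFP", "Sec21-2xEGFP",
      "iRFP-Rer1", "Sec7-tagRFP", "Sec7-mRFP", "Gea2-2xmCherry", "Ypt32-GFP")),
    c("Emp46", "Mnn9", "Grh1", "Sec21", "Rer1", "Sec7", "Sec7", "Gea2",
      "Ypt32"))
})

test_that("a single measured edge propagates directly", {
  d <- delay_df("Mnn9-mCherry", "Gea2-GFP", 76.2, 21.7, 13)
  d$early <- strip_fluorophore_tags(d$early)
  d$late <- strip_fluorophore_tags(d$late)
  tl <- assemble_timeline(d, "Mnn9")
  expect_equal(unname(tl$times["Gea2"]), 76.2)
  expect_equal(tl$residuals$residual_s, 0)
  expect_equal(unname(tl$times["Mnn9"]), 0)
})

test_that("consistent triangles are recovered exactly, any weighting", {
  d <- delay_df(c("A", "B", "A"), c("B", "C", "C"), c(10, 20, 30))
  for (w in c("equal", "invvar")) {
    tl <- assemble_timeline(d, "A", weighting = w)
    expect_equal(unname(tl$times[c("A", "B", "C")]), c(0, 10, 30))
    expect_equal(tl$rms_residual_s, 0, tolerance = 1e-9)
  }
})

test_that("the inconsistent triangle splits the tension as least squares", {
  d <- delay_df(c("A", "B", "A"), c("B", "C", "C"), c(10, 20, 36))
  tl <- assemble_timeline(d, "A", weighting = "equal")
  expect_equal(unname(tl$times["B"]), 12)
  expect_equal(unname(tl$times["C"]), 34)
  expect_equal(tl$residuals$residual_s, c(2, 2, -2))
})

test_that("re-anchoring shifts times by a constant", {
  d <- delay_df(c("A", "B", "A", "C"), c("B", "C", "C", "D"),
                c(10, 20, 36, 5))
  t1 <- assemble_timeline(d, "A", weighting = "equal")$times
  t2 <- assemble_timeline(d, "C", weighting = "equal")$times
  shift <- t1["C"] - t2["C"]
  expect_equal(unname(t1[names(t2)] - t2), rep(unname(shift), 4))
})

test_that("edge order does not matter", {
  d <- delay_df(c("A", "B", "A", "C"), c("B", "C", "C", "D"),
                c(10, 20, 36, 5), sd_s = c(3, 9, 2, 1), n = c(4, 9, 2, 7))
  t1 <- assemble_timeline(d, "A")$times
  t2 <- assemble_timeline(d[c(3, 1, 4, 2), ], "A")$times
  expect_equal(t1, t2)
})

test_that("consistent random delay graphs recover the true assignment", {
  set.seed(31)
  for (rep in 1:5) {
    truth <- setNames(runif(6, -50, 150), LETTERS[1:6])
    pairs <- t(combn(1:6, 2))
    pick <- pairs[sample(nrow(pairs), 9), , drop = FALSE]
    d <- delay_df(LETTERS[pick[, 1]], LETTERS[pick[, 2]],
                  truth[pick[, 2]] - truth[pick[, 1]],
                  sd_s = runif(9, 1, 20), n = sample(3:20, 9, TRUE))
    for (w in c("equal", "invvar")) {
      tl <- assemble_timeline(d, "A", weighting = w)
      expect_equal(unname(tl$times[LETTERS[1:6]]),
                   unname(truth - truth["A"]), tolerance = 1e-8)
    }
  }
})

test_that("markers outside the anchor component are reported unplaced", {
  d <- delay_df(c("A", "X"), c("B", "Y"), c(10, 5))
  tl <- assemble_timeline(d, "A")
  expect_setequal(tl$unplaced, c("X", "Y"))
  expect_error(assemble_timeline(d, "Q"), "anchor")
})

test_that("edges around the cis-Golgi reference keep their printed signs", {
  path <- system.file("extdata", "peak_to_peak_delays.csv",
                      package = "golgitrace")
  tab <- read_delay_table(path)
  sub <- tab[tab$no %in% c(1:4, 9:12), ]
  tl <- assemble_timeline(sub, "Mnn9")
  early <- c("Emp46", "Ypt1", "Rer1", "Erd2", "Sed5")
  late <- c("Vrg4", "Sec21", "Mnn2")
  expect_true(all(tl$times[early] <= 0))
  expect_true(all(tl$times[late] >= 0))
})

test_that("the full delay table yields the expected stage ordering", {
  path <- system.file("extdata", "peak_to_peak_delays.csv",
                      package = "golgitrace")
  tab <- read_delay_table(path)
  tl <- assemble_timeline(tab, "Mnn9")
  expect_equal(length(tl$unplaced), 0L)
  ord <- order_markers(tl)
  # pre-cis markers peak before the cis reference ...
  for (m in c("Grh1", "Emp46", "Ypt1", "Rer1", "Erd2", "Sed5")) {
    expect_lt(tl$times[m], 0)
  }
  # ... and the TGN-export marker is the last to peak
  expect_equal(ord[length(ord)], "Ypt32")
})
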