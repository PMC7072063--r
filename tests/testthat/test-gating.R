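# Brute-force octant construction: the label is literally the set of
# positive colours, built independently of the package's lookup.
octant_oracle <- function(r, g, b) {
  s <- c(if (r) "R", if (g) "G", if (b) "B")
  if (length(s) == 0) return("none")
  if (length(s) == 3) return("RGB")
  if (setequal(s, c("R", "G"))) return("RG")
  if (setequal(s, c("G", "B"))) return("GB")
  if (setequal(s, c("R", "B"))) return("BR")
  s
}

test_that("octant classification equals exhaustive set construction on all 8 inputs", {
  combos <- expand.grid(R = c(FALSE, TRUE), G = c(FALSE, TRUE),
                        B = c(FALSE, TRUE))
  got <- classify_octant(as.matrix(combos))
  want <- mapply(octant_oracle, combos$R, combos$G, combos$B)
  expect_equal(as.character(got), unname(want))
  expect_setequal(levels(got), octant_levels())
})

test_that("positivity is strict at the threshold and low events gate as none", {
  p <- case1_panel()
  s <- rgb_sample(c(1e3, 1e3 + 1e-6, 1e2), c(1e3, 2e3, 1e2),
                  c(1e3, 999, 1e2), compensated = TRUE)
  flags <- positivity_flags(s, p)
  expect_equal(unname(flags[1, ]), c(FALSE, FALSE, FALSE))  # at threshold
  expect_equal(unname(flags[2, ]), c(TRUE, TRUE, FALSE))
  expect_equal(as.character(classify_octant(flags)[3]), "none")
  expect_error(positivity_flags(s, p, channels = "GFP"), "GFP")
})

test_that("uncompensated samples are refused when the panel has spillover", {
  p <- case1_panel()
  s <- rgb_sample(1e4, 1e4, 1e4, compensated = FALSE)
  expect_error(positivity_flags(s, p), "compensated")
})

test_that("population sizes and marginals are consistent with the labels", {
  p <- case1_panel()
  s <- draw_cluster_events(c(RGB = 1), 200, p, seed = 8)
  g <- gate_rgb_sample(s, p)
  tab <- g$populations
  expect_equal(tab$fraction_pct[tab$population == "RGB"], 100)
  expect_equal(sum(tab$fraction_pct), 100)
  # marginal positive % equals the sum of its constituent octant fractions
  s2 <- draw_cluster_events(case1_day0_composition(), 20000, p, seed = 9)
  g2 <- gate_rgb_sample(s2, p)
  t2 <- g2$populations
  frac <- function(lab) t2$fraction_pct[t2$population == lab]
  expect_equal(unname(g2$marginals["R"]),
               frac("R") + frac("RG") + frac("BR") + frac("RGB"),
               tolerance = 1e-12)
  expect_gte(unname(g2$marginals["R"]),
             max(frac("R"), frac("RG"), frac("BR"), frac("RGB")))
  expect_error(population_sizes(character(0)), "empty")
})

test_that("a configured octant composition is recovered within 3 binomial SE", {
  p <- case1_panel()
  comp <- case1_day0_composition()
  # the reference composition is rounded per cluster; it sums to ~100.07
  expect_lte(abs(sum(comp) - 100), 0.2)
  want <- 100 * comp / sum(comp)
  n <- 20000
  g <- gate_rgb_sample(draw_cluster_events(comp, n, p, seed = 10), p)
  tab <- g$populations
  for (lab in names(want)) {
    got <- tab$fraction_pct[tab$population == lab]
    expect_lt(abs(got - want[[lab]]), three_se_pct(want[[lab]], n),
              label = paste("octant", lab))
  }
})

test_that("four-population centroid classification assigns, breaks ties, and separates clusters", {
  p <- case2_panel()
  cen <- p$centroids
  # an event exactly at a centroid gets that label
  ev <- cbind(singlet_scatter(4),
              as.data.frame(10^cen, optional = TRUE))
  names(ev)[4:5] <- colnames(cen)
  s <- flow_sample(ev)
  expect_equal(as.character(classify_four_color(s, p)), rownames(cen))
  # an equidistant event is unassigned (midpoint of two centroids)
  mid <- 10^((cen["Cerulean-EX", ] + cen["mTagBFP-TP", ]) / 2)
  ev2 <- cbind(singlet_scatter(1),
               data.frame(FL_450_45 = mid[1], FL_585_42 = mid[2]))
  expect_equal(as.character(classify_four_color(flow_sample(ev2), p)),
               "unassigned")
  # well-separated log-normal clusters: misassignment below 0.5 %
  n <- 20000
  s3 <- sample_events_from_culture(rep(0.25, 4) |>
                                     stats::setNames(rownames(cen)),
                                   p, n, seed = 12)
  got <- classify_four_color(s3, p)
  mis <- mean(as.character(got) != s3$truth$label)
  expect_lt(mis, 0.005)
  # recovered fractions within 3 SE of the configured quarter each
  sizes <- population_sizes(got)
  for (lab in rownames(cen)) {
    f <- sizes$fraction_pct[sizes$population == lab]
    expect_lt(abs(f - 25), three_se_pct(25, n))
  }
})

test_that("rectangular gates classify and flag ambiguous events", {
  p <- case2_panel()
  gates <- list("Venus-SP" = list(FL_585_42 = c(1e4, 1e7),
                                  FL_450_45 = c(0, 1e3)),
                "Cerulean-EX" = list(FL_450_45 = c(1e3, 1e5),
                                     FL_585_42 = c(0, 1e3)))
  ev <- cbind(singlet_scatter(3),
              data.frame(FL_450_45 = c(5e3, 10, 10),
                         FL_585_42 = c(10, 1e5, 5)))
  got <- classify_four_color(flow_sample(ev), p, method = "rectangle",
                             gates = gates)
  expect_equal(as.character(got),
               c("Cerulean-EX", "Venus-SP", "unassigned"))
})
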