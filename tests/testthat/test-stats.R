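test_that("Kruskal-Wallis H matches the hand-ranked worked example", {
  # groups {1,2,3}, {4,5,6}, {7,8,9}: ranks 1..9, rank sums 6, 15, 24
  # H = 12/(9*10) * (36 + 225 + 576)/3 - 3*10 = 7.2
  kw <- kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9)))
  expect_equal(kw$H, 7.2)
  expect_equal(kw$df, 2)
  # two identical groups carry no evidence
  expect_equal(kruskal_wallis(list(c(1, 2, 3), c(1, 2, 3)))$H, 0)
  # fully degenerate input follows the documented convention
  deg <- kruskal_wallis(list(c(2, 2), c(2, 2, 2)))
  expect_equal(deg$H, 0)
  expect_equal(deg$p_value, 1)
  expect_error(kruskal_wallis(list(1:3)), "two groups")
})

test_that("Kruskal-Wallis is invariant under monotone transforms", {
  set.seed(5)
  g <- list(rnorm(12), rnorm(10, 1), rnorm(15, -0.5))
  h0 <- kruskal_wallis(g)$H
  expect_equal(kruskal_wallis(lapply(g, function(x) exp(x)))$H, h0)
  expect_equal(kruskal_wallis(lapply(g, function(x) 5 * x - 2))$H, h0)
})

test_that("null simulation holds the nominal type-I error", {
  set.seed(20)
  reps <- 2000
  p <- replicate(reps, kruskal_wallis(
    list(rnorm(20), rnorm(20), rnorm(20)))$p_value)
  rate <- mean(p < 0.05)
  expect_gte(rate, 0.04)
  expect_lte(rate, 0.06)
})

test_that("Bonferroni correction multiplies and clamps", {
  expect_equal(bonferroni(0.01, m = 6), 0.06)
  expect_equal(bonferroni(0.5, m = 6), 1)
  expect_equal(bonferroni(c(0.2, 0.04), m = 1), c(0.2, 0.04))
  p <- c(0.001, 0.02, 0.3)
  adj <- bonferroni(p, m = 4)
  expect_true(all(adj >= p))
  expect_true(all(diff(adj[order(p)]) >= 0))  # monotone in raw p
  expect_error(bonferroni(0.1, m = 0), ">= 1")
})

test_that("Pearson chi-squared matches the hand-computed table", {
  # {{10,0},{0,10}}: expected 5 everywhere, X2 = 4 * 25/5 = 20
  ct <- pearson_chisq(rbind(c(10, 0), c(0, 10)))
  expect_equal(ct$statistic, 20)
  expect_equal(ct$df, 1)
})

test_that("Dice group test behaves on identical and shifted groups", {
  set.seed(31)
  base <- runif(100, 0.6, 0.95)
  same <- dice_group_test(list(a = base, b = base))
  expect_equal(same$statistic, 0)
  shifted <- dice_group_test(list(a = base,
                                  b = pmin(base + 0.1, 0.999)))
  expect_lt(shifted$p_value, 0.05)
  kw <- dice_group_test(list(a = base, b = base + 0.1), method = "kruskal")
  expect_lt(kw$p_value, 0.05)
  expect_error(dice_group_test(list(a = rep(0.5, 4), b = rep(0.5, 4))),
               "spread|insufficient")
})

test_that("modality comparison recovers a planted group difference", {
  set.seed(77)
  mk <- function(class, shift) {
    lapply(1:20, function(i) tibble::tibble(
      patient_id = paste0(class, i), implant_class = class,
      radius_mm = 2.5, tissue = "gm",
      total_mm3 = NA_real_,
      per_contact_mm3 = rnorm(1, 20 + shift, 3), n_contacts = 80))
  }
  curves <- dplyr::bind_rows(c(mk("D", 6), mk("S", 0)))
  cmp <- compare_modalities(curves, 2.5, "gm")
  expect_equal(nrow(cmp), 1)
  expect_lt(cmp$p_adj, 0.05)
  # identical generative distributions reject at about the nominal rate
  set.seed(78)
  hits <- replicate(400, {
    curves0 <- dplyr::bind_rows(c(mk("D", 0), mk("S", 0)))
    compare_modalities(curves0, 2.5, "gm")$p < 0.05
  })
  expect_lt(abs(mean(hits) - 0.05), 0.03)
  one <- dplyr::bind_rows(mk("D", 0))
  expect_error(compare_modalities(one, 2.5, "gm"), "two classes")
})

test_that("crossover radius detection is symmetric and can be absent", {
  mk_curve <- function(class, f) {
    radii <- seq(1, 15, 0.5)
    tibble::tibble(patient_id = class, implant_class = class,
                   radius_mm = radii, tissue = "gm",
                   total_mm3 = f(radii) * 10,
                   per_contact_mm3 = f(radii), n_contacts = 10)
  }
  flat <- dplyr::bind_rows(mk_curve("A", function(r) rep(5, length(r))),
                           mk_curve("B", function(r) rep(2, length(r))))
  expect_true(is.na(crossover_radius(flat, "A", "B")))
  crossing <- dplyr::bind_rows(mk_curve("A", function(r) 10 - r),
                               mk_curve("B", function(r) r))
  expect_equal(crossover_radius(crossing, "A", "B"), 5.5)
  expect_equal(crossover_radius(crossing, "B", "A"), 5.5)
  # anchoring the reference past the crossing leaves nothing to flip
  expect_true(is.na(crossover_radius(crossing, "A", "B",
                                     from_radius_mm = 6)))
  expect_equal(crossover_radius(crossing, "A", "B", from_radius_mm = 3), 5.5)
  expect_error(crossover_radius(flat, "A", "missing"), "present")
})

test_that("cohort summaries reduce correctly for a single patient", {
  curve <- tibble::tibble(patient_id = "pt1", implant_class = "D",
                          radius_mm = rep(c(2.5, 5), each = 2),
                          tissue = rep(c("gm", "wm"), 2),
                          total_mm3 = c(100, 10, 300, 60),
                          per_contact_mm3 = c(10, 1, 30, 6),
                          n_contacts = 10)
  regions <- tibble::tibble(patient_id = "pt1", implant_class = "D",
                            region_id = 1:2, region = c("a", "b"),
                            radius_mm = 5, gm_mm3 = c(0, 12),
                            included = c(FALSE, TRUE))
  rec <- list(list(patient_id = "pt1", implant_class = "D",
                   n_contacts = 10, curve = curve, regions = regions,
                   dice = NULL))
  s <- summarize_cohort(rec)
  expect_equal(s$curve_summary$per_contact_median,
               curve$per_contact_mm3[match(
                 paste(s$curve_summary$radius_mm, s$curve_summary$tissue),
                 paste(curve$radius_mm, curve$tissue))])
  expect_equal(unname(s$curve_summary$per_contact_q25),
               unname(s$curve_summary$per_contact_q75))  # zero dispersion
  rs <- s$region_summary
  expect_equal(rs$n_included[rs$region == "a"], 0)
  expect_true(is.na(rs$gm_median_mm3[rs$region == "a"]))
  # totals are per-contact times contact count, row-wise
  expect_equal(curve$total_mm3, curve$per_contact_mm3 * curve$n_contacts)
})
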