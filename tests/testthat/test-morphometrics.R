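test_that("size correction recovers exact and null allometries", {
  fl <- c(200, 250, 300, 350, 400, 450)
  # trait exactly proportional to fork length: residuals 0, R^2 = 1
  rec <- morphometric_records(
    paste0("f", 1:6), fl,
    data.frame(HL = 0.2 * fl, PEL = 0.15 * fl, HDE = 0.12 * fl,
               ED = 0.05 * fl, HDO = 0.14 * fl, BD = 0.22 * fl,
               CPD = 0.08 * fl, PFL = 0.13 * fl, ML = 0.09 * fl))
  sc <- suppressWarnings(size_correct(rec))  # perfect fits warn in summary()
  expect_true(all(abs(sc$residuals$HL) < 1e-9))
  expect_equal(sc$diagnostics$r_squared[sc$diagnostics$trait == "HL"], 1)

  # residuals of every trait are centred
  sim <- simulate_morphometrics(c(10, 8, 5), seed = 3)
  sc2 <- size_correct(sim$records)
  for (tr in setdiff(names(sc2$residuals), "fish_id"))
    expect_lt(abs(mean(sc2$residuals[[tr]])), 1e-9 * mean(sim$records[[tr]]))

  # a trait independent of FL: slope ~ 0, residuals ~ centred trait
  set.seed(1)
  ind <- rnorm(6, 30, 0.5)
  rec3 <- rec
  rec3$ED <- ind
  sc3 <- suppressWarnings(size_correct(rec3))  # other traits fit perfectly
  expect_lt(abs(sc3$diagnostics$slope[sc3$diagnostics$trait == "ED"]), 0.01)
  expect_equal(sc3$residuals$ED, ind - mean(ind), tolerance = 0.5)

  expect_error(size_correct(rec[1:2, ]), "at least 3")
  rec4 <- rec
  rec4$fork_length <- 300
  expect_error(size_correct(rec4), "constant")
})

test_that("the regression R^2 band is intermediate-to-high under matched noise", {
  sim <- simulate_morphometrics(c(12, 10, 6), seed = 1)
  sc <- size_correct(sim$records)
  expect_true(all(sc$diagnostics$r_squared > 0.55))
  expect_true(all(sc$diagnostics$r_squared < 0.99))
  expect_gt(max(sc$diagnostics$r_squared), 0.9)
})

test_that("stepwise insertion finds the informative trait first", {
  set.seed(8)
  n <- 30
  g <- rep(c("A", "B"), each = n / 2)
  res <- data.frame(fish_id = paste0("f", 1:n),
                    HL = rnorm(n) + ifelse(g == "A", 3, -3),
                    PEL = rnorm(n), HDE = rnorm(n), ED = rnorm(n))
  m <- stepwise_lda(res, g)
  expect_equal(m$traits[1], "HL")
  expect_true(all(diff(c(1, m$wilks_trace)) < 0))  # lambda non-increasing

  # indistinguishable groups: no trait enters
  res0 <- data.frame(fish_id = paste0("f", 1:n),
                     HL = rnorm(n), PEL = rnorm(n))
  expect_warning(m0 <- stepwise_lda(res0, g), "no trait")
  expect_equal(length(m0$traits), 0)

  expect_error(stepwise_lda(res, rep("A", n)), "2 groups")
})

test_that("well-separated synthetic clusters give low lambda and high LOO accuracy", {
  sim <- simulate_morphometrics(c(12, 10, 6), seed = 1)
  sc <- size_correct(sim$records)
  m <- stepwise_lda(sc$residuals, sim$groups)
  expect_lt(tail(m$wilks_trace, 1), 0.15)
  expect_true(sum(m$explained_pct) > 99.9)
  loo <- loo_accuracy(sc$residuals, sim$groups)
  expect_gte(loo$accuracy, 0.95)
})

test_that("canonical assignments are invariant to rescaling a trait", {
  sim <- simulate_morphometrics(c(12, 10, 6), seed = 2)
  sc <- size_correct(sim$records)
  m1 <- stepwise_lda(sc$residuals, sim$groups)
  c1 <- classify(m1, sc$residuals)
  scaled <- sc$residuals
  scaled$HDO <- scaled$HDO * 10
  m2 <- stepwise_lda(scaled, sim$groups)
  c2 <- classify(m2, scaled)
  expect_equal(c1$assigned, c2$assigned)
  expect_equal(m1$traits, m2$traits)
})

test_that("classification posteriors behave at centroids and ties", {
  sim <- simulate_morphometrics(c(12, 10, 6), seed = 1)
  sc <- size_correct(sim$records)
  m <- stepwise_lda(sc$residuals, sim$groups)
  # a fish placed exactly at a group centroid is assigned to it
  cent <- as.data.frame(as.list(m$group_means["Pelagic", ]))
  cent$fish_id <- "ghost"
  cl <- classify(m, cent)
  expect_equal(cl$assigned, "Pelagic")
  expect_gt(cl$Pelagic, 1 / 3)

  # equidistant point between two centroids: tie flagged, broken by order
  mid <- as.data.frame(as.list((m$group_means[1, ] + m$group_means[2, ]) / 2))
  mid$fish_id <- "mid"
  clm <- classify(m, mid)
  expect_true(clm$tie_flag)
  expect_equal(clm$assigned, m$groups[1])

  # explicit override is applied and flagged, never silently
  ov <- data.frame(fish_id = sc$residuals$fish_id[1], group = "DwarfMaturing",
                   reason = "expressing ova at 23 cm")
  clo <- classify(m, sc$residuals, overrides = ov)
  expect_true(clo$override_flag[1])
  expect_equal(clo$final_group[1], "DwarfMaturing")
  expect_false(any(clo$override_flag[-1]))

  expect_error(classify(m, sc$residuals[, 1:2]), "lacks trait")
})

test_that("stepwise agrees with an independent discriminant fit", {
  skip_if_not_installed("MASS")
  sim <- simulate_morphometrics(c(12, 10, 6), seed = 5)
  sc <- size_correct(sim$records)
  m <- stepwise_lda(sc$residuals, sim$groups)
  cl <- classify(m, sc$residuals)
  ref <- MASS::lda(sc$residuals[, m$traits, drop = FALSE],
                   grouping = sim$groups,
                   prior = rep(1 / 3, 3))
  pr <- predict(ref)$class
  expect_equal(as.character(pr), cl$assigned)
})

test_that("discriminative traits lead the insertion across replicates", {
  informative <- c("HL", "PEL", "HDE", "ED", "HDO", "BD")
  hits <- vapply(1:100, function(s) {
    sim <- simulate_morphometrics(c(10, 8, 6), seed = 1000 + s)
    sc <- size_correct(sim$records)
    m <- suppressWarnings(stepwise_lda(sc$residuals, sim$groups))
    length(m$traits) > 0 && m$traits[1] %in% informative
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("isotope summaries reproduce group means and flag degenerate SEs", {
  iso <- data.frame(fish_id = c("p1", "p2", "l1", "l2"),
                    d13C = c(-27.2, -26.8, -23.0, -24.0),
                    d15N = c(17.0, 17.8, 17.5, 18.1))
  gm <- c(p1 = "Pelagic", p2 = "Pelagic", l1 = "Littoral", l2 = "Littoral")
  s <- isotope_summary(iso, gm)
  expect_equal(s$mean_d13C[s$group == "Pelagic"], -27.0)
  expect_equal(s$mean_d13C[s$group == "Littoral"], -23.5)
  expect_equal(abs(attr(s, "difference")$d13C), 3.5)

  one <- isotope_summary(iso[c(1, 3), ], gm)
  expect_true(all(one$se_unavailable))
  expect_true(all(is.na(one$se_d13C)))

  same <- isotope_summary(data.frame(fish_id = c("a", "b"),
                                     d13C = c(-25, -25), d15N = c(17, 17)),
                          c(a = "G", b = "G"))
  expect_equal(same$se_d13C, 0)
})
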